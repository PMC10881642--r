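#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a connectivity matrix into long format
#'
#' @param x A `connectivity_matrix`.
#' @param ... Unused.
#' @return Tibble with `region_i`, `region_j`, `r`, `z` for the upper
#'   triangle (diagonal excluded).
#' @export
tidy.connectivity_matrix <- function(x, ...) {
  ut <- upper.tri(x$r)
  idx <- which(ut, arr.ind = TRUE)
  tibble::tibble(
    region_i = x$regions[idx[, 1]],
    region_j = x$regions[idx[, 2]],
    r = x$r[ut],
    z = x$z[ut]
  )
}

#' @rdname tidy.connectivity_matrix
#' @export
glance.connectivity_matrix <- function(x, ...) {
  tibble::tibble(
    group = paste(x$group, collapse = "+"),
    n_subjects = x$n_subjects,
    n_regions = length(x$regions),
    mean_z = mean(x$z[upper.tri(x$z)]),
    sd_z = stats::sd(x$z[upper.tri(x$z)])
  )
}

#' Tidy a connectivity-change matrix
#'
#' @param x A `delta_connectivity`.
#' @param ... Unused.
#' @return Tibble with `region_i`, `region_j`, `dz` (upper triangle).
#' @export
tidy.delta_connectivity <- function(x, ...) {
  ut <- upper.tri(x$dz)
  idx <- which(ut, arr.ind = TRUE)
  tibble::tibble(
    region_i = x$regions[idx[, 1]],
    region_j = x$regions[idx[, 2]],
    dz = x$dz[ut]
  )
}

#' Tidy a pattern model into a loadings table
#'
#' @param x An `ssm_model`.
#' @param ... Unused.
#' @return Long tibble with `region`, `component`, `loading`, and (when
#'   fitted) the component's weighting factor `beta`.
#' @export
tidy.ssm_model <- function(x, ...) {
  out <- tibble::tibble(
    region = rep(x$regions, times = x$k),
    component = rep(colnames(x$loadings), each = length(x$regions)),
    loading = as.numeric(x$loadings)
  )
  if (!is.null(x$beta)) {
    out$beta <- rep(unname(x$beta), each = length(x$regions))
  }
  out
}

#' @rdname tidy.ssm_model
#' @export
glance.ssm_model <- function(x, ...) {
  tibble::tibble(
    n_train = x$n_train,
    k = x$k,
    min_eigenvalue = min(x$eigenvalues),
    max_eigenvalue = max(x$eigenvalues),
    variance_explained = sum(x$eigenvalues) / length(x$regions),
    hc_ref_mean = x$hc_ref_mean %||% NA_real_,
    hc_ref_sd = x$hc_ref_sd %||% NA_real_
  )
}

#' Tidy expression-scoring results
#'
#' @param x A `dlb_expression`.
#' @param ... Unused.
#' @return The per-subject scores tibble.
#' @export
tidy.dlb_expression <- function(x, ...) x$scores

#' @rdname tidy.dlb_expression
#' @export
glance.dlb_expression <- function(x, ...) {
  tibble::tibble(
    n_scored = nrow(x$scores),
    n_runs = nrow(x$hc_runs),
    min_match_cor = min(x$scores$match_min_cor),
    stability_cov_percent = x$stability$summary_cov_percent %||% NA_real_
  )
}

#' Tidy a ROC result
#'
#' @param x A `dlb_roc`.
#' @param ... Unused.
#' @return The operating-point curve tibble.
#' @export
tidy.dlb_roc <- function(x, ...) x$curve

#' @rdname tidy.dlb_roc
#' @export
glance.dlb_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}
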