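#' Fisher transformation of correlation coefficients
#'
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`, the variance-stabilising
#' transform applied to inter-region correlations before group comparison.
#'
#' @param r Numeric values with |r| < 1 (callers clip degenerate
#'   correlations first).
#' @return Fisher z values.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    stop("|r| must be < 1 after clipping before the Fisher transform")
  }
  0.5 * log((1 + r) / (1 - r))
}

#' Group-level inter-region correlation (metabolic connectivity) matrix
#'
#' Computes, for one group of subjects, the Pearson correlation of every
#' pair of the 77 regional SUVr columns across subjects (the inter-region
#' correlation coefficient, ICC, in the metabolic-connectivity sense), and
#' its Fisher transform. Correlations are clipped to |r| <= 1 - 1e-7 before
#' `atanh` (with a message when clipping triggers). The upper triangle is
#' computed and mirrored, so symmetry is exact; the diagonal is set to `NA`
#' and excluded from all summaries.
#'
#' @param cohort Cohort tibble, or a plain subjects x regions numeric
#'   matrix with column names (useful for reduced region sets).
#' @param group Optional group label to subset `cohort` (default: use all
#'   rows, which must then be one group).
#' @param atlas A `dlb_atlas`; ignored when `cohort` is a matrix.
#' @return Object of class `connectivity_matrix`: list with `group`,
#'   `n_subjects`, `regions`, `r` and `z` (77x77 matrices, diagonal `NA`).
#' @export
icc_matrix <- function(cohort, group = NULL, atlas = hammers_atlas()) {
  if (is.matrix(cohort)) {
    vals <- cohort
    if (is.null(colnames(vals))) {
      colnames(vals) <- paste0("region_", seq_len(ncol(vals)))
    }
    if (is.null(group)) group <- "all"
  } else {
    if (!is.null(group)) cohort <- cohort[cohort$group %in% group, , drop = FALSE]
    vals <- cohort_values(cohort, atlas)
  }
  n <- nrow(vals)
  if (n < 4) stop("need at least 4 subjects for a connectivity matrix")
  sds <- apply(vals, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant region column(s): ",
         paste(colnames(vals)[sds == 0], collapse = ", "))
  }
  p <- ncol(vals)
  r <- matrix(NA_real_, p, p, dimnames = list(colnames(vals), colnames(vals)))
  cs <- scale(vals, center = TRUE, scale = TRUE)
  full <- crossprod(cs) / (n - 1)
  for (i in seq_len(p - 1)) {
    r[i, (i + 1):p] <- full[i, (i + 1):p]
    r[(i + 1):p, i] <- full[i, (i + 1):p]
  }
  clip <- 1 - 1e-7
  n_clip <- sum(abs(r) > clip, na.rm = TRUE)
  if (n_clip > 0) {
    message(n_clip, " correlation(s) clipped to |r| = 1 - 1e-7 before atanh")
  }
  rc <- pmin(pmax(r, -clip), clip)
  z <- atanh(rc)
  structure(
    list(group = if (is.null(group)) unique(cohort$group) else group,
         n_subjects = n, regions = colnames(vals), r = rc, z = z),
    class = "connectivity_matrix"
  )
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("<connectivity_matrix>", paste(x$group, collapse = "+"),
      "n =", x$n_subjects, "|", length(x$regions), "regions\n")
  invisible(x)
}

#' Difference of Fisher-transformed connectivity matrices
#'
#' Element-wise `z_a - z_b` of two group connectivity matrices on the same
#' atlas; antisymmetric under argument exchange, diagonal invalid.
#'
#' @param a,b `connectivity_matrix` objects sharing the region ordering.
#' @return Object of class `delta_connectivity`: list with `contrast`
#'   (group a, group b), `regions`, `dz` (77x77, diagonal `NA`).
#' @export
delta_matrix <- function(a, b) {
  stopifnot(inherits(a, "connectivity_matrix"),
            inherits(b, "connectivity_matrix"))
  if (!identical(a$regions, b$regions)) stop("atlas/region ordering mismatch")
  structure(
    list(contrast = c(paste(a$group, collapse = "+"),
                      paste(b$group, collapse = "+")),
         regions = a$regions, dz = a$z - b$z),
    class = "delta_connectivity"
  )
}

upper_tri_values <- function(m) m[upper.tri(m)]

#' Similarity of two connectivity-change matrices
#'
#' Regresses the off-diagonal upper-triangle entries of one delta matrix
#' (2926 region pairs for 77 regions) on the other by ordinary least
#' squares, reporting slope, intercept, R-squared and both a parametric
#' p-value (from the Pearson test, whose degrees of freedom overstate the
#' information in a symmetric matrix) and, when `n_perm > 0`, a
#' region-label permutation p-value that respects the dependence among
#' pairs and is the recommended inference.
#'
#' @param delta_a,delta_b `delta_connectivity` objects on the same atlas.
#' @param n_perm Number of region-label permutations (0 to skip).
#' @param seed Seed for the permutation draw.
#' @return Tibble with `slope`, `intercept`, `r_squared`, `p_parametric`,
#'   `p_permutation` (`NA` if not requested), `n_pairs`.
#' @export
connectivity_similarity <- function(delta_a, delta_b, n_perm = 0, seed = 1L) {
  stopifnot(inherits(delta_a, "delta_connectivity"),
            inherits(delta_b, "delta_connectivity"))
  if (!identical(delta_a$regions, delta_b$regions)) {
    stop("atlas/region ordering mismatch")
  }
  x <- upper_tri_values(delta_a$dz)
  y <- upper_tri_values(delta_b$dz)
  if (stats::sd(x) == 0) stop("constant predictor delta matrix")
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y)
  r2 <- unname(ct$estimate)^2
  p_perm <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    p <- length(delta_a$regions)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample.int(p)
      xp <- upper_tri_values(delta_a$dz[perm, perm])
      if (stats::cor(xp, y)^2 >= r2) exceed <- exceed + 1L
    }
    p_perm <- (exceed + 1) / (n_perm + 1)
  }
  tibble::tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    p_parametric = ct$p.value,
    p_permutation = p_perm,
    n_pairs = length(x)
  )
}

#' Null distribution of similarity R-squared under region permutation
#'
#' Returns the permutation R-squared values themselves, useful for
#' comparing an observed similarity against its null quantiles.
#'
#' @inheritParams connectivity_similarity
#' @return Numeric vector of length `n_perm`.
#' @export
similarity_null_r2 <- function(delta_a, delta_b, n_perm = 200, seed = 1L) {
  x <- upper_tri_values(delta_a$dz)
  y <- upper_tri_values(delta_b$dz)
  set.seed(seed)
  p <- length(delta_a$regions)
  vapply(seq_len(n_perm), function(b) {
    perm <- sample.int(p)
    stats::cor(upper_tri_values(delta_a$dz[perm, perm]), y)^2
  }, numeric(1))
}
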