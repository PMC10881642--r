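#' z-score an expression score against a reference distribution
#'
#' @param raw Numeric raw score(s).
#' @param reference Numeric vector of reference (healthy-control) raw
#'   scores from the same run.
#' @return `(raw - mean(reference)) / sd(reference)`.
#' @export
zscore_expression <- function(raw, reference) {
  s <- stats::sd(reference)
  if (!is.finite(s) || s <= 0) stop("reference SD must be positive")
  (raw - mean(reference)) / s
}

# greedy matching of reference components to rerun components by maximal
# |Pearson correlation| of loading vectors, descending, with sign alignment
match_components <- function(ref_loadings, new_loadings) {
  cm <- stats::cor(ref_loadings, new_loadings)
  k_ref <- ncol(ref_loadings)
  assign <- integer(k_ref)
  sign_k <- numeric(k_ref)
  quality <- numeric(k_ref)
  acm <- abs(cm)
  for (step in seq_len(min(k_ref, ncol(new_loadings)))) {
    best <- which(acm == max(acm, na.rm = TRUE), arr.ind = TRUE)[1, ]
    i <- best[1]; j <- best[2]
    assign[i] <- j
    sign_k[i] <- sign(cm[i, j])
    quality[i] <- abs(cm[i, j])
    acm[i, ] <- NA
    acm[, j] <- NA
  }
  unmatched <- assign == 0L
  list(assign = assign, sign = sign_k, quality = quality,
       unmatched = unmatched)
}

#' Leave-one-in expression score for a single test subject
#'
#' Implements the prospective scoring procedure: the test subject is added
#' to the training set, the log/double-centre/PCA/Varimax extraction is
#' re-run on the n+1 subjects, each reference component is re-identified in
#' the new run by maximal |correlation| of loading vectors (sign-aligned),
#' and the subject's matched factor scores are combined with the reference
#' weighting factors beta into a single expression score, which is z-scored
#' against the healthy-control scores of the same run.
#'
#' @param train_cohort Training cohort tibble (the subjects the reference
#'   model was fitted on).
#' @param model Reference `ssm_model` with beta (from [fit_dlb_pattern()]).
#' @param test_row One-row cohort tibble for the subject to score.
#' @param atlas A `dlb_atlas`.
#' @param match_warn Warn when a component's best |loading correlation|
#'   falls below this value (default 0.5); the score is still produced.
#' @return One-row tibble: `subject_id`, `raw_score`, `z_score`,
#'   `match_min_cor`, `k_run`, plus the run's HC scores as the
#'   `hc_scores` list column.
#' @export
leave_one_in_score <- function(train_cohort, model, test_row,
                               atlas = hammers_atlas(), match_warn = 0.5) {
  stopifnot(inherits(model, "ssm_model"), !is.null(model$beta))
  if (nrow(test_row) != 1) stop("test_row must contain exactly one subject")
  train_vals <- cohort_values(train_cohort, atlas)
  test_vals <- cohort_values(test_row, atlas)
  if (anyNA(test_vals)) stop("test subject has missing regional values")
  combined <- rbind(train_vals, test_vals)
  refit <- fit_ssm_pca(combined)
  mt <- match_components(model$loadings, refit$loadings)
  if (any(mt$unmatched)) {
    warning("component(s) ", paste(which(mt$unmatched), collapse = ", "),
            " could not be matched in the leave-one-in run; ",
            "their contribution is dropped for this subject")
  }
  ok <- !mt$unmatched
  min_q <- min(mt$quality[ok])
  if (min_q < match_warn) {
    warning("weak component match in leave-one-in run for ",
            test_row$subject_id, ": min |loading correlation| = ",
            signif(min_q, 3))
  }
  aligned_scores <- function(rows) {
    s <- refit$scores[rows, mt$assign[ok], drop = FALSE]
    sweep(s, 2, mt$sign[ok], "*")
  }
  beta <- model$beta[ok]
  intercept <- if (isTRUE(model$include_intercept)) model$beta_intercept else NULL
  n_train <- nrow(train_vals)
  hc_ids <- names(model$training_groups_by_id)[
    model$training_groups_by_id == model$train_groups[1]]
  hc_rows <- match(hc_ids, rownames(combined))
  hc_raw <- expression_raw_score(beta, aligned_scores(hc_rows), intercept)
  test_raw <- expression_raw_score(beta, aligned_scores(n_train + 1L), intercept)
  tibble::tibble(
    subject_id = test_row$subject_id,
    raw_score = test_raw,
    z_score = zscore_expression(test_raw, hc_raw),
    match_min_cor = min_q,
    k_run = refit$k,
    hc_scores = list(stats::setNames(hc_raw, hc_ids))
  )
}

#' Score a test cohort by leave-one-in PCA
#'
#' Runs [leave_one_in_score()] once per test subject (one PCA re-run each),
#' collecting per-subject raw and z-scored expression and the per-run
#' healthy-control scores needed for the stability analysis.
#'
#' @param train_cohort Training cohort tibble.
#' @param model Reference `ssm_model` with beta.
#' @param test_cohort Cohort tibble of subjects to score.
#' @param atlas A `dlb_atlas`.
#' @param ... Passed to [leave_one_in_score()].
#' @return Object of class `dlb_expression`: list with `scores` (tibble:
#'   subject_id, group, raw_score, z_score, match_min_cor, k_run),
#'   `hc_runs` (runs x HC matrix of control raw scores per run) and
#'   `stability` (see [stability_cov()]).
#' @export
score_cohort <- function(train_cohort, model, test_cohort,
                         atlas = hammers_atlas(), ...) {
  res <- purrr::map(seq_len(nrow(test_cohort)), function(i) {
    leave_one_in_score(train_cohort, model, test_cohort[i, , drop = FALSE],
                       atlas = atlas, ...)
  })
  res <- dplyr::bind_rows(res)
  hc_runs <- do.call(rbind, res$hc_scores)
  rownames(hc_runs) <- res$subject_id
  scores <- dplyr::select(res, -"hc_scores")
  if ("group" %in% names(test_cohort)) {
    scores <- dplyr::left_join(
      scores, dplyr::select(test_cohort, "subject_id", "group"),
      by = "subject_id"
    )
    scores <- dplyr::relocate(scores, "group", .after = "subject_id")
  }
  structure(
    list(scores = scores, hc_runs = hc_runs,
         stability = if (nrow(hc_runs) >= 2) stability_cov(hc_runs) else NULL),
    class = "dlb_expression"
  )
}

#' @export
print.dlb_expression <- function(x, ...) {
  cat("<dlb_expression>", nrow(x$scores), "subjects scored over",
      nrow(x$hc_runs), "leave-one-in runs\n")
  if (!is.null(x$stability)) {
    cat("  HC stability CoV:", signif(x$stability$summary_cov_percent, 3), "%\n")
  }
  invisible(x)
}

#' Stability of control expression scores across PCA runs
#'
#' For each healthy control, the coefficient of variation (sample SD across
#' runs divided by |mean across runs|) of its raw expression score over the
#' leave-one-in re-runs; the summary is the mean per-control CoV, in
#' percent. Controls with mean zero across runs are excluded with a
#' warning.
#'
#' @param hc_runs Runs x controls numeric matrix of raw HC scores.
#' @return List with `per_hc` (tibble: subject_id, mean, sd, cov_percent)
#'   and `summary_cov_percent`.
#' @export
stability_cov <- function(hc_runs) {
  hc_runs <- as.matrix(hc_runs)
  if (nrow(hc_runs) < 2) stop("need at least 2 runs for a stability analysis")
  mu <- unname(colMeans(hc_runs))
  sdv <- unname(apply(hc_runs, 2, stats::sd))
  cov_pct <- ifelse(mu == 0, NA_real_, 100 * sdv / abs(mu))
  if (any(mu == 0)) {
    warning(sum(mu == 0), " control(s) with zero mean score excluded from the CoV summary")
  }
  list(
    per_hc = tibble::tibble(
      subject_id = colnames(hc_runs) %||% paste0("hc_", seq_along(mu)),
      mean = mu, sd = sdv, cov_percent = cov_pct
    ),
    summary_cov_percent = mean(cov_pct, na.rm = TRUE)
  )
}

#' Across-subject variability of training expression scores
#'
#' Coefficient of variation (percent) of the training-run expression scores
#' of the reference (control) subjects: sample SD across controls divided
#' by the absolute mean.
#'
#' @param model An `ssm_model` from [fit_dlb_pattern()].
#' @return Scalar CoV in percent.
#' @export
training_cov <- function(model) {
  te <- model$training_expression
  hc <- te$raw_score[te$group == model$train_groups[1]]
  100 * stats::sd(hc) / abs(mean(hc))
}

#' Project new subjects onto a saved pattern model
#'
#' Scores subjects directly with the stored model (log transform, row
#' centering, stored column means/SDs, stored score weights and beta),
#' without re-running the PCA. Faster than leave-one-in scoring and usable
#' from a serialized model alone; z-scores use the stored training HC
#' reference.
#'
#' @param model An `ssm_model` with beta.
#' @param cohort Cohort tibble of subjects to score.
#' @param atlas A `dlb_atlas`.
#' @return Tibble: `subject_id`, `group` (if present), `raw_score`,
#'   `z_score`.
#' @export
project_expression <- function(model, cohort, atlas = hammers_atlas()) {
  vals <- cohort_values(cohort, atlas)
  vals <- vals[, model$regions, drop = FALSE]
  l <- log(vals)
  l <- l - rowMeans(l)
  C <- sweep(l, 2, model$col_means)
  Z <- sweep(C, 2, model$col_sd, "/")
  S <- sweep(Z %*% model$score_weights, 2, model$score_sd, "/")
  raw <- expression_raw_score(
    model$beta, S,
    intercept = if (isTRUE(model$include_intercept)) model$beta_intercept else NULL
  )
  out <- tibble::tibble(
    subject_id = cohort$subject_id,
    raw_score = raw,
    z_score = (raw - model$hc_ref_mean) / model$hc_ref_sd
  )
  if ("group" %in% names(cohort)) {
    out <- dplyr::mutate(out, group = cohort$group, .after = "subject_id")
  }
  out
}

#' ROC curve and AUC by pairwise comparison
#'
#' AUC is the Mann-Whitney probability: the fraction of (positive,
#' negative) score pairs where the positive scores higher, counting ties as
#' one half. The operating-point curve sweeps thresholds over the unique
#' scores with the rule "positive if score >= threshold".
#'
#' @param scores_positive,scores_negative Numeric score vectors; higher
#'   scores indicate the positive class.
#' @return Object of class `dlb_roc`: list with `auc`, `curve` (tibble:
#'   threshold, sensitivity, specificity), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores_positive, scores_negative) {
  np <- length(scores_positive); nn <- length(scores_negative)
  if (np == 0 || nn == 0) stop("both classes must be non-empty")
  r <- rank(c(scores_positive, scores_negative))
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
  thr <- sort(unique(c(scores_positive, scores_negative)), decreasing = TRUE)
  thr <- c(Inf, thr)
  curve <- tibble::tibble(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(scores_positive >= t), 0),
    specificity = vapply(thr, function(t) mean(scores_negative < t), 0)
  )
  structure(list(auc = auc, curve = curve, n_pos = np, n_neg = nn),
            class = "dlb_roc")
}

#' @export
print.dlb_roc <- function(x, ...) {
  cat("<dlb_roc> AUC =", signif(x$auc, 4),
      sprintf("(%d positive vs %d negative)\n", x$n_pos, x$n_neg))
  invisible(x)
}

#' Correlation of expression scores with a covariate
#'
#' Pearson correlation with R-squared and the two-sided test p-value, for
#' example expression z-score against MMSE or putaminal DaT z-score.
#'
#' @param z_scores Numeric expression scores.
#' @param covariate Numeric covariate of the same length (>= 3).
#' @return Tibble with `r`, `r_squared`, `p_value`, `n`.
#' @export
correlate_expression <- function(z_scores, covariate) {
  keep <- is.finite(z_scores) & is.finite(covariate)
  z <- z_scores[keep]; x <- covariate[keep]
  if (length(z) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(z) == 0 || stats::sd(x) == 0) stop("constant input")
  ct <- stats::cor.test(z, x)
  tibble::tibble(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
                 p_value = ct$p.value, n = length(z))
}

#' Site/scanner batch-effect check on expression scores
#'
#' Welch two-sample t-tests of the expression z-scores between every pair
#' of sites (or scanners) with at least 2 subjects each, within each cohort
#' when `group` is given, followed by Benjamini-Hochberg adjustment across
#' all comparisons. Undersized sites are excluded with a warning.
#'
#' @param z_scores Numeric expression scores.
#' @param site Site/scanner labels.
#' @param group Optional cohort labels; comparisons are made within group.
#' @return Tibble: `group`, `site_a`, `site_b`, `n_a`, `n_b`, `p_value`,
#'   `p_fdr`.
#' @export
batch_effect_check <- function(z_scores, site, group = NULL) {
  if (is.null(group)) group <- rep("all", length(z_scores))
  rows <- list()
  for (g in unique(group)) {
    idx <- group == g
    tab <- table(site[idx])
    small <- names(tab)[tab < 2]
    if (length(small)) {
      warning("site(s) with n < 2 excluded in group ", g, ": ",
              paste(small, collapse = ", "))
    }
    usable <- names(tab)[tab >= 2]
    if (length(usable) < 2) next
    for (pr in utils::combn(usable, 2, simplify = FALSE)) {
      a <- z_scores[idx & site == pr[1]]
      b <- z_scores[idx & site == pr[2]]
      tt <- stats::t.test(a, b)
      rows[[length(rows) + 1]] <- tibble::tibble(
        group = g, site_a = pr[1], site_b = pr[2],
        n_a = length(a), n_b = length(b), p_value = tt$p.value
      )
    }
  }
  if (!length(rows)) stop("fewer than two usable sites in every group")
  out <- dplyr::bind_rows(rows)
  out$p_fdr <- stats::p.adjust(out$p_value, method = "BH")
  out
}
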