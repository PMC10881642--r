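#' Global-mean scaling of regional values
#'
#' Divides each subject's regional values by the volume-weighted whole-brain
#' mean (the union of all 77 VOIs), so that the weighted whole-brain mean of
#' the result is exactly 1 and only relative metabolism remains.
#'
#' @param values Numeric vector of length p or subjects x p matrix of
#'   strictly positive regional values.
#' @param volumes Optional positive weights (region volumes); equal weights
#'   when `NULL`.
#' @return Scaled vector or matrix of the same shape.
#' @export
global_mean_scale <- function(values, volumes = NULL) {
  m <- if (is.matrix(values)) values else matrix(values, nrow = 1)
  if (any(m <= 0) || any(!is.finite(m))) {
    stop("regional values must be strictly positive and finite")
  }
  if (is.null(volumes)) volumes <- rep(1, ncol(m))
  if (any(volumes <= 0)) stop("volumes must be strictly positive")
  w <- volumes / sum(volumes)
  gm <- as.numeric(m %*% w)
  out <- m / gm
  if (is.matrix(values)) out else drop(out)
}

#' Composite-region means
#'
#' Volume-weighted means of the eight composite regions for each subject.
#'
#' @param cohort A cohort tibble (or a named 77-vector of SUVr values).
#' @param atlas A `dlb_atlas`.
#' @return A tibble with `subject_id` (when available) and one column per
#'   composite.
#' @export
composite_means <- function(cohort, atlas = hammers_atlas()) {
  if (is.numeric(cohort) && !is.matrix(cohort)) {
    cohort <- dplyr::bind_cols(tibble::tibble(subject_id = "subject"),
                               tibble::as_tibble(as.list(cohort)))
  }
  vals <- cohort_values(cohort, atlas)
  vols <- atlas_volumes(atlas)
  out <- lapply(names(atlas$composites), function(cn) {
    members <- atlas$composites[[cn]]
    if (!length(members)) stop("composite ", cn, " has no member regions")
    w <- vols[members] / sum(vols[members])
    as.numeric(vals[, members, drop = FALSE] %*% w)
  })
  names(out) <- names(atlas$composites)
  dplyr::bind_cols(
    tibble::tibble(subject_id = rownames(vals)),
    tibble::as_tibble(out)
  )
}

#' Cohen's d with pooled standard deviation
#'
#' Classical standardized mean difference `(mean(a) - mean(b)) / s_pooled`
#' with `s_pooled = sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a+n_b-2))`.
#' No small-sample correction is applied.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return Scalar d.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs n >= 2")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 <= 0) stop("pooled SD is zero")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' One-way ANCOVA with pairwise post-hoc contrasts
#'
#' Fits `value ~ group + age + sex` by ordinary least squares (age
#' mean-centred, sex as a binary indicator) and tests all pairwise
#' differences of covariate-adjusted group means with t tests on the model
#' coefficients. Constant covariates are dropped automatically, in which
#' case the contrasts reduce to the plain one-way ANOVA contrasts.
#'
#' @param values Numeric response per subject.
#' @param group Factor (or character) with >= 2 levels, each n >= 2.
#' @param age,sex Covariates (numeric; sex may be a factor/character with
#'   two levels). `NULL` omits the covariate.
#' @return Tibble with one row per pairwise contrast: `group_a`, `group_b`,
#'   `estimate` (adjusted mean difference a - b), `se`, `statistic`, `df`,
#'   `p_value`.
#' @export
ancova_region <- function(values, group, age = NULL, sex = NULL) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least two groups")
  if (any(table(group) < 2)) stop("every group needs n >= 2")
  dat <- data.frame(value = values, group = group)
  form <- value ~ group
  if (!is.null(age) && length(unique(age)) > 1) {
    dat$age_c <- age - mean(age)
    form <- stats::update(form, . ~ . + age_c)
  }
  if (!is.null(sex) && length(unique(sex)) > 1) {
    dat$sex_i <- as.numeric(factor(sex)) - 1
    form <- stats::update(form, . ~ . + sex_i)
  }
  fit <- stats::lm(form, data = dat)
  if (anyNA(stats::coef(fit))) stop("rank-deficient ANCOVA design")
  cf <- stats::coef(fit)
  V <- stats::vcov(fit)
  lv <- levels(group)
  cn <- names(cf)
  coef_of <- function(g) {
    v <- stats::setNames(rep(0, length(cf)), cn)
    nm <- paste0("group", g)
    if (nm %in% cn) v[nm] <- 1
    v
  }
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    cvec <- coef_of(pr[1]) - coef_of(pr[2])
    est <- sum(cvec * cf)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    tt <- est / se
    df <- fit$df.residual
    tibble::tibble(group_a = pr[1], group_b = pr[2], estimate = est,
                   se = se, statistic = tt, df = df,
                   p_value = 2 * stats::pt(abs(tt), df, lower.tail = FALSE))
  })
  dplyr::bind_rows(rows)
}

#' Bonferroni adjustment
#'
#' `min(1, p * m)` per p-value.
#'
#' @param p Numeric p-values in \[0, 1\].
#' @param m Family size (default `length(p)`).
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  pmin(1, p * m)
}

#' Region-wise group comparison table
#'
#' For every region: covariate-adjusted pairwise ANCOVA p-values between
#' the requested groups (raw and Bonferroni-adjusted, family = regions x
#' contrasts by default) and Cohen's d of each DLB stratum against HC.
#'
#' @param cohort A stratified cohort tibble.
#' @param atlas A `dlb_atlas`.
#' @param groups Groups to compare (default HC and the two DLB strata).
#' @param bonferroni_m Family size for the Bonferroni adjustment; default
#'   number of regions times number of pairwise contrasts.
#' @return Tibble with one row per region x contrast: group means, Cohen's d
#'   (for contrasts against HC), `p_raw`, `p_bonferroni`.
#' @export
regional_effects <- function(cohort, atlas = hammers_atlas(),
                             groups = c("HC", "DLB_DATNEG", "DLB_DATPOS"),
                             bonferroni_m = NULL) {
  sub <- cohort[cohort$group %in% groups, , drop = FALSE]
  vals <- cohort_values(sub, atlas)
  regions <- atlas_regions(atlas)
  n_contrast <- choose(length(groups), 2)
  if (is.null(bonferroni_m)) bonferroni_m <- length(regions) * n_contrast
  rows <- lapply(regions, function(r) {
    v <- vals[, r]
    ct <- ancova_region(v, sub$group, age = sub$age, sex = sub$sex)
    ct$region <- r
    ct$mean_a <- vapply(ct$group_a, function(g) mean(v[sub$group == g]), 0)
    ct$mean_b <- vapply(ct$group_b, function(g) mean(v[sub$group == g]), 0)
    ct$cohens_d <- mapply(function(a, b) {
      cohens_d(v[sub$group == a], v[sub$group == b])
    }, ct$group_a, ct$group_b)
    ct
  })
  out <- dplyr::bind_rows(rows)
  out$p_bonferroni <- bonferroni_adjust(out$p_value, bonferroni_m)
  dplyr::select(out, "region", "group_a", "group_b", "mean_a", "mean_b",
                "cohens_d", "estimate", "se", "statistic", "df",
                p_raw = "p_value", "p_bonferroni")
}

#' Correlation of regional effect-size profiles
#'
#' Ordinary least-squares regression of one 77-region Cohen's d profile on
#' another, with R-squared (squared Pearson correlation) and the two-sided
#' p-value of the correlation test. Used to quantify similarity of the
#' metabolic change pattern between two patient strata.
#'
#' @param d_a Predictor effect-size vector.
#' @param d_b Response effect-size vector, same length (>= 3).
#' @return Tibble with `slope`, `intercept`, `r`, `r_squared`, `p_value`,
#'   `n`.
#' @export
effect_size_correlation <- function(d_a, d_b) {
  if (length(d_a) != length(d_b) || length(d_a) < 3) {
    stop("need two equal-length vectors with n >= 3")
  }
  if (stats::sd(d_a) == 0 || stats::sd(d_b) == 0) stop("constant input vector")
  fit <- stats::lm(d_b ~ d_a)
  ct <- stats::cor.test(d_a, d_b)
  tibble::tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r = unname(ct$estimate),
    r_squared = unname(ct$estimate)^2,
    p_value = ct$p.value,
    n = length(d_a)
  )
}

#' Single-subject regional abnormality flags
#'
#' Expresses each subject's regional and composite SUVr as z-scores against
#' healthy-control means and SDs; a region or composite is flagged abnormal
#' when |z| >= `cut` (closed threshold), and a subject is flagged abnormal
#' when any composite-level |z| >= `cut`.
#'
#' @param cohort Cohort tibble of subjects to assess.
#' @param hc_cohort Cohort tibble of healthy controls providing the
#'   reference distribution.
#' @param atlas A `dlb_atlas`.
#' @param cut Abnormality threshold in SD units (default 2).
#' @return List with `regions` (long tibble: subject_id, region, z, flag),
#'   `composites` (subject_id, composite, z, flag) and `subjects`
#'   (subject_id, abnormal).
#' @export
subject_abnormality <- function(cohort, hc_cohort, atlas = hammers_atlas(),
                                cut = 2) {
  zflag <- function(vals, ref) {
    mu <- colMeans(ref)
    sdv <- apply(ref, 2, stats::sd)
    if (any(sdv <= 0)) stop("zero HC SD in column(s): ",
                            paste(colnames(ref)[sdv <= 0], collapse = ", "))
    sweep(sweep(vals, 2, mu), 2, sdv, "/")
  }
  vals <- cohort_values(cohort, atlas)
  ref <- cohort_values(hc_cohort, atlas)
  zr <- zflag(vals, ref)
  comp <- as.matrix(composite_means(cohort, atlas)[, -1])
  comp_ref <- as.matrix(composite_means(hc_cohort, atlas)[, -1])
  zc <- zflag(comp, comp_ref)
  long <- function(z, what) {
    tibble::tibble(
      subject_id = rep(cohort$subject_id, times = ncol(z)),
      "{what}" := rep(colnames(z), each = nrow(z)),
      z = as.numeric(z),
      flag = abs(as.numeric(z)) >= cut
    )
  }
  list(
    regions = long(zr, "region"),
    composites = long(zc, "composite"),
    subjects = tibble::tibble(
      subject_id = cohort$subject_id,
      abnormal = apply(abs(zc) >= cut, 1, any)
    )
  )
}
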