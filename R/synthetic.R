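#' Default DLB metabolic pattern in log-SUVr space
#'
#' Builds the signed regional mean-shift vector used by the synthetic cohort
#' generator to emulate the DLB covariance pattern: relative hypometabolism
#' of parietal, occipital and frontal cortex, relative hypermetabolism of
#' basal ganglia, limbic system, motor cortices, insula and cerebellum, and
#' near-zero change in the posterior cingulate (the cingulate-island
#' behaviour). Because regional values are global-mean scaled, only relative
#' contrasts are identifiable, so the vector is re-centred to mean zero.
#'
#' @param atlas A `dlb_atlas`.
#' @param magnitude Scale of the strongest regional shifts, in log-SUVr
#'   units at effect scale `delta = 1` (default 0.05, roughly a Cohen's d of
#'   0.8 against the default noise SD of 0.06).
#' @return Named numeric vector of length 77, mean zero.
#' @export
default_pattern <- function(atlas = hammers_atlas(), magnitude = 0.05) {
  weights <- c(
    frontal = -1, parietal = -1, occipital = -1.2, temporal = -0.3,
    insula = 0.5, limbic = 0.8, basal_ganglia = 1, cerebellum = 0.8,
    none = 0
  )
  p <- weights[atlas$regions$composite]
  names(p) <- atlas$regions$name
  # motor strip is hypermetabolic despite sitting in frontal/parietal lobes
  p[grepl("^precentral_gyrus|^postcentral_gyrus", names(p))] <- 0.8
  # posterior cingulate spared (cingulate island)
  p[grepl("^posterior_cingulate_gyrus", names(p))] <- 0
  p <- p * magnitude
  p - mean(p)
}

# mean-shift patterns for the disease control groups; shapes are standard
# clinical descriptions, magnitudes are generator defaults only
disease_pattern <- function(group, atlas, magnitude = 0.05) {
  weights <- switch(
    group,
    AD = c(frontal = -0.3, parietal = -1.2, temporal = -1, occipital = -0.2,
           insula = 0, limbic = -0.3, basal_ganglia = 0.4, cerebellum = 0.6,
           none = 0),
    PD = c(frontal = -0.2, parietal = -0.4, temporal = -0.1, occipital = -0.4,
           insula = 0.1, limbic = 0.2, basal_ganglia = 0.4, cerebellum = 0.3,
           none = 0),
    MSA = c(frontal = -0.4, parietal = 0, temporal = 0, occipital = 0.1,
            insula = 0, limbic = 0.1, basal_ganglia = -1, cerebellum = -1.2,
            none = -0.3),
    stop("no disease pattern for group ", group)
  )
  p <- weights[atlas$regions$composite]
  names(p) <- atlas$regions$name
  if (group == "AD") {
    # AD involves the posterior cingulate / precuneus territory
    p[grepl("^posterior_cingulate_gyrus", names(p))] <- -1.2
  }
  p <- p * magnitude
  p - mean(p)
}

default_cov_boost <- function() {
  tibble::tibble(
    composite_a = c("basal_ganglia", "limbic", "frontal",
                    "basal_ganglia", "occipital", "occipital"),
    composite_b = c("basal_ganglia", "limbic", "frontal",
                    "limbic", "limbic", "parietal"),
    boost = c(0.25, 0.20, 0.15, 0.25, -0.15, -0.10)
  )
}

default_base_cov <- function(atlas, sd_log = 0.06,
                             rho_within = 0.45, rho_between = 0.15) {
  comp <- atlas$regions$composite
  same <- outer(comp, comp, "==")
  r <- matrix(rho_between, 77, 77)
  r[same] <- rho_within
  diag(r) <- 1
  dimnames(r) <- list(atlas$regions$name, atlas$regions$name)
  r * (sd_log^2)
}

default_base_log_mean <- function(atlas) {
  base <- c(frontal = 1.05, parietal = 1.08, temporal = 1.0, occipital = 1.1,
            insula = 1.05, limbic = 0.95, basal_ganglia = 1.15,
            cerebellum = 0.95, none = 0.85)
  m <- log(base[atlas$regions$composite])
  names(m) <- atlas$regions$name
  m
}

#' Specify a synthetic FDG-PET cohort
#'
#' Collects the generative parameters of the synthetic cohort: group sizes
#' (defaults mirror the study-scale cohort: 23 HC, 86 DLB with dopamine
#' deficit, 22 DLB without, 19 MSA, 33 PD, 49 AD), a 77-region baseline
#' log-SUVr profile, the planted DLB pattern and per-group effect scales,
#' a base log-SUVr covariance with block "connectivity" boosts for the DLB
#' groups, putaminal DaT z-score distributions per group, demographics, and
#' a seed. Identical specs with identical seeds generate identical cohorts.
#'
#' @param n_per_group Named integer vector of group sizes.
#' @param atlas A `dlb_atlas`.
#' @param base_log_mean 77-vector of baseline log-SUVr means.
#' @param pattern 77-vector of signed DLB mean shifts (log space, mean 0).
#' @param effect_scale Named numeric vector of per-group multipliers delta
#'   applied to the group's pattern.
#' @param base_cov 77x77 positive-definite covariance of log-SUVr.
#' @param cov_boost Tibble with columns `composite_a`, `composite_b`,
#'   `boost`: additive correlation increments applied to the DLB groups'
#'   covariance (see [build_covariance()]).
#' @param cov_boost_groups Groups whose covariance receives the boosts.
#' @param dat_params Named list mapping group to `c(mean, sd)` of the mean
#'   putaminal DaT z-score.
#' @param age_params `c(mean, sd)` of age in years.
#' @param sex_ratio Probability of male sex.
#' @param site_labels Character vector of site names (subjects are assigned
#'   uniformly; scanner label is derived from site).
#' @param seed Integer RNG seed.
#' @return An object of class `dlb_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(
    n_per_group = c(HC = 23, DLB_DATPOS = 86, DLB_DATNEG = 22,
                    MSA = 19, PD = 33, AD = 49),
    atlas = hammers_atlas(),
    base_log_mean = default_base_log_mean(atlas),
    pattern = default_pattern(atlas),
    effect_scale = c(HC = 0, DLB_DATPOS = 1, DLB_DATNEG = 0.6,
                     AD = 1, PD = 0.7, MSA = 1),
    base_cov = default_base_cov(atlas),
    cov_boost = default_cov_boost(),
    cov_boost_groups = c("DLB_DATPOS", "DLB_DATNEG"),
    dat_params = list(HC = c(0, 1), DLB_DATPOS = c(-3.7, 0.9),
                      DLB_DATNEG = c(-1.1, 0.7), PD = c(-3.0, 1.0),
                      MSA = c(-2.5, 1.2), AD = c(-0.2, 1.0)),
    age_params = c(73, 7.5),
    sex_ratio = 0.61,
    site_labels = c("site_A", "site_B"),
    seed = 1L) {
  stopifnot(all(n_per_group >= 0), length(base_log_mean) == 77,
            length(pattern) == 77, all(dim(base_cov) == c(77, 77)))
  groups <- names(n_per_group)
  if (is.null(groups) || !all(groups %in% cohort_groups)) {
    stop("n_per_group must be named with known group labels")
  }
  miss <- setdiff(groups, names(effect_scale))
  if (length(miss)) stop("effect_scale missing for: ", paste(miss, collapse = ", "))
  spec <- list(
    n_per_group = n_per_group, atlas = atlas,
    base_log_mean = base_log_mean, pattern = pattern,
    effect_scale = effect_scale, base_cov = base_cov,
    cov_boost = cov_boost, cov_boost_groups = cov_boost_groups,
    dat_params = dat_params, age_params = age_params,
    sex_ratio = sex_ratio, site_labels = site_labels,
    seed = as.integer(seed)
  )
  structure(spec, class = "dlb_cohort_spec")
}

#' Apply block correlation boosts to a covariance matrix
#'
#' Converts a positive-definite covariance to correlation form, adds the
#' requested increment to every region pair of each listed composite block
#' (off-diagonal only), clips entries to |r| <= 0.99, repairs positive
#' definiteness by flooring eigenvalues at 1e-6, rescales to unit diagonal
#' and restores the original regional standard deviations.
#'
#' @param base_cov 77x77 (or smaller, matching `atlas`) SPD covariance.
#' @param cov_boost Tibble with columns `composite_a`, `composite_b`,
#'   `boost`; `NULL` or zero rows leaves the input unchanged.
#' @param atlas A `dlb_atlas`.
#' @return SPD covariance matrix of the same dimension.
#' @export
build_covariance <- function(base_cov, cov_boost, atlas = hammers_atlas()) {
  ev <- eigen(base_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8) stop("base covariance is not positive definite")
  if (is.null(cov_boost) || nrow(cov_boost) == 0) return(base_cov)
  sds <- sqrt(diag(base_cov))
  r <- stats::cov2cor(base_cov)
  rn <- atlas$regions$name
  comp <- atlas$regions$composite
  for (i in seq_len(nrow(cov_boost))) {
    a <- which(comp == cov_boost$composite_a[i])
    b <- which(comp == cov_boost$composite_b[i])
    if (!length(a) || !length(b)) stop("unknown composite in cov_boost")
    r[a, b] <- r[a, b] + cov_boost$boost[i]
    # within-composite blocks are already covered by the [a, b] assignment
    if (!identical(cov_boost$composite_a[i], cov_boost$composite_b[i])) {
      r[b, a] <- r[b, a] + cov_boost$boost[i]
    }
  }
  r <- pmin(pmax(r, -0.99), 0.99)
  diag(r) <- 1
  r <- (r + t(r)) / 2
  e <- eigen(r, symmetric = TRUE)
  if (min(e$values) < 1e-6) {
    vals <- pmax(e$values, 1e-6)
    r <- e$vectors %*% (vals * t(e$vectors))
    r <- stats::cov2cor(r)
    r <- (r + t(r)) / 2
  }
  out <- r * tcrossprod(sds)
  dimnames(out) <- dimnames(base_cov)
  out
}

# deterministic per-group sub-seed in fixed group order, independent of
# group sizes; kept below 2^31
group_subseed <- function(seed, group) {
  idx <- match(group, cohort_groups)
  (as.integer(seed) %% 20000000L) * 100L + idx
}

#' Simulate a synthetic cohort table
#'
#' Draws, per group, multivariate-normal regional log-SUVr profiles with
#' mean `base_log_mean + delta_g * pattern_g` and the group covariance
#' (base covariance, boosted for the DLB groups), exponentiates them and
#' global-mean scales every subject (volume-weighted). Putaminal DaT
#' z-scores, ages, sexes, sites and MMSE are drawn from the distributions in
#' the cohort specification. The result is deterministic under its seed.
#'
#' @param spec A `dlb_cohort_spec`.
#' @param scale If `TRUE` (default), global-mean scale each subject's
#'   regional values; `FALSE` returns the latent exponentiated profiles,
#'   which is useful for checking generator calibration.
#' @return A cohort tibble: `subject_id`, `group`, `age`, `sex`, `site`,
#'   `scanner`, `mmse`, `dat_z_left`, `dat_z_right`, then the 77 region
#'   columns in atlas order.
#' @export
simulate_cohort <- function(spec, scale = TRUE) {
  stopifnot(inherits(spec, "dlb_cohort_spec"))
  atlas <- spec$atlas
  rn <- atlas_regions(atlas)
  vols <- atlas_volumes(atlas)
  boosted <- build_covariance(spec$base_cov, spec$cov_boost, atlas)
  rows <- list()
  for (g in cohort_groups) {
    n <- spec$n_per_group[g]
    if (is.na(n) || n == 0) next
    set.seed(group_subseed(spec$seed, g))
    pat <- switch(g,
      HC = rep(0, 77),
      DLB = spec$pattern, DLB_DATPOS = spec$pattern, DLB_DATNEG = spec$pattern,
      disease_pattern(g, atlas)
    )
    delta <- spec$effect_scale[g]
    mu <- spec$base_log_mean + delta * pat
    covg <- if (g %in% spec$cov_boost_groups) boosted else spec$base_cov
    ch <- chol(covg)
    z <- matrix(stats::rnorm(n * 77), nrow = n)
    logx <- sweep(z %*% ch, 2, mu, "+")
    vals <- exp(logx)
    if (scale) vals <- global_mean_scale(vals, vols)
    colnames(vals) <- rn
    dp <- spec$dat_params[[g]]
    if (is.null(dp)) dp <- c(0, 1)
    z_mean <- stats::rnorm(n, dp[1], dp[2])
    z_half_gap <- stats::rnorm(n, 0, 0.2)
    age <- round(stats::rnorm(n, spec$age_params[1], spec$age_params[2]), 1)
    sex <- ifelse(stats::runif(n) < spec$sex_ratio, "M", "F")
    site <- sample(spec$site_labels, n, replace = TRUE)
    mmse_base <- switch(g, HC = 29, AD = 21, 23)
    mmse <- pmin(30, pmax(0, round(
      stats::rnorm(n, mmse_base, 3) - 10 * delta * (z %*% rep(1 / 77, 77))
    )))
    rows[[g]] <- dplyr::bind_cols(
      tibble::tibble(
        subject_id = sprintf("%s_%03d", g, seq_len(n)),
        group = g, age = age, sex = sex, site = site,
        scanner = paste0("scanner_", site),
        mmse = as.numeric(mmse),
        dat_z_left = z_mean + z_half_gap,
        dat_z_right = z_mean - z_half_gap
      ),
      tibble::as_tibble(vals)
    )
  }
  dplyr::bind_rows(rows)
}
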