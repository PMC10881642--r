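#' Normative putaminal DaT statistics
#'
#' Bundles healthy-control means and standard deviations of the putaminal
#' DaT ratio (putamen over occipital reference), per hemisphere, used to
#' express patient ratios as z-scores. The packaged defaults are synthetic
#' placeholders for use with simulated data only; they are not a clinical
#' normative sample.
#'
#' @param mean_left,mean_right HC mean ratios.
#' @param sd_left,sd_right HC standard deviations (> 0).
#' @return A list of class `dat_normative`.
#' @export
dat_normative <- function(mean_left = 2.8, sd_left = 0.35,
                          mean_right = 2.8, sd_right = 0.35) {
  if (sd_left <= 0 || sd_right <= 0) stop("normative SDs must be positive")
  structure(list(mean_left = mean_left, sd_left = sd_left,
                 mean_right = mean_right, sd_right = sd_right),
            class = "dat_normative")
}

#' Putaminal DaT z-scores and DaT stratum
#'
#' Expresses left and right putaminal DaT ratios as z-scores against a
#' healthy-control normative sample, averages the two hemispheric z-scores,
#' and assigns the DaT stratum: `DATPOS` (significant dopamine deficit)
#' when the mean z is at least 2 SD below controls (`z_mean <= -2`, closed
#' at the boundary), otherwise `DATNEG`.
#'
#' @param ratio_left,ratio_right Numeric vectors of putamen/occipital
#'   ratios.
#' @param norm A `dat_normative`.
#' @param threshold Stratification cut on the mean z (default -2).
#' @return Tibble with columns `z_left`, `z_right`, `z_mean`, `stratum`.
#' @export
putaminal_z <- function(ratio_left, ratio_right, norm = dat_normative(),
                        threshold = -2) {
  stopifnot(inherits(norm, "dat_normative"))
  z_left <- (ratio_left - norm$mean_left) / norm$sd_left
  z_right <- (ratio_right - norm$mean_right) / norm$sd_right
  z_mean <- (z_left + z_right) / 2
  tibble::tibble(
    z_left = z_left, z_right = z_right, z_mean = z_mean,
    stratum = ifelse(z_mean <= threshold, "DATPOS", "DATNEG")
  )
}

#' Stratify DLB subjects by dopamine deficit
#'
#' Relabels every DLB subject of a cohort as `DLB_DATPOS` or `DLB_DATNEG`
#' using the mean bilateral putaminal z-score. z-scores are taken from the
#' `dat_z_left`/`dat_z_right` columns if present, otherwise computed from
#' `dat_ratio_putamen_L`/`dat_ratio_putamen_R` against `norm`. DLB subjects
#' without DaT data are dropped with a warning (they cannot enter the
#' imaging analysis arms). Non-DLB rows pass through unchanged.
#'
#' @param cohort A cohort tibble.
#' @param norm A `dat_normative`, needed only when ratios must be converted.
#' @param threshold Stratification cut on the mean z (default -2).
#' @return The cohort tibble with updated `group` labels and added
#'   `dat_z_mean` column for DLB subjects.
#' @export
stratify_cohort <- function(cohort, norm = NULL, threshold = -2) {
  is_dlb <- grepl("^DLB", cohort$group)
  if (!any(is_dlb)) return(cohort)
  has_z <- all(c("dat_z_left", "dat_z_right") %in% names(cohort))
  has_ratio <- all(c("dat_ratio_putamen_L", "dat_ratio_putamen_R") %in% names(cohort))
  if (has_z) {
    z_mean <- (cohort$dat_z_left + cohort$dat_z_right) / 2
  } else if (has_ratio) {
    if (is.null(norm)) stop("DaT ratios supplied but no normative stats given")
    z_mean <- putaminal_z(cohort$dat_ratio_putamen_L,
                          cohort$dat_ratio_putamen_R, norm,
                          threshold = threshold)$z_mean
  } else {
    stop("cohort carries neither DaT z-scores nor putaminal ratios")
  }
  cohort$dat_z_mean <- ifelse(is_dlb, z_mean, NA_real_)
  drop <- is_dlb & !is.finite(z_mean)
  if (any(drop)) {
    warning(sum(drop), " DLB subject(s) without DaT data excluded: ",
            paste(cohort$subject_id[drop], collapse = ", "))
  }
  keep_dlb <- is_dlb & !drop
  cohort$group[keep_dlb] <- ifelse(z_mean[keep_dlb] <= threshold,
                                   "DLB_DATPOS", "DLB_DATNEG")
  out <- cohort[!drop, , drop = FALSE]
  counts <- table(out$group[grepl("^DLB", out$group)])
  message("DaT stratification: ",
          paste(names(counts), counts, sep = " = ", collapse = ", "))
  out
}
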