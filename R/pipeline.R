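#' Pipeline configuration
#'
#' Builds (or reads from YAML/JSON) the configuration driving
#' [run_pipeline()]: exactly one input mode (a cohort table on disk or a
#' synthetic cohort), analysis toggles and the fixed methodological
#' constants (DaT z cut -2, abnormality cut 2 SD, Kaiser eigenvalue cut 1.0,
#' display cut 0.1 for small loadings).
#'
#' @param input_table Path to a cohort CSV/TSV, or `NULL` to simulate.
#' @param synthetic Named list of overrides passed to
#'   [synthetic_cohort_spec()] when simulating.
#' @param seed Integer master seed; all stage seeds derive from it.
#' @param analyses Character subset of `c("regional", "connectivity",
#'   "expression")`.
#' @param dat_threshold DaT stratification cut on the mean putaminal z.
#' @param abnormality_cut Single-subject abnormality cut in HC SD units.
#' @param coefficient_display_cut Loadings below this absolute value are
#'   blanked in rendered report tables (display only).
#' @param n_perm Permutations for the connectivity-similarity p-value.
#' @param out_dir Output directory (created if needed).
#' @return List of class `dlb_pipeline_config`.
#' @export
pipeline_config <- function(input_table = NULL, synthetic = list(),
                            seed = 1L,
                            analyses = c("regional", "connectivity", "expression"),
                            dat_threshold = -2, abnormality_cut = 2,
                            coefficient_display_cut = 0.1,
                            n_perm = 500, out_dir = tempfile("dlbnet_run_")) {
  if (!is.null(input_table) && length(synthetic)) {
    stop("choose exactly one input mode: table or synthetic")
  }
  structure(
    list(input_table = input_table, synthetic = synthetic,
         seed = as.integer(seed), analyses = analyses,
         dat_threshold = dat_threshold, abnormality_cut = abnormality_cut,
         coefficient_display_cut = coefficient_display_cut,
         n_perm = n_perm, out_dir = out_dir),
    class = "dlb_pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path Path to a YAML or JSON config file with the same fields.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- cfg[intersect(names(cfg), names(formals(pipeline_config)))]
  # YAML parses named numeric maps as lists; the generator wants vectors
  if (!is.null(args$synthetic)) {
    args$synthetic <- lapply(args$synthetic, function(x) {
      if (is.list(x)) unlist(x) else x
    })
  }
  do.call(pipeline_config, args)
}

# loadings table for report rendering: sorted by absolute size with small
# coefficients suppressed -- display only, computation is never affected
format_loadings <- function(model, cut = 0.1) {
  L <- model$loadings
  out <- lapply(colnames(L), function(cn) {
    v <- L[, cn]
    keep <- abs(v) >= cut
    v <- sort(v[keep], decreasing = TRUE)
    as.list(round(v, 3))
  })
  names(out) <- colnames(L)
  out
}

#' Run the full analysis pipeline
#'
#' Executes the complete study flow on one cohort: DaT stratification,
#' region-wise ANCOVA/effect-size analysis with effect-size-profile
#' correlation, group-level metabolic connectivity with delta matrices and
#' delta-similarity regression, SSM/PCA pattern training on HC plus DLB
#' with dopamine deficit, leave-one-in expression scoring of every test
#' subject (DLB without deficit, AD, PD, MSA) with z-scoring, stability
#' analysis, four ROC contrasts, covariate correlations and site/scanner
#' batch checks. All tables, matrices, the serialized model and a run
#' manifest are written to the output directory.
#'
#' @param config A `dlb_pipeline_config` (or path to one).
#' @param atlas A `dlb_atlas`.
#' @return Invisibly, a list of class `dlb_pipeline_result` with all stage
#'   outputs.
#' @export
run_pipeline <- function(config, atlas = hammers_atlas()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "dlb_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list(config = config)
  log_stage <- function(...) message("[dlbnet] ", ...)

  # --- input -----------------------------------------------------------
  if (!is.null(config$input_table)) {
    log_stage("reading cohort table ", config$input_table)
    cohort <- read_cohort_table(config$input_table, atlas)
  } else {
    log_stage("simulating synthetic cohort (seed ", config$seed, ")")
    args <- config$synthetic
    args$atlas <- atlas
    if (is.null(args$seed)) args$seed <- config$seed
    spec <- do.call(synthetic_cohort_spec, args)
    cohort <- simulate_cohort(spec)
    out$spec <- spec
  }

  # --- stratification --------------------------------------------------
  cohort <- stratify_cohort(cohort, threshold = config$dat_threshold)
  out$cohort <- cohort
  write_cohort_table(cohort, file.path(config$out_dir, "cohort.csv"))
  counts <- table(cohort$group)
  log_stage("groups: ", paste(names(counts), counts, sep = "=", collapse = ", "))
  for (g in c("HC", "DLB_DATPOS", "DLB_DATNEG")) {
    if (!g %in% names(counts)) stop("stage stratify: no subjects in group ", g)
  }

  # --- regional metabolism --------------------------------------------
  if ("regional" %in% config$analyses) {
    log_stage("regional ANCOVA / effect sizes")
    eff <- regional_effects(cohort, atlas)
    out$regional <- eff
    readr::write_tsv(eff, file.path(config$out_dir, "regional_effects.tsv"))
    d_pos <- eff$cohens_d[eff$group_a == "DLB_DATPOS" & eff$group_b == "HC"]
    d_neg <- eff$cohens_d[eff$group_a == "DLB_DATNEG" & eff$group_b == "HC"]
    if (!length(d_pos)) {  # contrasts may be oriented the other way
      d_pos <- -eff$cohens_d[eff$group_a == "HC" & eff$group_b == "DLB_DATPOS"]
      d_neg <- -eff$cohens_d[eff$group_a == "HC" & eff$group_b == "DLB_DATNEG"]
    }
    out$effect_size_similarity <- effect_size_correlation(d_pos, d_neg)
    hc <- cohort[cohort$group == "HC", , drop = FALSE]
    out$abnormality <- subject_abnormality(
      cohort[cohort$group != "HC", , drop = FALSE], hc, atlas,
      cut = config$abnormality_cut
    )
  }

  # --- metabolic connectivity -----------------------------------------
  if ("connectivity" %in% config$analyses) {
    log_stage("metabolic connectivity matrices")
    cm <- lapply(c(HC = "HC", DLB_DATPOS = "DLB_DATPOS",
                   DLB_DATNEG = "DLB_DATNEG"),
                 function(g) icc_matrix(cohort, g, atlas))
    out$connectivity <- cm
    for (g in names(cm)) {
      zm <- cm[[g]]$z; diag(zm) <- 0
      write_matrix(zm, file.path(config$out_dir, paste0("icc_z_", g, ".tsv")))
    }
    d_pos <- delta_matrix(cm$DLB_DATPOS, cm$HC)
    d_neg <- delta_matrix(cm$DLB_DATNEG, cm$HC)
    out$delta <- list(datpos_vs_hc = d_pos, datneg_vs_hc = d_neg,
                      datpos_vs_datneg = delta_matrix(cm$DLB_DATPOS, cm$DLB_DATNEG))
    out$connectivity_similarity <- connectivity_similarity(
      d_pos, d_neg, n_perm = config$n_perm, seed = config$seed + 1L
    )
    long <- tidy(d_pos)
    readr::write_tsv(long, file.path(config$out_dir, "delta_datpos_vs_hc.tsv"))
  }

  # --- pattern expression ---------------------------------------------
  if ("expression" %in% config$analyses) {
    log_stage("training SSM/PCA pattern on HC + DLB_DATPOS")
    model <- fit_dlb_pattern(cohort, atlas)
    out$model <- model
    log_stage(model$k, " components retained (eigenvalue > 1)")
    write_ssm_model(model, file.path(config$out_dir, "pattern_model.json"))
    train <- cohort[cohort$group %in% model$train_groups, , drop = FALSE]
    test <- cohort[cohort$group %in% c("DLB_DATNEG", "AD", "PD", "MSA"), ,
                   drop = FALSE]
    log_stage("leave-one-in scoring of ", nrow(test), " test subjects")
    expr <- score_cohort(train, model, test, atlas)
    out$expression <- expr
    readr::write_tsv(expr$scores,
                     file.path(config$out_dir, "expression_scores.tsv"))
    pos <- expr$scores$z_score[expr$scores$group == "DLB_DATNEG"]
    rocs <- list(
      all = roc_auc(pos, expr$scores$z_score[expr$scores$group %in%
                                               c("AD", "PD", "MSA")]),
      PD = roc_auc(pos, expr$scores$z_score[expr$scores$group == "PD"]),
      MSA = roc_auc(pos, expr$scores$z_score[expr$scores$group == "MSA"]),
      AD = roc_auc(pos, expr$scores$z_score[expr$scores$group == "AD"])
    )
    out$roc <- rocs
    roc_tbl <- dplyr::bind_rows(lapply(names(rocs), function(nm) {
      dplyr::mutate(rocs[[nm]]$curve, contrast = nm, auc = rocs[[nm]]$auc)
    }))
    readr::write_tsv(roc_tbl, file.path(config$out_dir, "roc_curves.tsv"))
    dlb_scores <- dplyr::bind_rows(
      model$training_expression[model$training_expression$group == "DLB_DATPOS",
                                c("subject_id", "group", "z_score")],
      expr$scores[expr$scores$group == "DLB_DATNEG",
                  c("subject_id", "group", "z_score")]
    )
    dlb_meta <- cohort[match(dlb_scores$subject_id, cohort$subject_id), ]
    if ("mmse" %in% names(dlb_meta)) {
      out$mmse_correlation <- correlate_expression(dlb_scores$z_score,
                                                   dlb_meta$mmse)
    }
    if ("dat_z_mean" %in% names(dlb_meta)) {
      out$dat_correlation <- correlate_expression(dlb_scores$z_score,
                                                  dlb_meta$dat_z_mean)
    }
    if ("site" %in% names(cohort)) {
      all_scores <- dplyr::bind_rows(
        model$training_expression[, c("subject_id", "group", "z_score")],
        expr$scores[, c("subject_id", "group", "z_score")]
      )
      meta <- cohort[match(all_scores$subject_id, cohort$subject_id), ]
      out$batch_effects <- batch_effect_check(all_scores$z_score, meta$site,
                                              meta$group)
    }
  }

  # --- report + manifest ----------------------------------------------
  report <- list(
    group_counts = as.list(counts),
    effect_size_similarity = out$effect_size_similarity,
    connectivity_similarity = out$connectivity_similarity,
    n_components = out$model$k,
    training_cov_percent = if (!is.null(out$model)) training_cov(out$model),
    loi_stability_cov_percent = out$expression$stability$summary_cov_percent,
    auc = lapply(out$roc, function(r) r$auc),
    loadings_display = if (!is.null(out$model)) {
      format_loadings(out$model, config$coefficient_display_cut)
    }
  )
  write_report(report, file.path(config$out_dir, "report.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("dlbnet")),
    r_version = R.version.string,
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")],
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    timestamp_utc = format(Sys.time(), tz = "UTC")
  )
  write_report(manifest, file.path(config$out_dir, "manifest.json"))
  out$report <- report
  log_stage("done; outputs in ", config$out_dir)
  invisible(structure(out, class = "dlb_pipeline_result"))
}

#' @export
print.dlb_pipeline_result <- function(x, ...) {
  cat("<dlb_pipeline_result>\n")
  if (!is.null(x$model)) cat("  components retained:", x$model$k, "\n")
  if (!is.null(x$roc)) {
    cat("  AUC:", paste(names(x$roc),
                        signif(vapply(x$roc, function(r) r$auc, 0), 3),
                        sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
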