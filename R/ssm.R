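#' Log transform and double centering
#'
#' The scaled-subprofile-model preprocessing: natural log of the strictly
#' positive subjects x regions matrix, then subtraction of each subject's
#' row mean followed by each region's column mean, so that all row and
#' column means of the result are zero and residual covariance drives the
#' subsequent component extraction.
#'
#' @param values Subjects x regions matrix of strictly positive values.
#' @return Centred matrix with attributes `row_means` and `col_means`
#'   (the column means are those of the row-centred log matrix, needed to
#'   project new subjects).
#' @export
log_double_center <- function(values) {
  m <- as.matrix(values)
  if (any(m <= 0 | !is.finite(m))) {
    bad <- which(m <= 0 | !is.finite(m), arr.ind = TRUE)[1, ]
    stop("non-positive value at subject ",
         if (!is.null(rownames(m))) rownames(m)[bad[1]] else bad[1],
         ", region ",
         if (!is.null(colnames(m))) colnames(m)[bad[2]] else bad[2])
  }
  l <- log(m)
  rm <- rowMeans(l)
  l <- l - rm
  cm <- colMeans(l)
  out <- sweep(l, 2, cm)
  attr(out, "row_means") <- rm
  attr(out, "col_means") <- cm
  out
}

# orient each loading column so its largest-magnitude element is positive;
# adjusts a companion rotation matrix when given
sign_align_loadings <- function(L, rot = NULL) {
  flips <- apply(L, 2, function(col) {
    if (col[which.max(abs(col))] < 0) -1 else 1
  })
  L <- sweep(L, 2, flips, "*")
  if (!is.null(rot)) rot <- sweep(rot, 2, flips, "*")
  list(loadings = L, rotation = rot)
}

#' Fit the SSM-style PCA pattern model
#'
#' Eigendecomposes the region x region correlation matrix of the log
#' double-centred training data, retains components with eigenvalue > 1
#' (Kaiser criterion, with a small numerical guard band), applies
#' Kaiser-normalized Varimax rotation, derives regression-method factor
#' score weights (via the Moore-Penrose pseudoinverse, since double
#' centering renders the correlation matrix singular), and standardizes the
#' training factor scores to mean zero and unit variance per component.
#'
#' @param values Training subjects x 77 matrix of positive SUVr values
#'   (rownames = subject ids).
#' @param eigen_tol Guard band added to the Kaiser cut (default 1e-8).
#' @return Object of class `ssm_model` without regression weights; see
#'   [fit_weights()].
#' @export
fit_ssm_pca <- function(values, eigen_tol = 1e-8) {
  m <- as.matrix(values)
  if (nrow(m) < 2) stop("need at least 2 training subjects")
  C <- log_double_center(m)
  col_sd <- apply(C, 2, stats::sd)
  if (any(col_sd == 0)) {
    stop("constant region column(s) after centering: ",
         paste(colnames(C)[col_sd == 0], collapse = ", "))
  }
  R <- stats::cor(C)
  e <- eigen(R, symmetric = TRUE)
  keep <- which(e$values > 1 + eigen_tol)
  if (!length(keep)) stop("no components retained (no eigenvalue > 1)")
  K <- length(keep)
  if (nrow(m) <= K) stop("fewer subjects than retained components")
  L <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]), K)
  rownames(L) <- colnames(C)
  L <- sign_align_loadings(L)$loadings
  if (K >= 2) {
    vm <- stats::varimax(L, normalize = TRUE, eps = 1e-10)
    aligned <- sign_align_loadings(unclass(vm$loadings), vm$rotmat)
    L_rot <- aligned$loadings
    rot <- aligned$rotation
  } else {
    L_rot <- L
    rot <- matrix(1, 1, 1)
  }
  colnames(L_rot) <- paste0("comp_", seq_len(K))
  W <- MASS::ginv(R) %*% L_rot
  rownames(W) <- colnames(C)
  Z <- sweep(C, 2, col_sd, "/")
  S_raw <- Z %*% W
  s_sd <- apply(S_raw, 2, stats::sd)
  if (any(s_sd == 0)) stop("degenerate factor scores")
  S <- sweep(S_raw, 2, s_sd, "/")
  colnames(S) <- colnames(L_rot)
  structure(
    list(
      regions = colnames(C),
      training_ids = rownames(m),
      n_train = nrow(m),
      k = K,
      eigenvalues = e$values[keep],
      eigenvalues_all = e$values,
      loadings = L_rot,
      rotation = rot,
      score_weights = W,
      col_means = attr(C, "col_means"),
      col_sd = col_sd,
      score_sd = s_sd,
      scores = S,
      beta = NULL
    ),
    class = "ssm_model"
  )
}

#' @export
print.ssm_model <- function(x, ...) {
  cat("<ssm_model>", x$k, "components (eigenvalue > 1) from",
      x$n_train, "training subjects\n")
  if (!is.null(x$beta)) {
    cat("  weighting factors (beta) fitted; intercept =",
        signif(x$beta_intercept, 4), "\n")
  }
  invisible(x)
}

#' Fit component weighting factors (beta)
#'
#' Ordinary least-squares regression of disease status (HC = 0, patient
#' = 1) on the standardized training factor scores, with age (mean-centred)
#' and sex (binary indicator) as covariate adjusters. The per-component
#' coefficients are the weighting factors beta used to sum factor scores
#' into a single pattern-expression score; the covariate coefficients are
#' retained but by default do not enter the summed score.
#'
#' @param model An `ssm_model` from [fit_ssm_pca()].
#' @param status Numeric or logical vector (0/1) over the training subjects.
#' @param age,sex Optional covariates over the training subjects.
#' @return The model, with elements `beta` (named per component),
#'   `beta_intercept`, `beta_covariates`, `fitted_status`.
#' @export
fit_weights <- function(model, status, age = NULL, sex = NULL) {
  stopifnot(inherits(model, "ssm_model"))
  status <- as.numeric(status)
  if (length(status) != model$n_train) stop("status length mismatch")
  df <- data.frame(status = status, model$scores, check.names = FALSE)
  if (!is.null(age) && length(unique(age)) > 1) df$age_c <- age - mean(age)
  if (!is.null(sex) && length(unique(sex)) > 1) {
    df$sex_i <- as.numeric(factor(sex)) - 1
  }
  fit <- stats::lm(status ~ ., data = df)
  if (anyNA(stats::coef(fit))) stop("rank-deficient weighting regression")
  cf <- stats::coef(fit)
  comp_names <- colnames(model$scores)
  model$beta <- cf[comp_names]
  model$beta_intercept <- unname(cf["(Intercept)"])
  model$beta_covariates <- cf[setdiff(names(cf), c("(Intercept)", comp_names))]
  model$fitted_status <- unname(stats::fitted(fit))
  model
}

# raw expression score: weighted sum of (sign-aligned, matched) factor
# scores, optionally plus intercept and covariate terms
expression_raw_score <- function(beta, scores, intercept = NULL,
                                 covariate_terms = 0) {
  as.numeric(scores %*% beta) + covariate_terms +
    (if (is.null(intercept)) 0 else intercept)
}

#' Train the DLB pattern model on a cohort
#'
#' Convenience wrapper running [fit_ssm_pca()] on the training groups
#' (healthy controls plus DLB with dopamine deficit by default) and
#' [fit_weights()] with DLB status as outcome and age/sex as adjusters.
#' Also stores the training-run expression scores and the HC reference
#' distribution used for z-scoring.
#'
#' @param cohort Stratified cohort tibble.
#' @param atlas A `dlb_atlas`.
#' @param train_groups Character vector; the second and later entries are
#'   coded status 1.
#' @param include_intercept Include the regression intercept in the summed
#'   expression score (default `FALSE`: the intercept is constant within a
#'   run and cancels in z-scoring, and leaving it out keeps control scores
#'   bounded away from zero for the CoV stability diagnostic).
#' @return An `ssm_model` with beta, training expression scores
#'   (`training_expression` tibble) and HC reference mean/SD.
#' @export
fit_dlb_pattern <- function(cohort, atlas = hammers_atlas(),
                            train_groups = c("HC", "DLB_DATPOS"),
                            include_intercept = FALSE) {
  train <- cohort[cohort$group %in% train_groups, , drop = FALSE]
  if (!any(train$group == train_groups[1])) {
    stop("no subjects in reference group ", train_groups[1])
  }
  if (!any(train$group %in% train_groups[-1])) {
    stop("no subjects in pattern group(s) ",
         paste(train_groups[-1], collapse = ", "))
  }
  vals <- cohort_values(train, atlas)
  model <- fit_ssm_pca(vals)
  status <- as.numeric(train$group %in% train_groups[-1])
  model <- fit_weights(model, status,
                       age = if ("age" %in% names(train)) train$age else NULL,
                       sex = if ("sex" %in% names(train)) train$sex else NULL)
  model$train_groups <- train_groups
  model$training_groups_by_id <- stats::setNames(train$group, train$subject_id)
  model$include_intercept <- include_intercept
  raw <- expression_raw_score(
    model$beta, model$scores,
    intercept = if (include_intercept) model$beta_intercept else NULL
  )
  hc_idx <- train$group == train_groups[1]
  model$hc_ref_mean <- mean(raw[hc_idx])
  model$hc_ref_sd <- stats::sd(raw[hc_idx])
  if (model$hc_ref_sd <= 0) stop("degenerate HC reference distribution")
  model$training_expression <- tibble::tibble(
    subject_id = train$subject_id,
    group = train$group,
    raw_score = raw,
    z_score = (raw - model$hc_ref_mean) / model$hc_ref_sd
  )
  model
}

#' Serialize / restore a pattern model
#'
#' Writes the full model (regions, eigenvalues, rotated loadings, rotation,
#' score weights, centering statistics, beta, HC reference) to a single
#' JSON document, and reads it back.
#'
#' @param model An `ssm_model`.
#' @param path File path.
#' @return `path` invisibly / the restored `ssm_model`.
#' @export
write_ssm_model <- function(model, path) {
  payload <- model[c("regions", "training_ids", "n_train", "k",
                     "eigenvalues", "col_means", "col_sd", "score_sd",
                     "hc_ref_mean", "hc_ref_sd", "include_intercept",
                     "beta_intercept")]
  payload$loadings <- unname(model$loadings)
  payload$rotation <- unname(model$rotation)
  payload$score_weights <- unname(model$score_weights)
  payload$beta <- as.list(model$beta)
  payload$beta_covariates <- as.list(model$beta_covariates)
  payload$train_groups <- model$train_groups
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ssm_model
#' @export
read_ssm_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  k <- p$k
  model <- list(
    regions = p$regions, training_ids = p$training_ids, n_train = p$n_train,
    k = k, eigenvalues = p$eigenvalues,
    loadings = matrix(unlist(p$loadings), ncol = k,
                      dimnames = list(p$regions, paste0("comp_", 1:k))),
    rotation = matrix(unlist(p$rotation), ncol = k),
    score_weights = matrix(unlist(p$score_weights), ncol = k,
                           dimnames = list(p$regions, NULL)),
    col_means = stats::setNames(as.numeric(p$col_means), p$regions),
    col_sd = stats::setNames(as.numeric(p$col_sd), p$regions),
    score_sd = as.numeric(p$score_sd),
    beta = stats::setNames(as.numeric(unlist(p$beta)), names(p$beta)),
    beta_intercept = p$beta_intercept,
    beta_covariates = stats::setNames(as.numeric(unlist(p$beta_covariates)),
                                      names(p$beta_covariates)),
    hc_ref_mean = p$hc_ref_mean, hc_ref_sd = p$hc_ref_sd,
    include_intercept = isTRUE(p$include_intercept),
    train_groups = p$train_groups
  )
  structure(model, class = "ssm_model")
}
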