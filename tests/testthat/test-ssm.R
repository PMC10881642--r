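test_that("log double centering reproduces hand-worked 2x2 examples", {
  # exp of [[1,2],[3,4]]: rows differ only by offset -> centred to all zeros
  m1 <- exp(matrix(c(1, 3, 2, 4), 2, 2))
  c1 <- log_double_center(m1)
  expect_lt(max(abs(c1)), 1e-12)
  # exp of [[1,2],[4,3]]: interaction survives both centerings
  m2 <- exp(matrix(c(1, 4, 2, 3), 2, 2))
  c2 <- log_double_center(m2)
  expect_equal(unname(c2), matrix(c(-0.5, 0.5, 0.5, -0.5), 2, 2),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unname(attr(c2, "row_means")), c(1.5, 3.5))
})

test_that("double centering zeroes all row and column means and is idempotent", {
  set.seed(50)
  m <- matrix(rlnorm(15 * 8, 0, 0.3), 15, 8,
              dimnames = list(paste0("s", 1:15), paste0("r", 1:8)))
  C <- log_double_center(m)
  expect_lt(max(abs(rowMeans(C))), 1e-12)
  expect_lt(max(abs(colMeans(C))), 1e-12)
  # applying the operator to exp(C) returns C unchanged
  C2 <- log_double_center(exp(C))
  expect_equal(unname(C2), unname(C), ignore_attr = TRUE, tolerance = 1e-12)
  expect_lt(max(abs(attr(C2, "col_means"))), 1e-12)

  bad <- m; bad[3, 5] <- -1
  expect_error(log_double_center(bad), "s3")
  expect_error(log_double_center(bad), "r5")
})

test_that("two-region fits have the forced eigenvalues 2 and 0 and a trivial rotation", {
  # row centering makes the two columns exact mirrors: correlation -1
  set.seed(51)
  m <- matrix(rlnorm(20 * 2, 0, 0.2), 20, 2,
              dimnames = list(paste0("s", 1:20), c("a", "b")))
  fit <- fit_ssm_pca(m)
  expect_equal(fit$eigenvalues_all, c(2, 0), tolerance = 1e-10)
  expect_equal(fit$k, 1L)
  expect_identical(fit$rotation, matrix(1, 1, 1))
  # standardized scores: mean 0, sd 1
  expect_lt(abs(mean(fit$scores[, 1])), 1e-10)
  expect_equal(stats::sd(fit$scores[, 1]), 1, tolerance = 1e-12)
})

test_that("eigenvalues sum to the region count with at least one zero", {
  set.seed(52)
  coh <- simulate_cohort(small_spec(seed = 52,
                                    n_per_group = c(HC = 20, DLB_DATPOS = 30)))
  fit <- fit_ssm_pca(cohort_values(coh, ATLAS))
  expect_equal(sum(fit$eigenvalues_all), 77, tolerance = 1e-8)
  # double centering removes one rank; n < p removes more
  expect_lt(min(fit$eigenvalues_all), 1e-8)
  expect_true(all(fit$eigenvalues > 1))
  expect_lt(fit$k, fit$n_train)
})

test_that("varimax rotation matches the independent pairwise-sweep maximiser", {
  set.seed(53)
  coh <- simulate_cohort(small_spec(seed = 53,
                                    n_per_group = c(HC = 18, DLB_DATPOS = 25)))
  fit <- fit_ssm_pca(cohort_values(coh, ATLAS))
  expect_gte(fit$k, 2)
  # rotation is orthonormal and maps unrotated to rotated loadings
  expect_equal(t(fit$rotation) %*% fit$rotation, diag(fit$k),
               tolerance = 1e-8)
  L_unrot <- fit$loadings %*% t(fit$rotation)
  expect_equal(L_unrot %*% fit$rotation, fit$loadings,
               ignore_attr = TRUE, tolerance = 1e-10)
  # communalities are rotation-invariant
  expect_equal(rowSums(L_unrot^2), rowSums(fit$loadings^2), tolerance = 1e-8)
  # the fitted rotation is a fixed point of the independent pairwise-sweep
  # maximiser: further sweeps cannot improve the criterion
  crit_pkg <- varimax_criterion(fit$loadings)
  expect_gte(crit_pkg, varimax_criterion(L_unrot) - 1e-12)
  expect_lt(oracle_varimax(fit$loadings)$criterion - crit_pkg, 1e-8)

  # on well-separated problems the two maximisers find the same optimum
  set.seed(530)
  for (rep in 1:10) {
    L <- planted_loadings(sample(20:60, 1), sample(2:6, 1))
    vm <- stats::varimax(L, normalize = TRUE, eps = 1e-10)
    expect_equal(varimax_criterion(unclass(vm$loadings)),
                 oracle_varimax(L)$criterion, tolerance = 1e-6)
  }
})

test_that("sign alignment makes each column's largest-magnitude loading positive", {
  set.seed(54)
  L <- matrix(rnorm(30), 10, 3)
  out <- dlbnet:::sign_align_loadings(L)$loadings
  for (j in 1:3) {
    expect_gt(out[which.max(abs(out[, j])), j], 0)
  }
  # flipping input columns leaves the output unchanged
  out2 <- dlbnet:::sign_align_loadings(sweep(L, 2, c(-1, 1, -1), "*"))$loadings
  expect_equal(out2, out)
})

test_that("weighting-factor regression equals the normal-equations oracle", {
  set.seed(55)
  n <- 40
  S <- scale(matrix(rnorm(n * 3), n, 3))
  S <- sweep(S, 2, apply(S, 2, stats::sd), "/")
  colnames(S) <- paste0("comp_", 1:3)
  model <- structure(list(scores = S, n_train = n), class = "ssm_model")

  # exact linear status: beta recovered exactly, unused component beta 0
  status <- 0.5 + 0.5 * S[, 1] - 0.25 * S[, 3]
  fit <- fit_weights(model, status)
  expect_equal(unname(fit$beta), c(0.5, 0, -0.25), tolerance = 1e-10)
  expect_equal(fit$beta_intercept, 0.5, tolerance = 1e-10)

  # noisy 0/1 status with covariates: matches oracle OLS coefficient-for-coefficient
  status01 <- rbinom(n, 1, 0.5)
  age <- rnorm(n, 70, 7)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  fit2 <- fit_weights(model, status01, age = age, sex = sex)
  X <- cbind(S, age_c = age - mean(age),
             sex_i = as.numeric(factor(sex)) - 1)
  cf <- oracle_ols(X, status01)
  expect_equal(unname(fit2$beta), unname(cf[2:4]), tolerance = 1e-10)
  expect_equal(fit2$beta_intercept, unname(cf[1]), tolerance = 1e-10)
  expect_equal(unname(fit2$beta_covariates),
               unname(cf[c("age_c", "sex_i")]), tolerance = 1e-10)
  expect_error(fit_weights(model, status01[-1]), "length")
})

test_that("training factor scores are standardized and reproducible from the weights", {
  set.seed(56)
  coh <- simulate_cohort(small_spec(seed = 56,
                                    n_per_group = c(HC = 15, DLB_DATPOS = 20)))
  vals <- cohort_values(coh, ATLAS)
  fit <- fit_ssm_pca(vals)
  expect_lt(max(abs(colMeans(fit$scores))), 1e-10)
  expect_equal(apply(fit$scores, 2, stats::sd), rep(1, fit$k),
               ignore_attr = TRUE, tolerance = 1e-12)
  # recompute scores from stored centering stats and weights
  C <- log_double_center(vals)
  Z <- sweep(unclass(C), 2, fit$col_sd, "/")
  S <- sweep(Z %*% fit$score_weights, 2, fit$score_sd, "/")
  expect_equal(unname(S), unname(fit$scores), tolerance = 1e-10)
})

test_that("fit_dlb_pattern stores a usable HC reference and serializes losslessly", {
  coh <- simulate_cohort(small_spec(seed = 57,
                                    n_per_group = c(HC = 16, DLB_DATPOS = 24,
                                                    DLB_DATNEG = 8)))
  model <- fit_dlb_pattern(coh, ATLAS)
  te <- model$training_expression
  hc <- te[te$group == "HC", ]
  expect_equal(mean(hc$raw_score), model$hc_ref_mean, tolerance = 1e-12)
  expect_equal(stats::sd(hc$raw_score), model$hc_ref_sd, tolerance = 1e-12)
  expect_lt(abs(mean(hc$z_score)), 1e-10)
  # DLB patients express the pattern more than controls by construction
  expect_gt(mean(te$z_score[te$group == "DLB_DATPOS"]), mean(hc$z_score))

  path <- withr::local_tempfile(fileext = ".json")
  write_ssm_model(model, path)
  back <- read_ssm_model(path)
  expect_equal(back$loadings, model$loadings, tolerance = 1e-12)
  expect_equal(back$score_weights, model$score_weights, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(back$beta, model$beta, tolerance = 1e-12)
  expect_equal(back$hc_ref_mean, model$hc_ref_mean, tolerance = 1e-12)
  expect_equal(back$col_means, model$col_means, tolerance = 1e-12)
  # the restored model projects new subjects identically
  test_rows <- coh[coh$group == "DLB_DATNEG", ]
  expect_equal(project_expression(back, test_rows, ATLAS)$z_score,
               project_expression(model, test_rows, ATLAS)$z_score,
               tolerance = 1e-10)

  expect_error(fit_dlb_pattern(coh[coh$group != "HC", ], ATLAS), "HC")
})
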