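test_that("z-scoring against a reference matches the hand formula", {
  expect_equal(zscore_expression(3, c(1, 2, 3)), 1)
  expect_equal(zscore_expression(c(0, 10), c(4, 6)),
               c((0 - 5) / stats::sd(c(4, 6)), (10 - 5) / stats::sd(c(4, 6))))
  expect_error(zscore_expression(1, c(2, 2)), "positive")
})

test_that("component matching recovers permutations and sign flips exactly", {
  set.seed(60)
  L <- matrix(rnorm(77 * 4), 77, 4)
  perm <- c(3, 1, 4, 2)
  signs <- c(-1, 1, 1, -1)
  L_new <- sweep(L[, perm], 2, signs[perm], "*")
  mt <- dlbnet:::match_components(L, L_new)
  expect_equal(mt$assign, match(seq_len(4), perm))
  expect_equal(mt$sign, signs, tolerance = 1e-12)
  expect_equal(mt$quality, rep(1, 4), tolerance = 1e-12)
  expect_false(any(mt$unmatched))

  # a rerun with fewer components leaves the weakest reference unmatched
  mt2 <- dlbnet:::match_components(L, L_new[, 1:3])
  expect_equal(sum(mt2$unmatched), 1L)
})

test_that("leave-one-in scoring of a training subject reproduces its training score", {
  # duplicating a training subject perturbs the PCA only slightly; leading
  # components are re-identified, while near-degenerate noise components
  # rotate freely, so agreement is approximate by design
  coh <- simulate_cohort(small_spec(seed = 61,
                                    n_per_group = c(HC = 23, DLB_DATPOS = 86)))
  model <- fit_dlb_pattern(coh, ATLAS)
  ref <- model$training_expression
  idx <- c(which(coh$group == "DLB_DATPOS")[1:4], which(coh$group == "HC")[1:2])
  dz <- cors <- z_loi <- z_train <- numeric(0)
  for (i in idx) {
    subj <- coh[i, ]
    loi <- suppressWarnings(leave_one_in_score(coh, model, subj, ATLAS))
    expect_identical(loi$subject_id, subj$subject_id)
    zt <- ref$z_score[ref$subject_id == subj$subject_id]
    z_loi <- c(z_loi, loi$z_score); z_train <- c(z_train, zt)
    dz <- c(dz, abs(loi$z_score - zt))
    hc_loi <- loi$hc_scores[[1]]
    hc_ref <- ref$raw_score[match(names(hc_loi), ref$subject_id)]
    cors <- c(cors, stats::cor(hc_loi, hc_ref))
  }
  expect_lt(stats::median(dz), 1)
  expect_true(all(dz < 2.5))
  expect_true(all(cors > 0.7))
  # rank order and group separation survive the re-run
  expect_gt(stats::cor(z_loi, z_train), 0.9)
  expect_gt(min(z_loi[1:4]), max(z_loi[5:6]))

  expect_error(leave_one_in_score(coh, model, coh[1:2, ], ATLAS),
               "exactly one")
  subj <- coh[1, ]
  missing_region <- subj[, setdiff(names(subj), "hippocampus_L")]
  expect_error(leave_one_in_score(coh, model, missing_region, ATLAS),
               "hippocampus_L")
})

test_that("score_cohort collects per-run HC scores and a stability summary", {
  coh <- suppressWarnings(simulate_cohort(small_spec(
    seed = 62, n_per_group = c(HC = 14, DLB_DATPOS = 22, DLB_DATNEG = 6,
                               AD = 4)
  )))
  model <- fit_dlb_pattern(coh, ATLAS)
  train <- coh[coh$group %in% c("HC", "DLB_DATPOS"), ]
  test <- coh[coh$group %in% c("DLB_DATNEG", "AD"), ]
  expr <- suppressWarnings(score_cohort(train, model, test, ATLAS))
  expect_s3_class(expr, "dlb_expression")
  expect_equal(nrow(expr$scores), 10)
  expect_identical(dim(expr$hc_runs), c(10L, 14L))
  expect_identical(rownames(expr$hc_runs), expr$scores$subject_id)
  expect_true(all(expr$scores$group %in% c("DLB_DATNEG", "AD")))
  expect_true(is.finite(expr$stability$summary_cov_percent))
  expect_equal(nrow(expr$stability$per_hc), 14)
})

test_that("stability CoV matches the hand-worked two-run example", {
  runs <- rbind(c(9, 20), c(11, 20))  # control 1: mean 10, sd sqrt(2)
  colnames(runs) <- c("h1", "h2")
  st <- stability_cov(runs)
  expect_equal(st$per_hc$cov_percent[1], 100 * sqrt(2) / 10, tolerance = 1e-12)
  expect_equal(round(st$per_hc$cov_percent[1], 2), 14.14)
  expect_equal(st$per_hc$cov_percent[2], 0)
  expect_equal(st$summary_cov_percent, (100 * sqrt(2) / 10 + 0) / 2,
               tolerance = 1e-12)
  expect_error(stability_cov(runs[1, , drop = FALSE]), "at least 2")
  runs0 <- cbind(runs, h3 = c(-1, 1))
  expect_warning(st0 <- stability_cov(runs0), "zero mean")
  expect_equal(st0$summary_cov_percent, st$summary_cov_percent)
})

test_that("ROC AUC matches hand examples and the exhaustive pair-count oracle", {
  r1 <- roc_auc(c(1, 3), c(2, 0))
  expect_equal(r1$auc, 0.75)
  expect_equal(roc_auc(c(5, 5), c(5, 5))$auc, 0.5)   # all ties: half credit
  expect_equal(roc_auc(c(2, 3, 4), c(0, 1))$auc, 1)
  expect_equal(roc_auc(c(0, 1), c(2, 3, 4))$auc, 0)
  set.seed(63)
  for (rep in 1:20) {
    pos <- sample(round(rnorm(sample(3:15, 1), 1), 1))
    neg <- sample(round(rnorm(sample(3:15, 1)), 1))
    got <- roc_auc(pos, neg)
    expect_equal(got$auc, oracle_auc(pos, neg), tolerance = 1e-12)
    # curve endpoints and monotone sensitivity
    expect_equal(got$curve$sensitivity[1], 0)
    expect_equal(got$curve$specificity[1], 1)
    expect_equal(got$curve$sensitivity[nrow(got$curve)], 1)
    expect_true(all(diff(got$curve$sensitivity) >= 0))
    expect_true(all(diff(got$curve$specificity) <= 0))
  }
  expect_error(roc_auc(numeric(0), 1), "non-empty")
})

test_that("expression-covariate correlation matches cor.test and drops NAs", {
  set.seed(64)
  z <- rnorm(30); x <- 0.5 * z + rnorm(30)
  got <- correlate_expression(z, x)
  ct <- stats::cor.test(z, x)
  expect_equal(got$r, unname(ct$estimate))
  expect_equal(got$r_squared, unname(ct$estimate)^2)
  expect_equal(got$p_value, ct$p.value)
  expect_equal(got$n, 30)
  x2 <- x; x2[c(3, 7)] <- NA
  expect_equal(correlate_expression(z, x2)$n, 28)
  expect_error(correlate_expression(z[1:2], x[1:2]), "at least 3")
  expect_error(correlate_expression(rep(1, 10), x[1:10]), "constant")
})

test_that("batch-effect check uses Welch tests with BH adjustment", {
  set.seed(65)
  z <- rnorm(40)
  site <- rep(c("A", "B"), 20)
  grp <- rep(c("HC", "DLB"), each = 20)
  out <- batch_effect_check(z, site, grp)
  expect_equal(nrow(out), 2)
  for (g in unique(grp)) {
    idx <- grp == g
    tt <- stats::t.test(z[idx & site == "A"], z[idx & site == "B"])
    expect_equal(out$p_value[out$group == g], tt$p.value, tolerance = 1e-12)
  }
  expect_equal(out$p_fdr, stats::p.adjust(out$p_value, "BH"))

  # planted site shift is detected
  z2 <- z; z2[site == "A" & grp == "HC"] <- z2[site == "A" & grp == "HC"] + 3
  out2 <- batch_effect_check(z2, site, grp)
  expect_lt(out2$p_fdr[out2$group == "HC"], 0.01)

  expect_error(batch_effect_check(z, rep("A", 40)), "fewer than two")
  expect_warning(batch_effect_check(z, c("C", site[-1]), grp), "n < 2")
})

test_that("BH adjustment on a known vector matches p.adjust", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(stats::p.adjust(p, "BH"), rep(0.04, 4))
})

test_that("direct projection is deterministic and separates the planted groups", {
  coh <- simulate_cohort(small_spec(seed = 66,
                                    n_per_group = c(HC = 15, DLB_DATPOS = 25,
                                                    DLB_DATNEG = 10)))
  model <- fit_dlb_pattern(coh, ATLAS)
  test <- coh[coh$group == "DLB_DATNEG", ]
  a <- project_expression(model, test, ATLAS)
  b <- project_expression(model, test, ATLAS)
  expect_identical(a, b)
  # training subjects projected through the stored statistics reproduce
  # their training z-scores exactly
  train <- coh[coh$group %in% c("HC", "DLB_DATPOS"), ]
  proj <- project_expression(model, train, ATLAS)
  expect_equal(proj$z_score, model$training_expression$z_score,
               tolerance = 1e-10)
  # intermediate-expression group sits between HC and the pattern group
  expect_gt(mean(a$z_score),
            mean(proj$z_score[proj$group == "HC"]))
  expect_lt(mean(a$z_score),
            mean(proj$z_score[proj$group == "DLB_DATPOS"]))
})
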