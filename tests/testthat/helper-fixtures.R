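# shared fixtures: one atlas for the whole suite, small synthetic cohorts,
# and independent brute-force oracles used to cross-check the implementation

ATLAS <- hammers_atlas()

small_spec <- function(seed = 1, ...) {
  args <- list(
    n_per_group = c(HC = 14, DLB_DATPOS = 24, DLB_DATNEG = 10,
                    MSA = 6, PD = 8, AD = 10),
    atlas = ATLAS,
    seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(synthetic_cohort_spec, args)
}

# wrap a subjects x 77 positive matrix as a minimal cohort tibble
as_cohort <- function(values, group = "HC", ids = NULL) {
  n <- nrow(values)
  colnames(values) <- atlas_regions(ATLAS)
  dplyr::bind_cols(
    tibble::tibble(
      subject_id = ids %||% sprintf("S%03d", seq_len(n)),
      group = rep_len(group, n),
      age = seq(60, 80, length.out = n),
      sex = rep_len(c("M", "F"), n),
      site = rep_len(c("site_A", "site_B"), n)
    ),
    tibble::as_tibble(values)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- oracles -----------------------------------------------------------

# per-pair Pearson correlation by explicit loops
oracle_corr_matrix <- function(m) {
  p <- ncol(m)
  r <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i != j) r[i, j] <- stats::cor(m[, i], m[, j])
    }
  }
  r
}

# AUC by exhaustive pair counting with half-credit ties
oracle_auc <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + (p > q) + 0.5 * (p == q)
  }
  wins / (length(pos) * length(neg))
}

# OLS coefficients from the normal equations
oracle_ols <- function(X, y) {
  Xi <- cbind(1, X)
  solve(t(Xi) %*% Xi, t(Xi) %*% y)[, 1]
}

# raw varimax criterion (Kaiser-normalized), and an independent
# pairwise-sweep maximiser
varimax_criterion <- function(L, normalize = TRUE) {
  if (normalize) {
    h <- sqrt(rowSums(L^2))
    L <- L / h
  }
  p <- nrow(L)
  sum(apply(L^2, 2, function(x) mean(x^2) - mean(x)^2))
}

oracle_varimax <- function(L, max_sweeps = 2000) {
  h <- sqrt(rowSums(L^2))
  Ln <- L / h
  K <- ncol(Ln)
  rot <- diag(K)
  crit <- varimax_criterion(Ln, normalize = FALSE)
  for (sweep_i in seq_len(max_sweeps)) {
    crit_old <- crit
    for (i in seq_len(K - 1)) {
      for (j in (i + 1):K) {
        x <- Ln[, i]; y <- Ln[, j]
        u <- x^2 - y^2; v <- 2 * x * y
        A <- sum(u); B <- sum(v)
        C <- sum(u^2 - v^2); D <- sum(2 * u * v)
        num <- D - 2 * A * B / nrow(Ln)
        den <- C - (A^2 - B^2) / nrow(Ln)
        phi <- -atan2(num, den) / 4
        if (abs(phi) > 1e-15) {
          G <- matrix(c(cos(phi), -sin(phi), sin(phi), cos(phi)), 2, 2)
          Ln[, c(i, j)] <- Ln[, c(i, j)] %*% G
          rot[, c(i, j)] <- rot[, c(i, j)] %*% G
        }
      }
    }
    crit <- varimax_criterion(Ln, normalize = FALSE)
    if (abs(crit - crit_old) < 1e-16) break
  }
  list(loadings = Ln * h, rotmat = rot, criterion = crit)
}

# random loading matrix with planted simple structure (each variable loads
# on one factor), scrambled by a random orthogonal rotation: the varimax
# optimum is well separated, so independent maximisers agree
planted_loadings <- function(p, K) {
  B <- matrix(0, p, K)
  B[cbind(seq_len(p), sample(K, p, TRUE))] <-
    stats::runif(p, 0.5, 1) * sample(c(-1, 1), p, TRUE)
  B <- B + matrix(stats::rnorm(p * K, 0, 0.05), p, K)
  Q <- qr.Q(qr(matrix(stats::rnorm(K * K), K)))
  B %*% Q
}
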