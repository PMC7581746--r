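# mean-zero orthonormal columns scaled so x'x/n = 1
orthonormal_design <- function(n, p, seed = 1) {
  set.seed(seed)
  Xc <- scale(matrix(rnorm(n * (p + 1)), n, p + 1), scale = FALSE)
  Q <- qr.Q(qr(Xc))[, seq_len(p), drop = FALSE]
  Q * sqrt(n)
}

test_that("at or above lambda_max every penalised coefficient is zero", {
  set.seed(3)
  X <- matrix(rbinom(100 * 30, 2, 0.4), 100, 30)
  y <- rnorm(100)
  lmax <- lasso_lambda_max(y, X)
  fit <- solve_lasso(y, X, lambda = lmax * 1.000001)
  expect_true(all(fit$alpha == 0))
  fit2 <- solve_lasso(y, X, lambda = lmax * 0.9)
  expect_gt(sum(fit2$alpha != 0), 0)
})

test_that("orthonormal designs give the exact soft-thresholding solution", {
  n <- 60; p <- 10
  X <- orthonormal_design(n, p, seed = 4)
  set.seed(5)
  y <- rnorm(n)
  yc <- y - mean(y)
  lambda <- 0.08
  fit <- solve_lasso(y, X, lambda = lambda, standardize = FALSE)
  z <- as.numeric(crossprod(X, yc)) / n
  oracle <- sign(z) * pmax(abs(z) - lambda, 0)
  expect_equal(unname(fit$alpha), oracle, tolerance = 1e-9)
})

test_that("lambda = 0 on a full-rank toy equals least squares", {
  set.seed(6)
  X <- matrix(rnorm(50 * 5), 50, 5)
  y <- rnorm(50)
  fit <- solve_lasso(y, X, lambda = 0, tol = 1e-12)
  ols <- coef(lm(y ~ X))
  expect_equal(unname(fit$alpha), unname(ols[-1]), tolerance = 1e-7)
  expect_equal(fit$alpha0, unname(ols[1]), tolerance = 1e-7)
})

test_that("solutions agree with an independent solver and satisfy the KKT conditions", {
  skip_if_not_installed("glmnet")
  set.seed(7)
  for (case in 1:3) {
    n <- 80; p <- c(20, 60, 150)[case]
    X <- matrix(rbinom(n * p, 2, runif(p, 0.1, 0.5)[rep(seq_len(p),
                                                        each = n)]), n, p)
    colnames(X) <- paste0("m", seq_len(p))
    y <- as.numeric(scale(X[, 1])) * 0.5 + rnorm(n)
    lambda <- 0.1
    fit <- solve_lasso(y, X, lambda = lambda)
    g <- glmnet::glmnet(X, y, lambda = lambda, standardize = TRUE,
                        thresh = 1e-14)
    expect_equal(unname(fit$alpha), as.numeric(coef(g))[-1],
                 tolerance = 1e-5)
    expect_lt(max(lasso_kkt_violation(fit, y, X)), 1e-6)
  }
})

test_that("unpenalised covariates match a joint glmnet fit", {
  skip_if_not_installed("glmnet")
  set.seed(8)
  n <- 100; p <- 40
  X <- matrix(rbinom(n * p, 2, 0.3), n, p)
  C <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("PC1", "PC2")))
  y <- 0.8 * C[, 1] + as.numeric(scale(X[, 3])) * 0.4 + rnorm(n)
  lambda <- 0.05
  # Frisch-Waugh equivalence is exact on the unstandardized problem
  fit <- solve_lasso(y, X, C = C, lambda = lambda, standardize = FALSE)
  # glmnet with penalty.factor 0 on covariates, adjusting for its rescaling
  # of the penalty factors to mean 1
  XC <- cbind(X, C)
  pf <- c(rep(1, p), 0, 0)
  g <- glmnet::glmnet(XC, y, lambda = lambda * p / (p + 2),
                      penalty.factor = pf, standardize = FALSE,
                      thresh = 1e-14)
  co <- as.numeric(coef(g))
  expect_equal(unname(fit$alpha), co[2:(p + 1)], tolerance = 1e-6)
  expect_equal(unname(fit$covar_coef), co[(p + 2):(p + 3)], tolerance = 1e-6)
})

test_that("genotype PCs are orthogonal, deterministic and separate subpopulations", {
  cfg <- tiny_config(seed = 71, subpop_delta = 0.3, missing_rate = 0)
  geno <- simulate_genotypes(cfg)
  pcs <- genotype_pcs(geno, k = 5)
  expect_equal(crossprod(pcs[, 1], pcs[, 2])[1], 0, tolerance = 1e-8)
  expect_identical(pcs, genotype_pcs(geno, k = 5))
  # families are split into two halves with shifted allele frequencies
  design <- simulate_design(cfg)
  fams <- unique(design$family)
  first_half <- design$family %in% fams[seq_len(ceiling(length(fams) / 2))]
  expect_gt(abs(cor(pcs[, 1], as.numeric(first_half))), 0.9)
  # k = 0 gives intercept-only covariates
  expect_equal(ncol(genotype_pcs(geno, k = 0)), 0L)
  expect_error(genotype_pcs(geno, k = 10000), "k must be")
})

test_that("false-selection bound arithmetic", {
  # large catalogue: q ~ 84 of p = 178,101 puts the threshold at ~ 0.52
  expect_equal(buhlmann_threshold(178101, 84), 0.5198, tolerance = 1e-3)
  expect_gt(buhlmann_threshold(178101, 84), 0.5)
  # q -> 0 drives the threshold to 1/2
  expect_equal(buhlmann_threshold(1e5, 1e-3), 0.5, tolerance = 1e-6)
  # q^2 = p * ev_max caps at 1 with a warning
  expect_warning(thr <- buhlmann_threshold(100, 10), "capped")
  expect_equal(thr, 1)
  # inverse mode round-trips
  q <- buhlmann_max_q(178101, 0.52)
  expect_equal(buhlmann_threshold(178101, q), 0.52, tolerance = 1e-10)
  expect_error(buhlmann_threshold(100, 0), "q > 0")
})

test_that("stability selection is deterministic and finds a strong planted QTL", {
  set.seed(9)
  n <- 120; p <- 300
  X <- matrix(rbinom(n * p, 2, 0.3), n, p)
  colnames(X) <- paste0("m", seq_len(p))
  y <- as.numeric(scale(X[, 42])) * 1.5 + rnorm(n)
  s1 <- stability_selection(y, X, n_subsamples = 50, seed = 11)
  s2 <- stability_selection(y, X, n_subsamples = 50, seed = 11)
  expect_identical(s1$ssp, s2$ssp)
  expect_true(all(s1$ssp >= 0 & s1$ssp <= 1))
  expect_gt(s1$ssp[["m42"]], 0.95)
  expect_true("m42" %in% s1$selected)
  # q_avg close to the calibrated target
  expect_lt(abs(s1$q_avg - s1$q_target), 2)
})

test_that("pure-noise responses rarely reach the inclusion threshold", {
  set.seed(10)
  hits <- vapply(1:5, function(r) {
    n <- 100; p <- 400
    X <- matrix(rbinom(n * p, 2, 0.3), n, p)
    colnames(X) <- paste0("m", seq_len(p))
    ss <- stability_selection(rnorm(n), X, n_subsamples = 50, seed = r)
    sum(ss$ssp >= ss$pi_thr)
  }, numeric(1))
  expect_lte(mean(hits), 1)
})
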