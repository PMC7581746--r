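test_that("truncated-linear basis arithmetic and rank", {
  B <- spline_basis(1:10, c(3, 7))
  expect_equal(unname(B[B[, "t"] == 3, "t_k1"]), 0)   # continuity at K1
  expect_equal(unname(B[B[, "t"] == 5, "t_k1"]), 2)
  expect_equal(unname(B[B[, "t"] == 5, "t_k2"]), 0)
  expect_equal(qr(B)$rank, 4)                         # >= 2 ages per segment
  expect_error(spline_basis(1:10, c(3, 12)), "outside")
  expect_error(spline_basis(1:10, c(7, 3)), "increasing")
})

test_that("noise-free spline coefficients are recovered to machine tolerance", {
  beta <- c(10, 1.5, -0.8, 0.3)
  ages <- 1:15
  y <- as.numeric(spline_basis(ages, c(4, 9)) %*% beta)
  fit <- fit_linear_spline(ages, y, c(4, 9))
  expect_equal(unname(fit$beta), beta, tolerance = 1e-12)
  expect_lt(fit$sse, 1e-20)
  expect_true(fit$full_rank)
})

test_that("spline fit equals the normal-equations solution on noisy data", {
  set.seed(77)
  ages <- 1:14
  y <- rnorm(14)
  B <- spline_basis(ages, c(5, 10))
  beta_ne <- solve(crossprod(B), crossprod(B, y))
  fit <- fit_linear_spline(ages, y, c(5, 10))
  expect_equal(unname(fit$beta), as.numeric(beta_ne), tolerance = 1e-10)
})

test_that("rank-deficient fits are flagged with unidentified coefficients", {
  ages <- 1:8                      # no point beyond K2 = 8 except boundary
  y <- rnorm(8)
  expect_message(fit <- fit_linear_spline(ages, y, c(3, 8)),
                 "rank-deficient")
  expect_false(fit$full_rank)
  expect_true(is.na(fit$beta[["beta3"]]))
})

test_that("knot selection recovers the generating pair and breaks ties low", {
  set.seed(21)
  beta <- c(5, 1, -2, 1.5)
  ages <- 1:15
  ids <- paste0("F", 1:25)
  traj <- do.call(rbind, lapply(ids, function(id) {
    b <- beta + rnorm(4, 0, 0.05)
    data.frame(id = id, cambial_age = ages,
               value = as.numeric(spline_basis(ages, c(4, 9)) %*% b) +
                 rnorm(15, 0, 0.05))
  }))
  sel <- select_knots(traj)
  expect_equal(unname(sel$knots), c(4, 9))
  # one-pair grid returns that pair
  one <- select_knots(traj, grid = data.frame(K1 = 5, K2 = 11))
  expect_equal(unname(one$knots), c(5, 11))
  # pure straight lines fit every knot pair exactly: tie resolves to the
  # smallest K1 then K2 in the grid
  lin <- data.frame(id = "F1", cambial_age = ages, value = 2 + 3 * ages)
  tie <- select_knots(lin, grid = data.frame(K1 = c(4, 3), K2 = c(9, 8)))
  expect_equal(unname(tie$knots), c(3, 8))
  expect_error(select_knots(lin, grid = data.frame(K1 = numeric(0),
                                                   K2 = numeric(0))),
               "empty")
})

test_that("SSE at the true knots is no worse than at neighbouring pairs", {
  set.seed(31)
  ages <- 1:15
  y <- as.numeric(spline_basis(ages, c(4, 9)) %*% c(5, 1, -2, 1.5)) +
    rnorm(15, 0, 0.01)
  traj <- data.frame(id = "t", cambial_age = ages, value = y)
  grid <- expand.grid(K1 = 3:5, K2 = 8:10)
  sel <- select_knots(traj, grid)
  sse <- sel$grid_sse
  expect_equal(min(sse$sse), sse$sse[sse$K1 == 4 & sse$K2 == 9])
})

test_that("MFA latents: analytic crossing, core/outer means, flags", {
  # clean exponential decay from 30 to 10, rate 0.25
  ages <- 1:15
  v <- 10 + 20 * exp(-0.25 * (ages - 1))
  m <- mfa_latents(ages, v)
  expect_true(m$crossed)
  expect_equal(m$mfa_ta, 1 + log(20 / 10) / 0.25, tolerance = 1e-4)
  expect_equal(m$mfa_core, mean(v[ages <= m$mfa_ta]), tolerance = 1e-8)
  expect_equal(m$mfa_outer, mean(v[ages > m$mfa_ta]), tolerance = 1e-8)
  expect_gt(m$mfa_core, m$mfa_outer)

  # all values below the threshold: transition at the first age
  low <- 12 + 5 * exp(-0.3 * (ages - 1))
  ml <- mfa_latents(ages, low)
  expect_true(ml$crossed)
  expect_equal(ml$mfa_ta, 1)

  # plateau above the threshold: never crosses
  high <- 25 + 8 * exp(-0.3 * (ages - 1))
  mh <- mfa_latents(ages, high)
  expect_false(mh$crossed)
  expect_true(is.na(mh$mfa_ta))
})

test_that("hand series 30,25,19,12,11 crosses between ages 2 and 3", {
  m <- mfa_latents(1:5, c(30, 25, 19, 12, 11))
  expect_true(m$crossed)
  expect_gt(m$mfa_ta, 2)
  expect_lt(m$mfa_ta, 3)
  expect_equal(m$mfa_core, mean(c(30, 25)))
  expect_equal(m$mfa_outer, mean(c(19, 12, 11)))
})

test_that("transition-age recovery is sub-ring on noise-free curves", {
  cfg <- tiny_config(seed = 61,
                     mfa = list(start = 30, plateau = 11, rate = 0.19,
                                start_sd = 2, plateau_sd = 1, rate_cv = 0.15,
                                noise_sd = 0))
  sm <- simulate_mfa_series(cfg)
  lat <- mfa_latent_table(sm$rings)
  merged <- merge(lat, sm$truth, by = "tree_id")
  ok <- merged$crossed.x & merged$crossed.y
  expect_gt(mean(ok), 0.9)
  mae <- mean(abs(merged$mfa_ta[ok] - merged$true_ta[ok]))
  expect_lt(mae, 1)
})

test_that("latent traits are recovered at the documented trajectory noise", {
  # default between-family latent spread, trajectories observed with the
  # documented within-trajectory noise (noise_sd = 0.05 trait units per ring)
  cfg <- sim_config(seed = 62)
  set.seed(62)
  n_fam <- 200
  B <- spline_basis(seq_len(cfg$n_rings), cfg$knots)
  truth <- cbind(
    beta0 = cfg$spline_means[["beta0"]] +
      rnorm(n_fam, 0, sqrt(cfg$variance_components[["family"]])),
    beta1 = cfg$spline_means[["beta1"]] +
      rnorm(n_fam, 0, cfg$latent_family_sd[["beta1"]]),
    beta2 = cfg$spline_means[["beta2"]] +
      rnorm(n_fam, 0, cfg$latent_family_sd[["beta2"]]),
    beta3 = cfg$spline_means[["beta3"]] +
      rnorm(n_fam, 0, cfg$latent_family_sd[["beta3"]]))
  traj <- do.call(rbind, lapply(seq_len(n_fam), function(k)
    data.frame(id = sprintf("F%03d", k), cambial_age = seq_len(cfg$n_rings),
               value = as.numeric(B %*% truth[k, ]) +
                 rnorm(cfg$n_rings, 0, cfg$noise_sd))))
  lat <- fit_latent_traits(traj, knots = cfg$knots)
  lat <- lat[order(lat$id), ]
  expect_gt(cor(lat$beta0, truth[, "beta0"]), 0.9)
  expect_gt(cor(lat$beta1, truth[, "beta1"]), 0.9)
})

test_that("pipeline refinement preserves family latent ranking", {
  cfg <- sim_config(n_families = 80, seed = 63)
  st <- simulate_study(cfg)
  ref <- refine_trajectories(st$pheno$rings, st$design)
  tr <- ref$trajectories
  lat <- fit_latent_traits(data.frame(id = tr$family,
                                      cambial_age = tr$cambial_age,
                                      value = tr$value),
                           knots = cfg$knots)
  truth <- st$pheno$latent_true
  truth$family <- st$design$family[match(truth$tree_id, st$design$tree_id)]
  fam_truth <- aggregate(truth[paste0("beta", 0:3)],
                         by = list(family = truth$family), mean)
  m <- merge(lat, fam_truth, by.x = "id", by.y = "family")
  # field noise (residual + site-by-family) and age-varying BLUP shrinkage
  # attenuate the correlation; the ranking must still be clearly preserved
  expect_gt(cor(m$beta0.x, m$beta0.y), 0.4)
  expect_gt(cor(m$beta1.x, m$beta1.y), 0.55)
})
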