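test_that("simulation is byte-identical under a fixed seed", {
  cfg <- tiny_config(seed = 42)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$geno$codes, s2$geno$codes)
  expect_identical(s1$design, s2$design)
  expect_identical(s1$pheno$rings, s2$pheno$rings)
  expect_identical(s1$mfa$rings, s2$mfa$rings)
  s3 <- simulate_study(tiny_config(seed = 43))
  expect_false(identical(s1$geno$codes, s3$geno$codes))
})

test_that("genotype frequencies follow Hardy-Weinberg at fixed frequency", {
  cfg <- sim_config(n_families = 800, trees_per_family = 2, n_sites = 1,
                    n_markers = 40, maf_range = c(0.5, 0.5), n_qtl = 1,
                    missing_rate = 0, seed = 7)
  geno <- simulate_genotypes(cfg)
  n <- length(geno$codes)
  freq <- tabulate(as.vector(geno$codes) + 1L, 3) / n
  # half-sib sampling inflates the MC error over iid draws; 3 SE with a
  # conservative design-effect factor of 2
  se <- 2 * sqrt(c(.25 * .75, .5 * .5, .25 * .75) / n)
  expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < 3 * se))
})

test_that("marginal MAFs track the drawn allele frequencies", {
  cfg <- sim_config(n_families = 150, trees_per_family = 4, n_sites = 1,
                    n_markers = 200, n_qtl = 1, missing_rate = 0, seed = 3)
  geno <- simulate_genotypes(cfg)
  q <- attr(geno, "allele_freq")
  maf <- geno$marker_meta$maf
  # folded frequencies: compare against min(q, 1-q)
  expect_true(cor(maf, pmin(q, 1 - q)) > 0.98)
  expect_true(max(abs(maf - pmin(q, 1 - q))) < 0.1)
})

test_that("missing_rate = 0 gives complete genotypes, > 0 roughly the rate", {
  cfg0 <- tiny_config(seed = 5, missing_rate = 0)
  expect_false(anyNA(simulate_genotypes(cfg0)$codes))
  cfg1 <- tiny_config(seed = 5, missing_rate = 0.1)
  g1 <- simulate_genotypes(cfg1)
  expect_gt(mean(is.na(g1$codes)), 0.07)
  expect_lt(mean(is.na(g1$codes)), 0.13)
})

test_that("n_qtl > n_markers is a configuration error", {
  expect_error(sim_config(n_markers = 5, n_qtl = 10), "n_qtl")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(knots = c(9, 4)), "K1 < K2")
})

test_that("noise-free, effect-free phenotypes equal the population spline", {
  cfg <- tiny_config(
    seed = 2, missing_rate = 0, noise_sd = 0,
    qtl_effects = data.frame(trait = "beta0", a = 0, d = 0),
    variance_components = c(family = 0, site_family = 0, residual = 0),
    site_effects = c(0, 0), block_effects = c(0, 0),
    latent_family_sd = c(beta1 = 0, beta2 = 0, beta3 = 0))
  st <- simulate_study(cfg)
  B <- spline_basis(seq_len(cfg$n_rings), cfg$knots)
  expected <- as.numeric(B %*% cfg$spline_means)
  one_tree <- st$pheno$rings[st$pheno$rings$tree_id == st$design$tree_id[1], ]
  expect_equal(one_tree$value[order(one_tree$cambial_age)], expected,
               tolerance = 1e-12)
  # below the first knot, consecutive differences equal beta1 exactly
  d1 <- diff(expected[seq_len(cfg$knots[1])])
  expect_equal(d1, rep(cfg$spline_means[["beta1"]], cfg$knots[1] - 1),
               tolerance = 1e-12)
})

test_that("a single additive QTL shifts homozygote latent means by 2a", {
  cfg <- sim_config(n_families = 600, trees_per_family = 2, n_sites = 1,
                    n_markers = 20, n_qtl = 1, maf_range = c(0.4, 0.5),
                    qtl_effects = data.frame(trait = "beta0", a = 0.5, d = 0),
                    variance_components = c(family = 0.005,
                                            site_family = 0, residual = 0.1),
                    latent_family_sd = c(beta1 = 0, beta2 = 0, beta3 = 0),
                    missing_rate = 0, seed = 9)
  design <- simulate_design(cfg)
  geno <- simulate_genotypes(cfg, design)
  ph <- simulate_phenotypes(cfg, geno, design)
  x <- geno$codes[ph$latent_true$tree_id,
                  match(ph$qtl$marker_id, geno$marker_meta$marker_id)]
  b0 <- ph$latent_true$beta0
  gap <- mean(b0[x == 2]) - mean(b0[x == 0])
  expect_equal(gap, 2 * 0.5, tolerance = 0.05)
})

test_that("ring-value variance decomposition matches the configured components", {
  vc <- c(family = 0.06, site_family = 0.03, residual = 0.15)
  cfg <- sim_config(n_families = 400, trees_per_family = 4, n_sites = 2,
                    n_blocks_per_site = 1, n_markers = 10, n_qtl = 1,
                    qtl_effects = data.frame(trait = "beta0", a = 0, d = 0),
                    variance_components = vc, site_effects = c(0, 0),
                    block_effects = 0, noise_sd = 0,
                    latent_family_sd = c(beta1 = 0, beta2 = 0, beta3 = 0),
                    missing_rate = 0, seed = 21)
  st <- simulate_study(cfg)
  sub <- st$pheno$rings[st$pheno$rings$cambial_age == 1, ]
  d <- st$design[match(sub$tree_id, st$design$tree_id), ]
  # moment (ANOVA) decomposition on the balanced design:
  #   Var(cell mean)   = sF2 + sSF2 + se2/r
  #   Var(family mean) = sF2 + sSF2/S + se2/(S r)
  r <- cfg$trees_per_family
  S <- cfg$n_sites
  cell <- paste(d$site, d$family)
  se2_hat <- mean(tapply(sub$value, cell, var))
  v_cell <- var(tapply(sub$value, cell, mean))
  v_fam <- var(tapply(sub$value, d$family, mean))
  ssf2_hat <- (v_cell - v_fam) / (1 - 1 / S) - se2_hat / r
  sf2_hat <- v_fam - ssf2_hat / S - se2_hat / (S * r)
  expect_equal(se2_hat, vc[["residual"]], tolerance = 0.1)
  expect_equal(ssf2_hat, vc[["site_family"]], tolerance = 0.45)
  expect_equal(sf2_hat, vc[["family"]], tolerance = 0.3)
})

test_that("MFA curves cross the threshold at the analytic age", {
  cfg <- tiny_config(seed = 4,
                     mfa = list(start = 30, plateau = 10, rate = 0.2,
                                start_sd = 0, plateau_sd = 0, rate_cv = 0,
                                noise_sd = 0))
  sm <- simulate_mfa_series(cfg)
  expected_ta <- 1 + log((30 - 10) / (20 - 10)) / 0.2
  expect_true(all(abs(sm$truth$true_ta - expected_ta) < 1e-10))
  expect_true(all(sm$truth$crossed))
  # population defaults: mean pith value near 30 degrees
  sm2 <- simulate_mfa_series(tiny_config(seed = 6))
  pith <- sm2$rings$value[sm2$rings$cambial_age == 1]
  expect_equal(mean(pith), 30, tolerance = 1)
})

test_that("a plateau above the threshold is flagged as not crossing", {
  cfg <- tiny_config(seed = 8,
                     mfa = list(start = 30, plateau = 25, rate = 0.2,
                                start_sd = 0, plateau_sd = 0, rate_cv = 0,
                                noise_sd = 0))
  sm <- simulate_mfa_series(cfg)
  expect_true(all(!sm$truth$crossed))
  expect_true(all(is.na(sm$truth$true_ta)))
})
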