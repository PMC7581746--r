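#' Configuration for the synthetic half-sib trial generator
#'
#' Defines the conditions the generator emulates: an open-pollinated
#' (half-sib) progeny trial replicated on two sites with randomized blocks,
#' genotyped mothers' offspring scored for ring-resolved tracheid traits over
#' 10--20 cambial ages, and a sparse QTL architecture acting on the latent
#' (spline-coefficient) traits.
#'
#' @param n_families Number of half-sib families (mother trees).
#' @param trees_per_family Offspring per family *per site*.
#' @param n_sites Number of field sites.
#' @param n_blocks_per_site Randomized blocks within each site.
#' @param n_markers Number of bi-allelic SNP markers.
#' @param maf_range Allele-frequency range (pair in `(0, 0.5]`) from which
#'   each marker's alternate-allele frequency is drawn uniformly.
#' @param n_qtl Number of causal markers.
#' @param qtl_effects Data frame with one row per QTL and columns `trait`
#'   (one of `"beta0".."beta3"`), `a` (additive effect: half the difference
#'   between homozygote means, trait units) and `d` (dominance deviation).
#'   Rows are recycled to `n_qtl`. The default plants additive QTLs on the
#'   spline intercept, each explaining on the order of 2% of latent variance.
#' @param variance_components Named vector `c(family=, site_family=,
#'   residual=)` of variances for the family, site-by-family and residual
#'   random effects on the ring values (trait units squared).
#' @param site_effects Fixed site effects, length `n_sites` (trait units).
#' @param block_effects Fixed block effects, length `n_blocks_per_site`,
#'   reused across sites (trait units).
#' @param n_rings Number of annual rings (cambial ages `1..n_rings`).
#' @param knots Pair `(K1, K2)` of cambial ages where the population spline
#'   changes slope; `K1 < K2 < n_rings`.
#' @param spline_means Named vector `c(beta0=, beta1=, beta2=, beta3=)` of
#'   population-mean spline coefficients.
#' @param latent_family_sd Extra between-family SDs for the slope
#'   coefficients `beta1..beta3` (trajectory-shape heredity); the intercept's
#'   family variance is `variance_components["family"]`.
#' @param noise_sd Within-trajectory measurement noise SD (trait units).
#' @param missing_rate Fraction of genotype calls set missing at random.
#' @param subpop_delta Allele-frequency offset between two equal halves of
#'   the families (0 = panmictic); a minimal structure scenario used to
#'   exercise principal-component correction.
#' @param mfa Named list of microfibril-angle curve parameters: `start`
#'   (population-mean pith MFA, degrees), `plateau` (mature-wood MFA),
#'   `rate` (exponential decay rate per ring), `start_sd`, `plateau_sd`
#'   (between-tree SDs), `rate_cv` (lognormal CV of the rate) and `noise_sd`
#'   (per-ring measurement noise, degrees).
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#'
#' @details Default scale (200 families of 6 trees on each of 2 sites,
#'   2,000 markers, 10 QTLs) is a desk-scale rendition of a two-trial spruce
#'   progeny test. Default variance components give a ring-level
#'   narrow-sense heritability near 0.4 under the half-sib convention
#'   \eqn{h^2 = 4\sigma^2_F/\sigma^2_P}. The default MFA curve starts near
#'   30 degrees at the pith and settles at 10--12 degrees around cambial age
#'   10, so the 20-degree transition age falls near 5 years.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_families = 200, trees_per_family = 6, n_sites = 2,
                       n_blocks_per_site = 4, n_markers = 2000,
                       maf_range = c(0.1, 0.5), n_qtl = 10,
                       qtl_effects = data.frame(trait = "beta0",
                                                a = 0.03, d = 0),
                       variance_components = c(family = 0.02,
                                               site_family = 0.01,
                                               residual = 0.17),
                       site_effects = seq(0, by = 0.3,
                                          length.out = n_sites),
                       block_effects = seq(0, by = 0.1,
                                           length.out = n_blocks_per_site),
                       n_rings = 15, knots = c(4, 9),
                       spline_means = c(beta0 = 2.0, beta1 = 0.15,
                                        beta2 = -0.08, beta3 = 0.03),
                       latent_family_sd = c(beta1 = 0.05, beta2 = 0.04,
                                            beta3 = 0.03),
                       noise_sd = 0.05, missing_rate = 0.02,
                       subpop_delta = 0,
                       mfa = list(start = 30, plateau = 11, rate = 0.19,
                                  start_sd = 2, plateau_sd = 1,
                                  rate_cv = 0.15, noise_sd = 1),
                       seed = 1) {
  counts <- c(n_families = n_families, trees_per_family = trees_per_family,
              n_sites = n_sites, n_blocks_per_site = n_blocks_per_site,
              n_markers = n_markers, n_rings = n_rings)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("maf_range must lie within (0, 0.5]")
  if (n_qtl > n_markers) stop("n_qtl exceeds n_markers")
  if (!(knots[1] < knots[2] && knots[2] < n_rings))
    stop("need K1 < K2 < n_rings")
  if (any(variance_components < 0)) stop("variance components must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate in [0,1)")
  qtl_effects <- qtl_effects[rep_len(seq_len(nrow(qtl_effects)), n_qtl), ,
                             drop = FALSE]
  if (!all(qtl_effects$trait %in% paste0("beta", 0:3)))
    stop("QTL trait must be one of beta0..beta3")
  cfg <- list(n_families = n_families, trees_per_family = trees_per_family,
              n_sites = n_sites, n_blocks_per_site = n_blocks_per_site,
              n_markers = n_markers, maf_range = maf_range, n_qtl = n_qtl,
              qtl_effects = qtl_effects,
              variance_components = variance_components,
              site_effects = site_effects, block_effects = block_effects,
              n_rings = n_rings, knots = knots, spline_means = spline_means,
              latent_family_sd = latent_family_sd, noise_sd = noise_sd,
              missing_rate = missing_rate, subpop_delta = subpop_delta,
              mfa = mfa, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

n_trees <- function(cfg)
  cfg$n_families * cfg$trees_per_family * cfg$n_sites

#' Simulate the field design (tree -> site, block, family)
#'
#' Every family contributes `trees_per_family` trees on every site; each
#' tree is assigned a random block within its site. Block labels are
#' site-nested (`S1_B2`).
#'
#' @param cfg A [sim_config()].
#' @return Data frame with columns `tree_id`, `site`, `block`, `family`.
#' @export
simulate_design <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  site <- rep(paste0("S", seq_len(cfg$n_sites)),
              each = cfg$n_families * cfg$trees_per_family)
  family <- rep(rep(sprintf("F%03d", seq_len(cfg$n_families)),
                    each = cfg$trees_per_family), cfg$n_sites)
  block_no <- sample(cfg$n_blocks_per_site, n_trees(cfg), replace = TRUE)
  data.frame(tree_id = sprintf("T%05d", seq_len(n_trees(cfg))),
             site = site,
             block = paste0(site, "_B", block_no),
             family = family, stringsAsFactors = FALSE)
}

#' Simulate half-sib genotypes
#'
#' Per marker, an alternate-allele frequency is drawn uniformly from
#' `maf_range`. Each family's mother genotype is drawn under Hardy-Weinberg
#' at that frequency; every offspring inherits one maternal allele at random
#' and one pollen allele drawn from the population frequency (open
#' pollination). Codes: 0 = AA, 1 = AB, 2 = BB; missing calls (`NA`) are
#' injected completely at random at `missing_rate`. With `subpop_delta > 0`
#' the first and second halves of the families use frequencies shifted by
#' `-delta/2` and `+delta/2`.
#'
#' @param cfg A [sim_config()].
#' @param design Optional design table (defaults to [simulate_design()]);
#'   only the `tree_id`/`family` columns are used.
#' @return A [genotype_matrix()] with an attribute `"allele_freq"` holding
#'   the drawn per-marker frequencies.
#' @export
simulate_genotypes <- function(cfg, design = simulate_design(cfg)) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  p <- cfg$n_markers
  q <- runif(p, cfg$maf_range[1], cfg$maf_range[2])
  fams <- unique(design$family)
  K <- length(fams)
  half <- rep(c(-0.5, 0.5), c(ceiling(K / 2), floor(K / 2)))
  n <- nrow(design)
  fam_idx <- match(design$family, fams)
  codes <- matrix(NA_integer_, n, p)
  for (j in seq_len(p)) {
    qk <- pmin(pmax(q[j] + half * cfg$subpop_delta, 0.01), 0.99)
    mother <- rbinom(K, 2L, qk)                      # per-family HW mother
    m <- mother[fam_idx]
    maternal <- ifelse(m == 0L, 0L,
                       ifelse(m == 2L, 1L, rbinom(n, 1L, 0.5)))
    pollen <- rbinom(n, 1L, qk[fam_idx])
    codes[, j] <- maternal + pollen
  }
  complete <- codes
  if (cfg$missing_rate > 0) {
    miss <- runif(n * p) < cfg$missing_rate
    codes[miss] <- NA_integer_
  }
  rownames(codes) <- design$tree_id
  rownames(complete) <- design$tree_id
  geno <- genotype_matrix(codes,
                          contig = sprintf("MA_%06d", seq_len(p)),
                          pos = rep(1000L, p),
                          ref = rep("A", p), alt = rep("G", p))
  attr(geno, "allele_freq") <- q
  attr(geno, "complete_codes") <- complete  # pre-missingness truth
  geno
}

qtl_contributions <- function(cfg, geno, qtl_markers) {
  # per-tree additive + dominance contribution of each QTL to its latent
  # trait; the truth uses the underlying genotypes before missingness
  full <- attr(geno, "complete_codes")
  if (is.null(full)) full <- geno$codes
  contrib <- matrix(0, nrow(geno$codes), 4,
                    dimnames = list(rownames(geno$codes), paste0("beta", 0:3)))
  for (i in seq_along(qtl_markers)) {
    x <- full[, qtl_markers[i]]
    x[is.na(x)] <- 1L
    tr <- cfg$qtl_effects$trait[i]
    contrib[, tr] <- contrib[, tr] +
      cfg$qtl_effects$a[i] * (x - 1) + cfg$qtl_effects$d[i] * (x == 1)
  }
  contrib
}

#' Simulate ring-resolved phenotypes from a spline forward model
#'
#' Each tree's true latent traits are the population-mean spline
#' coefficients plus its QTL contributions plus family deviations (intercept
#' deviation ~ N(0, sigma2_family); slope deviations with SDs
#' `latent_family_sd`). The ring value at cambial age `t` is the tree's
#' spline evaluated at `t` plus fixed site and block effects, a
#' site-by-family deviation, a per-observation residual, and measurement
#' noise.
#'
#' @param cfg A [sim_config()].
#' @param geno [genotype_matrix()] covering the design's trees.
#' @param design Design table from [simulate_design()].
#' @param trait Trait label written into the output (default `"WT_Ring"`).
#' @return List with `rings` (data.frame `tree_id`, `trait`, `cambial_age`,
#'   `value`), `latent_true` (per-tree true `beta0..beta3`), and `qtl`
#'   (data.frame `marker_id`, `trait`, `a`, `d`).
#' @export
simulate_phenotypes <- function(cfg, geno, design, trait = "WT_Ring") {
  stopifnot(inherits(cfg, "sim_config"), inherits(geno, "genotype_matrix"))
  if (!setequal(rownames(geno$codes), design$tree_id))
    stop("genotypes and design must cover the same trees")
  set.seed(cfg$seed + 3L)
  n <- nrow(design)
  fams <- unique(design$family)
  K <- length(fams)
  vc <- cfg$variance_components

  qtl_markers <- sort(sample(cfg$n_markers, cfg$n_qtl))
  contrib <- qtl_contributions(cfg, geno, qtl_markers)
  contrib <- contrib[design$tree_id, , drop = FALSE]

  fam_dev <- cbind(beta0 = rnorm(K, 0, sqrt(vc[["family"]])),
                   beta1 = rnorm(K, 0, cfg$latent_family_sd[["beta1"]]),
                   beta2 = rnorm(K, 0, cfg$latent_family_sd[["beta2"]]),
                   beta3 = rnorm(K, 0, cfg$latent_family_sd[["beta3"]]))
  fam_idx <- match(design$family, fams)
  latent <- matrix(rep(cfg$spline_means, each = n), n, 4,
                   dimnames = list(design$tree_id, paste0("beta", 0:3)))
  latent <- latent + contrib + fam_dev[fam_idx, , drop = FALSE]

  ages <- seq_len(cfg$n_rings)
  B <- spline_basis(ages, cfg$knots)           # n_rings x 4
  traj <- latent %*% t(B)                      # n x n_rings, genetic signal

  site_idx <- match(design$site, paste0("S", seq_len(cfg$n_sites)))
  block_no <- as.integer(sub(".*_B", "", design$block))
  fixed <- cfg$site_effects[site_idx] + cfg$block_effects[block_no]

  sf_key <- paste(design$site, design$family)
  sf_levels <- unique(sf_key)
  sf_dev <- rnorm(length(sf_levels), 0, sqrt(vc[["site_family"]]))
  sf <- sf_dev[match(sf_key, sf_levels)]

  values <- traj + fixed + sf +
    matrix(rnorm(n * cfg$n_rings, 0, sqrt(vc[["residual"]])), n) +
    matrix(rnorm(n * cfg$n_rings, 0, cfg$noise_sd), n)

  rings <- data.frame(
    tree_id = rep(design$tree_id, times = cfg$n_rings),
    trait = trait,
    cambial_age = rep(ages, each = n),
    value = as.vector(values), stringsAsFactors = FALSE)
  latent_true <- data.frame(tree_id = design$tree_id, latent,
                            stringsAsFactors = FALSE, row.names = NULL)
  qtl <- data.frame(marker_id = geno$marker_meta$marker_id[qtl_markers],
                    trait = cfg$qtl_effects$trait,
                    a = cfg$qtl_effects$a, d = cfg$qtl_effects$d,
                    stringsAsFactors = FALSE)
  list(rings = rings, latent_true = latent_true, qtl = qtl)
}

#' Simulate microfibril-angle (MFA) ring series
#'
#' Per tree, MFA declines from a pith value near 30 degrees to a mature-wood
#' plateau of 10--12 degrees as `plateau + (start - plateau) *
#' exp(-rate * (age - 1))`, with per-tree random start, plateau and decay
#' rate plus per-ring noise. The true age at which each tree's noise-free
#' curve crosses the 20-degree level is returned for recovery tests
#' (`NA` when the curve never reaches 20 degrees within the ring range).
#'
#' @param cfg A [sim_config()].
#' @param design Optional design table; defaults to [simulate_design()].
#' @param threshold Crossing level in degrees (default 20).
#' @return List with `rings` (data.frame as in [simulate_phenotypes()], trait
#'   `"MFA_Ring"`) and `truth` (per-tree `start`, `plateau`, `rate`,
#'   `true_ta`, `crossed`).
#' @export
simulate_mfa_series <- function(cfg, design = simulate_design(cfg),
                                threshold = 20) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 4L)
  m <- cfg$mfa
  n <- nrow(design)
  start <- rnorm(n, m$start, m$start_sd)
  plateau <- rnorm(n, m$plateau, m$plateau_sd)
  rate <- m$rate * exp(rnorm(n, 0, m$rate_cv))
  ages <- seq_len(cfg$n_rings)
  curve <- sapply(ages, function(t)
    plateau + (start - plateau) * exp(-rate * (t - 1)))
  values <- curve + matrix(rnorm(n * cfg$n_rings, 0, m$noise_sd), n)
  true_ta <- decay_crossing_age(start, plateau, rate, threshold)
  crossed <- !is.na(true_ta) & true_ta <= cfg$n_rings
  true_ta[!crossed] <- NA_real_
  rings <- data.frame(
    tree_id = rep(design$tree_id, times = cfg$n_rings),
    trait = "MFA_Ring",
    cambial_age = rep(ages, each = n),
    value = as.vector(values), stringsAsFactors = FALSE)
  truth <- data.frame(tree_id = design$tree_id, start = start,
                      plateau = plateau, rate = rate, true_ta = true_ta,
                      crossed = crossed, stringsAsFactors = FALSE)
  list(rings = rings, truth = truth)
}

# Age at which plateau + (start-plateau) exp(-rate (t-1)) hits `level`;
# NA when the curve never reaches it (plateau >= level), the first age when
# it starts at or below the level.
decay_crossing_age <- function(start, plateau, rate, level) {
  ta <- rep(NA_real_, length(start))
  below_at_start <- start <= level
  ta[below_at_start] <- 1
  ok <- !below_at_start & plateau < level
  ta[ok] <- 1 + log((start[ok] - plateau[ok]) / (level - plateau[ok])) /
    rate[ok]
  ta
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: design, genotypes, a spline-trait ring series and an
#' MFA ring series under one configuration and seed.
#'
#' @param cfg A [sim_config()].
#' @return List `design`, `geno`, `pheno` (see [simulate_phenotypes()]),
#'   `mfa` (see [simulate_mfa_series()]).
#' @export
simulate_study <- function(cfg = sim_config()) {
  design <- simulate_design(cfg)
  geno <- simulate_genotypes(cfg, design)
  pheno <- simulate_phenotypes(cfg, geno, design)
  mfa <- simulate_mfa_series(cfg, design)
  list(design = design, geno = geno, pheno = pheno, mfa = mfa)
}
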