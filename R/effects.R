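#' Adaptive-LASSO effects and variance explained
#'
#' Re-estimates the effects of the stability-selected markers with an
#' adaptive LASSO: initial estimates from OLS (ridge when the selected set
#' is large relative to `n`) give per-marker weights `w_j =
#' 1/|beta_init_j|^gamma`; the weighted-L1 fit's penalty is chosen by
#' k-fold cross-validation. The data-adaptive weights shrink strong effects
#' less than the plain LASSO, countering its tendency to under-estimate the
#' variance a QTL explains. Each marker's contribution is reported as
#' `PVE_j = Var(x_j alpha_j) / Var(y) * 100`.
#'
#' @param y Latent-trait response.
#' @param X_selected Marker matrix restricted to the selected markers.
#' @param C Optional unpenalised covariates.
#' @param gamma Weight exponent (default 1).
#' @param nfolds Cross-validation folds (default 5).
#' @param n_lambda Penalty grid size (default 50).
#' @param weight_cap Cap on adaptive weights when an initial estimate is
#'   ~ 0 (default 1e6).
#' @param seed Seed for the fold split.
#' @return List of class `adaptive_lasso_fit`: `effects` (data.frame
#'   `marker_id`, `effect`, `pve_percent`), `lambda_cv`, `weights`,
#'   `total_pve_percent`.
#' @export
adaptive_lasso_pve <- function(y, X_selected, C = NULL, gamma = 1,
                               nfolds = 5, n_lambda = 50, weight_cap = 1e6,
                               seed = 1) {
  X <- as.matrix(X_selected)
  n <- length(y)
  p <- ncol(X)
  if (p < 1) stop("selected set is empty")
  r <- residualize_on(y, X, C)
  st <- standardize_cols(r$X)
  Xs <- st$X
  ys <- r$y
  ps <- ncol(Xs)

  beta_init <- if (ps < n / 2) {
    lm.fit(cbind(1, Xs), ys)$coefficients[-1]
  } else {
    lam_r <- 0.1 * ps / n
    as.numeric(solve(crossprod(Xs) / n + diag(lam_r, ps),
                     crossprod(Xs, ys) / n))
  }
  w <- pmin(1 / (abs(beta_init)^gamma), weight_cap)
  Xw <- sweep(Xs, 2, w, `/`)

  lam_max <- max(abs(crossprod(Xw, ys))) / n
  lambdas <- lam_max * exp(seq(0, log(1e-4), length.out = n_lambda))
  set.seed(as.integer(seed))
  fold <- sample(rep_len(seq_len(nfolds), n))
  cv_err <- matrix(NA_real_, nfolds, n_lambda)
  for (f in seq_len(nfolds)) {
    tr <- fold != f
    beta <- numeric(ncol(Xw))
    for (l in seq_along(lambdas)) {
      fit <- .cd_lasso(Xw[tr, , drop = FALSE], ys[tr], lambdas[l],
                       rep(1, ncol(Xw)), beta, 1e-6, 20000)
      beta <- fit$beta
      pred <- Xw[!tr, , drop = FALSE] %*% beta
      cv_err[f, l] <- mean((ys[!tr] - pred)^2)
    }
  }
  lambda_cv <- lambdas[which.min(colMeans(cv_err))]
  fit <- .cd_lasso(Xw, ys, lambda_cv, rep(1, ncol(Xw)),
                   numeric(ncol(Xw)), 1e-8, 100000)
  alpha_std <- fit$beta / w              # back to standardized-X scale
  alpha <- numeric(p)
  alpha[st$ok] <- alpha_std / st$scale[st$ok]   # original 0/1/2 scale

  var_y <- var(y)
  pve <- vapply(seq_len(p), function(j) {
    100 * var(X[, j] * alpha[j]) / var_y
  }, numeric(1))
  effects <- data.frame(marker_id = colnames(X) %||% paste0("m", seq_len(p)),
                        effect = alpha, pve_percent = pve,
                        stringsAsFactors = FALSE)
  structure(list(effects = effects, lambda_cv = lambda_cv, weights = w,
                 total_pve_percent = sum(pve)),
            class = "adaptive_lasso_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_association_frame <- function() {
  data.frame(trait = character(0), marker_id = character(0),
             ssp = numeric(0), effect = numeric(0),
             pve_percent = numeric(0), G_AA = numeric(0), G_AB = numeric(0),
             G_BB = numeric(0), two_a = numeric(0), d = numeric(0),
             d_over_a = numeric(0), mode = character(0),
             kw_statistic = numeric(0), kw_pvalue = numeric(0),
             stringsAsFactors = FALSE)
}

#' Genotype-class means and mode of gene action
#'
#' Computes, for one marker, the trait means of the three genotype classes
#' and the classical gene-action parameters: homozygote difference
#' `2a = |G_BB - G_AA|`, dominance deviation `d = G_AB - (G_BB + G_AA)/2`,
#' and their ratio `d/a`. Modes: `|d/a| <= 0.5` additive, `0.5 < |d/a| <
#' 1.25` partial-to-full dominant, `|d/a| >= 1.25` over-dominant (boundaries
#' resolve to the lower-named class). The sign of `d/a` follows the VCF
#' ref/alt orientation of the codes; its magnitude does not.
#'
#' @param y Trait values.
#' @param codes Genotype codes 0/1/2 (`NA` allowed, dropped).
#' @return List of class `gene_action`: `class_means` (named `G_AA`,
#'   `G_AB`, `G_BB`), `two_a`, `d`, `a`, `d_over_a`, `mode`. `d` (and the
#'   ratio/mode) are `NA` when the heterozygote class is empty; the ratio is
#'   `NA` when `a = 0`.
#' @export
gene_action <- function(y, codes) {
  stopifnot(length(y) == length(codes))
  ok <- !is.na(codes) & !is.na(y)
  y <- y[ok]
  codes <- codes[ok]
  m <- vapply(0:2, function(g) if (any(codes == g)) mean(y[codes == g])
              else NA_real_, numeric(1))
  names(m) <- c("G_AA", "G_AB", "G_BB")
  if (is.na(m["G_AA"]) || is.na(m["G_BB"]))
    stop("both homozygote classes must be observed")
  two_a <- abs(m[["G_BB"]] - m[["G_AA"]])
  a <- two_a / 2
  d <- if (is.na(m["G_AB"])) NA_real_ else
    m[["G_AB"]] - 0.5 * (m[["G_BB"]] + m[["G_AA"]])
  d_over_a <- if (is.na(d) || a == 0) NA_real_ else d / a
  structure(list(class_means = m, two_a = two_a, d = d, a = a,
                 d_over_a = d_over_a, mode = mode_of_action(d_over_a)),
            class = "gene_action")
}

#' Classify gene action from the dominance/additivity ratio
#'
#' @param d_over_a Signed ratio `d/a` (scalar or vector; `NA` propagates).
#' @return Character: `"additive"` (`|d/a| <= 0.5`), `"partial-to-full
#'   dominant"` (`0.5 < |d/a| < 1.25`) or `"over-dominant"` (`>= 1.25`).
#' @export
mode_of_action <- function(d_over_a) {
  r <- abs(d_over_a)
  out <- ifelse(r <= 0.5, "additive",
                ifelse(r < 1.25, "partial-to-full dominant",
                       "over-dominant"))
  out[is.na(r)] <- NA_character_
  out
}

#' Kruskal-Wallis test across genotype classes
#'
#' Rank-based H test (with tie correction, chi-square approximation on
#' `classes - 1` degrees of freedom) of whether the trait distribution
#' differs among the genotype classes of one marker, as used to annotate
#' per-marker genotype-class box plots.
#'
#' @param y Trait values.
#' @param codes Genotype codes 0/1/2 (`NA` dropped).
#' @return List: `statistic` (H), `p_value`, `df`.
#' @export
kw_genotype_test <- function(y, codes) {
  ok <- !is.na(codes) & !is.na(y)
  y <- y[ok]
  g <- factor(codes[ok])
  if (nlevels(g) < 2) stop("need >= 2 non-empty genotype classes")
  if (length(unique(y)) == 1)           # all tied: no evidence, H = 0
    return(list(statistic = 0, p_value = 1, df = nlevels(g) - 1L))
  kt <- kruskal.test(y, g)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}

#' Characterise significant markers (association records)
#'
#' For each stability-selected marker: inclusion frequency, adaptive-LASSO
#' effect and PVE (joint fit over the selected set), genotype-class means,
#' `2a`, `d`, `d/a`, gene-action mode and the Kruskal-Wallis class test.
#'
#' @param y Latent-trait response used in the association scan.
#' @param geno Imputed [genotype_matrix()] (rows aligned with `y`); class
#'   means use the original (un-imputed) calls when a `missing_mask` is
#'   present.
#' @param stability A `stability_result` from [stability_selection()].
#' @param C Optional covariates (passed to [adaptive_lasso_pve()]).
#' @param trait Trait label for the output table.
#' @param ... Passed to [adaptive_lasso_pve()].
#' @return Data frame, one row per selected marker: `trait`, `marker_id`,
#'   `ssp`, `effect`, `pve_percent`, `G_AA`, `G_AB`, `G_BB`, `two_a`, `d`,
#'   `d_over_a`, `mode`, `kw_statistic`, `kw_pvalue`. Zero selected markers
#'   give a zero-row frame.
#' @export
characterize_associations <- function(y, geno, stability, C = NULL,
                                      trait = "trait", ...) {
  stopifnot(inherits(geno, "genotype_matrix"),
            inherits(stability, "stability_result"))
  sel <- stability$selected
  if (!length(sel)) return(empty_association_frame())
  Xsel <- geno$codes[, sel, drop = FALSE]
  al <- adaptive_lasso_pve(y, Xsel, C = C, ...)
  raw <- geno$codes
  if (!is.null(geno$missing_mask)) raw[geno$missing_mask] <- NA
  raw <- round(raw)                     # class membership from called codes
  na_ga <- list(class_means = c(G_AA = NA_real_, G_AB = NA_real_,
                                G_BB = NA_real_),
                two_a = NA_real_, d = NA_real_, d_over_a = NA_real_,
                mode = NA_character_)
  rows <- lapply(seq_along(sel), function(i) {
    codes <- raw[, sel[i]]
    # a missing homozygote class (possible for aggregated genotypes) leaves
    # the gene-action fields empty instead of failing the whole table
    ga <- tryCatch(gene_action(y, codes), error = function(e) na_ga)
    kw <- tryCatch(kw_genotype_test(y, codes),
                   error = function(e) list(statistic = NA_real_,
                                            p_value = NA_real_))
    data.frame(trait = trait, marker_id = sel[i],
               ssp = unname(stability$ssp[sel[i]]),
               effect = al$effects$effect[i],
               pve_percent = al$effects$pve_percent[i],
               G_AA = ga$class_means[["G_AA"]],
               G_AB = ga$class_means[["G_AB"]],
               G_BB = ga$class_means[["G_BB"]],
               two_a = ga$two_a, d = ga$d, d_over_a = ga$d_over_a,
               mode = ga$mode, kw_statistic = kw$statistic,
               kw_pvalue = kw$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Published spruce tracheid association catalogue
#'
#' The catalogue of 30 reported marker-trait associations for Norway spruce
#' tracheid traits (trait, marker, annotation, alleles, inclusion frequency,
#' PVE, `2a`, `d`, `d/a`), shipped as a plain-text fixture. Used for worked
#' examples of the gene-action arithmetic: recomputing `d/a` from the
#' printed `2a` and `d` columns reproduces the printed ratio (at 3 decimals)
#' for the rows where the printed precision permits.
#'
#' @return Data frame with columns `trait`, `marker_id`, `region`,
#'   `alleles`, `inclusion_frequency`, `pve_percent`, `two_a`, `d`,
#'   `d_over_a`.
#' @export
tracheid_associations <- function() {
  path <- system.file("extdata", "tracheid_associations.tsv",
                      package = "tracheidGWAS", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
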