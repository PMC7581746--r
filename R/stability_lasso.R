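#' Principal-component population-structure covariates
#'
#' Top-`k` principal components of the column-centred (imputed) genotype
#' matrix, the standard correction for population stratification in
#' association models. Sign convention: within each component the loading of
#' largest magnitude is positive, so results are deterministic.
#'
#' @param geno An imputed [genotype_matrix()] (no missing calls) or a
#'   complete numeric matrix.
#' @param k Number of components (default 5); `k = 0` returns a zero-column
#'   matrix (intercept-only covariates).
#' @return Numeric score matrix, `n x k`, columns `PC1..PCk`.
#' @export
genotype_pcs <- function(geno, k = 5) {
  X <- if (inherits(geno, "genotype_matrix")) geno$codes else as.matrix(geno)
  if (anyNA(X)) stop("genotype matrix must be imputed (no missing calls)")
  n <- nrow(X)
  if (k == 0) {
    out <- matrix(numeric(0), n, 0)
    rownames(out) <- rownames(X)
    return(out)
  }
  if (k >= min(dim(X))) stop("k must be < min(n, p)")
  pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = k)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, `*`)
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(X)
  scores
}

# Residualize y and the columns of X on [1, C] (Frisch-Waugh): the penalised
# coefficients of the covariate-adjusted LASSO equal those of the joint fit
# with unpenalised covariates.
residualize_on <- function(y, X, C) {
  ones <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  Q <- qr(if (is.null(C)) ones else cbind(ones, C))
  list(y = qr.resid(Q, y), X = qr.resid(Q, X), qrC = Q)
}

standardize_cols <- function(X) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  s <- sqrt(colMeans(Xc^2))   # 1/n convention: x'x/n = 1 after scaling
  ok <- s > 1e-12
  Xs <- sweep(Xc[, ok, drop = FALSE], 2, s[ok], `/`)
  list(X = Xs, center = mu, scale = s, ok = ok)
}

#' Solve the multi-locus LASSO
#'
#' Minimizes \deqn{\frac{1}{2n}\sum_i (y_i - \alpha_0 - c_i^\top\gamma -
#' \sum_j x_{ij}\alpha_j)^2 + \lambda\sum_j w_j|\alpha_j|} by cyclic
#' coordinate descent with soft-thresholding. The intercept and the
#' covariates `C` are never penalised (they are projected out before the
#' penalised fit and their coefficients recovered afterwards). Markers are
#' standardized internally by default and coefficients returned on the
#' original scale; constant markers get coefficient 0.
#'
#' @param y Response vector (latent trait).
#' @param X Marker matrix, `n x p` (0/1/2 codes, possibly mean-imputed).
#' @param C Optional unpenalised covariate matrix (e.g. [genotype_pcs()]).
#' @param lambda Penalty `>= 0`.
#' @param penalty_factor Per-marker weights `w_j` (default 1).
#' @param standardize Standardize marker columns internally (default TRUE).
#' @param tol Convergence tolerance on the maximum coefficient change
#'   (default `1e-7`).
#' @param max_sweeps Sweep budget; exceeding it flags `converged = FALSE`.
#' @return List of class `lasso_fit`: `alpha0`, `covar_coef`, `alpha` (named
#'   marker effects, original scale), `lambda`, `converged`, `sweeps`.
#' @export
solve_lasso <- function(y, X, C = NULL, lambda, penalty_factor = NULL,
                        standardize = TRUE, tol = 1e-7,
                        max_sweeps = 100000) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), all(is.finite(y)), all(is.finite(X)),
            lambda >= 0)
  p <- ncol(X)
  if (is.null(penalty_factor)) penalty_factor <- rep(1, p)
  r <- residualize_on(y, X, C)
  if (standardize) {
    st <- standardize_cols(r$X)
    Xw <- st$X
    pf <- penalty_factor[st$ok]
  } else {
    st <- NULL
    Xw <- r$X
    pf <- penalty_factor
  }
  fit <- .cd_lasso(Xw, r$y, lambda, pf, numeric(ncol(Xw)), tol, max_sweeps)
  alpha <- numeric(p)
  if (standardize) {
    alpha[st$ok] <- fit$beta / st$scale[st$ok]
  } else {
    alpha <- fit$beta
  }
  names(alpha) <- colnames(X)
  # unpenalised part: regress the marker-adjusted response on [1, C]
  co <- qr.coef(r$qrC, y - X %*% alpha)
  co[is.na(co)] <- 0
  structure(list(alpha0 = unname(co[1]), covar_coef = co[-1], alpha = alpha,
                 lambda = lambda, converged = fit$converged,
                 sweeps = fit$sweeps),
            class = "lasso_fit")
}

#' Smallest penalty with an empty active set
#'
#' `lambda_max = max_j |x_j' r| / n` on the standardized, covariate-adjusted
#' problem; at or above it every penalised coefficient is zero.
#'
#' @inheritParams solve_lasso
#' @return The scalar `lambda_max`.
#' @export
lasso_lambda_max <- function(y, X, C = NULL, standardize = TRUE) {
  r <- residualize_on(y, as.matrix(X), C)
  Xw <- if (standardize) standardize_cols(r$X)$X else r$X
  max(abs(crossprod(Xw, r$y))) / length(y)
}

#' KKT residuals of a LASSO fit
#'
#' For each marker, the violation of the subgradient optimality condition
#' `|x_j'r/n| <= lambda` (inactive) or `x_j'r/n = lambda sign(alpha_j)`
#' (active), on the standardized problem. Used in tests.
#'
#' @inheritParams solve_lasso
#' @param fit A `lasso_fit` from [solve_lasso()].
#' @return Numeric vector of non-negative violations, one per marker kept
#'   after standardization.
#' @export
lasso_kkt_violation <- function(fit, y, X, C = NULL) {
  r <- residualize_on(y, as.matrix(X), C)
  st <- standardize_cols(r$X)
  beta_std <- fit$alpha[st$ok] * st$scale[st$ok]
  res <- r$y - st$X %*% beta_std
  g <- as.numeric(crossprod(st$X, res)) / length(y)
  active <- beta_std != 0
  viol <- pmax(abs(g) - fit$lambda, 0)
  viol[active] <- abs(g[active] - fit$lambda * sign(beta_std[active]))
  viol
}

#' Threshold from the stability-selection false-selection bound
#'
#' For stability selection over `p` variables with an average of `q`
#' variables selected per subsample, the expected number of falsely selected
#' variables at inclusion-frequency threshold `pi` is bounded by
#' `E[V] <= q^2 / ((2 pi - 1) p)`. This returns the smallest threshold
#' keeping the bound at or below `ev_max`:
#' `pi = min(1, (1 + q^2 / (p ev_max)) / 2)`.
#'
#' @param p Number of candidate markers.
#' @param q Average number selected per subsample.
#' @param ev_max Tolerated expected false selections (default 1).
#' @return The threshold `pi` in `(0.5, 1]`.
#' @export
buhlmann_threshold <- function(p, q, ev_max = 1) {
  stopifnot(p > 0, q > 0, q < p, ev_max > 0)
  ratio <- q^2 / (p * ev_max)
  if (ratio >= 1) {
    warning("bound cannot be met below pi = 1; threshold capped at 1")
    return(1)
  }
  (1 + ratio) / 2
}

#' Largest subsample selection size admissible at a given threshold
#'
#' Inverse of [buhlmann_threshold()]: the largest `q` with
#' `q^2 / ((2 pi - 1) p) <= ev_max`.
#'
#' @param p Number of candidate markers.
#' @param pi Inclusion-frequency threshold in `(0.5, 1]`.
#' @param ev_max Tolerated expected false selections (default 1).
#' @return The real-valued bound on `q` (callers typically take `floor()`).
#' @export
buhlmann_max_q <- function(p, pi, ev_max = 1) {
  stopifnot(p > 0, pi > 0.5, pi <= 1, ev_max > 0)
  sqrt((2 * pi - 1) * p * ev_max)
}

#' Stability selection for the multi-locus LASSO
#'
#' Draws `n_subsamples` half-samples (size `floor(n/2)`, without
#' replacement), runs the covariate-adjusted LASSO on each with the penalty
#' calibrated so that about `q_target` markers are active (the penalty
#' descends a warm-started geometric path from that subsample's
#' `lambda_max` and stops when the active set reaches `q_target`), and
#' reports each marker's inclusion frequency (stability selection
#' probability, SSP). `q_target` defaults to the largest selection size for
#' which the false-selection bound at `pi_thr` stays at or below `ev_max`
#' (see [buhlmann_max_q()]).
#'
#' @param y Latent-trait response, length `n >= 20`.
#' @param X Marker matrix `n x p`.
#' @param C Optional unpenalised covariates.
#' @param n_subsamples Number of half-samples (default 100).
#' @param q_target Markers to select per subsample (default from the bound).
#' @param pi_thr Inclusion-frequency threshold (default 0.52).
#' @param ev_max Tolerated expected false selections (default 1).
#' @param seed Integer seed; fixed seed gives identical SSPs.
#' @param n_lambda,lambda_min_ratio Path grid passed to the solver.
#' @return List of class `stability_result`: `ssp` (named, in `[0, 1]`),
#'   `pi_thr`, `q_avg`, `q_target`, `n_subsamples`, `selected` (marker names
#'   with `ssp >= pi_thr`), `ev_bound` (the bound evaluated at `q_avg`).
#' @export
stability_selection <- function(y, X, C = NULL, n_subsamples = 100,
                                q_target = NULL, pi_thr = 0.52, ev_max = 1,
                                seed = 1, n_lambda = 100,
                                lambda_min_ratio = 0.01) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  stopifnot(n == nrow(X), n >= 20)
  if (is.null(q_target))
    q_target <- max(1L, floor(buhlmann_max_q(p, pi_thr, ev_max)))
  if (q_target >= p) stop("q_target must be < p")
  set.seed(as.integer(seed))
  m <- floor(n / 2)
  counts <- numeric(p)
  q_sizes <- numeric(n_subsamples)
  for (b in seq_len(n_subsamples)) {
    idx <- sample.int(n, m)
    r <- residualize_on(y[idx], X[idx, , drop = FALSE],
                        if (is.null(C)) NULL else C[idx, , drop = FALSE])
    st <- standardize_cols(r$X)
    path <- .cd_lasso_path_qstop(st$X, r$y, q_target, n_lambda,
                                 lambda_min_ratio, 1e-5, 10000)
    sel_local <- which(st$ok)[path$selected]
    counts[sel_local] <- counts[sel_local] + 1
    q_sizes[b] <- path$q
  }
  ssp <- counts / n_subsamples
  names(ssp) <- colnames(X)
  q_avg <- mean(q_sizes)
  selected <- names(ssp)[ssp >= pi_thr]
  structure(list(ssp = ssp, pi_thr = pi_thr, q_avg = q_avg,
                 q_target = q_target, n_subsamples = n_subsamples,
                 selected = selected,
                 ev_bound = q_avg^2 / ((2 * pi_thr - 1) * p)),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf(
    "stability selection: %d subsamples, q_target=%d (q_avg=%.2f)\n",
    x$n_subsamples, x$q_target, x$q_avg))
  cat(sprintf("  threshold pi=%.3f; %d marker(s) selected; E[V] bound %.3f\n",
              x$pi_thr, length(x$selected), x$ev_bound))
  invisible(x)
}
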