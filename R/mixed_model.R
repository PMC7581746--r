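#' Joint-site mixed model for one cambial age
#'
#' Fits, by EM-REML, the univariate joint-site model
#' \deqn{Y_{ijkl} = u + S_i + B_{j(i)} + F_k + SF_{ik} + e_{ijkl}}
#' with fixed site and block-within-site effects and independent random
#' family, site-by-family and residual effects, then computes the family
#' BLUPs (estimated breeding values) from the mixed-model equations at the
#' converged variance estimates.
#'
#' @param values Numeric vector of trait values at one cambial age.
#' @param design Design table (`tree_id`, `site`, `block`, `family`) aligned
#'   with `values` (one row per observation).
#' @param tol Convergence tolerance on the relative change of the REML
#'   log-likelihood (default `1e-6`).
#' @param max_iter Maximum EM iterations (default 500).
#' @return List of class `ring_mm_fit`:
#'   `sigma2` (named `family`, `site_family`, `residual`),
#'   `fixed_effects` (named coefficient vector; intercept is the prediction
#'   at the baseline site/block), `ebv` (named family BLUPs),
#'   `converged`, `n_iter`, `loglik` (REML, up to a constant).
#' @details Variance iterates are floored just above zero (EM keeps them
#'   non-negative; the floor keeps the mixed-model equations well-posed when
#'   a component collapses). A singular fixed-effect design (confounded
#'   site/block columns) is an error naming the aliased columns.
#' @export
fit_ring_mixed_model <- function(values, design, tol = 1e-6,
                                 max_iter = 500) {
  validate_design(design)
  stopifnot(length(values) == nrow(design), all(is.finite(values)))
  if (length(unique(design$family)) < 2) stop("need >= 2 families")
  y <- as.numeric(values)
  n <- length(y)

  X <- fixed_design_matrix(design)
  p_x <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p_x) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):p_x]]
    stop("singular fixed-effect design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }

  fam <- factor(design$family)
  K <- nlevels(fam)
  Zf <- stats::model.matrix(~ fam - 1)
  # site-by-family term only identifiable with >= 2 sites (with one site it
  # is aliased with the family term and is dropped, sigma2 reported as 0)
  has_sf <- length(unique(design$site)) >= 2
  if (has_sf) {
    sf <- factor(paste(design$site, design$family, sep = ":"))
    Q2 <- nlevels(sf)
    W <- cbind(X, Zf, stats::model.matrix(~ sf - 1))
  } else {
    Q2 <- 0L
    W <- cbind(X, Zf)
  }
  WtW <- crossprod(W)
  Wty <- crossprod(W, y)
  yty <- sum(y^2)
  i_f <- p_x + seq_len(K)
  i_sf <- p_x + K + seq_len(Q2)

  vp <- var(y)
  s2 <- c(family = vp / 4,
          site_family = if (has_sf) vp / 8 else 0,
          residual = vp / 2)
  floor_v <- 1e-8 * vp
  solve_mme <- function(s2) {
    M <- WtW
    diag(M)[i_f] <- diag(WtW)[i_f] + s2[["residual"]] / s2[["family"]]
    if (has_sf)
      diag(M)[i_sf] <- diag(WtW)[i_sf] +
        s2[["residual"]] / s2[["site_family"]]
    R <- chol(M)
    list(sol = backsolve(R, forwardsolve(t(R), Wty)), R = R)
  }
  ll_old <- -Inf
  ll <- NA_real_
  converged <- FALSE
  it <- 0
  repeat {
    it <- it + 1
    mme <- solve_mme(s2)
    sol <- mme$sol
    Minv <- chol2inv(mme$R)
    resid_ss <- yty - sum(sol * Wty)      # y'(y - Xb - Zu)
    # REML log-likelihood at the current (pre-update) variances
    logdetM <- 2 * sum(log(diag(mme$R)))
    ll <- -0.5 * ((n - p_x - K - Q2) * log(s2[["residual"]]) +
                    K * log(s2[["family"]]) +
                    (if (has_sf) Q2 * log(s2[["site_family"]]) else 0) +
                    logdetM + resid_ss / s2[["residual"]])
    # EM updates use prediction-error traces C_uu = s2e * Minv_uu
    s2e <- max(resid_ss / (n - p_x), floor_v)
    s2f <- max((sum(sol[i_f]^2) + s2e * sum(diag(Minv)[i_f])) / K, floor_v)
    s2sf <- if (has_sf)
      max((sum(sol[i_sf]^2) + s2e * sum(diag(Minv)[i_sf])) / Q2, floor_v)
    else 0
    s2 <- c(family = s2f, site_family = s2sf, residual = s2e)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    if (it >= max_iter) break
  }

  # final solve of the mixed-model equations at the converged variances
  sol <- solve_mme(s2)$sol

  fixed <- setNames(sol[seq_len(p_x)], colnames(X))
  ebv <- setNames(sol[i_f], levels(fam))
  structure(list(sigma2 = s2, fixed_effects = fixed, ebv = ebv,
                 converged = converged, n_iter = it, loglik = ll,
                 sites = levels(factor(design$site))),
            class = "ring_mm_fit")
}

# Full-rank fixed design: intercept, site indicators (2..S), and
# block-within-site indicators (2..B within each site).
fixed_design_matrix <- function(design) {
  site <- factor(design$site)
  X <- if (nlevels(site) >= 2) stats::model.matrix(~ site) else
    matrix(1, nrow(design), 1)
  colnames(X)[1] <- "(Intercept)"
  for (s in levels(site)) {
    rows <- design$site == s
    blocks <- sort(unique(design$block[rows]))
    for (b in blocks[-1]) {
      X <- cbind(X, as.numeric(design$block == b))
      colnames(X)[ncol(X)] <- paste0("block", b)
    }
  }
  X
}

#' @export
print.ring_mm_fit <- function(x, ...) {
  cat("ring mixed-model fit (EM-REML)\n")
  cat(sprintf("  sigma2: family=%.4g site_family=%.4g residual=%.4g\n",
              x$sigma2[["family"]], x$sigma2[["site_family"]],
              x$sigma2[["residual"]]))
  cat(sprintf("  %d families; converged=%s after %d iterations\n",
              length(x$ebv), x$converged, x$n_iter))
  invisible(x)
}

#' Refine ring trajectories with per-age breeding values
#'
#' Runs [fit_ring_mixed_model()] at every cambial age of one trait and
#' reconstructs, per family, the refined trajectory `EBV_k(age) +
#' adjusted mean(age)`. The adjusted mean is the fixed-effect prediction at
#' the baseline (first) site and block levels, which makes the refined
#' trajectories exactly invariant to constant shifts of any other site's or
#' block's observations; the resulting overall level offset is common to all
#' families and harmless downstream (latent-trait responses are centred in
#' the association stage).
#'
#' @param rings Ring data.frame (`tree_id`, `trait`, `cambial_age`, `value`).
#' @param design Design table covering the trees.
#' @param trait Trait to refine (default: the single trait present).
#' @param ... Passed to [fit_ring_mixed_model()].
#' @return List of class `refined_trajectories`: `trajectories` (data.frame
#'   `family`, `cambial_age`, `value`), `fits` (per-age `ring_mm_fit`s),
#'   `trait`.
#' @export
refine_trajectories <- function(rings, design, trait = NULL, ...) {
  validate_design(design)
  if (is.null(trait)) {
    trait <- unique(rings$trait)
    if (length(trait) != 1) stop("specify `trait`: several present")
  }
  rr <- rings[rings$trait == trait, , drop = FALSE]
  if (!nrow(rr)) stop("no rows for trait ", trait)
  ages <- sort(unique(rr$cambial_age))
  fits <- vector("list", length(ages))
  names(fits) <- as.character(ages)
  out <- vector("list", length(ages))
  for (i in seq_along(ages)) {
    sub <- rr[rr$cambial_age == ages[i], , drop = FALSE]
    d <- design[match(sub$tree_id, design$tree_id), , drop = FALSE]
    if (any(is.na(d$tree_id))) stop("ring tree_id missing from design")
    fit <- fit_ring_mixed_model(sub$value, d, ...)
    fits[[i]] <- fit
    base_mean <- fit$fixed_effects[["(Intercept)"]]
    out[[i]] <- data.frame(family = names(fit$ebv),
                           cambial_age = ages[i],
                           value = unname(fit$ebv) + base_mean,
                           stringsAsFactors = FALSE)
  }
  structure(list(trajectories = do.call(rbind, out), fits = fits,
                 trait = trait),
            class = "refined_trajectories")
}
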