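#' Truncated-linear spline basis
#'
#' Design matrix `[1, t, (t - K1)+, (t - K2)+]` with `(x)+ = max(x, 0)`: a
#' continuous piecewise-linear curve whose slope changes at each knot.
#'
#' @param ages Numeric vector of cambial ages.
#' @param knots Pair `(K1, K2)` with `K1 < K2`, inside the age range.
#' @return Numeric matrix with columns `intercept`, `t`, `t_k1`, `t_k2`.
#' @export
spline_basis <- function(ages, knots) {
  if (length(knots) != 2 || knots[1] >= knots[2])
    stop("knots must be an increasing pair")
  if (knots[1] < min(ages) || knots[2] > max(ages))
    stop("knots outside the age range")
  cbind(intercept = 1, t = ages,
        t_k1 = pmax(ages - knots[1], 0),
        t_k2 = pmax(ages - knots[2], 0))
}

#' Fit a two-knot linear spline by ordinary least squares
#'
#' Estimates the four latent traits `beta0..beta3` of one trajectory. With
#' noise-free data generated from the same basis the coefficients are
#' recovered to machine precision. If the basis is rank-deficient on the
#' observed ages (e.g. no points beyond `K2`), the unidentified trailing
#' coefficients are reported as `NA` and the fit is flagged.
#'
#' @param ages,values Trajectory (>= 4 points, spanning both knots for a
#'   full-rank fit).
#' @param knots Pair `(K1, K2)`.
#' @return List of class `spline_fit`: `beta` (named `beta0..beta3`),
#'   `knots`, `sse`, `n_points`, `full_rank`.
#' @export
fit_linear_spline <- function(ages, values, knots) {
  stopifnot(length(ages) == length(values))
  if (length(ages) < 4) stop("need >= 4 points for 4 coefficients")
  B <- spline_basis(ages, knots)
  fit <- lm.fit(B, values)
  beta <- fit$coefficients
  full_rank <- fit$rank == 4L
  if (!full_rank)
    message("rank-deficient spline basis; ", 4L - fit$rank,
            " coefficient(s) not identified")
  structure(list(beta = setNames(unname(beta), paste0("beta", 0:3)),
                 knots = knots, sse = sum(fit$residuals^2),
                 n_points = length(ages), full_rank = full_rank),
            class = "spline_fit")
}

#' Select one shared knot pair per trait
#'
#' Scans a candidate grid of integer `(K1, K2)` pairs and returns the pair
#' minimizing the total spline SSE over all trajectories of the trait (one
#' fixed pair per trait; the per-curve coefficients are then the latent
#' traits). Ties resolve to the smaller `K1`, then the smaller `K2`.
#'
#' @param trajectories Data frame with columns `id` (tree or family),
#'   `cambial_age`, `value` — one trait.
#' @param grid Data frame of candidate pairs (`K1`, `K2`); default all
#'   integer pairs with `min(age)+1 <= K1 < K2 <= max(age)-1`.
#' @return List: `knots` (the selected pair), `sse` (its total SSE),
#'   `grid_sse` (per-candidate totals).
#' @export
select_knots <- function(trajectories, grid = NULL) {
  ages_all <- trajectories$cambial_age
  if (is.null(grid)) {
    lo <- min(ages_all) + 1
    hi <- max(ages_all) - 1
    ks <- seq(ceiling(lo), floor(hi))
    grid <- expand.grid(K1 = ks, K2 = ks)
    grid <- grid[grid$K1 < grid$K2, , drop = FALSE]
  }
  if (!nrow(grid)) stop("empty knot grid")
  split_traj <- split(trajectories[c("cambial_age", "value")],
                      trajectories$id)
  total <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    kn <- c(grid$K1[g], grid$K2[g])
    total[g] <- sum(vapply(split_traj, function(tr)
      fit_linear_spline(tr$cambial_age, tr$value, kn)$sse, numeric(1)))
  }
  ord <- order(total, grid$K1, grid$K2)
  best <- ord[1]
  list(knots = c(K1 = grid$K1[best], K2 = grid$K2[best]),
       sse = total[best],
       grid_sse = cbind(grid, sse = total))
}

#' Latent spline traits for a set of trajectories
#'
#' Applies [select_knots()] (unless `knots` is given) and then
#' [fit_linear_spline()] per trajectory.
#'
#' @param trajectories Data frame `id`, `cambial_age`, `value` (one trait).
#' @param knots `"auto"` (grid search) or a fixed pair.
#' @param grid Optional candidate grid for `"auto"`.
#' @return Data frame `id`, `beta0..beta3`, `sse`, plus attribute `"knots"`.
#' @export
fit_latent_traits <- function(trajectories, knots = "auto", grid = NULL) {
  if (identical(knots, "auto"))
    knots <- select_knots(trajectories, grid)$knots
  split_traj <- split(trajectories[c("cambial_age", "value")],
                      trajectories$id)
  rows <- lapply(names(split_traj), function(id) {
    tr <- split_traj[[id]]
    f <- fit_linear_spline(tr$cambial_age, tr$value, knots)
    data.frame(id = id, t(f$beta), sse = f$sse, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "knots") <- knots
  out
}

#' Fit a monotone exponential-decay MFA curve
#'
#' Least-squares fit of `plateau + (start - plateau) * exp(-rate *
#' (age - 1))` via Levenberg-Marquardt, with a coarse rate grid + linear
#' fallback when the nonlinear fit fails. A fit with `start <= plateau` or a
#' non-positive rate is flagged non-monotone.
#'
#' @param ages,values MFA trajectory (degrees), >= 3 rings.
#' @return List: `start`, `plateau`, `rate`, `fitted`, `sse`, `monotone`.
#' @export
fit_mfa_decay <- function(ages, values) {
  stopifnot(length(ages) == length(values))
  if (length(ages) < 3) stop("need >= 3 rings")
  df <- data.frame(t = ages, y = values)
  st <- list(plateau = min(values), start = values[which.min(ages)],
             rate = 0.2)
  if (st$start <= st$plateau) st$start <- st$plateau + 1
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ plateau + (start - plateau) * exp(-rate * (t - 1)),
                      data = df, start = st,
                      lower = c(plateau = -Inf, start = -Inf, rate = 1e-4),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- coef(fit)
    fitted_v <- cf[["plateau"]] +
      (cf[["start"]] - cf[["plateau"]]) * exp(-cf[["rate"]] * (ages - 1))
    return(list(start = cf[["start"]], plateau = cf[["plateau"]],
                rate = cf[["rate"]], fitted = fitted_v,
                sse = sum((values - fitted_v)^2),
                monotone = cf[["start"]] > cf[["plateau"]] &&
                  cf[["rate"]] > 0))
  }
  # fallback: profile the rate on a grid, solve start/plateau linearly
  best <- NULL
  for (r in exp(seq(log(0.02), log(2), length.out = 40))) {
    b <- exp(-r * (ages - 1))
    co <- lm.fit(cbind(1 - b, b), values)$coefficients  # plateau, start
    fv <- co[1] * (1 - b) + co[2] * b
    sse <- sum((values - fv)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(start = unname(co[2]), plateau = unname(co[1]), rate = r,
                   fitted = fv, sse = sse,
                   monotone = co[2] > co[1])
  }
  best
}

#' MFA latent traits: core/outer means and transition age
#'
#' Fits the decay curve to one tree's MFA series and derives the three MFA
#' latent traits: the transition age `mfa_ta` where the fitted curve first
#' reaches the threshold (20 degrees by default, solved exactly on the
#' fitted curve, i.e. interpolated between rings), and the means of the
#' observed MFA at ages at or below (`mfa_core`) and above (`mfa_outer`)
#' that age. Trees whose fitted curve never reaches the threshold within
#' the observed age range are flagged `crossed = FALSE` for exclusion from
#' association mapping. An optional per-tree MAD screen removes gross
#' outliers before fitting.
#'
#' @param ages,values One tree's MFA trajectory (degrees), >= 3 rings.
#' @param threshold Crossing level in degrees (default 20).
#' @param mad_k Outlier screen: after a preliminary decay fit, rings whose
#'   residual exceeds `mad_k` MADs of the residuals are dropped and the
#'   curve refitted (default 4; `Inf` disables). Screening residuals rather
#'   than raw values keeps the legitimately high pith rings of a decaying
#'   curve.
#' @return List of class `mfa_latent`: `mfa_core`, `mfa_outer`, `mfa_ta`,
#'   `crossed`, `monotone`, `n_outliers`, `fit`.
#' @export
mfa_latents <- function(ages, values, threshold = 20, mad_k = 4) {
  stopifnot(length(ages) == length(values))
  fit <- fit_mfa_decay(ages, values)
  keep <- rep(TRUE, length(values))
  if (is.finite(mad_k)) {
    res <- values - fit$fitted
    s <- mad(res)
    if (s > 0) keep <- abs(res - median(res)) <= mad_k * s
    if (sum(keep) < 3) keep <- rep(TRUE, length(values))
  }
  n_out <- sum(!keep)
  a <- ages[keep]
  v <- values[keep]
  if (n_out > 0) fit <- fit_mfa_decay(a, v)
  ta <- decay_crossing_age(fit$start, fit$plateau, fit$rate, threshold)
  crossed <- fit$monotone && !is.na(ta) && ta <= max(a)
  if (!crossed) ta <- NA_real_
  core <- if (crossed) mean(v[a <= ta]) else NA_real_
  outer <- if (crossed && any(a > ta)) mean(v[a > ta]) else NA_real_
  structure(list(mfa_core = core, mfa_outer = outer, mfa_ta = ta,
                 crossed = crossed, monotone = fit$monotone,
                 n_outliers = n_out, fit = fit),
            class = "mfa_latent")
}

#' MFA latent traits for a whole ring table
#'
#' @param rings Ring data.frame (`tree_id`, `trait`, `cambial_age`, `value`)
#'   holding an MFA trait.
#' @param trait Trait label to use (default `"MFA_Ring"`).
#' @param ... Passed to [mfa_latents()].
#' @return Data frame `tree_id`, `mfa_core`, `mfa_outer`, `mfa_ta`,
#'   `crossed`.
#' @export
mfa_latent_table <- function(rings, trait = "MFA_Ring", ...) {
  rr <- rings[rings$trait == trait, , drop = FALSE]
  if (!nrow(rr)) stop("no rows for trait ", trait)
  split_tr <- split(rr[c("cambial_age", "value")], rr$tree_id)
  rows <- lapply(names(split_tr), function(id) {
    tr <- split_tr[[id]]
    m <- mfa_latents(tr$cambial_age, tr$value, ...)
    data.frame(tree_id = id, mfa_core = m$mfa_core, mfa_outer = m$mfa_outer,
               mfa_ta = m$mfa_ta, crossed = m$crossed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
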