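#' Fit an FCS model to a correlation curve
#'
#' Weighted nonlinear least-squares (Levenberg-Marquardt) fit of
#' [model_diffusion_2d()] or [model_with_triplet()] to a correlation curve.
#' Any parameter can be frozen through `fixed` (for example the triplet
#' correlation time, conventionally fixed to an independently measured 5 us
#' for red-detection membrane curves). Per-lag standard errors, when present
#' in the curve, act as weights; otherwise unit weights are used and this is
#' recorded in the result. The first correlator lag is excluded by default
#' (shot-noise/afterpulsing convention at the shortest lag).
#'
#' @param curve a `correlation_curve`.
#' @param use_triplet include the triplet relaxation factor?
#' @param fixed named list freezing any of `N`, `tau_D`, `alpha`, `T`,
#'   `tau_triplet` at given values.
#' @param start optional named list of starting values.
#' @param drop_first number of leading lag points excluded from the fit.
#' @param alpha_limits allowed range for the anomaly parameter.
#' @return an `fcs_fit_result`: list with `params` (all five model
#'   parameters), `fixed_mask`, `Q` (= mean_rate / N when the curve carries a
#'   mean rate), `mean_rate`, `reduced_chi2`, `weighting`, `converged`,
#'   `boundary_pinned` and the fitted curve in `fitted`.
#' @export
fit_curve <- function(curve, use_triplet = FALSE, fixed = list(),
                      start = list(), drop_first = 1L,
                      alpha_limits = c(0.3, 2)) {
  stopifnot(inherits(curve, "correlation_curve"))
  keep <- seq_len(nrow(curve))
  if (drop_first > 0L) keep <- keep[-seq_len(drop_first)]
  lag <- curve$lag[keep]
  G <- curve$G[keep]
  se <- curve$stderr[keep]
  # per-lag standard errors act as weights where available; lags without one
  # (beyond the segment grid) are excluded from a weighted fit
  have_se <- sum(is.finite(se) & se > 0) >= 6L
  ok <- is.finite(G)
  if (have_se) ok <- ok & is.finite(se) & se > 0
  lag <- lag[ok]; G <- G[ok]
  if (have_se) se <- se[ok]
  if (length(lag) < 6L)
    stopf("need at least 6 usable lag points to fit (got %d)", length(lag))
  w <- if (have_se) 1 / se else rep(1, length(lag))

  if (!use_triplet) {
    fixed$T <- 0
    if (is.null(fixed$tau_triplet)) fixed$tau_triplet <- 5e-6
  }
  par_names <- c("N", "tau_D", "alpha", "T", "tau_triplet")
  bad <- setdiff(names(fixed), par_names)
  if (length(bad)) stopf("unknown fixed parameter(s): %s",
                         paste(bad, collapse = ", "))
  g1 <- max(G[1L], 1e-12)
  tau_half <- {
    below <- which(G <= g1 / 2)
    if (length(below)) lag[below[1L]] else exp(mean(log(range(lag))))
  }
  defaults <- list(N = 1 / g1, tau_D = tau_half, alpha = 1, T = 0.1,
                   tau_triplet = 5e-6)
  start <- modifyList(defaults, start)
  free <- setdiff(par_names, names(fixed))
  if (!length(free)) stopf("no free parameters to fit")
  # positive scale parameters are fitted in log10
  logpar <- c("N", "tau_D", "tau_triplet")
  to_fit <- function(vals) {
    v <- unlist(vals[free])
    v[free %in% logpar] <- log10(v[free %in% logpar])
    v
  }
  from_fit <- function(p) {
    vals <- as.list(p)
    names(vals) <- free
    for (nm in intersect(free, logpar)) vals[[nm]] <- 10^vals[[nm]]
    modifyList(fixed, vals)[par_names]
  }
  lower_full <- c(N = -12, tau_D = -12, alpha = alpha_limits[1L], T = 0,
                  tau_triplet = -12)
  upper_full <- c(N = 12, tau_D = 6, alpha = alpha_limits[2L], T = 0.999,
                  tau_triplet = 3)
  model_fn <- function(vals)
    model_with_triplet(lag, vals$N, vals$tau_D, vals$alpha, vals$T,
                       vals$tau_triplet)
  fit <- minpack.lm::nls.lm(
    par = to_fit(start), lower = lower_full[free], upper = upper_full[free],
    fn = function(p) (model_fn(from_fit(p)) - G) * w,
    control = minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-15,
                                         ptol = 1e-15))
  vals <- from_fit(fit$par)
  names(vals) <- par_names
  pinned <- any(vapply(seq_along(free), function(i) {
    p <- fit$par[i]
    span <- upper_full[free[i]] - lower_full[free[i]]
    p <= lower_full[free[i]] + 1e-6 * span ||
      p >= upper_full[free[i]] - 1e-6 * span
  }, NA))
  fit_g <- model_fn(vals)
  dof <- max(1L, length(G) - length(free))
  mean_rate <- attr(curve, "mean_rate")
  structure(list(params = vals,
                 fixed_mask = setNames(par_names %in% names(fixed), par_names),
                 Q = if (is.finite(mean_rate)) mean_rate / vals$N else NA_real_,
                 mean_rate = mean_rate,
                 reduced_chi2 = sum(((G - fit_g) * w)^2) / dof,
                 weighting = if (have_se) "stderr" else "unit",
                 converged = fit$info %in% 1:4 && !pinned,
                 boundary_pinned = pinned,
                 fitted = data.frame(lag = lag, G = G, fit = fit_g)),
            class = "fcs_fit_result")
}
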