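#' Binned photon-count intensity trace
#'
#' @param counts non-negative integer photon counts per bin.
#' @param bin_time bin duration (s, > 0).
#' @return an `intensity_trace` with derived fields `duration` and
#'   `mean_rate` (Hz).
#' @export
intensity_trace <- function(counts, bin_time) {
  if (!all(is.finite(counts)) || any(counts < 0))
    stopf("trace counts must be finite and >= 0")
  if (!is.finite(bin_time) || bin_time <= 0) stopf("bin_time must be > 0")
  counts <- as.numeric(counts)
  structure(list(counts = counts, bin_time = bin_time,
                 duration = length(counts) * bin_time,
                 mean_rate = mean(counts) / bin_time),
            class = "intensity_trace")
}

#' Multi-tau autocorrelation of an intensity trace
#'
#' Computes the normalized fluctuation autocorrelation
#' \deqn{G(\tau) = \langle \delta I(t)\, \delta I(t+\tau) \rangle /
#'   \langle I \rangle^2}
#' on a quasi-logarithmic lag grid: `m` linear lags in the first octave, then
#' `m/2` lags per octave with pairwise coarsening of the trace, using
#' symmetric normalization (the two window means of each lag are computed
#' over the overlapping samples only). This is the software analogue of a
#' hardware correlator card.
#'
#' When `n_segments > 1` the trace is split into equal contiguous segments,
#' each is correlated separately, and the per-lag standard error across
#' segments is attached (lags not reachable within one segment get `NA`).
#'
#' @param trace an [intensity_trace()].
#' @param m points per octave (even, default 16).
#' @param n_segments segments used for the standard-error estimate (default
#'   10; 1 disables it).
#' @return a `correlation_curve`: data.frame with columns `lag` (s), `G`,
#'   `stderr`, and attributes `mean_rate`, `bin_time`, `duration`.
#' @export
correlate_multi_tau <- function(trace, m = 16L, n_segments = 10L) {
  stopifnot(inherits(trace, "intensity_trace"))
  n <- length(trace$counts)
  if (n < 2L * m) stopf("trace must have at least 2*m bins (%d < %d)", n, 2L * m)
  if (mean(trace$counts) <= 0)
    stopf("zero-mean trace: fluctuation normalization undefined")
  base <- .multitau_core(trace$counts, as.integer(m))
  curve <- data.frame(lag = base$lag_bins * trace$bin_time, G = base$G,
                      stderr = NA_real_)
  if (n_segments > 1L) {
    seg_len <- n %/% n_segments
    if (seg_len >= 2L * m) {
      segs <- lapply(seq_len(n_segments), function(i) {
        idx <- ((i - 1L) * seg_len + 1L):(i * seg_len)
        seg <- trace$counts[idx]
        if (mean(seg) <= 0) return(NULL)
        .multitau_core(seg, as.integer(m))
      })
      segs <- Filter(Negate(is.null), segs)
      if (length(segs) >= 3L) {
        seg_lags <- segs[[1L]]$lag_bins
        gmat <- vapply(segs, function(s) {
          g <- rep(NA_real_, length(seg_lags))
          mlen <- min(length(s$G), length(seg_lags))
          g[seq_len(mlen)] <- s$G[seq_len(mlen)]
          g
        }, numeric(length(seg_lags)))
        se <- apply(gmat, 1L, function(v) {
          v <- v[is.finite(v)]
          if (length(v) >= 3L) sd(v) / sqrt(length(v)) else NA_real_
        })
        idx <- match(seg_lags, base$lag_bins)
        ok <- !is.na(idx)
        curve$stderr[idx[ok]] <- se[ok]
      }
    }
  }
  correlation_curve(curve$lag, curve$G, curve$stderr,
                    mean_rate = trace$mean_rate, bin_time = trace$bin_time,
                    duration = trace$duration)
}

#' Construct a correlation curve
#'
#' @param lags lag times (s), strictly increasing, > 0.
#' @param G correlation amplitudes.
#' @param stderr optional per-lag standard errors.
#' @param mean_rate mean count rate of the originating trace (Hz).
#' @param bin_time,duration optional trace metadata.
#' @return a `correlation_curve` data.frame.
#' @export
correlation_curve <- function(lags, G, stderr = NULL, mean_rate = NA_real_,
                              bin_time = NA_real_, duration = NA_real_) {
  if (any(lags <= 0) || any(diff(lags) <= 0))
    stopf("lags must be strictly increasing and > 0")
  if (!all(is.finite(G))) stopf("G must be finite")
  if (is.null(stderr)) stderr <- rep(NA_real_, length(lags))
  out <- data.frame(lag = lags, G = G, stderr = stderr)
  attr(out, "mean_rate") <- mean_rate
  attr(out, "bin_time") <- bin_time
  attr(out, "duration") <- duration
  class(out) <- c("correlation_curve", "data.frame")
  out
}

#' Average repeat correlation curves
#'
#' Averages curves from repeat measurements of the same spot lag-by-lag
#' (curves are averaged before fitting, not fit parameters), attaching the
#' across-repeat standard error per lag.
#'
#' @param curves list of `correlation_curve` objects on identical lag grids.
#' @return a single `correlation_curve` with the pooled mean rate.
#' @export
average_curves <- function(curves) {
  stopifnot(length(curves) >= 1L,
            all(vapply(curves, inherits, NA, "correlation_curve")))
  lags <- curves[[1L]]$lag
  for (cv in curves[-1L])
    if (length(cv$lag) != length(lags) || max(abs(cv$lag - lags)) > 1e-12)
      stopf("curves must share one lag grid")
  gmat <- vapply(curves, `[[`, numeric(length(lags)), "G")
  gmat <- matrix(gmat, nrow = length(lags))
  n <- length(curves)
  semat <- matrix(vapply(curves, `[[`, numeric(length(lags)), "stderr"),
                  nrow = length(lags))
  # propagate the members' per-lag errors when they carry them (they are far
  # more stable than an across-repeat sd over a handful of curves)
  se <- if (all(is.finite(semat[1L, ]))) sqrt(rowSums(semat^2)) / n
        else if (n >= 5L) apply(gmat, 1L, sd) / sqrt(n)
        else NULL
  correlation_curve(lags, rowMeans(gmat), se,
                    mean_rate = mean(vapply(curves, attr, 0, "mean_rate")),
                    bin_time = attr(curves[[1L]], "bin_time"),
                    duration = attr(curves[[1L]], "duration"))
}

#' Direct (reference) autocorrelation at multi-tau lags
#'
#' Brute-force evaluation of the same symmetrically normalized estimator as
#' [correlate_multi_tau()], computed in R with explicit per-lag sums over a
#' pairwise-coarsened copy of the trace. O(n) per lag with no shared code
#' with the streaming correlator; used as the independent oracle.
#'
#' @inheritParams correlate_multi_tau
#' @return data.frame with columns `lag_bins` (lag in base bins) and `G`.
#' @export
direct_correlate <- function(trace, m = 16L) {
  stopifnot(inherits(trace, "intensity_trace"))
  x <- trace$counts
  out_lag <- numeric(0)
  out_g <- numeric(0)
  level <- 0L
  repeat {
    n <- length(x)
    if (n < 2L * m) break
    k_set <- if (level == 0L) seq_len(m) else (m / 2 + 1):m
    for (k in k_set) {
      M <- n - k
      if (M < m) next
      left <- x[seq_len(M)]
      right <- x[k + seq_len(M)]
      sl <- sum(left)
      sr <- sum(right)
      if (sl <= 0 || sr <= 0) next
      out_lag <- c(out_lag, k * 2^level)
      out_g <- c(out_g, sum(left * right) * M / (sl * sr) - 1)
    }
    half <- n %/% 2L
    x <- x[2 * seq_len(half) - 1L] + x[2 * seq_len(half)]
    level <- level + 1L
  }
  data.frame(lag_bins = out_lag, G = out_g)
}
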