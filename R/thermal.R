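# differential scanning fluorimetry: melt-curve model, derivative-method Tm,
# delta-Tm with pooled two-sample t test

#' Construct a melt curve
#'
#' @param temperature strictly increasing temperature grid, degrees C.
#' @param fluorescence arbitrary units.
#' @param replicate_id replicate label.
#' @return data frame of class `melt_curve`.
#' @export
melt_curve <- function(temperature, fluorescence, replicate_id = 1L) {
  if (any(diff(temperature) <= 0))
    stopf("temperature grid must be strictly increasing")
  if (!all(is.finite(fluorescence))) stopf("non-finite fluorescence")
  structure(data.frame(temperature = temperature,
                       fluorescence = fluorescence,
                       replicate_id = replicate_id),
            class = c("melt_curve", "data.frame"))
}

#' Simulate a Sypro-Orange-style melt curve
#'
#' Sum of two-state sigmoids `A / (1 + exp((Tm - T)/s))` (one per unfolding
#' transition, e.g. Fab and Fc) plus a linear baseline, an optional
#' exponential post-peak quench, and seeded Gaussian noise.  The analytic
#' inflection of each noiseless sigmoid sits exactly at its Tm.
#'
#' @param transitions data frame or list with columns/fields `tm` (degrees
#'   C), `amplitude`, `slope` (degrees C, > 0).
#' @param temperature temperature grid (default 25-99 in 0.5 degree steps).
#' @param baseline `c(intercept, slope_per_degree)`.
#' @param quench optional `c(T_onset, rate)`: beyond `T_onset` the signal is
#'   scaled by `exp(-rate * (T - T_onset))`.
#' @param noise_sd Gaussian noise SD (signal units).
#' @param seed integer seed.
#' @param replicate_id replicate label.
#' @return a [melt_curve()].
#' @export
simulate_melt <- function(transitions, temperature = seq(25, 99, by = 0.5),
                          baseline = c(0, 0), quench = NULL, noise_sd = 0,
                          seed = 1, replicate_id = 1L) {
  tr <- as.data.frame(transitions)
  if (any(tr$slope <= 0)) stopf("transition slopes must be > 0")
  if (any(tr$tm < min(temperature) | tr$tm > max(temperature)))
    stopf("transition Tm outside the temperature grid")
  f <- baseline[1] + baseline[2] * temperature
  for (i in seq_len(nrow(tr)))
    f <- f + tr$amplitude[i] / (1 + exp((tr$tm[i] - temperature) / tr$slope[i]))
  if (!is.null(quench)) {
    past <- temperature > quench[1]
    f[past] <- f[past] * exp(-quench[2] * (temperature[past] - quench[1]))
  }
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    set.seed(seed)
    f <- f + stats::rnorm(length(f), sd = noise_sd)
    .Random.seed_restore(old)
  }
  melt_curve(temperature, f, replicate_id)
}

#' Melting temperatures by the derivative method
#'
#' Smooths dF/dT (moving-average of central differences, window in grid
#' points) and reports local maxima above a prominence floor, each refined by
#' parabolic interpolation of the peak vertex.  Results are sorted by
#' descending peak height; an empty result (flat curve) is not an error.
#' Multi-transition curves yield one row per peak; `peak_rank` and the
#' `range` filter (e.g. a 60-85 degree Fab window) support peak assignment
#' in place of guessing.
#'
#' @param curve a [melt_curve()].
#' @param window smoothing window in grid points (odd, default 5).
#' @param prominence_floor minimum peak height as a fraction of the largest
#'   |dF/dT| (default 0.1); peaks must also be positive.
#' @param range optional `c(lo, hi)` temperature window to restrict reported
#'   peaks.
#' @return data frame: tm, peak_height, peak_rank.
#' @export
tm_derivative <- function(curve, window = 5, prominence_floor = 0.1,
                          range = NULL) {
  tt <- curve$temperature
  ff <- curve$fluorescence
  if (length(tt) < 20) stopf("need at least 20 grid points")
  n <- length(tt)
  # central differences (one-sided at the ends)
  d <- c((ff[2] - ff[1]) / (tt[2] - tt[1]),
         (ff[3:n] - ff[1:(n - 2)]) / (tt[3:n] - tt[1:(n - 2)]),
         (ff[n] - ff[n - 1]) / (tt[n] - tt[n - 1]))
  if (window > 1) {
    k <- rep(1 / window, window)
    pad <- (window - 1) / 2
    d <- stats::filter(c(rep(d[1], pad), d, rep(d[n], pad)), k)
    d <- as.numeric(d[(pad + 1):(pad + n)])
  }
  floor_h <- prominence_floor * max(abs(d))
  peaks <- which(d > 0 & d >= floor_h)
  peaks <- peaks[peaks > 1 & peaks < n]
  peaks <- peaks[d[peaks] >= d[peaks - 1] & d[peaks] > d[peaks + 1]]
  if (!length(peaks))
    return(data.frame(tm = numeric(), peak_height = numeric(),
                      peak_rank = integer()))
  # parabolic refinement through the vertex
  tm <- vapply(peaks, function(i) {
    y1 <- d[i - 1]; y2 <- d[i]; y3 <- d[i + 1]
    den <- y1 - 2 * y2 + y3
    off <- if (abs(den) > 1e-12) 0.5 * (y1 - y3) / den else 0
    tt[i] + off * (tt[i + 1] - tt[i - 1]) / 2
  }, numeric(1))
  out <- data.frame(tm = tm, peak_height = d[peaks])
  if (!is.null(range))
    out <- out[out$tm >= range[1] & out$tm <= range[2], , drop = FALSE]
  out <- out[order(-out$peak_height), , drop = FALSE]
  out$peak_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

pooled_t_from_summary <- function(n1, m1, s1, n2, m2, s2) {
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  df <- n1 + n2 - 2
  p <- if (se == 0) {
    if (m1 == m2) 1 else 0
  } else 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

#' Melting-temperature shift with pooled Student's t test
#'
#' Delta-Tm = mean(test) - mean(ref), reported to one decimal (half away
#' from zero); the p-value comes from a two-tailed pooled-variance
#' two-sample Student's t test (not Welch).
#'
#' @param test,ref numeric vectors of replicate Tm values (>= 2 each).
#' @return list: `delta_tm` (1 decimal), `delta_tm_raw`, `p_value`, `t`,
#'   `df`.
#' @export
delta_tm <- function(test, ref) {
  if (length(test) < 2 || length(ref) < 2)
    stopf("need at least 2 replicates per group")
  res <- pooled_t_from_summary(length(test), mean(test), stats::sd(test),
                               length(ref), mean(ref), stats::sd(ref))
  d <- mean(test) - mean(ref)
  list(delta_tm = round_half_away(d, 1), delta_tm_raw = d,
       p_value = res$p, t = res$t, df = res$df)
}

#' Delta-Tm and pooled t test from summary statistics
#'
#' Same computation as [delta_tm()] starting from (n, mean, sd) per group,
#' as printed in stability tables.
#'
#' @param n_test,mean_test,sd_test,n_ref,mean_ref,sd_ref group summaries.
#' @return list as in [delta_tm()].
#' @export
delta_tm_summary <- function(n_test, mean_test, sd_test,
                             n_ref, mean_ref, sd_ref) {
  res <- pooled_t_from_summary(n_test, mean_test, sd_test,
                               n_ref, mean_ref, sd_ref)
  d <- mean_test - mean_ref
  list(delta_tm = round_half_away(d, 1), delta_tm_raw = d,
       p_value = res$p, t = res$t, df = res$df)
}
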