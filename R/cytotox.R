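# ADCC dose-response analysis: specific lysis, variable-slope 4PL fit,
# EC50, extra-sum-of-squares F test, relative potency

#' Percent specific lysis from chromium-release counts
#'
#' `100 * (sample - spontaneous) / (maximal - spontaneous)`.
#'
#' @param sample_cpm,spontaneous_cpm,maximal_cpm counts per minute.
#' @return percent specific lysis.
#' @export
specific_lysis <- function(sample_cpm, spontaneous_cpm, maximal_cpm) {
  if (any(maximal_cpm <= spontaneous_cpm))
    stopf("maximal release must exceed spontaneous release")
  100 * (sample_cpm - spontaneous_cpm) / (maximal_cpm - spontaneous_cpm)
}

#' Construct a dose-response table
#'
#' @param concentration antibody concentration, ug/mL (> 0, typically
#'   log-spaced).
#' @param lysis percent specific lysis.
#' @param replicate_id replicate labels.
#' @param sample sample name.
#' @return data frame of class `dose_response`.
#' @export
dose_response <- function(concentration, lysis, replicate_id = 1L,
                          sample = "sample") {
  if (any(concentration <= 0)) stopf("concentrations must be > 0")
  structure(data.frame(concentration = concentration, lysis = lysis,
                       replicate_id = replicate_id, sample = sample),
            class = c("dose_response", "data.frame"))
}

four_pl <- function(logx, bottom, top, log_ec50, hill)
  bottom + (top - bottom) / (1 + 10^((log_ec50 - logx) * hill))

fourpl_start <- function(logx, y) {
  qs <- stats::quantile(y, c(0.05, 0.95), names = FALSE)
  c(bottom = qs[1], top = qs[2],
    log_ec50 = stats::median(logx), hill = 1)
}

#' Fit a variable-slope four-parameter logistic dose-response model
#'
#' `y = bottom + (top - bottom) / (1 + 10^((log10 EC50 - log10 x) * hill))`,
#' fitted by nonlinear least squares ([minpack.lm::nls.lm()]) with starting
#' values from the data quartiles.
#'
#' @param dr a [dose_response()] (>= 5 distinct concentrations).
#' @return list of class `fourpl_fit`: bottom, top, log_ec50, ec50, hill,
#'   rss, n_points, se.
#' @export
fit_4pl <- function(dr) {
  logx <- log10(dr$concentration)
  y <- dr$lysis
  if (length(unique(dr$concentration)) < 5)
    stopf("need at least 5 distinct concentrations")
  if (stats::sd(y) == 0)
    stopf("non-convergence: constant response, EC50 unidentifiable")
  st <- fourpl_start(logx, y)
  fit <- minpack.lm::nls.lm(
    par = st,
    fn = function(p) four_pl(logx, p[1], p[2], p[3], p[4]) - y,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12))
  if (!fit$info %in% 1:4)
    stopf("non-convergence: %s", fit$message)
  p <- fit$par
  if (p[2] < p[1]) {  # normalise so top >= bottom (hill flips sign)
    p[c(1, 2)] <- p[c(2, 1)]
    p[4] <- -p[4]
  }
  rng <- range(logx)
  if (p[3] < rng[1] - 2 || p[3] > rng[2] + 2)
    stopf("EC50 estimate far outside the tested concentration range (log10 EC50 = %.2f)",
          p[3])
  rss <- sum(fit$fvec^2)
  dof <- length(y) - 4
  covm <- tryCatch(solve(fit$hessian) * rss / max(dof, 1),
                   error = function(e) matrix(NA, 4, 4))
  se <- sqrt(pmax(diag(covm), 0))
  names(se) <- c("bottom", "top", "log_ec50", "hill")
  structure(list(bottom = unname(p[1]), top = unname(p[2]),
                 log_ec50 = unname(p[3]), ec50 = 10^unname(p[3]),
                 hill = unname(p[4]), rss = rss, n_points = length(y),
                 se = se),
            class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf("<fourpl_fit> EC50 %.4g  hill %.2f  bottom %.1f  top %.1f  RSS %.3g (n=%d)\n",
              x$ec50, x$hill, x$bottom, x$top, x$rss, x$n_points))
  invisible(x)
}

# joint fit of two samples sharing log_ec50; per-sample bottom/top/hill.
# started from the separate fits (when supplied) so the constrained optimum
# is reached reliably
fit_4pl_shared <- function(dr_a, dr_b, fit_a = NULL, fit_b = NULL) {
  la <- log10(dr_a$concentration); ya <- dr_a$lysis
  lb <- log10(dr_b$concentration); yb <- dr_b$lysis
  resid_fn <- function(p) c(four_pl(la, p[1], p[2], p[5], p[6]) - ya,
                            four_pl(lb, p[3], p[4], p[5], p[7]) - yb)
  # several starting EC50s (each sample's own estimate and their midpoint);
  # the constrained optimum is the lowest RSS over starts
  starts <- if (!is.null(fit_a) && !is.null(fit_b)) {
    base <- c(bottom_a = fit_a$bottom, top_a = fit_a$top,
              bottom_b = fit_b$bottom, top_b = fit_b$top,
              log_ec50 = NA_real_,
              hill_a = fit_a$hill, hill_b = fit_b$hill)
    lapply(c((fit_a$log_ec50 + fit_b$log_ec50) / 2,
             fit_a$log_ec50, fit_b$log_ec50),
           function(le) { base["log_ec50"] <- le; base })
  } else {
    sa <- fourpl_start(la, ya); sb <- fourpl_start(lb, yb)
    list(c(sa[c("bottom", "top")], sb[c("bottom", "top")],
           log_ec50 = unname((sa["log_ec50"] + sb["log_ec50"]) / 2),
           hill_a = 1, hill_b = 1))
  }
  best <- NULL
  for (st in starts) {
    fit <- minpack.lm::nls.lm(
      par = st, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-12))
    if (!fit$info %in% 1:4) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(rss = rss, log_ec50 = unname(fit$par[5]))
  }
  if (is.null(best)) stopf("shared fit did not converge")
  list(rss = best$rss, n_par = 7,
       n_points = length(ya) + length(yb), log_ec50 = best$log_ec50)
}

#' Compare EC50s by the extra-sum-of-squares F test
#'
#' Null model: both samples share one log10 EC50 (bottom, top and hill remain
#' per-sample); alternative: separate EC50s (the two individual fits).
#' `F = [(RSS_shared - RSS_sep)/(df_shared - df_sep)] / [RSS_sep/df_sep]`,
#' p from the F distribution.  A shared fit that beats the separate fits
#' (RSS_sep > RSS_shared, possible only numerically) is clipped to F = 0,
#' p = 1.
#'
#' @param dr_a,dr_b the two [dose_response()] tables.
#' @param fit_a,fit_b optional precomputed [fit_4pl()] results.
#' @return list: `F`, `p_value`, `df1`, `df2`, RSS components, and the
#'   shared log10 EC50.
#' @export
compare_ec50 <- function(dr_a, dr_b, fit_a = NULL, fit_b = NULL) {
  fit_a <- fit_a %||% fit_4pl(dr_a)
  fit_b <- fit_b %||% fit_4pl(dr_b)
  shared <- fit_4pl_shared(dr_a, dr_b, fit_a, fit_b)
  rss_sep <- fit_a$rss + fit_b$rss
  n <- shared$n_points
  df_sep <- n - 8
  df_shared <- n - shared$n_par
  Fv <- ((shared$rss - rss_sep) / (df_shared - df_sep)) / (rss_sep / df_sep)
  if (!is.finite(Fv) || Fv < 0) Fv <- 0
  p <- stats::pf(Fv, df_shared - df_sep, df_sep, lower.tail = FALSE)
  list(F = Fv, p_value = p, df1 = df_shared - df_sep, df2 = df_sep,
       rss_shared = shared$rss, rss_separate = rss_sep,
       shared_log_ec50 = shared$log_ec50)
}

#' Relative potency of a test sample against a reference
#'
#' `EC50_ref / EC50_test`, one decimal with halves rounded away from zero
#' (a ratio above 1 means the test sample is more potent).
#'
#' @param ec50_ref,ec50_test EC50s in the same units (> 0).
#' @return potency ratio, 1 decimal.
#' @export
relative_potency <- function(ec50_ref, ec50_test) {
  if (ec50_ref <= 0 || ec50_test <= 0) stopf("EC50s must be > 0")
  round_half_away(ec50_ref / ec50_test, 1)
}
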