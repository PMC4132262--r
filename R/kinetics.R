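# bivalent-analyte SPR kinetics: forward simulator, global fitter, K_D
#
# Scheme: a two-armed analyte A binds one immobilized ligand site (apparent
# rates k_on, k_off; statistical factor 2 on the first binding) and may then
# bridge a second site (k_on2, k_off2; factor 2 on the second release):
#
#   d[AB]/dt  = 2 k_on C L - k_off [AB] - k_on2 [AB] L + 2 k_off2 [AB2]
#   d[AB2]/dt = k_on2 [AB] L - 2 k_off2 [AB2],   L = R_max - [AB] - [AB2]
#
# with C the analyte concentration during association and 0 afterwards;
# the reported response is [AB] + [AB2].  K_D = k_off / k_on refers to the
# first step.

#' Kinetic parameters of the bivalent-analyte model
#'
#' @param k_on apparent first-step association rate, 1/(M s).
#' @param k_off apparent first-step dissociation rate, 1/s.
#' @param k_on2 second-step (bridging) association rate, 1/(RU s).
#' @param k_off2 second-step dissociation rate, 1/s.
#' @param R_max surface capacity, RU.
#' @return list of class `kinetic_params`.
#' @export
kinetic_params <- function(k_on = 1e5, k_off = 1e-3, k_on2 = 1e-4,
                           k_off2 = 1e-3, R_max = 100) {
  p <- c(k_on = k_on, k_off = k_off, k_on2 = k_on2, k_off2 = k_off2,
         R_max = R_max)
  if (any(p < 0)) stopf("rates and R_max must be >= 0")
  if (R_max <= 0) stopf("R_max must be > 0")
  structure(as.list(p), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("<kinetic_params> k_on %.3g 1/(M s)  k_off %.3g 1/s  k_on2 %.3g  k_off2 %.3g  R_max %.3g RU  (K_D %.3g nM)\n",
              x$k_on, x$k_off, x$k_on2, x$k_off2, x$R_max,
              if (x$k_on > 0) 1e9 * x$k_off / x$k_on else NA))
  invisible(x)
}

#' Construct a sensorgram
#'
#' @param time strictly increasing time grid, s.
#' @param response RU.
#' @param concentration analyte concentration, M.
#' @param t_assoc_end end of the association phase, s.
#' @return data frame of class `sensorgram` with the concentration and phase
#'   boundary as attributes.
#' @export
sensorgram <- function(time, response, concentration, t_assoc_end) {
  if (any(diff(time) <= 0)) stopf("time grid must be strictly increasing")
  if (!all(is.finite(response))) stopf("non-finite response values")
  if (t_assoc_end <= 0 || t_assoc_end >= max(time))
    stopf("t_assoc_end must lie inside the time range")
  structure(data.frame(time = time, response = response),
            concentration = concentration, t_assoc_end = t_assoc_end,
            class = c("sensorgram", "data.frame"))
}

bivalent_rhs <- function(t, y, parms) {
  L <- parms$R_max - y[1] - y[2]
  v2 <- parms$k_on2 * y[1] * L - 2 * parms$k_off2 * y[2]
  d1 <- 2 * parms$k_on * parms$C * L - parms$k_off * y[1] - v2
  list(c(d1, v2))
}

#' Simulate a bivalent-analyte sensorgram
#'
#' Integrates the bivalent scheme with a stiff-safe solver
#' ([deSolve::lsoda()], rtol 1e-8) in two segments (association with C =
#' `conc`, dissociation with C = 0) and reports the response on the
#' requested output grid.
#'
#' @param p a [kinetic_params()].
#' @param conc analyte concentration, M.
#' @param grid output time grid, s (strictly increasing, starting at 0).
#' @param t_assoc_end association-phase end, s.
#' @return a [sensorgram()].
#' @export
simulate_bivalent <- function(p, conc, grid = seq(0, 420, by = 1),
                              t_assoc_end = 120) {
  stopifnot(inherits(p, "kinetic_params"))
  if (any(diff(grid) <= 0)) stopf("time grid must be strictly increasing")
  if (conc < 0) stopf("concentration must be >= 0")
  if (conc == 0)
    return(sensorgram(grid, rep(0, length(grid)), conc, t_assoc_end))
  ta <- sort(unique(c(grid[grid <= t_assoc_end], t_assoc_end)))
  if (ta[1] > 0) ta <- c(0, ta)
  parms <- c(p, list(C = conc))
  oa <- deSolve::lsoda(c(AB = 0, AB2 = 0), ta, bivalent_rhs, parms,
                       rtol = 1e-8, atol = 1e-10)
  td <- sort(unique(c(t_assoc_end, grid[grid > t_assoc_end])))
  y0 <- oa[nrow(oa), c("AB", "AB2")]
  parms$C <- 0
  od <- deSolve::lsoda(y0, td, bivalent_rhs, parms, rtol = 1e-8, atol = 1e-10)
  all_t <- c(oa[, "time"], od[-1, "time"])
  all_r <- c(oa[, "AB"] + oa[, "AB2"], od[-1, "AB"] + od[-1, "AB2"])
  resp <- stats::approx(all_t, all_r, xout = grid)$y
  sensorgram(grid, resp, conc, t_assoc_end)
}

#' Closed-form 1:1 Langmuir sensorgram (reduced model)
#'
#' Analytic solution of the bivalent scheme with `k_on2 = 0`: association
#' approaches the plateau `R_max * 2 k_on C / (2 k_on C + k_off)` with
#' observed rate `k_obs = 2 k_on C + k_off` (the statistical factor 2 on
#' first binding carries into the reduced model), and dissociation decays as
#' `exp(-k_off t)`.  Used as an independent oracle for the simulator.
#'
#' @inheritParams simulate_bivalent
#' @return a [sensorgram()].
#' @export
langmuir_closed_form <- function(p, conc, grid = seq(0, 420, by = 1),
                                 t_assoc_end = 120) {
  ka <- 2 * p$k_on * conc
  kobs <- ka + p$k_off
  req <- if (kobs > 0) p$R_max * ka / kobs else 0
  r <- ifelse(grid <= t_assoc_end,
              req * (1 - exp(-kobs * grid)),
              req * (1 - exp(-kobs * t_assoc_end)) *
                exp(-p$k_off * (grid - t_assoc_end)))
  sensorgram(grid, r, conc, t_assoc_end)
}

params_from_log <- function(th) {
  kinetic_params(k_on = exp(th[1]), k_off = exp(th[2]), k_on2 = exp(th[3]),
                 k_off2 = exp(th[4]), R_max = exp(th[5]))
}

#' Globally fit the bivalent model to a multi-concentration sensorgram set
#'
#' Joint nonlinear least squares over all curves with one shared parameter
#' vector (log-transformed to keep rates positive), via
#' [minpack.lm::nls.lm()].  Initial values default to k_on 1e5, k_off 1e-3,
#' k_on2 1e-4, k_off2 1e-3 and R_max = 1.1 x the maximum observed response.
#'
#' @param curves list of [sensorgram()]s at two or more concentrations
#'   spanning at least fourfold.
#' @param init optional [kinetic_params()] starting point.
#' @return list of class `bivalent_fit`: `params`, `rss`, `se` (per-parameter
#'   standard errors from the Jacobian), `diag` (optimizer diagnostics).
#' @export
fit_bivalent <- function(curves, init = NULL) {
  concs <- vapply(curves, function(s) attr(s, "concentration"), numeric(1))
  if (length(unique(concs)) < 2 || max(concs) / min(concs[concs > 0]) < 4)
    stopf("need >= 2 concentrations spanning >= 4-fold")
  obs <- unlist(lapply(curves, function(s) s$response))
  if (max(abs(obs)) == 0)
    stopf("non-convergence: all responses are zero, model is unidentifiable")
  if (is.null(init))
    init <- kinetic_params(R_max = 1.1 * max(obs))
  th0 <- log(c(init$k_on, init$k_off, init$k_on2, init$k_off2, init$R_max))
  resid_fun <- function(th) {
    p <- params_from_log(th)
    unlist(lapply(curves, function(s) {
      sim <- simulate_bivalent(p, attr(s, "concentration"), s$time,
                               attr(s, "t_assoc_end"))
      sim$response - s$response
    }))
  }
  fit <- minpack.lm::nls.lm(par = th0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-10))
  if (!fit$info %in% 1:4)
    stopf("non-convergence (%s); RSS trace: %s", fit$message,
          paste(signif(utils::tail(fit$rsstrace, 5), 6), collapse = ", "))
  th <- fit$par
  p <- params_from_log(th)
  rss <- sum(fit$fvec^2)
  dof <- length(fit$fvec) - length(th)
  # standard errors on the natural scale via the delta method
  covl <- tryCatch(solve(fit$hessian) * rss / dof,
                   error = function(e) matrix(NA, 5, 5))
  se_log <- sqrt(pmax(diag(covl), 0))
  se <- se_log * exp(th)
  names(se) <- c("k_on", "k_off", "k_on2", "k_off2", "R_max")
  structure(list(params = p, rss = rss, se = se,
                 diag = list(info = fit$info, message = fit$message,
                             niter = fit$niter,
                             rsstrace = fit$rsstrace)),
            class = "bivalent_fit")
}

#' @export
print.bivalent_fit <- function(x, ...) {
  print(x$params)
  cat(sprintf("  RSS %.4g, %d iterations\n", x$rss, x$diag$niter))
  invisible(x)
}

#' Equilibrium dissociation constant K_D = k_off / k_on
#'
#' @param p a [kinetic_params()], or a `bivalent_fit`.
#' @return K_D in nM, 3 significant figures.
#' @export
equilibrium_kd <- function(p) {
  if (inherits(p, "bivalent_fit")) p <- p$params
  if (p$k_on <= 0) stopf("k_on must be > 0 to form K_D")
  signif3(1e9 * p$k_off / p$k_on)
}
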