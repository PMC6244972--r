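# Piecewise stiff integration with bolus events inserted as hard breakpoints.
# The integrator is restarted at every dose time; bolus amounts are added to
# the central compartment instantaneously.  An observation falling exactly on
# a dose time reports the post-dose state (t = 0+ after a bolus at t = 0 is
# dose/V1).
.integrate_piecewise <- function(y0, times, dose_times, dose_amounts,
                                 parms, func, initfunc, rtol, atol,
                                 neg_tol = 1e-6) {
  stopifnot(!is.unsorted(times), all(times >= 0))
  keep <- dose_amounts > 0
  dose_times <- dose_times[keep]
  dose_amounts <- dose_amounts[keep]
  t_end <- max(times, dose_times, 0)
  brk <- sort(unique(c(0, dose_times, t_end)))
  y <- y0
  out_t <- numeric(0)
  out_y <- NULL
  for (i in seq_len(length(brk) - 1L)) {
    a <- brk[i]; b <- brk[i + 1L]
    y[1] <- y[1] + sum(dose_amounts[dose_times == a])
    seg_obs <- times[times >= a & times < b]
    if (i == length(brk) - 1L) seg_obs <- times[times >= a & times <= b]
    tt <- sort(unique(c(a, seg_obs, b)))
    if (length(tt) == 1L) tt <- c(a, a)  # degenerate: all mass at one instant
    sol <- deSolve::lsoda(y = y, times = tt, func = func, parms = parms,
                          dllname = "transpkpd", initfunc = initfunc,
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1L] < 0) {
      stop(sprintf("ODE solver failed to converge on [%g, %g] h", a, b))
    }
    m <- unclass(sol)
    if (length(seg_obs)) {
      sel <- match(seg_obs, m[, 1L])
      out_t <- c(out_t, seg_obs)
      out_y <- rbind(out_y, m[sel, -1L, drop = FALSE])
    }
    y <- m[nrow(m), -1L]
  }
  # a dose falling exactly on the final time: post-dose reporting convention
  amt_end <- sum(dose_amounts[dose_times == t_end])
  if (amt_end > 0 && any(out_t == t_end)) {
    out_y[out_t == t_end, 1L] <- out_y[out_t == t_end, 1L] + amt_end
  }
  if (any(out_y < -neg_tol)) {
    stop(sprintf("negative state (min %.3g) beyond tolerance %g",
                 min(out_y), neg_tol))
  }
  out_y[out_y < 0] <- 0
  # times may repeat if requested; return in the order requested
  idx <- match(times, out_t)
  list(times = times, states = out_y[idx, , drop = FALSE])
}

#' Simulate the concentration-time course of the two-compartment model
#'
#' Deterministically integrates the disposition system
#' \deqn{dA_1/dt = -\frac{CL}{V_1}A_1 - \frac{V_{max} C_1}{K_m + C_1}
#'   - \frac{Q}{V_1}A_1 + \frac{Q}{V_2}A_2, \qquad
#'   dA_2/dt = \frac{Q}{V_1}A_1 - \frac{Q}{V_2}A_2}
#' with \eqn{C_1 = A_1/V_1}, under an arbitrary bolus regimen.  A stiff
#' solver (lsoda) is used because the Michaelis-Menten term makes the system
#' stiff near \eqn{C \approx K_m}; integration restarts exactly at each dose
#' event.
#'
#' @param params A [pk_params()] set.
#' @param reg A [regimen()].
#' @param times Output time grid (h), sorted, non-negative.  Observations at
#'   a dose time report the post-dose concentration.
#' @param rtol,atol Relative / absolute solver tolerances (absolute in mg).
#'
#' @return A data frame of class `conc_course` with columns `time` (h),
#'   `conc` (mg/L, equal to `A1/V1`), `A1` and `A2` (mg).
#' @export
#' @examples
#' h <- human_default_params()
#' sim <- simulate_pk(h, regimen(0, 360), times = c(0, 1, 24, 168, 504))
#' sim$conc[1] * h$V1  # == 360
simulate_pk <- function(params, reg, times, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "pk_params"), inherits(reg, "regimen"))
  if (is.unsorted(times) || any(times < 0)) {
    stop("times must be sorted and non-negative")
  }
  sol <- .integrate_piecewise(y0 = c(0, 0, 0), times = times,
                              dose_times = reg$time,
                              dose_amounts = .regimen_amounts(reg),
                              parms = .pk_parvec(params),
                              func = "pk_derivs", initfunc = "pk_init",
                              rtol = rtol, atol = atol)
  out <- data.frame(time = times,
                    conc = sol$states[, 1L] / params$V1,
                    A1 = sol$states[, 1L],
                    A2 = sol$states[, 2L])
  class(out) <- c("conc_course", "data.frame")
  out
}

# Batched solve of m independent copies of the pk system (one lsoda call for
# a whole study): parmat is m x 6 (CL, V1, Q, V2, Vmax, Km), amt_rows m x k
# for k shared dose times.  Returns the m x length(times) concentration
# matrix.  Used by the estimation code, where solver-call overhead dominates.
.pk_multi_solve <- function(parmat, dose_times, amt_rows, times,
                            rtol = 1e-8, atol = 1e-10) {
  m <- nrow(parmat)
  stopifnot(m <= 1024L)
  parms <- c(m, as.vector(t(parmat)))
  parms <- c(parms, numeric(6145L - length(parms)))
  amt_rows <- matrix(amt_rows, nrow = m)
  y <- numeric(2L * m)
  t_end <- max(times, dose_times)
  brk <- sort(unique(c(0, dose_times, t_end)))
  out <- matrix(NA_real_, m, length(times))
  for (i in seq_len(length(brk) - 1L)) {
    a <- brk[i]; b <- brk[i + 1L]
    k <- which(dose_times == a)
    if (length(k)) {
      y[2L * seq_len(m) - 1L] <- y[2L * seq_len(m) - 1L] +
        rowSums(amt_rows[, k, drop = FALSE])
    }
    seg_obs <- times[times >= a & times < b]
    if (i == length(brk) - 1L) seg_obs <- times[times >= a & times <= b]
    tt <- sort(unique(c(a, seg_obs, b)))
    if (length(tt) == 1L) tt <- c(a, a)
    sol <- deSolve::lsoda(y = y, times = tt, func = "pk_multi_derivs",
                          parms = parms, dllname = "transpkpd",
                          initfunc = "pk_multi_init",
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1L] < 0) {
      stop(sprintf("batched ODE solve failed on [%g, %g] h", a, b))
    }
    mm <- unclass(sol)
    if (length(seg_obs)) {
      sel <- match(seg_obs, mm[, 1L])
      out[, match(seg_obs, times)] <- t(mm[sel, 1L + 2L * seq_len(m) - 1L,
                                           drop = FALSE])
    }
    y <- mm[nrow(mm), -1L]
  }
  out / parmat[, 2L]
}

# single-bolus simulation that also carries the running AUC state;
# internal workhorse for the exposure metrics
.simulate_single_bolus_auc <- function(params, dose, times,
                                       rtol = 1e-10, atol = 1e-12) {
  sol <- .integrate_piecewise(y0 = c(0, 0, 0), times = times,
                              dose_times = 0, dose_amounts = dose,
                              parms = .pk_parvec(params),
                              func = "pk_derivs", initfunc = "pk_init",
                              rtol = rtol, atol = atol)
  data.frame(time = times,
             conc = sol$states[, 1L] / params$V1,
             auc = sol$states[, 3L])
}
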