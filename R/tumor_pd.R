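#' Tumor-growth-inhibition model parameters
#'
#' Parameters of the JIMT-1 xenograft tumor model.  Untreated tumors grow
#' with a zero-order rate inflated over time by a progression factor; drug
#' acts twice: it inhibits the production side of an indirect-response
#' effect state `I` gating the growth flux (turnover rate `Kio`, potency
#' `EC50`), and it switches on a first-order kill term through a stimulatory
#' Emax function (potency `EC50_KD`).  The kill term is absent without drug,
#' so vehicle tumors grow; its very low `EC50_KD` means it is effectively
#' saturated at any measurable exposure and represents the natural dying
#' rate of a tumor whose growth signal has been shut off.
#'
#' @param Base Baseline tumor volume at treatment start (mm^3).
#' @param KG Zero-order growth rate (mm^3/h).
#' @param KD First-order dying rate (1/h).
#' @param Kio Turnover rate of the drug-effect state (1/h).
#' @param EC50 Drug concentration at half-maximal growth inhibition (mg/L).
#' @param EC50_KD Drug concentration at half-maximal kill stimulation
#'   (mg/L; note the published value of 0.0102 ug/L is 1.02e-5 mg/L).
#' @param Emax_g,Emax_d Maximum fractional effects, fixed at 1.
#' @param lam Progression factor (1/week); converted to 1/h internally.
#' @param progression `"linear"` for a growth flux `KG * (1 + lam * t)`
#'   (default) or `"exponential"` for `KG * exp(lam * t)`.
#'
#' @return An object of class `pd_params`.
#' @export
#' @examples
#' pd_params()  # published xenograft estimates
pd_params <- function(Base = 177, KG = 0.338, KD = 0.004, Kio = 0.143,
                      EC50 = 2.60, EC50_KD = 1.02e-5, Emax_g = 1,
                      Emax_d = 1, lam = 0.172,
                      progression = c("linear", "exponential")) {
  progression <- match.arg(progression)
  p <- list(Base = Base, KG = KG, KD = KD, Kio = Kio, EC50 = EC50,
            EC50_KD = EC50_KD, Emax_g = Emax_g, Emax_d = Emax_d, lam = lam,
            progression = progression)
  vals <- unlist(p[1:9])
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("PD parameters must be strictly positive and finite")
  }
  structure(p, class = "pd_params")
}

#' @export
print.pd_params <- function(x, ...) {
  cat("Xenograft tumor-growth-inhibition parameters:\n")
  cat(sprintf("  Base %.4g mm^3  KG %.4g mm^3/h  KD %.4g 1/h\n",
              x$Base, x$KG, x$KD))
  cat(sprintf("  Kio %.4g 1/h  EC50 %.4g mg/L  EC50_KD %.4g mg/L\n",
              x$Kio, x$EC50, x$EC50_KD))
  cat(sprintf("  lam %.4g 1/week (%s progression)\n", x$lam, x$progression))
  invisible(x)
}

# hours per week; the progression factor is reported per week
.H_PER_WEEK <- 168

.pkpd_parvec <- function(pd, pk) {
  c(.pk_parvec(pk), pd$KG, pd$KD, pd$Kio, pd$EC50, pd$EC50_KD,
    pd$Emax_g, pd$Emax_d, pd$lam / .H_PER_WEEK,
    if (pd$progression == "exponential") 1 else 0)
}

#' Simulate a tumor-volume course under a dosing regimen
#'
#' Jointly integrates the mouse disposition model and the tumor system
#' \deqn{dI/dt = K_{io}\left(1 - \frac{E_{max,g} C}{EC_{50}+C}\right) - K_{io} I,
#'   \quad I(0) = 1}
#' \deqn{dT/dt = K_G (1 + \lambda t)\, I -
#'   K_D \frac{E_{max,d} C}{EC_{50,KD}+C}\, T, \quad T(0) = Base}
#' with \eqn{C(t)} the central concentration from the allometrically scaled
#' mouse PK model.  The effect state gates the whole (progression-inflated)
#' growth flux; time zero of the progression term is treatment start.
#'
#' @param pd A [pd_params()] set.
#' @param mouse_pk A [pk_params()] set at mouse weight.
#' @param reg A [regimen()] (amounts in mg).
#' @param times Output grid (h).
#' @param rtol,atol Solver tolerances.
#' @return A data frame of class `tumor_course` with columns `time` (h),
#'   `volume` (mm^3), `effect` (the state `I`), `conc` (mg/L).
#' @export
#' @examples
#' tc <- simulate_tumor(pd_params(), mouse_default_params(),
#'                      weekly_regimen(0.19, 3), times = seq(0, 504, 24))
simulate_tumor <- function(pd, mouse_pk, reg, times,
                           rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(pd, "pd_params"), inherits(mouse_pk, "pk_params"),
            inherits(reg, "regimen"))
  if (is.unsorted(times) || any(times < 0)) {
    stop("times must be sorted and non-negative")
  }
  sol <- .integrate_piecewise(y0 = c(0, 0, 1, pd$Base), times = times,
                              dose_times = reg$time,
                              dose_amounts = .regimen_amounts(reg),
                              parms = .pkpd_parvec(pd, mouse_pk),
                              func = "pkpd_derivs", initfunc = "pkpd_init",
                              rtol = rtol, atol = atol)
  out <- data.frame(time = times,
                    volume = sol$states[, 4L],
                    effect = sol$states[, 3L],
                    conc = sol$states[, 1L] / mouse_pk$V1)
  class(out) <- c("tumor_course", "data.frame")
  out
}

#' Closed-form vehicle (untreated) tumor course
#'
#' With no drug the effect state stays at 1 and the tumor ODE integrates in
#' closed form to \eqn{T(t) = Base + K_G (t + \lambda t^2 / 2)} (linear
#' progression) or \eqn{T(t) = Base + K_G (e^{\lambda t} - 1)/\lambda}
#' (exponential progression).
#'
#' @param pd A [pd_params()] set.
#' @param times Times (h).
#' @return Tumor volumes (mm^3).
#' @export
vehicle_tumor_volume <- function(pd, times) {
  stopifnot(inherits(pd, "pd_params"))
  lam_h <- pd$lam / .H_PER_WEEK
  if (pd$progression == "linear") {
    pd$Base + pd$KG * (times + lam_h * times^2 / 2)
  } else {
    pd$Base + pd$KG * (exp(lam_h * times) - 1) / lam_h
  }
}

#' Tumor stasis metric
#'
#' Ratio of tumor volume at the evaluation day to baseline.  A ratio of at
#' most 1 is classified as stasis or regression, above 1 as progression.
#'
#' @param course A `tumor_course` from [simulate_tumor()] covering the day.
#' @param day Evaluation day (days after treatment start); 21 by default.
#' @return A list with `ratio`, `classification` and `day`.
#' @export
stasis_metric <- function(course, day = 21) {
  stopifnot(inherits(course, "tumor_course"))
  t_eval <- day * 24
  if (t_eval > max(course$time) || min(course$time) > 0) {
    stop("course must cover time 0 through day ", day)
  }
  v0 <- course$volume[course$time == min(course$time)][1L]
  v <- stats::approx(course$time, course$volume, xout = t_eval)$y
  ratio <- v / v0
  list(ratio = ratio,
       classification = if (ratio <= 1) "stasis or regression" else
         "progression",
       day = day)
}

#' Mouse weekly dose matching a human exposure
#'
#' Finds, by bisection, the weekly mouse dose whose total exposure over an
#' `n_weekly_doses`-dose weekly regimen equals the human single-dose
#' AUC(0-inf) of a candidate flat dose given once per three-week cycle.
#' Because clearance is saturable, AUC/dose grows with dose and the root is
#' unique.  The matching convention (which AUC is computed on each side) is
#' not uniquely determined by the published dose pairs; it is exposed via
#' `human_auc_method`/`mouse_auc_method` and the default matches total
#' mouse AUC(0-inf), with the human side on the reporting (NCA) convention.
#'
#' @param target_human_dose Human flat dose (mg).
#' @param n_weekly_doses Number of weekly mouse doses (3 for the day-21
#'   stasis evaluation).
#' @param human,mouse [pk_params()] sets for the two species.
#' @param mouse_weight Mouse weight (kg) used to report the dose per kg.
#' @param human_auc_method AUC convention for the human side (see
#'   [auc_inf()]); the mouse side is always the true integral of the
#'   simulated multi-dose curve.
#' @param tol Relative AUC-matching tolerance for the bisection.
#' @return A list with `weekly_dose_mg`, `weekly_dose_mg_per_kg`,
#'   `target_auc` and `achieved_auc` (g.h/L).
#' @export
#' @examples
#' auc_matched_mouse_dose(360)$weekly_dose_mg_per_kg
auc_matched_mouse_dose <- function(target_human_dose, n_weekly_doses = 3,
                                   human = human_default_params(),
                                   mouse = mouse_default_params(),
                                   mouse_weight = mouse$body_weight,
                                   human_auc_method = "nca",
                                   tol = 1e-4) {
  if (target_human_dose < 0) stop("target_human_dose must be non-negative")
  if (target_human_dose == 0) {
    return(list(weekly_dose_mg = 0, weekly_dose_mg_per_kg = 0,
                target_auc = 0, achieved_auc = 0))
  }
  target <- auc_inf(human, target_human_dose, method = human_auc_method)
  mouse_total_auc <- function(d) {
    reg <- weekly_regimen(d, n_weekly_doses, route = "iv_bolus")
    horizon <- .H_PER_WEEK * n_weekly_doses
    repeat {
      sim <- .integrate_piecewise(y0 = c(0, 0, 0),
                                  times = c(0, horizon),
                                  dose_times = reg$time,
                                  dose_amounts = .regimen_amounts(reg),
                                  parms = .pk_parvec(mouse),
                                  func = "pk_derivs", initfunc = "pk_init",
                                  rtol = 1e-10, atol = 1e-12)
      if (sim$states[2L, 1L] / mouse$V1 < 1e-6) break
      horizon <- horizon * 2
    }
    sim$states[2L, 3L] / 1000
  }
  # bracket: AUC is continuous and strictly increasing in dose
  lo <- 0
  hi <- target_human_dose * mouse$CL / human$CL  # generous linear guess
  while (mouse_total_auc(hi) < target) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    a <- mouse_total_auc(mid)
    if (abs(a - target) <= tol * target) break
    if (a < target) lo <- mid else hi <- mid
  }
  list(weekly_dose_mg = mid,
       weekly_dose_mg_per_kg = mid / mouse_weight,
       target_auc = target, achieved_auc = a)
}
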