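#' Caliper tumor volume
#'
#' `volume (mm^3) = width^2 * length / 2`, the standard two-axis caliper
#' formula (width is the shorter axis).
#'
#' @param width,length Caliper axes in mm, positive, `width <= length`.
#' @return Volume in mm^3; vectorized.
#' @export
#' @examples
#' caliper_volume(10, 10)  # 500
caliper_volume <- function(width, length) {
  if (any(width <= 0) || any(length <= 0)) {
    stop("caliper axes must be positive")
  }
  if (any(width > length)) {
    stop("width must not exceed length (width is the short axis)")
  }
  width^2 * length / 2
}

#' Monkey PK study designs
#'
#' The two cynomolgus toxicity-study layouts the PK model was estimated
#' from.  `monkey_single_dose_design()`: dose groups of 10, 30 and
#' 100 mg/kg IV, two animals each (one female, one male), 14 samples per
#' animal over 0-1007 h.  `monkey_repeat_dose_design()`: first week of the
#' repeated-dose study, 22 animals (6 / 6 / 10 per dose group), weekly
#' dosing, 10 samples per animal over 0-168 h (only the first dose falls in
#' the window).  Exact sampling times within the reported windows are not
#' part of the published record; the defaults are a standard rich sampling
#' grid and are configurable.
#'
#' @param sampling_times Sampling times (h) per animal.
#' @param weight_range Range (kg) monkey body weights are drawn from
#'   (uniformly); weights are not part of the published record either.
#' @return An object of class `study_design`.
#' @export
monkey_single_dose_design <- function(
    sampling_times = c(1, 4, 8, 24, 48, 96, 168, 240, 336, 432, 528, 672,
                       840, 1007),
    weight_range = c(2.5, 3.5)) {
  structure(list(arms = data.frame(dose_mg_per_kg = c(10, 30, 100),
                                   n = c(2, 2, 2)),
                 sampling_times = sampling_times,
                 dose_times = 0,
                 weight_range = weight_range,
                 route = "iv_bolus"),
            class = "study_design")
}

#' @rdname monkey_single_dose_design
#' @export
monkey_repeat_dose_design <- function(
    sampling_times = c(1, 4, 8, 24, 48, 72, 96, 120, 144, 168),
    weight_range = c(2.5, 3.5)) {
  structure(list(arms = data.frame(dose_mg_per_kg = c(10, 30, 100),
                                   n = c(6, 6, 10)),
                 sampling_times = sampling_times,
                 dose_times = 0,
                 weight_range = weight_range,
                 route = "iv_bolus"),
            class = "study_design")
}

#' Generate a synthetic monkey PK study
#'
#' Simulates a study-shaped concentration dataset: per animal, a body
#' weight drawn from the design's range, truth parameters allometrically
#' scaled to that weight, lognormal between-subject deviates on the
#' parameters named in `omega`, residual-perturbed observations and the
#' below-quantification-limit rule.  Doses are weight-based (mg/kg).
#'
#' @param truth A [pk_params()] set at its anchor weight (the generator
#'   scales it to each animal's weight).
#' @param omega An [omega_spec()]; defaults to the published CVs on `CL`
#'   and `V1`.
#' @param residual A [residual_spec()]; published combined PK error.
#' @param lloq An [lloq_rule()] or `NULL`.
#' @param design A [monkey_single_dose_design()] /
#'   [monkey_repeat_dose_design()] or compatible `study_design`.
#' @param seed Integer seed for reproducibility, or `NULL` to use the
#'   current random stream.
#' @return A dataset data frame in the [read_dataset()] dialect, with the
#'   generating truth, seed and per-animal parameters attached as the
#'   `"manifest"` attribute.
#' @export
#' @examples
#' d <- generate_monkey_pk_study(seed = 1)
#' table(d$DOSEGRP[d$EVID == 0])
generate_monkey_pk_study <- function(truth = human_default_params(),
                                     omega = pk_omega_defaults(),
                                     residual = pk_residual_defaults(),
                                     lloq = lloq_rule(),
                                     design = monkey_single_dose_design(),
                                     seed = NULL) {
  stopifnot(inherits(design, "study_design"))
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  etas <- list()
  id <- 0L
  for (a in seq_len(nrow(design$arms))) {
    dose_kg <- design$arms$dose_mg_per_kg[a]
    for (k in seq_len(design$arms$n[a])) {
      id <- id + 1L
      wt <- stats::runif(1, design$weight_range[1L], design$weight_range[2L])
      pop_i <- scale_params(truth, wt)
      ind <- draw_individual(pop_i, omega)
      etas[[id]] <- attr(ind, "eta")
      amt <- dose_kg * wt
      pred <- simulate_pk(ind, regimen(design$dose_times, amt,
                                       route = design$route),
                          times = design$sampling_times)$conc
      o <- apply_residual(pred, residual, lloq)
      o$obs <- pmax(o$obs, 0)
      dose_rows <- data.frame(ID = id, TIME = design$dose_times, AMT = amt,
                              DV = NA_real_, EVID = 1, MDV = 1, CMT = 1,
                              WT = wt, DOSEGRP = dose_kg, BLQ = 0)
      obs_rows <- data.frame(ID = id, TIME = design$sampling_times,
                             AMT = NA_real_, DV = o$obs, EVID = 0, MDV = 0,
                             CMT = 1, WT = wt, DOSEGRP = dose_kg,
                             BLQ = as.numeric(o$blq))[o$keep, , drop = FALSE]
      rows[[id]] <- rbind(dose_rows, obs_rows)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "manifest") <- list(truth = truth, omega = omega,
                                residual = residual, lloq = lloq,
                                seed = seed, eta = etas)
  out
}

#' Xenograft study rules
#'
#' Conduct rules of the JIMT-1 efficacy study: treatment starts with
#' baseline tumors in 108-172 mm^3, four weekly intraperitoneal doses,
#' caliper measurement twice weekly (days 0, 3, 7, 10, ... relative to
#' treatment start), euthanasia at the first measurement of 800 mm^3 or
#' more, study end day 68.
#'
#' @param baseline_range Admissible baseline volumes (mm^3).
#' @param euthanasia_volume Censoring threshold (mm^3).
#' @param study_end_day Last study day (relative to treatment start).
#' @param n_doses,dose_interval Weekly dosing, four administrations.
#' @return An object of class `xenograft_rules`.
#' @export
xenograft_rules <- function(baseline_range = c(108, 172),
                            euthanasia_volume = 800, study_end_day = 68,
                            n_doses = 4, dose_interval = 168) {
  if (euthanasia_volume <= max(baseline_range)) {
    stop("euthanasia_volume must exceed the largest baseline")
  }
  m_days <- sort(c(seq(0, study_end_day, by = 7),
                   seq(3, study_end_day, by = 7)))
  structure(list(baseline_range = baseline_range,
                 euthanasia_volume = euthanasia_volume,
                 study_end_day = study_end_day,
                 n_doses = n_doses, dose_interval = dose_interval,
                 measurement_days = m_days),
            class = "xenograft_rules")
}

#' Generate a synthetic xenograft efficacy study
#'
#' Simulates tumor-volume datasets with the structure of the JIMT-1 study:
#' arms of vehicle, 2.5 and 25 mg/kg (n = 10 each), per-mouse baselines
#' drawn lognormally around `Base` and redrawn until inside the admissible
#' range, between-subject deviates on the parameters named in `omega`,
#' proportional measurement noise, and informative dropout (records are
#' censored after the first observed volume at or above the euthanasia
#' threshold).
#'
#' @param truth A [pd_params()] set.
#' @param mouse_pk A [pk_params()] set at mouse weight.
#' @param omega An [omega_spec()] on PD parameters.
#' @param residual A [residual_spec()] (proportional-only for volumes).
#' @param rules An [xenograft_rules()].
#' @param arms Dose arms in mg/kg (0 = vehicle).
#' @param n_per_arm Mice per arm.
#' @param mouse_weight Body weight (kg) of every mouse.
#' @param seed Integer seed or `NULL`.
#' @return A dataset data frame (dialect of [read_dataset()], `CMT = 2`,
#'   `DV` in mm^3) with a `"manifest"` attribute.
#' @export
#' @examples
#' d <- generate_xenograft_study(seed = 1)
#' length(unique(d$ID))  # 30 mice
generate_xenograft_study <- function(truth = pd_params(),
                                     mouse_pk = mouse_default_params(),
                                     omega = pd_omega_defaults(),
                                     residual = pd_residual_defaults(),
                                     rules = xenograft_rules(),
                                     arms = c(0, 2.5, 25), n_per_arm = 10,
                                     mouse_weight = 0.02, seed = NULL) {
  stopifnot(inherits(truth, "pd_params"), inherits(rules, "xenograft_rules"))
  if (!is.null(seed)) set.seed(seed)
  times <- rules$measurement_days * 24
  dose_times <- rules$dose_interval * (seq_len(rules$n_doses) - 1)
  rows <- list()
  etas <- list()
  id <- 0L
  for (dose_kg in arms) {
    for (k in seq_len(n_per_arm)) {
      id <- id + 1L
      repeat {
        ind <- draw_individual(truth, omega)
        if (ind$Base >= rules$baseline_range[1L] &&
            ind$Base <= rules$baseline_range[2L]) break
      }
      etas[[id]] <- attr(ind, "eta")
      amt <- dose_kg * mouse_weight
      pred <- if (amt > 0) {
        simulate_tumor(ind, mouse_pk,
                       regimen(dose_times, amt, route = "ip_bolus"),
                       times = times)$volume
      } else {
        vehicle_tumor_volume(ind, times)
      }
      o <- apply_residual(pred, residual, lloq = NULL)
      obs <- pmax(o$obs, 1e-3)
      over <- which(obs >= rules$euthanasia_volume)
      last <- if (length(over)) over[1L] else length(times)
      keep <- seq_len(last)
      dt_alive <- dose_times[dose_times <= times[last]]
      dose_rows <- if (amt > 0 && length(dt_alive)) {
        data.frame(ID = id, TIME = dt_alive, AMT = amt, DV = NA_real_,
                   EVID = 1, MDV = 1, CMT = 2, WT = mouse_weight,
                   DOSEGRP = dose_kg, BLQ = 0)
      } else NULL
      obs_rows <- data.frame(ID = id, TIME = times[keep], AMT = NA_real_,
                             DV = obs[keep], EVID = 0, MDV = 0, CMT = 2,
                             WT = mouse_weight, DOSEGRP = dose_kg, BLQ = 0)
      rows[[id]] <- rbind(dose_rows, obs_rows)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "manifest") <- list(truth = truth, mouse_pk = mouse_pk,
                                omega = omega, residual = residual,
                                rules = rules, arms = arms,
                                n_per_arm = n_per_arm, seed = seed,
                                eta = etas)
  out
}
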