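#' Dosing regimen
#'
#' An ordered sequence of bolus dose events plus the observation cycle
#' length.  Both intravenous and intraperitoneal administration are modelled
#' as instantaneous boluses into the central compartment; for the
#' intraperitoneal route a bioavailable fraction can be applied (no
#' absorption model is supported, 1.0 by default).
#'
#' @param times Dose times (h), non-negative.
#' @param amounts Dose amounts (mg); recycled against `times`.
#' @param route `"iv_bolus"` or `"ip_bolus"`; recycled.
#' @param cycle_length Observation cycle length in hours: 504 for a
#'   three-weekly human cycle, 168 for weekly dosing.
#' @param bioavailability Fraction of each `ip_bolus` dose reaching the
#'   central compartment.
#'
#' @return An object of class `regimen`: a data frame of events with the
#'   cycle length and bioavailability as attributes.
#' @export
#' @examples
#' regimen(0, 360)                      # single 360 mg bolus, q3wk cycle
#' weekly_regimen(0.19, n = 3)          # 0.19 mg weekly x3 (mouse)
regimen <- function(times, amounts, route = "iv_bolus", cycle_length = 504,
                    bioavailability = 1) {
  if (length(times) == 0L) stop("a regimen needs at least one dose event")
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("dose times must be finite and non-negative")
  }
  if (any(!is.finite(amounts)) || any(amounts < 0)) {
    stop("dose amounts must be finite and non-negative")
  }
  route <- match.arg(route, c("iv_bolus", "ip_bolus"), several.ok = TRUE)
  if (cycle_length <= 0) stop("cycle_length must be positive")
  if (bioavailability <= 0 || bioavailability > 1) {
    stop("bioavailability must lie in (0, 1]")
  }
  ev <- data.frame(time = times, amount = rep_len(amounts, length(times)),
                   route = rep_len(route, length(times)),
                   stringsAsFactors = FALSE)
  ev <- ev[order(ev$time), , drop = FALSE]
  rownames(ev) <- NULL
  structure(ev, class = c("regimen", "data.frame"),
            cycle_length = cycle_length, bioavailability = bioavailability)
}

#' @rdname regimen
#' @param amount Dose amount (mg) per administration.
#' @param n Number of weekly administrations.
#' @param interval Dosing interval (h).
#' @export
weekly_regimen <- function(amount, n, interval = 168, route = "ip_bolus",
                           cycle_length = interval, bioavailability = 1) {
  regimen(times = interval * (seq_len(n) - 1), amounts = amount,
          route = route, cycle_length = cycle_length,
          bioavailability = bioavailability)
}

#' Read / write a regimen as CSV
#'
#' The on-disk form has columns `TIME` (h), `AMT` (mg) and `ROUTE`.
#'
#' @param path File path.
#' @param cycle_length,bioavailability Passed to [regimen()] on read (the
#'   CSV carries events only).
#' @return `read_regimen()` returns a [regimen()]; `write_regimen()` returns
#'   `path` invisibly.
#' @export
read_regimen <- function(path, cycle_length = 504, bioavailability = 1) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("TIME", "AMT", "ROUTE")
  if (!all(need %in% names(d))) {
    stop("regimen CSV must have columns TIME, AMT, ROUTE; missing: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  }
  regimen(d$TIME, d$AMT, d$ROUTE, cycle_length = cycle_length,
          bioavailability = bioavailability)
}

#' @rdname read_regimen
#' @param reg A [regimen()].
#' @export
write_regimen <- function(reg, path) {
  utils::write.csv(data.frame(TIME = reg$time, AMT = reg$amount,
                              ROUTE = reg$route),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# effective amount entering the central compartment per event
.regimen_amounts <- function(reg) {
  f <- ifelse(reg$route == "ip_bolus", attr(reg, "bioavailability"), 1)
  reg$amount * f
}
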