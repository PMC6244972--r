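#' Between-subject variability specification
#'
#' Lognormal between-subject variability: the individual value of a
#' parameter is \eqn{P_i = P_{pop} e^{\eta_i}} with
#' \eqn{\eta_i \sim N(0, \omega^2)}.  Variability is specified per parameter
#' as a coefficient of variation in percent; the conversion
#' \eqn{\omega^2 = \ln(1 + (CV/100)^2)} treats the reported CV as the CV of
#' the lognormal distribution (the standard pharmacometric convention).
#'
#' @param ... Named CV values in percent, e.g. `omega_spec(CL = 13.2,
#'   V1 = 14.6)`.  Names must match fields of the parameter set the spec is
#'   applied to.
#' @return An object of class `omega_spec` (named numeric vector of CVs).
#' @export
#' @examples
#' pk_omega_defaults()   # CL 13.2%, V1 14.6%
#' pd_omega_defaults()   # Base 20.6%, KG 55.1%, KD 35.5%
omega_spec <- function(...) {
  cv <- c(..., numeric(0))
  if (length(cv) && (is.null(names(cv)) || any(names(cv) == ""))) {
    stop("all CV entries must be named after model parameters")
  }
  if (any(cv < 0)) stop("CVs must be non-negative")
  structure(cv, class = "omega_spec")
}

#' @rdname omega_spec
#' @export
pk_omega_defaults <- function() omega_spec(CL = 13.2, V1 = 14.6)

#' @rdname omega_spec
#' @export
pd_omega_defaults <- function() omega_spec(Base = 20.6, KG = 55.1, KD = 35.5)

#' @rdname omega_spec
#' @param cv CV in percent.
#' @return `cv_to_omega2()` returns the lognormal variance \eqn{\omega^2}.
#' @export
cv_to_omega2 <- function(cv) log(1 + (cv / 100)^2)

#' Residual error specification
#'
#' Combined proportional and additive residual model,
#' \eqn{y_{obs} = y_{pred}(1 + \epsilon_p) + \epsilon_a} with independent
#' normal errors.  The PK defaults are a proportional SD of 0.108 and a
#' fixed additive SD of 0.039 mg/L (half the quantification limit, included
#' to weight below-limit observations); tumor volumes use a
#' proportional-only error (SD 0.256).
#'
#' @param proportional_sd Proportional error SD (fraction).
#' @param additive_sd Additive error SD (mg/L for concentrations; 0 for
#'   tumor volumes).
#' @return An object of class `residual_spec`.
#' @export
residual_spec <- function(proportional_sd, additive_sd = 0) {
  if (proportional_sd < 0 || additive_sd < 0) {
    stop("residual SDs must be non-negative")
  }
  if (proportional_sd == 0 && additive_sd == 0) {
    stop("at least one residual component must be positive")
  }
  structure(list(proportional_sd = proportional_sd,
                 additive_sd = additive_sd),
            class = "residual_spec")
}

#' @rdname residual_spec
#' @export
pk_residual_defaults <- function() residual_spec(0.108, 0.039)

#' @rdname residual_spec
#' @export
pd_residual_defaults <- function() residual_spec(0.256, 0)

#' Quantification-limit rule
#'
#' Assay rule for concentrations below the lower limit of quantification
#' (LLOQ, 0.078 mg/L): per subject, the first observation below the limit
#' is retained imputed at LLOQ/2; all later below-limit observations are
#' dropped.
#'
#' @param lloq Lower limit of quantification (mg/L).
#' @return An object of class `lloq_rule` with fields `lloq` and
#'   `first_blq_value = lloq/2`.
#' @export
lloq_rule <- function(lloq = 0.078) {
  if (lloq <= 0) stop("lloq must be positive")
  structure(list(lloq = lloq, first_blq_value = lloq / 2),
            class = "lloq_rule")
}

#' Draw an individual parameter set
#'
#' Applies independent lognormal deviates \eqn{P_i = P_{pop} e^{\eta_i}},
#' \eqn{\eta_i \sim N(0, \omega^2)}, to the parameters named in the omega
#' specification; all other parameters are copied unchanged.  Draws come
#' from the current R random stream (seed the stream with `set.seed()` for
#' reproducibility).
#'
#' @param pop Population parameter set: a [pk_params()], [pd_params()] or
#'   plain named list/vector.
#' @param omega An [omega_spec()].
#' @return An object of the same class as `pop`.
#' @export
#' @examples
#' set.seed(1)
#' draw_individual(human_default_params(), pk_omega_defaults())
draw_individual <- function(pop, omega) {
  stopifnot(inherits(omega, "omega_spec"))
  bad <- setdiff(names(omega), names(pop))
  if (length(bad)) {
    stop("omega names not present in the parameter set: ",
         paste(bad, collapse = ", "))
  }
  ind <- pop
  if (length(omega)) {
    eta <- stats::rnorm(length(omega), 0,
                        sqrt(cv_to_omega2(unclass(omega))))
    for (i in seq_along(omega)) {
      nm <- names(omega)[i]
      ind[[nm]] <- pop[[nm]] * exp(eta[i])
    }
    attr(ind, "eta") <- stats::setNames(eta, names(omega))
  }
  ind
}

#' Apply residual error and the quantification-limit rule
#'
#' Perturbs a predicted series with independent combined residual error and
#' optionally applies the below-limit rule.  The input is treated as one
#' subject's time-ordered series.
#'
#' @param pred Non-negative predicted values (one subject, time order).
#' @param spec A [residual_spec()].
#' @param lloq An [lloq_rule()] or `NULL` for no censoring.
#' @return A data frame with columns `pred`, `obs` (imputed value for the
#'   first below-limit point), `blq` (logical) and `keep` (logical; `FALSE`
#'   for below-limit points after the first, which are dropped from
#'   datasets).
#' @export
apply_residual <- function(pred, spec, lloq = NULL) {
  stopifnot(inherits(spec, "residual_spec"))
  if (any(pred < 0)) stop("predictions must be non-negative")
  n <- length(pred)
  obs <- pred * (1 + stats::rnorm(n, 0, spec$proportional_sd)) +
    stats::rnorm(n, 0, spec$additive_sd)
  blq <- rep(FALSE, n)
  keep <- rep(TRUE, n)
  if (!is.null(lloq)) {
    stopifnot(inherits(lloq, "lloq_rule"))
    below <- obs < lloq$lloq
    if (any(below)) {
      first <- which(below)[1L]
      blq[below] <- TRUE
      obs[first] <- lloq$first_blq_value
      keep[below] <- FALSE
      keep[first] <- TRUE
    }
  }
  data.frame(pred = pred, obs = obs, blq = blq, keep = keep)
}
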