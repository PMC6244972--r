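#' Structural PK parameter set
#'
#' Container for the parameters of the two-compartment disposition model with
#' parallel linear and Michaelis-Menten clearance, anchored at a reference
#' body weight.  Internal units are fixed at mg / L / h / kg.
#'
#' @param CL Linear clearance (L/h).
#' @param V1 Central volume of distribution (L).
#' @param Q Intercompartmental clearance (L/h).
#' @param V2 Peripheral volume of distribution (L).
#' @param Vmax Maximum saturable elimination rate (mg/h).
#' @param Km Concentration at half-saturation of the nonlinear clearance
#'   (mg/L).  Approximates the target-mediated disposition pathway.
#' @param body_weight Reference body weight (kg) the parameters refer to.
#'
#' @return An object of class `pk_params`.
#' @seealso [scale_params()], [human_default_params()]
#' @export
#' @examples
#' pk_params(CL = 0.0125, V1 = 3.17, Q = 0.0313, V2 = 3.51,
#'           Vmax = 0.5, Km = 0.219, body_weight = 70)
pk_params <- function(CL, V1, Q, V2, Vmax, Km, body_weight) {
  p <- list(CL = CL, V1 = V1, Q = Q, V2 = V2, Vmax = Vmax, Km = Km,
            body_weight = body_weight)
  vals <- unlist(p)
  if (length(vals) != 7L || !is.numeric(vals)) {
    stop("all seven PK parameters must be single numeric values")
  }
  if (any(!is.finite(vals)) || any(vals[-5L] <= 0) || Vmax < 0) {
    stop("PK parameters must be strictly positive and finite ",
         "(Vmax may be 0, giving the purely linear model); got: ",
         paste(names(vals)[!is.finite(vals) | vals <= 0], collapse = ", "))
  }
  structure(p, class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat(sprintf("Two-compartment PK parameters (anchor %.3g kg):\n",
              x$body_weight))
  cat(sprintf("  CL   %.4g L/h   V1 %.4g L\n", x$CL, x$V1))
  cat(sprintf("  Q    %.4g L/h   V2 %.4g L\n", x$Q, x$V2))
  cat(sprintf("  Vmax %.4g mg/h  Km %.4g mg/L\n", x$Vmax, x$Km))
  invisible(x)
}

#' Allometric scaling rule
#'
#' Power-law rule projecting PK parameters between body weights: clearances
#' (`CL`, `Q`, `Vmax`) scale with weight ratio to `exponent_flow`, volumes
#' (`V1`, `V2`) to `exponent_volume`.  `Km` is a concentration and is left
#' unscaled by default: the antibody is fully cross-reactive with the monkey
#' receptors and the mouse xenografts carry human target, so the
#' half-saturation concentration estimated in cynomolgus monkeys is carried
#' to human and mouse unchanged.
#'
#' @param reference_weight Anchor weight (kg) the rule scales from; 70 kg for
#'   the human-anchored parameterization.
#' @param exponent_flow Allometric exponent for clearances; 0.75.
#' @param exponent_volume Allometric exponent for volumes; 1.
#' @param scale_km If `TRUE`, scale `Km` with `exponent_flow` as well
#'   (not the default, see above).
#'
#' @return An object of class `allometric_rule`.
#' @export
allometric_rule <- function(reference_weight = 70, exponent_flow = 0.75,
                            exponent_volume = 1, scale_km = FALSE) {
  if (reference_weight <= 0) stop("reference_weight must be positive")
  if (exponent_flow <= 0 || exponent_flow > 1.5 ||
      exponent_volume <= 0 || exponent_volume > 1.5) {
    stop("allometric exponents must lie in (0, 1.5]")
  }
  structure(list(reference_weight = reference_weight,
                 exponent_flow = exponent_flow,
                 exponent_volume = exponent_volume,
                 scale_km = isTRUE(scale_km)),
            class = "allometric_rule")
}

#' Scale a PK parameter set to another body weight
#'
#' Applies the allometric rule `P(target) = P(anchor) * (W_target / W_ref) ^ e`
#' with `e = 0.75` for `CL`, `Q`, `Vmax` and `e = 1` for `V1`, `V2`.
#'
#' @param params A [pk_params()] set at its anchor weight.
#' @param target_weight Body weight (kg) to scale to.
#' @param rule An [allometric_rule()]; defaults to the standard exponents
#'   anchored at `params$body_weight`.
#'
#' @return A [pk_params()] set at `target_weight`.
#' @export
#' @examples
#' # human 70 kg typical values projected to a 0.02 kg mouse
#' scale_params(human_default_params(), 0.02)
scale_params <- function(params, target_weight,
                         rule = allometric_rule(reference_weight = params$body_weight)) {
  stopifnot(inherits(params, "pk_params"), inherits(rule, "allometric_rule"))
  if (!is.numeric(target_weight) || length(target_weight) != 1L ||
      !is.finite(target_weight) || target_weight <= 0) {
    stop("target_weight must be a single positive number")
  }
  ratio <- target_weight / rule$reference_weight
  ff <- ratio ^ rule$exponent_flow
  fv <- ratio ^ rule$exponent_volume
  pk_params(CL = params$CL * ff,
            V1 = params$V1 * fv,
            Q = params$Q * ff,
            V2 = params$V2 * fv,
            Vmax = params$Vmax * ff,
            Km = if (rule$scale_km) params$Km * ff else params$Km,
            body_weight = target_weight)
}

#' Published typical PK parameters
#'
#' `human_default_params()` returns the typical parameter values for a 70 kg
#' human (estimated from cynomolgus monkey concentration-time data and
#' allometrically anchored at 70 kg).  `mouse_default_params()` is the same
#' set projected to a 0.02 kg mouse; `monkey_params(weight)` projects to a
#' monkey of the given weight (monkey body weights are study-specific and
#' carry no endorsed default).
#'
#' @return A [pk_params()] set.
#' @export
human_default_params <- function() {
  pk_params(CL = 0.0125, V1 = 3.17, Q = 0.0313, V2 = 3.51,
            Vmax = 0.500, Km = 0.219, body_weight = 70)
}

#' @rdname human_default_params
#' @export
mouse_default_params <- function() {
  scale_params(human_default_params(), 0.02)
}

#' @rdname human_default_params
#' @param weight Monkey body weight in kg.
#' @export
monkey_params <- function(weight) {
  scale_params(human_default_params(), weight)
}

# numeric vector in the order the compiled pk system expects
.pk_parvec <- function(p) {
  c(p$CL, p$V1, p$Q, p$V2, p$Vmax, p$Km)
}
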