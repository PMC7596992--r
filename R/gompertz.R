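#' Gompertz-Makeham hazard parameters
#'
#' Bundles the three parameters of a Gompertz-Makeham daily mortality
#' schedule, m(i) = alpha * exp(beta * i) + gamma, for one worker role.
#' `alpha` is the initial age-dependent mortality, `beta` the exponential
#' rate of age-dependent increase (senescence), and `gamma` the
#' age-independent (extrinsic) component.  All three are on the scale of
#' a daily mortality probability contribution.
#'
#' @param alpha Initial age-dependent mortality (>= 0).
#' @param beta Exponential age-dependence rate per day (>= 0).
#' @param gamma Age-independent daily mortality probability, in [0, 1).
#' @return An object of class `gm_params`.
#' @examples
#' gm_params(alpha = 0.002, beta = 0.22, gamma = 0.3)
#' @export
gm_params <- function(alpha, beta, gamma) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta), length(beta) == 1L, is.finite(beta),
            is.numeric(gamma), length(gamma) == 1L, is.finite(gamma))
  if (alpha < 0) stop("alpha must be >= 0")
  if (beta < 0) stop("beta must be >= 0")
  if (gamma < 0 || gamma >= 1) stop("gamma must be in [0, 1)")
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "gm_params")
}

#' @export
print.gm_params <- function(x, ...) {
  cat(sprintf("Gompertz-Makeham hazard: m(i) = %g * exp(%g * i) + %g\n",
              x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Evaluate a Gompertz-Makeham hazard at given ages
#'
#' @param gm A [gm_params()] object.
#' @param ages Integer vector of ages in days (>= 1).
#' @return Numeric vector of daily mortality probabilities (unchecked;
#'   see [gm_schedule()] for the validated schedule).
#' @export
gm_hazard <- function(gm, ages) {
  stopifnot(inherits(gm, "gm_params"))
  gm$alpha * exp(gm$beta * ages) + gm$gamma
}

#' Age-specific mortality and survival schedule for one worker role
#'
#' Evaluates the Gompertz-Makeham hazard at ages `1..max_age` and returns
#' the paired daily mortality (`m`) and survival (`s = 1 - m`) columns.
#' A hazard exceeding 1 at any age in range is an error (never clamped):
#' clamping would flatten the hazard and corrupt finite-difference
#' elasticities downstream.
#'
#' @param gm A [gm_params()] object.
#' @param role `"nurse"` or `"forager"` (label only, used in messages
#'   and kept as an attribute).
#' @param max_age Last age class in days (>= 1).
#' @return A `data.frame` with columns `age`, `m`, `s` and attribute
#'   `role`, of class `mortality_schedule`.
#' @examples
#' gm_schedule(gm_params(0, 0.2, 0.05), "nurse", 10)  # constant m = 0.05
#' @export
gm_schedule <- function(gm, role = c("nurse", "forager"), max_age) {
  role <- match.arg(role)
  stopifnot(is.numeric(max_age), length(max_age) == 1L,
            max_age >= 1, max_age == round(max_age))
  ages <- seq_len(max_age)
  m <- gm_hazard(gm, ages)
  if (any(m > 1)) {
    bad <- ages[which(m > 1)[1L]]
    stop(sprintf(
      "infeasible %s schedule: mortality exceeds 1 at age %d (m = %.4f)",
      role, bad, m[bad]), call. = FALSE)
  }
  out <- data.frame(age = ages, m = m, s = 1 - m)
  attr(out, "role") <- role
  class(out) <- c("mortality_schedule", "data.frame")
  out
}
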