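#' Stage structure of the colony model
#'
#' Duration (in daily age classes) of the three worker stages.  Defaults
#' follow the standard honeybee schedule: 21 days of brood development,
#' nurse age classes up to 120 days, and forager age classes up to 19
#' days (survival of workers beyond 19 days as foragers is negligible
#' and the model removes them).
#'
#' @param brood_days,nurse_max_days,forager_max_days Positive integers.
#' @return An object of class `stage_structure`.
#' @export
stage_structure <- function(brood_days = 21L, nurse_max_days = 120L,
                            forager_max_days = 19L) {
  for (v in list(brood_days, nurse_max_days, forager_max_days)) {
    stopifnot(is.numeric(v), length(v) == 1L, is.finite(v),
              v >= 1, v == round(v))
  }
  structure(list(brood_days = as.integer(brood_days),
                 nurse_max_days = as.integer(nurse_max_days),
                 forager_max_days = as.integer(forager_max_days)),
            class = "stage_structure")
}

#' Full parameter set for one colony model instance
#'
#' Collects everything the projection matrix needs: stage durations,
#' daily brood survival `s_b`, daily nurse-to-forager transition
#' probability `g`, food provisioned per forager per day `p`, food
#' required per brood per day `c`, and the Gompertz-Makeham hazard
#' triples for nurses and foragers.  The per-forager brood production
#' rate is the derived ratio r = p / c (see [provisioning_ratio()]); it
#' is never stored separately.
#'
#' The constructor checks types and basic ranges only; use
#' [validate_colony_params()] for the full invariant report (including
#' the hazard-feasibility check over each role's age range).
#'
#' @param s_b Daily brood survival probability in [0, 1].
#' @param g Daily nurse-to-forager transition probability in [0, 1].
#' @param p Food provisioned per forager per day (>= 0).
#' @param c Food required per brood per day (> 0).
#' @param nurse_gm,forager_gm [gm_params()] hazard triples.
#' @param structure A [stage_structure()].
#' @return An object of class `colony_params`.
#' @examples
#' colony_params(s_b = 0.97, g = 0.06, p = 1, c = 1,
#'               nurse_gm = gm_params(2e-4, 0.004, 0.008),
#'               forager_gm = gm_params(0.002, 0.22, 0.30))
#' @export
colony_params <- function(s_b, g, p, c, nurse_gm, forager_gm,
                          structure = stage_structure()) {
  stopifnot(inherits(structure, "stage_structure"),
            inherits(nurse_gm, "gm_params"),
            inherits(forager_gm, "gm_params"))
  for (v in list(s_b, g, p, c)) {
    stopifnot(is.numeric(v), length(v) == 1L, is.finite(v))
  }
  structure(list(structure = structure, s_b = s_b, g = g, p = p, c = c,
                 nurse_gm = nurse_gm, forager_gm = forager_gm),
            class = "colony_params")
}

#' Per-forager daily brood production rate r = p / c
#'
#' @param params A [colony_params()] object.
#' @return The number of new brood a forager can provision per day.
#' @export
provisioning_ratio <- function(params) {
  stopifnot(inherits(params, "colony_params"))
  params$p / params$c
}

#' @export
print.colony_params <- function(x, ...) {
  st <- x$structure
  cat(sprintf(
    "colony_params: stages %d/%d/%d (brood/nurse/forager)\n",
    st$brood_days, st$nurse_max_days, st$forager_max_days))
  cat(sprintf("  s_b = %g, g = %g, p = %g, c = %g (r = %g)\n",
              x$s_b, x$g, x$p, x$c, x$p / x$c))
  cat(sprintf("  nurse hazard:   alpha %g, beta %g, gamma %g\n",
              x$nurse_gm$alpha, x$nurse_gm$beta, x$nurse_gm$gamma))
  cat(sprintf("  forager hazard: alpha %g, beta %g, gamma %g\n",
              x$forager_gm$alpha, x$forager_gm$beta, x$forager_gm$gamma))
  invisible(x)
}

#' Validate a colony parameter set
#'
#' Checks every model invariant and reports all violations rather than
#' stopping at the first: probability parameters in range, `c > 0`, both
#' hazard schedules feasible (daily mortality <= 1 at every age up to the
#' role's cap, reporting the first offending age), and positive stage
#' durations.  Callers decide whether a non-empty report is fatal.
#'
#' @param params A [colony_params()] object.
#' @return A `validation_report`: data.frame with columns `field` and
#'   `message`, zero rows when all invariants hold.  Use [is_valid()].
#' @export
validate_colony_params <- function(params) {
  stopifnot(inherits(params, "colony_params"))
  v <- list()
  add <- function(field, message) {
    v[[length(v) + 1L]] <<- data.frame(field = field, message = message)
  }
  if (params$s_b < 0 || params$s_b > 1)
    add("s_b", sprintf("s_b must be in [0, 1], got %g", params$s_b))
  if (params$g < 0 || params$g > 1)
    add("g", sprintf("g must be in [0, 1], got %g", params$g))
  if (params$p < 0)
    add("p", sprintf("p must be >= 0, got %g", params$p))
  if (params$c <= 0)
    add("c", sprintf("c must be > 0, got %g", params$c))
  for (role in c("nurse", "forager")) {
    gm <- params[[paste0(role, "_gm")]]
    cap <- if (role == "nurse") params$structure$nurse_max_days
           else params$structure$forager_max_days
    m <- gm_hazard(gm, seq_len(cap))
    if (any(m > 1)) {
      bad <- which(m > 1)[1L]
      add(paste0(role, "_gm"),
          sprintf("%s mortality m_i > 1 first at age %d (m = %.4f)",
                  role, bad, m[bad]))
    }
    if (gm$alpha < 0) add(paste0(role, "_gm"), "alpha must be >= 0")
    if (gm$beta < 0) add(paste0(role, "_gm"), "beta must be >= 0")
    if (gm$gamma < 0 || gm$gamma >= 1)
      add(paste0(role, "_gm"), "gamma must be in [0, 1)")
  }
  out <- if (length(v)) do.call(rbind, v) else
    data.frame(field = character(), message = character())
  class(out) <- c("validation_report", "data.frame")
  out
}

#' Does a validation report contain no violations?
#'
#' @param report A `validation_report` from [validate_colony_params()].
#' @return `TRUE` iff the report is empty.
#' @export
is_valid <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  nrow(report) == 0L
}

# internal: stop with all messages when params are invalid
assert_valid_params <- function(params) {
  rep <- validate_colony_params(params)
  if (!is_valid(rep)) {
    stop("invalid colony parameters:\n  ",
         paste(rep$message, collapse = "\n  "), call. = FALSE)
  }
  invisible(params)
}

#' One seasonal parameter scenario
#'
#' A labelled [colony_params()] plus a provenance note.  The note exists
#' because the numeric values of the bundled default scenarios are
#' calibrated implementer choices (the original per-season parameter
#' table is not publicly deposited), and anything built on them should
#' carry that caveat along.
#'
#' @param label Scenario name; the default set uses `"summer"`,
#'   `"spring_fall"` and `"winter"`.
#' @param params A [colony_params()] object.
#' @param provenance_note Free-text provenance of the numeric values.
#' @return An object of class `season_scenario`.
#' @export
season_scenario <- function(label, params, provenance_note = "") {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label),
            inherits(params, "colony_params"),
            is.character(provenance_note), length(provenance_note) == 1L)
  assert_valid_params(params)
  structure(list(label = label, params = params,
                 provenance_note = provenance_note),
            class = "season_scenario")
}

#' An ordered set of seasonal scenarios with unique labels
#'
#' @param scenarios List of [season_scenario()] objects.
#' @return An object of class `scenario_set`; supports `[[` by label
#'   and `names()`.
#' @export
scenario_set <- function(scenarios) {
  stopifnot(is.list(scenarios), length(scenarios) >= 1L,
            all(vapply(scenarios, inherits, TRUE, "season_scenario")))
  labels <- vapply(scenarios, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("scenario labels must be unique")
  names(scenarios) <- labels
  structure(scenarios, class = "scenario_set")
}

#' @export
print.scenario_set <- function(x, ...) {
  cat(sprintf("scenario_set with %d scenarios: %s\n",
              length(x), paste(names(x), collapse = ", ")))
  invisible(x)
}
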