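#' Colony state: stage-by-age abundances on one day
#'
#' Abundances are continuous expected counts (the model is
#' deterministic), not integer individuals.
#'
#' @param B,N,F Nonnegative numeric vectors of brood, nurse and forager
#'   abundances by age; lengths must match the stage structure they are
#'   used with.
#' @param day Integer day index (>= 0).
#' @return An object of class `colony_state`.
#' @export
colony_state <- function(B, N, F, day = 0L) {
  stopifnot(is.numeric(B), is.numeric(N), is.numeric(F),
            all(B >= 0), all(N >= 0), all(F >= 0),
            is.numeric(day), length(day) == 1L, day >= 0)
  structure(list(day = as.integer(day), B = as.numeric(B),
                 N = as.numeric(N), F = as.numeric(F)),
            class = "colony_state")
}

#' Default initial state: 100 nurses of age 1
#'
#' The asymptotic growth rate is independent of the initial condition;
#' this default exists so reporting runs are reproducible.
#'
#' @param structure A [stage_structure()].
#' @param nurses Number of age-1 nurses to start with.
#' @return A [colony_state()].
#' @export
initial_state <- function(structure = stage_structure(), nurses = 100) {
  N <- numeric(structure$nurse_max_days)
  N[1] <- nurses
  colony_state(B = numeric(structure$brood_days), N = N,
               F = numeric(structure$forager_max_days), day = 0L)
}

# internal: check state/params consistency
check_state <- function(state, params) {
  st <- params$structure
  if (length(state$B) != st$brood_days ||
      length(state$N) != st$nurse_max_days ||
      length(state$F) != st$forager_max_days)
    stop("state dimensions do not match the stage structure")
  invisible(state)
}

# internal: one recursion step on raw vectors with precomputed survivals
step_raw <- function(B, N, F, s_b, g, r, sn, sf) {
  list(B = c(r * sum(F), s_b * B[-length(B)]),
       N = c(s_b * B[length(B)], (sn * (1 - g) * N)[-length(N)]),
       F = c(sum(sn * g * N), (sf * F)[-length(F)]))
}

#' Advance the colony one day by the stage recursions
#'
#' Applies the three recursions directly (no matrix): new brood is
#' `r = p/c` per forager summed over forager ages; brood age up with
#' survival `s_b` and emerge as nurses after the brood stage; nurses
#' age up with Gompertz-Makeham survival and probability `1 - g` of
#' staying; new foragers recruit `s_n,j * g` from every nurse age; and
#' foragers age up with their Gompertz-Makeham survival.  Serves as the
#' independent oracle for [build_leslie_matrix()].
#'
#' @param state A [colony_state()].
#' @param params A valid [colony_params()] object.
#' @return The next day's [colony_state()].
#' @export
step_colony <- function(state, params) {
  stopifnot(inherits(state, "colony_state"))
  assert_valid_params(params)
  check_state(state, params)
  st <- params$structure
  sn <- gm_schedule(params$nurse_gm, "nurse", st$nurse_max_days)$s
  sf <- gm_schedule(params$forager_gm, "forager", st$forager_max_days)$s
  nxt <- step_raw(state$B, state$N, state$F, params$s_b, params$g,
                  provisioning_ratio(params), sn, sf)
  colony_state(nxt$B, nxt$N, nxt$F, day = state$day + 1L)
}

#' Project the colony forward and record every day
#'
#' Repeated application of the stage recursions (schedules precomputed
#' once, so long runs are cheap).
#'
#' @param params A valid [colony_params()] object.
#' @param initial Starting [colony_state()]; defaults to
#'   [initial_state()] for the parameter set's structure.
#' @param T Number of days to project (>= 0).
#' @return An object of class `trajectory`: list with `abundance`
#'   (a `(T + 1) x (D_b + D_n + D_f)` matrix, rows = days 0..T, columns
#'   labelled by stage and age) and `params`.  Use [state_at()] for a
#'   single day's [colony_state()] and `as.data.frame()` for the tidy
#'   long form (`day`, `stage`, `age`, `abundance`).
#' @export
project_colony <- function(params, initial = initial_state(params$structure),
                           T) {
  stopifnot(is.numeric(T), length(T) == 1L, T >= 0, T == round(T))
  assert_valid_params(params)
  check_state(initial, params)
  st <- params$structure
  sn <- gm_schedule(params$nurse_gm, "nurse", st$nurse_max_days)$s
  sf <- gm_schedule(params$forager_gm, "forager", st$forager_max_days)$s
  r <- provisioning_ratio(params)
  n <- st$brood_days + st$nurse_max_days + st$forager_max_days
  out <- matrix(0, T + 1L, n)
  idx <- block_index(st)
  colnames(out) <- paste(idx$stage, idx$age, sep = "_")
  B <- initial$B; N <- initial$N; F <- initial$F
  out[1L, ] <- c(B, N, F)
  for (t in seq_len(T)) {
    nxt <- step_raw(B, N, F, params$s_b, params$g, r, sn, sf)
    B <- nxt$B; N <- nxt$N; F <- nxt$F
    out[t + 1L, ] <- c(B, N, F)
  }
  structure(list(abundance = out, day0 = initial$day, params = params),
            class = "trajectory")
}

#' Extract one day's state from a trajectory
#'
#' @param traj A [project_colony()] result.
#' @param t Day offset from the trajectory start (0-based).
#' @return A [colony_state()].
#' @export
state_at <- function(traj, t) {
  stopifnot(inherits(traj, "trajectory"),
            t >= 0, t <= nrow(traj$abundance) - 1L)
  st <- traj$params$structure
  x <- traj$abundance[t + 1L, ]
  colony_state(B = x[seq_len(st$brood_days)],
               N = x[st$brood_days + seq_len(st$nurse_max_days)],
               F = x[st$brood_days + st$nurse_max_days +
                       seq_len(st$forager_max_days)],
               day = traj$day0 + t)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  st <- x$params$structure
  idx <- block_index(st)
  days <- x$day0 + seq_len(nrow(x$abundance)) - 1L
  data.frame(
    day = rep(days, each = nrow(idx)),
    stage = rep(idx$stage, times = length(days)),
    age = rep(idx$age, times = length(days)),
    abundance = as.vector(t(x$abundance)))
}

#' Total population per day of a trajectory
#'
#' @param traj A [project_colony()] result.
#' @return Numeric vector of daily totals (brood + nurses + foragers).
#' @export
total_population <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  rowSums(traj$abundance)
}

#' Empirical per-day growth factor of a trajectory
#'
#' Geometric mean of day-over-day total-population ratios after a
#' burn-in, i.e. `(total[T] / total[burn_in])^(1 / (T - burn_in))`.
#' After transients decay this converges to the dominant eigenvalue of
#' the projection matrix, making the simulator an independent oracle
#' for [eigen_analysis()].  The burn-in needed for a given accuracy is
#' set by the subdominant-to-dominant eigenvalue ratio; for the default
#' winter scenario (ratio ~0.99) a burn-in of a few thousand days gives
#' agreement well below 1e-6 relative.
#'
#' @param traj A [project_colony()] result.
#' @param burn_in Days to discard; the trajectory must extend at least
#'   2 days beyond it.
#' @return The per-day growth factor.  If the population is extinct
#'   (total 0) at or after the burn-in, an error of condition class
#'   `colony_extinct` is signalled.
#' @export
empirical_growth_rate <- function(traj, burn_in = 300) {
  stopifnot(inherits(traj, "trajectory"),
            is.numeric(burn_in), length(burn_in) == 1L, burn_in >= 0)
  tot <- total_population(traj)
  Tlast <- length(tot) - 1L
  if (Tlast < burn_in + 2)
    stop("trajectory must extend at least 2 days past the burn-in")
  seg <- tot[(burn_in + 1L):length(tot)]
  if (any(seg == 0))
    stop(structure(class = c("colony_extinct", "error", "condition"),
                   list(message = "population extinct before the growth rate could be estimated",
                        call = sys.call())))
  (seg[length(seg)] / seg[1L])^(1 / (length(seg) - 1L))
}
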