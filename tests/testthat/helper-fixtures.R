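# shared fixtures: toy life cycles, random parameter draws, oracles

# one-day-per-stage toy model; defaults give the 3-cycle with lambda = 2
toy_params <- function(r = 8, s_b = 1, nurse_m = 0, g = 1, forager_m = 0.5) {
  colony_params(
    s_b = s_b, g = g, p = r, c = 1,
    nurse_gm = gm_params(alpha = 0, beta = 0, gamma = nurse_m),
    forager_gm = gm_params(alpha = 0, beta = 0, gamma = forager_m),
    structure = stage_structure(1, 1, 1))
}

# random valid full-size parameter set; ranges keep hazards feasible by
# construction (worst-case m_n(120) ~ 0.03, m_f(19) ~ 0.7)
random_valid_params <- function() {
  repeat {
    p <- colony_params(
      s_b = runif(1, 0.5, 0.99), g = runif(1, 0.005, 0.15),
      p = runif(1, 0.05, 1.5), c = runif(1, 0.5, 2),
      nurse_gm = gm_params(10^runif(1, -5, -3.3), runif(1, 0.001, 0.03),
                           runif(1, 5e-4, 0.01)),
      forager_gm = gm_params(runif(1, 5e-4, 4e-3), runif(1, 0.05, 0.24),
                             runif(1, 1e-3, 0.3)))
    if (is_valid(validate_colony_params(p))) return(p)
  }
}

# long-run growth factor through the recursion simulator only, with
# chunked renormalization so subcritical colonies do not underflow
# (the recursions are linear, so rescaling leaves the rate unchanged)
projected_growth <- function(params, burn_in = 6000, window = 1500,
                             chunk = 500) {
  x <- initial_state(params$structure)
  done <- 0
  while (done < burn_in) {
    step <- min(chunk, burn_in - done)
    traj <- project_colony(params, x, T = step)
    y <- state_at(traj, step)
    tot <- sum(y$B) + sum(y$N) + sum(y$F)
    x <- colony_state(y$B / tot * 100, y$N / tot * 100, y$F / tot * 100)
    done <- done + step
  }
  empirical_growth_rate(project_colony(params, x, T = window),
                        burn_in = 300)
}

# stacked state vector in the Leslie matrix's block order
state_vec <- function(state) c(state$B, state$N, state$F)

# bare numeric matrix: drop class, dimnames and bookkeeping attributes
plain_matrix <- function(M) {
  x <- unclass(M)
  attributes(x) <- list(dim = dim(x))
  x
}
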