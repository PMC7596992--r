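#' Names of the six worker mortality parameters
#'
#' The three Gompertz-Makeham components for each role, in the order
#' used throughout the package: nurse extrinsic (`gamma_n`), nurse
#' initial age-dependent (`alpha_n`), nurse age-dependent increase
#' (`beta_n`), then the forager analogues.
#'
#' @export
mortality_params <- c("gamma_n", "alpha_n", "beta_n",
                      "gamma_f", "alpha_f", "beta_f")

# all perturbable parameter names
all_param_names <- c(mortality_params, "s_b", "g", "p", "c")

# internal: read a named scalar parameter out of colony_params
get_param <- function(params, name) {
  switch(name,
    gamma_n = params$nurse_gm$gamma,
    alpha_n = params$nurse_gm$alpha,
    beta_n = params$nurse_gm$beta,
    gamma_f = params$forager_gm$gamma,
    alpha_f = params$forager_gm$alpha,
    beta_f = params$forager_gm$beta,
    s_b = params$s_b,
    g = params$g,
    p = params$p,
    c = params$c,
    stop("unknown parameter name: ", name))
}

# internal: return params with one named scalar replaced
set_param <- function(params, name, value) {
  ngm <- params$nurse_gm
  fgm <- params$forager_gm
  fields <- list(s_b = params$s_b, g = params$g, p = params$p, c = params$c)
  switch(name,
    gamma_n = ngm <- gm_params(ngm$alpha, ngm$beta, value),
    alpha_n = ngm <- gm_params(value, ngm$beta, ngm$gamma),
    beta_n = ngm <- gm_params(ngm$alpha, value, ngm$gamma),
    gamma_f = fgm <- gm_params(fgm$alpha, fgm$beta, value),
    alpha_f = fgm <- gm_params(value, fgm$beta, fgm$gamma),
    beta_f = fgm <- gm_params(fgm$alpha, value, fgm$gamma),
    s_b = fields$s_b <- value,
    g = fields$g <- value,
    p = fields$p <- value,
    c = fields$c <- value,
    stop("unknown parameter name: ", name))
  colony_params(s_b = fields$s_b, g = fields$g, p = fields$p, c = fields$c,
                nurse_gm = ngm, forager_gm = fgm,
                structure = params$structure)
}

# internal: one-row elasticity tibble
elasticity_row <- function(param_name, scenario_label, elasticity, method,
                           rel_step, lam_base, zero_param = FALSE) {
  tibble::tibble(
    scenario = scenario_label,
    param = param_name,
    elasticity = elasticity,
    abs_elasticity = abs(elasticity),
    method = method,
    rel_step = rel_step,
    lam_base = lam_base,
    zero_param = zero_param)
}

#' Elasticity of the colony growth rate by numeric perturbation
#'
#' The elasticity of the growth rate to a parameter `x` is
#' `(d lambda / d x) * (x / lambda)`, the proportional response of
#' `lambda` to a proportional change in `x`.  It is estimated by finite
#' differences on the dominant eigenvalue with step `dx = rel_step * x`
#' (central differences by default; second-order accurate and validated
#' against [analytic_elasticity()]).
#'
#' If the parameter's current value is 0 the elasticity is 0 by the
#' `x / lambda` factor of the definition; the row is flagged
#' (`zero_param = TRUE`) so users know to consult the raw sensitivity
#' instead.
#'
#' @param params A valid [colony_params()] object with `lambda > 0`.
#' @param param_name One of `gamma_n`, `alpha_n`, `beta_n`, `gamma_f`,
#'   `alpha_f`, `beta_f`, `s_b`, `g`, `p`, `c`.
#' @param rel_step Relative perturbation (default `1e-4`).
#' @param scheme `"central"` or `"forward"`.
#' @param scenario_label Optional label carried into the result row.
#' @return A one-row [tibble::tibble] with columns `scenario`, `param`,
#'   `elasticity`, `abs_elasticity`, `method`, `rel_step`, `lam_base`,
#'   `zero_param`.
#' @examples
#' p <- default_scenarios()$winter$params
#' perturbation_elasticity(p, "gamma_f")
#' @export
perturbation_elasticity <- function(params, param_name, rel_step = 1e-4,
                                    scheme = c("central", "forward"),
                                    scenario_label = NA_character_) {
  scheme <- match.arg(scheme)
  stopifnot(param_name %in% all_param_names,
            is.numeric(rel_step), rel_step > 0)
  assert_valid_params(params)
  x <- get_param(params, param_name)
  lam0 <- spectral_radius(build_leslie_matrix(params))
  if (lam0 == 0)
    stop("growth rate is 0 at the base parameters; elasticity undefined")
  if (x == 0) {
    return(elasticity_row(param_name, scenario_label, 0, "perturbation",
                          rel_step, lam0, zero_param = TRUE))
  }
  dx <- rel_step * x
  lam_up <- spectral_radius(build_leslie_matrix(set_param(params, param_name, x + dx)))
  dlam <- if (scheme == "central") {
    lam_dn <- spectral_radius(build_leslie_matrix(set_param(params, param_name, x - dx)))
    (lam_up - lam_dn) / (2 * dx)
  } else {
    (lam_up - lam0) / dx
  }
  elasticity_row(param_name, scenario_label, dlam * x / lam0,
                 "perturbation", rel_step, lam0)
}

#' Elasticity via the eigenvector sensitivity identity (analytic oracle)
#'
#' The sensitivity of the dominant eigenvalue to matrix entry `(i, j)`
#' is `v_i * w_j / <v, w>`, with `w` and `v` the right and left
#' dominant eigenvectors.  Chaining through the exact partial
#' derivatives of each matrix entry with respect to the named model
#' parameter and scaling by `x / lambda` gives the elasticity without
#' finite differences.  Used as the independent cross-check for
#' [perturbation_elasticity()] (the numeric perturbation is the primary
#' method).
#'
#' @inheritParams perturbation_elasticity
#' @return A one-row tibble as in [perturbation_elasticity()] with
#'   `method = "analytic"` and `rel_step = NA`.
#' @export
analytic_elasticity <- function(params, param_name,
                                scenario_label = NA_character_) {
  stopifnot(param_name %in% all_param_names)
  assert_valid_params(params)
  M <- build_leslie_matrix(params)
  tri <- eigen_analysis(M)
  if (tri$lam == 0 || !tri$defined)
    stop("growth rate is 0 (or eigenvectors undefined); elasticity undefined")
  x <- get_param(params, param_name)
  if (x == 0) {
    return(elasticity_row(param_name, scenario_label, 0, "analytic",
                          NA_real_, tri$lam, zero_param = TRUE))
  }
  st <- params$structure
  Db <- st$brood_days; Dn <- st$nurse_max_days; Df <- st$forager_max_days
  w <- tri$stable_dist
  v <- tri$repro_values          # already scaled so sum(v * w) == 1
  S <- function(i, j) v[i] * w[j]  # d lambda / d M[i, j]

  ni <- seq_len(Dn)
  fi <- seq_len(Df)
  g <- params$g
  # partial of the survival probabilities w.r.t. the hazard parameters
  dsn <- switch(param_name,
    gamma_n = rep(-1, Dn),
    alpha_n = -exp(params$nurse_gm$beta * ni),
    beta_n = -params$nurse_gm$alpha * ni * exp(params$nurse_gm$beta * ni),
    NULL)
  dsf <- switch(param_name,
    gamma_f = rep(-1, Df),
    alpha_f = -exp(params$forager_gm$beta * fi),
    beta_f = -params$forager_gm$alpha * fi * exp(params$forager_gm$beta * fi),
    NULL)

  dlam <- 0
  if (!is.null(dsn)) {
    # nurse survival enters the stay arcs (times 1 - g) and recruit arcs (times g)
    stay <- sum(vapply(ni[-Dn], function(j)
      S(Db + j + 1L, Db + j) * (1 - g) * dsn[j], 0))
    recruit <- sum(S(Db + Dn + 1L, Db + ni) * g * dsn)
    dlam <- stay + recruit
  } else if (!is.null(dsf)) {
    dlam <- sum(vapply(fi[-Df], function(j)
      S(Db + Dn + j + 1L, Db + Dn + j) * dsf[j], 0))
  } else if (param_name == "s_b") {
    rows <- c(if (Db >= 2) 2:Db, Db + 1L)
    cols <- c(if (Db >= 2) 1:(Db - 1L), Db)
    dlam <- sum(v[rows] * w[cols])
  } else if (param_name == "g") {
    sn <- gm_schedule(params$nurse_gm, "nurse", Dn)$s
    stay <- sum(vapply(ni[-Dn], function(j)
      S(Db + j + 1L, Db + j) * (-sn[j]), 0))
    recruit <- sum(S(Db + Dn + 1L, Db + ni) * sn)
    dlam <- stay + recruit
  } else if (param_name == "p") {
    dlam <- sum(v[1L] * w[Db + Dn + fi]) / params$c
  } else if (param_name == "c") {
    dlam <- -sum(v[1L] * w[Db + Dn + fi]) * params$p / params$c^2
  }
  elasticity_row(param_name, scenario_label, dlam * x / tri$lam,
                 "analytic", NA_real_, tri$lam)
}

#' Seasonal comparison of mortality elasticities
#'
#' Perturbation elasticities of the growth rate to the six worker
#' mortality parameters (by default) for every scenario in the set —
#' the tabular form of the seasonal comparison figures.
#'
#' @param scenarios A [scenario_set()]; defaults to [default_scenarios()].
#' @param param_names Parameters to perturb; default [mortality_params].
#' @param rel_step Relative perturbation step.
#' @return An `elasticity_table`: tibble with one row per
#'   (scenario, parameter) pair, plus attributes `rel_step` and
#'   `provenance`.
#' @examples
#' \donttest{
#' tab <- season_comparison()
#' ordering_report(tab)
#' }
#' @export
season_comparison <- function(scenarios = default_scenarios(),
                              param_names = mortality_params,
                              rel_step = 1e-4) {
  stopifnot(inherits(scenarios, "scenario_set"))
  rows <- lapply(scenarios, function(sc) {
    do.call(rbind, lapply(param_names, function(pn)
      perturbation_elasticity(sc$params, pn, rel_step = rel_step,
                              scenario_label = sc$label)))
  })
  out <- do.call(rbind, rows)
  attr(out, "rel_step") <- rel_step
  attr(out, "provenance") <- vapply(scenarios, `[[`, "", "provenance_note")
  class(out) <- c("elasticity_table", class(out))
  out
}

#' Mortality elasticities across a brood-survival gradient
#'
#' Recomputes the six mortality elasticities for each brood survival
#' value in `sb_grid`, all other parameters held at the given (winter)
#' scenario's values — the model's probe of how brood-targeting
#' stressors (e.g. Varroa) change the colony's sensitivity to adult
#' worker mortality.
#'
#' The default grid spans daily brood survival 0.50-0.85, below the
#' healthy default (0.97): the regime of substantially reduced brood
#' survival the sweep is meant to examine, and the regime in which the
#' forager-senescence elasticity responds monotonically (see the
#' vignette for the shallow non-monotonicity near `s_b` ~ 0.9).
#'
#' @param winter A [season_scenario()] (winter by convention).
#' @param sb_grid Strictly increasing brood survival values in (0, 1].
#' @param rel_step Relative perturbation step.
#' @return A `sweep_table`: tibble with one row per (s_b, parameter)
#'   pair; rows at grid points where the growth rate is 0 are flagged
#'   (`lam_zero = TRUE`, elasticity `NA`) rather than fatal.
#' @export
brood_survival_sweep <- function(winter, sb_grid = seq(0.50, 0.85, by = 0.05),
                                 rel_step = 1e-4) {
  stopifnot(inherits(winter, "season_scenario"),
            is.numeric(sb_grid), length(sb_grid) >= 1L,
            all(sb_grid > 0), all(sb_grid <= 1),
            all(diff(sb_grid) > 0))
  rows <- lapply(sb_grid, function(sb) {
    pr <- set_param(winter$params, "s_b", sb)
    lam <- spectral_radius(build_leslie_matrix(pr))
    if (lam == 0) {
      out <- do.call(rbind, lapply(mortality_params, function(pn)
        elasticity_row(pn, winter$label, NA_real_, "perturbation",
                       rel_step, 0)))
    } else {
      out <- do.call(rbind, lapply(mortality_params, function(pn)
        perturbation_elasticity(pr, pn, rel_step = rel_step,
                                scenario_label = winter$label)))
    }
    out$s_b <- sb
    out$lam_zero <- lam == 0
    out
  })
  out <- do.call(rbind, rows)
  attr(out, "rel_step") <- rel_step
  attr(out, "grid") <- sb_grid
  class(out) <- c("sweep_table", class(out))
  out
}

#' Verdicts on the six qualitative seasonal elasticity orderings
#'
#' Checks the six season orderings of the mortality elasticities (by
#' magnitude) in an [season_comparison()] table:
#' \enumerate{
#'   \item `gamma_n`: summer >= spring_fall > winter, with summer and
#'     spring_fall similar (within 50% of their mean);
#'   \item `alpha_n`: winter above both other seasons;
#'   \item `beta_n`: winter above both other seasons;
#'   \item `gamma_f`: summer > spring_fall > winter;
#'   \item `alpha_f`: winter > spring_fall > summer;
#'   \item `beta_f`: winter > spring_fall > summer, with spring_fall
#'     closer to summer than to winter.
#' }
#' "Similar" and "closer" are operationalized with the explicit
#' thresholds recorded in the report metadata (the source claims are
#' qualitative).
#'
#' @param table An `elasticity_table` covering the three seasons and
#'   six mortality parameters.
#' @return An `ordering_report`: list with per-check `name`, `verdict`,
#'   `detail` and the season magnitudes, plus `all_pass` and
#'   `thresholds`.
#' @export
ordering_report <- function(table) {
  stopifnot(inherits(table, "elasticity_table") || is.data.frame(table))
  need <- c("summer", "spring_fall", "winter")
  if (!all(need %in% table$scenario))
    stop("table must cover scenarios: ", paste(need, collapse = ", "))
  if (!all(mortality_params %in% table$param))
    stop("table must cover all six mortality parameters")
  a <- function(season, pn) {
    x <- table$abs_elasticity[table$scenario == season & table$param == pn]
    if (length(x) != 1L) stop("expected exactly one row per (scenario, param)")
    x
  }
  similar_tol <- 0.5
  checks <- list()
  add <- function(name, verdict, detail, su, sp, wi) {
    checks[[length(checks) + 1L]] <<- list(
      name = name, verdict = verdict, detail = detail,
      summer = su, spring_fall = sp, winter = wi)
  }

  su <- a("summer", "gamma_n"); sp <- a("spring_fall", "gamma_n")
  wi <- a("winter", "gamma_n")
  add("gamma_n_summer_spring_high_winter_low",
      su >= sp && sp > wi && abs(su - sp) < similar_tol * mean(c(su, sp)),
      "|e(gamma_n)|: summer >= spring_fall > winter, summer ~ spring_fall",
      su, sp, wi)
  for (pn in c("alpha_n", "beta_n")) {
    su <- a("summer", pn); sp <- a("spring_fall", pn); wi <- a("winter", pn)
    add(paste0(pn, "_winter_highest"), wi > max(su, sp),
        sprintf("|e(%s)|: winter above both other seasons", pn), su, sp, wi)
  }
  su <- a("summer", "gamma_f"); sp <- a("spring_fall", "gamma_f")
  wi <- a("winter", "gamma_f")
  add("gamma_f_summer_spring_winter_decreasing", su > sp && sp > wi,
      "|e(gamma_f)|: summer > spring_fall > winter", su, sp, wi)
  su <- a("summer", "alpha_f"); sp <- a("spring_fall", "alpha_f")
  wi <- a("winter", "alpha_f")
  add("alpha_f_winter_spring_summer_decreasing", wi > sp && sp > su,
      "|e(alpha_f)|: winter > spring_fall > summer", su, sp, wi)
  su <- a("summer", "beta_f"); sp <- a("spring_fall", "beta_f")
  wi <- a("winter", "beta_f")
  add("beta_f_winter_highest_spring_near_summer",
      wi > sp && sp > su && (sp - su) < (wi - sp),
      "|e(beta_f)|: winter > spring_fall > summer, spring_fall nearer summer",
      su, sp, wi)

  structure(list(checks = checks,
                 all_pass = all(vapply(checks, `[[`, TRUE, "verdict")),
                 thresholds = list(similar_rel_tol = similar_tol)),
            class = "ordering_report")
}

#' @export
print.ordering_report <- function(x, ...) {
  for (ch in x$checks) {
    cat(sprintf("[%s] %s\n        summer %.3e  spring_fall %.3e  winter %.3e\n",
                if (ch$verdict) "PASS" else "FAIL", ch$detail,
                ch$summer, ch$spring_fall, ch$winter))
  }
  cat(sprintf("all %d orderings hold: %s\n", length(x$checks), x$all_pass))
  invisible(x)
}

#' @export
as.data.frame.ordering_report <- function(x, ...) {
  do.call(rbind, lapply(x$checks, function(ch)
    data.frame(name = ch$name, verdict = ch$verdict, detail = ch$detail,
               summer = ch$summer, spring_fall = ch$spring_fall,
               winter = ch$winter)))
}

#' Write an ordering report as JSON
#'
#' @param report An [ordering_report()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ordering_report <- function(report, path) {
  stopifnot(inherits(report, "ordering_report"))
  jsonlite::write_json(
    list(checks = report$checks, all_pass = report$all_pass,
         thresholds = report$thresholds),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
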