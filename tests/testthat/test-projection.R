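test_that("a single step reproduces the recursions on simple cases", {
  # all-zero state stays all-zero
  p <- default_scenarios()$summer$params
  z <- colony_state(numeric(21), numeric(120), numeric(19))
  nxt <- step_colony(z, p)
  expect_true(all(c(nxt$B, nxt$N, nxt$F) == 0))
  expect_identical(nxt$day, 1L)

  # toy 3-cycle: one forager cycles through brood and nurse, scaled by r
  tp <- toy_params(r = 8, s_b = 1, nurse_m = 0, g = 1)
  s0 <- colony_state(0, 0, 1)
  s1 <- step_colony(s0, tp)
  expect_equal(c(s1$B, s1$N, s1$F), c(8, 0, 0))
  s2 <- step_colony(s1, tp)
  expect_equal(c(s2$B, s2$N, s2$F), c(0, 8, 0))
  s3 <- step_colony(s2, tp)
  expect_equal(c(s3$B, s3$N, s3$F), c(0, 0, 8))

  # cap truncation: 100 immortal nurses walk off the 3-class chain
  pc <- colony_params(s_b = 1, g = 0, p = 0, c = 1,
                      nurse_gm = gm_params(0, 0, 0),
                      forager_gm = gm_params(0, 0, 0),
                      structure = stage_structure(1, 3, 1))
  traj <- project_colony(pc, colony_state(0, c(100, 0, 0), 0), T = 3)
  expect_equal(total_population(traj), c(100, 100, 100, 0))
})

test_that("matrix step and recursion step agree to floating-point roundoff", {
  set.seed(17)
  for (i in 1:5) {
    p <- random_valid_params()
    M <- unclass(build_leslie_matrix(p))
    st <- p$structure
    x <- colony_state(runif(st$brood_days, 0, 10),
                      runif(st$nurse_max_days, 0, 10),
                      runif(st$forager_max_days, 0, 10))
    via_matrix <- as.vector(M %*% state_vec(x))
    via_step <- state_vec(step_colony(x, p))
    nz <- via_matrix != 0
    expect_true(all(abs(via_step[nz] / via_matrix[nz] - 1) < 1e-12))
    expect_true(all(via_step[!nz] == 0))
  }
})

test_that("projection equals the matrix power applied to the start state", {
  set.seed(23)
  p <- random_valid_params()
  M <- unclass(build_leslie_matrix(p))
  st <- p$structure
  x <- colony_state(runif(st$brood_days), runif(st$nurse_max_days),
                    runif(st$forager_max_days))
  traj <- project_colony(p, x, T = 40)
  v <- state_vec(x)
  for (t in 1:40) v <- M %*% v
  expect_equal(unname(traj$abundance[41, ]), as.vector(v),
               tolerance = 1e-9)

  # T = 0 records only the initial state
  expect_identical(nrow(project_colony(p, x, T = 0)$abundance), 1L)
})

test_that("empirical growth rate recovers the toy closed form and flags extinction", {
  tp <- toy_params(r = 8, s_b = 1, nurse_m = 0, g = 1)
  traj <- project_colony(tp, colony_state(0, 0, 1), T = 9)
  # burn-in and endpoint both multiples of the 3-day loop: exact
  expect_equal(empirical_growth_rate(traj, burn_in = 3), 2, tolerance = 1e-12)

  # no reproduction: population dies out and the estimator says so
  p0 <- colony_params(s_b = 1, g = 0, p = 0, c = 1,
                      nurse_gm = gm_params(0, 0, 0),
                      forager_gm = gm_params(0, 0, 0),
                      structure = stage_structure(1, 3, 1))
  traj <- project_colony(p0, colony_state(0, c(100, 0, 0), 0), T = 10)
  expect_error(empirical_growth_rate(traj, burn_in = 4),
               class = "colony_extinct")
})

test_that("simulator growth rate matches the dominant eigenvalue at defaults", {
  for (sc in default_scenarios()) {
    lam <- eigen_analysis(build_leslie_matrix(sc$params))$lam
    emp <- empirical_growth_rate(project_colony(sc$params, T = 6000),
                                 burn_in = 3000)
    expect_equal(emp, lam, tolerance = 1e-6)
  }
})

test_that("tidy trajectory export has one row per day, stage and age", {
  p <- default_scenarios()$winter$params
  df <- as.data.frame(project_colony(p, T = 3))
  expect_identical(nrow(df), 4L * 160L)
  expect_identical(unique(df$stage), c("brood", "nurse", "forager"))
  expect_true(all(df$abundance >= 0))
  # day-0 nurses are the default initial condition
  expect_equal(sum(df$abundance[df$day == 0 & df$stage == "nurse"]), 100)
})
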