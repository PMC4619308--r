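test_that("the baseline target reduces to BASE for ANC and rises
           asymptotically for platelets", {
  anc <- table3_anc()
  pc <- table3_pc()
  expect_equal(baseline_at(anc, c(0, 500, 5000)), rep(3240, 3))
  expect_equal(baseline_at(pc, 0), 49200)
  expect_equal(baseline_at(pc, 1e9), 49200 + 55000)
  tt <- seq(0, 20000, by = 100)
  expect_false(is.unsorted(baseline_at(pc, tt)))
  expect_error(baseline_at(pc, -1), "non-negative")
  expect_error(pd_parameters(0.0132, 0.263, 3240, 0.193, imp = 100,
                             marker = "ANC"), "asymptotic")
})

test_that("the transit-system derivatives have the published algebraic
           form", {
  anc <- table3_anc()
  # steady state: all compartments at BASE with no drug
  expect_equal(pd_derivatives(rep(3240, 5), 0, anc, 0), rep(0, 5))
  # C = 1/SLOPE exactly cancels production
  st <- rep(3240, 5)
  d <- pd_derivatives(st, 0, anc, 1 / anc$slope)
  expect_equal(d[1], -anc$ktr * st[1])
  # direct arithmetic at C = 51 ng/mL, state at baseline
  d51 <- pd_derivatives(st, 0, anc, 51)
  expect_equal(d51[1], 0.0132 * 3240 * ((1 - 0.263 * 51) - 1))
  expect_lt(d51[1], 0)
  # finite difference of the integrated trajectory reproduces dA5/dt
  pk <- table3_pk()
  reg <- standard_regimen(5)
  grid <- c(0, 200 - 1e-3, 200, 200 + 1e-3)
  tr <- simulate_marker(anc, pk, reg, grid, full_state = TRUE)
  fd <- (tr$state[4, 5] - tr$state[2, 5]) / 2e-3
  dd <- pd_derivatives(tr$state[3, ], 200, anc,
                       predict_concentration(pk, reg, 200))
  expect_equal(fd, dd[5], tolerance = 1e-5)
  expect_error(pd_derivatives(c(3240, 3240, 3240, 3240, 0), 0, anc, 0),
               "positive")
})

test_that("simulated trajectories agree with an independent lsoda
           integration", {
  pk <- table3_pk()
  anc <- table3_anc()
  reg <- standard_regimen(5)
  grid <- seq(0, 8 * 168, by = 24)
  mine <- simulate_marker(anc, pk, reg, grid)$values
  orc <- pd_lsoda_oracle(anc, pk, reg, grid)
  expect_lt(max(abs(mine - orc) / abs(orc)), 1e-5)
})

test_that("zero-dose trajectories follow the baseline exactly", {
  pk <- table3_pk()
  grid <- seq(0, 2000, by = 24)
  anc_traj <- simulate_marker(table3_anc(), pk, standard_regimen(0), grid)
  expect_lt(max(abs(anc_traj$values - 3240)) / 3240, 1e-3)
  # platelets drift upward toward BASE + IMP by construction
  pc_traj <- simulate_marker(table3_pc(), pk, standard_regimen(0),
                             seq(0, 15000, by = 48))
  expect_false(is.unsorted(pc_traj$values))
  expect_equal(tail(pc_traj$values, 1), 104200, tolerance = 5e-3)
})

test_that("all five compartments stay positive under heavy dosing", {
  pk <- table3_pk()
  set.seed(42)
  for (i in 1:4) {
    pd <- pd_parameters(runif(1, 0.005, 0.05), runif(1, 0.05, 0.5),
                        runif(1, 1000, 50000), runif(1, 0, 0.5),
                        marker = "ANC")
    reg <- standard_regimen(runif(1, 2, 12), n_cycles = 2)
    tr <- simulate_marker(pd, pk, reg, seq(0, 10 * 168, by = 12),
                          full_state = TRUE)
    expect_true(all(tr$state > 0))
  }
})

test_that("one cycle at the published typical values gives the
           characteristic neutrophil time course", {
  pk <- table3_pk()
  anc <- table3_anc()
  tr <- simulate_marker(anc, pk, standard_regimen(5),
                        seq(0, 12 * 168, by = 6))
  nd <- find_nadir(tr)
  expect_gt(nd$value, 500)          # grade 4 avoided at 5 mg/m2/day
  expect_lt(abs(nd$time / 168 - 3.5), 0.5)
  # feedback rebound overshoots baseline after the nadir
  expect_gt(max(tr$values[tr$times > nd$time]), anc$base)
})

test_that("under repeated 4-week cycles the deepest neutrophil dip falls
           in the second cycle", {
  pk <- table3_pk()
  tr <- simulate_marker(table3_anc(), pk, standard_regimen(5, n_cycles = 4),
                        seq(0, 20 * 168, by = 6))
  g <- find_nadir(tr)
  expect_gt(g$time, 4 * 168)  # beyond the first 4-week cycle
  expect_lt(g$time, 8 * 168)
  c1 <- find_nadir(tr, c(0, 672))
  expect_lt(g$value, c1$value)
})

test_that("the nadir is monotone non-increasing in dose and halving the
           slope raises it", {
  pk <- table3_pk()
  anc <- table3_anc()
  grid <- seq(0, 10 * 168, by = 6)
  nads <- sapply(seq(0, 12, by = 2), function(d)
    find_nadir(simulate_marker(anc, pk, standard_regimen(d), grid))$value)
  expect_true(all(diff(nads) <= 1e-9))
  # monotone in SLOPE as well
  slopes <- c(0.1, 0.2, 0.263, 0.3, 0.4)
  nd_s <- sapply(slopes, function(s) {
    pd <- pd_parameters(0.0132, s, 3240, 0.193, marker = "ANC")
    find_nadir(simulate_marker(pd, pk, standard_regimen(5), grid))$value
  })
  expect_true(all(diff(nd_s) < 0))
})

test_that("tightening the integration tolerance leaves the nadir
           essentially unchanged", {
  pk <- table3_pk()
  anc <- table3_anc()
  grid <- seq(0, 10 * 168, by = 6)
  n1 <- find_nadir(simulate_marker(anc, pk, standard_regimen(5), grid,
                                   rtol = 1e-6))$value
  n2 <- find_nadir(simulate_marker(anc, pk, standard_regimen(5), grid,
                                   rtol = 1e-7))$value
  expect_lt(abs(n1 - n2) / n2, 1e-3)
})

test_that("find_nadir refines between grid points and breaks ties at the
           earliest time", {
  # flat trajectory: tie broken at the window start
  flat <- structure(list(times = 0:10, values = rep(5, 11), marker = "ANC"),
                    class = "mt_trajectory")
  nd <- find_nadir(flat, c(2, 8))
  expect_equal(nd$time, 2)
  expect_equal(nd$value, 5)
  # exact parabola: interior vertex recovered exactly
  tt <- seq(0, 10, by = 1)
  par_traj <- structure(list(times = tt, values = (tt - 4.3)^2 + 2,
                             marker = "ANC"), class = "mt_trajectory")
  nd2 <- find_nadir(par_traj)
  expect_equal(nd2$time, 4.3, tolerance = 1e-12)
  expect_equal(nd2$value, 2, tolerance = 1e-12)
  expect_error(find_nadir(flat, c(20, 30)), "empty")
})
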