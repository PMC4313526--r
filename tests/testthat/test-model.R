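pv_pso <- param_vector(bundled_params("pso"))

test_that("reaction rates follow the saturable law", {
  p <- bundled_params("pso")
  s <- t0_state()
  # hand evaluation of the biomass-synthesis rate at the t = 0 state
  expect_equal(reaction_rates(s, p)[["r7"]],
               3977 * 0.09 * 2.85 / (9324 + 2.85), tolerance = 1e-12)
  # full vector against the independent formula-by-formula oracle
  expect_equal(unname(reaction_rates(s, p)),
               unname(oracle_rates(s, pv_pso)), tolerance = 1e-12)
  # zero ceilings give zero rates
  p0 <- kinetic_parameters(rep(0, 9), p$ks, p$mu, p$kd)
  expect_equal(unname(reaction_rates(s, p0)), rep(0, 9))
  # half-saturation point: S = KS gives half the ceiling rate
  ks <- p$ks; ks[] <- 1e-12; ks["KS1_1"] <- 3.59
  ph <- kinetic_parameters(p$phi_star, ks, p$mu, p$kd)
  expect_equal(reaction_rates(s, ph)[["r1"]],
               0.5 * p$phi_star[["phi1"]] * 0.09, tolerance = 1e-6)
  # Monod factors stay within [0, 1]: rates never exceed phi* X
  expect_true(all(reaction_rates(s, p) <= p$phi_star * 0.09 + 1e-12))
})

test_that("simplified kinetics equals the zero-half-saturation limit", {
  p <- bundled_params("pso")
  simp <- kinetic_parameters(p$phi_star, p$ks, p$mu, p$kd,
                             kinetics_mode = "simplified")
  ks0 <- p$ks; ks0[] <- 0
  lim <- kinetic_parameters(p$phi_star, ks0, p$mu, p$kd)
  for (seed in 1:5) {
    set.seed(seed)
    s <- c(stats::runif(11, 0.01, 3), stats::runif(2, 0.01, 1))
    names(s) <- c("GLC", "GLN", "GLU", "ASN", "ASP", "LAC", "ALA",
                  "PRO", "MAb", "BM", "NH3", "X", "Xd")
    expect_equal(reaction_rates(s, simp), reaction_rates(s, lim))
    expect_equal(unname(reaction_rates(s, simp)),
                 unname(p$phi_star) * s[["X"]])
  }
})

test_that("rate laws reject negative states and parameters", {
  p <- bundled_params("pso")
  s <- t0_state(); s["GLC"] <- -0.1
  expect_error(reaction_rates(s, p), "negative")
  pneg <- p; pneg$phi_star["phi1"] <- -1
  expect_error(reaction_rates(t0_state(), pneg), "negative")
})

test_that("state derivative combines stoichiometry and cell dynamics", {
  p <- bundled_params("pso")
  s <- t0_state()
  d <- state_derivative(0, s, p)
  # growth-phase viable-cell balance, hand arithmetic
  expect_equal(d[["X"]], 0.043 * 0.09 - 0.067 * 0.09 * 0.02,
               tolerance = 1e-12)
  # species part equals K phi via the independent oracle
  expect_equal(unname(d[1:11]),
               unname(oracle_species_deriv(oracle_rates(s, pv_pso))),
               tolerance = 1e-12)
  # decline phase drops the growth term
  d60 <- state_derivative(60, s, p)
  expect_equal(d60[["X"]], -0.067 * 0.09 * 0.02, tolerance = 1e-12)
  # dead cells always gain what the death term removes
  expect_equal(d[["Xd"]], 0.067 * 0.09 * 0.02)
  # cells convert, not vanish: d(X + Xd)/dt = mu X in growth, 0 after
  expect_equal(d[["X"]] + d[["Xd"]], p$mu * 0.09)
  expect_equal(d60[["X"]] + d60[["Xd"]], 0)
  # all-zero parameters freeze the state
  p0 <- kinetic_parameters(rep(0, 9), p$ks * 0 + 1, 0, 0)
  expect_equal(unname(state_derivative(0, s, p0)), rep(0, 13))
})

test_that("simulation is constant under zero kinetics and exact at t=0", {
  p <- bundled_params("pso")
  p0 <- kinetic_parameters(rep(0, 9), p$ks, 0, 0)
  tr <- simulate_batch(t0_state(), p0, t_grid = c(0, 50, 100, 147))
  for (i in 2:4) expect_equal(unname(tr[i, -1]), unname(t0_state()))
  tr1 <- simulate_batch(t0_state(), p, t_grid = c(0, 147))
  expect_equal(unname(tr1[1, -1]), unname(t0_state()))
})

test_that("adaptive integration matches a fine fixed-step Euler oracle", {
  # short horizon here; the full 147 h comparison runs in the
  # acceptance suite.  The preset truth is used because the published
  # set drives glutamate quasi-steady at ~1e-4 mM, where an explicit
  # Euler oracle needs a far finer step than the smooth case to
  # converge at all.
  spec <- identifiable_preset()
  pv <- param_vector(spec$true_params)
  ref <- oracle_euler(spec$initial, pv, t_final = 40, h = 0.002,
                      save_at = c(20, 40))
  tr <- simulate_batch(spec$initial, spec$true_params,
                       t_grid = c(0, 20, 40))
  for (i in 1:2) {
    a <- unname(tr[i + 1, -1]); b <- unname(ref[i, ])
    expect_lt(max(abs(a - b) / pmax(abs(b), 1e-6)), 1e-3)
  }
})

test_that("simulated batch reproduces the published depletion pattern", {
  tr <- simulate_batch(t0_state(), bundled_params("pso"))
  expect_lt(tr[nrow(tr), "GLN"], 0.05)     # glutamine exhausted
  expect_gt(max(tr[, "X"]), 0.7)           # viable-cell peak
  expect_lt(max(tr[, "X"]), 1.0)
  peak <- which.max(tr[, "X"])
  expect_lt(tr[nrow(tr), "X"], tr[peak, "X"])  # rise then decline
  # dead cells are non-decreasing; states remain essentially nonnegative
  expect_true(all(diff(tr[, "Xd"]) >= -1e-10))
  expect_true(all(tr[, -1] > -1e-6))
})

test_that("phase-split simplified parameter sets can be simulated", {
  gao <- list(exponential = bundled_params("gao_exp"),
              decline = bundled_params("gao_decl"))
  tr <- simulate_batch(t0_state(), gao, t_grid = seq(0, 147, by = 1))
  expect_false(anyNA(tr))
  # growth stops at the switch: X declines afterwards
  expect_lt(tr[tr[, "time"] == 147, "X"], max(tr[, "X"]))
})

test_that("simulation rejects bad grids and initial states", {
  p <- bundled_params("pso")
  expect_error(simulate_batch(t0_state(), p, t_grid = c(0, 150)),
               "t_final")
  expect_error(simulate_batch(t0_state(), p, t_grid = c(10, 10)),
               "increasing")
  bad <- t0_state(); bad["GLC"] <- -1
  expect_error(simulate_batch(bad, p), "nonnegative")
})
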