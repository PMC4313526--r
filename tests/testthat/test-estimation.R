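test_that("the nine subproblems partition the 23 parameters", {
  specs <- default_subproblems()
  expect_length(specs, 9)
  expect_identical(names(specs), paste0("P", 1:9))
  free <- unlist(lapply(specs, `[[`, "free"))
  expect_length(free, 23)
  expect_length(unique(free), 23)          # disjoint
  expect_identical(specs$P1$free, c("phi7", "KS2_7"))
  expect_identical(specs$P2$free, c("phi8", "KS2_8"))
  expect_length(specs$P5$free, 5)
  expect_setequal(specs$P5$free,
                  c("phi6", "KS2_6", "KS2_9", "phi9", "KS5_6"))
  expect_identical(specs$P9$free, c("mu", "kd"))
})

test_that("freezing order is sound against the stoichiometric matrix", {
  # every parameter appearing in a subproblem's balance equation is
  # either free there or frozen by an earlier subproblem; recomputed
  # here from the matrix and the rate laws, independent of the package's
  # own bookkeeping
  K <- build_network()$K
  rate_pars <- list(
    r1 = c("phi1", "KS1_1"), r2 = c("phi2", "KS1_2", "KS3_2"),
    r3 = c("phi3", "KS1_3", "KS3_3"), r4 = c("phi4", "KS3_4"),
    r5 = c("phi5", "KS4_5"), r6 = c("phi6", "KS2_6", "KS5_6"),
    r7 = c("phi7", "KS2_7"), r8 = c("phi8", "KS2_8"),
    r9 = c("phi9", "KS2_9"))
  specs <- default_subproblems()
  seen <- character()
  for (sp in specs) {
    eq <- if (identical(sp$target, c("X", "Xd"))) c("mu", "kd") else
      unique(unlist(rate_pars[which(K[sp$target, ] != 0)]))
    expect_true(all(setdiff(eq, sp$free) %in% seen),
                info = sp$id)
    expect_setequal(sp$required, setdiff(eq, sp$free))
    seen <- c(seen, sp$free)
  }
})

test_that("objective equals the naive loop oracle on random candidates", {
  tab <- preset_table()            # noiseless synthetic, includes GLU
  traj <- interpolate_measurements(tab)
  truth <- param_vector(identifiable_preset()$true_params)
  specs <- default_subproblems()
  set.seed(42)
  for (id in c("P1", "P4", "P5", "P7", "P9")) {
    sp <- specs[[id]]
    frozen <- truth[setdiff(names(truth), sp$free)]
    for (r in 1:8) {
      cand <- truth[sp$free] * stats::runif(length(sp$free), 0.2, 5)
      pv <- truth; pv[sp$free] <- cand
      got <- subproblem_objective(sp, traj, frozen, cand)
      want <- naive_subproblem_sse(sp$target, traj, pv)
      expect_equal(got, want, tolerance = 1e-12, info = id)
    }
  }
})

test_that("objective is near zero at the generating parameters", {
  # with sampling dense enough that the interpolant tracks the model,
  # only Euler discretization error remains at the generating
  # parameters (with the sparse 7-point design, interpolation error
  # between knots dominates instead and the floor is much higher)
  pre <- identifiable_preset(noise_mode = "none")
  pre$sample_times <- seq(0, 147, by = 1)
  tab <- generate_measurements(pre)
  traj <- interpolate_measurements(tab)
  truth <- param_vector(pre$true_params)
  for (sp in default_subproblems()) {
    frozen <- truth[setdiff(names(truth), sp$free)]
    W <- subproblem_objective(sp, traj, frozen, truth[sp$free])
    expect_lt(W, 0.1)
    # and the floor is far below a detuned candidate
    off <- truth[sp$free] * 3
    expect_gt(subproblem_objective(sp, traj, frozen, off), W)
  }
})

test_that("a zero biomass-synthesis rate leaves biomass flat", {
  tab <- load_measurements()
  traj <- interpolate_measurements(tab)
  sp <- default_subproblems()$P1
  W <- subproblem_objective(sp, traj, c(), c(phi7 = 0, KS2_7 = 1))
  bm <- traj$values[, "BM"]
  expect_equal(W, sum((bm - bm[1])^2), tolerance = 1e-12)
})

test_that("missing frozen parameters are reported by name", {
  tab <- load_measurements()
  traj <- interpolate_measurements(tab)
  sp <- default_subproblems()$P3
  expect_error(subproblem_objective(sp, traj, c(), c(phi4 = 1,
                                                     KS3_4 = 1)),
               "phi7|KS2_7")
})

test_that("multistep estimation is complete, positive and deterministic", {
  tab <- preset_table(noise_mode = "cv", cv = 0.02, seed = 5)
  cfg <- tiny_swarm()
  r1 <- multistep_estimate(tab, cfg = cfg, seed = 3)
  r2 <- multistep_estimate(tab, cfg = cfg, seed = 3)
  v1 <- param_vector(r1$params)
  expect_length(v1, 23)
  expect_true(all(is.finite(v1)))
  expect_true(all(v1 > 0))
  expect_identical(v1, param_vector(r2$params))
  expect_identical(r1$subproblems$P5$history, r2$subproblems$P5$history)
  r3 <- multistep_estimate(tab, cfg = cfg, seed = 4)
  expect_false(identical(v1, param_vector(r3$params)))
})

test_that("returned optimum beats random feasible candidates", {
  tab <- preset_table(noise_mode = "cv", cv = 0.02, seed = 5)
  traj <- interpolate_measurements(tab)
  res <- multistep_estimate(tab, cfg = swarm_config(n_particles = 25,
                                                    max_iter = 40),
                            seed = 1)
  pv <- param_vector(res$params)
  specs <- default_subproblems()
  set.seed(99)
  for (id in c("P1", "P9")) {
    sp <- specs[[id]]
    frozen <- pv[setdiff(names(pv), sp$free)]
    W_opt <- subproblem_objective(sp, traj, frozen, pv[sp$free])
    for (r in 1:100) {
      th <- stats::runif(length(sp$free), sp$bounds[, 1],
                         sp$bounds[, 2])
      th[sp$log_scale] <- 10^th[sp$log_scale]
      names(th) <- sp$free
      expect_gte(subproblem_objective(sp, traj, frozen, th),
                 W_opt - 1e-9)
    }
  }
})

test_that("lumped slopes are stable across seeds when KS is outside the data range", {
  # when a fitted half-saturation constant far exceeds the observed
  # substrate range only the ratio phi*/KS is determined; the biomass
  # subproblem on the bundled data is exactly this case
  tab <- load_measurements()
  traj <- interpolate_measurements(tab)
  sp <- default_subproblems()$P1
  cfg <- swarm_config(n_particles = 30, max_iter = 60)
  slopes <- ks <- numeric(5)
  for (s in 1:5) {
    obj <- function(th) {
      subproblem_objective(sp, traj, c(),
                           c(phi7 = 10^th[1], KS2_7 = 10^th[2]))
    }
    cfg$bounds <- sp$bounds; cfg$seed <- s
    fit <- pso_minimize(obj, cfg)
    S2bar <- mean(range(tab$mean[, "GLN"]))
    slopes[s] <- 10^fit$par[1] / (10^fit$par[2] + S2bar)
    ks[s] <- 10^fit$par[2]
  }
  cv <- stats::sd(slopes) / mean(slopes)
  expect_lt(cv, 0.15)
})

test_that("estimation results serialize to YAML and CSV", {
  tab <- preset_table()
  res <- multistep_estimate(tab, cfg = tiny_swarm(), seed = 1)
  fy <- withr::local_tempfile(fileext = ".yaml")
  fc <- withr::local_tempfile(fileext = ".csv")
  write_estimation(res, fy, fc)
  back <- load_params(fy)
  expect_equal(param_vector(back), param_vector(res$params))
  h <- utils::read.csv(fc)
  expect_setequal(unique(h$subproblem), paste0("P", 1:9))
})
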