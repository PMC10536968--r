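test_that("harmonic boost obeys the piecewise law", {
  p <- gamd_params(E = 10, k = 0.1)
  expect_equal(boost_energy(10, p), 0)
  expect_equal(boost_energy(15, p), 0)
  expect_equal(force_scale(c(10, 15), p), c(1, 1))
  # V = v_min with E = v_max, k0 = 1: dV = (v_max - v_min)/2, lambda = 0
  vmin <- -3; vmax <- 17
  p1 <- gamd_params(E = vmax, k = 1 / (vmax - vmin), k0 = 1)
  expect_equal(boost_energy(vmin, p1), (vmax - vmin) / 2)
  expect_equal(force_scale(vmin, p1), 0)
  # random grid against direct re-evaluation of the formula
  set.seed(8)
  for (rep in 1:200) {
    V <- runif(1, -50, 50); E <- runif(1, -50, 50); k <- runif(1, 0, 0.5)
    pr <- gamd_params(E, k)
    expect_equal(boost_energy(V, pr), if (V < E) 0.5 * k * (E - V)^2 else 0)
    expect_gte(boost_energy(V, pr), 0)
    expect_equal(force_scale(V, pr), if (V < E) 1 - k * (E - V) else 1)
  }
})

test_that("force scale equals d(V + dV)/dV by finite differences", {
  set.seed(3)
  for (rep in 1:50) {
    E <- runif(1, -10, 30); k <- runif(1, 0.01, 0.3)
    p <- gamd_params(E, k)
    V <- runif(1, E - 25, E - 0.5)  # strictly inside the boosted branch
    h <- 1e-6
    fd <- 1 + (boost_energy(V + h, p) - boost_energy(V - h, p)) / (2 * h)
    expect_equal(force_scale(V, p), fd, tolerance = 1e-6)
  }
})

test_that("streaming statistics agree with direct computation and pooling", {
  set.seed(12)
  x <- rnorm(500, 5, 3)
  st <- stats_push(region_stats(), x)
  s <- stats_summary(st)
  expect_equal(s$v_avg, mean(x))
  expect_equal(s$v_std, sqrt(mean(x^2) - mean(x)^2), tolerance = 1e-10)
  expect_equal(s$v_min, min(x)); expect_equal(s$v_max, max(x))
  expect_true(s$v_min <= s$v_avg && s$v_avg <= s$v_max)
  # order independence within tolerance, and merge = push-all
  st2 <- stats_push(region_stats(), rev(x))
  expect_equal(stats_summary(st2)$v_std, s$v_std, tolerance = 1e-10)
  stm <- stats_merge(stats_push(region_stats(), x[1:200]),
                     stats_push(region_stats(), x[201:500]))
  expect_equal(stats_summary(stm)$v_std, s$v_std, tolerance = 1e-10)
  expect_equal(stats_summary(stm)$n_samples, 500)
})

test_that("parameter estimation follows the lower-bound rule", {
  st <- stats_push(region_stats(), c(0, 5, 10, 15, 20))
  s <- stats_summary(st)
  # large sigma0: k0 capped at 1
  p <- estimate_parameters(st, sigma0 = 100)
  expect_equal(p$E, 20)
  expect_equal(p$k0, 1)
  expect_equal(p$k, 1 / 20)
  # small sigma0: k0 = (sigma0/v_std) (v_max - v_min)/(v_max - v_avg) < 1
  p2 <- estimate_parameters(st, sigma0 = 1)
  k0_expected <- (1 / s$v_std) * (s$v_max - s$v_min) / (s$v_max - s$v_avg)
  expect_lt(k0_expected, 1)
  expect_equal(p2$k0, k0_expected)
  expect_equal(p2$k, k0_expected / 20)
  # degenerate statistics disable the boost
  stdeg <- stats_push(region_stats(), c(4, 4, 4))
  expect_warning(pd <- estimate_parameters(stdeg, 10), "degenerate")
  expect_equal(pd$k, 0)
  expect_equal(boost_energy(3.9, pd), 0)
  expect_error(estimate_parameters(stats_push(region_stats(), 1), 10),
               "at least 2")
})

test_that("dual boosting splits dihedral and remaining energies", {
  sys <- make_solute_solvent(4, 8, seed = 2)
  catg <- build_catalogue(sys, dual_boost = TRUE)
  suppressWarnings(rs <- validate_regions(list(
    acceleration_region("solute", c("1-1", "1-2"), dual_boost = TRUE),
    acceleration_region("solvent", "2-2", dual_boost = TRUE)), catg))
  e <- split_energy(sys, catalogue = catg)
  params <- list(solute = gamd_params(5, 0.1), solvent = gamd_params(2, 0.05))
  dpar <- list(solute = gamd_params(3, 0.2))
  res <- apply_dual_boost(e, rs, params, dpar)
  # independent evaluation of the two boost expressions
  v_sol <- sum(e[c("bonded_1", "self_1", "pair_1-2")])
  v_dih <- e[["dihedral_1"]]
  expect_equal(res$dV_total[res$region == "solute"],
               boost_energy(v_sol, params$solute))
  expect_equal(res$dV_dihedral[res$region == "solute"],
               boost_energy(v_dih, dpar$solute))
  expect_equal(res$dV, res$dV_total + res$dV_dihedral)
  # solvent group has no torsions: dihedral boost identically zero
  expect_equal(res$dV_dihedral[res$region == "solvent"], 0)
  # k_dih = 0 reduces to the single-boost result
  res0 <- apply_dual_boost(e, rs, params,
                           list(solute = gamd_params(3, 0)))
  expect_equal(res0$dV[res0$region == "solute"],
               boost_energy(v_sol, params$solute))
})

test_that("M=1 selective run is bit-identical to the monolithic reference", {
  sys <- make_solute_solvent(3, 6, seed = 3)
  sys1 <- bead_system(sys$positions, sys$masses, rep(1, 9), sys$bonds,
                      sys$torsions, box = sys$box)
  catg <- build_catalogue(sys1)
  rs <- validate_regions(acceleration_region("all", "1-1"), catg)
  p <- gamd_params(E = 3, k = 0.08)
  cfg <- integrator_config(n_steps = 800, output_stride = 8, seed = 17)
  t_sel <- run_gamd(sys1, cfg, params = list(all = p), regions = rs)
  t_ref <- run_gamd_reference(sys1, cfg, p)
  expect_identical(t_sel$positions, t_ref$positions)
  expect_identical(unname(t_sel$boost[, "dV_total"]),
                   unname(t_ref$boost[, "dV_total"]))
})

test_that("recorded boost replays from recorded energies", {
  dw <- make_double_well(15)
  p <- gamd_params(E = 14, k = 0.06)
  cfg <- integrator_config(n_steps = 5000, output_stride = 20, seed = 6)
  tr <- run_md(dw, cfg, bias = p)
  expect_equal(unname(tr$boost[, 1]),
               boost_energy(tr$term_energies[, "total"], p), tolerance = 1e-12)
  expect_true(all(tr$boost >= 0))
})

test_that("protocol stages behave as specified", {
  dw <- make_double_well(18)
  cfg <- integrator_config(n_steps = 1, output_stride = 10, seed = 13)
  # zero-length search: production parameters come from cMD stats alone
  res0 <- run_protocol(dw, cfg, stage_steps = list(cmd = 2e4, search = 0,
                                                   production = 2e4))
  st <- stats_summary(res0$search_stats)
  expect_equal(res0$params$E, st$v_max)
  expect_equal(res0$params$k, res0$params$k0 / (st$v_max - st$v_min))
  # with a search stage the threshold can only grow (cumulative stats)
  res1 <- run_protocol(dw, cfg, stage_steps = list(cmd = 2e4, search = 4e4,
                                                   production = 2e4))
  expect_gte(res1$params$E, res0$params$E)
  # production dV is consistent with frozen parameters
  expect_equal(unname(res1$production$boost[, 1]),
               boost_energy(res1$production$term_energies[, "total"],
                            res1$params),
               tolerance = 1e-12)
  expect_error(run_protocol(dw, cfg, stage_steps = list(cmd = 0, search = 1,
                                                        production = 1)),
               "positive")
  expect_error(run_protocol(dw, cfg,
                            stage_steps = list(cmd = 10, search = 10,
                                               production = 10),
                            update_interval = 20), "update interval")
})

test_that("boost distribution is near-Gaussian when region energy is", {
  # premise of the reliability argument: when a region's energy
  # fluctuates near-normally (a sum of many comparable terms, as in a
  # large solvent bath), the boost built from estimated parameters
  # keeps a near-Gaussian distribution (low anharmonicity), while a
  # single-degree-of-freedom energy (chi-square-like) does not
  set.seed(24)
  V <- rnorm(2e5, mean = -800, sd = 20)
  p <- estimate_parameters(stats_push(region_stats(), V), sigma0 = 10)
  dv <- boost_energy(V, p)
  expect_gt(stats::sd(dv), 0)
  expect_lt(anharmonicity(dv), 0.1)
  # contrast: one-degree-of-freedom energy, V ~ chi-square-like
  V1 <- 0.5 * kB * 300 * rnorm(2e5)^2
  p1 <- estimate_parameters(stats_push(region_stats(), V1), sigma0 = 10)
  expect_gt(anharmonicity(boost_energy(V1, p1)), 0.1)
})
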