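test_that("visit counting is exact and periodic", {
  b <- leus_bias(1, n_grid = 36)
  b <- le_update(b, -175)
  expect_equal(sum(b$visits), 1)
  expect_equal(which(b$visits == 1), 1)  # first cell covers [-180, -170)
  # Q and Q + 360 land in the same cell
  b2 <- le_update(b, -175 + 360)
  expect_equal(which(b2$visits == 2), 1)
  # m updates total m
  set.seed(1)
  qs <- runif(250, -180, 180)
  bm <- le_update(leus_bias(1), matrix(qs, ncol = 1))
  expect_equal(sum(bm$visits), 250)
  # boundary ties go to the lower cell: -170 opens the second cell
  bb <- le_update(leus_bias(1), -170)
  expect_equal(which(bb$visits == 1), 2)
  expect_error(le_update(freeze_bias(b), 0), "frozen")
})

test_that("bias energy matches the brute-force double loop", {
  set.seed(2)
  b <- leus_bias(1, n_grid = 36)
  b$visits[] <- rpois(36, 40)
  qs <- runif(25, -180, 180)
  expect_equal(bias_energy(b, qs),
               vapply(qs, function(q) brute_bias_energy(b, q), 0),
               tolerance = 1e-12)
  # 2D
  b2 <- leus_bias(2, n_grid = 12, sigma = 30)
  b2$visits[] <- rpois(144, 5)
  q2 <- cbind(runif(10, -180, 180), runif(10, -180, 180))
  expect_equal(bias_energy(b2, q2),
               apply(q2, 1, function(q) brute_bias_energy(b2, q)),
               tolerance = 1e-12)
  # kernel normalisation: single visit, probe at the cell centre
  b1 <- le_update(leus_bias(1), -175)
  expect_equal(bias_energy(b1, -175), b1$c)
  # c = 0 and empty grid give zero everywhere
  b0 <- leus_bias(1, c = 0)
  b0$visits[] <- 5
  expect_equal(bias_energy(b0, qs), rep(0, 25))
  expect_equal(bias_energy(leus_bias(1), qs), rep(0, 25))
  expect_true(all(bias_energy(b, qs) >= 0))
})

test_that("bias is translation-consistent over full periods", {
  set.seed(3)
  b <- leus_bias(1)
  b$visits[] <- rpois(36, 10)
  q <- runif(10, -180, 180)
  expect_equal(bias_energy(b, q), bias_energy(b, q + 360), tolerance = 1e-12)
  expect_equal(bias_energy(b, q), bias_energy(b, q - 720), tolerance = 1e-12)
})

test_that("frozen bias is time independent through a US phase", {
  dw <- make_double_well(8)
  cfg <- integrator_config(n_steps = 5000, output_stride = 50, seed = 4)
  res <- run_leus(dw, cfg, le_steps = 5000, us_steps = 5000)
  expect_true(res$bias$frozen)
  probe <- seq(-170, 170, by = 17)
  before <- bias_energy(res$bias, probe)
  cfg2 <- cfg; cfg2$n_steps <- 3000L
  more <- run_md(dw, cfg2, bias = res$bias)
  expect_identical(bias_energy(res$bias, probe), before)
  # recorded boost column equals the frozen bias at the positions
  expect_equal(unname(more$boost[, 1]),
               bias_energy(res$bias, more$positions[, 1]), tolerance = 1e-9)
  # LE phase accumulated one visit per step
  expect_equal(sum(res$bias$visits), 5000)
})

test_that("zero-length LE phase gives plain unbiased US dynamics", {
  dw <- make_double_well(8)
  cfg <- integrator_config(n_steps = 100, output_stride = 10, seed = 5)
  res <- run_leus(dw, cfg, le_steps = 0, us_steps = 1000)
  expect_null(res$le)
  expect_equal(sum(res$bias$visits), 0)
  expect_equal(unname(res$us$boost[, 1]), rep(0, n_frames(res$us)))
})

test_that("US reweighting identities hold", {
  set.seed(6)
  # B = 0: plain Boltzmann inversion of the histogram
  cv <- runif(3000, -180, 180)
  fes <- reweight_us(cv, rep(0, 3000), bins = 12, range = c(-180, 180))
  ref <- -kB * 300 * log(fes$counts / sum(fes$counts))
  ref <- ref - min(ref[fes$counts > 0])
  expect_equal(fes$pmf[fes$counts > 0], ref[fes$counts > 0], tolerance = 1e-12)
  # perfect flattening: B = -V + const makes the biased density uniform;
  # reweighting must return the true PMF (algebraic identity)
  dw <- make_double_well(10)
  grid <- seq(-179.5, 179.5, by = 1)
  cvs <- rep(grid, 40)  # exactly uniform biased samples
  B <- -surface_energy(dw, cvs) + 10
  fes2 <- reweight_us(cvs, B, bins = 36, range = c(-180, 180))
  cmp <- fes_rms(fes2, dw, max_pmf = Inf)
  expect_lt(cmp$rms, 0.1)  # only binning discretisation error remains
  # unfrozen bias object is rejected
  expect_error(reweight_us(cv, leus_bias(1)), "frozen")
})

test_that("bias state round-trips through its text serialization", {
  set.seed(7)
  b <- leus_bias(1, n_grid = 24, c = 0.0075, sigma = 12)
  b$visits[] <- rpois(24, 100)
  f <- tempfile(fileext = ".tsv")
  write_leus_bias(b, f)
  expect_identical(read_leus_bias(f), b)
  bf <- freeze_bias(b)
  write_leus_bias(bf, f)
  expect_identical(read_leus_bias(f), bf)
  b2 <- leus_bias(2, n_grid = 8, sigma = 45)
  b2$visits[] <- rpois(64, 3)
  write_leus_bias(b2, f)
  expect_identical(read_leus_bias(f), b2)
  unlink(f)
})
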