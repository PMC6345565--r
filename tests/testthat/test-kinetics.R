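test_that("local concentration follows the half-sphere formula", {
  # independent arithmetic: one molecule in (2/3)*pi*r^3 litres
  r_dm <- 180e-9
  expect_equal(local_concentration(180),
               1 / (6.022e23 * (2 / 3) * pi * r_dm^3), tolerance = 1e-12)
  expect_equal(local_concentration(180), 1.360e-4, tolerance = 5e-4)
  # cubic scaling and monotone decrease towards zero
  expect_equal(local_concentration(360), local_concentration(180) / 8)
  rr <- c(10, 100, 1000, 1e4, 1e6)
  expect_true(all(diff(local_concentration(rr)) < 0))
  expect_lt(local_concentration(1e9), 1e-18)
  expect_error(local_concentration(0), "positive")
  expect_error(local_concentration(-5), "positive")
})

test_that("composite rebinding rate k2 = k1 * L / f", {
  expect_equal(composite_k2(1.85e5, 180, 185), 0.136, tolerance = 1e-2)
  expect_equal(composite_k2(2e5, 200, 1), 2e5 * local_concentration(200))
  expect_equal(composite_k2(1.85e5, 180, 370),
               composite_k2(1.85e5, 180, 185) / 2)
  expect_error(composite_k2(1.85e5, 180, 0), "positive")
})

test_that("intrinsic Kd is k_off / k1", {
  expect_equal(intrinsic_kd(1.85e5, 0.0085), 4.594595e-8, tolerance = 1e-6)
  expect_equal(intrinsic_kd(1.85e5, 0), 0)
  expect_equal(intrinsic_kd(1, 1), 1)
  expect_error(intrinsic_kd(0, 0.01), "positive")
})

test_that("rate_parameters derives L, k2 and Kd and validates k2 overrides", {
  p <- rate_parameters(k1 = 1.85e5, k_off = 0.0085, r = 180, f = 185)
  expect_s3_class(p, "avk_params")
  expect_equal(p$k2, p$k1 * p$L / p$f, tolerance = 1e-12)
  expect_equal(p$kd_int, p$k_off / p$k1)
  expect_warning(
    rate_parameters(k1 = 1.85e5, k_off = 0.0085, r = 180, f = 185, k2 = 0.2),
    "differs from derived")
  expect_silent(
    rate_parameters(k1 = 1.85e5, k_off = 0.0085, r = 180, f = 185,
                    k2 = 0.136))
  expect_error(rate_parameters(k1 = 1.85e5, k_off = 0.0085), "supply either")
})

test_that("derivatives respect mass action and conserve target pairs", {
  p <- fig_params()
  # nothing to bind: all-free state at zero bulk ligand is stationary
  expect_equal(bivalent_derivatives(c(1, 0, 0, 0), p, 0), rep(0, 4))
  # pure bivalent complex at zero ligand can only open towards G
  d <- bivalent_derivatives(c(0, 0, 1, 0), p, 0)
  expect_lt(d[3], 0)
  expect_gt(d[2], 0)
  expect_equal(d[1], 0)
  expect_equal(d[4], 0)
  # conservation to machine precision for random states
  set.seed(101)
  for (i in 1:25) {
    d <- bivalent_derivatives(random_state(), random_params(),
                              10^stats::runif(1, -9, -5))
    expect_lt(abs(sum(d)), 1e-12 * max(1, max(abs(d))))
  }
  expect_error(bivalent_derivatives(c(-0.5, 0.5, 0.5, 0.5), p, 1e-7),
               "negative")
})

test_that("time-course simulation conserves pairs and matches the Euler oracle", {
  p <- fig_params()
  sched <- ligand_schedule(200e-9, 120, washout = TRUE, t_washout = 600)
  st <- seq(0, 720, by = 30)
  tc <- simulate_time_course(p, sched, sample_times = st)
  expect_equal(unname(rowSums(tc[, c("U", "G", "R", "B")])),
               rep(1, nrow(tc)), tolerance = 1e-8)
  expect_true(all(tc[, c("U", "G", "R", "B")] > -1e-10))
  # washout phase is non-increasing in signal
  wash <- tc$signal[tc$time_min >= 120]
  expect_true(all(diff(wash) <= 1e-10))
  # explicit small-step Euler as independent integration oracle
  tc_e <- simulate_time_course(p, sched, sample_times = st, method = "euler")
  expect_lt(max(abs(tc_e$signal - tc$signal)) / max(tc$signal), 0.005)
})

test_that("zero bulk ligand from an all-free start gives zero signal", {
  tc <- simulate_time_course(fig_params(), ligand_schedule(0, 120),
                             sample_times = seq(0, 120, by = 20))
  expect_equal(tc$signal, rep(0, nrow(tc)))
})

test_that("signal definitions weigh the ternary complex by 1 or 2 ligands", {
  p <- fig_params()
  sched <- ligand_schedule(500e-9, 120)
  tc_l <- simulate_time_course(p, sched, sample_times = c(0, 120))
  tc_c <- simulate_time_course(p, sched, sample_times = c(0, 120),
                               signal = "complex")
  end <- nrow(tc_l)
  expect_equal(tc_l$signal[end],
               tc_l$G[end] + tc_l$R[end] + 2 * tc_l$B[end])
  expect_equal(tc_c$signal[end],
               tc_c$G[end] + tc_c$R[end] + tc_c$B[end])
})

test_that("conservation holds across random parameter sets", {
  set.seed(202)
  for (i in 1:100) {
    p <- random_params()
    aa <- 10^stats::runif(1, -9, -5)
    tc <- simulate_time_course(p, ligand_schedule(aa, 60),
                               sample_times = seq(0, 60, by = 12))
    expect_true(all(abs(rowSums(tc[, c("U", "G", "R", "B")]) - 1) <= 1e-8))
    expect_true(all(tc[, c("U", "G", "R", "B")] > -1e-10))
  }
})

test_that("saturation curve is monotone and saturates into the ternary complex", {
  p <- fig_params()
  grid <- 10^seq(-9, -6, length.out = 30)
  sat <- simulate_saturation_curve(p, grid)
  expect_true(all(diff(sat$total_signal) > -1e-10))
  # at strongly saturating bulk ligand the ternary complex dominates
  high <- simulate_saturation_curve(p, 10^seq(-6, -3, length.out = 6))
  top <- high[nrow(high), ]
  expect_gt(top$B, top$R)
  expect_gt(top$B, top$G)
  expect_gt(top$B, top$U)
  # vanishing incubation time leaves everything unbound
  short <- simulate_saturation_curve(p, grid[seq(1, 30, by = 5)],
                                     t_incubation = 1e-5)
  expect_true(all(short$total_signal < 1e-4))
  expect_error(simulate_saturation_curve(p, c(1e-9, 2e-9, 3e-9)), "at least 6")
  expect_error(simulate_saturation_curve(p, seq(1e-9, 2e-9, length.out = 8)),
               "two decades")
})

test_that("species crossover is located by bisection and reports no-root", {
  p <- fig_params()
  cx <- find_species_crossover(p)
  tc <- simulate_time_course(p, ligand_schedule(cx, 120),
                             sample_times = c(0, 120))
  expect_equal(tc$B[2], tc$R[2], tolerance = 1e-2)
  # without the bivalent pathway the ternary complex wins everywhere
  p0 <- rate_parameters(k1 = 1.85e5, k_off = 0.0085, k2 = 0)
  expect_error(find_species_crossover(p0, search_range = c(1e-9, 1e-6)),
               "no B = R crossover")
})

test_that("monovalent kinetics match the pseudo-first-order closed form", {
  p <- fig_params()
  aa <- 100e-9
  tt <- seq(0, 300, by = 10)
  tc <- simulate_monovalent(p, ligand_schedule(aa, 300), sample_times = tt)
  kobs <- p$k1 * aa + p$k_off
  occ_eq <- aa / (aa + p$kd_int)
  expect_equal(tc$signal, occ_eq * (1 - exp(-kobs * tt)), tolerance = 1e-6)
  # isotherm midpoint and zero-ligand limits
  half <- simulate_monovalent(p, ligand_schedule(p$kd_int, 1e5),
                              sample_times = c(0, 1e5))
  expect_equal(half$signal[2], 0.5, tolerance = 1e-6)
  none <- simulate_monovalent(p, ligand_schedule(0, 100),
                              sample_times = c(0, 100))
  expect_equal(none$signal[2], 0)
})

test_that("monovalent endpoint occupancy traces the single-site isotherm", {
  p <- fig_params()
  aas <- 10^seq(-9, -6, length.out = 20)
  occ <- vapply(aas, function(aa) {
    tc <- simulate_monovalent(p, ligand_schedule(aa, 1e5),
                              sample_times = c(0, 1e5))
    tc$signal[2]
  }, numeric(1))
  expect_equal(occ, aas / (aas + p$kd_int), tolerance = 5e-3)
})
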