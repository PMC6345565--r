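test_that("polarization arithmetic and symmetry", {
  expect_equal(polarization(1, 1), 0)
  expect_equal(polarization(3, 1), 0.5)
  expect_equal(polarization(5, 0), 1)
  expect_equal(polarization(5, 0, g = 2.3), 1)
  # antisymmetric under swapping planes at g = 1
  set.seed(11)
  iv <- stats::runif(20, 0.1, 10)
  ih <- stats::runif(20, 0.1, 10)
  expect_equal(polarization(iv, ih), -polarization(ih, iv))
  expect_error(polarization(0, 0), "undefined")
  expect_error(polarization(-1, 2), "non-negative")
})

test_that("FP saturation model: limits and midpoint", {
  expect_equal(fp_saturation_model(9e-6, 50, 250, 9e-6), 150)
  expect_equal(fp_saturation_model(0, 50, 250, 9e-6), 50)
  expect_equal(fp_saturation_model(1, 50, 250, 9e-6), 250, tolerance = 1e-4)
  rr <- 10^seq(-8, -3, length.out = 40)
  expect_true(all(diff(fp_saturation_model(rr, 50, 250, 9e-6)) > 0))
})

test_that("FP competition model reduces to saturation and decays to free", {
  rt <- 21e-6; kd <- 9e-6; ki <- 2.1e-6
  expect_equal(fp_competition_model(0, 50, 250, rt, kd, ki),
               fp_saturation_model(rt, 50, 250, kd))
  expect_equal(fp_competition_model(10, 50, 250, rt, kd, ki), 50,
               tolerance = 1e-4)
  xx <- 10^seq(-8, -2, length.out = 40)
  expect_true(all(diff(fp_competition_model(xx, 50, 250, rt, kd, ki)) < 0))
  # algebraic midpoint: at x = ki * (1 + rt/kd) the bound term halves
  x_mid <- ki * (1 + rt / kd)
  y0 <- fp_competition_model(0, 50, 250, rt, kd, ki)
  expect_equal(fp_competition_model(x_mid, 50, 250, rt, kd, ki),
               (y0 + 50) / 2, tolerance = 1e-10)
  # infinite-ki competitor never displaces: equal to saturation for all x
  expect_equal(fp_competition_model(xx, 50, 250, rt, kd, 1e12),
               rep(fp_saturation_model(rt, 50, 250, kd), length(xx)),
               tolerance = 1e-9)
})

test_that("FP saturation fit round-trips and tolerates noise", {
  d <- gen_fp("saturation", kd = 9e-6, noise_sd = 0)
  fit <- fit_fp_saturation(d)
  expect_equal(fit$derived$kd, 9e-6, tolerance = 1e-3)
  expect_equal(unname(coef(fit)["fp_free"]), 50, tolerance = 1e-3)
  expect_equal(unname(coef(fit)["fp_bound"]), 250, tolerance = 1e-3)
  # 3 % noise: median kd bias below 10 % over 100 seeds
  rec <- vapply(1:100, function(s) {
    tryCatch(fit_fp_saturation(gen_fp("saturation", seed = s))$derived$kd,
             error = function(e) NA_real_)
  }, numeric(1))
  expect_lt(abs(stats::median(rec, na.rm = TRUE) - 9e-6) / 9e-6, 0.10)
  flat <- d
  flat$fp <- 100
  expect_error(fit_fp_saturation(flat), "no variation")
})

test_that("FP competition fit recovers ki with kd and rt held fixed", {
  d <- gen_fp("competition", kd = 9e-6, ki = 2.1e-6, noise_sd = 0)
  rt <- attr(d, "truth")$rt
  fit <- fit_fp_competition(d, rt = rt, kd = 9e-6)
  expect_equal(fit$derived$ki, 2.1e-6, tolerance = 1e-3)
  expect_error(fit_fp_competition(d, rt = rt), "kd")
  # 3 % noise: median ki bias below 15 % over 100 seeds
  rec <- vapply(1:100, function(s) {
    dn <- gen_fp("competition", seed = s)
    tryCatch(fit_fp_competition(dn, rt = rt, kd = 9e-6)$derived$ki,
             error = function(e) NA_real_)
  }, numeric(1))
  expect_lt(abs(stats::median(rec, na.rm = TRUE) - 2.1e-6) / 2.1e-6, 0.15)
})

test_that("a competitor range far below ki is flagged as uninformative", {
  set.seed(12)
  x <- 10^seq(-11, -8.7, length.out = 8)   # all below ki/100
  d <- data.frame(x = x,
                  fp = fp_competition_model(x, 50, 250, 21e-6, 9e-6, 2.1e-6))
  d$fp <- d$fp * (1 + stats::rnorm(8, 0, 0.002))
  res <- tryCatch(
    suppressWarnings(fit_fp_competition(d, rt = 21e-6, kd = 9e-6)),
    error = function(e) e)
  # either an explicit failure or a wide-stderr flag is acceptable
  informative_failure <- inherits(res, "error") ||
    isTRUE(res$wide_stderr) ||
    !is.finite(res$se[["log_ki"]]) || res$se[["log_ki"]] > 1
  expect_true(informative_failure)
})
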