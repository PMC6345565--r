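test_that("dose-response model hits its landmarks", {
  expect_equal(dose_response_model(47e-9, 100, 0, 47e-9), 50)
  expect_equal(dose_response_model(470e-9, 100, 0, 47e-9), 1000 / 11,
               tolerance = 1e-10)   # 10/11 of the span
  expect_equal(dose_response_model(1, 100, 0, 47e-9), 100, tolerance = 1e-6)
  expect_equal(dose_response_model(0, 100, 5, 47e-9), 5)
  # monotone in concentration for positive Hill slope
  cc <- 10^seq(-10, -5, length.out = 50)
  expect_true(all(diff(dose_response_model(cc, 100, 0, 47e-9, 1)) > 0))
  expect_true(all(diff(dose_response_model(cc, 100, 0, 47e-9, 2.5)) > 0))
})

test_that("saturation fit recovers noiseless generating parameters", {
  for (hill_free in c(FALSE, TRUE)) {
    d <- gen_saturation(ec50 = 47e-9, top = 100, bottom = 0, noise_sd = 0,
                        conc = 10^seq(-9.5, -6, length.out = 9))
    fit <- fit_dose_response(d, variable_slope = hill_free)
    expect_equal(fit$derived$ec50, 47e-9, tolerance = 1e-3)
    expect_equal(unname(fit$coefficients["top"]), 100, tolerance = 1e-3)
    expect_equal(unname(fit$coefficients["hill"]), 1, tolerance = 1e-3)
  }
})

test_that("saturation fit rejects degenerate inputs", {
  d <- data.frame(conc = rep(47e-9, 10), signal = stats::rnorm(10, 50, 1))
  expect_error(fit_dose_response(d), "5 distinct")
  flat <- gen_saturation(noise_sd = 0)
  flat$signal <- 42
  expect_error(fit_dose_response(flat), "no variation")
})

test_that("competition fit recovers a descending IC50", {
  x <- 10^seq(-9, -5.5, length.out = 9)
  d <- data.frame(conc = x,
                  signal = dose_response_model(x, 100, 0, 29e-9, hill = -1))
  fit <- fit_competition(d, tracer_conc = 100e-9)
  expect_equal(fit$derived$ic50, 29e-9, tolerance = 1e-3)
  expect_equal(fit$derived$tracer_conc, 100e-9)
  # with 5 % noise the median recovered IC50 stays within 10 % of truth
  set.seed(303)
  rec <- replicate(100, {
    dn <- d
    dn$signal <- dn$signal * (1 + stats::rnorm(nrow(dn), 0, 0.05))
    tryCatch(fit_competition(dn)$derived$ic50, error = function(e) NA)
  })
  expect_lt(abs(stats::median(rec, na.rm = TRUE) - 29e-9) / 29e-9, 0.10)
})

test_that("association fit recovers the half-maximum binding time", {
  tt <- seq(0, 180, by = 10)
  d <- data.frame(time = tt, signal = 80 * (1 - exp(-log(2) / 24 * tt)))
  fit <- fit_association(d)
  expect_equal(fit$derived$t_half, 24, tolerance = 1e-3)
  expect_equal(unname(fit$coefficients["plateau"]), 80, tolerance = 1e-3)
  expect_error(fit_association(data.frame(time = tt, signal = 0)),
               "no variation")
  # 5 % noise: median recovered half-time within 15 % over 100 seeds
  set.seed(304)
  d11 <- data.frame(time = tt, signal = 1 - exp(-log(2) / 11 * tt))
  rec <- replicate(100, {
    dn <- d11
    dn$signal <- dn$signal * (1 + stats::rnorm(nrow(dn), 0, 0.05))
    tryCatch(fit_association(dn)$derived$t_half, error = function(e) NA)
  })
  expect_lt(abs(stats::median(rec, na.rm = TRUE) - 11) / 11, 0.15)
})

test_that("decay fits recover one- and two-phase half-lives", {
  d1 <- gen_decay(half_life = 431, noise_sd = 0)
  f1 <- fit_decay(d1, mode = "one")
  expect_equal(f1$derived$t_half, 431, tolerance = 1e-3)

  d2 <- gen_decay(half_life = c(21, 373), fraction_fast = 0.4, noise_sd = 0,
                  times = seq(0, 600, by = 15))
  f2 <- fit_decay(d2, mode = "two")
  expect_equal(f2$derived$t_half_fast, 21, tolerance = 0.01)
  expect_equal(f2$derived$t_half_slow, 373, tolerance = 0.01)
  expect_equal(f2$derived$fraction_fast, 0.4, tolerance = 0.01)
  expect_false(f2$degenerate)

  # one-phase data forced through the two-phase model is flagged degenerate
  f_deg <- fit_decay(d1, mode = "two")
  expect_true(f_deg$degenerate)

  expect_error(fit_decay(d1[1:5, ], mode = "two"), "at least 6")
  expect_error(fit_decay(data.frame(time = 1:10, signal = exp(-0.01 * 1:10)),
                         mode = "one"), "time 0")
})

test_that("AICc model comparison separates one- from two-phase decays", {
  d1 <- gen_decay(half_life = 431, noise_sd = 0.02, seed = 7)
  expect_identical(compare_decay_models(d1)$preferred, "one")
  # well-separated phases (x10 rates, even split, 2 % noise): two-phase wins
  # in at least 95 of 100 seeds
  wins <- vapply(1:100, function(s) {
    d <- gen_decay(half_life = c(40, 400), fraction_fast = 0.5,
                   noise_sd = 0.02, times = seq(0, 600, by = 20), seed = s)
    compare_decay_models(d)$preferred == "two"
  }, logical(1))
  expect_gte(sum(wins), 95)
})

test_that("fit scale invariance: amplitudes rescale, locations do not", {
  d <- gen_saturation(noise_sd = 0.03, seed = 5)
  f1 <- fit_dose_response(d)
  d2 <- d
  d2$signal <- d$signal * 7.5
  f2 <- fit_dose_response(d2)
  expect_equal(f2$derived$ec50, f1$derived$ec50, tolerance = 1e-6)
  expect_equal(unname(f2$coefficients["top"]),
               7.5 * unname(f1$coefficients["top"]), tolerance = 1e-6)

  dd <- gen_decay(half_life = c(21, 373), noise_sd = 0.02, seed = 6)
  g1 <- fit_decay(dd, mode = "two")
  dd2 <- dd
  dd2$signal <- dd$signal * 3
  g2 <- fit_decay(dd2, mode = "two")
  expect_equal(g2$derived$t_half_fast, g1$derived$t_half_fast,
               tolerance = 1e-6)
  expect_equal(g2$derived$t_half_slow, g1$derived$t_half_slow,
               tolerance = 1e-6)
})

test_that("per-experiment normalization puts pooled curves on a common scale", {
  d1 <- gen_saturation(top = 50, noise_sd = 0, replicates = 1)
  d2 <- gen_saturation(top = 200, noise_sd = 0, replicates = 1)
  d1$replicate <- 1
  d2$replicate <- 2
  d <- rbind(d1, d2)
  norm <- normalize_experiments(d)
  tops <- tapply(norm$signal, norm$replicate, max)
  expect_equal(unname(tops[1]), unname(tops[2]), tolerance = 1e-3)
  fit <- fit_dose_response(norm)
  expect_equal(fit$derived$ec50, 47e-9, tolerance = 1e-3)
})

test_that("fit objects expose the standard modelling interface", {
  d <- gen_saturation(noise_sd = 0.02, seed = 9)
  fit <- fit_dose_response(d)
  expect_named(coef(fit), c("top", "bottom", "log_ec50", "hill"))
  expect_length(residuals(fit), nrow(d))
  expect_equal(predict(fit, 47e-9),
               (coef(fit)[["top"]] + coef(fit)[["bottom"]]) / 2,
               tolerance = 0.05)
  expect_output(print(fit), "dose-response")
  expect_output(print(summary(fit)), "ec50")
})
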