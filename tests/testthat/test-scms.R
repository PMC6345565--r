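test_that("degree of labeling follows the corrected absorbance ratio", {
  expect_equal(degree_of_labeling(0.5, 1.0, 5e4, 7e4, cf_280 = 0.1),
               (0.5 / 7e4) / ((1.0 - 0.05) / 5e4), tolerance = 1e-12)
  expect_equal(degree_of_labeling(0.5, 1.0, 5e4, 7e4, cf_280 = 0.1), 0.376,
               tolerance = 1e-3)
  expect_equal(degree_of_labeling(0, 1.0, 5e4, 7e4), 0)
  # equimolar dye with matched absorptivities gives stoichiometric labeling
  expect_equal(degree_of_labeling(0.8, 0.8, 6e4, 6e4, cf_280 = 0), 1)
  expect_error(degree_of_labeling(0.5, 0.04, 5e4, 7e4, cf_280 = 0.1),
               "non-positive")
})

test_that("PMT gain correction is a voltage-ratio power law", {
  expect_equal(gain_correction(500, 550, 0.7, 10), 1.1^7, tolerance = 1e-12)
  expect_equal(gain_correction(700, 700, 0.7, 10), 1)
  expect_equal(gain_correction(500, 800, 0, 10), 1)
  expect_error(gain_correction(0, 500, 0.7, 10), "positive")
})

test_that("corrected intensity divides by labeled fraction then subtracts background", {
  expect_equal(as.numeric(corrected_intensity(100, 10, 0.72)), 128.9,
               tolerance = 1e-3)
  expect_equal(as.numeric(corrected_intensity(50, 0, 1, 1)), 50)
  res <- corrected_intensity(7.2, 10, 0.72)   # i_obs = i_back * labeling
  expect_equal(as.numeric(res), 0)
  expect_true(attr(res, "flagged_dim"))
  expect_false(attr(corrected_intensity(100, 10, 0.72), "flagged_dim"))
  expect_error(corrected_intensity(-1, 0), "non-negative")
})

test_that("QC filter recovers a planted pass/saturated/dim partition", {
  tab <- gen_roi_table(n_pass = 10, n_saturated = 2, n_dim = 3, seed = 42)
  out <- qc_filter(tab)
  counts <- attr(out, "qc_counts")
  expect_equal(unname(counts["pass"]), 10)
  expect_equal(unname(counts["saturated"]), 2)
  expect_equal(unname(counts["dim"]), 3)
  truth <- attr(tab, "truth")$status
  got <- tapply(out$qc_status, out$sheet_id, function(x) x[1])
  expect_equal(as.character(got[names(truth)]), unname(truth))
})

test_that("QC filter is idempotent and honours sigma_mult", {
  tab <- gen_roi_table(seed = 43)
  once <- qc_filter(tab)
  pass1 <- once[once$qc_status == "pass",
                setdiff(names(once), "qc_status")]
  twice <- qc_filter(pass1)
  expect_true(all(twice$qc_status == "pass"))
  # sigma_mult = 0 removes only strictly sub-background sheets
  strict <- qc_filter(tab, sigma_mult = 0)
  dim_ids <- unique(strict$sheet_id[strict$qc_status == "dim"])
  for (id in dim_ids) {
    rows <- tab[tab$sheet_id == id, ]
    expect_true(any(rows$i_obs < rows$i_back))
  }
  expect_warning(qc_filter(tab[0, ]), "empty")
})

test_that("all-saturated input passes nothing", {
  tab <- gen_roi_table(n_pass = 0, n_saturated = 5, n_dim = 0, seed = 44)
  counts <- attr(qc_filter(tab), "qc_counts")
  expect_equal(unname(counts["pass"]), 0)
  expect_equal(unname(counts["saturated"]), 5)
})

test_that("normalized binding is the corrected-intensity ratio", {
  expect_equal(normalized_binding(100, 100), 1)
  expect_equal(normalized_binding(0, 50), 0)
  expect_equal(normalized_binding(80, 40), 2)
  expect_error(normalized_binding(10, 0), "positive")
})

test_that("quantification reproduces planted ratios exactly at zero noise", {
  cal_l <- channel_calibration(labeling_degree = 0.72, pmt_v1 = 500,
                               pmt_v2 = 550, alpha = 0.7, n_dynodes = 10)
  cal_r <- channel_calibration(labeling_degree = 0.9)
  ratios <- c(0.5, 1, 1.5, 2, 3)
  tab <- gen_roi_table(n_pass = 5, n_saturated = 1, n_dim = 2,
                       ratios = ratios, cal_ligand = cal_l,
                       cal_receptor = cal_r, noise_sd = 0, seed = 45)
  out <- quantify_binding(tab, cal_ligand = cal_l, cal_receptor = cal_r)
  truth <- attr(tab, "truth")$ratios
  pass <- out[out$qc_status == "pass", ]
  expect_equal(pass$ratio, unname(truth[pass$sheet_id]), tolerance = 1e-10)
  expect_true(all(is.na(out$ratio[out$qc_status != "pass"])))
})

test_that("ratio is invariant to common intensity scaling and shared gain", {
  tab <- gen_roi_table(n_pass = 6, n_saturated = 0, n_dim = 0, seed = 46)
  out1 <- quantify_binding(tab)
  scaled <- tab
  scaled$i_obs <- scaled$i_obs * 3.7
  scaled$i_back <- scaled$i_back * 3.7
  out2 <- quantify_binding(scaled)
  expect_equal(out2$ratio, out1$ratio, tolerance = 1e-12)
  # identical gain changes on both channels cancel in the ratio
  cal <- channel_calibration(pmt_v1 = 500, pmt_v2 = 600, alpha = 0.7,
                             n_dynodes = 10)
  out3 <- quantify_binding(tab, cal_ligand = cal, cal_receptor = cal)
  expect_equal(out3$ratio, out1$ratio, tolerance = 1e-12)
})
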