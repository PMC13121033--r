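test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 9, n_true_fates = 8, n_two_cys_fates = 2,
                    n_noise_peaks = 20, n_adduct_satellites = 4,
                    n_isotope_satellites = 4, n_blank_contaminants = 3)
  a <- simulate_peaklist(cfg)
  b <- simulate_peaklist(cfg)
  expect_equal(as.data.frame(a$peaks), as.data.frame(b$peaks))
  expect_equal(as.data.frame(a$truth), as.data.frame(b$truth))
})

test_that("planted species have the promised structure", {
  cfg <- sim_config(seed = 2, n_true_fates = 6, n_two_cys_fates = 3,
                    n_noise_peaks = 0, n_adduct_satellites = 2,
                    n_isotope_satellites = 2, n_blank_contaminants = 2,
                    area_lognormal_sd = 0)
  sim <- simulate_peaklist(cfg)
  shift <- heavy_shift()
  # one-cysteine fate: parent + partner at +4.0071 with partner share p
  fate1 <- sim$truth[sim$truth$class == "fate_1cys", ][1, ]
  parent <- sim$peaks[sim$peaks$neutral_mass == fate1$true_mass, ]
  partner <- sim$peaks[abs(sim$peaks$neutral_mass -
                             (fate1$true_mass + shift)) < 1e-9, ]
  expect_equal(nrow(parent), 1)
  expect_equal(nrow(partner), 1)
  fr <- labeling_fraction(parent$S1, partner$S1)
  expect_equal(fr, cfg$p_heavy, tolerance = 1e-12)
  # two-cysteine fate: M+0 / M+4 / M+8 at binomial shares
  fate2 <- sim$truth[sim$truth$class == "fate_2cys", ][1, ]
  trio <- sim$peaks[abs(sim$peaks$neutral_mass - fate2$true_mass) < 2.5 * shift, ]
  expect_equal(nrow(trio), 3)
  p <- cfg$p_heavy
  expect_equal(labeling_fraction(trio$S1[1], trio$S1[2]), 2 * p / (1 + p),
               tolerance = 1e-12)
  # contaminants are blank-dominated
  cont <- sim$truth[sim$truth$class == "contaminant", ]
  cpk <- sim$peaks[sim$peaks$neutral_mass %in% cont$true_mass, ]
  expect_true(all(cpk$B1 > cpk$S1))
})

test_that("mean pair fraction converges to the incorporation probability", {
  sim <- simulate_peaklist(sim_config(seed = 13, n_true_fates = 120,
                                      n_two_cys_fates = 0, n_noise_peaks = 0,
                                      n_adduct_satellites = 0,
                                      n_isotope_satellites = 0,
                                      n_blank_contaminants = 0,
                                      area_lognormal_sd = 0.1))
  pairs <- find_pairs(sim$peaks, sim$samples)
  expect_equal(nrow(pairs), 120)
  fr <- as.matrix(pairs[, grep("^frac_", names(pairs))])
  m <- mean(fr)
  se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(m - 0.24), 3 * se + 1e-3)
})

test_that("planted satellites are all flagged at zero jitter", {
  sim <- simulate_peaklist(sim_config(seed = 4, n_true_fates = 10,
                                      n_two_cys_fates = 0, n_noise_peaks = 0,
                                      n_adduct_satellites = 8,
                                      n_isotope_satellites = 8,
                                      n_blank_contaminants = 0,
                                      area_lognormal_sd = 0))
  run <- run_pipeline(sim$peaks, sim$samples)
  sat <- sim$truth[sim$truth$class %in% c("adduct", "isotope"), ]
  flagged <- run$flagged[run$flagged$status == "flagged", ]
  for (i in seq_len(nrow(sat))) {
    hit <- abs(flagged$parent_mass - sat$true_mass[i]) /
      sat$true_mass[i] * 1e6 <= 10
    expect_true(any(hit), label = paste("satellite", sat$species_id[i], "flagged"))
  }
})

test_that("recovery scoring handles perfect, empty and spurious detections", {
  sim <- simulate_peaklist(sim_config(seed = 6, n_true_fates = 5,
                                      n_two_cys_fates = 0, n_noise_peaks = 0,
                                      n_adduct_satellites = 0,
                                      n_isotope_satellites = 0,
                                      n_blank_contaminants = 0))
  run <- run_pipeline(sim$peaks, sim$samples)
  sc <- score_recovery(run$final, sim$truth)
  expect_equal(sc$precision, 1)
  expect_equal(sc$recall, 1)
  expect_warning(sc0 <- score_recovery(run$final[0, ], sim$truth),
                 "convention")
  expect_equal(sc0$precision, 1)
  expect_equal(sc0$recall, 0)
  fake <- run$final[1, ]
  fake$parent_mass <- 777.777
  sc_f <- score_recovery(fake, sim$truth)
  expect_equal(sc_f$precision, 0)
  expect_equal(sc_f$recall, 0)
})

test_that("growth-series simulation matches its planted kinetics", {
  sg <- simulate_growth_series(N0 = 2, k = 0, flux = c(a = -2e-15, b = 1e-15),
                               initial_moles = c(4e-6, 1e-6), noise_sd = 0,
                               schedule = c(0, 10, 20), seed = 3)
  expect_equal(unique(sg$volume_ul), 2)       # k = 0: constant volume
  expect_equal(sg$cvh_accumulated, 2 * sg$time_h)
  fit <- flux_fit(sg, "a", cvh_max = Inf)
  expect_equal(fit$slope, -2e-15, tolerance = 1e-12)
  fit_b <- flux_fit(sg, "b", cvh_max = Inf)
  expect_equal(fit_b$slope, 1e-15, tolerance = 1e-12)
  # reproducible under seed
  sg2 <- simulate_growth_series(N0 = 2, k = 0, flux = c(a = -2e-15, b = 1e-15),
                                initial_moles = c(4e-6, 1e-6), noise_sd = 1e-9,
                                schedule = c(0, 10, 20), seed = 3)
  sg3 <- simulate_growth_series(N0 = 2, k = 0, flux = c(a = -2e-15, b = 1e-15),
                                initial_moles = c(4e-6, 1e-6), noise_sd = 1e-9,
                                schedule = c(0, 10, 20), seed = 3)
  expect_equal(as.data.frame(sg2), as.data.frame(sg3))
})
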