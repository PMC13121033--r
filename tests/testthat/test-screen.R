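# Build a candidate pair tibble directly (as find_pairs would emit) so the
# screen operations can be exercised in isolation.
mk_pairs <- function(parent_mass, parent_rt, parent_total_area,
                     polarity = "negative", delta_ppm = 0, delta_rt = 0.01,
                     ids = NULL) {
  n <- length(parent_mass)
  tibble::tibble(
    parent_id = ids %||% sprintf("Q%03d", seq_len(n)),
    partner_id = sprintf("R%03d", seq_len(n)),
    polarity = rep_len(polarity, n),
    parent_mass = parent_mass,
    partner_mass = parent_mass + heavy_shift(),
    parent_rt = parent_rt,
    partner_rt = parent_rt,
    delta_ppm = rep_len(delta_ppm, n),
    delta_rt = rep_len(delta_rt, n),
    qualifying_window = 1L,
    parent_total_area = parent_total_area,
    flags = "",
    status = "candidate"
  )
}

test_that("adduct satellites are flagged within the mass and RT gates", {
  na_h <- atomic_masses[["Na"]] - atomic_masses[["H"]]
  pr <- mk_pairs(parent_mass = c(200.0000, 200.0000 + na_h),
                 parent_rt = c(5.0, 5.3), parent_total_area = c(1e6, 3e5))
  out <- flag_adducts(pr)
  expect_equal(out$flags, c("", "adduct_of:Q001"))
  expect_equal(out$status, c("candidate", "flagged"))

  # RT difference 1.0 min: outside the 0.8 min gate
  pr2 <- mk_pairs(parent_mass = c(200.0000, 200.0000 + na_h),
                  parent_rt = c(5.0, 6.0), parent_total_area = c(1e6, 3e5))
  expect_equal(flag_adducts(pr2)$flags, c("", ""))

  # mass off by 500 ppm: outside the 200 ppm gate
  pr3 <- mk_pairs(parent_mass = c(200.0000, 200.0000 + na_h + 0.111),
                  parent_rt = c(5.0, 5.3), parent_total_area = c(1e6, 3e5))
  expect_equal(flag_adducts(pr3)$flags, c("", ""))

  # proton-bound dimer: expected mass is twice the parent mass
  pr4 <- mk_pairs(parent_mass = c(200.0000, 400.0000),
                  parent_rt = c(5.0, 5.2), parent_total_area = c(1e6, 1e5))
  expect_match(flag_adducts(pr4)$flags[2], "adduct_of:Q001")

  expect_warning(flag_adducts(pr, rules = default_adduct_rules()[0, ]),
                 "empty")
})

test_that("isotopologue satellites need mass, RT, correlation and smaller area", {
  c13 <- atomic_masses[["C13"]] - atomic_masses[["C"]]
  st <- mk_samples(labeled = paste0("S", 1:3))
  peaks <- mk_peaks(
    mass = c(200.0000, 200.0000 + c13),
    rt = c(5.0, 5.1),
    areas = list(S1 = c(1.0e6, 0.11e6), S2 = c(0.9e6, 0.10e6),
                 S3 = c(1.1e6, 0.12e6)),
    ids = c("Q001", "Q002"))
  pr <- mk_pairs(parent_mass = peaks$neutral_mass, parent_rt = peaks$rt,
                 parent_total_area = c(3.0e6, 0.33e6),
                 ids = c("Q001", "Q002"))
  out <- flag_isotopologues(pr, peaks = peaks)
  expect_equal(out$flags, c("", "isotopologue_of:Q001"))

  # satellite larger than its parent is never an isotopologue
  pr_big <- mk_pairs(parent_mass = peaks$neutral_mass, parent_rt = peaks$rt,
                     parent_total_area = c(0.33e6, 3.0e6),
                     ids = c("Q001", "Q002"))
  expect_equal(flag_isotopologues(pr_big, peaks = peaks)$flags, c("", ""))

  # anticorrelated area profiles fail the r >= 0.7 gate
  peaks_anti <- peaks
  peaks_anti$S1 <- c(1.0e6, 0.12e6)
  peaks_anti$S3 <- c(1.1e6, 0.09e6)
  peaks_anti$S2 <- c(0.9e6, 0.115e6)
  expect_equal(flag_isotopologues(pr, peaks = peaks_anti)$flags, c("", ""))
})

test_that("stringent filtering removes flagged pairs and large deviations", {
  pr <- mk_pairs(parent_mass = c(200, 250, 300, 350),
                 parent_rt = c(1, 2, 3, 4),
                 parent_total_area = rep(1e6, 4),
                 delta_ppm = c(1.2, 0.5, 0.5, 0.2),
                 delta_rt = c(0.01, 0.02, 0.08, 0.01))
  pr$flags[4] <- "adduct_of:Q001"
  pr$status[4] <- "flagged"
  out <- stringent_filter(pr)
  # 1.2 ppm removed; 0.08 min removed; flagged removed regardless of deltas
  expect_equal(out$parent_id, "Q002")
  expect_equal(out$status, "stringent_pass")
  # boundary: exactly 1.0 ppm or 0.06 min is removed (>= rule)
  prb <- mk_pairs(parent_mass = c(200, 250), parent_rt = c(1, 2),
                  parent_total_area = rep(1e6, 2),
                  delta_ppm = c(1.0, 0.0), delta_rt = c(0.0, 0.06))
  expect_equal(nrow(stringent_filter(prb)), 0)
})

test_that("cross-polarity duplicates keep the higher ion count, negative on ties", {
  pr <- mk_pairs(parent_mass = rep(193.040879, 2), parent_rt = rep(7.3, 2),
                 parent_total_area = c(5e5, 1e5),
                 polarity = c("negative", "positive"))
  out <- dedup_polarity(pr)
  expect_equal(out$polarity, "negative")
  expect_equal(out$status, "final")

  pr_pos <- mk_pairs(parent_mass = rep(193.040879, 2), parent_rt = rep(7.3, 2),
                     parent_total_area = c(1e5, 5e5),
                     polarity = c("negative", "positive"))
  expect_equal(dedup_polarity(pr_pos)$polarity, "positive")

  # equal counts: deterministic tie-break toward negative mode
  pr_tie <- mk_pairs(parent_mass = rep(193.040879, 2), parent_rt = rep(7.3, 2),
                     parent_total_area = c(2e5, 2e5),
                     polarity = c("positive", "negative"))
  expect_equal(dedup_polarity(pr_tie)$polarity, "negative")

  # single-polarity pairs pass through
  single <- mk_pairs(parent_mass = c(193.040879, 500), parent_rt = c(7.3, 2),
                     parent_total_area = c(1e5, 1e5))
  expect_equal(nrow(dedup_polarity(single)), 2)

  # masses differing beyond the tolerance are different compounds
  far <- mk_pairs(parent_mass = c(193.040879, 193.060000),
                  parent_rt = rep(7.3, 2), parent_total_area = c(5e5, 1e5),
                  polarity = c("negative", "positive"))
  expect_equal(nrow(dedup_polarity(far)), 2)
})

test_that("feature names combine truncated mass and rounded RT", {
  expect_equal(name_feature(193.0409, 7.34), "C193_7.3")
  expect_equal(name_feature(191.0252, 10.44), "C191_10.4")
  expect_equal(name_feature(500.0, 0.0), "C500_0.0")
  expect_equal(name_feature(c(121.02, 307.08), c(7.8, 9.99)),
               c("C121_7.8", "C307_10.0"))
})

test_that("flagging never changes the number of rows; screens only remove", {
  st <- mk_samples(labeled = paste0("S", 1:3))
  pk <- random_peak_table(200, seed = 31, samples = st)
  pr <- find_pairs(pk, st)
  fl <- flag_adducts(pr) |> flag_isotopologues(peaks = pk)
  expect_equal(nrow(fl), nrow(pr))
  expect_true(nrow(stringent_filter(fl)) <= nrow(fl))
  expect_true(nrow(dedup_polarity(stringent_filter(fl))) <=
                nrow(stringent_filter(fl)))
})
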