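test_that("activation scores are z-score sums, invariant to gene scaling", {
  genes <- nrf2_target_genes()
  expect_length(genes, 9)
  set.seed(5)
  expr <- tibble::tibble(cell_line = paste0("L", 1:6))
  for (g in genes) expr[[g]] <- rnorm(6, mean = 5, sd = 2)
  sc <- nrf2_activation_score(expr)
  # independent hand computation per gene
  manual <- rowSums(vapply(genes, function(g) {
    (expr[[g]] - mean(expr[[g]])) / sd(expr[[g]])
  }, numeric(6)))
  expect_equal(sc$activation_score, manual)
  # translation/scale invariance per gene
  expr2 <- expr
  expr2$NQO1 <- expr2$NQO1 * 7 + 100
  expect_equal(nrf2_activation_score(expr2)$activation_score,
               sc$activation_score)
  # a line at the cross-line mean scores 0; +1 sd on every gene scores 9
  expr3 <- tibble::tibble(cell_line = c("A", "B", "C"))
  for (g in genes) expr3[[g]] <- c(1, 2, 3)
  sc3 <- nrf2_activation_score(expr3)
  expect_equal(sc3$activation_score[2], 0)
  expect_equal(sc3$activation_score[3], 9)
  # degenerate gene variance is a named error
  expr4 <- expr
  expr4$GSR <- 1
  expect_error(nrf2_activation_score(expr4), "GSR")
})

test_that("NRF2 classification uses strict dual thresholds", {
  expect_equal(classify_nrf2(-0.5, 5.0), "on")
  expect_equal(classify_nrf2(-0.1, 5.0), "off")
  expect_equal(classify_nrf2(-0.5, 3.0), "off")
  # boundary values are off (strict < and >)
  expect_equal(classify_nrf2(-0.3028, 4.06), "off")
  # vectorised
  expect_equal(classify_nrf2(c(-1, 0), c(10, 10)), c("on", "off"))
  # quintile helper recovers 20th/80th percentiles
  th <- quintile_thresholds(1:100, 1:100)
  expect_equal(th$dependency_max, 20.8)
  expect_equal(th$score_min, 80.2)
})

test_that("cell-volume-hours follow the exponential-growth integral", {
  # k -> 0 limit: constant volume integrates to N0 * T
  expect_equal(cell_volume_hours(100, 0, 24), 2400)
  # one doubling per day over 24 h: N0/(k ln2) (2^(kT)-1) = 100*24/ln2
  expect_equal(cell_volume_hours(100, 1 / 24, 24), 100 * 24 / log(2),
               tolerance = 1e-12)
  expect_equal(round(cell_volume_hours(100, 1 / 24, 24), 2), 3462.47)
  expect_equal(cell_volume_hours(0, 0.1, 10), 0)
  # continuity at k = 0
  expect_lt(abs(cell_volume_hours(100, 1e-9, 24) - 2400), 1e-3 * 2400)
  expect_error(cell_volume_hours(100, 0.1, -1), "negative")
})

test_that("accumulated CVH couples replicate wells through the previous average", {
  # two wells, constant volumes 100 and 200, two 12-h segments:
  # interval CVH = 1200 / 2400 per segment; accumulated at t2 uses the
  # average (1800) of the wells at t1
  series <- tidyr::expand_grid(time_h = c(0, 12, 24), well = c("W1", "W2"))
  series$volume_ul <- ifelse(series$well == "W1", 100, 200)
  acc <- accumulate_cvh(series)
  a1 <- acc[acc$time_h == 12, ]
  expect_equal(sort(a1$cvh_accumulated), c(1200, 2400))
  a2 <- acc[acc$time_h == 24, ]
  expect_equal(sort(a2$cvh_accumulated), c(1200 + 1800, 2400 + 1800))
  # single segment equals cell_volume_hours directly (per-well k inferred)
  g <- tibble::tibble(time_h = c(0, 24), well = "W1",
                      volume_ul = c(100, 200))
  acc_g <- accumulate_cvh(g)
  k <- log2(200 / 100) / 24
  expect_equal(acc_g$cvh_accumulated[acc_g$time_h == 24],
               cell_volume_hours(100, k, 24))
  bad <- tibble::tibble(time_h = c(0, 0), well = "W1", volume_ul = c(1, 2))
  expect_error(accumulate_cvh(bad), "strictly increasing")
})

test_that("flux regression recovers planted slopes and honours exclusions", {
  # noise-free line: slope recovered exactly
  d <- tibble::tibble(cvh_accumulated = seq(0, 250, length.out = 9))
  d$met <- 4e-6 - 1e-15 * d$cvh_accumulated
  fit <- flux_fit(d, "met")
  expect_equal(fit$slope, -1e-15, tolerance = 1e-10)
  expect_equal(fit$points_used, 9)
  expect_equal(nrow(fit$excluded), 0)

  # point beyond 300 ul h excluded as overgrowth
  d2 <- dplyr::bind_rows(d, tibble::tibble(cvh_accumulated = 310,
                                           met = 4e-6 - 1e-15 * 310))
  fit2 <- flux_fit(d2, "met")
  expect_equal(fit2$excluded$reason, "cvh_overgrowth")
  expect_equal(fit2$points_used, 9)

  # depletion to 8% of initial excludes that point for the metabolite
  d3 <- d
  d3$met[9] <- 0.08 * d3$met[1]
  fit3 <- flux_fit(d3, "met")
  expect_equal(fit3$excluded$reason, "depletion")
  # ... and for metabolites declared linked to it
  d4 <- d3
  d4$glu <- 1e-6 + 5e-16 * d4$cvh_accumulated
  fit4 <- flux_fit(d4, "glu", linked = "met")
  expect_equal(fit4$excluded$reason, "linked_depletion:met")
  expect_equal(fit4$slope, 5e-16, tolerance = 1e-10)

  expect_error(flux_fit(d[1, ], "met"), "fewer than 2")
})

test_that("flux slope stderr is honest under noise (bias within ~1 stderr)", {
  sg <- simulate_growth_series(N0 = 1, k = 1 / 24, flux = -1e-15,
                               initial_moles = 4e-6,
                               noise_sd = 0.05 * 1e-15 * 250,
                               schedule = seq(0, 96, by = 12), seed = 42)
  fit <- flux_fit(sg, "met1")
  expect_lt(abs(fit$slope - (-1e-15)), fit$stderr)
})

test_that("proliferation rate is log2 fold change per day", {
  expect_equal(proliferation_rate(1e5, 4e5, 2), 1.0)
  expect_equal(proliferation_rate(1e5, 1e5, 4), 0.0)
  expect_equal(proliferation_rate(2e5, 1e5, 1), -1.0)
  expect_error(proliferation_rate(0, 1e5, 1), "positive")
})

test_that("calibration picks the best of linear/power/quadratic and inverts", {
  lin <- tibble::tibble(ratio = c(0.5, 1, 2, 4),
                        concentration = 2 * c(0.5, 1, 2, 4))
  fl <- fit_calibration(lin)
  expect_equal(fl$model, "linear")
  expect_equal(quantify(fl, 1), 2, tolerance = 1e-9)

  pw <- tibble::tibble(ratio = c(0.5, 1, 2, 4), concentration = c(0.5, 1, 2, 4)^2)
  fp <- fit_calibration(pw)
  expect_equal(fp$model, "power")
  expect_equal(quantify(fp, 3), 9, tolerance = 1e-6)

  qd <- tibble::tibble(ratio = c(0.5, 1, 2, 4),
                       concentration = 1 + 0.5 * c(0.5, 1, 2, 4) +
                         3 * c(0.5, 1, 2, 4)^2)
  fq <- fit_calibration(qd)
  expect_equal(fq$model, "quadratic")
  expect_equal(quantify(fq, 2), 1 + 1 + 12, tolerance = 1e-9)

  expect_error(fit_calibration(lin[1:2, ]), "at least 3")
  expect_warning(quantify(fl, 100), "extrapolat")
})

test_that("fractional labelling requires detection of both M+0 and M+3", {
  out <- labeled_fraction_m3(m0 = 900, m3 = 100)
  expect_equal(out$fraction, 0.1)
  expect_true(out$included)
  expect_true(is.na(labeled_fraction_m3(900, m3 = 0)$fraction))
  expect_true(is.na(labeled_fraction_m3(0, m3 = 100)$fraction))
  # intermediate isotopologues enter the denominator
  expect_equal(labeled_fraction_m3(700, 100, 100, 100)$fraction, 0.1)
})

test_that("tidy and glance methods summarise fitted objects", {
  d <- tibble::tibble(cvh_accumulated = seq(0, 250, length.out = 9))
  d$met <- 4e-6 - 1e-15 * d$cvh_accumulated + rnorm(9, 0, 1e-17)
  fit <- flux_fit(d, "met")
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "cvh"))
  gl <- glance(fit)
  expect_equal(gl$slope, fit$slope)
  cal <- fit_calibration(tibble::tibble(ratio = 1:4, concentration = 2 * (1:4)))
  expect_equal(glance(cal)$model, "linear")
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(cal), "ggplot")
})
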