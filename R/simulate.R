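#' Simulator configuration
#'
#' Parameters of the synthetic peak-list generator, which emulates an
#' untargeted LC-MS feature table from a 1:1 heavy/light cystine tracing
#' experiment with known ground truth. Planted species:
#'
#' * one-cysteine fates: a light parent and a heavy partner at
#'   parent + 4.0071 Da carrying share `p_heavy` of the summed area;
#' * two-cysteine fates: M+0 / M+4 / M+8 peaks with binomial shares
#'   `(1-p)^2`, `2p(1-p)`, `p^2`, so the M+4/(M+0+M+4) pair fraction is
#'   `2p/(1+p)` (0.387 at p = 0.24);
#' * adduct satellites of planted fates at the default adduct deltas,
#'   within 0.8 min of the parent, as full light/heavy pairs;
#' * natural-isotope satellites at +1.00336 Da with area about
#'   1.1% per carbon of the parent, as full pairs;
#' * blank-enriched contaminants (blank area >= sample area);
#' * low-intensity noise peaks at random masses/RTs.
#'
#' Mass and RT jitter are applied to each derived peak (heavy partner,
#' satellite) about its theoretical position relative to the species
#' anchor, i.e. they parameterise the pair-differential measurement
#' scatter. Shared calibration offsets cancel in every pairwise gate of the
#' pipeline and are not simulated. Area noise is multiplicative lognormal.
#'
#' The default counts (50 one-cysteine fates, 10 two-cysteine fates, 20
#' adduct and 20 isotope satellites, 200 noise peaks, 20 contaminants over
#' 6 labelled-mix samples and 2 blanks) give a table of a few hundred
#' features, and `p_heavy = 0.24` sits at the midpoint of the
#' single-cysteine labelling window.
#'
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param n_true_fates Number of one-cysteine fates.
#' @param n_two_cys_fates Number of two-cysteine fates.
#' @param p_heavy Heavy-incorporation probability per cysteine.
#' @param n_noise_peaks,n_blank_contaminants,n_adduct_satellites,n_isotope_satellites
#'   Counts of the other planted species.
#' @param ppm_jitter_sd Pair-differential mass jitter (ppm, Gaussian sd).
#' @param rt_jitter_sd Pair-differential RT jitter (min, Gaussian sd).
#' @param area_lognormal_sd Lognormal sd of per-sample technical area
#'   noise (applied independently to every emitted peak area).
#' @param species_spread_sd Lognormal sd of a species' biological abundance
#'   across samples (shared by all peaks of the species). The default 1.0
#'   (roughly threefold spread) reflects how strongly metabolite levels
#'   differ across a cell-line panel; it is what makes parent/satellite
#'   area correlations high in real tables.
#' @param samples A sample table; default 6 labelled-mix samples and 2
#'   blanks.
#' @param mass_range,rt_range Ranges for planted fate masses (Da) and RTs
#'   (min).
#' @param base_area Median total area of planted fates (ion counts).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_true_fates = 50,
                       n_two_cys_fates = 10,
                       p_heavy = 0.24,
                       n_noise_peaks = 200,
                       n_blank_contaminants = 20,
                       n_adduct_satellites = 20,
                       n_isotope_satellites = 20,
                       ppm_jitter_sd = 0,
                       rt_jitter_sd = 0,
                       area_lognormal_sd = 0.25,
                       species_spread_sd = 1.0,
                       samples = NULL,
                       mass_range = c(150, 900),
                       rt_range = c(1, 18),
                       base_area = 1e7) {
  if (is.null(samples)) {
    samples <- sample_table(
      sample_id = c(paste0("S", 1:6), "B1", "B2"),
      role = c(rep("labeled_mix", 6), rep("blank", 2))
    )
  }
  stopifnot(p_heavy > 0, p_heavy < 1,
            n_true_fates >= 0, n_two_cys_fates >= 0, n_noise_peaks >= 0,
            n_blank_contaminants >= 0, n_adduct_satellites >= 0,
            n_isotope_satellites >= 0, ppm_jitter_sd >= 0, rt_jitter_sd >= 0,
            area_lognormal_sd >= 0, species_spread_sd >= 0, base_area > 0,
            mass_range[1] < mass_range[2], rt_range[1] < rt_range[2])
  if (n_adduct_satellites + n_isotope_satellites > 0 &&
      n_true_fates + n_two_cys_fates == 0) {
    stop("satellites require at least one planted fate", call. = FALSE)
  }
  structure(c(as.list(environment())), class = "sim_config")
}

#' Simulate a peak list with ground truth
#'
#' Generates the feature table described by [sim_config()], the matching
#' sample table, and a ground-truth table recording each planted species.
#'
#' @param config A [sim_config()].
#' @return A list with elements `peaks` (peak tibble), `samples` (sample
#'   table) and `truth` (tibble: `species_id`, `class`, `true_mass`,
#'   `true_rt`, `polarity`, `parent_species`).
#' @export
simulate_peaklist <- function(config = sim_config()) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(config$seed)
    expr
  }
  withr_seed(simulate_peaklist_impl(config))
}

simulate_peaklist_impl <- function(config) {
  samples <- config$samples
  labeled <- samples$sample_id[samples$role == "labeled_mix"]
  blanks <- samples$sample_id[samples$role == "blank"]
  all_ids <- samples$sample_id
  shift <- heavy_shift()
  p <- config$p_heavy

  peaks <- list()
  truth <- list()
  counter <- 0L
  next_id <- function() {
    counter <<- counter + 1L
    sprintf("P%04d", counter)
  }

  noisy_areas <- function(base) {
    # per-sample multiplicative lognormal noise around a shared base level
    base * stats::rlnorm(length(base), 0, config$area_lognormal_sd)
  }
  jitter_mass <- function(mass) {
    mass * (1 + stats::rnorm(length(mass), 0, config$ppm_jitter_sd) * 1e-6)
  }
  jitter_rt <- function(rt) {
    pmax(0, rt + stats::rnorm(length(rt), 0, config$rt_jitter_sd))
  }
  emit_peak <- function(mass, rt, polarity, areas_named) {
    id <- next_id()
    row <- tibble::tibble(peak_id = id, polarity = polarity,
                          neutral_mass = mass, rt = rt, flags = "")
    for (s in all_ids) {
      row[[s]] <- if (s %in% names(areas_named)) areas_named[[s]] else NA_real_
    }
    peaks[[length(peaks) + 1]] <<- row
    id
  }
  record_truth <- function(species_id, class, mass, rt, polarity,
                           parent_species = NA_character_) {
    truth[[length(truth) + 1]] <<- tibble::tibble(
      species_id = species_id, class = class, true_mass = mass,
      true_rt = rt, polarity = polarity, parent_species = parent_species)
  }

  n_fates <- config$n_true_fates + config$n_two_cys_fates
  fate_info <- list()
  if (n_fates > 0) {
    fate_mass <- stats::runif(n_fates, config$mass_range[1], config$mass_range[2])
    fate_rt <- stats::runif(n_fates, config$rt_range[1], config$rt_range[2])
    fate_pol <- sample(c("negative", "positive"), n_fates, replace = TRUE)
    fate_cls <- rep(c("fate_1cys", "fate_2cys"),
                    c(config$n_true_fates, config$n_two_cys_fates))
    for (f in seq_len(n_fates)) {
      sid <- sprintf("fate%03d", f)
      # shared per-sample base abundance for the species
      base <- rlang::set_names(
        config$base_area * stats::rlnorm(length(labeled), 0,
                                         config$species_spread_sd), labeled)
      shares <- if (fate_cls[f] == "fate_1cys") c(1 - p, p) else
        c((1 - p)^2, 2 * p * (1 - p), p^2)
      offsets <- shift * (seq_along(shares) - 1)
      for (iso in seq_along(shares)) {
        m <- fate_mass[f] + offsets[iso]
        rt <- fate_rt[f]
        if (iso > 1) {  # derived peaks carry the differential jitter
          m <- jitter_mass(m)
          rt <- jitter_rt(rt)
        }
        emit_peak(m, rt, fate_pol[f],
                  as.list(noisy_areas(base * shares[iso])))
      }
      record_truth(sid, fate_cls[f], fate_mass[f], fate_rt[f], fate_pol[f])
      fate_info[[f]] <- list(sid = sid, mass = fate_mass[f], rt = fate_rt[f],
                             pol = fate_pol[f], base = base, shares = shares)
    }
  }

  # satellites derive from planted fates (cycled); emitted as light/heavy
  # pairs so they reach the candidate list and must be caught by flagging
  add_satellite <- function(k, kind) {
    fi <- fate_info[[((k - 1) %% length(fate_info)) + 1]]
    if (kind == "adduct") {
      rules <- default_adduct_rules()
      rules <- rules[rules$mass_multiplier == 1, ]
      rule <- rules[((k - 1) %% nrow(rules)) + 1, ]
      m0 <- fi$mass + rule$mass_delta
      rt <- pmin(pmax(fi$rt + stats::runif(1, -0.3, 0.3), 0), Inf)
      ratio <- stats::runif(1, 0.2, 0.5)
      cls <- "adduct"
    } else {
      n_carbon <- sample(5:15, 1)
      m0 <- fi$mass + .mass$c13_gain
      rt <- fi$rt + stats::runif(1, -0.15, 0.15)
      ratio <- 0.011 * n_carbon
      cls <- "isotope"
    }
    if (m0 < 125) return(invisible(NULL))
    sid <- sprintf("%s%03d", cls, k)
    light_share <- fi$shares[1]
    heavy_share <- fi$shares[2]
    emit_peak(m0, rt, fi$pol, as.list(noisy_areas(fi$base * ratio * light_share)))
    emit_peak(jitter_mass(m0 + shift), jitter_rt(rt), fi$pol,
              as.list(noisy_areas(fi$base * ratio * heavy_share)))
    record_truth(sid, cls, m0, rt, fi$pol, parent_species = fi$sid)
  }
  for (k in seq_len(config$n_adduct_satellites)) add_satellite(k, "adduct")
  for (k in seq_len(config$n_isotope_satellites)) add_satellite(k, "isotope")

  if (config$n_blank_contaminants > 0) {
    for (k in seq_len(config$n_blank_contaminants)) {
      m <- stats::runif(1, config$mass_range[1], config$mass_range[2])
      rt <- stats::runif(1, config$rt_range[1], config$rt_range[2])
      pol <- sample(c("negative", "positive"), 1)
      lvl <- config$base_area * stats::runif(1, 0.01, 0.5)
      areas <- c(as.list(rlang::set_names(noisy_areas(rep(lvl, length(labeled))), labeled)),
                 as.list(rlang::set_names(noisy_areas(rep(lvl * 2, length(blanks))), blanks)))
      id <- emit_peak(m, rt, pol, areas)
      record_truth(sprintf("contam%03d", k), "contaminant", m, rt, pol)
    }
  }

  if (config$n_noise_peaks > 0) {
    for (k in seq_len(config$n_noise_peaks)) {
      m <- stats::runif(1, 120, config$mass_range[2] + 50)
      rt <- stats::runif(1, 0, config$rt_range[2] + 2)
      pol <- sample(c("negative", "positive"), 1)
      lvl <- 10^stats::runif(1, 3, 5.5)  # mostly low intensity
      areas <- as.list(rlang::set_names(
        noisy_areas(rep(lvl, length(labeled))), labeled))
      emit_peak(m, rt, pol, areas)
      record_truth(sprintf("noise%03d", k), "noise", m, rt, pol)
    }
  }

  peaks <- dplyr::bind_rows(peaks)
  truth <- dplyr::bind_rows(truth)
  list(peaks = peaks, samples = samples, truth = truth)
}

#' Score pipeline recovery against ground truth
#'
#' A final pair counts as a true positive when its parent matches a planted
#' fate (one- or two-cysteine) within `ppm_tol` and `rt_tol`. Precision is
#' TP / detections (reported as 1 with a warning when nothing was
#' detected); recall is the fraction of planted fates matched by at least
#' one detection.
#'
#' @param final_pairs A pair tibble (typically status `final`).
#' @param truth Ground-truth tibble from [simulate_peaklist()].
#' @param ppm_tol,rt_tol Matching tolerances (default: the pair-search
#'   gates, 10 ppm and 0.25 min).
#' @return A list: `precision`, `recall`, `n_detected`, `n_planted`, and a
#'   `detail` tibble mapping detections to planted species.
#' @export
score_recovery <- function(final_pairs, truth, ppm_tol = 10, rt_tol = 0.25) {
  fates <- truth[truth$class %in% c("fate_1cys", "fate_2cys"), , drop = FALSE]
  n_det <- nrow(final_pairs)
  n_fate <- nrow(fates)
  if (n_det == 0) {
    if (n_fate > 0) {
      warning("no detections; precision reported as 1 by convention")
    }
    return(list(precision = 1, recall = if (n_fate > 0) 0 else 1,
                n_detected = 0, n_planted = n_fate,
                detail = tibble::tibble(parent_id = character(0),
                                        matched_species = character(0))))
  }
  matched <- character(n_det)
  for (i in seq_len(n_det)) {
    if (n_fate == 0) { matched[i] <- NA_character_; next }
    dm <- abs(final_pairs$parent_mass[i] - fates$true_mass) /
      fates$true_mass * 1e6
    drt <- abs(final_pairs$parent_rt[i] - fates$true_rt)
    hit <- which(dm <= ppm_tol & drt <= rt_tol)
    matched[i] <- if (length(hit) > 0) fates$species_id[hit[1]] else NA_character_
  }
  tp <- sum(!is.na(matched))
  recall <- if (n_fate == 0) 1 else
    length(unique(matched[!is.na(matched)])) / n_fate
  list(precision = tp / n_det, recall = recall,
       n_detected = n_det, n_planted = n_fate,
       detail = tibble::tibble(parent_id = final_pairs$parent_id,
                               matched_species = matched))
}

#' Simulate a growth series with a planted exchange flux
#'
#' Total cell volume follows `N0 * 2^(k t)`; medium moles follow
#' `initial + flux * accumulated_CVH` plus Gaussian noise (signed-slope
#' convention: negative flux = consumption).
#'
#' @param N0 Initial total cell volume per well (ul).
#' @param k Proliferation rate (doublings per hour).
#' @param flux Planted slope, mol per (ul h); may be a named vector for
#'   several metabolites.
#' @param initial_moles Medium moles at time 0 (recycled to match `flux`).
#' @param noise_sd Gaussian noise sd on moles (absolute; use e.g. 5% of the
#'   planted range).
#' @param schedule Increasing vector of sampling times (h).
#' @param wells Number of replicate wells.
#' @param seed Integer seed.
#' @return A tibble: `time_h`, `well`, `volume_ul`, `cvh_accumulated`
#'   (true, noise-free), and one moles column per metabolite.
#' @export
simulate_growth_series <- function(N0 = 1, k = 1 / 24, flux = -1e-12,
                                   initial_moles = 4e-6, noise_sd = 0,
                                   schedule = seq(0, 96, by = 12),
                                   wells = 1, seed = 1) {
  stopifnot(all(diff(schedule) > 0), N0 > 0, wells >= 1)
  if (is.null(names(flux))) names(flux) <- paste0("met", seq_along(flux))
  initial_moles <- rep_len(initial_moles, length(flux))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  grid <- tidyr::expand_grid(time_h = schedule, well = paste0("W", seq_len(wells)))
  grid$volume_ul <- N0 * 2^(k * grid$time_h)
  # exact integral of the volume curve from 0 to t
  grid$cvh_accumulated <- cell_volume_hours(N0, k, grid$time_h)
  for (m in seq_along(flux)) {
    mol <- initial_moles[m] + flux[m] * grid$cvh_accumulated
    grid[[names(flux)[m]]] <- mol + stats::rnorm(nrow(grid), 0, noise_sd)
  }
  grid
}
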