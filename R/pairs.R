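#' Tracer label configuration
#'
#' Describes the heavy/light tracer and the pair-search gates. The defaults
#' describe 1:1 unlabelled / U-13C,15N cystine tracing: imported cystine is
#' reduced to cysteine, so each incorporated cysteine adds
#' 3 x (13C - 12C) + (15N - 14N) = 4.0071 Da. Candidate pairs must match the
#' theoretical partner mass within 10 ppm and 0.25 min and show a labelling
#' fraction inside one of two windows in at least one labelled-mix sample:
#' 0.20-0.28 for single-cysteine species and 0.34-0.42 for two-cysteine
#' species (a species carrying two independently labelled cysteines at
#' incorporation probability p shows the M+4/M+0-based fraction
#' 2p/(1+p) ~ 0.39 at p ~ 0.24).
#'
#' @param n_heavy_C,n_heavy_N Heavy atoms gained per incorporated tracer unit.
#' @param pair_ppm_max Maximum deviation of the observed partner mass from
#'   the theoretical parent+shift mass (ppm of the theoretical mass).
#' @param pair_rt_max Maximum parent/partner RT difference (min).
#' @param fraction_windows List of `c(lo, hi)` labelling-fraction windows in
#'   (0,1), non-overlapping.
#' @return A list of class `label_config`.
#' @export
label_config <- function(n_heavy_C = 3,
                         n_heavy_N = 1,
                         pair_ppm_max = 10,
                         pair_rt_max = 0.25,
                         fraction_windows = list(c(0.20, 0.28), c(0.34, 0.42))) {
  stopifnot(n_heavy_C >= 0, n_heavy_N >= 0, pair_ppm_max > 0, pair_rt_max > 0)
  for (w in fraction_windows) {
    stopifnot(length(w) == 2, w[1] >= 0, w[2] <= 1, w[1] < w[2])
  }
  structure(list(n_heavy_C = n_heavy_C, n_heavy_N = n_heavy_N,
                 pair_ppm_max = pair_ppm_max, pair_rt_max = pair_rt_max,
                 fraction_windows = fraction_windows),
            class = "label_config")
}

#' Labelling fraction of a peak pair
#'
#' Share of the summed parent+partner signal carried by the heavy partner,
#' `partner / (parent + partner)`. Equals the heavy-incorporation
#' probability p for one-cysteine species; for two-cysteine species the
#' M+4/(M+0 + M+4) share is 2p(1-p) / ((1-p)^2 + 2p(1-p)) = 2p/(1+p).
#'
#' @param parent_area,partner_area Non-negative ion counts (vectorised).
#' @return Fractions in `[0, 1]`; `NA` where both areas are zero/missing.
#' @export
labeling_fraction <- function(parent_area, partner_area) {
  pa <- ifelse(is.na(parent_area), 0, parent_area)
  qa <- ifelse(is.na(partner_area), 0, partner_area)
  stopifnot(all(pa >= 0), all(qa >= 0))
  out <- qa / (pa + qa)
  out[pa + qa == 0] <- NA_real_
  out
}

#' Find unlabelled/labelled isotopologue peak pairs
#'
#' The core pair search: for every feature P, looks for a same-polarity
#' partner Q whose mass matches mass(P) + tracer shift within
#' `pair_ppm_max` ppm (of the theoretical partner mass) and whose RT is
#' within `pair_rt_max` min. Labelling fractions are computed per
#' labelled-mix sample in which either peak is detected (an undetected
#' parent with a detected partner yields fraction 1); a candidate is emitted
#' only when at least one fraction lies inside one of the configured
#' windows. Output order is deterministic: by parent mass, then partner
#' mass.
#'
#' @param peaks A (prefiltered) peak tibble.
#' @param samples A sample table with at least one `labeled_mix` sample.
#' @param config A [label_config()].
#' @return A pair tibble: `parent_id`, `partner_id`, `polarity`,
#'   `parent_mass`, `partner_mass`, `parent_rt`, `partner_rt`, `delta_ppm`,
#'   `delta_rt`, `qualifying_window`, `parent_total_area`, `flags`,
#'   `status` (`"candidate"`), and one `frac_<sample>` column per
#'   labelled-mix sample.
#' @export
find_pairs <- function(peaks, samples, config = label_config()) {
  labeled <- samples$sample_id[samples$role == "labeled_mix"]
  if (length(labeled) == 0) {
    stop("no labeled_mix samples in sample table", call. = FALSE)
  }
  labeled <- intersect(labeled, names(peaks))
  shift <- heavy_shift(config)
  nonblank <- intersect(samples$sample_id[samples$role != "blank"], names(peaks))

  out <- empty_pair_table(labeled)
  if (nrow(peaks) < 2) return(out)

  ord <- order(peaks$neutral_mass)
  mass_sorted <- peaks$neutral_mass[ord]
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    theo <- peaks$neutral_mass[i] + shift
    tol <- config$pair_ppm_max * 1e-6 * theo
    lo <- findInterval(theo - tol, mass_sorted) + 1
    hi <- findInterval(theo + tol, mass_sorted)
    if (hi < lo) next
    for (j in ord[lo:hi]) {
      if (j == i) next
      if (peaks$polarity[j] != peaks$polarity[i]) next
      drt <- abs(peaks$rt[j] - peaks$rt[i])
      if (drt > config$pair_rt_max) next
      fr <- labeling_fraction(as.numeric(peaks[i, labeled]),
                              as.numeric(peaks[j, labeled]))
      win <- qualifying_window(fr, config$fraction_windows)
      if (is.na(win)) next
      row <- tibble::tibble(
        parent_id = peaks$peak_id[i],
        partner_id = peaks$peak_id[j],
        polarity = peaks$polarity[i],
        parent_mass = peaks$neutral_mass[i],
        partner_mass = peaks$neutral_mass[j],
        parent_rt = peaks$rt[i],
        partner_rt = peaks$rt[j],
        delta_ppm = abs(ppm_diff(peaks$neutral_mass[j], theo)),
        delta_rt = drt,
        qualifying_window = win,
        parent_total_area = sum(as.numeric(peaks[i, nonblank]), na.rm = TRUE),
        flags = "",
        status = "candidate"
      )
      for (k in seq_along(labeled)) {
        row[[paste0("frac_", labeled[k])]] <- fr[k]
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  if (length(rows) == 0) return(out)
  out <- dplyr::bind_rows(rows)
  out[order(out$parent_mass, out$partner_mass), , drop = FALSE]
}

# First window index containing any of the fractions, NA if none.
qualifying_window <- function(fractions, windows) {
  for (w in seq_along(windows)) {
    lo <- windows[[w]][1]; hi <- windows[[w]][2]
    if (any(!is.na(fractions) & fractions >= lo & fractions <= hi)) return(w)
  }
  NA_integer_
}

empty_pair_table <- function(labeled = character(0)) {
  out <- tibble::tibble(
    parent_id = character(0), partner_id = character(0),
    polarity = character(0), parent_mass = numeric(0),
    partner_mass = numeric(0), parent_rt = numeric(0),
    partner_rt = numeric(0), delta_ppm = numeric(0), delta_rt = numeric(0),
    qualifying_window = integer(0), parent_total_area = numeric(0),
    flags = character(0), status = character(0)
  )
  for (s in labeled) out[[paste0("frac_", s)]] <- numeric(0)
  out
}
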