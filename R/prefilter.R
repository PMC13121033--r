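#' Pre-pairing filter configuration
#'
#' Thresholds applied to the feature table before pair searching. Defaults
#' follow the published procedure: a feature is kept when at least one
#' non-blank sample exceeds 25,000 ion counts and at least one labelled-mix
#' sample exceeds 15,000 (both strict); features must exceed any blank
#' fourfold; features below 120 Da (one Dalton below cysteine) are dropped;
#' duplicate features (small uncollapsed mass defects) are merged when
#' within 50 ppm and either 0.1 min, or 0.2 min with a Pearson correlation
#' of peak areas across samples of at least 0.9.
#'
#' @param min_any_area Ion-count floor over all non-blank samples (strict `>`).
#' @param min_labeled_area Ion-count floor over labelled-mix samples (strict `>`).
#' @param blank_fold Required ratio of max non-blank area to max blank area.
#' @param mass_floor Minimum neutral mass in Da (kept when `>=`).
#' @param merge_ppm Maximum mass difference for duplicate merging (ppm,
#'   relative to the smaller mass).
#' @param merge_rt_tight,merge_rt_loose RT windows (min) for the two merge
#'   branches.
#' @param merge_corr_min Pearson threshold for the loose-RT branch.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_any_area = 25000,
                          min_labeled_area = 15000,
                          blank_fold = 4,
                          mass_floor = 120,
                          merge_ppm = 50,
                          merge_rt_tight = 0.1,
                          merge_rt_loose = 0.2,
                          merge_corr_min = 0.9) {
  stopifnot(min_any_area > 0, min_labeled_area > 0, blank_fold > 0,
            mass_floor > 0, merge_ppm > 0, merge_rt_tight > 0,
            merge_rt_loose > 0, merge_corr_min > 0,
            merge_rt_tight <= merge_rt_loose)
  structure(list(min_any_area = min_any_area,
                 min_labeled_area = min_labeled_area,
                 blank_fold = blank_fold, mass_floor = mass_floor,
                 merge_ppm = merge_ppm, merge_rt_tight = merge_rt_tight,
                 merge_rt_loose = merge_rt_loose,
                 merge_corr_min = merge_corr_min),
            class = "filter_config")
}

#' Ion-count intensity filter
#'
#' Keeps features whose maximum area over non-blank samples strictly exceeds
#' `min_any_area` and whose maximum area over labelled-mix samples strictly
#' exceeds `min_labeled_area`.
#'
#' @param peaks A peak tibble.
#' @param samples A sample table (needs at least one `labeled_mix` sample).
#' @param config A [filter_config()].
#' @return The surviving subset of `peaks`.
#' @export
intensity_filter <- function(peaks, samples, config = filter_config()) {
  labeled <- samples$sample_id[samples$role == "labeled_mix"]
  if (length(labeled) == 0) {
    stop("no labeled_mix samples in sample table", call. = FALSE)
  }
  nonblank <- samples$sample_id[samples$role != "blank"]
  keep <- row_max_area(peaks, intersect(nonblank, names(peaks))) > config$min_any_area &
    row_max_area(peaks, intersect(labeled, names(peaks))) > config$min_labeled_area
  peaks[keep, , drop = FALSE]
}

#' Blank-enrichment filter
#'
#' Keeps features whose maximum non-blank area is at least `blank_fold`
#' times the maximum blank area. Tables without blank samples pass
#' unchanged; a feature undetected in every blank always passes.
#'
#' @inheritParams intensity_filter
#' @return The surviving subset of `peaks`.
#' @export
blank_filter <- function(peaks, samples, config = filter_config()) {
  blanks <- intersect(samples$sample_id[samples$role == "blank"], names(peaks))
  if (length(blanks) == 0) return(peaks)
  nonblank <- intersect(samples$sample_id[samples$role != "blank"], names(peaks))
  keep <- row_max_area(peaks, nonblank) >=
    config$blank_fold * row_max_area(peaks, blanks)
  peaks[keep, , drop = FALSE]
}

#' Mass-floor filter
#'
#' Drops features with a neutral monoisotopic mass below `mass_floor`
#' (default 120 Da, one Dalton below cysteine); the boundary is inclusive.
#'
#' @inheritParams intensity_filter
#' @return The surviving subset of `peaks`.
#' @export
mass_floor_filter <- function(peaks, config = filter_config()) {
  peaks[peaks$neutral_mass >= config$mass_floor, , drop = FALSE]
}

#' Merge duplicate features
#'
#' Uncollapsed small mass defects leave several features for one molecule.
#' Two same-polarity features are duplicates when their masses differ by at
#' most `merge_ppm` (relative to the smaller mass) and their RTs by at most
#' `merge_rt_tight` min, or by at most `merge_rt_loose` min with a Pearson
#' correlation of areas across samples of at least `merge_corr_min`
#' (pairwise-complete, at least 3 shared samples). Duplicates are grouped by
#' transitive closure; each group collapses to one feature carrying the
#' element-wise sum of areas and the mass/RT (and id) of the member with the
#' largest total area, flagged `merged`.
#'
#' @param peaks A peak tibble.
#' @param config A [filter_config()].
#' @return A peak tibble with duplicate groups collapsed; total area per
#'   sample is conserved.
#' @export
merge_duplicates <- function(peaks, config = filter_config()) {
  if (nrow(peaks) < 2) return(peaks)
  area_cols <- setdiff(names(peaks), .peak_meta_cols)
  links <- duplicate_links(peaks, config, area_cols)
  grp <- union_find_groups(nrow(peaks), links)
  if (length(unique(grp)) == nrow(peaks)) return(peaks)

  out <- purrr::map_dfr(split(seq_len(nrow(peaks)), grp), function(idx) {
    sub <- peaks[idx, , drop = FALSE]
    if (length(idx) == 1) return(sub)
    tot <- row_total_area(sub, area_cols)
    best <- which.max(tot)
    rep <- sub[best, , drop = FALSE]
    for (cl in area_cols) {
      v <- sub[[cl]]
      rep[[cl]] <- if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
    }
    rep$flags <- add_flag(rep$flags, "merged")
    rep
  })
  # preserve input order by surviving representative position
  out[order(match(out$peak_id, peaks$peak_id)), , drop = FALSE]
}

# All index pairs (i, j) of same-polarity duplicate features.
duplicate_links <- function(peaks, config, area_cols) {
  ord <- order(peaks$neutral_mass)
  mass <- peaks$neutral_mass[ord]
  res <- list()
  n <- length(ord)
  for (a in seq_len(max(n - 1, 0))) {
    b <- a + 1
    while (b <= n && ppm_diff(mass[b], mass[a]) <= config$merge_ppm) {
      i <- ord[a]; j <- ord[b]
      if (peaks$polarity[i] == peaks$polarity[j] &&
          is_duplicate(peaks, i, j, config, area_cols)) {
        res[[length(res) + 1]] <- c(i, j)
      }
      b <- b + 1
    }
  }
  if (length(res) == 0) return(matrix(integer(0), ncol = 2))
  do.call(rbind, res)
}

is_duplicate <- function(peaks, i, j, config, area_cols) {
  drt <- abs(peaks$rt[i] - peaks$rt[j])
  if (drt <= config$merge_rt_tight) return(TRUE)
  if (drt <= config$merge_rt_loose) {
    r <- pairwise_pearson(as.numeric(peaks[i, area_cols]),
                          as.numeric(peaks[j, area_cols]))
    return(!is.na(r) && r >= config$merge_corr_min)
  }
  FALSE
}

#' Run all pre-pairing filters
#'
#' Applies, in order: intensity filter, blank filter, mass floor, duplicate
#' merging.
#'
#' @inheritParams intensity_filter
#' @return The filtered, merged peak tibble.
#' @export
prefilter <- function(peaks, samples, config = filter_config()) {
  peaks |>
    intensity_filter(samples, config) |>
    blank_filter(samples, config) |>
    mass_floor_filter(config) |>
    merge_duplicates(config)
}
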