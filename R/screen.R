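#' Artifact-screen configuration
#'
#' Gates for flagging adduct and natural-isotopologue satellite pairs and
#' for the final stringent mass/RT filter. Defaults follow the published
#' procedure: adduct matches within 200 ppm and 0.8 min; isotopologue
#' matches within 200 ppm and 0.4 min with an area correlation of at least
#' 0.7 and a satellite area below its parent; stringent filtering removes
#' pairs with a mass deviation of at least 1.0 ppm or an RT difference of at
#' least 0.06 min (known conjugates pair within 0.66 ppm / 0.04 min).
#'
#' @param adduct_ppm,adduct_rt Adduct match gates (ppm, min).
#' @param iso_ppm,iso_rt Isotopologue match gates (ppm, min).
#' @param iso_corr_min Pearson floor for isotopologue flagging.
#' @param stringent_dppm Pairs with `delta_ppm >=` this are removed (ppm).
#' @param stringent_drt Pairs with `delta_rt >=` this are removed (min).
#' @param xpol_ppm,xpol_rt Tolerances identifying the same compound across
#'   ionisation polarities (defaults reuse the pair-search gates).
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(adduct_ppm = 200, adduct_rt = 0.8,
                          iso_ppm = 200, iso_rt = 0.4, iso_corr_min = 0.7,
                          stringent_dppm = 1.0, stringent_drt = 0.06,
                          xpol_ppm = 10, xpol_rt = 0.25) {
  stopifnot(adduct_ppm > 0, adduct_rt > 0, iso_ppm > 0, iso_rt > 0,
            iso_corr_min > 0, stringent_dppm > 0, stringent_drt > 0,
            xpol_ppm > 0, xpol_rt > 0)
  structure(list(adduct_ppm = adduct_ppm, adduct_rt = adduct_rt,
                 iso_ppm = iso_ppm, iso_rt = iso_rt,
                 iso_corr_min = iso_corr_min,
                 stringent_dppm = stringent_dppm,
                 stringent_drt = stringent_drt,
                 xpol_ppm = xpol_ppm, xpol_rt = xpol_rt),
            class = "screen_config")
}

#' Default adduct rules
#'
#' Common neutral-mass deltas for electrospray adducts and in-source losses:
#' Na-H, K-H, +NH3, -H2O, +HCOOH, +HCl, and the proton-bound dimer (expected
#' mass twice the parent mass). All deltas derive from the shared
#' atomic-mass table. The list is a convention, not a claim of completeness;
#' supply your own via [read_rule_table()].
#'
#' @return A rule tibble (`name`, `mass_delta`, `mass_multiplier`,
#'   `polarity_scope`).
#' @export
default_adduct_rules <- function() {
  am <- atomic_masses
  tibble::tibble(
    name = c("Na-H", "K-H", "+NH3", "-H2O", "+HCOOH", "+HCl", "dimer"),
    mass_delta = c(am[["Na"]] - am[["H"]],
                   am[["K"]] - am[["H"]],
                   formula_mass(c(N = 1, H = 3)),
                   -.mass$h2o,
                   formula_mass(c(C = 1, H = 2, O = 2)),
                   am[["H"]] + am[["Cl"]],
                   0),
    mass_multiplier = c(1, 1, 1, 1, 1, 1, 2),
    polarity_scope = "any"
  )
}

#' Default natural-isotope rules
#'
#' The most abundant heavy-isotope satellites for CHNOPS metabolites: one
#' and two 13C, one 34S and one 18O.
#'
#' @return A rule tibble (`name`, `mass_delta`, `mass_multiplier`,
#'   `polarity_scope`).
#' @export
default_isotope_rules <- function() {
  tibble::tibble(
    name = c("13C1", "13C2", "34S", "18O"),
    mass_delta = c(.mass$c13_gain, 2 * .mass$c13_gain,
                   .mass$s34_gain, .mass$o18_gain),
    mass_multiplier = 1,
    polarity_scope = "any"
  )
}

#' Flag adduct satellite pairs
#'
#' For each ordered pair of candidate parents (A, B) of the same polarity,
#' flags pair B as `adduct_of:<A>` when mass(B) matches
#' `mass_multiplier * mass(A) + mass_delta` for some rule within
#' `adduct_ppm` and the parent RTs are within `adduct_rt`. Flags accumulate;
#' no rows are removed.
#'
#' @param pairs A pair tibble from [find_pairs()].
#' @param rules An adduct rule tibble; default [default_adduct_rules()].
#' @param config A [screen_config()].
#' @return `pairs` with updated `flags`.
#' @export
flag_adducts <- function(pairs, rules = default_adduct_rules(),
                         config = screen_config()) {
  if (is.null(rules) || nrow(rules) == 0) {
    warning("empty adduct rule list; nothing flagged")
    return(pairs)
  }
  flag_satellites(pairs, rules, config$adduct_ppm, config$adduct_rt,
                  prefix = "adduct_of", corr_min = NULL, require_smaller = FALSE)
}

#' Flag natural-isotopologue satellite pairs
#'
#' For each ordered pair of candidate parents (A, B) of the same polarity,
#' flags pair B as `isotopologue_of:<A>` when mass(B) matches
#' mass(A) + isotope delta within `iso_ppm`, RTs are within `iso_rt`, the
#' Pearson correlation of parent areas across samples is at least
#' `iso_corr_min` (pairwise-complete, at least 3 samples), and B's total
#' area is below A's.
#'
#' @param pairs A pair tibble from [find_pairs()].
#' @param rules An isotope rule tibble; default [default_isotope_rules()].
#' @param config A [screen_config()].
#' @param peaks Optional peak tibble; when supplied, the area correlation is
#'   computed from per-sample parent peak areas (recommended). Without it,
#'   correlation falls back to the per-sample labelling-fraction columns'
#'   implied areas and is skipped if unavailable.
#' @return `pairs` with updated `flags`.
#' @export
flag_isotopologues <- function(pairs, rules = default_isotope_rules(),
                               config = screen_config(), peaks = NULL) {
  if (is.null(rules) || nrow(rules) == 0) {
    warning("empty isotope rule list; nothing flagged")
    return(pairs)
  }
  flag_satellites(pairs, rules, config$iso_ppm, config$iso_rt,
                  prefix = "isotopologue_of", corr_min = config$iso_corr_min,
                  require_smaller = TRUE, peaks = peaks)
}

flag_satellites <- function(pairs, rules, ppm_max, rt_max, prefix,
                            corr_min = NULL, require_smaller = FALSE,
                            peaks = NULL) {
  n <- nrow(pairs)
  if (n < 2) return(pairs)
  area_cols <- if (!is.null(peaks)) setdiff(names(peaks), .peak_meta_cols)
  parent_areas <- if (!is.null(peaks)) {
    idx <- match(pairs$parent_id, peaks$peak_id)
    as.matrix(peaks[idx, area_cols, drop = FALSE])
  }
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      if (pairs$polarity[a] != pairs$polarity[b]) next
      if (abs(pairs$parent_rt[b] - pairs$parent_rt[a]) > rt_max) next
      expected <- rules$mass_multiplier * pairs$parent_mass[a] + rules$mass_delta
      scope_ok <- rules$polarity_scope %in% c("any", pairs$polarity[a])
      hit <- scope_ok &
        abs(ppm_diff(pairs$parent_mass[b], expected)) <= ppm_max &
        expected > 0
      if (!any(hit)) next
      if (require_smaller &&
          !(pairs$parent_total_area[b] < pairs$parent_total_area[a])) next
      if (!is.null(corr_min) && !is.null(parent_areas)) {
        r <- pairwise_pearson(parent_areas[a, ], parent_areas[b, ])
        if (is.na(r) || r < corr_min) next
      }
      pairs$flags[b] <- add_flag(pairs$flags[b],
                                 paste0(prefix, ":", pairs$parent_id[a]))
      pairs$status[b] <- "flagged"
    }
  }
  pairs
}

#' Stringent filtering of candidate pairs
#'
#' Removes pairs flagged as adducts or isotopologues, then removes pairs
#' with `delta_ppm >= stringent_dppm` or `delta_rt >= stringent_drt`.
#' Survivors get status `stringent_pass`.
#'
#' @param pairs A flagged pair tibble.
#' @param config A [screen_config()].
#' @return The surviving subset of `pairs`.
#' @export
stringent_filter <- function(pairs, config = screen_config()) {
  keep <- !has_flag(pairs$flags, "adduct_of") &
    !has_flag(pairs$flags, "isotopologue_of") &
    pairs$delta_ppm < config$stringent_dppm &
    pairs$delta_rt < config$stringent_drt
  out <- pairs[keep, , drop = FALSE]
  if (nrow(out) > 0) out$status <- "stringent_pass"
  out
}

#' Cross-polarity deduplication
#'
#' Compounds ionising in both polarities yield one pair per mode. Pairs
#' whose parents match across polarity within `xpol_ppm` and `xpol_rt`
#' are grouped (transitive closure); within a group only the pair whose
#' parent has the highest total ion count survives (ties broken toward
#' negative mode, then lexicographic parent id). Survivors get status
#' `final`.
#'
#' @param pairs A pair tibble (post stringent filtering).
#' @param config A [screen_config()].
#' @return The surviving subset of `pairs`, status `final`.
#' @export
dedup_polarity <- function(pairs, config = screen_config()) {
  n <- nrow(pairs)
  if (n == 0) return(pairs)
  links <- list()
  for (a in seq_len(max(n - 1, 0))) {
    for (b in seq((a + 1), n)) {
      if (pairs$polarity[a] == pairs$polarity[b]) next
      ref <- min(pairs$parent_mass[a], pairs$parent_mass[b])
      if (abs(pairs$parent_mass[a] - pairs$parent_mass[b]) / ref * 1e6 >
          config$xpol_ppm) next
      if (abs(pairs$parent_rt[a] - pairs$parent_rt[b]) > config$xpol_rt) next
      links[[length(links) + 1]] <- c(a, b)
    }
  }
  links <- if (length(links) == 0) matrix(integer(0), ncol = 2) else
    do.call(rbind, links)
  grp <- union_find_groups(n, links)
  keep <- unlist(lapply(split(seq_len(n), grp), function(idx) {
    if (length(idx) == 1) return(idx)
    sub <- pairs[idx, ]
    ord <- order(-sub$parent_total_area,
                 sub$polarity != "negative",  # FALSE (negative) sorts first
                 sub$parent_id)
    idx[ord[1]]
  }), use.names = FALSE)
  out <- pairs[sort(keep), , drop = FALSE]
  out$status <- "final"
  out
}

#' Feature naming
#'
#' Names a feature by its cysteine-fate convention: `"C"`, the integer part
#' of the neutral monoisotopic mass, `"_"`, and the RT rounded to one
#' decimal -- e.g. `name_feature(193.0409, 7.34)` is `"C193_7.3"`.
#'
#' @param neutral_mass Neutral monoisotopic mass in Da (vectorised).
#' @param rt Retention time in minutes (vectorised).
#' @param prefix Single-letter fate prefix, default `"C"`.
#' @return Character vector of feature names.
#' @export
name_feature <- function(neutral_mass, rt, prefix = "C") {
  stopifnot(all(neutral_mass > 0))
  sprintf("%s%d_%.1f", prefix, trunc(neutral_mass), round(rt, 1))
}
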