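#' Run the full peak-pair tracing pipeline
#'
#' Chains the stages in the published order: intensity filter, blank
#' filter, mass floor, duplicate merging, pair search, adduct flagging,
#' isotopologue flagging, stringent filtering, cross-polarity
#' deduplication, feature naming. Deterministic for fixed inputs.
#'
#' @param peaks A peak tibble ([read_peak_table()] or
#'   [simulate_peaklist()]`$peaks`).
#' @param samples A sample table.
#' @param filter A [filter_config()].
#' @param label A [label_config()].
#' @param screen A [screen_config()].
#' @param adduct_rules,isotope_rules Rule tibbles; defaults
#'   [default_adduct_rules()] / [default_isotope_rules()].
#' @return An object of class `trace_run`: a list with `final` (named final
#'   pairs), `candidates`, `flagged`, `stringent`, `peaks_filtered`, and
#'   `report` (per-stage survivor counts and echoed parameters). Methods:
#'   `print()`, [autoplot()][ggplot2::autoplot].
#' @export
run_pipeline <- function(peaks, samples,
                         filter = filter_config(),
                         label = label_config(),
                         screen = screen_config(),
                         adduct_rules = default_adduct_rules(),
                         isotope_rules = default_isotope_rules()) {
  validate_peaks(peaks)
  counts <- c(input = nrow(peaks))

  filtered <- intensity_filter(peaks, samples, filter)
  counts["intensity_filter"] <- nrow(filtered)
  filtered <- blank_filter(filtered, samples, filter)
  counts["blank_filter"] <- nrow(filtered)
  filtered <- mass_floor_filter(filtered, filter)
  counts["mass_floor"] <- nrow(filtered)
  filtered <- merge_duplicates(filtered, filter)
  counts["merge_duplicates"] <- nrow(filtered)

  candidates <- find_pairs(filtered, samples, label)
  counts["candidates"] <- nrow(candidates)

  flagged <- candidates |>
    flag_adducts(adduct_rules, screen) |>
    flag_isotopologues(isotope_rules, screen, peaks = filtered)
  counts["flagged"] <- sum(flagged$status == "flagged")

  stringent <- stringent_filter(flagged, screen)
  counts["stringent_pass"] <- nrow(stringent)

  final <- dedup_polarity(stringent, screen)
  counts["final"] <- nrow(final)
  if (nrow(final) > 0) {
    final$feature <- name_feature(final$parent_mass, final$parent_rt)
    final <- dplyr::relocate(final, "feature")
  } else {
    final$feature <- character(0)
  }

  structure(list(
    final = final,
    candidates = candidates,
    flagged = flagged,
    stringent = stringent,
    peaks_filtered = filtered,
    report = list(stage_counts = counts,
                  filter = unclass(filter),
                  label = unclass(label),
                  screen = unclass(screen))
  ), class = "trace_run")
}

#' @export
print.trace_run <- function(x, ...) {
  cat("Peak-pair tracing run\n")
  cnt <- x$report$stage_counts
  for (i in seq_along(cnt)) {
    cat(sprintf("  %-18s %d\n", names(cnt)[i], cnt[i]))
  }
  if (nrow(x$final) > 0) {
    cat("final features:", paste(utils::head(x$final$feature, 8), collapse = ", "),
        if (nrow(x$final) > 8) "..." else "", "\n")
  }
  invisible(x)
}
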