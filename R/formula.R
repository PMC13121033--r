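#' Implied added mass of a conjugate feature
#'
#' Mass added to a base metabolite (cysteine or glutathione) to reach an
#' observed feature mass: `feature_mass - base_mass`. Negative results are
#' permitted (a loss relative to the base) and simply returned.
#'
#' @param feature_mass Neutral monoisotopic feature mass in Da (vectorised).
#' @param base A base name (`"CYS"`/`"GSH"`), a row of [base_metabolites()],
#'   or a numeric base mass in Da.
#' @return Added mass in Da.
#' @examples
#' added_mass(193.04088, "CYS")  # ~72.021, a C3H4O2 addition
#' @export
added_mass <- function(feature_mass, base = "CYS") {
  feature_mass - base_mass(base)
}

base_mass <- function(base) {
  if (is.numeric(base)) return(base)
  if (is.data.frame(base)) return(base$monoisotopic_mass[1])
  bm <- base_metabolites()
  i <- match(toupper(base), bm$name)
  if (is.na(i)) stop("unknown base metabolite: ", base, call. = FALSE)
  bm$monoisotopic_mass[i]
}

#' Enumerate plausible CHNOPS elemental compositions for a mass
#'
#' Exhaustive bounded search over C, H, N, O, P, S counts whose
#' monoisotopic mass falls within `tol_ppm` of `target_mass`. Retained
#' candidates must have non-negative ring-plus-double-bond equivalents
#' (RDBE = C - H/2 + N/2 + 1) and pass element-ratio plausibility screens
#' (0.1 <= H/C <= 6, N/C <= 4, O/C <= 3, P/C <= 2, S/C <= 3). Carbon-free
#' (inorganic) candidates such as H3PO4 bypass the RDBE and ratio screens.
#' Results are sorted by absolute ppm error.
#'
#' @param target_mass Target neutral mass in Da.
#' @param tol_ppm Mass tolerance in ppm.
#' @param bounds Named list of per-element maximum counts; defaults
#'   `list(C = 39, H = 72, N = 20, O = 20, P = 9, S = 10)`, additionally
#'   capped by what fits in `target_mass`.
#' @param max_candidates Abort with an error if more than this many
#'   candidates are retained (tolerance too wide).
#' @return A tibble with columns `C`, `H`, `N`, `O`, `P`, `S`, `formula`,
#'   `theoretical_mass`, `ppm_error`, `rdbe`.
#' @export
enumerate_formulas <- function(target_mass, tol_ppm = 5,
                               bounds = list(C = 39, H = 72, N = 20,
                                             O = 20, P = 9, S = 10),
                               max_candidates = 10000) {
  stopifnot(tol_ppm > 0, target_mass > 0)
  am <- atomic_masses
  tol <- tol_ppm * 1e-6 * target_mass
  hi <- target_mass + tol
  cap <- function(el) min(bounds[[el]], floor(hi / am[[el]]))
  mH <- am[["H"]]

  rows <- list()
  for (s in 0:cap("S")) {
    ms <- s * am[["S"]]
    if (ms > hi) break
    for (p in 0:cap("P")) {
      mp <- ms + p * am[["P"]]
      if (mp > hi) break
      for (n in 0:cap("N")) {
        mn <- mp + n * am[["N"]]
        if (mn > hi) break
        for (o in 0:cap("O")) {
          mo <- mn + o * am[["O"]]
          if (mo > hi) break
          for (cc in 0:cap("C")) {
            mc <- mo + cc * am[["C"]]
            if (mc > hi) break
            # solve hydrogen count from the residual mass
            h0 <- round((target_mass - mc) / mH)
            for (h in unique(pmax(0, c(h0 - 1, h0, h0 + 1)))) {
              if (h > bounds$H) next
              theo <- mc + h * mH
              err <- ppm_diff(theo, target_mass)
              if (abs(err) > tol_ppm) next
              rdbe <- cc - h / 2 + n / 2 + 1
              if (cc >= 1) {
                if (rdbe < 0) next
                if (h / cc < 0.1 || h / cc > 6) next
                if (n / cc > 4 || o / cc > 3 || p / cc > 2 || s / cc > 3) next
              }
              rows[[length(rows) + 1]] <-
                c(C = cc, H = h, N = n, O = o, P = p, S = s,
                  theoretical_mass = theo, ppm_error = err, rdbe = rdbe)
              if (length(rows) > max_candidates) {
                stop("more than ", max_candidates, " candidate formulas; ",
                     "narrow the mass tolerance", call. = FALSE)
              }
            }
          }
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(C = integer(0), H = integer(0), N = integer(0),
                          O = integer(0), P = integer(0), S = integer(0),
                          formula = character(0), theoretical_mass = numeric(0),
                          ppm_error = numeric(0), rdbe = numeric(0)))
  }
  out <- tibble::as_tibble(as.data.frame(do.call(rbind, rows)))
  out <- dplyr::distinct(out)
  out$formula <- purrr::pmap_chr(out[, c("C", "H", "N", "O", "P", "S")],
                                 counts_to_formula)
  out <- out[order(abs(out$ppm_error)), ]
  dplyr::relocate(out, "formula", .after = "S")
}

counts_to_formula <- function(C, H, N, O, P, S) {
  cnt <- c(C = C, H = H, N = N, O = O, P = P, S = S)
  cnt <- cnt[cnt > 0]
  if (length(cnt) == 0) return("")
  paste0(names(cnt), ifelse(cnt > 1, cnt, ""), collapse = "")
}

#' Reaction modes for cysteine conjugation
#'
#' Leaving-group masses for the three conjugation chemistries considered:
#' thioether formation from a phosphorylated partner (loss of H3PO4,
#' 97.97690 Da), condensation with loss of water (18.01056 Da; e.g.
#' thiazolidine formation from an aldehyde or ketone), and direct
#' hemithioacetal addition (no loss).
#'
#' @return A tibble with columns `mode` and `leaving_mass`.
#' @export
reaction_modes <- function() {
  tibble::tibble(
    mode = c("thioether_phosphate_loss", "condensation_water_loss",
             "hemithioacetal_addition"),
    leaving_mass = c(.mass$h3po4, .mass$h2o, 0)
  )
}

#' Neutral mass of a base-partner conjugate
#'
#' `base + partner - leaving group` for the given reaction mode. For
#' example, cysteine + pyruvate with water loss gives the thiazolidine
#' 2-methyl-2,4-thiazolidine dicarboxylate at 191.0252 Da (feature C191),
#' and cysteine + dihydroxyacetone phosphate with phosphate loss gives the
#' sugar thioether at 193.0409 Da (feature C193).
#'
#' @param base A base name/mass as in [added_mass()].
#' @param partner_mass Neutral monoisotopic partner mass in Da (vectorised).
#' @param mode One of [reaction_modes()]`$mode`.
#' @return Conjugate neutral mass in Da.
#' @export
conjugate_mass <- function(base, partner_mass,
                           mode = c("thioether_phosphate_loss",
                                    "condensation_water_loss",
                                    "hemithioacetal_addition")) {
  mode <- match.arg(mode)
  rm <- reaction_modes()
  leaving <- rm$leaving_mass[match(mode, rm$mode)]
  out <- base_mass(base) + partner_mass - leaving
  if (any(out <= 0)) stop("conjugate mass is not positive", call. = FALSE)
  out
}

#' Annotate features with formulas and conjugate matches
#'
#' For each feature: the best elemental compositions for the feature mass
#' and for its added mass relative to each base, plus any match in a
#' partner conjugate library within `tol_ppm`.
#'
#' @param features Tibble with columns `feature` (name) and `neutral_mass`
#'   (and optionally `rt`).
#' @param bases Base metabolite tibble, default [base_metabolites()].
#' @param partner_library Tibble with columns `name` and `monoisotopic_mass`
#'   (or `formula`), the candidate reaction partners; may be empty.
#' @param modes Character vector of reaction modes to consider.
#' @param tol_ppm Match tolerance for features (ppm); added-mass formula
#'   enumeration uses `added_tol_ppm`.
#' @param added_tol_ppm Tolerance for added-mass compositions (ppm; wider,
#'   since a difference of two measured masses carries both errors).
#' @return A tibble, one row per feature x base, with the top feature
#'   formula, top added-mass formula, and the best conjugate-library match.
#' @export
annotate_features <- function(features,
                              bases = base_metabolites(),
                              partner_library = NULL,
                              modes = reaction_modes()$mode,
                              tol_ppm = 5,
                              added_tol_ppm = 10) {
  stopifnot(nrow(bases) > 0)
  if (!is.null(partner_library) && nrow(partner_library) > 0 &&
      !"monoisotopic_mass" %in% names(partner_library)) {
    partner_library$monoisotopic_mass <-
      vapply(partner_library$formula, formula_mass, numeric(1))
  }
  purrr::pmap_dfr(features[, c("feature", "neutral_mass")],
                  function(feature, neutral_mass) {
    feat_forms <- enumerate_formulas(neutral_mass, tol_ppm)
    top_formula <- if (nrow(feat_forms) > 0) feat_forms$formula[1] else NA_character_
    purrr::pmap_dfr(bases[, c("name", "monoisotopic_mass")],
                    function(name, monoisotopic_mass) {
      add <- neutral_mass - monoisotopic_mass
      add_formula <- NA_character_
      if (add > 2 * atomic_masses[["H"]]) {
        af <- enumerate_formulas(add, added_tol_ppm)
        if (nrow(af) > 0) add_formula <- af$formula[1]
      }
      hit <- conjugate_match(neutral_mass, monoisotopic_mass,
                             partner_library, modes, tol_ppm)
      tibble::tibble(
        feature = feature, neutral_mass = neutral_mass, base = name,
        added_mass = add, feature_formula = top_formula,
        added_formula = add_formula,
        conjugate_partner = hit$partner, conjugate_mode = hit$mode,
        conjugate_ppm = hit$ppm
      )
    })
  })
}

conjugate_match <- function(feature_mass, base_mass, partner_library, modes,
                            tol_ppm) {
  none <- list(partner = NA_character_, mode = NA_character_, ppm = NA_real_)
  if (is.null(partner_library) || nrow(partner_library) == 0) return(none)
  rm <- reaction_modes()
  best <- none
  for (mode in modes) {
    leaving <- rm$leaving_mass[match(mode, rm$mode)]
    theo <- base_mass + partner_library$monoisotopic_mass - leaving
    err <- ppm_diff(feature_mass, theo)
    ok <- which(abs(err) <= tol_ppm)
    for (i in ok) {
      if (is.na(best$ppm) || abs(err[i]) < abs(best$ppm)) {
        best <- list(partner = partner_library$name[i], mode = mode,
                     ppm = err[i])
      }
    }
  }
  best
}
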