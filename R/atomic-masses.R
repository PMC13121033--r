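#' Monoisotopic atomic masses
#'
#' Single source of truth for all mass arithmetic in the package
#' (CODATA/AME2020 values, Da). Isotope mass differences, elemental formula
#' masses, conjugate masses and the tracer mass shift are all derived from
#' this table.
#'
#' @format Named numeric vector of monoisotopic masses in Da.
#' @export
atomic_masses <- c(
  H    = 1.00782503207,
  C    = 12.0,
  C13  = 13.00335483507,
  N    = 14.0030740048,
  N15  = 15.0001088982,
  O    = 15.9949146196,
  O18  = 17.9991610,
  P    = 30.97376163,
  S    = 31.97207100,
  S34  = 33.96786690,
  Na   = 22.9897692809,
  K    = 38.96370668,
  Cl   = 34.96885268,
  e    = 0.00054857991,
  proton = 1.00727646688
)

#' Monoisotopic mass of a CHNOPS(+NaKCl) formula
#'
#' @param formula Either a character molecular formula such as `"C3H7NO2S"`,
#'   or a named integer vector / list of element counts
#'   (e.g. `c(C = 3, H = 7, N = 1, O = 2, S = 1)`).
#' @return Monoisotopic neutral mass in Da.
#' @examples
#' formula_mass("C3H7NO2S")   # cysteine, 121.01975
#' formula_mass(c(C = 3, H = 4, O = 3)) # pyruvate
#' @export
formula_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else unlist(formula)
  bad <- setdiff(names(counts), names(atomic_masses))
  if (length(bad) > 0) {
    stop("unknown element(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  sum(atomic_masses[names(counts)] * counts)
}

#' Parse a molecular formula string into element counts
#'
#' @param formula Character scalar like `"C10H17N3O6S"`.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  toks <- toks[nzchar(toks)]
  if (sum(nchar(toks)) != nchar(formula)) {
    stop("cannot parse formula: ", formula, call. = FALSE)
  }
  el <- sub("[0-9]*$", "", toks)
  n <- sub("^[A-Za-z]+", "", toks)
  n <- ifelse(n == "", 1L, as.integer(n))
  tapply(n, el, sum)[unique(el)]
}

# Frequently used neutral masses, derived once from the table.
.mass <- list(
  h2o   = 2 * atomic_masses[["H"]] + atomic_masses[["O"]],
  h3po4 = 3 * atomic_masses[["H"]] + atomic_masses[["P"]] + 4 * atomic_masses[["O"]],
  c13_gain = atomic_masses[["C13"]] - atomic_masses[["C"]],
  n15_gain = atomic_masses[["N15"]] - atomic_masses[["N"]],
  s34_gain = atomic_masses[["S34"]] - atomic_masses[["S"]],
  o18_gain = atomic_masses[["O18"]] - atomic_masses[["O"]]
)

#' Tracer mass shift between light and heavy isotopologues
#'
#' Mass gained when `n_heavy_C` carbons are replaced by 13C and `n_heavy_N`
#' nitrogens by 15N. For the cysteine backbone (3 carbons, 1 nitrogen) this
#' is 4.0071 Da, the shift separating the unlabelled and fully labelled
#' members of a peak pair.
#'
#' @param config A [label_config()], or `NULL` to use the defaults.
#' @param n_heavy_C,n_heavy_N Override the heavy-atom counts directly.
#' @return Mass shift in Da.
#' @examples
#' heavy_shift()                    # 4.0071
#' heavy_shift(n_heavy_C = 1, n_heavy_N = 0)  # 1.00336, one 13C
#' @export
heavy_shift <- function(config = NULL, n_heavy_C = NULL, n_heavy_N = NULL) {
  if (is.null(config)) config <- label_config()
  nc <- if (is.null(n_heavy_C)) config$n_heavy_C else n_heavy_C
  nn <- if (is.null(n_heavy_N)) config$n_heavy_N else n_heavy_N
  stopifnot(nc >= 0, nn >= 0)
  nc * .mass$c13_gain + nn * .mass$n15_gain
}

#' Reference base metabolites
#'
#' Cysteine and glutathione, the bases whose mass is subtracted from a
#' feature mass to obtain the implied added mass of a conjugate.
#'
#' @return A tibble with columns `name`, `formula`, `monoisotopic_mass`.
#' @export
base_metabolites <- function() {
  tibble::tibble(
    name = c("CYS", "GSH"),
    formula = c("C3H7NO2S", "C10H17N3O6S"),
    monoisotopic_mass = c(formula_mass("C3H7NO2S"), formula_mass("C10H17N3O6S"))
  )
}

# ppm difference of an observed mass from a reference mass
ppm_diff <- function(observed, reference) {
  (observed - reference) / reference * 1e6
}
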