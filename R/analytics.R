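#' NRF2 target genes
#'
#' The nine transcriptional targets whose standardized expression is summed
#' into the NRF2 activation score.
#'
#' @return Character vector of gene symbols.
#' @export
nrf2_target_genes <- function() {
  c("ABCC2", "ABCC3", "AKR1B10", "AKR1C1", "GCLM", "GSR", "ME1", "NQO1",
    "TXNRD1")
}

#' NRF2 activation score
#'
#' Sum of standardized expression scores over a gene set: for each gene,
#' `(x_i - mean(x)) / sd(x)` with mean and sd taken across all cell lines
#' in the matrix, summed over genes. The score is invariant to per-gene
#' translation and rescaling.
#'
#' @param expr Tibble with a `cell_line` column and one numeric column per
#'   gene; needs at least two cell lines.
#' @param genes Gene set to sum over; default [nrf2_target_genes()].
#' @return A tibble `cell_line`, `activation_score`.
#' @export
nrf2_activation_score <- function(expr, genes = nrf2_target_genes()) {
  missing_genes <- setdiff(genes, names(expr))
  if (length(missing_genes) > 0) {
    stop("expression matrix lacks gene(s): ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  }
  if (nrow(expr) < 2) stop("need at least two cell lines", call. = FALSE)
  z <- vapply(genes, function(g) {
    x <- expr[[g]]
    s <- stats::sd(x)
    if (is.na(s) || s == 0) {
      stop("zero expression variance for gene ", g, call. = FALSE)
    }
    (x - mean(x)) / s
  }, numeric(nrow(expr)))
  tibble::tibble(cell_line = expr$cell_line,
                 activation_score = rowSums(z))
}

#' Classify cell lines as NRF2-activated
#'
#' A line is `"on"` when it falls in the top quintile for both NRF2
#' dependency (Chronos score strictly below `dependency_max`; more negative
#' means more essential) and NRF2 activation score (strictly above
#' `score_min`). Default thresholds are the published quintile cutoffs
#' (-0.3028 and 4.06). Use [quintile_thresholds()] to recompute cutoffs for
#' a new cohort.
#'
#' @param dependency Chronos dependency scores (vectorised).
#' @param score Activation scores (vectorised).
#' @param dependency_max,score_min Classification thresholds.
#' @return Character vector, `"on"` / `"off"`.
#' @export
classify_nrf2 <- function(dependency, score,
                          dependency_max = -0.3028, score_min = 4.06) {
  ifelse(dependency < dependency_max & score > score_min, "on", "off")
}

#' Top-quintile thresholds for NRF2 classification
#'
#' Recomputes the quintile cutoffs used by [classify_nrf2()] from a cohort:
#' the 20th percentile of dependency (most negative fifth) and the 80th
#' percentile of the activation score.
#'
#' @param dependency,score Numeric vectors over the cohort.
#' @return A list with `dependency_max` and `score_min`.
#' @export
quintile_thresholds <- function(dependency, score) {
  list(dependency_max = unname(stats::quantile(dependency, 0.2, na.rm = TRUE)),
       score_min = unname(stats::quantile(score, 0.8, na.rm = TRUE)))
}

#' Cell-volume-hours over one growth interval
#'
#' Integral of exponentially growing total cell volume over an interval of
#' length `T` hours: `N0 / (k ln 2) * (2^(kT) - 1)`, where `N0` is the
#' initial total cell volume (ul) and `k` the proliferation rate in
#' volume doublings per hour. Continuous at `k = 0`, where it equals
#' `N0 * T`.
#'
#' @param N0 Initial total cell volume (ul).
#' @param k Proliferation rate (doublings per hour).
#' @param T Interval length (hours, non-negative).
#' @return Cell-volume-hours (ul h).
#' @export
cell_volume_hours <- function(N0, k, T) {
  if (any(T < 0)) stop("negative time interval", call. = FALSE)
  n <- max(length(N0), length(k), length(T))
  N0 <- rep_len(N0, n); k <- rep_len(k, n); T <- rep_len(T, n)
  out <- numeric(n)
  small <- abs(k) < 1e-12
  out[small] <- N0[small] * T[small]
  out[!small] <- N0[!small] / (k[!small] * log(2)) * (2^(k[!small] * T[!small]) - 1)
  out
}

#' Accumulated cell-volume-hours of a growth series
#'
#' Per replicate well: each interval's cell-volume-hours is computed with
#' the interval's own starting volume and per-well growth rate
#' (`k = log2(V1/V0) / dT`); a well's accumulated value at a time point is
#' its interval value plus the *average* accumulated value of all wells at
#' the previous time point (replicate-coupling follows the published
#' procedure).
#'
#' @param series Tibble with columns `time_h`, `well`, `volume_ul`
#'   (strictly increasing times per well; volumes > 0).
#' @return `series` with added columns `k`, `cvh_interval`,
#'   `cvh_accumulated` (0 at the first time point).
#' @export
accumulate_cvh <- function(series) {
  stopifnot(all(c("time_h", "well", "volume_ul") %in% names(series)))
  if (any(series$volume_ul <= 0)) stop("volumes must be > 0", call. = FALSE)
  series <- dplyr::arrange(series, .data$time_h, .data$well)
  times <- sort(unique(series$time_h))
  if (length(times) < 1) stop("empty series", call. = FALSE)
  per_well <- split(series, series$well)
  for (w in names(per_well)) {
    if (any(diff(per_well[[w]]$time_h) <= 0)) {
      stop("times must be strictly increasing within well ", w, call. = FALSE)
    }
  }
  out <- series
  out$k <- NA_real_
  out$cvh_interval <- NA_real_
  out$cvh_accumulated <- NA_real_
  prev_avg <- 0
  for (ti in seq_along(times)) {
    rows <- which(out$time_h == times[ti])
    if (ti == 1) {
      out$cvh_interval[rows] <- 0
      out$cvh_accumulated[rows] <- 0
    } else {
      prev_rows <- which(out$time_h == times[ti - 1])
      dT <- times[ti] - times[ti - 1]
      for (r in rows) {
        pr <- prev_rows[out$well[prev_rows] == out$well[r]]
        if (length(pr) != 1) {
          stop("well ", out$well[r], " missing at time ", times[ti - 1],
               call. = FALSE)
        }
        v0 <- out$volume_ul[pr]
        v1 <- out$volume_ul[r]
        k <- log2(v1 / v0) / dT
        out$k[r] <- k
        out$cvh_interval[r] <- cell_volume_hours(v0, k, dT)
        out$cvh_accumulated[r] <- out$cvh_interval[r] + prev_avg
      }
    }
    prev_avg <- mean(out$cvh_accumulated[rows])
  }
  out
}

#' Medium exchange-flux regression
#'
#' Ordinary least squares of medium metabolite moles against accumulated
#' cell-volume-hours. The slope is the exchange flux in mol per (ul h):
#' positive = production, negative = consumption. Points are excluded
#' (with reasons) when accumulated growth exceeds `cvh_max` (overgrowth
#' slows proliferation and distorts fluxes; reason `cvh_overgrowth`) or when
#' the metabolite -- or a metabolite whose flux is declared linked to it --
#' is depleted to at most `depletion_frac` of its initial level (reason
#' `depletion` / `linked_depletion`).
#'
#' @param data Tibble with one row per measurement: a CVH column, the
#'   metabolite moles column, and optionally further metabolite columns
#'   used for linked-depletion exclusions.
#' @param metabolite Name of the moles column to regress.
#' @param cvh Name of the accumulated CVH column (default
#'   `"cvh_accumulated"`).
#' @param linked Character vector of other metabolite columns whose
#'   depletion also excludes points for this metabolite (e.g. cystine for a
#'   glutamate-efflux fit).
#' @param cvh_max Overgrowth exclusion threshold (ul h).
#' @param depletion_frac Depletion exclusion: a point is dropped when the
#'   metabolite is at or below this fraction of its initial (lowest-CVH
#'   mean) level.
#' @return An object of class `flux_fit`: slope, stderr, fitted `lm`,
#'   points used and an exclusion table. Methods: [tidy()][generics::tidy],
#'   [glance()][generics::glance], [autoplot()][ggplot2::autoplot].
#' @export
flux_fit <- function(data, metabolite, cvh = "cvh_accumulated",
                     linked = character(0), cvh_max = 300,
                     depletion_frac = 0.1) {
  stopifnot(metabolite %in% names(data), cvh %in% names(data))
  missing_linked <- setdiff(linked, names(data))
  if (length(missing_linked) > 0) {
    stop("linked metabolite column(s) not found: ",
         paste(missing_linked, collapse = ", "), call. = FALSE)
  }
  x <- data[[cvh]]
  y <- data[[metabolite]]

  reason <- rep(NA_character_, nrow(data))
  reason[x > cvh_max] <- "cvh_overgrowth"
  initial_of <- function(col) {
    v <- data[[col]]
    mean(v[x == min(x)], na.rm = TRUE)
  }
  for (col in c(metabolite, linked)) {
    depleted <- data[[col]] <= depletion_frac * initial_of(col)
    why <- if (col == metabolite) "depletion" else
      paste0("linked_depletion:", col)
    reason[is.na(reason) & depleted] <- why
  }
  use <- is.na(reason) & !is.na(x) & !is.na(y)
  if (sum(use) < 2) {
    stop("fewer than 2 usable points for ", metabolite, call. = FALSE)
  }
  fit <- stats::lm(y[use] ~ x[use])
  # noise-free synthetic series legitimately fit exactly; keep summary.lm
  # from warning about it
  coefs <- withCallingHandlers(
    summary(fit)$coefficients,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  structure(list(
    metabolite = metabolite,
    slope = unname(coefs[2, 1]),
    stderr = unname(coefs[2, 2]),
    intercept = unname(coefs[1, 1]),
    points_used = sum(use),
    excluded = tibble::tibble(
      index = which(!is.na(reason)),
      cvh = x[!is.na(reason)],
      moles = y[!is.na(reason)],
      reason = reason[!is.na(reason)]
    ),
    data = tibble::tibble(cvh = x, moles = y, used = use),
    fit = fit
  ), class = "flux_fit")
}

#' @export
print.flux_fit <- function(x, ...) {
  cat("Exchange-flux fit for", x$metabolite, "\n")
  cat(sprintf("  slope: %.4g mol/(ul*h)  (stderr %.3g)\n", x$slope, x$stderr))
  cat(sprintf("  points used: %d, excluded: %d\n",
              x$points_used, nrow(x$excluded)))
  invisible(x)
}

#' Proliferation rate in doublings per day
#'
#' `log2(final / initial) / days`.
#'
#' @param initial_count,final_count Cell counts (> 0, vectorised).
#' @param days Elapsed time in days (> 0).
#' @return Doublings per day (negative when the population shrank).
#' @export
proliferation_rate <- function(initial_count, final_count, days) {
  if (any(initial_count <= 0) || any(final_count <= 0) || any(days <= 0)) {
    stop("counts and days must be positive", call. = FALSE)
  }
  log2(final_count / initial_count) / days
}

#' Fit a response-ratio calibration curve
#'
#' Standards map a response ratio (analyte peak area / labelled-standard
#' peak area) to a known concentration. Three models are fitted --
#' linear (`conc = a + b*ratio`), power (`conc = a * ratio^b`) and
#' second-degree polynomial -- and the one with the smallest residual sum of
#' squares is selected (exact ties resolved toward the simpler model, in
#' the order linear, power, quadratic).
#'
#' @param standards Tibble with columns `ratio` (> 0) and `concentration`;
#'   at least 3 standards.
#' @return An object of class `calibration_fit` with the chosen model, its
#'   coefficients and per-model diagnostics. Methods:
#'   [tidy()][generics::tidy], [glance()][generics::glance],
#'   [autoplot()][ggplot2::autoplot].
#' @export
fit_calibration <- function(standards) {
  stopifnot(all(c("ratio", "concentration") %in% names(standards)))
  if (nrow(standards) < 3) stop("need at least 3 standards", call. = FALSE)
  if (any(standards$ratio <= 0)) stop("ratios must be positive", call. = FALSE)
  r <- standards$ratio
  y <- standards$concentration

  fits <- list()
  lin <- stats::lm(y ~ r)
  fits$linear <- list(predict = function(x) unname(stats::coef(lin)[1] + stats::coef(lin)[2] * x),
                      rss = sum(stats::residuals(lin)^2),
                      coefficients = stats::coef(lin))
  pow <- tryCatch({
    ok <- y > 0
    if (sum(ok) < 3) stop("power model needs positive concentrations")
    ll <- stats::lm(log(y[ok]) ~ log(r[ok]))
    start <- list(a = exp(unname(stats::coef(ll)[1])), b = unname(stats::coef(ll)[2]))
    start_rss <- sum((y - start$a * r^start$b)^2)
    cf <- if (start_rss < 1e-12 * sum(y^2)) {
      # log-log start is already an (essentially) exact fit; nls cannot
      # iterate on zero residuals
      c(a = start$a, b = start$b)
    } else {
      nl <- stats::nls(y ~ a * r^b, start = start,
                       control = stats::nls.control(warnOnly = TRUE))
      stats::coef(nl)
    }
    list(predict = function(x) unname(cf["a"]) * x^unname(cf["b"]),
         rss = sum((y - cf["a"] * r^cf["b"])^2),
         coefficients = cf)
  }, error = function(e) NULL)
  if (!is.null(pow)) fits$power <- pow
  quad <- stats::lm(y ~ r + I(r^2))
  fits$quadratic <- list(predict = function(x) {
    cf <- stats::coef(quad)
    unname(cf[1] + cf[2] * x + cf[3] * x^2)
  }, rss = sum(stats::residuals(quad)^2), coefficients = stats::coef(quad))

  rss <- vapply(fits, function(f) f$rss, numeric(1))
  # exact/near-exact ties go to the simpler model (order: linear, power,
  # quadratic); tie scale set by the magnitude of the concentrations
  tol <- 1e-10 * sum(y^2)
  best <- names(fits)[which(rss <= min(rss) + tol)][1]
  structure(list(model = best, fits = fits, rss = rss,
                 standards = tibble::tibble(ratio = r, concentration = y)),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("Calibration curve:", x$model, "model\n")
  cat("  RSS:", paste(sprintf("%s=%.4g", names(x$rss), x$rss), collapse = ", "),
      "\n")
  invisible(x)
}

#' Quantify a sample from a calibration curve
#'
#' Evaluates the selected calibration model at the sample response ratio.
#' Warns when the ratio lies outside twice the standards' ratio range
#' (extrapolation).
#'
#' @param calibration A [fit_calibration()] object.
#' @param sample_ratio Response ratio(s) to quantify.
#' @return Estimated concentration(s).
#' @export
quantify <- function(calibration, sample_ratio) {
  stopifnot(inherits(calibration, "calibration_fit"))
  rng <- range(calibration$standards$ratio)
  if (any(sample_ratio > 2 * rng[2] | sample_ratio < rng[1] / 2)) {
    warning("sample ratio outside 2x the standard range; extrapolating")
  }
  calibration$fits[[calibration$model]]$predict(sample_ratio)
}

#' Fractional labelling with the isotopologue detection rule
#'
#' Returns `M+3 / (M+0 + M+1 + M+2 + M+3)` only for samples in which both
#' the M+0 and M+3 isotopologues were detected (area > 0); other samples
#' are excluded (`NA`).
#'
#' @param m0,m1,m2,m3 Isotopologue peak areas (vectorised, >= 0; `NA`
#'   treated as not detected).
#' @return A tibble with columns `fraction` (`NA` when excluded) and
#'   `included` (logical).
#' @export
labeled_fraction_m3 <- function(m0, m1 = 0, m2 = 0, m3 = 0) {
  z <- function(x) ifelse(is.na(x), 0, x)
  m0 <- z(m0); m1 <- z(m1); m2 <- z(m2); m3 <- z(m3)
  stopifnot(all(m0 >= 0), all(m1 >= 0), all(m2 >= 0), all(m3 >= 0))
  included <- m0 > 0 & m3 > 0
  fraction <- ifelse(included, m3 / (m0 + m1 + m2 + m3), NA_real_)
  tibble::tibble(fraction = fraction, included = included)
}
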