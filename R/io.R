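#' Read an untargeted LC-MS feature table
#'
#' Reads a delimited feature table (one row per aligned feature) into the
#' canonical wide peak tibble used throughout the package: columns `peak_id`,
#' `polarity` ("positive"/"negative"), `neutral_mass` (Da, monoisotopic,
#' neutral), `rt` (minutes), `flags` (";"-separated annotation flags, empty
#' on input) and one numeric area column per sample. Empty area cells become
#' `NA` ("not detected"). The delimiter is auto-detected (comma or tab).
#'
#' Upstream tools export either neutral monoisotopic masses or per-polarity
#' m/z. Set `mass_type = "mz"` to convert singly protonated/deprotonated m/z
#' to neutral mass using the row polarity; neutral mass is canonical
#' internally.
#'
#' @param path Path to a CSV/TSV file.
#' @param schema Named list mapping canonical names to file column names;
#'   recognised keys: `peak_id`, `neutral_mass` (or `mz`), `rt`, `polarity`,
#'   `samples` (character vector of sample area columns; default: every
#'   remaining column).
#' @param mass_type `"neutral"` (default) or `"mz"`.
#' @return A peak tibble, rows in file order.
#' @export
read_peak_table <- function(path,
                            schema = list(),
                            mass_type = c("neutral", "mz")) {
  mass_type <- match.arg(mass_type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_delim(path, delim = detect_delim(path),
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)

  mass_key <- if (mass_type == "mz") "mz" else "neutral_mass"
  defaults <- list(peak_id = "peak_id", neutral_mass = "neutral_mass",
                   mz = "mz", rt = "rt_min", polarity = "polarity")
  col_of <- function(key) {
    nm <- schema[[key]] %||% defaults[[key]]
    nm
  }
  required <- c(mass_key, "rt", "polarity")
  for (key in required) {
    if (!col_of(key) %in% names(raw)) {
      stop("required column missing: ", col_of(key), " (", key, ")", call. = FALSE)
    }
  }

  parse_num <- function(x, what) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & x != "" & is.na(out))
    if (length(bad) > 0) {
      stop("non-numeric ", what, " at row ", bad[1], ": '", x[bad[1]], "'",
           call. = FALSE)
    }
    out
  }

  mass <- parse_num(raw[[col_of(mass_key)]], if (mass_type == "mz") "m/z" else "mass")
  rt <- parse_num(raw[[col_of("rt")]], "rt")
  polarity <- normalize_polarity(raw[[col_of("polarity")]])

  if (mass_type == "mz") {
    # [M+H]+ / [M-H]- assumption for singly charged ions
    mass <- ifelse(polarity == "positive",
                   mass - atomic_masses[["proton"]],
                   mass + atomic_masses[["proton"]])
  }

  id_col <- col_of("peak_id")
  peak_id <- if (id_col %in% names(raw)) as.character(raw[[id_col]]) else
    sprintf("P%04d", seq_len(nrow(raw)))
  if (anyDuplicated(peak_id)) {
    stop("duplicate peak_id values in ", path, call. = FALSE)
  }

  used <- vapply(c("peak_id", mass_key, "rt", "polarity"), col_of, character(1))
  flags <- if ("flags" %in% names(raw)) {
    f <- as.character(raw$flags)
    ifelse(is.na(f), "", f)
  } else {
    rep("", nrow(raw))
  }
  area_cols <- schema$samples %||% setdiff(names(raw), c(used, "flags"))
  areas <- purrr::map_dfc(rlang::set_names(area_cols), function(cl) {
    v <- parse_num(raw[[cl]], paste0("area (", cl, ")"))
    if (any(v < 0, na.rm = TRUE)) {
      stop("negative area in column ", cl, call. = FALSE)
    }
    v
  })

  out <- tibble::tibble(peak_id = peak_id, polarity = polarity,
                        neutral_mass = mass, rt = rt, flags = flags)
  out <- dplyr::bind_cols(out, areas)
  validate_peaks(out)
  out
}

normalize_polarity <- function(x) {
  p <- tolower(as.character(x))
  p[p %in% c("pos", "+", "positive", "1")] <- "positive"
  p[p %in% c("neg", "-", "negative", "-1")] <- "negative"
  bad <- which(!p %in% c("positive", "negative"))
  if (length(bad) > 0) {
    stop("unrecognised polarity at row ", bad[1], ": '", x[bad[1]], "'",
         call. = FALSE)
  }
  p
}

validate_peaks <- function(peaks) {
  stopifnot(all(.peak_meta_cols %in% names(peaks)))
  if (any(peaks$neutral_mass <= 0, na.rm = TRUE)) stop("neutral_mass must be > 0", call. = FALSE)
  if (any(peaks$rt < 0, na.rm = TRUE)) stop("rt must be >= 0", call. = FALSE)
  if (anyDuplicated(peaks$peak_id)) stop("peak_id must be unique", call. = FALSE)
  invisible(peaks)
}

#' Read a sample metadata table
#'
#' Two required columns: `sample_id` and `role`
#' (labeled_mix / unlabeled_control / blank, matched case-insensitively);
#' an optional `group` column carries a free-text label.
#'
#' @param path Path to a CSV/TSV file.
#' @return A tibble with columns `sample_id`, `role`, `group`.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_delim(path, delim = detect_delim(path),
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  if (!all(c("sample_id", "role") %in% names(raw))) {
    stop("sample table needs columns sample_id and role", call. = FALSE)
  }
  sample_table(
    sample_id = raw$sample_id,
    role = raw$role,
    group = if ("group" %in% names(raw)) raw$group else NA_character_
  )
}

#' Construct a validated sample table
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param role Sample roles: `labeled_mix`, `unlabeled_control` or `blank`
#'   (case-insensitive).
#' @param group Optional free-text group labels.
#' @return A tibble with columns `sample_id`, `role`, `group`.
#' @export
sample_table <- function(sample_id, role, group = NA_character_) {
  role_norm <- tolower(trimws(role))
  valid <- c("labeled_mix", "unlabeled_control", "blank")
  bad <- which(!role_norm %in% valid)
  if (length(bad) > 0) {
    stop("unknown sample role: '", role[bad[1]], "'", call. = FALSE)
  }
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample_id: ",
         sample_id[duplicated(sample_id)][1], call. = FALSE)
  }
  tibble::tibble(sample_id = as.character(sample_id), role = role_norm,
                 group = rep_len(as.character(group), length(sample_id)))
}

#' Write / read a peak-pair table
#'
#' Serialises a pair tibble (see [find_pairs()]) to delimited text with one
#' row per ordered (parent, partner) pair, including match diagnostics,
#' per-sample labelling fractions, flags and status. `read_pair_table()`
#' round-trips the file losslessly (full numeric precision).
#'
#' @param pairs A pair tibble.
#' @param path Output file path.
#' @return `write_pair_table()` returns `path` invisibly;
#'   `read_pair_table()` returns the pair tibble.
#' @export
write_pair_table <- function(pairs, path) {
  readr::write_csv(pairs, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_pair_table
#' @export
read_pair_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (cl in intersect(c("flags", "status", "parent_id", "partner_id", "polarity"),
                       names(out))) {
    out[[cl]] <- as.character(out[[cl]])
    out[[cl]][is.na(out[[cl]])] <- ""
  }
  out
}

#' Write a peak table
#'
#' Inverse of [read_peak_table()] for the canonical schema; masses keep full
#' precision so that read(write(x)) equals x.
#'
#' @param peaks A peak tibble.
#' @param path Output file path.
#' @export
write_peak_table <- function(peaks, path) {
  out <- dplyr::rename(peaks, rt_min = "rt")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

detect_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0) return(",")
  n_tab <- lengths(regmatches(first, gregexpr("\t", first)))
  n_com <- lengths(regmatches(first, gregexpr(",", first)))
  if (n_tab > n_com) "\t" else ","
}

#' Read adduct or isotope rule tables
#'
#' Rule CSVs have columns `name`, `mass_delta` (Da; applied to the neutral
#' parent mass), optional `mass_multiplier` (default 1; 2 encodes a dimer
#' whose expected mass is twice the parent mass plus `mass_delta`) and
#' optional `polarity_scope` (`any`/`positive`/`negative`).
#'
#' @param path Path to a rule CSV.
#' @return A rule tibble.
#' @export
read_rule_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_delim(path, delim = detect_delim(path),
                           show_col_types = FALSE, progress = FALSE)
  if (!all(c("name", "mass_delta") %in% names(raw))) {
    stop("rule table needs columns name and mass_delta", call. = FALSE)
  }
  tibble::tibble(
    name = as.character(raw$name),
    mass_delta = as.numeric(raw$mass_delta),
    mass_multiplier = if ("mass_multiplier" %in% names(raw))
      as.numeric(raw$mass_multiplier) else 1,
    polarity_scope = if ("polarity_scope" %in% names(raw))
      as.character(raw$polarity_scope) else "any"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
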