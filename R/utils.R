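# Internal helpers shared across modules.

# Names of the per-sample area columns of a peak table: every sample_id from
# the sample table that is present as a column.
sample_cols <- function(peaks, samples) {
  intersect(samples$sample_id, names(peaks))
}

# Peak-table columns that are not sample areas.
.peak_meta_cols <- c("peak_id", "polarity", "neutral_mass", "rt", "flags")

# Maximum area over a set of columns, per row; NA (not detected) counts as 0.
# Returns 0 for an empty column set.
row_max_area <- function(peaks, cols) {
  if (length(cols) == 0) return(rep(0, nrow(peaks)))
  m <- as.matrix(peaks[, cols, drop = FALSE])
  m[is.na(m)] <- 0
  apply(m, 1, max)
}

row_total_area <- function(peaks, cols) {
  if (length(cols) == 0) return(rep(0, nrow(peaks)))
  m <- as.matrix(peaks[, cols, drop = FALSE])
  rowSums(m, na.rm = TRUE)
}

# Pearson correlation over pairwise-complete samples, requiring at least
# `min_n` shared detections; NA when undefined or below min_n.
pairwise_pearson <- function(x, y, min_n = 3L) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_n) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])
}

# Union-find over 1..n; returns integer group labels (1-based, arbitrary ids).
# Used for transitive-closure grouping in duplicate merging and polarity
# deduplication.
union_find_groups <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(pairs) > 0 && nrow(pairs) > 0) {
    for (k in seq_len(nrow(pairs))) {
      ri <- find(pairs[k, 1])
      rj <- find(pairs[k, 2])
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Append a flag to a ";"-separated flag string, avoiding duplicates.
add_flag <- function(flags, new) {
  out <- flags
  for (i in seq_along(out)) {
    cur <- flag_list(out[i])
    if (!(new[if (length(new) == 1L) 1L else i] %in% cur)) {
      cur <- c(cur, new[if (length(new) == 1L) 1L else i])
    }
    out[i] <- paste(cur, collapse = ";")
  }
  out
}

flag_list <- function(flags) {
  if (is.na(flags) || flags == "") character(0) else strsplit(flags, ";", fixed = TRUE)[[1]]
}

has_flag <- function(flags, prefix) {
  vapply(flags, function(f) any(startsWith(flag_list(f), prefix)), logical(1),
         USE.NAMES = FALSE)
}
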