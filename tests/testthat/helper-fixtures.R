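# Fixture builders and independent brute-force oracles used across tests.

# Build a peak tibble from vectors; `areas` is a named list, one numeric
# vector (length = n peaks) per sample.
mk_peaks <- function(mass, rt, areas, polarity = "negative", ids = NULL) {
  n <- length(mass)
  out <- tibble::tibble(
    peak_id = ids %||% sprintf("P%03d", seq_len(n)),
    polarity = rep_len(polarity, n),
    neutral_mass = mass,
    rt = rt,
    flags = ""
  )
  for (s in names(areas)) out[[s]] <- areas[[s]]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mk_samples <- function(labeled = "S1", control = character(0),
                       blank = character(0)) {
  sample_table(
    sample_id = c(labeled, control, blank),
    role = c(rep("labeled_mix", length(labeled)),
             rep("unlabeled_control", length(control)),
             rep("blank", length(blank)))
  )
}

# --- independent oracles ----------------------------------------------------

# O(n^2) pair search written directly from the gate definitions; no shared
# code with find_pairs() beyond heavy_shift().
brute_pairs <- function(peaks, samples, config = label_config()) {
  shift <- heavy_shift(config)
  labeled <- intersect(samples$sample_id[samples$role == "labeled_mix"],
                       names(peaks))
  A <- as.matrix(peaks[, labeled, drop = FALSE])
  A[is.na(A)] <- 0
  mass <- peaks$neutral_mass; rt <- peaks$rt; pol <- peaks$polarity
  hits <- character(0)
  for (i in seq_len(nrow(peaks))) {
    theo <- mass[i] + shift
    for (j in seq_len(nrow(peaks))) {
      if (i == j) next
      if (pol[i] != pol[j]) next
      if (abs(mass[j] - theo) / theo * 1e6 > config$pair_ppm_max) next
      if (abs(rt[j] - rt[i]) > config$pair_rt_max) next
      tot <- A[i, ] + A[j, ]
      fr <- ifelse(tot == 0, NA_real_, A[j, ] / tot)
      in_win <- FALSE
      for (w in config$fraction_windows) {
        if (any(!is.na(fr) & fr >= w[1] & fr <= w[2])) in_win <- TRUE
      }
      if (in_win) hits <- c(hits, paste(peaks$peak_id[i], peaks$peak_id[j]))
    }
  }
  sort(hits)
}

# All-pairs duplicate grouping: build the full n x n duplicate adjacency
# matrix directly from the rule, then take connected components by
# breadth-first search (independent of the union-find in the package).
brute_merge_groups <- function(peaks, config = filter_config()) {
  n <- nrow(peaks)
  area_cols <- setdiff(names(peaks),
                       c("peak_id", "polarity", "neutral_mass", "rt", "flags"))
  A <- as.matrix(peaks[, area_cols, drop = FALSE])
  mass <- peaks$neutral_mass
  ppm <- abs(outer(mass, mass, "-")) / outer(mass, mass, pmin) * 1e6
  drt <- abs(outer(peaks$rt, peaks$rt, "-"))
  same_pol <- outer(peaks$polarity, peaks$polarity, "==")
  adj <- same_pol & ppm <= config$merge_ppm & drt <= config$merge_rt_tight
  # loose-RT branch needs the correlation, computed only where it can matter
  need <- which(same_pol & ppm <= config$merge_ppm &
                  drt > config$merge_rt_tight &
                  drt <= config$merge_rt_loose, arr.ind = TRUE)
  for (k in seq_len(nrow(need))) {
    i <- need[k, 1]; j <- need[k, 2]
    x <- A[i, ]; y <- A[j, ]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) next
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) next
    if (cor(x[ok], y[ok]) >= config$merge_corr_min) adj[i, j] <- TRUE
  }
  diag(adj) <- TRUE
  adj <- adj | t(adj)
  seen <- rep(FALSE, n)
  groups <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- s
    frontier <- s
    seen[s] <- TRUE
    while (length(frontier) > 0) {
      nxt <- which(apply(adj[frontier, , drop = FALSE], 2, any) & !seen)
      seen[nxt] <- TRUE
      comp <- c(comp, nxt)
      frontier <- nxt
    }
    groups[[length(groups) + 1]] <- sort(comp)
  }
  groups[order(vapply(groups, `[`, integer(1), 1))]
}

# Exhaustive CHNOPS enumeration over a full grid (independent of the
# hydrogen-solving search in enumerate_formulas).
brute_formulas <- function(target, tol_ppm,
                           caps = c(C = 20, H = 40, N = 6, O = 12, P = 3, S = 3)) {
  am <- pairtrace::atomic_masses
  g <- expand.grid(C = 0:caps["C"], H = 0:caps["H"], N = 0:caps["N"],
                   O = 0:caps["O"], P = 0:caps["P"], S = 0:caps["S"])
  mass <- g$C * am["C"] + g$H * am["H"] + g$N * am["N"] + g$O * am["O"] +
    g$P * am["P"] + g$S * am["S"]
  err <- (mass - target) / target * 1e6
  keep <- abs(err) <= tol_ppm
  g <- g[keep, , drop = FALSE]
  rdbe <- g$C - g$H / 2 + g$N / 2 + 1
  organic <- g$C >= 1
  ratio_ok <- !organic | (rdbe >= 0 &
    g$H / g$C >= 0.1 & g$H / g$C <= 6 &
    g$N / g$C <= 4 & g$O / g$C <= 3 & g$P / g$C <= 2 & g$S / g$C <= 3)
  g <- g[ratio_ok, , drop = FALSE]
  key <- sprintf("C%dH%dN%dO%dP%dS%d", g$C, g$H, g$N, g$O, g$P, g$S)
  sort(key)
}

formula_key <- function(tbl) {
  sort(sprintf("C%dH%dN%dO%dP%dS%d", tbl$C, tbl$H, tbl$N, tbl$O, tbl$P, tbl$S))
}

# Random peak table for oracle-equivalence sweeps: a mix of random features
# plus planted partner/duplicate structure so matches actually occur.
random_peak_table <- function(n, seed, samples) {
  set.seed(seed)
  labeled <- samples$sample_id[samples$role == "labeled_mix"]
  n_base <- ceiling(n * 0.6)
  mass <- runif(n_base, 130, 600)
  rt <- runif(n_base, 0.5, 15)
  pol <- sample(c("negative", "positive"), n_base, replace = TRUE)
  # plant partners (some inside, some outside the gates)
  n_part <- n - n_base
  idx <- sample(n_base, n_part, replace = TRUE)
  mass <- c(mass, mass[idx] + heavy_shift() +
              runif(n_part, -1, 1) * 8e-6 * mass[idx])
  rt <- c(rt, rt[idx] + runif(n_part, -0.4, 0.4))
  pol <- c(pol, pol[idx])
  areas <- lapply(seq_along(labeled), function(s) {
    a <- 10^runif(n, 4.5, 6.5)
    a[sample(n, floor(n * 0.1))] <- NA
    a
  })
  names(areas) <- labeled
  mk_peaks(mass, pmax(rt, 0), areas, polarity = pol)
}
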