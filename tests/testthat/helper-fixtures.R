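# Shared fixtures and independent oracles, all built in code.

# -- landscape builders ------------------------------------------------------

uniform_landscape <- function(len = 1e7, rate = 5, name = "chr1") {
  make_landscape(stats::setNames(len, name),
                 background_rates = c(euchromatic = rate))
}

# the acceptance-scale world: 2 x 20 Mbp, distal euchromatin (5 cM/Mbp),
# central pericentromere (0.3 cM/Mbp), optionally 4 planted 200-kb hotspots
# at 10x the euchromatic background
acceptance_landscape <- function(with_hotspots = TRUE) {
  chroms <- c(chr1 = 2e7, chr2 = 2e7)
  chromatin <- do.call(rbind, lapply(names(chroms), function(cn)
    data.frame(chrom = cn, start = c(0, 6e6, 14e6), end = c(6e6, 14e6, 2e7),
               class = c("euchromatic", "heterochromatic", "euchromatic"),
               stringsAsFactors = FALSE)))
  hots <- if (with_hotspots)
    data.frame(chrom = c("chr1", "chr1", "chr2", "chr2"),
               center = c(2e6, 16.5e6, 3.5e6, 18e6),
               width = 2e5, peak_rate = 50)
  make_landscape(chroms, chromatin, hots,
                 background_rates = c(euchromatic = 5,
                                      heterochromatic = 0.3))
}

# -- synthetic profiles (grid-level fixtures for the hotspot caller) ---------

flat_profile <- function(rate = 2, n = 200, step = 10000, chrom = "chr1") {
  structure(data.frame(chrom = chrom, pos = seq(0, by = step,
                                                length.out = n),
                       rate = rate, stringsAsFactors = FALSE),
            grid_step = step, method = "spline", total_cM = NA,
            class = c("rate_profile", "data.frame"))
}

all_euchromatic <- function(profile) {
  chromatin_map(do.call(rbind, lapply(unique(profile$chrom), function(cn) {
    p <- profile$pos[profile$chrom == cn]
    data.frame(chrom = cn, start = 0,
               end = max(p) + attr(profile, "grid_step"),
               class = "euchromatic", stringsAsFactors = FALSE)
  })))
}

# -- independent oracles -----------------------------------------------------

# Tukey fence by literal sort-and-fence arithmetic (no quantile())
tukey_keep_oracle <- function(sizes) {
  n <- length(sizes)
  if (n < 4) return(rep(TRUE, n))
  s <- sort(sizes)
  q_at <- function(p) {            # type-7: linear interpolation of order stats
    h <- (n - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
  }
  q1 <- q_at(0.25); q3 <- q_at(0.75)
  sizes <= q3 + 1.5 * (q3 - q1)
}

# naive all-offsets motif scan, nested loops (forward strand only)
naive_iupac_scan <- function(seq, pattern, max_mm) {
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  hits <- integer(0)
  if (length(s) < length(p)) return(hits)
  for (o in 0:(length(s) - length(p))) {
    mm <- 0L
    for (j in seq_along(p)) {
      if (p[j] == "N") next
      cj <- s[o + j]
      if (cj == "N" || cj != p[j]) mm <- mm + 1L
    }
    if (mm <= max_mm) hits <- c(hits, o)
  }
  hits
}

random_dna <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# genotype matrix with arbitrary call vectors, markers 1 kb apart
gm_from_calls <- function(calls, chrom = "chr1") {
  if (!is.matrix(calls)) calls <- matrix(calls, nrow = 1)
  markers <- data.frame(id = sprintf("m%03d", seq_len(nrow(calls))),
                        chrom = chrom, pos = seq_len(nrow(calls)) * 1000,
                        stringsAsFactors = FALSE)
  colnames(calls) <- sprintf("L%03d", seq_len(ncol(calls)))
  new_genotype_matrix(markers, calls)
}

# calls vector with given A/B/H/missing counts, shuffled deterministically
calls_with_counts <- function(nA, nB, nH = 0, nmiss = 0) {
  v <- c(rep("A", nA), rep("B", nB), rep("H", nH),
         rep(NA_character_, nmiss))
  v[order(seq_along(v) %% 7)]  # fixed interleave, no RNG
}
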