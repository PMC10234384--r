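# Fixed-motif scanning of hotspot flanking sequence with a permutation
# background: a scan-based surrogate for de novo motif discovery, covering a
# poly-A run motif and a degenerate CCN-like consensus.

#' Motif specification
#'
#' Either a run motif (`base` + `min_run`: maximal runs of one base of at
#' least that length) or an IUPAC consensus (`pattern`, where `N` matches any
#' base and up to `max_mismatches` mismatches are allowed at non-N
#' positions; `N` in the scanned sequence matches nothing).
#'
#' @param name motif name.
#' @param pattern IUPAC pattern (A/C/G/T/N), or `NULL` for a run motif.
#' @param base,min_run run-motif base and minimum run length.
#' @param max_mismatches mismatch budget for pattern motifs.
#' @param both_strands also scan the reverse complement.
#' @return object of class `motif_spec`.
#' @export
motif_spec <- function(name, pattern = NULL, base = NULL, min_run = NULL,
                       max_mismatches = 0, both_strands = TRUE) {
  if (is.null(pattern) == is.null(base))
    stop("give exactly one of pattern or base/min_run")
  if (!is.null(pattern)) {
    pattern <- toupper(pattern)
    stopifnot(nzchar(pattern), max_mismatches < nchar(pattern),
              grepl("^[ACGTN]+$", pattern))
  } else stopifnot(base %in% c("A", "C", "G", "T"), min_run >= 1)
  structure(list(name = name, pattern = pattern, base = base,
                 min_run = min_run, max_mismatches = max_mismatches,
                 both_strands = both_strands), class = "motif_spec")
}

#' The two motifs reported near soybean hotspots
#'
#' A poly-A stretch (run of >= `polyA_min` A's; with both-strand scanning
#' this also detects poly-T) and the degenerate CCN-like consensus
#' `CNCCNCCACAACCAANNCANNA` with a 4-mismatch budget.
#'
#' @param polyA_min minimum poly-A run length.
#' @param ccn_mismatches mismatch budget for the CCN-like consensus.
#' @return list of two `motif_spec`s.
#' @export
default_motifs <- function(polyA_min = 8, ccn_mismatches = 4) {
  list(polyA = motif_spec("polyA", base = "A", min_run = polyA_min),
       ccn = motif_spec("ccn", pattern = "CNCCNCCACAACCAANNCANNA",
                        max_mismatches = ccn_mismatches))
}

#' Extract hotspot flanking sequences
#'
#' For each hotspot, the sequence from `start - upstream_bp` (clipped at the
#' chromosome start) to the hotspot end (plus `upstream_bp` downstream when
#' `both_flanks`), uppercased.
#'
#' @param hs a `hotspot_set`.
#' @param fasta FASTA path or a [Biostrings::DNAStringSet].
#' @param upstream_bp flank length.
#' @param both_flanks also include the downstream flank.
#' @return a `DNAStringSet`, one sequence per hotspot.
#' @export
extract_flanks <- function(hs, fasta, upstream_bp = 200,
                           both_flanks = FALSE) {
  seqs <- if (is.character(fasta)) Biostrings::readDNAStringSet(fasta)
          else fasta
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  miss <- setdiff(unique(hs$chrom), names(seqs))
  if (length(miss))
    stop("chromosome(s) missing from FASTA: ", paste(miss, collapse = ", "))
  out <- vector("list", nrow(hs))
  for (i in seq_len(nrow(hs))) {
    L <- length(seqs[[hs$chrom[i]]])
    from0 <- max(0, hs$start[i] - upstream_bp)
    to0 <- min(L, hs$end[i] + if (both_flanks) upstream_bp else 0)
    out[[i]] <- Biostrings::subseq(seqs[[hs$chrom[i]]], from0 + 1, to0)
  }
  res <- Biostrings::DNAStringSet(out)
  names(res) <- sprintf("%s:%d-%d", hs$chrom, hs$start, hs$end)
  Biostrings::DNAStringSet(toupper(res))
}

# Scan one forward-strand character sequence for an IUPAC pattern with a
# mismatch budget. Vectorized over offsets: one pass per pattern position.
scan_iupac_one <- function(seq_chars, pat_chars, max_mm) {
  n <- length(seq_chars); m <- length(pat_chars)
  if (n < m) return(integer(0))
  n_off <- n - m + 1L
  mm <- integer(n_off)
  for (j in seq_len(m)) {
    pj <- pat_chars[j]
    sj <- seq_chars[j:(j + n_off - 1L)]
    if (pj == "N") next                    # N in pattern matches anything
    mm <- mm + as.integer(sj != pj | sj == "N")  # N in sequence matches nothing
  }
  which(mm <= max_mm)
}

run_hits_one <- function(seq_str, base, min_run) {
  g <- gregexpr(sprintf("%s{%d,}", base, min_run), seq_str)[[1]]
  if (g[1] == -1) return(data.frame(offset = integer(), len = integer()))
  data.frame(offset = as.integer(g), len = attr(g, "match.length"))
}

#' Scan sequences for a motif
#'
#' @param seqs a `DNAStringSet` or character vector of sequences.
#' @param spec a [motif_spec()].
#' @return a `motif_hits` object: `hits` data.frame (`seq`, `offset`
#'   (0-based, forward-strand coordinates), `strand`, `match`) and
#'   `presence` data.frame (`seq`, `n_hits`, `present`).
#' @export
scan_motif <- function(seqs, spec) {
  ss <- as.character(seqs)
  ids <- if (!is.null(names(ss))) names(ss) else as.character(seq_along(ss))
  revcomp <- function(s) chartr("ACGTN", "TGCAN",
                                vapply(s, function(x)
                                  paste(rev(strsplit(x, "")[[1]]),
                                        collapse = ""), character(1),
                                  USE.NAMES = FALSE))
  all_hits <- list()
  for (i in seq_along(ss)) {
    s <- toupper(ss[i])
    strands <- list("+" = s)
    if (spec$both_strands) strands[["-"]] <- revcomp(s)
    for (st in names(strands)) {
      sc <- strands[[st]]
      if (!is.null(spec$base)) {
        rh <- run_hits_one(sc, spec$base, spec$min_run)
        off1 <- rh$offset
        mlen <- rh$len
      } else {
        chars <- strsplit(sc, "")[[1]]
        off1 <- scan_iupac_one(chars, strsplit(spec$pattern, "")[[1]],
                               spec$max_mismatches)
        mlen <- rep(nchar(spec$pattern), length(off1))
      }
      if (!length(off1)) next
      # map minus-strand offsets back to forward coordinates
      fwd0 <- if (st == "+") off1 - 1L else nchar(sc) - (off1 - 1L) - mlen
      all_hits[[length(all_hits) + 1L]] <- data.frame(
        seq = ids[i], offset = fwd0, strand = st,
        match = substring(toupper(ss[i]), fwd0 + 1L, fwd0 + mlen),
        stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(all_hits)) do.call(rbind, all_hits) else
    data.frame(seq = character(), offset = integer(), strand = character(),
               match = character())
  nh <- table(factor(hits$seq, levels = ids))
  presence <- data.frame(seq = ids, n_hits = as.integer(nh),
                         present = as.integer(nh) > 0,
                         stringsAsFactors = FALSE)
  structure(list(hits = hits, presence = presence, motif = spec$name),
            class = "motif_hits")
}

#' @export
print.motif_hits <- function(x, ...) {
  cat(sprintf("motif_hits (%s): %d hit(s) in %d/%d sequence(s)\n",
              x$motif, nrow(x$hits), sum(x$presence$present),
              nrow(x$presence)))
  invisible(x)
}

#' Permutation enrichment test for motif presence
#'
#' Compares the fraction of hotspot flanks containing the motif to
#' length-matched background windows by permuting the hotspot/background
#' labels. Empirical P = (1 + #\{permuted hotspot fractions >= observed\}) /
#' (1 + n_perm).
#'
#' @param hs_present logical: motif presence per hotspot flank.
#' @param bg_present logical: motif presence per background window.
#' @param n_perm number of permutations.
#' @return list `frac_hotspots`, `frac_background`, `fold`, `p`.
#' @export
enrichment_test <- function(hs_present, bg_present, n_perm = 1000) {
  nh <- length(hs_present); nb <- length(bg_present)
  stopifnot(nh > 0, nb > 0)
  obs <- mean(hs_present)
  fb <- mean(bg_present)
  if (obs == 0 && fb == 0)
    return(list(frac_hotspots = 0, frac_background = 0, fold = 1, p = 1))
  pool <- c(hs_present, bg_present)
  perm <- vapply(seq_len(n_perm), function(k)
    mean(pool[sample.int(nh + nb, nh)]), numeric(1))
  list(frac_hotspots = obs, frac_background = fb,
       fold = obs / max(fb, 1 / (2 * nb)),
       p = (1 + sum(perm >= obs)) / (1 + n_perm))
}

#' Sample length-matched background windows for motif enrichment
#'
#' Draws, for each hotspot flank length, a random window of the same length
#' from the same chromatin class, avoiding hotspot intervals.
#'
#' @param hs a `hotspot_set`.
#' @param cmap a `chromatin_map`.
#' @param lengths window lengths to match (defaults to the flank lengths).
#' @param n number of windows (recycled over `lengths`).
#' @param max_tries rejection-sampling attempts per window.
#' @return data.frame `chrom`, `start`, `end` (0-based half-open).
#' @export
sample_background_windows <- function(hs, cmap, lengths, n = length(lengths),
                                      max_tries = 50) {
  lengths <- rep_len(lengths, n)
  cls <- hs$chromatin[rep_len(seq_len(nrow(hs)), n)]
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cc <- cmap[cmap$class == cls[i] &
                 (cmap$end - cmap$start) >= lengths[i], , drop = FALSE]
    if (!nrow(cc)) cc <- cmap[(cmap$end - cmap$start) >= lengths[i], ,
                              drop = FALSE]
    for (t in seq_len(max_tries)) {
      j <- sample.int(nrow(cc), 1)
      s <- cc$start[j] +
        floor(stats::runif(1) * (cc$end[j] - cc$start[j] - lengths[i] + 1))
      e <- s + lengths[i]
      clash <- any(hs$chrom == cc$chrom[j] & hs$start < e & s < hs$end)
      if (!clash) break
    }
    out[[i]] <- data.frame(chrom = cc$chrom[j], start = s, end = e,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
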