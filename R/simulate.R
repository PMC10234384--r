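# Forward simulation of F_k-derived RIL populations by single seed descent.
#
# Haplotypes are stored as founder-origin step functions: a sorted vector of
# breakpoints (bp) plus the allele (0 = parent A, 1 = parent B) carried at the
# left end of the chromosome. The allele at position x is
# (start + #breaks <= x) mod 2, which makes marker readout a findInterval().

new_haplotype <- function(allele) list(breaks = numeric(0), start = allele)

hap_allele_at <- function(hap, x) {
  (hap$start + findInterval(x, hap$breaks)) %% 2L
}

# Form one gamete from a diploid pair of haplotypes given crossover positions.
# The gamete switches between the parental haplotypes at each crossover,
# starting from a uniformly chosen strand; the result is again a founder-origin
# step function (breakpoints merged and collapsed).
recombine_haps <- function(h1, h2, xo) {
  strand0 <- sample.int(2L, 1L) - 1L
  if (!length(xo)) return(if (strand0 == 0L) h1 else h2)
  cand <- sort(c(h1$breaks, h2$breaks, xo))
  cand <- cand[!duplicated(cand)]
  pts <- c(0, cand)                       # representative of [cand_i, cand_i+1)
  strand <- (strand0 + findInterval(pts, sort(xo))) %% 2L
  a1 <- (h1$start + findInterval(pts, h1$breaks)) %% 2L
  a2 <- (h2$start + findInterval(pts, h2$breaks)) %% 2L
  allele <- ifelse(strand == 0L, a1, a2)
  keep <- diff(allele) != 0L
  list(breaks = cand[keep], start = allele[1L])
}

# Poisson crossover count (mean = Morgans), positions by inverse transform on
# the cumulative map. Returns bp positions (possibly length 0).
draw_crossovers <- function(landscape, chrom) {
  total_cM <- landscape$per_chrom[[chrom]]$knots_cM
  total_cM <- total_cM[length(total_cM)]
  if (total_cM <= 0) return(numeric(0))
  k <- stats::rpois(1L, total_cM / 100)
  if (k == 0L) return(numeric(0))
  landscape_inv_cM(landscape, chrom, stats::runif(k, 0, total_cM))
}

#' Simulate one meiosis
#'
#' Produces a single gamete from a diploid parent over a landscape. Crossover
#' counts per chromosome are Poisson with mean equal to the chromosome map
#' length in Morgans (no interference); positions are drawn by
#' inverse-transform sampling on the cumulative genetic map, so the local
#' crossover density is proportional to the landscape rate. The gamete is a
#' mosaic of the two parental haplotypes switching at each crossover, with the
#' initial strand chosen uniformly.
#'
#' @param parent list with elements `hap1`, `hap2`, each a per-chromosome list
#'   of haplotypes as produced by the simulator (founder-origin breakpoints).
#' @param landscape a [make_landscape()] landscape.
#' @return list with `gamete` (per-chromosome haplotype list) and
#'   `crossovers` (data.frame `chrom`, `pos`).
#' @export
simulate_meiosis <- function(parent, landscape) {
  chroms <- names(landscape$chrom_len)
  gam <- vector("list", length(chroms))
  names(gam) <- chroms
  xo_chrom <- character(0); xo_pos <- numeric(0)
  for (cn in chroms) {
    xo <- draw_crossovers(landscape, cn)
    gam[[cn]] <- recombine_haps(parent$hap1[[cn]], parent$hap2[[cn]], xo)
    if (length(xo)) {
      xo_chrom <- c(xo_chrom, rep(cn, length(xo)))
      xo_pos <- c(xo_pos, xo)
    }
  }
  list(gamete = gam,
       crossovers = data.frame(chrom = xo_chrom, pos = xo_pos,
                               stringsAsFactors = FALSE))
}

founder_parent <- function(chroms) {
  h0 <- lapply(chroms, function(cn) new_haplotype(0L))
  h1 <- lapply(chroms, function(cn) new_haplotype(1L))
  names(h0) <- names(h1) <- chroms
  list(hap1 = h0, hap2 = h1)
}

# Gamete-level viability weighting for segregation distortion: a gamete
# carrying `allele` at (chrom, pos) survives with relative weight `weight`.
gamete_accept_prob <- function(gamete, distortion) {
  w <- 1
  wmax <- 1
  for (i in seq_len(nrow(distortion))) {
    a <- hap_allele_at(gamete[[distortion$chrom[i]]], distortion$pos[i])
    target <- if (distortion$allele[i] == "A") 0L else 1L
    wi <- distortion$weight[i]
    w <- w * if (a == target) wi else 1
    wmax <- wmax * max(wi, 1)
  }
  w / wmax
}

#' Simulate an F_k-derived RIL population by single seed descent
#'
#' Each line descends from a single F1 individual by `final_generation - 1`
#' rounds of self-fertilisation, keeping one offspring per generation (SSD).
#' Genotypes are read off at the supplied marker positions as `A`/`B`
#' (parental homozygotes) or `H` (residual heterozygote); missing calls are
#' then injected i.i.d. at `missing_rate`. Segregation distortion, if
#' requested, acts as a gamete-level viability weight at named loci.
#'
#' @param landscape a [make_landscape()] landscape (the ground truth).
#' @param markers data.frame with columns `id`, `chrom`, `pos` (bp); positions
#'   must lie within their chromosome.
#' @param n_lines number of RILs.
#' @param final_generation k of F_k; `5` reproduces an F5-derived population
#'   (expected residual heterozygosity `2^-(k-1)` = 6.25%).
#' @param missing_rate i.i.d. probability a call is set missing.
#' @param distortion `NULL`, or data.frame `chrom`, `pos`, `allele` (`"A"` or
#'   `"B"`), `weight` (>1 favours `allele`).
#' @param seed integer seed; recorded in the truth object.
#' @param population label stored in the genotype matrix.
#' @return list with `genotypes` (a `genotype_matrix`) and `truth` (a
#'   `sim_truth`: crossover records, landscape, generation, seed).
#' @export
simulate_ril_population <- function(landscape, markers, n_lines,
                                    final_generation = 5,
                                    missing_rate = 0,
                                    distortion = NULL,
                                    seed = NULL,
                                    population = "sim") {
  stopifnot(final_generation >= 2, missing_rate >= 0, missing_rate < 1,
            n_lines >= 1)
  if (!is.null(seed)) set.seed(seed)
  chroms <- names(landscape$chrom_len)
  markers <- markers[order(match(markers$chrom, chroms), markers$pos), ,
                     drop = FALSE]
  rownames(markers) <- NULL
  bad <- is.na(match(markers$chrom, chroms)) |
    markers$pos < 0 | markers$pos >= landscape$chrom_len[markers$chrom]
  if (any(bad))
    stop("markers outside chromosome bounds: ",
         paste(utils::head(markers$id[bad], 5), collapse = ", "))

  mk_by_chrom <- split(seq_len(nrow(markers)), markers$chrom)
  calls <- matrix(NA_character_, nrow(markers), n_lines)
  line_ids <- sprintf("L%04d", seq_len(n_lines))
  colnames(calls) <- line_ids

  rec_line <- vector("list", n_lines)
  for (li in seq_len(n_lines)) {
    indiv <- founder_parent(chroms)      # the F1
    xo_gen <- integer(0); xo_mei <- integer(0)
    xo_chr <- character(0); xo_pos <- numeric(0)
    for (gen in seq_len(final_generation - 1L)) {
      repeat {
        m1 <- simulate_meiosis(indiv, landscape)
        if (is.null(distortion) ||
            stats::runif(1) < gamete_accept_prob(m1$gamete, distortion)) break
      }
      repeat {
        m2 <- simulate_meiosis(indiv, landscape)
        if (is.null(distortion) ||
            stats::runif(1) < gamete_accept_prob(m2$gamete, distortion)) break
      }
      indiv <- list(hap1 = m1$gamete, hap2 = m2$gamete)
      for (mi in 1:2) {
        xo <- if (mi == 1) m1$crossovers else m2$crossovers
        if (nrow(xo)) {
          xo_gen <- c(xo_gen, rep(gen + 1L, nrow(xo)))
          xo_mei <- c(xo_mei, rep(mi, nrow(xo)))
          xo_chr <- c(xo_chr, xo$chrom)
          xo_pos <- c(xo_pos, xo$pos)
        }
      }
    }
    rec_line[[li]] <- data.frame(line = rep(line_ids[li], length(xo_gen)),
                                 generation = xo_gen,
                                 meiosis = xo_mei, chrom = xo_chr,
                                 pos = xo_pos, stringsAsFactors = FALSE)
    for (cn in chroms) {
      idx <- mk_by_chrom[[cn]]
      if (is.null(idx)) next
      a1 <- hap_allele_at(indiv$hap1[[cn]], markers$pos[idx])
      a2 <- hap_allele_at(indiv$hap2[[cn]], markers$pos[idx])
      calls[idx, li] <- ifelse(a1 == a2, ifelse(a1 == 0L, "A", "B"), "H")
    }
  }
  if (missing_rate > 0) {
    drop <- stats::runif(length(calls)) < missing_rate
    calls[drop] <- NA_character_
  }

  gm <- new_genotype_matrix(markers, calls, population = population)
  truth <- structure(
    list(crossovers = do.call(rbind, rec_line),
         landscape = landscape,
         generation = final_generation,
         seed = seed),
    class = "sim_truth")
  list(genotypes = gm, truth = truth)
}

#' Genotype matrix constructor
#'
#' @param markers data.frame `id`, `chrom`, `pos`, sorted by (chrom, pos).
#' @param calls character matrix markers x lines over `"A"`,`"B"`,`"H"`,`NA`.
#' @param population population label.
#' @return object of class `genotype_matrix`.
#' @export
new_genotype_matrix <- function(markers, calls, population = "") {
  stopifnot(nrow(markers) == nrow(calls))
  if (anyDuplicated(markers$id)) stop("duplicate marker ids")
  ok <- calls %in% c("A", "B", "H") | is.na(calls)
  if (!all(ok)) stop("invalid genotype calls")
  for (cn in unique(markers$chrom)) {
    p <- markers$pos[markers$chrom == cn]
    if (any(diff(p) <= 0)) {
      # resolve duplicated physical positions deterministically by keeping
      # strictly increasing order via stable sort; exact duplicates rejected
      if (any(diff(p) == 0)) stop("duplicate marker positions on ", cn)
      stop("markers not sorted by position on ", cn)
    }
  }
  rownames(calls) <- markers$id
  structure(list(markers = markers, calls = calls, population = population),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d markers x %d lines (%s), %d chromosome(s)\n",
              nrow(x$markers), ncol(x$calls),
              if (nzchar(x$population)) x$population else "unlabelled",
              length(unique(x$markers$chrom))))
  miss <- mean(is.na(x$calls))
  het <- mean(x$calls == "H", na.rm = TRUE)
  cat(sprintf("  missing %.2f%%, heterozygous %.2f%%\n", 100 * miss, 100 * het))
  invisible(x)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: F%d population, %d crossover records, seed %s\n",
              x$generation,
              if (is.null(x$crossovers)) 0L else nrow(x$crossovers),
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

#' Regularly spaced marker panel for a landscape
#'
#' @param landscape a landscape.
#' @param spacing_bp distance between adjacent markers.
#' @param offset_bp position of the first marker on each chromosome.
#' @return data.frame `id`, `chrom`, `pos`.
#' @export
make_marker_grid <- function(landscape, spacing_bp, offset_bp = spacing_bp / 2) {
  out <- lapply(names(landscape$chrom_len), function(cn) {
    pos <- seq(offset_bp, landscape$chrom_len[[cn]] - 1, by = spacing_bp)
    data.frame(id = sprintf("%s_m%05d", cn, seq_along(pos)),
               chrom = cn, pos = pos, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
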