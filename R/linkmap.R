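# Two-point linkage mapping on the physical marker order. The observed
# recombinant fraction R between adjacent markers in a selfed RIL population
# overestimates the meiotic fraction r because crossovers accumulate over the
# selfing generations (map expansion); the Haldane-Waddington relation at
# fixation, R = 2r/(1+2r), is inverted to correct it before a mapping
# function converts r to additive cM.

#' Two-point recombinant fraction between two markers
#'
#' R = discordant homozygote pairs / homozygote non-missing pairs; lines
#' heterozygous or missing at either marker are excluded.
#'
#' @param calls_i,calls_j equal-length call vectors over `"A"`,`"B"`,`"H"`,`NA`.
#' @return list with `R` (capped at 0.4999) and `n_informative`.
#' @export
two_point_R <- function(calls_i, calls_j) {
  stopifnot(length(calls_i) == length(calls_j))
  hom_i <- calls_i %in% c("A", "B")
  hom_j <- calls_j %in% c("A", "B")
  ok <- hom_i & hom_j
  n <- sum(ok)
  if (n == 0) stop("no informative lines")
  R <- sum(calls_i[ok] != calls_j[ok]) / n
  list(R = min(R, 0.4999), n_informative = n)
}

#' Haldane-Waddington correction for selfed RILs
#'
#' With `generation = Inf` (default), inverts the fixation relation
#' R = 2r/(1+2r): r = R / (2 - 2R). With a finite generation k, inverts the
#' exact two-locus selfing chain [ril_expected_R()] numerically; at F5 the
#' expected observed fraction among double homozygotes is only about
#' 0.73 x 2r for tightly linked markers, so the fixation formula
#' substantially under-corrects F5 data.
#'
#' @param R observed recombinant fraction(s), in `[0, 0.5)`.
#' @param generation k of the F_k population, or `Inf` for fixation.
#' @return meiotic recombination fraction(s) r.
#' @export
correct_ril <- function(R, generation = Inf) {
  if (any(R < 0 | R >= 0.5)) stop("R must lie in [0, 0.5)")
  if (is.infinite(generation)) return(R / (2 - 2 * R))
  stopifnot(generation >= 2)
  rmax <- 0.49999
  Rmax <- ril_expected_R(rmax, generation)
  uR <- unique(R)                       # two-point R values repeat a lot
  ur <- vapply(uR, function(Ri) {
    if (Ri == 0) return(0)
    if (Ri >= Rmax) return(rmax)
    stats::uniroot(function(r) ril_expected_R(r, generation) - Ri,
                   c(1e-12, rmax), tol = 1e-10)$root
  }, numeric(1))
  ur[match(R, uR)]
}

#' Expected observed recombinant fraction in a selfed F_k RIL
#'
#' Exact two-locus computation: the diplotype distribution of an F_k line is
#' propagated through k-1 rounds of selfing from a fully heterozygous F1
#' (recombination fraction r per meiosis, no interference), and the expected
#' recombinant fraction is taken conditional on both loci being homozygous --
#' the same conditioning [two_point_R()] applies. As k grows this converges
#' to the Haldane-Waddington fixation value 2r/(1+2r).
#'
#' @param r meiotic recombination fraction in `[0, 0.5]`.
#' @param generation k of F_k (>= 2).
#' @return expected observed fraction R.
#' @export
ril_expected_R <- function(r, generation) {
  stopifnot(r >= 0, r <= 0.5, generation >= 2, is.finite(generation))
  # haplotypes 1..4 = (a,b) alleles (0,0),(1,0),(0,1),(1,1)
  ha <- c(0L, 1L, 0L, 1L); hb <- c(0L, 0L, 1L, 1L)
  rec_idx <- function(i, j) which(ha == ha[i] & hb == hb[j])
  P <- matrix(0, 4, 4); P[1, 4] <- 1    # F1 = (0,0)/(1,1)
  for (g in seq_len(generation - 1L)) {
    Q <- matrix(0, 4, 4)
    for (i in 1:4) for (j in 1:4) {
      if (P[i, j] == 0) next
      gd <- numeric(4)
      gd[i] <- gd[i] + (1 - r) / 2
      gd[j] <- gd[j] + (1 - r) / 2
      gd[rec_idx(i, j)] <- gd[rec_idx(i, j)] + r / 2
      gd[rec_idx(j, i)] <- gd[rec_idx(j, i)] + r / 2
      Q <- Q + P[i, j] * outer(gd, gd)
    }
    P <- Q
  }
  den <- sum(diag(P))
  num <- P[2, 2] + P[3, 3]              # homozygous recombinant diplotypes
  num / den
}

#' Map distance from a recombination fraction
#'
#' Kosambi: d = 25 ln((1+2r)/(1-2r)); Haldane: d = -50 ln(1-2r); both in cM.
#'
#' @param r meiotic recombination fraction(s), in `[0, 0.5)`.
#' @param fun `"kosambi"` (default, partial-interference convention) or
#'   `"haldane"`.
#' @return distance(s) in cM.
#' @export
map_distance <- function(r, fun = c("kosambi", "haldane")) {
  fun <- match.arg(fun)
  if (any(r < 0 | r >= 0.5)) stop("r must lie in [0, 0.5)")
  switch(fun,
         kosambi = 25 * log((1 + 2 * r) / (1 - 2 * r)),
         haldane = -50 * log(1 - 2 * r))
}

#' Build per-chromosome genetic maps from a genotype matrix
#'
#' Marker order is fixed to the physical (reference) order. Adjacent-marker
#' distances come from [two_point_R()] -> [correct_ril()] -> [map_distance()]
#' and are accumulated from 0 cM at the first marker of each chromosome.
#'
#' @param gm a QC'd `genotype_matrix`.
#' @param fun mapping function, `"kosambi"` or `"haldane"`.
#' @param ril_correction apply the Haldane-Waddington selfing correction
#'   (set `FALSE` only for non-RIL designs).
#' @param generation F_k generation for the correction; `Inf` uses the
#'   fixation formula, a finite k (e.g. 5) the exact finite-generation
#'   inversion, which matters: see [correct_ril()].
#' @return a `genetic_map`: data.frame `chrom`, `id`, `pos`, `cM` with
#'   attributes `mapping_function` and `ril_scheme`.
#' @export
build_map <- function(gm, fun = c("kosambi", "haldane"),
                      ril_correction = TRUE, generation = Inf) {
  fun <- match.arg(fun)
  stopifnot(inherits(gm, "genotype_matrix"))
  code <- matrix(NA_integer_, nrow(gm$calls), ncol(gm$calls))
  code[gm$calls == "A"] <- 0L
  code[gm$calls == "B"] <- 1L

  out <- lapply(unique(gm$markers$chrom), function(cn) {
    idx <- which(gm$markers$chrom == cn)
    if (length(idx) < 2) {
      warning("chromosome ", cn, " has a single marker; map is a point")
      return(data.frame(chrom = cn, id = gm$markers$id[idx],
                        pos = gm$markers$pos[idx], cM = 0,
                        stringsAsFactors = FALSE))
    }
    X <- code[idx[-length(idx)], , drop = FALSE]
    Y <- code[idx[-1], , drop = FALSE]
    ok <- !is.na(X) & !is.na(Y)
    n_inf <- rowSums(ok)
    disc <- rowSums(X != Y & ok, na.rm = TRUE)
    if (any(n_inf == 0))
      stop("no informative lines for an adjacent pair on ", cn)
    R <- pmin(disc / n_inf, 0.4999)
    r <- if (ril_correction) correct_ril(R, generation) else R
    d <- map_distance(r, fun)
    data.frame(chrom = cn, id = gm$markers$id[idx], pos = gm$markers$pos[idx],
               cM = c(0, cumsum(d)), stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out),
            mapping_function = fun,
            ril_scheme = if (!ril_correction) "none"
                         else if (is.infinite(generation)) "Finf-self"
                         else sprintf("F%d-self", generation),
            population = gm$population,
            class = c("genetic_map", "data.frame"))
}

#' Total map length per chromosome
#'
#' @param map a `genetic_map`.
#' @return named numeric, cM.
#' @export
map_length <- function(map) {
  vapply(split(map$cM, map$chrom), max, numeric(1))
}

#' @export
print.genetic_map <- function(x, ...) {
  len <- map_length(x)
  cat(sprintf("genetic_map (%s, %s): %d markers, %d chromosome(s), %.4g cM total\n",
              attr(x, "mapping_function"), attr(x, "ril_scheme"),
              nrow(x), length(len), sum(len)))
  invisible(x)
}
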