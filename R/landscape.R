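#' Construct a piecewise-constant recombination landscape
#'
#' A landscape assigns every base of every chromosome a local recombination
#' rate in cM/Mbp: a chromatin-class background (euchromatic vs
#' heterochromatic/pericentromeric), overridden by a rectangular plateau at
#' `peak_rate` inside each hotspot interval. The implied cumulative genetic
#' map (bp -> cM) is the exact piecewise-linear integral of the rate and is
#' what the meiosis simulator inverts to place crossovers.
#'
#' Default background rates correspond to the soybean genome-wide averages of
#' 1 cM per 197 kb (euchromatic) and 1 cM per 3.5 Mb (pericentromeric).
#'
#' @param chromosomes named numeric vector of chromosome lengths in bp, or a
#'   data.frame with columns `name`, `length`.
#' @param chromatin data.frame with columns `chrom`, `start`, `end`, `class`
#'   (`"euchromatic"` or `"heterochromatic"`), 0-based half-open intervals
#'   that must tile each chromosome exactly. `NULL` means all-euchromatic.
#' @param hotspots data.frame with columns `chrom`, `center`, `width`,
#'   `peak_rate` (bp, bp, cM/Mbp), or `NULL`. Hotspot intervals are
#'   `[center - width/2, center + width/2)`; they must lie inside their
#'   chromosome and must not overlap one another.
#' @param background_rates named numeric, cM/Mbp per chromatin class.
#' @return An object of class `"landscape"`: per-chromosome rate segments,
#'   knot vectors of the cumulative map, and the inputs.
#' @examples
#' ls <- make_landscape(c(chr1 = 5e7), background_rates = c(euchromatic = 5))
#' total_map_length(ls)  # 250 cM
#' @export
make_landscape <- function(chromosomes,
                           chromatin = NULL,
                           hotspots = NULL,
                           background_rates = c(euchromatic = 1e3 / 197,
                                                heterochromatic = 1 / 3.5)) {
  if (is.data.frame(chromosomes)) {
    chrom_len <- stats::setNames(as.numeric(chromosomes$length), chromosomes$name)
  } else {
    chrom_len <- chromosomes
  }
  if (is.null(names(chrom_len)) || anyNA(names(chrom_len)))
    stop("chromosomes must be named")
  if (any(chrom_len <= 0)) stop("chromosome lengths must be > 0")
  if (any(background_rates < 0)) stop("background rates must be >= 0")

  if (is.null(chromatin)) {
    chromatin <- data.frame(chrom = names(chrom_len), start = 0,
                            end = unname(chrom_len), class = "euchromatic",
                            stringsAsFactors = FALSE)
  }
  if (!all(chromatin$class %in% names(background_rates)))
    stop("chromatin classes must have a background rate")

  if (!is.null(hotspots) && nrow(hotspots)) {
    hotspots$start <- hotspots$center - hotspots$width / 2
    hotspots$end <- hotspots$center + hotspots$width / 2
    if (any(hotspots$width <= 0)) stop("hotspot widths must be > 0")
    if (any(hotspots$peak_rate < 0)) stop("hotspot rates must be >= 0")
    for (i in seq_len(nrow(hotspots))) {
      L <- chrom_len[hotspots$chrom[i]]
      if (is.na(L) || hotspots$start[i] < 0 || hotspots$end[i] > L)
        stop("hotspot ", i, " lies outside its chromosome")
    }
    for (cn in unique(hotspots$chrom)) {
      h <- hotspots[hotspots$chrom == cn, , drop = FALSE]
      h <- h[order(h$start), , drop = FALSE]
      if (nrow(h) > 1 && any(h$start[-1] < h$end[-nrow(h)]))
        stop("overlapping hotspots on ", cn)
    }
  } else {
    hotspots <- data.frame(chrom = character(), center = numeric(),
                           width = numeric(), peak_rate = numeric(),
                           start = numeric(), end = numeric())
  }

  segs <- lapply(names(chrom_len), function(cn) {
    L <- unname(chrom_len[cn])
    cc <- chromatin[chromatin$chrom == cn, , drop = FALSE]
    cc <- cc[order(cc$start), , drop = FALSE]
    if (!nrow(cc) || cc$start[1] != 0 || cc$end[nrow(cc)] != L ||
        (nrow(cc) > 1 && any(cc$start[-1] != cc$end[-nrow(cc)])))
      stop("chromatin intervals must tile chromosome ", cn)
    hh <- hotspots[hotspots$chrom == cn, , drop = FALSE]
    cuts <- sort(unique(c(0, cc$end, hh$start, hh$end, L)))
    start <- cuts[-length(cuts)]
    end <- cuts[-1]
    mid <- (start + end) / 2
    cls <- cc$class[findInterval(mid, cc$start)]
    rate <- unname(background_rates[cls])
    if (nrow(hh)) {
      in_hot <- vapply(mid, function(x) {
        j <- which(hh$start <= x & x < hh$end)
        if (length(j)) j[1] else 0L
      }, integer(1))
      rate[in_hot > 0] <- hh$peak_rate[in_hot[in_hot > 0]]
    }
    cM <- c(0, cumsum(rate * (end - start) / 1e6))
    list(segments = data.frame(start = start, end = end, rate = rate,
                               class = cls, stringsAsFactors = FALSE),
         knots_bp = cuts, knots_cM = cM)
  })
  names(segs) <- names(chrom_len)

  structure(list(chrom_len = chrom_len, chromatin = chromatin,
                 hotspots = hotspots, background_rates = background_rates,
                 per_chrom = segs),
            class = "landscape")
}

#' Total genetic map length implied by a landscape
#'
#' @param landscape a [make_landscape()] object.
#' @return named numeric, cM per chromosome.
#' @export
total_map_length <- function(landscape) {
  vapply(landscape$per_chrom, function(p) p$knots_cM[length(p$knots_cM)],
         numeric(1))
}

#' Local recombination rate of a landscape
#'
#' @param landscape a landscape.
#' @param chrom chromosome name.
#' @param x positions in bp.
#' @return rates in cM/Mbp at `x`.
#' @export
landscape_rate <- function(landscape, chrom, x) {
  p <- landscape$per_chrom[[chrom]]
  if (is.null(p)) stop("unknown chromosome: ", chrom)
  i <- pmin(pmax(findInterval(x, p$segments$start), 1L), nrow(p$segments))
  p$segments$rate[i]
}

#' Cumulative genetic position implied by a landscape
#'
#' @inheritParams landscape_rate
#' @return cumulative cM at `x` (piecewise-linear interpolation of the exact
#'   integral of the rate function).
#' @export
landscape_cM <- function(landscape, chrom, x) {
  p <- landscape$per_chrom[[chrom]]
  if (is.null(p)) stop("unknown chromosome: ", chrom)
  stats::approx(p$knots_bp, p$knots_cM, xout = x, rule = 2)$y
}

# Inverse of the cumulative map: cM -> bp, used by the crossover sampler.
landscape_inv_cM <- function(landscape, chrom, u) {
  p <- landscape$per_chrom[[chrom]]
  n <- length(p$knots_bp)
  i <- pmin(pmax(findInterval(u, p$knots_cM), 1L), n - 1L)
  dcm <- p$knots_cM[i + 1L] - p$knots_cM[i]
  frac <- ifelse(dcm > 0, (u - p$knots_cM[i]) / dcm, 0)
  p$knots_bp[i] + frac * (p$knots_bp[i + 1L] - p$knots_bp[i])
}

#' Chromatin class at positions
#'
#' @inheritParams landscape_rate
#' @return character vector of classes.
#' @export
landscape_class <- function(landscape, chrom, x) {
  p <- landscape$per_chrom[[chrom]]
  i <- pmin(pmax(findInterval(x, p$segments$start), 1L), nrow(p$segments))
  p$segments$class[i]
}

#' Read a landscape from a structured JSON config
#'
#' The config lists `chromosomes` (name/length), optional `chromatin`
#' intervals, optional `hotspots` (chrom/center/width/peak_rate) and
#' `background_rates`. JSON is used as the structured key-value format.
#'
#' @param path path to a JSON file.
#' @return a landscape.
#' @export
landscape_from_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  make_landscape(
    chromosomes = stats::setNames(as.numeric(cfg$chromosomes$length),
                                  cfg$chromosomes$name),
    chromatin = cfg$chromatin,
    hotspots = cfg$hotspots,
    background_rates = unlist(cfg$background_rates)
  )
}

#' @export
print.landscape <- function(x, ...) {
  cat("Recombination landscape:", length(x$chrom_len), "chromosome(s)\n")
  tl <- total_map_length(x)
  for (cn in names(x$chrom_len)) {
    cat(sprintf("  %s: %.3g Mbp, %.4g cM, %d hotspot(s)\n", cn,
                x$chrom_len[cn] / 1e6, tl[cn],
                sum(x$hotspots$chrom == cn)))
  }
  invisible(x)
}
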