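# Hotspot and coldspot calling on recombination-rate profiles, Tukey outlier
# filtering within chromatin class, and cross-population comparison. All
# coordinates are 0-based half-open (BED convention).

#' Chromatin map constructor/validator
#'
#' @param df data.frame `chrom`, `start`, `end`, `class` with classes
#'   `"euchromatic"`/`"heterochromatic"`, non-overlapping sorted intervals.
#' @return the validated data.frame, class `chromatin_map`.
#' @export
chromatin_map <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "class") %in% names(df)))
  if (any(df$end <= df$start)) stop("empty chromatin interval")
  for (cn in unique(df$chrom)) {
    d <- df[df$chrom == cn, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
      stop("overlapping chromatin intervals on ", cn)
  }
  structure(df[order(df$chrom, df$start), ], class = c("chromatin_map",
                                                       "data.frame"))
}

chromatin_class_at <- function(cmap, chrom, pos) {
  out <- rep(NA_character_, length(pos))
  for (cn in unique(chrom)) {
    d <- cmap[cmap$chrom == cn, , drop = FALSE]
    j <- chrom == cn
    i <- findInterval(pos[j], d$start)
    cls <- rep(NA_character_, sum(j))
    ok <- i >= 1 & i <= nrow(d)
    cls[ok] <- ifelse(pos[j][ok] < d$end[i[ok]], d$class[i[ok]],
                      NA_character_)
    out[j] <- cls
  }
  out
}

# Per-chromosome, per-class median rate: the background the fold threshold
# and coldspot threshold refer to.
class_background <- function(profile, cmap) {
  cls <- chromatin_class_at(cmap, profile$chrom, profile$pos)
  stats::aggregate(list(background = profile$rate),
                   by = list(chrom = profile$chrom, class = cls),
                   FUN = stats::median)
}

#' Call recombination hotspots from a rate profile
#'
#' A grid point is a peak iff its rate is strictly greater than every other
#' rate within `window` grid points on each side and at least `min_fold`
#' times the background (per-chromosome median rate of its chromatin class).
#' Hotspot boundaries extend outward from the peak while the rate stays at or
#' above `max(background, boundary_frac * peak_rate)`; overlapping candidate
#' intervals are merged keeping the higher peak.
#'
#' @param profile a `rate_profile`.
#' @param cmap a `chromatin_map` covering the profiled chromosomes.
#' @param window half-width of the peak comparison window, in grid points.
#' @param min_fold minimum peak rate as a multiple of the class background.
#' @param boundary_frac boundary threshold as a fraction of the peak rate.
#' @param population population label stored in the output.
#' @return a `hotspot_set` data.frame: `chrom`, `start`, `end`, `peak`,
#'   `peak_rate`, `mean_rate`, `size`, `chromatin`, `population`, `kind`.
#' @export
call_hotspots <- function(profile, cmap, window = 5, min_fold = 2,
                          boundary_frac = 0.5, population = "") {
  stopifnot(window >= 1)  # comparison window spans >= 3 grid points
  step <- attr(profile, "grid_step")
  bg_tab <- class_background(profile, cmap)
  recs <- list()
  for (cn in unique(profile$chrom)) {
    p <- profile[profile$chrom == cn, , drop = FALSE]
    r <- p$rate
    n <- length(r)
    cls <- chromatin_class_at(cmap, p$chrom, p$pos)
    bg <- stats::setNames(bg_tab$background[bg_tab$chrom == cn],
                          bg_tab$class[bg_tab$chrom == cn])
    thr <- min_fold * unname(bg[cls])
    cand <- which(!is.na(thr) & r >= thr & r > 0)
    peaks <- cand[vapply(cand, function(i) {
      lo <- max(1L, i - window); hi <- min(n, i + window)
      all(r[i] > r[seq(lo, hi)[seq(lo, hi) != i]])
    }, logical(1))]
    if (!length(peaks)) next
    iv <- t(vapply(peaks, function(i) {
      stop_lvl <- max(bg[cls[i]], boundary_frac * r[i])
      l <- i; while (l > 1L && r[l - 1L] >= stop_lvl) l <- l - 1L
      h <- i; while (h < n && r[h + 1L] >= stop_lvl) h <- h + 1L
      c(l, h)
    }, numeric(2)))
    df <- data.frame(chrom = cn,
                     start = p$pos[iv[, 1]],
                     end = p$pos[iv[, 2]] + step,
                     peak = p$pos[peaks],
                     peak_rate = r[peaks],
                     stringsAsFactors = FALSE)
    # merge overlapping candidates, keeping the higher peak's identity
    df <- df[order(df$start), , drop = FALSE]
    merged <- df[1, , drop = FALSE]
    if (nrow(df) > 1) for (k in 2:nrow(df)) {
      last <- nrow(merged)
      if (df$start[k] < merged$end[last]) {
        merged$end[last] <- max(merged$end[last], df$end[k])
        if (df$peak_rate[k] > merged$peak_rate[last]) {
          merged$peak[last] <- df$peak[k]
          merged$peak_rate[last] <- df$peak_rate[k]
        }
      } else merged <- rbind(merged, df[k, ])
    }
    merged$mean_rate <- vapply(seq_len(nrow(merged)), function(k) {
      mean(r[p$pos >= merged$start[k] & p$pos < merged$end[k]])
    }, numeric(1))
    recs[[cn]] <- merged
  }
  hs <- if (length(recs)) do.call(rbind, recs) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               peak = numeric(), peak_rate = numeric(), mean_rate = numeric())
  hs$size <- hs$end - hs$start
  hs$chromatin <- chromatin_class_at(cmap, hs$chrom, hs$peak)
  hs$population <- rep(population, nrow(hs))
  hs$kind <- rep("hotspot", nrow(hs))
  rownames(hs) <- NULL
  structure(hs, class = c("hotspot_set", "data.frame"),
            params = list(window = window, min_fold = min_fold,
                          boundary_frac = boundary_frac,
                          quantile_type = 7))
}

#' Tukey upper-fence size filter within chromatin class
#'
#' Within each chromatin class, records whose size exceeds
#' Q3 + 1.5 (Q3 - Q1) of the class size distribution are removed (linear
#' interpolation "type 7" quantiles). Classes with fewer than 4 records are
#' left unfiltered.
#'
#' @param hs a `hotspot_set`.
#' @return filtered `hotspot_set`; attribute `removed` holds the dropped rows.
#' @export
tukey_filter <- function(hs) {
  if (!nrow(hs)) return(hs)
  keep <- rep(TRUE, nrow(hs))
  for (cl in unique(hs$chromatin)) {
    i <- which(hs$chromatin %in% cl)
    if (length(i) < 4) next
    q <- stats::quantile(hs$size[i], c(0.25, 0.75), type = 7, names = FALSE)
    fence <- q[2] + 1.5 * (q[2] - q[1])
    keep[i] <- hs$size[i] <= fence
  }
  out <- hs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "params") <- attr(hs, "params")
  attr(out, "removed") <- hs[!keep, , drop = FALSE]
  class(out) <- class(hs)
  out
}

#' Call recombination coldspots
#'
#' Maximal runs of grid points whose rate is below `max_frac` times the class
#' background, of physical length at least `min_len_bp`.
#'
#' @inheritParams call_hotspots
#' @param max_frac rate threshold as a fraction of the class background.
#' @param min_len_bp minimum coldspot length in bp.
#' @return a `hotspot_set` with `kind = "coldspot"`; `peak` is the
#'   minimum-rate grid point.
#' @export
call_coldspots <- function(profile, cmap, max_frac = 0.2, min_len_bp = 0,
                           population = "") {
  stopifnot(max_frac > 0, max_frac < 1)
  step <- attr(profile, "grid_step")
  bg_tab <- class_background(profile, cmap)
  recs <- list()
  for (cn in unique(profile$chrom)) {
    p <- profile[profile$chrom == cn, , drop = FALSE]
    cls <- chromatin_class_at(cmap, p$chrom, p$pos)
    bg <- stats::setNames(bg_tab$background[bg_tab$chrom == cn],
                          bg_tab$class[bg_tab$chrom == cn])
    below <- p$rate < max_frac * unname(bg[cls])
    below[is.na(below)] <- FALSE
    rl <- rle(below)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    for (k in which(rl$values)) {
      l <- starts[k]; h <- ends[k]
      start <- p$pos[l]; end <- p$pos[h] + step
      if (end - start < min_len_bp) next
      imin <- l - 1L + which.min(p$rate[l:h])
      recs[[length(recs) + 1L]] <- data.frame(
        chrom = cn, start = start, end = end, peak = p$pos[imin],
        peak_rate = p$rate[imin],
        mean_rate = mean(p$rate[l:h]),
        stringsAsFactors = FALSE)
    }
  }
  cs <- if (length(recs)) do.call(rbind, recs) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               peak = numeric(), peak_rate = numeric(), mean_rate = numeric())
  cs$size <- cs$end - cs$start
  cs$chromatin <- chromatin_class_at(cmap, cs$chrom, cs$peak)
  cs$population <- rep(population, nrow(cs))
  cs$kind <- rep("coldspot", nrow(cs))
  rownames(cs) <- NULL
  structure(cs, class = c("hotspot_set", "data.frame"),
            params = list(max_frac = max_frac, min_len_bp = min_len_bp))
}

#' Assign chromatin class by peak position
#'
#' @param hs a `hotspot_set`.
#' @param cmap a `chromatin_map` (half-open intervals; a peak at an interval
#'   start belongs to that interval).
#' @return `hs` with `chromatin` reassigned.
#' @export
classify_chromatin <- function(hs, cmap) {
  hs$chromatin <- chromatin_class_at(cmap, hs$chrom, hs$peak)
  hs
}

#' Compare hotspot locations between two populations
#'
#' A pair is shared iff the two intervals, on the same chromosome, overlap by
#' at least `min_overlap_bp` (half-open coordinates: intervals that merely
#' touch do not overlap).
#'
#' @param a,b `hotspot_set`s.
#' @param min_overlap_bp minimum overlap in bp.
#' @return list: `pairs` (data.frame of indices and overlap bp), `n_shared`
#'   (a-records with >= 1 partner), `frac_a`, `frac_b`.
#' @export
compare_hotspots <- function(a, b, min_overlap_bp = 1) {
  ga <- GenomicRanges::GRanges(a$chrom,
                               IRanges::IRanges(a$start + 1, a$end))
  gb <- GenomicRanges::GRanges(b$chrom,
                               IRanges::IRanges(b$start + 1, b$end))
  ov <- GenomicRanges::findOverlaps(ga, gb, minoverlap = min_overlap_bp)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  wid <- GenomicRanges::width(GenomicRanges::pintersect(ga[qh], gb[sh]))
  pairs <- data.frame(i_a = qh, i_b = sh, overlap_bp = wid)
  list(pairs = pairs,
       n_shared = length(unique(qh)),
       frac_a = if (nrow(a)) length(unique(qh)) / nrow(a) else NA_real_,
       frac_b = if (nrow(b)) length(unique(sh)) / nrow(b) else NA_real_)
}

#' Summary table of a hotspot set
#'
#' Per population x chromatin class (plus a pooled `all` row): count, mean
#' and median size, size range, mean peak rate and mean interval intensity.
#'
#' @param hs a `hotspot_set`.
#' @return data.frame summary.
#' @export
summarize_hotspots <- function(hs) {
  one <- function(d, pop, cl) {
    data.frame(population = pop, chromatin = cl, n = nrow(d),
               mean_size = mean(d$size), median_size = stats::median(d$size),
               min_size = min(d$size), max_size = max(d$size),
               mean_peak_rate = mean(d$peak_rate),
               mean_intensity = mean(d$mean_rate),
               stringsAsFactors = FALSE)
  }
  if (!nrow(hs)) return(data.frame())
  rows <- list()
  for (pop in unique(hs$population)) {
    dp <- hs[hs$population == pop, , drop = FALSE]
    for (cl in unique(dp$chromatin))
      rows[[length(rows) + 1L]] <-
        one(dp[dp$chromatin %in% cl, , drop = FALSE], pop, cl)
    rows[[length(rows) + 1L]] <- one(dp, pop, "all")
  }
  if (length(unique(hs$population)) > 1)
    rows[[length(rows) + 1L]] <- one(hs, "all", "all")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.hotspot_set <- function(x, ...) {
  cat(sprintf("hotspot_set: %d record(s) (%s)\n", nrow(x),
              paste(unique(x$kind), collapse = "/")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}
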