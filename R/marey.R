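# Marey maps: cumulative genetic position (cM) against physical position
# (bp). The slope of a fitted cubic spline, rescaled to cM/Mbp, is the local
# recombination rate; a window "frequency metric" (delta cM / delta Mbp) is
# provided as the model-free alternative.

#' Enforce monotonicity of a Marey map
#'
#' Replaces per-chromosome cM by its isotonic (least-squares non-decreasing)
#' regression on physical position. Already-monotone input is returned
#' unchanged.
#'
#' @param map a `genetic_map`.
#' @return a `genetic_map` with non-decreasing cM per chromosome.
#' @export
isotonize <- function(map) {
  out <- map
  for (cn in unique(map$chrom)) {
    i <- which(map$chrom == cn)
    y <- map$cM[i]
    if (length(i) > 1 && any(diff(y) < 0))
      out$cM[i] <- stats::isoreg(map$pos[i], y)$yf
  }
  out
}

#' Fit a cubic spline to a Marey map
#'
#' With `smoothing = "interpolating"` a natural cubic spline passes through
#' every (bp, cM) point, matching the behaviour of an interpolating Marey
#' spline; `"gcv"` fits a smoothing spline with generalized cross-validation;
#' a numeric value is used as an explicit `spar` for [stats::smooth.spline()].
#'
#' @param map a `genetic_map` (isotonize first if two-point noise may have
#'   produced non-monotone cM).
#' @param smoothing `"gcv"`, `"interpolating"`, a numeric `spar`, or
#'   `list(df = n)` for an explicit equivalent-degrees-of-freedom target
#'   (a resolution-matched choice: df of about chromosome span / feature
#'   scale resolves features of that scale while suppressing finer
#'   two-point noise, which generalized cross-validation tends to track).
#' @return object of class `marey_spline`: per-chromosome prediction
#'   functions with first derivatives.
#' @export
fit_spline <- function(map, smoothing = "gcv") {
  fits <- lapply(unique(map$chrom), function(cn) {
    i <- which(map$chrom == cn)
    x <- map$pos[i]; y <- map$cM[i]
    keep <- !duplicated(x)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 4)
      stop("insufficient markers on ", cn, " (need >= 4)")
    if (identical(smoothing, "interpolating")) {
      f <- stats::splinefun(x, y, method = "natural")
      list(predict = function(xx, deriv = 0) f(xx, deriv = deriv),
           range = range(x), total_cM = max(y) - min(y))
    } else {
      ss <- if (is.list(smoothing))
        stats::smooth.spline(x, y, df = min(smoothing$df, length(x) - 1))
      else if (is.numeric(smoothing))
        stats::smooth.spline(x, y, spar = smoothing)
      else stats::smooth.spline(x, y, cv = FALSE)
      list(predict = function(xx, deriv = 0)
             stats::predict(ss, xx, deriv = deriv)$y,
           range = range(x), total_cM = max(y) - min(y))
    }
  })
  names(fits) <- unique(map$chrom)
  structure(list(fits = fits, smoothing = smoothing),
            class = "marey_spline")
}

#' Recombination-rate profile from a fitted Marey spline
#'
#' Evaluates the spline derivative on a uniform physical grid and converts to
#' cM/Mbp; negative derivatives are clamped to 0 and the clamped fraction is
#' recorded as a fit diagnostic.
#'
#' @param spline a `marey_spline`.
#' @param grid_step grid spacing in bp (default 10 kb, below typical
#'   euchromatic marker spacing).
#' @return a `rate_profile`: data.frame `chrom`, `pos`, `rate` with
#'   attributes `grid_step`, `method`, `smoothing`, `clamped_frac`,
#'   `total_cM` (per chromosome, from the underlying map).
#' @export
rate_profile <- function(spline, grid_step = 10000) {
  out <- lapply(names(spline$fits), function(cn) {
    f <- spline$fits[[cn]]
    grid <- seq(f$range[1], f$range[2], by = grid_step)
    d <- f$predict(grid, deriv = 1) * 1e6
    data.frame(chrom = cn, pos = grid, rate = pmax(d, 0),
               stringsAsFactors = FALSE)
  })
  raw_neg <- vapply(names(spline$fits), function(cn) {
    f <- spline$fits[[cn]]
    grid <- seq(f$range[1], f$range[2], by = grid_step)
    mean(f$predict(grid, deriv = 1) < 0)
  }, numeric(1))
  prof <- do.call(rbind, out)
  structure(prof,
            grid_step = grid_step, method = "spline",
            smoothing = spline$smoothing,
            clamped_frac = raw_neg,
            total_cM = vapply(spline$fits, function(f) f$total_cM, numeric(1)),
            class = c("rate_profile", "data.frame"))
}

#' Windowed recombination frequency metric
#'
#' The ratio of genetic to physical distance per fixed physical window:
#' rate = delta cM / delta Mbp, with cM at window edges taken from linear
#' interpolation of the Marey map. Values are reported at window midpoints.
#'
#' @param map a `genetic_map`.
#' @param window_bp window size in bp.
#' @return a `rate_profile` (method `"window"`); attribute `window_bp`.
#' @export
window_rate <- function(map, window_bp) {
  stopifnot(window_bp > 0)
  out <- lapply(unique(map$chrom), function(cn) {
    i <- which(map$chrom == cn)
    x <- map$pos[i]; y <- map$cM[i]
    lo <- min(x); hi <- max(x)
    edges <- seq(lo, hi, by = window_bp)
    if (edges[length(edges)] < hi) edges <- c(edges, hi)
    if (length(edges) < 2) edges <- c(lo, hi)  # window larger than span
    ycum <- stats::approx(x, y, xout = edges, rule = 2, ties = "ordered")$y
    mid <- (edges[-1] + edges[-length(edges)]) / 2
    w <- diff(edges)
    data.frame(chrom = cn, pos = mid, rate = diff(ycum) / (w / 1e6),
               width = w, stringsAsFactors = FALSE)
  })
  prof <- do.call(rbind, out)
  structure(prof,
            grid_step = window_bp, window_bp = window_bp, method = "window",
            total_cM = vapply(split(map$cM, map$chrom)[unique(map$chrom)],
                              function(v) max(v) - min(v), numeric(1)),
            class = c("rate_profile", "data.frame"))
}

#' Integrate a rate profile over each chromosome
#'
#' Trapezoidal rule for spline profiles, exact rectangle sum for window
#' profiles; the result should match the chromosome map length (the
#' conservation property of a Marey-based rate estimate).
#'
#' @param profile a `rate_profile`.
#' @return named numeric, cM per chromosome.
#' @export
integrate_rate <- function(profile) {
  method <- attr(profile, "method")
  vapply(unique(profile$chrom), function(cn) {
    p <- profile[profile$chrom == cn, , drop = FALSE]
    if (identical(method, "window")) {
      sum(p$rate * p$width / 1e6)
    } else {
      sum(diff(p$pos) * (p$rate[-1] + p$rate[-nrow(p)]) / 2) / 1e6
    }
  }, numeric(1))
}

#' @export
print.rate_profile <- function(x, ...) {
  cat(sprintf("rate_profile (%s): %d grid points, %d chromosome(s), max %.3g cM/Mbp\n",
              attr(x, "method"), nrow(x), length(unique(x$chrom)),
              max(x$rate)))
  invisible(x)
}
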