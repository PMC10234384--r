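# hotspot/coldspot calling, Tukey filtering, comparison, summaries

bump_profile <- function(base = 2, peak = 10, n = 200, at = 100,
                         halfwidth = 3, step = 10000) {
  p <- flat_profile(base, n, step)
  idx <- pmax(1, at - halfwidth):pmin(n, at + halfwidth)
  p$rate[idx] <- base + (peak - base) *
    (1 - abs(idx - at) / (halfwidth + 1))
  p
}

test_that("flat profiles yield no hotspots and no coldspots", {
  p <- flat_profile(2)
  cm <- all_euchromatic(p)
  expect_equal(nrow(call_hotspots(p, cm)), 0)
  expect_equal(nrow(call_coldspots(p, cm)), 0)
})

test_that("a single bump yields exactly one hotspot containing the apex", {
  p <- bump_profile()
  cm <- all_euchromatic(p)
  hs <- call_hotspots(p, cm)
  expect_equal(nrow(hs), 1)
  apex <- p$pos[100]
  expect_equal(hs$peak, apex)
  expect_true(hs$start <= apex && apex < hs$end)
  expect_equal(hs$size, hs$end - hs$start)
  expect_equal(hs$kind, "hotspot")
})

test_that("planted plateau hotspots are recovered from simulation", {
  ls <- make_landscape(
    c(chr1 = 8e6),
    hotspots = data.frame(chrom = "chr1", center = c(2e6, 4e6),
                          width = 2e5, peak_rate = 10),
    background_rates = c(euchromatic = 1))
  mk <- make_marker_grid(ls, 25000)
  cm <- chromatin_map(ls$chromatin)
  hits <- 0L
  for (seed in 1:20) {
    sim <- simulate_ril_population(ls, mk, n_lines = 1000, seed = seed)
    map <- isotonize(build_map(sim$genotypes, generation = 5))
    prof <- rate_profile(fit_spline(map, 0.65), 1e4)
    hs <- call_hotspots(prof, cm)
    ok <- all(vapply(c(2e6, 4e6), function(ctr)
      any(abs(hs$peak - ctr) <= 1e5), logical(1))) && nrow(hs) == 2
    hits <- hits + ok
  }
  expect_gte(hits, 18)
})

test_that("tukey_filter reproduces hand-computed type-7 fences", {
  hs <- structure(data.frame(
    chrom = "chr1", start = 0, end = 1,
    peak = 0, peak_rate = 1, mean_rate = 1,
    size = c(10, 20, 30, 40, 1000) * 1e3,
    chromatin = "euchromatic", population = "p", kind = "hotspot"),
    class = c("hotspot_set", "data.frame"))
  out <- tukey_filter(hs)
  # Q1 = 20, Q3 = 40, fence = 40 + 1.5*20 = 70 kb: the 1000-kb record goes
  expect_equal(out$size, c(10, 20, 30, 40) * 1e3)
  expect_equal(attr(out, "removed")$size, 1e6)

  hs$size <- rep(85e3, 5)
  expect_equal(nrow(tukey_filter(hs)), 5)      # IQR = 0, fence = Q3

  hs3 <- hs[1:3, ]; hs3$size <- c(1, 2, 1e9)
  class(hs3) <- class(hs)
  expect_equal(nrow(tukey_filter(hs3)), 3)     # < 4 records: unfiltered
})

test_that("tukey_filter agrees with a sort-and-fence oracle", {
  set.seed(9)
  for (i in 1:1000) {
    n <- sample(4:40, 1)
    sizes <- stats::rlnorm(n, 11, 1)
    hs <- structure(data.frame(
      chrom = "chr1", start = 0, end = sizes, peak = 0, peak_rate = 1,
      mean_rate = 1, size = sizes, chromatin = "euchromatic",
      population = "p", kind = "hotspot"),
      class = c("hotspot_set", "data.frame"))
    expect_identical(tukey_filter(hs)$size, sizes[tukey_keep_oracle(sizes)])
  }
})

test_that("coldspots are maximal low-rate runs of sufficient length", {
  p <- flat_profile(5, n = 300)
  p$rate[100:199] <- 0                         # 1-Mbp zero-rate gap
  cm <- all_euchromatic(p)
  cs <- call_coldspots(p, cm, max_frac = 0.2, min_len_bp = 5e5)
  expect_equal(nrow(cs), 1)
  expect_true(cs$start <= p$pos[100] && cs$end >= p$pos[199])
  expect_equal(cs$kind, "coldspot")
  # too-short runs are dropped
  expect_equal(nrow(call_coldspots(p, cm, min_len_bp = 2e6)), 0)
})

test_that("hotspots and coldspots never overlap", {
  set.seed(13)
  for (i in 1:100) {
    p <- flat_profile(5, n = 150)
    p$rate <- pmax(0, 5 + stats::rnorm(150, 0, 2))
    p$rate[sample(140, 3) + 5] <- stats::runif(3, 15, 30)
    cm <- all_euchromatic(p)
    hs <- call_hotspots(p, cm)
    cs <- call_coldspots(p, cm)
    if (!nrow(hs) || !nrow(cs)) next
    for (k in seq_len(nrow(hs)))
      expect_false(any(cs$chrom == hs$chrom[k] & cs$start < hs$end[k] &
                         hs$start[k] < cs$end))
  }
})

test_that("chromatin classification is half-open and partitions the set", {
  cmap <- chromatin_map(data.frame(
    chrom = "chr1", start = c(0, 1e6), end = c(1e6, 2e6),
    class = c("heterochromatic", "euchromatic")))
  hs <- structure(data.frame(
    chrom = "chr1", start = c(4e5, 9.9e5), end = c(6e5, 1.2e6),
    peak = c(5e5, 1e6), peak_rate = 1, mean_rate = 1, size = 2e5,
    chromatin = NA, population = "p", kind = "hotspot"),
    class = c("hotspot_set", "data.frame"))
  out <- classify_chromatin(hs, cmap)
  expect_equal(out$chromatin, c("heterochromatic", "euchromatic"))
  expect_equal(sum(out$chromatin == "euchromatic") +
                 sum(out$chromatin == "heterochromatic"), nrow(out))
})

test_that("compare_hotspots uses half-open overlap and is symmetric", {
  mk_hs <- function(start, end) structure(
    data.frame(chrom = "chr1", start = start, end = end,
               peak = (start + end) / 2, peak_rate = 1, mean_rate = 1,
               size = end - start, chromatin = "euchromatic",
               population = "p", kind = "hotspot"),
    class = c("hotspot_set", "data.frame"))
  a <- mk_hs(100e3, 200e3); b <- mk_hs(150e3, 250e3)
  expect_equal(compare_hotspots(a, b)$n_shared, 1)

  touch <- mk_hs(200e3, 300e3)
  expect_equal(compare_hotspots(a, touch)$n_shared, 0)

  idm <- compare_hotspots(a, a)
  expect_equal(idm$frac_a, 1); expect_equal(idm$frac_b, 1)

  # pair identity symmetric under swapping the sets
  set.seed(3)
  sx <- sort(sample(1e6, 5)) * 10; sy <- sort(sample(1e6, 5)) * 10
  x <- mk_hs(sx, sx + 5e4)
  y <- mk_hs(sy, sy + 5e4)
  pab <- compare_hotspots(x, y)$pairs
  pba <- compare_hotspots(y, x)$pairs
  expect_setequal(paste(pab$i_a, pab$i_b), paste(pba$i_b, pba$i_a))
})

test_that("summaries echo single records and compute class medians", {
  hs <- structure(data.frame(
    chrom = "chr1", start = 0, end = 85e3, peak = 1e3, peak_rate = 7,
    mean_rate = 6, size = 85e3, chromatin = "euchromatic",
    population = "WE", kind = "hotspot"),
    class = c("hotspot_set", "data.frame"))
  s <- summarize_hotspots(hs)
  expect_equal(s$n[1], 1)
  expect_equal(s$median_size[1], 85e3)
  expect_equal(s$mean_intensity[1], 6)

  hs3 <- hs[rep(1, 3), ]; class(hs3) <- class(hs)
  s3 <- summarize_hotspots(hs3)
  expect_equal(s3$mean_size[1], 85e3)
  expect_equal(s3$median_size[1], 85e3)
})
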