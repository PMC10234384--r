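# simulator: landscape construction, meiosis, SSD population genetics

test_that("landscape map lengths follow the piecewise integral", {
  expect_equal(unname(total_map_length(uniform_landscape(5e7, 5))), 250)

  ls2 <- make_landscape(c(chr1 = 1e6),
                        hotspots = data.frame(chrom = "chr1", center = 5e5,
                                              width = 1e5, peak_rate = 10),
                        background_rates = c(euchromatic = 0))
  expect_equal(unname(total_map_length(ls2)), 1)

  # 10 Mbp at 1 cM/197 kb plus 10 Mbp at 1 cM/3.5 Mb
  ls3 <- make_landscape(
    c(chr1 = 2e7),
    chromatin = data.frame(chrom = "chr1", start = c(0, 1e7),
                           end = c(1e7, 2e7),
                           class = c("euchromatic", "heterochromatic")))
  expect_equal(unname(total_map_length(ls3)), 10 / 0.197 + 10 / 3.5,
               tolerance = 5e-4)
})

test_that("landscape validation rejects malformed specs", {
  expect_error(make_landscape(c(chr1 = -5)), "lengths")
  expect_error(make_landscape(c(chr1 = 1e6),
                              hotspots = data.frame(chrom = "chr1",
                                                    center = 1e6,
                                                    width = 2e5,
                                                    peak_rate = 10)),
               "outside")
  expect_error(make_landscape(c(chr1 = 1e6),
                              hotspots = data.frame(chrom = "chr1",
                                                    center = c(4e5, 4.5e5),
                                                    width = 2e5,
                                                    peak_rate = 10)),
               "overlapping")
  expect_error(make_landscape(c(chr1 = 1e6),
                              chromatin = data.frame(chrom = "chr1",
                                                     start = 0, end = 5e5,
                                                     class = "euchromatic")),
               "tile")
})

test_that("cumulative map is the non-decreasing integral of the rate", {
  ls <- acceptance_landscape()
  for (cn in names(ls$chrom_len)) {
    x <- seq(0, ls$chrom_len[[cn]], length.out = 500)
    cm <- landscape_cM(ls, cn, x)
    expect_true(all(diff(cm) >= 0))
    # numerical integral of the rate matches the analytic cumulative map
    mid <- (x[-1] + x[-length(x)]) / 2
    num <- cumsum(landscape_rate(ls, cn, mid) * diff(x) / 1e6)
    expect_equal(cm[-1], num + cm[1], tolerance = 0.05)
    # inverse round-trips
    u <- seq(0, max(cm), length.out = 50)
    expect_equal(landscape_cM(ls, cn, rilrec:::landscape_inv_cM(ls, cn, u)),
                 u, tolerance = 1e-8)
  }
})

test_that("landscape JSON config round-trips", {
  ls <- acceptance_landscape()
  cfg <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    chromosomes = data.frame(name = names(ls$chrom_len),
                             length = unname(ls$chrom_len)),
    chromatin = ls$chromatin,
    hotspots = ls$hotspots[c("chrom", "center", "width", "peak_rate")],
    background_rates = as.list(ls$background_rates)), cfg,
    auto_unbox = TRUE, digits = NA)
  ls2 <- landscape_from_config(cfg)
  expect_equal(total_map_length(ls2), total_map_length(ls))
  expect_equal(ls2$per_chrom$chr1$segments, ls$per_chrom$chr1$segments)
})

test_that("zero-rate landscape yields intact parental gametes", {
  ls <- uniform_landscape(1e6, 0)
  set.seed(1)
  parent <- rilrec:::founder_parent("chr1")
  for (i in 1:20) {
    m <- simulate_meiosis(parent, ls)
    expect_equal(nrow(m$crossovers), 0L)
    expect_length(m$gamete$chr1$breaks, 0)
    expect_true(m$gamete$chr1$start %in% c(0L, 1L))
  }
})

test_that("crossover count is Poisson with mean = map length in Morgans", {
  ls <- uniform_landscape(1e7, 10)   # 100 cM -> 1 Morgan
  set.seed(7)
  parent <- rilrec:::founder_parent("chr1")
  n <- 1e5
  counts <- vapply(seq_len(n),
                   function(i) nrow(simulate_meiosis(parent, ls)$crossovers),
                   numeric(1))
  se <- sqrt(1 / n)                  # Poisson var = mean = 1
  expect_lt(abs(mean(counts) - 1), 3 * se)
  expect_lt(abs(stats::var(counts) - 1), 0.05)
})

test_that("crossover positions are uniform on a uniform landscape", {
  ls <- uniform_landscape(1e7, 20)
  set.seed(11)
  parent <- rilrec:::founder_parent("chr1")
  pos <- unlist(lapply(seq_len(5000), function(i)
    simulate_meiosis(parent, ls)$crossovers$pos))
  pos <- pos[seq_len(min(length(pos), 1e4))]
  expect_gt(stats::ks.test(pos / 1e7, "punif")$p.value, 0.01)
})

test_that("F5 heterozygosity, symmetry and call conservation hold", {
  ls <- uniform_landscape(2e6, 5)
  mk <- data.frame(id = c("m1", "m2"), chrom = "chr1", pos = c(5e5, 1.5e6))
  n <- 1e4
  sim <- simulate_ril_population(ls, mk, n_lines = n, seed = 5)
  cc <- sim$genotypes$calls
  # every call present: conservation P(A)+P(B)+P(H)=1
  expect_false(anyNA(cc))
  # E[P(H)] = 2^-(k-1) = 6.25% at F5
  ph <- mean(cc == "H")
  se <- sqrt(0.0625 * 0.9375 / (2 * n))
  expect_lt(abs(ph - 0.0625), 3 * se)
  # A/B exchangeable without distortion
  fa <- mean(cc == "A"); fb <- mean(cc == "B")
  expect_lt(abs(fa - fb), 3 * sqrt(0.5 * 0.5 / n))
})

test_that("zero-rate landscape gives only parental two-locus genotypes", {
  ls <- uniform_landscape(1e6, 0)
  mk <- data.frame(id = c("m1", "m2"), chrom = "chr1", pos = c(2e5, 8e5))
  sim <- simulate_ril_population(ls, mk, n_lines = 500, seed = 3)
  cc <- sim$genotypes$calls
  expect_identical(unname(cc[1, ]), unname(cc[2, ]))  # fully linked
  expect_equal(nrow(sim$truth$crossovers), 0L)
})

test_that("observed R converges to Haldane-Waddington 2r/(1+2r) at F-infinity", {
  # uniform rate; markers 1.116 cM apart in Haldane distance gives r = 0.1
  d_M <- -log(1 - 2 * 0.1) / 2            # Morgans for r = 0.1
  ls <- uniform_landscape(1e6, d_M * 100 / 0.5)  # 0.5 Mbp between markers
  mk <- data.frame(id = c("m1", "m2"), chrom = "chr1", pos = c(2.5e5, 7.5e5))
  n <- 1e4
  sim <- simulate_ril_population(ls, mk, n_lines = n,
                                 final_generation = 26, seed = 9)
  cc <- sim$genotypes$calls
  hom <- cc[1, ] %in% c("A", "B") & cc[2, ] %in% c("A", "B")
  R <- sum(cc[1, hom] != cc[2, hom]) / sum(hom)
  target <- 2 * 0.1 / (1 + 2 * 0.1)
  se <- sqrt(target * (1 - target) / sum(hom))
  expect_lt(abs(R - target), 3 * se)
})

test_that("identical seed reproduces the genotype matrix exactly", {
  ls <- acceptance_landscape()
  mk <- make_marker_grid(ls, 2e6)
  a <- simulate_ril_population(ls, mk, n_lines = 30, seed = 123,
                               missing_rate = 0.05)
  b <- simulate_ril_population(ls, mk, n_lines = 30, seed = 123,
                               missing_rate = 0.05)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$truth$crossovers, b$truth$crossovers)
  expect_equal(a$truth$seed, 123)
})

test_that("missingness is injected at the requested rate", {
  ls <- uniform_landscape(1e7, 2)
  mk <- make_marker_grid(ls, 5e5)
  sim <- simulate_ril_population(ls, mk, n_lines = 300, seed = 2,
                                 missing_rate = 0.2)
  m <- mean(is.na(sim$genotypes$calls))
  expect_lt(abs(m - 0.2), 3 * sqrt(0.2 * 0.8 / length(sim$genotypes$calls)))
})

test_that("gamete-level distortion skews allele frequency at the locus", {
  ls <- uniform_landscape(1e6, 2)
  mk <- data.frame(id = "m1", chrom = "chr1", pos = 5e5)
  dist <- data.frame(chrom = "chr1", pos = 5e5, allele = "A", weight = 3)
  sim <- simulate_ril_population(ls, mk, n_lines = 800, seed = 17,
                                 distortion = dist)
  cc <- sim$genotypes$calls
  fa <- sum(cc == "A"); fb <- sum(cc == "B")
  expect_gt(fa / (fa + fb), 0.6)
  # and the QC chi-square filter catches it
  expect_lt(segregation_pvalue(fa, fb), 0.01)
})

test_that("markers outside the chromosome are rejected", {
  ls <- uniform_landscape(1e6, 1)
  mk <- data.frame(id = "m1", chrom = "chr1", pos = 2e6)
  expect_error(simulate_ril_population(ls, mk, n_lines = 2, seed = 1),
               "outside")
})
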