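# gene-region annotation, feature windows, logistic association

mk_hs <- function(peaks, chrom = "chr1") structure(
  data.frame(chrom = chrom, start = peaks - 5e3, end = peaks + 5e3,
             peak = peaks, peak_rate = 10, mean_rate = 6, size = 1e4,
             chromatin = "euchromatic", population = "p", kind = "hotspot",
             stringsAsFactors = FALSE),
  class = c("hotspot_set", "data.frame"))

test_that("gene-region categories follow the documented precedence", {
  # gene 1000-9999 (0-based): 5'UTR 1000-1999, CDS 1800-5999 (overlap ->
  # composite), exon 1000-5999, intron 6000-8999, 3'UTR none here
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = c(1001, 1001, 1801, 1001, 9001),
    end = c(10000, 2000, 6000, 6000, 9800)))
  gr$type <- c("gene", "five_prime_UTR", "CDS", "exon", "three_prime_UTR")

  hs <- mk_hs(c(7000,          # inside gene, outside exon -> intron
                50000,         # outside all genes -> intergenic
                1900,          # 5'UTR and CDS -> composite
                1200,          # 5'UTR only
                4000,          # CDS only
                9300))         # 3'UTR (outside gene span here -> still UTR)
  out <- annotate_gene_region(hs, gr)
  expect_equal(out$gene_region,
               c("intron", "intergenic", "5'UTR/CDS", "5'UTR", "CDS",
                 "3'UTR"))
  # categories partition the set
  expect_equal(sum(table(out$gene_region)), nrow(hs))
})

test_that("feature windows conserve intersection length", {
  hs <- mk_hs(250e3)
  te <- data.frame(chrom = "chr1",
                   start = c(0, 150e3, 420e3),
                   end = c(100e3, 170e3, 520e3),
                   class = "LTR")
  ft <- make_feature_table(hs, NULL, te, c(chr1 = 1e6), window_bp = 1e5)
  expect_equal(nrow(ft), 10)
  expect_equal(ft$LTR[1], 1.0)                   # fully covered window
  expect_equal(sum(ft$LTR * 1e5), 100e3 + 20e3 + 100e3)
  expect_equal(ft$status[3], "hotspot")
  expect_true(all(ft$status[-3] == "background"))

  ft0 <- make_feature_table(hs, NULL,
                            data.frame(chrom = "chr1", start = 1, end = 2,
                                       class = "none")[0, ],
                            c(chr1 = 1e6), window_bp = 1e5)
  expect_true(all(ft0$status %in% c("hotspot", "background")))
})

test_that("coldspot status yields to hotspot precedence", {
  hs <- mk_hs(250e3)
  cs <- mk_hs(c(250e3, 650e3)); cs$kind <- "coldspot"
  te <- data.frame(chrom = "chr1", start = 0, end = 1e4, class = "LTR")
  ft <- make_feature_table(hs, cs, te, c(chr1 = 1e6), window_bp = 1e5)
  expect_equal(ft$status[3], "hotspot")
  expect_equal(ft$status[7], "coldspot")
})

test_that("GLM slope equals the 2x2 log odds ratio for binary covariates", {
  mk_ft <- function(n11, n10, n01, n00) {
    # covariate present: n11 hotspot, n10 other; absent: n01 / n00
    structure(data.frame(
      chrom = "chr1", start = 0, end = 1,
      status = rep(c("hotspot", "background", "hotspot", "background"),
                   c(n11, n10, n01, n00)),
      x = rep(c(1, 1, 0, 0), c(n11, n10, n01, n00))),
      class = c("feature_table", "data.frame"))
  }
  res <- logistic_assoc(mk_ft(20, 80, 5, 95), "x")
  expect_equal(res$beta, log((20 * 95) / (80 * 5)), tolerance = 1e-6)
  expect_equal(res$beta, log(4.75), tolerance = 1e-6)
  expect_equal(res$flag, "ok")

  # property: 200 random tables without zero cells
  set.seed(14)
  for (i in 1:200) {
    n <- sample(20:60, 4, replace = TRUE)
    r <- logistic_assoc(mk_ft(n[1], n[2], n[3], n[4]), "x")
    expect_equal(r$beta, log((n[1] * n[4]) / (n[2] * n[3])),
                 tolerance = 1e-6)
  }
})

test_that("Wald P is invariant to covariate rescaling", {
  set.seed(15)
  ft <- structure(data.frame(
    chrom = "chr1", start = 0, end = 1,
    status = sample(c("hotspot", "background"), 300, TRUE, c(0.3, 0.7)),
    x = stats::runif(300)), class = c("feature_table", "data.frame"))
  ft$x10 <- 10 * ft$x
  a <- logistic_assoc(ft, "x"); b <- logistic_assoc(ft, "x10")
  expect_equal(a$p, b$p, tolerance = 1e-9)
  expect_equal(a$beta, 10 * b$beta, tolerance = 1e-6)
})

test_that("degenerate designs are rejected or flagged", {
  ft <- structure(data.frame(
    chrom = "chr1", start = 0, end = 1,
    status = rep(c("hotspot", "background"), each = 50),
    const = 1,
    sep = rep(c(1, 0), each = 50)),
    class = c("feature_table", "data.frame"))
  expect_error(logistic_assoc(ft, "const"), "constant")
  expect_error(logistic_assoc(ft, "missing_col"), "unknown feature")
  r <- logistic_assoc(ft, "sep")
  expect_equal(r$flag, "separation")
  expect_true(is.na(r$p))

  few <- ft[c(1:5, 51:99), ]; class(few) <- class(ft)
  expect_error(logistic_assoc(few, "sep"), ">= 10")
})

test_that("null slope estimates are consistent", {
  set.seed(16)
  cover <- 0L
  for (i in 1:100) {
    ft <- structure(data.frame(
      chrom = "chr1", start = 0, end = 1,
      status = sample(c("hotspot", "background"), 400, TRUE, c(0.25, 0.75)),
      x = stats::rnorm(400)), class = c("feature_table", "data.frame"))
    r <- logistic_assoc(ft, "x")
    cover <- cover + (abs(r$beta) < 3 * r$se)
  }
  expect_gte(cover, 95)
})

test_that("motif intensity test behaves at the extremes", {
  hs <- mk_hs(seq(1e5, 1e6, by = 1e5))
  hs$mean_rate <- rep(6, nrow(hs))
  same <- motif_intensity_test(hs, rep(c(TRUE, FALSE), 5))
  expect_equal(same$p, 1)

  set.seed(17)
  hs2 <- mk_hs(seq(1e5, 1e7, by = 1e5))
  grp <- rep(c(TRUE, FALSE), each = 50)
  hs2$mean_rate <- stats::rnorm(100, 6, 0.5) + ifelse(grp, 5, 0) # 10 SD shift
  shifted <- motif_intensity_test(hs2, grp)
  expect_lt(shifted$p, 1e-6)
  expect_gt(shifted$mean_with, shifted$mean_without)
})
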