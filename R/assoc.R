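# Association of hotspot/coldspot status with genomic features: gene-region
# annotation of hotspot peaks and binomial logistic regression of window
# status on feature coverage, with a Wald test on the covariate.

#' Annotate hotspot peaks with gene-region categories
#'
#' Assigns each hotspot peak one of: `5'UTR/CDS`, `3'UTR/CDS`, `5'UTR`,
#' `3'UTR`, `CDS`, `intron` (inside a gene but outside any exon feature) or
#' `intergenic`, by that precedence, using the feature interval containing
#' the peak position.
#'
#' @param hs a `hotspot_set`.
#' @param gff a GFF3 path or a `GRanges` (as from [read_intervals()] with
#'   `format = "GFF3"` keeping a `type` column).
#' @return `hs` with an added `gene_region` column.
#' @export
annotate_gene_region <- function(hs, gff) {
  gr <- if (is.character(gff)) rtracklayer::import(gff, format = "gff3")
        else gff
  type <- as.character(gr$type)
  peak <- GenomicRanges::GRanges(hs$chrom,
                                 IRanges::IRanges(hs$peak + 1, hs$peak + 1))
  inside <- function(what) {
    sel <- gr[type %in% what]
    IRanges::overlapsAny(peak, sel)
  }
  in5 <- inside("five_prime_UTR")
  in3 <- inside("three_prime_UTR")
  incds <- inside("CDS")
  inexon <- inside(c("exon", "CDS", "five_prime_UTR", "three_prime_UTR"))
  ingene <- inside(c("gene", "mRNA"))
  cat_ <- rep("intergenic", nrow(hs))
  cat_[ingene & !inexon] <- "intron"
  cat_[incds] <- "CDS"
  cat_[in3] <- "3'UTR"
  cat_[in5] <- "5'UTR"
  cat_[in3 & incds] <- "3'UTR/CDS"
  cat_[in5 & incds] <- "5'UTR/CDS"
  hs$gene_region <- cat_
  hs
}

#' Tile the genome into status/feature windows for the regression
#'
#' Windows of `window_bp` tile each chromosome. A window's status is
#' `hotspot` if it overlaps any hotspot, else `coldspot` if it overlaps any
#' coldspot, else `background`. Each feature class gets a column with the
#' fraction of the window covered by intervals of that class (or `presence`
#' coding, 0/1).
#'
#' @param hs,coldspots `hotspot_set`s (coldspots may be `NULL`).
#' @param features data.frame `chrom`, `start`, `end`, `class` (0-based
#'   half-open), e.g. transposable-element annotations.
#' @param chrom_len named numeric of chromosome lengths (bp).
#' @param window_bp window size.
#' @param coding `"coverage"` (fraction covered) or `"presence"` (0/1).
#' @return a `feature_table` data.frame.
#' @export
make_feature_table <- function(hs, coldspots = NULL, features, chrom_len,
                               window_bp = 100000,
                               coding = c("coverage", "presence")) {
  coding <- match.arg(coding)
  wins <- do.call(rbind, lapply(names(chrom_len), function(cn) {
    s <- seq(0, chrom_len[[cn]] - 1, by = window_bp)
    data.frame(chrom = cn, start = s, end = pmin(s + window_bp,
                                                 chrom_len[[cn]]),
               stringsAsFactors = FALSE)
  }))
  gw <- GenomicRanges::GRanges(wins$chrom,
                               IRanges::IRanges(wins$start + 1, wins$end))
  status <- rep("background", nrow(wins))
  overlaps_set <- function(set) {
    if (is.null(set) || !nrow(set)) return(rep(FALSE, nrow(wins)))
    IRanges::overlapsAny(gw, GenomicRanges::GRanges(
      set$chrom, IRanges::IRanges(set$start + 1, set$end)))
  }
  status[overlaps_set(coldspots)] <- "coldspot"
  status[overlaps_set(hs)] <- "hotspot"   # hotspot precedence
  wins$status <- status
  for (cl in unique(features$class)) {
    f <- features[features$class == cl, , drop = FALSE]
    gf <- GenomicRanges::reduce(GenomicRanges::GRanges(
      f$chrom, IRanges::IRanges(f$start + 1, f$end)))
    ov <- GenomicRanges::findOverlaps(gw, gf)
    wid <- GenomicRanges::width(GenomicRanges::pintersect(
      gw[S4Vectors::queryHits(ov)], gf[S4Vectors::subjectHits(ov)]))
    cov <- numeric(nrow(wins))
    tot <- tapply(wid, S4Vectors::queryHits(ov), sum)
    cov[as.integer(names(tot))] <- tot
    wins[[cl]] <- if (coding == "coverage")
      cov / (wins$end - wins$start) else as.numeric(cov > 0)
  }
  structure(wins, window_bp = window_bp, coding = coding,
            class = c("feature_table", "data.frame"))
}

#' Logistic-regression association of window status with a feature
#'
#' Fits logit P(status = target) = b0 + b1 x by binomial GLM (iteratively
#' reweighted least squares) and reports the covariate effect with its Wald
#' statistic b1/SE and a two-sided P from the normal reference (the
#' large-sample equivalent of a t test on the covariate).
#'
#' @param ft a `feature_table`.
#' @param feature feature column name.
#' @param contrast `"hotspot"` or `"coldspot"` (target status vs all other
#'   windows).
#' @return data.frame: `feature`, `contrast`, `beta`, `se`, `statistic`,
#'   `p`, `n`, `method`, `flag` (`"ok"` or `"separation"`, P omitted when
#'   separated).
#' @export
logistic_assoc <- function(ft, feature, contrast = c("hotspot", "coldspot")) {
  contrast <- match.arg(contrast)
  x <- ft[[feature]]
  if (is.null(x)) stop("unknown feature: ", feature)
  y <- as.integer(ft$status == contrast)
  if (sum(y) < 10 || sum(1 - y) < 10)
    stop("need >= 10 windows in each status group")
  if (stats::var(x) == 0) stop("constant covariate")
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial(),
                                     control = stats::glm.control(
                                       epsilon = 1e-8, maxit = 50)))
  co <- summary(fit)$coefficients
  beta <- co["x", "Estimate"]; se <- co["x", "Std. Error"]
  sep <- !fit$converged || abs(beta) > 15 || se > 100
  data.frame(feature = feature, contrast = contrast,
             beta = beta, se = se,
             statistic = if (sep) NA_real_ else beta / se,
             p = if (sep) NA_real_ else
               2 * stats::pnorm(-abs(beta / se)),
             n = length(y), method = "wald_t",
             flag = if (sep) "separation" else "ok",
             stringsAsFactors = FALSE)
}

#' Compare hotspot intensity by motif presence
#'
#' Welch two-sample t test of hotspot interval intensity (mean cM/Mbp)
#' between hotspots with and without a motif.
#'
#' @param hs a `hotspot_set`.
#' @param motif_present logical vector along `hs` rows.
#' @return list `mean_with`, `mean_without`, `statistic`, `p`.
#' @export
motif_intensity_test <- function(hs, motif_present) {
  stopifnot(length(motif_present) == nrow(hs))
  a <- hs$mean_rate[motif_present]
  b <- hs$mean_rate[!motif_present]
  if (!length(a) || !length(b))
    return(list(mean_with = mean(a), mean_without = mean(b),
                statistic = NA_real_, p = NA_real_))
  tt <- tryCatch(stats::t.test(a, b),
                 error = function(e) list(statistic = 0, p.value = 1))
  list(mean_with = mean(a), mean_without = mean(b),
       statistic = unname(tt$statistic), p = unname(tt$p.value))
}
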