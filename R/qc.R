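# Marker quality control: missingness filter, segregation-distortion filter,
# duplicate-pattern collapse, applied in that order.

#' Remove markers with too much missing data
#'
#' A marker is removed iff its missing fraction is strictly greater than
#' `max_missing` (the rule is ">10%", so exactly 10% is retained).
#'
#' @param gm a `genotype_matrix`.
#' @param max_missing maximum tolerated missing fraction.
#' @return filtered `genotype_matrix` with attribute `removed` (marker ids).
#' @export
filter_missing <- function(gm, max_missing = 0.10) {
  stopifnot(inherits(gm, "genotype_matrix"),
            max_missing >= 0, max_missing < 1)
  if (!nrow(gm$markers)) stop("empty genotype matrix")
  frac <- rowMeans(is.na(gm$calls))
  keep <- frac <= max_missing
  out <- subset_markers(gm, keep)
  attr(out, "removed") <- gm$markers$id[!keep]
  out
}

#' Remove markers with significant segregation distortion
#'
#' Per marker, homozygous A and B counts are tested against the Mendelian 1:1
#' expectation with a 1-df chi-square goodness-of-fit test (heterozygous and
#' missing calls excluded); the marker is removed iff P < `alpha`. With
#' `df2 = TRUE` a 2-df variant tests AA:H:BB against the F5 expectation
#' (0.46875 : 0.0625 : 0.46875), using the generation implied by
#' `expected_het = 2^-(k-1)`.
#'
#' @param gm a `genotype_matrix`.
#' @param alpha significance level.
#' @param df2 use the 2-df AA:H:BB variant.
#' @param expected_het expected heterozygote frequency for the 2-df variant.
#' @return filtered `genotype_matrix`; attributes `removed` and
#'   `uninformative` list marker ids (the latter had <2 informative calls and
#'   are also removed).
#' @export
filter_segregation <- function(gm, alpha = 0.01, df2 = FALSE,
                               expected_het = 0.0625) {
  stopifnot(inherits(gm, "genotype_matrix"), alpha > 0, alpha < 1)
  nA <- rowSums(gm$calls == "A", na.rm = TRUE)
  nB <- rowSums(gm$calls == "B", na.rm = TRUE)
  nH <- rowSums(gm$calls == "H", na.rm = TRUE)
  p <- segregation_pvalue(nA, nB, nH, df2 = df2, expected_het = expected_het)
  uninformative <- if (df2) (nA + nB + nH) < 2 else (nA + nB) < 2
  keep <- !uninformative & p >= alpha
  out <- subset_markers(gm, keep)
  attr(out, "removed") <- gm$markers$id[!keep & !uninformative]
  attr(out, "uninformative") <- gm$markers$id[uninformative]
  out
}

#' Segregation-distortion chi-square P-values
#'
#' @param nA,nB,nH homozygous A, homozygous B and heterozygous call counts.
#' @inheritParams filter_segregation
#' @return vector of P-values (`NA` where the test is undefined).
#' @export
segregation_pvalue <- function(nA, nB, nH = 0, df2 = FALSE,
                               expected_het = 0.0625) {
  if (df2) {
    n <- nA + nB + nH
    ph <- expected_het
    e <- cbind(n * (1 - ph) / 2, n * (1 - ph) / 2, n * ph)
    o <- cbind(nA, nB, nH)
    chi <- rowSums((o - e)^2 / e)
    stats::pchisq(chi, df = 2, lower.tail = FALSE)
  } else {
    n <- nA + nB
    chi <- (nA - nB)^2 / n
    stats::pchisq(chi, df = 1, lower.tail = FALSE)
  }
}

#' Collapse markers with identical segregation patterns
#'
#' Markers whose call vectors are identical (missing included as part of the
#' pattern) are grouped; the physically first marker of each group is
#' retained.
#'
#' @param gm a `genotype_matrix`.
#' @return filtered `genotype_matrix` with attribute `bins`: a named list
#'   mapping each retained marker id to the ids it absorbed (including
#'   itself), for groups of size > 1.
#' @export
collapse_identical <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  pat <- apply(gm$calls, 1L, function(v) paste(ifelse(is.na(v), "-", v),
                                               collapse = ""))
  # markers are stored in (chrom, pos) order, so the first of each duplicate
  # group is the physically first
  first <- !duplicated(pat)
  out <- subset_markers(gm, first)
  grp <- split(gm$markers$id, match(pat, pat[first]))
  names(grp) <- gm$markers$id[first]
  bins <- grp[lengths(grp) > 1]
  attr(out, "bins") <- bins
  out
}

#' Run the full marker QC chain
#'
#' Applies [filter_missing()], [filter_segregation()] and
#' [collapse_identical()] in order and returns the filtered matrix plus an
#' accounting report that partitions the input markers.
#'
#' @inheritParams filter_missing
#' @inheritParams filter_segregation
#' @return list with `genotypes` (filtered `genotype_matrix`) and `report`
#'   (class `qc_report`).
#' @export
run_qc <- function(gm, max_missing = 0.10, alpha = 0.01, df2 = FALSE) {
  g1 <- filter_missing(gm, max_missing)
  g2 <- filter_segregation(g1, alpha, df2 = df2)
  g3 <- collapse_identical(g2)
  reasons <- c(
    stats::setNames(rep("missing", length(attr(g1, "removed"))),
                    attr(g1, "removed")),
    stats::setNames(rep("distortion", length(attr(g2, "removed"))),
                    attr(g2, "removed")),
    stats::setNames(rep("uninformative", length(attr(g2, "uninformative"))),
                    attr(g2, "uninformative")),
    stats::setNames(rep("duplicate", length(unlist(attr(g3, "bins"))) -
                          length(attr(g3, "bins"))),
                    setdiff(unlist(attr(g3, "bins")), names(attr(g3, "bins"))))
  )
  report <- structure(list(
    n_input = nrow(gm$markers),
    n_removed_missing = length(attr(g1, "removed")),
    n_removed_distortion = length(attr(g2, "removed")) +
      length(attr(g2, "uninformative")),
    n_collapsed = nrow(g2$markers) - nrow(g3$markers),
    n_retained = nrow(g3$markers),
    reasons = reasons,
    bins = attr(g3, "bins"),
    alpha = alpha, max_missing = max_missing, df2 = df2
  ), class = "qc_report")
  list(genotypes = g3, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("QC report: %d markers in -> %d retained\n",
                     "  removed >%g%% missing: %d\n",
                     "  removed distorted (P<%g%s): %d\n",
                     "  collapsed duplicates: %d\n"),
              x$n_input, x$n_retained, 100 * x$max_missing,
              x$n_removed_missing, x$alpha,
              if (x$df2) ", 2 df" else ", 1 df", x$n_removed_distortion,
              x$n_collapsed))
  invisible(x)
}

subset_markers <- function(gm, keep) {
  out <- gm
  out$markers <- gm$markers[keep, , drop = FALSE]
  rownames(out$markers) <- NULL
  out$calls <- gm$calls[keep, , drop = FALSE]
  out
}
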