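# Readers and writers. Internal coordinates are 0-based half-open
# everywhere; GFF3 (1-based inclusive) is converted at the boundary.

#' Read a genotype TSV
#'
#' Expected layout: header `id`, `chrom`, `pos`, then one column per line;
#' calls in `A`/`B`/`H`/`-`.
#'
#' @param path TSV path.
#' @param population population label to attach.
#' @return a `genotype_matrix`. Rows out of (chrom, pos) order are sorted
#'   with a warning; duplicate ids, non-integer positions or unknown call
#'   symbols are errors naming the offending cell.
#' @export
read_genotypes <- function(path, population = "") {
  dt <- data.table::fread(path, sep = "\t", colClasses = "character",
                          header = TRUE, data.table = FALSE)
  need <- c("id", "chrom", "pos")
  if (!all(need %in% names(dt)[1:3]))
    stop("genotype file must start with columns id, chrom, pos")
  pos <- suppressWarnings(as.numeric(dt$pos))
  badp <- which(is.na(pos) | pos != floor(pos))
  if (length(badp))
    stop("non-integer position at row ", badp[1])
  if (anyDuplicated(dt$id))
    stop("duplicate marker id: ", dt$id[anyDuplicated(dt$id)])
  line_cols <- setdiff(names(dt), need)
  calls <- as.matrix(dt[, line_cols, drop = FALSE])
  bad <- which(!(calls %in% c("A", "B", "H", "-")))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(calls))
    stop(sprintf("unknown call '%s' at marker %s, line %s",
                 calls[bad[1]], dt$id[rc[1]], line_cols[rc[2]]))
  }
  calls[calls == "-"] <- NA_character_
  markers <- data.frame(id = dt$id, chrom = dt$chrom, pos = pos,
                        stringsAsFactors = FALSE)
  ord <- order(markers$chrom, markers$pos)
  if (!identical(ord, seq_len(nrow(markers)))) {
    warning("markers re-sorted by (chrom, pos)")
    markers <- markers[ord, , drop = FALSE]
    calls <- calls[ord, , drop = FALSE]
  }
  new_genotype_matrix(markers, calls, population = population)
}

#' Write a genotype TSV
#'
#' @param gm a `genotype_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path) {
  calls <- gm$calls
  calls[is.na(calls)] <- "-"
  df <- data.frame(gm$markers, calls, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df$pos <- format(df$pos, scientific = FALSE, trim = TRUE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read an interval file (BED or GFF3) to 0-based half-open intervals
#'
#' BED is already 0-based half-open; GFF3 (1-based inclusive) is converted.
#' The BED name column / the GFF3 attribute named by `class_attr` (falling
#' back to the feature type) becomes the `class` column.
#'
#' @param path file path.
#' @param format `"BED"` or `"GFF3"`; guessed from the extension by default.
#' @param class_attr GFF3 attribute holding the feature class.
#' @return data.frame `chrom`, `start`, `end`, `class`, `strand`.
#' @export
read_intervals <- function(path, format = NULL, class_attr = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
      "GFF3" else "BED"
  }
  format <- toupper(format)
  gr <- rtracklayer::import(path,
                            format = if (format == "GFF3") "gff3" else "bed")
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  bad <- which(end0 <= start0)
  if (length(bad))
    stop("empty interval (end <= start) at record ", bad[1], " of ", path)
  cls <- NULL
  md <- S4Vectors::mcols(gr)
  if (!is.null(class_attr) && class_attr %in% names(md))
    cls <- as.character(md[[class_attr]])
  else if ("name" %in% names(md)) cls <- as.character(md$name)
  else if ("type" %in% names(md)) cls <- as.character(md$type)
  if (is.null(cls)) cls <- rep(NA_character_, length(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = start0, end = end0, class = cls,
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write a genetic map TSV
#'
#' @param map a `genetic_map`.
#' @param path output path.
#' @export
write_map <- function(map, path) {
  data.table::fwrite(as.data.frame(map)[, c("chrom", "id", "pos", "cM")],
                     path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a genetic map TSV
#'
#' @param path TSV with columns chrom, id, pos, cM.
#' @param mapping_function,ril_scheme metadata to attach.
#' @return a `genetic_map`.
#' @export
read_map <- function(path, mapping_function = "kosambi",
                     ril_scheme = "Finf-self") {
  df <- data.table::fread(path, data.table = FALSE)
  structure(df, mapping_function = mapping_function, ril_scheme = ril_scheme,
            class = c("genetic_map", "data.frame"))
}

#' Write a rate profile as BedGraph-style TSV
#'
#' Four columns (chromosome, start, end, cM/Mbp), 0-based half-open; each
#' grid point covers `[pos, pos + grid_step)`.
#'
#' @param profile a `rate_profile`.
#' @param path output path.
#' @export
write_bedgraph <- function(profile, path) {
  step <- attr(profile, "grid_step")
  w <- if (!is.null(profile$width)) profile$width else rep(step, nrow(profile))
  start <- if (identical(attr(profile, "method"), "window"))
    profile$pos - w / 2 else profile$pos
  df <- data.frame(chrom = profile$chrom,
                   start = format(start, scientific = FALSE, trim = TRUE),
                   end = format(start + w, scientific = FALSE, trim = TRUE),
                   rate = profile$rate)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a hotspot/coldspot set as BED6+
#'
#' Columns: chrom, start, end, name, score (peak rate x 100, rounded),
#' strand ("."), then peak bp, mean rate, chromatin class, population, kind.
#'
#' @param hs a `hotspot_set`.
#' @param path output path.
#' @export
write_hotspots_bed <- function(hs, path) {
  df <- data.frame(
    chrom = hs$chrom,
    start = format(hs$start, scientific = FALSE, trim = TRUE),
    end = format(hs$end, scientific = FALSE, trim = TRUE),
    name = sprintf("%s_%s_%d", hs$kind,
                   ifelse(nzchar(hs$population), hs$population, "pop"),
                   seq_len(nrow(hs))),
    score = round(hs$peak_rate * 100),
    strand = ".",
    peak = format(hs$peak, scientific = FALSE, trim = TRUE),
    mean_rate = hs$mean_rate,
    chromatin = hs$chromatin,
    population = hs$population,
    kind = hs$kind)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6+ hotspot file written by [write_hotspots_bed()]
#'
#' @param path BED path.
#' @return a `hotspot_set`.
#' @export
read_hotspots_bed <- function(path) {
  df <- data.table::fread(path, data.table = FALSE, header = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand", "peak",
                                        "mean_rate", "chromatin",
                                        "population", "kind"))
  out <- data.frame(chrom = as.character(df$chrom), start = df$start,
                    end = df$end, peak = df$peak,
                    peak_rate = df$score / 100, mean_rate = df$mean_rate,
                    size = df$end - df$start,
                    chromatin = df$chromatin,
                    population = as.character(df$population),
                    kind = df$kind, stringsAsFactors = FALSE)
  structure(out, class = c("hotspot_set", "data.frame"))
}

#' Write crossover truth records
#'
#' @param truth a `sim_truth`.
#' @param path TSV path.
#' @export
write_truth <- function(truth, path) {
  data.table::fwrite(truth$crossovers, path, sep = "\t", quote = FALSE)
  invisible(path)
}
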