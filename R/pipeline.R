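# End-to-end orchestration: simulate (optional) -> qc -> map -> rates ->
# hotspots/coldspots -> compare/assoc/motifs (optional), writing every
# intermediate plus a JSON run manifest.

#' Run the full hotspot pipeline
#'
#' @param config a list (or path to a JSON file) with entries:
#' \describe{
#'   \item{out_dir}{output directory (created).}
#'   \item{seed}{integer seed for all randomness.}
#'   \item{simulate}{optional: `landscape` (JSON config path or a landscape),
#'     `marker_spacing_bp`, `n_lines`, `final_generation`, `missing_rate`,
#'     `population`.}
#'   \item{genotypes}{genotype TSV path (ignored when simulating).}
#'   \item{chromatin}{BED path or data.frame of chromatin intervals; when
#'     simulating, defaults to the landscape's own intervals.}
#'   \item{qc}{`max_missing`, `alpha`.}
#'   \item{map_function}{`"kosambi"` or `"haldane"`.}
#'   \item{spline}{`"gcv"`, `"interpolating"` or numeric spar.}
#'   \item{grid_step}{rate grid step, bp.}
#'   \item{hotspot}{`window`, `min_fold`, `boundary_frac`.}
#'   \item{coldspot}{`max_frac`, `min_len_bp`, or `NULL` to skip.}
#'   \item{compare}{path to a second hotspot BED, or `NULL`.}
#'   \item{assoc}{`te` (BED path or data.frame with class column),
#'     `window_bp`, or `NULL`.}
#'   \item{motifs}{`fasta` path, `upstream_bp`, `n_perm`, or `NULL`.}
#' }
#' @return the manifest list, invisibly; artifacts are written to `out_dir`.
#' @export
run_all <- function(config) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- utils::modifyList(list(
    out_dir = "rilrec_out", seed = 1L, qc = list(max_missing = 0.1,
                                                alpha = 0.01),
    map_function = "kosambi", spline = "gcv", grid_step = 10000,
    hotspot = list(window = 5, min_fold = 2, boundary_frac = 0.5),
    coldspot = list(max_frac = 0.2, min_len_bp = 0),
    compare = NULL, assoc = NULL, motifs = NULL, simulate = NULL,
    genotypes = NULL, chromatin = NULL
  ), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  set.seed(cfg$seed)
  stages <- character(0)
  manifest <- list(package = "rilrec",
                   version = as.character(utils::packageVersion("rilrec")),
                   seed = cfg$seed, config = cfg)

  # --- input genotypes -------------------------------------------------
  if (!is.null(cfg$simulate)) {
    ls <- cfg$simulate$landscape
    if (is.character(ls)) ls <- landscape_from_config(ls)
    markers <- make_marker_grid(ls, cfg$simulate$marker_spacing_bp)
    sim <- simulate_ril_population(
      ls, markers, n_lines = cfg$simulate$n_lines,
      final_generation = cfg$simulate$final_generation %||% 5,
      missing_rate = cfg$simulate$missing_rate %||% 0,
      seed = cfg$seed,
      population = cfg$simulate$population %||% "sim")
    gm <- sim$genotypes
    write_genotypes(gm, out("genotypes.tsv"))
    write_truth(sim$truth, out("truth_crossovers.tsv"))
    if (is.null(cfg$chromatin)) cfg$chromatin <- ls$chromatin
    stages <- c(stages, "simulate")
  } else {
    if (is.null(cfg$genotypes)) stop("stage qc: no genotype input configured")
    if (!file.exists(cfg$genotypes))
      stop("stage qc: missing input file ", cfg$genotypes)
    gm <- read_genotypes(cfg$genotypes)
  }
  cmap <- if (is.data.frame(cfg$chromatin)) chromatin_map(cfg$chromatin)
          else chromatin_map(read_intervals(cfg$chromatin, format = "BED"))

  # --- qc -> map -> rates ---------------------------------------------
  qc <- run_qc(gm, cfg$qc$max_missing, cfg$qc$alpha)
  write_genotypes(qc$genotypes, out("genotypes_qc.tsv"))
  stages <- c(stages, "qc")
  manifest$qc <- qc$report[c("n_input", "n_removed_missing",
                             "n_removed_distortion", "n_collapsed",
                             "n_retained")]

  map <- build_map(qc$genotypes, cfg$map_function)
  write_map(map, out("map.tsv"))
  stages <- c(stages, "map")

  spl <- fit_spline(isotonize(map), cfg$spline)
  prof <- rate_profile(spl, cfg$grid_step)
  write_bedgraph(prof, out("rates.bedgraph"))
  stages <- c(stages, "rates")
  manifest$clamped_frac <- as.list(attr(prof, "clamped_frac"))

  # --- hotspots / coldspots -------------------------------------------
  hs <- call_hotspots(prof, cmap, window = cfg$hotspot$window,
                      min_fold = cfg$hotspot$min_fold,
                      boundary_frac = cfg$hotspot$boundary_frac,
                      population = gm$population)
  hs <- tukey_filter(classify_chromatin(hs, cmap))
  write_hotspots_bed(hs, out("hotspots.bed"))
  stages <- c(stages, "hotspots")
  manifest$n_hotspots <- nrow(hs)

  cs <- NULL
  if (!is.null(cfg$coldspot)) {
    cs <- call_coldspots(prof, cmap, max_frac = cfg$coldspot$max_frac,
                         min_len_bp = cfg$coldspot$min_len_bp,
                         population = gm$population)
    write_hotspots_bed(cs, out("coldspots.bed"))
    stages <- c(stages, "coldspots")
    manifest$n_coldspots <- nrow(cs)
  }

  if (!is.null(cfg$compare)) {
    other <- read_hotspots_bed(cfg$compare)
    cmpres <- compare_hotspots(hs, other)
    data.table::fwrite(cmpres$pairs, out("shared.tsv"), sep = "\t")
    manifest$compare <- cmpres[c("n_shared", "frac_a", "frac_b")]
    stages <- c(stages, "compare")
  }

  if (!is.null(cfg$assoc)) {
    te <- cfg$assoc$te
    if (is.character(te)) te <- read_intervals(te)
    chrom_len <- tapply(prof$pos + attr(prof, "grid_step"), prof$chrom, max)
    ft <- make_feature_table(hs, cs, te, chrom_len,
                             window_bp = cfg$assoc$window_bp %||% 1e5)
    res <- do.call(rbind, lapply(setdiff(unique(te$class), NA), function(cl)
      rbind(logistic_assoc(ft, cl, "hotspot"),
            logistic_assoc(ft, cl, "coldspot"))))
    data.table::fwrite(res, out("assoc.tsv"), sep = "\t")
    stages <- c(stages, "assoc")
  }

  if (!is.null(cfg$motifs)) {
    flanks <- extract_flanks(hs, cfg$motifs$fasta,
                             upstream_bp = cfg$motifs$upstream_bp %||% 200)
    specs <- default_motifs()
    bg <- sample_background_windows(hs, cmap,
                                    lengths = Biostrings::width(flanks))
    bg_hs <- structure(data.frame(bg, peak = bg$start, kind = "bg",
                                  population = gm$population),
                       class = c("hotspot_set", "data.frame"))
    bg_seq <- extract_flanks(bg_hs, cfg$motifs$fasta, upstream_bp = 0)
    mres <- do.call(rbind, lapply(specs, function(sp) {
      mh <- scan_motif(flanks, sp)
      mb <- scan_motif(bg_seq, sp)
      en <- enrichment_test(mh$presence$present, mb$presence$present,
                            n_perm = cfg$motifs$n_perm %||% 1000)
      it <- motif_intensity_test(hs, mh$presence$present)
      data.frame(motif = sp$name, frac_hotspots = en$frac_hotspots,
                 frac_background = en$frac_background, fold = en$fold,
                 p_enrich = en$p, mean_with = it$mean_with,
                 mean_without = it$mean_without, p_intensity = it$p)
    }))
    data.table::fwrite(mres, out("motifs.tsv"), sep = "\t")
    stages <- c(stages, "motifs")
  }

  manifest$stages <- stages
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)

  smry <- summarize_hotspots(hs)
  writeLines(c("rilrec run summary", utils::capture.output(print(smry))),
             out("summary.txt"))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
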