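#' Read / write phenotype tables
#'
#' Tab-separated, first column `line_id`, remaining columns numeric traits.
#'
#' @param path file path.
#' @return data.frame with rownames = line ids.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", na.strings = c("NA", ""))
  if (names(df)[1] != "line_id") stop("phenotype file must start with a line_id column")
  rownames(df) <- df$line_id
  df
}

#' @param phenos data.frame with a `line_id` column.
#' @rdname read_phenotypes
#' @export
write_phenotypes <- function(phenos, path) {
  utils::write.table(phenos, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read true mosaic segments written by [write_truth_segments()]
#'
#' File coordinates are 0-based half-open and converted back to the internal
#' 1-based inclusive convention.
#'
#' @param path segments TSV.
#' @return data.frame: line, chrom, start_bp, end_bp, homolog, founder.
#' @export
read_truth_segments <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  data.frame(line = df$line, chrom = df$chrom,
             start_bp = df$start + 1L, end_bp = df$end,
             homolog = df$homolog, founder = df$founder)
}

#' End-to-end pipeline: simulate, reconstruct, scan, power
#'
#' Runs the requested stages from a single configuration (an R list or the
#' path to a JSON file) and writes all artifacts plus a manifest recording
#' inputs, derived seeds and output checksums. Stage seeds are derived from
#' the master seed with [derive_seed()], so each stage is independently
#' reproducible and identical configurations give identical manifests.
#'
#' Configuration fields (all optional unless noted): `out_dir` (required),
#' `seed` (master seed, default 1), `n_markers`, `n_lines`, `error_rate`,
#' `missing_rate`, `stages` (subset of "simulate", "reconstruct", "scan",
#' "power"), `trait` (named vector or phenotype file for "scan"), `n_perm`,
#' `power_grid` (data.frame as [power_scenarios()]), `n_runs`.
#'
#' @param config list or JSON path.
#' @return invisibly, the manifest list.
#' @examples
#' \dontrun{
#' cfg <- jsonlite::read_json(system.file("extdata", "demo_config.json",
#'                                        package = "magicpop"),
#'                            simplifyVector = TRUE)
#' cfg$out_dir <- tempfile("magicpop_demo")
#' magic_pipeline(cfg)
#' }
#' @export
magic_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- utils::modifyList(list(seed = 1L, n_markers = 2000L, n_lines = 200L,
                                error_rate = 0.01, missing_rate = 0.15,
                                stages = c("simulate", "reconstruct"),
                                n_perm = 200L, n_runs = 10L), config)
  if (is.null(cfg$out_dir)) stop("config must give out_dir")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = cfg[setdiff(names(cfg), "trait")], outputs = list())
  record <- function(path) {
    manifest$outputs[[basename(path)]] <<- unname(tools::md5sum(path))
    path
  }
  t0 <- Sys.time()
  map <- magic_map_synthetic(cfg$n_markers, seed = derive_seed(cfg$seed, "map"))
  founders <- simulate_founder_panel(map, seed = derive_seed(cfg$seed, "founders"))
  design <- funnel_design()
  pop <- geno <- recon <- NULL
  if ("simulate" %in% cfg$stages) {
    pop <- simulate_funnel_population(design, map, n_lines = cfg$n_lines,
                                      seed = derive_seed(cfg$seed, "breed"))
    geno <- genotype_mosaics(pop, founders, error_rate = cfg$error_rate,
                             missing_rate = cfg$missing_rate,
                             seed = derive_seed(cfg$seed, "genotype"))
    record(write_genetic_map(map, file.path(cfg$out_dir, "map.tsv")))
    record(write_founder_panel(founders, file.path(cfg$out_dir, "founders.tsv")))
    record(write_genotype_matrix(geno, file.path(cfg$out_dir, "genotypes.tsv")))
    record(write_truth_segments(pop, file.path(cfg$out_dir, "truth_segments.tsv")))
  }
  if ("reconstruct" %in% cfg$stages) {
    if (is.null(geno)) stop("reconstruct stage needs the simulate stage (or genotypes)")
    recon <- magic_reconstruct(geno, founders, map)
    smry <- summary(recon)
    p <- file.path(cfg$out_dir, "reconstruction_summary.tsv")
    utils::write.table(smry, p, sep = "\t", quote = FALSE, row.names = FALSE)
    record(p)
  }
  if ("scan" %in% cfg$stages) {
    if (is.null(recon)) stop("scan stage needs the reconstruct stage")
    y <- cfg$trait
    if (is.character(y) && length(y) == 1 && file.exists(y))
      y <- stats::setNames(read_phenotypes(y)[[2]], read_phenotypes(y)$line_id)
    sc <- magic_scan(y, recon)
    thr <- permutation_thresholds(y, recon, n_perm = cfg$n_perm,
                                  seed = derive_seed(cfg$seed, "perm"))
    peaks <- call_peaks(sc, thr$suggestive, thr$strong)
    p1 <- file.path(cfg$out_dir, "scan.tsv")
    utils::write.table(as.data.frame(sc), p1, sep = "\t", quote = FALSE, row.names = FALSE)
    record(p1)
    p2 <- file.path(cfg$out_dir, "thresholds.json")
    jsonlite::write_json(list(strong = thr$strong, suggestive = thr$suggestive),
                         p2, auto_unbox = TRUE, digits = NA)
    record(p2)
    p3 <- file.path(cfg$out_dir, "peaks.tsv")
    utils::write.table(peaks, p3, sep = "\t", quote = FALSE, row.names = FALSE)
    record(p3)
  }
  if ("power" %in% cfg$stages) {
    if (is.null(recon)) stop("power stage needs the reconstruct stage")
    grid <- if (is.null(cfg$power_grid)) power_scenarios() else as.data.frame(cfg$power_grid)
    pw <- run_power_study(recon, grid, n_runs = cfg$n_runs,
                          seed = derive_seed(cfg$seed, "power"))
    p <- file.path(cfg$out_dir, "power.tsv")
    utils::write.table(pw$runs, p, sep = "\t", quote = FALSE, row.names = FALSE)
    record(p)
  }
  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  mp <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
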