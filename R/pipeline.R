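#' End-to-end run configuration
#'
#' Exactly one input mode: a real four-sample VCF (`vcf` + `sample_map`) or
#' simulate-on-the-fly (`cross` config). Filtering and scanning thresholds
#' default to the study design this package models: bulk depth >= 10,
#' QUAL >= 100, 2-Mb windows at 10-kb step, green-bulk mean index > 0.9,
#' mean Fisher P < 0.05, bulks of 30.
#'
#' @param vcf path to a VCF, or NULL to simulate.
#' @param sample_map role-to-sample map for `vcf` (see [read_variants()]).
#' @param cross a [cross_config()] when simulating.
#' @param filter a [filter_config()].
#' @param scan a [scan_config()].
#' @param outdir output directory; NULL keeps everything in memory.
#' @param seed integer seed (overrides `cross$seed` when simulating).
#' @param plots write per-chromosome scan plots (needs `outdir`).
#' @param null_bulks simulate phenotype-independent (null) bulks; see
#'   [simulate_cross_dataset()].
#' @return a `run_config` list.
#' @export
run_config <- function(vcf = NULL, sample_map = NULL, cross = NULL,
                       filter = filter_config(), scan = scan_config(),
                       outdir = NULL, seed = 1L, plots = FALSE,
                       null_bulks = FALSE) {
  if (is.null(vcf) && is.null(cross))
    cross <- cross_config()
  if (!is.null(vcf) && !is.null(cross))
    stop("choose one input mode: a VCF or a simulated cross, not both")
  stopifnot(inherits(filter, "filter_config"), inherits(scan, "scan_config"))
  structure(list(vcf = vcf, sample_map = sample_map, cross = cross,
                 filter = filter, scan = scan, outdir = outdir,
                 seed = as.integer(seed), plots = isTRUE(plots),
                 null_bulks = isTRUE(null_bulks)),
            class = "run_config")
}

#' Run the full BSA-seq mapping pipeline
#'
#' simulate (or read) -> filter -> polarize -> SNP-index + Fisher ->
#' sliding-window scan -> candidate regions, with every intermediate
#' written to `outdir` (filtered sites TSV, index TSV, window TSV, region
#' BED, summary JSON, optional scan plots). Deterministic given the seed
#' and inputs.
#'
#' @param config a [run_config()].
#' @return a summary list: site/filter counts, the region table, the
#'   thresholds applied, and (for simulated runs) truth and recovery flags.
#' @examples
#' \donttest{
#' cfg <- run_config(cross = cross_config(
#'   chrom_lengths = c(chr01 = 2e7, chr02 = 2e7),
#'   causal_loci = data.frame(chrom = c("chr01", "chr02"), pos = c(1e7, 5e6)),
#'   seed = 1))
#' res <- run_bsaseq(cfg)
#' res$regions
#' }
#' @export
run_bsaseq <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  truth <- NULL
  chrom_lengths <- NULL
  if (!is.null(config$cross)) {
    cross <- config$cross
    cross$seed <- config$seed
    ds <- stage("simulate",
                simulate_cross_dataset(cross,
                                       null_bulks = config$null_bulks))
    sites <- ds$sites
    truth <- ds$truth
    chrom_lengths <- cross$chrom_lengths
  } else {
    sm <- config$sample_map
    sites <- stage("read", if (is.null(sm)) read_variants(config$vcf)
                   else read_variants(config$vcf, sm))
    chrom_lengths <- tapply(sites$pos, sites$chrom, max)
    chrom_lengths <- setNames(as.numeric(chrom_lengths),
                              names(chrom_lengths))
  }
  n_input <- nrow(sites)
  filtered <- stage("filter", select_informative(sites, config$filter))
  pol <- stage("polarize", polarize(filtered))
  idx <- stage("index", compute_index_table(pol))
  ws <- stage("scan", window_stats(idx, chrom_lengths, config$scan))
  regions <- stage("regions", call_regions(ws, config$scan))

  recovery <- NULL
  if (!is.null(truth)) {
    cl <- truth$causal_loci
    recovery <- vapply(seq_len(nrow(cl)), function(k)
      any(regions$chrom == cl$chrom[k] & regions$start <= cl$pos[k] &
            regions$end >= cl$pos[k]), logical(1))
  }
  summary <- list(
    n_sites_input = n_input,
    n_sites_filtered = nrow(filtered),
    drop_counts = attr(filtered, "drop_counts"),
    thresholds = list(filter = unclass(config$filter),
                      scan = unclass(config$scan)),
    n_regions = nrow(regions),
    regions = regions,
    loci_recovered = recovery,
    seed = config$seed)

  if (!is.null(config$outdir)) {
    outdir <- config$outdir
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    write_sites_tsv(filtered, file.path(outdir, "filtered_sites.tsv"))
    write_sites_tsv(idx, file.path(outdir, "snp_index.tsv"))
    write_sites_tsv(ws, file.path(outdir, "windows.tsv"))
    regions_to_bed(regions, file.path(outdir, "regions.bed"))
    jsonlite::write_json(
      summary[c("n_sites_input", "n_sites_filtered", "n_regions", "seed")],
      file.path(outdir, "summary.json"), auto_unbox = TRUE)
    write_sites_tsv(regions, file.path(outdir, "regions.tsv"))
    if (config$plots) {
      for (ch in unique(ws$chrom)) {
        dev_ok <- tryCatch({
          grDevices::png(file.path(outdir, paste0("scan_", ch, ".png")),
                         width = 900, height = 700)
          TRUE
        }, error = function(e) FALSE)
        if (!dev_ok) {
          grDevices::pdf(file.path(outdir, paste0("scan_", ch, ".pdf")),
                         width = 9, height = 7)
        }
        try(plot_scan(ws, ch, regions), silent = TRUE)
        grDevices::dev.off()
      }
    }
  }
  summary$index_table <- idx
  summary$window_stats <- ws
  summary$truth <- truth
  invisible(summary)
}

#' Locus-recovery power study over replicated simulations
#'
#' Re-runs the simulate-and-scan pipeline across seeds, optionally varying
#' bulk size and bulk depth, recording for each replicate how many planted
#' loci fall inside called regions and how wide the regions are. Quantifies
#' the design intuition that mapping resolution is limited by bulk size and
#' recombination, not by sequencing depth alone.
#'
#' @param cross a [cross_config()] template.
#' @param n_replicates replicates per condition.
#' @param bulk_sizes,depths optional vectors of conditions; default keeps
#'   the template's values.
#' @param filter,scan configs passed through to the pipeline.
#' @param base_seed replicate r of every condition uses seed base_seed + r,
#'   so conditions are seed-paired.
#' @return data.frame with one row per (condition, replicate): bulk_size,
#'   depth_bulk, seed, n_regions, n_recovered, median_region_width.
#' @export
run_recovery_study <- function(cross, n_replicates,
                               bulk_sizes = NULL, depths = NULL,
                               filter = filter_config(),
                               scan = scan_config(),
                               base_seed = 1000L) {
  stopifnot(n_replicates >= 1)
  if (is.null(bulk_sizes)) bulk_sizes <- cross$bulk_size
  if (is.null(depths)) depths <- cross$depth_bulk
  grid <- expand.grid(bulk_size = bulk_sizes, depth_bulk = depths,
                      rep = seq_len(n_replicates))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cc <- cross
    cc$bulk_size <- as.integer(grid$bulk_size[i])
    cc$depth_bulk <- grid$depth_bulk[i]
    seed <- base_seed + grid$rep[i]
    res <- run_bsaseq(run_config(cross = cc, filter = filter, scan = scan,
                                 seed = seed))
    data.frame(bulk_size = cc$bulk_size, depth_bulk = cc$depth_bulk,
               seed = seed, n_regions = res$n_regions,
               n_recovered = sum(res$loci_recovered),
               median_region_width = if (res$n_regions)
                 stats::median(res$regions$end - res$regions$start + 1)
               else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
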