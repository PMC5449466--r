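#' Configuration of the simulated biparental F2 cross
#'
#' Bundles every knob of the synthetic cross: genome shape, genetic map
#' density, the two planted causal loci, population and bulk sizes,
#' marker density, sequencing depths and error, and the RNG seed.
#'
#' Defaults describe the stated world this package is tested against: an F2
#' of n = 495 from a yellow-cotyledon x green-cotyledon cross, bulks of 30
#' individuals per phenotype, bulk depth ~55x and parent depth ~10x, on a
#' two-chromosome 50-Mb genome with one informative SNP every 10 kb.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param cm_per_mb genetic map density in centiMorgan per megabase. The
#'   Haldane map function converts distances to recombination fractions.
#' @param causal_loci data.frame with columns `chrom` and `pos` — exactly two
#'   rows, the planted recessive loci. Green phenotype requires homozygosity
#'   for the green-parent allele at both.
#' @param n_f2 F2 population size.
#' @param bulk_size individuals pooled per phenotype bulk.
#' @param marker_spacing_bp spacing of informative SNPs along each chromosome.
#' @param depth_bulk mean per-site sequencing depth of each bulk (Poisson mean).
#' @param depth_parent mean per-site depth of each parent.
#' @param seq_error per-read allele miscall rate, applied symmetrically.
#' @param f3_seeds_per_line seeds phenotyped per selfed F2:3 line.
#' @param seed integer RNG seed; `NULL` leaves the RNG state untouched.
#'
#' @return an object of class `cross_config` (a validated list).
#' @examples
#' cfg <- cross_config(n_f2 = 200, seed = 1)
#' cfg$causal_loci
#' @export
cross_config <- function(chrom_lengths = c(chr01 = 50e6, chr02 = 50e6),
                         cm_per_mb = 2.5,
                         causal_loci = data.frame(
                           chrom = c("chr01", "chr02"),
                           pos   = c(35e6, 12e6)),
                         n_f2 = 495L,
                         bulk_size = 30L,
                         marker_spacing_bp = 10000,
                         depth_bulk = 55,
                         depth_parent = 10,
                         seq_error = 0.001,
                         f3_seeds_per_line = 60L,
                         seed = NULL) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be a named vector")
  if (any(chrom_lengths < 1)) stop("chromosome lengths must be >= 1 bp")
  causal_loci <- as.data.frame(causal_loci)
  if (!all(c("chrom", "pos") %in% names(causal_loci)))
    stop("causal_loci needs columns 'chrom' and 'pos'")
  if (nrow(causal_loci) != 2L)
    stop("exactly 2 causal loci are required, got ", nrow(causal_loci))
  if (!all(causal_loci$chrom %in% names(chrom_lengths)))
    stop("causal locus on unknown chromosome")
  inside <- causal_loci$pos >= 1 &
    causal_loci$pos <= chrom_lengths[causal_loci$chrom]
  if (!all(inside)) stop("causal locus outside its chromosome")
  stopifnot(cm_per_mb > 0, n_f2 >= 1, bulk_size >= 1,
            marker_spacing_bp > 0, depth_bulk > 0, depth_parent > 0,
            seq_error >= 0, seq_error < 0.5, f3_seeds_per_line >= 1)
  structure(list(
    chrom_lengths = chrom_lengths,
    cm_per_mb = cm_per_mb,
    causal_loci = causal_loci,
    n_f2 = as.integer(n_f2),
    bulk_size = as.integer(bulk_size),
    marker_spacing_bp = marker_spacing_bp,
    depth_bulk = depth_bulk,
    depth_parent = depth_parent,
    seq_error = seq_error,
    f3_seeds_per_line = as.integer(f3_seeds_per_line),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "cross_config")
}

#' @export
print.cross_config <- function(x, ...) {
  cat("cross_config:",
      length(x$chrom_lengths), "chromosomes,",
      "n_f2 =", x$n_f2, ", bulks of", x$bulk_size, "\n")
  cat("  causal loci:",
      paste0(x$causal_loci$chrom, ":", x$causal_loci$pos, collapse = ", "),
      "\n")
  cat("  map", x$cm_per_mb, "cM/Mb; depths bulk", x$depth_bulk,
      "parent", x$depth_parent, "; seq error", x$seq_error, "\n")
  invisible(x)
}

# marker ladder + causal positions per chromosome; causal loci are also
# genotyped sites so downstream indices are defined exactly at the truth
template_positions <- function(config) {
  lapply(setNames(names(config$chrom_lengths), names(config$chrom_lengths)),
         function(ch) {
           len <- config$chrom_lengths[[ch]]
           pos <- seq(config$marker_spacing_bp, len,
                      by = config$marker_spacing_bp)
           extra <- config$causal_loci$pos[config$causal_loci$chrom == ch]
           sort(unique(c(pos, extra)))
         })
}
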