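#' Simulate a complete BSA-seq dataset
#'
#' One-stop assembly of the stated world: an F2 population, phenotype bulks,
#' per-site read depths for the four sequenced samples, F2:3 seed counts per
#' selfed line, marker genotypes around each causal locus for fine mapping,
#' and the truth needed to score recovery. REF/ALT orientation is randomized
#' per site (the green-parent allele is ALT at ~half of sites) so downstream
#' polarization is exercised.
#'
#' @param config a [cross_config()]; its `seed` drives all randomness.
#' @param finemap_halfwidth_bp half-width of the fine-mapping marker window
#'   around each causal locus.
#' @param finemap_spacing_bp marker spacing inside that window.
#' @param null_bulks if TRUE, bulks are drawn at random from the population
#'   irrespective of phenotype — the biological null of a trait with no
#'   causal locus in the genome, used for false-positive studies.
#' @return an object of class `bsa_dataset`: the population, bulk members,
#'   a `sites` variant table (same shape as [read_variants()] output), the
#'   F2:3 phenotype table, the long-format marker table, and a `truth` list.
#' @examples
#' ds <- simulate_cross_dataset(cross_config(
#'   chrom_lengths = c(chr01 = 5e6, chr02 = 5e6),
#'   causal_loci = data.frame(chrom = c("chr01", "chr02"), pos = c(3e6, 1e6)),
#'   n_f2 = 120, marker_spacing_bp = 1e5, seed = 42))
#' head(ds$sites)
#' @export
simulate_cross_dataset <- function(config,
                                   finemap_halfwidth_bp = 1e6,
                                   finemap_spacing_bp = 5e4,
                                   null_bulks = FALSE) {
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg_noseed <- config
  cfg_noseed$seed <- NULL
  # an F2 of 495 leaves < 30 green individuals in almost half of draws
  # (Binomial(495, 1/16)); re-draw the cross rather than fail, as a breeder
  # would grow another population
  for (attempt in 1:50) {
    pop <- simulate_f2(cfg_noseed)
    n_green <- sum(pop$phenotype == "green")
    n_yellow <- sum(pop$phenotype == "yellow")
    if (n_green >= config$bulk_size && n_yellow >= config$bulk_size) break
    if (attempt == 50L)
      stop("no population with ", config$bulk_size,
           " individuals per phenotype in 50 draws; last draw had ",
           n_green, " green / ", n_yellow, " yellow")
  }
  if (attempt > 1L)
    message("re-drew the F2 population ", attempt - 1L,
            " time(s) to fill both bulks")
  bulks <- if (null_bulks) {
    shuffled <- sample(length(pop$phenotype))
    list(yellow = sort(shuffled[seq_len(config$bulk_size)]),
         green = sort(shuffled[config$bulk_size + seq_len(config$bulk_size)]))
  } else select_bulks(pop, config$bulk_size)
  f_g <- bulk_allele_freqs(pop, bulks$green)
  f_y <- bulk_allele_freqs(pop, bulks$yellow)
  chrom <- rep(names(pop$template), lengths(pop$template))
  pos <- unlist(pop$template, use.names = FALSE)
  fg <- unlist(f_g, use.names = FALSE)
  fy <- unlist(f_y, use.names = FALSE)
  depths <- simulate_depths(fg, fy, config)

  n <- length(pos)
  bases <- c("A", "C", "G", "T")
  a_yellow <- sample(bases, n, replace = TRUE)   # yellow-parent base
  a_green <- vapply(a_yellow,
                    function(b) sample(setdiff(bases, b), 1L), "")
  green_is_alt <- as.logical(rbinom(n, 1L, 0.5))
  qual <- round(rgamma(n, shape = 4, scale = 120), 1)

  pick <- function(g, y) ifelse(green_is_alt, y, g)   # ref-column chooser
  sites <- data.frame(
    chrom = chrom, pos = pos,
    ref = ifelse(green_is_alt, a_yellow, a_green),
    alt = ifelse(green_is_alt, a_green, a_yellow),
    qual = qual,
    parent_yellow_gt = ifelse(green_is_alt, "hom_ref", "hom_alt"),
    parent_green_gt = ifelse(green_is_alt, "hom_alt", "hom_ref"),
    py_ref = pick(depths$py_g, depths$py_y),
    py_alt = pick(depths$py_y, depths$py_g),
    pg_ref = pick(depths$pg_g, depths$pg_y),
    pg_alt = pick(depths$pg_y, depths$pg_g),
    yb_ref = pick(depths$yb_g, depths$yb_y),
    yb_alt = pick(depths$yb_y, depths$yb_g),
    gb_ref = pick(depths$gb_g, depths$gb_y),
    gb_alt = pick(depths$gb_y, depths$gb_g),
    stringsAsFactors = FALSE)

  f3 <- simulate_f3_counts(pop, config)
  markers <- finemap_marker_calls(pop, finemap_halfwidth_bp,
                                  finemap_spacing_bp)
  truth <- list(
    causal_loci = config$causal_loci,
    bulk_yellow = bulks$yellow,
    bulk_green = bulks$green,
    causal_genotypes = cbind(locus1 = geno_code_to_char(pop$causal_geno[, 1]),
                             locus2 = geno_code_to_char(pop$causal_geno[, 2])),
    phenotype = pop$phenotype,
    freq_green_bulk = data.frame(chrom = chrom, pos = pos, f = fg),
    freq_yellow_bulk = data.frame(chrom = chrom, pos = pos, f = fy))
  structure(list(config = config, population = pop, bulks = bulks,
                 sites = sites, f3_counts = f3, markers = markers,
                 truth = truth),
            class = "bsa_dataset")
}

#' Marker genotype calls around each causal locus
#'
#' True genotype calls (A/H/B) for every line at a ladder of markers around
#' each planted causal locus, in the long format of the marker TSV
#' (line_id, marker_id, chrom, pos, call, region). The error-free input of
#' the fine-mapping stage.
#'
#' @param pop an `f2_population`.
#' @param halfwidth_bp half-width of the marker window around each locus.
#' @param spacing_bp marker spacing inside the window.
#' @return long-format data.frame.
#' @export
finemap_marker_calls <- function(pop, halfwidth_bp = 1e6,
                                 spacing_bp = 5e4) {
  cfg <- pop$config
  out <- list()
  for (k in seq_len(nrow(cfg$causal_loci))) {
    ch <- cfg$causal_loci$chrom[k]
    cpos <- cfg$causal_loci$pos[k]
    templ <- pop$template[[ch]]
    lo <- max(1, cpos - halfwidth_bp)
    hi <- min(cfg$chrom_lengths[[ch]], cpos + halfwidth_bp)
    want <- seq(lo, hi, by = spacing_bp)
    idx <- unique(vapply(want, function(p) which.min(abs(templ - p)), 1L))
    mpos <- templ[idx]
    g <- pop$hap1[[ch]][idx, , drop = FALSE] +
      pop$hap2[[ch]][idx, , drop = FALSE]
    n <- ncol(g)
    out[[k]] <- data.frame(
      line_id = rep(sprintf("F2_%04d", seq_len(n)), each = length(mpos)),
      marker_id = rep(sprintf("M_%s_%08d", ch, as.integer(mpos)), n),
      chrom = ch,
      pos = rep(mpos, n),
      call = c("A", "H", "B")[as.vector(g) + 1L],
      region = paste0("region", k),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write a simulated dataset to disk
#'
#' Emits (i) a 4-sample VCF 4.2 (samples parent_yellow, parent_green,
#' bulk_yellow, bulk_green; FORMAT GT:AD:DP, QUAL populated), (ii) a
#' phenotype TSV of per-line F2:3 seed counts, (iii) a long-format
#' marker-genotype TSV for fine mapping, and (iv) a truth JSON.
#'
#' @param ds a `bsa_dataset` from [simulate_cross_dataset()].
#' @param outdir output directory (created if absent).
#' @return invisibly, a named list of the file paths written.
#' @export
write_dataset <- function(ds, outdir) {
  stopifnot(inherits(ds, "bsa_dataset"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- list(vcf = file.path(outdir, "cross.vcf"),
                phenotypes = file.path(outdir, "phenotypes.tsv"),
                markers = file.path(outdir, "markers.tsv"),
                truth = file.path(outdir, "truth.json"))
  write_sites_vcf(ds$sites, ds$config$chrom_lengths, paths$vcf)
  write.table(ds$f3_counts, paths$phenotypes, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ds$markers, paths$markers, sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- ds$truth
  truth$bulk_yellow <- as.integer(truth$bulk_yellow)
  truth$bulk_green <- as.integer(truth$bulk_green)
  truth$causal_genotypes <- as.data.frame(truth$causal_genotypes)
  jsonlite::write_json(truth, paths$truth, dataframe = "columns",
                       digits = NA)
  invisible(paths)
}

# plain-text VCF 4.2 emission; GT for parents, ./. for pooled bulks
write_sites_vcf <- function(sites, chrom_lengths, path) {
  gt_code <- c(hom_ref = "0/0", hom_alt = "1/1", het = "0/1",
               missing = "./.")
  fmt <- function(gt, rd, ad)
    paste0(gt, ":", rd, ",", ad, ":", rd + ad)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=bsascan_simulate_cross_dataset",
    paste0("##contig=<ID=", names(chrom_lengths),
           ",length=", format(chrom_lengths, scientific = FALSE,
                              trim = TRUE), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,Description=",
           "\"Allelic depths for the ref and alt alleles\">"),
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "parent_yellow", "parent_green", "bulk_yellow",
          "bulk_green", sep = "\t"))
  body <- paste(
    sites$chrom, format(sites$pos, scientific = FALSE, trim = TRUE), ".",
    sites$ref, sites$alt,
    format(sites$qual, scientific = FALSE, trim = TRUE), "PASS", ".",
    "GT:AD:DP",
    fmt(gt_code[sites$parent_yellow_gt], sites$py_ref, sites$py_alt),
    fmt(gt_code[sites$parent_green_gt], sites$pg_ref, sites$pg_alt),
    fmt("./.", sites$yb_ref, sites$yb_alt),
    fmt("./.", sites$gb_ref, sites$gb_alt),
    sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
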