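#' Site-selection filter settings
#'
#' @param min_bulk_depth minimum total read depth required in the bulks
#'   (default 10).
#' @param min_qual minimum variant QUAL (default 100).
#' @param require_parents_homozygous_opposite drop sites unless the two
#'   parents are homozygous for different alleles (default TRUE).
#' @param depth_rule apply `min_bulk_depth` to `"both"` bulks (default,
#'   strictest reading) or to `"either"`.
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_bulk_depth = 10, min_qual = 100,
                          require_parents_homozygous_opposite = TRUE,
                          depth_rule = c("both", "either")) {
  stopifnot(min_bulk_depth >= 0, min_qual >= 0)
  depth_rule <- match.arg(depth_rule)
  structure(list(min_bulk_depth = min_bulk_depth, min_qual = min_qual,
                 require_parents_homozygous_opposite =
                   isTRUE(require_parents_homozygous_opposite),
                 depth_rule = depth_rule),
            class = "filter_config")
}

gt_string_to_code <- function(gt) {
  out <- rep("missing", length(gt))
  gt <- gsub("|", "/", gt, fixed = TRUE)
  out[gt %in% c("0/0")] <- "hom_ref"
  out[gt %in% c("1/1")] <- "hom_alt"
  out[gt %in% c("0/1", "1/0")] <- "het"
  out
}

#' Read a four-sample VCF into a variant-site table
#'
#' Parses biallelic SNVs from a VCF holding the two parents and the two
#' phenotype bulks, extracting parental GT calls and per-sample allelic
#' depths (AD). Multiallelic records, indels and records with missing or
#' malformed AD in any sample are skipped and counted.
#'
#' @param vcf_path path to an (uncompressed or bgzipped) VCF.
#' @param sample_map named character vector mapping the roles
#'   `parent_yellow`, `parent_green`, `bulk_yellow`, `bulk_green` to sample
#'   names in the VCF. Defaults to identically-named samples.
#' @return data.frame with one row per retained site: chrom, pos, ref, alt,
#'   qual, parent genotype codes (`hom_ref`/`hom_alt`/`het`/`missing`) and
#'   ref/alt depth pairs for the four samples. The number of skipped
#'   records is in `attr(, "n_skipped")`.
#' @export
read_variants <- function(vcf_path,
                          sample_map = c(parent_yellow = "parent_yellow",
                                         parent_green = "parent_green",
                                         bulk_yellow = "bulk_yellow",
                                         bulk_green = "bulk_green")) {
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path)
  roles <- c("parent_yellow", "parent_green", "bulk_yellow", "bulk_green")
  if (!all(roles %in% names(sample_map)))
    stop("sample_map must name all of: ", paste(roles, collapse = ", "))
  vcf <- VariantAnnotation::readVcf(vcf_path)
  have <- colnames(vcf)
  missing_samples <- setdiff(unname(sample_map[roles]), have)
  if (length(missing_samples))
    stop("samples absent from VCF: ", paste(missing_samples, collapse = ", "))

  n_total <- nrow(vcf)
  snv <- VariantAnnotation::isSNV(vcf, singleAltOnly = TRUE)
  vcf <- vcf[snv]
  gt <- VariantAnnotation::geno(vcf)$GT
  ad <- VariantAnnotation::geno(vcf)$AD
  if (is.null(ad)) stop("VCF has no AD FORMAT field")

  rr <- SummarizedExperiment::rowRanges(vcf)
  get_ad <- function(role) {
    v <- ad[, sample_map[[role]]]
    ok <- vapply(v, function(x) is.numeric(x) && length(x) == 2L &&
                   !anyNA(x), logical(1))
    cbind(ref = vapply(v, function(x) if (length(x) >= 1) x[1] else NA_real_,
                       0),
          alt = vapply(v, function(x) if (length(x) >= 2) x[2] else NA_real_,
                       0),
          ok = ok)
  }
  ad_py <- get_ad("parent_yellow"); ad_pg <- get_ad("parent_green")
  ad_yb <- get_ad("bulk_yellow");   ad_gb <- get_ad("bulk_green")
  ok <- ad_py[, "ok"] & ad_pg[, "ok"] & ad_yb[, "ok"] & ad_gb[, "ok"]
  if (any(!ok))
    warning(sum(!ok), " record(s) skipped for missing/malformed AD")

  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = as.character(unlist(rr$ALT)),
    qual = as.numeric(rr$QUAL),
    parent_yellow_gt = gt_string_to_code(gt[, sample_map[["parent_yellow"]]]),
    parent_green_gt = gt_string_to_code(gt[, sample_map[["parent_green"]]]),
    py_ref = ad_py[, "ref"], py_alt = ad_py[, "alt"],
    pg_ref = ad_pg[, "ref"], pg_alt = ad_pg[, "alt"],
    yb_ref = ad_yb[, "ref"], yb_alt = ad_yb[, "alt"],
    gb_ref = ad_gb[, "ref"], gb_alt = ad_gb[, "alt"],
    stringsAsFactors = FALSE)
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_total - nrow(out)
  out
}

#' Select analysis-ready informative sites
#'
#' Retains sites where (i) the two parents are homozygous for different
#' alleles, (ii) QUAL meets `min_qual`, and (iii) total bulk depth
#' (ref + alt) meets `min_bulk_depth` in both bulks (or either, per
#' `depth_rule`). Order-preserving and idempotent.
#'
#' @param sites a variant table from [read_variants()] (or the simulator).
#' @param config a [filter_config()].
#' @return the filtered data.frame; per-rule drop counts in
#'   `attr(, "drop_counts")`.
#' @export
select_informative <- function(sites, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  hom <- c("hom_ref", "hom_alt")
  ok_parents <- if (config$require_parents_homozygous_opposite)
    sites$parent_yellow_gt %in% hom & sites$parent_green_gt %in% hom &
      sites$parent_yellow_gt != sites$parent_green_gt
  else rep(TRUE, nrow(sites))
  ok_qual <- !is.na(sites$qual) & sites$qual >= config$min_qual
  d_y <- sites$yb_ref + sites$yb_alt
  d_g <- sites$gb_ref + sites$gb_alt
  ok_depth <- if (config$depth_rule == "both")
    d_y >= config$min_bulk_depth & d_g >= config$min_bulk_depth
  else d_y >= config$min_bulk_depth | d_g >= config$min_bulk_depth
  keep <- ok_parents & ok_qual & ok_depth
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drop_counts") <- c(parents = sum(!ok_parents),
                                qual = sum(!ok_qual),
                                depth = sum(!ok_depth))
  attr(out, "filter_config") <- config
  out
}

#' Polarize sites to the green-parent (index) allele
#'
#' Relabels each site's bulk allele depths so the counted "index allele" is
#' the allele carried by the green parent: if the green parent is
#' homozygous-ALT the index allele is ALT; if homozygous-REF, REF and ALT
#' swap roles. Downstream SNP-indices then measure the green-parent allele
#' fraction regardless of which strand the caller put in REF.
#'
#' @param sites filtered sites from [select_informative()].
#' @return the same data.frame with added columns `index_allele`
#'   (`"ref"`/`"alt"`) and polarized depths `gb_idx`, `gb_oth`, `yb_idx`,
#'   `yb_oth`. Idempotent.
#' @export
polarize <- function(sites) {
  if (isTRUE(attr(sites, "polarized"))) return(sites)
  bad <- !sites$parent_green_gt %in% c("hom_ref", "hom_alt")
  if (any(bad))
    stop(sum(bad), " site(s) with het/missing green parent; ",
         "run select_informative() first")
  green_alt <- sites$parent_green_gt == "hom_alt"
  sites$index_allele <- ifelse(green_alt, "alt", "ref")
  sites$gb_idx <- ifelse(green_alt, sites$gb_alt, sites$gb_ref)
  sites$gb_oth <- ifelse(green_alt, sites$gb_ref, sites$gb_alt)
  sites$yb_idx <- ifelse(green_alt, sites$yb_alt, sites$yb_ref)
  sites$yb_oth <- ifelse(green_alt, sites$yb_ref, sites$yb_alt)
  attr(sites, "polarized") <- TRUE
  sites
}

#' Write / read the filtered-sites table
#'
#' @param sites a variant-site data.frame.
#' @param path TSV path.
#' @return `write_sites_tsv`: the path, invisibly. `read_sites_tsv`: the
#'   data.frame.
#' @export
write_sites_tsv <- function(sites, path) {
  write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sites_tsv
#' @export
read_sites_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}
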