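#' Per-bulk SNP-index
#'
#' The SNP-index at a site is the fraction of that bulk's reads carrying the
#' index (green-parent) allele: 0 when every read matches the yellow parent,
#' 1 when every read matches the green parent.
#'
#' @param index_allele_depth,other_allele_depth non-negative read counts
#'   (vectorized).
#' @return numeric in \[0, 1\].
#' @examples
#' snp_index(20, 0)   # 1.0
#' snp_index(7, 8)    # 7/15
#' @export
snp_index <- function(index_allele_depth, other_allele_depth) {
  stopifnot(all(index_allele_depth >= 0), all(other_allele_depth >= 0))
  tot <- index_allele_depth + other_allele_depth
  if (any(tot == 0))
    stop("SNP-index undefined at zero total depth; ",
         "such sites must be removed by the depth filter")
  index_allele_depth / tot
}

#' Delta(SNP-index)
#'
#' Green-bulk index minus yellow-bulk index. Near 0 at sites unlinked to the
#' trait; approaches 1 - 7/15 = 8/15 in expectation at a causal locus of
#' this two-locus recessive model, because the green bulk is fixed for the
#' green-parent allele while yellow-phenotype F2s carry it at frequency 7/15.
#'
#' @param index_green,index_yellow per-bulk SNP-indices in \[0, 1\].
#' @return numeric in \[-1, 1\]; antisymmetric under bulk swap.
#' @export
delta_index <- function(index_green, index_yellow) {
  stopifnot(all(index_green >= 0 & index_green <= 1),
            all(index_yellow >= 0 & index_yellow <= 1))
  index_green - index_yellow
}

#' Two-sided Fisher exact test of a 2x2 allele-count table
#'
#' Exact P for the bulk x allele table, using the conventional
#' probability-mass rule: the sum of hypergeometric probabilities of all
#' tables with the observed margins whose probability does not exceed that
#' of the observed table. Vectorized over sites.
#'
#' @param green_ref,green_alt,yellow_ref,yellow_alt non-negative integer
#'   allele depths for the two bulks.
#' @return two-sided P in (0, 1\]. An all-zero table returns 1 (with a
#'   message).
#' @examples
#' fisher_test(5, 5, 5, 5)      # 1: perfectly balanced
#' fisher_test(10, 0, 0, 10)    # 2 / choose(20, 10)
#' @export
fisher_test <- function(green_ref, green_alt, yellow_ref, yellow_alt) {
  n <- length(green_ref)
  stopifnot(length(green_alt) == n, length(yellow_ref) == n,
            length(yellow_alt) == n,
            all(c(green_ref, green_alt, yellow_ref, yellow_alt) >= 0))
  p <- vapply(seq_len(n), function(i) {
    fisher_2x2_p(green_ref[i], green_alt[i], yellow_ref[i], yellow_alt[i])
  }, 0)
  if (any(is.na(p))) {
    message(sum(is.na(p)), " all-zero table(s): P set to 1 by convention")
    p[is.na(p)] <- 1
  }
  p
}

# scalar core: X = green_ref ~ Hypergeom(margins); NA flags an empty table
fisher_2x2_p <- function(a, b, c, d) {
  N <- a + b + c + d
  if (N == 0) return(NA_real_)
  m <- a + b          # green-bulk total
  k <- a + c          # ref-allele total
  lo <- max(0L, k - (N - m))
  hi <- min(k, m)
  pr <- dhyper(lo:hi, m, N - m, k)
  p_obs <- pr[a - lo + 1L]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

#' Per-site SNP-index table
#'
#' Computes, for every polarized site, the SNP-index in each bulk, their
#' difference, and the Fisher exact P between bulks, sorted by (chrom, pos).
#'
#' @param sites polarized sites from [polarize()].
#' @return data.frame with chrom, pos, index_green, index_yellow, delta,
#'   fisher_p, and the four polarized depth columns.
#' @export
compute_index_table <- function(sites) {
  if (!isTRUE(attr(sites, "polarized")))
    stop("sites must be polarized; call polarize() first")
  if (nrow(sites) == 0L)
    return(data.frame(chrom = character(), pos = numeric(),
                      index_green = numeric(), index_yellow = numeric(),
                      delta = numeric(), fisher_p = numeric(),
                      gb_idx = numeric(), gb_oth = numeric(),
                      yb_idx = numeric(), yb_oth = numeric()))
  o <- order(sites$chrom, sites$pos)
  s <- sites[o, , drop = FALSE]
  ig <- snp_index(s$gb_idx, s$gb_oth)
  iy <- snp_index(s$yb_idx, s$yb_oth)
  out <- data.frame(chrom = s$chrom, pos = s$pos,
                    index_green = ig, index_yellow = iy,
                    delta = delta_index(ig, iy),
                    fisher_p = fisher_test(s$gb_idx, s$gb_oth,
                                           s$yb_idx, s$yb_oth),
                    gb_idx = s$gb_idx, gb_oth = s$gb_oth,
                    yb_idx = s$yb_idx, yb_oth = s$yb_oth,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
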