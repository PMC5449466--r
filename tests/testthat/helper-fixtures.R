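# small stated-world variants used across test files

small_cross <- function(seed = NULL, n_f2 = 150L, bulk_size = 8L, ...) {
  cross_config(
    chrom_lengths = c(chr01 = 5e6, chr02 = 5e6),
    causal_loci = data.frame(chrom = c("chr01", "chr02"),
                             pos = c(3e6, 1.5e6)),
    n_f2 = n_f2, bulk_size = bulk_size, marker_spacing_bp = 1e5,
    seed = seed, ...)
}

# hand-built variant table in read_variants() column layout
toy_sites <- function(n = 4, chrom = "chr01", pos = NULL, qual = 500,
                      p_y = "hom_ref", p_g = "hom_alt",
                      yb = c(30, 30), gb = c(30, 30)) {
  if (is.null(pos)) pos <- seq_len(n) * 1000
  n <- length(pos)
  data.frame(chrom = rep(chrom, n), pos = pos,
             ref = rep("A", n), alt = rep("G", n),
             qual = rep(qual, length.out = n),
             parent_yellow_gt = rep(p_y, length.out = n),
             parent_green_gt = rep(p_g, length.out = n),
             py_ref = rep(10, n), py_alt = rep(0, n),
             pg_ref = rep(0, n), pg_alt = rep(10, n),
             yb_ref = rep(yb[1], length.out = n),
             yb_alt = rep(yb[2], length.out = n),
             gb_ref = rep(gb[1], length.out = n),
             gb_alt = rep(gb[2], length.out = n),
             stringsAsFactors = FALSE)
}

# independent Fisher oracle: exhaustive enumeration over tables with the
# observed margins, probabilities from lchoose (no dhyper), conventional
# probability-mass two-sided rule
fisher_oracle <- function(a, b, c, d) {
  N <- a + b + c + d
  if (N == 0) return(1)
  m <- a + b; k <- a + c
  supp <- max(0, k - (N - m)):min(k, m)
  logp <- lchoose(m, supp) + lchoose(N - m, k - supp) - lchoose(N, k)
  pr <- exp(logp)
  sum(pr[pr <= pr[supp == a] * (1 + 1e-7)])
}
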