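#' Haldane map function
#'
#' Converts a genetic distance in centiMorgan to a recombination fraction
#' under the Haldane (no-interference) model, r = (1 - exp(-2d/100)) / 2.
#'
#' @param d_cm genetic distance in centiMorgan (vectorized, >= 0).
#' @return recombination fraction in \[0, 0.5).
#' @examples
#' haldane_r(0)            # 0: complete linkage
#' haldane_r(2.5)          # 1 Mb at 2.5 cM/Mb
#' haldane_r(1e6)          # -> 0.5: free recombination
#' @export
haldane_r <- function(d_cm) {
  stopifnot(all(d_cm >= 0))
  0.5 * (1 - exp(-2 * d_cm / 100))
}

# ancestry switches along a position ladder for `n` gametes at once.
# Returns an integer matrix (positions x gametes) of 0/1 = which parental
# haplotype is read at each position (Markov chain, Haldane transition).
sim_meiosis_indicator <- function(positions, n, cm_per_mb) {
  m <- length(positions)
  start <- rbinom(n, 1L, 0.5)
  if (m == 1L) return(matrix(as.integer(start), nrow = 1L))
  r <- haldane_r(diff(positions) / 1e6 * cm_per_mb)
  sw <- matrix(rbinom(n * (m - 1L), 1L, rep(r, n)), nrow = m - 1L)
  ind <- rbind(start, apply(sw, 2L, cumsum) + rep(start, each = m - 1L))
  dimnames(ind) <- NULL
  matrix(as.integer(ind %% 2L), nrow = m)
}

#' Draw one recombinant gamete from a parent
#'
#' Produces a single gamete haplotype along a ladder of template positions.
#' Between adjacent positions d cM apart, the haplotype being copied switches
#' with Haldane probability r = (1 - exp(-2d/100))/2; chromosomes (separate
#' calls) assort independently.
#'
#' @param hap1,hap2 the parent's two haplotypes: equal-length vectors of
#'   allele/ancestry codes at `positions`.
#' @param positions increasing bp positions of the template sites.
#' @param cm_per_mb map density (cM per Mb).
#' @return a vector of the same length as `positions`.
#' @examples
#' set.seed(1)
#' g <- make_gamete(rep(0, 100), rep(1, 100), seq(1e5, 1e7, by = 1e5))
#' table(g)
#' @export
make_gamete <- function(hap1, hap2, positions, cm_per_mb = 2.5) {
  stopifnot(length(hap1) == length(positions),
            length(hap2) == length(positions),
            !is.unsorted(positions, strictly = TRUE))
  ind <- sim_meiosis_indicator(positions, 1L, cm_per_mb)[, 1L]
  ifelse(ind == 0L, hap1, hap2)
}

#' Phenotype under duplicate-dominant epistasis
#'
#' Two unlinked recessive loci: the recessive (green) phenotype appears only
#' when an individual is homozygous for the green-parent allele ("BB") at
#' BOTH loci; any dominant allele at either locus yields yellow. In an F2
#' this gives the 15:1 yellow:green ratio.
#'
#' @param genotype_locus1,genotype_locus2 genotype codes, each one of
#'   `"AA"`, `"AB"`, `"BB"` (B = green-parent allele). Vectorized.
#' @return character vector of `"yellow"` / `"green"`.
#' @examples
#' phenotype_of("BB", "BB")  # green
#' phenotype_of("AA", "BB")  # yellow
#' @export
phenotype_of <- function(genotype_locus1, genotype_locus2) {
  valid <- c("AA", "AB", "BB")
  if (!all(genotype_locus1 %in% valid) || !all(genotype_locus2 %in% valid))
    stop("genotype codes must be one of 'AA', 'AB', 'BB'")
  ifelse(genotype_locus1 == "BB" & genotype_locus2 == "BB",
         "green", "yellow")
}

geno_code_to_char <- function(g) c("AA", "AB", "BB")[g + 1L]

#' Simulate an F2 population from the F1 of a biparental cross
#'
#' Each F2 individual is the union of two independent F1 gametes. The F1
#' carries one yellow-parent and one green-parent haplotype per chromosome,
#' so a gamete's ancestry along the marker ladder is a Markov chain with
#' Haldane transition probabilities. Phenotypes follow [phenotype_of()] at
#' the two causal loci.
#'
#' @param config a [cross_config()].
#' @return an object of class `f2_population`: per-chromosome template
#'   positions and two ancestry matrices (positions x individuals, 0 =
#'   yellow-parent, 1 = green-parent allele), causal-locus genotype codes
#'   (0/1/2 copies of the green-parent allele), and phenotypes.
#' @examples
#' pop <- simulate_f2(cross_config(
#'   chrom_lengths = c(chr01 = 2e6, chr02 = 2e6),
#'   causal_loci = data.frame(chrom = c("chr01", "chr02"), pos = c(1e6, 1e6)),
#'   n_f2 = 50, marker_spacing_bp = 1e5, seed = 7))
#' table(pop$phenotype)
#' @export
simulate_f2 <- function(config) {
  stopifnot(inherits(config, "cross_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  templ <- template_positions(config)
  n <- config$n_f2
  hap1 <- hap2 <- list()
  for (ch in names(templ)) {
    pos <- templ[[ch]]
    # F1 haplotypes are constant 0 (yellow parent) / 1 (green parent), so a
    # gamete equals its meiosis indicator chain directly
    hap1[[ch]] <- sim_meiosis_indicator(pos, n, config$cm_per_mb)
    hap2[[ch]] <- sim_meiosis_indicator(pos, n, config$cm_per_mb)
  }
  causal_geno <- matrix(0L, nrow = n, ncol = 2L)
  for (k in 1:2) {
    ch <- config$causal_loci$chrom[k]
    i <- match(config$causal_loci$pos[k], templ[[ch]])
    causal_geno[, k] <- hap1[[ch]][i, ] + hap2[[ch]][i, ]
  }
  phen <- phenotype_of(geno_code_to_char(causal_geno[, 1L]),
                       geno_code_to_char(causal_geno[, 2L]))
  structure(list(config = config, template = templ,
                 hap1 = hap1, hap2 = hap2,
                 causal_geno = causal_geno, phenotype = phen),
            class = "f2_population")
}

#' @export
print.f2_population <- function(x, ...) {
  cat("f2_population: n =", length(x$phenotype), "(",
      sum(x$phenotype == "yellow"), "yellow /",
      sum(x$phenotype == "green"), "green ),",
      sum(lengths(x$template)), "template sites\n")
  invisible(x)
}

#' Ancestry blocks of one individual
#'
#' Converts an individual's per-site ancestry into haplotype blocks that tile
#' each chromosome exactly (1-based inclusive bp intervals). Crossover
#' breakpoints are placed at the midpoint between adjacent template sites of
#' different ancestry (the simulator does not resolve them more finely).
#'
#' @param pop an `f2_population`.
#' @param i individual index.
#' @return a data.frame with columns chrom, haplotype (1/2), start, end,
#'   ancestry ("yellow"/"green").
#' @export
ancestry_blocks <- function(pop, i) {
  stopifnot(inherits(pop, "f2_population"))
  out <- list()
  for (ch in names(pop$template)) {
    pos <- pop$template[[ch]]
    len <- pop$config$chrom_lengths[[ch]]
    for (h in 1:2) {
      anc <- pop[[paste0("hap", h)]][[ch]][, i]
      r <- rle(anc)
      k <- length(r$lengths)
      last <- cumsum(r$lengths)          # index of last site in each run
      first <- c(1L, head(last, -1L) + 1L)
      # block boundary = midpoint between flanking sites of different runs
      cuts <- if (k > 1L)
        floor((pos[last[-k]] + pos[first[-1L]]) / 2) else numeric(0)
      start <- c(1, cuts + 1)
      end <- c(cuts, len)
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, haplotype = h, start = start, end = end,
        ancestry = c("yellow", "green")[r$values + 1L])
    }
  }
  do.call(rbind, out)
}

#' Genotype of one individual at an arbitrary position
#'
#' @param pop an `f2_population`.
#' @param i individual index.
#' @param chrom chromosome name.
#' @param pos bp position (1-based).
#' @return `"AA"`, `"AB"` or `"BB"` (B = green-parent allele).
#' @export
genotype_at <- function(pop, i, chrom, pos) {
  stopifnot(inherits(pop, "f2_population"), chrom %in% names(pop$template))
  blocks <- ancestry_blocks(pop, i)
  b <- blocks[blocks$chrom == chrom & blocks$start <= pos & blocks$end >= pos, ]
  stopifnot(nrow(b) == 2L)
  geno_code_to_char(sum(b$ancestry == "green"))
}

#' Select phenotype bulks from an F2 population
#'
#' Random sample without replacement of `bulk_size` individuals per
#' phenotype class, mimicking equal-mass DNA pooling of selected progeny.
#'
#' @param x an `f2_population`, or a character vector of per-individual
#'   phenotypes (`"yellow"`/`"green"`).
#' @param bulk_size individuals per bulk.
#' @return list with integer index vectors `yellow` and `green`.
#' @export
select_bulks <- function(x, bulk_size) {
  phen <- if (inherits(x, "f2_population")) x$phenotype else x
  stopifnot(all(phen %in% c("yellow", "green")), bulk_size >= 1)
  idx_y <- which(phen == "yellow")
  idx_g <- which(phen == "green")
  if (length(idx_g) < bulk_size)
    stop("cannot form green bulk: need ", bulk_size, " green individuals, ",
         "only ", length(idx_g), " available")
  if (length(idx_y) < bulk_size)
    stop("cannot form yellow bulk: need ", bulk_size, " yellow individuals, ",
         "only ", length(idx_y), " available")
  list(yellow = sort(sample(idx_y, bulk_size)),
       green = sort(sample(idx_g, bulk_size)))
}

# true green-parent allele frequency in a bulk at every template site
bulk_allele_freqs <- function(pop, members) {
  lapply(setNames(names(pop$template), names(pop$template)), function(ch) {
    (rowSums(pop$hap1[[ch]][, members, drop = FALSE]) +
       rowSums(pop$hap2[[ch]][, members, drop = FALSE])) /
      (2 * length(members))
  })
}

#' Simulate sequencing depths for bulks and parents at each site
#'
#' Total depth per site and sample is Poisson; reads carrying the
#' green-parent allele are Binomial(depth, f(1-eps) + (1-f)eps) where f is
#' the sample's true green-allele frequency and eps the symmetric per-read
#' miscall rate. Parents are homozygous, f = 0 (yellow parent) and f = 1
#' (green parent).
#'
#' @param f_green,f_yellow true green-parent allele frequency per site in
#'   the green and yellow bulk (vectors in \[0,1\]).
#' @param config a [cross_config()] (uses depth_bulk, depth_parent,
#'   seq_error).
#' @return data.frame with per-site green-allele (`*_g`) and other-allele
#'   (`*_y`) read counts for samples pg/py (parents) and gb/yb (bulks).
#' @export
simulate_depths <- function(f_green, f_yellow, config) {
  stopifnot(length(f_green) == length(f_yellow),
            all(f_green >= 0 & f_green <= 1),
            all(f_yellow >= 0 & f_yellow <= 1))
  n <- length(f_green)
  eps <- config$seq_error
  draw <- function(f, lambda) {
    d <- rpois(n, lambda)
    g <- rbinom(n, d, f * (1 - eps) + (1 - f) * eps)
    list(g = g, y = d - g)
  }
  gb <- draw(f_green, config$depth_bulk)
  yb <- draw(f_yellow, config$depth_bulk)
  pg <- draw(rep(1, n), config$depth_parent)
  py <- draw(rep(0, n), config$depth_parent)
  data.frame(py_g = py$g, py_y = py$y, pg_g = pg$g, pg_y = pg$y,
             yb_g = yb$g, yb_y = yb$y, gb_g = gb$g, gb_y = gb$y)
}

#' Simulate F2:3 seed-color counts by selfing each F2 individual
#'
#' Each line's green-seed probability is the product over the two causal
#' loci of the chance a selfed offspring is homozygous recessive there
#' (AA: 0, AB: 1/4, BB: 1; loci are unlinked, so within-line linkage is
#' ignored). Expected F2:3 class proportions (all-yellow : 3:1 : 15:1 :
#' all-green) are 7:4:4:1.
#'
#' @param x an `f2_population`, or an n x 2 integer matrix of causal-locus
#'   genotype codes (0/1/2 copies of the green-parent allele).
#' @param config a [cross_config()] (uses f3_seeds_per_line).
#' @return data.frame with line_id, n_yellow, n_green.
#' @export
simulate_f3_counts <- function(x, config) {
  geno <- if (inherits(x, "f2_population")) x$causal_geno else x
  stopifnot(is.matrix(geno), ncol(geno) == 2L, all(geno %in% 0:2))
  p_bb <- c(0, 0.25, 1)
  p_green <- p_bb[geno[, 1L] + 1L] * p_bb[geno[, 2L] + 1L]
  n <- nrow(geno)
  g <- rbinom(n, config$f3_seeds_per_line, p_green)
  data.frame(line_id = sprintf("F2_%04d", seq_len(n)),
             n_yellow = config$f3_seeds_per_line - g, n_green = g)
}

#' Draw independent two-locus F2 genotypes (no linkage bookkeeping)
#'
#' Lightweight alternative to [simulate_f2()] when only the two causal-locus
#' genotypes matter (segregation and bulk-frequency studies): each locus is
#' an independent 1:2:1 draw.
#'
#' @param n number of individuals.
#' @return n x 2 integer matrix of genotype codes (0/1/2).
#' @export
sim_two_locus_genotypes <- function(n) {
  matrix(sample(0:2, 2L * n, replace = TRUE, prob = c(1, 2, 1) / 4),
         ncol = 2L)
}
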