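test_that("haldane_r has the right limits and closed form", {
  expect_identical(haldane_r(0), 0)
  expect_equal(haldane_r(1e9), 0.5)
  # 1 Mb at 2.5 cM/Mb
  expect_equal(haldane_r(2.5), 0.5 * (1 - exp(-0.05)), tolerance = 1e-12)
  expect_equal(haldane_r(2.5), 0.02438529, tolerance = 1e-6)
  expect_true(all(diff(haldane_r(seq(0, 300, by = 0.5))) > 0))
})

test_that("phenotype_of implements duplicate-dominant epistasis", {
  expect_identical(phenotype_of("BB", "BB"), "green")
  expect_identical(phenotype_of("AA", "BB"), "yellow")
  expect_error(phenotype_of("XX", "BB"), "genotype codes")
  # enumeration of the 16 equiprobable two-locus gamete combinations:
  # each locus has gametes {A, B} from each F1 parent
  g1 <- expand.grid(a = c("A", "B"), b = c("A", "B"),
                    c = c("A", "B"), d = c("A", "B"),
                    stringsAsFactors = FALSE)
  geno <- function(x, y) paste0(sort(c(as.character(x),
                                       as.character(y))), collapse = "")
  phen <- mapply(function(a, b, c, d)
    phenotype_of(geno(a, b), geno(c, d)), g1$a, g1$b, g1$c, g1$d)
  expect_equal(mean(phen == "green"), 1 / 16)
})

test_that("make_gamete respects linkage limits", {
  pos <- seq(1e5, 2e6, by = 1e5)
  set.seed(11)
  # essentially zero map distance: alleles co-inherited, gamete is one
  # parental haplotype end to end
  g <- make_gamete(rep(0L, 20), rep(1L, 20), pos, cm_per_mb = 1e-9)
  expect_true(all(g == g[1]))
  # huge distance: adjacent sites recombine freely (r -> 0.5)
  g2 <- replicate(400, {
    h <- make_gamete(rep(0L, 2), rep(1L, 2), c(1, 2e6), cm_per_mb = 5e4)
    h[1] != h[2]
  })
  expect_gt(mean(g2), 0.40)
  expect_lt(mean(g2), 0.60)
})

test_that("simulate_f2 is deterministic and diploid-closed", {
  cfg <- small_cross(seed = 5)
  p1 <- simulate_f2(cfg)
  p2 <- simulate_f2(cfg)
  expect_identical(p1$hap1, p2$hap1)
  expect_identical(p1$phenotype, p2$phenotype)
  expect_true(all(p1$causal_geno %in% 0:2))
  for (ch in names(p1$template))
    expect_true(all((p1$hap1[[ch]] + p1$hap2[[ch]]) %in% 0:2))
})

test_that("F2 segregation does not reject 15:1 at alpha = 0.01", {
  # large-n light path (two unlinked loci are all that matter)
  set.seed(21)
  geno <- sim_two_locus_genotypes(10000)
  phen <- phenotype_of(c("AA", "AB", "BB")[geno[, 1] + 1],
                       c("AA", "AB", "BB")[geno[, 2] + 1])
  res <- chi2_gof(sum(phen == "yellow"), sum(phen == "green"),
                  ratio = c(15, 1))
  expect_gt(res$p_uncorrected, 0.01)
})

test_that("mean green fraction matches 1/16 over 200 replicates", {
  set.seed(31)
  R <- 200; n <- 495
  frac <- replicate(R, {
    geno <- sim_two_locus_genotypes(n)
    mean(geno[, 1] == 2 & geno[, 2] == 2)
  })
  se <- sqrt(1 / 16 * 15 / 16 / (R * n))
  expect_lt(abs(mean(frac) - 1 / 16), 3 * se)
})

test_that("ancestry blocks tile each chromosome exactly", {
  pop <- simulate_f2(small_cross(seed = 13))
  for (i in c(1, 50, 150)) {
    bl <- ancestry_blocks(pop, i)
    for (ch in names(pop$config$chrom_lengths)) {
      for (h in 1:2) {
        b <- bl[bl$chrom == ch & bl$haplotype == h, ]
        b <- b[order(b$start), ]
        expect_equal(b$start[1], 1)
        expect_equal(b$end[nrow(b)],
                     unname(pop$config$chrom_lengths[[ch]]))
        if (nrow(b) > 1)
          expect_true(all(b$start[-1] == head(b$end, -1) + 1))
      }
    }
  }
  expect_true(genotype_at(pop, 1, "chr01", 3e6) %in% c("AA", "AB", "BB"))
})

test_that("select_bulks: green bulk fixed at causal loci, errors on shortfall", {
  cfg <- small_cross(seed = 17, n_f2 = 400L)
  pop <- simulate_f2(cfg)
  set.seed(1)
  bulks <- select_bulks(pop, 8)
  expect_length(bulks$green, 8)
  expect_true(all(pop$phenotype[bulks$green] == "green"))
  # all green individuals are double-homozygous for the green allele
  fg <- bsascan:::bulk_allele_freqs(pop, bulks$green)
  for (k in 1:2) {
    ch <- cfg$causal_loci$chrom[k]
    i <- match(cfg$causal_loci$pos[k], pop$template[[ch]])
    expect_identical(fg[[ch]][i], 1)
  }
  expect_error(select_bulks(rep("yellow", 50), 5), "green")
  expect_error(select_bulks(c(rep("green", 5), rep("yellow", 2)), 5),
               "yellow bulk.*only 2")
})

test_that("yellow-bulk causal allele frequency converges to 7/15", {
  set.seed(41)
  reps <- 60
  f <- replicate(reps, {
    repeat {   # re-draw crosses that leave the green bulk short, as the
      geno <- sim_two_locus_genotypes(495)   # simulator does
      phen <- ifelse(geno[, 1] == 2 & geno[, 2] == 2, "green", "yellow")
      if (sum(phen == "green") >= 30) break
    }
    members <- select_bulks(phen, 30)$yellow
    mean(geno[members, 1]) / 2
  })
  expect_lt(abs(mean(f) - 7 / 15), 0.03)
})

test_that("unlinked markers sit at frequency ~0.5 in both bulks", {
  # at 2.5 cM/Mb a 5-Mb toy chromosome is linked end to end, so crank the
  # map density: 2.5 Mb from the causal locus is then > 200 cM (r ~ 0.5)
  for (s in 19 + 0:20 * 100) {   # redraw crosses short of 30 green
    pop <- simulate_f2(small_cross(seed = s, n_f2 = 500L,
                                   bulk_size = 30L, cm_per_mb = 100))
    if (sum(pop$phenotype == "green") >= 30) break
  }
  set.seed(2)
  bulks <- select_bulks(pop, 30)
  far <- which(pop$template$chr01 < 5e5)   # causal locus is at 3 Mb
  fy <- bsascan:::bulk_allele_freqs(pop, bulks$yellow)$chr01[far]
  fg <- bsascan:::bulk_allele_freqs(pop, bulks$green)$chr01[far]
  expect_lt(abs(mean(fy) - 0.5), 0.1)
  expect_lt(abs(mean(fg) - 0.5), 0.15)  # green bulk is smaller-sample
})

test_that("simulate_depths: degenerate and mean-depth behavior", {
  cfg <- small_cross()
  cfg$seq_error <- 0
  set.seed(7)
  n <- 10000
  d1 <- simulate_depths(rep(1, n), rep(0, n), cfg)
  expect_true(all(d1$gb_y == 0))   # f = 1, eps = 0: all green-allele reads
  expect_true(all(d1$yb_g == 0))   # f = 0: none
  depth <- d1$gb_g + d1$gb_y
  expect_lt(abs(mean(depth) - cfg$depth_bulk) / cfg$depth_bulk, 0.02)
})

test_that("simulate_f3_counts matches per-genotype expectations", {
  cfg <- small_cross()
  cfg$f3_seeds_per_line <- 60L
  set.seed(9)
  n <- 4000
  for (case in list(list(g = c(0, 1), p = 0),       # (AA, AB)
                    list(g = c(1, 2), p = 1 / 4),   # (AB, BB)
                    list(g = c(1, 1), p = 1 / 16))) { # (AB, AB)
    geno <- matrix(rep(case$g, each = n), ncol = 2)
    cnt <- simulate_f3_counts(geno, cfg)
    frac <- sum(cnt$n_green) / sum(cnt$n_green + cnt$n_yellow)
    if (case$p == 0) expect_identical(frac, 0)
    else expect_lt(abs(frac - case$p), 0.02)
  }
})

test_that("write_dataset round-trips through the VCF and is byte-deterministic", {
  cfg <- small_cross(seed = 23)
  ds <- simulate_cross_dataset(cfg)
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  p1 <- write_dataset(ds, d1)
  sites <- read_variants(p1$vcf)
  expect_equal(nrow(sites), nrow(ds$sites))
  for (col in c("pos", "yb_ref", "yb_alt", "gb_ref", "gb_alt",
                "py_ref", "py_alt", "pg_ref", "pg_alt"))
    expect_equal(sites[[col]], ds$sites[[col]])
  expect_equal(sites$parent_green_gt, ds$sites$parent_green_gt)
  # truth has exactly 2 causal loci
  truth <- jsonlite::read_json(p1$truth, simplifyVector = TRUE)
  expect_length(truth$causal_loci$pos, 2L)   # exactly 2 causal loci
  # identical seed => byte-identical files
  ds2 <- simulate_cross_dataset(cfg)
  p2 <- write_dataset(ds2, d2)
  for (f in names(p1))
    expect_identical(unname(tools::md5sum(p1[[f]])),
                     unname(tools::md5sum(p2[[f]])))
  # format contract against an external validator when present
  if (nzchar(Sys.which("bcftools"))) {
    ok <- system2("bcftools", c("view", p1$vcf), stdout = FALSE,
                  stderr = FALSE)
    expect_identical(ok, 0L)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("cross_config validates its invariants", {
  expect_error(cross_config(causal_loci = data.frame(
    chrom = "chr01", pos = 1e6)), "exactly 2")
  expect_error(cross_config(causal_loci = data.frame(
    chrom = c("chr01", "chr02"), pos = c(1e6, 9e9))), "outside")
  expect_error(cross_config(seq_error = -1))
  expect_error(cross_config(depth_bulk = 0))
})
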