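test_that("consensus_genotype takes the majority, NA on ties", {
  expect_identical(consensus_genotype(c("H", "H", "B")), "H")
  expect_identical(consensus_genotype(c("B", NA, "B")), "B")
  expect_true(is.na(consensus_genotype(c("A", "B"))))
  expect_true(is.na(consensus_genotype(c(NA_character_, NA))))
})

test_that("assign_controlling_locus follows the recessive-background rule", {
  expect_identical(assign_controlling_locus("H", "B"), "locus1")
  expect_identical(assign_controlling_locus("B", "H"), "locus2")
  # both regions het would segregate 15:1, not 3:1
  expect_identical(assign_controlling_locus("H", "H"), "inconsistent")
  expect_identical(assign_controlling_locus("A", "B"), "inconsistent")
  expect_identical(assign_controlling_locus(NA, "B"), "inconsistent")
  expect_equal(assign_controlling_locus(c("H", "B"), c("B", "H")),
               c("locus1", "locus2"))
})

test_that("infer_causal_genotype maps segregation classes", {
  expect_equal(infer_causal_genotype(
    c("all_recessive", "seg_3_1", "all_dominant", "ambiguous")),
    c("B", "H", "A", NA))
  expect_error(infer_causal_genotype("what"), "unknown")
})

test_that("find_recombinants detects breakpoints between flanking markers", {
  pos <- c(100e3, 200e3, 300e3)
  expect_equal(nrow(find_recombinants(rbind(l1 = c("H", "H", "H")), pos)),
               0L)
  r <- find_recombinants(rbind(l1 = c("H", "H", "B")), pos)
  expect_equal(r$left_pos, 200e3)
  expect_equal(r$right_pos, 300e3)
  # missing markers are bridged
  r2 <- find_recombinants(rbind(l1 = c("H", NA, "B")), pos)
  expect_equal(unlist(r2[, 2:3], use.names = FALSE), c(100e3, 300e3))
  # 20-line fixture with 6 planted recombinants
  set.seed(20)
  calls <- matrix("H", 20, 5,
                  dimnames = list(sprintf("l%02d", 1:20), NULL))
  rec_lines <- c(2, 5, 9, 12, 17, 20)
  for (i in rec_lines) calls[i, sample(2:5, 1):5] <- "B"
  found <- find_recombinants(calls, c(1, 2, 3, 4, 5) * 1e5)
  expect_equal(sort(unique(found$line_id)), sprintf("l%02d", rec_lines))
  expect_equal(nrow(found), 6L)
})

test_that("refine_interval intersects open-flank constraints", {
  # single line: locus in (100, 300]
  one <- refine_interval(rbind(l1 = c("A", "H", "H")), c(100, 200, 300),
                         "H")
  expect_equal(c(one$start, one$end), c(101, 300))
  # two lines narrow from both sides
  two <- refine_interval(rbind(l1 = c("A", "H", "H", "H"),
                               l2 = c("H", "H", "H", "B")),
                         c(100, 200, 300, 400), c("H", "H"))
  expect_equal(c(two$start, two$end), c(101, 399))
  # a non-recombinant line adds no constraint
  three <- refine_interval(rbind(l1 = c("A", "H", "H", "H"),
                                 l2 = c("H", "H", "H", "B"),
                                 l3 = c("H", "H", "H", "H")),
                           c(100, 200, 300, 400), c("H", "H", "H"))
  expect_equal(c(three$start, three$end), c(two$start, two$end))
  expect_equal(three$n_informative, 2L)
  # contradictions fail loudly with the offending lines
  expect_error(refine_interval(rbind(l1 = c("A", "A", "H"),
                                     l2 = c("H", "A", "A")),
                               c(100, 200, 300), c("H", "H")),
               "contradictory.*l2")
  expect_error(refine_interval(rbind(l1 = c("A", "A", "A")),
                               c(100, 200, 300), "H"),
               "no marker matching")
})

test_that("interval width is non-increasing as lines are added", {
  set.seed(22)
  pos <- seq(1e5, 2e6, by = 5e4)
  truth_pos <- 1.05e6
  make_line <- function() {
    # random heterozygous line recombining around the locus
    g <- rep("H", length(pos))
    if (runif(1) < 0.5) g[pos < truth_pos - runif(1, 0, 8e5)] <- "A"
    if (runif(1) < 0.5) g[pos > truth_pos + runif(1, 0, 8e5)] <- "B"
    g
  }
  calls <- do.call(rbind, replicate(15, make_line(), simplify = FALSE))
  rownames(calls) <- sprintf("l%02d", 1:15)
  widths <- vapply(1:15, function(k) {
    iv <- refine_interval(calls[1:k, , drop = FALSE], pos,
                          rep("H", k))
    iv$end - iv$start + 1
  }, 0)
  expect_true(all(diff(widths) <= 0))
  iv <- refine_interval(calls, pos, rep("H", 15))
  expect_true(iv$start <= truth_pos && iv$end >= truth_pos)
})

test_that("marker_matrix pivots the long table", {
  pop <- simulate_f2(small_cross(seed = 33))
  mk <- finemap_marker_calls(pop, halfwidth_bp = 5e5, spacing_bp = 1e5)
  mm <- marker_matrix(mk, region = "region1")
  expect_true(is.matrix(mm$calls))
  expect_equal(nrow(mm$calls), 150L)
  expect_false(is.unsorted(mm$positions, strictly = TRUE))
  # calls agree with the population's true genotypes at a marker
  j <- ceiling(length(mm$positions) / 2)
  ch <- small_cross()$causal_loci$chrom[1]
  i <- match(mm$positions[j], pop$template[[ch]])
  truth <- c("A", "H", "B")[pop$hap1[[ch]][i, ] + pop$hap2[[ch]][i, ] + 1]
  expect_equal(unname(mm$calls[, j]), truth)
})

test_that("simulated fine mapping recovers and brackets the planted locus", {
  cfg <- small_cross(seed = 44, n_f2 = 200L)
  pop <- simulate_f2(cfg)
  mk <- finemap_marker_calls(pop, halfwidth_bp = 1e6, spacing_bp = 5e4)
  mm1 <- marker_matrix(mk, "region1")
  mm2 <- marker_matrix(mk, "region2")
  # consensus genotypes + controlling-locus assignment against truth
  cons1 <- apply(mm1$calls, 1, consensus_genotype)
  cons2 <- apply(mm2$calls, 1, consensus_genotype)
  truth_class <- ifelse(pop$causal_geno[, 1] == 1 & pop$causal_geno[, 2] == 2,
                        "locus1",
                 ifelse(pop$causal_geno[, 1] == 2 & pop$causal_geno[, 2] == 1,
                        "locus2", "other"))
  assigned <- assign_controlling_locus(cons1, cons2)
  sel <- truth_class != "other"
  expect_gt(mean(assigned[sel] == truth_class[sel]), 0.9)
  # error-free refinement: interval brackets the planted locus
  genos <- c("A", "H", "B")[pop$causal_geno[, 1] + 1]
  iv <- refine_interval(mm1$calls, mm1$positions, genos)
  expect_true(iv$start <= cfg$causal_loci$pos[1] &&
                iv$end >= cfg$causal_loci$pos[1])
})
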