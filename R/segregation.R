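#' Chi-square goodness of fit to a two-class segregation ratio
#'
#' Tests observed (yellow, green) counts against an expected a:b ratio with
#' 1 df, reporting both the uncorrected Pearson statistic and the Yates
#' continuity-corrected statistic, each with its upper-tail P.
#'
#' The default correction is the classical Yates form (|O-E| - 0.5)^2 / E
#' without flooring the absolute deviation at 0.5: for near-perfect fits
#' (|O-E| < 0.5) this makes the "corrected" statistic exceed the
#' uncorrected one — the historical convention most segregation tables in
#' the genetics literature follow. Set `floor_correction = TRUE` for the
#' variant max(|O-E| - 0.5, 0)^2 / E, which is never anticonservative.
#'
#' @param n_yellow,n_green observed counts (vectorized; equal length).
#' @param ratio expected yellow:green ratio as a length-2 positive vector,
#'   default `c(15, 1)`.
#' @param floor_correction floor |O-E| - 0.5 at 0 before squaring.
#' @return data.frame of class `chi2_gof` with columns n_yellow, n_green,
#'   expected_yellow, expected_green, chi2_uncorrected, chi2_corrected, df,
#'   p_uncorrected, p_corrected.
#' @examples
#' chi2_gof(295, 19)                       # chi2_corrected 0.0008
#' chi2_gof(45, 15, ratio = c(3, 1))       # perfect 3:1 fit
#' @export
chi2_gof <- function(n_yellow, n_green, ratio = c(15, 1),
                     floor_correction = FALSE) {
  stopifnot(length(ratio) == 2L, all(ratio > 0),
            length(n_yellow) == length(n_green),
            all(n_yellow >= 0), all(n_green >= 0),
            all(n_yellow + n_green >= 1))
  n <- n_yellow + n_green
  e_y <- n * ratio[1] / sum(ratio)
  e_g <- n * ratio[2] / sum(ratio)
  dev_y <- abs(n_yellow - e_y)
  dev_g <- abs(n_green - e_g)
  chi_u <- dev_y^2 / e_y + dev_g^2 / e_g
  corr <- function(d) if (floor_correction) pmax(d - 0.5, 0) else d - 0.5
  chi_c <- corr(dev_y)^2 / e_y + corr(dev_g)^2 / e_g
  out <- data.frame(
    n_yellow = n_yellow, n_green = n_green,
    expected_yellow = e_y, expected_green = e_g,
    chi2_uncorrected = chi_u, chi2_corrected = chi_c, df = 1L,
    p_uncorrected = pchisq(chi_u, 1, lower.tail = FALSE),
    p_corrected = pchisq(chi_c, 1, lower.tail = FALSE))
  class(out) <- c("chi2_gof", "data.frame")
  attr(out, "ratio") <- ratio
  out
}

#' Classify an F2:3 line from its seed-color counts
#'
#' Under the two-locus recessive model an F2 plant's selfed progeny
#' segregate all-yellow, 3:1, 15:1 or all-green according to its two-locus
#' genotype (expected class proportions 7:4:4:1). A line with green seeds
#' present and yellow seeds present is assigned by testing 3:1 and 15:1
#' (Yates-corrected chi-square): the ratio that is not rejected at `alpha`;
#' if both fit, the smaller statistic wins; if neither, `ambiguous`.
#'
#' @param n_yellow,n_green per-line seed counts (vectorized).
#' @param alpha rejection level for the per-ratio tests (default 0.05).
#' @return character vector over \{`all_dominant`, `seg_3_1`, `seg_15_1`,
#'   `all_recessive`, `ambiguous`\}.
#' @examples
#' classify_f3(c(60, 45, 57, 0), c(0, 15, 3, 60))
#' @export
classify_f3 <- function(n_yellow, n_green, alpha = 0.05) {
  stopifnot(length(n_yellow) == length(n_green),
            all(n_yellow + n_green >= 1))
  t3 <- chi2_gof(n_yellow, n_green, ratio = c(3, 1))
  t15 <- chi2_gof(n_yellow, n_green, ratio = c(15, 1))
  fit3 <- t3$p_corrected >= alpha
  fit15 <- t15$p_corrected >= alpha
  out <- rep("ambiguous", length(n_yellow))
  out[fit3 & !fit15] <- "seg_3_1"
  out[fit15 & !fit3] <- "seg_15_1"
  both <- fit3 & fit15
  out[both] <- ifelse(t3$chi2_corrected[both] <= t15$chi2_corrected[both],
                      "seg_3_1", "seg_15_1")
  out[n_green == 0] <- "all_dominant"
  out[n_yellow == 0] <- "all_recessive"
  out
}

#' Two-gene (duplicate-dominant) model test on F2:3 class counts
#'
#' Goodness of fit of the four observed F2:3 class counts (all-dominant,
#' 3:1-segregating, 15:1-segregating, all-recessive) to the 7:4:4:1
#' proportions expected when two unlinked recessive loci jointly control
#' the trait. Pearson chi-square, 3 df, no continuity correction.
#'
#' @param class_counts integer vector of length 4, ordered (all_dominant,
#'   seg_3_1, seg_15_1, all_recessive).
#' @param ratio expected class proportions, default `c(7, 4, 4, 1)`.
#' @return list with observed, expected, chi2, df, p_value.
#' @examples
#' two_gene_model_test(c(228, 133, 102, 32))
#' @export
two_gene_model_test <- function(class_counts, ratio = c(7, 4, 4, 1)) {
  stopifnot(length(class_counts) == 4L, all(class_counts >= 0),
            sum(class_counts) >= 1, length(ratio) == 4L, all(ratio > 0))
  expected <- sum(class_counts) * ratio / sum(ratio)
  if (any(expected < 1))
    warning("expected class count below 1; chi-square approximation weak")
  chi2 <- sum((class_counts - expected)^2 / expected)
  list(observed = class_counts, expected = expected, chi2 = chi2,
       df = 3L, p_value = pchisq(chi2, 3, lower.tail = FALSE),
       ratio = ratio)
}

#' Observed F2 seed-color counts of the motivating soybean cross
#'
#' Seed cotyledon-color counts from eleven F2 populations of a cross between
#' a yellow-cotyledon cultivar (Zhonghuang 30) and a green-cotyledon
#' cultivar (Jiyu 102), used throughout the tests and acceptance report as
#' the canonical 15:1 segregation input.
#'
#' @return data.frame with columns population, n_yellow, n_green.
#' @examples
#' chi2_gof(f2_cotyledon_counts()$n_yellow, f2_cotyledon_counts()$n_green)
#' @export
f2_cotyledon_counts <- function() {
  data.frame(
    population = c("130028-1", "130028-3", "130028-4", "130029-1",
                   "130029-2", "130030-1", "130030-2", "130030-3",
                   "130030-4", "130034-1", "130034-2"),
    n_yellow = c(295L, 319L, 234L, 251L, 232L, 234L, 347L, 231L, 244L,
                 316L, 277L),
    n_green = c(19L, 22L, 13L, 19L, 20L, 14L, 27L, 16L, 14L, 21L, 25L),
    stringsAsFactors = FALSE)
}
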