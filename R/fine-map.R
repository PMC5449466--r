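#' Reshape a long-format marker table into a call matrix
#'
#' Pivots the marker-genotype TSV layout (line_id, marker_id, chrom, pos,
#' call, region) emitted by [write_dataset()] into the lines x markers call
#' matrix the fine-mapping operations consume.
#'
#' @param markers long-format data.frame.
#' @param region restrict to one `region` label (when the column exists).
#' @return list with `calls` (character matrix, rownames = line ids,
#'   columns ordered by position) and `positions` (bp).
#' @export
marker_matrix <- function(markers, region = NULL) {
  if (!is.null(region) && "region" %in% names(markers))
    markers <- markers[markers$region == region, , drop = FALSE]
  stopifnot(nrow(markers) > 0)
  pos_of <- tapply(markers$pos, markers$marker_id, unique)
  ord <- order(unlist(pos_of))
  mk <- names(pos_of)[ord]
  lines <- unique(markers$line_id)
  calls <- matrix(NA_character_, length(lines), length(mk),
                  dimnames = list(lines, mk))
  calls[cbind(match(markers$line_id, lines),
              match(markers$marker_id, mk))] <- markers$call
  list(calls = calls, positions = as.numeric(unlist(pos_of)[ord]))
}

#' Consensus genotype of a line across a region's markers
#'
#' Majority call over non-missing markers (ties and all-missing give NA),
#' ignoring recombinant tails — the consensus is meant to capture which
#' allele the bulk of the region carries.
#'
#' @param calls character vector of marker calls in \{"A", "B", "H"\}, NA
#'   for missing.
#' @return a single call or NA.
#' @export
consensus_genotype <- function(calls) {
  calls <- calls[!is.na(calls)]
  if (!length(calls)) return(NA_character_)
  tab <- sort(table(calls), decreasing = TRUE)
  if (length(tab) > 1L && tab[1] == tab[2]) return(NA_character_)
  names(tab)[1]
}

#' Which locus controls a 3:1-segregating line
#'
#' In material segregating 3:1 for the recessive phenotype, exactly one of
#' the two causal regions is heterozygous while the other is fixed for the
#' recessive (green-parent) allele. Given the consensus genotype of each
#' candidate region, returns which region is the segregating one.
#'
#' @param region1_genotype,region2_genotype consensus calls (`"A"`, `"B"`,
#'   `"H"`, or NA) for the two candidate regions. Vectorized.
#' @return character vector: `"locus1"`, `"locus2"`, or `"inconsistent"`
#'   (e.g. both regions H — such a line would segregate 15:1, not 3:1).
#' @examples
#' assign_controlling_locus("H", "B")   # locus1
#' assign_controlling_locus("H", "H")   # inconsistent
#' @export
assign_controlling_locus <- function(region1_genotype, region2_genotype) {
  out <- rep("inconsistent", length(region1_genotype))
  g1 <- region1_genotype
  g2 <- region2_genotype
  out[!is.na(g1) & !is.na(g2) & g1 == "H" & g2 == "B"] <- "locus1"
  out[!is.na(g1) & !is.na(g2) & g1 == "B" & g2 == "H"] <- "locus2"
  out
}

#' Causal-locus genotype implied by a line's F2:3 segregation class
#'
#' For lines whose other (background) locus is fixed recessive, the F2:3
#' seed ratio reveals the genotype at the segregating locus: all-recessive
#' lines are B, 3:1 lines are H, all-dominant lines are A.
#'
#' @param seg_class character vector of [classify_f3()] classes.
#' @return genotype codes `"A"`, `"B"`, `"H"`, or NA (`ambiguous` /
#'   `seg_15_1` lines carry no single-locus information here).
#' @export
infer_causal_genotype <- function(seg_class) {
  map <- c(all_recessive = "B", seg_3_1 = "H", all_dominant = "A",
           seg_15_1 = NA_character_, ambiguous = NA_character_)
  bad <- !seg_class %in% names(map)
  if (any(bad)) stop("unknown segregation class: ",
                     paste(unique(seg_class[bad]), collapse = ", "))
  unname(map[seg_class])
}

#' Identify recombinant lines and their breakpoint intervals
#'
#' A line is recombinant within a region when its genotype call changes
#' between consecutive non-missing markers; each change brackets a
#' crossover strictly between the two flanking marker positions.
#'
#' @param calls matrix of marker calls (lines x markers, values `"A"`,
#'   `"B"`, `"H"` or NA), columns ordered by position; rownames are line
#'   ids.
#' @param positions increasing bp positions of the markers (columns).
#' @return data.frame with line_id, left_pos, right_pos — one row per
#'   breakpoint (open interval between the flanking markers).
#' @export
find_recombinants <- function(calls, positions) {
  stopifnot(is.matrix(calls), ncol(calls) == length(positions),
            !is.unsorted(positions, strictly = TRUE))
  ids <- rownames(calls)
  if (is.null(ids)) ids <- sprintf("line_%d", seq_len(nrow(calls)))
  out <- lapply(seq_len(nrow(calls)), function(i) {
    obs <- which(!is.na(calls[i, ]))
    if (length(obs) < 2L) return(NULL)
    chg <- which(calls[i, obs[-length(obs)]] != calls[i, obs[-1L]])
    if (!length(chg)) return(NULL)
    data.frame(line_id = ids[i],
               left_pos = positions[obs[chg]],
               right_pos = positions[obs[chg + 1L]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(line_id = character(), left_pos = numeric(),
                      right_pos = numeric())
  rownames(out) <- NULL
  out
}

# per-line allowed intervals: maximal runs of markers matching the line's
# causal genotype, opened up to (but excluding) the flanking mismatching
# markers; region bounds are closed
line_constraint_ranges <- function(calls_i, positions, genotype) {
  obs <- which(!is.na(calls_i))
  if (!length(obs)) return(NULL)
  match_run <- rle(calls_i[obs] == genotype)
  if (!any(match_run$values)) return(NULL)
  last <- cumsum(match_run$lengths)
  first <- c(1L, head(last, -1L) + 1L)
  k <- which(match_run$values)
  left <- ifelse(first[k] == 1L, positions[obs[1L]],
                 positions[obs[first[k] - 1L]] + 1)
  right <- ifelse(last[k] == length(obs), positions[obs[length(obs)]],
                  positions[obs[last[k] + 1L]] - 1)
  IRanges::IRanges(start = as.integer(left), end = as.integer(right))
}

#' Refine a locus interval by intersecting recombinant constraints
#'
#' Each informative line restricts the causal locus to marker stretches
#' whose call equals the line's inferred causal genotype (open at the
#' flanking mismatching markers, since the crossover lies strictly between
#' markers). The refined interval is the intersection of these constraints
#' over all lines.
#'
#' @param calls matrix of marker calls (lines x markers), columns ordered
#'   by position; rownames are line ids.
#' @param positions increasing bp positions of the markers.
#' @param genotypes per-line inferred causal genotype (`"A"`, `"B"`, `"H"`,
#'   NA to skip a line), e.g. from [infer_causal_genotype()].
#' @return list with `start`, `end` (bp, 1-based inclusive) and
#'   `n_informative` (lines that actually constrained the interval).
#' @examples
#' calls <- rbind(l1 = c("A", "H", "H"))
#' refine_interval(calls, c(100, 200, 300), "H")  # (100, 300] -> 101..300
#' @export
refine_interval <- function(calls, positions, genotypes) {
  stopifnot(is.matrix(calls), nrow(calls) == length(genotypes),
            ncol(calls) == length(positions))
  ids <- rownames(calls)
  if (is.null(ids)) ids <- sprintf("line_%d", seq_len(nrow(calls)))
  cur <- IRanges::IRanges(as.integer(min(positions)),
                          as.integer(max(positions)))
  n_informative <- 0L
  used <- character()
  for (i in seq_len(nrow(calls))) {
    if (is.na(genotypes[i])) next
    rng <- line_constraint_ranges(calls[i, ], positions, genotypes[i])
    if (is.null(rng))
      stop("line ", ids[i], " has no marker matching its inferred ",
           "genotype '", genotypes[i], "': genotyping/phenotyping conflict")
    nxt <- IRanges::intersect(cur, IRanges::reduce(rng))
    if (length(nxt) == 0L)
      stop("contradictory constraints: line ", ids[i],
           " excludes the interval supported by line(s) ",
           paste(used, collapse = ", "))
    if (!identical(nxt, cur)) {
      n_informative <- n_informative + 1L
      used <- c(used, ids[i])
    }
    cur <- nxt
  }
  list(start = min(IRanges::start(cur)), end = max(IRanges::end(cur)),
       n_informative = n_informative)
}
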