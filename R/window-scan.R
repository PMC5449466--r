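#' Sliding-window scan settings
#'
#' @param window_bp window size in bp (default 2 Mb).
#' @param step_bp step between window starts (default 10 kb).
#' @param index_threshold a window qualifies when its mean SNP-index in the
#'   trait (green) bulk exceeds this (default 0.9).
#' @param p_threshold ... and its mean per-site Fisher P is below this
#'   (default 0.05).
#' @param min_snps_per_window windows with fewer SNPs are ineligible
#'   (default 10).
#' @param min_windows_per_region merged runs of qualifying windows shorter
#'   than this are discarded (default 5).
#' @param bulk which bulk carries the recessive trait: `"green"` (default)
#'   uses mean_index_green for qualification, `"yellow"` the mirror.
#' @return a `scan_config` list.
#' @export
scan_config <- function(window_bp = 2e6, step_bp = 1e4,
                        index_threshold = 0.9, p_threshold = 0.05,
                        min_snps_per_window = 10,
                        min_windows_per_region = 5,
                        bulk = c("green", "yellow")) {
  stopifnot(step_bp > 0, window_bp >= step_bp,
            index_threshold > 0, index_threshold < 1,
            p_threshold > 0, p_threshold < 1,
            min_snps_per_window >= 1, min_windows_per_region >= 1)
  structure(list(window_bp = window_bp, step_bp = step_bp,
                 index_threshold = index_threshold,
                 p_threshold = p_threshold,
                 min_snps_per_window = min_snps_per_window,
                 min_windows_per_region = min_windows_per_region,
                 bulk = match.arg(bulk)),
            class = "scan_config")
}

#' Tile one chromosome with sliding windows
#'
#' Windows are left-anchored at 1, 1+step, 1+2*step, ... (every start up to
#' the chromosome length) and truncated at the chromosome end; interior
#' positions are therefore covered by exactly window_bp/step_bp windows.
#'
#' @param chrom_length chromosome length in bp (>= 1).
#' @param config a [scan_config()].
#' @return data.frame with columns start, end (1-based inclusive).
#' @examples
#' nrow(make_windows(2e6, scan_config()))  # 200
#' @export
make_windows <- function(chrom_length, config = scan_config()) {
  stopifnot(chrom_length >= 1)
  start <- seq(1, chrom_length, by = config$step_bp)
  data.frame(start = start,
             end = pmin(start + config$window_bp - 1, chrom_length))
}

#' Windowed means of SNP-index statistics
#'
#' Arithmetic means of index_green, index_yellow, delta and fisher_p over
#' the SNPs inside each sliding window of each chromosome. Windows with
#' fewer than `min_snps_per_window` SNPs are flagged ineligible (their means
#' are NA when empty).
#'
#' @param records per-site table from [compute_index_table()].
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param config a [scan_config()].
#' @return data.frame of per-window stats (chrom, start, end, n_snps,
#'   mean_index_green, mean_index_yellow, mean_delta, mean_p, eligible),
#'   with `records` attached as an attribute for region annotation.
#' @export
window_stats <- function(records, chrom_lengths, config = scan_config()) {
  out <- lapply(names(chrom_lengths), function(ch) {
    w <- make_windows(chrom_lengths[[ch]], config)
    r <- records[records$chrom == ch, , drop = FALSE]
    r <- r[order(r$pos), , drop = FALSE]
    # prefix sums => O(n + windows) window means
    cum <- function(x) c(0, cumsum(x))
    ci_g <- cum(r$index_green); ci_y <- cum(r$index_yellow)
    cd <- cum(r$delta); cp <- cum(r$fisher_p)
    i0 <- findInterval(w$start - 1, r$pos)   # SNPs strictly before window
    i1 <- findInterval(w$end, r$pos)         # SNPs up to window end
    n <- i1 - i0
    mean_of <- function(cs) ifelse(n > 0, (cs[i1 + 1] - cs[i0 + 1]) / n, NA)
    data.frame(chrom = ch, start = w$start, end = w$end, n_snps = n,
               mean_index_green = mean_of(ci_g),
               mean_index_yellow = mean_of(ci_y),
               mean_delta = mean_of(cd),
               mean_p = mean_of(cp),
               eligible = n >= config$min_snps_per_window,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "records") <- records
  attr(out, "scan_config") <- config
  out
}

#' Call candidate regions from windowed statistics
#'
#' A window qualifies when it is eligible, its mean SNP-index in the trait
#' bulk exceeds `index_threshold`, and its mean Fisher P is below
#' `p_threshold`. Overlapping qualifying windows are merged into maximal
#' runs; runs of at least `min_windows_per_region` windows become candidate
#' regions spanning the union of their member windows.
#'
#' @param ws window table from [window_stats()].
#' @param config a [scan_config()] (defaults to the one `ws` was built with).
#' @return data.frame of regions: chrom, start, end, n_windows, n_snps
#'   (distinct SNPs in the span, when records are available), max_mean_delta,
#'   min_mean_p.
#' @export
call_regions <- function(ws, config = attr(ws, "scan_config")) {
  if (is.null(config)) config <- scan_config()
  idx_col <- if (config$bulk == "green") "mean_index_green"
             else "mean_index_yellow"
  qual <- ws$eligible & !is.na(ws[[idx_col]]) & !is.na(ws$mean_p) &
    ws[[idx_col]] > config$index_threshold & ws$mean_p < config$p_threshold
  records <- attr(ws, "records")
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_windows = integer(),
                      n_snps = integer(), max_mean_delta = numeric(),
                      min_mean_p = numeric())
  if (!any(qual)) return(empty)
  regions <- lapply(split(ws[qual, , drop = FALSE], ws$chrom[qual]),
                    function(q) {
    q <- q[order(q$start), , drop = FALSE]
    # new cluster when a qualifying window starts past everything seen so far
    run_end <- cummax(q$end)
    new_cluster <- c(TRUE, q$start[-1] > head(run_end, -1) + 1)
    cl <- cumsum(new_cluster)
    do.call(rbind, lapply(split(q, cl), function(m) {
      n_snps <- if (!is.null(records))
        sum(records$chrom == m$chrom[1] & records$pos >= min(m$start) &
              records$pos <= max(m$end))
      else NA_integer_
      data.frame(chrom = m$chrom[1], start = min(m$start), end = max(m$end),
                 n_windows = nrow(m), n_snps = n_snps,
                 max_mean_delta = max(m$mean_delta),
                 min_mean_p = min(m$mean_p), stringsAsFactors = FALSE)
    }))
  })
  regions <- do.call(rbind, regions)
  regions <- regions[regions$n_windows >= config$min_windows_per_region, ,
                     drop = FALSE]
  if (nrow(regions) == 0L) return(empty)
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  regions
}

#' Export candidate regions as BED
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open, so
#' start is decremented at the boundary.
#'
#' @param regions region table from [call_regions()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
regions_to_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom,
                    start = format(regions$start - 1, scientific = FALSE,
                                   trim = TRUE),
                    end = format(regions$end, scientific = FALSE,
                                 trim = TRUE),
                    name = sprintf("region_%d", seq_len(nrow(regions))))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Three-track scan plot for one chromosome
#'
#' Green-bulk index, yellow-bulk index and delta(SNP-index) window means
#' along the chromosome, with called regions shaded.
#'
#' @param ws window table from [window_stats()].
#' @param chrom chromosome to draw.
#' @param regions optional region table; matching rows are shaded.
#' @export
plot_scan <- function(ws, chrom, regions = NULL) {
  w <- ws[ws$chrom == chrom & !is.na(ws$mean_delta), , drop = FALSE]
  if (nrow(w) == 0L) stop("no windows with data on ", chrom)
  mid <- (w$start + w$end) / 2 / 1e6
  old <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  shade <- function(ylim) {
    if (is.null(regions)) return()
    r <- regions[regions$chrom == chrom, , drop = FALSE]
    if (nrow(r)) graphics::rect(r$start / 1e6, ylim[1], r$end / 1e6,
                                ylim[2], col = "#fff3b0", border = NA)
  }
  tracks <- list(
    list(y = w$mean_index_green, ylab = "SNP-index (green bulk)",
         ylim = c(0, 1), col = "forestgreen"),
    list(y = w$mean_index_yellow, ylab = "SNP-index (yellow bulk)",
         ylim = c(0, 1), col = "goldenrod3"),
    list(y = w$mean_delta, ylab = "delta(SNP-index)",
         ylim = c(-1, 1), col = "steelblue"))
  for (tr in tracks) {
    graphics::plot(NA, xlim = range(mid), ylim = tr$ylim, xlab = "",
                   ylab = tr$ylab, main = if (tr$ylab == tracks[[1]]$ylab)
                     chrom else "")
    shade(tr$ylim)
    graphics::lines(mid, tr$y, col = tr$col, lwd = 1.5)
    graphics::abline(h = 0, lty = 3)
  }
  invisible(NULL)
}
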