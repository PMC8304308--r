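# Interval algebra over QTL calls from independent experiments.
#
# Intervals are carried in Mb with 1-based inclusive endpoints, the way QTL
# mapping papers print them; full numeric precision is kept internally and
# only printing rounds to two decimals.

#' Construct a genomic interval (Mb coordinates)
#'
#' @param chrom Chromosome name.
#' @param start_mb,end_mb Physical endpoints in Mb, 1-based inclusive;
#'   `start_mb <= end_mb` required.
#' @param label Interval name (e.g. the QTL name).
#' @return A one-row interval data frame (`chrom`, `start_mb`, `end_mb`,
#'   `label`).
#' @export
genomic_interval <- function(chrom, start_mb, end_mb, label = NA_character_) {
  if (any(start_mb > end_mb)) {
    stop("'start_mb' must not exceed 'end_mb'", call. = FALSE)
  }
  data.frame(chrom = chrom, start_mb = as.numeric(start_mb),
             end_mb = as.numeric(end_mb), label = label,
             stringsAsFactors = FALSE)
}

.empty_interval <- function() {
  data.frame(chrom = character(), start_mb = numeric(), end_mb = numeric(),
             label = character(), stringsAsFactors = FALSE)
}

#' Intersect QTL intervals from multiple experiments
#'
#' The consensus region supported by every experiment:
#' `[max(starts), min(ends)]` when all intervals share a chromosome and
#' overlap, otherwise an empty interval. Order-invariant.
#'
#' @param intervals Interval data frame (one row per experiment), as built
#'   by [genomic_interval()] / `rbind`, or read with [read_intervals()].
#' @param label Label for the consensus interval.
#' @return A one-row interval data frame, or a zero-row one when the
#'   intervals do not all overlap.
#' @examples
#' ivs <- rbind(genomic_interval("chr1", 19.13, 27.72, "exp1"),
#'              genomic_interval("chr1", 21.65, 25.00, "exp2"),
#'              genomic_interval("chr1", 20.00, 23.03, "exp3"))
#' intersect_intervals(ivs)
#' @export
intersect_intervals <- function(intervals, label = "consensus") {
  if (nrow(intervals) < 1L) stop("at least one interval is required", call. = FALSE)
  if (length(unique(intervals$chrom)) > 1L) return(.empty_interval())
  s <- max(intervals$start_mb)
  e <- min(intervals$end_mb)
  if (s > e) return(.empty_interval())
  genomic_interval(intervals$chrom[1], s, e, label)
}

#' Width of an interval in Mb
#'
#' @param interval A one-row interval data frame.
#' @return `end_mb - start_mb` (0 for a degenerate point interval).
#' @export
interval_width <- function(interval) {
  if (nrow(interval) == 0L) return(numeric(0))
  interval$end_mb - interval$start_mb
}

#' Genes overlapping a consensus region
#'
#' Any-overlap semantics with inclusive endpoints: a gene is reported when
#' its span intersects the region at all, including genes straddling a
#' region boundary.
#'
#' @param features Gene feature data frame: `gene_id`, `chrom`, `start_bp`,
#'   `end_bp`, `strand`.
#' @param region A one-row interval data frame (Mb coordinates).
#' @return The overlapping features, sorted by start; empty (with a warning)
#'   when no feature shares the region's chromosome.
#' @export
genes_in_region <- function(features, region) {
  stopifnot(nrow(region) == 1L)
  if (any(features$start_bp > features$end_bp)) {
    stop("gene features must satisfy start_bp <= end_bp", call. = FALSE)
  }
  on_chrom <- features[features$chrom == region$chrom, , drop = FALSE]
  if (nrow(on_chrom) == 0L) {
    warning("no gene features on chromosome ", region$chrom,
            "; returning an empty set", call. = FALSE)
    return(features[0, , drop = FALSE])
  }
  r_start <- round(region$start_mb * 1e6)
  r_end <- round(region$end_mb * 1e6)
  hit <- on_chrom$start_bp <= r_end & on_chrom$end_bp >= r_start
  out <- on_chrom[hit, , drop = FALSE]
  out[order(out$start_bp), , drop = FALSE]
}
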