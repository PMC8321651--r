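## Copy-number segment filtering and altered-genome fraction.

checkSegments <- function(segments) {
  need <- c("sample_id", "chrom", "start", "end", "log2_ratio", "n_bins")
  if (!all(need %in% names(segments)))
    stop("segment table missing column(s): ",
         paste(setdiff(need, names(segments)), collapse = ", "))
  if (any(segments$end <= segments$start))
    stop("segments must satisfy end > start (0-based half-open)")
  if (any(segments$n_bins < 1L)) stop("n_bins must be >= 1")
  # overlapping segments within a sample/chromosome are a validation error
  sp <- split(segments, paste(segments$sample_id, segments$chrom, sep = "\r"))
  bad <- names(sp)[vapply(sp, function(g) {
    g <- g[order(g$start), , drop = FALSE]
    nrow(g) > 1L && any(g$start[-1L] < g$end[-nrow(g)])
  }, logical(1))]
  if (length(bad))
    stop("overlapping segments within sample/chromosome: ",
         paste(gsub("\r", "/", bad), collapse = ", "))
  segments
}

#' Filter copy-number segments by amplitude and bin support
#'
#' Retains segments with \code{|log2_ratio| >= log2_threshold} (inclusive:
#' boundary values are reported) and \code{n_bins >= min_bins}, labeling
#' each retained segment as gain (positive ratio) or loss (negative).
#'
#' @param segments segment table (see [readSegmentsTsv()]).
#' @param log2_threshold absolute log2 copy-ratio threshold (default 0.2).
#' @param min_bins minimum supporting bins (default 5).
#' @return The retained segments with an added \code{direction} column.
#' @export
filterSegments <- function(segments, log2_threshold = 0.2, min_bins = 5L) {
  segments <- checkSegments(segments)
  keep <- abs(segments$log2_ratio) >= log2_threshold &
    segments$n_bins >= min_bins
  out <- segments[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2_ratio > 0, "gain", "loss")
  rownames(out) <- NULL
  out
}

#' Fraction of the segmented genome that is copy-number altered
#'
#' Per sample, the summed footprint (end - start) of altered segments
#' divided by the summed footprint of all segments.  Samples whose total
#' footprint is zero (or absent from \code{all_segments}) are flagged NA.
#'
#' @param all_segments every segment for the samples of interest.
#' @param altered_segments the subset passing [filterSegments()].
#' @param include_sex include sex chromosomes (chrX/chrY/X/Y) in the
#'   footprints (default TRUE).
#' @return Named numeric vector of fractions in [0, 1] (NA when
#'   undefined).
#' @export
genomeAlteredFraction <- function(all_segments, altered_segments,
                                  include_sex = TRUE) {
  all_segments <- checkSegments(all_segments)
  if (!include_sex) {
    sex <- c("chrX", "chrY", "X", "Y")
    all_segments <- all_segments[!all_segments$chrom %in% sex, , drop = FALSE]
    altered_segments <-
      altered_segments[!altered_segments$chrom %in% sex, , drop = FALSE]
  }
  samples <- sort(unique(all_segments$sample_id))
  len <- function(df) {
    v <- tapply(as.numeric(df$end - df$start),
                factor(df$sample_id, levels = samples), sum)
    ifelse(is.na(v), 0, v)
  }
  total <- len(all_segments)
  altered <- len(altered_segments)
  out <- ifelse(total > 0, altered / total, NA_real_)
  if (any(total == 0))
    warning("zero total segment footprint for: ",
            paste(samples[total == 0], collapse = ", "))
  setNames(as.numeric(out), samples)
}
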