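#' Sbs96Catalog: per-sample SBS96 mutation counts
#'
#' A samples x 96 non-negative count matrix over the canonical COSMIC
#' channel order (see [sbs96Channels()]).  Row sums equal each sample's
#' single-base-substitution event count; dinucleotide (e.g. CC>TT) events
#' are excluded from the catalog and tracked separately.
#'
#' @slot counts samples x 96 numeric matrix, columns named by channel.
#' @export
setClass("Sbs96Catalog", representation(counts = "matrix"))

setValidity("Sbs96Catalog", function(object) {
  m <- object@counts
  msg <- character()
  if (!identical(colnames(m), sbs96Channels()))
    msg <- c(msg, "columns must be the 96 canonical channels in COSMIC order")
  if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
  if (any(m != round(m))) msg <- c(msg, "counts must be integral")
  if (is.null(rownames(m))) msg <- c(msg, "rows must be named by sample")
  if (length(msg)) msg else TRUE
})

#' Construct an Sbs96Catalog from a count matrix
#'
#' @param counts samples x 96 matrix with channel column names (any order;
#'   reordered to canonical), rows named by sample.
#' @return An [Sbs96Catalog-class] object.
#' @export
Sbs96Catalog <- function(counts) {
  counts <- as.matrix(counts)
  chan <- sbs96Channels()
  if (!setequal(colnames(counts), chan))
    stop("count matrix must have exactly the 96 canonical channel columns")
  new("Sbs96Catalog", counts = counts[, chan, drop = FALSE])
}

#' SignatureMatrix: column-stochastic SBS96 signature profiles
#'
#' 96 x K matrix of non-negative reals; each column is a probability
#' distribution over the 96 channels (sums to 1 within 1e-9).
#'
#' @slot profiles 96 x K numeric matrix, rows the canonical channels,
#'   columns the signature labels.
#' @export
setClass("SignatureMatrix", representation(profiles = "matrix"))

setValidity("SignatureMatrix", function(object) {
  p <- object@profiles
  msg <- character()
  if (!identical(rownames(p), sbs96Channels()))
    msg <- c(msg, "rows must be the 96 canonical channels in COSMIC order")
  if (any(p < 0)) msg <- c(msg, "profiles must be non-negative")
  if (ncol(p) < 1L) msg <- c(msg, "at least one signature required")
  if (any(abs(colSums(p) - 1) > 1e-9))
    msg <- c(msg, "each profile must sum to 1 (tolerance 1e-9)")
  if (length(msg)) msg else TRUE
})

#' Construct a SignatureMatrix
#'
#' @param profiles 96 x K non-negative matrix, rows named by channel
#'   (reordered to canonical order).  Columns are renormalized to sum to 1.
#' @param labels optional signature names (default \code{Signature1..K}).
#' @return A [SignatureMatrix-class] object.
#' @export
SignatureMatrix <- function(profiles, labels = NULL) {
  profiles <- as.matrix(profiles)
  chan <- sbs96Channels()
  if (is.null(rownames(profiles)) && nrow(profiles) == 96L)
    rownames(profiles) <- chan
  if (!setequal(rownames(profiles), chan))
    stop("profiles must have exactly the 96 canonical channel rows")
  profiles <- profiles[chan, , drop = FALSE]
  cs <- colSums(profiles)
  if (any(cs <= 0)) stop("all-zero signature profile")
  profiles <- sweep(profiles, 2L, cs, "/")
  if (!is.null(labels)) colnames(profiles) <- labels
  else if (is.null(colnames(profiles)))
    colnames(profiles) <- paste0("Signature", seq_len(ncol(profiles)))
  new("SignatureMatrix", profiles = profiles)
}

#' ActivityMatrix: per-sample signature activities
#'
#' Samples x K non-negative activities in units of mutation counts, plus a
#' per-sample unassigned count: mutations whose maximum posterior signature
#' probability fell below the attribution confidence threshold.  Per sample,
#' \code{rowSums(activities) + unassigned} equals the total SNV count.
#'
#' @slot activities samples x K numeric matrix.
#' @slot unassigned per-sample numeric vector.
#' @export
setClass("ActivityMatrix",
         representation(activities = "matrix", unassigned = "numeric"))

setValidity("ActivityMatrix", function(object) {
  msg <- character()
  if (any(object@activities < 0)) msg <- c(msg, "activities must be >= 0")
  if (any(object@unassigned < 0)) msg <- c(msg, "unassigned must be >= 0")
  if (length(object@unassigned) != nrow(object@activities))
    msg <- c(msg, "unassigned length must match sample count")
  if (length(msg)) msg else TRUE
})

#' RankSelectionReport: NMF rank-selection diagnostics
#'
#' One row per candidate rank with bootstrap-stability and model-fit
#' metrics, and the selected rank.
#'
#' @slot metrics data.frame with columns rank, stability,
#'   reconstruction_error, cophenetic, evar, rss, dispersion, sparseness.
#' @slot selectedRank integer.
#' @export
setClass("RankSelectionReport",
         representation(metrics = "data.frame", selectedRank = "integer"))

setValidity("RankSelectionReport", function(object) {
  msg <- character()
  need <- c("rank", "stability", "reconstruction_error", "cophenetic",
            "evar", "rss", "dispersion", "sparseness")
  if (!all(need %in% names(object@metrics)))
    msg <- c(msg, "metrics must contain the full diagnostic column set")
  if (!(object@selectedRank %in% object@metrics$rank))
    msg <- c(msg, "selected rank must be among the candidate ranks")
  if (length(msg)) msg else TRUE
})

#' SpectralIrradiance: a relative lamp emission spectrum
#'
#' Wavelength grid (nm, strictly increasing, within 250-400) with
#' non-negative relative intensities, used for erythemal weighting.
#'
#' @slot wavelengths numeric vector (nm).
#' @slot intensities numeric vector, same length.
#' @export
setClass("SpectralIrradiance",
         representation(wavelengths = "numeric", intensities = "numeric"))

setValidity("SpectralIrradiance", function(object) {
  w <- object@wavelengths; s <- object@intensities
  msg <- character()
  if (length(w) < 2L) msg <- c(msg, "at least 2 spectral points required")
  if (length(w) != length(s)) msg <- c(msg, "wavelength/intensity length mismatch")
  if (any(diff(w) <= 0)) msg <- c(msg, "wavelengths must be strictly increasing")
  if (any(w < 250 | w > 400)) msg <- c(msg, "wavelengths must lie in [250, 400] nm")
  if (any(s < 0)) msg <- c(msg, "intensities must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a SpectralIrradiance
#' @param wavelengths numeric, nm, strictly increasing within [250, 400].
#' @param intensities numeric, relative units, >= 0.
#' @return A [SpectralIrradiance-class] object.
#' @export
SpectralIrradiance <- function(wavelengths, intensities) {
  new("SpectralIrradiance", wavelengths = as.numeric(wavelengths),
      intensities = as.numeric(intensities))
}
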