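#' Accessors for uvsig S4 containers
#'
#' \code{catalogCounts} returns the samples x 96 count matrix of an
#' [Sbs96Catalog-class]; \code{sampleIds} its sample names.
#' \code{signatureProfiles} returns the 96 x K profile matrix of a
#' [SignatureMatrix-class]; \code{signatureLabels} its column labels.
#' \code{activityScores} and \code{unassignedCounts} return the activity
#' matrix and the per-sample unassigned counts of an
#' [ActivityMatrix-class]. \code{selectedRank} and \code{rankMetrics}
#' read a [RankSelectionReport-class].
#'
#' @param object an object of the matching class.
#' @return The slot content as a base matrix/vector/data.frame.
#' @name uvsig-accessors
NULL

#' @rdname uvsig-accessors
#' @export
setGeneric("catalogCounts", function(object) standardGeneric("catalogCounts"))
#' @rdname uvsig-accessors
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))
#' @rdname uvsig-accessors
#' @export
setGeneric("signatureProfiles", function(object) standardGeneric("signatureProfiles"))
#' @rdname uvsig-accessors
#' @export
setGeneric("signatureLabels", function(object) standardGeneric("signatureLabels"))
#' @rdname uvsig-accessors
#' @export
setGeneric("activityScores", function(object) standardGeneric("activityScores"))
#' @rdname uvsig-accessors
#' @export
setGeneric("unassignedCounts", function(object) standardGeneric("unassignedCounts"))
#' @rdname uvsig-accessors
#' @export
setGeneric("selectedRank", function(object) standardGeneric("selectedRank"))
#' @rdname uvsig-accessors
#' @export
setGeneric("rankMetrics", function(object) standardGeneric("rankMetrics"))

#' @rdname uvsig-accessors
#' @export
setMethod("catalogCounts", "Sbs96Catalog", function(object) object@counts)
#' @rdname uvsig-accessors
#' @export
setMethod("sampleIds", "Sbs96Catalog", function(object) rownames(object@counts))
#' @rdname uvsig-accessors
#' @export
setMethod("signatureProfiles", "SignatureMatrix", function(object) object@profiles)
#' @rdname uvsig-accessors
#' @export
setMethod("signatureLabels", "SignatureMatrix", function(object) colnames(object@profiles))
#' @rdname uvsig-accessors
#' @export
setMethod("activityScores", "ActivityMatrix", function(object) object@activities)
#' @rdname uvsig-accessors
#' @export
setMethod("unassignedCounts", "ActivityMatrix", function(object) object@unassigned)
#' @rdname uvsig-accessors
#' @export
setMethod("selectedRank", "RankSelectionReport", function(object) object@selectedRank)
#' @rdname uvsig-accessors
#' @export
setMethod("rankMetrics", "RankSelectionReport", function(object) object@metrics)

setMethod("show", "Sbs96Catalog", function(object) {
  m <- object@counts
  cat("Sbs96Catalog:", nrow(m), "samples x 96 channels;",
      "total mutations:", sum(m), "\n")
  cat("  samples:", paste(head(rownames(m), 5L), collapse = ", "),
      if (nrow(m) > 5L) "..." else "", "\n")
})

setMethod("show", "SignatureMatrix", function(object) {
  p <- object@profiles
  cat("SignatureMatrix: 96 channels x", ncol(p), "signatures (",
      paste(colnames(p), collapse = ", "), ")\n")
  top <- apply(p, 2L, function(x) rownames(p)[which.max(x)])
  cat("  top channel per signature:", paste(top, collapse = ", "), "\n")
})

setMethod("show", "ActivityMatrix", function(object) {
  a <- object@activities
  cat("ActivityMatrix:", nrow(a), "samples x", ncol(a), "signatures;",
      "mean unassigned:", round(mean(object@unassigned), 2), "\n")
})

setMethod("show", "RankSelectionReport", function(object) {
  cat("RankSelectionReport: selected rank", object@selectedRank, "\n")
  print(object@metrics, row.names = FALSE, digits = 4)
})

setMethod("show", "SpectralIrradiance", function(object) {
  cat("SpectralIrradiance:", length(object@wavelengths), "points,",
      min(object@wavelengths), "-", max(object@wavelengths), "nm\n")
})
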