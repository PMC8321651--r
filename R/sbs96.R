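SBS_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
BASES <- c("A", "C", "G", "T")

#' Canonical SBS96 channel order
#'
#' The 96 single-base-substitution channels in the COSMIC convention:
#' the six pyrimidine-centric substitution classes in the order
#' C>A, C>G, C>T, T>A, T>C, T>G, and within each class the 16 flanking
#' contexts ordered alphabetically by 5' then 3' base.  Channel labels use
#' the COSMIC style \code{"T[C>T]T"}.
#'
#' @return Character vector of length 96.
#' @examples
#' head(sbs96Channels())
#' @export
sbs96Channels <- function() {
  unlist(lapply(SBS_CLASSES, function(cl) {
    ref <- substr(cl, 1L, 1L)
    as.vector(t(outer(BASES, BASES, function(p5, p3)
      paste0(p5, "[", cl, "]", p3))))
  }))
}

#' @rdname sbs96Channels
#' @return \code{sbs96Contexts()}: the 32 pyrimidine-centric trinucleotides
#'   (16 C-centered, 16 T-centered) in alphabetical order within center base.
#' @export
sbs96Contexts <- function() {
  unlist(lapply(c("C", "T"), function(mid)
    as.vector(t(outer(BASES, BASES, function(p5, p3) paste0(p5, mid, p3))))))
}

sbs96Channel <- function(class, context) {
  stopifnot(substr(context, 2L, 2L) == substr(class, 1L, 1L))
  paste0(substr(context, 1L, 1L), "[", class, "]", substr(context, 3L, 3L))
}

channelClass <- function(channel) substr(channel, 3L, 5L)
channelContext <- function(channel) {
  paste0(substr(channel, 1L, 1L), substr(channel, 3L, 3L), substr(channel, 7L, 7L))
}

revcompChar <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", vapply(x, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""), ""))
}

isPyrimidine <- function(base) base %in% c("C", "T")
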