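## SBS96 catalogs, 6+1 mutation-type occurrence tables, exome
## trinucleotide normalization, transcriptional strand assignment and the
## exact strand-bias test.

#' Build an SBS96 catalog from classified events
#'
#' Tallies classified \code{snv} events into the canonical 96-channel
#' order.  Dinucleotide and indel events are excluded; events flagged with
#' unresolvable context are skipped.
#'
#' @param events classified event table (see [classifySnvs()]).
#' @param samples optional sample universe (rows of the catalog); defaults
#'   to the samples present.
#' @return An [Sbs96Catalog-class].
#' @export
buildSbs96 <- function(events, samples = NULL) {
  ev <- events[events$event_kind == "snv", , drop = FALSE]
  if ("context_ok" %in% names(ev)) ev <- ev[ev$context_ok, , drop = FALSE]
  if (nrow(ev) && anyNA(ev$snv_class))
    stop("unclassified snv events present; run classifySnvs() first")
  if (is.null(samples)) samples <- sort(unique(events$sample_id))
  chan <- sbs96Channels()
  lab <- if (nrow(ev)) sbs96Channel(ev$snv_class, ev$context) else character()
  tab <- table(factor(ev$sample_id, levels = samples),
               factor(lab, levels = chan))
  m <- matrix(as.numeric(tab), nrow = length(samples),
              dimnames = list(samples, chan))
  Sbs96Catalog(m)
}

#' Per-sample mutation-type occurrence table
#'
#' Counts the six pyrimidine-centric substitution classes per sample plus
#' the "C>T at CpG" sub-tally, with relative frequencies (class count /
#' total SNVs).  Samples with zero SNVs get NA frequencies and are listed
#' in the \code{undefined} attribute rather than propagating NaN.
#'
#' @param events classified event table.
#' @return list with elements \code{counts} (samples x 7 matrix),
#'   \code{frequencies} (same shape; the CpG column is a sub-fraction of
#'   C>T) and \code{total} (per-sample SNV counts).
#' @export
countMutationTypes <- function(events) {
  ev <- events[events$event_kind == "snv", , drop = FALSE]
  if ("context_ok" %in% names(ev)) ev <- ev[ev$context_ok, , drop = FALSE]
  samples <- sort(unique(events$sample_id))
  cls <- table(factor(ev$sample_id, levels = samples),
               factor(ev$snv_class, levels = SBS_CLASSES))
  cpg <- table(factor(ev$sample_id[ev$snv_class == "C>T" & ev$at_cpg],
                      levels = samples))
  counts <- cbind(matrix(as.numeric(cls), nrow = length(samples)),
                  as.numeric(cpg))
  dimnames(counts) <- list(samples, c(SBS_CLASSES, "C>T at CpG"))
  total <- rowSums(counts[, SBS_CLASSES, drop = FALSE])
  freq <- counts / ifelse(total > 0, total, NA_real_)
  undefined <- samples[total == 0]
  structure(list(counts = counts, frequencies = freq, total = total),
            undefined = undefined)
}

#' Trinucleotide occurrences of a region set
#'
#' Counts, for each of the 32 pyrimidine-centric trinucleotides, its
#' occurrences within the supplied regions, aggregating both strands via
#' complementation (occ(NpNpN) + occ(revcomp)).  Windows do not cross
#' region boundaries.
#'
#' @param reference reference ([loadReference()]).
#' @param regions \code{GRanges} of regions, or NULL for whole sequences.
#' @return Named integer vector over [sbs96Contexts()].
#' @export
trinucleotideOccurrences <- function(reference, regions = NULL) {
  reference <- loadReference(reference)
  if (is.null(regions)) {
    seqs <- reference
  } else {
    if (length(regions) == 0L) stop("region set is empty")
    chrom <- as.character(GenomicRanges::seqnames(regions))
    if (!all(chrom %in% names(reference)))
      stop("regions reference chromosomes absent from the reference")
    seqs <- Biostrings::DNAStringSet(lapply(seq_along(regions), function(i)
      Biostrings::subseq(reference[[chrom[i]]],
                         GenomicRanges::start(regions)[i],
                         GenomicRanges::end(regions)[i])))
  }
  fwd <- Biostrings::trinucleotideFrequency(seqs, simplify.as = "collapse")
  ctx <- sbs96Contexts()
  occ <- fwd[ctx] + fwd[revcompChar(ctx)]
  setNames(as.integer(occ), ctx)
}

#' Normalize an SBS96 catalog to trinucleotide frequencies
#'
#' Converts channel counts to rates per million context occurrences in a
#' region set (e.g. the captured exome):
#' \code{rate = count * 1e6 / occurrences(context)}.
#'
#' @param catalog an [Sbs96Catalog-class].
#' @param reference reference sequences.
#' @param regions \code{GRanges} region set (NULL = whole reference).
#' @return samples x 96 numeric matrix of rates.
#' @export
normalizeSpectrum <- function(catalog, reference, regions = NULL) {
  counts <- catalogCounts(catalog)
  occ <- trinucleotideOccurrences(reference, regions)
  ctx <- channelContext(colnames(counts))
  denom <- occ[ctx]
  missing <- unique(ctx[denom == 0 & colSums(counts) > 0])
  if (length(missing))
    stop("context(s) absent from the region set but present in catalog: ",
         paste(missing, collapse = ", "))
  rate <- sweep(counts, 2L, ifelse(denom > 0, denom, NA_real_), "/") * 1e6
  rate[, denom == 0] <- 0
  rate
}

#' Assign transcriptional strand labels to events
#'
#' For every classified SNV inside a gene, determines whether the
#' pyrimidine of the mutated base pair lies on the template (transcribed)
#' strand or the coding (untranscribed) strand of that gene.  Intergenic
#' events and events overlapped by genes on both strands are labeled
#' \code{unknown} and excluded from strand tallies.
#'
#' @param events classified event table.
#' @param genes stranded \code{GRanges} of gene bodies (see
#'   [readGeneAnnotation()]).
#' @return The event table with \code{strand_label} filled in.
#' @export
assignTranscriptionalStrand <- function(events, genes) {
  if (!all(as.character(GenomicRanges::strand(genes)) %in% c("+", "-")))
    stop("gene annotation must carry +/- strands")
  idx <- which(events$event_kind == "snv")
  events$strand_label <- "unknown"
  if (!length(idx)) return(events)
  gr <- GenomicRanges::GRanges(events$chrom[idx],
                               IRanges::IRanges(events$start[idx],
                                                events$start[idx]))
  hits <- GenomicRanges::findOverlaps(gr, genes, ignore.strand = TRUE)
  gene_strand <- as.character(GenomicRanges::strand(genes))
  by_event <- split(gene_strand[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits))
  pyr_plus <- isPyrimidine(events$ref_allele[idx])
  for (k in seq_along(by_event)) {
    i <- as.integer(names(by_event)[k])
    s <- unique(by_event[[k]])
    if (length(s) != 1L) next  # genes on both strands: unknown
    pyr_strand <- if (pyr_plus[i]) "+" else "-"
    events$strand_label[idx[i]] <-
      if (pyr_strand == s) "untranscribed" else "transcribed"
  }
  events
}

#' Strand-resolved SBS96 tallies
#'
#' @param events classified, strand-assigned event table.
#' @return list of samples x 96 matrices \code{transcribed} and
#'   \code{untranscribed}, plus \code{excluded_count} (strand unknown).
#' @export
strandResolvedCounts <- function(events) {
  samples <- sort(unique(events$sample_id))
  snv <- events[events$event_kind == "snv", , drop = FALSE]
  if ("context_ok" %in% names(snv)) snv <- snv[snv$context_ok, , drop = FALSE]
  tally <- function(lab) {
    catalogCounts(buildSbs96(snv[snv$strand_label == lab, , drop = FALSE],
                             samples = samples))
  }
  list(transcribed = tally("transcribed"),
       untranscribed = tally("untranscribed"),
       excluded_count = sum(snv$strand_label == "unknown"))
}

#' Exact test for transcriptional strand bias
#'
#' Two-sided exact test of whether mutations fall on the transcribed and
#' untranscribed strand with equal probability — the conditional-binomial
#' form of the classical two-count Poisson rate test, using the
#' minimum-likelihood two-sided rule.  The log2 ratio of
#' transcribed/untranscribed counts gets a +0.5 continuity adjustment to
#' both counts when either is zero (raw counts are always retained).
#'
#' @param transcribed,untranscribed non-negative integer counts.
#' @return data.frame with transcribed_count, untranscribed_count,
#'   log2_ratio, p_value and a logical \code{testable} flag (FALSE when
#'   both counts are zero).
#' @export
strandBiasTest <- function(transcribed, untranscribed) {
  stopifnot(length(transcribed) == length(untranscribed))
  if (any(transcribed < 0 | untranscribed < 0))
    stop("counts must be non-negative")
  n <- transcribed + untranscribed
  res <- data.frame(transcribed_count = transcribed,
                    untranscribed_count = untranscribed,
                    log2_ratio = NA_real_, p_value = NA_real_,
                    testable = n > 0)
  for (i in seq_along(n)) {
    t <- transcribed[i]; u <- untranscribed[i]
    if (n[i] == 0) next
    res$log2_ratio[i] <- if (t > 0 && u > 0) log2(t / u)
      else log2((t + 0.5) / (u + 0.5))
    res$p_value[i] <- stats::binom.test(t, n[i], p = 0.5)$p.value
  }
  res
}

#' Per-class strand-bias tests on pooled counts
#'
#' Aggregates strand-labeled SNVs over all samples (or a supplied sample
#' subset, e.g. one exposure group) by substitution class and applies
#' [strandBiasTest()] per class.
#'
#' @param events classified, strand-assigned event table.
#' @param samples optional subset of sample ids to pool.
#' @return data.frame, one row per substitution class.
#' @export
classStrandBias <- function(events, samples = NULL) {
  ev <- events[events$event_kind == "snv" &
               events$strand_label != "unknown", , drop = FALSE]
  if (!is.null(samples)) ev <- ev[ev$sample_id %in% samples, , drop = FALSE]
  tr <- table(factor(ev$snv_class[ev$strand_label == "transcribed"],
                     levels = SBS_CLASSES))
  un <- table(factor(ev$snv_class[ev$strand_label == "untranscribed"],
                     levels = SBS_CLASSES))
  out <- strandBiasTest(as.integer(tr), as.integer(un))
  cbind(class = SBS_CLASSES, out)
}
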