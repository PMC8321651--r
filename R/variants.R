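## Consensus-call ingestion, dipyrimidine collapsing, classification and
## burden summaries.  Variant calls and mutation events are plain
## data.frames with fixed column sets so they round-trip through TSV.

CALL_COLS <- c("sample_id", "chrom", "pos", "ref", "alt", "variant_kind",
               "caller_id")
EVENT_COLS <- c("sample_id", "chrom", "start", "ref_allele", "alt_allele",
                "event_kind", "snv_class", "context", "at_cpg", "strand_label")

#' Assemble a variant-call table
#'
#' Builds and validates the standard per-caller call table used across the
#' package.  \code{variant_kind} is derived from allele lengths when not
#' supplied: equal-length single bases are \code{snv}, longer ALT is
#' \code{insertion}, longer REF \code{deletion}.
#'
#' @param sample_id,chrom,pos,ref,alt,caller_id vectors of equal length;
#'   \code{pos} is 1-based.
#' @param variant_kind optional; one of \code{snv}, \code{insertion},
#'   \code{deletion} per record.
#' @return data.frame with columns sample_id, chrom, pos, ref, alt,
#'   variant_kind, caller_id.
#' @export
variantCalls <- function(sample_id, chrom, pos, ref, alt,
                         caller_id = "caller", variant_kind = NULL) {
  df <- data.frame(sample_id = as.character(sample_id),
                   chrom = as.character(chrom), pos = as.integer(pos),
                   ref = toupper(as.character(ref)),
                   alt = toupper(as.character(alt)),
                   caller_id = as.character(caller_id),
                   stringsAsFactors = FALSE)
  if (is.null(variant_kind)) {
    variant_kind <- ifelse(nchar(df$ref) == 1L & nchar(df$alt) == 1L, "snv",
                    ifelse(nchar(df$alt) > nchar(df$ref), "insertion",
                           "deletion"))
  }
  df$variant_kind <- as.character(variant_kind)
  bad <- which(df$ref == df$alt | df$pos < 1L)
  if (length(bad))
    stop("invalid variant record(s): ", paste(head(bad, 5L), collapse = ", "))
  bad <- which(df$variant_kind == "snv" &
               (nchar(df$ref) != 1L | nchar(df$alt) != 1L))
  if (length(bad))
    stop("snv records must have single-base ref and alt: record(s) ",
         paste(head(bad, 5L), collapse = ", "))
  df[, CALL_COLS]
}

variantKey <- function(calls, with_sample = TRUE) {
  if (with_sample)
    paste(calls$sample_id, calls$chrom, calls$pos, calls$ref, calls$alt,
          sep = "\r")
  else paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = "\r")
}

#' Ensemble consensus of per-caller somatic call sets
#'
#' Retains variants reported by every supplied caller (keyed by sample,
#' chromosome, position, ref, alt) and then removes known polymorphisms
#' listed in the exclusion set (keyed by site: chromosome, position, ref,
#' alt — the convention of dbSNP/Ensembl-variation exports).
#'
#' @param callsets list of call tables (see [variantCalls()]), one per
#'   caller.
#' @param exclusion_set optional data.frame with columns chrom, pos, ref,
#'   alt of known variants to drop.
#' @return A call table containing the consensus records (caller_id
#'   \code{"consensus"}), sorted by sample, chrom, pos.
#' @export
buildConsensus <- function(callsets, exclusion_set = NULL) {
  if (!is.list(callsets) || length(callsets) == 0L)
    stop("at least one call set must be supplied")
  callsets <- lapply(callsets, checkCallTable)
  keys <- lapply(callsets, variantKey)
  keep <- Reduce(intersect, keys)
  out <- callsets[[1L]][keys[[1L]] %in% keep, , drop = FALSE]
  if (!is.null(exclusion_set) && nrow(exclusion_set)) {
    need <- c("chrom", "pos", "ref", "alt")
    if (!all(need %in% names(exclusion_set)))
      stop("exclusion set must have columns chrom, pos, ref, alt")
    excl <- paste(exclusion_set$chrom, exclusion_set$pos,
                  toupper(exclusion_set$ref), toupper(exclusion_set$alt),
                  sep = "\r")
    out <- out[!(variantKey(out, with_sample = FALSE) %in% excl), ,
               drop = FALSE]
  }
  out$caller_id <- rep("consensus", nrow(out))
  out <- out[order(out$sample_id, out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

checkCallTable <- function(calls) {
  if (!all(CALL_COLS %in% names(calls)))
    stop("call table missing column(s): ",
         paste(setdiff(CALL_COLS, names(calls)), collapse = ", "))
  calls
}

#' Collapse adjacent SNV pairs into dinucleotide events
#'
#' SNVs at adjacent positions in the same sample and chromosome (the
#' CC>TT pattern of UVB photoproducts, though any adjacent pair qualifies)
#' are merged into a single event of kind \code{dinucleotide}; runs of
#' three or more adjacent SNVs are merged into pairs greedily left to
#' right.  All other SNVs become \code{snv} events and indels pass through
#' as \code{indel} events.  Collapsing is idempotent on its own output.
#'
#' @param calls a call table ([variantCalls()] layout).
#' @param reference optional reference ([loadReference()]) used only for a
#'   bounds check on positions.
#' @return An event table with columns sample_id, chrom, start,
#'   ref_allele, alt_allele, event_kind, snv_class, context, at_cpg,
#'   strand_label (classification columns NA until [classifySnvs()]).
#' @export
collapseDinucleotideEvents <- function(calls, reference = NULL) {
  calls <- checkCallTable(calls)
  if (!is.null(reference)) {
    reference <- loadReference(reference)
    lens <- setNames(Biostrings::width(reference), names(reference))
    bad <- calls$pos > lens[calls$chrom]
    if (any(bad, na.rm = TRUE) || anyNA(bad))
      stop("variant position beyond reference length (or unknown chrom)")
  }
  calls <- calls[order(calls$sample_id, calls$chrom, calls$pos), ,
                 drop = FALSE]
  is_snv <- calls$variant_kind == "snv"
  snv <- calls[is_snv, , drop = FALSE]
  n <- nrow(snv)
  merged_with_prev <- rep(FALSE, n)
  if (n > 1L) {
    for (i in 2:n) {
      adjacent <- snv$sample_id[i] == snv$sample_id[i - 1L] &&
        snv$chrom[i] == snv$chrom[i - 1L] &&
        snv$pos[i] == snv$pos[i - 1L] + 1L
      # greedy left-to-right: an SNV already consumed by the previous pair
      # cannot anchor a new pair
      merged_with_prev[i] <- adjacent && !merged_with_prev[i - 1L]
    }
  }
  first_of_pair <- c(merged_with_prev[-1L], FALSE)
  events <- list()
  if (any(first_of_pair)) {
    i <- which(first_of_pair)
    events$dinuc <- data.frame(
      sample_id = snv$sample_id[i], chrom = snv$chrom[i],
      start = snv$pos[i],
      ref_allele = paste0(snv$ref[i], snv$ref[i + 1L]),
      alt_allele = paste0(snv$alt[i], snv$alt[i + 1L]),
      event_kind = "dinucleotide", stringsAsFactors = FALSE)
  }
  solo <- !first_of_pair & !merged_with_prev
  if (any(solo)) {
    events$snv <- data.frame(
      sample_id = snv$sample_id[solo], chrom = snv$chrom[solo],
      start = snv$pos[solo], ref_allele = snv$ref[solo],
      alt_allele = snv$alt[solo], event_kind = "snv",
      stringsAsFactors = FALSE)
  }
  ind <- calls[!is_snv, , drop = FALSE]
  if (nrow(ind)) {
    events$indel <- data.frame(
      sample_id = ind$sample_id, chrom = ind$chrom, start = ind$pos,
      ref_allele = ind$ref, alt_allele = ind$alt, event_kind = "indel",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, events)
  if (is.null(out))
    out <- data.frame(sample_id = character(), chrom = character(),
                      start = integer(), ref_allele = character(),
                      alt_allele = character(), event_kind = character(),
                      stringsAsFactors = FALSE)
  out$snv_class <- NA_character_
  out$context <- NA_character_
  out$at_cpg <- NA
  out$strand_label <- "unknown"
  out <- out[order(out$sample_id, out$chrom, out$start), EVENT_COLS,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify SNV events into the six pyrimidine-centric types
#'
#' Assigns to every \code{snv} event its substitution class (C>A, C>G,
#' C>T, T>A, T>C, T>G), its pyrimidine-centered trinucleotide context and
#' its CpG status.  Purine-reference SNVs are reported on the reverse
#' complement, so a G>A in 5'-AGA-3' becomes C>T in context TCT.  An event
#' is at a CpG iff the mutated cytosine is immediately followed by a G on
#' the pyrimidine-bearing strand (context \code{.CG}).  Events whose
#' flanks contain an ambiguous base (N) are flagged with
#' \code{context_ok = FALSE}, left unclassified and excluded from context
#' analyses downstream.
#'
#' @param events event table from [collapseDinucleotideEvents()].
#' @param reference reference sequence set (see [loadReference()]).
#' @return The event table with snv_class, context, at_cpg and a logical
#'   context_ok column filled in for snv events.
#' @export
classifySnvs <- function(events, reference) {
  reference <- loadReference(reference)
  events$context_ok <- TRUE
  idx <- which(events$event_kind == "snv")
  if (!length(idx)) return(events)
  lens <- setNames(Biostrings::width(reference), names(reference))
  for (i in idx) {
    chrom <- events$chrom[i]; pos <- events$start[i]
    if (!chrom %in% names(reference))
      stop("chromosome absent from reference: ", chrom)
    if (pos < 2L || pos + 1L > lens[[chrom]]) {
      events$context_ok[i] <- FALSE
      next
    }
    tri <- toupper(as.character(Biostrings::subseq(reference[[chrom]],
                                                   pos - 1L, pos + 1L)))
    ref <- events$ref_allele[i]; alt <- events$alt_allele[i]
    if (substr(tri, 2L, 2L) != ref)
      stop("reference mismatch at ", chrom, ":", pos, " (expected ", ref,
           ", found ", substr(tri, 2L, 2L), ")")
    if (grepl("[^ACGT]", tri) || !alt %in% BASES) {
      events$context_ok[i] <- FALSE
      next
    }
    if (!isPyrimidine(ref)) {
      tri <- revcompChar(tri)
      ref <- revcompChar(ref)
      alt <- revcompChar(alt)
    }
    events$snv_class[i] <- paste0(ref, ">", alt)
    events$context[i] <- tri
    events$at_cpg[i] <- ref == "C" && substr(tri, 3L, 3L) == "G"
  }
  n_bad <- sum(!events$context_ok[idx])
  if (n_bad)
    warning(n_bad,
            " snv event(s) with unresolvable context flagged and excluded")
  events
}

#' Mutation burden per megabase
#'
#' Per-sample event count scaled to the capture footprint:
#' \code{count * 1e6 / capture_size_bp}.  With \code{kind = "snv"},
#' dinucleotide events contribute 1 event each, following the convention
#' that dipyrimidine substitutions are a single mutational event.
#'
#' @param events event table.
#' @param capture_size_bp total captured bases (> 0).
#' @param kind one of \code{"snv"} (SNVs plus dinucleotides),
#'   \code{"indel"}, \code{"dinucleotide"}.
#' @return Named numeric vector, one burden per sample present in
#'   \code{events}.
#' @export
burdenPerMb <- function(events, capture_size_bp, kind = c("snv", "indel",
                                                          "dinucleotide")) {
  kind <- match.arg(kind)
  if (!is.numeric(capture_size_bp) || capture_size_bp <= 0)
    stop("capture_size_bp must be a positive number")
  keep <- switch(kind,
                 snv = events$event_kind %in% c("snv", "dinucleotide"),
                 indel = events$event_kind == "indel",
                 dinucleotide = events$event_kind == "dinucleotide")
  samples <- sort(unique(events$sample_id))
  counts <- table(factor(events$sample_id[keep], levels = samples))
  setNames(as.numeric(counts) * 1e6 / capture_size_bp, samples)
}

#' Gene-level recurrence table
#'
#' Tallies, per gene, the number of distinct samples carrying at least one
#' event (multiple events in one gene/sample count once) and keeps genes
#' altered in at least \code{min_samples} samples — the criterion used to
#' select genes for recurrence displays.  The \code{"intergenic"} sentinel
#' is ignored.
#'
#' @param events event table with an additional \code{gene} column and
#'   optionally \code{mutation_type} labels.
#' @param cohort_size number of samples in the cohort (>= distinct samples
#'   in \code{events}).
#' @param min_samples retention threshold (default 3).
#' @return data.frame with columns gene, n_samples, frequency and
#'   sample_types (per-sample "sample:type" labels, semicolon-joined),
#'   sorted by decreasing recurrence.
#' @export
geneRecurrence <- function(events, cohort_size, min_samples = 3L) {
  if (!"gene" %in% names(events))
    stop("events must carry a gene column (use 'intergenic' as sentinel)")
  n_seen <- length(unique(events$sample_id))
  if (cohort_size < n_seen)
    stop("cohort_size (", cohort_size, ") below number of distinct samples (",
         n_seen, ")")
  ev <- events[events$gene != "intergenic" & !is.na(events$gene), ,
               drop = FALSE]
  if (!"mutation_type" %in% names(ev)) ev$mutation_type <- ev$event_kind
  key <- !duplicated(paste(ev$gene, ev$sample_id, sep = "\r"))
  per_gene <- split(ev[key, , drop = FALSE], ev$gene[key])
  rows <- lapply(per_gene, function(g) {
    data.frame(gene = g$gene[1L], n_samples = nrow(g),
               frequency = nrow(g) / cohort_size,
               sample_types = paste(g$sample_id, g$mutation_type, sep = ":",
                                    collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(gene = character(), n_samples = integer(),
                      frequency = numeric(), sample_types = character()))
  out <- out[out$n_samples >= min_samples, , drop = FALSE]
  out <- out[order(-out$n_samples, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
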