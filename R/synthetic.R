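## Seeded synthetic-data generator: reference + gene models, mutation
## catalogs with planted signatures, strand bias and CC>TT dinucleotide
## events, per-caller call sets with dropout/false positives, CNA
## segments with a known altered fraction, and two-group survival times.
## Every generator is deterministic under its seed, and the module's
## reason for existing is that simulate -> analyze recovers the planted
## parameters.

#' Generate a synthetic reference with stranded genes and capture regions
#'
#' Emits an i.i.d. random sequence at the requested GC content, a set of
#' non-overlapping genes with alternating +/- strands, and capture
#' regions covering the whole sequence.
#'
#' @param length_bp sequence length (>= 10 kb).
#' @param gc_fraction GC content in (0, 1).
#' @param n_genes number of non-overlapping genes.
#' @param gene_fraction fraction of the sequence covered by genes.
#' @param seed integer seed.
#' @param chrom chromosome name.
#' @return list with \code{reference} (DNAStringSet), \code{genes}
#'   (stranded GRanges with gene ids) and \code{capture} (GRanges).
#' @export
generateReference <- function(length_bp = 1e5, gc_fraction = 0.45,
                              n_genes = 20L, gene_fraction = 0.6,
                              seed = 1L, chrom = "chr1") {
  if (length_bp < 1e4) stop("reference length must be >= 10 kb")
  if (gc_fraction <= 0 || gc_fraction >= 1) stop("gc_fraction must be in (0,1)")
  gene_len <- floor(length_bp * gene_fraction / n_genes)
  gap <- floor(length_bp * (1 - gene_fraction) / (n_genes + 1L))
  if (gene_len < 100L)
    stop("n_genes infeasible for this reference length")
  withSeed(seed, {
    p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
           G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
    seq <- paste(sample(names(p), length_bp, replace = TRUE, prob = p),
                 collapse = "")
    reference <- Biostrings::DNAStringSet(setNames(seq, chrom))
    starts <- gap + (seq_len(n_genes) - 1L) * (gene_len + gap) + 1L
    genes <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(starts, starts + gene_len - 1L),
      strand = rep(c("+", "-"), length.out = n_genes))
    genes$gene <- sprintf("gene%03d", seq_len(n_genes))
    capture <- GenomicRanges::GRanges(chrom, IRanges::IRanges(1L, length_bp))
    list(reference = reference, genes = genes, capture = capture)
  })
}

#' Construct mutational-signature profiles for simulation
#'
#' \code{uvb_like} concentrates mass on C>T channels with a 5' pyrimidine
#' in the order TCT > TCC > TCA > TCG (the hallmark of CPD-driven UVB
#' mutagenesis), with minor mass elsewhere; \code{flat} is uniform over
#' the 96 channels; \code{custom} normalizes a user profile.
#'
#' @param kind \code{"uvb_like"}, \code{"flat"} or \code{"custom"}.
#' @param profile for \code{custom}: non-negative 96-vector (named by
#'   channel or in canonical order).
#' @return Named numeric 96-vector summing to 1 in canonical channel
#'   order.
#' @export
makeSignature <- function(kind = c("uvb_like", "flat", "custom"),
                          profile = NULL) {
  kind <- match.arg(kind)
  chan <- sbs96Channels()
  if (kind == "flat") return(setNames(rep(1 / 96, 96), chan))
  if (kind == "custom") {
    if (is.null(profile) || length(profile) != 96L)
      stop("custom profile must be a 96-vector")
    if (any(profile < 0)) stop("custom profile has negative entries")
    if (is.null(names(profile))) names(profile) <- chan
    profile <- profile[chan]
    if (anyNA(profile)) stop("custom profile names must be the 96 channels")
    return(profile / sum(profile))
  }
  # concentrated like the canonical UVB/CPD signature: >90% of mass in
  # C>T channels, strongest at 5'-pyrimidine (dipyrimidine) contexts
  prof <- setNames(rep(0.04 / 80, 96), chan)
  ct <- paste0(rep(BASES, each = 4), "[C>T]", rep(BASES, 4))
  prof[ct] <- 0.04 / 8
  peaks <- c("T[C>T]T" = 0.28, "T[C>T]C" = 0.20, "T[C>T]A" = 0.14,
             "T[C>T]G" = 0.06, "C[C>T]T" = 0.11, "C[C>T]C" = 0.06,
             "C[C>T]A" = 0.05, "C[C>T]G" = 0.02)
  prof[names(peaks)] <- peaks
  prof / sum(prof)
}

contextSiteIndex <- function(reference, genes) {
  # every position whose pyrimidine-centric 3-mer is resolvable, with the
  # strand carrying the pyrimidine and its transcription status
  ref <- loadReference(reference)
  gene_strand <- as.character(GenomicRanges::strand(genes))
  rows <- list()
  for (chrom in names(ref)) {
    seq <- ref[[chrom]]
    for (ctx in sbs96Contexts()) {
      for (pyr_strand in c("+", "-")) {
        pat <- if (pyr_strand == "+") ctx else revcompChar(ctx)
        hits <- Biostrings::matchPattern(pat, seq)
        if (!length(hits)) next
        pos <- Biostrings::start(hits) + 1L  # center base
        rows[[length(rows) + 1L]] <-
          data.frame(chrom = chrom, pos = pos, context = ctx,
                     pyr_strand = pyr_strand, stringsAsFactors = FALSE)
      }
    }
  }
  sites <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(sites$pos, sites$pos))
  hits <- GenomicRanges::findOverlaps(gr, genes, ignore.strand = TRUE)
  sites$status <- "intergenic"
  gs <- split(gene_strand[S4Vectors::subjectHits(hits)],
              S4Vectors::queryHits(hits))
  for (k in seq_along(gs)) {
    i <- as.integer(names(gs)[k])
    s <- unique(gs[[k]])
    sites$status[i] <- if (length(s) != 1L) "ambiguous"
      else if (sites$pyr_strand[i] == s) "untranscribed" else "transcribed"
  }
  sites
}

#' Simulate a multi-sample mutation catalog with planted structure
#'
#' Per sample, draws each signature's activity level from a gamma
#' distribution around its cohort mean (coefficient of variation
#' \code{activity_cv}, reflecting the strong tumor-to-tumor variation in
#' signature activity seen in real cohorts), then a Poisson mutation
#' count at that level, draws channels from the signature profile, and
#' places each mutation uniformly among reference sites matching its
#' trinucleotide context (collisions re-drawn).  Genic C>T-class events
#' are placed on untranscribed-pyrimidine sites with odds
#' \code{strand_bias_rho} : 1 against transcribed sites.  A fraction
#' \code{dinucleotide_rate} of C>T events whose pyrimidine-strand 3'
#' neighbor is also a C are emitted as adjacent CC>TT pairs.  Each true
#' variant is emitted to three synthetic callers, each independently
#' missing it with probability \code{caller_dropout}; callers also add
#' private false-positive calls at \code{false_positive_rate} per true
#' variant.
#'
#' @param bundle reference bundle from [generateReference()].
#' @param n_samples number of tumors.
#' @param signatures named list of 96-profiles ([makeSignature()]).
#' @param mean_activities named numeric, expected mutations per sample
#'   per signature (defaults: uvb 300, flat 100 — the regime of a
#'   UVB-accelerated cohort).
#' @param activity_cv coefficient of variation of the per-sample gamma
#'   activity levels (0 = identical expected mixing in every sample,
#'   which makes the mixture unidentifiable; default 0.7).
#' @param strand_bias_rho untranscribed:transcribed odds for C>T-class
#'   genic placement (>= 1; 1 = no bias).
#' @param dinucleotide_rate fraction of eligible C>T events converted to
#'   CC>TT pairs, in [0, 1).
#' @param caller_dropout,false_positive_rate per-caller noise knobs.
#' @param seed integer seed.
#' @return list with \code{callsets} (3 per-caller call tables),
#'   \code{truth} (signature matrix, per-sample realized activities,
#'   per-event table with generating signature and planted strand
#'   status, dinucleotide pair count) and \code{samples}.
#' @export
simulateCatalog <- function(bundle, n_samples = 30L,
                            signatures = list(uvb = makeSignature("uvb_like"),
                                              flat = makeSignature("flat")),
                            mean_activities = c(uvb = 300, flat = 100),
                            activity_cv = 0.7,
                            strand_bias_rho = 2, dinucleotide_rate = 0.05,
                            caller_dropout = 0, false_positive_rate = 0,
                            seed = 1L) {
  if (strand_bias_rho < 1) stop("strand_bias_rho must be >= 1")
  if (dinucleotide_rate < 0 || dinucleotide_rate >= 1)
    stop("dinucleotide_rate must be in [0, 1)")
  stopifnot(identical(sort(names(signatures)), sort(names(mean_activities))))
  ref <- loadReference(bundle$reference)
  sites <- contextSiteIndex(ref, bundle$genes)
  site_by_ctx <- split(seq_len(nrow(sites)), sites$context)
  need <- unique(unlist(lapply(signatures, function(p)
    channelContext(names(p)[p > 0]))))
  absent <- setdiff(need, names(site_by_ctx))
  if (length(absent))
    stop("context(s) with signature mass absent from reference: ",
         paste(absent, collapse = ", "))
  chan <- sbs96Channels()
  samples <- sprintf("S%02d", seq_len(n_samples))
  seqs <- lapply(ref, function(x) x)  # DNAString per chrom
  baseAt <- function(chrom, pos)
    toupper(as.character(Biostrings::subseq(seqs[[chrom]], pos, pos)))

  withSeed(seed, {
    truth_events <- list()
    activities <- matrix(0, n_samples, length(signatures),
                         dimnames = list(samples, names(signatures)))
    dinuc_pairs <- setNames(integer(n_samples), samples)
    calls <- list()
    for (s in seq_len(n_samples)) {
      used <- character()
      for (g in names(signatures)) {
        level <- if (activity_cv > 0)
          rgamma(1L, shape = 1 / activity_cv^2,
                 scale = mean_activities[[g]] * activity_cv^2)
          else mean_activities[[g]]
        n_mut <- rpois(1L, level)
        if (n_mut == 0L) next
        drawn <- rmultinom(1L, n_mut, signatures[[g]])[, 1L]
        for (ci in which(drawn > 0L)) {
          channel <- chan[ci]
          ctx <- channelContext(channel)
          cls <- channelClass(channel)
          cand <- site_by_ctx[[ctx]]
          wts <- rep(1, length(cand))
          if (startsWith(cls, "C>")) {
            st <- sites$status[cand]
            wts[st == "untranscribed"] <- strand_bias_rho
            wts[st == "ambiguous"] <- 0
            if (all(wts == 0)) wts <- rep(1, length(cand))
          }
          m <- drawn[ci]
          picked <- integer(0)
          tries <- 0L
          while (length(picked) < m && tries < 50L) {
            extra <- sample(cand, m - length(picked), replace = TRUE,
                            prob = wts)
            key <- paste(sites$chrom[extra], sites$pos[extra])
            fresh <- !(key %in% used) & !duplicated(key)
            picked <- c(picked, extra[fresh])
            used <- c(used, key[fresh])
            tries <- tries + 1L
          }
          for (i in picked) {
            chromi <- sites$chrom[i]; posi <- sites$pos[i]
            pyr_plus <- sites$pyr_strand[i] == "+"
            pyr_ref <- substr(ctx, 2L, 2L)
            pyr_alt <- substr(cls, 3L, 3L)
            ref_b <- if (pyr_plus) pyr_ref else revcompChar(pyr_ref)
            alt_b <- if (pyr_plus) pyr_alt else revcompChar(pyr_alt)
            rec <- data.frame(sample_id = samples[s], chrom = chromi,
                              pos = posi, ref = ref_b, alt = alt_b,
                              signature = g, status = sites$status[i],
                              channel = channel, dinuc = FALSE,
                              stringsAsFactors = FALSE)
            # CC>TT planting: eligible when the pyrimidine-strand 3'
            # neighbor is also a C (context ends in C)
            if (cls == "C>T" && substr(ctx, 3L, 3L) == "C" &&
                runif(1L) < dinucleotide_rate) {
              ppos <- if (pyr_plus) posi + 1L else posi - 1L
              pkey <- paste(chromi, ppos)
              if (!(pkey %in% used)) {
                used <- c(used, pkey)
                partner <- rec
                partner$pos <- ppos
                partner$ref <- if (pyr_plus) "C" else "G"
                partner$alt <- if (pyr_plus) "T" else "A"
                partner$dinuc <- TRUE
                rec$dinuc <- TRUE
                truth_events[[length(truth_events) + 1L]] <- partner
                dinuc_pairs[s] <- dinuc_pairs[s] + 1L
              }
            }
            truth_events[[length(truth_events) + 1L]] <- rec
            if (!rec$dinuc)
              activities[s, g] <- activities[s, g] + 1
          }
        }
      }
    }
    truth <- do.call(rbind, truth_events)
    truth <- truth[order(truth$sample_id, truth$chrom, truth$pos), ,
                   drop = FALSE]
    rownames(truth) <- NULL
    callers <- paste0("caller", 1:3)
    callsets <- lapply(callers, function(cl) {
      keep <- runif(nrow(truth)) >= caller_dropout
      df <- truth[keep, c("sample_id", "chrom", "pos", "ref", "alt"),
                  drop = FALSE]
      n_fp <- rpois(1L, false_positive_rate * nrow(truth))
      if (n_fp > 0L) {
        fp_idx <- sample(nrow(sites), n_fp, replace = TRUE)
        fp_ref <- vapply(fp_idx, function(i)
          baseAt(sites$chrom[i], sites$pos[i]), "")
        fp_alt <- vapply(fp_ref, function(b)
          sample(setdiff(BASES, b), 1L), "")
        df <- rbind(df, data.frame(
          sample_id = sample(samples, n_fp, replace = TRUE),
          chrom = sites$chrom[fp_idx], pos = sites$pos[fp_idx],
          ref = fp_ref, alt = fp_alt, stringsAsFactors = FALSE))
      }
      variantCalls(df$sample_id, df$chrom, df$pos, df$ref, df$alt, cl)
    })
    names(callsets) <- callers
    sig_mat <- do.call(cbind, signatures)
    rownames(sig_mat) <- chan
    list(callsets = callsets,
         truth = list(signatures = sig_mat, activities = activities,
                      events = truth, dinucleotide_pairs = dinuc_pairs),
         samples = samples)
  })
}

#' Simulate survival records and copy-number segments
#'
#' Survival times are exponential per group with right-censoring at a
#' fixed horizon.  Copy-number segments tile one synthetic chromosome per
#' sample into equal-length segments; a planted subset carries an
#' elevated log2 ratio so that the altered-genome fraction is known by
#' construction (reported in the truth slot as realized).
#'
#' @param groups named list; each element a list with \code{n} (subjects)
#'   and \code{scale} (mean survival time in weeks).
#' @param horizon censoring horizon (weeks).
#' @param n_samples samples to simulate segments for.
#' @param altered_fraction target fraction of the segmented footprint
#'   altered, in [0, 1].
#' @param n_segments segments per sample (altered count =
#'   \code{round(altered_fraction * n_segments)}).
#' @param chrom_length_bp footprint per sample.
#' @param altered_log2 log2 ratio planted on altered segments.
#' @param seed integer seed.
#' @return list with \code{survival} (subject_id, group, time, event),
#'   \code{segments} (sample_id, chrom, start, end, log2_ratio, n_bins)
#'   and \code{truth} (realized altered fraction per sample).
#' @export
simulateClinical <- function(groups = list(control = list(n = 15, scale = 22),
                                           uvb = list(n = 15, scale = 9)),
                             horizon = 40, n_samples = 10L,
                             altered_fraction = 0.25, n_segments = 20L,
                             chrom_length_bp = 1e8, altered_log2 = 0.8,
                             seed = 1L) {
  if (altered_fraction < 0 || altered_fraction > 1)
    stop("altered_fraction must be in [0, 1]")
  withSeed(seed, {
    surv <- do.call(rbind, lapply(names(groups), function(g) {
      n <- groups[[g]]$n
      t_true <- rexp(n, rate = 1 / groups[[g]]$scale)
      data.frame(subject_id = paste0(g, seq_len(n)), group = g,
                 time = pmin(t_true, horizon), event = t_true <= horizon,
                 stringsAsFactors = FALSE)
    }))
    seg_len <- floor(chrom_length_bp / n_segments)
    n_alt <- round(altered_fraction * n_segments)
    samples <- sprintf("S%02d", seq_len(n_samples))
    segments <- do.call(rbind, lapply(samples, function(s) {
      alt <- sample(n_segments, n_alt)
      data.frame(sample_id = s, chrom = "chr1",
                 start = (seq_len(n_segments) - 1L) * seg_len,
                 end = seq_len(n_segments) * seg_len,
                 log2_ratio = ifelse(seq_len(n_segments) %in% alt,
                                     altered_log2 * sample(c(-1, 1),
                                                           n_segments,
                                                           replace = TRUE),
                                     0),
                 n_bins = 10L, stringsAsFactors = FALSE)
    }))
    rownames(segments) <- NULL
    list(survival = surv, segments = segments,
         truth = list(altered_fraction = n_alt / n_segments))
  })
}

#' Write a simulated dataset to disk
#'
#' Emits FASTA, gene/capture BED, one VCF per sample per caller, a
#' segments TSV, a survival TSV and a ground-truth JSON under one
#' directory.
#'
#' @param bundle reference bundle ([generateReference()]).
#' @param catalog_sim output of [simulateCatalog()].
#' @param clinical_sim optional output of [simulateClinical()].
#' @param dir output directory (created).
#' @return Invisibly, \code{dir}.
#' @export
writeSimulatedData <- function(bundle, catalog_sim, clinical_sim = NULL,
                               dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(bundle$reference,
                              file.path(dir, "reference.fa"))
  bed <- function(gr, path, extra = NULL) {
    df <- data.frame(as.character(GenomicRanges::seqnames(gr)),
                     GenomicRanges::start(gr) - 1L,
                     GenomicRanges::end(gr))
    if (!is.null(extra)) df <- cbind(df, extra)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  bed(bundle$genes, file.path(dir, "genes.bed"),
      data.frame(bundle$genes$gene, 0,
                 as.character(GenomicRanges::strand(bundle$genes))))
  bed(bundle$capture, file.path(dir, "capture.bed"))
  for (cl in names(catalog_sim$callsets)) {
    cs <- catalog_sim$callsets[[cl]]
    for (s in unique(cs$sample_id)) {
      ev <- cs[cs$sample_id == s, , drop = FALSE]
      writeMinimalVcf(data.frame(sample_id = ev$sample_id, chrom = ev$chrom,
                                 start = ev$pos, ref_allele = ev$ref,
                                 alt_allele = ev$alt, event_kind = "snv"),
                      file.path(dir, paste0(s, ".", cl, ".vcf")))
    }
  }
  if (!is.null(clinical_sim)) {
    write.table(clinical_sim$survival, file.path(dir, "survival.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(clinical_sim$segments, file.path(dir, "segments.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(list(activities = catalog_sim$truth$activities,
                            dinucleotide_pairs =
                              catalog_sim$truth$dinucleotide_pairs),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
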