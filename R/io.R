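## Readers/writers for the plain-text formats the pipeline consumes:
## FASTA references, call tables and VCFs, BED/GFF3 gene models, COSMIC
## tabular signature catalogs, CNVkit-style segment tables, spectra.

#' Load a reference sequence set
#'
#' Accepts a FASTA path or an existing \code{DNAStringSet} and returns a
#' \code{DNAStringSet} keyed by chromosome name (first whitespace token of
#' each FASTA header).
#'
#' @param x FASTA file path or \code{DNAStringSet}.
#' @return \code{DNAStringSet}.
#' @export
loadReference <- function(x) {
  if (is(x, "DNAStringSet")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    ref <- Biostrings::readDNAStringSet(x)
    names(ref) <- sub("\\s.*$", "", names(ref))
    return(ref)
  }
  stop("reference must be a DNAStringSet or a FASTA path")
}

#' Read a tabular call set
#'
#' Expects a TSV with columns sample, chrom, pos, ref, alt and optionally
#' caller (aliases sample_id/caller_id accepted).
#'
#' @param path TSV path.
#' @param caller_id caller label when the file has no caller column.
#' @return A call table ([variantCalls()] layout).
#' @export
readCallTable <- function(path, caller_id = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "sample"] <- "sample_id"
  names(df)[names(df) == "caller"] <- "caller_id"
  need <- c("sample_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(df)))
    stop("call table ", path, " missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (is.null(df$caller_id))
    df$caller_id <- if (is.null(caller_id))
      tools::file_path_sans_ext(basename(path)) else caller_id
  variantCalls(df$sample_id, df$chrom, df$pos, df$ref, df$alt, df$caller_id)
}

#' Read a VCF call set
#'
#' Minimal single-sample somatic VCF reader: CHROM/POS/REF/ALT are parsed,
#' multi-allelic records are split into biallelic records, and the sample
#' is taken from the header genotype column when present, otherwise from
#' the file name.
#'
#' @param path VCF path (uncompressed).
#' @param sample_id,caller_id overrides for the sample and caller labels.
#' @return A call table.
#' @export
readCallVcf <- function(path, sample_id = NULL, caller_id = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines, value = TRUE)
  if (is.null(sample_id)) {
    fields <- if (length(hdr)) strsplit(hdr[1L], "\t")[[1]] else character()
    sample_id <- if (length(fields) >= 10L) fields[10L]
      else tools::file_path_sans_ext(basename(path))
  }
  if (is.null(caller_id))
    caller_id <- tools::file_path_sans_ext(basename(path))
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body))
    return(variantCalls(character(), character(), integer(), character(),
                        character(), caller_id))
  parts <- strsplit(body, "\t")
  chrom <- vapply(parts, `[`, "", 1L)
  pos <- as.integer(vapply(parts, `[`, "", 2L))
  ref <- vapply(parts, `[`, "", 4L)
  alt <- vapply(parts, `[`, "", 5L)
  if (anyNA(pos)) stop("malformed VCF record in ", path)
  alts <- strsplit(alt, ",", fixed = TRUE)
  n <- lengths(alts)
  variantCalls(rep(sample_id, sum(n)), rep(chrom, n), rep(pos, n),
               rep(ref, n), unlist(alts), caller_id)
}

#' Write a minimal single-sample VCF of consensus events
#'
#' @param events event table (snv/dinucleotide/indel rows for a single
#'   sample).
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeMinimalVcf <- function(events, path) {
  if (length(unique(events$sample_id)) > 1L)
    stop("writeMinimalVcf expects events for a single sample")
  sample <- if (nrow(events)) events$sample_id[1L] else "sample"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=uvsig",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sample, sep = "\t")), con)
  if (nrow(events))
    writeLines(paste(events$chrom, events$start, ".", events$ref_allele,
                     events$alt_allele, ".", "PASS",
                     paste0("KIND=", events$event_kind), "GT", "0/1",
                     sep = "\t"), con)
  invisible(path)
}

#' Read an exclusion (known-variant) list
#'
#' Accepts a VCF or a TSV with columns chrom, pos, ref, alt.
#'
#' @param path file path.
#' @return data.frame with columns chrom, pos, ref, alt.
#' @export
readExclusionList <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##fileformat=VCF") || grepl("\\.vcf$", path)) {
    calls <- readCallVcf(path, sample_id = "excluded")
    return(calls[, c("chrom", "pos", "ref", "alt")])
  }
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(df)))
    stop("exclusion list must have columns chrom, pos, ref, alt")
  df[, need]
}

#' Read/write event tables
#' @param path TSV path.
#' @param events event table.
#' @return \code{readEventsTsv}: the event table; writers return the path
#'   invisibly.
#' @export
readEventsTsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(EVENT_COLS %in% names(df)))
    stop("event table missing column(s): ",
         paste(setdiff(EVENT_COLS, names(df)), collapse = ", "))
  df
}

#' @rdname readEventsTsv
#' @export
writeEventsTsv <- function(events, path) {
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write SBS96 catalogs in COSMIC tabular layout
#'
#' The on-disk layout is channels x samples with a leading
#' \code{MutationType} column of COSMIC channel labels (\code{A[C>A]A}
#' ...), one column per sample.
#'
#' @param path TSV path.
#' @param catalog an [Sbs96Catalog-class].
#' @return \code{readCatalogTsv}: an [Sbs96Catalog-class].
#' @export
readCatalogTsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "MutationType")
    stop("catalog file must start with a MutationType column")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$MutationType
  if (!setequal(rownames(m), sbs96Channels()))
    stop("catalog channels do not match the canonical SBS96 set")
  Sbs96Catalog(t(m[sbs96Channels(), , drop = FALSE]))
}

#' @rdname readCatalogTsv
#' @export
writeCatalogTsv <- function(catalog, path) {
  m <- t(catalogCounts(catalog))
  df <- data.frame(MutationType = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a reference signature catalog (COSMIC layout)
#'
#' 96 rows by K named signatures, leading MutationType column; columns are
#' renormalized to sum to 1.
#'
#' @param path TSV path.
#' @return A [SignatureMatrix-class].
#' @export
readSignatureCatalogTsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "MutationType")
    stop("signature catalog must start with a MutationType column")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$MutationType
  SignatureMatrix(m)
}

#' @rdname readSignatureCatalogTsv
#' @param signatures a [SignatureMatrix-class].
#' @export
writeSignatureTsv <- function(signatures, path) {
  p <- signatureProfiles(signatures)
  df <- data.frame(MutationType = rownames(p), p, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read stranded gene annotations
#'
#' BED (0-based half-open, columns chrom/start/end/name/score/strand) or
#' GFF3 (1-based, gene lines) chosen by file extension; both return a
#' stranded \code{GRanges} of gene bodies.
#'
#' @param path .bed or .gff/.gff3 path.
#' @return \code{GRanges} with a \code{gene} metadata column.
#' @export
readGeneAnnotation <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 6L) stop("BED gene file needs 6 columns incl. strand")
    if (!all(df[[6]] %in% c("+", "-")))
      stop("malformed strand field in ", path)
    gr <- GenomicRanges::GRanges(df[[1]],
                                 IRanges::IRanges(df[[2]] + 1L, df[[3]]),
                                 strand = df[[6]])
    gr$gene <- as.character(df[[4]])
  } else if (ext %in% c("gff", "gff3")) {
    df <- read.delim(path, header = FALSE, comment.char = "#",
                     stringsAsFactors = FALSE)
    df <- df[df[[3]] == "gene", , drop = FALSE]
    if (!all(df[[7]] %in% c("+", "-")))
      stop("malformed strand field in ", path)
    gr <- GenomicRanges::GRanges(df[[1]],
                                 IRanges::IRanges(df[[4]], df[[5]]),
                                 strand = df[[7]])
    id <- sub(".*ID=([^;]+).*", "\\1", df[[9]])
    gr$gene <- id
  } else stop("unsupported gene annotation extension: ", ext)
  gr
}

#' Read capture/target regions from BED
#'
#' @param path BED path (0-based half-open).
#' @return \code{GRanges}.
#' @export
readRegionsBed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  GenomicRanges::GRanges(df[[1]], IRanges::IRanges(df[[2]] + 1L, df[[3]]))
}

#' Read copy-number segments
#'
#' Accepts CNVkit \code{.cns}-style columns (chromosome, start, end, log2,
#' probes) or a generic TSV (chrom, start, end, log2_ratio, n_bins), with
#' an optional sample/sample_id column.  Coordinates are 0-based
#' half-open.
#'
#' @param path TSV path.
#' @param sample_id sample label when the file has no sample column.
#' @return data.frame with columns sample_id, chrom, start, end,
#'   log2_ratio, n_bins.
#' @export
readSegmentsTsv <- function(path, sample_id = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "chromosome"] <- "chrom"
  names(df)[names(df) == "log2"] <- "log2_ratio"
  names(df)[names(df) == "probes"] <- "n_bins"
  names(df)[names(df) == "sample"] <- "sample_id"
  need <- c("chrom", "start", "end", "log2_ratio", "n_bins")
  if (!all(need %in% names(df)))
    stop("segment table missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (is.null(df$sample_id))
    df$sample_id <- if (is.null(sample_id))
      tools::file_path_sans_ext(basename(path)) else sample_id
  df[, c("sample_id", need)]
}

#' Read a lamp emission spectrum
#'
#' Two-column CSV/TSV (wavelength nm, relative intensity); delimiter
#' sniffed from the first line.
#'
#' @param path file path.
#' @return A [SpectralIrradiance-class].
#' @export
readSpectrumTable <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("spectrum file needs two columns")
  SpectralIrradiance(df[[1]], df[[2]])
}
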