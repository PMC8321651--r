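## End-to-end orchestration from a single configuration: consensus ->
## collapse -> classify -> spectra -> signatures -> catalog matching,
## with CNA, group/survival statistics and dosimetry as enabled.

#' Validate and normalize a pipeline configuration
#'
#' A configuration is a named list (or a YAML file containing one) with
#' the stage inputs; missing required inputs for an enabled stage fail
#' fast with the stage name.  Fields: \code{calls} (list of call tables
#' or file paths, one per caller), \code{reference} (DNAStringSet or
#' FASTA path), \code{exclusion} (optional data.frame/path),
#' \code{genes} (GRanges/BED/GFF path), \code{regions} (GRanges/BED
#' path), \code{capture_size_bp}, \code{segments}
#' (data.frame/path), \code{survival} (data.frame/path),
#' \code{spectrum} (SpectralIrradiance/path) with \code{dose_kj_m2},
#' \code{reference_catalog} (SignatureMatrix/path), \code{stages}
#' (character subset of variants, spectrum, signatures, comparison, cna,
#' stats, dosimetry), \code{seed}, and signature-extraction parameters
#' \code{rank_range}, \code{n_bootstrap}.
#'
#' @param config named list or YAML path.
#' @return The normalized configuration list.
#' @export
pipelineConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path")
  defaults <- list(stages = c("variants", "spectrum", "signatures"),
                   seed = 1L, rank_range = 1:5, n_bootstrap = 50L,
                   capture_size_bp = NULL, dose_kj_m2 = NULL,
                   min_recurrent_samples = 3L)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  need <- function(field, stage)
    if (is.null(config[[field]]))
      stop("stage '", stage, "' enabled but required input '", field,
           "' is missing")
  st <- config$stages
  if ("variants" %in% st) {
    need("calls", "variants")
    need("reference", "variants")
  }
  if ("spectrum" %in% st) need("genes", "spectrum")
  if ("signatures" %in% st && !"spectrum" %in% st)
    stop("stage 'signatures' enabled but required input 'spectrum stage' is missing")
  if ("comparison" %in% st) need("reference_catalog", "comparison")
  if ("cna" %in% st) need("segments", "cna")
  if ("stats" %in% st) need("survival", "stats")
  if ("dosimetry" %in% st) {
    need("spectrum", "dosimetry")
    need("dose_kj_m2", "dosimetry")
  }
  config
}

resolveInput <- function(x, reader) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) reader(x) else x
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in order and returns a result bundle; the
#' JSON summary is stamped with a hash of the configuration and the seed,
#' so identical configurations reproduce identical summaries.
#'
#' @param config see [pipelineConfig()].
#' @param out_dir optional directory: tables and \code{summary.json} are
#'   written there.
#' @return list with per-stage results and \code{summary} (the content
#'   of summary.json).
#' @export
runPipeline <- function(config, out_dir = NULL) {
  config <- pipelineConfig(config)
  st <- config$stages
  res <- list()
  log <- character()
  note <- function(...) log <<- c(log, paste0(...))

  if ("variants" %in% st) {
    note("stage variants")
    calls <- lapply(config$calls, function(x)
      resolveInput(x, function(p)
        if (grepl("\\.vcf$", p)) readCallVcf(p) else readCallTable(p)))
    reference <- loadReference(config$reference)
    exclusion <- if (!is.null(config$exclusion))
      resolveInput(config$exclusion, readExclusionList)
    consensus <- buildConsensus(calls, exclusion)
    events <- collapseDinucleotideEvents(consensus, reference)
    events <- classifySnvs(events, reference)
    res$variants <- list(consensus = consensus, events = events)
    if (!is.null(config$capture_size_bp)) {
      res$variants$snv_per_mb <-
        burdenPerMb(events, config$capture_size_bp, "snv")
      res$variants$indel_per_mb <-
        burdenPerMb(events, config$capture_size_bp, "indel")
      res$variants$dinucleotide_per_mb <-
        burdenPerMb(events, config$capture_size_bp, "dinucleotide")
    }
  }
  if ("spectrum" %in% st) {
    note("stage spectrum")
    if (is.null(res$variants)) stop("stage 'spectrum' requires stage 'variants'")
    genes <- resolveInput(config$genes, readGeneAnnotation)
    events <- assignTranscriptionalStrand(res$variants$events, genes)
    catalog <- buildSbs96(events)
    res$spectrum <- list(events = events, catalog = catalog,
                         type_counts = countMutationTypes(events),
                         strand_bias = classStrandBias(events))
    if (!is.null(config$regions)) {
      regions <- resolveInput(config$regions, readRegionsBed)
      res$spectrum$normalized <-
        normalizeSpectrum(catalog, loadReference(config$reference), regions)
    }
  }
  if ("signatures" %in% st) {
    note("stage signatures")
    ext <- extractWithStability(res$spectrum$catalog,
                                rank_range = config$rank_range,
                                n_bootstrap = config$n_bootstrap,
                                seed = config$seed)
    act <- attributeActivities(res$spectrum$catalog, ext$signatures)
    res$signatures <- list(signatures = ext$signatures,
                           report = ext$report, activities = act)
  }
  if ("comparison" %in% st) {
    note("stage comparison")
    if (is.null(res$signatures))
      stop("stage 'comparison' requires stage 'signatures'")
    refcat <- resolveInput(config$reference_catalog, readSignatureCatalogTsv)
    res$comparison <- matchToCatalog(res$signatures$signatures, refcat)
  }
  if ("cna" %in% st) {
    note("stage cna")
    segments <- resolveInput(config$segments, readSegmentsTsv)
    altered <- filterSegments(segments)
    res$cna <- list(altered = altered,
                    fraction = genomeAlteredFraction(segments, altered))
  }
  if ("stats" %in% st) {
    note("stage stats")
    surv <- resolveInput(config$survival, function(p)
      read.delim(p, stringsAsFactors = FALSE))
    res$stats <- list(km = kmEstimate(surv))
    if (length(unique(surv$group)) == 2L)
      res$stats$gehan <- gehanBreslowWilcoxon(surv)
  }
  if ("dosimetry" %in% st) {
    note("stage dosimetry")
    spec <- resolveInput(config$spectrum, readSpectrumTable)
    eee <- effectiveDose(spec, kJm2TomJcm2(config$dose_kj_m2))
    res$dosimetry <- list(eee_mj_cm2 = eee, sed = mJcm2ToSed(eee))
  }

  cfg_file <- tempfile()
  writeBin(serialize(config[order(names(config))], NULL, version = 3L),
           cfg_file)
  summary <- list(
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = config$seed,
    stages = st,
    n_samples = if (!is.null(res$spectrum))
      length(sampleIds(res$spectrum$catalog)) else NA,
    total_snvs = if (!is.null(res$spectrum))
      sum(catalogCounts(res$spectrum$catalog)) else NA,
    selected_rank = if (!is.null(res$signatures))
      selectedRank(res$signatures$report) else NA)
  unlink(cfg_file)
  res$summary <- summary
  res$log <- log
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(res$variants))
      writeEventsTsv(res$spectrum$events %||% res$variants$events,
                     file.path(out_dir, "events.tsv"))
    if (!is.null(res$spectrum))
      writeCatalogTsv(res$spectrum$catalog, file.path(out_dir, "catalog.tsv"))
    if (!is.null(res$signatures))
      writeSignatureTsv(res$signatures$signatures,
                        file.path(out_dir, "signatures.tsv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
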