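classifiedEvents <- function(n, seed, samples = c("s1", "s2")) {
  fix <- allTrimerReference()
  set.seed(seed)
  idx <- sample(seq_along(fix$trimers), n, replace = TRUE)
  mid <- substr(fix$trimers[idx], 2L, 2L)
  alt <- vapply(mid, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  df <- data.frame(sample = sample(samples, n, TRUE), chrom = "chrT",
                   pos = fix$center_pos[idx], ref = mid, alt = alt,
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(paste(df$sample, df$pos)), ]
  classifySnvs(collapseDinucleotideEvents(callsOf(df)), fix$reference)
}

test_that("SBS96 catalog matches an independent per-channel tally", {
  ev <- classifiedEvents(500L, 21)
  cat96 <- buildSbs96(ev)
  m <- catalogCounts(cat96)
  snv <- ev[ev$event_kind == "snv" & ev$context_ok, ]
  for (s in rownames(m)) {
    sub <- snv[snv$sample_id == s, ]
    oracle <- table(paste0(substr(sub$context, 1, 1), "[", sub$snv_class, "]",
                           substr(sub$context, 3, 3)))
    expect_equal(sum(m[s, ]), nrow(sub))
    for (ch in names(oracle)) expect_equal(m[s, ch], unname(oracle[[ch]]))
  }
  # pooling samples then tallying equals summing per-sample catalogs
  pooled <- ev; pooled$sample_id <- "all"
  expect_equal(unname(catalogCounts(buildSbs96(pooled))[1, ]),
               unname(colSums(m)))
})

test_that("purine-representation input yields the identical catalog", {
  ref <- Biostrings::DNAStringSet(setNames("TTAGATTAGATT", "chr1"))
  # the same genomic change written as G>A (purine strand record)
  df <- data.frame(sample = "s1", chrom = "chr1", pos = c(4L, 9L),
                   ref = "G", alt = "A", stringsAsFactors = FALSE)
  ev <- classifySnvs(collapseDinucleotideEvents(callsOf(df)), ref)
  m <- catalogCounts(buildSbs96(ev))
  expect_equal(unname(m[1, "T[C>T]T"]), 2)
  expect_equal(sum(m), 2)
})

test_that("mutation-type occurrences include the CpG sub-tally", {
  ref <- Biostrings::DNAStringSet(setNames(strrep("ACGT", 30), "chr1"))
  # ACG context at pos 2, 6, ... -> C>T at CpG
  df <- data.frame(sample = "s1", chrom = "chr1",
                   pos = seq(2L, by = 4L, length.out = 10L),
                   ref = "C", alt = "T", stringsAsFactors = FALSE)
  ev <- classifySnvs(collapseDinucleotideEvents(callsOf(df)), ref)
  tt <- countMutationTypes(ev)
  expect_equal(unname(tt$counts["s1", "C>T"]), 10)
  expect_equal(unname(tt$counts["s1", "C>T at CpG"]), 10)
  expect_equal(unname(tt$frequencies["s1", "C>T"]), 1)
  # frequencies over the six classes sum to 1 for samples with SNVs
  ev2 <- classifiedEvents(300L, 5)
  tt2 <- countMutationTypes(ev2)
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  expect_equal(unname(rowSums(tt2$frequencies[, classes])),
               rep(1, nrow(tt2$frequencies)))
})

test_that("trinucleotide occurrences match a sliding-window count", {
  set.seed(31)
  seq <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  ref <- Biostrings::DNAStringSet(setNames(seq, "chr1"))
  occ <- trinucleotideOccurrences(ref)
  # oracle: explicit windows on both strands
  comp <- function(s) chartr("ACGT", "TGCA",
                             paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  wins <- substring(seq, 1:(nchar(seq) - 2), 3:nchar(seq))
  oracle <- table(c(wins, vapply(wins, comp, "")))
  for (ctx in names(occ))
    expect_equal(unname(occ[[ctx]]), unname(oracle[[ctx]]))
})

test_that("normalization converts counts into per-context rates", {
  ev <- classifiedEvents(400L, 41)
  cat96 <- buildSbs96(ev)
  fix <- allTrimerReference()
  regions <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1, 318))
  occ <- trinucleotideOccurrences(fix$reference, regions)
  rate <- normalizeSpectrum(cat96, fix$reference, regions)
  m <- catalogCounts(cat96)
  ch <- "T[C>T]T"
  expect_equal(rate[, ch], m[, ch] * 1e6 / occ[["TCT"]])
  expect_equal(sum(rate[m == 0]), 0)
  # two channels with equal counts and 2:1 context occurrence give 1:2 rates
  counts <- matrix(0, 1, 96, dimnames = list("s", sbs96Channels()))
  counts[1, c("A[C>A]A", "A[C>A]C")] <- 5
  toy <- Sbs96Catalog(counts)
  toyref <- Biostrings::DNAStringSet(setNames(
    paste0(strrep("ACAGG", 10), strrep("ACCGG", 5)), "chr1"))
  occ_toy <- trinucleotideOccurrences(toyref)
  r <- normalizeSpectrum(toy, toyref)
  expect_equal(unname(r[1, "A[C>A]A"] / r[1, "A[C>A]C"]),
               unname(occ_toy[["ACC"]] / occ_toy[["ACA"]]))
})

test_that("transcriptional strand follows the template-strand convention", {
  ref <- Biostrings::DNAStringSet(setNames(strrep("TTCTT", 40), "chr1"))
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 51), c(40, 90)),
                                  strand = c("+", "-"))
  genes$gene <- c("gplus", "gminus")
  df <- data.frame(sample = "s1", chrom = "chr1", pos = c(8L, 58L, 148L),
                   ref = "C", alt = "T", stringsAsFactors = FALSE)
  ev <- classifySnvs(collapseDinucleotideEvents(callsOf(df)), ref)
  ev <- assignTranscriptionalStrand(ev, genes)
  # pyrimidine on + strand: + gene -> untranscribed, - gene -> transcribed
  expect_equal(ev$strand_label, c("untranscribed", "transcribed", "unknown"))
  # strand-resolved counts plus unknowns recover the totals
  src <- strandResolvedCounts(ev)
  expect_equal(sum(src$transcribed) + sum(src$untranscribed) +
               src$excluded_count, 3)
})

test_that("strand-bias test is exact, symmetric and flags untestable input", {
  even <- strandBiasTest(50L, 50L)
  expect_equal(even$log2_ratio, 0)
  expect_equal(even$p_value, 1)
  skew <- strandBiasTest(8L, 2L)
  expect_equal(skew$p_value, 112 / 1024)  # enumeration of Binomial(10, 1/2)
  expect_equal(strandBiasTest(2L, 8L)$p_value, skew$p_value)  # symmetry
  zero <- strandBiasTest(0L, 0L)
  expect_false(zero$testable)
  # zero counts get the +0.5 continuity adjustment in the ratio only
  one_sided <- strandBiasTest(4L, 0L)
  expect_equal(one_sided$log2_ratio, log2(4.5 / 0.5))
  expect_equal(one_sided$transcribed_count, 4L)
})
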