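test_that("reference generation is deterministic and honors its knobs", {
  b1 <- generateReference(length_bp = 2e4, n_genes = 6L, seed = 5)
  b2 <- generateReference(length_bp = 2e4, n_genes = 6L, seed = 5)
  expect_identical(as.character(b1$reference), as.character(b2$reference))
  expect_equal(Biostrings::width(b1$reference), 20000L)
  expect_equal(length(b1$genes), 6L)
  expect_setequal(as.character(GenomicRanges::strand(b1$genes)), c("+", "-"))
  # genes are non-overlapping
  expect_equal(length(GenomicRanges::findOverlaps(
    b1$genes, drop.self = TRUE, drop.redundant = TRUE)), 0L)
  expect_error(generateReference(length_bp = 5e3), ">= 10 kb")
})

test_that("generated GC content is within sampling error of the request", {
  b <- generateReference(length_bp = 1e5, gc_fraction = 0.5, seed = 8)
  freq <- Biostrings::oligonucleotideFrequency(b$reference, 1)[1, ]
  gc <- sum(freq[c("C", "G")]) / sum(freq)
  se <- sqrt(0.5 * 0.5 / 1e5)
  expect_lt(abs(gc - 0.5), 3 * se)
})

test_that("signature profiles have the documented shapes", {
  uvb <- makeSignature("uvb_like")
  flat <- makeSignature("flat")
  expect_equal(sum(uvb), 1)
  expect_equal(unname(flat), rep(1 / 96, 96))
  expect_true(uvb[["T[C>T]T"]] > uvb[["T[C>T]C"]])
  expect_true(uvb[["T[C>T]C"]] > uvb[["T[C>T]A"]])
  expect_true(uvb[["T[C>T]A"]] > uvb[["T[C>T]G"]])
  expect_error(makeSignature("custom", profile = c(-1, rep(1, 95))),
               "negative")
  cust <- makeSignature("custom", profile = rep(2, 96))
  expect_equal(sum(cust), 1)
})

test_that("every emitted variant's reference context matches its channel", {
  b <- generateReference(length_bp = 2e4, n_genes = 6L, seed = 9)
  sim <- simulateCatalog(b, n_samples = 3L,
                         mean_activities = c(uvb = 60, flat = 20), seed = 10)
  tr <- sim$truth$events
  ref <- b$reference[[1]]
  for (i in sample(nrow(tr), 50L)) {
    tri <- as.character(Biostrings::subseq(ref, tr$pos[i] - 1L, tr$pos[i] + 1L))
    expect_equal(substr(tri, 2, 2), tr$ref[i])
    if (!tr$ref[i] %in% c("C", "T"))
      tri <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(tri)))
    if (!tr$dinuc[i])
      expect_equal(tri, paste0(substr(tr$channel[i], 1, 1),
                               substr(tr$channel[i], 3, 3),
                               substr(tr$channel[i], 7, 7)))
  }
})

test_that("caller dropout and false positives exercise the consensus filter", {
  b <- generateReference(length_bp = 2e4, n_genes = 6L, seed = 11)
  sim <- simulateCatalog(b, n_samples = 3L,
                         mean_activities = c(uvb = 80, flat = 30),
                         caller_dropout = 0.1, false_positive_rate = 0.05,
                         seed = 12)
  cons <- buildConsensus(sim$callsets)
  key <- function(df, pos = "pos") paste(df$sample_id, df$chrom, df[[pos]])
  truth_keys <- key(sim$truth$events)
  # consensus loses dropped variants but admits no caller-private noise
  # (a false positive appearing in all three callers is vanishingly rare)
  expect_true(all(key(cons) %in% truth_keys))
  expect_lt(nrow(cons), nrow(sim$truth$events))
  # with clean callers the consensus is exactly the truth
  sim0 <- simulateCatalog(b, n_samples = 3L,
                          mean_activities = c(uvb = 80, flat = 30), seed = 12)
  expect_setequal(key(buildConsensus(sim0$callsets)), key(sim0$truth$events))
})

test_that("planted strand bias shows up in the recovered tallies", {
  b <- generateReference(length_bp = 5e4, n_genes = 20L, gene_fraction = 0.8,
                         seed = 13)
  sim <- simulateCatalog(b, n_samples = 10L,
                         mean_activities = c(uvb = 200, flat = 0),
                         strand_bias_rho = 4, dinucleotide_rate = 0, seed = 14)
  cons <- buildConsensus(sim$callsets)
  ev <- classifySnvs(collapseDinucleotideEvents(cons, b$reference),
                     b$reference)
  ev <- assignTranscriptionalStrand(ev, b$genes)
  sb <- classStrandBias(ev)
  ct <- sb[sb$class == "C>T", ]
  expect_gt(ct$untranscribed_count, ct$transcribed_count)
  expect_lt(ct$p_value, 0.01)
  # the planted labels agree with the analysis labels on genic events
  merged <- merge(ev[ev$event_kind == "snv", ],
                  sim$truth$events[!sim$truth$events$dinuc, ],
                  by.x = c("sample_id", "chrom", "start"),
                  by.y = c("sample_id", "chrom", "pos"))
  genic <- merged[merged$status %in% c("transcribed", "untranscribed"), ]
  expect_true(all(genic$strand_label == genic$status))
})

test_that("clinical simulation plants exact CNA fractions and censoring", {
  cl <- simulateClinical(altered_fraction = 0.25, n_segments = 20L,
                         n_samples = 4L, seed = 15)
  alt <- filterSegments(cl$segments)
  fr <- genomeAlteredFraction(cl$segments, alt)
  expect_equal(unname(fr), rep(0.25, 4))
  expect_equal(cl$truth$altered_fraction, 0.25)
  # a horizon below every event time censors everything
  cl2 <- simulateClinical(groups = list(g = list(n = 10, scale = 50)),
                          horizon = 1e-6, seed = 16)
  expect_true(all(!cl2$survival$event))
  expect_error(simulateClinical(altered_fraction = 1.5), "altered_fraction")
})

test_that("null survival groups give a well-behaved Gehan test", {
  set.seed(17)
  pvals <- replicate(60, {
    cl <- simulateClinical(groups = list(a = list(n = 12, scale = 10),
                                         b = list(n = 12, scale = 10)),
                           horizon = 30, seed = sample.int(1e6, 1))
    gehanBreslowWilcoxon(cl$survival)$p
  })
  # under the null, p-values should not pile up near 0
  expect_gt(mean(pvals > 0.05), 0.8)
})
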