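test_that("consensus keeps only variants seen by every caller and not excluded", {
  base <- data.frame(sample = "s1", chrom = "chr1", pos = c(10L, 20L, 30L),
                     ref = "C", alt = "T", stringsAsFactors = FALSE)
  a <- callsOf(base, "a")
  b <- callsOf(base[1:2, ], "b")
  c <- callsOf(base, "c")
  cons <- buildConsensus(list(a, b, c))
  expect_equal(cons$pos, c(10L, 20L))  # pos 30 only in 2 of 3
  excl <- data.frame(chrom = "chr1", pos = 20L, ref = "C", alt = "T")
  cons2 <- buildConsensus(list(a, b, c), excl)
  expect_equal(cons2$pos, 10L)
  expect_error(buildConsensus(list()), "at least one")
})

test_that("consensus equals brute-force set algebra on random call sets", {
  sets <- lapply(1:3, function(i) randomCallSet(500L, paste0("c", i), 100 + i))
  excl_src <- randomCallSet(80L, "x", 999)
  excl <- data.frame(chrom = excl_src$chrom, pos = excl_src$pos,
                     ref = excl_src$ref, alt = excl_src$alt)
  cons <- buildConsensus(sets, excl)
  key <- function(df) paste(df$sample_id, df$chrom, df$pos, df$ref, df$alt)
  skey <- function(df) paste(df$chrom, df$pos, df$ref, df$alt)
  expected <- Reduce(intersect, lapply(sets, key))
  expected <- expected[!(sub("^\\S+ ", "", expected) %in% skey(excl))]
  expect_setequal(key(cons), expected)
  # consensus is a subset of every input
  for (s in sets) expect_true(all(key(cons) %in% key(s)))
})

test_that("adjacent SNV pairs collapse into single dinucleotide events", {
  df <- data.frame(sample = "s1", chrom = "chr1",
                   pos = c(100L, 101L, 103L, 200L),
                   ref = c("C", "C", "C", "T"), alt = c("T", "T", "A", "G"),
                   stringsAsFactors = FALSE)
  ev <- collapseDinucleotideEvents(callsOf(df))
  expect_equal(sum(ev$event_kind == "dinucleotide"), 1L)
  expect_equal(ev$ref_allele[ev$event_kind == "dinucleotide"], "CC")
  expect_equal(ev$alt_allele[ev$event_kind == "dinucleotide"], "TT")
  expect_equal(nrow(ev), 3L)  # pair + pos 103 + pos 200
  # runs of three merge greedily left to right: one pair + one snv
  run <- data.frame(sample = "s1", chrom = "chr1", pos = 300:302,
                    ref = "C", alt = "T", stringsAsFactors = FALSE)
  ev3 <- collapseDinucleotideEvents(callsOf(run))
  expect_equal(sort(table(ev3$event_kind))[["dinucleotide"]], 1L)
  expect_equal(ev3$start, c(300L, 302L))
})

test_that("collapsing matches a brute-force scan and is idempotent", {
  set.seed(42)
  n_pairs <- 25L
  pair_start <- seq(10L, by = 40L, length.out = n_pairs)
  solo_pos <- setdiff(seq(5L, 40000L, by = 41L),
                      c(pair_start, pair_start + 1L))[1:950]
  pos <- sort(c(pair_start, pair_start + 1L, solo_pos))
  df <- data.frame(sample = "s1", chrom = "chr1", pos = pos,
                   ref = "C", alt = "T", stringsAsFactors = FALSE)
  ev <- collapseDinucleotideEvents(callsOf(df))
  # brute-force scan oracle: walk sorted positions, consume pairs
  oracle_events <- 0L; i <- 1L
  while (i <= length(pos)) {
    if (i < length(pos) && pos[i + 1L] == pos[i] + 1L) i <- i + 2L else i <- i + 1L
    oracle_events <- oracle_events + 1L
  }
  expect_equal(nrow(ev), oracle_events)
  expect_equal(nrow(ev), length(pos) - n_pairs)
  # idempotence: re-collapsing the snv stream of the output changes nothing
  snv <- ev[ev$event_kind == "snv", ]
  again <- collapseDinucleotideEvents(
    variantCalls(snv$sample_id, snv$chrom, snv$start, snv$ref_allele,
                 snv$alt_allele, "again"))
  expect_equal(nrow(again), nrow(snv))
})

test_that("classification maps purine SNVs onto the pyrimidine strand", {
  ref <- Biostrings::DNAStringSet(setNames("TTAGATTACGTT", "chr1"))
  # middle G>A of AGA at pos 3..5 -> C>T in TCT
  df <- data.frame(sample = "s1", chrom = "chr1", pos = c(4L, 9L),
                   ref = c("G", "C"), alt = c("A", "T"),
                   stringsAsFactors = FALSE)
  ev <- classifySnvs(collapseDinucleotideEvents(callsOf(df)), ref)
  expect_equal(ev$snv_class, c("C>T", "C>T"))
  expect_equal(ev$context, c("TCT", "ACG"))
  expect_equal(ev$at_cpg, c(FALSE, TRUE))
})

test_that("all 192 strand-specific substitutions map 2-to-1 onto 96 channels", {
  fix <- allTrimerReference()
  recs <- list()
  for (i in seq_along(fix$trimers)) {
    tri <- fix$trimers[i]
    mid <- substr(tri, 2L, 2L)
    for (alt in setdiff(c("A", "C", "G", "T"), mid)) {
      recs[[length(recs) + 1L]] <- data.frame(
        sample = "s1", chrom = "chrT", pos = fix$center_pos[i],
        ref = mid, alt = alt, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, recs)
  ev <- collapseDinucleotideEvents(callsOf(df))
  ev <- ev[ev$event_kind == "snv", ]
  ev <- classifySnvs(ev, fix$reference)
  expect_equal(nrow(ev), 192L)
  expect_true(all(ev$context_ok))
  hits <- table(paste(ev$snv_class, ev$context))
  expect_equal(length(hits), 96L)
  # exhaustive complementation: each channel is reached exactly twice, once
  # from the pyrimidine and once from the purine representation
  expect_true(all(hits == 2L))
  pyr <- ev[ev$ref_allele %in% c("C", "T"), ]
  pur <- ev[ev$ref_allele %in% c("A", "G"), ]
  expect_equal(sort(paste(pyr$snv_class, pyr$context)),
               sort(paste(pur$snv_class, pur$context)))
})

test_that("six-class counts sum to the SNV event count", {
  fix <- allTrimerReference()
  set.seed(7)
  idx <- sample(seq_along(fix$trimers), 200L, replace = TRUE)
  mid <- substr(fix$trimers[idx], 2L, 2L)
  alt <- vapply(mid, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  df <- data.frame(sample = sample(c("s1", "s2"), 200L, TRUE), chrom = "chrT",
                   pos = fix$center_pos[idx], ref = mid, alt = alt,
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(paste(df$sample, df$pos)), ]
  ev <- classifySnvs(collapseDinucleotideEvents(callsOf(df)), fix$reference)
  tt <- countMutationTypes(ev)
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  snv_per_sample <- table(ev$sample_id[ev$event_kind == "snv" & ev$context_ok])
  for (s in names(snv_per_sample))
    expect_equal(sum(tt$counts[s, classes]), unname(snv_per_sample[[s]]))
})

test_that("burden per megabase scales collapsed event counts", {
  df <- data.frame(sample = "s1", chrom = "chr1",
                   pos = c(seq(10L, by = 10L, length.out = 48L), 1000L, 1001L),
                   ref = "C", alt = "T", stringsAsFactors = FALSE)
  ev <- collapseDinucleotideEvents(callsOf(df))
  expect_equal(unname(burdenPerMb(ev, 50e6, "snv")), 49 * 1e6 / 50e6)
  expect_equal(unname(burdenPerMb(ev, 50e6, "dinucleotide")), 1e6 / 50e6)
  expect_equal(unname(burdenPerMb(ev[0, ], 50e6, "snv")), numeric(0))
  expect_error(burdenPerMb(ev, 0), "positive")
  # 1,000 SNVs with 10 adjacent pairs over 49.6 Mb -> 990 events
  pair_start <- seq(100L, by = 100L, length.out = 10L)
  solo <- setdiff(seq(5L, 50000L, by = 50L), c(pair_start, pair_start + 1L))[1:980]
  big <- data.frame(sample = "s1", chrom = "chr1",
                    pos = sort(c(pair_start, pair_start + 1L, solo)),
                    ref = "C", alt = "T", stringsAsFactors = FALSE)
  bev <- collapseDinucleotideEvents(callsOf(big))
  expect_equal(unname(burdenPerMb(bev, 49.6e6, "snv")), 990 * 1e6 / 49.6e6)
})

test_that("gene recurrence keeps genes altered in enough distinct samples", {
  ev <- data.frame(sample_id = c("s1", "s2", "s3", "s1", "s1", "s4"),
                   gene = c("A", "A", "A", "B", "B", "B"),
                   event_kind = "snv", stringsAsFactors = FALSE)
  rt <- geneRecurrence(ev, cohort_size = 36L, min_samples = 3L)
  expect_equal(rt$gene, "A")           # B altered in 2 distinct samples only
  expect_equal(rt$frequency, 3 / 36)
  expect_error(geneRecurrence(ev, cohort_size = 2L), "cohort_size")
  # random tally oracle
  set.seed(11)
  big <- data.frame(sample_id = sample(paste0("s", 1:12), 400L, TRUE),
                    gene = sample(c(paste0("g", 1:30), "intergenic"), 400L, TRUE),
                    event_kind = "snv", stringsAsFactors = FALSE)
  rt2 <- geneRecurrence(big, cohort_size = 12L, min_samples = 3L)
  tal <- tapply(big$sample_id[big$gene != "intergenic"],
                big$gene[big$gene != "intergenic"],
                function(x) length(unique(x)))
  expect_setequal(rt2$gene, names(tal)[tal >= 3])
  expect_equal(rt2$n_samples, as.vector(tal[rt2$gene]))
})
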