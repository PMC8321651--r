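# Shared fixtures, all built in code.

# a reference containing every trinucleotide once, padded so windows are
# unambiguous: trimer i sits at positions (5i-4)..(5i-2), separated by "NN"
allTrimerReference <- function() {
  bases <- c("A", "C", "G", "T")
  trimers <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  seq <- paste(trimers, collapse = "NN")
  list(reference = Biostrings::DNAStringSet(setNames(seq, "chrT")),
       trimers = trimers,
       center_pos = 5L * seq_along(trimers) - 3L)
}

# small deterministic call table
callsOf <- function(df, caller = "c1") {
  variantCalls(df$sample, df$chrom, df$pos, df$ref, df$alt, caller)
}

# random call set drawn from a shared finite key universe so that the
# intersection across callers is non-trivial
randomCallSet <- function(n, caller, seed, universe_seed = 12345) {
  set.seed(universe_seed)
  ref <- sample(c("A", "C", "G", "T"), 700, TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  universe <- data.frame(sample = sample(c("s1", "s2"), 700, TRUE),
                         chrom = "chr1", pos = sample.int(5000, 700),
                         ref = ref, alt = alt, stringsAsFactors = FALSE)
  set.seed(seed)
  df <- universe[sample.int(700, n, replace = FALSE), , drop = FALSE]
  variantCalls(df$sample, df$chrom, df$pos, df$ref, df$alt, caller)
}

# independent enumeration of all permutations (distinct from the package's
# generator: recursive insertion)
permsByInsertion <- function(n) {
  if (n == 1L) return(list(1L))
  smaller <- permsByInsertion(n - 1L)
  out <- list()
  for (p in smaller) for (k in 0:(n - 1L)) {
    out[[length(out) + 1L]] <- append(p, n, after = k)
  }
  out
}

cosOf <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
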