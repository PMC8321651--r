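## Cosine similarity, empirical permutation p-values, reference-catalog
## matching and cross-extractor correlation.

#' Cosine similarity of two non-negative profiles
#'
#' \code{dot(a, b) / (|a| |b|)}; scale-invariant, in [0, 1] for
#' non-negative inputs.
#'
#' @param a,b numeric vectors of equal length, not all-zero.
#' @return numeric scalar.
#' @export
cosineSimilarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine undefined for an all-zero vector")
  sum(a * b) / (na * nb)
}

permutations <- function(n) {
  # all n! permutations of 1..n, one per row
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, ifelse(sub >= i, sub + 1L, sub))))
}

#' Empirical permutation p-value for a cosine similarity
#'
#' Shuffles the entries of the second profile and compares the permuted
#' cosines against the observed one.  In Monte-Carlo mode the p-value is
#' \code{(1 + #\{permuted >= observed\}) / (n + 1)} (pseudo-count, so p is
#' never 0 and at least \code{1/(n+1)}).  When the vector is short enough
#' that all permutations can be enumerated (length! <= 5040, i.e. length
#' <= 7) exhaustive mode is auto-selected and returns the exact tail
#' fraction over all permutations.
#'
#' @param a,b numeric vectors of equal length.
#' @param n_permutations Monte-Carlo draws (default 1e6, the convention
#'   for signature-catalog comparisons).
#' @param seed integer seed for Monte-Carlo mode.
#' @param mode \code{"auto"}, \code{"exhaustive"} or \code{"montecarlo"}.
#' @return list with \code{cosine}, \code{p_empirical},
#'   \code{n_permutations}, \code{mode}, \code{seed}.
#' @export
cosinePermutationPvalue <- function(a, b, n_permutations = 1e6, seed = 1L,
                                    mode = c("auto", "exhaustive",
                                             "montecarlo")) {
  mode <- match.arg(mode)
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  obs <- cosineSimilarity(a, b)
  n <- length(b)
  if (mode == "auto")
    mode <- if (factorial(n) <= 5040) "exhaustive" else "montecarlo"
  if (mode == "exhaustive") {
    perms <- permutations(n)
    cvals <- apply(perms, 1L, function(p) cosineSimilarity(a, b[p]))
    p <- mean(cvals >= obs - 1e-12)
    return(list(cosine = obs, p_empirical = p,
                n_permutations = nrow(perms), mode = "exhaustive",
                seed = NA_integer_))
  }
  withSeed(seed, {
    hits <- 0L
    block <- 10000L
    done <- 0
    while (done < n_permutations) {
      k <- min(block, n_permutations - done)
      for (i in seq_len(k)) {
        if (cosineSimilarity(a, b[sample.int(n)]) >= obs - 1e-12)
          hits <- hits + 1L
      }
      done <- done + k
    }
    list(cosine = obs, p_empirical = (1 + hits) / (n_permutations + 1),
         n_permutations = n_permutations, mode = "montecarlo", seed = seed)
  })
}

#' Match extracted signatures against a reference catalog
#'
#' Computes the full K x M cosine matrix between extracted signatures and
#' a named reference catalog (same channel order, validated), the best
#' match per extracted signature, and optionally a permutation p-value
#' per best pair.
#'
#' @param signatures a [SignatureMatrix-class].
#' @param reference a [SignatureMatrix-class] of named reference profiles
#'   (e.g. a COSMIC SBS set read with [readSignatureCatalogTsv()]).
#' @param n_permutations permutations for the optional p-values; set to 0
#'   to skip.
#' @param seed seed for the permutation p-values.
#' @return list with \code{similarity} (K x M matrix) and \code{best}
#'   (data.frame: signature, match, cosine, p_empirical).
#' @export
matchToCatalog <- function(signatures, reference, n_permutations = 0,
                           seed = 1L) {
  S <- signatureProfiles(signatures)
  R <- signatureProfiles(reference)
  if (!identical(rownames(S), rownames(R)))
    stop("signature and reference channel orders disagree")
  sim <- cosineMatrix(S, R)
  dimnames(sim) <- list(colnames(S), colnames(R))
  best <- data.frame(
    signature = colnames(S),
    match = colnames(R)[apply(sim, 1L, which.max)],
    cosine = apply(sim, 1L, max),
    p_empirical = NA_real_, stringsAsFactors = FALSE)
  if (n_permutations > 0) {
    for (i in seq_len(nrow(best))) {
      best$p_empirical[i] <- cosinePermutationPvalue(
        S[, i], R[, best$match[i]], n_permutations = n_permutations,
        seed = seed + i, mode = "montecarlo")$p_empirical
    }
  }
  list(similarity = sim, best = best)
}

#' Correlation between signature sets from different extractors
#'
#' Pearson correlation between every pair of signatures across a list of
#' signature sets (e.g. KL- vs Frobenius-objective extractions), signed
#' in [-1, 1] so discordant profiles show as negative after
#' mean-centering.  Constant profiles yield NA with a warning.
#'
#' @param signature_sets named list of [SignatureMatrix-class] objects on
#'   a common channel order.
#' @return square correlation matrix over all signatures, labeled
#'   \code{set.signature}.
#' @export
crossMethodCorrelation <- function(signature_sets) {
  mats <- lapply(signature_sets, signatureProfiles)
  rn <- lapply(mats, rownames)
  if (!all(vapply(rn, identical, TRUE, rn[[1]])))
    stop("all signature sets must share the channel order")
  nm <- names(signature_sets)
  if (is.null(nm)) nm <- paste0("set", seq_along(signature_sets))
  all <- do.call(cbind, mats)
  colnames(all) <- unlist(mapply(function(n, m)
    paste(n, colnames(m), sep = "."), nm, mats, SIMPLIFY = FALSE))
  if (any(apply(all, 2L, stats::sd) == 0))
    warning("constant profile(s): correlations undefined (NA)")
  suppressWarnings(stats::cor(all))
}
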