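## De novo signature extraction: multiplicative-update NMF (KL and
## Frobenius objectives), bootstrap stability with k-medoids consensus,
## rank-selection diagnostics and NNLS activity attribution.

withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

cosineMatrix <- function(a, b = a) {
  na <- sqrt(colSums(a^2)); nb <- sqrt(colSums(b^2))
  crossprod(a, b) / outer(na, nb)
}

nndsvdInit <- function(V, rank) {
  # non-negative double SVD: deterministic, extremal starting point that
  # avoids the interior of the scale/mixing ambiguity valley
  s <- svd(V, nu = rank, nv = rank)
  W <- matrix(0, nrow(V), rank)
  H <- matrix(0, rank, ncol(V))
  W[, 1L] <- sqrt(s$d[1L]) * abs(s$u[, 1L])
  H[1L, ] <- sqrt(s$d[1L]) * abs(s$v[, 1L])
  if (rank > 1L) for (j in 2:rank) {
    u <- s$u[, j]; v <- s$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
    nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
    if (nup * nvp >= nun * nvn) {
      W[, j] <- sqrt(s$d[j] * nup * nvp) * up / max(nup, 1e-12)
      H[j, ] <- sqrt(s$d[j] * nup * nvp) * vp / max(nvp, 1e-12)
    } else {
      W[, j] <- sqrt(s$d[j] * nun * nvn) * un / max(nun, 1e-12)
      H[j, ] <- sqrt(s$d[j] * nun * nvn) * vn / max(nvn, 1e-12)
    }
  }
  floor <- mean(V) * 1e-4
  W[W < floor] <- floor
  H[H < floor] <- floor
  list(W = W, H = H)
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a non-negative channels x samples matrix V into W H with
#' W (channels x rank) and H (rank x samples), minimizing either the
#' generalized Kullback-Leibler divergence or the Frobenius norm with the
#' classical multiplicative updates.  The objective is non-increasing
#' along the recorded trace.  On return W is column-normalized with the
#' scale moved into H.
#'
#' @param V non-negative numeric matrix (channels x samples).
#' @param rank number of factors, \code{1 <= rank < min(dim(V))}.
#' @param objective \code{"kl"} (default, the convention of count-based
#'   signature extractors) or \code{"frobenius"}.
#' @param init \code{"nndsvd"} (default; deterministic SVD-based
#'   initialization, which starts at an extremal vertex of the
#'   non-negative solution set instead of the interior of its mixing
#'   ambiguity), \code{"random"}, or a list with entries \code{W} and
#'   \code{H} to warm-start.
#' @param seed optional integer; when supplied the random initialization
#'   is seeded (RNG state restored afterwards).
#' @param max_iter,tol iteration cap and relative-objective convergence
#'   tolerance.
#' @return list with \code{W}, \code{H}, \code{trace} (objective values),
#'   \code{converged}, \code{objective}, and \code{dropped} (indices of
#'   all-zero input columns removed before fitting).
#' @export
nmfFactorize <- function(V, rank, objective = c("kl", "frobenius"),
                         init = "nndsvd", seed = NULL, max_iter = 500L,
                         tol = 1e-6) {
  objective <- match.arg(objective)
  V <- as.matrix(V)
  if (any(V < 0)) stop("input matrix must be non-negative")
  dropped <- which(colSums(V) == 0)
  if (length(dropped)) {
    warning(length(dropped), " all-zero column(s) dropped before NMF")
    V <- V[, -dropped, drop = FALSE]
  }
  if (rank < 1L || rank >= min(dim(V)))
    stop("rank must satisfy 1 <= rank < min(dim(V))")
  withSeed(seed, {
    eps <- .Machine$double.eps
    n <- nrow(V); m <- ncol(V)
    if (is.list(init)) {
      W <- init$W; H <- init$H
      stopifnot(dim(W) == c(n, rank), dim(H) == c(rank, m))
      W <- pmax(W, eps); H <- pmax(H, eps)
    } else if (identical(init, "nndsvd")) {
      ini <- nndsvdInit(V, rank)
      W <- ini$W; H <- ini$H
    } else {
      W <- matrix(runif(n * rank, 0.1, 1), n, rank)
      H <- matrix(runif(rank * m, 0.1, 1), rank, m)
    }
    obj <- function(WH) {
      if (objective == "kl") {
        P <- V > 0
        sum(V[P] * log(V[P] / WH[P])) - sum(V) + sum(WH)
      } else sqrt(sum((V - WH)^2))
    }
    trace <- numeric(0)
    converged <- FALSE
    last <- Inf
    for (it in seq_len(max_iter)) {
      if (objective == "kl") {
        WH <- pmax(W %*% H, eps)
        W <- W * ((V / WH) %*% t(H)) /
          pmax(matrix(colSums(t(H)), n, rank, byrow = TRUE), eps)
        WH <- pmax(W %*% H, eps)
        H <- H * (t(W) %*% (V / WH)) /
          pmax(matrix(colSums(W), rank, m), eps)
      } else {
        H <- H * (t(W) %*% V) / pmax(t(W) %*% W %*% H, eps)
        W <- W * (V %*% t(H)) / pmax(W %*% (H %*% t(H)), eps)
      }
      cur <- obj(pmax(W %*% H, eps))
      trace <- c(trace, cur)
      if (is.finite(last) && abs(last - cur) <= tol * max(1, abs(last))) {
        converged <- TRUE
        last <- cur
        break
      }
      last <- cur
    }
    scale <- colSums(W)
    scale[scale == 0] <- 1
    W <- sweep(W, 2L, scale, "/")
    H <- sweep(H, 1L, scale, "*")
    list(W = W, H = H, trace = trace, converged = converged,
         objective = objective, dropped = dropped)
  })
}

klDivergence <- function(V, WH) {
  P <- V > 0
  sum(V[P] * log(V[P] / pmax(WH[P], .Machine$double.eps))) - sum(V) + sum(WH)
}

bootstrapCatalog <- function(V) {
  # per-sample multinomial resampling of mutation counts
  apply(V, 2L, function(v) {
    tot <- sum(v)
    if (tot == 0) return(v)
    as.numeric(rmultinom(1L, tot, v / tot))
  })
}

nnlsExposures <- function(W, V) {
  H <- vapply(seq_len(ncol(V)), function(j)
    pracma::lsqnonneg(W, V[, j])$x, numeric(ncol(W)))
  matrix(H, nrow = ncol(W), ncol = ncol(V),
         dimnames = list(colnames(W), colnames(V)))
}

#' De novo signature extraction with bootstrap stability
#'
#' For each candidate rank, resamples every sample's mutation counts by a
#' multinomial bootstrap, factorizes each replicate, pools the replicate
#' signatures and partitions them into rank clusters by k-medoids on
#' cosine distance.  Stability is the mean silhouette width of that
#' clustering (mean cosine similarity to the medoid at rank 1, where a
#' single cluster leaves the silhouette undefined); consensus signatures
#' are the normalized cluster centroids.  Reconstruction error is the
#' Frobenius norm of the residual when the unresampled catalog is refit on
#' the consensus signatures by NNLS.
#'
#' Rank selection: bootstrap stability stays high up to the true rank
#' (splitting a real process across replicates reproduces the same
#' clusters) and collapses beyond it (surplus clusters partition noise
#' differently in every replicate), while the absolute reconstruction
#' error is dominated by the Poisson sampling-noise floor and therefore
#' discriminates ranks poorly on count catalogs.  Profile stability
#' alone can still over-select: a single peaked process can be split
#' into reproducible sub-profiles, but then the assignment of samples
#' to clusters is arbitrary, which the cophenetic coefficient of the
#' sample-consensus matrix detects.  The selected rank is therefore the
#' largest candidate with stability >= \code{stability_threshold} and
#' cophenetic >= \code{cophenetic_threshold}; if none qualifies, the
#' rank with maximal stability is used.  All fit diagnostics (error,
#' cophenetic, explained variance, rss, dispersion, sparseness) are
#' reported per rank for inspection.
#'
#' @param catalog an [Sbs96Catalog-class]; every sample must carry at
#'   least one mutation.
#' @param rank_range candidate ranks (default 1:5; trimmed with a warning
#'   if it reaches the sample count).
#' @param n_bootstrap bootstrap replicates per rank (>= 2).
#' @param seed integer seed; the whole extraction is reproducible from it.
#' @param objective,init,max_iter,tol passed to [nmfFactorize()].
#' @param stability_threshold minimum mean-silhouette stability for a
#'   rank to be accepted (default 0.8).
#' @param cophenetic_threshold minimum sample-consensus cophenetic
#'   coefficient for a rank to be accepted (default 0.9).
#'
#' @details The returned profiles are the consensus centroids refit on
#' the unresampled catalog (a warm-started factorization), so they are a
#' stationary point of the chosen objective on the observed data rather
#' than a raw average of bootstrap replicates.
#' @return list with \code{signatures} (a [SignatureMatrix-class] at the
#'   selected rank), \code{report} (a [RankSelectionReport-class]),
#'   \code{exposures} (NNLS refit of the catalog on the consensus
#'   signatures) and \code{perRank} (per-rank consensus profiles).
#' @export
extractWithStability <- function(catalog, rank_range = 1:5,
                                 n_bootstrap = 50L, seed = 1L,
                                 objective = "kl", init = "nndsvd",
                                 max_iter = 2000L, tol = 1e-7,
                                 stability_threshold = 0.8,
                                 cophenetic_threshold = 0.9) {
  V <- t(catalogCounts(catalog))  # 96 x samples
  if (any(colSums(V) == 0))
    stop("every sample must carry at least one mutation")
  if (n_bootstrap < 2L) stop("n_bootstrap must be >= 2")
  rank_range <- sort(unique(as.integer(rank_range)))
  ok <- rank_range >= 1L & rank_range < min(dim(V))
  if (!all(ok)) {
    warning("rank range trimmed to the feasible candidates")
    rank_range <- rank_range[ok]
  }
  if (!length(rank_range)) stop("no feasible candidate rank")
  nS <- ncol(V)
  withSeed(seed, {
    perRank <- lapply(rank_range, function(r) {
      pool <- vector("list", n_bootstrap)
      conn <- matrix(0, nS, nS)
      for (b in seq_len(n_bootstrap)) {
        Vb <- bootstrapCatalog(V)
        fit <- nmfFactorize(Vb, r, objective = objective, init = init,
                            max_iter = max_iter, tol = tol)
        pool[[b]] <- fit$W
        memb <- apply(fit$H, 2L, which.max)
        conn <- conn + outer(memb, memb, "==")
      }
      P <- do.call(cbind, pool)            # 96 x (n_bootstrap * r)
      C <- conn / n_bootstrap              # sample consensus matrix
      if (r == 1L) {
        sim <- cosineMatrix(P)
        medoid <- which.max(colSums(sim))
        stability <- mean(sim[, medoid])
        centroid <- rowMeans(P)
        consensus <- matrix(centroid / sum(centroid), ncol = 1L)
        sil <- stability
      } else {
        D <- 1 - cosineMatrix(P)
        D[D < 0] <- 0
        pm <- cluster::pam(stats::as.dist(D), k = r, diss = TRUE)
        sil <- pm$silinfo$avg.width
        stability <- sil
        consensus <- vapply(seq_len(r), function(k) {
          cen <- rowMeans(P[, pm$clustering == k, drop = FALSE])
          cen / sum(cen)
        }, numeric(nrow(P)))
      }
      rownames(consensus) <- rownames(V)
      H <- nnlsExposures(consensus, V)
      resid <- V - consensus %*% H
      rss <- sum(resid^2)
      dC <- stats::as.dist(1 - C)
      coph <- if (stats::sd(dC) == 0) 1 else {
        hc <- stats::hclust(dC, method = "average")
        suppressWarnings(cor(dC, stats::cophenetic(hc)))
      }
      if (!is.finite(coph)) coph <- 1
      hoyer <- function(x) {
        n <- length(x)
        (sqrt(n) - sum(abs(x)) / sqrt(sum(x^2))) / (sqrt(n) - 1)
      }
      list(rank = r, consensus = consensus, stability = stability,
           reconstruction_error = sqrt(rss), cophenetic = coph,
           evar = 1 - rss / sum(V^2), rss = rss,
           dispersion = mean(4 * (C - 0.5)^2),
           sparseness = mean(apply(consensus, 2L, hoyer)))
    })
    metrics <- do.call(rbind, lapply(perRank, function(x)
      data.frame(rank = x$rank, stability = x$stability,
                 reconstruction_error = x$reconstruction_error,
                 cophenetic = x$cophenetic, evar = x$evar, rss = x$rss,
                 dispersion = x$dispersion, sparseness = x$sparseness)))
    stable <- which(metrics$stability >= stability_threshold &
                    metrics$cophenetic >= cophenetic_threshold)
    selected <- if (length(stable)) metrics$rank[max(stable)]
      else metrics$rank[which.max(metrics$stability)]
    sel <- perRank[[match(selected, rank_range)]]
    # polish: refit the original catalog warm-started at the consensus
    # centroids, so the final profiles are a stationary point of the
    # objective on the unresampled data
    polish <- nmfFactorize(V, selected, objective = objective,
                           init = list(W = sel$consensus,
                                       H = nnlsExposures(sel$consensus, V)),
                           max_iter = max_iter * 5L, tol = tol / 100)
    profiles <- sweep(polish$W, 2L, colSums(polish$W), "/")
    rownames(profiles) <- rownames(V)
    sig <- SignatureMatrix(profiles,
                           labels = paste0("Signature",
                                           seq_len(ncol(profiles))))
    report <- new("RankSelectionReport", metrics = metrics,
                  selectedRank = as.integer(selected))
    exposures <- nnlsExposures(signatureProfiles(sig), V)
    list(signatures = sig, report = report, exposures = exposures,
         perRank = perRank)
  })
}

#' Attribute per-sample activities to signatures
#'
#' Refits each sample's SBS96 count vector on the signature profiles by
#' non-negative least squares, then converts the fit into mutation counts
#' through per-mutation posterior probabilities: a mutation in channel c
#' has posterior \code{a_k S[c,k] / sum_j a_j S[c,j]} of arising from
#' signature k.  Channels whose maximum posterior falls below
#' \code{threshold} contribute their mutations to the unassigned pool;
#' the rest are allocated to signatures in proportion to the posterior,
#' so activities plus unassigned reconstruct the total exactly.
#'
#' @param catalog an [Sbs96Catalog-class].
#' @param signatures a [SignatureMatrix-class] on the same channel order.
#' @param threshold minimum posterior for assignment (default 0.5).
#' @return An [ActivityMatrix-class].
#' @export
attributeActivities <- function(catalog, signatures, threshold = 0.5) {
  counts <- catalogCounts(catalog)
  W <- signatureProfiles(signatures)
  if (!identical(colnames(counts), rownames(W)))
    stop("catalog and signature channel orders disagree")
  K <- ncol(W)
  acts <- matrix(0, nrow(counts), K,
                 dimnames = list(rownames(counts), colnames(W)))
  unassigned <- numeric(nrow(counts))
  for (s in seq_len(nrow(counts))) {
    v <- counts[s, ]
    if (sum(v) == 0) next
    a <- pracma::lsqnonneg(W, v)$x
    expected <- W %*% a                 # fitted intensity per channel
    for (c in which(v > 0)) {
      if (expected[c] <= 0) {
        unassigned[s] <- unassigned[s] + v[c]
        next
      }
      post <- a * W[c, ] / expected[c]
      if (max(post) < threshold) unassigned[s] <- unassigned[s] + v[c]
      else acts[s, ] <- acts[s, ] + v[c] * post
    }
  }
  new("ActivityMatrix", activities = acts, unassigned = unassigned)
}
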