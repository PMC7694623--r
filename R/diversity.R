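# Fingerprint-based structural diversity: median pairwise Tanimoto
# similarity, exact or averaged over random samples.
#
# The exact median never materializes the full n^2 similarity matrix: the
# population is processed in row blocks and every pairwise value is
# accumulated into an exact integer histogram over (intersection, union)
# popcount pairs, from which the median is read off. This makes the exact
# statistic feasible for populations of tens of thousands of fingerprints
# in bounded memory.

#' Diversity configuration
#'
#' @param n_samples Number of random samples (default 10).
#' @param sample_size Compounds per sample (default 10000). Populations no
#'   larger than this are evaluated exactly instead of sampled.
#' @param seed Master seed; per-sample draws are derived deterministically.
#' @param kind Informational fingerprint-kind label carried into results.
#' @return A `diversity_config` list.
#' @export
diversity_config <- function(n_samples = 10L, sample_size = 10000L,
                             seed = 1L, kind = "circular_r2_1024") {
  stopifnot(n_samples >= 1L, sample_size >= 2L)
  structure(list(n_samples = as.integer(n_samples),
                 sample_size = as.integer(sample_size),
                 seed = as.integer(seed), kind = kind),
            class = "diversity_config")
}

# Exact histogram of pairwise (intersection, union) counts for rows of a
# 0/1 matrix; returns counts indexed by key = inter * (2*nbits + 1) + union.
.pairwise_histogram <- function(X, block = 1024L) {
  n <- nrow(X); nb <- ncol(X)
  pop <- as.integer(rowSums(X))
  ncell <- (nb + 1L) * (2L * nb + 1L)
  counts <- numeric(ncell)
  starts <- seq.int(1L, n, by = block)
  for (bi in seq_along(starts)) {
    i0 <- starts[bi]; i1 <- min(i0 + block - 1L, n)
    Xi <- X[i0:i1, , drop = FALSE]
    for (bj in seq.int(bi, length(starts))) {
      j0 <- starts[bj]; j1 <- min(j0 + block - 1L, n)
      Xj <- X[j0:j1, , drop = FALSE]
      I <- tcrossprod(Xi, Xj)
      U <- outer(pop[i0:i1], pop[j0:j1], "+") - I
      if (bi == bj) {
        sel <- upper.tri(I)
        iv <- I[sel]; uv <- U[sel]
      } else {
        iv <- as.vector(I); uv <- as.vector(U)
      }
      if (length(iv)) {
        key <- iv * (2L * nb + 1L) + uv + 1L
        tb <- tabulate(key, nbins = ncell)
        counts <- counts + tb
      }
    }
  }
  counts
}

# median from the (intersection, union) histogram
.median_from_histogram <- function(counts, nb) {
  idx <- which(counts > 0)
  inter <- (idx - 1L) %/% (2L * nb + 1L)
  uni <- (idx - 1L) %% (2L * nb + 1L)
  val <- ifelse(uni == 0L, 1.0, inter / pmax(uni, 1L))
  ord <- order(val)
  val <- val[ord]; cnt <- counts[idx][ord]
  total <- sum(cnt)
  cum <- cumsum(cnt)
  if (total %% 2 == 1) {
    k <- (total + 1) / 2
    return(val[which(cum >= k)[1L]])
  }
  k1 <- total / 2; k2 <- k1 + 1
  v1 <- val[which(cum >= k1)[1L]]
  v2 <- val[which(cum >= k2)[1L]]
  (v1 + v2) / 2
}

#' Median pairwise Tanimoto similarity (exact)
#'
#' Median over all `choose(n, 2)` pairwise similarities; for an even
#' number of pairs, the mean of the two middle values. Pairs of all-zero
#' fingerprints count as similarity 1.
#'
#' @param pop List of fingerprints (one kind) or a 0/1 matrix from
#'   [fingerprint_matrix()].
#' @return Median similarity in \[0, 1\].
#' @export
median_pairwise <- function(pop) {
  X <- if (is.matrix(pop)) pop else fingerprint_matrix(pop)
  if (nrow(X) < 2L) stop("median_pairwise needs at least 2 fingerprints")
  counts <- .pairwise_histogram(X)
  .median_from_histogram(counts, ncol(X))
}

#' Sampled median pairwise similarity
#'
#' If the population does not exceed `cfg$sample_size`, the exact median
#' of the whole population is returned (`sampled = FALSE`). Otherwise
#' `cfg$n_samples` random samples of `cfg$sample_size` fingerprints are
#' drawn without replacement (independently per sample, seeded), the
#' median computed within each, and the medians averaged.
#'
#' @param pop List of fingerprints or a 0/1 matrix.
#' @param cfg A [diversity_config()].
#' @return A `diversity_result`: `per_sample_medians`, `averaged_median`,
#'   `n_used`, `sampled`, `config`.
#' @export
sampled_median <- function(pop, cfg = diversity_config()) {
  X <- if (is.matrix(pop)) pop else fingerprint_matrix(pop)
  n <- nrow(X)
  if (n < 2L) stop("population must have at least 2 fingerprints")
  if (n <= cfg$sample_size) {
    med <- median_pairwise(X)
    res <- list(per_sample_medians = med, averaged_median = med,
                n_used = n, sampled = FALSE, config = cfg)
    return(structure(res, class = "diversity_result"))
  }
  meds <- numeric(cfg$n_samples)
  for (s in seq_len(cfg$n_samples)) {
    set.seed(cfg$seed + 7919L * s)
    idx <- sample.int(n, cfg$sample_size)
    meds[s] <- median_pairwise(X[idx, , drop = FALSE])
  }
  structure(list(per_sample_medians = meds,
                 averaged_median = mean(meds),
                 n_used = n, sampled = TRUE, config = cfg),
            class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf("<diversity_result: averaged median %.4f over %s (n=%d)>\n",
              x$averaged_median,
              if (x$sampled) sprintf("%d samples", length(x$per_sample_medians))
              else "full population", x$n_used))
  invisible(x)
}

#' Write diversity results as JSON
#'
#' @param results Named list of `diversity_result` objects (for example
#'   `dataset.fingerprint_kind` -> result).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_diversity_json <- function(results, path) {
  payload <- lapply(results, function(r) {
    list(kind = r$config$kind,
         n_samples = length(r$per_sample_medians),
         sample_size = r$config$sample_size,
         seed = r$config$seed,
         sampled = r$sampled,
         n_used = r$n_used,
         per_sample_medians = r$per_sample_medians,
         averaged_median = r$averaged_median)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
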