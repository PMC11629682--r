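# Hill-number beta diversity for pairs of samples (equal weights w = 1/2),
# the local overlap-based dissimilarity transform to [0,1], PCoA by Gower
# double-centering, Mantel permutation tests for correlating dissimilarity
# matrices, and the prevalence-by-completeness stratification.
#
# For diversity order q (q = 0 richness, q = 1 Shannon-like, q = 2
# dominance-weighted):
#   gamma = (sum_i pbar_i^q)^(1/(1-q)),   pbar = (p1 + p2)/2
#   alpha = (1/2) (sum_{ij} (p_ij/2)^q)^(1/(1-q))   (sums over support)
#   beta  = gamma/alpha in [1, 2]
#   d     = 1 - ((1/beta)^(q-1) - (1/2)^(q-1)) / (1 - (1/2)^(q-1)),  q != 1
#   d     = ln(beta)/ln(2),                                          q  = 1
# d reads as the proportion of (order-q weighted) taxa differing between the
# two samples.

#' Pairwise Hill-number dissimilarity
#'
#' @param p1,p2 non-negative abundance vectors over the same taxa (any
#'   scale; renormalized to proportions; zero-abundance taxa are dropped
#'   per sample since Hill numbers are support-based)
#' @param q diversity order >= 0
#' @return list of class `hill_decomposition`: q, gamma, alpha, beta, N = 2,
#'   d
#' @export
pairwise_dissimilarity <- function(p1, p2, q) {
  if (length(p1) != length(p2) || any(p1 < 0) || any(p2 < 0) ||
      sum(p1) <= 0 || sum(p2) <= 0 || is.na(q) || q < 0) {
    mp_stop("invalid-input",
            "need two normalizable non-negative vectors and q >= 0")
  }
  p1 <- p1 / sum(p1)
  p2 <- p2 / sum(p2)
  pbar <- (p1 + p2) / 2
  pooled <- pbar[pbar > 0]
  parts <- c(p1[p1 > 0], p2[p2 > 0]) / 2
  if (abs(q - 1) < 1e-12) {
    gamma <- exp(-sum(pooled * log(pooled)))
    alpha <- exp(-sum(parts * log(parts))) / 2
    beta <- gamma / alpha
    d <- log(beta) / log(2)
  } else {
    gamma <- sum(pooled^q)^(1 / (1 - q))
    alpha <- sum(parts^q)^(1 / (1 - q)) / 2
    beta <- gamma / alpha
    d <- 1 - ((1 / beta)^(q - 1) - (1 / 2)^(q - 1)) / (1 - (1 / 2)^(q - 1))
  }
  structure(list(q = q, gamma = gamma, alpha = alpha, beta = beta, N = 2L,
                 d = min(1, max(0, d))),
            class = "hill_decomposition")
}

#' Pairwise dissimilarity matrix over samples
#'
#' Applies [pairwise_dissimilarity()] to every pair of columns after
#' renormalizing each column over the included taxa.
#'
#' @param abundance taxa x sample matrix (any non-negative scale)
#' @param q diversity order
#' @param samples optional subset of column names
#' @return symmetric matrix of d values with zero diagonal, attribute
#'   `q`
#' @export
dissimilarity_matrix <- function(abundance, q, samples = NULL) {
  if (!is.null(samples)) abundance <- abundance[, samples, drop = FALSE]
  if (ncol(abundance) < 2L) {
    mp_stop("invalid-input", "need at least two samples")
  }
  if (any(colSums(abundance) <= 0)) {
    mp_stop("empty-sample",
            paste("empty columns:",
                  paste(colnames(abundance)[colSums(abundance) <= 0],
                        collapse = ", ")))
  }
  n <- ncol(abundance)
  D <- matrix(0, n, n, dimnames = list(colnames(abundance),
                                       colnames(abundance)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- pairwise_dissimilarity(abundance[, i], abundance[, j], q)$d
      D[i, j] <- d
      D[j, i] <- d
    }
  }
  attr(D, "q") <- q
  D
}

#' Principal coordinate analysis (Gower double-centering)
#'
#' A = -d^2/2 is double-centered and eigendecomposed; coordinates are
#' eigenvectors scaled by sqrt(eigenvalue) for positive eigenvalues only.
#' Negative eigenvalues are reported verbatim (no Lingoes/Cailliez
#' correction); proportion explained is relative to the sum of positive
#' eigenvalues.
#'
#' @param D symmetric dissimilarity matrix (>= 3 samples)
#' @param n_axes maximum number of axes to return (default all positive)
#' @return list of class `pcoa_result`: coordinates (samples x axes),
#'   eigenvalues (all, descending), prop_explained (per positive axis)
#' @export
pcoa <- function(D, n_axes = NULL) {
  n <- nrow(D)
  if (n < 3L) mp_stop("invalid-input", "PCoA needs at least 3 samples")
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  pos <- which(e$values > max(1e-12, 1e-9 * abs(e$values[1])))
  k <- if (is.null(n_axes)) length(pos) else min(n_axes, length(pos))
  coords <- if (k > 0L) {
    e$vectors[, pos[seq_len(k)], drop = FALSE] %*%
      diag(sqrt(e$values[pos[seq_len(k)]]), k)
  } else matrix(numeric(0), nrow = n, ncol = 0L)
  rownames(coords) <- rownames(D)
  if (k > 0L) colnames(coords) <- paste0("PCo", seq_len(k))
  prop <- if (length(pos)) e$values[pos] / sum(e$values[pos]) else numeric(0)
  structure(list(coordinates = coords, eigenvalues = e$values,
                 prop_explained = prop[seq_len(k)]),
            class = "pcoa_result")
}

#' Mantel correlation between two dissimilarity matrices
#'
#' Pearson r over upper-triangle entries; two-sided p-value from a Mantel
#' permutation test permuting the sample labels of `dB`:
#' p = (1 + #{|r_perm| >= |r_obs|}) / (1 + n_perm).
#'
#' @param dA,dB symmetric matrices over the same samples in the same order
#' @param n_perm number of permutations, default 9999
#' @param seed RNG seed
#' @return list(r, p, n_perm, n_samples)
#' @export
correlate_dissimilarities <- function(dA, dB, n_perm = 9999L, seed = 1L) {
  n <- nrow(dA)
  if (n < 4L) mp_stop("insufficient-samples",
                      "Mantel test needs at least 4 samples")
  stopifnot(all(dim(dA) == dim(dB)))
  if (!is.null(rownames(dA)) && !is.null(rownames(dB)) &&
      !identical(rownames(dA), rownames(dB))) {
    mp_stop("invalid-input", "matrices must cover the same samples in order")
  }
  ut <- upper.tri(dA)
  if (stats::sd(dA[ut]) == 0 || stats::sd(dB[ut]) == 0) {
    # a constant matrix carries no pairwise signal to correlate
    return(list(r = NA_real_, p = NA_real_, n_perm = n_perm, n_samples = n))
  }
  r_obs <- stats::cor(dA[ut], dB[ut])
  set.seed(seed)
  r_perm <- replicate(n_perm, {
    p <- sample.int(n)
    stats::cor(dA[ut], dB[p, p][ut])
  })
  p <- (1 + sum(abs(r_perm) >= abs(r_obs))) / (1 + n_perm)
  list(r = r_obs, p = p, n_perm = n_perm, n_samples = n)
}

#' Feature prevalence stratified by bin completeness
#'
#' Bins are sorted by increasing completeness (ties by bin id) and chunked
#' into consecutive groups of `group_size` (default 36); the final partial
#' group is retained and flagged. Each group reports its completeness range
#' and the fraction of bins carrying the feature.
#'
#' @param bins data.frame with columns bin_id, completeness and a logical
#'   feature column named by `feature`
#' @param feature feature column name, e.g. "has_prophage" or "has_crispr"
#' @param group_size default 36
#' @return data.frame(group, n, completeness_min, completeness_max,
#'   fraction, partial)
#' @export
prevalence_by_completeness <- function(bins, feature, group_size = 36L) {
  stopifnot(feature %in% names(bins))
  ord <- order(bins$completeness, bins$bin_id)
  b <- bins[ord, , drop = FALSE]
  n <- nrow(b)
  grp <- (seq_len(n) - 1L) %/% group_size + 1L
  out <- do.call(rbind, lapply(split(seq_len(n), grp), function(i) {
    data.frame(n = length(i),
               completeness_min = min(b$completeness[i]),
               completeness_max = max(b$completeness[i]),
               fraction = mean(b[[feature]][i]),
               partial = length(i) < group_size)
  }))
  out$group <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("group", "n", "completeness_min", "completeness_max", "fraction",
          "partial")]
}

#' Shared fraction of taxa from a dissimilarity value
#'
#' 100 x (1 - d), rounded to integer percent for reporting ("1 - 1d" read as
#' the share of common taxa two communities have in common).
#'
#' @param d dissimilarity in [0, 1]
#' @return integer percent
#' @export
shared_fraction <- function(d) {
  if (any(d < 0 | d > 1)) mp_stop("invalid-input", "d must lie in [0,1]")
  round(100 * (1 - d))
}
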