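#' Nonnegative matrix factorization of a positioning-signal matrix
#'
#' Decomposes a nonnegative variants x positions matrix `X` into `rank`
#' basis dyad patterns with nonnegative per-variant weights, `X ~ W H`,
#' by Lee-Seung multiplicative updates minimizing squared Frobenius error.
#' Basis rows are normalized to sum 1 with the scale moved into the weights,
#' so weights are comparable across variants.
#'
#' @param X nonnegative matrix, rows = variants (rownames kept), columns =
#'   dyad positions.
#' @param rank number of basis patterns, `1 <= rank <= min(dim(X))`.
#' @param seed integer seed for the random nonnegative initialization.
#' @param max_iter,tol stopping rule: stop when the relative error change
#'   drops below `tol` or after `max_iter` iterations.
#' @return object of class `nmf_decomposition`: list with `weights`
#'   (V x rank), `basis` (rank x T, rows sum to 1), `error_trace`,
#'   `iterations`, `converged`.
#' @export
nmf_decompose <- function(X, rank, seed = 1L, max_iter = 500L, tol = 1e-8) {
  X <- as.matrix(X)
  if (any(X < 0) || any(!is.finite(X))) stop("X must be finite nonnegative")
  V <- nrow(X); Tn <- ncol(X)
  if (rank < 1L || rank > min(V, Tn))
    stop("rank must be within [1, min(dim(X))]")
  set.seed(seed)
  eps <- 1e-12
  W <- matrix(stats::runif(V * rank, 0.1, 1), V, rank)
  H <- matrix(stats::runif(rank * Tn, 0.1, 1), rank, Tn)
  err <- numeric(0)
  prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, X)) / (crossprod(W, W %*% H) + eps)
    W <- W * (X %*% t(H)) / (W %*% tcrossprod(H, H) + eps)
    e <- sqrt(sum((X - W %*% H)^2))
    err <- c(err, e)
    if (is.finite(prev) && abs(prev - e) <= tol * max(prev, eps)) {
      converged <- TRUE
      break
    }
    prev <- e
  }
  s <- rowSums(H)
  s[s < eps] <- eps
  H <- H / s
  W <- sweep(W, 2L, s, `*`)
  rownames(W) <- rownames(X)
  structure(list(weights = W, basis = H, error_trace = err,
                 iterations = length(err), converged = converged),
            class = "nmf_decomposition")
}

# Spread per-variant values onto the bp covered by each perturbation and
# average overlapping contributions per (length, position) cell.
map_values_to_grid <- function(metadata, values) {
  need <- c("start_dyad", "length")
  if (!all(need %in% names(metadata)))
    stop("metadata must contain columns start_dyad and length")
  stopifnot(nrow(metadata) == length(values))
  if (nrow(metadata) == 0L) {
    return(structure(list(values = matrix(NA_real_, 0, 0),
                          counts = matrix(0L, 0, 0),
                          lengths = integer(0), positions = integer(0)),
                     class = "score_map"))
  }
  lengths <- sort(unique(metadata$length))
  pos_min <- min(metadata$start_dyad)
  pos_max <- max(metadata$start_dyad + metadata$length - 1L)
  positions <- pos_min:pos_max
  sums <- matrix(0, length(lengths), length(positions))
  counts <- matrix(0L, length(lengths), length(positions))
  for (i in seq_len(nrow(metadata))) {
    r <- match(metadata$length[i], lengths)
    cov <- metadata$start_dyad[i] + 0:(metadata$length[i] - 1L)
    cc <- match(cov, positions)
    sums[r, cc] <- sums[r, cc] + values[i]
    counts[r, cc] <- counts[r, cc] + 1L
  }
  vals <- sums / counts          # zero-occupancy cells become NaN -> NA
  vals[counts == 0L] <- NA_real_
  dimnames(vals) <- dimnames(counts) <- list(lengths, positions)
  structure(list(values = vals, counts = counts, lengths = lengths,
                 positions = positions), class = "score_map")
}

#' Geographic NMF score map
#'
#' Maps each variant's weight for one basis pattern onto every base pair its
#' perturbation covers, averaging where perturbations from different
#' variants overlap. Rows of the grid are perturbation lengths, columns are
#' dyad-relative positions, giving the geographic heat-map layout; cells
#' never covered by a perturbation are `NA`, not zero.
#'
#' @param decomp an [nmf_decompose()] result.
#' @param metadata data.frame aligned with the rows of `decomp$weights`
#'   (matched by `uid` against rownames when present), holding `start_dyad`
#'   and `length`.
#' @param basis_index which basis pattern's weights to map.
#' @return object of class `score_map`: list with `values`, `counts`,
#'   `lengths`, `positions`.
#' @export
nmf_score_map <- function(decomp, metadata, basis_index) {
  W <- decomp$weights
  if (basis_index < 1L || basis_index > ncol(W)) stop("no such basis pattern")
  if (!is.null(rownames(W)) && "uid" %in% names(metadata)) {
    idx <- match(rownames(W), metadata$uid)
    if (anyNA(idx)) stop("metadata missing for variants: ",
                         paste(rownames(W)[is.na(idx)], collapse = ", "))
    metadata <- metadata[idx, , drop = FALSE]
  }
  map_values_to_grid(metadata, W[, basis_index])
}

#' Jensen-Shannon similarity between probability vectors
#'
#' `exp(-JSD(p, q))` with the divergence in nats, so identical distributions
#' score 1 and disjoint supports score `exp(-ln 2) = 0.5`.
#'
#' @param p,q probability vectors of equal length.
#' @return similarity in (0, 1].
#' @export
js_similarity <- function(p, q) {
  if (length(p) != length(q)) stop("probability vectors differ in length")
  exp(-js_divergence(p, q))
}

js_divergence <- function(p, q) {
  m <- (p + q) / 2
  xlx <- function(a, b) {
    i <- a > 0
    sum(a[i] * log(a[i] / b[i]))
  }
  0.5 * xlx(p, m) + 0.5 * xlx(q, m)
}

#' Pairwise Jensen-Shannon similarity matrix
#' @param X matrix with probability rows.
#' @return symmetric matrix with unit diagonal.
#' @export
js_similarity_matrix <- function(X) {
  V <- nrow(X)
  S <- diag(1, V)
  if (V > 1L) for (i in 1:(V - 1L)) for (j in (i + 1L):V) {
    S[i, j] <- S[j, i] <- js_similarity(X[i, ], X[j, ])
  }
  dimnames(S) <- list(rownames(X), rownames(X))
  S
}

#' Spectral clustering of a similarity matrix
#'
#' Normalized-Laplacian spectral embedding (Ng-Jordan-Weiss: top-k
#' eigenvectors of `D^-1/2 S D^-1/2`, rows renormalized) followed by seeded
#' k-means. Intended for the exp(-JSD) similarity of positioning signals.
#'
#' @param S symmetric similarity matrix with positive entries.
#' @param k number of clusters (`1 <= k <= nrow(S)`).
#' @param seed integer seed for k-means.
#' @return integer vector of cluster labels (named by rownames of `S`).
#' @export
spectral_cluster <- function(S, k, seed = 1L) {
  V <- nrow(S)
  if (k < 1L || k > V) stop("k must be within [1, nrow(S)]")
  if (max(abs(S - t(S))) > 1e-8) stop("similarity matrix must be symmetric")
  if (k == 1L) return(stats::setNames(rep(1L, V), rownames(S)))
  d <- rowSums(S)
  Dm <- 1 / sqrt(d)
  A <- S * tcrossprod(Dm)
  ev <- eigen(A, symmetric = TRUE)
  U <- ev$vectors[, seq_len(k), drop = FALSE]
  nrm <- sqrt(rowSums(U^2))
  nrm[nrm == 0] <- 1
  U <- U / nrm
  set.seed(seed)
  km <- stats::kmeans(U, centers = k, nstart = 25L, iter.max = 100L)
  stats::setNames(km$cluster, rownames(S))
}

#' Silhouette widths over candidate cluster counts
#'
#' Supports the trial-and-error choice of the minimal cluster number giving
#' well-isolated clusters: reports the mean silhouette width (dissimilarity
#' `1 - S`) for each candidate `k`.
#'
#' @param S similarity matrix.
#' @param ks integer vector of candidate cluster counts (each >= 2).
#' @param seed k-means seed.
#' @return data.frame with `k` and `mean_silhouette`.
#' @export
cluster_silhouettes <- function(S, ks = 2:6, seed = 1L) {
  d <- stats::as.dist(1 - S)
  res <- vapply(ks, function(k) {
    lab <- spectral_cluster(S, k, seed = seed)
    mean(cluster::silhouette(lab, d)[, "sil_width"])
  }, numeric(1))
  data.frame(k = ks, mean_silhouette = res)
}

#' Kullback-Leibler divergence with pseudocounts
#'
#' `KL(p || q)` in nats after adding pseudocount `alpha` to both vectors and
#' renormalizing, so zero-probability positions stay finite.
#'
#' @param p,q probability vectors of equal length.
#' @param alpha pseudocount (default 1e-6).
#' @return nonnegative divergence in nats.
#' @export
kl_divergence <- function(p, q, alpha = 1e-6) {
  if (length(p) != length(q)) stop("probability vectors differ in length")
  p <- (p + alpha) / sum(p + alpha)
  q <- (q + alpha) / sum(q + alpha)
  sum(p * log(p / q))
}

#' KL-divergence map against a reference positioning signal
#'
#' Quantifies how far each perturbed positioning distribution deviates from
#' the unperturbed one: computes `KL(perturbed || original)` per variant and
#' maps the values onto the perturbation coordinates, averaging overlaps.
#'
#' @param X matrix of positioning probabilities (rows = variants).
#' @param reference_signal probability vector of the unperturbed construct.
#' @param metadata perturbation metadata as in [nmf_score_map()].
#' @param alpha pseudocount.
#' @return list with `kl` (per-variant divergences) and `map` (a
#'   `score_map`).
#' @export
kl_divergence_map <- function(X, reference_signal, metadata, alpha = 1e-6) {
  if (any(reference_signal < 0) || sum(reference_signal) <= 0)
    stop("invalid reference signal")
  reference_signal <- reference_signal / sum(reference_signal)
  if (ncol(X) != length(reference_signal))
    stop("signal length mismatch with reference")
  kl <- apply(X, 1L, kl_divergence, q = reference_signal, alpha = alpha)
  if (!is.null(rownames(X)) && "uid" %in% names(metadata)) {
    idx <- match(rownames(X), metadata$uid)
    if (anyNA(idx)) stop("metadata missing for variants: ",
                         paste(rownames(X)[is.na(idx)], collapse = ", "))
    metadata <- metadata[idx, , drop = FALSE]
  }
  list(kl = kl, map = map_values_to_grid(metadata, kl))
}
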