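#' Phylogenetic distance kernel over a taxon set
#'
#' `K_ij = exp(-lambda_k * d_ij)` with `d` the patristic (branch-length)
#' distance; similarity decays with evolutionary divergence, diagonal is
#' exactly 1 and entries lie in (0, 1].
#'
#' @param tree `ape::phylo` whose leaves include all `taxa`.
#' @param taxa Character vector of taxon IDs (kernel row/col order).
#' @param lambda_k Decay rate per branch-length unit (>= 0); 0 gives the
#'   all-ones kernel.
#' @return A `phylo_model` holding `taxa`, `d`, `K` and `lambda_k`
#'   (features `h` are added by [kernel_features()]).
#' @export
phylo_kernel <- function(tree, taxa, lambda_k = 1.0) {
  validate_tree(tree)
  if (lambda_k < 0) stop("lambda_k must be >= 0")
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing) > 0)
    stop("taxa missing from tree: ", paste(missing, collapse = ", "))
  d <- patristic_distances(ape::keep.tip(tree, taxa))[taxa, taxa]
  K <- exp(-lambda_k * d)
  diag(K) <- 1
  structure(list(taxa = taxa, d = d, K = K, lambda_k = lambda_k, h = NULL),
            class = "phylo_model")
}

#' Identity phylogeny fallback
#'
#' When no tree is available: `K = I`, one-hot taxon features. The model
#' then carries no phylogenetic information but degrades gracefully.
#'
#' @param taxa Character vector of taxon IDs.
#' @param m Feature dimension (capped at `length(taxa)`).
#' @return A `phylo_model` with identity kernel and one-hot `h`.
#' @export
phylo_identity <- function(taxa, m = length(taxa)) {
  n <- length(taxa)
  m <- min(m, n)
  K <- diag(1, n)
  dimnames(K) <- list(taxa, taxa)
  h <- diag(1, n)[, seq_len(m), drop = FALSE]
  rownames(h) <- taxa
  message("no phylogeny supplied: using identity kernel / one-hot features")
  structure(list(taxa = taxa, d = NULL, K = K, lambda_k = NA_real_, h = h,
                 uninformative = TRUE),
            class = "phylo_model")
}

#' @export
print.phylo_model <- function(x, ...) {
  cat(sprintf("phylo_model: %d taxa, lambda_k = %s, features: %s\n",
              length(x$taxa), format(x$lambda_k),
              if (is.null(x$h)) "none" else paste0(ncol(x$h), "-dim")))
  invisible(x)
}

#' Spectral taxon features from the phylogenetic kernel
#'
#' Eigendecomposes the (symmetric) kernel, clips negative eigenvalues to
#' zero, and returns the top-`m` eigenvectors scaled by the square root of
#' their eigenvalues, so `h %*% t(h)` is the best rank-`m` PSD
#' approximation of the clipped kernel. Eigenvectors are ordered by
#' descending eigenvalue with the sign fixed so each vector's
#' largest-magnitude entry is positive (reproducible across runs).
#'
#' @param model `phylo_model` from [phylo_kernel()].
#' @param m Feature dimension, `1 <= m <= n_taxa`.
#' @return The model with `h` (taxa x m matrix) filled in.
#' @export
kernel_features <- function(model, m) {
  stopifnot(inherits(model, "phylo_model"))
  n <- length(model$taxa)
  if (m < 1 || m > n) stop("m must be in [1, n_taxa]")
  eig <- eigen(model$K, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vecs <- eig$vectors
  for (k in seq_len(n)) {                     # deterministic sign convention
    i <- which.max(abs(vecs[, k]))
    if (vecs[i, k] < 0) vecs[, k] <- -vecs[, k]
  }
  h <- vecs[, seq_len(m), drop = FALSE] %*%
    diag(sqrt(vals[seq_len(m)]), m)
  rownames(h) <- model$taxa
  colnames(h) <- sprintf("pc%02d", seq_len(m))
  model$h <- h
  model
}

#' Mean off-diagonal kernel similarity per taxon
#'
#' The averaged phylogenetic similarity entering the compositional token
#' weight. A single-taxon kernel has no off-diagonal; its mean similarity
#' is defined as 1. The tree-free identity fallback also returns 1 for
#' every taxon: its off-diagonal mean of 0 would annihilate the
#' compositional weight `log(1 + x* K)`, whereas without phylogenetic
#' information the weight should reduce to pure abundance.
#'
#' @param model `phylo_model` (or a bare kernel matrix).
#' @return Named per-taxon vector.
#' @export
mean_similarity <- function(model) {
  if (inherits(model, "phylo_model") && isTRUE(model$uninformative)) {
    return(stats::setNames(rep(1, length(model$taxa)), model$taxa))
  }
  K <- if (inherits(model, "phylo_model")) model$K else model
  n <- nrow(K)
  if (n == 1) {
    message("single-taxon kernel: mean similarity defined as 1")
    return(stats::setNames(1, rownames(K)))
  }
  stats::setNames((rowSums(K) - diag(K)) / (n - 1), rownames(K))
}
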