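#' Raw multiset token features for every sample
#'
#' For each sample, one token per taxon with nonzero raw count. The raw
#' feature vector of taxon i concatenates its spectral phylogenetic
#' features, its (harmonized) CLR value, and its compositional weight
#' `w_i = log(1 + x*_i * Kbar_i)` -- the weight combines abundance
#' magnitude with averaged phylogenetic similarity, and additionally
#' multiplies the projected token downstream, so the information survives
#' feature standardization.
#'
#' @param clr `composition_matrix` (clr mode, possibly batch-corrected).
#' @param frac `composition_matrix` (fraction mode, for `x*`).
#' @param counts `count_table` (presence is raw count > 0).
#' @param phylo `phylo_model` with features `h` (see [kernel_features()]).
#' @return List of per-sample token inputs:
#'   `list(e = features (n_present x (m+2)), w, taxa)`, named by sample.
#' @export
raw_token_features <- function(clr, frac, counts, phylo) {
  stopifnot(inherits(clr, "composition_matrix"),
            inherits(frac, "composition_matrix"),
            inherits(counts, "count_table"),
            inherits(phylo, "phylo_model"))
  if (is.null(phylo$h)) stop("phylo model has no features; run kernel_features")
  missing <- setdiff(counts$taxa, phylo$taxa)
  if (length(missing) > 0)
    stop("taxa absent from phylo model: ", paste(missing[1:min(3, length(missing))],
                                                 collapse = ", "))
  kbar <- mean_similarity(phylo)
  h <- phylo$h[counts$taxa, , drop = FALSE]
  out <- lapply(seq_along(counts$samples), function(j) {
    present <- which(counts$counts[, j] > 0)
    taxa <- counts$taxa[present]
    w <- log(1 + frac$values[present, j] * kbar[taxa])
    e <- cbind(h[present, , drop = FALSE],
               clr = clr$values[present, j],
               w = unname(w))
    list(e = e, w = unname(w), taxa = taxa)
  })
  names(out) <- counts$samples
  out
}

#' Fit the global token-feature normalizer
#'
#' Per-dimension mean and SD over all tokens of the training samples
#' (global moments, not per-taxon); SDs of constant dimensions are
#' floored at 1e-6 with a warning. Records the fitted-on sample list for
#' leakage assertions.
#'
#' @param token_inputs Output of [raw_token_features()] restricted to
#'   training samples.
#' @return A `tokenizer_state` with `mu`, `sigma`, `fitted_on`.
#' @export
fit_normalizer <- function(token_inputs) {
  E <- do.call(rbind, lapply(token_inputs, `[[`, "e"))
  if (nrow(E) < 2) stop("need >= 2 training tokens to fit the normalizer")
  mu <- colMeans(E)
  sigma <- apply(E, 2, stats::sd)
  if (any(sigma < 1e-6)) {
    warning("constant token feature dimension(s); SD floored at 1e-6")
    sigma <- pmax(sigma, 1e-6)
  }
  structure(list(mu = mu, sigma = sigma,
                 fitted_on = names(token_inputs)),
            class = "tokenizer_state")
}

#' Standardize token features with a fitted normalizer
#'
#' `e_tilde = (e - mu) / sigma`, always using the training-fitted moments
#' (held-out samples are transformed, never refit).
#'
#' @param token_inputs Output of [raw_token_features()].
#' @param state A [fit_normalizer()] state.
#' @return Token inputs with standardized `e`.
#' @export
normalize_tokens <- function(token_inputs, state) {
  stopifnot(inherits(state, "tokenizer_state"))
  lapply(token_inputs, function(s) {
    s$e <- sweep(sweep(s$e, 2, state$mu, "-"), 2, state$sigma, "/")
    s
  })
}

#' Project normalized tokens into the latent multiset
#'
#' `z_i = w_i * (W_e e_tilde_i + b_e)`: the compositional weight scales
#' the projected token, so abundant / phylogenetically central taxa carry
#' proportionally more attention mass. Exposed mainly for inspection;
#' [net_forward()] performs the same projection internally.
#'
#' @param sample One token-input sample (`e`, `w`, `taxa`).
#' @param We Projection matrix (feature_dim x token_dim).
#' @param be Bias (token_dim).
#' @return Token matrix z (n_present x token_dim).
#' @export
project_tokens <- function(sample, We, be) {
  if (ncol(sample$e) != nrow(We)) stop("feature/projection dimension mismatch")
  sweep(sample$e %*% We, 2, be, "+") * sample$w
}
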