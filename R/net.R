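#' Network configuration
#'
#' Defaults give the full-size model: token dimensionality 128, 4 Set
#' Attention Block (SAB) layers, 8 attention heads, 16 PMA seed vectors,
#' dropout 0.2, batch size 64, learning rate 5e-4, up to 200 epochs, CLR
#' pseudo-count 1e-6 and empirical-Bayes lambda 0.01 (the latter two
#' consumed by the preprocessing stages). The feed-forward hidden width
#' (2048) completes the architecture at its nominal scale of ~3.2M
#' trainable parameters.
#'
#' @param token_dim Latent token dimension (must be divisible by
#'   `n_heads`).
#' @param sab_layers Number of stacked SABs.
#' @param n_heads Attention heads per block.
#' @param pma_seeds Number of learnable PMA seed vectors.
#' @param dropout Dropout rate on feed-forward hidden activations.
#' @param ffn_hidden Hidden width of the per-token feed-forward inside
#'   each block.
#' @param head_hidden Hidden width of the classifier head.
#' @param pool `"concat"` (seed outputs concatenated) or `"mean"`.
#' @param labels Class label set; the last label is the positive class.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement); only active when `val_frac > 0`.
#' @param val_frac Fraction of training samples held out for early
#'   stopping.
#' @param phylo_m Spectral phylogenetic feature dimension.
#' @param delta CLR pseudo-count (preprocessing).
#' @param eb_lambda Empirical-Bayes shrinkage strength (preprocessing).
#' @param seed Master RNG seed governing initialization, shuffling and
#'   dropout.
#' @return A `net_config` list.
#' @export
net_config <- function(token_dim = 128, sab_layers = 4, n_heads = 8,
                       pma_seeds = 16, dropout = 0.2, ffn_hidden = 2048,
                       head_hidden = 256, pool = c("concat", "mean"),
                       labels = c("control", "disease"),
                       lr = 5e-4, batch_size = 64, epochs = 200,
                       patience = 20, val_frac = 0.1,
                       phylo_m = 32, delta = 1e-6, eb_lambda = 0.01,
                       seed = 42L) {
  pool <- match.arg(pool)
  if (token_dim %% n_heads != 0)
    stop("token_dim must be divisible by n_heads")
  structure(list(token_dim = token_dim, sab_layers = sab_layers,
                 n_heads = n_heads, pma_seeds = pma_seeds,
                 dropout = dropout, ffn_hidden = ffn_hidden,
                 head_hidden = head_hidden, pool = pool, labels = labels,
                 lr = lr, batch_size = batch_size, epochs = epochs,
                 patience = patience, val_frac = val_frac,
                 phylo_m = phylo_m, delta = delta, eb_lambda = eb_lambda,
                 seed = as.integer(seed)),
            class = "net_config")
}

#' Scaled-down configuration for desk-scale benchmarks
#'
#' Same architecture at reduced width/depth: token dim 32, 2 SABs, 4
#' heads, 4 seeds, 30 epochs; feed-forward and head widths shrink
#' proportionally and the learning rate rises to 1e-3 (small-data
#' regime; larger rates destabilize individual folds). The spectral
#' phylogenetic feature dimension stays at full rank (capped at the
#' taxon count by the CV driver) because tokens are identified to their
#' taxon only through these features -- low-rank features blur nearby
#' taxa together and the classifier cannot localize planted effects. No
#' validation split is held out: at 30 epochs the budget is the stopping
#' rule and training data is scarce.
#'
#' @param seed Master RNG seed.
#' @param epochs Training epochs.
#' @return A `net_config`.
#' @export
scaled_config <- function(seed = 42L, epochs = 30) {
  net_config(token_dim = 32, sab_layers = 2, n_heads = 4, pma_seeds = 4,
             dropout = 0.2, ffn_hidden = 64, head_hidden = 64,
             lr = 1e-3, batch_size = 32, epochs = epochs, patience = 10,
             val_frac = 0, phylo_m = 1000, seed = seed)
}

xavier <- function(fan_in, fan_out) {
  a <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -a, a), fan_in, fan_out)
}

mab_params <- function(d, ffn) {
  list(Wq = xavier(d, d), Wk = xavier(d, d), Wv = xavier(d, d),
       Wo = xavier(d, d),
       bq = numeric(d), bk = numeric(d), bv = numeric(d), bo = numeric(d),
       g1 = rep(1, d), b1 = numeric(d), g2 = rep(1, d), b2 = numeric(d),
       Wf1 = xavier(d, ffn), bf1 = numeric(ffn),
       Wf2 = xavier(ffn, d), bf2 = numeric(d))
}

#' Initialize network parameters
#'
#' Xavier-uniform initialization under the configuration seed; gains of
#' the layer norms start at 1, biases at 0, PMA seeds Xavier over
#' (1, token_dim).
#'
#' @param config A [net_config()].
#' @param feature_dim Raw token feature dimension (phylo_m + 2).
#' @return A `dysbio_net` parameter container.
#' @export
init_net <- function(config, feature_dim) {
  d <- config$token_dim
  with_seed(config$seed, {
    params <- list(
      We = xavier(feature_dim, d), be = numeric(d),
      sab = lapply(seq_len(config$sab_layers),
                   function(i) mab_params(d, config$ffn_hidden)),
      pma = c(list(S = xavier(config$pma_seeds, d)),
              mab_params(d, config$ffn_hidden)),
      head = list(
        W1 = xavier(if (config$pool == "concat") config$pma_seeds * d else d,
                    config$head_hidden),
        b1 = numeric(config$head_hidden),
        W2 = xavier(config$head_hidden, length(config$labels)),
        b2 = numeric(length(config$labels))))
    structure(list(params = params, config = config,
                   feature_dim = feature_dim),
              class = "dysbio_net")
  })
}

#' @export
print.dysbio_net <- function(x, ...) {
  cat(sprintf(paste0("dysbio_net: token_dim %d, %d SAB layers x %d heads, ",
                     "%d PMA seeds, %s pooling\n  %s trainable parameters\n"),
              x$config$token_dim, x$config$sab_layers, x$config$n_heads,
              x$config$pma_seeds, x$config$pool,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#' @param net A `dysbio_net` (or a bare parameter list).
#' @return Integer total.
#' @export
count_parameters <- function(net) {
  params <- if (inherits(net, "dysbio_net")) net$params else net
  n <- 0
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else n <<- n + length(x)
    invisible(NULL)
  }
  walk(params)
  n
}

# ---- token batch container ---------------------------------------------

#' Assemble per-sample token inputs into a training batch
#'
#' Token rows of all samples are stacked so linear layers run as single
#' matrix products; attention operates on per-sample row slices. An
#' optional per-token logical mask marks padded rows (FALSE = padding),
#' which receive exactly zero attention.
#'
#' @param samples List of token inputs, each
#'   `list(e = features (n x F), w = weights (n), taxa = taxon ids[,
#'   mask = logical(n)])`.
#' @return A `token_batch`.
#' @export
build_batch <- function(samples) {
  sizes <- vapply(samples, function(s) nrow(s$e), 0L)
  E <- do.call(rbind, lapply(samples, `[[`, "e"))
  w <- unlist(lapply(samples, `[[`, "w"), use.names = FALSE)
  mask <- unlist(lapply(samples, function(s) {
    if (is.null(s$mask)) rep(TRUE, nrow(s$e)) else s$mask
  }), use.names = FALSE)
  ends <- cumsum(sizes)
  structure(list(E = E, w = w, sizes = sizes,
                 starts = ends - sizes + 1L, ends = ends,
                 mask = mask, B = length(samples),
                 taxa = lapply(samples, `[[`, "taxa")),
            class = "token_batch")
}

row_softmax <- function(A) {
  # max.col is C-level; guard the all--Inf row case never arises here
  mx <- A[cbind(seq_len(nrow(A)), max.col(A, ties.method = "first"))]
  e <- exp(A - mx)
  e / rowSums(e)
}

add_row <- function(M, b) add_bias_inplace(M, b)  # M is always a fresh temporary

layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  Y <- sweep(sweep(xhat, 2, g, "*"), 2, b, "+")
  list(Y = Y, xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dY, cache, g) {
  dxhat <- sweep(dY, 2, g, "*")
  dg <- colSums(dY * cache$xhat)
  db <- colSums(dY)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dX <- cache$inv * (dxhat - m1 - cache$xhat * m2)
  list(dX = dX, dg = dg, db = db)
}

# Multihead attention block: queries X attend over keys/values Y.
# self-attention: X and Y are the same stacked matrix with shared slices;
# PMA: X = seeds replicated per sample. Returns output after attention +
# residual-LN + feed-forward + residual-LN, plus a cache for backward.
mab_forward <- function(X, Y, prm, cfg, batch, mode = c("self", "pma"),
                        training = FALSE) {
  mode <- match.arg(mode)
  H <- cfg$n_heads
  d <- cfg$token_dim
  dk <- d / H
  scl <- 1 / sqrt(dk)
  Km <- add_row(Y %*% prm$Wk, prm$bk)
  Vm <- add_row(Y %*% prm$Wv, prm$bv)
  Qm <- add_row(X %*% prm$Wq, prm$bq)  # X = seeds (S x d) in pma mode
  af <- attn_forward_cpp(Qm, Km, Vm, batch$starts, batch$ends, H,
                         as.integer(batch$mask), mode == "self")
  Oc <- af$O
  O <- add_row(Oc %*% prm$Wo, prm$bo)
  Xres <- if (mode == "self") X else X[rep(seq_len(nrow(X)), batch$B), ,
                                       drop = FALSE]
  ln1 <- layernorm_fwd(Xres + O, prm$g1, prm$b1)
  H1 <- ln1$Y
  F1pre <- add_row(H1 %*% prm$Wf1, prm$bf1)
  F1 <- pmax(F1pre, 0)
  if (training && cfg$dropout > 0) {
    dmask <- (matrix(stats::runif(length(F1)), nrow(F1)) >= cfg$dropout) /
      (1 - cfg$dropout)
    F1d <- F1 * dmask
  } else {
    dmask <- NULL
    F1d <- F1
  }
  F2 <- add_row(F1d %*% prm$Wf2, prm$bf2)
  ln2 <- layernorm_fwd(H1 + F2, prm$g2, prm$b2)
  list(out = ln2$Y,
       cache = list(X = X, Y = Y, Km = Km, Vm = Vm, Qm = Qm,
                    alph = af$alph, offsets = af$offsets, Oc = Oc, H1 = H1,
                    F1pre = F1pre, F1d = F1d, dmask = dmask,
                    ln1 = ln1, ln2 = ln2, mode = mode))
}

mab_backward <- function(dout, cache, prm, cfg, batch) {
  H <- cfg$n_heads
  d <- cfg$token_dim
  dk <- d / H
  scl <- 1 / sqrt(dk)
  g <- list()

  l2 <- layernorm_bwd(dout, cache$ln2, prm$g2)
  g$g2 <- l2$dg; g$b2 <- l2$db
  dH1 <- l2$dX
  dF2 <- l2$dX
  g$Wf2 <- crossprod(cache$F1d, dF2)
  g$bf2 <- colSums(dF2)
  dF1d <- tcrossprod(dF2, prm$Wf2)
  dF1 <- if (is.null(cache$dmask)) dF1d else dF1d * cache$dmask
  dF1pre <- dF1 * (cache$F1pre > 0)
  g$Wf1 <- crossprod(cache$H1, dF1pre)
  g$bf1 <- colSums(dF1pre)
  dH1 <- dH1 + tcrossprod(dF1pre, prm$Wf1)

  l1 <- layernorm_bwd(dH1, cache$ln1, prm$g1)
  g$g1 <- l1$dg; g$b1 <- l1$db
  dres <- l1$dX                       # gradient of (Xres + O_proj)
  dOproj <- dres

  # output projection: Oproj = Oc %*% Wo + bo
  dOc <- tcrossprod(dOproj, prm$Wo)
  self <- cache$mode == "self"
  nq <- if (self) NA_integer_ else nrow(cache$X)
  g$Wo <- crossprod(cache$Oc, dOproj)
  g$bo <- colSums(dOproj)

  ab <- attn_backward_cpp(dOc, cache$alph, cache$offsets, cache$Qm,
                          cache$Km, cache$Vm, batch$starts, batch$ends, H,
                          self)
  dQm <- ab$dQ; dKm <- ab$dK; dVm <- ab$dV
  g$Wq <- crossprod(cache$X, dQm)
  g$bq <- colSums(dQm)
  g$Wk <- crossprod(cache$Y, dKm)
  g$bk <- colSums(dKm)
  g$Wv <- crossprod(cache$Y, dVm)
  g$bv <- colSums(dVm)

  dY <- tcrossprod(dKm, prm$Wk) + tcrossprod(dVm, prm$Wv)
  dX_query <- tcrossprod(dQm, prm$Wq)
  if (self) {
    dX <- dres + dX_query     # residual carried X itself
    dY <- dY                  # caller adds dY into the same tensor
  } else {
    # residual rows are replicated seeds: fold back per sample
    nq <- nrow(cache$X)
    dX <- dX_query
    for (s in seq_len(batch$B)) {
      dX <- dX + dres[((s - 1) * nq + 1):(s * nq), , drop = FALSE]
    }
  }
  list(dX = dX, dY = dY, grads = g)
}

#' Full network forward pass
#'
#' Token projection (`z_i = w_i * (W_e e_i + b_e)`), stacked SABs, PMA
#' pooling and the feed-forward classifier head. Probabilities are a
#' softmax over the configured label set.
#'
#' @param net A `dysbio_net`.
#' @param batch A [build_batch()] token batch (or a single sample list,
#'   which is wrapped automatically).
#' @param training Enable dropout.
#' @param trace Keep the per-sample attention matrices (`sab` per
#'   layer/head and PMA `gamma` per head) in the result.
#' @return List with `probs` (B x n_labels), `logits`, `cache`
#'   (when `training`), `trace` (when requested).
#' @export
net_forward <- function(net, batch, training = FALSE, trace = FALSE) {
  if (!inherits(batch, "token_batch")) batch <- build_batch(list(batch))
  cfg <- net$config
  p <- net$params
  Pre <- add_row(batch$E %*% p$We, p$be)
  Z0 <- Pre * batch$w
  Z <- Z0
  sab_caches <- vector("list", cfg$sab_layers)
  for (l in seq_len(cfg$sab_layers)) {
    fw <- mab_forward(Z, Z, p$sab[[l]], cfg, batch, "self", training)
    sab_caches[[l]] <- fw$cache
    Z <- fw$out
  }
  pm <- mab_forward(p$pma$S, Z, p$pma, cfg, batch, "pma", training)
  G <- pm$out                                  # (B*S) x d
  S <- cfg$pma_seeds
  d <- cfg$token_dim
  if (cfg$pool == "concat") {
    Xh <- matrix(0, batch$B, S * d)
    for (s in seq_len(batch$B))
      Xh[s, ] <- as.vector(t(G[((s - 1) * S + 1):(s * S), , drop = FALSE]))
  } else {
    Xh <- matrix(0, batch$B, d)
    for (s in seq_len(batch$B))
      Xh[s, ] <- colMeans(G[((s - 1) * S + 1):(s * S), , drop = FALSE])
  }
  Upre <- add_row(Xh %*% p$head$W1, p$head$b1)
  U <- pmax(Upre, 0)
  if (training && cfg$dropout > 0) {
    hmask <- (matrix(stats::runif(length(U)), nrow(U)) >= cfg$dropout) /
      (1 - cfg$dropout)
    Ud <- U * hmask
  } else {
    hmask <- NULL
    Ud <- U
  }
  logits <- add_row(Ud %*% p$head$W2, p$head$b2)
  probs <- row_softmax(logits)
  colnames(probs) <- cfg$labels
  out <- list(probs = probs, logits = logits)
  if (training) {
    out$cache <- list(Pre = Pre, Z0 = Z0, sab = sab_caches, pma = pm$cache,
                      G = G, Xh = Xh, Upre = Upre, Ud = Ud, hmask = hmask,
                      batch = batch)
  }
  if (trace) {
    out$trace <- lapply(seq_len(batch$B), function(s) {
      msk <- batch$mask[batch$starts[s]:batch$ends[s]]
      list(taxa = batch$taxa[[s]][msk],
           sab = lapply(sab_caches, function(cc) {
             al <- alphas_from_flat(cc, s, batch, cfg$n_heads, self = TRUE)
             lapply(al, function(a) a[msk, msk, drop = FALSE])
           }),
           gamma = lapply(alphas_from_flat(pm$cache, s, batch, cfg$n_heads,
                                           self = FALSE, nq = S),
                          function(a) a[, msk, drop = FALSE]))
    })
  }
  out
}

# slice the flat attention buffer of one MAB cache back into per-head
# matrices for sample s (trace / attribution path only)
alphas_from_flat <- function(cache, s, batch, H, self, nq = 0L) {
  n <- batch$sizes[s]
  nqs <- if (self) n else nq
  out <- vector("list", H)
  for (h in seq_len(H)) {
    off <- cache$offsets[s] + (h - 1L) * nqs * n
    out[[h]] <- matrix(cache$alph[(off + 1L):(off + nqs * n)], nqs, n)
  }
  out
}

#' Pre-softmax SAB attention scores of one sample
#'
#' Recomputes the scaled dot-product scores
#' `A_ij = (Q z_i).(K z_j) / sqrt(d_k)` of a given layer and head for
#' inspection; the row-softmax of this matrix is the attention the model
#' actually applies.
#'
#' @param net A `dysbio_net`.
#' @param sample One token-input sample.
#' @param layer SAB layer index.
#' @param head Head index.
#' @return The n x n score matrix over the sample's (unmasked) tokens.
#' @export
sab_scores <- function(net, sample, layer = 1, head = 1) {
  cfg <- net$config
  stopifnot(layer >= 1, layer <= cfg$sab_layers,
            head >= 1, head <= cfg$n_heads)
  if (nrow(sample$e) == 0) stop("empty token set")
  net$config$dropout <- 0   # inspection path: deterministic forward
  fw <- net_forward(net, build_batch(list(sample)), training = TRUE)
  cc <- fw$cache$sab[[layer]]
  dk <- cfg$token_dim / cfg$n_heads
  ch <- ((head - 1) * dk + 1):(head * dk)
  A <- tcrossprod(cc$Qm[, ch, drop = FALSE],
                  cc$Km[, ch, drop = FALSE]) / sqrt(dk)
  msk <- if (is.null(sample$mask)) rep(TRUE, nrow(sample$e)) else sample$mask
  A[msk, msk, drop = FALSE]
}

net_backward <- function(net, fwd, dlogits) {
  cfg <- net$config
  p <- net$params
  cache <- fwd$cache
  batch <- cache$batch
  S <- cfg$pma_seeds
  d <- cfg$token_dim
  g <- list(head = list(), pma = list(), sab = vector("list", cfg$sab_layers))

  g$head$W2 <- crossprod(cache$Ud, dlogits)
  g$head$b2 <- colSums(dlogits)
  dUd <- tcrossprod(dlogits, p$head$W2)
  dU <- if (is.null(cache$hmask)) dUd else dUd * cache$hmask
  dUpre <- dU * (cache$Upre > 0)
  g$head$W1 <- crossprod(cache$Xh, dUpre)
  g$head$b1 <- colSums(dUpre)
  dXh <- tcrossprod(dUpre, p$head$W1)

  dG <- matrix(0, nrow(cache$G), d)
  for (s in seq_len(batch$B)) {
    rows <- ((s - 1) * S + 1):(s * S)
    if (cfg$pool == "concat") {
      dG[rows, ] <- matrix(dXh[s, ], nrow = S, byrow = TRUE)
    } else {
      dG[rows, ] <- matrix(dXh[s, ] / S, nrow = S, ncol = d, byrow = TRUE)
    }
  }

  bp <- mab_backward(dG, cache$pma, p$pma, cfg, batch)
  g$pma <- bp$grads
  g$pma$S <- bp$dX
  dZ <- bp$dY
  for (l in rev(seq_len(cfg$sab_layers))) {
    bs <- mab_backward(dZ, cache$sab[[l]], p$sab[[l]], cfg, batch)
    g$sab[[l]] <- bs$grads
    dZ <- bs$dX + bs$dY
  }
  dPre <- dZ * batch$w
  g$We <- crossprod(batch$E, dPre)
  g$be <- colSums(dPre)
  g
}

# ---- Adam ---------------------------------------------------------------

flatten_params <- function(x, prefix = "") {
  if (is.list(x)) {
    out <- list()
    nm <- names(x)
    if (is.null(nm)) nm <- as.character(seq_along(x))
    for (i in seq_along(x))
      out <- c(out, flatten_params(x[[i]], paste0(prefix, ".", nm[i])))
    out
  } else {
    stats::setNames(list(x), prefix)
  }
}

adam_init <- function(params) {
  fl <- flatten_params(params)
  list(m = lapply(fl, function(v) v * 0),
       v = lapply(fl, function(v) v * 0), t = 0)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  fp <- flatten_params(params)
  fg <- flatten_params(grads)
  state$t <- state$t + 1
  t <- state$t
  for (k in names(fp)) {
    gk <- fg[[k]]
    if (is.null(gk)) next
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * gk
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * gk * gk
    mhat <- state$m[[k]] / (1 - beta1^t)
    vhat <- state$v[[k]] / (1 - beta2^t)
    fp[[k]] <- fp[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = unflatten_params(fp, params), state = state)
}

unflatten_params <- function(flat, skeleton, prefix = "") {
  if (is.list(skeleton)) {
    nm <- names(skeleton)
    if (is.null(nm)) nm <- as.character(seq_along(skeleton))
    out <- skeleton
    for (i in seq_along(skeleton))
      out[[i]] <- unflatten_params(flat, skeleton[[i]],
                                   paste0(prefix, ".", nm[i]))
    out
  } else {
    flat[[prefix]]
  }
}

# ---- training -----------------------------------------------------------

weighted_ce <- function(probs, y_idx, cw) {
  -mean(cw[y_idx] * log(pmax(probs[cbind(seq_along(y_idx), y_idx)], 1e-12)))
}

#' Train the multiset transformer
#'
#' Minibatch Adam on class-weighted cross-entropy (inverse-frequency
#' weights guard against the strong case/control imbalance of typical
#' cohorts). A stratified fraction of the training samples is held out
#' for early stopping on validation loss; the best-validation parameters
#' are restored. All randomness (shuffling, dropout) derives from the
#' configuration seed.
#'
#' @param net An initialized `dysbio_net`.
#' @param samples List of token-input samples (see [build_batch()]).
#' @param labels Character vector of labels aligned with `samples`.
#' @param verbose Print per-epoch losses.
#' @return The trained `dysbio_net`, with `$history` (per-epoch train /
#'   validation loss).
#' @export
train_net <- function(net, samples, labels, verbose = FALSE) {
  cfg <- net$config
  y_idx <- match(labels, cfg$labels)
  if (anyNA(y_idx)) stop("labels outside the configured label set")
  n_cls <- length(cfg$labels)
  freq <- tabulate(y_idx, n_cls)
  cw <- sum(freq) / (n_cls * pmax(freq, 1))

  with_seed(cfg$seed + 1L, {
    n <- length(samples)
    val_idx <- integer(0)
    if (cfg$val_frac > 0 && n >= 20) {
      for (c in seq_len(n_cls)) {
        ic <- which(y_idx == c)
        nv <- max(1, round(length(ic) * cfg$val_frac))
        val_idx <- c(val_idx, sample(ic, nv))
      }
    }
    tr_idx <- setdiff(seq_len(n), val_idx)
    val_batch <- if (length(val_idx) > 0) build_batch(samples[val_idx])

    state <- adam_init(net$params)
    best <- list(loss = Inf, params = net$params, epoch = 0)
    hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_loss = numeric(0))
    wait <- 0
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(tr_idx)
      ep_loss <- 0; nb <- 0
      for (b0 in seq(1, length(ord), by = cfg$batch_size)) {
        ib <- ord[b0:min(b0 + cfg$batch_size - 1, length(ord))]
        batch <- build_batch(samples[ib])
        fwd <- net_forward(net, batch, training = TRUE)
        yb <- y_idx[ib]
        loss <- weighted_ce(fwd$probs, yb, cw)
        one <- matrix(0, length(ib), n_cls)
        one[cbind(seq_along(ib), yb)] <- 1
        dlogits <- (fwd$probs - one) * cw[yb] / length(ib)
        grads <- net_backward(net, fwd, dlogits)
        upd <- adam_step(net$params, grads, state, cfg$lr)
        net$params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + loss; nb <- nb + 1
      }
      vl <- NA_real_
      if (!is.null(val_batch)) {
        vf <- net_forward(net, val_batch)
        vl <- weighted_ce(vf$probs, y_idx[val_idx], cw)
        if (vl < best$loss - 1e-5) {
          best <- list(loss = vl, params = net$params, epoch = ep)
          wait <- 0
        } else wait <- wait + 1
      }
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                     val_loss = vl))
      if (verbose) message(sprintf("epoch %3d  train %.4f  val %s", ep,
                                   ep_loss / nb, format(vl, digits = 4)))
      if (!is.null(val_batch) && wait >= cfg$patience) break
    }
    if (!is.null(val_batch) && is.finite(best$loss))
      net$params <- best$params
    net$history <- hist
    net
  })
}

#' Predict class probabilities for a list of samples
#' @param net Trained `dysbio_net`.
#' @param samples List of token-input samples.
#' @return Matrix (n x labels) of probabilities.
#' @export
predict_net <- function(net, samples) {
  net_forward(net, build_batch(samples))$probs
}
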