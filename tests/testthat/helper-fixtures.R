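# shared fixtures, all generated in code

tiny_counts <- function() {
  m <- matrix(c(2, 3, 5,
                0, 1, 4), nrow = 2, byrow = TRUE,
              dimnames = list(c("taxA", "taxB"),
                              c("s1", "s2", "s3")))
  count_table(m)
}

tiny_meta <- function() {
  validate_metadata(data.frame(
    sample_id = c("s1", "s2", "s3"),
    study_id = c("st1", "st1", "st2"),
    label = c("control", "disease", "control"),
    stringsAsFactors = FALSE))
}

# brute-force patristic distances by path enumeration over the edge list
brute_force_patristic <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  adj <- vector("list", n_node)
  for (k in seq_len(nrow(tree$edge))) {
    a <- tree$edge[k, 1]; b <- tree$edge[k, 2]; w <- tree$edge.length[k]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  dist_from <- function(src) {
    d <- rep(NA_real_, n_node)
    d[src] <- 0
    queue <- src
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (r in seq_len(NROW(adj[[v]]))) {
        u <- adj[[v]][r, 1]
        if (is.na(d[u])) {
          d[u] <- d[v] + adj[[v]][r, 2]
          queue <- c(queue, u)
        }
      }
    }
    d
  }
  D <- matrix(0, n_tip, n_tip,
              dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n_tip)) D[i, ] <- dist_from(i)[seq_len(n_tip)]
  D
}

# random token-input samples for model tests
random_samples <- function(n_samples, feature_dim, max_tokens = 8,
                           seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_samples), function(i) {
    n <- sample(2:max_tokens, 1)
    list(e = matrix(rnorm(n * feature_dim), n, feature_dim),
         w = runif(n, 0.05, 1),
         taxa = sprintf("t%02d", sample(50, n)))
  })
}

small_net <- function(feature_dim = 5, seed = 11, dropout = 0) {
  cfg <- net_config(token_dim = 8, sab_layers = 2, n_heads = 2,
                    pma_seeds = 3, dropout = dropout, ffn_hidden = 10,
                    head_hidden = 6, seed = seed)
  init_net(cfg, feature_dim)
}
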