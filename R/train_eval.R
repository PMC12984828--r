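#' Build a cross-validation fold plan
#'
#' Two split modes. `stratified`: samples of each class are shuffled and
#' dealt round-robin into `n_folds` folds, preserving the class ratio per
#' fold to within one sample (5 folds = 80/20 splits). `leave_study_out`:
#' whole studies are held out -- no study ever appears on both sides of a
#' fold -- testing cross-cohort generalization; with `n_folds` equal to
#' the number of studies each fold's test set is exactly one study,
#' otherwise studies are packed into folds by a balanced greedy rule.
#'
#' @param meta `sample_metadata`.
#' @param mode `"stratified"` or `"leave_study_out"`.
#' @param n_folds Number of folds (default 5; for `leave_study_out`,
#'   `NULL` means one fold per study).
#' @param seed RNG seed; fixed seed gives an identical plan.
#' @return A `fold_plan`: list of folds, each with `train` and `test`
#'   sample-ID vectors.
#' @export
make_folds <- function(meta, mode = c("stratified", "leave_study_out"),
                       n_folds = 5, seed = 42L) {
  mode <- match.arg(mode)
  ids <- meta$sample_id
  folds <- vector("list", 0)
  if (mode == "stratified") {
    if (any(table(meta$label) < n_folds))
      stop("every class needs >= n_folds samples for stratified folds")
    assign <- integer(length(ids))
    with_seed(seed, {
      for (lab in unique(meta$label)) {
        il <- which(meta$label == lab)
        il <- il[sample.int(length(il))]
        assign[il] <- rep_len(seq_len(n_folds), length(il))
      }
    })
    folds <- lapply(seq_len(n_folds), function(k)
      list(train = ids[assign != k], test = ids[assign == k]))
  } else {
    studies <- unique(meta$study_id)
    if (is.null(n_folds)) n_folds <- length(studies)
    if (length(studies) < n_folds)
      stop("need >= n_folds studies for leave_study_out folds")
    sizes <- table(meta$study_id)[studies]
    ord <- order(-as.numeric(sizes))
    group <- integer(length(studies))
    tot <- numeric(n_folds)
    with_seed(seed, {
      for (i in ord) {
        k <- which.min(tot)
        group[i] <- k
        tot[k] <- tot[k] + sizes[i]
      }
    })
    folds <- lapply(seq_len(n_folds), function(k) {
      test_st <- studies[group == k]
      list(train = ids[!meta$study_id %in% test_st],
           test = ids[meta$study_id %in% test_st])
    })
  }
  structure(list(mode = mode, n_folds = n_folds, seed = seed,
                 folds = folds), class = "fold_plan")
}

#' Assert that a fitted object saw none of the test samples
#'
#' The structural leakage guard: every fitted object carries the sample
#' IDs it was estimated on; any overlap with a test set is a hard error.
#'
#' @param fitted_on Character vector of fitted-on sample IDs (or an
#'   object with a `fitted_on` element).
#' @param test_ids Test sample IDs.
#' @param what Label used in the error message.
#' @return Invisibly TRUE.
#' @export
assert_no_leakage <- function(fitted_on, test_ids, what = "fitted object") {
  if (is.list(fitted_on)) fitted_on <- fitted_on$fitted_on
  bad <- intersect(fitted_on, test_ids)
  if (length(bad) > 0)
    stop("leakage: ", what, " was fitted on test sample(s) ",
         paste(utils::head(bad, 3), collapse = ", "),
         if (length(bad) > 3) " ..." else "")
  invisible(TRUE)
}

#' Classification metrics from probabilities
#'
#' Binary metrics at threshold 0.5 (prediction = positive when the
#' positive-class probability is >= 0.5) plus the rank-statistic AUC
#' (Mann-Whitney with midrank ties). Multiclass inputs are macro-averaged
#' one-vs-rest.
#'
#' @param y_true Character labels.
#' @param y_prob Probability matrix with one column per label (or a
#'   vector of positive-class probabilities for the binary case).
#' @param labels Label set; the last is the positive class.
#' @return Named list: accuracy, precision, recall, f1, auc.
#' @export
compute_metrics <- function(y_true, y_prob,
                            labels = c("control", "disease")) {
  if (is.matrix(y_prob)) {
    if (length(labels) > 2) {
      per <- lapply(labels, function(lab) {
        binary_metrics(as.integer(y_true == lab), y_prob[, lab])
      })
      out <- as.list(colMeans(do.call(rbind, lapply(per, unlist))))
      return(out)
    }
    p <- y_prob[, labels[2]]
  } else p <- y_prob
  binary_metrics(as.integer(y_true == labels[2]), p)
}

binary_metrics <- function(y, p) {
  pred <- as.integer(p >= 0.5)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  auc <- if (n1 == 0 || n0 == 0) {
    warning("single-class y_true: AUC undefined")
    NA_real_
  } else {
    r <- rank(p)
    (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  list(accuracy = mean(pred == y), precision = precision, recall = recall,
       f1 = f1, auc = auc)
}

#' Run one cross-validation fold end to end
#'
#' Leakage-safe orchestration: the CLR transform is a per-sample map; the
#' batch model, the token normalizer and the network are fitted on
#' training samples only and applied frozen to the test samples (test
#' studies unseen at fit time pass through the batch correction
#' unchanged). Fitted-on/test disjointness is asserted structurally.
#'
#' @param fold One element of a [make_folds()] plan.
#' @param counts `count_table`.
#' @param meta `sample_metadata`.
#' @param phylo `phylo_model` with features.
#' @param config `net_config`.
#' @param fold_seed Seed offset for this fold's network.
#' @return List with `metrics`, `probs`, `y_true`, trained `net`,
#'   `history`, `attribution` (importance report over the fold's
#'   training samples) and the fitted preprocessing states.
#' @export
run_fold <- function(fold, counts, meta, phylo, config, fold_seed = 0L) {
  if (length(intersect(fold$train, fold$test)) > 0)
    stop("leakage: fold train/test sets overlap")

  frac <- zero_replace(counts, config$delta)
  clr <- clr_transform(frac)

  sub_cm <- function(cm, ids) {
    composition_matrix(cm$values[, ids, drop = FALSE], cm$mode,
                       validate = FALSE)
  }
  clr_tr <- sub_cm(clr, fold$train)
  clr_te <- sub_cm(clr, fold$test)

  bm <- estimate_batch_params(clr_tr, meta, config$eb_lambda)
  assert_no_leakage(bm, fold$test, "batch model")
  clr_tr_c <- apply_batch_correction(clr_tr, bm, meta)
  clr_te_c <- apply_batch_correction(clr_te, bm, meta,
                                     unknown_batch = "identity")

  sub_ct <- function(ct, ids) count_table(ct$counts[, ids, drop = FALSE])
  toks_tr <- raw_token_features(clr_tr_c, sub_cm(frac, fold$train),
                                sub_ct(counts, fold$train), phylo)
  toks_te <- raw_token_features(clr_te_c, sub_cm(frac, fold$test),
                                sub_ct(counts, fold$test), phylo)

  norm <- fit_normalizer(toks_tr)
  assert_no_leakage(norm, fold$test, "token normalizer")
  toks_tr <- normalize_tokens(toks_tr, norm)
  toks_te <- normalize_tokens(toks_te, norm)

  cfg <- config
  cfg$seed <- config$seed + as.integer(fold_seed)
  net <- init_net(cfg, feature_dim = ncol(toks_tr[[1]]$e))
  y_tr <- meta$label[match(fold$train, meta$sample_id)]
  net <- train_net(net, toks_tr, y_tr)
  net$fitted_on <- fold$train
  assert_no_leakage(net, fold$test, "network")

  probs <- predict_net(net, toks_te)
  y_te <- meta$label[match(fold$test, meta$sample_id)]
  metrics <- compute_metrics(y_te, probs, config$labels)

  attribution <- taxon_importance(net, toks_tr, clr_tr_c, meta)

  list(metrics = metrics, probs = probs, y_true = y_te, net = net,
       history = net$history, attribution = attribution,
       batch_model = bm, normalizer = norm)
}

#' Study-aware cross-validated training and evaluation
#'
#' Runs [run_fold()] for every fold of the plan and aggregates: per-fold
#' metrics, their mean and SD (the reported headline numbers are the
#' arithmetic mean over folds), pooled test predictions, and the
#' per-fold attribution reports for stability selection.
#'
#' @param counts `count_table`.
#' @param meta `sample_metadata`.
#' @param tree `ape::phylo` (or `NULL` for the identity-phylogeny
#'   fallback).
#' @param config `net_config`.
#' @param mode Split mode, see [make_folds()].
#' @param n_folds Number of folds.
#' @param seed Seed for the fold plan.
#' @return A `cv_result`.
#' @export
run_cv <- function(counts, meta, tree, config,
                   mode = c("leave_study_out", "stratified"),
                   n_folds = 5, seed = 42L) {
  mode <- match.arg(mode)
  plan <- make_folds(meta, mode, n_folds, seed)
  m <- min(config$phylo_m, length(counts$taxa))
  phylo <- if (is.null(tree)) {
    phylo_identity(counts$taxa, m)
  } else {
    kernel_features(phylo_kernel(tree, counts$taxa), m)
  }
  fold_res <- lapply(seq_along(plan$folds), function(k) {
    run_fold(plan$folds[[k]], counts, meta, phylo, config, fold_seed = k)
  })
  mtab <- do.call(rbind, lapply(fold_res, function(fr)
    as.data.frame(fr$metrics)))
  pooled_probs <- do.call(rbind, lapply(fold_res, `[[`, "probs"))
  pooled_y <- unlist(lapply(fold_res, `[[`, "y_true"))
  structure(list(plan = plan, folds = fold_res, metrics = mtab,
                 mean = colMeans(mtab, na.rm = TRUE),
                 sd = apply(mtab, 2, stats::sd, na.rm = TRUE),
                 pooled = compute_metrics(pooled_y, pooled_probs,
                                          config$labels),
                 config = config),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d folds (%s)\n", x$plan$n_folds, x$plan$mode))
  m <- x$mean; s <- x$sd
  for (k in names(m))
    cat(sprintf("  %-9s %.3f +/- %.3f\n", k, m[k], s[k]))
  invisible(x)
}
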