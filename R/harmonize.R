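#' Estimate empirical-Bayes batch-correction parameters
#'
#' Per (taxon, batch) location/scale moments on CLR values, shrunk toward
#' the pooled cross-batch moments. Means are shrunk with prior weight
#' `lambda` pseudo-samples, `mu_hat_b = (n_b * mean_b + lambda * mu_pool) /
#' (n_b + lambda)`; variances are shrunk multiplicatively toward the pooled
#' variance with weight `lambda / (lambda + 1)`. The default `lambda =
#' 0.01` therefore performs near-standard location/scale correction; large
#' `lambda` collapses every batch onto the pooled moments (identity
#' correction). Disease labels never enter the fit.
#'
#' @param X `composition_matrix` in clr mode.
#' @param meta `sample_metadata` covering the samples of `X`.
#' @param lambda Shrinkage strength (>= 0), dimensionless.
#' @return A `batch_model`: per-batch shrunken means/SDs, raw batch means,
#'   pooled targets `mu_star`/`sigma_star`, and the fitted-on sample list
#'   (for leakage assertions).
#' @export
estimate_batch_params <- function(X, meta, lambda = 0.01) {
  stopifnot(inherits(X, "composition_matrix"))
  if (X$mode != "clr") stop("estimate_batch_params expects clr-mode input")
  if (lambda < 0) stop("lambda must be >= 0")
  idx <- match(X$samples, meta$sample_id)
  if (anyNA(idx)) stop("samples missing from metadata: ",
                       paste(X$samples[is.na(idx)][1], "..."))
  batch <- meta$study_id[idx]
  V <- X$values
  taxa <- X$taxa

  mu_pool <- rowMeans(V)
  var_pool <- apply(V, 1, stats::var)

  batches <- unique(batch)
  skipped <- character(0)
  mu_hat <- sd_hat <- mu_raw <- list()
  for (b in batches) {
    cols <- which(batch == b)
    if (length(cols) < 2) {
      warning("batch '", b, "' has < 2 samples; excluded from fitting ",
              "(identity correction will apply)")
      skipped <- c(skipped, b)
      next
    }
    n_b <- length(cols)
    m_b <- rowMeans(V[, cols, drop = FALSE])
    v_b <- apply(V[, cols, drop = FALSE], 1, stats::var)
    w <- lambda / (lambda + 1)
    mu_raw[[b]] <- m_b
    mu_hat[[b]] <- (n_b * m_b + lambda * mu_pool) / (n_b + lambda)
    sd_hat[[b]] <- sqrt(pmax((1 - w) * v_b + w * var_pool, 1e-12))
    sd_hat[[b]] <- pmax(sd_hat[[b]], 1e-6)
  }
  structure(list(taxa = taxa, batches = setdiff(batches, skipped),
                 skipped_batches = skipped,
                 mu_hat = mu_hat, sd_hat = sd_hat, mu_raw = mu_raw,
                 mu_star = mu_pool,
                 sigma_star = pmax(sqrt(pmax(var_pool, 0)), 1e-6),
                 lambda = lambda, fitted_on = X$samples),
            class = "batch_model")
}

#' @export
print.batch_model <- function(x, ...) {
  cat(sprintf("batch_model: %d taxa, %d batches (lambda = %g), fitted on %d samples\n",
              length(x$taxa), length(x$batches), x$lambda,
              length(x$fitted_on)))
  invisible(x)
}

#' Estimated location shift of one batch relative to another
#'
#' Difference of raw per-batch CLR means, averaged or per taxon; the
#' diagnostic used to check shift recovery on simulations.
#'
#' @param model `batch_model`.
#' @param batch,reference Batch IDs.
#' @return Named per-taxon vector of mean differences.
#' @export
estimated_batch_shift <- function(model, batch, reference) {
  stopifnot(inherits(model, "batch_model"))
  model$mu_raw[[batch]] - model$mu_raw[[reference]]
}

#' Apply a fitted batch correction
#'
#' `x_tilde = ((x - mu_hat_b) / sd_hat_b) * sigma_star + mu_star`, a
#' monotone affine map per (taxon, batch). A model fitted on training
#' samples may be applied to held-out samples (transform-only contract);
#' batches unseen at fit time either raise an error (default) or pass
#' through unchanged.
#'
#' @param X `composition_matrix` (clr mode).
#' @param model `batch_model`.
#' @param meta `sample_metadata` covering the samples of `X`.
#' @param unknown_batch `"error"` or `"identity"`.
#' @return Corrected `composition_matrix` (mode preserved; zero-sum is not
#'   re-imposed -- the correction is a per-taxon moment match).
#' @export
apply_batch_correction <- function(X, model, meta,
                                   unknown_batch = c("error", "identity")) {
  stopifnot(inherits(X, "composition_matrix"), inherits(model, "batch_model"))
  unknown_batch <- match.arg(unknown_batch)
  if (!identical(X$taxa, model$taxa)) stop("taxa order mismatch with model")
  idx <- match(X$samples, meta$sample_id)
  if (anyNA(idx)) stop("samples missing from metadata")
  batch <- meta$study_id[idx]
  V <- X$values
  out <- V
  for (b in unique(batch)) {
    cols <- which(batch == b)
    if (!b %in% model$batches) {
      if (unknown_batch == "error" && !b %in% model$skipped_batches)
        stop("batch '", b, "' unknown to the fitted model")
      next  # identity fallback
    }
    out[, cols] <- ((V[, cols, drop = FALSE] - model$mu_hat[[b]]) /
                      model$sd_hat[[b]]) * model$sigma_star + model$mu_star
  }
  composition_matrix(out, X$mode, validate = FALSE)
}

#' Moment-based batch alignment score
#'
#' Sum of squared differences between each batch's per-taxon (mean, SD)
#' and the pooled per-taxon (mean, SD); zero iff every batch's moments
#' coincide with the pooled moments. Lower is better aligned.
#'
#' @param X `composition_matrix` (clr mode).
#' @param meta `sample_metadata`.
#' @return List with `per_batch` (named vector) and `total`.
#' @export
alignment_score <- function(X, meta) {
  stopifnot(inherits(X, "composition_matrix"))
  idx <- match(X$samples, meta$sample_id)
  batch <- meta$study_id[idx]
  V <- X$values
  mu_g <- rowMeans(V)
  sd_g <- apply(V, 1, stats::sd)
  per_batch <- vapply(unique(batch), function(b) {
    cols <- which(batch == b)
    m_b <- rowMeans(V[, cols, drop = FALSE])
    s_b <- if (length(cols) >= 2)
      apply(V[, cols, drop = FALSE], 1, stats::sd) else sd_g
    sum((m_b - mu_g)^2) + sum((s_b - sd_g)^2)
  }, 0)
  list(per_batch = per_batch, total = sum(per_batch))
}
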