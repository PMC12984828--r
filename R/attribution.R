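#' Attention-derived taxon importance
#'
#' Aggregates the model's attention over a sample set into per-taxon
#' scores. `sab_score`: incoming attention mass of a taxon (column sums
#' of the row-softmaxed SAB attention, divided by the number of querying
#' tokens so samples of different richness are comparable), averaged over
#' layers, heads and the samples where the taxon is present -- how much
#' the community attends TO the taxon. `pma_score`: the taxon's mean PMA
#' seed affinity (gamma), averaged over seeds, heads and samples; per
#' sample and seed the gammas over present taxa sum to 1. The combined
#' score is the mean of the min-max-scaled components (their native
#' scales differ); ranks are dense over all taxa. The enrichment
#' direction is annotated from the data (sign of the case-minus-control
#' CLR mean), not from attention, which is magnitude-only.
#'
#' @param net Trained `dysbio_net`.
#' @param samples Token-input samples (normalized).
#' @param clr `composition_matrix` (clr mode) covering the same samples,
#'   for the direction annotation; `NULL` skips it.
#' @param meta `sample_metadata` (labels for the direction annotation).
#' @param positive Positive-class label for the direction sign.
#' @return An `attribution_report` data.frame: taxon, sab_score,
#'   pma_score, combined, rank, n_samples, direction.
#' @export
taxon_importance <- function(net, samples, clr = NULL, meta = NULL,
                             positive = "disease") {
  if (is.null(net$history))
    warning("model appears untrained; attribution scores are not meaningful")
  taxa_all <- sort(unique(unlist(lapply(samples, `[[`, "taxa"))))
  sab_sum <- pma_sum <- n_seen <- stats::setNames(numeric(length(taxa_all)),
                                                  taxa_all)
  # traced forward in manageable chunks
  chunk <- 64
  for (b0 in seq(1, length(samples), by = chunk)) {
    sl <- samples[b0:min(b0 + chunk - 1, length(samples))]
    fw <- net_forward(net, build_batch(sl), trace = TRUE)
    for (tr in fw$trace) {
      n <- length(tr$taxa)
      sab <- numeric(n)
      cnt <- 0
      for (lay in tr$sab) for (al in lay) {
        sab <- sab + colSums(al) / nrow(al)
        cnt <- cnt + 1
      }
      sab <- sab / cnt
      gam <- numeric(n)
      for (gh in tr$gamma) gam <- gam + colMeans(gh)
      gam <- gam / length(tr$gamma)
      sab_sum[tr$taxa] <- sab_sum[tr$taxa] + sab
      pma_sum[tr$taxa] <- pma_sum[tr$taxa] + gam
      n_seen[tr$taxa] <- n_seen[tr$taxa] + 1
    }
  }
  seen <- n_seen > 0
  sab_score <- ifelse(seen, sab_sum / pmax(n_seen, 1), 0)
  pma_score <- ifelse(seen, pma_sum / pmax(n_seen, 1), 0)
  minmax <- function(v) {
    rng <- range(v)
    if (diff(rng) < 1e-12) rep(0.5, length(v)) else (v - rng[1]) / diff(rng)
  }
  combined <- (minmax(sab_score) + minmax(pma_score)) / 2

  direction <- rep(NA_character_, length(taxa_all))
  if (!is.null(clr) && !is.null(meta)) {
    idx <- match(clr$samples, meta$sample_id)
    is_case <- meta$label[idx] == positive
    if (any(is_case) && any(!is_case)) {
      dmean <- rowMeans(clr$values[, is_case, drop = FALSE]) -
        rowMeans(clr$values[, !is_case, drop = FALSE])
      direction <- ifelse(dmean[taxa_all] >= 0, "enriched", "depleted")
    }
  }
  out <- data.frame(taxon = taxa_all, sab_score = sab_score,
                    pma_score = pma_score, combined = combined,
                    rank = rank(-combined, ties.method = "first"),
                    n_samples = as.integer(n_seen),
                    direction = direction,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$rank), ]
  class(out) <- c("attribution_report", "data.frame")
  out
}

#' Cross-fold stability selection of biomarkers
#'
#' Ranks taxa by how often they enter the top-`k` of the per-fold
#' attribution reports; ties are broken by the mean combined score.
#' Taxa missing from a fold's report count as non-members for that fold.
#'
#' @param reports List of `attribution_report`s (>= 2), one per fold.
#' @param k Top-k membership cutoff.
#' @return Data.frame: taxon, stability (membership frequency in [0,1]),
#'   mean_combined, ordered by stability then score.
#' @export
stability_selection <- function(reports, k = 10) {
  if (length(reports) < 2) stop("need >= 2 fold reports")
  taxa <- sort(unique(unlist(lapply(reports, `[[`, "taxon"))))
  member <- sapply(reports, function(r) {
    topk <- r$taxon[r$rank <= k]
    taxa %in% topk
  })
  score <- sapply(reports, function(r) {
    v <- unname(stats::setNames(r$combined, r$taxon)[taxa])
    ifelse(is.na(v), 0, v)
  })
  out <- data.frame(taxon = taxa,
                    stability = rowMeans(member),
                    mean_combined = rowMeans(score),
                    stringsAsFactors = FALSE)
  out[order(-out$stability, -out$mean_combined), ]
}
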