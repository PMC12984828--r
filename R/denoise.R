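#' Error model for amplicon denoising
#'
#' The per-base error probability is `exp(-alpha * Q)`, an exponential
#' decay in the Phred score; `alpha = log(10)/10` makes this coincide with
#' the standard Phred definition `10^(-Q/10)`. Substitution-only: an error
#' re-draws the base uniformly over the three alternatives.
#'
#' @param alpha Decay rate per Phred unit (> 0).
#' @param max_expected_errors Read-level filter threshold on the expected
#'   error count `sum_i exp(-alpha * Q_i)` (> 0).
#' @param omega Abundance p-value threshold below which a sequence is too
#'   abundant to be an error shadow of an existing center and founds a new
#'   ASV.
#' @return An `error_model` list.
#' @export
error_model <- function(alpha = log(10) / 10, max_expected_errors = 2.0,
                        omega = 1e-6) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (max_expected_errors <= 0) stop("max_expected_errors must be > 0")
  if (omega <= 0 || omega >= 1) stop("omega must be in (0, 1)")
  structure(list(alpha = alpha, max_expected_errors = max_expected_errors,
                 omega = omega), class = "error_model")
}

#' Per-base sequencing error probability
#'
#' `P(err) = exp(-alpha * Q)`, in (0, 1], monotone decreasing in Q.
#'
#' @param Q Phred score(s), >= 0.
#' @param alpha Decay rate (> 0).
#' @return Numeric vector of probabilities.
#' @export
error_probability <- function(Q, alpha = log(10) / 10) {
  if (any(Q < 0)) stop("Phred scores must be >= 0")
  if (alpha <= 0) stop("alpha must be > 0")
  exp(-alpha * Q)
}

#' Expected error count of each read
#' @param reads A [read_set()].
#' @param alpha Decay rate.
#' @return Numeric vector, one expected-error sum per read.
#' @export
expected_errors <- function(reads, alpha = log(10) / 10) {
  vapply(reads$quals, function(q) sum(error_probability(q, alpha)), 0)
}

#' Quality-filter a read set
#'
#' Keeps reads whose expected error count is at most
#' `model$max_expected_errors`.
#'
#' @param reads A [read_set()].
#' @param model An [error_model()].
#' @return Filtered `read_set` with attribute `retention` (fraction kept).
#' @export
filter_reads <- function(reads, model) {
  stopifnot(inherits(reads, "read_set"), inherits(model, "error_model"))
  ee <- expected_errors(reads, model$alpha)
  keep <- ee <= model$max_expected_errors
  out <- read_set(reads$ids[keep], reads$seqs[keep], reads$quals[keep])
  attr(out, "retention") <- mean(keep)
  out
}

#' Denoise reads into amplicon sequence variants
#'
#' Greedy abundance-ranked partitioning. Unique sequences are visited in
#' decreasing abundance (ties broken lexicographically). Each candidate is
#' scored against every existing same-length center by the read-error
#' likelihood `prod_mismatch p_i/3 * prod_match (1 - p_i)` with
#' `p_i = exp(-alpha * Q_i)` taken from the candidate's mean quality
#' profile. If the candidate's abundance is implausibly high under the
#' best center's error model -- Poisson tail
#' `P(X >= n_r), X ~ Poisson(n_center * p(r|center))` at most `omega` --
#' it founds a new center; otherwise its reads are absorbed. Ties in
#' center likelihood go to the more abundant center, then the
#' lexicographically smaller sequence. Read counts are conserved.
#'
#' @param reads Filtered [read_set()].
#' @param model [error_model()].
#' @param omega Override of `model$omega`.
#' @return An `asv_table`: `seqs`, named `counts`, `provenance` (read IDs
#'   per ASV) and an empty `removed` log.
#' @export
denoise_reads <- function(reads, model, omega = model$omega) {
  stopifnot(inherits(reads, "read_set"), inherits(model, "error_model"))
  n_reads <- length(reads$ids)
  if (n_reads == 0) {
    return(structure(list(seqs = character(0), counts = numeric(0),
                          provenance = list(), removed = character(0)),
                     class = "asv_table"))
  }
  uniq <- sort(unique(reads$seqs))
  ab <- vapply(uniq, function(s) sum(reads$seqs == s), 0)
  ord <- order(-ab, uniq)                    # abundance desc, then lexicographic
  uniq <- uniq[ord]; ab <- ab[ord]
  # mean quality profile per unique sequence
  qprof <- lapply(uniq, function(s) {
    qs <- reads$quals[reads$seqs == s]
    Reduce(`+`, qs) / length(qs)
  })

  centers <- integer(0)                      # indices into uniq
  assign_to <- integer(length(uniq))
  for (u in seq_along(uniq)) {
    if (length(centers) == 0) {
      centers <- u; assign_to[u] <- u; next
    }
    cand_len <- nchar(uniq[u])
    perr <- error_probability(qprof[[u]], model$alpha)
    best <- 0L; best_ll <- -Inf
    cand_chars <- strsplit(uniq[u], "")[[1]]
    for (ci in centers) {
      if (nchar(uniq[ci]) != cand_len) next
      mism <- strsplit(uniq[ci], "")[[1]] != cand_chars
      ll <- sum(log(ifelse(mism, perr / 3, 1 - perr)))
      better <- ll > best_ll + 1e-12 ||
        (abs(ll - best_ll) <= 1e-12 && best != 0L &&
           (ab[ci] > ab[best] ||
              (ab[ci] == ab[best] && uniq[ci] < uniq[best])))
      if (best == 0L || better) { best <- ci; best_ll <- ll }
    }
    if (best == 0L) {                        # no comparable center
      centers <- c(centers, u); assign_to[u] <- u; next
    }
    lam <- ab[best] * exp(best_ll)
    pval <- stats::ppois(ab[u] - 1, lam, lower.tail = FALSE)
    if (pval <= omega) {
      centers <- c(centers, u); assign_to[u] <- u
    } else {
      assign_to[u] <- best
    }
  }

  seqs <- uniq[centers]
  counts <- vapply(centers, function(ci) sum(ab[assign_to == ci]), 0)
  prov <- lapply(centers, function(ci) {
    members <- uniq[assign_to == ci]
    reads$ids[reads$seqs %in% members]
  })
  names(counts) <- seqs
  structure(list(seqs = seqs, counts = counts, provenance = prov,
                 removed = character(0)),
            class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("asv_table: %d ASVs, %s reads assigned, %d removed as chimeric\n",
              length(x$seqs), format(sum(x$counts), big.mark = ","),
              length(x$removed)))
  invisible(x)
}

identity_fraction <- function(a, b) {
  mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
}

#' Remove chimeric ASVs by two-parent split modeling
#'
#' An ASV is flagged chimeric when some split point partitions it into a
#' left segment matching one parent and a right segment matching a
#' different parent -- both parents at least `min_parent_fold` times more
#' abundant -- such that the combined two-parent identity exceeds the
#' ASV's best single-parent identity by at least `min_gain`. Flagged ASVs
#' are removed and logged in `$removed`.
#'
#' @param asvs An `asv_table`.
#' @param min_parent_fold Minimum parent/candidate abundance ratio.
#' @param min_gain Minimum identity improvement of the best split over the
#'   best single parent (identity fraction units).
#' @return The filtered `asv_table`.
#' @export
remove_chimeras <- function(asvs, min_parent_fold = 2, min_gain = 0.02) {
  stopifnot(inherits(asvs, "asv_table"))
  n <- length(asvs$seqs)
  if (n < 3) return(asvs)                    # need candidate + 2 parents
  flagged <- logical(n)
  chars <- lapply(asvs$seqs, function(s) strsplit(s, "")[[1]])
  for (i in seq_len(n)) {
    L <- length(chars[[i]])
    parents <- setdiff(which(asvs$counts >= min_parent_fold * asvs$counts[i] &
                               nchar(asvs$seqs) == L), i)
    if (length(parents) < 2) next
    # prefix match counts of candidate vs each parent
    pref <- vapply(parents, function(p) cumsum(chars[[p]] == chars[[i]]),
                   numeric(L))
    total <- pref[L, ]
    best_single <- max(total) / L
    splits <- seq_len(L - 1)
    suf <- sweep(-pref[splits, , drop = FALSE], 2, total, `+`)  # matches after split
    # exact max over ordered parent pairs (a != b) at every split point
    combined <- vapply(seq_along(splits), function(s) {
      l <- pref[splits[s], ]
      r <- suf[s, ]
      best <- -Inf
      for (a in seq_along(parents)) {
        rr <- r; rr[a] <- -Inf
        best <- max(best, l[a] + max(rr))
      }
      best / L
    }, 0)
    if (max(combined) >= best_single + min_gain) flagged[i] <- TRUE
  }
  removed <- asvs$seqs[flagged]
  structure(list(seqs = asvs$seqs[!flagged],
                 counts = asvs$counts[!flagged],
                 provenance = asvs$provenance[!flagged],
                 removed = c(asvs$removed, removed)),
            class = "asv_table")
}
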