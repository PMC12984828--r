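#' Composition matrix container
#'
#' Taxa-by-samples numeric matrix tagged with its mode: `fraction`
#' (strictly positive columns summing to 1), `clr` (columns summing to 0)
#' or `css` (cumulative-sum-scaled counts).
#'
#' @param values Numeric matrix with taxon rownames and sample colnames.
#' @param mode One of `"fraction"`, `"clr"`, `"css"`.
#' @param validate Check the mode invariant (column sums).
#' @return A `composition_matrix`.
#' @export
composition_matrix <- function(values, mode = c("fraction", "clr", "css"),
                               validate = TRUE) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (validate) {
    cs <- colSums(values)
    if (mode == "fraction" &&
        (any(abs(cs - 1) > 1e-9) || any(values <= 0)))
      stop("fraction mode requires strictly positive columns summing to 1")
    if (mode == "clr" && any(abs(cs) > 1e-9))
      stop("clr mode requires zero-sum columns")
  }
  structure(list(taxa = rownames(values), samples = colnames(values),
                 values = values, mode = mode),
            class = "composition_matrix")
}

#' @export
print.composition_matrix <- function(x, ...) {
  cat(sprintf("composition_matrix [%s]: %d taxa x %d samples\n",
              x$mode, length(x$taxa), length(x$samples)))
  invisible(x)
}

#' Zero replacement and closure to relative abundances
#'
#' Per sample, `x*_i = (x_i + delta) / sum_j (x_j + delta)`: every taxon
#' becomes strictly positive and each column sums to 1. An all-zero sample
#' degenerates to the uniform composition and is reported via the
#' `degenerate_samples` attribute.
#'
#' @param counts A [count_table()].
#' @param delta Pseudo-count (> 0); default `1e-6`.
#' @return `composition_matrix` in fraction mode.
#' @export
zero_replace <- function(counts, delta = 1e-6) {
  stopifnot(inherits(counts, "count_table"))
  if (delta <= 0) stop("delta must be > 0")
  x <- counts$counts + delta
  frac <- sweep(x, 2, colSums(x), "/")
  degen <- counts$samples[colSums(counts$counts) == 0]
  out <- composition_matrix(frac, "fraction")
  attr(out, "degenerate_samples") <- degen
  out
}

#' Cumulative sum scaling (CSS)
#'
#' Library-size normalization: each sample's counts are divided by the
#' cumulative sum of its sorted counts up to the per-sample `quantile`-th
#' count value, then multiplied by 1000. Reduces the influence of
#' high-count taxa on library-size differences.
#'
#' @param counts A [count_table()].
#' @param quantile Quantile in (0, 1); default 0.5.
#' @return `composition_matrix` in css mode. All-zero samples are scaled
#'   by 1 and reported via `degenerate_samples`.
#' @export
css_scale <- function(counts, quantile = 0.5) {
  stopifnot(inherits(counts, "count_table"))
  if (quantile <= 0 || quantile >= 1) stop("quantile must be in (0, 1)")
  x <- counts$counts
  scaled <- x
  degen <- character(0)
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    pos <- v[v > 0]
    if (length(pos) == 0) {
      degen <- c(degen, counts$samples[j])
      next
    }
    qv <- stats::quantile(pos, probs = quantile, type = 7, names = FALSE)
    denom <- sum(v[v <= qv])
    if (denom == 0) denom <- 1
    scaled[, j] <- v / denom * 1000
  }
  out <- composition_matrix(scaled, "css", validate = FALSE)
  attr(out, "degenerate_samples") <- degen
  out
}

#' Centered log-ratio transform
#'
#' `CLR(x_i) = ln(x_i / g(x))` with `g` the per-sample geometric mean.
#' Maps compositions to unconstrained coordinates; every column sums to
#' zero and the transform is invariant to positive scaling of a sample.
#'
#' @param x `composition_matrix` in fraction mode (strictly positive).
#' @return `composition_matrix` in clr mode.
#' @export
clr_transform <- function(x) {
  stopifnot(inherits(x, "composition_matrix"))
  if (x$mode != "fraction")
    stop("clr_transform expects fraction-mode input; run zero_replace first")
  if (any(x$values <= 0))
    stop("nonpositive entries; run zero_replace first")
  lx <- log(x$values)
  clr <- sweep(lx, 2, colMeans(lx), "-")
  composition_matrix(clr, "clr")
}

#' Counts to CLR in one call
#'
#' Convenience composition `clr_transform(zero_replace(counts, delta))`.
#'
#' @inheritParams zero_replace
#' @return `composition_matrix` in clr mode.
#' @export
counts_to_clr <- function(counts, delta = 1e-6) {
  clr_transform(zero_replace(counts, delta))
}
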