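#' Construct and validate a taxon-by-sample count table
#'
#' The count table is the raw input of the whole pipeline: an integer matrix
#' of sequence counts with taxa as rows and samples as columns.
#'
#' @param counts Non-negative integer matrix (taxa x samples) with unique
#'   rownames (taxon IDs) and colnames (sample IDs).
#' @return An object of class `count_table`: a list with elements `taxa`,
#'   `samples` and `counts`.
#' @export
count_table <- function(counts) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix")
  taxa <- rownames(counts)
  samples <- colnames(counts)
  if (is.null(taxa) || is.null(samples)) {
    stop("`counts` must carry taxon rownames and sample colnames")
  }
  if (anyDuplicated(taxa)) stop("duplicate taxon IDs: ",
                                paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  if (anyDuplicated(samples)) stop("duplicate sample IDs: ",
                                   paste(unique(samples[duplicated(samples)]), collapse = ", "))
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("invalid count at taxon '%s', sample '%s' (value %s)",
                 taxa[bad[1, 1]], samples[bad[1, 2]], counts[bad[1, 1], bad[1, 2]]))
  }
  storage.mode(counts) <- "double"  # keeps large depths exact, avoids int overflow in sums
  structure(list(taxa = taxa, samples = samples, counts = counts),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d taxa x %d samples, total reads %s\n",
              length(x$taxa), length(x$samples),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' Read a taxon-by-sample count table from TSV
#'
#' Expects a header row of sample IDs and a first column of taxon IDs; every
#' cell must be a non-negative integer. Row and column order are preserved.
#'
#' @param path Path to a tab-separated file.
#' @return A validated [count_table()].
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("count table needs a taxon ID column plus >= 1 sample column")
  taxa <- df[[1]]
  mat <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat),
                                 dimnames = list(taxa, colnames(mat))))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("invalid count '%s' at taxon '%s', sample '%s'",
                 mat[bad[1, 1], bad[1, 2]], taxa[bad[1, 1]],
                 colnames(mat)[bad[1, 2]]))
  }
  count_table(num)
}

#' Write a count table to TSV
#'
#' Inverse of [read_count_table()]; round-trips exactly.
#'
#' @param ct A `count_table`.
#' @param path Output path.
#' @export
write_count_table <- function(ct, path) {
  stopifnot(inherits(ct, "count_table"))
  df <- data.frame(taxon = ct$taxa, ct$counts, check.names = FALSE)
  utils::write.table(format(df, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import a BIOM-JSON table as a count table
#'
#' Thin converter onto the same dense model used by [read_count_table()];
#' requires the \pkg{biomformat} package. Dense and sparse BIOM-JSON both
#' work; BIOM-HDF5 is out of scope.
#'
#' @param path Path to a BIOM-JSON file.
#' @return A validated [count_table()].
#' @export
read_biom_counts <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("reading BIOM files requires the 'biomformat' package")
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")
  count_table(m)
}

#' Read per-sample metadata from TSV
#'
#' Mandatory columns: `sample_id`, `study_id`, `label`. Optional columns
#' `age`, `bmi`, `sex` are parsed when present; empty cells become `NA` and
#' are never imputed here.
#'
#' @param path Path to a tab-separated file.
#' @return A data.frame of class `sample_metadata` with attribute
#'   `label_set` (sorted unique labels).
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  validate_metadata(df)
}

#' Validate a metadata data.frame
#'
#' @param df data.frame with at least sample_id, study_id, label.
#' @return The validated data.frame, classed `sample_metadata`.
#' @export
validate_metadata <- function(df) {
  need <- c("sample_id", "study_id", "label")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("metadata missing mandatory column(s): ",
                             paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  if (any(is.na(df$study_id) | df$study_id == "")) stop("empty study_id in metadata")
  if (any(is.na(df$label) | df$label == "")) stop("empty label in metadata")
  for (col in c("age", "bmi")) {
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  }
  df$sample_id <- as.character(df$sample_id)
  df$study_id <- as.character(df$study_id)
  df$label <- as.character(df$label)
  attr(df, "label_set") <- sort(unique(df$label))
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Write sample metadata to TSV
#' @param meta `sample_metadata` data.frame.
#' @param path Output path.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Histogram of labels in a metadata table
#' @param meta `sample_metadata`.
#' @return Named integer vector of label counts.
#' @export
label_histogram <- function(meta) {
  table(meta$label)
}

#' Cross-check samples between a count table and metadata
#'
#' @param ct `count_table`.
#' @param meta `sample_metadata`.
#' @return List with `missing_in_meta` (samples in counts only) and
#'   `missing_in_counts` (samples in metadata only).
#' @export
check_sample_join <- function(ct, meta) {
  list(missing_in_meta = setdiff(ct$samples, meta$sample_id),
       missing_in_counts = setdiff(meta$sample_id, ct$samples))
}

#' Read a rooted phylogenetic tree from Newick
#'
#' Parses with \pkg{ape} and validates: unique leaf labels, non-negative
#' branch lengths.
#'
#' @param path Path to a Newick file.
#' @return An `ape::phylo` tree.
#' @export
read_tree <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("unparseable Newick: ", conditionMessage(e)))
  if (is.null(tree)) stop("unparseable Newick file: ", path)
  validate_tree(tree)
}

#' @rdname read_tree
#' @param tree An `ape::phylo` object to validate.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo tree")
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels in tree")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  tree
}

#' Write a tree to Newick
#' @param tree `ape::phylo`.
#' @param path Output path.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Patristic distance matrix of a tree
#'
#' Pairwise sum of branch lengths along the connecting path, for all leaves.
#'
#' @param tree `ape::phylo`.
#' @return Symmetric matrix with zero diagonal, dimnames = leaf labels.
#' @export
patristic_distances <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Construct a set of sequencing reads with Phred qualities
#'
#' @param ids Character vector of read identifiers.
#' @param seqs Character vector of sequences over A,C,G,T,N.
#' @param quals List of integer vectors of per-base Phred scores (>= 0),
#'   one per read, each the same length as its sequence.
#' @return Object of class `read_set`.
#' @export
read_set <- function(ids, seqs, quals) {
  stopifnot(length(ids) == length(seqs), length(seqs) == length(quals))
  nc <- nchar(seqs)
  ql <- lengths(quals)
  if (any(nc != ql)) {
    i <- which(nc != ql)[1]
    stop(sprintf("read '%s': sequence length %d != quality length %d",
                 ids[i], nc[i], ql[i]))
  }
  if (any(unlist(quals, use.names = FALSE) < 0)) stop("negative Phred score")
  structure(list(ids = as.character(ids), seqs = as.character(seqs),
                 quals = quals), class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d reads, lengths %s\n", length(x$ids),
              paste(range(nchar(x$seqs)), collapse = "-")))
  invisible(x)
}

#' @export
length.read_set <- function(x) length(x$ids)

#' Read a FASTQ file (Phred+33)
#'
#' Qualities are decoded to integers with the Phred+33 convention
#' ('!' = 0, 'I' = 40). Phred+64 files are rejected: a read whose quality
#' characters are all >= 'K' with none below ';' is assumed mis-encoded.
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return A [read_set()].
#' @export
read_fastq <- function(path) {
  sset <- Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred")
  seqs <- as.character(sset)
  qchars <- as.character(Biostrings::quality(sset))
  quals <- lapply(qchars, function(q) as.integer(utf8ToInt(q)) - 33L)
  allq <- unlist(quals, use.names = FALSE)
  if (length(allq) > 0 && min(allq) >= 42L) {
    stop("quality scores look Phred+64-encoded; only Phred+33 is supported")
  }
  read_set(names(sset), unname(seqs), unname(quals))
}

#' Write a read set to FASTQ (Phred+33)
#' @param rs `read_set`.
#' @param path Output path.
#' @export
write_fastq <- function(rs, path) {
  stopifnot(inherits(rs, "read_set"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(rs$ids)) {
    writeLines(c(paste0("@", rs$ids[i]), rs$seqs[i], "+",
                 intToUtf8(rs$quals[[i]] + 33L)), con)
  }
  invisible(path)
}
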