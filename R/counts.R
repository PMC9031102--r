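#' Isoform count matrix
#'
#' Container for non-negative integer read counts per transcript isoform
#' (rows) per sample (columns), with a parallel vector of gene symbols so
#' isoforms can be grouped by gene.
#'
#' @param counts integer matrix, isoforms x samples, non-negative.
#' @param isoform_ids character vector, one per row.
#' @param gene_ids character vector parallel to \code{isoform_ids}.
#' @param sample_ids character vector, one per column.
#' @return an object of class \code{isoform_counts}.
#' @export
isoform_counts <- function(counts, isoform_ids, gene_ids, sample_ids) {
  counts <- as.matrix(counts)
  if (length(isoform_ids) != nrow(counts))
    stop("isoform_ids length must equal nrow(counts)")
  if (length(gene_ids) != nrow(counts))
    stop("gene_ids length must equal nrow(counts)")
  if (length(sample_ids) != ncol(counts))
    stop("sample_ids length must equal ncol(counts)")
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(as.character(isoform_ids),
                           as.character(sample_ids))
  structure(list(counts = counts,
                 isoform_ids = as.character(isoform_ids),
                 gene_ids = as.character(gene_ids),
                 sample_ids = as.character(sample_ids)),
            class = "isoform_counts")
}

#' @export
print.isoform_counts <- function(x, ...) {
  cat(sprintf("isoform_counts: %d isoforms x %d samples (%d genes)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$gene_ids))))
  invisible(x)
}

#' @export
dim.isoform_counts <- function(x) dim(x$counts)

#' Filter isoforms detected in too few samples
#'
#' Removes isoforms with non-zero counts in fewer than \code{min_samples}
#' samples; with the default of 3 this drops isoforms detected in less than
#' three samples, the detection rule applied before model fitting.
#'
#' @param mat an \code{\link{isoform_counts}}.
#' @param min_samples minimum number of samples with a non-zero count for an
#'   isoform to be retained (default 3).
#' @return list with \code{retained} (an \code{isoform_counts}) and
#'   \code{excluded} (data.frame of \code{isoform_id}, \code{gene_id},
#'   \code{n_detected}).
#' @export
filter_low_detection <- function(mat, min_samples = 3) {
  stopifnot(inherits(mat, "isoform_counts"))
  if (min_samples < 1) stop("min_samples must be >= 1")
  if (nrow(mat$counts) == 0L) stop("empty count matrix")
  n_det <- rowSums(mat$counts > 0)
  keep <- n_det >= min_samples
  excluded <- data.frame(isoform_id = mat$isoform_ids[!keep],
                         gene_id = mat$gene_ids[!keep],
                         n_detected = as.integer(n_det[!keep]),
                         stringsAsFactors = FALSE)
  retained <- isoform_counts(mat$counts[keep, , drop = FALSE],
                             mat$isoform_ids[keep], mat$gene_ids[keep],
                             mat$sample_ids)
  list(retained = retained, excluded = excluded)
}

#' Read / write an isoform count matrix as TSV
#'
#' First two columns are \code{isoform_id} and \code{gene_id}; every further
#' column is one sample of integer counts.
#'
#' @param path file path.
#' @return \code{read_counts} returns an \code{\link{isoform_counts}}.
#' @export
read_counts <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                         comment.char = "#")
  if (!all(c("isoform_id", "gene_id") %in% names(d)[1:2]))
    stop("count table must start with columns isoform_id, gene_id")
  cnt <- as.matrix(d[, -(1:2), drop = FALSE])
  isoform_counts(cnt, d$isoform_id, d$gene_id, colnames(cnt))
}

#' @rdname read_counts
#' @param mat an \code{\link{isoform_counts}} to write.
#' @param header_comment optional character vector written as leading
#'   \code{#}-prefixed lines (run provenance).
#' @export
write_counts <- function(mat, path, header_comment = NULL) {
  stopifnot(inherits(mat, "isoform_counts"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  d <- data.frame(isoform_id = mat$isoform_ids, gene_id = mat$gene_ids,
                  mat$counts, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
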