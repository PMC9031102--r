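#' Classify one assembly-to-reference match
#'
#' Rules applied to a BLAST-style tabular match: \code{complete} means full
#' sequence identity with no gap openings over the whole subject
#' (percent identity = 100, gap openings = 0, alignment length = subject
#' length); \code{partial} means at least 95 percent identity with no gap
#' openings; anything else is \code{unmatched}. The subject-coverage
#' requirement on \code{complete} can be dropped with
#' \code{coverage_check = FALSE}, in which case 100 percent identity and no
#' gaps suffice regardless of alignment length.
#'
#' @param percent_identity in [0, 100].
#' @param gap_openings integer >= 0.
#' @param alignment_length integer > 0.
#' @param subject_length integer > 0.
#' @param coverage_check require full subject coverage for \code{complete}?
#' @return one of \code{"complete"}, \code{"partial"}, \code{"unmatched"}.
#' @export
classify_match <- function(percent_identity, gap_openings, alignment_length,
                           subject_length, coverage_check = TRUE) {
  if (percent_identity < 0 || percent_identity > 100)
    stop("percent_identity must be in [0, 100]")
  if (gap_openings < 0) stop("gap_openings must be >= 0")
  if (alignment_length <= 0 || subject_length <= 0)
    stop("alignment and subject lengths must be positive")
  covered <- !coverage_check || alignment_length == subject_length
  if (percent_identity == 100 && gap_openings == 0 && covered) "complete"
  else if (percent_identity >= 95 && gap_openings == 0) "partial"
  else "unmatched"
}

class_rank <- c(unmatched = 0L, partial = 1L, complete = 2L)

#' Summarize detection frequency per gene and group
#'
#' For each subject gene and treatment-by-region group: the number of samples
#' whose best match (complete > partial > unmatched) reaches each class, and
#' the percentage of the group's samples in which the gene was detected
#' (best class partial or better). Samples with no match to a gene count as
#' class \code{none}.
#'
#' @param matches data.frame with columns \code{query_id}, \code{subject_id},
#'   \code{gene_id}, \code{percent_identity}, \code{gap_openings},
#'   \code{alignment_length}, \code{subject_length}, \code{sample_id}.
#' @param design a \code{\link{sample_design}}; every \code{sample_id} in
#'   \code{matches} must appear in it.
#' @param coverage_check passed to \code{\link{classify_match}}.
#' @param genes optional gene universe; genes without any match are reported
#'   as all-none rows. Defaults to the genes present in \code{matches}.
#' @return data.frame with one row per gene x group: \code{gene_id},
#'   \code{treatment}, \code{region}, \code{n_samples}, \code{n_complete},
#'   \code{n_partial}, \code{n_none}, \code{percent_detected}.
#' @export
summarize_detection <- function(matches, design, coverage_check = TRUE,
                                genes = NULL) {
  stopifnot(inherits(design, "sample_design"))
  if (nrow(matches) > 0) {
    bad <- setdiff(unique(matches$sample_id), design$sample_id)
    if (length(bad))
      stop("unknown sample_id(s) in match table: ", paste(bad, collapse = ", "))
    matches$class <- vapply(seq_len(nrow(matches)), function(i) {
      classify_match(matches$percent_identity[i], matches$gap_openings[i],
                     matches$alignment_length[i], matches$subject_length[i],
                     coverage_check = coverage_check)
    }, character(1))
  }
  genes <- sort(unique(c(genes,
                         if (nrow(matches) > 0) matches$gene_id)))
  groups <- unique(design[, c("treatment", "region")])
  out <- do.call(rbind, lapply(genes, function(g) {
    do.call(rbind, lapply(seq_len(nrow(groups)), function(k) {
      sel <- design$treatment == groups$treatment[k] &
        design$region == groups$region[k]
      samp <- design$sample_id[sel]
      best <- vapply(samp, function(s) {
        cl <- matches$class[matches$gene_id == g & matches$sample_id == s]
        if (length(cl) == 0L) "none"
        else cl[which.max(class_rank[cl])]
      }, character(1))
      n_complete <- sum(best == "complete")
      n_partial <- sum(best == "partial")
      n_none <- sum(best %in% c("none", "unmatched"))
      data.frame(gene_id = g, treatment = groups$treatment[k],
                 region = groups$region[k], n_samples = length(samp),
                 n_complete = n_complete, n_partial = n_partial,
                 n_none = n_none,
                 percent_detected = 100 * (n_complete + n_partial) /
                   length(samp),
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(out))
    out <- data.frame(gene_id = character(0), treatment = character(0),
                      region = character(0), n_samples = integer(0),
                      n_complete = integer(0), n_partial = integer(0),
                      n_none = integer(0), percent_detected = numeric(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read BLAST tabular matches (outfmt 6)
#'
#' Standard 12-column tabular output (\code{qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore}), joined with a
#' subject-length table and a query-to-sample map.
#'
#' @param path BLAST tabular file (no header).
#' @param subject_lengths data.frame with \code{subject_id},
#'   \code{subject_length}, and \code{gene_id}.
#' @param sample_of_query function mapping query ids to sample ids, or a
#'   named character vector.
#' @return match data.frame suitable for \code{\link{summarize_detection}}.
#' @export
read_blast_matches <- function(path, subject_lengths, sample_of_query) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 12) stop("expected 12 tab-separated BLAST outfmt 6 columns")
  names(d)[1:12] <- cols
  idx <- match(d$sseqid, subject_lengths$subject_id)
  if (any(is.na(idx)))
    stop("subject id(s) missing from subject_lengths: ",
         paste(unique(d$sseqid[is.na(idx)]), collapse = ", "))
  sample_id <- if (is.function(sample_of_query)) {
    vapply(d$qseqid, sample_of_query, character(1))
  } else {
    unname(sample_of_query[d$qseqid])
  }
  data.frame(query_id = d$qseqid, subject_id = d$sseqid,
             gene_id = subject_lengths$gene_id[idx],
             percent_identity = d$pident, gap_openings = d$gapopen,
             alignment_length = d$length,
             subject_length = subject_lengths$subject_length[idx],
             sample_id = sample_id, stringsAsFactors = FALSE)
}
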