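#' Construct a 2x2 sample design table
#'
#' Describes the treatment-by-region layout of the experiment: each sample is
#' assigned to a treatment group (\code{NTG}, nitroglycerin-elicited
#' hyperalgesia, or \code{CON}, saline control) and a brain region
#' (\code{NAc}, nucleus accumbens, or \code{TG}, trigeminal ganglia), with an
#' optional library-size factor used to build model offsets.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param treatment character vector, each \code{"NTG"} or \code{"CON"}.
#' @param region character vector, each \code{"NAc"} or \code{"TG"}.
#' @param lib_size positive numeric library-size factors (default all 1).
#'
#' @return A \code{data.frame} of class \code{sample_design} with columns
#'   \code{sample_id}, \code{treatment}, \code{region}, \code{lib_size}.
#' @export
sample_design <- function(sample_id, treatment, region,
                          lib_size = rep(1, length(sample_id))) {
  sample_id <- as.character(sample_id)
  treatment <- as.character(treatment)
  region <- as.character(region)
  n <- length(sample_id)
  if (length(treatment) != n || length(region) != n || length(lib_size) != n)
    stop("sample_id, treatment, region and lib_size must have equal length")
  if (anyDuplicated(sample_id))
    stop("sample_ids must be unique")
  if (!all(treatment %in% c("NTG", "CON")))
    stop("treatment must be 'NTG' or 'CON'")
  if (!all(region %in% c("NAc", "TG")))
    stop("region must be 'NAc' or 'TG'")
  if (!is.numeric(lib_size) || any(!is.finite(lib_size)) || any(lib_size <= 0))
    stop("lib_size must be positive and finite")
  cells <- table(treatment, region)
  if (length(cells) < 4L || any(cells == 0L))
    stop("every treatment x region cell must contain at least one sample")
  out <- data.frame(sample_id = sample_id, treatment = treatment,
                    region = region, lib_size = as.numeric(lib_size),
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_design", "data.frame")
  out
}

#' Balanced default design
#'
#' Convenience constructor for the balanced 2x2 layout of the study: two
#' treatments crossed with two regions, \code{replicates_per_cell} samples in
#' each of the four cells (default 5, i.e. 20 samples).
#'
#' @param replicates_per_cell integer >= 1.
#' @return a \code{\link{sample_design}}.
#' @export
default_design <- function(replicates_per_cell = 5) {
  stopifnot(replicates_per_cell >= 1)
  grid <- expand.grid(rep = seq_len(replicates_per_cell),
                      region = c("TG", "NAc"), treatment = c("CON", "NTG"),
                      stringsAsFactors = FALSE)
  sample_design(
    sample_id = sprintf("%s_%s_%d", grid$treatment, grid$region, grid$rep),
    treatment = grid$treatment, region = grid$region
  )
}

#' Model matrix for the 2x2 design
#'
#' Reference cell is CON x TG, so that \code{exp(beta_treatment)} is the
#' NTG/CON fold change and \code{exp(beta_region)} the NAc/TG fold change,
#' matching the fold-change reporting convention of the analysis.
#'
#' @param design a \code{\link{sample_design}}.
#' @param include_interaction include the treatment:region column?
#' @return numeric model matrix with named columns, rows in design order.
#' @export
design_matrix <- function(design, include_interaction = TRUE) {
  trt <- as.numeric(design$treatment == "NTG")
  reg <- as.numeric(design$region == "NAc")
  X <- cbind(intercept = 1, treatment = trt, region = reg)
  if (include_interaction)
    X <- cbind(X, interaction = trt * reg)
  rownames(X) <- design$sample_id
  X
}

#' Library-size offsets
#'
#' Natural-log offsets o_j = log(lib_size_j / geometric mean lib_size), so a
#' constant library size yields zero offsets and the intercept stays on the
#' per-average-library scale.
#'
#' @param design a \code{\link{sample_design}}.
#' @param mode \code{"libsize"} for geometric-mean-centred log factors,
#'   \code{"none"} for all-zero offsets.
#' @return numeric vector of per-sample offsets.
#' @export
design_offsets <- function(design, mode = c("libsize", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(rep(0, nrow(design)))
  ls <- design$lib_size
  log(ls) - mean(log(ls))
}

#' Read / write a design table as TSV
#'
#' Plain tab-separated columns \code{sample_id}, \code{treatment},
#' \code{region}, \code{lib_size}.
#'
#' @param path file path.
#' @return \code{read_design} returns a \code{\link{sample_design}}.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "treatment", "region", "lib_size")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("design table missing column(s): ", paste(miss, collapse = ", "))
  sample_design(d$sample_id, d$treatment, d$region, d$lib_size)
}

#' @rdname read_design
#' @param design a \code{\link{sample_design}} to write.
#' @export
write_design <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
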