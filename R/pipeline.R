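#' Run the differential-isoform-expression stage
#'
#' Filter, fit, test, adjust, categorize: isoforms detected in fewer than
#' \code{min_samples} samples are removed; each remaining isoform is fitted
#' with the ZINB model under the full (interaction) and additive mean models;
#' likelihood-ratio tests are computed for the interaction (full vs
#' additive), the treatment and region main effects (within the additive
#' model, or within the full model for isoforms whose interaction survives
#' FDR screening), and excess zeros (ZINB vs NB, boundary mixture null);
#' p-values are BH-adjusted per effect family across isoforms; each isoform
#' is assigned one result category.
#'
#' @param counts an \code{\link{isoform_counts}}.
#' @param design a \code{\link{sample_design}} covering the count columns.
#' @param q_interaction,q_main significance thresholds passed to
#'   \code{\link{categorize_results}}.
#' @param min_samples detection filter threshold.
#' @param offsets \code{"libsize"} or \code{"none"}
#'   (see \code{\link{design_offsets}}).
#' @param verbose log per-category counts to stderr.
#' @return list with \code{results} (long data.frame: one row per isoform x
#'   effect with \code{isoform_id, gene_id, effect, lr_stat, df, p_value,
#'   q_value, fold_change, direction, category, converged}),
#'   \code{categories}, \code{excluded}, and \code{category_counts}.
#' @export
run_de <- function(counts, design, q_interaction = 0.10, q_main = 0.05,
                   min_samples = 3, offsets = "libsize", verbose = FALSE) {
  stopifnot(inherits(counts, "isoform_counts"),
            inherits(design, "sample_design"))
  if (!identical(counts$sample_ids, design$sample_id)) {
    extra <- setdiff(counts$sample_ids, design$sample_id)
    missing <- setdiff(design$sample_id, counts$sample_ids)
    if (length(extra) || length(missing))
      stop("count/design sample mismatch; counts-only: [",
           paste(extra, collapse = ", "), "]; design-only: [",
           paste(missing, collapse = ", "), "]")
    counts$counts <- counts$counts[, design$sample_id, drop = FALSE]
    counts$sample_ids <- design$sample_id
  }
  flt <- filter_low_detection(counts, min_samples)
  mat <- flt$retained
  n_iso <- nrow(mat$counts)
  if (n_iso == 0L) {
    if (verbose) message("0 isoforms analyzed after detection filter")
    return(list(results = NULL, categories = NULL, excluded = flt$excluded,
                category_counts = integer(0)))
  }
  o <- design_offsets(design, offsets)
  X_full <- design_matrix(design, include_interaction = TRUE)
  X_add <- design_matrix(design, include_interaction = FALSE)

  rows <- vector("list", n_iso)
  fits_full <- vector("list", n_iso)
  for (i in seq_len(n_iso)) {
    y <- mat$counts[i, ]
    full <- fit_zinb(y, X_full, o)
    add <- fit_zinb(y, X_add, o)
    add_nt <- fit_zinb(y, X_add[, c("intercept", "region"), drop = FALSE], o)
    add_nr <- fit_zinb(y, X_add[, c("intercept", "treatment"),
                                drop = FALSE], o)
    tests <- rbind(test_effect(full, add, "interaction"),
                   test_effect(add, add_nt, "treatment"),
                   test_effect(add, add_nr, "region"),
                   test_zero_inflation(full, full$nb_fit))
    tests$isoform_id <- mat$isoform_ids[i]
    tests$gene_id <- mat$gene_ids[i]
    rows[[i]] <- tests
    fits_full[[i]] <- full
  }
  res <- do.call(rbind, rows)

  # interaction screening pass: for interaction-significant isoforms, retest
  # main effects within the full model
  res$q_value <- NA_real_
  for (eff in unique(res$effect)) {
    sel <- res$effect == eff
    res$q_value[sel] <- bh_adjust(res$p_value[sel])
  }
  int_sig <- res$isoform_id[res$effect == "interaction" &
                              !is.na(res$q_value) &
                              res$q_value < q_interaction]
  if (length(int_sig)) {
    for (id in int_sig) {
      i <- match(id, mat$isoform_ids)
      y <- mat$counts[i, ]
      full <- fits_full[[i]]
      f_nt <- fit_zinb(y, X_full[, c("intercept", "region", "interaction"),
                                 drop = FALSE], o)
      f_nr <- fit_zinb(y, X_full[, c("intercept", "treatment", "interaction"),
                                 drop = FALSE], o)
      for (eff in c("treatment", "region")) {
        new <- test_effect(full, if (eff == "treatment") f_nt else f_nr, eff)
        sel <- res$isoform_id == id & res$effect == eff
        res[sel, c("lr_stat", "df", "p_value", "fold_change", "direction",
                   "converged")] <-
          new[, c("lr_stat", "df", "p_value", "fold_change", "direction",
                  "converged")]
      }
    }
    for (eff in c("treatment", "region")) {
      sel <- res$effect == eff
      res$q_value[sel] <- bh_adjust(res$p_value[sel])
    }
  }

  cats <- categorize_results(res[res$effect %in%
                                   c("treatment", "region", "interaction"), ],
                             q_interaction, q_main)
  res$category <- cats$category[match(res$isoform_id, cats$isoform_id)]
  res <- res[, c("isoform_id", "gene_id", "effect", "lr_stat", "df",
                 "p_value", "q_value", "fold_change", "direction",
                 "category", "converged")]
  counts_by_cat <- table(cats$category)
  if (verbose)
    message(sprintf("%d isoforms analyzed; categories: %s", n_iso,
                    paste(names(counts_by_cat), counts_by_cat,
                          sep = "=", collapse = ", ")))
  list(results = res, categories = cats, excluded = flt$excluded,
       category_counts = counts_by_cat)
}

# Restrict an event's group count vectors to samples from one region.
stratify_event <- function(event, design, region) {
  if (is.null(event$sample_ids_group1) || is.null(event$sample_ids_group2))
    stop("event lacks per-sample ids; cannot stratify")
  keep1 <- design$region[match(event$sample_ids_group1,
                               design$sample_id)] == region
  keep2 <- design$region[match(event$sample_ids_group2,
                               design$sample_id)] == region
  splicing_event(event$event_id, event$gene_id, event$event_type,
                 event$ijc_group1[keep1], event$sjc_group1[keep1],
                 event$ijc_group2[keep2], event$sjc_group2[keep2],
                 event$inc_form_len, event$skip_form_len,
                 event$count_mode,
                 event$sample_ids_group1[keep1],
                 event$sample_ids_group2[keep2])
}

#' Run the differential-splicing stage
#'
#' Tests every event with the beta-binomial likelihood-ratio test, adjusts
#' p-values by BH (pooled across event types by default, or within each
#' type), and tallies significant events by type. With \code{strata = TRUE}
#' and a design carrying the events' sample ids, the comparison is repeated
#' within each region (joint, NAc-only, TG-only).
#'
#' @param events list of \code{\link{splicing_event}}.
#' @param q_threshold significance threshold for the tally.
#' @param family \code{"pooled"} (one BH family) or \code{"per_type"}.
#' @param strata run region-stratified comparisons as well?
#' @param design required when \code{strata = TRUE}.
#' @return list of per-comparison lists (\code{joint}, and \code{NAc},
#'   \code{TG} when stratified), each with \code{results} and \code{tally}.
#' @export
run_splice <- function(events, q_threshold = 0.10, family = "pooled",
                       strata = FALSE, design = NULL) {
  run_one <- function(evs) {
    res <- do.call(rbind, lapply(evs, test_differential_psi))
    res$q_value <- NA_real_
    if (family == "per_type") {
      for (ty in unique(res$event_type)) {
        sel <- res$event_type == ty
        res$q_value[sel] <- bh_adjust(res$p_value[sel])
      }
    } else {
      res$q_value <- bh_adjust(res$p_value)
    }
    list(results = res,
         tally = tally_event_types(res, evs, q_threshold))
  }
  out <- list(joint = run_one(events))
  if (strata) {
    if (is.null(design)) stop("strata = TRUE requires a design")
    for (rg in c("NAc", "TG"))
      out[[rg]] <- run_one(lapply(events, stratify_event,
                                  design = design, region = rg))
  }
  out
}

#' Run the match-classification stage
#'
#' Classifies every match and summarizes detection per gene and
#' treatment-by-region group.
#'
#' @param matches match data.frame (see \code{\link{summarize_detection}}).
#' @param design a \code{\link{sample_design}}.
#' @param coverage_check passed to \code{\link{classify_match}}.
#' @return the detection summary data.frame.
#' @export
run_classify <- function(matches, design, coverage_check = TRUE) {
  summarize_detection(matches, design, coverage_check)
}

#' Simulate and write a full synthetic dataset
#'
#' Writes the count matrix, design table, per-isoform truth table and
#' splicing-event tables to \code{out_dir}, plus a JSON manifest recording
#' the package version, seed and configuration.
#'
#' @param config a \code{\link{sim_config}}.
#' @param splice_config a \code{\link{splice_sim_config}} or NULL.
#' @param out_dir output directory (must exist).
#' @return invisible named vector of written paths.
#' @export
run_simulate <- function(config, splice_config = NULL, out_dir) {
  if (!dir.exists(out_dir)) stop("output directory does not exist: ", out_dir)
  sim <- simulate_counts(config)
  hdr <- sprintf("zinbsplice %s; seed=%d",
                 as.character(utils::packageVersion("zinbsplice")),
                 config$seed)
  paths <- c(counts = file.path(out_dir, "counts.tsv"),
             design = file.path(out_dir, "design.tsv"),
             truth = file.path(out_dir, "truth.tsv"),
             manifest = file.path(out_dir, "manifest.json"))
  write_counts(sim$counts, paths["counts"], header_comment = hdr)
  write_design(sim$design, paths["design"])
  write_truth(sim$truth, paths["truth"])
  manifest <- list(package = "zinbsplice",
                   version = as.character(utils::packageVersion("zinbsplice")),
                   seed = config$seed,
                   config = config[setdiff(names(config),
                                           "library_size_factors")])
  if (!is.null(splice_config)) {
    evs <- simulate_splicing(splice_config, sim$design)
    paths["splicing"] <- file.path(out_dir,
                                   sprintf("%s.MATS.JC.txt",
                                           splice_config$event_type))
    write_splicing_events(evs, paths["splicing"])
    write_truth(attr(evs, "truth"),
                file.path(out_dir, "splicing_truth.tsv"))
    manifest$splice_config <- unclass(splice_config)
  }
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Write the long-format expression results table
#'
#' @param results data.frame from \code{\link{run_de}}.
#' @param path file path.
#' @param header_comment optional provenance comment lines.
#' @export
write_de_results <- function(results, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.table(results, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the splicing results table
#'
#' Columns \code{event_id, type, psi1, psi2, inc_level_diff, lr_stat,
#' p_value, q_value}.
#'
#' @param results per-comparison results from \code{\link{run_splice}}.
#' @param path file path.
#' @export
write_splice_results <- function(results, path) {
  out <- data.frame(event_id = results$event_id, type = results$event_type,
                    psi1 = results$psi1, psi2 = results$psi2,
                    inc_level_diff = results$inc_level_diff,
                    lr_stat = results$lr_stat, p_value = results$p_value,
                    q_value = results$q_value, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
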