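#' Configuration for the isoform-count simulator
#'
#' Defines a zero-inflated negative binomial (ZINB) generating process on a
#' 2x2 treatment-by-region design. Counts for sample j are 0 with probability
#' \code{zero_inflation} (structural zeros) and otherwise NB2 with mean
#' mu_j = baseline_mean * exp(design effects) * size factor and variance
#' mu_j + dispersion * mu_j^2, so sampling zeros also arise from the NB part.
#'
#' Defaults emulate the study layout: 5 replicates per cell (20 samples), a
#' moderately expressed isoform, moderate overdispersion and zero inflation.
#'
#' @param n_isoforms number of isoforms to simulate.
#' @param replicates_per_cell samples per treatment x region cell.
#' @param baseline_mean expected count at the reference cell (CON x TG).
#' @param log_fc_treatment,log_fc_region,log_fc_interaction natural-log fold
#'   changes; scalars or vectors of length \code{n_isoforms}.
#' @param dispersion NB2 dispersion alpha >= 0 (0 = Poisson limit).
#' @param zero_inflation structural-zero probability pi in [0, 1).
#' @param library_size_factors positive per-sample factors, or NULL for 1.
#' @param seed integer RNG seed.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(n_isoforms = 100, replicates_per_cell = 5,
                       baseline_mean = 50,
                       log_fc_treatment = 0, log_fc_region = 0,
                       log_fc_interaction = 0,
                       dispersion = 0.5, zero_inflation = 0.2,
                       library_size_factors = NULL, seed = 1L) {
  chk <- function(ok, field)
    if (!ok) stop("invalid simulation config field: ", field)
  chk(is.numeric(n_isoforms) && n_isoforms >= 1, "n_isoforms")
  chk(is.numeric(replicates_per_cell) && replicates_per_cell >= 2,
      "replicates_per_cell")
  chk(is.numeric(baseline_mean) && baseline_mean > 0, "baseline_mean")
  chk(is.numeric(dispersion) && all(dispersion >= 0), "dispersion")
  chk(is.numeric(zero_inflation) && all(zero_inflation >= 0) &&
        all(zero_inflation < 1), "zero_inflation")
  if (!is.null(library_size_factors))
    chk(all(library_size_factors > 0), "library_size_factors")
  structure(list(n_isoforms = as.integer(n_isoforms),
                 replicates_per_cell = as.integer(replicates_per_cell),
                 baseline_mean = baseline_mean,
                 log_fc_treatment = log_fc_treatment,
                 log_fc_region = log_fc_region,
                 log_fc_interaction = log_fc_interaction,
                 dispersion = dispersion,
                 zero_inflation = zero_inflation,
                 library_size_factors = library_size_factors,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw zero-inflated negative binomial deviates
#'
#' Mixture draw: 0 with probability \code{pi}, otherwise NB2(mu, alpha);
#' alpha = 0 falls back to Poisson sampling.
#'
#' @param n number of draws.
#' @param mu positive mean(s) of the count component.
#' @param alpha NB2 dispersion >= 0.
#' @param pi structural-zero probability in [0, 1).
#' @return integer-valued numeric vector.
#' @export
rzinb <- function(n, mu, alpha, pi) {
  stopifnot(all(mu > 0), all(alpha >= 0), all(pi >= 0), all(pi < 1))
  y <- if (all(alpha == 0)) stats::rpois(n, lambda = mu)
       else stats::rnbinom(n, size = 1 / pmax(alpha, 1e-12), mu = mu)
  y[stats::runif(n) < pi] <- 0
  y
}

#' Simulate an isoform count matrix with known truth
#'
#' Generates \code{config$n_isoforms} ZINB count rows over the samples of
#' \code{design}. Every generating value is recorded in the returned
#' \code{truth} table so estimators can be checked against it.
#'
#' @param config a \code{\link{sim_config}}.
#' @param design a \code{\link{sample_design}}; defaults to the balanced
#'   layout implied by \code{config$replicates_per_cell}.
#' @return list with \code{counts} (an \code{\link{isoform_counts}}),
#'   \code{design}, and \code{truth} (data.frame of per-isoform generating
#'   parameters).
#' @export
simulate_counts <- function(config, design = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(design)) design <- default_design(config$replicates_per_cell)
  stopifnot(inherits(design, "sample_design"))
  n_s <- nrow(design)
  n_i <- config$n_isoforms
  rep_len_ <- function(v) rep_len(v, n_i)
  lfc_t <- rep_len_(config$log_fc_treatment)
  lfc_r <- rep_len_(config$log_fc_region)
  lfc_i <- rep_len_(config$log_fc_interaction)
  alpha <- rep_len_(config$dispersion)
  pi0 <- rep_len_(config$zero_inflation)
  sf <- config$library_size_factors
  if (is.null(sf)) sf <- rep(1, n_s)
  if (length(sf) != n_s) stop("library_size_factors length != n samples")
  design$lib_size <- sf

  X <- design_matrix(design, include_interaction = TRUE)
  set.seed(config$seed)
  counts <- matrix(0, n_i, n_s)
  for (i in seq_len(n_i)) {
    beta <- c(log(config$baseline_mean), lfc_t[i], lfc_r[i], lfc_i[i])
    mu <- exp(drop(X %*% beta)) * sf
    counts[i, ] <- rzinb(n_s, mu, alpha[i], pi0[i])
  }
  ids <- sprintf("ISO%05d", seq_len(n_i))
  genes <- sprintf("GENE%04d", (seq_len(n_i) - 1L) %/% 3L + 1L)
  truth <- data.frame(isoform_id = ids, gene_id = genes,
                      baseline_mean = config$baseline_mean,
                      log_fc_treatment = lfc_t, log_fc_region = lfc_r,
                      log_fc_interaction = lfc_i,
                      dispersion = alpha, zero_inflation = pi0,
                      stringsAsFactors = FALSE)
  list(counts = isoform_counts(counts, ids, genes, design$sample_id),
       design = design, truth = truth)
}

#' Configuration for the splicing-event simulator
#'
#' Per sample, a fixed total of junction reads is split between the inclusion
#' and skipping forms of an event. The inclusion count is beta-binomial with
#' mean f(psi_g) = lI*psi / (lI*psi + lS*(1-psi)) for the sample's group g —
#' the length-biased probability that a junction read supports inclusion when
#' the true inclusion level is psi — and intra-group overdispersion rho.
#'
#' @param n_events number of events.
#' @param psi_group1,psi_group2 true inclusion levels in [0, 1]; scalars or
#'   vectors of length \code{n_events}.
#' @param intra_group_dispersion rho in [0, 1); 0 = binomial sampling.
#' @param total_junction_reads_per_sample positive integer n per sample.
#' @param inc_form_len,skip_form_len positive effective lengths lI, lS.
#' @param event_type one of SE, A3SS, A5SS, MXE, RI.
#' @param seed integer RNG seed.
#' @return a \code{splice_sim_config} list.
#' @export
splice_sim_config <- function(n_events = 50, psi_group1 = 0.5,
                              psi_group2 = 0.5,
                              intra_group_dispersion = 0.01,
                              total_junction_reads_per_sample = 100,
                              inc_form_len = 2, skip_form_len = 1,
                              event_type = "SE", seed = 1L) {
  chk <- function(ok, field)
    if (!ok) stop("invalid splicing sim config field: ", field)
  chk(is.numeric(n_events) && n_events >= 1, "n_events")
  chk(all(psi_group1 >= 0 & psi_group1 <= 1), "psi_group1")
  chk(all(psi_group2 >= 0 & psi_group2 <= 1), "psi_group2")
  chk(intra_group_dispersion >= 0 && intra_group_dispersion < 1,
      "intra_group_dispersion")
  chk(total_junction_reads_per_sample >= 1,
      "total_junction_reads_per_sample")
  chk(inc_form_len > 0 && skip_form_len > 0, "form lengths")
  chk(event_type %in% c("SE", "A3SS", "A5SS", "MXE", "RI"), "event_type")
  structure(list(n_events = as.integer(n_events),
                 psi_group1 = psi_group1, psi_group2 = psi_group2,
                 intra_group_dispersion = intra_group_dispersion,
                 total_junction_reads_per_sample =
                   as.integer(total_junction_reads_per_sample),
                 inc_form_len = inc_form_len, skip_form_len = skip_form_len,
                 event_type = event_type, seed = as.integer(seed)),
            class = "splice_sim_config")
}

#' Beta-binomial deviates (mean / overdispersion parameterization)
#'
#' @param n number of draws.
#' @param size number of trials.
#' @param m mean probability in [0, 1].
#' @param rho overdispersion in [0, 1); 0 gives binomial draws.
#' @return integer vector of successes.
#' @export
rbetabinom <- function(n, size, m, rho) {
  stopifnot(m >= 0, m <= 1, rho >= 0, rho < 1)
  if (rho == 0 || m == 0 || m == 1)
    return(stats::rbinom(n, size, m))
  s <- (1 - rho) / rho
  p <- stats::rbeta(n, m * s, (1 - m) * s)
  stats::rbinom(n, size, p)
}

#' Simulate splicing events with known truth
#'
#' Groups are the two treatment levels of \code{design} (group 1 = NTG,
#' group 2 = CON). Inclusion counts follow the beta-binomial model of
#' \code{\link{splice_sim_config}}; skipping counts are the remainder.
#'
#' @param config a \code{\link{splice_sim_config}}.
#' @param design a \code{\link{sample_design}}; defaults to the balanced 2x2
#'   layout with 5 replicates per cell.
#' @return list of \code{splicing_event} objects (see
#'   \code{\link{splicing_event}}) with a \code{truth} attribute.
#' @export
simulate_splicing <- function(config, design = default_design(5)) {
  stopifnot(inherits(config, "splice_sim_config"),
            inherits(design, "sample_design"))
  g1 <- design$treatment == "NTG"
  psi1 <- rep_len(config$psi_group1, config$n_events)
  psi2 <- rep_len(config$psi_group2, config$n_events)
  lI <- config$inc_form_len
  lS <- config$skip_form_len
  ntot <- config$total_junction_reads_per_sample
  rho <- config$intra_group_dispersion
  f <- function(psi) lI * psi / (lI * psi + lS * (1 - psi))
  set.seed(config$seed)
  events <- vector("list", config$n_events)
  for (i in seq_len(config$n_events)) {
    i1 <- rbetabinom(sum(g1), ntot, f(psi1[i]), rho)
    i2 <- rbetabinom(sum(!g1), ntot, f(psi2[i]), rho)
    events[[i]] <- splicing_event(
      event_id = sprintf("EV%05d", i),
      gene_id = sprintf("GENE%04d", i),
      event_type = config$event_type,
      ijc_group1 = i1, sjc_group1 = ntot - i1,
      ijc_group2 = i2, sjc_group2 = ntot - i2,
      inc_form_len = lI, skip_form_len = lS,
      sample_ids_group1 = design$sample_id[g1],
      sample_ids_group2 = design$sample_id[!g1])
  }
  attr(events, "truth") <- data.frame(
    event_id = sprintf("EV%05d", seq_len(config$n_events)),
    psi_group1 = psi1, psi_group2 = psi2, rho = rho,
    stringsAsFactors = FALSE)
  events
}

#' Write simulation truth table as a sidecar TSV
#'
#' @param truth data.frame of generating parameters.
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
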