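# Independent oracle implementations used to check the package's optimizers
# and summaries. Written directly from the probability definitions, not by
# calling the package's own likelihood code.

# ZINB log-likelihood of a count vector under an intercept-only mean model,
# evaluated directly from the mixture definition with gamma functions.
oracle_zinb_ll <- function(y, b0, alpha, pi) {
  mu <- exp(b0)
  r <- 1 / alpha
  lognb <- lgamma(y + r) - lgamma(r) - lgamma(y + 1) +
    r * (log(r) - log(r + mu)) + y * (log(mu) - log(r + mu))
  p <- (1 - pi) * exp(lognb)
  p[y == 0] <- p[y == 0] + pi
  sum(log(p))
}

# Coarse-to-fine grid maximization of the intercept-only ZINB likelihood.
oracle_zinb_grid <- function(y, n_refine = 3) {
  m <- max(mean(y), 0.2)
  b_grid <- seq(log(m) - 2, log(m) + 2, length.out = 41)
  # alpha grid reaches the Poisson boundary: the likelihood is flat in
  # log-alpha below ~1e-6, so the boundary is represented by tiny values
  a_grid <- exp(seq(log(1e-7), log(10), length.out = 51))
  p_grid <- seq(1e-8, 0.9, length.out = 46)
  best <- c(NA, NA, NA); best_ll <- -Inf
  eval_grid <- function(bs, as, ps) {
    g <- expand.grid(b = bs, a = as, p = ps)
    ll <- numeric(nrow(g))
    for (j in seq_along(y)) {
      mu <- exp(g$b); r <- 1 / g$a
      lognb <- lgamma(y[j] + r) - lgamma(r) - lgamma(y[j] + 1) +
        r * (log(r) - log(r + mu)) + y[j] * (log(mu) - log(r + mu))
      pj <- (1 - g$p) * exp(lognb)
      if (y[j] == 0) pj <- pj + g$p
      ll <- ll + log(pj)
    }
    k <- which.max(ll)
    list(par = c(g$b[k], g$a[k], g$p[k]), ll = ll[k],
         steps = c(bs[2] - bs[1], as[2] / as[1], ps[2] - ps[1]))
  }
  res <- eval_grid(b_grid, a_grid, p_grid)
  for (r in seq_len(n_refine)) {
    b0 <- res$par[1]; a0 <- res$par[2]; p0 <- res$par[3]
    db <- res$steps[1]; ra <- res$steps[2]; dp <- res$steps[3]
    bs <- seq(b0 - db, b0 + db, length.out = 21)
    as <- exp(seq(log(a0) - log(ra), log(a0) + log(ra), length.out = 21))
    as <- pmax(as, 1e-8)
    ps <- seq(max(p0 - dp, 1e-8), min(p0 + dp, 0.999), length.out = 21)
    res <- eval_grid(bs, as, ps)
  }
  res
}

# Beta-binomial log-likelihood of grouped inclusion counts, straight from the
# beta-binomial pmf with a = m*(1-rho)/rho, b = (1-m)*(1-rho)/rho, where the
# mean m is the length-biased inclusion probability.
oracle_bb_ll <- function(i1, n1, i2, n2, psi1, psi2, rho, lI, lS) {
  f <- function(psi) lI * psi / (lI * psi + lS * (1 - psi))
  one <- function(k, n, m) {
    s <- (1 - rho) / rho
    a <- m * s; b <- (1 - m) * s
    sum(lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b))
  }
  one(i1, n1, f(psi1)) + one(i2, n2, f(psi2))
}

# Grid maximization over (psi1, psi2, rho); the likelihood separates in psi1
# and psi2 given rho, so each rho value costs two 1-D scans.
oracle_bb_grid <- function(i1, n1, i2, n2, lI, lS,
                           psi_step = 1e-3, rho_max = 0.6) {
  psis <- seq(psi_step, 1 - psi_step, by = psi_step)
  # rho grid reaches the binomial boundary (likelihood flat below ~1e-6)
  rhos <- c(1e-8, 1e-6, 1e-5, 1e-4, 3e-4, seq(psi_step, rho_max,
                                              by = psi_step))
  f <- lI * psis / (lI * psis + lS * (1 - psis))
  best_ll <- -Inf; best <- c(NA, NA, NA)
  for (rho in rhos) {
    s <- (1 - rho) / rho
    a <- f * s; b <- (1 - f) * s
    ll1 <- rep(0, length(psis)); ll2 <- rep(0, length(psis))
    for (j in seq_along(i1))
      ll1 <- ll1 + lchoose(n1[j], i1[j]) + lbeta(i1[j] + a, n1[j] - i1[j] + b) -
        lbeta(a, b)
    for (j in seq_along(i2))
      ll2 <- ll2 + lchoose(n2[j], i2[j]) + lbeta(i2[j] + a, n2[j] - i2[j] + b) -
        lbeta(a, b)
    k1 <- which.max(ll1); k2 <- which.max(ll2)
    if (ll1[k1] + ll2[k2] > best_ll) {
      best_ll <- ll1[k1] + ll2[k2]
      best <- c(psis[k1], psis[k2], rho)
    }
  }
  list(par = best, ll = best_ll)
}

# Brute-force per-sample best-class detection summary: for every gene, group
# and sample, scan all matches and take the maximum class.
oracle_detection <- function(matches, design, classify_fun) {
  rank <- c(none = -1, unmatched = 0, partial = 1, complete = 2)
  genes <- sort(unique(matches$gene_id))
  groups <- unique(design[, c("treatment", "region")])
  out <- list()
  for (g in genes) for (k in seq_len(nrow(groups))) {
    samp <- design$sample_id[design$treatment == groups$treatment[k] &
                               design$region == groups$region[k]]
    best <- character(0)
    for (s in samp) {
      rows <- which(matches$gene_id == g & matches$sample_id == s)
      cls <- "none"
      for (r in rows) {
        c_r <- classify_fun(matches$percent_identity[r],
                            matches$gap_openings[r],
                            matches$alignment_length[r],
                            matches$subject_length[r])
        if (rank[c_r] > rank[cls]) cls <- c_r
      }
      best <- c(best, cls)
    }
    out[[length(out) + 1L]] <- data.frame(
      gene_id = g, treatment = groups$treatment[k],
      region = groups$region[k], n_samples = length(samp),
      n_complete = sum(best == "complete"),
      n_partial = sum(best == "partial"),
      n_none = sum(best %in% c("none", "unmatched")),
      percent_detected = 100 * mean(best %in% c("complete", "partial")),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Random synthetic BLAST-style match table with labels drawn to hit all three
# classes.
random_match_table <- function(design, n_genes = 5, n_matches = 60) {
  genes <- sprintf("G%02d", seq_len(n_genes))
  slen <- sample(200:1000, n_genes, replace = TRUE)
  idx <- sample(n_genes, n_matches, replace = TRUE)
  samp <- sample(design$sample_id, n_matches, replace = TRUE)
  kind <- sample(c("complete", "partial", "bad_ident", "gapped", "short"),
                 n_matches, replace = TRUE)
  pid <- ifelse(kind == "complete", 100,
         ifelse(kind == "partial", round(runif(n_matches, 95, 99.9), 2),
         ifelse(kind == "bad_ident", round(runif(n_matches, 50, 94.9), 2),
                100)))
  gap <- ifelse(kind == "gapped", sample(1:3, n_matches, replace = TRUE), 0)
  alen <- ifelse(kind %in% c("short"), pmax(30, slen[idx] - 50), slen[idx])
  data.frame(query_id = sprintf("q%03d", seq_len(n_matches)),
             subject_id = paste0("ref_", genes[idx]),
             gene_id = genes[idx], percent_identity = pid,
             gap_openings = gap, alignment_length = alen,
             subject_length = slen[idx], sample_id = samp,
             stringsAsFactors = FALSE)
}
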