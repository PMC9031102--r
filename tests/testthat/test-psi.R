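test_that("psi follows its length-adjusted definition", {
  # symmetric: equal length-normalized counts
  expect_equal(psi(10, 20, 1, 2), 0.5)
  # degenerate
  expect_equal(psi(0, 5, 2, 1), 0)
  expect_equal(psi(5, 0, 2, 1), 1)
  # hand case: (30/2) / (30/2 + 10/1) = 15/25
  expect_equal(psi(30, 10, 2, 1), 0.6)
  # no informative reads: undefined, never 0
  expect_true(is.na(psi(0, 0, 2, 1)))
  # monotone non-decreasing in ijc for fixed sjc and lengths
  v <- psi(0:50, 10, 2, 1)
  expect_true(all(diff(v) >= 0))
  expect_error(psi(-1, 3, 2, 1))
  expect_error(psi(1, 3, 0, 1))
})

test_that("default effective lengths reflect junction multiplicity", {
  expect_equal(default_effective_lengths("SE", "junction"), c(2, 1))
  expect_equal(default_effective_lengths("MXE", "junction"), c(2, 2))
  expect_equal(default_effective_lengths("A3SS", "junction"), c(1, 1))
  expect_equal(default_effective_lengths("A5SS", "junction"), c(1, 1))
  expect_equal(default_effective_lengths("RI", "junction"), c(2, 1))
  expect_error(default_effective_lengths("RI", "exon"), "user-supplied")
  expect_error(default_effective_lengths("XX", "junction"), "event_type")
})

test_that("beta-binomial likelihood reduces to binomial as rho -> 0", {
  k <- c(0, 3, 7, 10); n <- rep(10, 4)
  for (m in c(0.2, 0.5, 0.9)) {
    expect_lt(max(abs(betabinom_logpmf(k, n, m, 1e-9) -
                        dbinom(k, n, m, log = TRUE))), 1e-6)
  }
  # normalization at rho > 0
  expect_equal(sum(exp(betabinom_logpmf(0:20, 20, 0.3, 0.2))), 1,
               tolerance = 1e-10)
})

test_that("identical groups give a null differential-splicing result", {
  ijc <- c(30, 40, 35, 38, 32); sjc <- c(10, 12, 9, 11, 10)
  ev <- splicing_event("e1", "g1", "SE", ijc, sjc, ijc, sjc)
  r <- test_differential_psi(ev)
  expect_true(r$testable)
  expect_equal(r$inc_level_diff, 0, tolerance = 1e-6)
  expect_lt(r$lr_stat, 1e-3)
  expect_gt(r$p_value, 0.97)
})

test_that("events with too few informative samples are flagged untestable", {
  ev <- splicing_event("e1", "g1", "SE", c(10, 0, 0), c(5, 0, 0),
                       c(8, 9, 7), c(3, 4, 5))
  r <- test_differential_psi(ev)
  expect_false(r$testable)
  expect_true(is.na(r$p_value))
})

test_that("beta-binomial optimizer reaches the grid-search optimum", {
  set.seed(30)
  for (k in 1:4) {
    i1 <- rbetabinom(2, 60, runif(1, 0.2, 0.8), 0.05)
    i2 <- rbetabinom(2, 60, runif(1, 0.2, 0.8), 0.05)
    ev <- splicing_event("e", "g", "SE", i1, 60 - i1, i2, 60 - i2,
                         inc_form_len = 2, skip_form_len = 1)
    r <- test_differential_psi(ev)
    grid <- oracle_bb_grid(i1, c(60, 60), i2, c(60, 60), 2, 1)
    ll_fit <- oracle_bb_ll(i1, c(60, 60), i2, c(60, 60),
                           r$psi1, r$psi2, r$rho, 2, 1)
    expect_lt(abs(ll_fit - grid$ll), 1e-3)
  }
})

test_that("strong splicing differences are detected with high power", {
  d <- default_design(5)
  cfg <- splice_sim_config(n_events = 40, psi_group1 = 0.9, psi_group2 = 0.1,
                           intra_group_dispersion = 0.01,
                           total_junction_reads_per_sample = 500, seed = 31)
  res <- do.call(rbind, lapply(simulate_splicing(cfg, d),
                               test_differential_psi))
  expect_gte(mean(res$p_value < 1e-6), 0.95)
  expect_true(all(res$inc_level_diff > 0.5))
})

test_that("event-type tallies match direct counting", {
  mk <- function(id, type) splicing_event(id, paste0("g", id), type,
                                          c(5, 6), c(2, 3), c(4, 7), c(3, 2))
  evs <- list(mk("1", "SE"), mk("2", "SE"), mk("3", "SE"), mk("4", "A3SS"))
  res <- data.frame(event_id = c("1", "2", "3", "4"),
                    q_value = c(0.01, 0.02, 0.03, 0.04))
  tl <- tally_event_types(res, evs, q_threshold = 0.10)
  expect_equal(tl$significant$n[tl$significant$event_type == "SE"], 3L)
  expect_equal(tl$significant$percent[tl$significant$event_type == "SE"], 75)
  expect_equal(tl$significant$percent[tl$significant$event_type == "A3SS"], 25)
  # nothing significant: all-zero tally
  res0 <- transform(res, q_value = 0.5)
  tl0 <- tally_event_types(res0, evs, q_threshold = 0.10)
  expect_true(all(tl0$significant$n == 0))
  # independent groupby oracle on a random set
  set.seed(32)
  types <- sample(c("SE", "A3SS", "A5SS", "MXE", "RI"), 100, replace = TRUE)
  evs2 <- lapply(seq_along(types), function(i) mk(as.character(i), types[i]))
  q <- runif(100)
  tl2 <- tally_event_types(data.frame(event_id = as.character(seq_len(100)),
                                      q_value = q), evs2, 0.10)
  ref <- table(factor(types[q < 0.10], levels = tl2$significant$event_type))
  expect_equal(tl2$significant$n, as.integer(ref))
})

test_that("splicing-event tables round-trip through the TSV layout", {
  d <- default_design(2)
  cfg <- splice_sim_config(n_events = 4, psi_group1 = 0.7, psi_group2 = 0.3,
                           seed = 33)
  evs <- simulate_splicing(cfg, d)
  path <- tempfile(fileext = ".txt")
  write_splicing_events(evs, path)
  back <- read_splicing_events(path, "SE")
  expect_equal(length(back), 4L)
  expect_equal(back[[2]]$ijc_group1, evs[[2]]$ijc_group1)
  expect_equal(back[[2]]$skip_form_len, evs[[2]]$skip_form_len)
  # malformed table: missing column named in the error
  d2 <- utils::read.delim(path)
  d2$IJC_SAMPLE_1 <- NULL
  path2 <- tempfile(fileext = ".txt")
  utils::write.table(d2, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_splicing_events(path2, "SE"), "IJC_SAMPLE_1")
})
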