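test_that("zinb_logpmf matches its mixture definition", {
  # pi = 0 degenerates to the plain NB2 pmf
  y <- 0:20
  expect_equal(zinb_logpmf(y, mu = 3, alpha = 0.7, pi = 0),
               dnbinom(y, size = 1 / 0.7, mu = 3, log = TRUE))
  # all mass at zero: positive counts are impossible
  expect_identical(zinb_logpmf(1, mu = 2, alpha = 1, pi = 1), -Inf)
  expect_equal(zinb_logpmf(0, mu = 2, alpha = 1, pi = 1), 0)
  # hand case: NB2(0; 2, 1) = 1/3, so P(0) = 0.5 + 0.5/3 = 2/3
  expect_equal(zinb_logpmf(0, mu = 2, alpha = 1, pi = 0.5), log(2 / 3),
               tolerance = 1e-9)
  # alpha = 0 is the Poisson limit
  expect_equal(zinb_logpmf(y, mu = 4, alpha = 0, pi = 0.3),
               log(0.3 * (y == 0) + 0.7 * dpois(y, 4)))
  # domain errors
  expect_error(zinb_logpmf(-1, 2, 1, 0.5))
  expect_error(zinb_logpmf(1, 0, 1, 0.5))
  expect_error(zinb_logpmf(1, 2, -1, 0.5))
  expect_error(zinb_logpmf(1, 2, 1, 1.5))
})

test_that("zinb_logpmf is properly normalized across parameter grid", {
  for (mu in c(0.5, 5, 50)) for (alpha in c(0, 0.3, 2)) {
    for (pi0 in c(0, 0.2, 0.6)) {
      v <- mu + alpha * mu^2
      v <- (1 - pi0) * mu * (1 + alpha * mu + pi0 * mu)
      Y <- ceiling(mu + 20 * sqrt(max(v, mu)))
      total <- sum(exp(zinb_logpmf(0:Y, mu, alpha, pi0)))
      expect_gte(total, 0.999)
      expect_lte(total, 1 + 1e-8)
    }
  }
})

test_that("detection filter drops isoforms seen in fewer than min_samples", {
  counts <- rbind(c(rep(5, 2), rep(0, 18)),   # 2 of 20: excluded
                  c(rep(7, 3), rep(0, 17)),   # exactly 3: retained
                  rep(0, 20),                 # all-zero: excluded, count 0
                  rep(1, 20))                 # everywhere: retained
  mat <- isoform_counts(counts, paste0("I", 1:4), paste0("G", 1:4),
                        paste0("S", 1:20))
  flt <- filter_low_detection(mat, min_samples = 3)
  expect_identical(flt$retained$isoform_ids, c("I2", "I4"))
  expect_identical(flt$excluded$isoform_id, c("I1", "I3"))
  expect_identical(flt$excluded$n_detected, c(2L, 0L))
  expect_error(filter_low_detection(
    isoform_counts(matrix(0, 0, 3), character(0), character(0),
                   paste0("S", 1:3))), "empty")
})

test_that("fitting constant counts recovers a flat mean model", {
  d <- default_design(5)
  X <- design_matrix(d)
  f <- fit_zinb(rep(7, 20), X)
  expect_true(f$converged)
  expect_equal(unname(f$beta["intercept"]), log(7), tolerance = 1e-3)
  expect_lt(max(abs(f$beta[c("treatment", "region", "interaction")])), 1e-3)
  expect_error(fit_zinb(rep(0, 20), X), "all-zero")
})

test_that("pi is consistently estimated near zero when data have no excess zeros", {
  set.seed(10)
  y <- rnbinom(10000, size = 2, mu = 8)  # pure NB, pi = 0
  X <- matrix(1, length(y), 1, dimnames = list(NULL, "intercept"))
  f <- fit_zinb(y, X)
  expect_lt(f$pi, 0.02)
  expect_equal(unname(exp(f$beta)), 8, tolerance = 0.1)
  expect_equal(f$alpha, 0.5, tolerance = 0.1)
})

test_that("optimizer reaches the grid-search optimum on toy rows", {
  set.seed(11)
  X <- matrix(1, 6, 1, dimnames = list(NULL, "intercept"))
  for (k in 1:5) {
    y <- rzinb(6, mu = sample(c(5, 20, 60), 1), alpha = runif(1, 0.1, 1),
               pi = runif(1, 0, 0.4))
    if (all(y == 0)) y[1] <- 1
    fit <- fit_zinb(y, X)
    grid <- oracle_zinb_grid(y)
    expect_lt(abs(fit$loglik - grid$ll), 1e-3)
  }
})

test_that("model nesting is respected: ZINB >= NB >= Poisson log-likelihood", {
  set.seed(12)
  d <- default_design(5)
  X <- design_matrix(d, include_interaction = FALSE)
  sim <- simulate_counts(sim_config(n_isoforms = 20, seed = 13))
  for (i in 1:20) {
    y <- sim$counts$counts[i, ]
    zinb <- fit_zinb(y, X)
    nb <- zinb$nb_fit
    pois <- glm(y ~ X - 1, family = poisson())
    expect_gte(zinb$loglik, nb$loglik - 1e-6)
    expect_gte(nb$loglik, as.numeric(logLik(pois)) - 1e-6)
  }
})

test_that("maximized log-likelihood agrees with glmmTMB on the same model", {
  library(glmmTMB)
  d <- default_design(5)
  Xa <- design_matrix(d, include_interaction = FALSE)
  sim <- simulate_counts(sim_config(n_isoforms = 6, seed = 14))
  df <- data.frame(trt = factor(d$treatment, c("CON", "NTG")),
                   reg = factor(d$region, c("TG", "NAc")))
  for (i in 1:6) {
    y <- sim$counts$counts[i, ]
    df$y <- y
    mine <- fit_zinb(y, Xa)
    ref <- suppressWarnings(
      glmmTMB(y ~ trt + reg, ziformula = ~1, family = nbinom2, data = df))
    expect_equal(mine$loglik, as.numeric(logLik(ref)), tolerance = 1e-5)
    expect_equal(unname(mine$beta), unname(fixef(ref)$cond),
                 tolerance = 1e-3)
  }
})

test_that("effect LRT handles identical and non-nested models", {
  set.seed(15)
  d <- default_design(5)
  X <- design_matrix(d, include_interaction = FALSE)
  y <- rzinb(20, 30, 0.4, 0.1)
  f <- fit_zinb(y, X)
  same <- test_effect(f, f, "treatment")
  expect_equal(same$lr_stat, 0)
  expect_equal(same$p_value, 1)
  f_other <- fit_zinb(y, design_matrix(d)[, c("intercept", "interaction")])
  expect_error(test_effect(f, f_other), "not nested")
})

test_that("fold change and direction follow the reporting conventions", {
  set.seed(16)
  d <- default_design(5)
  Xa <- design_matrix(d, include_interaction = FALSE)
  cfg <- sim_config(n_isoforms = 1, baseline_mean = 100,
                    log_fc_treatment = log(4), dispersion = 0.1,
                    zero_inflation = 0, seed = 17)
  sim <- simulate_counts(cfg)
  y <- sim$counts$counts[1, ]
  full <- fit_zinb(y, Xa)
  red <- fit_zinb(y, Xa[, c("intercept", "region")])
  tt <- test_effect(full, red, "treatment")
  expect_equal(tt$fold_change, 4, tolerance = 0.5)
  expect_identical(tt$direction, "NTG")
  expect_equal(tt$fold_change, exp(unname(full$beta["treatment"])))
})

test_that("excess-zero boundary test uses the half chi-square mixture", {
  mkfit <- function(ll, fixed) structure(
    list(beta = c(intercept = 1), alpha = 0.5, pi = if (fixed) 0 else 0.1,
         loglik = ll, converged = TRUE, n_obs = 20,
         n_params = if (fixed) 2 else 3, fix_pi_zero = fixed),
    class = "zinb_fit")
  # LR = 0 sits on the boundary: p = 1
  expect_equal(test_zero_inflation(mkfit(-50, FALSE), mkfit(-50, TRUE))$p_value, 1)
  # LR = 3.84: p = 0.5 * P(chi2_1 >= 3.84) ~ 0.025
  zi <- test_zero_inflation(mkfit(-50 + 3.84 / 2, FALSE), mkfit(-50, TRUE))
  expect_equal(zi$p_value, 0.5 * pchisq(3.84, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(zi$p_value, 0.025, tolerance = 1e-3)
  # nesting violation -> optimization-failure error
  expect_error(test_zero_inflation(mkfit(-51, FALSE), mkfit(-50, TRUE)),
               "optimization failure")
})

test_that("result categories partition isoforms with the stated precedence", {
  mk <- function(id, q_int, q_trt, q_reg)
    data.frame(isoform_id = id, effect = c("interaction", "treatment", "region"),
               q_value = c(q_int, q_trt, q_reg), stringsAsFactors = FALSE)
  tests <- rbind(mk("a", 0.02, 0.03, 0.001),  # interaction
                 mk("b", 0.5, 0.03, 0.01),    # both main effects
                 mk("c", 0.5, 0.03, 0.5),     # treatment only
                 mk("d", 0.5, 0.9, 0.04),     # region only
                 mk("e", 0.5, 0.5, 0.5))      # none
  cats <- categorize_results(tests, q_interaction = 0.10, q_main = 0.05)
  expect_identical(cats$category[match(letters[1:5], cats$isoform_id)],
                   c("interaction", "both_main", "treatment_only",
                     "region_only", "none"))
  expect_error(categorize_results(tests[tests$effect != "region", ]),
               "region")
})

test_that("confidence intervals bracket the estimate and widen with level", {
  set.seed(18)
  d <- default_design(5)
  Xa <- design_matrix(d, include_interaction = FALSE)
  y <- rzinb(20, 30, 0.4, 0.1)
  f0 <- fit_zinb(y, Xa)
  expect_error(confint(f0, method = "wald"), "standard errors")
  f <- fit_zinb(y, Xa, se = TRUE)
  # Wald intervals: symmetric around the estimate
  cw <- confint(f, method = "wald")
  expect_identical(rownames(cw), names(f$beta))
  expect_true(all(cw[, "lower"] < cw[, "upper"]))
  mid <- (cw[, "lower"] + cw[, "upper"]) / 2
  expect_equal(unname(mid), unname(f$beta), tolerance = 1e-10)
  # profile intervals: contain the MLE, nested in a wider level
  cp95 <- confint(f, "treatment", method = "profile")
  cp99 <- confint(f, "treatment", method = "profile", level = 0.99)
  expect_lt(cp95[, "lower"], f$beta["treatment"])
  expect_gt(cp95[, "upper"], f$beta["treatment"])
  expect_lte(cp99[, "lower"], cp95[, "lower"])
  expect_gte(cp99[, "upper"], cp95[, "upper"])
})
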