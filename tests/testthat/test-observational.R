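test_that("item dichotomization codes flags, count, and category", {
  items <- rbind(rep(1, 5), c(3, 3, 3, 3, 1), c(5, 5, 5, 5, 5),
                 c(3, 1, 1, 1, 1), c(3, 3, 3, 3, 2))
  ex <- dichotomize_items(items, cutoffs = rep(3, 5))
  expect_equal(ex$count, c(0L, 4L, 5L, 1L, 4L))
  expect_equal(as.character(ex$category), c("0", "4-5", "4-5", "1", "4-5"))
  expect_equal(ex$score, c(0, 4, 4, 1, 4))
  # scores exactly at the cut-off set the flag (inclusive threshold)
  ex2 <- dichotomize_items(matrix(3, 1, 5), cutoffs = rep(3, 5))
  expect_equal(ex2$count, 5L)
  expect_error(dichotomize_items(matrix(c(NA, 1, 1, 1, 1), 1), rep(3, 5)),
               "missing")
  expect_error(dichotomize_items(matrix(c(-1, 1, 1, 1, 1), 1), rep(3, 5)),
               "prefer not to say")
})

test_that("outcome screening applies the prevalence and missingness rules", {
  set.seed(1)
  n <- 1000
  d <- data.frame(
    y_rare = c(rep(1, 5), rep(0, n - 5)),          # prevalence 0.5%
    y_gappy = c(rep(NA, 450), rnorm(n - 450)),     # 45% missing
    y_ok = c(rep(NA, 100), rnorm(n - 100)),        # 10% missing
    y_bin = rbinom(n, 1, 0.3)
  )
  cat <- data.frame(name = c("y_rare", "y_gappy", "y_ok", "y_bin", "y_absent"),
                    type = c("binary", "continuous", "continuous", "binary",
                             "binary"))
  sc <- screen_outcomes(cat, d)
  expect_false(sc$included[sc$name == "y_rare"])
  expect_equal(sc$exclusion_reason[sc$name == "y_rare"], "prevalence")
  expect_false(sc$included[sc$name == "y_gappy"])
  expect_equal(sc$exclusion_reason[sc$name == "y_gappy"], "missingness")
  expect_true(sc$included[sc$name == "y_ok"])
  expect_true(sc$included[sc$name == "y_bin"])
  expect_equal(sc$exclusion_reason[sc$name == "y_absent"], "absent")
})

test_that("family dispatch is a pure function of type and prevalence", {
  expect_equal(select_family("binary", 0.09), "logistic")
  expect_equal(select_family("binary", 0.10), "modified-poisson")  # boundary
  expect_equal(select_family("continuous"), "linear")
  expect_equal(select_family("categorical"), "multinomial")
  expect_error(select_family("binary"), "prevalence")
  expect_error(select_family("weird"), "unknown")
  set.seed(2)
  for (i in 1:50) {
    pr <- runif(1)
    expect_equal(select_family("binary", pr),
                 if (pr < 0.10) "logistic" else "modified-poisson")
  }
})

test_that("test enumeration reproduces the published expansion pattern", {
  # 414 outcomes of which 4 categorical (k = 3,3,4,3) -> 419 tests
  cat414 <- data.frame(name = paste0("o", 1:414),
                       type = c(rep("continuous", 79), rep("binary", 331),
                                rep("categorical", 4)),
                       k = c(rep(NA, 410), 3, 3, 4, 3))
  expect_equal(count_tests(cat414), 419L)
  # 298 outcomes with the same categorical block -> 303 tests
  cat298 <- data.frame(name = paste0("o", 1:298),
                       type = c(rep("continuous", 60), rep("binary", 234),
                                rep("categorical", 4)),
                       k = c(rep(NA, 294), 3, 3, 4, 3))
  expect_equal(count_tests(cat298), 303L)
})

simulate_ordinal <- function(n, beta_common, beta_split2 = beta_common,
                             seed = 1) {
  # 3-level ordinal via two cumulative logits with (possibly unequal)
  # exposure coefficients
  set.seed(seed)
  x <- rnorm(n)
  # P(y > 1) and P(y > 2) with intercepts keeping categories populated
  p1 <- plogis(0.5 + beta_common * x)
  p2 <- plogis(-0.5 + beta_split2 * x)
  u <- runif(n)
  y <- ifelse(u < 1 - p1, 1L, ifelse(u < 1 - pmin(p2, p1), 2L, 3L))
  data.frame(y = factor(y, levels = 1:3, ordered = TRUE), x = x)
}

test_that("Brant-style test keeps its size under proportional odds", {
  holds <- vapply(1:100, function(s) {
    d <- simulate_ordinal(400, beta_common = 0.5, seed = s)
    check_proportional_odds(d, "y", "x")$holds
  }, logical(1))
  expect_gte(mean(holds), 0.90)
})

test_that("Brant-style test detects split-specific effects", {
  viol <- vapply(1:11, function(s) {
    d <- simulate_ordinal(5000, beta_common = 0, beta_split2 = log(2),
                          seed = 1000 + s)
    !check_proportional_odds(d, "y", "x")$holds
  }, logical(1))
  expect_gt(mean(viol), 0.5)
})

test_that("Brant-style test rejects two-level outcomes", {
  d <- data.frame(y = factor(rep(1:2, 50)), x = rnorm(100))
  expect_error(check_proportional_odds(d, "y", "x"), "fewer than 3")
})

test_that("trend fit equals the generating slope in the noiseless limit", {
  set.seed(8)
  n <- 500
  d <- data.frame(mt_score = sample(0:4, n, TRUE), sex = rnorm(n))
  d$y <- 0.3 * d$mt_score + 0.1 * d$sex  # no noise
  spec <- list(name = "y", type = "continuous", prevalence = NA)
  rec <- suppressWarnings(trend_fit(d, "mt_score", "sex", spec))
  # analysis z-scores the outcome, so the slope is 0.3 / sd(y)
  expect_equal(rec$estimate, 0.3 / sd(d$y), tolerance = 1e-10)
})

test_that("trend fit recovers a simulated dose-response log-OR", {
  cfg <- sim_config(n_individuals = 8000, n_variants = 10, pns_rate = 0,
                    missing_rate_covariates = 0,
                    outcome_specs = list(
                      outcome_truth("y", "binary", true_effect_exposure = 0.1,
                                    base_rate = 0.06, link = "logit")
                    ), seed = 77)
  panel <- simulate_genotypes(cfg)
  coh <- simulate_cohort(cfg, panel)
  d <- coh$data
  ex <- dichotomize_items(d[grep("^item_", names(d))], rep(3, 5))
  d$mt_score <- ex$score
  spec <- list(name = "y", type = "binary", prevalence = mean(d$y))
  rec <- trend_fit(d, "mt_score", owa_covariates(), spec)
  expect_equal(rec$scale, "OR")
  expect_lt(abs(log(rec$estimate) - 0.1), 2 * rec$se)
})

test_that("null trend p-values are uniform across seeds", {
  pvals <- vapply(1:200, function(s) {
    set.seed(s)
    n <- 300
    d <- data.frame(mt_score = sample(0:4, n, TRUE), sex = rnorm(n),
                    y = rnorm(n))
    spec <- list(name = "y", type = "continuous", prevalence = NA)
    trend_fit(d, "mt_score", "sex", spec)$p
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("BH implementation matches the brute-force oracle and edge cases", {
  set.seed(3)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p)$q, brute_bh(p))
  }
  # worked example: all four q-values collapse to 0.04
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04))$q, rep(0.04, 4))
  expect_false(any(bh_fdr(rep(1, 10))$rejected))
  one <- bh_fdr(0.04)
  expect_true(one$rejected)
  expect_equal(one$q, 0.04)
  expect_equal(nrow(bh_fdr(numeric(0))), 0)
  expect_error(bh_fdr(c(0.5, 1.2)), "0,1")
})

test_that("constant exposure raises a no-contrast error", {
  d <- data.frame(mt_category = factor(rep("0", 50), levels = c("0", "1")),
                  y = rnorm(50), sex = rnorm(50))
  spec <- list(name = "y", type = "continuous", prevalence = NA)
  expect_error(fit_outcome(d, "mt_category", "sex", spec), "no contrast")
})

test_that("the OWA sweep ranks truly associated outcomes first", {
  specs <- c(
    lapply(1:3, function(i) {
      outcome_truth(paste0("y_hit", i), "continuous",
                    true_effect_exposure = 0.25)
    }),
    lapply(1:7, function(i) outcome_truth(paste0("y_null", i), "continuous"))
  )
  hits_first <- vapply(1:3, function(s) {
    cfg <- sim_config(n_individuals = 1500, n_variants = 10, pns_rate = 0,
                      missing_rate_covariates = 0, outcome_specs = specs,
                      seed = 600 + s)
    panel <- simulate_genotypes(cfg)
    coh <- simulate_cohort(cfg, panel)
    d <- coh$data
    catalog <- data.frame(name = vapply(specs, `[[`, "", "name"),
                          type = "continuous")
    res <- run_observational_owa(d, catalog,
                                 list(cutoffs = rep(3, 5), strata = "all",
                                      contrasts = "trend"))
    top3 <- res$outcome[order(res$q)][1:3]
    setequal(top3, c("y_hit1", "y_hit2", "y_hit3"))
  }, logical(1))
  expect_true(all(hits_first))
})

test_that("per-contrast FDR pools only p-values from the same contrast", {
  specs <- list(outcome_truth("y1", "continuous", true_effect_exposure = 0.2),
                outcome_truth("y2", "continuous"))
  cfg <- sim_config(n_individuals = 1200, n_variants = 10, pns_rate = 0,
                    missing_rate_covariates = 0, outcome_specs = specs,
                    seed = 91)
  panel <- simulate_genotypes(cfg)
  coh <- simulate_cohort(cfg, panel)
  catalog <- data.frame(name = c("y1", "y2"), type = "continuous")
  res <- run_observational_owa(coh$data, catalog,
                               list(cutoffs = rep(3, 5), strata = "all"))
  for (cg in unique(res$contrast_group)) {
    sel <- res$contrast_group == cg & res$converged & is.finite(res$p)
    expect_equal(res$q[sel], bh_fdr(res$p[sel])$q)
  }
  # every level contrast is present for both outcomes
  expect_setequal(unique(res$contrast_group),
                  c("1v0", "2v0", "3v0", "4-5v0", "trend"))
  # enumeration attribute reflects the sweep
  en <- attr(res, "enumeration")
  expect_true(all(en$n_tests == 2))
})

test_that("empty catalogs and sex strata are handled", {
  specs <- list(outcome_truth("y1", "continuous", true_effect_exposure = 0.2))
  cfg <- sim_config(n_individuals = 1000, n_variants = 10, pns_rate = 0,
                    missing_rate_covariates = 0, outcome_specs = specs,
                    seed = 13)
  panel <- simulate_genotypes(cfg)
  coh <- simulate_cohort(cfg, panel)
  catalog0 <- data.frame(name = character(0), type = character(0))
  res0 <- run_observational_owa(coh$data, catalog0,
                                list(cutoffs = rep(3, 5)))
  expect_equal(nrow(res0), 0)
  catalog <- data.frame(name = "y1", type = "continuous")
  res <- run_observational_owa(coh$data, catalog,
                               list(cutoffs = rep(3, 5), contrasts = "trend",
                                    strata = c("all", "female", "male")))
  expect_setequal(unique(res$stratum), c("all", "female", "male"))
  n_all <- res$n_used[res$stratum == "all"][1]
  expect_equal(sum(res$n_used[res$stratum != "all"][c(1, 2)]), n_all)
})

test_that("multinomial outcomes produce per-level records on the OR scale", {
  specs <- list(outcome_truth("y_cat", "categorical",
                              true_effect_exposure = 0.3, k = 3))
  cfg <- sim_config(n_individuals = 2500, n_variants = 10, pns_rate = 0,
                    missing_rate_covariates = 0, outcome_specs = specs,
                    seed = 29)
  panel <- simulate_genotypes(cfg)
  coh <- simulate_cohort(cfg, panel)
  catalog <- data.frame(name = "y_cat", type = "categorical", k = 3)
  res <- run_observational_owa(coh$data, catalog,
                               list(cutoffs = rep(3, 5), strata = "all",
                                    contrasts = "trend"))
  expect_equal(nrow(res), 2)  # one record per non-reference outcome level
  expect_true(all(res$family == "multinomial"))
  expect_true(all(res$scale == "OR"))
  expect_true(all(res$conf_low <= res$estimate & res$estimate <= res$conf_high))
})
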