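toy_sumstats <- function(n = 6) {
  data.frame(snp = paste0("rs", 1:n), chr = 1L, pos = (1:n) * 1000L,
             a1 = "A", a2 = "G", beta = seq(0.1, by = 0.1, length.out = n),
             se = 0.01, p = rep(0.001, n), maf = rep(0.2, n),
             info = rep(0.95, n), hwe_p = rep(0.5, n),
             stringsAsFactors = FALSE)
}

test_that("variant QC applies strict thresholds with recorded reasons", {
  s <- toy_sumstats(5)
  s$maf <- c(0.005, 0.01, 0.011, 0.3, 0.3)
  s$info <- c(0.95, 0.95, 0.95, 0.8, 0.95)     # 0.8 exactly must fail
  s$hwe_p <- c(0.5, 0.5, 0.5, 0.5, 1e-10)      # boundary fails
  out <- variant_qc(s)
  expect_equal(out$snp, "rs3")
  rep <- attr(out, "qc_report")
  expect_equal(rep$reason[rep$snp == "rs1"], "maf")
  expect_equal(rep$reason[rep$snp == "rs2"], "maf")  # 0.01 exactly fails
  expect_equal(rep$reason[rep$snp == "rs4"], "info")
  expect_equal(rep$reason[rep$snp == "rs5"], "hwe")
  expect_error(variant_qc(s[, setdiff(names(s), "maf")]), "columns")
})

test_that("greedy clumping keeps the smallest p among correlated neighbours", {
  set.seed(4)
  n <- 400
  base <- rbinom(n, 2, 0.3)
  flip <- function(x) ifelse(runif(n) < 0.03, sample(0:2, n, TRUE), x)
  dos <- cbind(rs1 = base, rs2 = flip(base), rs3 = flip(base))
  s <- toy_sumstats(3)
  s$p <- c(1e-10, 1e-9, 1e-8)
  s$pos <- c(1000L, 2000L, 3000L)
  cl <- greedy_clump(s, dos)
  expect_equal(cl$retained, "rs1")
  expect_true(all(grepl("clumped-by:rs1", cl$removed$reason)))

  # same R^2 but 300 kb apart: outside the window, both retained
  s2 <- s[1:2, ]
  s2$pos <- c(1000L, 301000L)
  cl2 <- greedy_clump(s2, dos[, 1:2])
  expect_setequal(cl2$retained, c("rs1", "rs2"))

  # mutually independent variants are all retained
  set.seed(5)
  dos3 <- sapply(1:4, function(i) rbinom(n, 2, 0.3))
  colnames(dos3) <- paste0("rs", 1:4)
  s3 <- toy_sumstats(4)
  cl3 <- greedy_clump(s3, dos3)
  expect_setequal(cl3$retained, paste0("rs", 1:4))

  # absent variants are skipped with a warning
  expect_warning(cl4 <- greedy_clump(s3, dos3[, 1:3]), "absent")
  expect_true("rs4" %in% cl4$removed$snp)
})

test_that("clump output never violates the pairwise R^2-within-window invariant", {
  cfg <- sim_config(n_individuals = 1500, n_variants = 60, block_size = 10,
                    ld_rho = 0.6, seed = 8)
  panel <- simulate_genotypes(cfg)
  gw <- emulate_gwas(cfg, panel)
  st <- prs_settings()
  cl <- greedy_clump(gw, panel$dosages, st)
  keep <- gw[gw$snp %in% cl$retained, ]
  expect_gte(nrow(keep), 1)
  if (nrow(keep) > 1) {
    for (i in 1:(nrow(keep) - 1)) {
      for (j in (i + 1):nrow(keep)) {
        if (keep$chr[i] == keep$chr[j] &&
            abs(keep$pos[i] - keep$pos[j]) <= st$clump_kb * 1000) {
          r2 <- stats::cor(panel$dosages[, keep$snp[i]],
                           panel$dosages[, keep$snp[j]])^2
          expect_lt(r2, st$clump_r2)
        }
      }
    }
  }
})

test_that("scores are weighted allele sums matching a brute-force oracle", {
  # single-variant worked example
  dos <- matrix(c(0, 1, 2), 3, 1, dimnames = list(NULL, "rs1"))
  s <- toy_sumstats(1)
  s$beta <- 0.5
  sc <- compute_score(dos, s, threshold = 1)
  expect_equal(sc$raw, c(0, 0.5, 1.0))
  expect_equal(mean(sc$standardized), 0, tolerance = 1e-8)
  expect_equal(stats::sd(sc$standardized), 1, tolerance = 1e-8)

  # random 50-variant panels against the oracle, including allele flips
  for (rep in 1:5) {
    set.seed(rep)
    m <- 50
    n <- 60
    dos <- matrix(rbinom(n * m, 2, runif(m, 0.1, 0.5)[rep(1:m, each = n)]),
                  n, m, dimnames = list(NULL, paste0("rs", 1:m)))
    pa <- data.frame(snp = paste0("rs", 1:m),
                     a1 = sample(c("A", "C"), m, TRUE), a2 = "G",
                     stringsAsFactors = FALSE)
    s <- data.frame(snp = pa$snp, chr = 1L, pos = (1:m) * 1000L,
                    a1 = pa$a1, a2 = pa$a2,
                    beta = rnorm(m), se = 0.01, p = runif(m),
                    maf = 0.3, info = 0.95, hwe_p = 0.5,
                    stringsAsFactors = FALSE)
    flip <- sample(m, 10)  # summary lists the other allele for 10 variants
    s$a1[flip] <- pa$a2[flip]
    s$a2[flip] <- pa$a1[flip]
    sc <- compute_score(dos, s, panel_alleles = pa, threshold = 0.5)
    expect_equal(sc$raw, brute_score(dos, s[s$p < 0.5, ], pa, 0.5),
                 tolerance = 1e-12)
  }
})

test_that("flipping a variant's orientation leaves the score unchanged", {
  set.seed(9)
  n <- 40
  dos <- matrix(rbinom(n * 3, 2, 0.3), n, 3,
                dimnames = list(NULL, paste0("rs", 1:3)))
  pa <- data.frame(snp = paste0("rs", 1:3), a1 = "A", a2 = "G",
                   stringsAsFactors = FALSE)
  s <- toy_sumstats(3)
  sc1 <- compute_score(dos, s, panel_alleles = pa, threshold = 1)
  # flip rs2 in the panel: complementary dosage, swapped alleles
  dos2 <- dos
  dos2[, 2] <- 2 - dos2[, 2]
  pa2 <- pa
  pa2$a1[2] <- "G"
  pa2$a2[2] <- "A"
  sc2 <- compute_score(dos2, s, panel_alleles = pa2, threshold = 1)
  expect_equal(sc1$raw, sc2$raw, tolerance = 1e-12)
})

test_that("degenerate thresholds and allele mismatches are handled", {
  dos <- matrix(c(0, 1, 2), 3, 1, dimnames = list(NULL, "rs1"))
  s <- toy_sumstats(1)
  s$p <- 0.9
  expect_warning(sc <- compute_score(dos, s, threshold = 5e-8), "zero")
  expect_equal(sc$raw, rep(0, 3))
  pa <- data.frame(snp = "rs1", a1 = "T", a2 = "C", stringsAsFactors = FALSE)
  w <- capture_warnings(compute_score(dos, toy_sumstats(1), panel_alleles = pa,
                                      threshold = 1))
  expect_true(any(grepl("mismatch", w)))
})

test_that("quintile bins are near-equal with stable tie handling", {
  q <- quintile_bins(1:100)
  expect_equal(as.integer(table(q)), rep(20L, 5))
  q5 <- quintile_bins(c(3, 1, 4, 1, 5))
  expect_setequal(q5, 1:5)
  qt <- quintile_bins(rep(0, 12))
  expect_lte(diff(range(table(qt))), 1)
  expect_error(quintile_bins(1:4), "at least 5")
})

test_that("score-liability correlation is nondecreasing in heritability", {
  cors <- vapply(c(0, 0.1, 0.3), function(h2) {
    cfg <- sim_config(n_individuals = 2500, n_variants = 60, block_size = 10,
                      h2_liability = h2, gwas_n = 500000, seed = 71)
    panel <- simulate_genotypes(cfg)
    coh <- simulate_cohort(cfg, panel)
    gw <- emulate_gwas(cfg, panel)
    pr <- prs_pipeline(panel$dosages, gw,
                       prs_settings(p_thresholds = 0.5),
                       panel_alleles = panel$variants)
    suppressWarnings(
      stats::cor(pr$scores[[1]]$raw, coh$truth$liability)
    )
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
})
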