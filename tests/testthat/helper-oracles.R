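# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# Brute-force Benjamini-Hochberg step-up: q_i = min over j with
# p_(j) >= p_(i) of p_(j) * m / j, computed by direct enumeration.
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  ps <- p[ord]
  for (i in seq_len(m)) {
    q_sorted[i] <- min(vapply(i:m, function(j) m / j * ps[j], numeric(1)))
  }
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Invert the confounding bias factor B(E) = E^2 / (2E - 1) at a given
# risk ratio by bisection; the E-value is the unique solution >= 1.
evalue_by_bisection <- function(rr) {
  stopifnot(rr >= 1)
  if (rr == 1) return(1)
  f <- function(e) e^2 / (2 * e - 1) - rr
  lo <- 1
  hi <- 2 * rr + 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Brute-force polygenic score: explicit per-individual loop over
# variants, with allele alignment handled by complementary dosage.
brute_score <- function(dosages, summary, panel_alleles, threshold) {
  use <- summary[summary$p < threshold, , drop = FALSE]
  n <- nrow(dosages)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (r in seq_len(nrow(use))) {
      snp <- use$snp[r]
      if (!snp %in% colnames(dosages)) next
      pa <- panel_alleles[panel_alleles$snp == snp, ]
      d <- dosages[i, snp]
      if (use$a1[r] == pa$a1) {
        s <- s + use$beta[r] * d
      } else if (use$a1[r] == pa$a2) {
        s <- s + use$beta[r] * (2 - d)
      }
    }
    out[i] <- s
  }
  out
}

# Small standard test cohort used by several files.
make_test_specs <- function() {
  list(
    outcome_truth("y_cont", "continuous", true_effect_exposure = 0.1,
                  confounder_loadings = c(sex = 0.2), theme = "a"),
    outcome_truth("y_common", "binary", true_effect_exposure = 0.1,
                  base_rate = 0.30, link = "log", theme = "b")
  )
}
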