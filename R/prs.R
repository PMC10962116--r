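#' Polygenic-score construction settings
#'
#' @param maf_min Minimum minor allele frequency (strict `>`).
#' @param hwe_p_min Minimum Hardy-Weinberg equilibrium p-value (strict).
#' @param info_min Minimum imputation information score (strict).
#' @param clump_r2 Squared-correlation threshold for clumping.
#' @param clump_kb Distance window for clumping, in kilobases.
#' @param p_thresholds P-value cut-offs at which scores are built
#'   (variants with `p < threshold` contribute).
#' @param standardize Whether to add a standardized copy of each score.
#' @return A `prs_settings` object.
#' @export
prs_settings <- function(maf_min = 0.01, hwe_p_min = 1e-10, info_min = 0.8,
                         clump_r2 = 0.1, clump_kb = 250,
                         p_thresholds = c(5e-8, 0.5), standardize = TRUE) {
  stopifnot(maf_min >= 0, maf_min < 0.5, hwe_p_min >= 0, hwe_p_min < 1,
            info_min >= 0, info_min <= 1, clump_r2 > 0, clump_r2 <= 1,
            clump_kb > 0, all(p_thresholds > 0 & p_thresholds <= 1))
  structure(list(maf_min = maf_min, hwe_p_min = hwe_p_min,
                 info_min = info_min, clump_r2 = clump_r2,
                 clump_kb = clump_kb, p_thresholds = p_thresholds,
                 standardize = standardize),
            class = "prs_settings")
}

#' Variant quality control on a summary-statistics table
#'
#' Retains variants with MAF, HWE p-value, and info score strictly above
#' their thresholds; removal reasons are recorded in the `qc_report`
#' attribute.
#'
#' @param summary Summary-statistics data frame with columns `snp, maf,
#'   info, hwe_p` (plus the usual effect columns).
#' @param settings A [prs_settings()].
#' @return Filtered table; attribute `qc_report` maps removed variants
#'   to their (first) failing filter.
#' @export
variant_qc <- function(summary, settings = prs_settings()) {
  need <- c("snp", "maf", "info", "hwe_p")
  if (!all(need %in% names(summary))) {
    stop("summary statistics must have columns: ",
         paste(setdiff(need, names(summary)), collapse = ", "), call. = FALSE)
  }
  reason <- rep(NA_character_, nrow(summary))
  reason[summary$info <= settings$info_min] <- "info"
  reason[summary$hwe_p <= settings$hwe_p_min] <- "hwe"
  reason[summary$maf <= settings$maf_min] <- "maf"
  keep <- is.na(reason)
  out <- summary[keep, , drop = FALSE]
  attr(out, "qc_report") <- data.frame(snp = summary$snp[!keep],
                                       reason = reason[!keep],
                                       stringsAsFactors = FALSE)
  out
}

#' Greedy LD clumping
#'
#' Iterates variants by ascending p-value (ties broken by chromosome
#' then position); each retained index variant removes every
#' not-yet-retained variant on the same chromosome within the distance
#' window whose squared dosage correlation with it is at or above
#' `clump_r2`.
#'
#' @param summary Summary-statistics table (post-QC) with `snp, chr,
#'   pos, p`.
#' @param dosages Individuals x variants dosage matrix with variant ids
#'   as column names (used to estimate pairwise R^2 in the scoring
#'   sample).
#' @param settings A [prs_settings()].
#' @return List with `retained` (index-variant ids, in input order) and
#'   `removed` (data frame: snp, reason — `"clumped-by:<index>"`);
#'   variants missing from the dosage panel are skipped with a warning
#'   and listed with reason `"no-genotypes"`.
#' @export
greedy_clump <- function(summary, dosages, settings = prs_settings()) {
  in_panel <- summary$snp %in% colnames(dosages)
  if (any(!in_panel)) {
    warning(sum(!in_panel), " variant(s) absent from the genotype panel; skipped")
  }
  tab <- summary[in_panel, , drop = FALSE]
  removed <- data.frame(snp = summary$snp[!in_panel],
                        reason = rep("no-genotypes", sum(!in_panel)),
                        stringsAsFactors = FALSE)
  # ties on p (including floating-point underflow at extreme z) break by
  # Wald z when available, then by genomic position; fully deterministic
  ord <- if (!is.null(tab$beta) && !is.null(tab$se)) {
    order(tab$p, -abs(tab$beta / tab$se), tab$chr, tab$pos)
  } else {
    order(tab$p, tab$chr, tab$pos)
  }
  status <- rep("free", nrow(tab))  # free | index | clumped
  window <- settings$clump_kb * 1000
  for (i in ord) {
    if (status[i] != "free") next
    status[i] <- "index"
    near <- which(status == "free" & tab$chr == tab$chr[i] &
                    abs(tab$pos - tab$pos[i]) <= window)
    if (length(near) == 0) next
    x <- dosages[, tab$snp[i]]
    r2 <- vapply(near, function(j) {
      suppressWarnings(stats::cor(x, dosages[, tab$snp[j]]))^2
    }, numeric(1))
    r2[is.na(r2)] <- 0
    hit <- near[r2 >= settings$clump_r2]
    if (length(hit)) {
      status[hit] <- "clumped"
      removed <- rbind(removed,
                       data.frame(snp = tab$snp[hit],
                                  reason = paste0("clumped-by:", tab$snp[i]),
                                  stringsAsFactors = FALSE))
    }
  }
  list(retained = tab$snp[status == "index"], removed = removed)
}

#' Compute a polygenic score
#'
#' The raw score is the effect-allele dosage weighted by the GWAS effect
#' size, summed over retained variants with `p <` the threshold. Effect
#' alleles are aligned to the dosage orientation: when the summary
#' table's effect allele is the panel's other allele, the weighted
#' contribution uses the complementary dosage `2 - d` (equivalently a
#' sign flip plus constant); variants matching neither allele are
#' dropped with a warning.
#'
#' @param dosages Individuals x variants dosage matrix (column names =
#'   variant ids); attribute or companion `panel_alleles` gives the
#'   counted allele.
#' @param summary Summary-statistics table with `snp, a1, a2, beta, p`.
#' @param panel_alleles Data frame `snp, a1, a2` describing the panel's
#'   counted (a1) and other allele; defaults to the summary table's own
#'   alleles (already aligned).
#' @param threshold P-value cut-off.
#' @param retained Optional character vector of index variants from
#'   [greedy_clump()]; defaults to all variants in `summary`.
#' @param standardize Add a standardized copy.
#' @return A `score_vector` data frame: `raw`, `standardized` (mean 0,
#'   SD 1 in the scoring sample), `quintile` (1-5 on the raw score);
#'   attribute `n_variants` = number of contributing variants. All-zero
#'   scores (no variant passes) trigger a warning.
#' @export
compute_score <- function(dosages, summary, panel_alleles = NULL,
                          threshold = 1, retained = NULL,
                          standardize = TRUE) {
  if (is.null(retained)) retained <- summary$snp
  use <- summary[summary$snp %in% retained & summary$p < threshold, ,
                 drop = FALSE]
  use <- use[use$snp %in% colnames(dosages), , drop = FALSE]
  n <- nrow(dosages)
  raw <- rep(0, n)
  n_var <- 0L
  if (nrow(use) > 0) {
    if (is.null(panel_alleles)) {
      aligned_sign <- rep(1, nrow(use))
      offset <- rep(0, nrow(use))
      keep <- rep(TRUE, nrow(use))
    } else {
      pa <- panel_alleles[match(use$snp, panel_alleles$snp), ]
      same <- use$a1 == pa$a1 & use$a2 == pa$a2
      flipped <- use$a1 == pa$a2 & use$a2 == pa$a1
      keep <- same | flipped
      if (any(!keep)) {
        warning(sum(!keep), " variant(s) with unresolvable allele mismatch dropped")
      }
      aligned_sign <- ifelse(flipped, -1, 1)
      offset <- ifelse(flipped, 2 * use$beta, 0)
    }
    use <- use[keep, , drop = FALSE]
    sgn <- aligned_sign[keep]
    off <- offset[keep]
    if (nrow(use) > 0) {
      w <- use$beta * sgn
      raw <- as.numeric(dosages[, use$snp, drop = FALSE] %*% w) + sum(off)
      n_var <- nrow(use)
    }
  }
  if (n_var == 0L) {
    warning("no variant passed the threshold; score is identically zero")
  }
  out <- data.frame(raw = raw)
  if (standardize) {
    out$standardized <- if (stats::sd(raw) < 1e-12) rep(0, n) else zstd(raw)
  }
  out$quintile <- if (n >= 5) quintile_bins(raw) else rep(NA_integer_, n)
  attr(out, "n_variants") <- n_var
  class(out) <- c("score_vector", "data.frame")
  out
}

#' Rank-based quintile labels
#'
#' Bins values into five near-equal groups on the raw scale, ties broken
#' by stable input order, so bin sizes never differ by more than one.
#'
#' @param x Numeric vector, length >= 5.
#' @return Integer labels 1-5.
#' @export
quintile_bins <- function(x) {
  n <- length(x)
  if (n < 5) stop("quintiles need at least 5 observations", call. = FALSE)
  sizes <- rep(n %/% 5, 5) + c(rep(1, n %% 5), rep(0, 5 - n %% 5))
  ord <- order(x)  # stable: ties keep input order
  labels <- integer(n)
  labels[ord] <- rep(1:5, times = sizes)
  labels
}

#' Full clumping-and-thresholding polygenic score pipeline
#'
#' Applies variant QC, greedy LD clumping, and per-threshold scoring
#' with standardization and quintile binning.
#'
#' @param dosages Dosage matrix.
#' @param summary Summary-statistics table.
#' @param settings A [prs_settings()].
#' @param panel_alleles Optional panel allele table (see
#'   [compute_score()]).
#' @return List with one `score_vector` per p-value threshold (named
#'   by threshold), plus `qc` (filtered summary) and `clump` (the clump
#'   result).
#' @export
prs_pipeline <- function(dosages, summary, settings = prs_settings(),
                         panel_alleles = NULL) {
  qc <- variant_qc(summary, settings)
  cl <- greedy_clump(qc, dosages, settings)
  scores <- lapply(settings$p_thresholds, function(th) {
    compute_score(dosages, qc, panel_alleles = panel_alleles,
                  threshold = th, retained = cl$retained,
                  standardize = settings$standardize)
  })
  names(scores) <- format(settings$p_thresholds, scientific = TRUE, trim = TRUE)
  list(scores = scores, qc = qc, clump = cl)
}
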