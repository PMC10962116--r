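#' E-value for a risk ratio
#'
#' The E-value is the minimum strength of association, on the risk-ratio
#' scale, that an unmeasured confounder would need to have with both the
#' exposure and the outcome, conditional on the measured covariates, to
#' fully explain away an observed exposure-outcome association. For an
#' apparent risk ratio \eqn{RR \ge 1} it equals
#' \deqn{E = RR + \sqrt{RR (RR - 1)},}
#' and for a protective ratio (\eqn{RR < 1}) the formula is applied to
#' \eqn{1/RR}. \eqn{E(1) = 1}: a null association needs no confounding to
#' be explained away.
#'
#' @param rr Positive numeric vector of risk (or odds) ratios.
#' @return Numeric vector of E-values, each \eqn{\ge 1}.
#' @examples
#' evalue_from_rr(1.53) # 2.43 to two decimals
#' evalue_from_rr(c(1, 0.91))
#' @export
evalue_from_rr <- function(rr) {
  if (!is.numeric(rr) || any(!is.finite(rr)) || any(rr <= 0)) {
    stop("`rr` must be a finite positive numeric vector", call. = FALSE)
  }
  r <- ifelse(rr < 1, 1 / rr, rr)
  r + sqrt(r * (r - 1))
}

#' Confidence-limit E-value
#'
#' Applies the E-value formula to the confidence limit closest to the
#' null: the lower limit when the estimate is above 1, the upper limit
#' when below 1. If the interval contains (or touches) the null, the
#' confidence-limit E-value is 1 -- no unmeasured confounding is needed
#' to move the interval to cover the null.
#'
#' @param estimate Ratio-scale point estimate.
#' @param lcl,ucl Lower and upper confidence limits (ratio scale).
#' @return E-value at the limit closest to the null (scalar, vectorized
#'   over the three arguments).
#' @examples
#' ci_evalue(1.57, 1.53, 1.62) # 2.43
#' ci_evalue(1.05, 0.98, 1.12) # 1
#' @export
ci_evalue <- function(estimate, lcl, ucl) {
  n <- max(length(estimate), length(lcl), length(ucl))
  estimate <- rep_len(estimate, n)
  lcl <- rep_len(lcl, n)
  ucl <- rep_len(ucl, n)
  if (any(!is.finite(c(estimate, lcl, ucl))) ||
      any(c(estimate, lcl, ucl) <= 0)) {
    stop("estimate and confidence limits must be finite and positive",
         call. = FALSE)
  }
  if (any(lcl > estimate | estimate > ucl)) {
    stop("confidence limits must bracket the estimate (lcl <= estimate <= ucl)",
         call. = FALSE)
  }
  out <- numeric(n)
  crosses <- lcl <= 1 & ucl >= 1
  out[crosses] <- 1
  hi <- !crosses & estimate > 1
  lo <- !crosses & estimate < 1
  if (any(hi)) out[hi] <- evalue_from_rr(lcl[hi])
  if (any(lo)) out[lo] <- evalue_from_rr(ucl[lo])
  out
}

#' Approximate risk ratio for a standardized mean difference
#'
#' Converts a regression coefficient expressed in standard-deviation
#' units of a continuous outcome to an approximate risk ratio via
#' \eqn{RR \approx \exp(0.91\,\beta)}, the standard conversion used to
#' place standardized mean differences on the E-value scale. The
#' conversion is symmetric: \code{rr_from_standardized_beta(-b)} is the
#' reciprocal of \code{rr_from_standardized_beta(b)}.
#'
#' @param beta Numeric vector of standardized coefficients.
#' @return Approximate risk ratios.
#' @examples
#' rr_from_standardized_beta(0.12)
#' @export
rr_from_standardized_beta <- function(beta) {
  if (!is.numeric(beta) || any(!is.finite(beta))) {
    stop("`beta` must be finite numeric", call. = FALSE)
  }
  exp(0.91 * beta)
}

#' Classify robustness of an association against a benchmark covariate
#'
#' An association on the ratio scale is judged potentially robust when
#' its confidence-limit E-value exceeds the magnitude of a benchmark
#' covariate coefficient from the same model (a plausible stand-in for
#' an unmeasured confounder of similar strength, e.g. maternal smoking
#' around birth). Protective benchmarks are compared on the
#' away-from-null scale, i.e. against \code{max(b, 1/b)}. When no
#' ratio-scale benchmark exists (continuous outcomes, where the
#' benchmark coefficient is a beta), the association is robust when its
#' confidence-limit E-value is in the top half (at or above the median)
#' of confidence-limit E-values across all outcomes.
#'
#' @param evalue_ci Confidence-limit E-value for the association.
#' @param benchmark_ratio Ratio-scale benchmark coefficient, or `NA`
#'   when unavailable.
#' @param all_ci_evalues Numeric vector of confidence-limit E-values
#'   across the full outcome catalog (used by the percentile rule).
#' @return A list with `robust` (logical) and `rule_used`
#'   (`"benchmark-comparison"` or `"percentile"`).
#' @export
classify_robust <- function(evalue_ci, benchmark_ratio, all_ci_evalues) {
  stopifnot(is.numeric(evalue_ci), length(evalue_ci) == 1L, evalue_ci >= 1)
  if (evalue_ci <= 1) {
    # CI crosses or touches the null: never robust, but report the rule
    # that would have applied.
    rule <- if (is.na(benchmark_ratio)) "percentile" else "benchmark-comparison"
    return(list(robust = FALSE, rule_used = rule))
  }
  if (!is.na(benchmark_ratio)) {
    if (benchmark_ratio <= 0) {
      stop("benchmark ratio must be positive", call. = FALSE)
    }
    mag <- max(benchmark_ratio, 1 / benchmark_ratio)
    list(robust = evalue_ci > mag, rule_used = "benchmark-comparison")
  } else {
    if (length(all_ci_evalues) == 0 || all(is.na(all_ci_evalues))) {
      stop("percentile rule requires the CI E-values of all outcomes",
           call. = FALSE)
    }
    med <- stats::median(all_ci_evalues, na.rm = TRUE)
    list(robust = evalue_ci >= med, rule_used = "percentile")
  }
}

#' Append E-values and robustness flags to a results table
#'
#' Takes a table of fitted associations (as produced by
#' [run_observational_owa()] or [fit_outcome()]) and appends, per row:
#' the ratio fed to the E-value formula (`rr_used`), the point E-value,
#' the confidence-limit E-value, the robustness flag, and the rule used.
#' Linear-family estimates (standardized betas) are first converted with
#' [rr_from_standardized_beta()]; for those rows the benchmark
#' comparison is unavailable and the percentile rule applies, with the
#' median taken over the confidence-limit E-values of all rows supplied.
#'
#' @param results Data frame with columns `estimate`, `conf_low`,
#'   `conf_high`, `scale` (one of `"beta"`, `"OR"`, `"RR"`), and
#'   optionally `benchmark_ratio` (ratio-scale benchmark per row, `NA`
#'   where absent).
#' @return `results` with columns `rr_used`, `evalue_point`,
#'   `evalue_ci`, `robust`, `rule_used` appended.
#' @export
add_evalues <- function(results) {
  stopifnot(is.data.frame(results),
            all(c("estimate", "conf_low", "conf_high", "scale") %in%
                  names(results)))
  if (is.null(results$benchmark_ratio)) results$benchmark_ratio <- NA_real_
  is_beta <- results$scale == "beta"
  est <- ifelse(is_beta, rr_from_standardized_beta(results$estimate),
                results$estimate)
  lcl <- ifelse(is_beta, rr_from_standardized_beta(results$conf_low),
                results$conf_low)
  ucl <- ifelse(is_beta, rr_from_standardized_beta(results$conf_high),
                results$conf_high)
  results$rr_used <- est
  results$evalue_point <- evalue_from_rr(est)
  results$evalue_ci <- ci_evalue(est, lcl, ucl)
  bench <- results$benchmark_ratio
  bench[is_beta] <- NA_real_  # beta-scale benchmark is not comparable
  all_ci <- results$evalue_ci
  cls <- lapply(seq_len(nrow(results)), function(i) {
    classify_robust(results$evalue_ci[i], bench[i], all_ci)
  })
  results$robust <- vapply(cls, `[[`, logical(1), "robust")
  results$rule_used <- vapply(cls, `[[`, character(1), "rule_used")
  results
}
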