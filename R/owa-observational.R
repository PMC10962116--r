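#' Code the maltreatment exposure from the five ordinal items
#'
#' Dichotomizes each 1-5 item at its cut-off (inclusive: a score at the
#' cut-off sets the flag), counts the exposure-positive types, and codes
#' the analysis category 0, 1, 2, 3, "4-5" (the two highest counts are
#' combined because of their low prevalence).
#'
#' @param items Data frame or matrix with the five item columns (scores
#'   1-5; no missing values or "prefer not to say" sentinels -- resolve
#'   those by imputation first).
#' @param cutoffs Integer vector of length 5: per-item cut-offs.
#' @return Data frame with the five binary flags (`flag_*`), `count`
#'   (0-5), `category` (factor `0,1,2,3,4-5`), and `score` (numeric
#'   trend coding 0-4, with "4-5" scored 4).
#' @export
dichotomize_items <- function(items, cutoffs) {
  items <- as.matrix(items)
  if (ncol(items) != 5L) stop("expected five item columns", call. = FALSE)
  if (length(cutoffs) != 5L) stop("expected five cut-offs", call. = FALSE)
  if (anyNA(items)) {
    stop("items contain missing values; impute before dichotomizing",
         call. = FALSE)
  }
  if (any(items == -1L)) {
    stop("items contain 'prefer not to say' sentinels; impute them first",
         call. = FALSE)
  }
  if (any(items < 1L | items > 5L)) {
    stop("item scores must be in 1..5", call. = FALSE)
  }
  flags <- sweep(items, 2, cutoffs, `>=`)
  count <- rowSums(flags)
  category <- factor(ifelse(count >= 4, "4-5", as.character(count)),
                     levels = c("0", "1", "2", "3", "4-5"))
  out <- as.data.frame(flags * 1L)
  names(out) <- paste0("flag_", seq_len(5))
  if (!is.null(colnames(items))) {
    names(out) <- paste0("flag_", sub("^item_", "", colnames(items)))
  }
  out$count <- as.integer(count)
  out$category <- category
  out$score <- pmin(count, 4)
  out
}

#' Screen an outcome catalog against the analytic sample
#'
#' Binary outcomes must have prevalence above 1%; any outcome with more
#' than 40% missingness is excluded. Exclusion reasons are recorded.
#'
#' @param catalog Data frame with columns `name`, `type` (continuous /
#'   binary / categorical) and optionally `theme`.
#' @param data Analytic-sample data frame (pre-imputation) holding the
#'   outcome columns.
#' @return The catalog with `prevalence`, `missing_fraction`, `included`,
#'   and `exclusion_reason` columns appended.
#' @export
screen_outcomes <- function(catalog, data) {
  stopifnot(is.data.frame(catalog), all(c("name", "type") %in% names(catalog)))
  if (is.null(catalog$theme)) catalog$theme <- rep("general", nrow(catalog))
  n <- nrow(catalog)
  prevalence <- rep(NA_real_, n)
  missing_fraction <- rep(NA_real_, n)
  included <- rep(TRUE, n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    nm <- catalog$name[i]
    if (!nm %in% names(data)) {
      included[i] <- FALSE
      reason[i] <- "absent"
      next
    }
    x <- data[[nm]]
    missing_fraction[i] <- mean(is.na(x))
    if (catalog$type[i] == "binary") {
      xo <- x[!is.na(x)]
      prevalence[i] <- mean(if (is.factor(xo)) xo == levels(xo)[2] else xo == 1)
    }
    if (missing_fraction[i] > 0.40) {
      included[i] <- FALSE
      reason[i] <- "missingness"
    } else if (catalog$type[i] == "binary" &&
               !is.na(prevalence[i]) && prevalence[i] <= 0.01) {
      included[i] <- FALSE
      reason[i] <- "prevalence"
    }
  }
  catalog$prevalence <- prevalence
  catalog$missing_fraction <- missing_fraction
  catalog$included <- included
  catalog$exclusion_reason <- reason
  catalog
}

#' Select the regression family for an outcome
#'
#' Continuous outcomes are z-scored and fit with linear regression;
#' binary outcomes with prevalence below 10% with logistic regression
#' (odds ratios); binary outcomes with prevalence at or above 10% with
#' modified Poisson regression (log link, robust sandwich variance; risk
#' ratios); categorical outcomes with multinomial logit.
#'
#' @param type Declared outcome type.
#' @param prevalence Prevalence (binary outcomes only).
#' @return One of `"linear"`, `"logistic"`, `"modified-poisson"`,
#'   `"multinomial"`.
#' @export
select_family <- function(type, prevalence = NA_real_) {
  switch(type,
    continuous = "linear",
    binary = {
      if (is.na(prevalence)) stop("binary dispatch needs prevalence",
                                  call. = FALSE)
      if (prevalence < 0.10) "logistic" else "modified-poisson"
    },
    categorical = "multinomial",
    stop("unknown outcome type: ", type, call. = FALSE)
  )
}

scale_of_family <- function(family) {
  switch(family, linear = "beta", logistic = "OR",
         `modified-poisson` = "RR", multinomial = "OR")
}

#' Brant-style test of the proportional-odds assumption
#'
#' Fits a separate binary logistic regression at each cumulative split
#' of an ordered outcome and tests equality of the exposure coefficient
#' across splits with a Wald chi-square, using the cross-split
#' coefficient covariances implied by the fitted split probabilities.
#'
#' @param data Data frame.
#' @param outcome Name of an ordered categorical outcome with >= 3
#'   levels.
#' @param exposure Name of the (single, numeric) exposure column whose
#'   coefficient is tested.
#' @param covariates Additional adjustment columns.
#' @param alpha Significance level for the `holds` verdict.
#' @return List with `statistic`, `df`, `p`, and `holds`
#'   (`p >= alpha`).
#' @export
check_proportional_odds <- function(data, outcome, exposure,
                                    covariates = character(), alpha = 0.05) {
  y <- data[[outcome]]
  if (!is.factor(y)) y <- factor(y)
  y <- droplevels(y)
  J <- nlevels(y)
  if (J < 3) stop("proportional odds is not testable with fewer than 3 levels",
                  call. = FALSE)
  rhs <- paste(c(exposure, covariates), collapse = " + ")
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), data = data)
  exp_col <- which(colnames(X) == exposure)
  if (length(exp_col) != 1) {
    stop("exposure must enter the design as a single numeric column",
         call. = FALSE)
  }
  yi <- as.integer(y)
  nsplit <- J - 1
  betas <- numeric(nsplit)
  pis <- matrix(0, nrow(X), nsplit)
  xwx_inv <- vector("list", nsplit)
  for (j in seq_len(nsplit)) {
    z <- as.numeric(yi > j)
    if (all(z == 0) || all(z == 1)) {
      stop("degenerate cumulative split at level ", j, call. = FALSE)
    }
    fit <- suppressWarnings(
      stats::glm.fit(X, z, family = stats::binomial())
    )
    betas[j] <- stats::coef(fit)[exp_col]
    pis[, j] <- fit$fitted.values
    w <- pis[, j] * (1 - pis[, j])
    xwx_inv[[j]] <- solve(crossprod(X * sqrt(w)))
  }
  # cross-split covariance of the full coefficient vectors (Brant 1990):
  # cov(b_j, b_k) = (X'W_j X)^-1 X' diag(pi_k - pi_j pi_k) X (X'W_k X)^-1
  V <- matrix(0, nsplit, nsplit)
  for (j in seq_len(nsplit)) {
    for (k in j:nsplit) {
      w_jk <- pis[, k] - pis[, j] * pis[, k]
      mid <- crossprod(X * w_jk, X)
      full <- xwx_inv[[j]] %*% mid %*% xwx_inv[[k]]
      V[j, k] <- full[exp_col, exp_col]
      V[k, j] <- V[j, k]
    }
  }
  D <- diff(diag(nsplit))  # (nsplit-1) x nsplit difference matrix
  db <- D %*% betas
  stat <- as.numeric(t(db) %*% solve(D %*% V %*% t(D)) %*% db)
  df <- nsplit - 1
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p, holds = p >= alpha)
}

# ---- single-dataset model fits ------------------------------------------

# Fit one outcome model on one completed dataset and return a data frame
# of (term, outcome_level, estimate, se) for every requested coefficient,
# plus the convergence flag and the benchmark coefficient.
fit_once <- function(data, outcome, exposure_term, covariates, family,
                     benchmark = "maternal_smoking") {
  rhs <- paste(c(exposure_term, covariates), collapse = " + ")
  f <- stats::as.formula(paste(outcome, "~", rhs))
  bench_pat <- paste0("^", benchmark)
  if (family == "linear") {
    dat <- data
    dat[[outcome]] <- zstd(as.numeric(dat[[outcome]]))
    fit <- stats::lm(f, data = dat)
    sm <- summary(fit)$coefficients
    list(coefs = data.frame(term = rownames(sm), outcome_level = NA,
                            estimate = sm[, 1], se = sm[, 2],
                            row.names = NULL),
         converged = TRUE,
         benchmark_link = {
           i <- grep(bench_pat, rownames(sm))
           if (length(i) == 1) sm[i, 1] else NA_real_
         },
         benchmark_is_ratio = FALSE)
  } else if (family %in% c("logistic", "modified-poisson")) {
    dat <- data
    y <- dat[[outcome]]
    if (is.factor(y)) dat[[outcome]] <- as.numeric(y == levels(y)[2])
    fam <- if (family == "logistic") stats::binomial() else stats::poisson()
    fit <- suppressWarnings(stats::glm(f, data = dat, family = fam))
    est <- stats::coef(fit)
    vc <- if (family == "modified-poisson") {
      sandwich::vcovHC(fit, type = "HC1")
    } else {
      stats::vcov(fit)
    }
    se <- sqrt(diag(vc))
    list(coefs = data.frame(term = names(est), outcome_level = NA,
                            estimate = est, se = se, row.names = NULL),
         converged = isTRUE(fit$converged),
         benchmark_link = {
           i <- grep(bench_pat, names(est))
           if (length(i) == 1) est[i] else NA_real_
         },
         benchmark_is_ratio = TRUE)
  } else if (family == "multinomial") {
    dat <- data
    y <- droplevels(as.factor(dat[[outcome]]))
    ref <- names(which.max(table(y)))  # most frequent category as reference
    dat[[outcome]] <- stats::relevel(y, ref = ref)
    fit <- nnet::multinom(f, data = dat, trace = FALSE, maxit = 300,
                          MaxNWts = 5000)
    co <- stats::coef(fit)
    if (is.null(dim(co))) {
      co <- matrix(co, nrow = 1,
                   dimnames = list(levels(dat[[outcome]])[2], names(co)))
    }
    sm <- summary(fit)$standard.errors
    if (is.null(dim(sm))) sm <- matrix(sm, nrow = 1, dimnames = dimnames(co))
    rows <- do.call(rbind, lapply(rownames(co), function(lv) {
      data.frame(term = colnames(co), outcome_level = lv,
                 estimate = co[lv, ], se = sm[lv, ], row.names = NULL)
    }))
    list(coefs = rows, converged = fit$convergence == 0,
         benchmark_link = NA_real_, benchmark_is_ratio = TRUE)
  } else {
    stop("unknown family: ", family, call. = FALSE)
  }
}

contrast_label <- function(term, exposure_var, ref = "0") {
  lev <- sub(paste0("^", exposure_var), "", term)
  paste0(lev, "v", ref)
}

# Pool a set of per-imputation fit_once results into FitRecord rows for
# the exposure terms.
pool_fits <- function(fits, exposure_var, exposure_is_factor, family,
                      outcome, n_used, stratum, level = 0.95, ref = "0") {
  scale <- scale_of_family(family)
  converged <- all(vapply(fits, `[[`, logical(1), "converged"))
  pat <- if (exposure_is_factor) paste0("^", exposure_var) else
    paste0("^", exposure_var, "$")
  keys <- unique(do.call(rbind, lapply(fits, function(f) {
    k <- f$coefs[grepl(pat, f$coefs$term), c("term", "outcome_level")]
    k
  })))
  bench_links <- vapply(fits, `[[`, numeric(1), "benchmark_link")
  bench_ratio <- if (fits[[1]]$benchmark_is_ratio &&
                     all(is.finite(bench_links))) {
    exp(mean(bench_links))
  } else NA_real_
  out <- lapply(seq_len(nrow(keys)), function(i) {
    tm <- keys$term[i]
    lv <- keys$outcome_level[i]
    est <- vapply(fits, function(f) {
      r <- f$coefs$term == tm &
        (is.na(lv) & is.na(f$coefs$outcome_level) |
           !is.na(lv) & !is.na(f$coefs$outcome_level) &
           f$coefs$outcome_level == lv)
      f$coefs$estimate[which(r)[1]]
    }, numeric(1))
    se <- vapply(fits, function(f) {
      r <- f$coefs$term == tm &
        (is.na(lv) & is.na(f$coefs$outcome_level) |
           !is.na(lv) & !is.na(f$coefs$outcome_level) &
           f$coefs$outcome_level == lv)
      f$coefs$se[which(r)[1]]
    }, numeric(1))
    if (any(!is.finite(est)) || any(!is.finite(se)) || any(se <= 0)) {
      return(fitrecord_row(outcome, "unestimable", family, scale, stratum,
                           n_used, converged = FALSE,
                           benchmark_ratio = bench_ratio))
    }
    pl <- pool_rubin(est, se)
    tcrit <- stats::qt(1 - (1 - level) / 2, df = pl$df)
    lo <- pl$estimate - tcrit * pl$se
    hi <- pl$estimate + tcrit * pl$se
    pval <- 2 * stats::pt(-abs(pl$estimate / pl$se), df = pl$df)
    contrast <- if (exposure_is_factor) {
      contrast_label(tm, exposure_var, ref)
    } else "trend"
    if (!is.na(lv)) contrast <- paste0(lv, ":", contrast)
    ratio <- scale %in% c("OR", "RR")
    fitrecord_row(outcome, contrast, family, scale, stratum, n_used,
                  estimate = if (ratio) exp(pl$estimate) else pl$estimate,
                  se = pl$se,
                  conf_low = if (ratio) exp(lo) else lo,
                  conf_high = if (ratio) exp(hi) else hi,
                  p = pval, converged = converged,
                  benchmark_ratio = bench_ratio)
  })
  do.call(rbind, out)
}

fitrecord_row <- function(outcome, contrast, family, scale, stratum, n_used,
                          estimate = NA_real_, se = NA_real_,
                          conf_low = NA_real_, conf_high = NA_real_,
                          p = NA_real_, converged = FALSE,
                          benchmark_ratio = NA_real_) {
  data.frame(outcome = outcome, contrast = contrast, family = family,
             scale = scale, estimate = estimate, se = se,
             conf_low = conf_low, conf_high = conf_high, p = p,
             q = NA_real_, n_used = n_used, stratum = stratum,
             converged = converged, benchmark_ratio = benchmark_ratio,
             stringsAsFactors = FALSE)
}

#' Fit one outcome against the categorical exposure, pooled over
#' imputations
#'
#' One record per non-reference exposure level (1, 2, 3, 4-5 versus 0);
#' multinomial outcomes yield one record per outcome level and exposure
#' level. Estimates are pooled on the link scale by Rubin's rules and
#' exponentiated for ratio families; modified Poisson uses an HC1
#' sandwich variance. Non-convergent or inestimable fits return flagged
#' records rather than aborting.
#'
#' @param stack An `imputed_stack` (or a single data frame, treated as
#'   m = 1) whose datasets contain the exposure column.
#' @param exposure Name of the categorical exposure column (factor with
#'   reference level first).
#' @param covariates Adjustment covariate names.
#' @param spec One-row list/data frame with `name`, `type`, `prevalence`.
#' @param stratum Label stored on the records.
#' @param benchmark Covariate whose coefficient is kept as the
#'   E-value robustness benchmark.
#' @return Data frame of fit records.
#' @export
fit_outcome <- function(stack, exposure, covariates, spec, stratum = "all",
                        benchmark = "maternal_smoking") {
  datasets <- if (inherits(stack, "imputed_stack")) stack$complete
    else list(stack)
  family <- select_family(spec$type, spec$prevalence %||% NA_real_)
  ex0 <- datasets[[1]][[exposure]]
  if (length(unique(stats::na.omit(ex0))) < 2) {
    stop("exposure is constant: no contrast estimable", call. = FALSE)
  }
  n_used <- nrow(datasets[[1]])
  fits <- tryCatch(
    lapply(datasets, fit_once, outcome = spec$name, exposure_term = exposure,
           covariates = covariates, family = family, benchmark = benchmark),
    error = function(e) NULL
  )
  if (is.null(fits)) {
    return(fitrecord_row(spec$name, "all-levels", family,
                         scale_of_family(family), stratum, n_used))
  }
  pool_fits(fits, exposure, exposure_is_factor = is.factor(ex0),
            family = family, outcome = spec$name, n_used = n_used,
            stratum = stratum,
            ref = if (is.factor(ex0)) levels(droplevels(ex0))[1] else "0")
}

#' Linear trend fit across exposure categories
#'
#' Treats the 5-level exposure category as a continuous score (0, 1, 2,
#' 3, 4 -- the combined top category scored 4) and reports a single
#' per-level estimate, pooled over imputations.
#'
#' @inheritParams fit_outcome
#' @param exposure Name of the numeric trend-score column.
#' @return Data frame with one record (several for multinomial).
#' @export
trend_fit <- function(stack, exposure, covariates, spec, stratum = "all",
                      benchmark = "maternal_smoking") {
  datasets <- if (inherits(stack, "imputed_stack")) stack$complete
    else list(stack)
  family <- select_family(spec$type, spec$prevalence %||% NA_real_)
  ex0 <- datasets[[1]][[exposure]]
  if (!is.numeric(ex0)) stop("trend exposure must be numeric", call. = FALSE)
  if (stats::sd(ex0, na.rm = TRUE) < 1e-12) {
    stop("exposure is constant: no contrast estimable", call. = FALSE)
  }
  n_used <- nrow(datasets[[1]])
  fits <- tryCatch(
    lapply(datasets, fit_once, outcome = spec$name, exposure_term = exposure,
           covariates = covariates, family = family, benchmark = benchmark),
    error = function(e) NULL
  )
  if (is.null(fits)) {
    return(fitrecord_row(spec$name, "trend", family,
                         scale_of_family(family), stratum, n_used))
  }
  pool_fits(fits, exposure, exposure_is_factor = FALSE, family = family,
            outcome = spec$name, n_used = n_used, stratum = stratum)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH q-values with rejection at `q <= alpha`.
#'
#' @param p Numeric vector of p-values in [0,1].
#' @param alpha FDR level.
#' @return Data frame with `p`, `q`, `rejected`.
#' @export
bh_fdr <- function(p, alpha = 0.05) {
  if (length(p) == 0) {
    return(data.frame(p = numeric(0), q = numeric(0), rejected = logical(0)))
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0,1]", call. = FALSE)
  }
  q <- stats::p.adjust(p, method = "BH")
  data.frame(p = p, q = q, rejected = !is.na(q) & q <= alpha)
}

#' Count FDR tests contributed by an outcome catalog
#'
#' Each continuous or binary outcome contributes one test per exposure
#' contrast; a categorical outcome with `k` levels contributes `k - 1`.
#'
#' @param catalog Screened catalog with `type` and, for categorical
#'   outcomes, `k` columns.
#' @return Integer test count per contrast.
#' @export
count_tests <- function(catalog) {
  k <- catalog$k %||% rep(NA_integer_, nrow(catalog))
  per <- ifelse(catalog$type == "categorical", k - 1L, 1L)
  if (any(is.na(per))) {
    stop("categorical outcomes need a `k` column to enumerate tests",
         call. = FALSE)
  }
  sum(per)
}

#' Run the observational outcome-wide analysis
#'
#' Screens the catalog, codes the exposure from the imputed item scores,
#' fits every included outcome with its dispatched family (per-level
#' contrasts and the linear trend), pools over imputations, and applies
#' BH FDR separately within each stratum and exposure contrast.
#' Per-outcome failures are carried as flagged records, never aborting
#' the sweep; non-convergent records are excluded from the FDR
#' enumeration (their count is logged in the `enumeration` attribute).
#'
#' @param stack An `imputed_stack` (or a complete data frame, treated as
#'   m = 1). Each dataset must contain the five `item_*` columns and the
#'   covariates.
#' @param catalog Outcome catalog (`name`, `type`, optional `theme`,
#'   `k`).
#' @param config List: `cutoffs` (mandatory, five per-item cut-offs),
#'   `alpha` (default 0.05), `covariates` (default [owa_covariates()]),
#'   `strata` (subset of `c("all","female","male")`), `contrasts`
#'   (subset of `c("levels","trend")`), `screen_data` (pre-imputation
#'   data frame used for screening; defaults to the first completed
#'   dataset).
#' @return Data frame of fit records with q-values; attributes
#'   `screening` (the screened catalog) and `enumeration` (tests per
#'   stratum x contrast).
#' @export
run_observational_owa <- function(stack, catalog, config) {
  if (is.null(config$cutoffs)) {
    stop("config$cutoffs (five item cut-offs) is mandatory", call. = FALSE)
  }
  alpha <- config$alpha %||% 0.05
  covariates <- config$covariates %||% owa_covariates()
  strata <- config$strata %||% c("all", "female", "male")
  contrasts <- config$contrasts %||% c("levels", "trend")
  datasets <- if (inherits(stack, "imputed_stack")) stack$complete
    else list(stack)
  item_cols <- grep("^item_", names(datasets[[1]]), value = TRUE)

  # exposure coding per completed dataset
  datasets <- lapply(datasets, function(d) {
    ex <- dichotomize_items(d[item_cols], config$cutoffs)
    d$mt_category <- ex$category
    d$mt_score <- ex$score
    d
  })

  screen_data <- config$screen_data %||% datasets[[1]]
  screened <- screen_outcomes(catalog, screen_data)
  if (nrow(screened) == 0 || !any(screened$included)) {
    out <- fitrecord_row("x", "x", "x", "x", "x", 0L)[0, ]
    attr(out, "screening") <- screened
    attr(out, "enumeration") <- data.frame()
    return(out)
  }
  todo <- screened[screened$included, , drop = FALSE]

  records <- list()
  for (st in strata) {
    sub <- lapply(datasets, function(d) {
      if (st == "all") d else d[d$sex == st, , drop = FALSE]
    })
    covs <- if (st == "all") covariates else setdiff(covariates, "sex")
    substack <- structure(list(complete = sub), class = "imputed_stack")
    for (i in seq_len(nrow(todo))) {
      spec <- as.list(todo[i, ])
      if ("levels" %in% contrasts) {
        rec <- tryCatch(
          fit_outcome(substack, "mt_category", covs, spec, stratum = st),
          error = function(e) {
            fitrecord_row(spec$name, "levels", "error", "beta", st,
                          nrow(sub[[1]]))
          })
        records[[length(records) + 1]] <- rec
      }
      if ("trend" %in% contrasts) {
        rec <- tryCatch(
          trend_fit(substack, "mt_score", covs, spec, stratum = st),
          error = function(e) {
            fitrecord_row(spec$name, "trend", "error", "beta", st,
                          nrow(sub[[1]]))
          })
        records[[length(records) + 1]] <- rec
      }
    }
  }
  res <- do.call(rbind, records)
  rownames(res) <- NULL

  # FDR separately per stratum and per exposure contrast; multinomial
  # outcome-level records are grouped with their exposure contrast.
  res$contrast_group <- sub("^.*:", "", res$contrast)
  res$q <- NA_real_
  enumeration <- list()
  for (st in unique(res$stratum)) {
    for (cg in unique(res$contrast_group[res$stratum == st])) {
      sel <- which(res$stratum == st & res$contrast_group == cg &
                     res$converged & is.finite(res$p))
      if (length(sel) == 0) next
      adj <- bh_fdr(res$p[sel], alpha)
      res$q[sel] <- adj$q
      enumeration[[length(enumeration) + 1]] <-
        data.frame(stratum = st, contrast = cg, n_tests = length(sel),
                   n_dropped = sum(res$stratum == st &
                                     res$contrast_group == cg) - length(sel))
    }
  }
  res$rejected <- !is.na(res$q) & res$q <= alpha
  attr(res, "screening") <- screened
  attr(res, "enumeration") <- do.call(rbind, enumeration)
  res
}
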