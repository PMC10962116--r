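#' Top principal components of a dosage matrix
#'
#' Column-standardizes the dosages (zero-variance variants dropped) and
#' returns the top `k` right-singular-vector scores. Components are
#' orthogonal; each component's sign is fixed by making its
#' largest-magnitude variant loading positive, so results do not depend
#' on the SVD implementation's sign convention.
#'
#' @param dosages Individuals x variants dosage matrix (complete, or
#'   mean-imputed per variant beforehand).
#' @param k Number of components (default 20).
#' @return n x k matrix of component scores, columns `PC1..PCk`.
#' @export
compute_pcs <- function(dosages, k = 20L) {
  X <- as.matrix(dosages)
  if (anyNA(X)) {
    # mean-impute per variant
    for (j in seq_len(ncol(X))) {
      nas <- is.na(X[, j])
      if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
    }
  }
  sds <- apply(X, 2, stats::sd)
  X <- X[, sds > 1e-12, drop = FALSE]
  X <- scale(X)
  if (k > min(dim(X))) {
    stop("k exceeds the rank of the dosage matrix", call. = FALSE)
  }
  sv <- svd(X, nu = k, nv = k)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  for (j in seq_len(k)) {
    i_max <- which.max(abs(sv$v[, j]))
    if (sv$v[i_max, j] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}

#' Run the genetic outcome-wide analysis
#'
#' Regresses every included outcome on the standardized polygenic score
#' (or on its quintiles, with quintile 1 as reference plus a linear test
#' of trend over the quintile index), adjusting for birth year, sex,
#' sequencing array, and the top principal components. Family dispatch
#' reuses the observational rule; BH FDR is applied per contrast within
#' stratum.
#'
#' @param data Cohort data frame (complete covariates and outcomes) with
#'   columns `birth_year`, `sex`, `seq_array`.
#' @param scores A `score_vector` (from [compute_score()] or
#'   [prs_pipeline()]) aligned row-wise with `data`.
#' @param catalog Outcome catalog (`name`, `type`, optional `theme`,
#'   `k`).
#' @param config List: `alpha` (default 0.05), `pcs` (matrix from
#'   [compute_pcs()], or NULL to omit), `strata` (default `"all"`),
#'   `use_quintiles` (default FALSE), `screen_data` (defaults to
#'   `data`).
#' @return Data frame of fit records (estimates per SD of the PRS, or
#'   per quintile contrast) with q-values; attributes as in
#'   [run_observational_owa()].
#' @export
run_genetic_owa <- function(data, scores, catalog, config = list()) {
  stopifnot(inherits(scores, "score_vector") || is.data.frame(scores))
  alpha <- config$alpha %||% 0.05
  strata <- config$strata %||% "all"
  use_quintiles <- isTRUE(config$use_quintiles)
  if (nrow(scores) != nrow(data)) {
    stop("scores and cohort rows must align", call. = FALSE)
  }
  if (stats::sd(scores$raw) < 1e-12) {
    stop("PRS has zero variance: no contrast estimable", call. = FALSE)
  }
  d <- data
  d$prs_std <- scores$standardized %||% zstd(scores$raw)
  d$prs_quintile <- factor(scores$quintile, levels = 1:5)
  d$prs_quintile_score <- as.numeric(scores$quintile)

  pcs <- config$pcs
  pc_names <- character(0)
  if (!is.null(pcs)) {
    pc_names <- colnames(pcs)
    d[pc_names] <- as.data.frame(pcs)
  }
  base_covs <- c("birth_year", "sex", "seq_array", pc_names)

  screened <- screen_outcomes(catalog, config$screen_data %||% data)
  todo <- screened[screened$included, , drop = FALSE]

  records <- list()
  for (st in strata) {
    sub <- if (st == "all") d else d[d$sex == st, , drop = FALSE]
    covs <- if (st == "all") base_covs else setdiff(base_covs, "sex")
    for (i in seq_len(nrow(todo))) {
      spec <- as.list(todo[i, ])
      if (use_quintiles) {
        rec <- tryCatch(
          fit_outcome(sub, "prs_quintile", covs, spec, stratum = st),
          error = function(e) fitrecord_row(spec$name, "quintiles", "error",
                                            "beta", st, nrow(sub)))
        records[[length(records) + 1]] <- rec
        rec <- tryCatch(
          trend_fit(sub, "prs_quintile_score", covs, spec, stratum = st),
          error = function(e) fitrecord_row(spec$name, "trend", "error",
                                            "beta", st, nrow(sub)))
        records[[length(records) + 1]] <- rec
      } else {
        rec <- tryCatch(
          trend_fit(sub, "prs_std", covs, spec, stratum = st),
          error = function(e) fitrecord_row(spec$name, "per-sd", "error",
                                            "beta", st, nrow(sub)))
        rec$contrast[rec$contrast == "trend"] <- "per-sd"
        rec$contrast <- sub(":trend$", ":per-sd", rec$contrast)
        records[[length(records) + 1]] <- rec
      }
    }
  }
  res <- do.call(rbind, records)
  rownames(res) <- NULL
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
        data.frame(stratum = st, contrast = cg, n_tests = length(sel))
    }
  }
  res$rejected <- !is.na(res$q) & res$q <= alpha
  attr(res, "screening") <- screened
  attr(res, "enumeration") <- do.call(rbind, enumeration)
  res
}
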