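#' Settings for multiple imputation by chained equations
#'
#' @param m Number of completed datasets.
#' @param max_iterations Gibbs sweeps of the chained equations.
#' @param pmm_donors Donor-pool size for predictive mean matching.
#' @param method_map Optional named character vector mapping variable
#'   names to `"pmm"`, `"logistic"`, or `"polytomous"`; variables not
#'   named fall back to the type default (numeric -> pmm, two-level
#'   factor -> logistic, multi-level factor -> polytomous).
#' @param auxiliary_variables Optional character vector of extra columns
#'   to include as predictors in every imputation model (e.g. a capped
#'   list of outcomes).
#' @param seed Integer seed.
#' @return An `impute_settings` object.
#' @export
impute_settings <- function(m = 10L, max_iterations = 10L, pmm_donors = 5L,
                            method_map = NULL, auxiliary_variables = NULL,
                            seed = 1L) {
  stopifnot(m >= 1, max_iterations >= 1, pmm_donors >= 1)
  structure(list(m = as.integer(m),
                 max_iterations = as.integer(max_iterations),
                 pmm_donors = as.integer(pmm_donors),
                 method_map = method_map,
                 auxiliary_variables = auxiliary_variables,
                 seed = as.integer(seed)),
            class = "impute_settings")
}

# Bayesian linear regression draw (as used by PMM): returns the
# least-squares fit and a posterior draw of the coefficients.
draw_lm <- function(X, y) {
  p <- ncol(X)
  xtx <- crossprod(X) + diag(1e-8, p)  # ridge jitter against singularity
  R <- chol(xtx)
  beta_hat <- backsolve(R, forwardsolve(t(R), crossprod(X, y)))
  resid <- y - X %*% beta_hat
  df <- max(length(y) - p, 1)
  sigma2_star <- sum(resid^2) / stats::rchisq(1, df)
  beta_star <- beta_hat +
    backsolve(R, stats::rnorm(p)) * sqrt(sigma2_star)
  list(beta_hat = beta_hat, beta_star = beta_star)
}

# Draw coefficients from the asymptotic normal posterior of a fitted
# glm / multinomial model.
draw_coef <- function(coefs, vc) {
  coefs[!is.finite(coefs)] <- 0  # aliased/singular terms contribute nothing
  vc[!is.finite(vc)] <- 0
  L <- tryCatch(chol(vc), error = function(e) {
    chol(vc + diag(max(diag(vc), 1e-8) * 1e-6 + 1e-10, nrow(vc)))
  })
  coefs + as.numeric(t(L) %*% stats::rnorm(length(coefs)))
}

impute_one_variable <- function(data, target, predictors, method, donors) {
  obs <- !is.na(data[[target]])
  mis <- which(!obs)
  if (length(mis) == 0) return(data)
  rhs <- paste(predictors, collapse = " + ")
  X_all <- stats::model.matrix(
    stats::as.formula(paste("~", rhs)), data = data
  )
  X_obs <- X_all[obs, , drop = FALSE]
  X_mis <- X_all[!obs, , drop = FALSE]
  y_obs <- data[[target]][obs]

  if (method == "pmm") {
    d <- draw_lm(X_obs, as.numeric(y_obs))
    yhat_obs <- as.numeric(X_obs %*% d$beta_hat)   # type-1 matching
    yhat_mis <- as.numeric(X_mis %*% d$beta_star)
    # k-nearest donors by predicted mean: the nearest k live in a window
    # of 2k sorted predictions around each missing value's insertion point
    ord <- order(yhat_obs)
    yh_s <- yhat_obs[ord]
    y_s <- as.numeric(y_obs)[ord]
    n_obs <- length(y_s)
    k <- min(donors, n_obs)
    pos <- findInterval(yhat_mis, yh_s)
    n_mis <- length(yhat_mis)
    cand <- pmin(pmax(outer(pos, (-k + 1L):k, `+`), 1L), n_obs)
    D <- abs(matrix(yh_s[cand], n_mis) - yhat_mis)
    kth <- apply(D, 1, function(r) sort.int(r, partial = k)[k])
    elig <- D <= kth
    # uniform draw among eligible donors: argmax of iid uniforms
    score <- matrix(stats::runif(length(elig)), n_mis)
    score[!elig] <- -1
    pick <- max.col(score)
    imp <- y_s[cand[cbind(seq_len(n_mis), pick)]]
    if (is.integer(data[[target]])) imp <- as.integer(round(imp))
    data[[target]][mis] <- imp
  } else if (method == "logistic") {
    yf <- if (is.factor(y_obs)) y_obs else factor(y_obs)
    fit <- suppressWarnings(
      stats::glm.fit(X_obs, as.numeric(yf) - 1, family = stats::binomial())
    )
    vc <- tryCatch({
      w <- fit$weights
      solve(crossprod(X_obs * sqrt(w)))
    }, error = function(e) diag(1e6, ncol(X_obs)))
    beta_star <- draw_coef(stats::coef(fit), vc)
    p <- stats::plogis(as.numeric(X_mis %*% beta_star))
    draw <- as.integer(stats::runif(length(mis)) < p) + 1L
    imp <- levels(yf)[draw]
    data[[target]][mis] <- if (is.factor(data[[target]])) {
      factor(imp, levels = levels(data[[target]]))[seq_along(mis)]
    } else {
      methods_cast(imp, data[[target]])
    }
  } else if (method == "polytomous") {
    yf <- droplevels(if (is.factor(y_obs)) y_obs else factor(y_obs))
    k <- nlevels(yf)
    if (k < 2) {
      data[[target]][mis] <- levels(yf)[1]
      return(data)
    }
    fit <- nnet::multinom(yf ~ X_obs - 1, trace = FALSE,
                          MaxNWts = 5000, maxit = 200)
    co <- stats::coef(fit)
    if (is.null(dim(co))) co <- matrix(co, nrow = 1)
    vc <- tryCatch(stats::vcov(fit),
                   error = function(e) diag(1e-4, length(co)))
    # nnet stacks coefficients row-wise per non-reference class
    beta_star <- draw_coef(as.numeric(t(co)), vc)
    B <- matrix(beta_star, nrow = k - 1, byrow = TRUE)
    eta <- cbind(0, X_mis %*% t(B))
    pr <- exp(eta - apply(eta, 1, max))
    pr <- pr / rowSums(pr)
    draw <- vapply(seq_len(nrow(pr)), function(i) {
      sample.int(k, 1, prob = pr[i, ])
    }, integer(1))
    imp <- levels(yf)[draw]
    data[[target]][mis] <- factor(imp, levels = levels(data[[target]]))[seq_along(mis)]
  } else {
    stop("unknown imputation method: ", method, call. = FALSE)
  }
  # hot-deck fallback for any cell a degenerate model failed to fill
  still <- is.na(data[[target]][mis])
  if (any(still)) {
    data[[target]][mis[still]] <- sample(y_obs, sum(still), replace = TRUE)
  }
  data
}

methods_cast <- function(x, template) {
  if (is.integer(template)) as.integer(x)
  else if (is.numeric(template)) as.numeric(x)
  else x
}

default_method <- function(x) {
  if (is.numeric(x)) "pmm"
  else if (is.factor(x) && nlevels(droplevels(x[!is.na(x)])) <= 2) "logistic"
  else "polytomous"
}

#' Multiple imputation by chained equations
#'
#' Iteratively imputes each variable with missingness from all other
#' variables (plus declared auxiliaries): predictive mean matching for
#' numeric variables (posterior-draw regression, type-1 matching,
#' hot-deck donors), logistic regression for binary variables, and
#' polytomous (multinomial-logit) regression for categorical variables,
#' drawing model parameters from their asymptotic posterior at each
#' step. Variables are visited in order of ascending missingness.
#' Exposure-item "prefer not to say" sentinels must be converted to `NA`
#' first (see [resolve_pns()]).
#'
#' @param data Data frame with missing cells.
#' @param settings An [impute_settings()].
#' @param predictors Optional character vector of predictor columns;
#'   defaults to every column except `id`, with imputation targets
#'   included as they complete.
#' @return An `imputed_stack`: list with `complete` (list of `m`
#'   completed data frames), `trace` (per chain x iteration x variable
#'   mean of imputed values), and `settings`.
#' @export
impute_chained <- function(data, settings = impute_settings(),
                           predictors = NULL) {
  stopifnot(is.data.frame(data), inherits(settings, "impute_settings"))
  if (any(vapply(data, function(x) all(is.na(x)), logical(1)))) {
    stop("a variable is 100% missing and cannot be imputed", call. = FALSE)
  }
  item_cols <- grep("^item_", names(data), value = TRUE)
  if (any(vapply(data[item_cols], function(x) any(x == -1L, na.rm = TRUE),
                 logical(1)))) {
    stop("exposure items still carry the PNS sentinel; run resolve_pns() first",
         call. = FALSE)
  }
  targets <- names(data)[vapply(data, anyNA, logical(1))]
  if (length(targets) == 0) {
    return(structure(list(
      complete = rep(list(data), settings$m),
      trace = NULL, settings = settings
    ), class = "imputed_stack"))
  }
  method_of <- vapply(targets, function(v) {
    mm <- settings$method_map
    if (!is.null(mm) && v %in% names(mm)) mm[[v]] else default_method(data[[v]])
  }, character(1))
  bad <- !method_of %in% c("pmm", "logistic", "polytomous")
  if (any(bad)) {
    stop("no imputation method for: ",
         paste(targets[bad], collapse = ", "), call. = FALSE)
  }
  # visit order: ascending missingness fraction
  miss_frac <- vapply(targets, function(v) mean(is.na(data[[v]])), numeric(1))
  targets <- targets[order(miss_frac)]
  method_of <- method_of[targets]

  if (is.null(predictors)) {
    predictors <- setdiff(names(data), "id")
  }
  aux <- settings$auxiliary_variables
  if (!is.null(aux)) predictors <- union(predictors, aux)

  na_mask <- lapply(data[targets], is.na)
  names(na_mask) <- targets

  set.seed(settings$seed)
  chain_seeds <- sample.int(2^30, settings$m)
  completes <- vector("list", settings$m)
  trace <- array(NA_real_,
                 dim = c(settings$m, settings$max_iterations, length(targets)),
                 dimnames = list(NULL, NULL, targets))
  for (ch in seq_len(settings$m)) {
    set.seed(chain_seeds[ch])
    cur <- data
    # initialize missing cells by sampling observed values
    for (v in targets) {
      obs_vals <- cur[[v]][!is.na(cur[[v]])]
      cur[[v]][na_mask[[v]]] <- sample(obs_vals, sum(na_mask[[v]]),
                                       replace = TRUE)
    }
    for (it in seq_len(settings$max_iterations)) {
      for (v in targets) {
        cur[[v]][na_mask[[v]]] <- NA
        preds <- setdiff(predictors, v)
        cur <- impute_one_variable(cur, v, preds, method_of[[v]],
                                   settings$pmm_donors)
        imp_vals <- cur[[v]][na_mask[[v]]]
        trace[ch, it, v] <- if (is.numeric(imp_vals)) mean(imp_vals) else {
          mean(as.numeric(factor(imp_vals)))
        }
      }
    }
    completes[[ch]] <- cur
  }
  structure(list(complete = completes, trace = trace, settings = settings),
            class = "imputed_stack")
}

#' Extract one completed dataset from an imputed stack
#' @param stack An `imputed_stack`.
#' @param i Index in `1..m`.
#' @return The i-th completed data frame.
#' @export
complete_data <- function(stack, i = 1L) {
  stopifnot(inherits(stack, "imputed_stack"))
  stack$complete[[i]]
}

#' Pool estimates across imputations by Rubin's rules
#'
#' The pooled estimate is the mean of the per-imputation estimates; the
#' total variance is the mean within-imputation variance plus
#' `(1 + 1/m)` times the between-imputation variance; degrees of freedom
#' follow Barnard-Rubin (reducing to the classical Rubin df when the
#' complete-data df is infinite).
#'
#' @param estimates Numeric vector of per-imputation estimates.
#' @param ses Numeric vector of their standard errors (all > 0).
#' @param dfcom Complete-data degrees of freedom (default `Inf`).
#' @return List with `estimate`, `se`, `df`, and the variance
#'   components `within` and `between`.
#' @export
pool_rubin <- function(estimates, ses, dfcom = Inf) {
  if (length(estimates) != length(ses)) {
    stop("estimates and ses must have equal length", call. = FALSE)
  }
  if (any(ses <= 0) || any(!is.finite(estimates)) || any(!is.finite(ses))) {
    stop("all estimates must be finite and all SEs positive", call. = FALSE)
  }
  m <- length(estimates)
  qbar <- mean(estimates)
  within <- mean(ses^2)
  between <- if (m > 1) stats::var(estimates) else 0
  total <- within + (1 + 1 / m) * between
  if (between < 1e-300 || m == 1) {
    df <- dfcom
  } else {
    r <- (1 + 1 / m) * between / within
    df_old <- (m - 1) * (1 + 1 / r)^2
    if (is.finite(dfcom)) {
      lambda <- (1 + 1 / m) * between / total
      df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
      df <- 1 / (1 / df_old + 1 / df_obs)
    } else {
      df <- df_old
    }
  }
  list(estimate = qbar, se = sqrt(total), df = df,
       within = within, between = between)
}
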