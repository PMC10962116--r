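#' Outcome ground truth for the synthetic cohort
#'
#' Declares one outcome of the synthetic cohort together with the causal
#' structure that generates it. The three effect channels --
#' `true_effect_exposure` (a real effect of the maltreatment count),
#' `confounder_loadings` (including the unmeasured childhood confounder
#' `u_childhood`, which biases the observational arm only), and
#' `pleiotropy_effect` (a direct genetic effect bypassing the exposure,
#' which biases the genetic arm only) -- are exactly the structures the
#' two analysis arms are differentially sensitive to.
#'
#' @param name Outcome column name.
#' @param family One of `"continuous"`, `"binary"`, `"categorical"`.
#' @param true_effect_exposure Effect per unit of the analysis-coded
#'   maltreatment category (0,1,2,3,4) on the linear predictor.
#' @param confounder_loadings Named numeric vector of effects of
#'   standardized covariates (or `u_childhood`) on the linear predictor.
#' @param pleiotropy_effect Effect of the standardized true genetic
#'   score on the linear predictor, bypassing the exposure.
#' @param base_rate Target prevalence for binary outcomes (in (0,1)).
#' @param k Number of categories for categorical outcomes (>= 3).
#' @param link Link for binary outcomes: `"logit"` (odds-ratio truth) or
#'   `"log"` (risk-ratio truth, for common outcomes).
#' @param theme Grouping label used by the triangulation summary.
#' @return An `outcome_truth` object (a list).
#' @export
outcome_truth <- function(name,
                          family = c("continuous", "binary", "categorical"),
                          true_effect_exposure = 0,
                          confounder_loadings = numeric(),
                          pleiotropy_effect = 0,
                          base_rate = NULL,
                          k = 3L,
                          link = c("logit", "log"),
                          theme = "general") {
  family <- match.arg(family)
  link <- match.arg(link)
  if (family == "binary") {
    if (is.null(base_rate) || base_rate <= 0 || base_rate >= 1) {
      stop("binary outcomes need base_rate in (0,1)", call. = FALSE)
    }
  }
  if (family == "categorical" && k < 3L) {
    stop("categorical outcomes need k >= 3", call. = FALSE)
  }
  structure(list(name = name, family = family,
                 true_effect_exposure = true_effect_exposure,
                 confounder_loadings = confounder_loadings,
                 pleiotropy_effect = pleiotropy_effect,
                 base_rate = base_rate, k = as.integer(k), link = link,
                 theme = theme),
            class = "outcome_truth")
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic study: cohort size, genotype
#' panel layout (LD blocks of correlated biallelic variants), the
#' liability model for the five maltreatment items, the outcome truth
#' list, questionnaire non-response, covariate missingness, and the
#' emulated GWAS discovery sample size.
#'
#' @param n_individuals,n_variants Cohort and panel dimensions.
#' @param block_size Variants per LD block.
#' @param ld_rho Target dosage correlation within a block, in [0,1).
#' @param maf_range Length-2 vector of minor-allele-frequency bounds in
#'   (0, 0.5].
#' @param h2_liability Share of maltreatment-liability variance
#'   explained by the genetic score, in [0,1).
#' @param confounder_effects Named numeric vector: effect of each
#'   standardized covariate (and of the unmeasured `u_childhood`) on the
#'   liability.
#' @param item_thresholds 5 x 4 matrix of strictly increasing cutpoints
#'   mapping the latent item value (liability + item noise) to the
#'   ordinal 1-5 response.
#' @param item_noise_sd Standard deviation of the per-item noise added
#'   to the shared liability.
#' @param item_cutoffs Integer vector of length 5: the score at or above
#'   which each item counts as exposure-positive (used both to generate
#'   outcome effects of the count and, downstream, to code the exposure).
#' @param outcome_specs List of [outcome_truth()] objects.
#' @param pns_rate Probability an item response is replaced by the
#'   "prefer not to say" sentinel, in [0, 0.01].
#' @param missing_rate_covariates Marginal covariate missingness rate.
#' @param missing_targets Covariates subjected to missingness (default:
#'   every covariate except the complete conditioning set sex, ages,
#'   birth year, and sequencing array).
#' @param info_range Range of simulated imputation info scores.
#' @param gwas_n Emulated discovery-GWAS sample size.
#' @param seed Integer seed; all generator operations are deterministic
#'   functions of it.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_individuals = 5000L,
                       n_variants = 200L,
                       block_size = 10L,
                       ld_rho = 0.4,
                       maf_range = c(0.05, 0.45),
                       h2_liability = 0.25,
                       confounder_effects = c(maternal_smoking = 0.25,
                                              maternal_depression = 0.20,
                                              n_siblings = 0.10,
                                              breastfed = -0.10,
                                              sex = 0.15,
                                              u_childhood = 0.35),
                       item_thresholds = NULL,
                       item_noise_sd = 0.8,
                       item_cutoffs = rep(3L, 5L),
                       outcome_specs = list(),
                       pns_rate = 0.005,
                       missing_rate_covariates = 0.05,
                       missing_targets = NULL,
                       info_range = c(0.9, 1.0),
                       gwas_n = 185414L,
                       seed = 1L) {
  if (n_individuals <= 0 || n_variants <= 0 || block_size <= 0) {
    stop("dimensions must be positive", call. = FALSE)
  }
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must be in [0,1)", call. = FALSE)
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5) {
    stop("maf_range must be an increasing pair in (0, 0.5]", call. = FALSE)
  }
  if (h2_liability < 0 || h2_liability >= 1) {
    stop("h2_liability must be in [0,1)", call. = FALSE)
  }
  if (pns_rate < 0 || pns_rate > 0.01) {
    stop("pns_rate must be in [0, 0.01]", call. = FALSE)
  }
  if (missing_rate_covariates < 0 || missing_rate_covariates > 1) {
    stop("missing_rate_covariates must be a probability", call. = FALSE)
  }
  if (is.null(item_thresholds)) {
    # latent item = liability (var 1) + noise: default cutpoints give
    # marginal response shares of roughly 55/20/12/8/5 percent
    latent_sd <- sqrt(1 + item_noise_sd^2)
    item_thresholds <- matrix(
      rep(stats::qnorm(c(0.55, 0.75, 0.87, 0.95)) * latent_sd, each = 5),
      nrow = 5
    )
  }
  item_thresholds <- as.matrix(item_thresholds)
  if (!all(dim(item_thresholds) == c(5L, 4L))) {
    stop("item_thresholds must be a 5 x 4 matrix (4 cutpoints per item)",
         call. = FALSE)
  }
  if (any(apply(item_thresholds, 1, function(r) any(diff(r) <= 0)))) {
    stop("item thresholds must be strictly increasing", call. = FALSE)
  }
  if (length(item_cutoffs) != 5L || any(item_cutoffs < 2L | item_cutoffs > 5L)) {
    stop("item_cutoffs must be 5 integers in 2..5", call. = FALSE)
  }
  if (gwas_n <= 0) stop("gwas_n must be positive", call. = FALSE)
  if (!is.numeric(seed) || seed >= 2^31 - 10) {
    stop("seed must be an integer below 2^31 - 10", call. = FALSE)
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 n_variants = as.integer(n_variants),
                 block_size = as.integer(block_size),
                 ld_rho = ld_rho, maf_range = maf_range,
                 h2_liability = h2_liability,
                 confounder_effects = confounder_effects,
                 item_thresholds = item_thresholds,
                 item_noise_sd = item_noise_sd,
                 item_cutoffs = as.integer(item_cutoffs),
                 outcome_specs = outcome_specs,
                 pns_rate = pns_rate,
                 missing_rate_covariates = missing_rate_covariates,
                 missing_targets = missing_targets,
                 info_range = info_range,
                 gwas_n = as.integer(gwas_n),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# P(Z1 < t1, Z2 < t2) for standard bivariate normal with correlation rho,
# by 1-D quadrature: integral over z1 of Phi((t2 - rho z1)/sqrt(1-rho^2)).
bvn_lower <- function(t1, t2, rho) {
  if (abs(rho) < 1e-12) return(stats::pnorm(t1) * stats::pnorm(t2))
  s <- sqrt(1 - rho^2)
  stats::integrate(function(z) {
    stats::pnorm((t2 - rho * z) / s) * stats::dnorm(z)
  }, lower = -Inf, upper = t1, rel.tol = 1e-10)$value
}

# Latent Gaussian correlation that yields a target Pearson correlation
# between two allele indicators thresholded at frequency `maf`.
calibrate_latent_rho <- function(target, maf) {
  if (target <= 0) return(0)
  t <- stats::qnorm(maf)
  f <- function(rho) {
    p11 <- bvn_lower(t, t, rho)
    (p11 - maf^2) / (maf * (1 - maf)) - target
  }
  hi <- 1 - 1e-9
  if (f(hi) < 0) return(hi)  # target unreachable; saturate
  stats::uniroot(f, c(0, hi), tol = 1e-8)$root
}

#' Simulate an LD-structured biallelic genotype panel
#'
#' Haplotypes are drawn from a per-block Gaussian copula (equicorrelated
#' latent factors, thresholded at the allele frequency) so that dosage
#' correlations within a block approximate `ld_rho`; blocks are mutually
#' independent and separated by large positional gaps. One variant per
#' block (the middle one) carries a causal effect on the maltreatment
#' liability.
#'
#' @param config A [sim_config()].
#' @return A `genotype_panel`: list with `dosages` (n x m integer matrix,
#'   values 0-2, columns named by variant id) and `variants` (metadata
#'   data frame: snp, chr, pos, a1 = counted/effect allele, a2,
#'   beta_liability = raw causal effect, maf, info, hwe_p, block).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  m <- config$n_variants
  bs <- config$block_size
  n_blocks <- ceiling(m / bs)
  block <- rep(seq_len(n_blocks), each = bs)[seq_len(m)]
  # one MAF per block: equal thresholds make the copula calibration of
  # the within-block dosage correlation exact
  maf_block <- stats::runif(n_blocks, config$maf_range[1], config$maf_range[2])
  maf <- maf_block[block]

  dos <- matrix(0L, n, m)
  for (b in seq_len(n_blocks)) {
    idx <- which(block == b)
    k <- length(idx)
    rho_lat <- if (k > 1) {
      calibrate_latent_rho(config$ld_rho, mean(maf[idx]))
    } else 0
    for (hap in 1:2) {
      shared <- stats::rnorm(n)
      z <- sqrt(rho_lat) * matrix(shared, n, k) +
        sqrt(1 - rho_lat) * matrix(stats::rnorm(n * k), n, k)
      alleles <- sweep(z, 2, stats::qnorm(maf[idx]), `<`)
      dos[, idx] <- dos[, idx] + alleles
    }
  }
  storage.mode(dos) <- "integer"

  # two chromosomes, blocks 1 Mb apart, variants 5 kb apart within block
  chr_of_block <- ifelse(seq_len(n_blocks) <= ceiling(n_blocks / 2), 1L, 2L)
  chr <- chr_of_block[block]
  pos <- integer(m)
  for (cc in unique(chr)) {
    on_c <- which(chr == cc)
    blk_local <- match(block[on_c], unique(block[on_c]))
    within <- stats::ave(seq_along(on_c), blk_local, FUN = seq_along)
    pos[on_c] <- blk_local * 1000000L + within * 5000L
  }

  # one causal variant per block (middle of block)
  beta <- numeric(m)
  for (b in seq_len(n_blocks)) {
    idx <- which(block == b)
    causal <- idx[ceiling(length(idx) / 2)]
    beta[causal] <- stats::rnorm(1)
  }

  bases <- c("A", "C", "G", "T")
  a1 <- sample(bases, m, replace = TRUE)
  a2 <- vapply(a1, function(x) sample(setdiff(bases, x), 1), character(1))

  # HWE exact-ish chi-square p from realized genotype counts
  hwe_p <- vapply(seq_len(m), function(j) {
    counts <- tabulate(dos[, j] + 1L, nbins = 3L)
    p_hat <- (2 * counts[3] + counts[2]) / (2 * n)
    e <- n * c((1 - p_hat)^2, 2 * p_hat * (1 - p_hat), p_hat^2)
    if (any(e < 1e-9)) return(1)
    x2 <- sum((counts - e)^2 / e)
    stats::pchisq(x2, df = 1, lower.tail = FALSE)
  }, numeric(1))

  variants <- data.frame(
    snp = sprintf("rs%05d", seq_len(m)),
    chr = chr, pos = pos, a1 = a1, a2 = a2,
    beta_liability = beta, maf = maf,
    info = stats::runif(m, config$info_range[1], config$info_range[2]),
    hwe_p = hwe_p, block = block,
    stringsAsFactors = FALSE
  )
  colnames(dos) <- variants$snp
  structure(list(dosages = dos, variants = variants), class = "genotype_panel")
}

# standardized true genetic score of a panel
true_genetic_score <- function(panel) {
  g <- as.numeric(panel$dosages %*% panel$variants$beta_liability)
  if (stats::sd(g) < 1e-12) return(rep(0, length(g)))
  as.numeric(scale(g))
}

# standardize a numeric vector; constant vectors map to zero
zstd <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Simulate a synthetic cohort from a genotype panel
#'
#' Builds the covariate roster (sex, two ages, birth year, ethnicity,
#' country of birth, breastfed, multiple birth, sibling count,
#' birthweight, maternal smoking, maternal depression, sequencing
#' array), a liability-threshold model for five ordinal maltreatment
#' items, and the declared outcomes. The liability is
#' `sqrt(h2) * G_std + confounder terms + noise`, standardized to unit
#' variance; each item adds independent noise and is cut at the item
#' thresholds into a 1-5 response. Outcome linear predictors act on the
#' analysis-coded maltreatment category (0,1,2,3,4; items dichotomized
#' at `item_cutoffs`, counts of 4-5 capped at 4).
#'
#' @param config A [sim_config()].
#' @param panel A `genotype_panel` with `n_individuals` rows.
#' @return A `synthetic_cohort`: list with `data` (one row per
#'   individual) and `truth` (hidden channel: standardized genetic
#'   score, liability, unmeasured confounder, true item scores, exposure
#'   count/category, per-outcome linear predictors).
#' @export
simulate_cohort <- function(config, panel) {
  stopifnot(inherits(config, "sim_config"), inherits(panel, "genotype_panel"))
  if (nrow(panel$dosages) != config$n_individuals) {
    stop("panel rows must equal n_individuals", call. = FALSE)
  }
  if (ncol(config$item_thresholds) != 4L) {
    stop("item_thresholds must supply 4 cutpoints per item", call. = FALSE)
  }
  set.seed(config$seed + 1L)
  n <- config$n_individuals

  sex <- factor(ifelse(stats::runif(n) < 0.56, "female", "male"),
                levels = c("female", "male"))
  age_enroll <- round(stats::runif(n, 40, 70))
  age_mhq <- age_enroll + round(stats::runif(n, 5, 10))
  birth_year <- 2008L - as.integer(age_enroll)
  ethnicity <- factor(sample(c("white", "mixed", "asian", "black", "other"),
                             n, TRUE, prob = c(0.97, 0.005, 0.011, 0.008, 0.006)),
                      levels = c("white", "mixed", "asian", "black", "other"))
  country_uk <- factor(ifelse(stats::runif(n) < 0.93, "uk", "elsewhere"),
                       levels = c("uk", "elsewhere"))
  breastfed <- factor(ifelse(stats::runif(n) < 0.73, "yes", "no"),
                      levels = c("no", "yes"))
  multiple_birth <- factor(ifelse(stats::runif(n) < 0.02, "yes", "no"),
                           levels = c("no", "yes"))
  n_siblings <- stats::rpois(n, 2)
  birthweight <- stats::rnorm(n, 3.34, 0.62)
  maternal_smoking <- factor(ifelse(stats::runif(n) < 0.29, "yes", "no"),
                             levels = c("no", "yes"))
  maternal_depression <- factor(ifelse(stats::runif(n) < 0.07, "yes", "no"),
                                levels = c("no", "yes"))
  seq_array <- factor(ifelse(stats::runif(n) < 0.5, "batch1", "batch2"))
  u_childhood <- stats::rnorm(n)

  cov_std <- list(
    sex = zstd(as.numeric(sex == "female")),
    age_enroll = zstd(age_enroll),
    age_mhq = zstd(age_mhq),
    breastfed = zstd(as.numeric(breastfed == "yes")),
    multiple_birth = zstd(as.numeric(multiple_birth == "yes")),
    n_siblings = zstd(n_siblings),
    birthweight = zstd(birthweight),
    maternal_smoking = zstd(as.numeric(maternal_smoking == "yes")),
    maternal_depression = zstd(as.numeric(maternal_depression == "yes")),
    u_childhood = u_childhood
  )

  lin_comb <- function(loadings) {
    out <- rep(0, n)
    for (nm in names(loadings)) {
      if (!nm %in% names(cov_std)) {
        stop("unknown covariate in loadings: ", nm, call. = FALSE)
      }
      out <- out + loadings[[nm]] * cov_std[[nm]]
    }
    out
  }

  g_std <- true_genetic_score(panel)
  conf_part <- lin_comb(config$confounder_effects)
  h2 <- config$h2_liability
  resid_var <- max(0, 1 - h2 - stats::var(conf_part))
  liability <- sqrt(h2) * g_std + conf_part + stats::rnorm(n, 0, sqrt(resid_var))
  liability <- zstd(liability)

  item_names <- c("item_emotional_abuse", "item_physical_abuse",
                  "item_sexual_abuse", "item_emotional_neglect",
                  "item_physical_neglect")
  items <- matrix(0L, n, 5, dimnames = list(NULL, item_names))
  for (i in 1:5) {
    latent <- liability + stats::rnorm(n, 0, config$item_noise_sd)
    items[, i] <- 1L + as.integer(
      rowSums(outer(latent, config$item_thresholds[i, ], `>=`))
    )
  }
  flags <- sweep(items, 2, config$item_cutoffs, `>=`)
  count <- rowSums(flags)
  count_cat <- pmin(count, 4L)  # analysis coding: 4-5 combined

  data <- data.frame(
    id = sprintf("ind%06d", seq_len(n)),
    sex = sex, age_enroll = age_enroll, age_mhq = age_mhq,
    birth_year = birth_year, ethnicity = ethnicity,
    country_uk = country_uk, breastfed = breastfed,
    multiple_birth = multiple_birth, n_siblings = n_siblings,
    birthweight = birthweight, maternal_smoking = maternal_smoking,
    maternal_depression = maternal_depression, seq_array = seq_array,
    stringsAsFactors = FALSE
  )
  data[item_names] <- as.data.frame(items)

  truth <- data.frame(id = data$id, g_true = g_std, liability = liability,
                      u_childhood = u_childhood, count = count,
                      count_cat = count_cat, stringsAsFactors = FALSE)
  truth[paste0("true_", item_names)] <- as.data.frame(items)

  for (spec in config$outcome_specs) {
    stopifnot(inherits(spec, "outcome_truth"))
    lp <- spec$true_effect_exposure * count_cat +
      lin_comb(spec$confounder_loadings) +
      spec$pleiotropy_effect * g_std
    if (spec$family == "continuous") {
      data[[spec$name]] <- lp + stats::rnorm(n)
    } else if (spec$family == "binary") {
      if (spec$link == "logit") {
        a <- stats::uniroot(function(a) {
          mean(stats::plogis(a + lp)) - spec$base_rate
        }, c(-30, 30))$root
        p <- stats::plogis(a + lp)
      } else {
        a <- stats::uniroot(function(a) {
          mean(pmin(exp(a + lp), 1)) - spec$base_rate
        }, c(-30, 5))$root
        p <- pmin(exp(a + lp), 1)
      }
      data[[spec$name]] <- as.integer(stats::runif(n) < p)
    } else {
      # multinomial logit: reference class 1, class j slope grows with j
      k <- spec$k
      slopes <- seq(0.5, 1, length.out = k - 1)
      eta <- cbind(0, outer(lp, slopes))
      pr <- exp(eta) / rowSums(exp(eta))
      cls <- apply(pr, 1, function(p) sample.int(k, 1, prob = p))
      data[[spec$name]] <- factor(paste0("cat", cls),
                                  levels = paste0("cat", seq_len(k)))
    }
    truth[[paste0("lp_", spec$name)]] <- lp
  }

  structure(list(data = data, truth = truth, config = config),
            class = "synthetic_cohort")
}

#' Emulate GWAS summary statistics for a genotype panel
#'
#' Computes, for each variant, the marginal effect of its dosage on the
#' liability's genetic component (so LD partners of a causal variant
#' carry proportional marginal effects, as in a real GWAS), then adds
#' estimation noise with standard error `1/sqrt(gwas_n * 2 * MAF * (1 -
#' MAF))` and derives Wald p-values. Null variants therefore yield
#' uniformly distributed p-values.
#'
#' @param config A [sim_config()].
#' @param panel A `genotype_panel`.
#' @return A `summary_stats` data frame with columns `snp, chr, pos, a1,
#'   a2, beta, se, p, maf, info, hwe_p` (a1 is the effect allele).
#' @export
emulate_gwas <- function(config, panel) {
  stopifnot(inherits(config, "sim_config"), inherits(panel, "genotype_panel"))
  if (config$gwas_n <= 0) stop("gwas_n must be positive", call. = FALSE)
  set.seed(config$seed + 2L)
  g_contrib <- sqrt(config$h2_liability) * true_genetic_score(panel)
  dos <- panel$dosages
  v <- panel$variants
  true_marginal <- vapply(seq_len(ncol(dos)), function(j) {
    x <- dos[, j]
    vx <- stats::var(x)
    if (vx < 1e-12) return(0)
    stats::cov(x, g_contrib) / vx
  }, numeric(1))
  se <- 1 / sqrt(config$gwas_n * 2 * v$maf * (1 - v$maf))
  beta_hat <- true_marginal + stats::rnorm(nrow(v), 0, se)
  p <- 2 * stats::pnorm(-abs(beta_hat / se))
  p <- pmax(p, .Machine$double.xmin)  # keep p in (0,1]
  out <- data.frame(snp = v$snp, chr = v$chr, pos = v$pos,
                    a1 = v$a1, a2 = v$a2,
                    beta = beta_hat, se = se, p = p,
                    maf = v$maf, info = v$info, hwe_p = v$hwe_p,
                    stringsAsFactors = FALSE)
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Inject MAR covariate missingness and "prefer not to say" responses
#'
#' Covariate cells (all covariates except sex, ages, birth year, and
#' sequencing array, which condition the missingness) are set missing at
#' random with probability depending on observed sex and age, calibrated
#' to the marginal `missing_rate_covariates`. Item responses are
#' replaced by the "prefer not to say" sentinel (integer code -1,
#' written as `"PNS"` in TSV exports) with probability `pns_rate`.
#' The pre-missingness values are retained in the cohort's truth channel.
#'
#' @param cohort A `synthetic_cohort`.
#' @param config The same [sim_config()] used to build it.
#' @return The cohort with missingness applied; `truth` gains copies of
#'   the original covariate columns (prefixed `true_`).
#' @export
inject_missingness <- function(cohort, config) {
  stopifnot(inherits(cohort, "synthetic_cohort"),
            inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  data <- cohort$data
  truth <- cohort$truth
  n <- nrow(data)
  rate <- config$missing_rate_covariates

  miss_targets <- config$missing_targets
  if (is.null(miss_targets)) {
    miss_targets <- c("ethnicity", "country_uk", "breastfed", "multiple_birth",
                      "n_siblings", "birthweight", "maternal_smoking",
                      "maternal_depression")
  }
  for (v in miss_targets) truth[[paste0("true_", v)]] <- data[[v]]
  if (rate > 0) {
    z_age <- zstd(data$age_enroll)
    eta <- 0.6 * as.numeric(data$sex == "female") + 0.4 * z_age
    a <- stats::uniroot(function(a) mean(stats::plogis(a + eta)) - rate,
                        c(-30, 30))$root
    p_miss <- stats::plogis(a + eta)
    for (v in miss_targets) {
      data[[v]][stats::runif(n) < p_miss] <- NA
    }
  }

  item_names <- grep("^item_", names(data), value = TRUE)
  if (config$pns_rate > 0) {
    for (v in item_names) {
      hit <- stats::runif(n) < config$pns_rate
      data[[v]][hit] <- -1L
    }
  }

  cohort$data <- data
  cohort$truth <- truth
  cohort
}

#' Convert "prefer not to say" sentinels to missing values
#'
#' The questionnaire's "prefer not to say" responses are a distinct
#' category, not plain missingness; before imputation they are converted
#' to `NA` so the chained-equations engine treats them as values to
#' impute.
#'
#' @param data Cohort data frame.
#' @param columns Columns to scan (default: all `item_*` columns).
#' @return The data frame with sentinels (-1) replaced by `NA`.
#' @export
resolve_pns <- function(data, columns = grep("^item_", names(data), value = TRUE)) {
  for (v in columns) {
    x <- data[[v]]
    x[!is.na(x) & x == -1L] <- NA
    data[[v]] <- x
  }
  data
}

#' Standard covariate roster for the observational analysis
#'
#' @return Character vector of adjustment covariates: sociodemographic
#'   (sex, country of birth, ethnicity, the two ages), childhood
#'   (birthweight, sibling count, breastfed, multiple birth), and family
#'   (maternal smoking around birth, maternal severe depression) factors.
#' @export
owa_covariates <- function() {
  c("sex", "country_uk", "ethnicity", "age_enroll", "age_mhq",
    "birthweight", "n_siblings", "breastfed", "multiple_birth",
    "maternal_smoking", "maternal_depression")
}
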