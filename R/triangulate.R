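#' Classify concordance between the two analysis arms
#'
#' A pure function of the two rejection flags and effect directions:
#' both rejected with the same direction is `concordant_significant`;
#' both rejected with opposite directions is `discordant`; exactly one
#' rejected is `observational_only` or `genetic_only`; neither is
#' `neither`. Direction is the sign of the log estimate for ratio scales
#' and of the estimate itself for betas.
#'
#' @param obs_rejected,gen_rejected Logical rejection flags.
#' @param obs_direction,gen_direction Signs (+1/-1/0) of the two
#'   effects.
#' @return Category string.
#' @export
classify_concordance <- function(obs_rejected, gen_rejected,
                                 obs_direction, gen_direction) {
  if (obs_rejected && gen_rejected) {
    if (obs_direction * gen_direction > 0) "concordant_significant"
    else "discordant"
  } else if (obs_rejected) {
    "observational_only"
  } else if (gen_rejected) {
    "genetic_only"
  } else {
    "neither"
  }
}

effect_direction <- function(estimate, scale) {
  ifelse(scale %in% c("OR", "RR"), sign(log(estimate)), sign(estimate))
}

#' Join observational and genetic results into triangulation records
#'
#' Pairs the observational trend record with the genetic per-SD record
#' for every outcome present in both arms, classifies concordance, and
#' carries the observational robustness flag. Outcomes present in only
#' one arm are returned separately, not forced into a category.
#'
#' @param obs Observational results (trend contrast, `stratum == "all"`)
#'   -- typically [run_observational_owa()] output passed through
#'   [add_evalues()] so the `robust` column is available.
#' @param gen Genetic results (per-SD contrast, `stratum == "all"`).
#' @param catalog Optional catalog supplying `theme` per outcome.
#' @return List with `records` (one row per joined outcome: estimates,
#'   rejection flags, category, robustness) and `unjoined` (outcomes in
#'   only one arm).
#' @export
triangulate <- function(obs, gen, catalog = NULL) {
  o <- obs[obs$stratum == "all" & obs$contrast == "trend" & obs$converged, ,
           drop = FALSE]
  g <- gen[gen$stratum == "all" & gen$contrast == "per-sd" & gen$converged, ,
           drop = FALSE]
  both <- intersect(o$outcome, g$outcome)
  only <- union(setdiff(o$outcome, g$outcome), setdiff(g$outcome, o$outcome))
  oo <- o[match(both, o$outcome), ]
  gg <- g[match(both, g$outcome), ]
  theme <- if (!is.null(catalog) && "theme" %in% names(catalog)) {
    catalog$theme[match(both, catalog$name)]
  } else rep("general", length(both))
  category <- vapply(seq_along(both), function(i) {
    classify_concordance(oo$rejected[i], gg$rejected[i],
                         effect_direction(oo$estimate[i], oo$scale[i]),
                         effect_direction(gg$estimate[i], gg$scale[i]))
  }, character(1))
  records <- data.frame(
    outcome = both, theme = theme,
    obs_estimate = oo$estimate, obs_scale = oo$scale,
    obs_conf_low = oo$conf_low, obs_conf_high = oo$conf_high,
    obs_q = oo$q, obs_rejected = oo$rejected,
    gen_estimate = gg$estimate, gen_scale = gg$scale,
    gen_conf_low = gg$conf_low, gen_conf_high = gg$conf_high,
    gen_q = gg$q, gen_rejected = gg$rejected,
    category = category,
    robust_observational = if ("robust" %in% names(oo)) oo$robust else NA,
    stringsAsFactors = FALSE
  )
  list(records = records,
       unjoined = data.frame(outcome = only, stringsAsFactors = FALSE))
}

#' Summarize triangulation records by theme and overall
#'
#' @param records The `records` data frame from [triangulate()].
#' @return List with `overall` (category proportions plus the robust
#'   share among concordant and observational-only associations),
#'   `by_theme` (per-theme counts and proportions), and `scatter`
#'   (observational vs genetic estimate per outcome, for plotting).
#' @export
summarize_triangulation <- function(records) {
  cats <- c("concordant_significant", "observational_only", "genetic_only",
            "neither", "discordant")
  if (nrow(records) == 0) {
    return(list(overall = data.frame(category = cats, n = 0, proportion = NA),
                by_theme = data.frame(), scatter = data.frame()))
  }
  tab <- table(factor(records$category, levels = cats))
  overall <- data.frame(category = cats, n = as.integer(tab),
                        proportion = as.numeric(tab) / nrow(records))
  rob <- records$robust_observational
  overall$robust_share <- NA_real_
  for (cc in c("concordant_significant", "observational_only")) {
    sel <- records$category == cc
    if (any(sel) && !all(is.na(rob[sel]))) {
      overall$robust_share[overall$category == cc] <-
        mean(rob[sel], na.rm = TRUE)
    }
  }
  by_theme <- do.call(rbind, lapply(split(records, records$theme), function(r) {
    t2 <- table(factor(r$category, levels = cats))
    data.frame(theme = r$theme[1], category = cats, n = as.integer(t2),
               proportion = as.numeric(t2) / nrow(r),
               stringsAsFactors = FALSE)
  }))
  rownames(by_theme) <- NULL
  scatter <- records[, c("outcome", "theme", "obs_estimate", "obs_scale",
                         "gen_estimate", "gen_scale", "category")]
  list(overall = overall, by_theme = by_theme, scatter = scatter)
}
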