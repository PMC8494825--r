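# Determining each species' activity pattern. Well-sampled species (> 50
# events) go through a Poisson GLMM on per-camera period counts; species
# with 10-50 events through a Manly design-I selection-ratio test against
# period availability; species under 10 events are excluded.

#' Poisson mixed model for diel period use
#'
#' Counts independent events per camera x period (zeros included for every
#' deployed camera) and fits a Poisson GLMM with the period as fixed
#' effect, random intercepts for study site and camera, and the camera's
#' operating days as a log offset. The overall period effect is tested by a
#' Wald chi-squared on 2 df; the three pairwise period contrasts use
#' multcomp's single-step (Tukey) adjustment.
#'
#' The default offset is `log(operating_days)`, i.e. period lengths are
#' ignored and the model compares raw per-period counts;
#' `offset = "day_period_hours"` uses `log(operating_days * period_hours)`
#' so the comparison is on a per-hour rate scale.
#'
#' If the mixed model fails to converge the function falls back to a
#' fixed-effect Poisson regression with site as a covariate and flags the
#' result.
#'
#' @param events an event table (one species, or use `species` to select).
#' @param deployments a [deployment_table()] covering every camera.
#' @param spec a [diel_period_spec()].
#' @param species optional species label to subset `events`.
#' @param offset `"days"` (default) or `"day_period_hours"`.
#' @return Object of class `period_glmm`: `species`, `n`, `coefficients`
#'   (log-rate of day and twilight relative to night), `wald_chisq`, `df`,
#'   `p_value`, `pairwise` (data frame: contrast, estimate, z, p_adj),
#'   `fallback`, `model`.
#' @export
fit_period_glmm <- function(events, deployments, spec = diel_period_spec(),
                            species = NULL, offset = c("days", "day_period_hours")) {
  offset <- match.arg(offset)
  df <- as.data.frame(events)
  if (!is.null(species)) df <- df[df$species == species, , drop = FALSE]
  if (length(unique(df$species)) > 1)
    stop("events contain multiple species; pass `species`")
  sp <- if (nrow(df) > 0) df$species[1] else species
  .check_cameras_deployed(df, deployments)
  dep <- as.data.frame(deployments)
  periods <- c("night", "day", "twilight")
  dat <- expand.grid(camera_id = dep$camera_id, period = periods,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  dat <- merge(dat, dep, by = "camera_id")
  if (nrow(df) > 0) {
    obs <- as.data.frame(table(
      camera_id = df$camera_id,
      period = classify_period(df$timestamp, spec)), stringsAsFactors = FALSE)
    names(obs)[3] <- "count"
    dat <- merge(dat, obs, by = c("camera_id", "period"), all.x = TRUE)
    dat$count[is.na(dat$count)] <- 0L
  } else {
    dat$count <- 0L
  }
  dat$period <- factor(dat$period, levels = periods)
  dat$off <- if (offset == "days") log(dat$operating_days)
             else log(dat$operating_days * spec$hours[as.character(dat$period)])
  fallback <- FALSE
  model <- tryCatch({
    withCallingHandlers(
      suppressMessages(
        lme4::glmer(count ~ period + (1 | site) + (1 | camera_id),
                    data = dat, family = stats::poisson(), offset = dat$off)),
      warning = function(w) {
        if (grepl("converge", conditionMessage(w), ignore.case = TRUE))
          stop("non-convergence: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }, error = function(e) NULL)
  if (is.null(model)) {
    fallback <- TRUE
    model <- stats::glm(count ~ period + site, data = dat,
                        family = stats::poisson(), offset = dat$off)
  }
  beta <- if (fallback) stats::coef(model) else lme4::fixef(model)
  vc <- suppressWarnings(as.matrix(stats::vcov(model)))
  idx <- c("periodday", "periodtwilight")
  b <- beta[idx]
  wald <- as.numeric(t(b) %*% solve(vc[idx, idx]) %*% b)
  p <- stats::pchisq(wald, df = 2, lower.tail = FALSE)
  glht_fit <- suppressWarnings(
    multcomp::glht(model, linfct = multcomp::mcp(period = "Tukey")))
  sm <- suppressWarnings(summary(glht_fit))  # single-step adjustment
  pairwise <- data.frame(contrast = names(sm$test$coefficients),
                         estimate = as.numeric(sm$test$coefficients),
                         z = as.numeric(sm$test$tstat),
                         p_adj = as.numeric(sm$test$pvalues),
                         method = "wald", stringsAsFactors = FALSE)
  # complete separation: a period never recorded makes its Wald contrasts
  # meaningless (unbounded coefficient, huge se, p near 1); fall back to an
  # exact binomial comparison of the two periods' pooled counts, with the
  # null share set by the offset scale
  tot <- tapply(dat$count, dat$period, sum)[periods]
  for (k in seq_len(nrow(pairwise))) {
    pr <- strsplit(pairwise$contrast[k], " - ", fixed = TRUE)[[1]]
    if (min(tot[pr]) == 0 && max(tot[pr]) > 0) {
      share <- if (offset == "days") 0.5 else
        spec$hours[pr[1]] / sum(spec$hours[pr])
      bt <- stats::binom.test(tot[pr[1]], sum(tot[pr]), p = unname(share))
      pairwise$p_adj[k] <- min(1, nrow(pairwise) * bt$p.value)
      pairwise$z[k] <- NA_real_
      pairwise$method[k] <- "exact-binomial"
    }
  }
  structure(list(species = sp, n = nrow(df),
                 coefficients = c(day = unname(b[1]), twilight = unname(b[2])),
                 period_counts = tot,
                 wald_chisq = wald, df = 2L, p_value = p,
                 pairwise = pairwise, fallback = fallback, model = model),
            class = "period_glmm")
}

#' @export
print.period_glmm <- function(x, ...) {
  cat(sprintf("period GLMM for %s (n = %d%s): Wald chisq = %.2f (2 df), p = %.3g\n",
              x$species, x$n, if (x$fallback) ", fixed-effect fallback" else "",
              x$wald_chisq, x$p_value))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Manly design-I selection-ratio test of diel period use
#'
#' Tests whether events are distributed across the three diel periods in
#' proportion to the periods' availability (hours out of 24). The global
#' test is the Pearson goodness-of-fit chi-squared on 2 df. Selection
#' ratios `w_i = (o_i/n) / pi_i` get normal-theory confidence intervals
#' with Bonferroni adjustment over the three periods; a period is used
#' "more" or "less" than expected when its CI excludes 1. Pairwise
#' differences between selection ratios are tested with the standard
#' multinomial variance and Bonferroni adjustment over the three pairs.
#'
#' @param counts named vector of used counts for `night`, `day`,
#'   `twilight` (any order; names required).
#' @param availability named availability fractions summing to 1 (default
#'   from [period_availability()]).
#' @param alpha nominal significance level.
#' @return Object of class `selection_result`: `counts`, `n`,
#'   `availability`, `w` (selection ratios), `se_w`, `ci` (matrix),
#'   `sign` (`"more"`/`"less"`/`"neither"` per period), `chisq`, `df`,
#'   `p_value`, `pairwise`.
#' @export
selection_ratio_test <- function(counts, availability = period_availability(),
                                 alpha = 0.05) {
  periods <- c("night", "day", "twilight")
  if (is.null(names(counts)) || !all(periods %in% names(counts)))
    stop("counts must be named with night, day, twilight")
  if (any(availability <= 0)) stop("availability must be positive")
  o <- as.numeric(counts[periods])
  pi_i <- as.numeric(availability[periods])
  pi_i <- pi_i / sum(pi_i)
  n <- sum(o)
  if (n <= 0) stop("no events")
  u <- o / n
  w <- u / pi_i
  chisq <- sum((o - n * pi_i)^2 / (n * pi_i))
  p <- stats::pchisq(chisq, df = 2, lower.tail = FALSE)
  se_w <- sqrt(u * (1 - u) / n) / pi_i
  z <- stats::qnorm(1 - alpha / (2 * length(periods)))
  ci <- cbind(lower = w - z * se_w, upper = w + z * se_w)
  rownames(ci) <- periods
  sign <- ifelse(ci[, "lower"] > 1, "more",
                 ifelse(ci[, "upper"] < 1, "less", "neither"))
  pairs <- utils::combn(periods, 2)
  zp <- stats::qnorm(1 - alpha / (2 * ncol(pairs)))
  pw <- data.frame(contrast = apply(pairs, 2, paste, collapse = " - "),
                   estimate = NA_real_, z = NA_real_, p_adj = NA_real_,
                   stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    i <- match(pairs[1, k], periods); j <- match(pairs[2, k], periods)
    diff <- w[i] - w[j]
    v <- (u[i] * (1 - u[i]) / pi_i[i]^2 + u[j] * (1 - u[j]) / pi_i[j]^2 +
            2 * u[i] * u[j] / (pi_i[i] * pi_i[j])) / n
    zval <- diff / sqrt(v)
    pw$estimate[k] <- diff
    pw$z[k] <- zval
    pw$p_adj[k] <- min(1, ncol(pairs) * 2 * stats::pnorm(-abs(zval)))
  }
  structure(list(counts = stats::setNames(o, periods), n = n,
                 availability = stats::setNames(pi_i, periods),
                 w = stats::setNames(w, periods),
                 se_w = stats::setNames(se_w, periods), ci = ci,
                 sign = stats::setNames(sign, periods),
                 chisq = chisq, df = 2L, p_value = p, pairwise = pw,
                 alpha = alpha),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection-ratio test: chisq = %.2f (2 df), p = %.3g, n = %d\n",
              x$chisq, x$p_value, as.integer(x$n)))
  tab <- data.frame(period = names(x$w), w = round(x$w, 3),
                    lower = round(x$ci[, 1], 3), upper = round(x$ci[, 2], 3),
                    use = x$sign)
  print(tab, row.names = FALSE)
  invisible(x)
}

# Shared classification input: per-period scores (any monotone use scale)
# and the three pairwise adjusted p-values with directions.
.pattern_from_scores <- function(scores, pairwise, alpha = 0.05) {
  periods <- names(scores)
  sig <- function(a, b) {
    hit <- grepl(a, pairwise$contrast) & grepl(b, pairwise$contrast)
    any(pairwise$p_adj[hit] < alpha)
  }
  label <- c(night = "nocturnal", day = "diurnal", twilight = "crepuscular")
  ord <- periods[order(scores, decreasing = TRUE)]
  top <- ord[1]; second <- ord[2]; third <- ord[3]
  any_sig <- any(pairwise$p_adj < alpha)
  if (!any_sig) return("cathemeral")
  if (sig(top, second) && sig(top, third)) return(unname(label[top]))
  if (!sig(top, second) && sig(top, third))
    return(paste(label[top], label[second], sep = "+"))
  "cathemeral"
}

#' Classify a species' diel activity pattern
#'
#' Maps a fitted [fit_period_glmm()] or [selection_ratio_test()] result to
#' one of `nocturnal`, `diurnal`, `crepuscular`, `cathemeral`, or a
#' compound label such as `diurnal+crepuscular`. A single pattern requires
#' the dominant period to differ significantly from both others; a
#' compound label is given when the top two periods do not differ from
#' each other but the dominant one exceeds the weakest; with no
#' significant differences the species is cathemeral.
#'
#' @param result a `period_glmm` or `selection_result` object.
#' @param alpha significance level applied to adjusted pairwise p-values.
#' @return Pattern label (character scalar).
#' @export
classify_activity_pattern <- function(result, alpha = 0.05) {
  UseMethod("classify_activity_pattern")
}

#' @export
classify_activity_pattern.period_glmm <- function(result, alpha = 0.05) {
  scores <- c(night = 0, result$coefficients)  # log-rates relative to night
  .pattern_from_scores(scores, result$pairwise, alpha)
}

#' @export
classify_activity_pattern.selection_result <- function(result, alpha = 0.05) {
  # ordering follows the used proportions (the field convention labels the
  # most-used period first); significance comes from the pairwise
  # selection-ratio tests
  .pattern_from_scores(result$counts, result$pairwise, alpha)
}

#' Activity-pattern report for every species
#'
#' Routes each species by sample size — excluded below `min_n` events,
#' selection-ratio test from `min_n` to `glmm_threshold`, Poisson GLMM
#' above — and classifies its diel activity pattern.
#'
#' @param events an event table (all species).
#' @param deployments a [deployment_table()].
#' @param spec a [diel_period_spec()].
#' @param min_n exclusion floor (default 10).
#' @param glmm_threshold smallest GLMM-routed sample size is
#'   `glmm_threshold + 1` (default 50, i.e. the GLMM route is used for
#'   n > 50 and the selection route for 10-50).
#' @param alpha significance level.
#' @param offset passed to [fit_period_glmm()].
#' @return Data frame: `species`, `n`, `route`, `pattern`, `statistic`,
#'   `p_value`, `details`.
#' @export
activity_pattern_report <- function(events, deployments,
                                    spec = diel_period_spec(), min_n = 10,
                                    glmm_threshold = 50, alpha = 0.05,
                                    offset = "days") {
  df <- as.data.frame(events)
  species <- sort(unique(df$species))
  rows <- lapply(species, function(sp) {
    sub <- df[df$species == sp, , drop = FALSE]
    n <- nrow(sub)
    if (n < min_n) {
      return(data.frame(species = sp, n = n, route = "excluded",
                        pattern = NA_character_, statistic = NA_real_,
                        p_value = NA_real_, details = "below inclusion floor",
                        stringsAsFactors = FALSE))
    }
    if (n > glmm_threshold) {
      fit <- fit_period_glmm(sub, deployments, spec, offset = offset)
      data.frame(species = sp, n = n, route = "glmm",
                 pattern = classify_activity_pattern(fit, alpha),
                 statistic = fit$wald_chisq, p_value = fit$p_value,
                 details = paste0("Wald chisq 2 df",
                                  if (fit$fallback) "; fixed-effect fallback" else ""),
                 stringsAsFactors = FALSE)
    } else {
      counts <- table(classify_period(sub$timestamp, spec))
      fit <- selection_ratio_test(c(counts), period_availability(spec), alpha)
      data.frame(species = sp, n = n, route = "selection",
                 pattern = classify_activity_pattern(fit, alpha),
                 statistic = fit$chisq, p_value = fit$p_value,
                 details = "Pearson goodness-of-fit, 2 df",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
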