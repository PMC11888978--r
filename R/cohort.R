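# Longitudinal endpoint simulation and group-comparison statistics.

.LOGNORMAL_ENDPOINTS <- c("ast_UL", "alt_UL")

#' Simulate per-mouse longitudinal endpoints
#'
#' Draws a cohort of mice per group with endpoint values at every day the
#' supplied profiles cover. Each mouse x day value has the profile mean;
#' its standard deviation is \code{sem * sqrt(n)} with the profile's group
#' size, partitioned into a shared per-mouse random intercept (intra-class
#' correlation \code{icc}) plus residual noise, giving within-mouse
#' correlation across days. Serum transaminases (AST/ALT) are simulated
#' log-normally (moment-matched to the printed mean and SD) since they are
#' strictly positive and right-skewed; all other endpoints are Gaussian.
#'
#' @param profiles list of \linkS4class{ConditionProfile}
#'   (default \code{\link{builtinProfiles}()}).
#' @param nPerGroup mice per group (>= 2).
#' @param seed RNG seed; identical inputs give identical tables.
#' @param icc within-mouse intra-class correlation in [0, 1).
#' @param lognormalTransaminases set FALSE for Gaussian AST/ALT.
#' @return Long-format data.frame: mouse_id, group, day, rlw_bw_pct,
#'   ast_UL, alt_UL, albumin, pcna_pct (NA where the profile reports no
#'   mean).
#' @export
simulateEndpoints <- function(profiles = builtinProfiles(), nPerGroup = 6,
                              seed = 1, icc = 0.5,
                              lognormalTransaminases = TRUE) {
  if (nPerGroup < 2) stop("nPerGroup must be at least 2")
  stopifnot(icc >= 0, icc < 1)
  groups <- unique(vapply(profiles, function(p) p@group, ""))
  withSeed(seed, {
    out <- list()
    for (g in groups) {
      pg <- Filter(function(p) p@group == g, profiles)
      days <- sort(vapply(pg, function(p) p@day, integer(1)))
      # one random intercept per mouse per endpoint, shared across days
      b <- matrix(stats::rnorm(nPerGroup * length(.ENDPOINTS)),
                  nPerGroup, length(.ENDPOINTS),
                  dimnames = list(NULL, .ENDPOINTS))
      for (d in days) {
        p <- getProfile(g, d, profiles)
        em <- endpointMeans(p)
        vals <- matrix(NA_real_, nPerGroup, length(.ENDPOINTS),
                       dimnames = list(NULL, .ENDPOINTS))
        for (i in seq_len(nrow(em))) {
          ep <- em$endpoint[i]
          m <- em$mean[i]
          if (is.na(m)) next
          sdv <- em$sem[i] * sqrt(em$n[i])
          z <- sqrt(icc) * b[, ep] +
            sqrt(1 - icc) * stats::rnorm(nPerGroup)
          if (lognormalTransaminases && ep %in% .LOGNORMAL_ENDPOINTS &&
              m > 0) {
            s2 <- log(1 + (sdv / m)^2)
            vals[, ep] <- exp(log(m) - s2 / 2 + sqrt(s2) * z)
          } else {
            vals[, ep] <- m + sdv * z
          }
        }
        out[[length(out) + 1L]] <- data.frame(
          mouse_id = sprintf("%s_m%02d", gsub("\\+", "p", gsub("-", "m", g)),
                             seq_len(nPerGroup)),
          group = g, day = d, vals, row.names = NULL)
      }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Compare groups at one day
#'
#' Two groups: Welch two-sample t test (two-sided). More than two: one-way
#' ANOVA with Tukey honestly-significant-difference post-hoc pairwise
#' comparisons. Group means and SEMs are reported alongside.
#'
#' @param table endpoint table from \code{\link{simulateEndpoints}}.
#' @param endpoint endpoint column name.
#' @param day post-operative day to compare at.
#' @param groups optional subset of groups.
#' @return List: \code{summary} (group, n, mean, sem), \code{method},
#'   \code{statistic}, \code{p_value}, and \code{tukey} (pairwise adjusted
#'   p, ANOVA only).
#' @export
compareGroups <- function(table, endpoint, day, groups = NULL) {
  stopifnot(endpoint %in% names(table))
  d <- table[table$day == day & !is.na(table[[endpoint]]), ]
  if (!is.null(groups)) d <- d[d$group %in% groups, ]
  cnt <- table(d$group)
  cnt <- cnt[cnt >= 2]
  if (length(cnt) < 2)
    stop("insufficient replication: need >= 2 groups with >= 2 mice each")
  d <- d[d$group %in% names(cnt), ]
  d$group <- factor(d$group)
  v <- d[[endpoint]]
  summ <- do.call(rbind, lapply(levels(d$group), function(g) {
    x <- v[d$group == g]
    data.frame(group = g, n = length(x), mean = mean(x),
               sem = stats::sd(x) / sqrt(length(x)))
  }))
  if (nlevels(d$group) == 2L) {
    tt <- stats::t.test(v ~ d$group)
    list(summary = summ, method = "welch_t",
         statistic = unname(tt$statistic), p_value = tt$p.value,
         tukey = NULL)
  } else {
    fit <- stats::aov(v ~ group, data = d)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$group
    list(summary = summ, method = "anova_tukey",
         statistic = an[["F value"]][1], p_value = an[["Pr(>F)"]][1],
         tukey = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                            p_adj = tk[, "p adj"], row.names = NULL))
  }
}

#' Mixed-effect repeated-measures group effect
#'
#' Random-intercept model \code{endpoint ~ group + day + (1 | mouse)}
#' (day as a factor; the group x day interaction optional and off by
#' default), testing the group fixed effect. The default Satterthwaite
#' F test has better small-sample calibration than the maximum-likelihood
#' likelihood-ratio chi-square, which is also available.
#'
#' @param table endpoint table from \code{\link{simulateEndpoints}}.
#' @param endpoint endpoint column name.
#' @param method \code{"satterthwaite"} (default) or \code{"lrt"}.
#' @param interaction include group x day (default FALSE).
#' @return List: \code{p_group}, \code{method}, \code{model} (the lmer
#'   fit), \code{messages} (convergence/singularity notes, never silently
#'   swallowed).
#' @export
repeatedMeasures <- function(table, endpoint,
                             method = c("satterthwaite", "lrt"),
                             interaction = FALSE) {
  method <- match.arg(method)
  stopifnot(endpoint %in% names(table))
  d <- table[!is.na(table[[endpoint]]), ]
  dayCnt <- tapply(d$day, d$mouse_id, function(x) length(unique(x)))
  if (!length(dayCnt) || max(dayCnt) < 2L)
    stop("repeated measures need >= 2 days per mouse")
  d <- d[d$mouse_id %in% names(dayCnt)[dayCnt >= 2L], ]
  d$group <- factor(d$group)
  if (nlevels(d$group) < 2L) stop("need >= 2 groups")
  d$dayf <- factor(d$day)
  d$y <- d[[endpoint]]
  msgs <- character(0)
  noteHandler <- function(w) {
    msgs <<- c(msgs, trimws(conditionMessage(w)))
    invokeRestart("muffleWarning")
  }
  msgHandler <- function(m) {
    msgs <<- c(msgs, trimws(conditionMessage(m)))
    invokeRestart("muffleMessage")
  }
  form <- if (interaction) y ~ group * dayf + (1 | mouse_id)
          else y ~ group + dayf + (1 | mouse_id)
  if (method == "satterthwaite") {
    fit <- withCallingHandlers(
      lmerTest::lmer(form, data = d),
      warning = noteHandler, message = msgHandler)
    an <- suppressMessages(stats::anova(fit, type = 3))
    p <- an["group", "Pr(>F)"]
  } else {
    fit <- withCallingHandlers(
      lme4::lmer(form, data = d, REML = FALSE),
      warning = noteHandler, message = msgHandler)
    red <- withCallingHandlers(
      lme4::lmer(stats::update.formula(form, . ~ . - group), data = d,
                 REML = FALSE),
      warning = noteHandler, message = msgHandler)
    cmp <- stats::anova(red, fit)
    p <- cmp[2, "Pr(>Chisq)"]
  }
  list(p_group = unname(p), method = method, model = fit, messages = msgs)
}
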