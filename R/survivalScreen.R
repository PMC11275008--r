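#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper around [survival::survfit()] for a single group:
#' product-limit survival with subjects censored at an event time still
#' counted at risk at that time.
#'
#' @param table data frame with columns `time` (>= 0) and `event`
#'   (1 = death, 0 = censored).
#' @return A `survfit` object; `summary()` gives event times, at-risk
#'   counts and survival probabilities.
#' @examples
#' km <- kmEstimate(data.frame(time = c(1, 2, 3, 4, 5),
#'                             event = c(1, 0, 1, 0, 1)))
#' summary(km)$surv   # 4/5, 8/15, 0
#' @export
kmEstimate <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("time", "event") %in% names(table)))
  if (any(!is.finite(table$time)) || any(table$time < 0))
    stop("survival times must be finite and non-negative")
  if (!all(table$event %in% c(0, 1)))
    stop("'event' must be 0 (censored) or 1 (death)")
  survival::survfit(survival::Surv(time, event) ~ 1, data = table)
}

#' Dichotomize an expression covariate into high/low groups
#'
#' Splits a continuous expression vector at its median (default) or at
#' an arbitrary quantile.  Values strictly below the cutoff are `low`,
#' strictly above are `high`; values exactly at the cutoff are assigned
#' to `high` and flagged in the `"atCutoff"` attribute.
#'
#' @param expression numeric vector with >= 2 distinct values.
#' @param method `"median"` or `"quantile"`.
#' @param q quantile for `method = "quantile"` (default 0.5).
#' @return Factor with levels `low`, `high`; attributes `cutoff` and
#'   `atCutoff` (indices of exact-cutoff values).
#' @examples
#' dichotomize(c(1, 2, 3, 4))            # low low high high
#' @export
dichotomize <- function(expression, method = c("median", "quantile"),
                        q = 0.5) {
  method <- match.arg(method)
  x <- expression
  if (length(unique(x[is.finite(x)])) < 2L)
    stop("expression is constant; cannot dichotomize")
  cutoff <- if (method == "median") median(x, na.rm = TRUE)
            else quantile(x, q, na.rm = TRUE, names = FALSE)
  g <- factor(ifelse(x < cutoff, "low", "high"),
              levels = c("low", "high"))
  attr(g, "cutoff") <- cutoff
  attr(g, "atCutoff") <- which(x == cutoff)
  g
}

#' Two-group Mantel-Haenszel log-rank test
#'
#' Standard log-rank test via [survival::survdiff()] (rho = 0): at each
#' distinct event time the observed events in group A are compared with
#' their hypergeometric expectation, ties pooled, and the summed
#' deviation referenced against chi-squared with 1 df (two-sided).
#'
#' @param table data frame with columns `time`, `event`.
#' @param group two-level factor/vector aligned with `table` rows.
#' @return List with `statistic`, `p`, `observed`, `expected`.
#' @export
logrankTest <- function(table, group) {
  stopifnot(is.data.frame(table),
            all(c("time", "event") %in% names(table)),
            length(group) == nrow(table))
  if (sum(table$event) == 0) stop("no events; log-rank undefined")
  g <- factor(group)
  if (nlevels(g) != 2L) stop("'group' must have exactly 2 levels")
  dat <- data.frame(time = table$time, event = table$event, g = g)
  sd0 <- survival::survdiff(survival::Surv(time, event) ~ g, data = dat)
  stat <- unname(sd0$chisq)
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE),
       observed = sd0$obs, expected = sd0$exp)
}

#' Benjamini-Hochberg FDR screen of a p-value list
#'
#' Step-up BH q-values with pass = q <= `fdr` (default 5%), the
#' retention rule applied across cohorts in a multi-cohort survival
#' screen.
#'
#' @param pvalues numeric vector in [0, 1].
#' @param fdr FDR level (default 0.05).
#' @return Data frame `p`, `q`, `pass` in input order.
#' @examples
#' fdrScreen(c(0.01, 0.02, 0.03, 0.04))$q   # all 0.04
#' @export
fdrScreen <- function(pvalues, fdr = 0.05) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  q <- p.adjust(pvalues, method = "BH")
  data.frame(p = pvalues, q = q, pass = q <= fdr)
}

# Median survival per arm; restricted mean over observed follow-up when
# the median is never reached.
.armLocation <- function(table) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = table)
  tab <- summary(fit, rmean = max(table$time))$table
  med <- unname(tab["median"])
  if (is.na(med)) unname(tab["rmean"]) else med
}

#' Multi-cohort Kaplan-Meier screening with FDR control
#'
#' For each cohort: dichotomizes the expression covariate, runs the
#' two-group log-rank test, and determines the survival direction
#' (which expression group lives longer, by median survival, falling
#' back to the restricted mean when a median is not reached).  P-values
#' are then screened across cohorts with Benjamini-Hochberg at the
#' given FDR level, mirroring a KM-Plotter style mining pass over many
#' tumor entities.
#'
#' @param cohorts named list of data frames, each with columns `time`,
#'   `event`, `expression`.
#' @param method,q passed to [dichotomize()].
#' @param fdr FDR level (default 0.05).
#' @return A data frame with one row per cohort: `cohort`, `n`,
#'   `statistic`, `p`, `q`, `pass`, `longerSurvival` (`"low"` or
#'   `"high"` expression); KM fits per cohort and group in
#'   `attr(, "curves")`.
#' @examples
#' coh <- simSurvivalCohorts(nCohorts = 2, hazardRatio = 2, seed = 1)
#' survivalScreen(coh)[, c("cohort", "p", "pass", "longerSurvival")]
#' @export
survivalScreen <- function(cohorts, method = c("median", "quantile"),
                           q = 0.5, fdr = 0.05) {
  method <- match.arg(method)
  if (length(cohorts) == 0L) stop("empty cohort list")
  if (is.null(names(cohorts)))
    names(cohorts) <- paste0("cohort", seq_along(cohorts))
  rows <- list(); curves <- list()
  for (label in names(cohorts)) {
    tab <- cohorts[[label]]
    stopifnot(all(c("time", "event", "expression") %in% names(tab)))
    grp <- tryCatch(dichotomize(tab$expression, method = method, q = q),
                    error = function(e)
                      stop("cohort '", label, "': ", conditionMessage(e)))
    lr <- tryCatch(logrankTest(tab, grp),
                   error = function(e)
                     stop("cohort '", label, "': ", conditionMessage(e)))
    locLow <- .armLocation(tab[grp == "low", , drop = FALSE])
    locHigh <- .armLocation(tab[grp == "high", , drop = FALSE])
    rows[[label]] <- data.frame(
      cohort = label, n = nrow(tab),
      statistic = lr$statistic, p = lr$p,
      longerSurvival = if (locLow >= locHigh) "low" else "high",
      stringsAsFactors = FALSE)
    curves[[label]] <- list(
      low = kmEstimate(tab[grp == "low", , drop = FALSE]),
      high = kmEstimate(tab[grp == "high", , drop = FALSE]))
  }
  out <- do.call(rbind, rows)
  scr <- fdrScreen(out$p, fdr = fdr)
  out$q <- scr$q
  out$pass <- scr$pass
  out <- out[, c("cohort", "n", "statistic", "p", "q", "pass",
                 "longerSurvival")]
  rownames(out) <- NULL
  attr(out, "curves") <- curves
  out
}
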