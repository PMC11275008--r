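#' Relative expression by the delta-delta-Ct method
#'
#' Computes delta Ct = mean Ct(target) - mean Ct(reference) within each
#' sample group, delta-delta Ct = delta Ct(treated) - delta Ct(control)
#' and the fold change 2^(-ddCt) (Livak convention, the default, under
#' which downregulation yields negative log2 folds).  The literal
#' 2^(+ddCt) convention is available via `convention = "literal"`.
#'
#' @param ct data frame with columns `group` (`"treated"`/`"control"`),
#'   `role` (`"target"`/`"reference"`) and `ct` (cycle threshold > 0);
#'   a `replicate` column is allowed and ignored (replicates are
#'   averaged within group x role).
#' @param convention `"livak"` (fold = 2^-ddCt) or `"literal"`
#'   (fold = 2^+ddCt).
#' @return List with `fold`, `log2Fold` and `ddct`.
#' @examples
#' ct <- simCtTable(log2Fold = -1.11, noiseSD = 0, seed = 1)
#' ddctFold(ct)$log2Fold   # -1.11
#' @export
ddctFold <- function(ct, convention = c("livak", "literal")) {
  convention <- match.arg(convention)
  stopifnot(is.data.frame(ct),
            all(c("group", "role", "ct") %in% names(ct)))
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0))
    stop("Ct values must be positive and finite")
  need <- expand.grid(group = c("treated", "control"),
                      role = c("target", "reference"))
  have <- unique(ct[, c("group", "role")])
  missing <- !mapply(function(g, r) any(have$group == g & have$role == r),
                     need$group, need$role)
  if (any(missing))
    stop("missing Ct rows for: ",
         paste(paste(need$group, need$role)[missing], collapse = ", "))
  mct <- function(g, r) mean(ct$ct[ct$group == g & ct$role == r])
  dct <- c(treated = mct("treated", "target") - mct("treated", "reference"),
           control = mct("control", "target") - mct("control", "reference"))
  ddct <- unname(dct["treated"] - dct["control"])
  l2 <- if (convention == "livak") -ddct else ddct
  list(fold = 2^l2, log2Fold = l2, ddct = ddct)
}

#' Censored concentration values
#'
#' A concentration that may only be known as a lower bound ("> max
#' tested"), as happens when a dose-response curve never crosses 50%
#' viability.  Censoring propagates through ratios such as the degree
#' of resistance.
#'
#' @param value the concentration (for censored values, the bound).
#' @param censored TRUE when the value is a "greater than" bound.
#' @return A `"censoredValue"` object.
#' @export
censoredValue <- function(value, censored = FALSE) {
  stopifnot(is.numeric(value), length(value) == 1L)
  structure(list(value = value, censored = isTRUE(censored)),
            class = "censoredValue")
}

#' @export
print.censoredValue <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.censoredValue <- function(x, digits = 3, ...) {
  paste0(if (x$censored) "> " else "", signif(x$value, digits))
}

#' Summarize a dose-response curve into an IC50
#'
#' Fits a monotone-decreasing four-parameter logistic
#' v = bottom + (top - bottom) / (1 + (c / ic50)^hill)
#' to percent-viability data (top constrained to at most 110% and
#' bottom to at least -10% of control, hill > 0) and returns the
#' concentration at the midpoint of the fitted span.  When viability
#' never falls to 50% of control within the tested range the IC50 is
#' not identified and a censored value "> max tested" is returned
#' instead of an extrapolation.
#'
#' @param concentrations positive, increasing concentrations (M).
#' @param viability percent viability, same length, >= 4 points.
#' @return A `"censoredValue"`: the fitted IC50 (M), or the highest
#'   tested concentration with `censored = TRUE`.
#' @examples
#' conc <- 10^seq(-8, -4, length.out = 8)
#' v <- 100 / (1 + (conc / 1e-5))
#' ic50FromCurve(conc, v)   # ~1e-5, not censored
#' @export
ic50FromCurve <- function(concentrations, viability) {
  stopifnot(length(concentrations) == length(viability),
            length(concentrations) >= 4L)
  if (any(concentrations <= 0) || any(diff(concentrations) <= 0))
    stop("'concentrations' must be positive and increasing")
  if (any(!is.finite(viability))) stop("'viability' must be finite")
  if (min(viability) > 50)
    return(censoredValue(max(concentrations), censored = TRUE))
  top0 <- min(max(viability), 110)
  bot0 <- max(min(viability), -10)
  mid <- (top0 + bot0) / 2
  i0 <- which.min(abs(viability - mid))
  dat <- data.frame(lc = log(concentrations), v = viability)
  fit <- minpack.lm::nlsLM(
    v ~ bot + (top - bot) / (1 + exp(hill * (lc - lic50))),
    data = dat,
    start = list(top = top0, bot = bot0, hill = 1,
                 lic50 = dat$lc[i0]),
    lower = c(top = -10, bot = -10, hill = 1e-3,
              lic50 = min(dat$lc) - log(100)),
    upper = c(top = 110, bot = 110, hill = 20,
              lic50 = max(dat$lc) + log(100)),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- coef(fit)
  ic50 <- exp(est[["lic50"]])
  if (ic50 > max(concentrations))
    return(censoredValue(max(concentrations), censored = TRUE))
  censoredValue(ic50, censored = FALSE)
}

#' Degree of resistance between a resistant and a parental line
#'
#' Ratio of the IC50 of the resistant line to that of its parental
#' line.  A censored resistant IC50 ("> max tested") propagates to a
#' censored fold ("> x"); a censored denominator leaves the fold
#' undetermined and errors.
#'
#' @param ic50Resistant,ic50Parental positive concentrations, numeric
#'   or `"censoredValue"`.
#' @return A `"censoredValue"` fold change (dimensionless).
#' @examples
#' degreeOfResistance(32e-6, 10e-6)                       # 3.2
#' degreeOfResistance(censoredValue(100e-6, TRUE), 13.7e-6) # > 7.3
#' @export
degreeOfResistance <- function(ic50Resistant, ic50Parental) {
  asCV <- function(x) if (inherits(x, "censoredValue")) x
                      else censoredValue(x)
  r <- asCV(ic50Resistant); p <- asCV(ic50Parental)
  if (!is.finite(r$value) || r$value <= 0 ||
      !is.finite(p$value) || p$value <= 0)
    stop("IC50 values must be positive")
  if (p$censored)
    stop("parental IC50 is censored; fold change undetermined")
  censoredValue(r$value / p$value, censored = r$censored)
}
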