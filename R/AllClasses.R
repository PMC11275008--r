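#' @import methods
#' @importFrom stats cor cor.test median quantile pchisq pt rnorm runif
#'   rexp complete.cases hclust dist cutree as.dist chisq.test p.adjust
#'   coef vcov setNames sd var predict
NULL

#' Cell line panel with tissue-of-origin annotation
#'
#' Ordered set of tumor cell line identifiers, each labelled with its
#' tissue of origin.  The default simulated panel mirrors the NCI-60
#' layout: 60 lines over nine tissue types (leukemia, melanoma, brain,
#' colon, ovary, breast, kidney, lung, prostate).
#'
#' @slot cellLines character vector of unique cell line identifiers.
#' @slot tissue factor of the same length giving the tissue of origin.
#'
#' @seealso [simPanel()], [tissueMeanIC50()]
#' @export
setClass("CellLinePanel",
  representation(cellLines = "character", tissue = "factor"))

setValidity("CellLinePanel", function(object) {
  msg <- character()
  if (anyDuplicated(object@cellLines))
    msg <- c(msg, "cell line identifiers must be unique")
  if (length(object@tissue) != length(object@cellLines))
    msg <- c(msg, "every cell line needs a tissue label")
  if (anyNA(object@tissue))
    msg <- c(msg, "tissue labels must not be NA")
  if (length(msg)) msg else TRUE
})

#' Per-compound cytotoxicity profile over a cell line panel
#'
#' Named vector of log10(IC50) values (molar scale) for one compound,
#' indexed by cell line identifier.  Missing entries (untested lines)
#' are allowed but at least three finite values are required, the
#' minimum for any correlation downstream.
#'
#' @slot compound single compound identifier.
#' @slot values named numeric vector, log10(IC50) in log10 molar.
#'
#' @seealso [compareRank()], [classifySensitivity()]
#' @export
setClass("ActivityProfile",
  representation(compound = "character", values = "numeric"))

setValidity("ActivityProfile", function(object) {
  msg <- character()
  if (length(object@compound) != 1L || is.na(object@compound))
    msg <- c(msg, "'compound' must be a single non-NA identifier")
  if (is.null(names(object@values)) || anyDuplicated(names(object@values)))
    msg <- c(msg, "'values' must be named by unique cell line identifiers")
  if (sum(is.finite(object@values)) < 3L)
    msg <- c(msg, "an activity profile needs >= 3 non-missing values")
  if (length(msg)) msg else TRUE
})

#' Library of reference agents with annotated modes of action
#'
#' Matrix of log10(IC50) profiles (agents x cell lines) together with a
#' mode-of-action class label per agent, the reference set a COMPARE
#' analysis ranks a query compound against.
#'
#' @slot profiles numeric matrix, rows = agents, columns = cell lines.
#' @slot moa named character vector, one class label per agent.
#'
#' @seealso [compareRank()], [moaEnrichment()], [simActivity()]
#' @export
setClass("AgentLibrary",
  representation(profiles = "matrix", moa = "character"))

setValidity("AgentLibrary", function(object) {
  msg <- character()
  if (nrow(object@profiles) > 0L &&
      (is.null(rownames(object@profiles)) ||
       anyDuplicated(rownames(object@profiles))))
    msg <- c(msg, "'profiles' must have unique agent row names")
  if (is.null(colnames(object@profiles)))
    msg <- c(msg, "'profiles' must have cell line column names")
  if (length(object@moa) != nrow(object@profiles) ||
      !identical(names(object@moa), rownames(object@profiles)))
    msg <- c(msg, "'moa' must be named identically to the agent rows")
  if (any(!nzchar(object@moa)) || anyNA(object@moa))
    msg <- c(msg, "every agent needs a non-empty mode-of-action class")
  if (length(msg)) msg else TRUE
})

#' Ligand titration series for binding-isotherm fitting
#'
#' One microscale-thermophoresis-type dilution series: total ligand
#' concentrations (strictly decreasing, molar) with the measured
#' normalized signal at each point, plus the fixed total concentration
#' of the labelled target.
#'
#' @slot ligandTotal numeric, total ligand concentrations (M),
#'   strictly decreasing.
#' @slot signal numeric, normalized signal per titration point.
#' @slot targetTotal single numeric, labelled target concentration (M).
#'
#' @seealso [fitKd()], [simTitration()]
#' @export
setClass("TitrationSeries",
  representation(ligandTotal = "numeric", signal = "numeric",
                 targetTotal = "numeric"))

setValidity("TitrationSeries", function(object) {
  msg <- character()
  L <- object@ligandTotal
  if (length(L) < 6L)
    msg <- c(msg, "a titration series needs >= 6 points")
  if (any(!is.finite(L)) || any(L <= 0))
    msg <- c(msg, "ligand concentrations must be positive and finite")
  if (length(L) > 1L && any(diff(L) >= 0))
    msg <- c(msg, "ligand concentrations must be strictly decreasing")
  if (length(object@signal) != length(L))
    msg <- c(msg, "'signal' must match the number of titration points")
  if (length(object@targetTotal) != 1L || !is.finite(object@targetTotal) ||
      object@targetTotal <= 0)
    msg <- c(msg, "'targetTotal' must be a single positive concentration")
  if (length(msg)) msg else TRUE
})

#' Result of a dissociation-constant fit
#'
#' Estimated K_D with its standard error (from the curvature of the
#' least-squares surface), the fitted unbound/bound signal plateaus,
#' the residual norm, and a flag raised when the series does not span
#' the binding transition.
#'
#' @slot kd estimated dissociation constant (M).
#' @slot kdSE standard error of the estimate (M), delta method from
#'   the log-scale fit.
#' @slot signalUnbound,signalBound fitted signal plateaus.
#' @slot residualNorm Euclidean norm of the residuals.
#' @slot poorlyConstrained TRUE when all points sit below 10% or above
#'   90% fraction bound at the fitted K_D.
#' @slot model "quadratic" (ligand depletion) or "hyperbolic".
#'
#' @seealso [fitKd()]
#' @export
setClass("KdFit",
  representation(kd = "numeric", kdSE = "numeric",
                 signalUnbound = "numeric", signalBound = "numeric",
                 residualNorm = "numeric", poorlyConstrained = "logical",
                 model = "character"))

setValidity("KdFit", function(object) {
  msg <- character()
  if (!is.finite(object@kd) || object@kd <= 0)
    msg <- c(msg, "'kd' must be a positive concentration")
  if (object@residualNorm < 0)
    msg <- c(msg, "'residualNorm' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a cell line panel
#'
#' @param cellLines character vector of unique identifiers.
#' @param tissue tissue-of-origin labels, recycled checkably to one per
#'   cell line.
#' @return A [CellLinePanel-class] object.
#' @examples
#' CellLinePanel(c("LE01", "LE02", "ME01"),
#'               c("leukemia", "leukemia", "melanoma"))
#' @export
CellLinePanel <- function(cellLines, tissue) {
  new("CellLinePanel", cellLines = as.character(cellLines),
      tissue = factor(tissue))
}

#' Construct an activity profile
#'
#' @param compound compound identifier.
#' @param values named numeric vector of log10(IC50) values (log10 M);
#'   `NA` marks untested cell lines.
#' @return An [ActivityProfile-class] object.
#' @examples
#' ActivityProfile("lupeol", c(LE01 = -5.2, LE02 = -5.6, ME01 = -4.8))
#' @export
ActivityProfile <- function(compound, values) {
  new("ActivityProfile", compound = as.character(compound),
      values = values)
}

#' Construct an agent library
#'
#' @param profiles numeric matrix, agents in rows (named), cell lines in
#'   columns (named).
#' @param moa mode-of-action class per agent, in row order or named by
#'   agent.
#' @return An [AgentLibrary-class] object.
#' @export
AgentLibrary <- function(profiles, moa) {
  if (is.null(names(moa))) names(moa) <- rownames(profiles)
  moa <- moa[rownames(profiles)]
  new("AgentLibrary", profiles = profiles, moa = moa)
}

#' Construct a titration series
#'
#' @param ligandTotal total ligand concentrations (M), strictly
#'   decreasing.
#' @param signal normalized signal, one value per concentration.
#' @param targetTotal labelled target concentration (M).
#' @return A [TitrationSeries-class] object.
#' @export
TitrationSeries <- function(ligandTotal, signal, targetTotal) {
  new("TitrationSeries", ligandTotal = as.numeric(ligandTotal),
      signal = as.numeric(signal), targetTotal = as.numeric(targetTotal))
}
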