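#' Accessors for panel, profile, library and titration objects
#'
#' `cellLines()` returns the cell line identifiers of a panel (or the
#' lines covered by a profile/library); `tissues()` the tissue factor;
#' `profileValues()` the named log10(IC50) vector; `moaClass()` the
#' agent-to-class map; `kd()` and `kdSE()` the fitted dissociation
#' constant and its standard error.
#'
#' @param x an object of the documented class.
#' @return The slot content described above.
#' @name accessors
#' @aliases cellLines tissues profileValues moaClass kd kdSE
#' @examples
#' pan <- simPanel(seed = 1)
#' head(cellLines(pan))
#' table(tissues(pan))
NULL

#' @rdname accessors
#' @export
setGeneric("cellLines", function(x) standardGeneric("cellLines"))
#' @rdname accessors
#' @export
setGeneric("tissues", function(x) standardGeneric("tissues"))
#' @rdname accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))
#' @rdname accessors
#' @export
setGeneric("moaClass", function(x) standardGeneric("moaClass"))
#' @rdname accessors
#' @export
setGeneric("kd", function(x) standardGeneric("kd"))
#' @rdname accessors
#' @export
setGeneric("kdSE", function(x) standardGeneric("kdSE"))

#' @rdname accessors
#' @export
setMethod("cellLines", "CellLinePanel", function(x) x@cellLines)
#' @rdname accessors
#' @export
setMethod("cellLines", "ActivityProfile", function(x) names(x@values))
#' @rdname accessors
#' @export
setMethod("cellLines", "AgentLibrary", function(x) colnames(x@profiles))
#' @rdname accessors
#' @export
setMethod("tissues", "CellLinePanel",
  function(x) setNames(x@tissue, x@cellLines))
#' @rdname accessors
#' @export
setMethod("profileValues", "ActivityProfile", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("profileValues", "AgentLibrary", function(x) x@profiles)
#' @rdname accessors
#' @export
setMethod("moaClass", "AgentLibrary", function(x) x@moa)
#' @rdname accessors
#' @export
setMethod("kd", "KdFit", function(x) x@kd)
#' @rdname accessors
#' @export
setMethod("kdSE", "KdFit", function(x) x@kdSE)

setMethod("show", "CellLinePanel", function(object) {
  cat("CellLinePanel with", length(object@cellLines), "cell lines over",
      nlevels(object@tissue), "tissues\n")
  print(table(object@tissue))
})

setMethod("show", "ActivityProfile", function(object) {
  v <- object@values
  cat("ActivityProfile for", object@compound, "over", length(v),
      "cell lines (", sum(is.finite(v)), "measured )\n")
  cat("  log10(IC50) range:",
      paste(signif(range(v, na.rm = TRUE), 4), collapse = " .. "), "\n")
})

setMethod("show", "AgentLibrary", function(object) {
  cat("AgentLibrary with", nrow(object@profiles), "agents over",
      ncol(object@profiles), "cell lines\n")
  cat("  mode-of-action classes:", nlevels(factor(object@moa)), "\n")
})

setMethod("show", "TitrationSeries", function(object) {
  cat("TitrationSeries:", length(object@ligandTotal), "points,",
      "ligand", format(max(object@ligandTotal), digits = 3), "..",
      format(min(object@ligandTotal), digits = 3), "M, target",
      format(object@targetTotal, digits = 3), "M\n")
})

setMethod("show", "KdFit", function(object) {
  cat(sprintf("KdFit (%s isotherm): K_D = %.4g M (SE %.2g M)\n",
              object@model, object@kd, object@kdSE))
  cat(sprintf("  plateaus: unbound %.4g, bound %.4g; residual norm %.3g\n",
              object@signalUnbound, object@signalBound,
              object@residualNorm))
  if (object@poorlyConstrained)
    cat("  warning: series does not span the binding transition\n")
})

#' Length of a titration series
#' @param x a [TitrationSeries-class] object.
#' @return Number of titration points.
#' @export
setMethod("length", "TitrationSeries", function(x) length(x@ligandTotal))
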