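# Pairwise-complete Pearson r/p for one profile against the rows of a
# matrix; returns NA rows where the correlation is undefined.
.profileCorRows <- function(values, mat, minOverlap = 3L) {
  out <- data.frame(id = rownames(mat), n = NA_integer_,
                    r = NA_real_, p = NA_real_,
                    reason = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(mat))) {
    y <- mat[i, ][names(values)]
    ok <- is.finite(values) & is.finite(y)
    n <- sum(ok)
    out$n[i] <- n
    if (n < minOverlap) {
      out$reason[i] <- sprintf("only %d overlapping cell lines", n)
      next
    }
    if (sd(values[ok]) == 0 || sd(y[ok]) == 0) {
      out$reason[i] <- "zero variance"
      next
    }
    ct <- pearsonTest(values[ok], y[ok])
    out$r[i] <- ct$r
    out$p[i] <- ct$p
  }
  out
}

#' Rank reference agents by profile similarity (COMPARE analysis)
#'
#' Correlates a compound's log10(IC50) profile against every agent in an
#' annotated library over their shared cell lines and ranks the agents
#' by decreasing Pearson r.  High positive correlation with agents of a
#' known mode of action is the COMPARE rationale for inferring that the
#' query compound shares that mechanism.
#'
#' Agents with fewer than `minOverlap` shared measured cell lines (or
#' zero variance over the overlap) are excluded from the ranking and
#' listed in the `"excluded"` attribute with the reason.
#'
#' @param profile an [ActivityProfile-class].
#' @param library an [AgentLibrary-class].
#' @param minOverlap minimum number of pairwise-complete cell lines
#'   (default 3).
#' @return A data frame with columns `agent`, `moa`, `n`, `r`, `p`,
#'   sorted by `r` descending (ties broken by agent id); excluded
#'   agents in `attr(, "excluded")`.
#' @examples
#' sim <- simActivity(simPanel(seed = 1), seed = 1)
#' ranked <- compareRank(sim$profile, sim$library)
#' head(ranked, 3)
#' @export
compareRank <- function(profile, library, minOverlap = 3L) {
  stopifnot(is(profile, "ActivityProfile"), is(library, "AgentLibrary"))
  if (nrow(library@profiles) == 0L) stop("empty agent library")
  res <- .profileCorRows(profile@values, library@profiles, minOverlap)
  res$moa <- unname(library@moa[res$id])
  excluded <- res[!is.na(res$reason), c("id", "n", "reason")]
  res <- res[is.na(res$reason), c("id", "moa", "n", "r", "p")]
  names(res)[1] <- "agent"
  res <- res[order(-res$r, res$agent), ]
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  res
}

#' Summarize a COMPARE ranking by mode-of-action class
#'
#' Counts, per mode-of-action class, the agents whose correlation with
#' the query compound passes the significance rule r >= `rMin` and
#' p <= `alpha` (only positive correlations count as mechanistic hits;
#' negative ones remain visible in the ranking but are not class
#' evidence).  Classes are ranked by the number of significant agents,
#' ties broken alphabetically.
#'
#' @param ranked output of [compareRank()].
#' @param rMin minimum correlation for a hit (default 0.30).
#' @param alpha significance level (default 0.05).
#' @return A list of class `"MoaSummary"`: `perClass` data frame
#'   (`moa`, `nSignificant`, `nAgents`, `meanR`) in ranked order, and
#'   `rankedClasses` character vector.
#' @examples
#' sim <- simActivity(simPanel(seed = 1), seed = 1)
#' moaEnrichment(compareRank(sim$profile, sim$library))$rankedClasses[1]
#' @export
moaEnrichment <- function(ranked, rMin = 0.30, alpha = 0.05) {
  stopifnot(is.data.frame(ranked),
            all(c("moa", "r", "p") %in% names(ranked)),
            rMin >= -1, rMin <= 1, alpha > 0, alpha <= 1)
  hit <- ranked$r >= rMin & ranked$p <= alpha
  per <- do.call(rbind, lapply(split(seq_len(nrow(ranked)), ranked$moa),
    function(idx) data.frame(
      moa = ranked$moa[idx[1]],
      nSignificant = sum(hit[idx]),
      nAgents = length(idx),
      meanR = mean(ranked$r[idx]),
      stringsAsFactors = FALSE)))
  per <- per[order(-per$nSignificant, per$moa), ]
  rownames(per) <- NULL
  structure(list(perClass = per, rankedClasses = per$moa),
            class = "MoaSummary")
}

#' @export
print.MoaSummary <- function(x, ...) {
  cat("Mode-of-action enrichment (classes by significant agents):\n")
  print(x$perClass, row.names = FALSE)
  invisible(x)
}

#' Oncobiogram correlation vector against a reference agent set
#'
#' Returns the Pearson r of the query profile against each reference
#' agent (e.g. a set of known tubulin inhibitors), the vector an
#' oncobiogram plots.  Agents with insufficient overlap or zero
#' variance map to `NA` rather than erroring.
#'
#' @param profile an [ActivityProfile-class].
#' @param referenceAgents a named list of [ActivityProfile-class]
#'   objects, or an agents-by-cell-lines matrix with row names.
#' @param minOverlap minimum pairwise-complete cell lines (default 3).
#' @return Named numeric vector of correlation coefficients.
#' @export
oncobiogramVector <- function(profile, referenceAgents, minOverlap = 3L) {
  stopifnot(is(profile, "ActivityProfile"))
  if (is.list(referenceAgents)) {
    if (length(referenceAgents) == 0L) stop("empty reference agent list")
    lines <- unique(unlist(lapply(referenceAgents, cellLines)))
    mat <- t(vapply(referenceAgents,
                    function(p) profileValues(p)[lines],
                    numeric(length(lines))))
    colnames(mat) <- lines
  } else {
    mat <- referenceAgents
    if (is.null(mat) || nrow(mat) == 0L) stop("empty reference agent list")
  }
  common <- intersect(colnames(mat), names(profile@values))
  res <- .profileCorRows(profile@values[common],
                         mat[, common, drop = FALSE], minOverlap)
  setNames(res$r, res$id)
}

#' Mean log10(IC50) per tissue of origin
#'
#' Averages a compound's profile within each tissue class of the panel,
#' the per-tumor-type summary used to compare growth-inhibitory
#' efficacy across tissues.  Tissues with no measured line are omitted.
#'
#' @param profile an [ActivityProfile-class]; every profiled cell line
#'   must be in the panel.
#' @param panel a [CellLinePanel-class].
#' @return Named numeric vector, mean log10(IC50) per tissue.
#' @export
tissueMeanIC50 <- function(profile, panel) {
  stopifnot(is(profile, "ActivityProfile"), is(panel, "CellLinePanel"))
  unknown <- setdiff(names(profile@values), panel@cellLines)
  if (length(unknown))
    stop("cell line(s) not in panel: ", paste(unknown, collapse = ", "))
  tl <- tissues(panel)[names(profile@values)]
  v <- profile@values
  means <- tapply(v[is.finite(v)], droplevels(tl[is.finite(v)]), mean)
  setNames(as.numeric(means), names(means))
}
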