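#' Resistance-marker correlation report
#'
#' Correlates a compound's log10(IC50) profile against a set of
#' resistance-marker measurements (ABC transporter expression, gene
#' copy numbers, functional assays, ...) over the shared cell lines and
#' flags associations by the screening rule p < `alpha` and |r| >
#' `rMin` (both strict, so a marker at exactly r = 0.30 is not
#' flagged).  Both signs are flagged: positive r marks a resistance
#' factor, negative r collateral sensitivity.
#'
#' @param profile an [ActivityProfile-class].
#' @param markers a data frame with columns `marker`, `assay` and one
#'   column per cell line (as read by [readMarkerTable()]), or a
#'   markers-by-cell-lines matrix with row names.
#' @param rMin correlation magnitude threshold (default 0.30).
#' @param alpha significance threshold (default 0.05).
#' @param minOverlap minimum pairwise-complete cell lines (default 3).
#' @return A data frame `marker`, `assay`, `n`, `r`, `p`, `flagged`,
#'   one row per marker/assay, in input order.
#' @examples
#' prof <- simActivity(simPanel(seed = 1), seed = 1)$profile
#' m <- rbind(ABCB1 = profileValues(prof))   # self-correlated marker
#' resistanceTable(prof, m)
#' @export
resistanceTable <- function(profile, markers, rMin = 0.30, alpha = 0.05,
                            minOverlap = 3L) {
  stopifnot(is(profile, "ActivityProfile"))
  if (is.data.frame(markers)) {
    meta <- markers[, intersect(c("marker", "assay"), names(markers)),
                    drop = FALSE]
    valcols <- setdiff(names(markers), c("marker", "assay", "control_drug"))
    mat <- as.matrix(markers[, valcols, drop = FALSE])
    rownames(mat) <- if ("marker" %in% names(meta)) meta$marker
                     else paste0("marker", seq_len(nrow(mat)))
  } else {
    mat <- markers
    meta <- data.frame(marker = rownames(mat),
                       assay = rep(NA_character_, nrow(mat)),
                       stringsAsFactors = FALSE)
  }
  if (is.null(mat) || nrow(mat) == 0L) stop("empty marker list")
  common <- intersect(colnames(mat), names(profile@values))
  res <- .profileCorRows(profile@values[common],
                         mat[, common, drop = FALSE], minOverlap)
  out <- data.frame(marker = meta$marker,
                    assay = if ("assay" %in% names(meta)) meta$assay
                            else NA_character_,
                    n = res$n, r = res$r, p = res$p,
                    stringsAsFactors = FALSE)
  out$flagged <- !is.na(out$r) & !is.na(out$p) &
    out$p < alpha & abs(out$r) > rMin
  out
}
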