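.assayMatrix <- function(x) {
  if (is(x, "SummarizedExperiment"))
    return(SummarizedExperiment::assay(x))
  if (is.matrix(x)) return(x)
  stop("expected a matrix or SummarizedExperiment of abundances")
}

#' Correlate every feature of an abundance matrix with a drug profile
#'
#' The proteome COMPARE stage: each feature (protein) of the matrix is
#' correlated with the compound's log10(IC50) profile over the shared
#' cell lines.  Positive r marks a candidate resistance factor (high
#' abundance where IC50 is high), negative r a sensitivity factor.
#' Vectorized, so thousands of features are correlated in one pass.
#'
#' @param profile an [ActivityProfile-class].
#' @param omics a features-by-cell-lines numeric matrix (named) or a
#'   `SummarizedExperiment` whose first assay is such a matrix.
#' @param minOverlap minimum pairwise-complete cell lines per feature
#'   (default 3).
#' @return A data frame `feature`, `n`, `r`, `p` for eligible features,
#'   sorted by input order; ineligible features with reasons in
#'   `attr(, "excluded")`.
#' @examples
#' pan <- simPanel(seed = 1)
#' prof <- simActivity(pan, seed = 1)$profile
#' se <- simProteome(prof, nProteins = 50, seed = 1)
#' head(compareProteins(prof, se))
#' @export
compareProteins <- function(profile, omics, minOverlap = 3L) {
  stopifnot(is(profile, "ActivityProfile"))
  mat <- .assayMatrix(omics)
  common <- intersect(colnames(mat), names(profile@values))
  if (length(common) == 0L)
    stop("no overlapping cell lines between profile and matrix")
  x <- profile@values[common]
  m <- mat[, common, drop = FALSE]
  fin <- is.finite(m)
  xfin <- is.finite(x)
  n <- as.integer(fin %*% xfin)
  r <- suppressWarnings(
    as.numeric(cor(x, t(m), use = "pairwise.complete.obs")))
  tstat <- r * sqrt(pmax(n - 2L, 0L)) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * pt(abs(tstat), df = n - 2L, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  bad <- n < minOverlap | !is.finite(r)
  reason <- ifelse(n < minOverlap,
                   sprintf("only %d overlapping cell lines", n),
                   "zero variance or undefined correlation")
  out <- data.frame(feature = rownames(m), n = n, r = r, p = p,
                    stringsAsFactors = FALSE)[!bad, ]
  rownames(out) <- NULL
  attr(out, "excluded") <-
    data.frame(feature = rownames(m)[bad], n = n[bad],
               reason = reason[bad], stringsAsFactors = FALSE)
  out
}

#' Select the top directly and inversely correlated features
#'
#' Picks the `kDirect` features with the largest positive r and the
#' `kInverse` features with the most negative r from a feature
#' correlation table, the "top 20 + 20" selection feeding the
#' two-dimensional cluster map.  Ties are broken by feature id so the
#' selection is deterministic and invariant to input row order.
#'
#' @param correlations data frame from [compareProteins()].
#' @param kDirect,kInverse numbers of features per direction
#'   (defaults 20 and 20).
#' @return A list of class `"CompareSelection"` with data frames
#'   `direct` (r descending) and `inverse` (r ascending).
#' @export
selectTop <- function(correlations, kDirect = 20L, kInverse = 20L) {
  stopifnot(is.data.frame(correlations),
            all(c("feature", "r") %in% names(correlations)),
            kDirect >= 0, kInverse >= 0)
  pos <- correlations[correlations$r > 0, ]
  neg <- correlations[correlations$r < 0, ]
  if (nrow(pos) < kDirect)
    stop(sprintf("only %d positively correlated features, need %d",
                 nrow(pos), kDirect))
  if (nrow(neg) < kInverse)
    stop(sprintf("only %d negatively correlated features, need %d",
                 nrow(neg), kInverse))
  pos <- pos[order(-pos$r, pos$feature), ][seq_len(kDirect), ]
  neg <- neg[order(neg$r, neg$feature), ][seq_len(kInverse), ]
  rownames(pos) <- rownames(neg) <- NULL
  structure(list(direct = pos, inverse = neg),
            class = "CompareSelection")
}

#' @export
print.CompareSelection <- function(x, ...) {
  cat(sprintf("CompareSelection: %d direct (r %s..%s), %d inverse (r %s..%s)\n",
              nrow(x$direct),
              signif(max(x$direct$r), 3), signif(min(x$direct$r), 3),
              nrow(x$inverse),
              signif(min(x$inverse$r), 3), signif(max(x$inverse$r), 3)))
  invisible(x)
}

#' Quartile-code an abundance matrix for heat map display
#'
#' Recodes continuous abundances into the five display categories of
#' the cluster heat map: the four quartile bins plus an explicit
#' "median" category for values exactly equal to the median of their
#' coding unit.  Bins are Q1 = [min, q25), Q2 = [q25, median),
#' MEDIAN = {median}, Q3 = (median, q75], Q4 = (q75, max].
#'
#' @param mat numeric matrix (features x cell lines) or
#'   `SummarizedExperiment`.
#' @param axis `"per_feature"` (each row coded on its own quantiles,
#'   the default) or `"global"` (one set of quantiles for the whole
#'   matrix).
#' @return Character matrix of codes in
#'   `c("Q1", "Q2", "MEDIAN", "Q3", "Q4")`, same dimensions; `NA`
#'   propagates.
#' @examples
#' quartileCode(matrix(1:5, 1, dimnames = list("f", letters[1:5])))
#' @export
quartileCode <- function(mat, axis = c("per_feature", "global")) {
  axis <- match.arg(axis)
  mat <- .assayMatrix(mat)
  codeVec <- function(v, q) {
    out <- rep(NA_character_, length(v))
    ok <- is.finite(v)
    out[ok & v == q[2]] <- "MEDIAN"
    out[ok & v < q[1]] <- "Q1"
    out[ok & v >= q[1] & v < q[2]] <- "Q2"
    out[ok & v > q[2] & v <= q[3]] <- "Q3"
    out[ok & v > q[3]] <- "Q4"
    out
  }
  coded <- matrix(NA_character_, nrow(mat), ncol(mat),
                  dimnames = dimnames(mat))
  if (axis == "global") {
    v <- mat[is.finite(mat)]
    if (length(v) < 4L) stop("need >= 4 non-missing values to code")
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    coded[] <- codeVec(as.vector(mat), q)
  } else {
    for (i in seq_len(nrow(mat))) {
      v <- mat[i, ]
      if (sum(is.finite(v)) < 4L)
        stop("feature '", rownames(mat)[i],
             "' has < 4 non-missing values")
      q <- quantile(v[is.finite(v)], c(0.25, 0.5, 0.75), names = FALSE)
      coded[i, ] <- codeVec(v, q)
    }
  }
  coded
}

#' Ward minimum-variance hierarchical clustering
#'
#' Agglomerative clustering under Ward's criterion: at each step the
#' pair of clusters whose merger least increases the total
#' within-cluster sum of squares is merged.  Distances are Euclidean on
#' per-feature z-scores by default, making features with different
#' dynamic ranges commensurate (disable with `zscore = FALSE` to
#' cluster raw values).  Merge heights are reported as the
#' within-cluster sum-of-squares increase of each merge, which Ward's
#' criterion guarantees to be non-decreasing.
#'
#' @param mat numeric matrix (features x cell lines) or
#'   `SummarizedExperiment`.
#' @param axis `"rows"` to cluster features, `"cols"` to cluster cell
#'   lines.
#' @param zscore z-score each feature before computing distances
#'   (default TRUE).
#' @return An object of class [stats::hclust] whose `height` component
#'   holds the sum-of-squares increments.
#' @examples
#' m <- matrix(rnorm(40), 8, 5,
#'             dimnames = list(paste0("f", 1:8), paste0("c", 1:5)))
#' wardCluster(m, axis = "rows")$merge
#' @export
wardCluster <- function(mat, axis = c("rows", "cols"), zscore = TRUE) {
  axis <- match.arg(axis)
  mat <- .assayMatrix(mat)
  if (zscore) {
    mu <- rowMeans(mat, na.rm = TRUE)
    sdv <- apply(mat, 1, sd, na.rm = TRUE)
    sdv[sdv == 0] <- 1   # constant features carry no distance
    mat <- (mat - mu) / sdv
  }
  items <- if (axis == "rows") mat else t(mat)
  if (nrow(items) < 2L) stop("need >= 2 items to cluster")
  allmiss <- rowSums(is.finite(items)) == 0L
  if (any(allmiss))
    stop("item(s) with no finite values: ",
         paste(rownames(items)[allmiss], collapse = ", "))
  d <- dist(items, method = "euclidean")
  # Lance-Williams Ward on squared distances; those heights are twice
  # the SS increment of each merge.
  hc <- hclust(d^2, method = "ward.D")
  hc$height <- hc$height / 2
  hc$method <- "ward (SS increments)"
  hc$dist.method <- if (zscore) "euclidean on z-scores" else "euclidean"
  hc
}

#' Cut a dendrogram into K clusters with stable labels
#'
#' Cuts the merge tree after its last K - 1 merges and relabels the
#' clusters 1..K in order of first item appearance, so the labelling
#' does not depend on internal merge order.
#'
#' @param tree an [stats::hclust] object (e.g. from [wardCluster()]).
#' @param K number of clusters, between 1 and the number of items.
#' @return Named integer vector of cluster indices 1..K.
#' @export
cutTreeK <- function(tree, K) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$labels)
  if (K < 1L || K > n) stop("'K' must be between 1 and ", n)
  raw <- cutree(tree, k = K)
  relabel <- match(raw, unique(raw))
  setNames(as.integer(relabel), names(raw))
}

#' Median-split sensitivity calls from an activity profile
#'
#' Cell lines with log10(IC50) strictly below the panel median are
#' called sensitive, strictly above it resistant; values exactly at the
#' median are labelled `tie` (the strict-inequality rule leaves them
#' unclassified) and are dropped from downstream contingency tests.
#'
#' @param profile an [ActivityProfile-class] with >= 2 measured lines.
#' @return A list of class `"SensitivityCall"`: `calls` (named factor
#'   with levels sensitive/resistant/tie) and `threshold` (the median).
#' @examples
#' classifySensitivity(
#'   ActivityProfile("x", c(a = -7, b = -6, c = -5, d = -4)))
#' @export
classifySensitivity <- function(profile) {
  stopifnot(is(profile, "ActivityProfile"))
  v <- profile@values[is.finite(profile@values)]
  if (length(v) < 2L) stop("need >= 2 measured values")
  med <- median(v)
  calls <- factor(ifelse(v < med, "sensitive",
                  ifelse(v > med, "resistant", "tie")),
                  levels = c("sensitive", "resistant", "tie"))
  structure(list(calls = setNames(calls, names(v)), threshold = med),
            class = "SensitivityCall")
}

#' @export
print.SensitivityCall <- function(x, ...) {
  cat(sprintf("SensitivityCall: median log10(IC50) = %.4g\n", x$threshold))
  print(table(x$calls))
  invisible(x)
}

#' Chi-squared test of cluster membership versus drug response
#'
#' Builds the K x 2 contingency table of cell line cluster membership
#' against sensitive/resistant calls (tie lines are excluded) and
#' applies Pearson's chi-squared test without continuity correction,
#' df = K - 1.  A significant result means the proteome-derived
#' clusters separate responders from non-responders.
#'
#' @param clusters named cluster assignment (from [cutTreeK()]).
#' @param calls a `"SensitivityCall"` (from [classifySensitivity()]) or
#'   a named factor with levels including sensitive/resistant.
#' @param correct apply Yates continuity correction (default FALSE).
#' @return A list of class `"ChiSquareResult"`: `statistic`, `df`, `p`,
#'   `table` (observed counts), `expected`.
#' @export
clusterResponseChi2 <- function(clusters, calls, correct = FALSE) {
  if (inherits(calls, "SensitivityCall")) calls <- calls$calls
  common <- intersect(names(clusters), names(calls))
  cl <- clusters[common]
  ca <- calls[common]
  keep <- ca %in% c("sensitive", "resistant")
  cl <- factor(cl[keep])
  ca <- factor(as.character(ca[keep]),
               levels = c("sensitive", "resistant"))
  if (nlevels(cl) < 2L)
    stop("need >= 2 non-empty clusters after dropping tie cell lines")
  tab <- table(cluster = cl, response = ca)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("empty margin in contingency table; consider merging clusters")
  ht <- suppressWarnings(chisq.test(tab, correct = correct))
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p = ht$p.value,
                 table = tab, expected = ht$expected),
            class = "ChiSquareResult")
}

#' @export
print.ChiSquareResult <- function(x, ...) {
  cat(sprintf("Chi-squared = %.4g, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p))
  print(x$table)
  invisible(x)
}

#' Two-dimensional cluster map of selected proteomic correlates
#'
#' Convenience wrapper running the full proteome COMPARE display stage:
#' subsets the matrix to a [selectTop()] selection, Ward-clusters both
#' dimensions, quartile-codes the values and attaches median-split
#' response calls and their chi-squared association with the cell line
#' clusters.
#'
#' @param omics abundance matrix or `SummarizedExperiment`.
#' @param selection a `"CompareSelection"`.
#' @param profile the [ActivityProfile-class] used for response calls.
#' @param kRow,kCol numbers of feature and cell line clusters
#'   (defaults 3 and 2).
#' @param zscore passed to [wardCluster()].
#' @return A list of class `"ClusterMap"`: `rowTree`, `colTree`
#'   (hclust), `rowClusters`, `colClusters`, `coded` (quartile codes),
#'   `calls`, `chi2`.
#' @export
clusterMap <- function(omics, selection, profile, kRow = 3L, kCol = 2L,
                       zscore = TRUE) {
  stopifnot(inherits(selection, "CompareSelection"))
  mat <- .assayMatrix(omics)
  feats <- c(selection$direct$feature, selection$inverse$feature)
  sub <- mat[feats, , drop = FALSE]
  rowTree <- wardCluster(sub, axis = "rows", zscore = zscore)
  colTree <- wardCluster(sub, axis = "cols", zscore = zscore)
  rowClusters <- cutTreeK(rowTree, kRow)
  colClusters <- cutTreeK(colTree, kCol)
  calls <- classifySensitivity(profile)
  chi2 <- tryCatch(clusterResponseChi2(colClusters, calls),
                   error = function(e) e)
  structure(list(rowTree = rowTree, colTree = colTree,
                 rowClusters = rowClusters, colClusters = colClusters,
                 coded = quartileCode(sub), calls = calls, chi2 = chi2),
            class = "ClusterMap")
}

#' @export
print.ClusterMap <- function(x, ...) {
  cat(sprintf("ClusterMap: %d features x %d cell lines (%d x %d clusters)\n",
              nrow(x$coded), ncol(x$coded),
              max(x$rowClusters), max(x$colClusters)))
  if (inherits(x$chi2, "ChiSquareResult"))
    cat(sprintf("  cluster-response chi-squared p = %.3g\n", x$chi2$p))
  invisible(x)
}
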