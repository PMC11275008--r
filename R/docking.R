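# Gas constant in kcal / (mol K), the AutoDock convention.
.RGAS <- 1.98719e-3

#' Convert a binding free energy to a predicted inhibition constant
#'
#' Applies the thermodynamic relation Ki = exp(deltaG / (R T)) with
#' R = 1.98719e-3 kcal mol^-1 K^-1, the convention AutoDock uses to
#' derive its predicted inhibition constants from docking free
#' energies.  A more negative energy gives a smaller (tighter) Ki.
#'
#' @param deltaG binding free energy in kcal/mol (negative for
#'   favorable binding); vectorized.
#' @param temperature absolute temperature in K (default 298.15).
#' @return Predicted inhibition constant(s) in molar units.
#' @examples
#' kiFromEnergy(-8.70) * 1e6   # 0.42 uM
#' kiFromEnergy(0)             # 1 M by construction
#' @seealso [energyFromKi()], [correlateLbePki()]
#' @export
kiFromEnergy <- function(deltaG, temperature = 298.15) {
  if (any(!is.finite(deltaG)))
    stop("'deltaG' must be finite (kcal/mol)")
  stopifnot(is.numeric(temperature), temperature > 0)
  exp(deltaG / (.RGAS * temperature))
}

#' Convert an inhibition constant back to a binding free energy
#'
#' Inverse of [kiFromEnergy()]: deltaG = R T ln(Ki).
#'
#' @param ki inhibition constant(s) in molar units, > 0.
#' @param temperature absolute temperature in K (default 298.15).
#' @return Binding free energy in kcal/mol.
#' @examples
#' energyFromKi(kiFromEnergy(-7.59))  # -7.59
#' @export
energyFromKi <- function(ki, temperature = 298.15) {
  if (any(!is.finite(ki)) || any(ki <= 0))
    stop("'ki' must be positive and finite (molar)")
  stopifnot(is.numeric(temperature), temperature > 0)
  .RGAS * temperature * log(ki)
}

#' Pearson correlation with a t-distributed two-sided p-value
#'
#' Product-moment correlation over pairwise-complete observations with
#' the usual two-sided p-value from t = r sqrt(n-2)/sqrt(1-r^2) on
#' n - 2 degrees of freedom (delegated to [stats::cor.test()]).
#' Profiles over cell line panels routinely have gaps, so pairs with a
#' missing member are dropped before anything else.
#'
#' @param x,y numeric vectors of equal length.
#' @return A list of class `"CorrelationResult"` with elements `r`,
#'   `p` (two-sided) and `n` (complete pairs used).
#' @examples
#' pearsonTest(1:4, c(2, 1, 4, 3))   # r = 0.6
#' @export
pearsonTest <- function(x, y) {
  if (length(x) != length(y))
    stop("'x' and 'y' must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L)
    stop("correlation undefined: fewer than 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined: zero variance in an argument")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = n),
            class = "CorrelationResult")
}

#' @export
print.CorrelationResult <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f, two-sided p = %.3g (n = %d)\n",
              x$r, x$p, x$n))
  invisible(x)
}

#' Correlation quality control of a docking score table
#'
#' Correlates the mean lowest binding energies (kcal/mol) of a set of
#' docked compounds with their mean predicted inhibition constants.
#' Since Ki is an exponential transform of the free energy the two
#' columns must agree strongly; a weak correlation flags transcription
#' or unit errors in the table.  All pKi values must share one unit
#' before correlating.
#'
#' @param compounds a data frame with columns `lbe_mean` and `pki_mean`
#'   (as produced by [readDockingTable()]).  If a `pki_unit` column is
#'   present it must be constant; mixed units raise an error.
#' @return A `"CorrelationResult"` (see [pearsonTest()]).
#' @examples
#' tab <- readDockingTable(system.file("extdata", "nfkb_docking.tsv",
#'                                     package = "OncoCompare"))
#' correlateLbePki(tab)   # r = 0.76 over the 28 compounds
#' @export
correlateLbePki <- function(compounds) {
  stopifnot(is.data.frame(compounds),
            all(c("lbe_mean", "pki_mean") %in% names(compounds)))
  if ("pki_unit" %in% names(compounds) &&
      length(unique(compounds$pki_unit)) > 1L)
    stop("mixed pKi units: convert to a single unit before correlating")
  if (nrow(compounds) < 3L)
    stop("need at least 3 compounds")
  pearsonTest(compounds$lbe_mean, compounds$pki_mean)
}

#' Read a docking score table
#'
#' Reads a TSV of docked compounds with columns `name`, `lbe_mean`,
#' `lbe_sd`, `pki_mean`, `pki_sd`, `pki_unit`, `site` and a
#' semicolon-separated `pharmacophore` residue list.  Two such tables
#' ship with the package: `nfkb_docking.tsv` (28 phytochemicals docked
#' to the NF-kB p65-RelA homodimer) and `tubulin_docking.tsv` (ligand /
#' binding-site pairs docked to alpha/beta-tubulin).
#'
#' @param path path to the TSV file.
#' @return A data frame; the `pharmacophore` column is a list of
#'   character vectors of residue identifiers.
#' @export
readDockingTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  need <- c("name", "lbe_mean", "pki_mean", "pki_unit")
  if (!all(need %in% names(tab)))
    stop("docking table must contain columns: ",
         paste(need, collapse = ", "))
  if (anyDuplicated(paste(tab$name, tab$site)))
    stop("duplicate compound/site rows in docking table")
  if (any(tab$pki_mean <= 0)) stop("pKi values must be positive")
  if (!all(tab$pki_unit %in% c("M", "mM", "uM", "nM")))
    stop("pki_unit must be one of M, mM, uM, nM")
  if ("pharmacophore" %in% names(tab)) {
    tab$pharmacophore <- lapply(strsplit(tab$pharmacophore, ";"),
                                trimws)
    bad <- !vapply(tab$pharmacophore, function(res)
      all(grepl("^([A-Za-z]+: ?)?[A-Za-z]+[0-9]+$", res)), logical(1))
    if (any(bad))
      stop("malformed residue identifiers for: ",
           paste(tab$name[bad], collapse = ", "))
  }
  tab
}

#' Reconstruct predicted inhibition constants for a docking table
#'
#' Applies [kiFromEnergy()] to each mean binding energy and reports the
#' reconstructed Ki next to the printed one, in the unit the table
#' declares, together with the relative error.
#'
#' @param compounds data frame from [readDockingTable()].
#' @param temperature absolute temperature in K.
#' @return The input with columns `ki_reconstructed` (same unit as
#'   `pki_mean`) and `rel_error` appended.
#' @export
reconstructKi <- function(compounds, temperature = 298.15) {
  scale <- c(M = 1, mM = 1e3, uM = 1e6, nM = 1e9)[compounds$pki_unit]
  compounds$ki_reconstructed <-
    kiFromEnergy(compounds$lbe_mean, temperature) * scale
  compounds$rel_error <-
    abs(compounds$ki_reconstructed - compounds$pki_mean) /
    compounds$pki_mean
  compounds
}
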