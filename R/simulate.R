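# Generators consume the global RNG stream; pass `seed` for
# bit-reproducible output.

#' Default tissue composition of the simulated 60-line panel
#'
#' Nine tumor tissue types with the line counts of the NCI-60 screening
#' panel: leukemia 6, melanoma 9, brain 6, colon 7, ovary 7, breast 6,
#' kidney 8, lung 9, prostate 2.
#'
#' @return Named integer vector summing to 60.
#' @export
nci60TissueCounts <- function() {
  c(leukemia = 6L, melanoma = 9L, brain = 6L, colon = 7L, ovary = 7L,
    breast = 6L, kidney = 8L, lung = 9L, prostate = 2L)
}

.tissuePrefix <- c(leukemia = "LE", melanoma = "ME", brain = "BN",
                   colon = "CO", ovary = "OV", breast = "BR",
                   kidney = "KI", lung = "LC", prostate = "PR")

#' Simulate a cell line panel
#'
#' Deterministic panel of named cell lines with tissue labels; the
#' default reproduces the 60-line / 9-tissue layout of
#' [nci60TissueCounts()].
#'
#' @param tissueCounts named integer vector, lines per tissue.
#' @param seed unused (the panel is deterministic); accepted for
#'   interface uniformity with the other generators.
#' @return A [CellLinePanel-class].
#' @examples
#' simPanel()
#' @export
simPanel <- function(tissueCounts = nci60TissueCounts(), seed = NULL) {
  stopifnot(!is.null(names(tissueCounts)), all(tissueCounts >= 1))
  pref <- .tissuePrefix[names(tissueCounts)]
  pref[is.na(pref)] <- toupper(substr(names(tissueCounts)[is.na(pref)],
                                      1, 2))
  ids <- unlist(mapply(function(p, k) sprintf("%s%02d", p, seq_len(k)),
                       pref, tissueCounts, SIMPLIFY = FALSE))
  CellLinePanel(ids, rep(names(tissueCounts), tissueCounts))
}

.defaultMoaSizes <- c(alkylating = 12L, antimetabolite = 12L,
                      microtubule = 10L, topoisomerase2 = 10L,
                      mTOR = 8L, topoisomerase1 = 8L, platinum = 8L,
                      antibiotic = 8L, kinase = 8L, hormonal = 7L)

#' Simulate a compound profile and an annotated agent library
#'
#' Single-factor model of mode-of-action structure: each class has a
#' latent response factor over the panel, each agent's log10(IC50)
#' profile is sqrt(rho) x its class factor + sqrt(1 - rho) x noise, and
#' the query compound is tied to `compoundClass` at the same rho, so
#' within-class profile correlations are rho in expectation.  The
#' default library has 91 agents over 10 mechanism classes (10 of them
#' microtubule inhibitors).  A tissue shift (default: leukemia lines
#' 0.5 log10 units more sensitive) is added to every profile, emulating
#' the uniformly higher sensitivity of leukemia lines.
#'
#' @param panel a [CellLinePanel-class].
#' @param classSizes named integer vector of agents per class.
#' @param rho within-class profile correlation in (0, 1), default 0.8.
#' @param compoundClass class the query compound belongs to (default
#'   `"microtubule"`).
#' @param baseMean,baseSD location/scale of log10(IC50) values (log10
#'   molar; defaults -5 and 0.5).
#' @param tissueShift named numeric, additive log10(IC50) shift per
#'   tissue (default `c(leukemia = -0.5)`).
#' @param seed RNG seed.
#' @return List: `profile` ([ActivityProfile-class]), `library`
#'   ([AgentLibrary-class]), `compoundClass` (ground truth).
#' @examples
#' sim <- simActivity(simPanel(), seed = 7)
#' sim$compoundClass
#' @export
simActivity <- function(panel, classSizes = .defaultMoaSizes, rho = 0.8,
                        compoundClass = "microtubule",
                        baseMean = -5, baseSD = 0.5,
                        tissueShift = c(leukemia = -0.5), seed = NULL) {
  stopifnot(is(panel, "CellLinePanel"), rho > 0, rho < 1,
            compoundClass %in% names(classSizes))
  if (!is.null(seed)) set.seed(seed)
  lines <- cellLines(panel)
  nL <- length(lines)
  shift <- tissueShift[as.character(tissues(panel))]
  shift[is.na(shift)] <- 0
  factors <- matrix(rnorm(length(classSizes) * nL), ncol = nL,
                    dimnames = list(names(classSizes), lines))
  mix <- function(f) sqrt(rho) * f + sqrt(1 - rho) * rnorm(nL)
  agents <- character(0); moa <- character(0)
  prof <- matrix(NA_real_, sum(classSizes), nL,
                 dimnames = list(NULL, lines))
  k <- 0L
  for (cls in names(classSizes)) {
    for (j in seq_len(classSizes[[cls]])) {
      k <- k + 1L
      agents <- c(agents, sprintf("%s_%02d", cls, j))
      moa <- c(moa, cls)
      prof[k, ] <- baseMean + baseSD * mix(factors[cls, ]) + shift
    }
  }
  rownames(prof) <- agents
  compound <- baseMean + baseSD * mix(factors[compoundClass, ]) + shift
  list(profile = ActivityProfile("compound", setNames(compound, lines)),
       library = AgentLibrary(prof, setNames(moa, agents)),
       compoundClass = compoundClass)
}

#' Simulate an abundance matrix with planted response correlates
#'
#' Proteome-like features x cell lines matrix: `nDirect` features are
#' planted with population correlation `+targetR` to the supplied
#' profile, `nInverse` with `-targetR`, the remainder are independent
#' noise.  Planted features are x = +/- (alpha z + sqrt(1 - alpha^2) e)
#' with z the standardized profile and alpha = targetR, then each
#' feature is given its own arbitrary abundance location and scale
#' (correlations are unaffected).
#'
#' @param profile an [ActivityProfile-class].
#' @param nProteins total number of features (default 500, a reduced
#'   stand-in for a full cell-panel proteome).
#' @param nDirect,nInverse planted counts (defaults 20 and 20).
#' @param targetR planted correlation magnitude in (0, 1), default 0.6.
#' @param seed RNG seed.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `abundance`, a `planted` column in `rowData`, and the planted
#'   feature ids in `metadata(.)$direct` / `$inverse`.
#' @examples
#' prof <- simActivity(simPanel(), seed = 1)$profile
#' se <- simProteome(prof, nProteins = 100, seed = 1)
#' table(SummarizedExperiment::rowData(se)$planted)
#' @export
simProteome <- function(profile, nProteins = 500L, nDirect = 20L,
                        nInverse = 20L, targetR = 0.6, seed = NULL) {
  stopifnot(is(profile, "ActivityProfile"),
            nDirect + nInverse <= nProteins,
            targetR > 0, targetR < 1)
  if (!is.null(seed)) set.seed(seed)
  v <- profileValues(profile)
  lines <- names(v)[is.finite(v)]
  z <- as.numeric(scale(v[lines]))
  nL <- length(lines)
  status <- rep(c("direct", "inverse", "null"),
                c(nDirect, nInverse, nProteins - nDirect - nInverse))
  sign <- c(direct = 1, inverse = -1, null = 0)[status]
  core <- t(vapply(sign, function(s) {
    if (s == 0) rnorm(nL)
    else s * (targetR * z + sqrt(1 - targetR^2) * rnorm(nL))
  }, numeric(nL)))
  scalef <- exp(rnorm(nProteins, 0, 0.3))
  locf <- rnorm(nProteins, 10, 2)
  mat <- core * scalef + locf
  dimnames(mat) <- list(sprintf("P%04d", seq_len(nProteins)), lines)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = mat),
    rowData = S4Vectors::DataFrame(planted = status))
  S4Vectors::metadata(se) <- list(
    direct = rownames(mat)[status == "direct"],
    inverse = rownames(mat)[status == "inverse"],
    targetR = targetR)
  se
}

#' Simulate a binding titration series
#'
#' Serial-dilution titration of a ligand against a fixed labelled
#' target, signals drawn from the quadratic mass-action model with
#' multiplicative Gaussian noise (noise proportional to signal, as for
#' normalized fluorescence readouts).  The defaults emulate a 14-point
#' 1:1 dilution from 300 uM against 200 nM of target with a true K_D
#' of 943 nM and 2% noise; the signal plateaus (1.0 unbound, 0.5
#' bound) are calibrated so that at this noise level the replicate
#' spread of the fitted K_D reproduces the roughly +/-113 nM
#' uncertainty typical of such an experiment.
#'
#' @param kd true dissociation constant (M).
#' @param targetTotal labelled target concentration (M).
#' @param nPoints number of titration points.
#' @param topConc highest ligand concentration (M).
#' @param dilutionFactor serial dilution factor (default 2, i.e. 1:1).
#' @param signalUnbound,signalBound normalized signal plateaus.
#' @param noiseSD multiplicative noise SD (default 0.02).
#' @param seed RNG seed.
#' @return A [TitrationSeries-class]; the generating K_D is in
#'   `attr(, "trueKd")`.
#' @examples
#' ts <- simTitration(seed = 3)
#' attr(ts, "trueKd")
#' @export
simTitration <- function(kd = 943e-9, targetTotal = 200e-9,
                         nPoints = 14L, topConc = 300e-6,
                         dilutionFactor = 2, signalUnbound = 1,
                         signalBound = 0.5, noiseSD = 0.02,
                         seed = NULL) {
  stopifnot(kd > 0, targetTotal > 0, nPoints >= 6, noiseSD >= 0)
  if (!is.null(seed)) set.seed(seed)
  L <- topConc / dilutionFactor^(seq_len(nPoints) - 1)
  s <- predictSignal(L, kd, signalUnbound, signalBound, targetTotal)
  s <- s * (1 + rnorm(nPoints, 0, noiseSD))
  out <- TitrationSeries(L, s, targetTotal)
  attr(out, "trueKd") <- kd
  out
}

#' Simulate a survival cohort with expression-dependent hazard
#'
#' Two equal arms with exponential event times: the low-expression arm
#' has median survival `medianLowMonths`, the high-expression arm's
#' hazard is `hazardRatio` times larger.  Expression is drawn so that a
#' median split exactly recovers the arms (low arm uniform on (0, 1),
#' high arm on (1, 2)).  Each subject is independently censored with
#' probability `censorFraction`, at a uniform time before its event.
#'
#' @param nPerArm subjects per arm (default 200).
#' @param hazardRatio hazard of the high-expression arm relative to the
#'   low arm (default 2; 1 gives exchangeable arms).
#' @param censorFraction expected censored fraction (default 0.2).
#' @param medianLowMonths median survival of the low arm in months
#'   (default 60).
#' @param seed RNG seed.
#' @return Data frame `subject`, `time`, `event`, `expression`; the
#'   generating hazard ratio in `attr(, "trueHR")`.
#' @export
simSurvivalCohort <- function(nPerArm = 200L, hazardRatio = 2,
                              censorFraction = 0.2,
                              medianLowMonths = 60, seed = NULL) {
  stopifnot(hazardRatio > 0, censorFraction >= 0, censorFraction < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- 2L * nPerArm
  arm <- rep(c("low", "high"), each = nPerArm)
  rate <- ifelse(arm == "low", log(2) / medianLowMonths,
                 hazardRatio * log(2) / medianLowMonths)
  t_event <- rexp(n, rate)
  censored <- runif(n) < censorFraction
  time <- ifelse(censored, runif(n) * t_event, t_event)
  expr <- ifelse(arm == "low", runif(n), 1 + runif(n))
  out <- data.frame(subject = sprintf("S%04d", seq_len(n)),
                    time = time, event = as.integer(!censored),
                    expression = expr, stringsAsFactors = FALSE)
  attr(out, "trueHR") <- hazardRatio
  out
}

#' Simulate a multi-cohort survival screen input
#'
#' Named list of independent cohorts from [simSurvivalCohort()],
#' emulating a mining pass over many tumor entities (default 21).
#' `hazardRatio` may be a vector (recycled) to plant signal in selected
#' cohorts only.
#'
#' @param nCohorts number of cohorts (default 21).
#' @param hazardRatio scalar or vector of arm hazard ratios (default 1,
#'   i.e. a null screen).
#' @param nPerArm,censorFraction,medianLowMonths passed through.
#' @param seed RNG seed.
#' @return Named list of cohort data frames.
#' @export
simSurvivalCohorts <- function(nCohorts = 21L, hazardRatio = 1,
                               nPerArm = 200L, censorFraction = 0.2,
                               medianLowMonths = 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hr <- rep_len(hazardRatio, nCohorts)
  out <- lapply(seq_len(nCohorts), function(i)
    simSurvivalCohort(nPerArm = nPerArm, hazardRatio = hr[i],
                      censorFraction = censorFraction,
                      medianLowMonths = medianLowMonths, seed = NULL))
  names(out) <- sprintf("cohort%02d", seq_len(nCohorts))
  out
}

#' Simulate a qPCR Ct table with a known fold change
#'
#' Treated/control by target/reference Ct rows with replicate Gaussian
#' noise.  The treated target Ct is offset by minus the true log2 fold
#' (downregulation raises the Ct), so [ddctFold()] recovers `log2Fold`
#' exactly at zero noise.
#'
#' @param log2Fold true log2 fold change (default -1.11).
#' @param noiseSD replicate Ct noise SD in cycles (default 0.1).
#' @param nReplicates replicates per group x role (default 3).
#' @param referenceCt,targetControlCt baseline cycle thresholds
#'   (defaults 18 and 25).
#' @param seed RNG seed.
#' @return Data frame `group`, `role`, `ct`, `replicate`.
#' @examples
#' ddctFold(simCtTable(noiseSD = 0, seed = 1))$log2Fold   # -1.11
#' @export
simCtTable <- function(log2Fold = -1.11, noiseSD = 0.1,
                       nReplicates = 3L, referenceCt = 18,
                       targetControlCt = 25, seed = NULL) {
  stopifnot(noiseSD >= 0, nReplicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(replicate = seq_len(nReplicates),
                      role = c("target", "reference"),
                      group = c("treated", "control"),
                      stringsAsFactors = FALSE)
  base <- ifelse(grid$role == "reference", referenceCt,
                 ifelse(grid$group == "treated",
                        targetControlCt - log2Fold, targetControlCt))
  grid$ct <- base + rnorm(nrow(grid), 0, noiseSD)
  grid[, c("group", "role", "ct", "replicate")]
}
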