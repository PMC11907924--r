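# Synthetic data generators with planted ground truth. These emulate the
# statistical shape of label-free phosphoproteomics experiments: log-normal
# peptide intensities (log2 baseline ~ Normal(20, 2), the typical LC-MS
# dynamic range), per-cell missingness, small replicated control/treated
# contrasts with kinase-level shifts, and a cohort whose drug sensitivity is
# carried by a handful of co-regulated phosphosites.

#' Simulate a kinase-substrate style set database
#'
#' Draws `nSets` named feature sets over a universe of `nFeatures` site ids.
#' A shared core of `round(overlapFraction * featuresPerSet)` sites is
#' placed in every set so that the expected pairwise overlap is controlled;
#' the remaining members are drawn independently per set from the rest of
#' the universe.
#'
#' @param nSets number of sets (kinases/compounds/TFs).
#' @param nFeatures size of the feature universe.
#' @param featuresPerSet members per set; must not exceed `nFeatures`.
#' @param overlapFraction fraction of each set shared with every other set.
#' @param seed integer seed; output is deterministic given the seed.
#' @param sources source labels cycled over the sets.
#' @return A [SetDb-class] whose `universe` holds all `nFeatures` site ids.
#' @examples
#' db <- simulateSetDb(5, 200, 10, overlapFraction = 0.2, seed = 1)
#' lengths(featureSets(db))
#' @export
simulateSetDb <- function(nSets, nFeatures, featuresPerSet,
                          overlapFraction = 0, seed = 1,
                          sources = c("PDTs", "pSite", "Signor")) {
  nSets <- .checkCount(nSets, "nSets")
  nFeatures <- .checkCount(nFeatures, "nFeatures")
  featuresPerSet <- .checkCount(featuresPerSet, "featuresPerSet")
  overlapFraction <- .checkFraction(overlapFraction, "overlapFraction")
  if (featuresPerSet > nFeatures)
    stop("'featuresPerSet' cannot exceed 'nFeatures'", call. = FALSE)
  withr::with_seed(seed, {
    universe <- .makeSiteIds(nFeatures)
    coreSize <- round(overlapFraction * featuresPerSet)
    core <- if (coreSize > 0) sample(universe, coreSize) else character()
    rest <- setdiff(universe, core)
    sets <- lapply(seq_len(nSets), function(i)
      c(core, sample(rest, featuresPerSet - coreSize)))
    names(sets) <- sprintf("K%02d", seq_len(nSets))
    SetDb(sets, source = rep_len(sources, nSets), universe = universe)
  })
}

#' Simulate a control/treated phosphoproteomics contrast
#'
#' Emits raw-scale peptide-ion intensities for `nControl` control and
#' `nTreated` treated samples over the universe of `setDb`. Each site has a
#' log2 baseline ~ Normal(20, 2); in treated samples, substrate sites of
#' each planted kinase are shifted by the planted log2 amount; every cell
#' receives independent Normal(0, `noiseSd`) log2 noise. A configurable
#' fraction of sites is carried by two peptide ions (to exercise site
#' roll-up) and cells go missing with probability `missingRate`, either
#' completely at random or preferentially at low intensity
#' (`missingMode = "censored"`, emulating left-censored detection).
#'
#' @param setDb a [SetDb-class]; its universe defines the quantified sites.
#' @param plantedShifts named numeric, log2 shift per planted kinase; every
#'   name must be a set in `setDb`.
#' @param nControl,nTreated replicates per arm.
#' @param noiseSd log2-scale noise standard deviation.
#' @param missingRate per-cell missingness probability in \[0, 1\].
#' @param twoIonFraction fraction of sites represented by 2 peptide ions.
#' @param missingMode `"mcar"` (default) or `"censored"`.
#' @param seed integer seed.
#' @return list with elements `peptides` (a [PeptideQuant-class] whose
#'   `colData$group` is `"control"`/`"treated"`) and `truth`
#'   (a [GroundTruth-class]).
#' @examples
#' db <- simulateSetDb(3, 100, 10, seed = 1)
#' sim <- simulateTreatmentContrast(db, c(K01 = -1), seed = 2)
#' table(SummarizedExperiment::colData(sim$peptides)$group)
#' @export
simulateTreatmentContrast <- function(setDb, plantedShifts = numeric(),
                                      nControl = 4, nTreated = 4,
                                      noiseSd = 0.5, missingRate = 0,
                                      twoIonFraction = 0,
                                      missingMode = c("mcar", "censored"),
                                      seed = 1) {
  stopifnot(methods::is(setDb, "SetDb"))
  missingMode <- match.arg(missingMode)
  nControl <- .checkCount(nControl, "nControl")
  nTreated <- .checkCount(nTreated, "nTreated")
  missingRate <- .checkFraction(missingRate, "missingRate")
  twoIonFraction <- .checkFraction(twoIonFraction, "twoIonFraction")
  if (length(plantedShifts)) {
    bad <- setdiff(names(plantedShifts), names(setDb))
    if (length(bad))
      stop("planted kinase(s) not in the set database: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  sites <- setUniverse(setDb)
  if (!length(sites)) stop("'setDb' has an empty universe", call. = FALSE)
  withr::with_seed(seed, {
    shift <- setNames(numeric(length(sites)), sites)
    for (k in names(plantedShifts))
      shift[intersect(setDb[[k]], sites)] <-
        shift[intersect(setDb[[k]], sites)] + plantedShifts[[k]]
    nTwo <- round(twoIonFraction * length(sites))
    twoIon <- if (nTwo > 0) sample(sites, nTwo) else character()
    ionSite <- c(sites, twoIon)
    ionSite <- ionSite[order(match(ionSite, sites))]
    nIon <- length(ionSite)
    samples <- c(sprintf("ctrl_%d", seq_len(nControl)),
                 sprintf("trt_%d", seq_len(nTreated)))
    group <- rep(c("control", "treated"), c(nControl, nTreated))
    baseline <- rnorm(nIon, mean = 20, sd = 2)
    log2m <- matrix(baseline, nIon, length(samples)) +
      matrix(rnorm(nIon * length(samples), sd = noiseSd), nIon) +
      outer(shift[ionSite], as.numeric(group == "treated"))
    m <- 2^log2m
    if (missingRate > 0) {
      pm <- if (missingMode == "mcar") {
        matrix(missingRate, nIon, length(samples))
      } else {
        # low-intensity cells are more likely absent; expected rate preserved
        r <- matrix(rank(log2m) / length(log2m), nIon)
        pmin(1, 2 * missingRate * (1 - r))
      }
      m[matrix(runif(length(m)), nIon) < pm] <- NA
    }
    dimnames(m) <- list(sprintf("ion%05d", seq_len(nIon)), samples)
    pep <- PeptideQuant(m,
      protein = .siteProtein(ionSite), sites = ionSite,
      sequence = .randomPeptide(nIon),
      colData = S4Vectors::DataFrame(group = group, row.names = samples))
    truth <- methods::new("GroundTruth",
      plantedKinaseShifts = unlist(plantedShifts) %||% numeric())
    list(peptides = pep, truth = truth)
  })
}

#' Simulate a drug-sensitivity cohort with informative phosphosites
#'
#' Emits a phosphosite ppIndex matrix for `nSamples` samples in which
#' `nInformative` sites are co-regulated through a latent per-sample kinase
#' activity (site log2 value = baseline + activity + Normal(0, 0.5)
#' residual) while all other sites are independent noise. The continuous
#' sensitivity of each sample is
#' `effectSdUnits * sum(z-scores of the informative sites) + Normal(0, 1)`,
#' so `effectSdUnits = 0` makes sensitivity independent of the data.
#' Sensitive/resistant labels are assigned downstream by
#' [classifySensitivity()].
#'
#' @param nSamples cohort size.
#' @param nSites number of quantified phosphosites.
#' @param nInformative number of sensitivity-carrying sites (\eqn{\le}
#'   `nSites`).
#' @param effectSdUnits per-site signal weight in noise-sd units.
#' @param seed integer seed.
#' @return list with `sites` (a [SiteQuant-class], raw scale), `sensitivity`
#'   (named numeric) and `truth` (a [GroundTruth-class]).
#' @examples
#' cohort <- simulateCohort(36, 200, 5, effectSdUnits = 2, seed = 11)
#' head(cohort$sensitivity)
#' @export
simulateCohort <- function(nSamples = 36, nSites = 1000, nInformative = 10,
                           effectSdUnits = 2, seed = 1) {
  nSamples <- .checkCount(nSamples, "nSamples", min = 2L)
  nSites <- .checkCount(nSites, "nSites")
  nInformative <- .checkCount(nInformative, "nInformative")
  if (nInformative > nSites)
    stop("'nInformative' cannot exceed 'nSites'", call. = FALSE)
  if (effectSdUnits < 0)
    stop("'effectSdUnits' must be non-negative", call. = FALSE)
  withr::with_seed(seed, {
    siteIds <- .makeSiteIds(nSites)
    samples <- sprintf("case_%02d", seq_len(nSamples))
    baseline <- rnorm(nSites, 20, 2)
    log2m <- matrix(baseline, nSites, nSamples) +
      matrix(rnorm(nSites * nSamples), nSites)
    informative <- sample(siteIds, nInformative)
    idx <- match(informative, siteIds)
    activity <- rnorm(nSamples)
    log2m[idx, ] <- baseline[idx] +
      matrix(activity, nInformative, nSamples, byrow = TRUE) +
      matrix(rnorm(nInformative * nSamples, sd = 0.5), nInformative)
    z <- t(scale(t(log2m[idx, , drop = FALSE])))
    sens <- effectSdUnits * colSums(z) + rnorm(nSamples)
    names(sens) <- samples
    dimnames(log2m) <- list(siteIds, samples)
    truth <- methods::new("GroundTruth", informativeSites = informative,
                          trueSensitivity = sens)
    list(sites = SiteQuant(2^log2m), sensitivity = sens, truth = truth)
  })
}

#' Simulate a dose-viability curve
#'
#' Viability follows a four-parameter-logistic-shaped decreasing curve over
#' log-spaced doses, scaled by `effect`: `effect = 0` leaves viability
#' identically 1, `effect = 1` lets viability fall to the logistic floor at
#' the top dose.
#'
#' @param nDoses number of doses (>= 2), log-spaced over `doseRange`.
#' @param effect maximal fractional kill in \[0, 1\].
#' @param seed integer seed (used only when `noiseSd > 0`).
#' @param doseRange length-2 numeric, lowest and highest dose.
#' @param ec50 dose of half-maximal effect (default: geometric mid-range).
#' @param hill Hill slope of the logistic.
#' @param noiseSd optional viability measurement noise (truncated at 0).
#' @return data.frame with columns `dose` and `viability`.
#' @examples
#' simulateDoseResponse(6, effect = 1, seed = 3)
#' @export
simulateDoseResponse <- function(nDoses = 8, effect = 1, seed = 1,
                                 doseRange = c(1e-3, 10), ec50 = NULL,
                                 hill = 1, noiseSd = 0) {
  nDoses <- .checkCount(nDoses, "nDoses", min = 2L)
  effect <- .checkFraction(effect, "effect")
  stopifnot(length(doseRange) == 2L, all(doseRange > 0),
            doseRange[2] > doseRange[1])
  doses <- 10^seq(log10(doseRange[1]), log10(doseRange[2]),
                  length.out = nDoses)
  if (is.null(ec50)) ec50 <- sqrt(doseRange[1] * doseRange[2])
  v <- 1 - effect * (1 - 1 / (1 + (doses / ec50)^hill))
  if (noiseSd > 0)
    v <- withr::with_seed(seed, pmax(0, v + rnorm(nDoses, sd = noiseSd)))
  data.frame(dose = doses, viability = v)
}
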