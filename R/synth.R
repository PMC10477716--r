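#' Fluorescence component template
#'
#' A unimodal humic-like fluorophore described by Gaussian excitation and
#' emission profiles on the instrument lattice. Emission peak must lie
#' red of the excitation peak (positive Stokes shift).
#'
#' @param exPeak,emPeak peak wavelengths (nm).
#' @param exWidth,emWidth Gaussian standard deviations (nm).
#' @param label free-text component label.
#' @return A `ComponentSpec` list.
#' @export
componentSpec <- function(exPeak, emPeak, exWidth = 15, emWidth = 30,
                          label = "") {
  .stopIfNot(emPeak > exPeak,
             sprintf("Stokes shift must be positive (ex %g / em %g)",
                     exPeak, emPeak))
  .stopIfNot(exWidth > 0 && emWidth > 0, "widths must be positive")
  .stopIfNot(exPeak >= 200 && exPeak <= 450,
             sprintf("excitation peak %g nm outside instrument range",
                     exPeak))
  .stopIfNot(emPeak >= 250 && emPeak <= 600,
             sprintf("emission peak %g nm outside instrument range", emPeak))
  structure(
    list(exPeak = exPeak, emPeak = emPeak, exWidth = exWidth,
         emWidth = emWidth, label = label),
    class = "ComponentSpec"
  )
}

#' Default three-component humic-like library
#'
#' Peak geometry of the three dissolved-organic-matter components the
#' pipeline is built around: a microbial humic acid-like component
#' (ex/em 280/401 nm) and two terrestrial humic acid-like components
#' (355/443 and 275/468 nm).
#'
#' @return A list of three [componentSpec()] objects.
#' @export
defaultComponents <- function() {
  list(
    componentSpec(280, 401, exWidth = 15, emWidth = 28,
                  label = "Microbial humic acid-like"),
    componentSpec(355, 443, exWidth = 20, emWidth = 32,
                  label = "Terrestrial humic acid-like"),
    componentSpec(275, 468, exWidth = 15, emWidth = 38,
                  label = "Terrestrial humic acid-like")
  )
}

#' Synthetic study design
#'
#' Parameters of the simulated incubation study: a 3-treatment (NPK, GM,
#' GMC) by 8-replicate pot design whose samples carry fluorescence
#' component scores, a planted-module microbial community, and a 30-day
#' CO2 titration series.
#'
#' @param treatments character vector of treatment labels.
#' @param replicates replicates (pots) per treatment.
#' @param seed integer seed controlling every random draw.
#' @param noiseSd additive Gaussian noise sd on EEM intensities, in
#'   fluorescence units; `NULL` means 0.5\% of the maximum noiseless
#'   signal.
#' @param scoreEffects treatment x component multiplier matrix for
#'   fluorescence scores (rows named by treatment).
#' @param nTaxa,nModules,moduleSize community size and planted-module
#'   layout.
#' @param moduleLatentWeight weight of the shared per-module latent
#'   factor on the log-abundance scale; the default is calibrated so
#'   count-level within-module Spearman correlation is near 0.8 at the
#'   default abundance scale and dropout.
#' @param taxonNoiseSd sd of the taxon-level log-abundance noise.
#' @param effectTaxa number of background taxa shifted by treatment.
#' @param effectMultipliers named per-treatment abundance multipliers for
#'   the effect taxa.
#' @param zeroInflation dropout strength in `[0, 1]`: a cell with
#'   expected abundance `lambda` is forced to zero with probability
#'   `zeroInflation * exp(-lambda / 10)`, concentrating zeros in rare
#'   observations as in real OTU tables.
#' @param countScale median count scale of the community table.
#' @param silenceModule optional `list(treatment =, module =)` or a list
#'   of such entries; abundances of that module's taxa are suppressed in
#'   that treatment (so the module drops out of the treatment's
#'   subnetwork, creating treatment-graded network complexity).
#' @param cumTargets named per-treatment 30-day cumulative CO2-C targets
#'   (mg kg^-1).
#' @param decayRate first-order decay (d^-1) of the daily emission curve;
#'   0 gives a constant rate.
#' @param titrationNoiseSd Gaussian sd (mL) added to titration volumes.
#' @return A `SynthDesign` list, validated.
#' @export
synthDesign <- function(treatments = c("NPK", "GM", "GMC"),
                        replicates = 8L,
                        seed = 1L,
                        noiseSd = NULL,
                        scoreEffects = NULL,
                        nTaxa = 300L,
                        nModules = 4L,
                        moduleSize = 25L,
                        moduleLatentWeight = 1.2,
                        taxonNoiseSd = 0.5,
                        effectTaxa = 40L,
                        effectMultipliers = c(NPK = 1, GM = 1.5, GMC = 2.2),
                        zeroInflation = 0.3,
                        countScale = 100,
                        silenceModule = NULL,
                        cumTargets = c(NPK = 2592, GM = 2934, GMC = 3434),
                        decayRate = 0.05,
                        titrationNoiseSd = 0.05) {
  .stopIfNot(replicates >= 2, "replicates must be >= 2")
  .stopIfNot(nModules * moduleSize <= nTaxa,
             "nModules * moduleSize must not exceed nTaxa")
  .stopIfNot(zeroInflation >= 0 && zeroInflation <= 1,
             "zeroInflation must be a probability")
  if (is.null(scoreEffects)) {
    scoreEffects <- rbind(
      NPK = c(1.00, 1.00, 1.15),
      GM  = c(1.10, 1.05, 1.05),
      GMC = c(1.35, 1.10, 0.90)
    )
    scoreEffects <- scoreEffects[
      intersect(rownames(scoreEffects), treatments), , drop = FALSE]
    if (nrow(scoreEffects) < length(treatments)) {
      extra <- setdiff(treatments, rownames(scoreEffects))
      scoreEffects <- rbind(
        scoreEffects,
        matrix(1, length(extra), ncol(scoreEffects),
               dimnames = list(extra, NULL))
      )
    }
  }
  structure(
    list(
      treatments = treatments, replicates = as.integer(replicates),
      seed = as.integer(seed), noiseSd = noiseSd,
      scoreEffects = scoreEffects, nTaxa = as.integer(nTaxa),
      nModules = as.integer(nModules), moduleSize = as.integer(moduleSize),
      moduleLatentWeight = moduleLatentWeight,
      taxonNoiseSd = taxonNoiseSd,
      effectTaxa = as.integer(effectTaxa),
      effectMultipliers = effectMultipliers,
      zeroInflation = zeroInflation, countScale = countScale,
      silenceModule = silenceModule, cumTargets = cumTargets,
      decayRate = decayRate, titrationNoiseSd = titrationNoiseSd
    ),
    class = "SynthDesign"
  )
}

.designSamples <- function(design) {
  data.frame(
    sample = paste0(
      rep(design$treatments, each = design$replicates), "_",
      rep(seq_len(design$replicates), length(design$treatments))
    ),
    treatment = rep(design$treatments, each = design$replicates),
    replicate = rep(seq_len(design$replicates), length(design$treatments)),
    stringsAsFactors = FALSE
  )
}

.defaultExGrid <- function() seq(200, 450, by = 5)
.defaultEmGrid <- function() seq(250, 600, by = 1)

# Gaussian loading on a grid, unit Euclidean norm
.gaussLoading <- function(grid, peak, width) {
  v <- exp(-((grid - peak)^2) / (2 * width^2))
  v / sqrt(sum(v^2))
}

# water scatter pattern shared by blanks and samples: first- and
# second-order Rayleigh ridges plus the Raman band (3400 cm^-1 shift)
.scatterPattern <- function(exGrid, emGrid,
                            rayleighHeight = 1, ramanHeight = 0.05) {
  out <- matrix(0, length(emGrid), length(exGrid))
  for (k in seq_along(exGrid)) {
    ex <- exGrid[k]
    ray1 <- rayleighHeight * exp(-((emGrid - ex)^2) / (2 * 4^2))
    ray2 <- 0.3 * rayleighHeight * exp(-((emGrid - 2 * ex)^2) / (2 * 4^2))
    emRaman <- 1 / (1 / ex - 3400e-7)
    raman <- ramanHeight * exp(-((emGrid - emRaman)^2) / (2 * 6^2))
    out[, k] <- ray1 + ray2 + raman
  }
  out
}

#' Simulate an EEM dataset with known trilinear structure
#'
#' Builds one excitation-emission matrix per sample as a non-negative
#' trilinear combination of the supplied component templates plus water
#' scatter (Rayleigh ridges and the Raman band) and optional Gaussian
#' noise, together with a scatter-only blank and the exact ground truth.
#'
#' Scores are drawn log-normal (fluorescence intensities are positive and
#' right-skewed) and multiplied by the design's per-treatment component
#' effects. Truth loadings are unit-norm with magnitude absorbed into the
#' scores, matching the fitted-model convention.
#'
#' @param design a [synthDesign()].
#' @param components list of [componentSpec()]; peaks must sit on the
#'   instrument lattice (ex multiples of 5 nm in 200-450, em integer nm in
#'   250-600).
#' @return `list(cube, blank, truth)` where `cube` and `blank` are
#'   [EEMCube-class] objects and `truth` holds `exLoadings`, `emLoadings`
#'   (unit-norm), `scores`, and the sample sheet.
#' @export
simulateEEMs <- function(design, components = defaultComponents()) {
  .stopIfNot(length(components) >= 1, "need at least one component")
  exG <- .defaultExGrid()
  emG <- .defaultEmGrid()
  for (cp in components) {
    if (!(cp$exPeak %in% exG)) {
      stop(sprintf("excitation peak %g nm is off the 5-nm lattice",
                   cp$exPeak), call. = FALSE)
    }
    if (!(cp$emPeak %in% emG)) {
      stop(sprintf("emission peak %g nm is off the 1-nm lattice",
                   cp$emPeak), call. = FALSE)
    }
  }
  samples <- .designSamples(design)
  n <- nrow(samples)
  R <- length(components)
  exL <- sapply(components, function(cp) .gaussLoading(exG, cp$exPeak,
                                                       cp$exWidth))
  emL <- sapply(components, function(cp) .gaussLoading(emG, cp$emPeak,
                                                       cp$emWidth))

  set.seed(deriveSeed(design$seed, "eem-scores"))
  eff <- design$scoreEffects
  mult <- matrix(1, n, R)
  for (r in seq_len(R)) {
    cidx <- min(r, ncol(eff))
    mult[, r] <- eff[samples$treatment, cidx]
  }
  scoresTrue <- matrix(rlnorm(n * R, meanlog = log(20), sdlog = 0.15),
                       n, R) * mult

  signal <- array(0, dim = c(n, length(emG), length(exG)))
  for (r in seq_len(R)) {
    slab <- outer(emL[, r], exL[, r])  # em x ex
    for (i in seq_len(n)) {
      signal[i, , ] <- signal[i, , ] + scoresTrue[i, r] * slab
    }
  }
  maxSig <- max(signal)
  noiseSd <- if (is.null(design$noiseSd)) 0.005 * maxSig else design$noiseSd

  scatter <- .scatterPattern(exG, emG)
  cube <- signal
  set.seed(deriveSeed(design$seed, "eem-noise"))
  for (i in seq_len(n)) {
    layer <- cube[i, , ] + scatter
    if (noiseSd > 0) {
      layer <- layer + matrix(rnorm(length(layer), sd = noiseSd),
                              nrow(layer), ncol(layer))
    }
    cube[i, , ] <- pmax(layer, 0)
  }

  blankArr <- array(0, dim = c(1, length(emG), length(exG)))
  blankLayer <- scatter
  if (noiseSd > 0) {
    blankLayer <- blankLayer +
      matrix(rnorm(length(scatter), sd = noiseSd / 5),
             nrow(scatter), ncol(scatter))
  }
  blankArr[1, , ] <- pmax(blankLayer, 0)

  truth <- list(
    exLoadings = exL, emLoadings = emL, scores = scoresTrue,
    labels = vapply(components, `[[`, "", "label"),
    samples = samples, noiseSd = noiseSd
  )
  list(
    cube = EEMCube(cube, exG, emG, sampleIds = samples$sample),
    blank = EEMCube(blankArr, exG, emG, sampleIds = "blank"),
    truth = truth
  )
}

#' Simulate an OTU community table with planted correlation modules
#'
#' Taxa inside a planted module share a latent Gaussian factor added on
#' the log-abundance scale, inducing positive monotone (Spearman)
#' association. A block of background taxa responds to treatment through
#' multiplicative shifts; counts are Poisson draws around the scaled
#' abundances, with zero inflation applied first.
#'
#' @param design a [synthDesign()].
#' @return `list(otu, truth)`: `otu` is a
#'   [SummarizedExperiment::SummarizedExperiment] (assay `counts`, rowData
#'   taxonomy, colData treatment/replicate); `truth` records the module
#'   assignment (`0` = background) and treatment effects.
#' @export
simulateCommunity <- function(design) {
  .stopIfNot(design$moduleSize >= 2,
             "module size must be >= 2 (a module must be connectable)")
  samples <- .designSamples(design)
  n <- nrow(samples)
  p <- design$nTaxa
  set.seed(deriveSeed(design$seed, "community"))

  moduleOf <- integer(p)
  idx <- 1L
  for (m in seq_len(design$nModules)) {
    moduleOf[idx:(idx + design$moduleSize - 1L)] <- m
    idx <- idx + design$moduleSize
  }
  effectIdx <- integer(0)
  nBackground <- p - design$nModules * design$moduleSize
  if (design$effectTaxa > 0 && nBackground > 0) {
    effectIdx <- seq(idx, min(p, idx + design$effectTaxa - 1L))
  }

  baseAbund <- rlnorm(p, meanlog = log(design$countScale), sdlog = 0.6)
  latent <- matrix(rnorm(design$nModules * n), design$nModules, n)
  w <- design$moduleLatentWeight

  logA <- matrix(rnorm(p * n, sd = design$taxonNoiseSd), p, n)
  for (i in seq_len(p)) {
    if (moduleOf[i] > 0) logA[i, ] <- logA[i, ] + w * latent[moduleOf[i], ]
  }
  lambda <- baseAbund * exp(logA)

  if (length(effectIdx)) {
    em <- design$effectMultipliers[samples$treatment]
    lambda[effectIdx, ] <- sweep(lambda[effectIdx, , drop = FALSE], 2, em,
                                 `*`)
  }
  if (!is.null(design$silenceModule)) {
    sms <- design$silenceModule
    if (!is.null(sms$treatment)) sms <- list(sms)  # single entry
    for (sm in sms) {
      sel <- moduleOf == sm$module
      cols <- samples$treatment == sm$treatment
      lambda[sel, cols] <- lambda[sel, cols] * 1e-3
    }
  }

  pZero <- design$zeroInflation * exp(-lambda / 10)
  keepMask <- matrix(rbinom(p * n, 1, 1 - pZero), p, n)
  counts <- matrix(rpois(p * n, lambda * keepMask), p, n)

  # guarantee positive column totals
  for (j in which(colSums(counts) == 0)) counts[1, j] <- 1L

  otuIds <- sprintf("OTU%04d", seq_len(p))
  rownames(counts) <- otuIds
  colnames(counts) <- samples$sample
  taxonomy <- data.frame(
    domain = "Bacteria",
    phylum = paste0("Phylum", (moduleOf %% 6) + 1),
    class = paste0("Class", (seq_len(p) %% 12) + 1),
    genus = paste0("Genus", seq_len(p)),
    row.names = otuIds, stringsAsFactors = FALSE
  )
  otu <- makeOtuExperiment(counts, taxonomy, samples)
  truth <- list(
    moduleAssignment = stats::setNames(moduleOf, otuIds),
    effectTaxa = otuIds[effectIdx],
    effectMultipliers = design$effectMultipliers,
    samples = samples
  )
  list(otu = otu, truth = truth)
}

#' Incubation sampling schedule (days)
#' @return Integer vector of the nine alkali-trap sampling days.
#' @export
samplingDays <- function() c(1L, 3L, 5L, 7L, 10L, 15L, 20L, 25L, 30L)

#' Simulate alkali-trap titration records for a 30-day incubation
#'
#' Each sample jar emits CO2 along a (optionally decaying) daily emission
#' curve whose 30-day cumulative total equals the design's per-treatment
#' target; the trapped CO2 is converted to residual-NaOH HCl titration
#' volumes via the inverse of [titrationToCO2()]. Blank jars carry the
#' full unconsumed alkali.
#'
#' @param design a [synthDesign()].
#' @param baseRates named per-treatment mean daily CO2-C rates
#'   (mg kg^-1 d^-1); defaults to the design's cumulative targets / 30.
#' @param sampleEffects optional named per-jar rate multipliers (e.g. a
#'   coupling of mineralization to each sample's dissolved-organic-matter
#'   composition); default 1 for every jar.
#' @param nBlanks number of blank jars per sampling day.
#' @param soilMassKg soil per jar (kg).
#' @param hclMolarity,naohMolarity,naohVolumeML trap chemistry settings.
#' @return `list(titration, truth)`: `titration` is a data.frame
#'   (jar, treatment, day, hclML, isBlank) with trap settings as
#'   attributes; `truth` holds the exact interval emissions and per-jar
#'   cumulative totals.
#' @export
simulateTitration <- function(design,
                              baseRates = design$cumTargets / 30,
                              sampleEffects = NULL,
                              nBlanks = 6L,
                              soilMassKg = 0.030,
                              hclMolarity = 0.4,
                              naohMolarity = 0.5,
                              naohVolumeML = 20) {
  .stopIfNot(all(baseRates >= 0), "base rates must be non-negative")
  samples <- .designSamples(design)
  days <- samplingDays()
  k <- design$decayRate
  cumAt <- function(t, total) {
    if (k == 0) total * t / 30
    else total * (1 - exp(-k * t)) / (1 - exp(-k * 30))
  }
  naohMol <- naohMolarity * naohVolumeML / 1000
  blankML <- naohMol / hclMolarity * 1000

  set.seed(deriveSeed(design$seed, "titration"))
  rows <- list()
  truthInt <- list()
  for (i in seq_len(nrow(samples))) {
    eff <- if (is.null(sampleEffects)) 1 else
      sampleEffects[[samples$sample[i]]]
    total <- 30 * baseRates[[samples$treatment[i]]] * eff
    prevDay <- 0
    for (d in days) {
      interval <- cumAt(d, total) - cumAt(prevDay, total)  # mg CO2-C / kg
      mgC <- interval * soilMassKg
      molCO2 <- mgC / 12.01 / 1000
      consumed <- 2 * molCO2
      if (consumed > naohMol) {
        stop(sprintf(
          "trap capacity exceeded on day %d (all NaOH consumed)", d
        ), call. = FALSE)
      }
      hcl <- (naohMol - consumed) / hclMolarity * 1000
      rows[[length(rows) + 1L]] <- data.frame(
        jar = samples$sample[i], treatment = samples$treatment[i],
        day = d, hclML = hcl, isBlank = FALSE
      )
      truthInt[[length(truthInt) + 1L]] <- data.frame(
        jar = samples$sample[i], day = d, interval = interval
      )
      prevDay <- d
    }
  }
  for (b in seq_len(nBlanks)) {
    for (d in days) {
      rows[[length(rows) + 1L]] <- data.frame(
        jar = paste0("blank_", b), treatment = "blank",
        day = d, hclML = blankML, isBlank = TRUE
      )
    }
  }
  titration <- do.call(rbind, rows)
  if (design$titrationNoiseSd > 0) {
    titration$hclML <- pmax(
      0, titration$hclML + rnorm(nrow(titration),
                                 sd = design$titrationNoiseSd)
    )
  }
  attr(titration, "hclMolarity") <- hclMolarity
  attr(titration, "naohMolarity") <- naohMolarity
  attr(titration, "naohVolumeML") <- naohVolumeML
  attr(titration, "soilMassKg") <- soilMassKg
  truthInt <- do.call(rbind, truthInt)
  cumTruth <- tapply(truthInt$interval, truthInt$jar, sum)
  list(
    titration = titration,
    truth = list(
      intervals = truthInt,
      cumulative = cumTruth[unique(samples$sample)],
      samples = samples
    )
  )
}
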