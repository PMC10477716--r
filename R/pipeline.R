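#' Pipeline configuration
#'
#' Settings for the end-to-end analysis. Exactly one of `simulate`
#' (a [synthDesign()], or `TRUE` for the default design) or `inputs`
#' (paths to measured data files) must be provided; `seed` is mandatory
#' and controls every stage through derived per-stage seeds.
#'
#' @param seed integer global seed.
#' @param simulate a [synthDesign()], `TRUE` (default design with this
#'   config's seed), or `NULL` when reading real inputs.
#' @param inputs `NULL`, or a list with `eemCsvs`, `blankCsv`, `otuTsv`
#'   (named list per community), `metaTsv`, `titrationTsv`.
#' @param nComponents PARAFAC rank.
#' @param nStarts,parafacTol,parafacMaxIter PARAFAC fitting settings.
#' @param nSplits split-half repetitions (0 disables validation).
#' @param alpha adjusted-p edge cutoff.
#' @param minPrevalence prevalence-filter fraction.
#' @param nTrees,nPermRF random-forest settings.
#' @param nPermAssoc permutations for eigengene-environment tests.
#' @param fungiDesign optional [synthDesign()] for the second (fungal)
#'   community; defaults to a smaller community sharing the seed.
#' @param outDir output directory (`NULL`: nothing written).
#' @return A validated `PipelineConfig` list.
#' @export
pipelineConfig <- function(seed,
                           simulate = TRUE,
                           inputs = NULL,
                           nComponents = 3L,
                           nStarts = 6L,
                           parafacTol = 1e-8,
                           parafacMaxIter = 2500L,
                           nSplits = 2L,
                           alpha = 0.01,
                           minPrevalence = 0.5,
                           nTrees = 300L,
                           nPermRF = 30L,
                           nPermAssoc = 199L,
                           fungiDesign = NULL,
                           outDir = NULL) {
  .stopIfNot(!missing(seed) && is.numeric(seed), "seed is mandatory")
  wantSim <- !is.null(simulate) && !isFALSE(simulate)
  .stopIfNot(xor(wantSim, !is.null(inputs)),
             "provide exactly one of 'simulate' or 'inputs'")
  if (isTRUE(simulate)) {
    # default simulated world: bacterial network complexity reduced under
    # the green-manure + biochar treatment (one planted module silenced
    # there); the fungal counterpart is set in runPipeline
    simulate <- synthDesign(
      seed = seed,
      silenceModule = list(list(treatment = "GMC", module = 4))
    )
  }
  if (!wantSim) simulate <- NULL
  structure(
    list(
      seed = as.integer(seed), simulate = simulate, inputs = inputs,
      nComponents = as.integer(nComponents),
      nStarts = as.integer(nStarts), parafacTol = parafacTol,
      parafacMaxIter = as.integer(parafacMaxIter),
      nSplits = as.integer(nSplits), alpha = alpha,
      minPrevalence = minPrevalence, nTrees = as.integer(nTrees),
      nPermRF = as.integer(nPermRF), nPermAssoc = as.integer(nPermAssoc),
      fungiDesign = fungiDesign, outDir = outDir
    ),
    class = "PipelineConfig"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipelineConfig()] arguments; a
#' `simulate:` mapping is passed to [synthDesign()].
#'
#' @param path YAML file.
#' @return A `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate) && is.list(y$simulate)) {
    y$simulate <- do.call(synthDesign, y$simulate)
  }
  do.call(pipelineConfig, y)
}

.networkStage <- function(otu, config, seed) {
  filtered <- prevalenceFilter(otu, config$minPrevalence)
  net <- correlationNetwork(filtered, alpha = config$alpha)
  net <- detectModules(net, seed = seed)
  treatments <- unique(.otuTreatments(otu))
  subTopo <- list()
  for (tr in treatments) {
    sub <- treatmentSubnetwork(net, otu, tr,
                               minFraction = config$minPrevalence)
    subTopo[[tr]] <- networkTopology(sub)
  }
  list(
    filtered = filtered, network = net,
    topology = networkTopology(net),
    subnetworkTopology = subTopo
  )
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order: titration arithmetic
#' (cumulative mineralization), EEM correction and indices, PARAFAC with
#' optional split-half validation and library matching, community
#' ordination and PERMANOVA, co-occurrence networks (global, per
#' treatment, modules, eigengene-environment associations) for the
#' bacterial and fungal communities, and driver attribution (permutation
#' random forest and variance partitioning of DOC vs network blocks).
#' Reruns with an identical config are bit-identical.
#'
#' @param config a [pipelineConfig()].
#' @return A `RunReport` list of per-stage summaries; when
#'   `config$outDir` is set, stage artifacts and `report.json` are
#'   written there and the report carries the report file's md5 hash.
#' @export
runPipeline <- function(config) {
  .stopIfNot(inherits(config, "PipelineConfig"),
             "config must come from pipelineConfig()")
  seed <- config$seed
  warnings <- character(0)

  # ---- inputs: simulate or load
  if (!is.null(config$simulate)) {
    design <- config$simulate
    eem <- simulateEEMs(design)
    bact <- simulateCommunity(design)
    fdesign <- config$fungiDesign
    if (is.null(fdesign)) {
      # fungal network complexity increases along NPK < GM < GMC: the
      # unamended treatment loses two planted modules, green manure alone
      # loses one, the co-amended treatment keeps all four
      fdesign <- synthDesign(
        seed = deriveSeed(seed, "fungi"), nTaxa = 120L, nModules = 4L,
        moduleSize = 15L, replicates = design$replicates,
        treatments = design$treatments,
        zeroInflation = design$zeroInflation,
        silenceModule = list(
          list(treatment = "NPK", module = 3),
          list(treatment = "NPK", module = 4),
          list(treatment = "GM", module = 4)
        )
      )
    }
    fung <- simulateCommunity(fdesign)
    # couple each jar's mineralization to its microbial humic-like (C1)
    # proportion: the within-treatment DOC-composition signal the driver
    # stage is meant to detect
    relC1 <- eem$truth$scores[, 1] / rowSums(eem$truth$scores)
    relC1 <- relC1 - stats::ave(relC1, eem$truth$samples$treatment)
    effects <- stats::setNames(exp(2 * relC1),
                               eem$truth$samples$sample)
    tit <- simulateTitration(design, sampleEffects = effects)
    cube <- eem$cube
    blank <- eem$blank
    otuTables <- list(bacteria = bact$otu, fungi = fung$otu)
    titration <- tit$titration
    metadata <- .designSamples(design)
    truth <- list(eem = eem$truth, bacteria = bact$truth,
                  fungi = fung$truth, titration = tit$truth)
  } else {
    inp <- config$inputs
    metadata <- readMetadataTsv(inp$metaTsv)
    cube <- readEEMCsv(inp$eemCsvs)
    blank <- readEEMCsv(inp$blankCsv)
    otuTables <- lapply(inp$otuTsv, readOtuTsv, metadata = metadata)
    titration <- readTitrationTsv(inp$titrationTsv)
    truth <- NULL
  }

  # ---- stage: mineralization
  series <- withCallingHandlers(
    cumulativeMineralization(titration),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  cumSummary <- mineralizationSummary(series)
  finalCum <- series[series$day == max(series$day), ]
  cumPerSample <- stats::setNames(finalCum$cum, finalCum$jar)

  # ---- stage: EEM correction + indices
  corrected <- correctEEMs(cube, blank)
  indices <- withCallingHandlers(
    fluorescenceIndices(corrected),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )

  # ---- stage: PARAFAC
  model <- fitParafac(
    corrected, nComponents = config$nComponents,
    nStarts = config$nStarts, tol = config$parafacTol,
    maxIter = config$parafacMaxIter, seed = deriveSeed(seed, "parafac")
  )
  fmax <- computeFmax(model)
  fmaxRel <- computeFmax(model, relative = TRUE)
  matches <- matchComponents(model)
  splitHalf <- NULL
  if (config$nSplits > 0) {
    splitHalf <- splitHalfValidate(
      corrected, nComponents = config$nComponents,
      nSplits = config$nSplits, seed = deriveSeed(seed, "splithalf")
    )
  }

  # ---- stage: community composition
  community <- list()
  for (nm in names(otuTables)) {
    otu <- otuTables[[nm]]
    d <- brayCurtis(otu)
    ord <- pcoaOrdination(d)
    pm <- permanovaTest(d, .otuTreatments(otu), nPerm = 999,
                        seed = deriveSeed(seed, paste0("permanova-", nm)))
    community[[nm]] <- list(distance = d, pcoa = ord, permanova = pm)
  }

  # ---- stage: networks + module-environment associations
  env <- data.frame(
    Cum = cumPerSample[metadata$sample],
    BIX = indices$BIX[match(metadata$sample, indices$sample)],
    HIX = indices$HIX[match(metadata$sample, indices$sample)],
    FI = indices$FI[match(metadata$sample, indices$sample)],
    fmaxRel[metadata$sample, , drop = FALSE],
    row.names = metadata$sample
  )
  networks <- list()
  for (nm in names(otuTables)) {
    st <- .networkStage(otuTables[[nm]], config,
                        seed = deriveSeed(seed, paste0("network-", nm)))
    eg <- moduleEigengenes(otuTables[[nm]], st$network)
    assoc <- moduleEnvAssociation(
      eg[metadata$sample, , drop = FALSE], env,
      nPerm = config$nPermAssoc,
      seed = deriveSeed(seed, paste0("assoc-", nm))
    )
    st$eigengenes <- eg
    st$associations <- assoc
    networks[[nm]] <- st
  }

  # ---- stage: drivers (RF + VPA)
  bacc <- vapply(
    networks$bacteria$subnetworkTopology,
    function(x) x$averageClusteringCoefficient, numeric(1)
  )
  facc <- vapply(
    networks$fungi$subnetworkTopology,
    function(x) x$averageClusteringCoefficient, numeric(1)
  )
  warnings <- c(
    warnings,
    paste("BACC/FACC are treatment-level metrics broadcast to samples;",
          "predictor pseudo-replication within treatment")
  )
  compCols <- colnames(fmaxRel)
  driverTable <- data.frame(
    Cum = env$Cum,
    env[, compCols, drop = FALSE],
    BIX = env$BIX, HIX = env$HIX, FI = env$FI,
    BACC = unname(bacc[metadata$treatment]),
    FACC = unname(facc[metadata$treatment]),
    row.names = metadata$sample
  )
  rf <- rfImportance(driverTable, response = "Cum",
                     nTrees = config$nTrees, nPerm = config$nPermRF,
                     seed = deriveSeed(seed, "rf"))
  docCols <- c(compCols, "BIX", "HIX", "FI")
  netCols <- c("BACC", "FACC")
  vpa <- variancePartition(driverTable$Cum,
                           driverTable[, docCols, drop = FALSE],
                           driverTable[, netCols, drop = FALSE])
  shares <- list(
    doc = withinCategoryShare(driverTable$Cum,
                              driverTable[, docCols, drop = FALSE]),
    network = withinCategoryShare(driverTable$Cum,
                                  driverTable[, netCols, drop = FALSE])
  )

  report <- list(
    package = "soilCNet",
    version = as.character(utils::packageVersion("soilCNet")),
    seed = seed,
    mineralization = list(
      summary = cumSummary,
      cumPerSample = as.list(cumPerSample)
    ),
    indices = indices,
    parafac = list(
      explainedVariance = explainedVariance(model),
      peaks = componentPeaks(model),
      fmax = as.data.frame(fmax),
      fmaxRelative = as.data.frame(fmaxRel),
      matches = matches,
      splitHalf = if (is.null(splitHalf)) NULL else
        list(pass = splitHalf$pass, threshold = splitHalf$threshold)
    ),
    community = lapply(community, function(x) {
      list(permanova = x$permanova,
           axisFractions = x$pcoa$fractions)
    }),
    networks = lapply(networks, function(x) {
      list(
        topology = x$topology,
        subnetworkTopology = x$subnetworkTopology,
        modularity = x$network@modularity,
        nModules = max(x$network@modules),
        associations = x$associations
      )
    }),
    drivers = list(
      importance = rf$importance, modelR2 = rf$modelR2,
      modelP = rf$modelP,
      vpa = vpa[c("uniqueX1", "uniqueX2", "shared", "residual")],
      shares = shares
    ),
    warnings = warnings
  )
  class(report) <- "RunReport"

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    write.table(series, file.path(config$outDir, "mineralization.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.csv(indices, file.path(config$outDir, "indices.csv"),
              row.names = FALSE)
    write.csv(
      data.frame(wavelength = emGrid(model), emLoadings(model)),
      file.path(config$outDir, "parafac_em_loadings.csv"),
      row.names = FALSE
    )
    write.csv(
      data.frame(wavelength = exGrid(model), exLoadings(model)),
      file.path(config$outDir, "parafac_ex_loadings.csv"),
      row.names = FALSE
    )
    write.csv(as.data.frame(fmax),
              file.path(config$outDir, "fmax.csv"))
    for (nm in names(networks)) {
      writeEdgeList(networks[[nm]]$network,
                    file.path(config$outDir, paste0("network_", nm,
                                                    "_edges.csv")))
      writeNetworkGraphML(networks[[nm]]$network,
                          file.path(config$outDir,
                                    paste0("network_", nm, ".graphml")))
    }
    write.table(rf$importance,
                file.path(config$outDir, "rf_importance.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    reportPath <- file.path(config$outDir, "report.json")
    jsonlite::write_json(.reportForJson(report), reportPath,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    report$reportHash <- unname(tools::md5sum(reportPath))
  }
  report
}

# strip non-serializable pieces and keep stable ordering
.reportForJson <- function(report) {
  r <- unclass(report)
  r
}

#' @export
print.RunReport <- function(x, ...) {
  cat("soilCNet run report (seed", x$seed, ")\n")
  cat("- cumulative mineralization (mg/kg):\n")
  print(x$mineralization$summary, row.names = FALSE)
  cat(sprintf("- PARAFAC: %d components, explained variance %.4f\n",
              length(x$parafac$peaks$ex), x$parafac$explainedVariance))
  if (!is.null(x$parafac$splitHalf)) {
    cat("  split-half pass:", x$parafac$splitHalf$pass, "\n")
  }
  for (nm in names(x$networks)) {
    t <- x$networks[[nm]]$topology
    cat(sprintf(
      "- %s network: %d nodes, %d edges, ACC %.3f, Q %.3f\n",
      nm, t$nodes, t$edges, t$averageClusteringCoefficient,
      x$networks[[nm]]$modularity
    ))
  }
  cat(sprintf(
    "- drivers: top RF predictor %s; VPA unique DOC %.3f / unique net %.3f / shared %.3f\n",
    x$drivers$importance$predictor[1], x$drivers$vpa$uniqueX1,
    x$drivers$vpa$uniqueX2, x$drivers$vpa$shared
  ))
  invisible(x)
}
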