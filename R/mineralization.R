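#' Convert an alkali-trap titration difference to CO2-C
#'
#' The trap's NaOH captures CO2 as carbonate; after BaCl2 precipitation
#' the residual NaOH is titrated 1:1 with HCl. Each mole of CO2 consumes
#' two moles of NaOH, so
#' `CO2-C (mg kg^-1) = (blank_mL - sample_mL) * M_HCl / 2 * 12.01 /
#' soil_kg` with the carbon molar mass 12.01 g mol^-1 (configurable).
#' Volumes in mL and molarity in mol L^-1 cancel to mmol, hence mg.
#'
#' @param blankML mean blank titration volume (mL).
#' @param sampleML sample titration volume (mL); vectors recycle.
#' @param hclMolarity HCl molarity (mol L^-1).
#' @param soilMassKg incubated soil mass (kg).
#' @param carbonMolarMass molar mass of carbon (g mol^-1).
#' @return mg CO2-C per kg soil; values where `sampleML > blankML`
#'   (apparent negative CO2) are clipped to 0 with a warning.
#' @export
titrationToCO2 <- function(blankML, sampleML, hclMolarity = 0.4,
                           soilMassKg = 0.030,
                           carbonMolarMass = 12.01) {
  .stopIfNot(all(blankML >= 0) && all(sampleML >= 0),
             "volumes must be non-negative")
  .stopIfNot(hclMolarity > 0 && soilMassKg > 0,
             "molarity and soil mass must be positive")
  out <- (blankML - sampleML) * hclMolarity / 2 * carbonMolarMass /
    soilMassKg
  if (any(out < 0)) {
    warning(sprintf(
      "%d titration(s) exceeded the blank volume; clipped to 0 CO2-C",
      sum(out < 0)
    ), call. = FALSE)
    out[out < 0] <- 0
  }
  out
}

#' Cumulative carbon mineralization from titration records
#'
#' For every jar and sampling day the interval CO2-C is computed against
#' that day's blank mean via [titrationToCO2()]; the daily rate divides
#' by the days since the previous sampling (day 0 origin) and the
#' cumulative mineralization (Cum) is the running sum through day 30.
#'
#' @param titration data.frame with columns `jar`, `day`, `hclML`,
#'   `isBlank` (and optionally `treatment`); trap settings may ride along
#'   as attributes (as written by [simulateTitration()]) or be given
#'   explicitly.
#' @param hclMolarity,soilMassKg,carbonMolarMass see [titrationToCO2()];
#'   defaults are taken from the table's attributes when present.
#' @return data.frame per jar x day: `jar`, `treatment`, `day`,
#'   `interval` (mg kg^-1), `rate` (mg kg^-1 d^-1), `cum` (mg kg^-1).
#' @export
cumulativeMineralization <- function(titration,
                                     hclMolarity = NULL,
                                     soilMassKg = NULL,
                                     carbonMolarMass = 12.01) {
  if (is.null(hclMolarity)) {
    hclMolarity <- attr(titration, "hclMolarity")
    if (is.null(hclMolarity)) hclMolarity <- 0.4
  }
  if (is.null(soilMassKg)) {
    soilMassKg <- attr(titration, "soilMassKg")
    if (is.null(soilMassKg)) soilMassKg <- 0.030
  }
  blanks <- titration[titration$isBlank, , drop = FALSE]
  samples <- titration[!titration$isBlank, , drop = FALSE]
  days <- sort(unique(samples$day))
  blankMean <- tapply(blanks$hclML, blanks$day, mean)
  missingBlank <- setdiff(as.character(days), names(blankMean))
  .stopIfNot(length(missingBlank) == 0,
             sprintf("no blank jar for day(s): %s",
                     paste(missingBlank, collapse = ", ")))
  jars <- unique(samples$jar)
  rows <- list()
  for (j in jars) {
    sj <- samples[samples$jar == j, , drop = FALSE]
    sj <- sj[order(sj$day), , drop = FALSE]
    miss <- setdiff(days, sj$day)
    if (length(miss)) {
      stop(sprintf("jar '%s' is missing day(s): %s", j,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    interval <- suppressWarnings(titrationToCO2(
      blankMean[as.character(sj$day)], sj$hclML,
      hclMolarity = hclMolarity, soilMassKg = soilMassKg,
      carbonMolarMass = carbonMolarMass
    ))
    prevDay <- c(0, sj$day[-length(sj$day)])
    rows[[length(rows) + 1L]] <- data.frame(
      jar = j,
      treatment = if ("treatment" %in% names(sj)) sj$treatment else NA,
      day = sj$day,
      interval = as.numeric(interval),
      rate = as.numeric(interval) / (sj$day - prevDay),
      cum = cumsum(as.numeric(interval)),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-treatment summary of cumulative mineralization
#'
#' Mean and standard error of the final cumulative CO2-C across the jars
#' of each treatment.
#'
#' @param series output of [cumulativeMineralization()].
#' @return data.frame: `treatment`, `n`, `meanCum`, `seCum`.
#' @export
mineralizationSummary <- function(series) {
  finalDay <- max(series$day)
  fin <- series[series$day == finalDay, , drop = FALSE]
  agg <- split(fin$cum, fin$treatment)
  out <- data.frame(
    treatment = names(agg),
    n = vapply(agg, length, integer(1)),
    meanCum = vapply(agg, mean, numeric(1)),
    seCum = vapply(agg, function(x) sd(x) / sqrt(length(x)), numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
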