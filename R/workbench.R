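## I/O and run configuration: peptide tables, spectra files, and the
## serializable run configuration tying the stages into reproducible
## runs.

#' Read a peptide definition table
#'
#' Delimited text with a header; required columns `protein`, `start`,
#' `end`; optional `sequence`, `charge`, `plus_met`, `n_exchangeable`,
#' `mass_da`. Coordinates are 1-based inclusive; violations are
#' reported with their line number (header = line 1).
#'
#' @param path CSV file path.
#' @return list of [PeptideSpec-class] objects.
#' @export
readPeptideTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("protein", "start", "end")
  if (!all(need %in% names(df)))
    stop("peptide table must have header columns protein, start, end")
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    out[[i]] <- tryCatch(
      PeptideSpec(
        row$protein, row$start, row$end,
        sequence = if ("sequence" %in% names(df) &&
                       !is.na(row$sequence) && nzchar(row$sequence))
          row$sequence else NA_character_,
        charge = if ("charge" %in% names(df)) row$charge
                 else NA_integer_,
        nExchangeable = if ("n_exchangeable" %in% names(df))
          row$n_exchangeable else NA_integer_,
        plusMet = "plus_met" %in% names(df) && isTRUE(row$plus_met),
        massDa = if ("mass_da" %in% names(df)) row$mass_da
                 else NA_real_),
      error = function(e)
        stop(sprintf("line %d: %s", i + 1, conditionMessage(e)),
             call. = FALSE))
  }
  out
}

#' Write a peptide definition table
#'
#' @param peptides list of [PeptideSpec-class] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writePeptideTable <- function(peptides, path) {
  df <- do.call(rbind, lapply(peptides, function(p) data.frame(
    protein = p@protein, start = p@start, end = p@end,
    sequence = ifelse(is.na(p@sequence), "", p@sequence),
    charge = p@charge, plus_met = p@plusMet,
    n_exchangeable = p@nExchangeable, mass_da = p@massDa)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spectra table into simulated-spectrum objects
#'
#' Reads the spectra CSV dialect written by [writeFixtures()] (columns
#' `preset`, `replicate`, `time_min`, `mass_da`, `intensity`), groups
#' rows by (preset, replicate, time) and sorts masses. Duplicate masses
#' within a spectrum are summed with a warning; negative intensities
#' are rejected; an empty file is an explicit error.
#'
#' @param path spectra CSV path.
#' @param peptide the [PeptideSpec-class] the spectra belong to
#'   (default [diagnosticPeptide()]).
#' @return list of [SyntheticSpectrum-class] objects.
#' @export
readSpectra <- function(path, peptide = diagnosticPeptide()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("preset", "replicate", "time_min", "mass_da", "intensity")
  if (!all(need %in% names(df)))
    stop("spectra file must have columns ", paste(need, collapse = ", "))
  if (!nrow(df)) stop("spectra file is empty: ", path)
  if (any(df$intensity < 0))
    stop("negative intensities in spectra file: ", path)
  groups <- split(df, list(df$preset, df$replicate, df$time_min),
                  drop = TRUE)
  out <- lapply(groups, function(g) {
    if (is.unsorted(g$mass_da))
      warning("unsorted masses in spectrum; sorting")
    if (anyDuplicated(g$mass_da)) {
      warning("duplicate masses within a spectrum; summing intensities")
      agg <- stats::aggregate(intensity ~ mass_da, data = g, FUN = sum)
      g <- data.frame(preset = g$preset[1], replicate = g$replicate[1],
                      time_min = g$time_min[1], mass_da = agg$mass_da,
                      intensity = agg$intensity)
    }
    new("SyntheticSpectrum",
        envelope = IsotopeEnvelope(g$mass_da, g$intensity),
        peptide = peptide, replicate = as.integer(g$replicate[1]),
        timeMin = g$time_min[1], preset = g$preset[1],
        metadata = list(source = path))
  })
  names(out) <- NULL
  out[order(vapply(out, function(s) s@preset, character(1)),
            vapply(out, function(s) s@timeMin, numeric(1)),
            vapply(out, function(s) s@replicate, integer(1)))]
}

#' Write spectra objects to the spectra CSV dialect
#'
#' @param spectra list of [SyntheticSpectrum-class] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSpectra <- function(spectra, path) {
  rows <- do.call(rbind, lapply(spectra, function(sp) {
    pk <- peaks(sp)
    data.frame(preset = sp@preset, replicate = sp@replicate,
               time_min = sp@timeMin, mass_da = round(pk$mass, 6),
               intensity = round(pk$abundance, 6))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' A fully serializable bundle of every tunable the pipeline uses.
#' Round-trips losslessly through YAML ([writeRunConfig()] /
#' [readRunConfig()]); every pipeline run writes its resolved
#' configuration next to its results.
#'
#' @param seed integer base seed.
#' @param presets character vector of preset names to simulate.
#' @param replicates replicates per condition.
#' @param d2oFraction,pulseDuration labeling parameters.
#' @param pFolded folded-state incorporation probability.
#' @param noiseCv,noiseBaseline noise model parameters.
#' @param deltaBicThreshold bimodality acceptance threshold.
#' @param depletionCutoff initial-rate exclusion threshold.
#' @param maxTime linear-phase time cap in minutes.
#' @param outputDir output directory.
#' @return a list of class `RunConfig`.
#' @export
runConfig <- function(seed, presets = names(presetRegistry()$empirical),
                      replicates = 3, d2oFraction = 0.70,
                      pulseDuration = 10, pFolded = 0.25,
                      noiseCv = 0.03, noiseBaseline = 0.005,
                      deltaBicThreshold = 6, depletionCutoff = 0.30,
                      maxTime = 10, outputDir = ".") {
  if (missing(seed)) stop("a seed is mandatory")
  structure(list(seed = as.integer(seed), presets = presets,
                 replicates = as.integer(replicates),
                 d2oFraction = d2oFraction,
                 pulseDuration = pulseDuration, pFolded = pFolded,
                 noiseCv = noiseCv, noiseBaseline = noiseBaseline,
                 deltaBicThreshold = deltaBicThreshold,
                 depletionCutoff = depletionCutoff, maxTime = maxTime,
                 outputDir = outputDir),
            class = "RunConfig")
}

#' @rdname runConfig
#' @param config a `RunConfig`.
#' @param path YAML file path.
#' @export
writeRunConfig <- function(config, path) {
  stopifnot(inherits(config, "RunConfig"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
  lst <- yaml::read_yaml(path)
  do.call(runConfig, lst)
}
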