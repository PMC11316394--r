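#' Read and write growth series CSV files
#'
#' Long format, columns `time_h`, `condition`, `replicate`, `partner`,
#' `density`, `unit` (`"CFU/ml"` or `"cells/ml"`).
#'
#' @param series a [GrowthSeries-class].
#' @param path CSV path.
#' @return `readGrowthCsv()` returns a validated [GrowthSeries-class].
#' @export
writeGrowthCsv <- function(series, path) {
  utils::write.csv(growthData(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGrowthCsv
#' @export
readGrowthCsv <- function(path) {
  GrowthSeries(utils::read.csv(path))
}

#' Write or read a coculture scenario as YAML
#'
#' All scenario slots are serialized under their slot names; reading
#' re-validates the object.
#'
#' @param scenario a [CocultureScenario-class].
#' @param path YAML path.
#' @return `readScenarioYaml()` returns a [CocultureScenario-class].
#' @export
writeScenarioYaml <- function(scenario, path) {
  sl <- slotNames("CocultureScenario")
  vals <- lapply(sl, function(s) slot(scenario, s))
  names(vals) <- sl
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @rdname writeScenarioYaml
#' @export
readScenarioYaml <- function(path) {
  vals <- yaml::read_yaml(path)
  sl <- slotNames("CocultureScenario")
  miss <- setdiff(sl, names(vals))
  if (length(miss))
    stop("scenario YAML missing field(s): ", paste(miss, collapse = ", "))
  vals <- vals[sl]
  vals$seed <- as.integer(vals$seed)
  do.call(new, c(list(Class = "CocultureScenario"), vals))
}

# Internal: md5 hash of a config list via its canonical YAML serialization.
.configHash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(config, f)
  unname(tools::md5sum(f))
}
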