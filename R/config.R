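## Run configuration: a serialisable record of scenario, composition,
## analysis parameters and seeds, embedded in every written output so any
## result file is regenerable.

#' Create a run configuration
#'
#' @param scenario scenario name or `NA`.
#' @param composition a [compositionSpec()] (stored as plain lists).
#' @param layout a [phaseLayout()].
#' @param seed integer seed.
#' @param analysis named list of analysis parameter overrides (cell sizes,
#'   thresholds, cutoffs).
#' @return list of class `RunConfig` with a stable content hash in
#'   `$hash`.
#' @export
runConfig <- function(scenario = NA_character_,
                      composition = compositionSpec(),
                      layout = phaseLayout("mixed"),
                      seed = 1L, analysis = list()) {
  cfg <- list(scenario = scenario,
              composition = unclass(composition),
              layout = unclass(layout),
              seed = as.integer(seed),
              analysis = analysis)
  cfg$hash <- .configHash(cfg)
  class(cfg) <- "RunConfig"
  cfg
}

.configHash <- function(cfg) {
  cfg$hash <- NULL
  txt <- paste(deparse(cfg), collapse = "")
  ## small stable rolling hash; provenance only, not cryptographic
  h <- 0
  for (ch in utf8ToInt(txt)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Write / read a run configuration as YAML
#'
#' @param cfg a [runConfig()].
#' @param path file path.
#' @return `readRunConfig` returns the `RunConfig`; `writeRunConfig`
#'   returns `path` invisibly.
#' @export
writeRunConfig <- function(cfg, path) {
  stopifnot(inherits(cfg, "RunConfig"))
  out <- unclass(cfg)
  ## named vectors serialise as YAML maps, not bare sequences
  out$composition$counts <- as.list(out$composition$counts)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$composition$counts <- unlist(cfg$composition$counts)
  storedHash <- cfg$hash
  class(cfg) <- "RunConfig"
  cfg
}

#' Write analysis outputs with provenance
#'
#' Tables go to CSV and the summary to JSON; both carry the configuration
#' hash and seed so the result is regenerable from its embedded provenance.
#'
#' @param tables named list of data.frames.
#' @param summary named list of summary values.
#' @param dir output directory (created if needed).
#' @param cfg a [runConfig()].
#' @return character vector of written paths, invisibly.
#' @export
writeOutputs <- function(tables = list(), summary = list(), dir, cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    con <- file(p, "w")
    writeLines(sprintf("# cgraft config=%s seed=%d", cfg$hash, cfg$seed), con)
    utils::write.csv(tables[[nm]], con, row.names = FALSE)
    close(con)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "summary.json")
  payload <- c(list(provenance = list(config = cfg$hash, seed = cfg$seed)),
               summary)
  jsonlite::write_json(payload, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
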