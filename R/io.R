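#' Read / write a flat key-value configuration file
#'
#' One \code{key = value} pair per line (\code{#} comments and blank lines
#' ignored); keys are exactly the \code{\link{simulation_config}} fields.
#' Unknown keys are an error so typos fail fast.
#'
#' @param path file path.
#' @param overrides named list merged over the file values (e.g. CLI flags).
#' @return \code{read_config}: a \code{\link{simulation_config}}.
#' @export
read_config <- function(path, overrides = list()) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  vals <- stats::setNames(lapply(kv, `[[`, 2), vapply(kv, `[[`, "", 1))
  vals <- utils::modifyList(vals, overrides)
  allowed <- names(formals(simulation_config))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  numeric_keys <- setdiff(allowed, "mode")
  for (k in intersect(names(vals), numeric_keys)) vals[[k]] <- as.numeric(vals[[k]])
  do.call(simulation_config, vals)
}

#' @rdname read_config
#' @param config a \code{\link{simulation_config}}.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  writeLines(paste(names(config), "=",
                   vapply(config, function(v) format(v, digits = 17), "")),
             path)
  invisible(path)
}

#' Export run traces and grid summaries as tidy CSV
#'
#' \code{write_run_csv} writes one run's thinned metric trace (columns
#' \code{iteration, planarity, angle_deg, vaf_pct, reward});
#' \code{write_summary_csv} writes a grid aggregate table as produced by
#' \code{\link{run_grid}}.
#'
#' @param result a \code{coadapt_run}.
#' @param path file path.
#' @export
write_run_csv <- function(result, path) {
  stopifnot(inherits(result, "coadapt_run"))
  utils::write.csv(result$series, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_run_csv
#' @param summary data frame from \code{run_grid()$summary}.
#' @export
write_summary_csv <- function(summary, path) {
  utils::write.csv(summary, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a sequence as headered CSV
#'
#' One column per sensor channel, one row per sample.
#'
#' @param sequence samples x channels matrix.
#' @param path file path.
#' @export
write_sequence_csv <- function(sequence, path) {
  X <- as.data.frame(as.matrix(sequence))
  names(X) <- paste0("ch", seq_len(ncol(X)))
  utils::write.csv(X, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sequence_csv
#' @export
read_sequence_csv <- function(path) {
  as.matrix(utils::read.csv(path))
}

#' Run manifest
#'
#' JSON snapshot written next to every set of outputs: the full configuration,
#' package version, master seed, timestamp and output-file inventory.
#' Re-running the same command from a manifest's configuration and seed
#' reproduces the outputs bit-identically.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param outputs character vector of files written.
#' @param dir output directory.
#' @param extra optional named list of additional fields.
#' @return Path of the manifest, invisibly.
#' @export
write_manifest <- function(config, outputs, dir, extra = list()) {
  manifest <- c(list(
    package = "coadapt",
    version = as.character(utils::packageVersion("coadapt")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    master_seed = config$seed,
    config = unclass(config),
    outputs = as.list(outputs)
  ), extra)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(dir) {
  jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
}
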