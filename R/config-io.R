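# YAML round trip for experiment configurations.

#' Write an experiment configuration as YAML
#'
#' @param config An \code{\link{experiment_config}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  out <- unclass(config)
  # named atomic vectors must become maps, or YAML drops the names
  out$counts <- lapply(out$counts, as.list)
  out$multiplicity <- as.list(out$multiplicity)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Read an experiment configuration from YAML
#'
#' Values missing from the file fall back to the
#' \code{\link{experiment_config}} defaults.
#'
#' @param path YAML file written by \code{\link{write_experiment_config}}
#'   (or hand-edited).
#' @return An \code{experiment_config}.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$counts)) {
    raw$counts <- lapply(raw$counts, function(x) unlist(x))
  }
  if (!is.null(raw$multiplicity)) raw$multiplicity <- unlist(raw$multiplicity)
  known <- names(formals(experiment_config))
  do.call(experiment_config, raw[intersect(names(raw), known)])
}
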