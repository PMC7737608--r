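#' @keywords internal
"_PACKAGE"

#' Write a JSON provenance record for a run
#'
#' Every command-line run (and any scripted analysis that wants an audit
#' trail) records its inputs, parameters and seed as a small JSON file next
#' to its outputs, so results can be traced back to the exact invocation.
#'
#' @param path Output path for the JSON file.
#' @param inputs Named list of input file paths or descriptions.
#' @param params Named list of parameters/thresholds in force.
#' @param seed Integer seed used for any randomness (or `NULL`).
#' @return Invisibly, the provenance list that was written.
#' @export
write_provenance <- function(path, inputs = list(), params = list(), seed = NULL) {
  prov <- list(
    tool = "perturbscape",
    version = as.character(utils::packageVersion("perturbscape")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = inputs,
    params = params,
    seed = seed
  )
  jsonlite::write_json(prov, path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(prov)
}

# stop() with a classed condition so callers/tests can match on class
ps_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "perturbscape_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# sign() mapped to the {+, -, 0} alphabet used by interaction calls
dir_symbol <- function(x) c("-", "0", "+")[sign(x) + 2L]
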