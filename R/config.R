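# YAML configuration: `curation:`, `model:`, `shallow:` and `subsets:`
# blocks mirroring the corresponding config constructors.

#' Load a pipeline configuration file
#'
#' Reads a YAML file whose top-level blocks mirror the package's config
#' constructors: `curation` -> [curation_config()], `model` ->
#' [fnn_config()], `shallow` -> [shallow_hyper()], `subsets` ->
#' [subset_spec()]. Missing blocks fall back to defaults; unknown keys in
#' a block are an error (typo safety).
#'
#' @param path Path to a YAML file.
#' @return Named list with elements `curation`, `model`, `shallow`,
#'   `subsets`.
#' @export
load_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("the yaml package is required to read configuration files",
          "dti_config_error")
  }
  raw <- yaml::read_yaml(path)
  build <- function(block, fn) {
    args <- raw[[block]] %||% list()
    known <- names(formals(fn))
    bad <- setdiff(names(args), known)
    if (length(bad)) {
      abort(sprintf("unknown key(s) in '%s' block: %s", block,
                    paste(bad, collapse = ", ")),
            "dti_config_error")
    }
    do.call(fn, args)
  }
  list(curation = build("curation", curation_config),
       model = build("model", fnn_config),
       shallow = build("shallow", shallow_hyper),
       subsets = build("subsets", subset_spec))
}
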