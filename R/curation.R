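# Curation: attribute filtering, duplicate aggregation, activity labeling.
#
# Mirrors the standard ChEMBL curation protocol for family-level
# ligand-based classification: keep single-protein human targets measured
# in binding assays with a half-maximal standard type, collapse repeated
# (compound, target) measurements to their median pChEMBL, and threshold
# at pChEMBL 7.0 (100 nM) to call actives.

#' Curation configuration
#'
#' @param pchembl_threshold Activity threshold on the pChEMBL scale
#'   (default 7.0, i.e. XC50 = 100 nM).
#' @param allowed_target_types Target types kept (default `"SINGLE PROTEIN"`).
#' @param allowed_taxonomy Organisms kept (default `"human"`).
#' @param allowed_assay_types Assay types kept. Default keeps binding
#'   assays only; add `"functional"` to retain functional assays.
#' @param allowed_standard_types Measurement standard types kept (default
#'   IC50, EC50, AC50, Ki, Kd, Potency).
#' @param require_pchembl Drop records without a pChEMBL value (default TRUE).
#' @param active_if_equal Label a compound sitting exactly at the threshold
#'   as active (default TRUE, i.e. active iff pchembl >= threshold).
#' @return A `curation_config` object.
#' @export
curation_config <- function(pchembl_threshold = 7.0,
                            allowed_target_types = "SINGLE PROTEIN",
                            allowed_taxonomy = "human",
                            allowed_assay_types = "binding",
                            allowed_standard_types = STANDARD_TYPES,
                            require_pchembl = TRUE,
                            active_if_equal = TRUE) {
  if (!is_scalar_number(pchembl_threshold) ||
      pchembl_threshold <= 0 || pchembl_threshold >= 14) {
    abort("pchembl_threshold must be a finite number in (0, 14)",
          "dti_config_error")
  }
  sets <- list(allowed_target_types = allowed_target_types,
               allowed_taxonomy = allowed_taxonomy,
               allowed_assay_types = allowed_assay_types,
               allowed_standard_types = allowed_standard_types)
  for (nm in names(sets)) {
    if (!length(sets[[nm]])) {
      abort(sprintf("%s must be non-empty", nm), "dti_config_error")
    }
  }
  structure(c(list(pchembl_threshold = pchembl_threshold),
              sets,
              list(require_pchembl = isTRUE(require_pchembl),
                   active_if_equal = isTRUE(active_if_equal))),
            class = "curation_config")
}

#' Filter activity records on assay/target attributes
#'
#' Keeps records whose target type, taxonomy, assay type and standard type
#' all lie in the configured allowed sets, and (when required) that carry a
#' pChEMBL value. Order is preserved; the input is not modified; an empty
#' result is legal.
#'
#' @param records Activity-record data.frame.
#' @param config A [curation_config()].
#' @return The surviving records, same columns, original order.
#' @export
apply_filters <- function(records, config = curation_config()) {
  stopifnot(inherits(config, "curation_config"))
  if (!nrow(records)) return(records)
  keep <- records$target_type %in% config$allowed_target_types &
    records$taxonomy %in% config$allowed_taxonomy &
    records$assay_type %in% config$allowed_assay_types &
    records$standard_type %in% config$allowed_standard_types
  if (config$require_pchembl) keep <- keep & !is.na(records$pchembl)
  records[keep, , drop = FALSE]
}

#' Collapse duplicate (compound, target) measurements to their median
#'
#' Repeated measurements of the same compound-target pair (typically from
#' different bioassays) are replaced by a single record whose pChEMBL is
#' the median of the group; all other fields come from the group's first
#' record in input order.
#'
#' @param records Activity-record data.frame; every record must have a
#'   pChEMBL value.
#' @return One record per (compound_id, target_id) pair, ordered by first
#'   appearance.
#' @export
aggregate_duplicates <- function(records) {
  if (!nrow(records)) return(records)
  if (any(is.na(records$pchembl))) {
    abort("aggregate_duplicates requires a pChEMBL value on every record",
          "dti_precondition_error")
  }
  key <- paste(records$compound_id, records$target_id, sep = "\r")
  first <- !duplicated(key)
  out <- records[first, , drop = FALSE]
  med <- tapply(records$pchembl, key, stats::median)
  out$pchembl <- unname(med[key[first]])
  rownames(out) <- NULL
  out
}

#' Label activity from a pChEMBL value
#'
#' @param pchembl Numeric vector of pChEMBL values.
#' @param threshold Activity threshold (default 7.0).
#' @param active_if_equal Whether the boundary value itself is active
#'   (default TRUE: active iff `pchembl >= threshold`).
#' @return Character vector, `"active"` or `"inactive"`.
#' @export
label_activity <- function(pchembl, threshold = 7.0, active_if_equal = TRUE) {
  if (any(!is.finite(pchembl)) || !is_scalar_number(threshold)) {
    abort("label_activity requires finite pChEMBL values and threshold",
          "dti_value_error")
  }
  hit <- if (active_if_equal) pchembl >= threshold else pchembl > threshold
  ifelse(hit, "active", "inactive")
}

#' Convert pChEMBL to XC50 in nanomolar
#'
#' pChEMBL is the negative log10 of a molar half-maximal measurement, so
#' the concentration is `10^(9 - pchembl)` nM; 7.0 corresponds to 100 nM.
#'
#' @param pchembl Numeric vector.
#' @return XC50 in nM.
#' @export
pchembl_to_xc50 <- function(pchembl) {
  10^(9 - pchembl)
}

#' Curate raw activity records into labeled compound sets per family
#'
#' Composition of [apply_filters()], [aggregate_duplicates()] and
#' [label_activity()], in that order, with the output partitioned by
#' protein family.
#'
#' @param records Activity-record data.frame.
#' @param config A [curation_config()].
#' @return Named list (one element per family present) of data.frames with
#'   columns `compound_id`, `smiles`, `family`, `pchembl`, `label`.
#' @export
curate <- function(records, config = curation_config()) {
  filtered <- apply_filters(records, config)
  deduped <- aggregate_duplicates(filtered)
  labeled <- data.frame(
    compound_id = deduped$compound_id,
    smiles = deduped$smiles,
    family = deduped$family,
    pchembl = deduped$pchembl,
    label = if (nrow(deduped)) {
      label_activity(deduped$pchembl, config$pchembl_threshold,
                     config$active_if_equal)
    } else {
      character(0)
    },
    stringsAsFactors = FALSE
  )
  split(labeled, labeled$family, drop = TRUE)
}
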