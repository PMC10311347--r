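# Tabular IO: activity tables, embedding files, split manifests, checkpoints.
#
# Activity tables are plain data.frames with the canonical columns
# compound_id, smiles, target_id, target_type, taxonomy, assay_type,
# standard_type, pchembl, family. Files may use other column names; a
# "dialect" maps canonical names to the candidates found in the file.

ACTIVITY_COLUMNS <- c(
  "compound_id", "smiles", "target_id", "target_type", "taxonomy",
  "assay_type", "standard_type", "pchembl", "family"
)

FAMILY_LEVELS <- c(
  "GPCR", "ion_channel", "kinase", "nuclear_receptor", "protease",
  "transporter", "other"
)

STANDARD_TYPES <- c("IC50", "EC50", "AC50", "Ki", "Kd", "Potency")

#' Column dialect for ChEMBL-style activity exports
#'
#' Maps each canonical column to the candidate header names accepted in an
#' input file (matched case-insensitively, spaces treated as underscores).
#' The built-in preset covers both the canonical names and common ChEMBL
#' export headers; ChEMBL exports vary by version, so the mapping is
#' user-overridable.
#'
#' @param ... named character vectors overriding or extending the preset,
#'   e.g. `pchembl = "p_chembl_median"`.
#' @return A named list: canonical column name -> candidate header names.
#' @export
chembl_dialect <- function(...) {
  preset <- list(
    compound_id = c("compound_id", "molecule_chembl_id", "compound_chembl_id"),
    smiles = c("smiles", "canonical_smiles"),
    target_id = c("target_id", "target_chembl_id"),
    target_type = c("target_type"),
    taxonomy = c("taxonomy", "organism"),
    assay_type = c("assay_type"),
    standard_type = c("standard_type"),
    pchembl = c("pchembl", "pchembl_value"),
    family = c("family", "protein_family", "protein_class")
  )
  override <- list(...)
  bad <- setdiff(names(override), ACTIVITY_COLUMNS)
  if (length(bad)) {
    abort(sprintf("unknown dialect column(s): %s", paste(bad, collapse = ", ")),
          "dti_config_error")
  }
  for (nm in names(override)) {
    preset[[nm]] <- unique(c(override[[nm]], preset[[nm]]))
  }
  preset
}

norm_header <- function(x) gsub(" ", "_", tolower(trimws(x)), fixed = TRUE)

detect_delim <- function(line) {
  if (lengths(regmatches(line, gregexpr("\t", line))) >=
      lengths(regmatches(line, gregexpr(",", line)))) "\t" else ","
}

normalize_assay_type <- function(x) {
  x <- tolower(trimws(x))
  out <- rep("other", length(x))
  out[x %in% c("b", "binding")] <- "binding"
  out[x %in% c("f", "functional")] <- "functional"
  out[is.na(x) | x == ""] <- "other"
  out
}

normalize_taxonomy <- function(x) {
  x <- tolower(trimws(x))
  x[x == "homo sapiens"] <- "human"
  x[is.na(x)] <- ""
  x
}

normalize_family <- function(x) {
  x <- trimws(x)
  key <- gsub("[ -]", "_", tolower(x))
  map <- c(
    gpcr = "GPCR", gpcrs = "GPCR", g_protein_coupled_receptor = "GPCR",
    ion_channel = "ion_channel", ion_channels = "ion_channel",
    kinase = "kinase", kinases = "kinase",
    nuclear_receptor = "nuclear_receptor", nuclear_receptors = "nuclear_receptor",
    protease = "protease", proteases = "protease",
    transporter = "transporter", transporters = "transporter"
  )
  out <- unname(map[key])
  out[is.na(out)] <- "other"
  out
}

normalize_standard_type <- function(x) {
  x <- trimws(x)
  idx <- match(tolower(x), tolower(STANDARD_TYPES))
  out <- STANDARD_TYPES[idx]
  out[is.na(idx)] <- "other"
  out
}

#' Read a bioactivity activity table
#'
#' Reads a CSV/TSV export of bioactivity measurements into the canonical
#' activity-record layout. Delimiter is auto-detected (comma or tab).
#' Missing pChEMBL cells become `NA` (never zero); unknown assay types,
#' families and standard types map to `"other"`.
#'
#' @param path Path to a delimited text file.
#' @param dialect Column dialect, see [chembl_dialect()].
#' @return A data.frame with columns `compound_id`, `smiles`, `target_id`,
#'   `target_type`, `taxonomy`, `assay_type`, `standard_type`, `pchembl`,
#'   `family`.
#' @export
read_activity_table <- function(path, dialect = chembl_dialect()) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), "dti_format_error")
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- detect_delim(first)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", na.strings = character(),
                           fileEncoding = "UTF-8", comment.char = "")
  headers <- norm_header(names(raw))

  resolve <- function(canonical) {
    hit <- match(norm_header(dialect[[canonical]]), headers)
    hit <- hit[!is.na(hit)]
    if (length(hit)) hit[1L] else NA_integer_
  }
  mandatory <- c("compound_id", "smiles", "target_id", "pchembl")
  cols <- vapply(ACTIVITY_COLUMNS, resolve, integer(1))
  missing_mand <- mandatory[is.na(cols[mandatory])]
  if (length(missing_mand)) {
    abort(sprintf("activity table is missing mandatory column(s): %s",
                  paste(missing_mand, collapse = ", ")),
          "dti_format_error", columns = missing_mand)
  }

  get_col <- function(canonical, default = NA_character_) {
    i <- cols[[canonical]]
    if (is.na(i)) rep(default, nrow(raw)) else raw[[i]]
  }

  pchembl_raw <- trimws(get_col("pchembl"))
  empty <- is.na(pchembl_raw) | pchembl_raw == "" |
    toupper(pchembl_raw) %in% c("NA", "NULL", "NONE")
  pchembl <- suppressWarnings(as.numeric(pchembl_raw))
  bad <- which(!empty & is.na(pchembl))
  if (length(bad)) {
    abort(sprintf("unparseable pChEMBL value '%s' at row %d",
                  pchembl_raw[bad[1L]], bad[1L]),
          "dti_value_error", row = bad[1L])
  }
  pchembl[empty] <- NA_real_
  out_of_range <- which(!is.na(pchembl) & (pchembl <= 0 | pchembl > 14 |
                                             !is.finite(pchembl)))
  if (length(out_of_range)) {
    abort(sprintf("pChEMBL value %s at row %d outside (0, 14]",
                  format(pchembl[out_of_range[1L]]), out_of_range[1L]),
          "dti_value_error", row = out_of_range[1L])
  }

  smiles <- trimws(get_col("smiles"))
  if (any(smiles == "" | is.na(smiles))) {
    i <- which(smiles == "" | is.na(smiles))[1L]
    abort(sprintf("empty SMILES at row %d", i), "dti_value_error", row = i)
  }

  data.frame(
    compound_id = trimws(get_col("compound_id")),
    smiles = smiles,
    target_id = trimws(get_col("target_id")),
    target_type = trimws(get_col("target_type", "")),
    taxonomy = normalize_taxonomy(get_col("taxonomy", "")),
    assay_type = normalize_assay_type(get_col("assay_type", "")),
    standard_type = normalize_standard_type(get_col("standard_type", "")),
    pchembl = pchembl,
    family = normalize_family(get_col("family", "")),
    stringsAsFactors = FALSE
  )
}

#' Write an activity table
#'
#' @param records Activity-record data.frame (canonical columns).
#' @param path Output path; `.tsv` extension writes tab-separated.
#' @export
write_activity_table <- function(records, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(records, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a compound embedding table
#'
#' Delimited text, one compound per row: an id followed by `d` numeric
#' fields. The dimension is inferred from the first row; every row must
#' conform.
#'
#' @param path Path to the embedding file (TSV or CSV).
#' @return An `embedding_table`: list with `dimension` and `vectors`
#'   (numeric matrix, one row per compound, rownames = compound ids).
#' @export
read_embeddings <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), "dti_format_error")
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    abort("embedding file is empty", "dti_format_error")
  }
  sep <- detect_delim(lines[1L])
  fields <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(fields)
  d <- widths[1L] - 1L
  if (d < 1L) {
    abort("embedding rows need an id plus at least one numeric field",
          "dti_format_error")
  }
  ragged <- which(widths != widths[1L])
  if (length(ragged)) {
    abort(sprintf("ragged embedding row %d: expected %d fields, got %d",
                  ragged[1L], widths[1L], widths[ragged[1L]]),
          "dti_format_error", row = ragged[1L])
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  vals <- suppressWarnings(
    vapply(fields, function(f) as.numeric(f[-1L]), numeric(d))
  )
  vecs <- if (d == 1L) matrix(vals, ncol = 1L) else t(vals)
  bad <- which(apply(is.na(vecs), 1L, any))
  if (length(bad)) {
    abort(sprintf("non-numeric embedding value at row %d", bad[1L]),
          "dti_format_error", row = bad[1L])
  }
  rownames(vecs) <- ids
  embedding_table(vecs)
}

#' Construct an embedding table from a matrix
#'
#' @param vectors Numeric matrix, rownames are compound ids.
#' @return An `embedding_table` object.
#' @export
embedding_table <- function(vectors) {
  stopifnot(is.matrix(vectors), is.numeric(vectors),
            !is.null(rownames(vectors)))
  structure(list(dimension = ncol(vectors), vectors = vectors),
            class = "embedding_table")
}

#' Write a compound embedding table
#'
#' @param table An `embedding_table`.
#' @param path Output path (tab-separated).
#' @export
write_embeddings <- function(table, path) {
  stopifnot(inherits(table, "embedding_table"))
  lines <- vapply(seq_len(nrow(table$vectors)), function(i) {
    paste(c(rownames(table$vectors)[i],
            format(table$vectors[i, ], digits = 17, trim = TRUE,
                   scientific = FALSE)),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Construct a train/test split
#'
#' @param train_ids,test_ids Character vectors of compound ids; must be
#'   disjoint.
#' @param seed Integer seed used to draw the split (or `NA`).
#' @param test_fraction Requested test fraction (or `NA`).
#' @return A `dataset_split` object.
#' @export
dataset_split <- function(train_ids, test_ids, seed = NA_integer_,
                          test_fraction = NA_real_) {
  train_ids <- as.character(train_ids)
  test_ids <- as.character(test_ids)
  overlap <- intersect(train_ids, test_ids)
  if (length(overlap)) {
    abort(sprintf("train/test partitions overlap (e.g. '%s')", overlap[1L]),
          "dti_integrity_error", ids = overlap)
  }
  if (!length(test_ids)) {
    warning("dataset_split has an empty test partition", call. = FALSE)
  }
  structure(list(train_ids = train_ids, test_ids = test_ids,
                 seed = as.integer(seed), test_fraction = as.numeric(test_fraction)),
            class = "dataset_split")
}

#' Write a split manifest
#'
#' Two-column CSV (`compound_id,partition`) with the seed and test fraction
#' preserved in commented header lines, so the manifest round-trips to an
#' identical `dataset_split`.
#'
#' @param split A `dataset_split`.
#' @param path Output path.
#' @export
write_split_manifest <- function(split, path) {
  stopifnot(inherits(split, "dataset_split"))
  header <- c(
    sprintf("#seed=%s", ifelse(is.na(split$seed), "NA", split$seed)),
    sprintf("#test_fraction=%s",
            ifelse(is.na(split$test_fraction), "NA",
                   format(split$test_fraction, digits = 17))),
    "compound_id,partition"
  )
  body <- c(paste0(split$train_ids, ",train"), paste0(split$test_ids, ",test"))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read a split manifest
#'
#' @param path Manifest written by [write_split_manifest()].
#' @return A `dataset_split`; an empty test partition is read back with a
#'   warning; overlapping partitions raise an integrity error.
#' @export
read_split_manifest <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), "dti_format_error")
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  meta <- lines[startsWith(lines, "#")]
  get_meta <- function(key) {
    hit <- grep(paste0("^#", key, "="), meta, value = TRUE)
    if (!length(hit)) return(NA_character_)
    sub(paste0("^#", key, "="), "", hit[1L])
  }
  seed <- suppressWarnings(as.integer(get_meta("seed")))
  frac <- suppressWarnings(as.numeric(get_meta("test_fraction")))
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(trimws(body))]
  if (!length(body) || norm_header(body[1L]) != "compound_id,partition") {
    abort("split manifest missing 'compound_id,partition' header",
          "dti_format_error")
  }
  body <- body[-1L]
  parts <- strsplit(body, ",", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    abort(sprintf("malformed manifest row %d",
                  which(lengths(parts) != 2L)[1L] + 1L),
          "dti_format_error")
  }
  ids <- vapply(parts, `[[`, character(1), 1L)
  partition <- vapply(parts, `[[`, character(1), 2L)
  unknown <- setdiff(unique(partition), c("train", "test"))
  if (length(unknown)) {
    abort(sprintf("unknown partition label '%s'", unknown[1L]),
          "dti_format_error")
  }
  dataset_split(ids[partition == "train"], ids[partition == "test"],
                seed = seed, test_fraction = frac)
}

#' Save a classifier checkpoint
#'
#' A single-file archive of the per-layer weight arrays plus metadata
#' (layer sizes, init seed, training-epoch count, provenance). Round-trips
#' bit-exactly, so frozen-weight identity is checkable across save/load.
#'
#' @param params An `fnn_params` object.
#' @param path Output path.
#' @export
write_checkpoint <- function(params, path) {
  stopifnot(inherits(params, "fnn_params"))
  saveRDS(params, path, version = 3)
  invisible(path)
}

#' Load a classifier checkpoint
#'
#' @param path Path written by [write_checkpoint()].
#' @return The stored `fnn_params`.
#' @export
read_checkpoint <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), "dti_format_error")
  }
  params <- readRDS(path)
  if (!inherits(params, "fnn_params")) {
    abort("checkpoint does not contain classifier parameters",
          "dti_format_error")
  }
  params
}
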