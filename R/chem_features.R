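# Compound representations: ECFP4 fingerprints for clustering, 300-d
# vectors for the classifier (imported embeddings or a folded fingerprint).

#' Construct a fingerprint from set-bit indices
#'
#' @param bits Integer vector of set-bit indices (0-based), duplicates
#'   collapsed.
#' @param nbits Fingerprint length.
#' @param radius Circular-environment radius (2 for ECFP4).
#' @return A `fingerprint` object.
#' @export
fingerprint <- function(bits, nbits, radius = 2L) {
  bits <- sort(unique(as.integer(bits)))
  if (length(bits) && (min(bits) < 0L || max(bits) >= nbits)) {
    abort(sprintf("bit index outside [0, %d)", nbits), "dti_value_error")
  }
  structure(list(bits = bits, nbits = as.integer(nbits),
                 radius = as.integer(radius)),
            class = "fingerprint")
}

#' ECFP4 fingerprint of a SMILES string
#'
#' Extended-connectivity circular fingerprint of radius 2, computed with
#' OpenBabel (via ChemmineOB) and folded to `nbits` bits by index modulo.
#' Deterministic for a given SMILES.
#'
#' @param smiles A single SMILES string.
#' @param nbits Folded length (default 2048).
#' @return A `fingerprint`.
#' @export
ecfp4 <- function(smiles, nbits = 2048L) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!nzchar(trimws(smiles))) {
    abort("empty SMILES string", "dti_parse_error", smiles = smiles)
  }
  raw <- tryCatch(
    ChemmineOB::forEachMol("SMILES", smiles, function(mol) {
      ChemmineOB::fingerprint_OB(list(mol), "ECFP4")
    }),
    error = function(e) NULL
  )
  if (is.null(raw) || !length(raw)) {
    abort(sprintf("unparsable SMILES: '%s'", smiles), "dti_parse_error",
          smiles = smiles)
  }
  bv <- as.numeric(raw[[1L]])
  on_bits <- which(bv != 0) - 1L
  fingerprint(on_bits %% as.integer(nbits), nbits = nbits, radius = 2L)
}

#' Tanimoto similarity of two fingerprints
#'
#' `|A n B| / |A u B|`; defined as 1 when both fingerprints are empty.
#'
#' @param a,b `fingerprint` objects of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "fingerprint"), inherits(b, "fingerprint"))
  if (a$nbits != b$nbits) {
    abort(sprintf("fingerprint lengths differ: %d vs %d", a$nbits, b$nbits),
          "dti_dimension_error")
  }
  ni <- length(intersect(a$bits, b$bits))
  nu <- length(a$bits) + length(b$bits) - ni
  if (nu == 0L) return(1.0)
  ni / nu
}

# Dense pairwise Tanimoto matrix over a list of fingerprints (internal,
# used by clustering; one matrix multiply instead of n^2 set operations).
#' @keywords internal
tanimoto_matrix <- function(fps) {
  n <- length(fps)
  nbits <- unique(vapply(fps, `[[`, integer(1), "nbits"))
  if (length(nbits) != 1L) {
    abort("fingerprints have mixed lengths", "dti_dimension_error")
  }
  m <- matrix(0, nrow = n, ncol = nbits)
  for (i in seq_len(n)) m[i, fps[[i]]$bits + 1L] <- 1
  inter <- tcrossprod(m)
  sizes <- rowSums(m)
  uni <- outer(sizes, sizes, "+") - inter
  sim <- ifelse(uni == 0, 1, inter / pmax(uni, 1))
  dimnames(sim) <- list(names(fps), names(fps))
  sim
}

#' Fold a fingerprint to a fixed-length 0/1 vector
#'
#' @param fp A `fingerprint`.
#' @param dimension Output length.
#' @return Numeric 0/1 vector of the requested length.
#' @export
fold_fingerprint <- function(fp, dimension = 300L) {
  stopifnot(inherits(fp, "fingerprint"))
  v <- numeric(dimension)
  v[(fp$bits %% as.integer(dimension)) + 1L] <- 1
  v
}

#' Fixed-length numeric representation of compounds
#'
#' Builds the classifier input vectors, one row per compound. The
#' `imported_embedding` scheme looks each compound id up in an embedding
#' table (e.g. penultimate-layer representations of an external
#' message-passing network) and returns the stored vector verbatim. The
#' self-contained `folded_fingerprint` scheme folds the compound's ECFP4
#' fingerprint to `dimension` 0/1 entries, so the full pipeline runs
#' without any learned-representation dependency.
#'
#' @param compounds Data.frame with at least `compound_id` and (for the
#'   folded scheme) `smiles`.
#' @param scheme `"folded_fingerprint"` (default) or `"imported_embedding"`.
#' @param embeddings An `embedding_table`, required for the imported scheme.
#' @param dimension Representation length (default 300, matching the
#'   classifier input).
#' @return Numeric matrix, `nrow(compounds)` x `dimension`, rownames =
#'   compound ids.
#' @export
featurize <- function(compounds,
                      scheme = c("folded_fingerprint", "imported_embedding"),
                      embeddings = NULL, dimension = 300L) {
  scheme <- match.arg(scheme)
  ids <- compounds$compound_id
  if (scheme == "imported_embedding") {
    if (is.null(embeddings) || !inherits(embeddings, "embedding_table")) {
      abort("imported_embedding scheme requires an embedding_table",
            "dti_config_error")
    }
    missing <- setdiff(ids, rownames(embeddings$vectors))
    if (length(missing)) {
      abort(sprintf("compound id(s) absent from embedding table: %s",
                    paste(utils::head(missing, 5L), collapse = ", ")),
            "dti_lookup_error", ids = missing)
    }
    out <- embeddings$vectors[ids, , drop = FALSE]
    rownames(out) <- ids
    return(out)
  }
  out <- t(vapply(compounds$smiles,
                  function(s) fold_fingerprint(ecfp4(s), dimension),
                  numeric(dimension)))
  rownames(out) <- ids
  out
}
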