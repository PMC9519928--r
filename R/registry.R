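#' Entity registries
#'
#' A registry fixes a stable bijection between external identifiers (miRNA
#' accessions, disease identifiers, gene symbols) and dense matrix indices so
#' that every matrix in the pipeline can be addressed both ways. Lookups are
#' exact and case-preserving.
#'
#' @param ids Character vector of unique identifiers.
#' @param kind One of `"miRNA"`, `"disease"`, `"PCG"`.
#' @return An `entity_registry` object.
#' @examples
#' reg <- entity_registry(c("hsa-mir-21", "hsa-mir-155"), "miRNA")
#' registry_index(reg, "hsa-mir-155")
#' @export
entity_registry <- function(ids, kind = c("miRNA", "disease", "PCG")) {
  kind <- match.arg(kind)
  ids <- as.character(ids)
  if (anyNA(ids) || any(!nzchar(ids))) {
    abort("registry identifiers must be non-missing, non-empty strings")
  }
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate %s identifiers in registry", kind))
  }
  structure(
    list(kind = kind, ids = ids, index = setNames(seq_along(ids), ids)),
    class = "entity_registry"
  )
}

#' @export
print.entity_registry <- function(x, ...) {
  cat(sprintf("<entity_registry: %d %s ids>\n", length(x$ids), x$kind))
  invisible(x)
}

#' @export
length.entity_registry <- function(x) length(x$ids)

#' Map identifiers to registry indices
#'
#' @param reg An [entity_registry()].
#' @param ids Character vector of identifiers.
#' @param strict Error on unknown identifiers (default) or return `NA`.
#' @return Integer indices (1-based, contiguous).
#' @export
registry_index <- function(reg, ids, strict = TRUE) {
  idx <- unname(reg$index[as.character(ids)])
  if (strict && anyNA(idx)) {
    missing <- setdiff(as.character(ids), reg$ids)
    abort(sprintf(
      "unknown %s identifier(s): %s", reg$kind,
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  as.integer(idx)
}

#' Map registry indices back to identifiers
#'
#' @param reg An [entity_registry()].
#' @param idx Integer indices.
#' @return Character identifiers.
#' @export
registry_id <- function(reg, idx) {
  idx <- as.integer(idx)
  if (any(idx < 1L | idx > length(reg$ids))) {
    abort("registry index out of range")
  }
  reg$ids[idx]
}
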