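#' Build a directed PCG functional interaction network from an edge table
#'
#' The protein functional interaction network is a multi-relational directed
#' graph over protein-coding genes. Binding is symmetric and contributes two
#' directed edges; inhibits / activates / regulates / catalyzes are one-way
#' relations and contribute a single directed edge. Parallel edges collapse to
#' one ordered pair. Isolated PCGs are allowed (and can be forced into the
#' registry via `pcg_ids`).
#'
#' @param edges A data frame with columns `source`, `target`, `relation`.
#' @param pcg_ids Optional character vector of PCG ids to register even when
#'   they carry no edge.
#' @return A `pcg_network` with the PCG registry, the deduplicated ordered
#'   edge set, and in/out degrees.
#' @examples
#' net <- pcg_network(tibble::tibble(
#'   source = "TP53", target = "MDM2", relation = "binding"
#' ))
#' net$out_degree
#' @export
pcg_network <- function(edges, pcg_ids = NULL) {
  required <- c("source", "target", "relation")
  if (!all(required %in% names(edges))) {
    abort("edge table needs columns source, target, relation")
  }
  known <- c("binding", "inhibits", "activates", "regulates", "catalyzes")
  bad <- which(!edges$relation %in% known)
  if (length(bad) > 0) {
    abort(sprintf(
      "unknown relation %s at row %d", edges$relation[bad[1]], bad[1]
    ))
  }
  sym <- edges$relation == "binding"
  from <- c(edges$source, edges$target[sym])
  to <- c(edges$target, edges$source[sym])
  ids <- sort(unique(c(from, to, as.character(pcg_ids %||% character()))))
  reg <- entity_registry(ids, "PCG")
  ft <- unique(cbind(registry_index(reg, from), registry_index(reg, to)))
  n <- length(ids)
  adj <- Matrix::sparseMatrix(
    i = ft[, 1], j = ft[, 2], x = 1, dims = c(n, n)
  )
  structure(
    list(
      pcg_registry = reg,
      edges = tibble::tibble(
        source = ids[ft[, 1]], target = ids[ft[, 2]],
        source_index = ft[, 1], target_index = ft[, 2]
      ),
      adjacency = adj,
      in_degree = Matrix::colSums(adj),
      out_degree = Matrix::rowSums(adj)
    ),
    class = "pcg_network"
  )
}

#' @export
print.pcg_network <- function(x, ...) {
  cat(sprintf(
    "<pcg_network: %d PCGs, %d directed edges>\n",
    length(x$pcg_registry), nrow(x$edges)
  ))
  invisible(x)
}

#' Read a directed PCG interaction network from a TSV file
#'
#' Expects a header row and columns `source`, `target`, `relation` with
#' relation labels in {binding, inhibits, activates, regulates, catalyzes}.
#'
#' @param path Path to a tab-delimited file.
#' @inheritParams pcg_network
#' @return A `pcg_network`.
#' @export
read_edge_list <- function(path, pcg_ids = NULL) {
  edges <- read_tsv_strict(path, c("source", "target", "relation"))
  if (nrow(edges) == 0) abort(sprintf("empty edge list: %s", path))
  pcg_network(edges, pcg_ids = pcg_ids)
}

#' Load an association table between two entity kinds
#'
#' Associations connect miRNAs or diseases to PCGs, or miRNAs to diseases.
#' In `"binary"` mode every listed pair gets weight 1. In `"score"` mode the
#' third column carries a confidence score; scores already inside \[0, 1\]
#' pass through untouched, otherwise the whole table is min-max rescaled to
#' \[0, 1\]. Duplicate (left, right) pairs collapse to the maximum weight.
#'
#' @param x A data frame whose first two columns are left/right identifiers
#'   (and, in score mode, a numeric third column).
#' @param left_kind,right_kind Entity kinds of the two columns.
#' @param weight_mode `"binary"` or `"score"`.
#' @return A tibble with columns `left_id`, `right_id`, `weight` (class
#'   `association_table`, carrying `left_kind` / `right_kind` attributes).
#' @examples
#' association_table(
#'   data.frame(d = c("d1", "d1"), g = c("g1", "g2"), s = c(1, 5)),
#'   "disease", "PCG", weight_mode = "score"
#' )
#' @export
association_table <- function(x, left_kind, right_kind,
                              weight_mode = c("binary", "score")) {
  weight_mode <- match.arg(weight_mode)
  if (weight_mode == "score") {
    if (ncol(x) < 3) abort("score mode needs a third (score) column")
    w <- suppressWarnings(as.numeric(x[[3]]))
    if (anyNA(w)) abort("non-numeric score values in score column")
    if (any(w < 0 | w > 1)) {
      rng <- range(w)
      w <- if (rng[1] == rng[2]) rep(1, length(w)) else (w - rng[1]) / diff(rng)
    }
  } else {
    w <- rep(1, nrow(x))
  }
  out <- tibble::tibble(
    left_id = as.character(x[[1]]),
    right_id = as.character(x[[2]]),
    weight = w
  ) |>
    dplyr::group_by(.data$left_id, .data$right_id) |>
    dplyr::summarise(weight = max(.data$weight), .groups = "drop")
  structure(out,
    class = c("association_table", class(out)),
    left_kind = left_kind, right_kind = right_kind
  )
}

#' @rdname association_table
#' @param path Path to a tab-delimited file with a header row.
#' @export
read_association_table <- function(path, left_kind, right_kind,
                                   weight_mode = c("binary", "score")) {
  weight_mode <- match.arg(weight_mode)
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (weight_mode == "score" && ncol(x) < 3) {
    abort(sprintf("score column missing in %s", path))
  }
  association_table(x, left_kind, right_kind, weight_mode)
}

#' Read a disease ontology as tree-coded records
#'
#' The ontology is given as (disease_id, tree_code) records in the style of a
#' hierarchical medical vocabulary: a dot-delimited code fixes a position in
#' the category tree and its parent is the code minus its last segment. A
#' disease may hold several codes (several tree positions). Prefix codes that
#' no record owns are synthesised as implicit category nodes so every
#' non-root code has a parent.
#'
#' @param x A data frame with columns `disease_id`, `tree_code`, or (for
#'   `read_ontology`) a TSV path with those columns.
#' @return An `ontology` object: the code table with per-code parents, owner
#'   lookup, and depth.
#' @examples
#' onto <- ontology(data.frame(
#'   disease_id = c("melanoma", "neoplasms"),
#'   tree_code = c("C04.557", "C04")
#' ))
#' onto$codes
#' @export
ontology <- function(x) {
  if (!all(c("disease_id", "tree_code") %in% names(x))) {
    abort("ontology needs columns disease_id, tree_code")
  }
  codes <- as.character(x$tree_code)
  segs <- strsplit(codes, ".", fixed = TRUE)
  if (any(vapply(segs, function(s) length(s) == 0 || any(!nzchar(s)), TRUE))) {
    abort("malformed tree code (empty segment)")
  }
  # close the code set under prefixes; unowned prefixes become implicit nodes
  all_codes <- unique(unlist(lapply(segs, function(s) {
    vapply(seq_along(s), function(k) paste(s[1:k], collapse = "."), "")
  })))
  owner <- setNames(as.character(x$disease_id), codes)
  tab <- tibble::tibble(
    code = sort(all_codes),
    owner_id = ifelse(is.na(owner[sort(all_codes)]),
      sort(all_codes), unname(owner[sort(all_codes)])
    ),
    implicit = is.na(owner[sort(all_codes)])
  )
  tab$parent <- vapply(tab$code, code_parent, "", USE.NAMES = FALSE)
  tab$depth <- lengths(strsplit(tab$code, ".", fixed = TRUE))
  structure(
    list(
      codes = tab,
      records = tibble::tibble(
        disease_id = as.character(x$disease_id), tree_code = codes
      )
    ),
    class = "ontology"
  )
}

code_parent <- function(code) {
  s <- strsplit(code, ".", fixed = TRUE)[[1]]
  if (length(s) <= 1) NA_character_ else paste(s[-length(s)], collapse = ".")
}

#' @rdname ontology
#' @export
read_ontology <- function(x) {
  ontology(read_tsv_strict(x, c("disease_id", "tree_code")))
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf(
    "<ontology: %d codes (%d implicit), %d disease records>\n",
    nrow(x$codes), sum(x$codes$implicit), nrow(x$records)
  ))
  invisible(x)
}

#' Write (and read back) a ranked miRNA-disease score table
#'
#' Scores are written as TSV with columns `miRNA_id`, `disease_id`, `score`,
#' `rank`, ordered by descending score with lexicographic
#' (miRNA_id, disease_id) tie-breaks, so output is deterministic.
#'
#' @param scores A data frame with columns `miRNA_id`, `disease_id`, `score`.
#' @param path Output path.
#' @return The written tibble, invisibly.
#' @export
write_score_table <- function(scores, path) {
  if (!all(c("miRNA_id", "disease_id", "score") %in% names(scores))) {
    abort("score table needs miRNA_id, disease_id, score")
  }
  s <- scores$score
  if (any(!is.finite(s)) || any(s < 0 | s > 1)) {
    abort("scores must be finite and in [0, 1]")
  }
  out <- tibble::as_tibble(scores[c("miRNA_id", "disease_id", "score")]) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$miRNA_id, .data$disease_id) |>
    dplyr::mutate(rank = dplyr::row_number())
  readr::write_tsv(out, path, progress = FALSE)
  invisible(out)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  read_tsv_strict(path, c("miRNA_id", "disease_id", "score", "rank"))
}

read_tsv_strict <- function(path, required) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(required %in% names(x))) {
    abort(sprintf(
      "%s: expected columns %s", path, paste(required, collapse = ", ")
    ))
  }
  x
}
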