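#' Atom-type vocabulary for node featurization
#'
#' Eleven element slots plus one ligand-flag bit give the model's 12 node
#' features. The last slot, `other`, optionally absorbs elements outside the
#' list.
#'
#' @param elements Ordered character vector of 11 element symbols (the last
#'   may be the literal `"other"` bucket).
#' @param other_bucket_policy `"map"` (unknown elements go to the last slot)
#'   or `"reject"` (unknown elements raise an error).
#' @return A `type_vocabulary` object.
#' @export
type_vocabulary <- function(elements = c("C", "N", "O", "S", "P", "F",
                                         "Cl", "Br", "I", "B", "other"),
                            other_bucket_policy = c("map", "reject")) {
  other_bucket_policy <- match.arg(other_bucket_policy)
  if (anyDuplicated(elements)) stop("duplicate elements in vocabulary", call. = FALSE)
  if (length(elements) != 11L) {
    stop("vocabulary must have 11 element slots (11 + ligand bit = 12 features)",
         call. = FALSE)
  }
  structure(list(elements = elements, other_bucket_policy = other_bucket_policy),
            class = "type_vocabulary")
}

#' Build distance-cutoff edges between atoms
#'
#' An edge joins atoms `i != j` whenever their Euclidean distance is at most
#' the cutoff for their pair class: `lp_cutoff` for mixed ligand-protein
#' pairs, `intra_cutoff` for ligand-ligand and protein-protein pairs (the
#' short intramolecular cutoff closely mimics covalent structure). Edges are
#' emitted in both directions; the boundary is closed (distance equal to the
#' cutoff produces an edge).
#'
#' @param positions n x 3 coordinate matrix (Angstrom).
#' @param is_ligand Logical vector of length n.
#' @param lp_cutoff Ligand-protein cutoff in Angstrom (default 10).
#' @param intra_cutoff Intramolecular cutoff in Angstrom (default 2).
#' @return A list with `edge_index` (m x 2 integer matrix, columns receiver
#'   and sender) and `edge_attrs` (m x 3 binary matrix, columns LL, LP, PP).
#' @export
build_edges <- function(positions, is_ligand, lp_cutoff = 10.0, intra_cutoff = 2.0) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 2L) stop("need at least 2 atoms to build edges", call. = FALSE)
  stopifnot(length(is_ligand) == n, lp_cutoff >= intra_cutoff, intra_cutoff > 0)
  s2 <- rowSums(positions^2)
  d2 <- outer(s2, s2, "+") - 2 * (positions %*% t(positions))
  d2[d2 < 0] <- 0
  mixed <- outer(is_ligand, is_ligand, "!=")
  cutoff2 <- ifelse(mixed, lp_cutoff^2, intra_cutoff^2)
  adj <- d2 <= cutoff2
  diag(adj) <- FALSE
  idx <- which(adj, arr.ind = TRUE)  # both directions present by symmetry
  edge_index <- cbind(receiver = as.integer(idx[, 1]), sender = as.integer(idx[, 2]))
  cls <- edge_class(is_ligand[edge_index[, 1]], is_ligand[edge_index[, 2]])
  edge_attrs <- matrix(0L, nrow(edge_index), 3,
                       dimnames = list(NULL, c("LL", "LP", "PP")))
  edge_attrs[cbind(seq_len(nrow(edge_index)), cls)] <- 1L
  list(edge_index = edge_index, edge_attrs = edge_attrs)
}

# 1 = LL, 2 = LP (either direction), 3 = PP
edge_class <- function(lig_i, lig_j) {
  ifelse(lig_i & lig_j, 1L, ifelse(!lig_i & !lig_j, 3L, 2L))
}

#' Convert a complex into the model's graph representation
#'
#' Each atom becomes a node with a 12-wide binary feature row: one element
#' bit under the vocabulary plus a ligand-flag bit (so protein rows sum to 1
#' and ligand rows to 2). Edges come from [build_edges()].
#'
#' @param cx A `complex` with the pocket already applied.
#' @param vocab A [type_vocabulary()].
#' @param lp_cutoff,intra_cutoff Edge cutoffs in Angstrom, passed to
#'   [build_edges()].
#' @return A `complex_graph`: list with `positions` (n x 3), `node_features`
#'   (n x 12), `edge_index` (m x 2), `edge_attrs` (m x 3), `is_ligand`,
#'   `source_atom_ids`, `hbond_role`, `atom_key` (chain|residue|atom-name for
#'   protein atoms), and the cutoffs used.
#' @export
featurize <- function(cx, vocab = type_vocabulary(),
                      lp_cutoff = 10.0, intra_cutoff = 2.0) {
  stopifnot(inherits(cx, "complex"))
  if (!isTRUE(cx$pocket_applied)) {
    stop("featurize expects a pocket-applied complex; call extract_pocket() first",
         call. = FALSE)
  }
  atoms <- cx$atoms
  n <- nrow(atoms)
  slot <- match(atoms$element, vocab$elements)
  if (anyNA(slot)) {
    if (vocab$other_bucket_policy == "reject") {
      bad <- unique(atoms$element[is.na(slot)])
      stop(sprintf("element(s) not in vocabulary: %s", paste(bad, collapse = ", ")),
           call. = FALSE)
    }
    slot[is.na(slot)] <- length(vocab$elements)
  }
  nf <- matrix(0, n, length(vocab$elements) + 1L,
               dimnames = list(NULL, c(vocab$elements, "is_ligand")))
  nf[cbind(seq_len(n), slot)] <- 1
  nf[, ncol(nf)] <- as.numeric(atoms$is_ligand)
  pos <- coords(cx)
  ed <- build_edges(pos, atoms$is_ligand, lp_cutoff, intra_cutoff)
  structure(list(
    positions = pos,
    node_features = nf,
    edge_index = ed$edge_index,
    edge_attrs = ed$edge_attrs,
    is_ligand = atoms$is_ligand,
    source_atom_ids = atoms$atom_id,
    hbond_role = atoms$hbond_role,
    atom_key = ifelse(atoms$is_ligand, NA_character_,
                      paste(atoms$chain, atoms$residue_index, atoms$atom_name,
                            sep = "|")),
    lp_cutoff = lp_cutoff, intra_cutoff = intra_cutoff
  ), class = "complex_graph")
}

#' @export
print.complex_graph <- function(x, ...) {
  cat(sprintf("<complex_graph> %d nodes (%d ligand), %d directed edges\n",
              nrow(x$positions), sum(x$is_ligand), nrow(x$edge_index)))
  invisible(x)
}

#' Edge table of a complex graph
#'
#' @param g A `complex_graph`.
#' @return Tibble with receiver/sender indices and atom ids, pair class and
#'   edge length in Angstrom.
#' @export
edge_table <- function(g) {
  cls <- c("LL", "LP", "PP")[max.col(g$edge_attrs)]
  d <- sqrt(rowSums((g$positions[g$edge_index[, 1], , drop = FALSE] -
                     g$positions[g$edge_index[, 2], , drop = FALSE])^2))
  tibble::tibble(
    receiver = g$edge_index[, 1], sender = g$edge_index[, 2],
    receiver_id = g$source_atom_ids[g$edge_index[, 1]],
    sender_id = g$source_atom_ids[g$edge_index[, 2]],
    class = cls, distance = d
  )
}

#' Serialize / restore a complex graph
#'
#' Writes the graph as a gzip-compressed JSON archive: a header recording
#' shapes, feature names and cutoffs, followed by the plain numeric arrays
#' at full precision.
#'
#' @param g A `complex_graph`.
#' @param path Archive path (conventionally `.json.gz`).
#' @return `path` invisibly for `write_graph_archive`; a `complex_graph` for
#'   `read_graph_archive`.
#' @export
write_graph_archive <- function(g, path) {
  obj <- list(
    header = list(n = nrow(g$positions), m = nrow(g$edge_index),
                  lp_cutoff = g$lp_cutoff, intra_cutoff = g$intra_cutoff,
                  features = colnames(g$node_features)),
    positions = unname_mat(g$positions),
    node_features = unname_mat(g$node_features),
    edge_index = unname_mat(g$edge_index),
    edge_attrs = unname_mat(g$edge_attrs),
    is_ligand = g$is_ligand,
    source_atom_ids = g$source_atom_ids,
    hbond_role = g$hbond_role,
    atom_key = g$atom_key
  )
  con <- gzfile(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(jsonlite::toJSON(obj, digits = NA, na = "null"), con)
  invisible(path)
}

#' @rdname write_graph_archive
#' @export
read_graph_archive <- function(path) {
  con <- gzfile(path, "r")
  on.exit(close(con), add = TRUE)
  obj <- jsonlite::fromJSON(paste(readLines(con, warn = FALSE), collapse = "\n"))
  ei <- matrix(as.integer(obj$edge_index), ncol = 2)
  nf <- matrix(as.numeric(obj$node_features), ncol = length(obj$header$features))
  colnames(nf) <- obj$header$features
  structure(list(
    positions = matrix(as.numeric(obj$positions), ncol = 3),
    node_features = nf,
    edge_index = ei,
    edge_attrs = matrix(as.numeric(obj$edge_attrs), ncol = 3),
    is_ligand = as.logical(obj$is_ligand),
    source_atom_ids = obj$source_atom_ids,
    hbond_role = as.character(obj$hbond_role),
    atom_key = as.character(obj$atom_key),
    lp_cutoff = obj$header$lp_cutoff, intra_cutoff = obj$header$intra_cutoff
  ), class = "complex_graph")
}

unname_mat <- function(m) { dimnames(m) <- NULL; m }
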