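#' @name attribution
#' @title Attribution of model predictions to atoms and interactions
#'
#' @description Three procedures assign importance scores to the input of a
#' trained model. Masking methods re-predict with part of the input removed
#' and report the score drop: [atom_masking()] removes one atom (and all its
#' incident edges) at a time; [bond_masking()] removes one ligand-protein
#' edge at a time, restricted by convention to intermolecular edges shorter
#' than 4 Angstrom. [attention_attribution()] simply reads out the
#' final-layer edge attention weights, which the network already uses to
#' weight each edge's message. All three return an `attribution_result`.
NULL

attribution_result <- function(method, atom_scores, edge_scores,
                               baseline_score, complex_id = NA_character_) {
  structure(list(method = method,
                 atom_scores = atom_scores,
                 edge_scores = edge_scores,
                 baseline_score = baseline_score,
                 complex_id = complex_id),
            class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf("<attribution_result: %s> baseline %.4f; %d atom scores, %d edge scores\n",
              x$method, x$baseline_score, nrow(x$atom_scores), nrow(x$edge_scores)))
  invisible(x)
}

#' Tidy an attribution result
#' @param x An `attribution_result`.
#' @param ... Unused.
#' @return The atom-score tibble with method and baseline columns attached.
#' @method tidy attribution_result
#' @export
tidy.attribution_result <- function(x, ...) {
  dplyr::mutate(x$atom_scores, method = x$method,
                baseline_score = x$baseline_score)
}

# Remove one node (and incident edges) from a graph, preserving ids.
drop_node <- function(graph, i) {
  keep <- setdiff(seq_len(nrow(graph$positions)), i)
  remap <- integer(nrow(graph$positions))
  remap[keep] <- seq_along(keep)
  ekeep <- graph$edge_index[, 1] != i & graph$edge_index[, 2] != i
  g <- graph
  g$positions <- graph$positions[keep, , drop = FALSE]
  g$node_features <- graph$node_features[keep, , drop = FALSE]
  g$edge_index <- matrix(remap[graph$edge_index[ekeep, , drop = FALSE]],
                         ncol = 2)
  g$edge_attrs <- graph$edge_attrs[ekeep, , drop = FALSE]
  g$is_ligand <- graph$is_ligand[keep]
  g$source_atom_ids <- graph$source_atom_ids[keep]
  g$hbond_role <- graph$hbond_role[keep]
  g$atom_key <- graph$atom_key[keep]
  g
}

drop_edges <- function(graph, eidx) {
  keep <- setdiff(seq_len(nrow(graph$edge_index)), eidx)
  g <- graph
  g$edge_index <- graph$edge_index[keep, , drop = FALSE]
  g$edge_attrs <- graph$edge_attrs[keep, , drop = FALSE]
  g
}

#' Atom-masking attribution
#'
#' For each atom `i`, the score is the model output on the intact graph
#' minus the output with atom `i` removed (the atom and every incident edge
#' are deleted; nothing else is rebuilt). Positive scores mark atoms whose
#' presence raises the prediction.
#'
#' @param params A trained `egnn_model`.
#' @param graph A `complex_graph`.
#' @return An `attribution_result` with per-atom scores.
#' @export
atom_masking <- function(params, graph) {
  n <- nrow(graph$positions)
  if (n < 2L) stop("atom masking needs at least 2 atoms", call. = FALSE)
  baseline <- predict_graph(params, graph)$score
  n_lig <- sum(graph$is_ligand)
  scores <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (graph$is_ligand[i] && n_lig == 1L) {
      warning("skipping atom whose removal would leave no ligand atoms")
      next
    }
    scores[i] <- baseline - predict_graph(params, drop_node(graph, i))$score
  }
  atom_scores <- tibble::tibble(
    atom_id = graph$source_atom_ids, is_ligand = graph$is_ligand,
    score = scores)
  attribution_result("atom_masking", atom_scores,
                     empty_edge_scores(), baseline)
}

empty_edge_scores <- function() {
  tibble::tibble(protein_atom_id = integer(), ligand_atom_id = integer(),
                 score = numeric(), distance = numeric())
}

# Undirected LP edge table: one row per unordered pair, with the member
# directed-edge indices.
lp_edge_pairs <- function(graph) {
  ei <- graph$edge_index
  if (nrow(ei) == 0L) return(NULL)
  is_lp <- graph$edge_attrs[, 2] == 1
  idx <- which(is_lp)
  if (length(idx) == 0L) return(NULL)
  a <- pmin(ei[idx, 1], ei[idx, 2]); b <- pmax(ei[idx, 1], ei[idx, 2])
  key <- paste(a, b)
  first <- !duplicated(key)
  pair_of <- match(key, key[first])
  pairs <- tibble::tibble(a = a[first], b = b[first])
  members <- split(idx, pair_of)
  pairs$fwd <- vapply(members, `[`, integer(1), 1)
  pairs$rev <- vapply(members, function(v) if (length(v) > 1) v[2] else NA_integer_, integer(1))
  pairs$protein_node <- ifelse(graph$is_ligand[pairs$a], pairs$b, pairs$a)
  pairs$ligand_node <- ifelse(graph$is_ligand[pairs$a], pairs$a, pairs$b)
  pairs$distance <- sqrt(rowSums((graph$positions[pairs$a, , drop = FALSE] -
                                  graph$positions[pairs$b, , drop = FALSE])^2))
  pairs
}

#' Bond-masking attribution
#'
#' For each eligible edge (both directions removed together), the score is
#' the model output on the intact graph minus the output with that edge
#' deleted. By convention only intermolecular (ligand-protein) edges with
#' endpoint distance below `max_dist` are scored.
#'
#' @param params A trained `egnn_model`.
#' @param graph A `complex_graph`.
#' @param max_dist Distance ceiling in Angstrom (default 4.0, strict `<`).
#' @param intermolecular_only Restrict to ligand-protein edges? Default
#'   `TRUE`; `FALSE` scores every edge.
#' @return An `attribution_result` with per-edge scores; protein
#'   `atom_scores` are each atom's best incident edge score.
#' @export
bond_masking <- function(params, graph, max_dist = 4.0,
                         intermolecular_only = TRUE) {
  baseline <- predict_graph(params, graph)$score
  pairs <- if (intermolecular_only) lp_edge_pairs(graph) else all_edge_pairs(graph)
  if (!is.null(pairs)) pairs <- pairs[pairs$distance < max_dist, , drop = FALSE]
  if (is.null(pairs) || nrow(pairs) == 0L) {
    warning("no eligible edges for bond masking")
    return(attribution_result("bond_masking",
                              tibble::tibble(atom_id = integer(),
                                             is_ligand = logical(),
                                             score = numeric()),
                              empty_edge_scores(), baseline))
  }
  pairs$score <- vapply(seq_len(nrow(pairs)), function(r) {
    eidx <- stats::na.omit(c(pairs$fwd[r], pairs$rev[r]))
    baseline - predict_graph(params, drop_edges(graph, eidx))$score
  }, numeric(1))
  edge_scores <- tibble::tibble(
    protein_atom_id = graph$source_atom_ids[pairs$protein_node],
    ligand_atom_id = graph$source_atom_ids[pairs$ligand_node],
    score = pairs$score, distance = pairs$distance)
  attribution_result("bond_masking",
                     protein_atom_scores(edge_scores, graph),
                     edge_scores, baseline,
                     complex_id = NA_character_)
}

all_edge_pairs <- function(graph) {
  ei <- graph$edge_index
  if (nrow(ei) == 0L) return(NULL)
  a <- pmin(ei[, 1], ei[, 2]); b <- pmax(ei[, 1], ei[, 2])
  key <- paste(a, b)
  first <- !duplicated(key)
  pair_of <- match(key, key[first])
  pairs <- tibble::tibble(a = a[first], b = b[first])
  members <- split(seq_len(nrow(ei)), pair_of)
  pairs$fwd <- vapply(members, `[`, integer(1), 1)
  pairs$rev <- vapply(members, function(v) if (length(v) > 1) v[2] else NA_integer_, integer(1))
  pairs$protein_node <- ifelse(graph$is_ligand[pairs$a], pairs$b, pairs$a)
  pairs$ligand_node <- ifelse(graph$is_ligand[pairs$a], pairs$a, pairs$b)
  pairs$distance <- sqrt(rowSums((graph$positions[pairs$a, , drop = FALSE] -
                                  graph$positions[pairs$b, , drop = FALSE])^2))
  pairs
}

# Max edge score per protein atom (the convention used to turn edge-level
# attribution into protein-atom scores).
protein_atom_scores <- function(edge_scores, graph) {
  if (nrow(edge_scores) == 0L) {
    return(tibble::tibble(atom_id = integer(), is_ligand = logical(),
                          score = numeric()))
  }
  agg <- dplyr::summarise(
    dplyr::group_by(edge_scores, atom_id = .data$protein_atom_id),
    score = max(.data$score), .groups = "drop")
  dplyr::arrange(dplyr::mutate(agg, is_ligand = FALSE, .after = "atom_id"),
                 .data$atom_id)
}

#' Edge-attention attribution
#'
#' Reads the final layer's attention weights for ligand-protein edges
#' (directed duplicates averaged) as importance scores; per-atom protein
#' scores are each atom's maximum incident edge score. All scores lie in
#' \[0,1\].
#'
#' @param params A trained `egnn_model`.
#' @param graph A `complex_graph`.
#' @return An `attribution_result`.
#' @export
attention_attribution <- function(params, graph) {
  pred <- predict_graph(params, graph)
  pairs <- lp_edge_pairs(graph)
  if (is.null(pairs)) {
    warning("graph has no ligand-protein edges")
    return(attribution_result("edge_attention",
                              tibble::tibble(atom_id = integer(),
                                             is_ligand = logical(),
                                             score = numeric()),
                              empty_edge_scores(), pred$score))
  }
  att <- pred$attention
  pairs$score <- ifelse(is.na(pairs$rev), att[pairs$fwd],
                        (att[pairs$fwd] + att[pairs$rev]) / 2)
  edge_scores <- tibble::tibble(
    protein_atom_id = graph$source_atom_ids[pairs$protein_node],
    ligand_atom_id = graph$source_atom_ids[pairs$ligand_node],
    score = pairs$score, distance = pairs$distance)
  attribution_result("edge_attention",
                     protein_atom_scores(edge_scores, graph),
                     edge_scores, pred$score)
}

#' Top-ranked protein atoms of an attribution result
#'
#' Takes the `k` highest-scoring edges, collects their protein endpoints,
#' deduplicates keeping each atom's best score, and returns them in rank
#' order. Ties are broken by atom id for determinism.
#'
#' @param result An `attribution_result` with edge scores.
#' @param k Number of edges to take.
#' @return Tibble with `atom_id`, `score` and `rank`.
#' @export
top_protein_atoms <- function(result, k) {
  if (!is.numeric(k) || k <= 0) stop("k must be a positive integer", call. = FALSE)
  es <- result$edge_scores
  if (is.null(es) || nrow(es) == 0L) {
    stop("attribution result has no ligand-protein edge scores", call. = FALSE)
  }
  es <- es[order(-es$score, es$protein_atom_id, es$ligand_atom_id), , drop = FALSE]
  top <- es[seq_len(min(k, nrow(es))), , drop = FALSE]
  dedup <- dplyr::summarise(dplyr::group_by(top, atom_id = .data$protein_atom_id),
                            score = max(.data$score), .groups = "drop")
  dedup <- dedup[order(-dedup$score, dedup$atom_id), , drop = FALSE]
  dplyr::mutate(dedup, rank = dplyr::row_number())
}

#' Distance-rank diagnostic for attribution quality
#'
#' For the protein atoms attached to the `k` best-scoring edges, computes
#' each atom's distance to the nearest polar ligand atom (N/O element or a
#' ligand atom with a hydrogen-bond role) and returns the Spearman rank
#' correlation between attribution score and negated distance, with average
#' ranks for ties. A positive value means the attribution concentrates on
#' protein atoms close to polar ligand atoms, as geometric interaction
#' rules would.
#'
#' @param result An `attribution_result`.
#' @param cx The `complex` the attribution was computed on.
#' @param k Number of top protein atoms to use (>= 3).
#' @param nearest `"polar"` (default) measures distance to the nearest
#'   polar ligand atom; `"any"` to the nearest ligand atom of any type.
#' @return Spearman's rho.
#' @export
distance_rank_correlation <- function(result, cx, k = 10, nearest = c("polar", "any")) {
  nearest <- match.arg(nearest)
  if (k < 3) stop("k must be at least 3 for a rank correlation", call. = FALSE)
  # rank protein atoms by their atom-level scores (for edge-based methods,
  # each atom's best incident edge score), then take the top k atoms
  as_ <- result$atom_scores
  as_ <- as_[!as_$is_ligand & !is.na(as_$score), , drop = FALSE]
  as_ <- as_[order(-as_$score, as_$atom_id), , drop = FALSE]
  top <- utils::head(as_[, c("atom_id", "score")], k)
  if (nrow(top) < 3) {
    stop("fewer than 3 scored protein atoms available", call. = FALSE)
  }
  at <- cx$atoms
  lig <- at[at$is_ligand, , drop = FALSE]
  if (nearest == "polar") {
    lig <- lig[lig$element %in% c("N", "O") | lig$hbond_role != "none", ,
               drop = FALSE]
  }
  if (nrow(lig) == 0L) {
    stop("complex has no polar ligand atom for the distance diagnostic",
         call. = FALSE)
  }
  pidx <- match(top$atom_id, at$atom_id)
  d <- min_dist_to_set(as.matrix(at[pidx, c("x", "y", "z")]),
                       as.matrix(lig[, c("x", "y", "z")]))
  stats::cor(top$score, -d, method = "spearman")
}

#' Attribution scores as a ranked CSV-ready table
#'
#' @param result An `attribution_result`.
#' @param cx The source `complex` (for residue labels).
#' @return Tibble with method, atom/edge identity, residue label, score and
#'   rank, ordered by score.
#' @export
attribution_table <- function(result, cx) {
  at <- cx$atoms
  lab <- function(id) {
    i <- match(id, at$atom_id)
    ifelse(at$is_ligand[i], paste0("LIG:", at$atom_name[i]),
           paste0(at$chain[i], ":", at$residue_name[i], at$residue_index[i],
                  ":", at$atom_name[i]))
  }
  if (nrow(result$edge_scores) > 0) {
    out <- dplyr::mutate(result$edge_scores,
                         method = result$method,
                         protein_label = lab(.data$protein_atom_id),
                         ligand_label = lab(.data$ligand_atom_id))
    out <- out[order(-out$score), ]
  } else {
    out <- dplyr::mutate(result$atom_scores, method = result$method,
                         label = lab(.data$atom_id))
    out <- out[order(-out$score), ]
  }
  dplyr::mutate(out, rank = dplyr::row_number())
}
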