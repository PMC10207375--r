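test_that("atom masking scores an isolated atom by its pooling contribution alone", {
  # one ligand atom far from everything: no edges touch it, so removing it
  # only changes the global average pool; recompute that change in closed
  # form from the final node features.
  pos <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(3, 0, 0), c(100, 100, 100))
  lig <- c(TRUE, FALSE, FALSE, TRUE)
  ed <- build_edges(pos, lig, 10, 4)
  nf <- matrix(0, 4, 12); nf[cbind(1:4, c(1, 2, 3, 1))] <- 1
  nf[, 12] <- as.numeric(lig)
  g <- structure(list(positions = pos, node_features = nf, edge_index = ed$edge_index,
                      edge_attrs = ed$edge_attrs, is_ligand = lig,
                      source_atom_ids = 1:4, hbond_role = rep("none", 4),
                      atom_key = rep(NA_character_, 4), lp_cutoff = 10,
                      intra_cutoff = 4), class = "complex_graph")
  expect_true(all(ed$edge_index != 4))  # isolated
  p <- tiny_model(seed = 31)
  res <- atom_masking(p, g)
  fw <- eqscore:::egnn_forward(p, eqscore:::combine_graphs(g))
  H <- fw$H_final
  pool_with <- colMeans(H)
  pool_without <- colMeans(H[1:3, , drop = FALSE])
  head_out <- function(pool) {
    1 / (1 + exp(-(sum(pool * p$head$w) + p$head$b)))
  }
  oracle <- head_out(pool_with) - head_out(pool_without)
  expect_equal(res$atom_scores$score[4], oracle, tolerance = 1e-10)
  # determinism
  res2 <- atom_masking(p, g)
  expect_identical(res$atom_scores, res2$atom_scores)
  expect_equal(res$baseline_score, fw$output[1])
})

test_that("masking the only ligand atom is skipped with a warning", {
  g <- random_graph(5, seed = 3)
  g$is_ligand <- c(TRUE, FALSE, FALSE, FALSE, FALSE)
  expect_warning(res <- atom_masking(tiny_model(), g), "no ligand")
  expect_true(is.na(res$atom_scores$score[1]))
  expect_false(anyNA(res$atom_scores$score[-1]))
})

test_that("bond masking respects the 4 Angstrom intermolecular convention", {
  # one LP pair at 3 A (eligible) and one at 5 A (not)
  pos <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 5, 0))
  lig <- c(TRUE, FALSE, FALSE)
  ed <- build_edges(pos, lig, 10, 2)
  nf <- matrix(0, 3, 12); nf[cbind(1:3, c(1, 2, 3))] <- 1; nf[, 12] <- as.numeric(lig)
  g <- structure(list(positions = pos, node_features = nf, edge_index = ed$edge_index,
                      edge_attrs = ed$edge_attrs, is_ligand = lig,
                      source_atom_ids = 1:3, hbond_role = rep("none", 3),
                      atom_key = rep(NA_character_, 3), lp_cutoff = 10,
                      intra_cutoff = 2), class = "complex_graph")
  res <- bond_masking(tiny_model(), g, max_dist = 4)
  expect_equal(nrow(res$edge_scores), 1)
  expect_equal(res$edge_scores$protein_atom_id, 2)
  expect_equal(res$edge_scores$distance, 3)
})

test_that("bond masking equals the brute-force re-prediction oracle", {
  p <- tiny_model(seed = 8)
  g <- random_graph(10, seed = 19)
  res <- bond_masking(p, g, max_dist = 6)
  expect_gt(nrow(res$edge_scores), 1)
  base <- predict_graph(p, g)$score
  for (r in seq_len(nrow(res$edge_scores))) {
    pn <- match(res$edge_scores$protein_atom_id[r], g$source_atom_ids)
    ln <- match(res$edge_scores$ligand_atom_id[r], g$source_atom_ids)
    drop <- which((g$edge_index[, 1] == pn & g$edge_index[, 2] == ln) |
                    (g$edge_index[, 1] == ln & g$edge_index[, 2] == pn))
    keep <- setdiff(seq_len(nrow(g$edge_index)), drop)
    g2 <- g
    g2$edge_index <- g$edge_index[keep, , drop = FALSE]
    g2$edge_attrs <- g$edge_attrs[keep, , drop = FALSE]
    expect_equal(res$edge_scores$score[r],
                 base - predict_graph(p, g2)$score, tolerance = 1e-12)
  }
})

test_that("an edge with attention forced to zero has zero masking score", {
  p <- tiny_model(seed = 2)
  g <- random_graph(8, seed = 9)
  pairs <- eqscore:::lp_edge_pairs(g)
  pair <- c(pairs$fwd[1], pairs$rev[1])
  base_zero <- predict_graph(p, g, zero_edges = pair)$score
  keep <- setdiff(seq_len(nrow(g$edge_index)), pair)
  g2 <- g
  g2$edge_index <- g$edge_index[keep, , drop = FALSE]
  g2$edge_attrs <- g$edge_attrs[keep, , drop = FALSE]
  masked <- base_zero - predict_graph(p, g2)$score
  expect_lt(abs(masked), 1e-5)
})

test_that("attention attribution returns [0,1] scores and ranks a lone LP edge first", {
  p <- tiny_model(seed = 5)
  g <- random_graph(8, seed = 14)
  res <- attention_attribution(p, g)
  expect_true(all(res$edge_scores$score >= 0 & res$edge_scores$score <= 1))
  expect_true(all(res$atom_scores$score >= 0 & res$atom_scores$score <= 1))
  # single-LP-edge graph
  pos <- rbind(c(0, 0, 0), c(3, 0, 0), c(3, 30, 0), c(4.5, 30, 0))
  lig <- c(TRUE, FALSE, FALSE, FALSE)
  ed <- build_edges(pos, lig, 10, 2)
  nf <- matrix(0, 4, 12); nf[, 1] <- 1; nf[, 12] <- as.numeric(lig)
  g1 <- structure(list(positions = pos, node_features = nf,
                       edge_index = ed$edge_index, edge_attrs = ed$edge_attrs,
                       is_ligand = lig, source_atom_ids = 1:4,
                       hbond_role = rep("none", 4),
                       atom_key = rep(NA_character_, 4),
                       lp_cutoff = 10, intra_cutoff = 2), class = "complex_graph")
  res1 <- attention_attribution(p, g1)
  expect_equal(nrow(res1$edge_scores), 1)
  expect_equal(top_protein_atoms(res1, 1)$atom_id, 2)
})

test_that("top_protein_atoms deduplicates and matches a sort-and-scan oracle", {
  set.seed(55)
  for (rep in 1:100) {
    m <- sample(4:20, 1)
    es <- tibble::tibble(
      protein_atom_id = sample(10:15, m, replace = TRUE),
      ligand_atom_id = sample(1:5, m, replace = TRUE),
      score = round(runif(m), 2),   # rounding forces ties
      distance = runif(m, 2, 8))
    res <- eqscore:::attribution_result("edge_attention",
                                        tibble::tibble(), es, 0.5)
    k <- sample(1:m, 1)
    got <- top_protein_atoms(res, k)
    ord <- order(-es$score, es$protein_atom_id, es$ligand_atom_id)
    top_edges <- es[ord[seq_len(min(k, m))], ]
    best <- list()
    for (r in seq_len(nrow(top_edges))) {
      id <- as.character(top_edges$protein_atom_id[r])
      best[[id]] <- max(best[[id]] %||% -Inf, top_edges$score[r])
    }
    want <- tibble::tibble(atom_id = as.integer(names(best)),
                           score = unlist(best, use.names = FALSE))
    want <- want[order(-want$score, want$atom_id), ]
    expect_equal(got$atom_id, want$atom_id)
    expect_equal(got$score, want$score)
    expect_equal(got$rank, seq_len(nrow(want)))
  }
  expect_error(top_protein_atoms(
    eqscore:::attribution_result("edge_attention", tibble::tibble(),
                                 eqscore:::empty_edge_scores(), 0), 5),
    "no ligand-protein")
  es1 <- tibble::tibble(protein_atom_id = 1L, ligand_atom_id = 2L,
                        score = 0.5, distance = 3)
  expect_error(top_protein_atoms(
    eqscore:::attribution_result("edge_attention", tibble::tibble(), es1, 0), 0),
    "positive")
})

test_that("the distance-rank diagnostic recovers perfect and inverted orderings", {
  gen <- generate_complex(synthetic_spec(n_planted_contacts = 3), seed = 51)
  cx <- gen$complex
  at <- cx$atoms
  prot <- at[!at$is_ligand, ]
  lig_polar <- at[at$is_ligand & at$hbond_role != "none", ]
  d <- eqscore:::min_dist_to_set(as.matrix(prot[, c("x", "y", "z")]),
                                 as.matrix(lig_polar[, c("x", "y", "z")]))
  # scores exactly ordered by closeness -> rho = 1; anti-ordered -> -1
  mk <- function(score) eqscore:::attribution_result(
    "edge_attention",
    tibble::tibble(atom_id = prot$atom_id, is_ligand = FALSE, score = score),
    eqscore:::empty_edge_scores(), 0)
  expect_equal(distance_rank_correlation(mk(-d), cx, k = nrow(prot)), 1.0)
  expect_equal(distance_rank_correlation(mk(d), cx, k = nrow(prot)), -1.0)
  expect_error(distance_rank_correlation(mk(-d), cx, k = 2), "at least 3")
})

test_that("the Spearman computation matches a rank-then-Pearson oracle", {
  set.seed(88)
  for (rep in 1:50) {
    x <- sample(round(runif(10), 1))  # ties likely
    y <- runif(10)
    expect_equal(stats::cor(x, y, method = "spearman"), spearman_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("masking and attention attributions are invariant under rigid motion", {
  p <- tiny_model(seed = 6)
  gen <- generate_complex(synthetic_spec(), seed = 60)
  g <- featurize(gen$complex)
  base_att <- attention_attribution(p, g)
  base_atom <- atom_masking(p, g)
  motion <- random_rigid_motion(reflect = TRUE)
  cx2 <- transform_complex(gen$complex, motion)
  g2 <- featurize(cx2)
  att2 <- attention_attribution(p, g2)
  expect_equal(att2$edge_scores$score, base_att$edge_scores$score,
               tolerance = 1e-8)
  atom2 <- atom_masking(p, g2)
  expect_equal(atom2$atom_scores$score, base_atom$atom_scores$score,
               tolerance = 1e-8)
})
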