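# Shared fixtures: toy graphs, rigid motions, tiny structure files, and a
# memoized desk-scale trained model reused across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

random_rigid_motion <- function(reflect = FALSE) {
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  if (reflect) Q[, 1] <- -Q[, 1]
  list(Q = Q, t = rnorm(3, sd = 5))
}

apply_motion <- function(pos, motion) {
  sweep(pos %*% motion$Q, 2, motion$t, "+")
}

transform_complex <- function(cx, motion) {
  p <- apply_motion(coords(cx), motion)
  cx$atoms$x <- p[, 1]; cx$atoms$y <- p[, 2]; cx$atoms$z <- p[, 3]
  cx
}

# A random featurized graph (not from the generator) for pure model tests.
random_graph <- function(n = 10, seed = NULL, lp_cutoff = 10, intra_cutoff = 4) {
  if (!is.null(seed)) set.seed(seed)
  pos <- matrix(rnorm(n * 3, sd = 3), n, 3)
  lig <- rep(c(TRUE, FALSE), length.out = n)
  ed <- build_edges(pos, lig, lp_cutoff, intra_cutoff)
  nf <- matrix(0, n, 12)
  nf[cbind(seq_len(n), sample(1:11, n, replace = TRUE))] <- 1
  nf[, 12] <- as.numeric(lig)
  structure(list(positions = pos, node_features = nf,
                 edge_index = ed$edge_index, edge_attrs = ed$edge_attrs,
                 is_ligand = lig, source_atom_ids = seq_len(n),
                 hbond_role = rep("none", n),
                 atom_key = ifelse(lig, NA, paste0("A|", seq_len(n), "|CA")),
                 lp_cutoff = lp_cutoff, intra_cutoff = intra_cutoff),
            class = "complex_graph")
}

transform_graph <- function(g, motion) {
  g$positions <- apply_motion(g$positions, motion)
  g
}

permute_graph <- function(g, perm) {
  inv <- order(perm)
  g2 <- g
  g2$positions <- g$positions[perm, , drop = FALSE]
  g2$node_features <- g$node_features[perm, , drop = FALSE]
  g2$is_ligand <- g$is_ligand[perm]
  g2$source_atom_ids <- g$source_atom_ids[perm]
  g2$hbond_role <- g$hbond_role[perm]
  g2$atom_key <- g$atom_key[perm]
  g2$edge_index <- matrix(inv[g$edge_index], ncol = 2)
  g2
}

tiny_model <- function(n_layers = 2, width = 8, seed = 1) {
  init_params(model_config(n_layers = n_layers, hidden_width = width,
                           attention_hidden = 4, coord_hidden = 4,
                           seed = seed))
}

write_toy_pdb <- function(path, include_water = FALSE, include_h = FALSE) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   5.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       1.200   5.500   0.000  1.00 10.00           C",
    "ATOM      3  O   ALA A   1       2.400   4.800   0.000  1.00 10.00           O")
  if (include_h) lines <- c(lines,
    "ATOM      4  H   ALA A   1       0.500   6.000   1.000  1.00 10.00           H")
  if (include_water) lines <- c(lines,
    "HETATM    5  O   HOH A 101       8.000   8.000   8.000  1.00 20.00           O")
  writeLines(c(lines, "END"), path)
  path
}

write_water_only_pdb <- function(path) {
  writeLines(c(
    "HETATM    1  O   HOH A 101       8.000   8.000   8.000  1.00 20.00           O",
    "END"), path)
  path
}

write_toy_sdf <- function(path, include_h = FALSE) {
  n <- if (include_h) 3 else 2
  lines <- c(
    "toy", "  fixture", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, n - 1),
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5000    0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0")
  if (include_h) lines <- c(lines,
    "    2.1000    0.8000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0")
  lines <- c(lines, "  1  2  1  0",
             if (include_h) "  2  3  1  0",
             "M  END", "$$$$")
  writeLines(lines, path)
  path
}

# Memoized trained models so the acceptance tests share one training run per
# seed instead of retraining.
.model_cache <- new.env(parent = emptyenv())

trained_pose_model <- function(seed, n_examples = 200, epochs = 50) {
  key <- sprintf("pose_%d_%d_%d", seed, n_examples, epochs)
  if (is.null(.model_cache[[key]])) {
    ds <- generate_pose_dataset(synthetic_spec(), n_examples, seed = seed)
    fit <- train_pose_classifier(
      ds$examples, model_config(n_layers = 4, hidden_width = 32, seed = seed),
      train_config(epochs = epochs, patience = 25, seed = seed))
    .model_cache[[key]] <- list(fit = fit, dataset = ds)
  }
  .model_cache[[key]]
}

# Independent Spearman implementation: average ranks, then the Pearson
# product-moment formula written out.
spearman_oracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Independent Gotoh global alignment (affine gaps) returning the optimal
# score under match = 1, mismatch = 0, gap = -(open + k * extend).
gotoh_score <- function(a, b, match = 1, mismatch = 0, open = 10, extend = 0.5) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1); Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -(open + extend * i)
  for (j in seq_len(m)) Iy[1, j + 1] <- -(open + extend * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (a[i] == b[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                              Ix[i, j + 1] - extend)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                              Iy[i + 1, j] - extend)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

random_molecule <- function(n_atoms = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  els <- sample(c("C", "C", "C", "N", "O"), n_atoms, replace = TRUE)
  # random tree plus occasional extra edge (kept acyclic for simplicity)
  bonds <- if (n_atoms > 1) {
    tibble::tibble(i = 2:n_atoms,
                   j = vapply(2:n_atoms, function(k) sample(k - 1, 1), integer(1)),
                   order = sample(1:2, n_atoms - 1, replace = TRUE, prob = c(0.8, 0.2)))
  } else tibble::tibble(i = integer(), j = integer(), order = integer())
  molecule(tibble::tibble(element = els,
                          x = rnorm(n_atoms), y = rnorm(n_atoms), z = rnorm(n_atoms)),
           bonds, name = "random")
}
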