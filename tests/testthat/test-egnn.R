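test_that("attention scores lie in [0,1], are deterministic, and match a hand-rolled forward pass", {
  p <- tiny_model()
  att <- p$layers[[1]][c("A1", "a1", "A2", "a2")]
  set.seed(9)
  emb <- matrix(rnorm(100 * p$config$hidden_width), 100)
  s <- attention_scores(emb, att)
  expect_true(all(s >= 0 & s <= 1))
  expect_identical(s, attention_scores(emb, att))
  # two identical embeddings -> identical scores
  expect_equal(attention_scores(emb[c(1, 1), ], att)[1],
               attention_scores(emb[c(1, 1), ], att)[2])
  # independent forward computation, element by element
  oracle <- vapply(seq_len(nrow(emb)), function(k) {
    hidden <- numeric(ncol(att$A1))
    for (h in seq_along(hidden)) {
      hidden[h] <- tanh(sum(emb[k, ] * att$A1[, h]) + att$a1[h])
    }
    1 / (1 + exp(-(sum(hidden * att$A2) + att$a2)))
  }, numeric(1))
  expect_equal(s, oracle, tolerance = 1e-12)
  expect_error(attention_scores(matrix(c(1, NaN), 1, 2),
                                list(A1 = matrix(0, 2, 2), a1 = c(0, 0),
                                     A2 = c(0, 0), a2 = 0)),
               "finite")
})

test_that("an edgeless graph reduces the layer to the self-term", {
  p <- tiny_model()
  n <- 4; d <- p$config$hidden_width
  h <- matrix(rnorm(n * d), n, d)
  pos <- matrix(rnorm(n * 3), n, 3)
  out <- egnn_layer(h, pos, matrix(integer(0), 0, 2), matrix(0, 0, 3), p)
  expect_equal(out$m_i, matrix(0, n, d))
  expect_equal(out$positions, pos)
  # self-term: residual + node net applied to [h, 0]
  pl <- p$layers[[1]]
  t1 <- tanh(sweep(cbind(h, matrix(0, n, d)) %*% pl$V1, 2, pl$c1, "+"))
  expect_equal(out$node_features, h + tanh(sweep(t1 %*% pl$V2, 2, pl$c2, "+")))
})

test_that("per-node aggregates equal an explicit loop over edges", {
  p <- tiny_model(n_layers = 1, width = 6)
  g <- random_graph(6, seed = 12)
  d <- p$config$hidden_width
  h <- matrix(rnorm(6 * d), 6, d)
  out <- egnn_layer(h, g$positions, g$edge_index, g$edge_attrs, p)
  m_oracle <- matrix(0, 6, d)
  for (k in seq_len(nrow(g$edge_index))) {
    i <- g$edge_index[k, 1]
    m_oracle[i, ] <- m_oracle[i, ] + out$attention[k] * out$messages[k, ]
  }
  expect_equal(out$m_i, m_oracle, tolerance = 1e-12)
})

test_that("layer updates are equivariant under rigid motions", {
  p <- tiny_model()
  g <- random_graph(9, seed = 4)
  d <- p$config$hidden_width
  h <- matrix(rnorm(9 * d), 9, d)
  base <- egnn_layer(h, g$positions, g$edge_index, g$edge_attrs, p)
  set.seed(5)
  for (rep in 1:5) {
    motion <- random_rigid_motion(reflect = rep %% 2 == 0)
    moved <- egnn_layer(h, apply_motion(g$positions, motion),
                        g$edge_index, g$edge_attrs, p)
    expect_equal(moved$positions, apply_motion(base$positions, motion),
                 tolerance = 1e-8)
    expect_equal(moved$node_features, base$node_features, tolerance = 1e-10)
  }
})

test_that("head outputs respect their ranges and invariances", {
  g <- random_graph(12, seed = 3)
  pose <- init_params(model_config(n_layers = 3, hidden_width = 16, seed = 2,
                                   head = "pose"))
  aff <- init_params(model_config(n_layers = 3, hidden_width = 16, seed = 2,
                                  head = "affinity"))
  sp <- predict_graph(pose, g)$score
  sa <- predict_graph(aff, g)$score
  expect_gte(sp, 0); expect_lte(sp, 1)
  expect_gte(sa, 0)
  set.seed(10)
  for (rep in 1:20) {
    motion <- random_rigid_motion(reflect = rep %% 2 == 0)
    perm <- sample(nrow(g$positions))
    g2 <- permute_graph(transform_graph(g, motion), perm)
    expect_equal(predict_graph(pose, g2)$score, sp, tolerance = 1e-4)
    expect_equal(predict_graph(aff, g2)$score, sa, tolerance = 1e-4)
  }
  expect_error(predict_graph(pose, structure(list(positions = matrix(0, 0, 3)),
                                             class = "complex_graph")),
               "empty")
})

test_that("doubling the layer count preserves shapes and invariances", {
  g <- random_graph(8, seed = 6)
  for (L in c(2, 4)) {
    p <- init_params(model_config(n_layers = L, hidden_width = 8, seed = 1))
    s <- predict_graph(p, g)$score
    expect_length(s, 1)
    motion <- random_rigid_motion()
    expect_equal(predict_graph(p, transform_graph(g, motion))$score, s,
                 tolerance = 1e-6)
  }
})

test_that("forcing an edge's attention to zero equals deleting the edge", {
  set.seed(21)
  for (rep in 1:10) {
    g <- random_graph(sample(6:12, 1))
    p <- tiny_model(seed = rep)
    ei <- g$edge_index
    k <- sample(nrow(ei), 1)
    mate <- which(ei[, 1] == ei[k, 2] & ei[, 2] == ei[k, 1])
    pair <- c(k, mate)
    s_zero <- predict_graph(p, g, zero_edges = pair)$score
    keep <- setdiff(seq_len(nrow(ei)), pair)
    g_del <- g
    g_del$edge_index <- ei[keep, , drop = FALSE]
    g_del$edge_attrs <- g$edge_attrs[keep, , drop = FALSE]
    expect_equal(s_zero, predict_graph(p, g_del)$score, tolerance = 1e-12)
  }
})

test_that("analytic gradients match central finite differences", {
  g <- random_graph(7, seed = 42)
  p <- init_params(model_config(n_layers = 2, hidden_width = 5,
                                attention_hidden = 3, coord_hidden = 3,
                                seed = 7))
  batch <- eqscore:::combine_graphs(list(g, g))
  labels <- c(1, 0)
  lg <- eqscore:::batch_loss_grad(p, batch, labels)
  fg <- eqscore:::flatten_grads(lg$grads)
  fp <- flatten_params(p)
  eps <- 1e-6
  set.seed(1)
  idx <- sort(sample(seq_along(fp), 50))
  num <- vapply(idx, function(i) {
    up <- fp; up[i] <- up[i] + eps
    dn <- fp; dn[i] <- dn[i] - eps
    (eqscore:::batch_loss(unflatten_params(up, p), batch, labels) -
       eqscore:::batch_loss(unflatten_params(dn, p), batch, labels)) / (2 * eps)
  }, numeric(1))
  expect_equal(fg[idx], num, tolerance = 1e-5)
  # affinity head too
  pa <- p; pa$config$head <- "affinity"
  lga <- eqscore:::batch_loss_grad(pa, batch, c(2, 0.5))
  fga <- eqscore:::flatten_grads(lga$grads)
  numa <- vapply(idx, function(i) {
    up <- fp; up[i] <- up[i] + eps
    dn <- fp; dn[i] <- dn[i] - eps
    (eqscore:::batch_loss(unflatten_params(up, pa), batch, c(2, 0.5)) -
       eqscore:::batch_loss(unflatten_params(dn, pa), batch, c(2, 0.5))) / (2 * eps)
  }, numeric(1))
  expect_equal(fga[idx], numa, tolerance = 1e-5)
})

test_that("parameters round-trip bit-exactly through flattening and checkpoints", {
  p <- tiny_model(n_layers = 3, width = 10, seed = 13)
  flat <- flatten_params(p)
  p2 <- unflatten_params(flat, p)
  expect_identical(flatten_params(p2), flat)
  expect_equal(p2$layers, p$layers)
  ckpt <- tempfile(fileext = ".ckpt")
  save_checkpoint(p, ckpt)
  p3 <- load_checkpoint(ckpt)
  expect_identical(flatten_params(p3), flat)
  expect_equal(p3$config$n_layers, p$config$n_layers)
  g <- random_graph(6, seed = 2)
  expect_identical(predict_graph(p3, g)$score, predict_graph(p, g)$score)
})
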