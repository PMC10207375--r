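test_that("generated complexes honor the planted geometry exactly", {
  for (seed in 1:20) {
    spec <- synthetic_spec()
    gen <- generate_complex(spec, seed = seed)
    cx <- gen$complex
    at <- cx$atoms
    # brute-force distance audit
    lig <- which(at$is_ligand); prot <- which(!at$is_ligand)
    planted <- paste(gen$truth$contacts$ligand_atom_id,
                     gen$truth$contacts$protein_atom_id)
    for (i in lig) for (j in prot) {
      d <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
                  (at$z[i] - at$z[j])^2)
      if (paste(at$atom_id[i], at$atom_id[j]) %in% planted) {
        expect_true(abs(d - spec$contact_distance) <= 0.1 + 1e-9)
      } else {
        expect_gte(d, spec$min_noncontact_dist - 1e-9)
      }
    }
    # every protein atom lies in the 6 A pocket of the ligand
    expect_equal(n_atoms(extract_pocket(cx, 6)), n_atoms(cx))
    # planted pairs are complementary donor/acceptor
    roles <- cbind(at$hbond_role[gen$truth$contacts$ligand_atom_id],
                   at$hbond_role[match(gen$truth$contacts$protein_atom_id, at$atom_id)])
    expect_true(all((roles[, 1] == "donor" & roles[, 2] == "acceptor") |
                      (roles[, 1] == "acceptor" & roles[, 2] == "donor")))
  }
})

test_that("generation is deterministic and zero-contact specs carry empty truths", {
  a <- generate_complex(synthetic_spec(), seed = 4)
  b <- generate_complex(synthetic_spec(), seed = 4)
  expect_identical(a, b)
  none <- generate_complex(synthetic_spec(n_planted_contacts = 0), seed = 2)
  expect_equal(nrow(none$truth$contacts), 0)
  expect_equal(none$truth$contact_count, 0)
})

test_that("pose labels are recomputable from the emitted geometry", {
  spec <- synthetic_spec()
  ds <- generate_pose_dataset(spec, 40, seed = 6)
  expect_length(ds$examples, 40)
  expect_equal(nrow(ds$truths), 40)
  expect_true(all(table(ds$truths$label) > 0))
  expect_length(unique(ds$truths$group_id), 20)
  for (k in seq_along(ds$examples)) {
    g <- ds$examples[[k]]$graph
    # re-apply the label rule to the emitted coordinates: a planted contact
    # is intact when its pair sits within hydrogen-bond range
    contacts <- ds$truths$contacts[[k]]
    intact <- 0L
    for (r in seq_len(nrow(contacts))) {
      i <- match(contacts$ligand_atom_id[r], g$source_atom_ids)
      j <- match(contacts$protein_atom_id[r], g$source_atom_ids)
      if (is.na(i) || is.na(j)) next
      d <- sqrt(sum((g$positions[i, ] - g$positions[j, ])^2))
      if (d <= 3.5) intact <- intact + 1L
    }
    expect_equal(ds$examples[[k]]$label,
                 as.integer(intact >= spec$label_rule_k))
    expect_equal(ds$truths$intact[k], intact)
  }
})

test_that("zero decoy perturbation yields all-binder labels", {
  ds <- generate_pose_dataset(synthetic_spec(decoy_perturbation = 0), 10, seed = 2)
  expect_true(all(vapply(ds$examples, function(e) e$label, numeric(1)) == 1))
})

test_that("affinity labels equal contact counts plus bounded noise", {
  spec <- synthetic_spec()
  ds <- generate_affinity_dataset(spec, 30, seed = 3)
  expect_true(all(abs(ds$truths$label - ds$truths$contact_count) <=
                    pmax(5 * spec$noise_sigma, ds$truths$contact_count)))
  expect_true(all(ds$truths$label >= 0))
  expect_gt(length(unique(ds$truths$contact_count)), 2)
})

test_that("screens share one protein and always contact the dominant site", {
  scr <- generate_screen(synthetic_spec(), n_structures = 6, n_sites = 5, seed = 9)
  ref <- NULL
  for (cx in scr$complexes) {
    prot <- cx$atoms[!cx$atoms$is_ligand,
                     c("chain", "residue_index", "atom_name", "x", "y", "z")]
    if (is.null(ref)) ref <- prot else expect_equal(as.data.frame(prot),
                                                    as.data.frame(ref))
  }
  # dominant site contacted in every structure
  for (s in seq_along(scr$complexes)) {
    tr <- scr$truth[scr$truth$structure == s, ]
    cx <- scr$complexes[[s]]
    keys <- paste(cx$atoms$chain, cx$atoms$residue_index, cx$atoms$atom_name,
                  sep = "|")[match(tr$protein_atom_id, cx$atoms$atom_id)]
    expect_true(scr$dominant_key %in% keys)
    # contacts realized at hydrogen-bond range
    li <- match(tr$ligand_atom_id, cx$atoms$atom_id)
    pi_ <- match(tr$protein_atom_id, cx$atoms$atom_id)
    d <- sqrt(rowSums((coords(cx)[li, , drop = FALSE] -
                         coords(cx)[pi_, , drop = FALSE])^2))
    expect_true(all(abs(d - 2.9) <= 0.1 + 1e-9))
  }
})

test_that("fragment enumeration handles the canonical molecules", {
  ethane <- molecule(tibble::tibble(element = c("C", "C"),
                                    x = c(0, 1.5), y = 0, z = 0),
                     tibble::tibble(i = 1, j = 2, order = 1))
  fr <- enumerate_fragments(ethane)
  expect_length(fr, 2)
  for (f in fr) {
    expect_equal(sum(f$fragment$atoms$element == "*"), 1)
    expect_equal(nrow(f$fragment$atoms), 2)  # one C + dummy
  }
  benzene <- molecule(
    tibble::tibble(element = rep("C", 6),
                   x = cos(0:5 * pi / 3), y = sin(0:5 * pi / 3), z = 0),
    tibble::tibble(i = 1:6, j = c(2:6, 1), order = c(1, 2, 1, 2, 1, 2)))
  expect_length(enumerate_fragments(benzene), 0)
})

test_that("fragment sets match a brute-force enumeration on a branched alkane", {
  # 2-methylpentane skeleton: C1-C2-C3-C4-C5 with C6 on C2
  hexane <- molecule(
    tibble::tibble(element = rep("C", 6), x = 1:6, y = 0, z = 0),
    tibble::tibble(i = c(1, 2, 3, 4, 2), j = c(2, 3, 4, 5, 6),
                   order = 1L))
  fr <- enumerate_fragments(hexane)
  # every bond is an acyclic single bond: 5 bonds x 2 sides
  expect_length(fr, 10)
  sizes <- sort(vapply(fr, function(f) nrow(f$fragment$atoms), integer(1)))
  # oracle: cut each tree edge, component sizes + 1 dummy
  g <- igraph::graph_from_edgelist(cbind(c(1, 2, 3, 4, 2), c(2, 3, 4, 5, 6)),
                                   directed = FALSE)
  want <- sort(unlist(lapply(igraph::E(g), function(e) {
    comp <- igraph::components(igraph::delete_edges(g, e))$csize + 1L
    comp
  })))
  expect_equal(sizes, want)
  # every fragment ends in exactly one dummy bonded to the exit atom
  for (f in fr) {
    dummy_idx <- which(f$fragment$atoms$element == "*")
    expect_length(dummy_idx, 1)
    bonds <- f$fragment$bonds
    db <- bonds[bonds$i == dummy_idx | bonds$j == dummy_idx, ]
    expect_equal(nrow(db), 1)
    expect_true(f$exit_atom %in% c(db$i, db$j))
  }
})

test_that("protected functional groups block adjacent cuts", {
  # acetamide CH3-C(=O)-NH2 (heavy atoms): C1-C2(=O3)-N4
  acetamide <- molecule(
    tibble::tibble(element = c("C", "C", "O", "N"),
                   x = c(0, 1.5, 2.1, 2.2), y = c(0, 0, 1.1, -1.1), z = 0),
    tibble::tibble(i = c(1, 2, 2), j = c(2, 3, 4), order = c(1L, 2L, 1L)))
  expect_length(enumerate_fragments(acetamide), 0)
  # without protection, the C1-C2 and C2-N4 single bonds become cuttable
  expect_length(enumerate_fragments(acetamide, protected = character(0)), 4)
  # nitro: CH3-NO2
  nitromethane <- molecule(
    tibble::tibble(element = c("C", "N", "O", "O"),
                   x = c(0, 1.5, 2.2, 2.2), y = c(0, 0, 1, -1), z = 0),
    tibble::tibble(i = c(1, 2, 2), j = c(2, 3, 4), order = c(1L, 2L, 1L)))
  expect_length(enumerate_fragments(nitromethane), 0)
})

test_that("graphs built from synthetic datasets batch consistently", {
  ds <- generate_pose_dataset(synthetic_spec(), 6, seed = 10)
  graphs <- lapply(ds$examples, function(e) e$graph)
  batch <- eqscore:::combine_graphs(graphs)
  p <- tiny_model()
  out <- eqscore:::egnn_forward(p, batch)
  singles <- vapply(graphs, function(g) predict_graph(p, g)$score, numeric(1))
  expect_equal(out$output, singles, tolerance = 1e-10)
})
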