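test_that("identical ligands are removed, disjoint ligands kept", {
  eth <- molecule(tibble::tibble(element = c("C", "C"), x = c(0, 1.5), y = 0, z = 0),
                  tibble::tibble(i = 1, j = 2, order = 1))
  nn <- molecule(tibble::tibble(element = c("N", "N", "N"),
                                x = c(0, 1.2, 2.4), y = 0, z = 0),
                 tibble::tibble(i = c(1, 2), j = c(2, 3), order = c(2, 1)))
  man <- ligand_similarity_filter(list(same = eth, other = nn), list(t1 = eth))
  m <- man$manifest
  expect_false(m$kept[m$id == "same"])
  expect_equal(m$similarity[m$id == "same"], 1.0)
  expect_equal(m$offending_test_id[m$id == "same"], "t1")
  expect_true(m$kept[m$id == "other"])
  expect_equal(m$similarity[m$id == "other"], 0.0)
  # partition invariant
  expect_setequal(c(kept_ids(man), removed_ids(man)), c("same", "other"))
})

test_that("unparseable ligands are removed with reason parse_failure", {
  eth <- molecule(tibble::tibble(element = c("C", "C"), x = c(0, 1.5), y = 0, z = 0),
                  tibble::tibble(i = 1, j = 2, order = 1))
  bad <- tempfile(fileext = ".sdf")
  writeLines("garbage", bad)
  man <- ligand_similarity_filter(list(ok = eth, broken = bad), list(t = eth))
  m <- man$manifest
  expect_equal(m$reason[m$id == "broken"], "parse_failure")
  expect_false(m$kept[m$id == "broken"])
})

test_that("the similarity filter matches an exhaustive pairwise-Tanimoto oracle", {
  set.seed(501)
  train <- lapply(1:20, function(i) random_molecule(sample(4:9, 1)))
  names(train) <- paste0("tr", 1:20)
  test <- lapply(1:6, function(i) random_molecule(sample(4:9, 1)))
  # make sure some removals occur: copy two test molecules into train
  train[["tr1"]] <- test[[1]]; train[["tr2"]] <- test[[3]]
  names(test) <- paste0("te", 1:6)
  man <- ligand_similarity_filter(train, test, threshold = 0.8)
  fps_train <- lapply(train, morgan_fingerprint)
  fps_test <- lapply(test, morgan_fingerprint)
  kept_oracle <- character(0)
  for (id in names(train)) {
    mx <- 0
    for (t in names(test)) {
      inter <- length(intersect(fps_train[[id]], fps_test[[t]]))
      uni <- length(union(fps_train[[id]], fps_test[[t]]))
      mx <- max(mx, if (uni == 0) 0 else inter / uni)
    }
    if (!(mx > 0.8)) kept_oracle <- c(kept_oracle, id)
  }
  expect_setequal(kept_ids(man), kept_oracle)
  expect_true(all(c("tr1", "tr2") %in% removed_ids(man)))
})

test_that("fingerprints are invariant to atom order and coordinates", {
  set.seed(31)
  mol <- random_molecule(8)
  fp <- morgan_fingerprint(mol)
  # coordinates are irrelevant (topological fingerprint)
  mol2 <- mol
  mol2$atoms$x <- rnorm(8)
  expect_identical(morgan_fingerprint(mol2), fp)
  # relabeling atoms consistently leaves the fingerprint unchanged
  perm <- sample(8)
  inv <- order(perm)
  mol3 <- molecule(mol$atoms[perm, ],
                   tibble::tibble(i = inv[mol$bonds$i], j = inv[mol$bonds$j],
                                  order = mol$bonds$order))
  expect_identical(morgan_fingerprint(mol3), fp)
})

test_that("identical sequences are removed and dissimilar ones kept", {
  man <- sequence_identity_filter(
    list(dup = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
         far = "GGGGGGGGPPPPPPPPWWWWWWWW"),
    list(t1 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"))
  m <- man$manifest
  expect_false(m$kept[m$id == "dup"])
  expect_equal(m$similarity[m$id == "dup"], 1.0)
  expect_true(m$kept[m$id == "far"])
  expect_lt(m$similarity[m$id == "far"], 0.8)
  # empty sequence -> parse failure
  man2 <- sequence_identity_filter(list(empty = ""), list(t = "MKTA"))
  expect_equal(man2$manifest$reason, "parse_failure")
})

test_that("alignment scores match an independent Gotoh dynamic program", {
  set.seed(71)
  aas <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P",
           "S","T","W","Y","V")
  for (rep in 1:10) {
    a <- paste(sample(aas, 50, replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(30:60, 1), replace = TRUE), collapse = "")
    got <- attr(sequence_identity(a, b), "score")
    expect_equal(got, gotoh_score(a, b), tolerance = 1e-9)
  }
})

test_that("identity decisions agree with the oracle away from the threshold", {
  set.seed(72)
  aas <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P",
           "S","T","W","Y","V")
  mutate_seq <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    idx <- sample(length(v), k)
    v[idx] <- sample(aas, k, replace = TRUE)
    paste(v, collapse = "")
  }
  base <- paste(sample(aas, 60, replace = TRUE), collapse = "")
  train <- list(near = mutate_seq(base, 3),     # ~95% identical
                mid = mutate_seq(base, 30),     # ~50-60%
                far = paste(sample(aas, 60, replace = TRUE), collapse = ""))
  man <- sequence_identity_filter(train, list(t = base), threshold = 0.8)
  m <- man$manifest
  expect_false(m$kept[m$id == "near"])
  expect_true(m$kept[m$id == "mid"])
  expect_true(m$kept[m$id == "far"])
})

test_that("multi-chain proteins use the maximum identity over chain pairs", {
  base <- "MKTAYIAKQRQISFVKSHFSRQ"
  man <- sequence_identity_filter(
    list(multi = c("GGGGGGGGGGGGGGGGGG", base)),
    list(t = base))
  expect_false(man$manifest$kept[1])
  expect_equal(man$manifest$similarity[1], 1.0)
})

test_that("the two filters commute on the kept set", {
  set.seed(91)
  mols <- lapply(1:8, function(i) random_molecule(6))
  names(mols) <- paste0("id", 1:8)
  mols[["id2"]] <- mols[["id1"]]
  aas <- c("A","R","N","D","C","Q","E","G")
  seqs <- lapply(1:8, function(i) paste(sample(aas, 30, replace = TRUE), collapse = ""))
  names(seqs) <- names(mols)
  seqs[["id5"]] <- seqs[["id1"]]
  test_mol <- list(t = mols[["id1"]])
  test_seq <- list(t = seqs[["id1"]])
  k_lig <- kept_ids(ligand_similarity_filter(mols, test_mol))
  k_seq <- kept_ids(sequence_identity_filter(seqs, test_seq))
  ab <- intersect(kept_ids(sequence_identity_filter(seqs[k_lig], test_seq)), k_lig)
  ba <- intersect(kept_ids(ligand_similarity_filter(mols[k_seq], test_mol)), k_seq)
  expect_setequal(ab, ba)
  expect_setequal(ab, intersect(k_lig, k_seq))
})

test_that("random matched subsets are exact-size, reproducible and uniform", {
  ids <- sprintf("id%02d", 1:12)
  man <- random_matched_subset(ids, 12, seed = 1)
  expect_setequal(kept_ids(man), ids)
  m1 <- random_matched_subset(ids, 5, seed = 7)
  m2 <- random_matched_subset(ids, 5, seed = 7)
  expect_identical(kept_ids(m1), kept_ids(m2))
  expect_length(kept_ids(m1), 5)
  expect_error(random_matched_subset(ids, 13), "exceeds")
  # inclusion frequency ~ target/n within 3 binomial sigma over many seeds
  n_seeds <- 1000
  counts <- stats::setNames(numeric(12), ids)
  for (s in seq_len(n_seeds)) {
    counts[kept_ids(random_matched_subset(ids, 5, seed = s))] <-
      counts[kept_ids(random_matched_subset(ids, 5, seed = s))] + 1
  }
  p <- 5 / 12
  sigma <- sqrt(n_seeds * p * (1 - p))
  expect_true(all(abs(counts - n_seeds * p) <= 3 * sigma))
})
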