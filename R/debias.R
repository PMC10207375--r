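#' @name debias
#' @title Train/test leakage filters
#' @description Memorization of dataset biases inflates benchmark numbers;
#' removing training items too similar to the test set measures what a
#' model actually generalizes. Two filters operate on the training side
#' only: a ligand filter removing molecules whose circular-fingerprint
#' Tanimoto similarity to any test ligand exceeds a threshold, and a
#' protein filter removing chains whose global-alignment sequence identity
#' to any test protein exceeds a threshold. Size-matched random subsets
#' provide the control that separates debiasing effects from data-reduction
#' effects.
NULL

# --- circular (Morgan-style) fingerprints ----------------------------------

.element_numbers <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, P = 15,
                      S = 16, Cl = 17, Br = 35, I = 53)

# Deterministic polynomial hash of an integer vector (mod a prime below
# 2^29, exact in double arithmetic).
hash_ints <- function(v) {
  p <- 536870909
  h <- 17
  for (x in v) h <- (h * 31 + (x %% p)) %% p
  h
}

#' Circular substructure fingerprint of a molecule
#'
#' An ECFP-style fingerprint: each atom starts from an invariant of
#' (element, heavy degree, total bond order, formal charge); `radius`
#' rounds of neighborhood hashing grow the environments, and every
#' environment identifier from every round is folded into a fixed-width bit
#' vector.
#'
#' @param mol A `molecule`.
#' @param bits Fingerprint width (default 2048).
#' @param radius Neighborhood radius (default 2, the conventional choice
#'   for a "radius-2, 2048-bit" circular fingerprint).
#' @return Sorted integer vector of on-bit positions (1-based).
#' @export
morgan_fingerprint <- function(mol, bits = 2048L, radius = 2L) {
  stopifnot(inherits(mol, "molecule"))
  a <- mol$atoms; b <- mol$bonds
  n <- nrow(a)
  nbrs <- vector("list", n)
  border <- vector("list", n)
  if (nrow(b) > 0) {
    for (r in seq_len(nrow(b))) {
      i <- b$i[r]; j <- b$j[r]; o <- b$order[r]
      nbrs[[i]] <- c(nbrs[[i]], j); border[[i]] <- c(border[[i]], o)
      nbrs[[j]] <- c(nbrs[[j]], i); border[[j]] <- c(border[[j]], o)
    }
  }
  elno <- .element_numbers[a$element]
  elno[is.na(elno)] <- 0
  deg <- lengths(nbrs)
  bsum <- vapply(border, function(x) sum(x %||% 0L), numeric(1))
  ids <- vapply(seq_len(n), function(i) {
    hash_ints(c(elno[i], deg[i], bsum[i], round(a$charge[i] * 10)))
  }, numeric(1))
  all_ids <- ids
  if (radius >= 1) {
    for (r in seq_len(radius)) {
      new_ids <- vapply(seq_len(n), function(i) {
        if (deg[i] == 0) return(hash_ints(c(r, ids[i])))
        env <- cbind(border[[i]], ids[nbrs[[i]]])
        env <- env[order(env[, 1], env[, 2]), , drop = FALSE]
        hash_ints(c(r, ids[i], as.numeric(t(env))))
      }, numeric(1))
      ids <- new_ids
      all_ids <- c(all_ids, ids)
    }
  }
  sort(unique(as.integer(all_ids %% bits) + 1L))
}

#' Tanimoto similarity of two bit sets
#'
#' @param fp1,fp2 On-bit position vectors (as returned by
#'   [morgan_fingerprint()]).
#' @return Intersection over union; 0 when both are empty.
#' @export
tanimoto <- function(fp1, fp2) {
  u <- length(union(fp1, fp2))
  if (u == 0) return(0)
  length(intersect(fp1, fp2)) / u
}

split_manifest <- function(ids, kept, reason, similarity, offending,
                           thresholds, seed = NA_integer_) {
  structure(list(
    manifest = tibble::tibble(id = ids, kept = kept, reason = reason,
                              similarity = similarity,
                              offending_test_id = offending),
    thresholds = thresholds, seed = seed),
    class = "split_manifest")
}

#' @export
print.split_manifest <- function(x, ...) {
  cat(sprintf("<split_manifest> %d kept, %d removed\n",
              sum(x$manifest$kept), sum(!x$manifest$kept)))
  print(x$manifest, n = 6)
  invisible(x)
}

#' Kept / removed ids of a split manifest
#' @param x A `split_manifest`.
#' @return Character vector of ids.
#' @export
kept_ids <- function(x) x$manifest$id[x$manifest$kept]

#' @rdname kept_ids
#' @export
removed_ids <- function(x) x$manifest$id[!x$manifest$kept]

#' Tidy a split manifest
#' @param x A `split_manifest`.
#' @param ... Unused.
#' @return The manifest tibble.
#' @method tidy split_manifest
#' @export
tidy.split_manifest <- function(x, ...) x$manifest

resolve_molecules <- function(objs) {
  lapply(objs, function(o) {
    if (inherits(o, "molecule")) return(o)
    if (is.character(o) && length(o) == 1L) {
      return(tryCatch(read_molecule_sdf(o), error = function(e) NULL))
    }
    NULL
  })
}

#' Ligand similarity filter
#'
#' Removes every training ligand whose maximum fingerprint Tanimoto
#' similarity over all test ligands is strictly greater than `threshold`.
#' Only training items are ever removed; test items pass through untouched.
#' Unparseable training ligands are removed with reason `parse_failure`.
#'
#' @param train_ligands Named list of `molecule` objects (or SDF paths).
#' @param test_ligands Named list of `molecule` objects (or SDF paths);
#'   unparseable test ligands are skipped from the comparison.
#' @param threshold Similarity cutoff (default 0.8, strict `>`).
#' @param fp_bits,fp_radius Fingerprint parameters (defaults 2048 bits,
#'   radius 2).
#' @return A `split_manifest` recording, per removed item, the maximum
#'   similarity and the test id achieving it.
#' @export
ligand_similarity_filter <- function(train_ligands, test_ligands,
                                     threshold = 0.8, fp_bits = 2048L,
                                     fp_radius = 2L) {
  stopifnot(threshold > 0, threshold <= 1)
  train_ids <- names(train_ligands) %||% as.character(seq_along(train_ligands))
  test_ids <- names(test_ligands) %||% as.character(seq_along(test_ligands))
  train_mols <- resolve_molecules(train_ligands)
  test_mols <- resolve_molecules(test_ligands)
  ok_test <- !vapply(test_mols, is.null, logical(1))
  test_fps <- lapply(test_mols[ok_test], morgan_fingerprint,
                     bits = fp_bits, radius = fp_radius)
  test_ids_ok <- test_ids[ok_test]
  n <- length(train_mols)
  kept <- logical(n); reason <- rep(NA_character_, n)
  simmax <- rep(NA_real_, n); offender <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (is.null(train_mols[[i]])) {
      kept[i] <- FALSE; reason[i] <- "parse_failure"
      next
    }
    fp <- morgan_fingerprint(train_mols[[i]], bits = fp_bits, radius = fp_radius)
    sims <- vapply(test_fps, tanimoto, numeric(1), fp1 = fp)
    if (length(sims) == 0) { kept[i] <- TRUE; next }
    simmax[i] <- max(sims)
    offender[i] <- test_ids_ok[which.max(sims)]
    if (simmax[i] > threshold) {
      kept[i] <- FALSE; reason[i] <- "ligand_similarity"
    } else {
      kept[i] <- TRUE
      offender[i] <- NA_character_
    }
  }
  split_manifest(train_ids, kept, reason, simmax, offender,
                 thresholds = list(ligand_similarity = threshold,
                                   fp_bits = fp_bits, fp_radius = fp_radius))
}

# --- sequence identity -----------------------------------------------------

aa_substitution_matrix <- function(match = 1, mismatch = 0) {
  letters <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P",
               "S","T","W","Y","V","B","J","Z","X","*")
  m <- matrix(mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- match
  m
}

#' Global sequence identity between two protein sequences
#'
#' Needleman-Wunsch global alignment with match 1, mismatch 0 and affine
#' gaps (opening 10, extension 0.5); identity is the number of identical
#' aligned positions divided by the alignment length (gaps included), or by
#' the shorter sequence length when `denominator = "shorter"`.
#'
#' @param a,b Amino-acid sequences as character strings.
#' @param denominator `"alignment"` (default) or `"shorter"`.
#' @return Identity in \[0,1\], with the alignment score as attribute
#'   `"score"`.
#' @export
sequence_identity <- function(a, b, denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = aa_substitution_matrix(),
    gapOpening = 10, gapExtension = 0.5)
  pid_type <- if (denominator == "alignment") "PID1" else "PID3"
  structure(Biostrings::pid(al, type = pid_type) / 100,
            score = Biostrings::score(al))
}

#' Protein sequence identity filter
#'
#' Removes every training protein whose maximum global-alignment identity
#' over all test proteins is strictly greater than `threshold`. Multi-chain
#' entries (character vectors of length > 1) use the maximum identity over
#' chain pairs. Empty or missing sequences are removed with reason
#' `parse_failure`.
#'
#' @param train_seqs Named list (or character vector) of training
#'   sequences; each element may hold several chains.
#' @param test_seqs Named list/vector of test sequences.
#' @param threshold Identity cutoff (default 0.8, strict `>`).
#' @param denominator Passed to [sequence_identity()].
#' @return A `split_manifest`.
#' @export
sequence_identity_filter <- function(train_seqs, test_seqs, threshold = 0.8,
                                     denominator = "alignment") {
  train_ids <- names(train_seqs) %||% as.character(seq_along(train_seqs))
  test_ids <- names(test_seqs) %||% as.character(seq_along(test_seqs))
  as_chains <- function(x) {
    ch <- unlist(x, use.names = FALSE)
    ch[!is.na(ch) & nchar(ch) > 0 & grepl("^[A-Za-z*]+$", ch)]
  }
  test_chains <- lapply(test_seqs, as_chains)
  n <- length(train_seqs)
  kept <- logical(n); reason <- rep(NA_character_, n)
  simmax <- rep(NA_real_, n); offender <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    chains <- as_chains(train_seqs[[i]])
    if (length(chains) == 0L) {
      kept[i] <- FALSE; reason[i] <- "parse_failure"
      next
    }
    best <- -Inf; best_id <- NA_character_
    for (t in seq_along(test_chains)) {
      for (tc in test_chains[[t]]) {
        for (trc in chains) {
          id <- as.numeric(sequence_identity(trc, tc, denominator))
          if (id > best) { best <- id; best_id <- test_ids[t] }
        }
      }
    }
    if (!is.finite(best)) { kept[i] <- TRUE; next }
    simmax[i] <- best
    if (best > threshold) {
      kept[i] <- FALSE; reason[i] <- "sequence_identity"; offender[i] <- best_id
    } else {
      kept[i] <- TRUE
    }
  }
  split_manifest(train_ids, kept, reason, simmax, offender,
                 thresholds = list(sequence_identity = threshold,
                                   denominator = denominator))
}

#' Size-matched random training subset
#'
#' Uniform sample without replacement, reproducible by seed — the control
#' sets that are the same size as a filtered set but may still contain
#' structures similar to the test set.
#'
#' @param train_ids Character vector of training ids.
#' @param target_size Subset size.
#' @param seed Integer seed.
#' @return A `split_manifest` (removed items carry reason
#'   `random_subset`).
#' @export
random_matched_subset <- function(train_ids, target_size, seed = 1L) {
  if (target_size > length(train_ids)) {
    stop("target_size exceeds the number of training ids", call. = FALSE)
  }
  keep_idx <- with_seed(seed, sample(length(train_ids), target_size))
  kept <- seq_along(train_ids) %in% keep_idx
  split_manifest(train_ids, kept,
                 ifelse(kept, NA_character_, "random_subset"),
                 rep(NA_real_, length(train_ids)),
                 rep(NA_character_, length(train_ids)),
                 thresholds = list(target_size = target_size), seed = seed)
}

#' Write a split manifest to CSV plus a JSON summary
#'
#' @param x A `split_manifest`.
#' @param csv_path,json_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_manifest <- function(x, csv_path, json_path) {
  utils::write.csv(x$manifest, csv_path, row.names = FALSE)
  jsonlite::write_json(list(
    n_total = nrow(x$manifest), n_kept = sum(x$manifest$kept),
    n_removed = sum(!x$manifest$kept),
    removal_reasons = as.list(table(x$manifest$reason[!x$manifest$kept])),
    thresholds = x$thresholds), json_path, auto_unbox = TRUE, digits = NA)
  invisible(list(csv = csv_path, json = json_path))
}
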