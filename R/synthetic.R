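#' Specification for synthetic protein-ligand complexes
#'
#' The generator emulates the statistical structure the attribution and
#' hotspot machinery assumes: a compact ligand bound in a protein pocket,
#' with a known set of planted donor-acceptor contacts at hydrogen-bond
#' range driving the label, and every non-planted ligand-protein pair kept
#' beyond hydrogen-bond range. Contact sites sit on well-separated
#' (icosahedral) directions so the geometric constraints hold by
#' construction; a full distance audit runs after generation and fails
#' loudly if they do not.
#'
#' @param n_ligand_atoms Total ligand atoms (contact atoms + apolar core).
#' @param n_pocket_atoms Total protein atoms (contact partners + shell).
#' @param n_planted_contacts Number of planted donor-acceptor contacts.
#' @param contact_distance Planted contact length in Angstrom (default 2.9,
#'   a typical hydrogen bond); realized as `contact_distance +/- 0.1`.
#' @param min_noncontact_dist Minimum allowed distance for all non-planted
#'   ligand-protein pairs (default 4.5 Angstrom).
#' @param decoy_perturbation Rigid-body displacement applied to the ligand
#'   to form decoy poses (default 3.0 Angstrom).
#' @param label_rule_k Minimum intact contacts for the binder label
#'   (default 2).
#' @param noise_sigma Gaussian noise on synthetic affinity labels
#'   (default 0.1).
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_ligand_atoms = 8L, n_pocket_atoms = 16L,
                           n_planted_contacts = 3L, contact_distance = 2.9,
                           min_noncontact_dist = 4.5,
                           decoy_perturbation = 3.0, label_rule_k = 2L,
                           noise_sigma = 0.1) {
  stopifnot(n_ligand_atoms >= 1, n_pocket_atoms >= 1,
            n_planted_contacts >= 0,
            n_planted_contacts <= min(n_ligand_atoms, n_pocket_atoms),
            contact_distance > 0, contact_distance < 6,
            decoy_perturbation >= 0, label_rule_k >= 0, noise_sigma >= 0)
  if (n_planted_contacts > 6L) {
    stop("at most 6 planted contacts are geometrically feasible on the contact shell",
         call. = FALSE)
  }
  structure(list(n_ligand_atoms = as.integer(n_ligand_atoms),
                 n_pocket_atoms = as.integer(n_pocket_atoms),
                 n_planted_contacts = as.integer(n_planted_contacts),
                 contact_distance = contact_distance,
                 min_noncontact_dist = min_noncontact_dist,
                 decoy_perturbation = decoy_perturbation,
                 label_rule_k = as.integer(label_rule_k),
                 noise_sigma = noise_sigma),
            class = "synthetic_spec")
}

# Unit icosahedron vertices: 12 directions with 63.43 degrees minimum
# pairwise separation. Contact sites use these so that planted contacts and
# the non-contact clearance can coexist.
icosahedron_directions <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
    c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
    c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1)
  )
  v / sqrt(rowSums(v^2))
}

.geom <- list(contact_shell = 2.5,   # radius of contact ligand atoms
              core_radius = 0.5,     # apolar ligand core ball
              shell_min = 5.05, shell_max = 5.45)  # apolar protein shell

# Rejection-sample `n` shell positions with every position at least
# `clearance` from each row of `avoid` (the polar ligand atoms).
sample_shell <- function(n, avoid, clearance) {
  out <- matrix(0, 0, 3)
  guard <- 0L
  while (nrow(out) < n) {
    guard <- guard + 1L
    if (guard > 20000L) {
      stop("infeasible geometry: cannot place pocket shell clear of contact sites",
           call. = FALSE)
    }
    p <- as.numeric(random_unit(1L)) * stats::runif(1, .geom$shell_min, .geom$shell_max)
    if (nrow(avoid) > 0 &&
        min(sqrt(rowSums(sweep(avoid, 2, p)^2))) < clearance) next
    out <- rbind(out, p)
  }
  out
}

random_unit <- function(n = 1L) {
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

#' Generate one synthetic complex with planted contacts
#'
#' Ligand atoms form a compact cluster (an apolar core plus one polar atom
#' per planted contact); protein atoms sit on a surrounding shell. Each
#' planted contact is a complementary donor-acceptor pair at
#' `contact_distance +/- 0.1` Angstrom; every other ligand-protein pair is
#' at least `min_noncontact_dist` apart. Reproducible by seed.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @param complex_id Identifier for the emitted complex.
#' @return A list with `complex` (pocket applied) and `truth` (a
#'   `planted_truth`: tibble of contacts, the true label and contact count).
#' @export
generate_complex <- function(spec = synthetic_spec(), seed = 1L,
                             complex_id = sprintf("synth_%d", seed)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(seed, generate_complex_impl(spec, complex_id))
}

generate_complex_impl <- function(spec, complex_id,
                                  site_dirs = NULL, contact_mask = NULL,
                                  shell_pos = NULL) {
  nc <- spec$n_planted_contacts
  dirs <- if (is.null(site_dirs)) {
    ico <- icosahedron_directions()
    ico[sample(nrow(ico), max(nc, 1L))[seq_len(nc)], , drop = FALSE]
  } else site_dirs
  if (is.null(contact_mask)) contact_mask <- rep(TRUE, nc)

  # polar ligand atoms on the contact shell; alternating donor/acceptor
  lig_contact_pos <- dirs * .geom$contact_shell
  lig_el <- rep(c("N", "O"), length.out = nc)
  lig_role <- rep(c("donor", "acceptor"), length.out = nc)

  # apolar ligand core
  n_core <- spec$n_ligand_atoms - nc
  core <- if (n_core > 0) {
    random_unit(n_core) * stats::runif(n_core, 0, .geom$core_radius)
  } else matrix(0, 0, 3)

  # protein contact partners, complementary role, along the same direction
  d_real <- spec$contact_distance + stats::runif(nc, -0.1, 0.1)
  prot_contact_pos <- lig_contact_pos + dirs * d_real
  prot_el <- ifelse(lig_role == "donor", "O", "N")
  prot_role <- ifelse(lig_role == "donor", "acceptor", "donor")

  # apolar protein shell, kept clear of every polar ligand atom
  n_shell <- spec$n_pocket_atoms - nc
  if (is.null(shell_pos)) {
    shell_pos <- sample_shell(n_shell, lig_contact_pos,
                              spec$min_noncontact_dist + 0.05)
  }

  lig <- tibble::tibble(
    element = c(lig_el, rep("C", n_core)),
    x = c(lig_contact_pos[, 1], core[, 1]),
    y = c(lig_contact_pos[, 2], core[, 2]),
    z = c(lig_contact_pos[, 3], core[, 3]),
    is_ligand = TRUE,
    atom_name = paste0(c(lig_el, rep("C", n_core)), seq_len(spec$n_ligand_atoms)),
    residue_name = "", residue_index = NA_integer_, chain = "",
    hbond_role = c(lig_role, rep("none", n_core))
  )
  n_prot <- nc + nrow(shell_pos)
  prot <- tibble::tibble(
    element = c(prot_el, rep("C", nrow(shell_pos))),
    x = c(prot_contact_pos[, 1], shell_pos[, 1]),
    y = c(prot_contact_pos[, 2], shell_pos[, 2]),
    z = c(prot_contact_pos[, 3], shell_pos[, 3]),
    is_ligand = FALSE,
    atom_name = c(if (nc > 0) paste0(prot_el, "D") else character(0),
                  rep("CA", nrow(shell_pos))),
    residue_name = c(rep("SIT", nc), rep("GLY", nrow(shell_pos))),
    residue_index = seq_len(n_prot),
    chain = "A",
    hbond_role = c(prot_role, rep("none", nrow(shell_pos)))
  )
  atoms <- dplyr::bind_rows(lig, prot)
  atoms$atom_id <- seq_len(nrow(atoms))
  cx <- complex(atoms, complex_id = complex_id, pocket_applied = TRUE)

  contacts_all <- tibble::tibble(
    ligand_atom_id = seq_len(nc),
    protein_atom_id = spec$n_ligand_atoms + seq_len(nc),
    distance = d_real
  )
  # audit against every planted pair (the mask only restricts which pairs
  # count as contacts in the emitted truth, not which atoms exist)
  audit_complex(cx, contacts_all, spec)
  contacts <- contacts_all[contact_mask, , drop = FALSE]
  truth <- structure(list(
    contacts = contacts,
    contact_count = nrow(contacts),
    label = as.integer(nrow(contacts) >= spec$label_rule_k)
  ), class = "planted_truth")
  list(complex = cx, truth = truth)
}

# Exhaustive distance audit of the planted geometry.
audit_complex <- function(cx, contacts, spec) {
  pos <- coords(cx)
  lig <- cx$atoms$is_ligand
  d <- sqrt(outer(rowSums(pos[lig, , drop = FALSE]^2),
                  rowSums(pos[!lig, , drop = FALSE]^2), "+") -
            2 * pos[lig, , drop = FALSE] %*% t(pos[!lig, , drop = FALSE]))
  lig_ids <- cx$atoms$atom_id[lig]
  prot_ids <- cx$atoms$atom_id[!lig]
  planted <- matrix(FALSE, sum(lig), sum(!lig))
  if (nrow(contacts)) {
    planted[cbind(match(contacts$ligand_atom_id, lig_ids),
                  match(contacts$protein_atom_id, prot_ids))] <- TRUE
  }
  if (nrow(contacts) &&
      any(abs(d[planted] - spec$contact_distance) > 0.1 + 1e-9)) {
    stop("generation audit failed: planted contact outside tolerance", call. = FALSE)
  }
  if (any(d[!planted] < spec$min_noncontact_dist - 1e-9)) {
    stop("infeasible geometry: non-contact ligand-protein pair below clearance",
         call. = FALSE)
  }
  invisible(TRUE)
}

# Count planted contacts still intact (within `intact_dist`) in a complex
# whose ligand may have been perturbed.
intact_contacts <- function(cx, contacts, intact_dist = 3.5) {
  if (nrow(contacts) == 0L) return(0L)
  at <- cx$atoms
  li <- match(contacts$ligand_atom_id, at$atom_id)
  pi_ <- match(contacts$protein_atom_id, at$atom_id)
  ok <- !is.na(li) & !is.na(pi_)
  if (!any(ok)) return(0L)
  p <- coords(cx)
  d <- sqrt(rowSums((p[li[ok], , drop = FALSE] - p[pi_[ok], , drop = FALSE])^2))
  sum(d <= intact_dist)
}

shift_ligand <- function(cx, shift) {
  lig <- cx$atoms$is_ligand
  cx$atoms$x[lig] <- cx$atoms$x[lig] + shift[1]
  cx$atoms$y[lig] <- cx$atoms$y[lig] + shift[2]
  cx$atoms$z[lig] <- cx$atoms$z[lig] + shift[3]
  cx
}

#' Generate a labeled pose-classification dataset
#'
#' Each system contributes a binder pose (planted contacts intact) and a
#' decoy pose (ligand rigidly displaced by `decoy_perturbation`, breaking at
#' least one contact). The label is 1 iff at least `label_rule_k` planted
#' contacts remain within hydrogen-bond range (3.5 Angstrom) in the emitted
#' geometry, so labels are always recomputable from coordinates alone.
#'
#' The pocket is defined once per system from the reference (binder) pose
#' and shared by its decoy, as for a fixed set of binding-site residues:
#' binder and decoy therefore present identical atom sets and differ only in
#' ligand placement, so nothing but geometry separates the classes.
#'
#' @param spec A [synthetic_spec()].
#' @param n_examples Number of examples (systems = `n_examples / 2`).
#' @param seed Integer seed.
#' @return List with `examples` (list of [labeled_example()]) and `truths`
#'   (tibble: group, pose type, intact contact count, label, planted
#'   contacts).
#' @export
generate_pose_dataset <- function(spec = synthetic_spec(), n_examples = 200L,
                                  seed = 1L) {
  stopifnot(n_examples >= 2)
  n_sys <- ceiling(n_examples / 2)
  examples <- list(); truths <- list()
  for (s in seq_len(n_sys)) {
    gen <- generate_complex(spec, seed = seed * 100000L + s,
                            complex_id = sprintf("sys%d", s))
    poses <- with_seed(seed * 100000L + 50000L + s, {
      decoy <- NULL
      for (try in 1:50) {
        cand <- shift_ligand(gen$complex,
                             as.numeric(random_unit(1L)) * spec$decoy_perturbation)
        n_int <- intact_contacts(cand, gen$truth$contacts)
        if (spec$decoy_perturbation == 0 ||
            n_int < gen$truth$contact_count || gen$truth$contact_count == 0L) {
          decoy <- cand
          break
        }
      }
      if (is.null(decoy)) stop("could not break a contact with the configured decoy perturbation",
                               call. = FALSE)
      list(binder = gen$complex, decoy = decoy)
    })
    for (kind in names(poses)) {
      cx <- poses[[kind]]
      n_int <- intact_contacts(cx, gen$truth$contacts)
      label <- as.integer(n_int >= spec$label_rule_k)
      examples[[length(examples) + 1L]] <-
        labeled_example(featurize(cx), label, group_id = sprintf("sys%d", s))
      truths[[length(truths) + 1L]] <- tibble::tibble(
        group_id = sprintf("sys%d", s), pose = kind,
        intact = n_int, label = label,
        contacts = list(gen$truth$contacts))
    }
  }
  keep <- seq_len(n_examples)
  truths <- dplyr::bind_rows(truths)[keep, ]
  labels <- truths$label
  if (spec$decoy_perturbation > 0 && length(unique(labels)) < 2L) {
    stop("generated dataset is single-class; adjust decoy_perturbation/label_rule_k",
         call. = FALSE)
  }
  list(examples = examples[keep], truths = truths)
}

#' Generate a labeled affinity-regression dataset
#'
#' One system per example; the planted contact count is drawn uniformly
#' between 0 and `spec$n_planted_contacts` and the label is that count plus
#' Gaussian noise (`spec$noise_sigma`), floored at zero so labels remain
#' valid affinities.
#'
#' @inheritParams generate_pose_dataset
#' @return List with `examples` and `truths` (tibble with the true contact
#'   counts).
#' @export
generate_affinity_dataset <- function(spec = synthetic_spec(), n_examples = 200L,
                                      seed = 1L) {
  stopifnot(n_examples >= 2)
  examples <- list(); truths <- list()
  for (s in seq_len(n_examples)) {
    sp <- spec
    sp$n_planted_contacts <- with_seed(seed * 200000L + s,
                                       sample(0:spec$n_planted_contacts, 1))
    gen <- generate_complex(sp, seed = seed * 300000L + s,
                            complex_id = sprintf("aff%d", s))
    label <- with_seed(seed * 400000L + s,
                       max(0, gen$truth$contact_count +
                             stats::rnorm(1, 0, spec$noise_sigma)))
    examples[[s]] <- labeled_example(featurize(gen$complex), label,
                                     group_id = sprintf("aff%d", s))
    truths[[s]] <- tibble::tibble(group_id = sprintf("aff%d", s),
                                  contact_count = gen$truth$contact_count,
                                  label = label)
  }
  list(examples = examples, truths = dplyr::bind_rows(truths))
}

#' Generate a synthetic fragment screen against one fixed pocket
#'
#' All structures share one protein (identical shell and contact-site
#' atoms, so cross-structure atom keys match); each structure binds a
#' different synthetic ligand contacting a random subset of the candidate
#' sites. Site 1 (the dominant site) is contacted in every structure.
#'
#' @param spec A [synthetic_spec()]; its ligand/pocket sizes set the
#'   per-structure geometry.
#' @param n_structures Number of bound structures in the screen.
#' @param n_sites Number of candidate contact sites (2..12).
#' @param contact_prob Probability that a non-dominant site is contacted in
#'   a given structure.
#' @param seed Integer seed.
#' @return List with `complexes`, `truth` (per-structure contact tibble) and
#'   `dominant_key` (the always-contacted protein atom's chain|residue|name
#'   key).
#' @export
generate_screen <- function(spec = synthetic_spec(), n_structures = 10L,
                            n_sites = 6L, contact_prob = 0.35, seed = 1L) {
  stopifnot(n_sites >= 2, n_sites <= 8, n_structures >= 1)
  dirs <- icosahedron_directions()[seq_len(n_sites), , drop = FALSE]
  sp <- spec
  sp$n_planted_contacts <- as.integer(n_sites)
  n_shell <- max(0L, spec$n_pocket_atoms - n_sites)
  shell_pos <- with_seed(seed * 7L + 1L,
                         sample_shell(n_shell, dirs * .geom$contact_shell,
                                      spec$min_noncontact_dist + 0.3))
  complexes <- list(); truth <- list()
  dominant_key <- NULL
  for (s in seq_len(n_structures)) {
    res <- with_seed(seed * 100000L + s, {
      contacted <- c(TRUE, stats::runif(n_sites - 1) < contact_prob)
      # fixed protein: every site partner present; ligand only contacts some
      full <- generate_complex_impl(sp, sprintf("screen%d", s),
                                    site_dirs = dirs,
                                    contact_mask = contacted,
                                    shell_pos = shell_pos)
      # remove ligand polar atoms of non-contacted sites
      drop_ids <- which(!contacted)
      cx <- full$complex
      keep <- !(cx$atoms$atom_id %in% drop_ids)
      cx$atoms <- cx$atoms[keep, ]
      truth_s <- full$truth$contacts
      list(cx = cx, truth_s = truth_s, contacted = contacted)
    })
    # fix the contact-site realization of partner positions across structures:
    # partner atoms must be bit-identical between structures, so rebuild them
    # from structure 1.
    if (s == 1L) {
      ref_prot <- res$cx$atoms[!res$cx$atoms$is_ligand, ]
      dominant_key <- paste(ref_prot$chain[1], ref_prot$residue_index[1],
                            ref_prot$atom_name[1], sep = "|")
    } else {
      at <- res$cx$atoms
      lig_at <- at[at$is_ligand, ]
      res$cx$atoms <- dplyr::bind_rows(lig_at, ref_prot)
      res$cx$atoms$atom_id <- seq_len(nrow(res$cx$atoms))
      # re-anchor contacted ligand polar atoms to the reference partners
      nc_here <- sum(res$contacted)
      site_idx <- which(res$contacted)
      d_real <- spec$contact_distance +
        with_seed(seed * 500000L + s, stats::runif(nc_here, -0.1, 0.1))
      ppos <- as.matrix(ref_prot[site_idx, c("x", "y", "z")])
      lpos <- ppos - dirs[site_idx, , drop = FALSE] * d_real
      res$cx$atoms[seq_len(nc_here), c("x", "y", "z")] <-
        as.data.frame(lpos)
      res$truth_s <- tibble::tibble(
        ligand_atom_id = seq_len(nc_here),
        protein_atom_id = nrow(lig_at) + site_idx,
        distance = d_real)
    }
    complexes[[s]] <- res$cx
    truth[[s]] <- dplyr::mutate(res$truth_s, structure = s, .before = 1)
  }
  list(complexes = complexes, truth = dplyr::bind_rows(truth),
       dominant_key = dominant_key, site_directions = dirs)
}
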