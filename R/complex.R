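#' Construct a protein-ligand complex
#'
#' A complex is the unified atom model used throughout the package: an ordered
#' atom table covering both the ligand and (a subset of) the receptor, with a
#' per-atom ligand/receptor flag, protein provenance fields and a
#' hydrogen-bond role. Most functions in the package take or return one.
#'
#' @param atoms A data frame with one row per atom. Required columns:
#'   `element` (chemical symbol), `x`, `y`, `z` (coordinates in Angstrom) and
#'   `is_ligand` (logical). Optional columns `atom_id`, `atom_name`,
#'   `residue_name`, `residue_index`, `chain` and `hbond_role` are filled
#'   with defaults when absent (`hbond_role` defaults to `"none"`).
#' @param complex_id Identifier string for the complex.
#' @param pocket_applied Logical; whether the protein atoms have already been
#'   restricted to the binding pocket (see [extract_pocket()]).
#'
#' @return An object of class `complex`: a list with elements `complex_id`,
#'   `atoms` (a tibble) and `pocket_applied`.
#' @examples
#' atoms <- tibble::tibble(
#'   element = c("C", "N", "O"),
#'   x = c(0, 1.5, 4), y = 0, z = 0,
#'   is_ligand = c(TRUE, TRUE, FALSE)
#' )
#' cx <- complex(atoms, complex_id = "toy")
#' n_atoms(cx)
#' @export
complex <- function(atoms, complex_id = "complex", pocket_applied = FALSE) {
  atoms <- tibble::as_tibble(atoms)
  required <- c("element", "x", "y", "z", "is_ligand")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atoms is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(atoms) == 0L) stop("complex must contain at least one atom", call. = FALSE)
  if (!any(atoms$is_ligand)) stop("complex must contain at least one ligand atom", call. = FALSE)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("atom positions must be finite", call. = FALSE)
  }
  defaults <- list(
    atom_id = seq_len(nrow(atoms)),
    atom_name = atoms$element,
    residue_name = ifelse(atoms$is_ligand, "", "UNK"),
    residue_index = ifelse(atoms$is_ligand, NA_integer_, 0L),
    chain = ifelse(atoms$is_ligand, "", "A"),
    hbond_role = "none"
  )
  for (nm in names(defaults)) {
    if (is.null(atoms[[nm]])) atoms[[nm]] <- defaults[[nm]]
  }
  if (anyDuplicated(atoms$atom_id)) stop("atom_ids must be unique", call. = FALSE)
  if (!all(atoms$hbond_role %in% c("donor", "acceptor", "both", "none"))) {
    stop("hbond_role must be one of donor/acceptor/both/none", call. = FALSE)
  }
  atoms$element <- normalize_element(atoms$element)
  atoms <- atoms[, c("atom_id", "element", "x", "y", "z", "is_ligand",
                     "atom_name", "residue_name", "residue_index", "chain",
                     "hbond_role")]
  structure(
    list(complex_id = complex_id, atoms = atoms, pocket_applied = pocket_applied),
    class = "complex"
  )
}

#' @export
print.complex <- function(x, ...) {
  cat(sprintf("<complex '%s'> %d atoms (%d ligand, %d protein)%s\n",
              x$complex_id, nrow(x$atoms), sum(x$atoms$is_ligand),
              sum(!x$atoms$is_ligand),
              if (x$pocket_applied) ", pocket applied" else ""))
  print(x$atoms, n = 6)
  invisible(x)
}

#' @method as_tibble complex
#' @export
as_tibble.complex <- function(x, ...) x$atoms

#' Number of atoms in a complex
#' @param x A `complex`.
#' @return Integer atom count.
#' @export
n_atoms <- function(x) nrow(x$atoms)

#' Atom coordinates of a complex as a matrix
#' @param x A `complex`.
#' @return An n x 3 numeric matrix of coordinates in Angstrom.
#' @export
coords <- function(x) {
  as.matrix(x$atoms[, c("x", "y", "z")])
}

normalize_element <- function(el) {
  el <- trimws(el)
  paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, nchar(el))))
}

# Hydrogen-bond role lookup. Backbone N is a donor and backbone O an
# acceptor for every residue; side-chain O/N roles follow standard residue
# templates. Ligand atoms (no residue context) fall back to an element rule:
# N -> donor, O -> acceptor, S -> acceptor, everything else none.
.protein_hbond_table <- list(
  backbone = c(N = "donor", O = "acceptor", OXT = "acceptor"),
  sidechain = list(
    SER = c(OG  = "both"),
    THR = c(OG1 = "both"),
    TYR = c(OH  = "both"),
    CYS = c(SG  = "donor"),
    ASN = c(OD1 = "acceptor", ND2 = "donor"),
    GLN = c(OE1 = "acceptor", NE2 = "donor"),
    ASP = c(OD1 = "acceptor", OD2 = "acceptor"),
    GLU = c(OE1 = "acceptor", OE2 = "acceptor"),
    LYS = c(NZ  = "donor"),
    ARG = c(NE  = "donor", NH1 = "donor", NH2 = "donor"),
    HIS = c(ND1 = "both", NE2 = "both"),
    TRP = c(NE1 = "donor"),
    MET = c(SD  = "acceptor")
  )
)

.element_hbond_rule <- c(N = "donor", O = "acceptor", S = "acceptor")

#' Assign hydrogen-bond roles from a fixed rule table
#'
#' Protein atoms are looked up by residue and atom name (backbone N/O plus
#' side-chain templates); ligand atoms, and protein atoms not covered by the
#' table, fall back to an element rule (N donor, O acceptor, S acceptor).
#' Atoms matching neither rule get `"none"`.
#'
#' @param atoms An atom tibble (as inside a `complex`).
#' @return The tibble with `hbond_role` filled in.
#' @export
assign_hbond_roles <- function(atoms) {
  role <- rep("none", nrow(atoms))
  bb <- .protein_hbond_table$backbone
  for (i in seq_len(nrow(atoms))) {
    if (atoms$is_ligand[i]) {
      r <- .element_hbond_rule[atoms$element[i]]
      if (!is.na(r)) role[i] <- r
    } else {
      an <- toupper(atoms$atom_name[i])
      rn <- toupper(atoms$residue_name[i])
      sc <- .protein_hbond_table$sidechain[[rn]]
      if (!is.null(sc) && an %in% names(sc)) {
        role[i] <- sc[[an]]
      } else if (an %in% names(bb)) {
        role[i] <- bb[[an]]
      } else {
        r <- .element_hbond_rule[atoms$element[i]]
        if (!is.na(r)) role[i] <- r
      }
    }
  }
  atoms$hbond_role <- role
  atoms
}

#' Restrict a complex to its binding pocket
#'
#' Keeps all ligand atoms and exactly those protein atoms whose minimum
#' Euclidean distance to any ligand atom is at most `radius` (closed
#' boundary). Atom order is otherwise preserved.
#'
#' @param cx A `complex`.
#' @param radius Pocket radius in Angstrom (default 6.0).
#' @return A `complex` with `pocket_applied = TRUE`.
#' @examples
#' atoms <- tibble::tibble(
#'   element = c("C", "N", "O"), x = c(0, 5, 7), y = 0, z = 0,
#'   is_ligand = c(TRUE, FALSE, FALSE)
#' )
#' extract_pocket(complex(atoms), radius = 6)
#' @export
extract_pocket <- function(cx, radius = 6.0) {
  stopifnot(inherits(cx, "complex"))
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0) {
    stop("radius must be a positive number", call. = FALSE)
  }
  atoms <- cx$atoms
  lig <- atoms$is_ligand
  if (!any(lig)) stop("complex has no ligand atoms", call. = FALSE)
  if (all(lig)) {
    cx$pocket_applied <- TRUE
    return(cx)
  }
  dmin <- min_dist_to_set(coords(cx)[!lig, , drop = FALSE],
                          coords(cx)[lig, , drop = FALSE])
  keep_protein <- dmin <= radius
  if (!any(keep_protein)) {
    stop(sprintf(
      "no protein atom within %.2f Angstrom of the ligand (closest at %.2f)",
      radius, min(dmin)), call. = FALSE)
  }
  keep <- lig
  keep[!lig] <- keep_protein
  cx$atoms <- atoms[keep, ]
  cx$pocket_applied <- TRUE
  cx
}

# Row-wise minimum distance from each point in `a` to the point set `b`.
min_dist_to_set <- function(a, b) {
  cross <- a %*% t(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * cross
  d2[d2 < 0] <- 0
  sqrt(apply(d2, 1, min))
}

#' Write a complex to a JSON-lines atom table
#'
#' One JSON object per atom, in atom order, for external inspection.
#'
#' @param cx A `complex`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_complex_jsonl <- function(cx, path) {
  stopifnot(inherits(cx, "complex"))
  lines <- vapply(seq_len(nrow(cx$atoms)), function(i) {
    jsonlite::toJSON(as.list(cx$atoms[i, ]), auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
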