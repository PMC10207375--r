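#' Read a protein-ligand complex from structure files
#'
#' Parses the protein from PDB and the ligand from SDF or MOL2 (chosen by
#' file extension), merges them into a single atom table with `is_ligand`
#' set from the file of origin, normalizes element symbols, and assigns
#' hydrogen-bond roles from the package's rule table
#' ([assign_hbond_roles()]). Alternate-location PDB records are resolved by
#' keeping the highest-occupancy conformer.
#'
#' @param protein_path Path to a PDB file.
#' @param ligand_path Path to an SDF (`.sdf`/`.mol`) or MOL2 (`.mol2`) file.
#' @param keep_hydrogens Keep hydrogen atoms? Default `FALSE`.
#' @param keep_waters Keep water (HOH/WAT) residues? Default `FALSE`.
#' @param complex_id Identifier; defaults to the protein file name.
#' @return A `complex` (pocket not yet applied).
#' @seealso [extract_pocket()], [featurize()]
#' @export
read_complex <- function(protein_path, ligand_path,
                         keep_hydrogens = FALSE, keep_waters = FALSE,
                         complex_id = NULL) {
  prot <- read_protein_pdb(protein_path, keep_hydrogens, keep_waters)
  lig <- read_ligand(ligand_path, keep_hydrogens)
  if (nrow(lig) == 0L) {
    stop(sprintf("ligand file '%s' contains zero atoms after filtering", ligand_path),
         call. = FALSE)
  }
  if (nrow(prot) == 0L) {
    stop(sprintf("protein file '%s' contains zero atoms after filtering (waters/hydrogens removed)",
                 protein_path), call. = FALSE)
  }
  lig$is_ligand <- TRUE
  prot$is_ligand <- FALSE
  atoms <- dplyr::bind_rows(lig, prot)
  atoms$atom_id <- seq_len(nrow(atoms))
  atoms$element <- normalize_element(atoms$element)
  atoms <- assign_hbond_roles(atoms)
  if (is.null(complex_id)) {
    complex_id <- sub("\\.[^.]+$", "", basename(protein_path))
  }
  complex(atoms, complex_id = complex_id, pocket_applied = FALSE)
}

read_protein_pdb <- function(path, keep_hydrogens, keep_waters) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)),
    error = function(e) stop(sprintf("could not parse PDB file '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  at <- pdb$atom
  el <- trimws(at$elesy)
  # derive element from the atom name where the element column is blank
  fallback <- gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", trimws(at$elety)))
  el[el == "" | is.na(el)] <- substr(fallback[el == "" | is.na(el)], 1, 2)
  el <- normalize_element(el)
  keep <- rep(TRUE, nrow(at))
  if (!keep_waters) keep <- keep & !(trimws(at$resid) %in% c("HOH", "WAT", "DOD"))
  if (!keep_hydrogens) keep <- keep & !(el %in% c("H", "D"))
  at <- at[keep, , drop = FALSE]
  el <- el[keep]
  df <- tibble::tibble(
    element = el,
    x = at$x, y = at$y, z = at$z,
    atom_name = trimws(at$elety),
    residue_name = trimws(at$resid),
    residue_index = as.integer(at$resno),
    chain = ifelse(is.na(at$chain), "A", as.character(at$chain)),
    alt = ifelse(is.na(at$alt) | trimws(at$alt) == "", "", trimws(at$alt)),
    occupancy = ifelse(is.na(at$o), 1, at$o)
  )
  df <- resolve_altloc(df)
  df[, setdiff(names(df), c("alt", "occupancy"))]
}

# Keep only the highest-occupancy alternate-location conformer per atom site.
resolve_altloc <- function(df) {
  if (all(df$alt == "")) return(df)
  df$.site <- paste(df$chain, df$residue_index, df$residue_name, df$atom_name, sep = "|")
  df <- dplyr::arrange(
    dplyr::group_by(df, .data$.site),
    dplyr::desc(.data$occupancy), .data$alt, .by_group = TRUE
  )
  df <- dplyr::ungroup(dplyr::slice_head(df, n = 1, by = NULL))
  df <- dplyr::distinct(df, .data$.site, .keep_all = TRUE)
  df$.site <- NULL
  df
}

read_ligand <- function(path, keep_hydrogens) {
  ext <- tolower(sub("^.*\\.", "", path))
  mol <- if (ext %in% c("sdf", "mol")) {
    read_molecule_sdf(path)
  } else if (ext == "mol2") {
    read_molecule_mol2(path)
  } else {
    stop(sprintf("unsupported ligand format '.%s' (expected .sdf or .mol2)", ext),
         call. = FALSE)
  }
  atoms <- mol$atoms
  if (!keep_hydrogens) atoms <- atoms[atoms$element != "H", , drop = FALSE]
  tibble::tibble(
    element = atoms$element,
    x = atoms$x, y = atoms$y, z = atoms$z,
    atom_name = paste0(atoms$element, seq_len(nrow(atoms))),
    residue_name = "", residue_index = NA_integer_, chain = ""
  )
}

#' Read a small molecule (with bonds) from an SDF file
#'
#' Returns the package's light molecule representation used by the
#' fingerprint and fragment-enumeration code.
#'
#' @param path Path to an SDF/MOL V2000 file.
#' @param which Index of the record to read when the file holds several.
#' @return A `molecule`: list with `atoms` (tibble: `element`, `x`, `y`, `z`,
#'   `charge`) and `bonds` (tibble: `i`, `j`, `order`).
#' @export
read_molecule_sdf <- function(path, which = 1L) {
  sdfs <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(path)),
    error = function(e) stop(sprintf("could not parse SDF file '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  if (length(sdfs) < which) stop("SDF record index out of range", call. = FALSE)
  sdf <- sdfs[[which]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  el <- sub("_.*$", "", rownames(ab))
  atoms <- tibble::tibble(
    element = normalize_element(el),
    x = ab[, 1], y = ab[, 2], z = ab[, 3],
    charge = 0
  )
  bonds <- if (is.matrix(bb) && nrow(bb) > 0 && ncol(bb) >= 3) {
    tibble::tibble(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                   order = as.integer(bb[, 3]))
  } else {
    tibble::tibble(i = integer(), j = integer(), order = integer())
  }
  molecule(atoms, bonds, name = unname(ChemmineR::header(sdf)["Molecule_Name"]))
}

read_molecule_mol2 <- function(path) {
  m <- tryCatch(
    suppressWarnings(bio3d::read.mol2(path)),
    error = function(e) stop(sprintf("could not parse MOL2 file '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  at <- m$atom
  el <- sub("\\..*$", "", at$elety)
  atoms <- tibble::tibble(
    element = normalize_element(el),
    x = at$x, y = at$y, z = at$z,
    charge = if (!is.null(at$charge)) at$charge else 0
  )
  bonds <- if (!is.null(m$bond) && nrow(m$bond) > 0) {
    ord <- suppressWarnings(as.integer(m$bond$type))
    ord[is.na(ord)] <- 1L  # aromatic ("ar") and amide ("am") types
    tibble::tibble(i = as.integer(m$bond$origin), j = as.integer(m$bond$target),
                   order = ord)
  } else {
    tibble::tibble(i = integer(), j = integer(), order = integer())
  }
  molecule(atoms, bonds, name = basename(path))
}

#' Construct a small-molecule object
#'
#' @param atoms Tibble with columns `element`, `x`, `y`, `z` and optionally
#'   `charge`.
#' @param bonds Tibble with columns `i`, `j` (1-based atom indices) and
#'   `order` (1, 2, 3).
#' @param name Molecule name.
#' @return A `molecule` object.
#' @export
molecule <- function(atoms, bonds, name = "mol") {
  atoms <- tibble::as_tibble(atoms)
  bonds <- tibble::as_tibble(bonds)
  if (!("charge" %in% names(atoms))) atoms$charge <- 0
  if (nrow(bonds) > 0) {
    stopifnot(all(bonds$i >= 1), all(bonds$j >= 1),
              all(bonds$i <= nrow(atoms)), all(bonds$j <= nrow(atoms)))
  }
  structure(list(atoms = atoms, bonds = bonds, name = name), class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule '%s'> %d atoms, %d bonds\n", x$name,
              nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

#' Write a complex to a PDB file (protein part) and SDF file (ligand part)
#'
#' Used by the synthetic-data tooling so that generated complexes can be fed
#' back through [read_complex()].
#'
#' @param cx A `complex`.
#' @param pdb_path Output PDB path for the protein atoms.
#' @param sdf_path Output SDF path for the ligand atoms.
#' @param ligand_bonds Optional bond tibble (`i`, `j`, `order`) for the
#'   ligand, indexed over ligand atoms in order; when `NULL` no bonds are
#'   written.
#' @return Invisibly, a list with the two paths.
#' @export
write_complex_files <- function(cx, pdb_path, sdf_path, ligand_bonds = NULL) {
  stopifnot(inherits(cx, "complex"))
  atoms <- cx$atoms
  prot <- atoms[!atoms$is_ligand, , drop = FALSE]
  lig <- atoms[atoms$is_ligand, , drop = FALSE]
  # protein -> PDB via bio3d
  if (nrow(prot) > 0) {
    bio3d::write.pdb(
      file = pdb_path,
      xyz = as.numeric(t(as.matrix(prot[, c("x", "y", "z")]))),
      resno = ifelse(is.na(prot$residue_index), 1L, prot$residue_index),
      resid = ifelse(prot$residue_name == "", "UNK", prot$residue_name),
      eleno = seq_len(nrow(prot)),
      elety = prot$atom_name,
      chain = ifelse(prot$chain == "", "A", prot$chain),
      elesy = prot$element
    )
  }
  write_sdf_v2000(
    molecule(lig[, c("element", "x", "y", "z")],
             if (is.null(ligand_bonds)) tibble::tibble(i = integer(), j = integer(), order = integer())
             else ligand_bonds,
             name = cx$complex_id),
    sdf_path
  )
  invisible(list(pdb = pdb_path, sdf = sdf_path))
}

#' Write a molecule as an SDF (V2000) record
#'
#' @param mol A `molecule`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sdf_v2000 <- function(mol, path) {
  a <- mol$atoms
  b <- mol$bonds
  lines <- c(
    mol$name, "  eqscore", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(a), nrow(b)),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            a$x, a$y, a$z, a$element),
    if (nrow(b) > 0) sprintf("%3d%3d%3d  0", b$i, b$j, b$order),
    "M  END", "$$$$"
  )
  writeLines(lines, path)
  invisible(path)
}
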