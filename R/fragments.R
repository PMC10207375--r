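#' Enumerate fragments of a molecule by cutting acyclic single bonds
#'
#' Every acyclic (non-ring) single bond whose endpoints are not part of a
#' protected functional group is cut; each cut yields two fragments, one
#' per side, with a dummy atom (`*`) placed at the position of the lost
#' neighbor to mark the elaboration exit vector. Ring bonds, multiple
#' bonds and bonds inside amide, ester, sulfonamide or nitro groups are
#' never cut.
#'
#' @param mol A `molecule` (with explicit bonds), or a path to an SDF file.
#' @param protected Character vector naming the functional-group patterns
#'   whose atoms may not flank a cut (any of `"amide"`, `"ester"`,
#'   `"sulfonamide"`, `"nitro"`).
#' @return A list with one element per emitted fragment: `fragment` (a
#'   `molecule` whose last atom is the dummy), `exit_atom` (index of the
#'   atom bearing the dummy, in fragment numbering), and `cut_bond` (the
#'   original atom indices of the cut bond, kept-side first).
#' @examples
#' ethane <- molecule(
#'   tibble::tibble(element = c("C", "C"), x = c(0, 1.5), y = 0, z = 0),
#'   tibble::tibble(i = 1, j = 2, order = 1))
#' length(enumerate_fragments(ethane))  # 2
#' @export
enumerate_fragments <- function(mol, protected = c("amide", "ester",
                                                   "sulfonamide", "nitro")) {
  if (is.character(mol)) mol <- read_molecule_sdf(mol)
  stopifnot(inherits(mol, "molecule"))
  b <- mol$bonds
  if (nrow(b) == 0L) return(list())
  heavy <- mol$atoms$element != "H"
  g <- igraph::graph_from_edgelist(as.matrix(b[, c("i", "j")]), directed = FALSE)
  if (igraph::vcount(g) < nrow(mol$atoms)) {
    g <- igraph::add_vertices(g, nrow(mol$atoms) - igraph::vcount(g))
  }
  bridge_ids <- igraph::bridges(g)
  is_bridge <- seq_len(nrow(b)) %in% as.integer(bridge_ids)
  excluded <- protected_atoms(mol, protected)
  eligible <- which(b$order == 1L & is_bridge &
                      heavy[b$i] & heavy[b$j] &
                      !(b$i %in% excluded) & !(b$j %in% excluded))
  out <- list()
  for (e in eligible) {
    i <- b$i[e]; j <- b$j[e]
    g_cut <- igraph::delete_edges(g, e)
    comp <- igraph::components(g_cut)$membership
    for (side in list(c(keep = i, lost = j), c(keep = j, lost = i))) {
      atoms_in <- which(comp == comp[side["keep"]])
      out[[length(out) + 1L]] <- make_fragment(mol, atoms_in,
                                               side["keep"], side["lost"])
    }
  }
  out
}

make_fragment <- function(mol, atoms_in, keep, lost) {
  remap <- integer(nrow(mol$atoms))
  remap[atoms_in] <- seq_along(atoms_in)
  a <- mol$atoms[atoms_in, , drop = FALSE]
  dummy <- mol$atoms[lost, , drop = FALSE]
  dummy$element <- "*"
  a <- dplyr::bind_rows(a, dummy)
  b <- mol$bonds
  inb <- b$i %in% atoms_in & b$j %in% atoms_in
  bonds <- tibble::tibble(i = remap[b$i[inb]], j = remap[b$j[inb]],
                          order = b$order[inb])
  bonds <- dplyr::bind_rows(bonds, tibble::tibble(
    i = remap[keep], j = nrow(a), order = 1L))
  list(fragment = molecule(a, bonds,
                           name = sprintf("%s_cut%d_%d", mol$name, keep, lost)),
       exit_atom = unname(remap[keep]),
       cut_bond = unname(c(keep, lost)))
}

# Atom indices belonging to protected functional groups. Detection works on
# the element/bond tables directly:
#   nitro        N(~O)(~O) with terminal oxygens      -> N + O
#   amide        C(=O)-N                              -> C + O + N
#   ester        C(=O)-O-C                            -> C + both O
#   sulfonamide  S(=O)(=O)-N                          -> S + O + N
protected_atoms <- function(mol, protected) {
  a <- mol$atoms; b <- mol$bonds
  n <- nrow(a)
  nbr <- function(i) {
    rows <- b$i == i | b$j == i
    tibble::tibble(other = ifelse(b$i[rows] == i, b$j[rows], b$i[rows]),
                   order = b$order[rows])
  }
  deg <- vapply(seq_len(n), function(i) sum(b$i == i | b$j == i), integer(1))
  excluded <- integer(0)
  for (i in seq_len(n)) {
    el <- a$element[i]
    nb <- nbr(i)
    if ("nitro" %in% protected && el == "N") {
      os <- nb$other[a$element[nb$other] == "O" & deg[nb$other] == 1L]
      if (length(os) >= 2L) excluded <- c(excluded, i, os)
    }
    if (el == "C") {
      dbl_o <- nb$other[a$element[nb$other] == "O" & nb$order == 2L]
      if (length(dbl_o) >= 1L) {
        if ("amide" %in% protected) {
          ns <- nb$other[a$element[nb$other] == "N" & nb$order == 1L]
          if (length(ns)) excluded <- c(excluded, i, dbl_o, ns)
        }
        if ("ester" %in% protected) {
          single_o <- nb$other[a$element[nb$other] == "O" & nb$order == 1L]
          bridging <- single_o[vapply(single_o, function(o) {
            others <- nbr(o)$other
            any(a$element[others] == "C" & others != i)
          }, logical(1))]
          if (length(bridging)) excluded <- c(excluded, i, dbl_o, bridging)
        }
      }
    }
    if ("sulfonamide" %in% protected && el == "S") {
      dbl_o <- nb$other[a$element[nb$other] == "O" & nb$order == 2L]
      ns <- nb$other[a$element[nb$other] == "N" & nb$order == 1L]
      if (length(dbl_o) >= 2L && length(ns) >= 1L) {
        excluded <- c(excluded, i, dbl_o, ns)
      }
    }
  }
  unique(excluded)
}
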