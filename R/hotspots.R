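#' @name hotspots
#' @title Hotspot maps from aggregated attribution
#' @description Attribution on a single bound structure scores the protein
#' atoms of that structure's pocket. Repeating the attribution over a
#' fragment screen (many structures of one rigid target) and averaging per
#' protein atom yields a ranked hotspot map: the protein atoms the model
#' consistently judges important for binding, each typed as a donor or
#' acceptor. A purely geometric hydrogen-bond counting baseline and a
#' subsampling stability analysis accompany it.
NULL

hotspot_map <- function(hotspots, target_id, provenance) {
  structure(list(target_id = target_id, hotspots = hotspots,
                 provenance = provenance),
            class = "hotspot_map")
}

#' @export
print.hotspot_map <- function(x, ...) {
  cat(sprintf("<hotspot_map '%s'> %d hotspots from %d structures\n",
              x$target_id, nrow(x$hotspots), length(x$provenance)))
  print(utils::head(x$hotspots, 5))
  invisible(x)
}

#' @method as_tibble hotspot_map
#' @export
as_tibble.hotspot_map <- function(x, ...) x$hotspots

#' Tidy a hotspot map
#' @param x A `hotspot_map`.
#' @param ... Unused.
#' @return The ranked hotspot tibble.
#' @method tidy hotspot_map
#' @export
tidy.hotspot_map <- function(x, ...) x$hotspots

# protein-atom key (chain|residue_index|atom_name) for each complex atom id
atom_keys <- function(cx) {
  at <- cx$atoms
  ifelse(at$is_ligand, NA_character_,
         paste(at$chain, at$residue_index, at$atom_name, sep = "|"))
}

#' Aggregate per-structure attribution into a hotspot map
#'
#' Protein atoms are matched across structures by their
#' (chain, residue index, atom name) key; each atom's hotspot score is the
#' mean of its attribution scores over the structures in which it was
#' scored (structures where the atom falls outside the scored pocket do not
#' contribute zeros). The pharmacophore type comes from the atom's
#' hydrogen-bond role; atoms typed `both` take the role with the higher
#' per-type sub-score (the best edge score against complementary ligand
#' partners), ties resolving to donor.
#'
#' @param results List of per-structure pairs: each element a list with
#'   `complex` (a `complex`) and `attribution` (an `attribution_result`).
#' @param target_id Identifier for the shared target.
#' @param normalize Min-max normalize each structure's scores before
#'   averaging? Default `FALSE` (raw scores).
#' @return A `hotspot_map`; its `hotspots` tibble has rank, atom key fields,
#'   coordinates, `pharmacophore_type`, `mean_score` and `n_structures`.
#' @export
aggregate_hotspots <- function(results, target_id = "target", normalize = FALSE) {
  stopifnot(length(results) >= 1)
  rows <- purrr::map_dfr(results, function(r) {
    cx <- r$complex; attr_ <- r$attribution
    at <- cx$atoms
    keys <- atom_keys(cx)
    sc <- attr_$atom_scores
    sc <- sc[!sc$is_ligand & !is.na(sc$score), , drop = FALSE]
    if (nrow(sc) == 0L) return(NULL)
    if (normalize) {
      rng <- range(sc$score)
      sc$score <- if (diff(rng) > 0) (sc$score - rng[1]) / diff(rng) else 0
    }
    i <- match(sc$atom_id, at$atom_id)
    donor_sub <- acceptor_sub <- rep(NA_real_, nrow(sc))
    es <- attr_$edge_scores
    if (!is.null(es) && nrow(es) > 0) {
      lig_role <- at$hbond_role[match(es$ligand_atom_id, at$atom_id)]
      for (j in seq_len(nrow(sc))) {
        mine <- es[es$protein_atom_id == sc$atom_id[j], , drop = FALSE]
        lr <- lig_role[es$protein_atom_id == sc$atom_id[j]]
        if (nrow(mine)) {
          dsc <- mine$score[lr %in% c("acceptor", "both")]
          asc <- mine$score[lr %in% c("donor", "both")]
          donor_sub[j] <- if (length(dsc)) max(dsc) else NA_real_
          acceptor_sub[j] <- if (length(asc)) max(asc) else NA_real_
        }
      }
    }
    tibble::tibble(
      complex_id = cx$complex_id,
      key = keys[i], chain = at$chain[i], residue_index = at$residue_index[i],
      residue_name = at$residue_name[i], atom_name = at$atom_name[i],
      x = at$x[i], y = at$y[i], z = at$z[i],
      hbond_role = at$hbond_role[i], score = sc$score,
      donor_sub = donor_sub, acceptor_sub = acceptor_sub)
  })
  if (is.null(rows) || nrow(rows) == 0L) {
    stop("no shared scored protein atoms across structures", call. = FALSE)
  }
  agg <- dplyr::summarise(
    dplyr::group_by(rows, .data$key),
    chain = dplyr::first(.data$chain),
    residue_index = dplyr::first(.data$residue_index),
    residue_name = dplyr::first(.data$residue_name),
    atom_name = dplyr::first(.data$atom_name),
    x = dplyr::first(.data$x), y = dplyr::first(.data$y),
    z = dplyr::first(.data$z),
    hbond_role = dplyr::first(.data$hbond_role),
    mean_score = mean(.data$score),
    n_structures = dplyr::n(),
    donor_sub = if (all(is.na(.data$donor_sub))) NA_real_ else
      mean(.data$donor_sub, na.rm = TRUE),
    acceptor_sub = if (all(is.na(.data$acceptor_sub))) NA_real_ else
      mean(.data$acceptor_sub, na.rm = TRUE),
    .groups = "drop")
  agg$pharmacophore_type <- mapply(function(role, ds, as_) {
    if (role == "donor") "donor"
    else if (role == "acceptor") "acceptor"
    else if (role == "both") {
      if (!is.na(as_) && !is.na(ds)) {
        if (as_ > ds) "acceptor" else "donor"
      } else "donor"
    } else NA_character_
  }, agg$hbond_role, agg$donor_sub, agg$acceptor_sub)
  agg <- agg[order(-agg$mean_score, agg$key), , drop = FALSE]
  agg$rank <- seq_len(nrow(agg))
  cols <- c("rank", "key", "chain", "residue_index", "residue_name",
            "atom_name", "x", "y", "z", "pharmacophore_type", "mean_score",
            "n_structures")
  hotspot_map(agg[, cols],
              target_id,
              provenance = vapply(results, function(r) r$complex$complex_id,
                                  character(1)))
}

#' Geometric hydrogen-bond-count hotspots
#'
#' A deliberately simple geometric baseline: a protein atom is highlighted
#' in a structure when a ligand atom of complementary hydrogen-bond role
#' (donor opposite acceptor; `both` matches either) lies within
#' `hbond_dist`. Atoms highlighted in strictly more than `min_count`
#' structures become hotspots, ranked by their count. This is a declared
#' simplification of full interaction-profiling rules (no angle terms).
#'
#' @param complexes List of `complex` objects sharing one reference protein.
#' @param hbond_dist Highlight distance in Angstrom (default 3.5).
#' @param min_count Strict count threshold (default 5: "more than five").
#' @return A `hotspot_map` whose `mean_score` column holds the counts.
#' @export
geometric_hotspots <- function(complexes, hbond_dist = 3.5, min_count = 5L) {
  stopifnot(length(complexes) >= 1)
  complement <- c(donor = "acceptor", acceptor = "donor", both = "both")
  rows <- purrr::map_dfr(complexes, function(cx) {
    at <- cx$atoms
    prot <- at[!at$is_ligand & at$hbond_role != "none", , drop = FALSE]
    lig <- at[at$is_ligand & at$hbond_role != "none", , drop = FALSE]
    if (nrow(prot) == 0L || nrow(lig) == 0L) return(NULL)
    hit <- vapply(seq_len(nrow(prot)), function(i) {
      want <- complement[[prot$hbond_role[i]]]
      partners <- lig[lig$hbond_role %in%
                        (if (want == "both") c("donor", "acceptor", "both")
                         else c(want, "both")), , drop = FALSE]
      if (nrow(partners) == 0L) return(FALSE)
      d <- min_dist_to_set(as.matrix(prot[i, c("x", "y", "z")]),
                           as.matrix(partners[, c("x", "y", "z")]))
      d <= hbond_dist
    }, logical(1))
    prot <- prot[hit, , drop = FALSE]
    if (nrow(prot) == 0L) return(NULL)
    tibble::tibble(
      key = paste(prot$chain, prot$residue_index, prot$atom_name, sep = "|"),
      chain = prot$chain, residue_index = prot$residue_index,
      residue_name = prot$residue_name, atom_name = prot$atom_name,
      x = prot$x, y = prot$y, z = prot$z, hbond_role = prot$hbond_role)
  })
  if (is.null(rows) || nrow(rows) == 0L) {
    return(hotspot_map(tibble::tibble(), "geometric",
                       vapply(complexes, function(c) c$complex_id, character(1))))
  }
  agg <- dplyr::summarise(
    dplyr::group_by(rows, .data$key),
    chain = dplyr::first(.data$chain),
    residue_index = dplyr::first(.data$residue_index),
    residue_name = dplyr::first(.data$residue_name),
    atom_name = dplyr::first(.data$atom_name),
    x = dplyr::first(.data$x), y = dplyr::first(.data$y),
    z = dplyr::first(.data$z),
    pharmacophore_type = dplyr::first(.data$hbond_role),
    count = dplyr::n(), .groups = "drop")
  agg <- agg[agg$count > min_count, , drop = FALSE]
  agg <- agg[order(-agg$count, agg$key), , drop = FALSE]
  agg$rank <- seq_len(nrow(agg))
  agg$mean_score <- as.numeric(agg$count)
  agg$n_structures <- agg$count
  cols <- c("rank", "key", "chain", "residue_index", "residue_name",
            "atom_name", "x", "y", "z", "pharmacophore_type", "mean_score",
            "n_structures")
  hotspot_map(agg[, cols], "geometric",
              vapply(complexes, function(c) c$complex_id, character(1)))
}

#' Stability of hotspot maps under screen subsampling
#'
#' Repeatedly draws random subsets of the per-structure attribution results,
#' recomputes the top-`top_k` hotspot set from each subset, and reports (a)
#' how often each protein atom lands in the subsampled top set and (b) the
#' mean Jaccard overlap between subsampled and full-data top sets, per
#' subset size. Larger screens should give more consistent maps.
#'
#' @param results As in [aggregate_hotspots()].
#' @param subset_sizes Integer vector of screen sizes to sample.
#' @param n_repeats Repeats per size (default 40).
#' @param top_k Size of the hotspot set compared (default 5).
#' @param seed Integer seed.
#' @return A `stability_report`: list with `summary` (tibble: subset size,
#'   mean/sd Jaccard), `inclusion` (tibble: size, atom key, inclusion
#'   frequency) and `full_top` (the full-data top-k keys).
#' @export
hotspot_stability <- function(results, subset_sizes, n_repeats = 40L,
                              top_k = 5L, seed = 1L) {
  n <- length(results)
  if (any(subset_sizes > n)) {
    stop("subset size exceeds the number of available structures", call. = FALSE)
  }
  full_top <- utils::head(aggregate_hotspots(results)$hotspots$key, top_k)
  summary_rows <- list(); incl_rows <- list()
  for (size in subset_sizes) {
    jac <- numeric(n_repeats)
    counts <- list()
    for (r in seq_len(n_repeats)) {
      take <- with_seed(seed * 1000L + size * 100L + r,
                        sample(n, size))
      top <- utils::head(aggregate_hotspots(results[take])$hotspots$key, top_k)
      jac[r] <- length(intersect(top, full_top)) / length(union(top, full_top))
      for (k in top) counts[[k]] <- (counts[[k]] %||% 0L) + 1L
    }
    summary_rows[[length(summary_rows) + 1L]] <- tibble::tibble(
      subset_size = size, mean_jaccard = mean(jac), sd_jaccard = stats::sd(jac),
      n_repeats = n_repeats)
    incl_rows[[length(incl_rows) + 1L]] <- tibble::tibble(
      subset_size = size, key = names(counts),
      inclusion_freq = unlist(counts) / n_repeats,
      in_full_top = names(counts) %in% full_top)
  }
  structure(list(summary = dplyr::bind_rows(summary_rows),
                 inclusion = dplyr::bind_rows(incl_rows),
                 full_top = full_top, top_k = top_k),
            class = "stability_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report>\n")
  print(x$summary)
  invisible(x)
}

#' Plot a stability report
#' @param report A `stability_report`.
#' @return A ggplot of mean Jaccard overlap against subset size.
#' @export
plot_stability <- function(report) {
  ggplot2::ggplot(report$summary,
                  ggplot2::aes(x = .data$subset_size, y = .data$mean_jaccard)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(0, .data$mean_jaccard - .data$sd_jaccard),
      ymax = pmin(1, .data$mean_jaccard + .data$sd_jaccard))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "structures sampled", y = "mean Jaccard vs full data") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a hotspot map
#' @param map A `hotspot_map`.
#' @param top_n Number of hotspots to display.
#' @return A ggplot showing ranked mean scores colored by pharmacophore
#'   type.
#' @export
plot_hotspots <- function(map, top_n = 10L) {
  h <- utils::head(map$hotspots, top_n)
  ggplot2::ggplot(h, ggplot2::aes(x = stats::reorder(.data$key, -.data$rank),
                                  y = .data$mean_score,
                                  fill = .data$pharmacophore_type)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean attribution score", fill = "type") +
    ggplot2::theme_minimal()
}

#' Write hotspots as a PDB-format pseudo-atom file
#'
#' One HETATM pseudo-atom per hotspot for visualization in molecular
#' viewers; the B-factor column carries the mean score.
#'
#' @param map A `hotspot_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hotspot_pdb <- function(map, path) {
  h <- map$hotspots
  lines <- sprintf(
    "HETATM%5d %-4s HTS %s%4d    %8.3f%8.3f%8.3f  1.00%6.2f          %2s",
    h$rank, substr(ifelse(is.na(h$pharmacophore_type), "X",
                          toupper(substr(h$pharmacophore_type, 1, 1))), 1, 4),
    substr(h$chain, 1, 1), h$rank, h$x, h$y, h$z,
    pmin(h$mean_score * 100, 999), "C")
  writeLines(c(lines, "END"), path)
  invisible(path)
}
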