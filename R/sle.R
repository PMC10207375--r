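#' @name sle
#' @title Standardized ligand-efficiency statistics for fragment elaboration
#' @description Generated elaborations of a fragment are docked and scored;
#' dividing each docking score by the molecule's heavy-atom count gives a
#' ligand efficiency (LE) that compensates for the size bias of docking
#' scores. Within each (fragment, hotspot) pool — the elaborations plus the
#' ground-truth molecule the fragment was cut from — LEs are standardized
#' to zero mean and unit variance. Delta-SLE_alpha is the mean of the top
#' alpha standardized elaboration LEs minus the standardized LE of the
#' ground truth: positive values mean the elaborations improved on the
#' original molecule. Per-hotspot means over successfully elaborated
#' fragments summarize how productive each targeted hotspot was.
NULL

#' Ligand efficiency
#'
#' @param score Docking score(s).
#' @param heavy_atoms Heavy-atom count(s), at least 1.
#' @return `score / heavy_atoms`, vectorized.
#' @examples
#' ligand_efficiency(30, 10)  # 3
#' @export
ligand_efficiency <- function(score, heavy_atoms) {
  if (any(heavy_atoms < 1)) stop("heavy_atoms must be >= 1", call. = FALSE)
  score / heavy_atoms
}

#' Standardize a pool of ligand efficiencies
#'
#' Centers and scales to zero mean and unit variance (population variance
#' by default). A zero-variance pool returns all zeros with a warning, so
#' that batch reports complete (the corresponding delta-SLE is then 0 by
#' convention).
#'
#' @param les Numeric vector (elaborations plus ground truth).
#' @param variance `"population"` (default) or `"sample"`.
#' @return Standardized vector, order preserved.
#' @export
standardize_pool <- function(les, variance = c("population", "sample")) {
  variance <- match.arg(variance)
  if (length(les) < 2L) stop("pool must contain at least 2 values", call. = FALSE)
  mu <- mean(les)
  v <- if (variance == "population") mean((les - mu)^2) else stats::var(les)
  if (v <= 0) {
    warning("zero-variance pool; returning all zeros")
    return(rep(0, length(les)))
  }
  (les - mu) / sqrt(v)
}

#' Delta-SLE for one (fragment, hotspot) pool
#'
#' Computes LEs for the pool rows, standardizes them jointly, sorts the
#' elaborations' standardized values descending, takes the mean of the top
#' `min(alpha, n)` and subtracts the ground truth's standardized value.
#'
#' @param pool Tibble with columns `docking_score`, `heavy_atoms`,
#'   `is_ground_truth` (exactly one `TRUE` row) for a single
#'   (fragment, hotspot) pool.
#' @param alpha Number of top elaborations averaged (default 20).
#' @param variance Passed to [standardize_pool()].
#' @return Delta-SLE_alpha as a single number.
#' @export
delta_sle <- function(pool, alpha = 20L, variance = "population") {
  gt <- which(pool$is_ground_truth)
  if (length(gt) != 1L) {
    stop("pool must contain exactly one ground-truth row", call. = FALSE)
  }
  if (nrow(pool) < 2L) {
    stop("pool must contain at least one elaboration besides the ground truth",
         call. = FALSE)
  }
  les <- ligand_efficiency(pool$docking_score, pool$heavy_atoms)
  sles <- withCallingHandlers(
    standardize_pool(les, variance),
    warning = function(w) {
      if (grepl("zero-variance", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (all(sles == 0)) return(0)
  elab <- sort(sles[-gt], decreasing = TRUE)
  mean(elab[seq_len(min(alpha, length(elab)))]) - sles[gt]
}

#' Per-hotspot delta-SLE report
#'
#' Groups a score table by (fragment, hotspot), computes delta-SLE_alpha per
#' pool, and summarizes per hotspot: the mean delta-SLE over successfully
#' elaborated fragments, the number of fragments with at least one
#' elaboration, and the mean number of elaborations per fragment. Hotspots
#' whose pools contain no elaborations are reported with `n = 0` and a
#' missing mean.
#'
#' @param table A score table: tibble with columns `molecule_id`,
#'   `fragment_id`, `hotspot_rank`, `docking_score`, `heavy_atoms`,
#'   `is_ground_truth`.
#' @param alpha Top-alpha parameter (default 20).
#' @param variance Passed to [standardize_pool()].
#' @return An `sle_report`: list with `pairs` (per fragment-hotspot
#'   delta-SLE) and `hotspots` (per-hotspot summary).
#' @export
hotspot_report <- function(table, alpha = 20L, variance = "population") {
  stopifnot(nrow(table) > 0)
  required <- c("fragment_id", "hotspot_rank", "docking_score", "heavy_atoms",
                "is_ground_truth")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols)) {
    stop("score table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  pairs <- dplyr::group_modify(
    dplyr::group_by(table, .data$hotspot_rank, .data$fragment_id),
    function(df, key) {
      n_elab <- sum(!df$is_ground_truth)
      tibble::tibble(
        n_elaborations = n_elab,
        delta_sle = if (n_elab >= 1L) delta_sle(df, alpha, variance) else NA_real_)
    })
  pairs <- dplyr::ungroup(pairs)
  hotspots <- dplyr::summarise(
    dplyr::group_by(pairs, .data$hotspot_rank),
    mean_delta_sle = if (any(.data$n_elaborations >= 1L))
      mean(.data$delta_sle[.data$n_elaborations >= 1L]) else NA_real_,
    n_fragments_successful = sum(.data$n_elaborations >= 1L),
    mean_elaborations_per_fragment = mean(.data$n_elaborations),
    .groups = "drop")
  structure(list(pairs = pairs, hotspots = hotspots, alpha = alpha),
            class = "sle_report")
}

#' @export
print.sle_report <- function(x, ...) {
  cat(sprintf("<sle_report> alpha = %d\n", x$alpha))
  print(x$hotspots)
  invisible(x)
}

#' Tidy an SLE report
#' @param x An `sle_report`.
#' @param ... Unused.
#' @return The per-(fragment, hotspot) tibble.
#' @method tidy sle_report
#' @export
tidy.sle_report <- function(x, ...) x$pairs

#' One-row-per-hotspot summary of an SLE report
#' @param x An `sle_report`.
#' @param ... Unused.
#' @return The per-hotspot tibble.
#' @method glance sle_report
#' @export
glance.sle_report <- function(x, ...) x$hotspots

#' Annotate a score table with the quasi-active distance convention
#'
#' Elaborations only count when docking placed a donor/acceptor within a
#' set distance of the targeted hotspot: 2 Angstrom for hotspots placed in
#' the open pocket, 3 Angstrom for hotspots sitting on protein atoms. The
#' thresholds are recorded as metadata columns for upstream filtering; the
#' docking and generation steps that measure the distances are external.
#'
#' @param table A score table.
#' @param hotspot_source `"protein_atom"` (3 Angstrom) or `"pocket_grid"`
#'   (2 Angstrom).
#' @return The table with `quasi_active_dist` and `hotspot_source` columns.
#' @export
annotate_quasi_active <- function(table,
                                  hotspot_source = c("protein_atom", "pocket_grid")) {
  hotspot_source <- match.arg(hotspot_source)
  dist <- if (hotspot_source == "protein_atom") 3.0 else 2.0
  dplyr::mutate(table,
                hotspot_source = hotspot_source,
                quasi_active_dist = dist)
}

#' Generate a synthetic docking-score table with a planted hotspot ordering
#'
#' Hotspot quality decreases linearly with true rank: elaborations targeted
#' at hotspot `h` draw ligand efficiencies from
#' `N(-(h - 1) * effect_size, 1)`, while ground-truth molecules draw from
#' `N(0, 1)`; docking scores are LE times a random heavy-atom count. With
#' `effect_size = 0` no hotspot is systematically better; with a large
#' effect the true ordering is recoverable from the per-hotspot mean
#' delta-SLE.
#'
#' @param n_hotspots,n_fragments,n_molecules Table dimensions (molecules =
#'   elaborations per fragment-hotspot pool, plus one ground truth).
#' @param effect_size Per-rank LE decrement, in pooled standard deviations.
#' @param seed Integer seed.
#' @return List with `table` (a score table) and `true_order` (hotspot
#'   ranks, best first).
#' @export
generate_score_table <- function(n_hotspots = 3L, n_fragments = 5L,
                                 n_molecules = 25L, effect_size = 2.0,
                                 seed = 1L) {
  stopifnot(n_hotspots >= 1, n_fragments >= 1, n_molecules >= 1)
  with_seed(seed, {
    rows <- list()
    for (h in seq_len(n_hotspots)) {
      for (f in seq_len(n_fragments)) {
        ha_gt <- sample(8:15, 1)
        le_gt <- stats::rnorm(1, 0, 1)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          molecule_id = sprintf("h%d_f%d_gt", h, f),
          fragment_id = sprintf("f%d", f), hotspot_rank = h,
          docking_score = le_gt * ha_gt, heavy_atoms = ha_gt,
          is_ground_truth = TRUE)
        ha <- sample(10:25, n_molecules, replace = TRUE)
        le <- stats::rnorm(n_molecules, -(h - 1) * effect_size, 1)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          molecule_id = sprintf("h%d_f%d_m%d", h, f, seq_len(n_molecules)),
          fragment_id = sprintf("f%d", f), hotspot_rank = h,
          docking_score = le * ha, heavy_atoms = ha,
          is_ground_truth = FALSE)
      }
    }
    list(table = dplyr::bind_rows(rows), true_order = seq_len(n_hotspots))
  })
}
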