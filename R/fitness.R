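# Fitness proxies. The framework is fitness-agnostic: any per-model scalar
# works. The default proxy is thermodynamic stability, as the unfolding
# free energy per residue (raw unfolding energies are not comparable across
# proteins of different size).

#' Unfolding energy per residue
#'
#' @param delta_g Unfolding free energy, kcal/mol.
#' @param r Residue count (>= 1).
#' @return `delta_g / r`, kcal/mol/residue.
#' @export
per_residue_energy <- function(delta_g, r) {
  if (any(r < 1)) abort("residue count must be >= 1")
  delta_g / r
}

#' Stability-times-efficiency fitness
#'
#' Couples stability with catalytic efficiency on a common substrate:
#' unfolding energy multiplied by kcat / KM.
#'
#' @param delta_g Unfolding free energy, kcal/mol.
#' @param kcat Turnover number, 1/s.
#' @param km Michaelis constant, M (> 0).
#' @return Fitness value `delta_g * kcat / km`.
#' @export
combined_fitness <- function(delta_g, kcat, km) {
  if (any(km <= 0)) abort("KM must be positive")
  delta_g * kcat / km
}

#' Read a per-model energy (fitness) table
#'
#' Parses a tab-separated table of per-model total energies, e.g. tabulated
#' FoldX output. Expected header: `structure_id`, `model_id`,
#' `total_energy`; optional columns `n_residues`, `kcat`, `km`,
#' `substrate_id`. Per-residue energy is computed when a residue count is
#' available (explicit column or the `n_residues` argument); the combined
#' stability-efficiency fitness is added when `kcat` and `km` are both
#' present, which requires a single common `substrate_id`.
#'
#' @param path File path.
#' @param n_residues Optional named integer vector (names = structure ids)
#'   supplying residue counts when the file has no `n_residues` column,
#'   e.g. landmark counts from the analysis.
#' @param negate_energy If `TRUE`, the sign of `total_energy` is flipped on
#'   input. Whether raw totals need negation so that larger means more
#'   stable depends on the producing program's convention; the loader never
#'   guesses.
#' @return Tibble with columns `structure_id`, `model_id`, `dg_unfold`,
#'   `n_residues`, `dg_hat`, and when available `kcat`, `km`,
#'   `substrate_id`, `fitness`.
#' @export
read_energy_table <- function(path, n_residues = NULL, negate_energy = FALSE) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    structure_id = readr::col_character(),
    model_id = readr::col_integer(),
    .default = readr::col_guess()
  ))
  if (nrow(tbl) == 0L) {
    warn("empty energy table")
    return(tibble::tibble(structure_id = character(), model_id = integer(),
                          dg_unfold = numeric(), n_residues = integer(),
                          dg_hat = numeric()))
  }
  need <- c("structure_id", "model_id", "total_energy")
  if (!all(need %in% names(tbl))) {
    abort(sprintf("energy table must have columns: %s", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(tbl[c("structure_id", "model_id")])) {
    abort("duplicate (structure_id, model_id) keys in energy table")
  }
  out <- tibble::tibble(
    structure_id = tbl$structure_id,
    model_id = tbl$model_id,
    dg_unfold = if (negate_energy) -tbl$total_energy else tbl$total_energy
  )
  if ("n_residues" %in% names(tbl)) {
    out$n_residues <- as.integer(tbl$n_residues)
  } else if (!is.null(n_residues)) {
    out$n_residues <- as.integer(n_residues[out$structure_id])
  } else {
    out$n_residues <- NA_integer_
  }
  out$dg_hat <- ifelse(is.na(out$n_residues), NA_real_,
                       per_residue_energy(out$dg_unfold,
                                          pmax(out$n_residues, 1L)))
  if (all(c("kcat", "km") %in% names(tbl))) {
    if ("substrate_id" %in% names(tbl) &&
        length(unique(tbl$substrate_id)) > 1L) {
      abort("combined fitness requires a single common substrate_id")
    }
    out$kcat <- tbl$kcat
    out$km <- tbl$km
    if ("substrate_id" %in% names(tbl)) out$substrate_id <- tbl$substrate_id
    out$fitness <- combined_fitness(out$dg_unfold, out$kcat, out$km)
  }
  out
}

#' Pick target and source models from a fitness table
#'
#' By default the target is the model with the highest fitness and the
#' source the one with the lowest (any source-to-target gradient is valid;
#' the extremes are merely the natural default). Ties break toward the
#' lexicographically lowest (structure_id, model_id). An explicit pair
#' passes through unchanged.
#'
#' @param table Fitness tibble (e.g. from [read_energy_table()]).
#' @param fitness_col Name of the fitness column (default `"dg_hat"`,
#'   falling back to `"dg_unfold"` if absent or all-`NA`).
#' @param target,source Optional explicit `c(structure_id, model_id)`
#'   pairs overriding the extremes.
#' @return Tibble with two rows (`role` = `"target"`, `"source"`) and the
#'   corresponding keys and fitness values.
#' @export
select_extremes <- function(table, fitness_col = "dg_hat",
                            target = NULL, source = NULL) {
  if (nrow(table) < 2L) abort("need at least 2 models to pick extremes")
  if (!fitness_col %in% names(table) || all(is.na(table[[fitness_col]]))) {
    fitness_col <- "dg_unfold"
  }
  f <- table[[fitness_col]]
  if (is.null(f)) abort(sprintf("fitness column '%s' not found", fitness_col))
  ord <- order(table$structure_id, table$model_id)
  pick <- function(idx_set) {
    cand <- intersect(ord, idx_set)
    cand[1L]
  }
  i_target <- if (is.null(target)) pick(which(f == max(f))) else {
    which(table$structure_id == target[[1L]] &
            table$model_id == as.integer(target[[2L]]))[1L]
  }
  i_source <- if (is.null(source)) pick(which(f == min(f))) else {
    which(table$structure_id == source[[1L]] &
            table$model_id == as.integer(source[[2L]]))[1L]
  }
  if (is.na(i_target) || is.na(i_source)) {
    abort("requested target/source model not present in the fitness table")
  }
  tibble::tibble(
    role = c("target", "source"),
    structure_id = table$structure_id[c(i_target, i_source)],
    model_id = table$model_id[c(i_target, i_source)],
    fitness = f[c(i_target, i_source)]
  )
}

#' Fitness surface over the leading shape principal components
#'
#' Projects every aligned shape onto the first two principal components of
#' the phenotype matrix and pairs the scores with the per-model fitness,
#' giving the (PC1, PC2, fitness) triples of a fitness-surface plot.
#' Eigenvector signs are fixed so that each component's largest-magnitude
#' loading is positive.
#'
#' @param data Phenotype tibble (n >= 3 rows).
#' @param table Fitness tibble covering every row of `data`.
#' @param fitness_col Fitness column name, as in [select_extremes()].
#' @return Tibble `structure_id`, `model_id`, `pc1`, `pc2`, `fitness`, of
#'   class `"fitness_surface"`; eigenvalues of all components in attribute
#'   `"eigenvalues"`.
#' @export
fitness_surface <- function(data, table, fitness_col = "dg_hat") {
  m <- pheno_matrix(data)
  if (nrow(m) < 3L) abort("need at least 3 observations for a fitness surface")
  if (!fitness_col %in% names(table) || all(is.na(table[[fitness_col]]))) {
    fitness_col <- "dg_unfold"
  }
  key_data <- paste(data$structure_id, data$model_id, sep = ":")
  key_tab <- paste(table$structure_id, table$model_id, sep = ":")
  idx <- match(key_data, key_tab)
  if (anyNA(idx)) {
    abort(sprintf("fitness table does not cover model(s): %s",
                  paste(head(key_data[is.na(idx)], 5L), collapse = ", ")))
  }
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  flip <- function(v) if (v[which.max(abs(v))] < 0) -1 else 1
  s1 <- flip(pc$rotation[, 1L]); s2 <- flip(pc$rotation[, 2L])
  out <- tibble::tibble(
    structure_id = data$structure_id, model_id = data$model_id,
    pc1 = s1 * unname(pc$x[, 1L]), pc2 = s2 * unname(pc$x[, 2L]),
    fitness = table[[fitness_col]][idx]
  )
  attr(out, "eigenvalues") <- pc$sdev^2
  class(out) <- c("fitness_surface", class(out))
  out
}

#' @rdname fitness_surface
#' @param object A `fitness_surface` tibble.
#' @param ... Unused.
#' @export
autoplot.fitness_surface <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                       colour = .data$fitness)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = "PC1 (Å)", y = "PC2 (Å)", colour = "fitness",
                  title = "Fitness surface over leading shape components")
}
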