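#' Compute the centroid landmark of a residue
#'
#' A residue is abstracted as a single 3-D landmark: the unweighted mean of
#' the coordinates of its side-chain heavy atoms together with the alpha
#' carbon. Backbone N, C, O (and terminal OXT) are excluded so that the
#' landmark tracks side-chain position as well as backbone placement through
#' CA; hydrogens are never counted. For glycine, which has no side-chain
#' heavy atom, the centroid is exactly the CA position.
#'
#' @param atoms Data frame of atoms with columns `elety` (PDB atom name),
#'   `x`, `y`, `z`, and optionally `element` (element symbol; inferred from
#'   `elety` when absent).
#' @param strict_con If `TRUE`, restrict side-chain atoms to elements C, N
#'   and O, excluding sulfur/selenium (affects Cys, Met, Mse). The default
#'   `FALSE` uses all non-hydrogen side-chain atoms.
#' @return Numeric vector `c(x, y, z)` in Angstrom.
#' @export
#' @examples
#' ala <- data.frame(elety = c("N", "CA", "C", "O", "CB"),
#'                   x = c(0, 0, 1, 2, 2), y = 0, z = 0)
#' residue_centroid(ala) # mean of CA and CB
residue_centroid <- function(atoms, strict_con = FALSE) {
  stopifnot(is.data.frame(atoms), all(c("elety", "x", "y", "z") %in% names(atoms)))
  if (!"CA" %in% atoms$elety) {
    abort("residue has no CA atom; cannot place a landmark")
  }
  el <- .atom_elements(atoms)
  keep <- .centroid_atoms(atoms$elety, el, strict_con = strict_con)
  m <- as.matrix(atoms[keep, c("x", "y", "z")])
  if (!all(is.finite(m))) abort("residue has non-finite coordinates")
  colMeans(m)
}

# element symbols, from `element` column or inferred from the atom name
.atom_elements <- function(atoms) {
  if ("element" %in% names(atoms) && !all(is.na(atoms$element) | atoms$element == "")) {
    el <- toupper(trimws(as.character(atoms$element)))
    miss <- is.na(el) | el == ""
    if (any(miss)) el[miss] <- .infer_element(atoms$elety[miss])
    return(el)
  }
  .infer_element(atoms$elety)
}

.infer_element <- function(elety) {
  nm <- gsub("^[0-9]+", "", trimws(as.character(elety)))
  two <- toupper(substr(nm, 1, 2))
  one <- toupper(substr(nm, 1, 1))
  ifelse(two %in% c("SE", "FE", "MG", "ZN", "CL", "BR"), two,
         ifelse(one %in% c("H", "D"), "H", one))
}

# logical selector of atoms entering the centroid
.centroid_atoms <- function(elety, element, strict_con = FALSE) {
  elety <- trimws(elety)
  backbone <- elety %in% c("N", "C", "O", "OXT")
  hydrogen <- element %in% c("H", "D")
  keep <- !backbone & !hydrogen
  if (strict_con) keep <- keep & (element %in% c("C", "N", "O") | elety == "CA")
  keep | elety == "CA"
}

#' Read a multi-model PDB file as a landmark ensemble
#'
#' Parses a PDB file (MODEL/ENDMDL records delimit molecular-dynamics
#' snapshots or NMR models; a file without MODEL records is a single model)
#' and reduces each model to one 3-D centroid landmark per amino-acid
#' residue. Waters, hetero groups and hydrogens are excluded. Residues
#' missing a CA atom, or with non-finite coordinates in any model, are
#' dropped from every model of the structure with a warning.
#'
#' @param path Path to a PDB file.
#' @param structure_id Identifier recorded for this structure; defaults to
#'   the file name without extension.
#' @param strict_con Passed to [residue_centroid()].
#' @return A landmark tibble with columns `structure_id`, `model_id`,
#'   `chain`, `resnum`, `icode`, `resname`, `x`, `y`, `z`; residues ordered
#'   by (chain, resnum, icode) identically in every model.
#' @export
read_ensemble <- function(path, structure_id = NULL,
                          strict_con = FALSE) {
  if (!file.exists(path)) abort(sprintf("PDB file not found: %s", path))
  structure_id <- structure_id %||% sub("\\.[^.]*$", "", basename(path))
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) abort(sprintf("cannot parse PDB file %s: %s",
                                      path, conditionMessage(e)))
  )
  at <- pdb$atom
  at$chain <- ifelse(is.na(at$chain), "", at$chain)
  at$insert <- ifelse(is.na(at$insert), "", at$insert)
  at$alt <- ifelse(is.na(at$alt), "", at$alt)
  at$row <- seq_len(nrow(at))

  # amino-acid ATOM records only: no waters, no hetero groups
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (nrow(at) == 0L) abort(sprintf("no ATOM records in %s", path))
  el <- .atom_elements(data.frame(elety = at$elety, element = at$elesy))
  at <- at[!(el %in% c("H", "D")), , drop = FALSE]

  # alternate locations: keep the highest occupancy, ties to the first
  # alt id in alphabetical order
  at <- dplyr::as_tibble(at)
  at <- dplyr::arrange(at, .data$chain, .data$resno, .data$insert,
                       .data$elety, dplyr::desc(.data$o), .data$alt)
  at <- dplyr::distinct(at, .data$chain, .data$resno, .data$insert,
                        .data$elety, .keep_all = TRUE)

  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  n_models <- nrow(xyz)

  key <- paste(at$chain, at$resno, at$insert, sep = "\r")
  res_tbl <- dplyr::distinct(at, .data$chain, .data$resno, .data$insert, .data$resid)
  res_tbl <- dplyr::arrange(res_tbl, .data$chain, .data$resno, .data$insert)
  res_keys <- paste(res_tbl$chain, res_tbl$resno, res_tbl$insert, sep = "\r")

  # residues lacking CA are dropped from the common set
  has_ca <- res_keys %in% key[at$elety == "CA"]
  if (any(!has_ca)) {
    warn(sprintf("%s: dropping %d residue(s) without a CA atom (%s)",
                 structure_id, sum(!has_ca),
                 paste(res_tbl$resno[!has_ca], collapse = ", ")))
    res_tbl <- res_tbl[has_ca, , drop = FALSE]
    res_keys <- res_keys[has_ca]
  }
  if (nrow(res_tbl) == 0L) abort(sprintf("%s: no usable residues", structure_id))

  el <- .atom_elements(data.frame(elety = at$elety, element = at$elesy))
  use <- .centroid_atoms(at$elety, el, strict_con = strict_con) & key %in% res_keys
  sel <- at[use, , drop = FALSE]
  sel_key <- factor(paste(sel$chain, sel$resno, sel$insert, sep = "\r"),
                    levels = res_keys)

  configs <- vector("list", n_models)
  bad <- rep(FALSE, nrow(res_tbl))
  for (m in seq_len(n_models)) {
    co <- matrix(xyz[m, ], ncol = 3L, byrow = TRUE)[sel$row, , drop = FALSE]
    cen <- rowsum(co, sel_key) / as.vector(table(sel_key))
    bad <- bad | !apply(is.finite(cen), 1L, all)
    configs[[m]] <- cen
  }
  if (any(bad)) {
    warn(sprintf("%s: dropping %d residue(s) with non-finite coordinates",
                 structure_id, sum(bad)))
    configs <- lapply(configs, function(cc) cc[!bad, , drop = FALSE])
    res_tbl <- res_tbl[!bad, , drop = FALSE]
  }

  purrr::map_dfr(seq_len(n_models), function(m) {
    tibble::tibble(
      structure_id = structure_id, model_id = m,
      chain = res_tbl$chain, resnum = res_tbl$resno,
      icode = res_tbl$insert, resname = res_tbl$resid,
      x = configs[[m]][, 1L], y = configs[[m]][, 2L], z = configs[[m]][, 3L]
    )
  })
}

#' Read a homology map
#'
#' The homology map lists, for each fully homologous alignment column (a
#' site present in every structure of the analysis, as identified by an
#' external multiple structure alignment), the residue of each structure
#' occupying that column.
#'
#' @param path Tab-separated file with header
#'   `column structure_id chain resnum icode resname`.
#' @return Tibble with those columns; missing `icode`/`chain` become `""`.
#' @export
read_homology_map <- function(path) {
  hmap <- readr::read_tsv(path, col_types = readr::cols(
    column = readr::col_integer(),
    structure_id = readr::col_character(),
    chain = readr::col_character(),
    resnum = readr::col_integer(),
    icode = readr::col_character(),
    resname = readr::col_character()
  ))
  need <- c("column", "structure_id", "chain", "resnum", "icode", "resname")
  if (!all(need %in% names(hmap))) {
    abort(sprintf("homology map must have columns: %s", paste(need, collapse = ", ")))
  }
  hmap$chain[is.na(hmap$chain)] <- ""
  hmap$icode[is.na(hmap$icode)] <- ""
  ids <- unique(hmap$structure_id)
  cnt <- table(hmap$column)
  if (any(cnt != length(ids))) {
    abort("homology map is not fully homologous: some columns miss structures")
  }
  hmap
}

#' Assemble the phenotype matrix from ensembles and a homology map
#'
#' Restricts every landmark configuration to the fully homologous sites of
#' the homology map and concatenates the three coordinates of each site,
#' producing one row per (structure, model) and columns
#' `res<j>_x, res<j>_y, res<j>_z` in the map's column order.
#'
#' @param ensembles A landmark tibble covering all structures (rows from
#'   [read_ensemble()], possibly `dplyr::bind_rows()`-ed), or a list of such
#'   tibbles.
#' @param hmap Homology map tibble from [read_homology_map()].
#' @return A phenotype tibble: `structure_id`, `model_id`, then `3 *
#'   n_columns` coordinate traits.
#' @export
apply_homology_map <- function(ensembles, hmap) {
  if (is.list(ensembles) && !is.data.frame(ensembles)) {
    ensembles <- dplyr::bind_rows(ensembles)
  }
  ids <- unique(hmap$structure_id)
  missing_ids <- setdiff(ids, unique(ensembles$structure_id))
  if (length(missing_ids) > 0L) {
    abort(sprintf("no ensemble provided for structure(s): %s",
                  paste(missing_ids, collapse = ", ")))
  }
  lm <- dplyr::filter(ensembles, .data$structure_id %in% ids)
  lm$chain[is.na(lm$chain)] <- ""
  lm$icode[is.na(lm$icode)] <- ""

  j <- dplyr::inner_join(
    dplyr::select(hmap, "column", "structure_id", "chain", "resnum", "icode"),
    dplyr::select(lm, "structure_id", "model_id", "chain", "resnum", "icode",
                  "x", "y", "z"),
    by = c("structure_id", "chain", "resnum", "icode"),
    relationship = "many-to-many"
  )

  # every (structure, column) must resolve in every model of that structure
  n_models <- dplyr::summarise(dplyr::group_by(lm, .data$structure_id),
                               n_models = dplyr::n_distinct(.data$model_id))
  got <- dplyr::summarise(dplyr::group_by(j, .data$structure_id, .data$column),
                          got = dplyr::n(), .groups = "drop")
  expect <- tidyr::expand_grid(structure_id = ids,
                               column = unique(hmap$column))
  chk <- dplyr::left_join(expect, got, by = c("structure_id", "column"))
  chk <- dplyr::left_join(chk, n_models, by = "structure_id")
  bad <- chk[is.na(chk$got) | chk$got != chk$n_models, , drop = FALSE]
  if (nrow(bad) > 0L) {
    abort(sprintf(
      "homology map names residues absent from the ensemble: %s",
      paste(sprintf("structure %s column %d", bad$structure_id, bad$column),
            collapse = "; ")))
  }

  wide <- tidyr::pivot_wider(
    dplyr::select(j, "structure_id", "model_id", "column", "x", "y", "z"),
    names_from = "column", values_from = c("x", "y", "z"),
    names_glue = "res{column}_{.value}"
  )
  ord <- as.vector(t(outer(unique(hmap$column), c("x", "y", "z"),
                           function(jj, ax) sprintf("res%d_%s", jj, ax))))
  out <- dplyr::arrange(wide[, c("structure_id", "model_id", ord)],
                        .data$structure_id, .data$model_id)
  tibble::as_tibble(out)
}

#' Select the ambassador model of an aligned ensemble
#'
#' The ambassador is the ensemble member geometrically closest to the mean
#' configuration (root-sum-of-squares distance over landmarks); it stands in
#' for the whole ensemble when building the cross-structure alignment. Ties
#' are broken toward the lowest model id.
#'
#' @param ensemble Landmark tibble of one structure, GPS-aligned.
#' @return Integer model id.
#' @export
select_ambassador <- function(ensemble) {
  stopifnot(is.data.frame(ensemble))
  models <- sort(unique(ensemble$model_id))
  if (length(models) == 0L) abort("empty ensemble")
  configs <- lapply(models, function(m) {
    .coords3(ensemble[ensemble$model_id == m, , drop = FALSE])
  })
  k <- unique(vapply(configs, nrow, integer(1)))
  if (length(k) != 1L) abort("models have differing landmark counts")
  mean_cfg <- Reduce(`+`, configs) / length(configs)
  d <- vapply(configs, function(cc) sqrt(sum((cc - mean_cfg)^2)), numeric(1))
  models[which.min(d)]
}

#' Write / read a phenotype tibble as a tab-separated table
#'
#' The file has a header of trait names and a first column
#' `structure_id:model_id`.
#'
#' @param data Phenotype tibble.
#' @param path Output path.
#' @return `write_phenotype()` returns `path` invisibly; `read_phenotype()`
#'   returns the phenotype tibble.
#' @export
write_phenotype <- function(data, path) {
  m <- pheno_matrix(data)
  out <- tibble::as_tibble(m)
  out <- dplyr::bind_cols(
    tibble::tibble(id = paste(data$structure_id, data$model_id, sep = ":")),
    out
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_phenotype
#' @export
read_phenotype <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(), .default = readr::col_double()
  ))
  parts <- strsplit(tbl$id, ":", fixed = TRUE)
  dplyr::bind_cols(
    tibble::tibble(
      structure_id = vapply(parts, `[`, "", 1L),
      model_id = as.integer(vapply(parts, `[`, "", 2L))
    ),
    tbl[, setdiff(names(tbl), "id"), drop = FALSE]
  )
}
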