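# End-to-end orchestration: ensembles -> GPA -> phenotype matrix ->
# covariance decomposition -> fitness-driven selection analysis ->
# artifacts.

# one phenotype row (trait vector, column order res<j>_{x,y,z}) as k x 3
.row_to_config <- function(v) matrix(as.numeric(v), ncol = 3L, byrow = TRUE)

# phenotype tibble -> named list of k x 3 configurations
.pheno_to_configs <- function(data) {
  m <- pheno_matrix(data)
  out <- lapply(seq_len(nrow(m)), function(i) .row_to_config(m[i, ]))
  names(out) <- rownames(m)
  out
}

# write aligned configurations back into the phenotype tibble
.configs_to_pheno <- function(data, configs) {
  m <- t(vapply(configs, function(cc) as.numeric(t(cc)),
                numeric(3L * nrow(configs[[1L]]))))
  traits <- setdiff(names(data), .id_cols)
  data[traits] <- tibble::as_tibble(m, .name_repair = "minimal")
  data
}

#' Run the full comparative quantitative genetics pipeline
#'
#' Executes, in order: per-ensemble GPA, ambassador selection, assembly of
#' the homology-restricted phenotype matrix, a global GPA over the pooled
#' shapes, the V_P / W / B covariance decomposition, target/source
#' selection from the fitness table, the realized response, selection and
#' dynamic gradients (on B and on W), constraint and eigenspace angles,
#' per-residue gradient maps and residue rankings. All numeric outputs are
#' reproducible bit-exactly from the same config.
#'
#' @param config Named list:
#'   \describe{
#'     \item{ensembles}{Named vector of PDB paths (names = structure ids),
#'       or a pre-built landmark tibble covering all structures.}
#'     \item{homology_map}{Path to a homology-map TSV, or its tibble.}
#'     \item{energy_table}{Optional path/tibble of per-model energies.}
#'     \item{target, source}{Optional explicit `c(structure_id, model_id)`
#'       pairs; default: fitness extremes.}
#'     \item{reference}{Structure id whose author numbering labels residues
#'       in rankings (default: the source structure).}
#'     \item{scale, gpa_tol, gpa_max_iter}{GPA options, see [gpa()].}
#'     \item{inv_tol, ridge}{Pseudo-inverse options, see [pseudo_inverse()].}
#'     \item{fraction}{Eigenvalue share for [subspace_angle()] (0.99).}
#'     \item{top}{Rows per ranking panel (5).}
#'     \item{n_skewers, seed}{Skewer count and seed for the B-vs-W matrix
#'       comparison recorded in the bundle.}
#'     \item{negate_energy, strict_con}{Loader options.}
#'     \item{out_dir}{Optional directory; when set, all artifacts and a run
#'       manifest are written there.}
#'   }
#' @return Object of class `"shapeselect_run"` with elements `pheno`,
#'   `decomposition`, `extremes`, `delta_z`, `selection_G`, `selection_M`,
#'   `angles`, `ambassadors`, `gpa_global`, `config`.
#' @export
run_pipeline <- function(config) {
  cfg <- utils::modifyList(list(
    scale = FALSE, gpa_tol = 1e-10, gpa_max_iter = 100L,
    inv_tol = NULL, ridge = NULL, fraction = 0.99, top = 5L,
    n_skewers = 1000L, seed = NULL, negate_energy = FALSE,
    strict_con = FALSE, out_dir = NULL, target = NULL, source = NULL,
    reference = NULL, energy_table = NULL
  ), config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  landmarks <- stage("read_ensembles", {
    if (is.data.frame(cfg$ensembles)) cfg$ensembles
    else dplyr::bind_rows(purrr::imap(
      as.list(cfg$ensembles),
      function(p, id) read_ensemble(p, structure_id = id,
                                    strict_con = cfg$strict_con)))
  })
  hmap <- stage("homology_map", {
    if (is.data.frame(cfg$homology_map)) cfg$homology_map
    else read_homology_map(cfg$homology_map)
  })

  ids <- unique(landmarks$structure_id)
  aligned <- stage("gpa_within", {
    dplyr::bind_rows(lapply(ids, function(id) {
      fit <- gpa(landmarks[landmarks$structure_id == id, , drop = FALSE],
                 scale = cfg$scale, tol = cfg$gpa_tol,
                 max_iter = cfg$gpa_max_iter)
      fit$aligned
    }))
  })
  ambassadors <- stage("ambassadors", {
    setNames(vapply(ids, function(id) {
      select_ambassador(aligned[aligned$structure_id == id, , drop = FALSE])
    }, integer(1)), ids)
  })

  pheno <- stage("phenotype_matrix", apply_homology_map(aligned, hmap))
  gpa_global <- stage("gpa_global", {
    gpa(.pheno_to_configs(pheno), scale = cfg$scale, tol = cfg$gpa_tol,
        max_iter = cfg$gpa_max_iter)
  })
  pheno <- .configs_to_pheno(pheno, gpa_global$aligned)

  decomposition <- stage("covariance", covariance_decomposition(pheno))

  fit_tbl <- stage("fitness", {
    if (is.null(cfg$energy_table)) NULL
    else if (is.data.frame(cfg$energy_table)) cfg$energy_table
    else {
      counts <- table(landmarks$structure_id[landmarks$model_id == 1L])
      read_energy_table(cfg$energy_table,
                        n_residues = setNames(as.integer(counts), names(counts)),
                        negate_energy = cfg$negate_energy)
    }
  })
  extremes <- stage("select_extremes", {
    if (!is.null(fit_tbl)) {
      select_extremes(fit_tbl, target = cfg$target, source = cfg$source)
    } else if (!is.null(cfg$target) && !is.null(cfg$source)) {
      tibble::tibble(
        role = c("target", "source"),
        structure_id = c(cfg$target[[1L]], cfg$source[[1L]]),
        model_id = as.integer(c(cfg$target[[2L]], cfg$source[[2L]])),
        fitness = NA_real_)
    } else {
      abort("no energy_table and no explicit target/source pair")
    }
  })

  m <- pheno_matrix(pheno)
  key <- rownames(m)
  row_of <- function(role) {
    r <- extremes[extremes$role == role, ]
    i <- match(paste(r$structure_id, r$model_id, sep = ":"), key)
    if (is.na(i)) abort(sprintf("%s model %s:%d not in the phenotype matrix",
                                role, r$structure_id, r$model_id))
    m[i, ]
  }
  delta_z <- stage("realized_response",
                   realized_response(row_of("target"), row_of("source")))

  ref_id <- cfg$reference %||% extremes$structure_id[extremes$role == "source"]
  labels <- stage("labels", {
    ref <- hmap[hmap$structure_id == ref_id, , drop = FALSE]
    ref <- ref[match(unique(hmap$column), ref$column), , drop = FALSE]
    tibble::tibble(res_index = ref$resnum, res_name = ref$resname)
  })

  degenerate <- all(delta_z == 0)
  sel <- function(mat, tag) {
    if (degenerate) {
      k <- length(delta_z) %/% 3L
      structure(list(
        delta_z = delta_z, beta = rep(0, length(delta_z)), matrix_used = tag,
        theta_constraint = NA_real_, theta_response = NA_real_,
        theta_gradient = NA_real_, fraction = cfg$fraction,
        per_residue = rep(0, k),
        ranking = rank_residues(rep(0, length(delta_z)), delta_z,
                                labels = labels, top = min(cfg$top, k))),
        class = "selection_analysis")
    } else {
      k <- length(delta_z) %/% 3L
      selection_analysis(mat, delta_z, matrix_used = tag, tol = cfg$inv_tol,
                         ridge = cfg$ridge, labels = labels,
                         top = min(cfg$top, k), fraction = cfg$fraction)
    }
  }
  selection_G <- stage("selection_gradient", sel(decomposition$B, "G"))
  selection_M <- stage("dynamic_gradient", sel(decomposition$W, "M"))

  angles <- tibble::tibble(
    angle = c("theta", "theta_M", "theta_dz_beta", "theta_dz_beta_M",
              "theta_beta", "theta_beta_M"),
    degrees = c(selection_G$theta_response, selection_M$theta_response,
                selection_G$theta_constraint, selection_M$theta_constraint,
                selection_G$theta_gradient, selection_M$theta_gradient),
    description = c(
      "response vs 99% eigenspace of G",
      "response vs 99% eigenspace of M",
      "response vs selection gradient",
      "response vs dynamic gradient",
      "selection gradient vs 99% eigenspace of G",
      "dynamic gradient vs 99% eigenspace of M")
  )

  run <- structure(
    list(pheno = pheno, decomposition = decomposition, extremes = extremes,
         delta_z = delta_z, selection_G = selection_G,
         selection_M = selection_M, angles = angles,
         ambassadors = ambassadors, gpa_global = gpa_global,
         labels = labels, config = cfg),
    class = "shapeselect_run"
  )
  if (!is.null(cfg$out_dir)) write_run_artifacts(run, cfg$out_dir)
  run
}

#' @export
print.shapeselect_run <- function(x, ...) {
  cat("shapeselect pipeline run\n")
  print(x$decomposition)
  cat(sprintf("  target: %s:%d   source: %s:%d\n",
              x$extremes$structure_id[1L], x$extremes$model_id[1L],
              x$extremes$structure_id[2L], x$extremes$model_id[2L]))
  print(x$angles, n = nrow(x$angles))
  invisible(x)
}

#' Write all artifacts of a pipeline run
#'
#' Emits the phenotype matrix, the three covariance matrices, the gradient
#' vectors, per-residue maps, ranking tables, the angle table and a plain
#' run manifest into `dir`.
#'
#' @param run A `shapeselect_run` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_artifacts <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)
  write_phenotype(run$pheno, fp("phenotype.tsv"))
  write_covariance(run$decomposition$V_P, fp("V_P.tsv"))
  write_covariance(run$decomposition$W, fp("W.tsv"))
  write_covariance(run$decomposition$B, fp("B.tsv"))
  readr::write_tsv(run$extremes, fp("extremes.tsv"))
  readr::write_tsv(run$angles, fp("angles.tsv"))
  traits <- colnames(run$decomposition$V_P)
  readr::write_tsv(tibble::tibble(
    trait = traits, delta_z = run$delta_z,
    beta_G = run$selection_G$beta, beta_M = run$selection_M$beta
  ), fp("gradients.tsv"))
  readr::write_tsv(tibble::tibble(
    res_index = run$labels$res_index, res_name = run$labels$res_name,
    magnitude_G = run$selection_G$per_residue,
    magnitude_M = run$selection_M$per_residue
  ), fp("per_residue.tsv"))
  readr::write_tsv(run$selection_G$ranking, fp("ranking_G.tsv"))
  readr::write_tsv(run$selection_M$ranking, fp("ranking_M.tsv"))

  cfg <- run$config
  scal <- vapply(cfg, function(v) is.atomic(v) && length(v) <= 2L, logical(1))
  lines <- c(
    sprintf("package_version: %s",
            as.character(utils::packageVersion("shapeselect"))),
    sprintf("r_version: %s", R.version.string),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    vapply(names(cfg)[scal], function(nm) {
      sprintf("%s: %s", nm, paste(format(cfg[[nm]]), collapse = ","))
    }, character(1)),
    sprintf("ambassadors: %s",
            paste(sprintf("%s=%d", names(run$ambassadors), run$ambassadors),
                  collapse = ","))
  )
  writeLines(lines, fp("manifest.txt"))
  invisible(dir)
}

#' Annotate a PDB file with per-residue gradient magnitudes
#'
#' Writes a copy of the source structure with the B-factor column carrying
#' `100 x` the standardized per-residue value for homologous residues and a
#' `-1.00` sentinel for non-homologous residues, so that any molecular
#' viewer can render the gradient map by coloring on B-factor.
#'
#' @param source_pdb Path to the source structure.
#' @param values Tibble with one row per homologous residue: columns
#'   `resnum`, `value` (in \[0, 1\]) and optionally `chain`, `icode`.
#' @param out Output PDB path.
#' @return `out`, invisibly.
#' @export
write_gradient_pdb <- function(source_pdb, values, out) {
  stopifnot(is.data.frame(values), all(c("resnum", "value") %in% names(values)))
  if (any(values$value < 0 | values$value > 1)) {
    abort("values must be standardized to [0, 1]")
  }
  pdb <- bio3d::read.pdb(source_pdb, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at_chain <- ifelse(is.na(at$chain), "", at$chain)
  at_icode <- ifelse(is.na(at$insert), "", at$insert)
  keys <- if ("chain" %in% names(values)) {
    paste(values$chain, values$resnum,
          if ("icode" %in% names(values)) values$icode else "", sep = "\r")
  } else paste(at_chain[match(values$resnum, at$resno)], values$resnum, "", sep = "\r")
  atom_key <- paste(at_chain, at$resno, at_icode, sep = "\r")
  idx <- match(atom_key, keys)
  if (!all(keys %in% atom_key)) {
    abort("residue mismatch: some values do not match a residue in the PDB")
  }
  pdb$atom$b <- ifelse(is.na(idx), -1, 100 * values$value[idx])
  bio3d::write.pdb(pdb, file = out)
  invisible(out)
}
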