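# Fixtures are built in code: toy PDB files, landmark tibbles, homology
# maps and energy tables are written to tempfiles at test time.

# --- oracles shared across files -------------------------------------------

# elementwise brute-force sample covariance (independent of cov())
brute_cov <- function(m) {
  mu <- colMeans(m)
  acc <- matrix(0, ncol(m), ncol(m))
  for (i in seq_len(nrow(m))) acc <- acc + tcrossprod(m[i, ] - mu)
  acc / (nrow(m) - 1)
}

# Independent closed-form oracle for the optimal proper-rotation RMSD:
# computed from the singular values of the cross-covariance only, never
# constructing the rotation (and so independent of the alignment path).
kabsch_rmsd_oracle <- function(X, Y) {
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  d <- svd(crossprod(Xc, Yc))$d
  s <- sign(det(crossprod(Xc, Yc)))
  if (s == 0) s <- 1
  sqrt(max(0, sum(Xc^2) + sum(Yc^2) - 2 * sum(d * c(1, 1, s))) / nrow(X))
}

# --- geometry helpers -------------------------------------------------------

rand_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid <- function(m, R = diag(3), t = c(0, 0, 0)) {
  sweep(m %*% R, 2L, t, `+`)
}

rot_z_90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)

# landmark tibble from a named list of k x 3 matrices per (structure, model)
landmark_tbl <- function(configs, structure_id = "s1") {
  dplyr::bind_rows(lapply(seq_along(configs), function(i) {
    m <- configs[[i]]
    tibble::tibble(structure_id = structure_id, model_id = i,
                   chain = "A", resnum = seq_len(nrow(m)), icode = "",
                   resname = "ALA",
                   x = m[, 1], y = m[, 2], z = m[, 3])
  }))
}

# --- toy PDB writer ---------------------------------------------------------

pdb_atom_line <- function(serial, elety, resname, chain, resnum, x, y, z,
                          element = substr(trimws(elety), 1, 1),
                          record = "ATOM") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial,
          if (nchar(elety) < 4) paste0(" ", elety) else elety,
          " ", resname, chain, resnum, " ", x, y, z, 1.00, 0.00, element)
}

# residues: list of lists with resname, resnum, atoms = data.frame(elety, x, y, z)
write_toy_pdb <- function(path, residues, n_models = 1L,
                          jitter = function(m, xyz) xyz,
                          extra_lines = character()) {
  lines <- character()
  for (m in seq_len(n_models)) {
    if (n_models > 1L) lines <- c(lines, sprintf("MODEL     %4d", m))
    serial <- 0L
    for (res in residues) {
      for (i in seq_len(nrow(res$atoms))) {
        serial <- serial + 1L
        a <- res$atoms[i, ]
        xyz <- jitter(m, c(a$x, a$y, a$z))
        lines <- c(lines, pdb_atom_line(serial, a$elety, res$resname, "A",
                                        res$resnum, xyz[1], xyz[2], xyz[3]))
      }
    }
    lines <- c(lines, extra_lines)
    if (n_models > 1L) lines <- c(lines, "ENDMDL")
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  path
}

toy_residue <- function(resname, resnum, shift = c(0, 0, 0)) {
  atoms <- switch(resname,
    GLY = data.frame(elety = c("N", "CA", "C", "O"),
                     x = c(-1.4, 0, 1.5, 2.1), y = c(0.2, 0, 0, 1.1), z = 0),
    ALA = data.frame(elety = c("N", "CA", "C", "O", "CB"),
                     x = c(-1.4, 0, 1.5, 2.1, 0.2),
                     y = c(0.2, 0, 0, 1.1, 1.4), z = c(0, 0, 0, 0, 0.8)),
    CYS = data.frame(elety = c("N", "CA", "C", "O", "CB", "SG"),
                     x = c(-1.4, 0, 1.5, 2.1, 0.2, 0.5),
                     y = c(0.2, 0, 0, 1.1, 1.4, 2.2), z = c(0, 0, 0, 0, 0.8, 2.1)),
    stop("unknown toy residue"))
  atoms$x <- atoms$x + shift[1]; atoms$y <- atoms$y + shift[2]
  atoms$z <- atoms$z + shift[3]
  list(resname = resname, resnum = resnum, atoms = atoms)
}

toy_protein <- function(resnames = c("ALA", "GLY", "CYS")) {
  lapply(seq_along(resnames), function(i) {
    toy_residue(resnames[i], i, shift = c(3.8 * (i - 1), (i %% 2) * 1.5, 0))
  })
}

write_hmap <- function(path, structures, columns, resnums = NULL) {
  # default: column j maps to residue j in every structure
  rows <- purrr::map_dfr(columns, function(j) {
    tibble::tibble(column = j, structure_id = structures, chain = "A",
                   resnum = if (is.null(resnums)) j else resnums[[as.character(j)]],
                   icode = "", resname = "ALA")
  })
  readr::write_tsv(rows, path)
  path
}

write_energy_tsv <- function(path, df) {
  readr::write_tsv(df, path)
  path
}

# phenotype tibble from a plain matrix + group labels
pheno_tbl <- function(m, groups) {
  colnames(m) <- sprintf("tr%d", seq_len(ncol(m)))
  dplyr::bind_cols(
    tibble::tibble(structure_id = as.character(groups),
                   model_id = stats::ave(seq_along(groups), groups,
                                         FUN = seq_along)),
    tibble::as_tibble(m)
  )
}
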