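test_that("residue centroid follows the side-chain-plus-CA rule", {
  # glycine: no side-chain heavy atoms, centroid is the CA exactly
  gly <- data.frame(elety = c("N", "CA", "C", "O"),
                    x = c(-1.4, 0.7, 1.5, 2.1), y = c(0.2, -0.3, 0, 1.1),
                    z = c(0, 0.5, 0, 0))
  expect_identical(residue_centroid(gly), c(x = 0.7, y = -0.3, z = 0.5))

  # alanine-like: mean of CA and CB, backbone excluded
  ala <- data.frame(elety = c("N", "CA", "C", "O", "CB"),
                    x = c(9, 0, 9, 9, 2), y = c(9, 0, 9, 9, 0),
                    z = c(9, 0, 9, 9, 0))
  expect_equal(unname(residue_centroid(ala)), c(1, 0, 0))

  # side chain on the 8 corners of a unit cube centered on CA at the origin
  corners <- expand.grid(x = c(-0.5, 0.5), y = c(-0.5, 0.5), z = c(-0.5, 0.5))
  cube <- rbind(data.frame(elety = "CA", x = 0, y = 0, z = 0),
                data.frame(elety = paste0("C", 1:8), corners))
  expect_equal(unname(residue_centroid(cube)), c(0, 0, 0))

  # hydrogens never count; strict CON drops sulfur
  cys <- data.frame(elety = c("N", "CA", "C", "O", "CB", "SG", "HB2"),
                    x = c(9, 0, 9, 9, 1, 5, 50), y = 0, z = 0)
  expect_equal(unname(residue_centroid(cys)), c(2, 0, 0))
  expect_equal(unname(residue_centroid(cys, strict_con = TRUE)), c(0.5, 0, 0))

  expect_error(residue_centroid(data.frame(elety = "CB", x = 1, y = 1, z = 1)),
               "CA")
})

test_that("residue centroid is rigid-motion equivariant", {
  set.seed(42)
  for (i in 1:10) {
    atoms <- data.frame(elety = c("CA", paste0("C", 1:5)),
                        x = rnorm(6), y = rnorm(6), z = rnorm(6))
    R <- rand_rotation(); t <- rnorm(3)
    moved <- atoms
    xyz <- apply_rigid(as.matrix(atoms[, c("x", "y", "z")]), R, t)
    moved[, c("x", "y", "z")] <- xyz
    expect_equal(unname(residue_centroid(moved)),
                 unname(drop(residue_centroid(atoms) %*% R) + t),
                 tolerance = 1e-9)
  }
})

test_that("read_ensemble parses single- and multi-model toy PDBs", {
  p1 <- write_toy_pdb(withr::local_tempfile(fileext = ".pdb"), toy_protein())
  lm1 <- read_ensemble(p1, "toy")
  expect_equal(unique(lm1$model_id), 1L)
  expect_equal(nrow(lm1), 3L)
  expect_equal(lm1$resname, c("ALA", "GLY", "CYS"))

  p5 <- write_toy_pdb(withr::local_tempfile(fileext = ".pdb"), toy_protein(),
                      n_models = 5L)
  lm5 <- read_ensemble(p5, "toy")
  expect_equal(sort(unique(lm5$model_id)), 1:5)
  for (m in 2:5) {
    expect_identical(lm5[lm5$model_id == m, c("x", "y", "z")],
                     lm5[lm5$model_id == 1, c("x", "y", "z")])
  }
})

test_that("waters are excluded and missing CA drops the residue", {
  water <- pdb_atom_line(99, "O", "HOH", "A", 200, 0, 0, 0, record = "HETATM")
  pw <- write_toy_pdb(withr::local_tempfile(fileext = ".pdb"), toy_protein(),
                      extra_lines = water)
  lm <- read_ensemble(pw, "toy")
  expect_equal(nrow(lm), 3L)
  expect_false(200 %in% lm$resnum)

  # a residue without CA is dropped with a warning
  broken <- toy_protein()
  broken[[2]]$atoms <- broken[[2]]$atoms[broken[[2]]$atoms$elety != "CA", ]
  pb <- write_toy_pdb(withr::local_tempfile(fileext = ".pdb"), broken)
  expect_warning(lmb <- read_ensemble(pb, "toy"), "CA")
  expect_equal(lmb$resnum, c(1L, 3L))
})

test_that("apply_homology_map concatenates coordinates in map order", {
  set.seed(7)
  cfg <- lapply(1:2, function(i) matrix(rnorm(12), 4))
  lm <- dplyr::bind_rows(landmark_tbl(cfg, "sA"), landmark_tbl(cfg, "sB"))
  hp <- write_hmap(withr::local_tempfile(fileext = ".tsv"),
                   c("sA", "sB"), 1:4)
  hmap <- read_homology_map(hp)
  ph <- apply_homology_map(lm, hmap)
  expect_equal(dim(ph), c(4L, 2L + 12L))
  expect_equal(names(ph)[3:5], c("res1_x", "res1_y", "res1_z"))
  # reading back column block j reproduces the mapped residue's centroid
  for (j in 1:4) {
    got <- as.numeric(ph[ph$structure_id == "sA" & ph$model_id == 2,
                         sprintf("res%d_%s", j, c("x", "y", "z"))])
    expect_identical(got, as.numeric(cfg[[2]][j, ]))
  }

  # restricting the map drops the corresponding trait columns
  hp3 <- write_hmap(withr::local_tempfile(fileext = ".tsv"),
                    c("sA", "sB"), c(1L, 2L, 4L))
  ph3 <- apply_homology_map(lm, read_homology_map(hp3))
  expect_equal(ncol(ph3), 2L + 9L)
  expect_false(any(grepl("^res3_", names(ph3))))

  # unknown residue index is a missing-homology error naming the column
  hbad <- tibble::tibble(column = 1L, structure_id = c("sA", "sB"),
                         chain = "A", resnum = c(999L, 1L), icode = "",
                         resname = "ALA")
  expect_error(apply_homology_map(lm, hbad), "sA column 1")
})

test_that("dropping a model leaves other phenotype rows bit-identical", {
  set.seed(8)
  cfg <- lapply(1:3, function(i) matrix(rnorm(9), 3))
  lm <- landmark_tbl(cfg, "sA")
  hmap <- tibble::tibble(column = 1:3, structure_id = "sA", chain = "A",
                         resnum = 1:3, icode = "", resname = "ALA")
  full <- apply_homology_map(lm, hmap)
  dropped <- apply_homology_map(lm[lm$model_id != 2L, ], hmap)
  expect_identical(dropped, full[full$model_id != 2L, ])
})

test_that("ambassador minimizes distance to the mean configuration", {
  one <- landmark_tbl(list(matrix(rnorm(9), 3)), "s")
  expect_equal(select_ambassador(one), 1L)

  same <- landmark_tbl(rep(list(matrix(1:9, 3)), 4), "s")
  expect_equal(select_ambassador(same), 1L)  # tie-break: lowest model id

  set.seed(13)
  configs <- c(lapply(1:10, function(i) matrix(rnorm(15, sd = 0.2), 5)),
               list(matrix(rnorm(15, sd = 0.2), 5) + 10))
  ens <- landmark_tbl(configs, "s")
  amb <- select_ambassador(ens)
  # brute-force oracle over all models
  mean_cfg <- Reduce(`+`, configs) / length(configs)
  d <- vapply(configs, function(m) sqrt(sum((m - mean_cfg)^2)), numeric(1))
  expect_equal(amb, which.min(d))
  expect_lte(amb, 10L)
})

test_that("phenotype TSV round-trips", {
  set.seed(3)
  ph <- pheno_tbl(matrix(rnorm(12), 4), c("a", "a", "b", "b"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_phenotype(ph, f)
  back <- read_phenotype(f)
  expect_equal(back$structure_id, ph$structure_id)
  expect_equal(pheno_matrix(back), pheno_matrix(ph), tolerance = 1e-12)
})
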