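test_that("energy arithmetic is exact and linear", {
  expect_equal(per_residue_energy(-300, 100), -3)
  expect_equal(per_residue_energy(0, 7), 0)
  expect_equal(per_residue_energy(5, 2), 2.5)
  expect_error(per_residue_energy(1, 0), ">= 1")
  # linearity in the energy
  expect_equal(per_residue_energy(3 * 11, 4), 3 * per_residue_energy(11, 4))

  expect_equal(combined_fitness(-2, 10, 5), -4)
  expect_equal(combined_fitness(-2, 0, 5), 0)
  expect_error(combined_fitness(-2, 10, 0), "positive")
})

test_that("energy table parsing enforces keys and substrates", {
  f <- write_energy_tsv(withr::local_tempfile(fileext = ".tsv"), tibble::tibble(
    structure_id = c("a", "a", "b"), model_id = c(1L, 2L, 1L),
    total_energy = c(-100, -110, -90), n_residues = c(50L, 50L, 45L)))
  tb <- read_energy_table(f)
  expect_equal(nrow(tb), 3L)
  expect_equal(tb$dg_hat, tb$dg_unfold / tb$n_residues)

  # negation flag flips the stored sign, nothing else
  tbn <- read_energy_table(f, negate_energy = TRUE)
  expect_equal(tbn$dg_unfold, -tb$dg_unfold)

  dup <- write_energy_tsv(withr::local_tempfile(fileext = ".tsv"), tibble::tibble(
    structure_id = c("a", "a"), model_id = c(1L, 1L), total_energy = c(1, 2)))
  expect_error(read_energy_table(dup), "duplicate")

  empty <- write_energy_tsv(withr::local_tempfile(fileext = ".tsv"),
                            tibble::tibble(structure_id = character(),
                                           model_id = integer(),
                                           total_energy = numeric()))
  expect_warning(tbe <- read_energy_table(empty), "empty")
  expect_equal(nrow(tbe), 0L)

  two_sub <- write_energy_tsv(withr::local_tempfile(fileext = ".tsv"), tibble::tibble(
    structure_id = c("a", "b"), model_id = 1L, total_energy = c(-1, -2),
    kcat = c(10, 20), km = c(1, 2), substrate_id = c("s1", "s2")))
  expect_error(read_energy_table(two_sub), "substrate")

  one_sub <- write_energy_tsv(withr::local_tempfile(fileext = ".tsv"), tibble::tibble(
    structure_id = c("a", "b"), model_id = 1L, total_energy = c(-1, -2),
    kcat = c(10, 20), km = c(2, 4), substrate_id = "s1"))
  tbk <- read_energy_table(one_sub)
  expect_equal(tbk$fitness, c(-1 * 10 / 2, -2 * 20 / 4))
})

test_that("extreme selection picks argmax/argmin with lexicographic ties", {
  tb <- tibble::tibble(structure_id = c("A", "B", "C"), model_id = 1L,
                       dg_unfold = c(1, 3, 2), n_residues = 1L,
                       dg_hat = c(1, 3, 2))
  ex <- select_extremes(tb)
  expect_equal(ex$structure_id[ex$role == "target"], "B")
  expect_equal(ex$structure_id[ex$role == "source"], "A")

  ties <- tibble::tibble(structure_id = c("B", "A", "A"),
                         model_id = c(1L, 2L, 1L), dg_hat = 7)
  ex2 <- select_extremes(ties)
  expect_equal(ex2$structure_id, c("A", "A"))
  expect_equal(ex2$model_id, c(1L, 1L))

  ex3 <- select_extremes(tb, target = c("C", 1), source = c("B", 1))
  expect_equal(ex3$structure_id, c("C", "B"))
  expect_error(select_extremes(tb[1, ]), "at least 2")
})

test_that("extreme selection is invariant to monotone fitness transforms", {
  set.seed(71)
  for (i in 1:10) {
    tb <- tibble::tibble(structure_id = sample(letters[1:4], 8, TRUE),
                         model_id = 1:8, dg_hat = rnorm(8))
    f <- function(x) exp(2 * x) + 1   # strictly increasing
    a <- select_extremes(tb)
    b <- select_extremes(dplyr::mutate(tb, dg_hat = f(dg_hat)))
    expect_equal(a[c("role", "structure_id", "model_id")],
                 b[c("role", "structure_id", "model_id")])
  }
})

test_that("fitness surface scores match an independent eigen oracle", {
  set.seed(72)
  m <- matrix(rnorm(270), 30, 9)
  ph <- pheno_tbl(m, rep(letters[1:3], each = 10))
  tb <- tibble::tibble(structure_id = ph$structure_id, model_id = ph$model_id,
                       dg_unfold = rnorm(30), n_residues = 9L,
                       dg_hat = rnorm(30))
  fs <- fitness_surface(ph, tb)
  # oracle: eigen-decompose the covariance, project centered data
  e <- eigen(brute_cov(m), symmetric = TRUE)
  ctr <- sweep(m, 2, colMeans(m))
  for (j in 1:2) {
    sc_oracle <- drop(ctr %*% e$vectors[, j])
    got <- fs[[paste0("pc", j)]]
    # sign convention may differ between paths; compare up to sign
    expect_equal(abs(got), abs(sc_oracle), tolerance = 1e-8)
  }
  # total score variance equals the top-2 eigenvalue sum
  expect_equal(var(fs$pc1) + var(fs$pc2), sum(e$values[1:2]), tolerance = 1e-8)
  # sign convention: the largest-magnitude loading is positive
  pc <- prcomp(m)$rotation[, 1]
  expect_gte(sign(cor(fs$pc1, drop(ctr %*% (pc * sign(pc[which.max(abs(pc))]))))), 0)
})

test_that("fitness surface degenerate geometries behave", {
  # variation along a single coordinate: PC1 carries everything
  m <- cbind(rnorm(10), 0, 0)
  ph <- pheno_tbl(m, rep(c("a", "b"), 5))
  tb <- tibble::tibble(structure_id = ph$structure_id, model_id = ph$model_id,
                       dg_unfold = 1, dg_hat = 1)
  fs <- fitness_surface(ph, tb)
  expect_lt(max(abs(fs$pc2)), 1e-10)
  ev <- attr(fs, "eigenvalues")
  expect_equal(ev[1] / sum(ev), 1, tolerance = 1e-12)

  # duplicated rows get identical scores
  m2 <- rbind(matrix(rnorm(15), 5, 3), matrix(rnorm(15), 5, 3))
  m2[6:10, ] <- m2[1:5, ]
  ph2 <- pheno_tbl(m2, rep(c("a", "b"), each = 5))
  fs2 <- fitness_surface(ph2, tb)
  expect_equal(fs2$pc1[1:5], fs2$pc1[6:10], tolerance = 1e-12)

  expect_error(fitness_surface(ph[1:2, ], tb), "at least 3")
  expect_error(fitness_surface(ph, tb[-1, ]), "cover")
})
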