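rand_psd_rank <- function(l, r, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(l * l), l)))[, seq_len(r), drop = FALSE]
  ev <- sort(runif(r, 0.5, 3), decreasing = TRUE)
  Q %*% (ev * t(Q))
}

test_that("breeder's equation and realized response behave elementwise", {
  expect_equal(response_to_selection(diag(3), c(1, 2, 3)), c(1, 2, 3))
  expect_equal(response_to_selection(matrix(0, 2, 2), c(1, 1)), c(0, 0))
  expect_equal(response_to_selection(diag(c(2, 1)), c(1, 1)), c(2, 1))
  expect_error(response_to_selection(diag(2), 1:3), "conformable")

  expect_equal(realized_response(c(1, 1, 1), c(0, 1, 2)), c(1, 0, -1))
  expect_equal(realized_response(c(0, 1, 2), c(1, 1, 1)), -c(1, 0, -1))
  expect_equal(realized_response(1:4, 1:4), rep(0L, 4))
  expect_error(realized_response(1:3, 1:4), "length")
})

test_that("selection gradient uses the pseudo-inverse", {
  expect_equal(selection_gradient(diag(3), c(1, 2, 3)), c(1, 2, 3))
  expect_equal(selection_gradient(diag(c(2, 1)), c(2, 1)), c(1, 1))
  # the direction carrying no variation is annihilated, not amplified
  expect_equal(selection_gradient(diag(c(1, 0)), c(1, 1)), c(1, 0))
  expect_error(selection_gradient(matrix(0, 2, 2), c(1, 1)), "zero")

  # pseudo-inverse agrees with MASS::ginv on rank-deficient matrices
  set.seed(61)
  for (i in 1:5) {
    G <- rand_psd_rank(12, 5)
    expect_equal(pseudo_inverse(G), MASS::ginv(G), tolerance = 1e-8)
  }
})

test_that("response round-trip is exact for responses within range(G)", {
  set.seed(62)
  for (i in 1:50) {
    l <- sample(6:20, 1)
    r <- sample(2:(l - 1), 1)
    G <- rand_psd_rank(l, r)
    dz <- drop(G %*% rnorm(l))       # guaranteed in range(G)
    beta <- selection_gradient(G, dz)
    expect_equal(response_to_selection(G, beta), dz, tolerance = 1e-8)
  }
})

test_that("G beta_lambda is the projection of delta_z onto range(G)", {
  set.seed(63)
  for (i in 1:10) {
    G <- rand_psd_rank(10, 4)
    dz <- rnorm(10)
    beta <- selection_gradient(G, dz)
    e <- eigen(G, symmetric = TRUE)
    Q <- e$vectors[, e$values > 1e-8, drop = FALSE]
    expect_equal(response_to_selection(G, beta), drop(Q %*% crossprod(Q, dz)),
                 tolerance = 1e-8)
  }
})

test_that("constraint angle hits its geometric limits", {
  expect_equal(constraint_angle(c(1, 0), c(2, 0)), 0)
  expect_equal(constraint_angle(c(1, 0), c(0, 1)), 90)
  expect_equal(constraint_angle(c(1, 1), c(1, 0)), 45)
  expect_error(constraint_angle(c(0, 0), c(1, 0)), "zero")

  set.seed(64)
  for (i in 1:20) {
    v <- rnorm(sample(2:30, 1))
    expect_equal(constraint_angle(v, v), 0, tolerance = 1e-9)
    expect_equal(constraint_angle(v, -v), 180, tolerance = 1e-9)
    expect_equal(constraint_angle(v, runif(1, 0.1, 10) * v), 0,
                 tolerance = 1e-9)
  }
  # isotropic G imposes no constraint whatever the response direction
  for (i in 1:10) {
    dz <- rnorm(6)
    beta <- selection_gradient(3.7 * diag(6), dz)
    expect_equal(constraint_angle(dz, beta), 0, tolerance = 1e-9)
  }
})

test_that("subspace angle measures distance to the leading eigenspace", {
  G <- diag(c(10, 1, 0.001))
  e1 <- c(1, 0, 0)
  expect_equal(subspace_angle(e1, G), 0, tolerance = 1e-9)
  # 99% of the mass needs the first two axes; e3 is orthogonal to them
  expect_equal(subspace_angle(c(0, 0, 1), G, fraction = 0.99), 90)
  # (e1 + e2)/sqrt(2) against span(e1): retain only the dominant axis
  G1 <- diag(c(100, 1e-6, 1e-6))
  expect_equal(subspace_angle(c(1, 1, 0) / sqrt(2), G1, fraction = 0.9), 45,
               tolerance = 1e-6)
  expect_error(subspace_angle(c(1, 0), -diag(2)), "positive eigenvalues")
})

test_that("per-residue magnitudes are min-max standardized", {
  beta <- c(1, -2, 1,   0, 0, 0,   1, 1, 0)  # raw sums 4, 0, 2
  expect_equal(per_residue_gradient(beta), c(1, 0, 0.5))
  expect_equal(per_residue_gradient(c(0, 0, 0, 2, -1, 0)), c(0, 1))
  expect_equal(per_residue_gradient(rep(1, 9)), c(0, 0, 0))
  expect_error(per_residue_gradient(1:4), "divisible by 3")
})

test_that("residue ranking matches an exhaustive sort oracle", {
  b <- c(1, 0, 0, -1, 0, 0)
  d <- rep(0.5, 6)
  rk <- rank_residues(b, d, top = 1)
  expect_equal(rk$res_index[rk$panel == "directional"], 1L)
  expect_equal(rk$res_index[rk$panel == "purifying"], 2L)

  all_pos <- rank_residues(abs(rnorm(6)) + 0.1, rnorm(6), top = 2)
  expect_equal(sum(all_pos$panel == "purifying"), 0L)

  set.seed(65)
  beta <- rnorm(60); dz <- rnorm(60)
  expect_warning(rk <- rank_residues(beta, dz, top = 50), "exceeds")
  bm <- matrix(beta, 3)
  abs_sum <- colSums(abs(bm)); raw_sum <- colSums(bm)
  dir_oracle <- order(-abs_sum)[order(-abs_sum) %in% which(apply(bm > 0, 2, any))]
  pur_oracle <- order(raw_sum)[order(raw_sum) %in% which(apply(bm < 0, 2, any))]
  expect_equal(rk$res_index[rk$panel == "directional"], dir_oracle)
  expect_equal(rk$res_index[rk$panel == "purifying"], pur_oracle)
})

test_that("selection_analysis bundles angles, maps and rankings", {
  set.seed(66)
  G <- rand_psd_rank(9, 4)
  dz <- drop(G %*% rnorm(9))
  sa <- selection_analysis(G, dz, matrix_used = "G", top = 3)
  expect_s3_class(sa, "selection_analysis")
  expect_equal(sa$theta_constraint, constraint_angle(dz, sa$beta))
  expect_true(all(sa$per_residue >= 0 & sa$per_residue <= 1))
  expect_equal(range(sa$per_residue), c(0, 1))
  gl <- glance(sa)
  expect_equal(gl$matrix_used, "G")
  expect_true(all(c("theta_constraint", "theta_response", "theta_gradient")
                  %in% names(gl)))
  td <- tidy(sa)
  expect_equal(td$beta, sa$beta)
})
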