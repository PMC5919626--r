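# Multivariate breeder's-equation machinery: responses to selection,
# selection/dynamic gradients, constraint angles, per-residue maps and
# residue rankings.

#' Moore-Penrose pseudo-inverse of a symmetric matrix
#'
#' Between-structure covariance matrices are rank-deficient by construction
#' (rank at most S - 1 for S structures, while the trait count is 3k), so
#' gradients are computed with a pseudo-inverse: singular values below
#' `tol * max(singular value)` are treated as zero. The default relative
#' tolerance is `1e-10 * l` for an l x l matrix.
#'
#' @param m Symmetric matrix.
#' @param tol Relative singular-value tolerance; `NULL` for the default.
#' @param ridge Optional ridge term: when non-`NULL`, `solve(m + ridge * I)`
#'   is used instead of truncation.
#' @return Matrix pseudo-inverse.
#' @export
pseudo_inverse <- function(m, tol = NULL, ridge = NULL) {
  .check_sym(m, "m")
  if (!is.null(ridge)) {
    return(solve(m + diag(ridge, nrow(m))))
  }
  tol <- tol %||% (1e-10 * ncol(m))
  sv <- svd(m)
  keep <- sv$d > tol * max(sv$d)
  if (!any(keep)) abort("matrix has no usable singular values (all zero)")
  sv$v[, keep, drop = FALSE] %*%
    ((1 / sv$d[keep]) * t(sv$u[, keep, drop = FALSE]))
}

#' Predicted response to selection
#'
#' The multivariate breeder's equation: the change in the mean phenotype is
#' the product of the genetic covariance matrix and the selection gradient.
#'
#' @param g Genetic (or dynamic, or phenotypic) covariance matrix.
#' @param beta Selection-gradient vector, length `ncol(g)`.
#' @return Response vector, length `nrow(g)`.
#' @export
response_to_selection <- function(g, beta) {
  if (ncol(g) != length(beta)) abort("g and beta are not conformable")
  drop(g %*% beta)
}

#' Realized response to selection between two mean shapes
#'
#' The elementwise difference between a target (after-selection) mean and a
#' source (before-selection) mean, both expressed in the common Procrustes
#' frame.
#'
#' @param target_mean,source_mean Numeric vectors of equal length.
#' @return `target_mean - source_mean`.
#' @export
realized_response <- function(target_mean, source_mean) {
  if (length(target_mean) != length(source_mean)) {
    abort("mean vectors have different lengths (frames do not match)")
  }
  target_mean - source_mean
}

#' Long-term selection gradient from an observed response
#'
#' Inverts the breeder's equation: the gradient that, applied to `g`, best
#' reproduces the observed response. Computed with the pseudo-inverse, so
#' directions carrying no (genetic) variation are annihilated rather than
#' amplified.
#'
#' @inheritParams pseudo_inverse
#' @param g Covariance matrix (genetic B for the selection gradient,
#'   within-group W for the dynamic gradient, phenotypic V_P for the
#'   differential gradient).
#' @param delta_z Response (or selection differential) vector.
#' @return Gradient vector of length `ncol(g)`.
#' @export
selection_gradient <- function(g, delta_z, tol = NULL, ridge = NULL) {
  .check_sym(g, "g")
  if (ncol(g) != length(delta_z)) abort("g and delta_z are not conformable")
  if (all(g == 0)) abort("covariance matrix is all zero: no variation to select on")
  drop(pseudo_inverse(g, tol = tol, ridge = ridge) %*% delta_z)
}

#' @rdname selection_gradient
#' @param v_p Phenotypic covariance matrix.
#' @param s_diff Selection-differential vector.
#' @export
differential_gradient <- function(v_p, s_diff, tol = NULL, ridge = NULL) {
  selection_gradient(v_p, s_diff, tol = tol, ridge = ridge)
}

#' Angle between a response and a gradient
#'
#' The evolutionary-constraint angle: 0 degrees when response and gradient
#' are parallel (no genetic constraint), 90 degrees when the available
#' variation is orthogonal to the direction selection favours (absolute
#' constraint).
#'
#' @param delta_z,beta Non-zero numeric vectors of equal length.
#' @return Angle in degrees, in \[0, 180\].
#' @export
constraint_angle <- function(delta_z, beta) {
  if (length(delta_z) != length(beta)) abort("vectors have different lengths")
  na <- sqrt(sum(delta_z^2)); nb <- sqrt(sum(beta^2))
  if (na == 0 || nb == 0) abort("angle undefined for a zero vector")
  # atan2 form of the angle between unit vectors: numerically exact near
  # 0 and 180 degrees, where acos of the clamped cosine loses precision
  u <- delta_z / na; w <- beta / nb
  2 * atan2(sqrt(sum((u - w)^2)), sqrt(sum((u + w)^2))) * 180 / pi
}

#' Angle between a vector and the leading eigenspace of a covariance matrix
#'
#' Retains the smallest set of leading eigenvectors whose cumulative
#' eigenvalue share reaches `fraction` of the total positive eigenvalue
#' mass, and returns the angle between `v` and its orthogonal projection
#' onto that subspace. Small angles mean the vector lies almost entirely
#' within the well-supported variation of the matrix.
#'
#' @param v Non-zero numeric vector.
#' @param g Symmetric covariance matrix.
#' @param fraction Cumulative eigenvalue share to retain, in (0, 1\];
#'   default 0.99.
#' @return Angle in degrees, in \[0, 90\].
#' @export
subspace_angle <- function(v, g, fraction = 0.99) {
  .check_sym(g, "g")
  if (length(v) != ncol(g)) abort("v and g are not conformable")
  if (sum(v^2) == 0) abort("angle undefined for a zero vector")
  if (fraction <= 0 || fraction > 1) abort("fraction must be in (0, 1]")
  e <- eigen(g, symmetric = TRUE)
  pos <- e$values > 0
  if (!any(pos)) abort("matrix has no positive eigenvalues")
  vals <- e$values[pos]
  share <- cumsum(vals) / sum(vals)
  r <- which(share >= fraction)[1L]
  Q <- e$vectors[, which(pos)[seq_len(r)], drop = FALSE]
  proj <- Q %*% crossprod(Q, v)
  np <- sqrt(sum(proj^2))
  if (np == 0) return(90)
  constraint_angle(v, drop(proj))
}

#' Per-residue gradient magnitudes
#'
#' Collapses a coordinate-level gradient to one magnitude per residue (sum
#' of the absolute values of its x, y, z components) and min-max scales the
#' result to \[0, 1\] for rendering. If every residue has the same raw sum
#' there is nothing to rank and all zeros are returned.
#'
#' @param beta Gradient vector, length divisible by 3 (x, y, z per residue).
#' @return Numeric vector of length `length(beta) / 3` in \[0, 1\].
#' @export
per_residue_gradient <- function(beta) {
  if (length(beta) %% 3L != 0L) abort("gradient length must be divisible by 3")
  raw <- colSums(matrix(abs(beta), nrow = 3L))
  rng <- range(raw)
  if (rng[2L] == rng[1L]) return(rep(0, length(raw)))
  (raw - rng[1L]) / (rng[2L] - rng[1L])
}

#' Rank residues under directional and purifying selection
#'
#' Splits residues into two panels: the directional panel contains residues
#' with at least one positive gradient component, ranked by descending sum
#' of absolute component values; the purifying panel contains residues with
#' at least one negative component, ranked by ascending sum of the raw
#' (signed) components. A residue with mixed-sign components can appear in
#' both panels.
#'
#' @param beta Gradient vector (length 3k).
#' @param delta_z Response vector of the same length, reported alongside.
#' @param labels Optional tibble with one row per residue (columns
#'   `res_index`, `res_name`) giving author numbering of a reference
#'   structure; defaults to 1..k with blank names.
#' @param top Number of rows per panel (default 5); if larger than k, all
#'   residues are returned with a warning.
#' @return Tibble with columns `panel` (`"directional"` / `"purifying"`),
#'   `rank`, `res_index`, `res_name`, `beta_x`, `beta_y`, `beta_z`,
#'   `dz_x`, `dz_y`, `dz_z`.
#' @export
rank_residues <- function(beta, delta_z, labels = NULL, top = 5L) {
  if (length(beta) %% 3L != 0L) abort("gradient length must be divisible by 3")
  if (length(delta_z) != length(beta)) abort("beta and delta_z differ in length")
  k <- length(beta) %/% 3L
  if (top > k) {
    warn(sprintf("top = %d exceeds residue count %d; returning all", top, k))
    top <- k
  }
  if (is.null(labels)) {
    labels <- tibble::tibble(res_index = seq_len(k), res_name = "")
  }
  stopifnot(nrow(labels) == k)
  bm <- matrix(beta, nrow = 3L)
  dm <- matrix(delta_z, nrow = 3L)
  base <- tibble::tibble(
    res_index = labels$res_index, res_name = labels$res_name,
    beta_x = bm[1L, ], beta_y = bm[2L, ], beta_z = bm[3L, ],
    dz_x = dm[1L, ], dz_y = dm[2L, ], dz_z = dm[3L, ],
    abs_sum = colSums(abs(bm)), raw_sum = colSums(bm),
    any_pos = apply(bm > 0, 2L, any), any_neg = apply(bm < 0, 2L, any)
  )
  directional <- dplyr::slice_head(
    dplyr::arrange(dplyr::filter(base, .data$any_pos),
                   dplyr::desc(.data$abs_sum)), n = top)
  purifying <- dplyr::slice_head(
    dplyr::arrange(dplyr::filter(base, .data$any_neg), .data$raw_sum), n = top)
  out <- dplyr::bind_rows(
    dplyr::mutate(directional, panel = "directional", rank = dplyr::row_number()),
    dplyr::mutate(purifying, panel = "purifying", rank = dplyr::row_number())
  )
  dplyr::select(out, "panel", "rank", "res_index", "res_name",
                "beta_x", "beta_y", "beta_z", "dz_x", "dz_y", "dz_z")
}

#' Full selection analysis against one covariance matrix
#'
#' Bundles the realized response, the gradient obtained by inverting the
#' breeder's equation on `g`, the constraint and subspace angles, the
#' per-residue magnitude map and the residue rankings.
#'
#' @inheritParams selection_gradient
#' @param matrix_used Tag recorded in the result (`"G"`, `"M"` or `"V_P"`).
#' @param labels,top Passed to [rank_residues()].
#' @param fraction Passed to [subspace_angle()].
#' @return Object of class `"selection_analysis"`.
#' @export
selection_analysis <- function(g, delta_z, matrix_used = "G", tol = NULL,
                               ridge = NULL, labels = NULL, top = 5L,
                               fraction = 0.99) {
  beta <- selection_gradient(g, delta_z, tol = tol, ridge = ridge)
  per_res <- if (length(delta_z) %% 3L == 0L) per_residue_gradient(beta) else NULL
  ranking <- if (length(delta_z) %% 3L == 0L) {
    rank_residues(beta, delta_z, labels = labels, top = top)
  } else NULL
  structure(
    list(
      delta_z = delta_z, beta = beta, matrix_used = matrix_used,
      theta_constraint = constraint_angle(delta_z, beta),
      theta_response = subspace_angle(delta_z, g, fraction),
      theta_gradient = subspace_angle(beta, g, fraction),
      fraction = fraction,
      per_residue = per_res, ranking = ranking
    ),
    class = "selection_analysis"
  )
}

#' @export
print.selection_analysis <- function(x, ...) {
  cat(sprintf("Selection analysis on %s (%d traits)\n",
              x$matrix_used, length(x$beta)))
  cat(sprintf("  constraint angle theta(dz, beta): %.3f deg\n", x$theta_constraint))
  cat(sprintf("  angle of dz to %.0f%% eigenspace:   %.3f deg\n",
              100 * x$fraction, x$theta_response))
  cat(sprintf("  angle of beta to %.0f%% eigenspace: %.3f deg\n",
              100 * x$fraction, x$theta_gradient))
  if (!is.null(x$ranking)) {
    cat("  top-ranked residues:\n")
    print(x$ranking, n = nrow(x$ranking))
  }
  invisible(x)
}

#' @rdname selection_analysis
#' @param x,object A `selection_analysis` object.
#' @param ... Unused.
#' @export
tidy.selection_analysis <- function(x, ...) {
  tibble::tibble(
    trait = seq_along(x$beta),
    delta_z = x$delta_z,
    beta = x$beta
  )
}

#' @rdname selection_analysis
#' @export
glance.selection_analysis <- function(x, ...) {
  tibble::tibble(
    matrix_used = x$matrix_used,
    traits = length(x$beta),
    theta_constraint = x$theta_constraint,
    theta_response = x$theta_response,
    theta_gradient = x$theta_gradient,
    eigen_fraction = x$fraction
  )
}

#' @rdname selection_analysis
#' @export
autoplot.selection_analysis <- function(object, ...) {
  if (is.null(object$per_residue)) abort("no per-residue map available")
  df <- tibble::tibble(residue = seq_along(object$per_residue),
                       magnitude = object$per_residue)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residue, y = .data$magnitude)) +
    ggplot2::geom_col(width = 1, fill = "firebrick") +
    ggplot2::labs(x = "homologous residue", y = "standardized |gradient|",
                  title = sprintf("Per-residue gradient magnitude (%s)",
                                  object$matrix_used))
}
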