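# Rigid-body (optionally similarity) superposition and Generalized
# Procrustes Analysis over landmark configurations.

# Kabsch solution of the orthogonal Procrustes problem.
# Returns the transformed mobile configuration (in the target frame) and
# the residual RMSD. Rotations are proper: reflections are never used,
# protein chirality being physical.
.kabsch <- function(mobile, target, scale = FALSE) {
  X <- mobile; Y <- target
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2L, cx); Yc <- sweep(Y, 2L, cy)
  C <- crossprod(Xc, Yc)
  sv <- svd(C)
  s <- sign(det(sv$u) * det(sv$v))
  if (s == 0) s <- 1
  R <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
  b <- 1
  if (scale) {
    ssx <- sum(Xc^2)
    if (ssx == 0) abort("degenerate configuration: zero size")
    b <- sum(sv$d * c(1, 1, s)) / ssx
  }
  aligned <- b * (Xc %*% R)
  aligned <- sweep(aligned, 2L, cy, `+`)
  rmsd <- sqrt(sum((aligned - Y)^2) / nrow(Y))
  list(aligned = aligned, rmsd = rmsd, rotation = R, scale = b)
}

.check_config <- function(m, who = "configuration") {
  if (nrow(m) < 3L) abort(sprintf("%s has fewer than 3 landmarks", who))
  if (!all(is.finite(m))) abort(sprintf("%s has non-finite coordinates", who))
  ctr <- sweep(m, 2L, colMeans(m))
  if (qr(ctr)$rank < 2L) {
    abort(sprintf("%s is degenerate (collinear landmarks)", who))
  }
  invisible(m)
}

#' Superimpose one landmark configuration onto another
#'
#' Least-squares rigid-body superposition (translation + proper rotation,
#' optionally a uniform scale) of a mobile configuration onto a target.
#'
#' @param mobile,target Landmark tibbles (columns `x`, `y`, `z`) or k x 3
#'   matrices with identical landmark counts (k >= 3, non-collinear).
#' @param scale If `TRUE`, additionally fit a uniform scale factor.
#' @return List with `aligned` (same type as `mobile`), `rmsd` (Angstrom),
#'   `rotation` (3 x 3 proper rotation), and `scale`.
#' @export
superimpose_pair <- function(mobile, target, scale = FALSE) {
  X <- .coords3(mobile); Y <- .coords3(target)
  if (nrow(X) != nrow(Y)) abort("landmark counts differ")
  .check_config(X, "mobile"); .check_config(Y, "target")
  fit <- .kabsch(X, Y, scale = scale)
  if (is.data.frame(mobile)) {
    out <- mobile
    out$x <- fit$aligned[, 1L]; out$y <- fit$aligned[, 2L]; out$z <- fit$aligned[, 3L]
    fit$aligned <- out
  }
  fit
}

# internal: split a landmark tibble into a named list of k x 3 matrices,
# one per (structure_id, model_id), preserving residue order
.split_configs <- function(landmarks) {
  key <- paste(landmarks$structure_id, landmarks$model_id, sep = ":")
  idx <- split(seq_len(nrow(landmarks)), factor(key, levels = unique(key)))
  lapply(idx, function(i) .coords3(landmarks[i, , drop = FALSE]))
}

#' Generalized Procrustes Analysis
#'
#' Iteratively superimposes every configuration onto the current mean shape
#' and re-estimates the mean, until the Procrustes objective (sum of squared
#' distances to the mean, in squared Angstrom) changes by less than `tol`.
#' All configurations are returned in the mean's frame, and the mean shape
#' is centered at the origin. By default no size scaling is performed:
#' protein dimensions in Angstrom are physically meaningful.
#'
#' @param landmarks Landmark tibble covering >= 1 configuration (grouped by
#'   `structure_id` + `model_id`), or a list of k x 3 matrices.
#' @param scale If `TRUE`, full similarity GPA (uniform scaling allowed).
#' @param tol Convergence tolerance on the objective, squared Angstrom.
#' @param max_iter Maximum number of align-to-mean sweeps; non-convergence
#'   raises a warning and is flagged in the result.
#' @return Object of class `"gpa_fit"`: `aligned` (same type as input),
#'   `mean_shape` (k x 3, centered), `iterations`, `objective` (per-sweep
#'   trace, last entry final), `converged`.
#' @export
gpa <- function(landmarks, scale = FALSE, tol = 1e-10, max_iter = 100L) {
  is_tbl <- is.data.frame(landmarks)
  configs <- if (is_tbl) .split_configs(landmarks) else landmarks
  if (length(configs) == 0L) abort("no configurations supplied")
  k <- unique(vapply(configs, nrow, integer(1)))
  if (length(k) != 1L) abort("configurations have differing landmark counts")
  for (i in seq_along(configs)) .check_config(configs[[i]])

  # start from centered configurations, mean of the centered set
  configs <- lapply(configs, function(m) sweep(m, 2L, colMeans(m)))
  mean_shape <- Reduce(`+`, configs) / length(configs)
  if (length(configs) == 1L) {
    aligned <- configs
    if (is_tbl) {
      out <- landmarks
      out$x <- configs[[1L]][, 1L]; out$y <- configs[[1L]][, 2L]
      out$z <- configs[[1L]][, 3L]
      aligned <- out
    }
    return(structure(
      list(aligned = aligned, mean_shape = mean_shape, iterations = 1L,
           objective = 0, converged = TRUE, scale = scale),
      class = "gpa_fit"
    ))
  }
  objective <- numeric(0)
  prev <- Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    configs <- lapply(configs, function(m) .kabsch(m, mean_shape, scale = scale)$aligned)
    mean_shape <- Reduce(`+`, configs) / length(configs)
    mean_shape <- sweep(mean_shape, 2L, colMeans(mean_shape))
    if (scale) {
      cs <- sqrt(sum(mean_shape^2))
      if (cs > 0) mean_shape <- mean_shape / cs * sqrt(sum(configs[[1L]]^2))
    }
    obj <- sum(vapply(configs, function(m) sum((m - mean_shape)^2), numeric(1)))
    objective <- c(objective, obj)
    if (abs(prev - obj) < tol) { converged <- TRUE; break }
    prev <- obj
  }
  if (!converged && length(configs) > 1L) {
    warn(sprintf("GPA did not converge in %d iterations (last change %.3g)",
                 max_iter, abs(prev - objective[length(objective)])))
  }
  if (length(configs) == 1L) converged <- TRUE

  aligned <- configs
  if (is_tbl) {
    out <- landmarks
    key <- paste(out$structure_id, out$model_id, sep = ":")
    idx <- split(seq_len(nrow(out)), factor(key, levels = unique(key)))
    for (j in seq_along(idx)) {
      out$x[idx[[j]]] <- configs[[j]][, 1L]
      out$y[idx[[j]]] <- configs[[j]][, 2L]
      out$z[idx[[j]]] <- configs[[j]][, 3L]
    }
    aligned <- out
  }
  structure(
    list(aligned = aligned, mean_shape = mean_shape,
         iterations = iter, objective = objective,
         converged = converged, scale = scale),
    class = "gpa_fit"
  )
}

#' @export
print.gpa_fit <- function(x, ...) {
  n <- if (is.data.frame(x$aligned)) {
    length(unique(paste(x$aligned$structure_id, x$aligned$model_id)))
  } else length(x$aligned)
  cat(sprintf(
    "Generalized Procrustes fit: %d configurations, %d landmarks\n", n,
    nrow(x$mean_shape)))
  cat(sprintf("  iterations: %d (%s), final objective %.6g A^2\n",
              x$iterations, if (x$converged) "converged" else "NOT converged",
              x$objective[length(x$objective)]))
  invisible(x)
}

#' @rdname gpa
#' @param x A `gpa_fit` object.
#' @param ... Unused.
#' @export
tidy.gpa_fit <- function(x, ...) {
  if (is.data.frame(x$aligned)) return(tibble::as_tibble(x$aligned))
  purrr::imap_dfr(x$aligned, function(m, nm) {
    tibble::tibble(configuration = nm, landmark = seq_len(nrow(m)),
                   x = m[, 1L], y = m[, 2L], z = m[, 3L])
  })
}

#' @rdname gpa
#' @export
glance.gpa_fit <- function(x, ...) {
  tibble::tibble(
    n_landmarks = nrow(x$mean_shape),
    iterations = x$iterations,
    objective = x$objective[length(x$objective)],
    converged = x$converged,
    scaled = x$scale
  )
}

#' @rdname gpa
#' @param object A `gpa_fit` object.
#' @export
autoplot.gpa_fit <- function(object, ...) {
  pts <- tidy.gpa_fit(object)
  if (!"x" %in% names(pts)) abort("nothing to plot")
  mean_df <- tibble::tibble(x = object$mean_shape[, 1L],
                            y = object$mean_shape[, 2L])
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_point(data = mean_df, colour = "red", size = 1.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (Å)", y = "y (Å)",
                  title = "GPA-aligned landmarks (xy projection)",
                  subtitle = "red: mean shape")
}
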