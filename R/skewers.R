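# Cheverud's random-skewers comparison of covariance matrices: apply the
# same random selection vectors to both matrices and correlate the paired
# response vectors.

#' Random-skewers comparison of two covariance matrices
#'
#' Draws `n_skewers` random selection vectors uniform on the unit sphere
#' (normalized standard normals), applies each to both matrices, and
#' averages the similarity of the paired response vectors. The p-value is
#' the fraction of a null distribution -- the same similarity between
#' responses to *independent* random unit vectors of the same dimension --
#' that meets or exceeds the observed mean.
#'
#' @param a,b Conformable symmetric matrices.
#' @param n_skewers Number of skewers (default 1000).
#' @param seed Optional integer seed; fixing it makes the result
#'   bit-reproducible.
#' @param method `"cosine"` (vector correlation of the responses, the
#'   default) or `"pearson"` (mean-centered correlation).
#' @return Object of class `"skewer_result"`: `rho`, `p_value`,
#'   `n_skewers`, `n_used` (skewers with non-zero responses), `dim`,
#'   `seed`, `method`.
#' @export
random_skewers <- function(a, b, n_skewers = 1000L, seed = NULL,
                           method = c("cosine", "pearson")) {
  method <- match.arg(method)
  .check_sym(a, "a"); .check_sym(b, "b")
  if (!all(dim(a) == dim(b))) abort("matrices have different dimensions")
  if (n_skewers < 1L) abort("need at least one skewer")
  if (!is.null(seed)) set.seed(seed)
  p <- nrow(a)

  unit_vectors <- function(n) {
    v <- matrix(rnorm(n * p), nrow = p)
    nv <- sqrt(colSums(v^2))
    sweep(v, 2L, nv, `/`)
  }
  similarity <- function(ra, rb) {
    if (method == "pearson") {
      ra <- sweep(ra, 2L, colMeans(ra)); rb <- sweep(rb, 2L, colMeans(rb))
    }
    num <- colSums(ra * rb)
    den <- sqrt(colSums(ra^2) * colSums(rb^2))
    num / den
  }

  v <- unit_vectors(n_skewers)
  ra <- a %*% v; rb <- b %*% v
  ok <- colSums(ra^2) > 0 & colSums(rb^2) > 0
  if (!any(ok)) abort("all skewers produced a zero response")
  if (!all(ok)) {
    warn(sprintf("skipping %d skewer(s) with zero response", sum(!ok)))
  }
  rho <- mean(similarity(ra[, ok, drop = FALSE], rb[, ok, drop = FALSE]))

  null <- similarity(unit_vectors(n_skewers), unit_vectors(n_skewers))
  p_value <- mean(null >= rho)

  structure(
    list(rho = rho, p_value = p_value, n_skewers = n_skewers,
         n_used = sum(ok), dim = p, seed = seed, method = method),
    class = "skewer_result"
  )
}

#' @export
print.skewer_result <- function(x, ...) {
  cat(sprintf("Random skewers (%s, %d skewers, dim %d): rho = %.4f, p = %.4g\n",
              x$method, x$n_skewers, x$dim, x$rho, x$p_value))
  invisible(x)
}

#' @rdname random_skewers
#' @param x A `skewer_result` object.
#' @param ... Unused.
#' @export
tidy.skewer_result <- function(x, ...) {
  tibble::tibble(rho = x$rho, p_value = x$p_value,
                 n_skewers = x$n_skewers, n_used = x$n_used,
                 dim = x$dim, method = x$method)
}

#' @rdname random_skewers
#' @export
glance.skewer_result <- function(x, ...) tidy.skewer_result(x)
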