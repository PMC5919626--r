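# Phenotypic, pooled-within-group and between-group covariance estimation.
#
# The phenotypic covariance V_P of the aligned shape coordinates is split
# into a pooled-within-structure component W (the "dynamic" matrix M,
# carrying snapshot-to-snapshot flexibility) and a between-structure
# component B = V_P - W, which proxies the additive genetic G-matrix when
# groups are homologous structures. The iid measurement-error term cannot
# be separated: W absorbs within-group error, B between-group error.

#' Phenotypic covariance matrix
#'
#' Sample covariance (divisor n - 1) of the coordinate traits across all
#' observations, ignoring group structure.
#'
#' @param data Phenotype tibble (see [pheno_matrix()]).
#' @return l x l symmetric matrix with trait-name dimnames.
#' @export
phenotypic_covariance <- function(data) {
  m <- pheno_matrix(data)
  if (nrow(m) < 2L) abort("need at least 2 observations")
  cov(m)
}

#' Pooled within-group covariance matrix
#'
#' Deviations from each group's own mean are cross-multiplied and summed
#' over all observations of all groups, then normalized by n - S (total
#' observations minus number of groups). Between-group mean differences do
#' not enter: the estimate captures only within-group (dynamic) variation.
#'
#' @param data Phenotype tibble.
#' @param group Grouping column name (default `"structure_id"`).
#' @return l x l symmetric matrix.
#' @export
pooled_within <- function(data, group = "structure_id") {
  m <- pheno_matrix(data)
  g <- pheno_groups(data, group)
  sizes <- table(g)
  if (any(sizes < 2L)) {
    abort(sprintf("group(s) with fewer than 2 observations: %s",
                  paste(names(sizes)[sizes < 2L], collapse = ", ")))
  }
  n <- nrow(m); S <- length(sizes)
  if (n - S < 1L) abort("no within-group degrees of freedom")
  gm <- rowsum(m, g) / as.vector(sizes)          # group means, level order
  centred <- m - gm[match(g, rownames(gm)), , drop = FALSE]
  W <- crossprod(centred) / (n - S)
  (W + t(W)) / 2
}

#' Between-group covariance matrix
#'
#' The between-structure (genetic-proxy) component is the plain difference
#' B = V_P - W, symmetrized to kill round-off asymmetry. B is not
#' guaranteed positive semidefinite; see [psd_repair()] if a PSD matrix is
#' required downstream.
#'
#' @param v_p Phenotypic covariance matrix.
#' @param w Pooled within-group covariance matrix of the same dimension.
#' @return l x l symmetric matrix.
#' @export
between_covariance <- function(v_p, w) {
  .check_sym(v_p, "v_p"); .check_sym(w, "w")
  if (!all(dim(v_p) == dim(w))) abort("v_p and w have different dimensions")
  b <- v_p - w
  (b + t(b)) / 2
}

#' Clip a symmetric matrix to the nearest PSD matrix by eigenvalue repair
#'
#' Negative eigenvalues are set to zero and the matrix reconstructed. Only
#' needed when a strictly PSD between-group matrix is required; the raw
#' difference is used everywhere by default.
#'
#' @param m Symmetric matrix.
#' @return PSD matrix of the same dimension.
#' @export
psd_repair <- function(m) {
  .check_sym(m, "m")
  e <- eigen(m, symmetric = TRUE)
  v <- pmax(e$values, 0)
  out <- e$vectors %*% (v * t(e$vectors))
  dimnames(out) <- dimnames(m)
  (out + t(out)) / 2
}

#' Decompose phenotypic variation into within- and between-group parts
#'
#' Convenience wrapper computing `V_P`, `W` and `B = V_P - W` in one pass,
#' so that the additive decomposition holds exactly by construction.
#'
#' @inheritParams pooled_within
#' @return Object of class `"cov_decomp"` with elements `V_P`, `W`, `B`,
#'   `n`, `S`, `group_sizes`.
#' @export
covariance_decomposition <- function(data, group = "structure_id") {
  V_P <- phenotypic_covariance(data)
  W <- pooled_within(data, group)
  B <- between_covariance(V_P, W)
  g <- pheno_groups(data, group)
  structure(
    list(V_P = V_P, W = W, B = B,
         n = nrow(data), S = length(unique(g)),
         group_sizes = table(g)),
    class = "cov_decomp"
  )
}

#' @export
print.cov_decomp <- function(x, ...) {
  cat(sprintf("Covariance decomposition: %d traits, n = %d observations in %d groups\n",
              ncol(x$V_P), x$n, x$S))
  cat(sprintf("  tr(V_P) = %.4g = tr(W) %.4g + tr(B) %.4g\n",
              sum(diag(x$V_P)), sum(diag(x$W)), sum(diag(x$B))))
  invisible(x)
}

#' @rdname covariance_decomposition
#' @param x,object A `cov_decomp` object.
#' @param ... Unused.
#' @export
tidy.cov_decomp <- function(x, ...) {
  tibble::tibble(
    trait = colnames(x$V_P) %||% as.character(seq_len(ncol(x$V_P))),
    var_phenotypic = diag(x$V_P),
    var_within = diag(x$W),
    var_between = diag(x$B)
  )
}

#' @rdname covariance_decomposition
#' @export
glance.cov_decomp <- function(x, ...) {
  evB <- eigen(x$B, symmetric = TRUE, only.values = TRUE)$values
  tibble::tibble(
    n = x$n, groups = x$S, traits = ncol(x$V_P),
    trace_V_P = sum(diag(x$V_P)),
    trace_W = sum(diag(x$W)),
    trace_B = sum(diag(x$B)),
    rank_B = sum(evB > max(evB) * 1e-10),
    min_eigen_B = min(evB)
  )
}

#' Write / read a covariance matrix as a tab-separated table
#'
#' @param m Matrix with trait-name dimnames (or none).
#' @param path File path.
#' @return `write_covariance()` returns `path` invisibly;
#'   `read_covariance()` returns a matrix.
#' @export
write_covariance <- function(m, path) {
  tbl <- tibble::as_tibble(m, .name_repair = "minimal")
  if (is.null(colnames(m))) names(tbl) <- sprintf("tr%d", seq_len(ncol(m)))
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' @rdname write_covariance
#' @export
read_covariance <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_double()))
  m <- as.matrix(tbl)
  rownames(m) <- colnames(m)
  m
}
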