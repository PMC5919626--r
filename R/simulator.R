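# Synthetic grouped-landmark data with known generating covariance
# structure, and the accuracy/feasibility benchmark of the pooled-within
# estimator built on it.

#' Random PSD covariance matrix with a log-uniform spectrum
#'
#' Builds Q L Q' with a uniformly random orthogonal Q and eigenvalues drawn
#' log-uniformly over `decades` decades below `max_eigen`. The spread
#' creates matrix anisotropy, so that random-skewer comparisons are
#' informative (a flat spectrum makes every response parallel to its
#' skewer and the test trivially 1).
#'
#' @param p Dimension.
#' @param decades Decades spanned by the eigenvalues (default 2).
#' @param max_eigen Largest possible eigenvalue (default 1).
#' @return List with `S` (the covariance matrix), `sqrt` (its symmetric
#'   square root) and `eigenvalues`.
#' @export
random_psd_matrix <- function(p, decades = 2, max_eigen = 1) {
  ev <- 10^runif(p, -decades, 0) * max_eigen
  Q <- qr.Q(qr(matrix(rnorm(p * p), p)))
  list(S = Q %*% (ev * t(Q)),
       sqrt = Q %*% (sqrt(ev) * t(Q)),
       eigenvalues = sort(ev, decreasing = TRUE))
}

# symmetric square root of a user-supplied PSD matrix (tolerant of tiny
# negative round-off eigenvalues; genuinely indefinite input is an error)
.psd_sqrt <- function(m, name = "matrix") {
  .check_sym(m, name)
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values), 1)) {
    abort(sprintf("`%s` is not positive semidefinite", name))
  }
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

#' Simulate a grouped phenotype dataset with known covariance structure
#'
#' Emulates the grouped structure of ensemble-derived shape data: each
#' taxon (homologous structure) has a mean phenotype drawn from a
#' multivariate normal with between-group covariance `B_true`; each
#' within-taxon replicate (a molecular-dynamics-snapshot stand-in) adds
#' multivariate-normal within-group variation `W_true` plus an independent
#' isotropic error term. The generating matrices are returned with the
#' data, so estimator accuracy can be scored exactly.
#'
#' @param n_taxa Number of groups (>= 2).
#' @param n_replicates Replicates per group (>= 2).
#' @param p_traits Trait count.
#' @param B,W Optional user-supplied PSD generating matrices; by default
#'   both are drawn with [random_psd_matrix()].
#' @param sigma2_e Variance of the iid error term added to every
#'   observation. Default: 5% of the mean diagonal of `W` (a small
#'   measurement-error share). Use 0 for error-free data.
#' @param seed Optional integer seed (bit-reproducibility).
#' @return Object of class `"sim_dataset"`: `data` (phenotype tibble with
#'   `structure_id` = taxon, `model_id` = replicate, traits `tr1..trp`),
#'   `B_true`, `W_true`, `B_realized` (sample covariance of the drawn taxon
#'   means -- the between-group structure actually expressed in this finite
#'   sample), `taxon_means`, `sigma2_e`, `params`.
#' @export
simulate_dataset <- function(n_taxa = 100L, n_replicates = 500L, p_traits,
                             B = NULL, W = NULL, sigma2_e = NULL,
                             seed = NULL) {
  if (n_taxa < 2L) abort("need at least 2 taxa")
  if (n_replicates < 2L) abort("need at least 2 replicates per taxon")
  if (p_traits < 1L) abort("need at least 1 trait")
  if (!is.null(seed)) set.seed(seed)

  if (is.null(B)) {
    Bm <- random_psd_matrix(p_traits); B_true <- Bm$S; B_sqrt <- Bm$sqrt
  } else {
    stopifnot(all(dim(B) == p_traits))
    B_true <- B; B_sqrt <- .psd_sqrt(B, "B")
  }
  if (is.null(W)) {
    Wm <- random_psd_matrix(p_traits); W_true <- Wm$S; W_sqrt <- Wm$sqrt
  } else {
    stopifnot(all(dim(W) == p_traits))
    W_true <- W; W_sqrt <- .psd_sqrt(W, "W")
  }
  sigma2_e <- sigma2_e %||% (0.05 * mean(diag(W_true)))

  mu <- matrix(rnorm(n_taxa * p_traits), n_taxa) %*% B_sqrt
  n <- n_taxa * n_replicates
  X <- mu[rep(seq_len(n_taxa), each = n_replicates), , drop = FALSE]
  X <- X + matrix(rnorm(n * p_traits), n) %*% W_sqrt
  if (sigma2_e > 0) X <- X + matrix(rnorm(n * p_traits, 0, sqrt(sigma2_e)), n)

  taxa <- sprintf("t%03d", seq_len(n_taxa))
  colnames(X) <- sprintf("tr%d", seq_len(p_traits))
  data <- dplyr::bind_cols(
    tibble::tibble(structure_id = rep(taxa, each = n_replicates),
                   model_id = rep(seq_len(n_replicates), times = n_taxa)),
    tibble::as_tibble(X)
  )
  dimnames(B_true) <- dimnames(W_true) <- list(colnames(X), colnames(X))
  structure(
    list(data = data, B_true = B_true, W_true = W_true,
         B_realized = cov(mu), taxon_means = mu, sigma2_e = sigma2_e,
         params = list(n_taxa = n_taxa, n_replicates = n_replicates,
                       p_traits = p_traits, seed = seed)),
    class = "sim_dataset"
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Simulated grouped dataset: %d taxa x %d replicates, %d traits (sigma2_e = %.4g)\n",
    p$n_taxa, p$n_replicates, p$p_traits, x$sigma2_e))
  invisible(x)
}

#' Simulate taxon means by Brownian motion on a phylogeny
#'
#' Alternative mean generator for users who want phylogenetic signal: taxon
#' means are multivariate normal with among-taxon covariance `vcv(tree)`
#' (shared-path lengths) and trait covariance `B`, i.e. a matrix-normal
#' Brownian-motion model on the supplied tree.
#'
#' @param tree An `ape::phylo` tree (e.g. read with [ape::read.tree()]).
#' @param B Trait covariance of the Brownian process (p x p PSD).
#' @param seed Optional integer seed.
#' @return Matrix of taxon means (tips x p), rownames = tip labels.
#' @export
simulate_means_bm <- function(tree, B, seed = NULL) {
  if (!inherits(tree, "phylo")) abort("`tree` must be an ape phylo object")
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("the 'ape' package is required for tree-based simulation")
  }
  if (!is.null(seed)) set.seed(seed)
  C <- ape::vcv(tree)
  p <- ncol(B)
  Z <- matrix(rnorm(nrow(C) * p), nrow(C))
  mu <- .psd_sqrt(C, "vcv(tree)") %*% Z %*% .psd_sqrt(B, "B")
  rownames(mu) <- rownames(C)
  mu
}

#' Accuracy and feasibility benchmark of the pooled-within estimator
#'
#' For each trait count in `traits`: simulate a grouped dataset, estimate
#' `V_P`, the pooled-within `W` and `B = V_P - W`, and score both estimates
#' by random skewers against the truth. The between-group estimate is
#' scored against the *realized* between-group covariance (the sample
#' covariance of the drawn taxon means) by default: that is the estimand
#' the pooled-within construction targets, and the iid error term cancels
#' in the `V_P - W` difference, while at trait counts above the taxon count
#' the generating matrix is not even identifiable. The within estimate is
#' always scored against the generating `W_true` (the error term inflates
#' `W` away from it, which is what the within-accuracy column measures).
#'
#' @param traits Integer vector of trait counts.
#' @param n_taxa,n_replicates,sigma2_e Passed to [simulate_dataset()].
#' @param n_skewers Skewers per comparison (default 1000).
#' @param seed Integer seed driving the whole benchmark.
#' @param truth `"realized"` (default) or `"generating"`: the between-group
#'   reference matrix.
#' @return Tibble of class `"feasibility_benchmark"`: one row per trait
#'   count with `rs_b_rho`, `rs_b_p`, `rs_w_rho`, `rs_w_p`, and an
#'   informational `seconds` column (wall time, hardware-dependent).
#' @export
feasibility_benchmark <- function(traits, n_taxa = 100L, n_replicates = 500L,
                                  n_skewers = 1000L, seed = NULL,
                                  sigma2_e = NULL,
                                  truth = c("realized", "generating")) {
  truth <- match.arg(truth)
  if (length(traits) == 0L) abort("empty trait series")
  if (!is.null(seed)) set.seed(seed)
  rows <- purrr::map_dfr(traits, function(p) {
    t0 <- proc.time()[["elapsed"]]
    sim <- simulate_dataset(n_taxa, n_replicates, p, sigma2_e = sigma2_e)
    dec <- covariance_decomposition(sim$data)
    b_ref <- if (truth == "realized") sim$B_realized else sim$B_true
    rs_b <- random_skewers(dec$B, b_ref, n_skewers = n_skewers)
    rs_w <- random_skewers(dec$W, sim$W_true, n_skewers = n_skewers)
    tibble::tibble(
      traits = p,
      rs_b_rho = rs_b$rho, rs_b_p = rs_b$p_value,
      rs_w_rho = rs_w$rho, rs_w_p = rs_w$p_value,
      seconds = proc.time()[["elapsed"]] - t0
    )
  })
  attr(rows, "params") <- list(n_taxa = n_taxa, n_replicates = n_replicates,
                               n_skewers = n_skewers, seed = seed,
                               truth = truth)
  class(rows) <- c("feasibility_benchmark", class(rows))
  rows
}

#' @rdname feasibility_benchmark
#' @param object A `feasibility_benchmark` tibble.
#' @param ... Unused.
#' @export
autoplot.feasibility_benchmark <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "traits", "rs_b_rho", "rs_w_rho"),
    c("rs_b_rho", "rs_w_rho"),
    names_to = "component", values_to = "rho")
  long$component <- ifelse(long$component == "rs_b_rho",
                           "between (B)", "within (W)")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$traits, y = .data$rho,
                                     colour = .data$component)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "traits", y = "random-skewer correlation",
                  colour = NULL,
                  title = "Accuracy of the pooled-within decomposition")
}
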