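# Structural connectome handling: validation, homotopic reinforcement,
# synthetic generation, nodal strength and the inter-regional coupling input.

#' Construct and validate a connectome
#'
#' Accepts a square nonnegative matrix, symmetrizes it as (M + t(M))/2 when
#' the asymmetry is within tolerance, zeroes the diagonal, and rescales so the
#' maximum weight is 1 (weights are interpreted on a \[0, 1\] scale
#' throughout).
#'
#' @param weights Square numeric matrix of nonnegative weights.
#' @param labels Optional character vector of region names; defaults to
#'   `"roi_1"`, ... .
#' @param tol_asym Maximal allowed max|M - t(M)| before symmetrization is
#'   refused.
#' @return An object of class `connectome`: the normalized weight matrix with
#'   `labels` attached.
#' @export
connectome <- function(weights, labels = NULL, tol_asym = 1e-6) {
  if (!is.matrix(weights) || nrow(weights) != ncol(weights))
    stop("weights must be a square matrix")
  if (any(!is.finite(weights))) stop("weights contain NaN/Inf")
  if (any(weights < 0)) stop("weights must be nonnegative")
  asym <- max(abs(weights - t(weights)))
  scale_ref <- max(abs(weights), 1e-300)
  if (asym > tol_asym * max(1, scale_ref))
    stop("matrix asymmetry exceeds tolerance")
  w <- (weights + t(weights)) / 2
  diag(w) <- 0
  mx <- max(w)
  if (mx > 0) w <- w / mx
  n <- nrow(w)
  if (is.null(labels)) labels <- paste0("roi_", seq_len(n))
  if (length(labels) != n) stop("labels length must match matrix dimension")
  dimnames(w) <- list(labels, labels)
  structure(w, class = c("connectome", "matrix", "array"))
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("connectome: %d regions, density %.2f, max weight %.3g\n",
              nrow(x), mean(x[upper.tri(x)] > 0), max(x)))
  invisible(x)
}

#' Reinforce homotopic (inter-hemispheric) connections
#'
#' Assumes AAL-style region ordering in which homotopic pairs sit on the
#' anti-diagonal of the matrix (region i pairs with region N + 1 - i). Each
#' anti-diagonal entry is raised to at least `weight`, then the matrix is
#' renormalized to maximum 1.
#'
#' @param c A [connectome()].
#' @param weight Reinforcement weight in \[0, 1\].
#' @return A new `connectome`.
#' @export
reinforce_homotopic <- function(c, weight) {
  stopifnot(inherits(c, "connectome"), weight >= 0, weight <= 1)
  n <- nrow(c)
  if (n %% 2L == 1L)
    stop("odd region count: the middle region would pair with itself")
  w <- unclass(c)
  for (i in seq_len(n)) {
    j <- n + 1L - i
    w[i, j] <- max(w[i, j], weight)
  }
  connectome(w, labels = rownames(c))
}

#' Generate a synthetic connectome
#'
#' Produces a symmetric, \[0, 1\]-normalized, zero-diagonal weight matrix
#' with log-normal weights, block-modular structure and mirror symmetry
#' between the two hemispheres (regions 1..N/2 and N..N/2+1, so homotopic
#' pairs sit on the anti-diagonal). A deterministic stand-in for
#' tractography-derived connectomes.
#'
#' @param n_nodes Even number of regions (>= 4).
#' @param seed Integer seed (local RNG; the global seed is untouched).
#' @param density Fraction of nonzero within-hemisphere edges, in (0, 1\].
#' @param modules Number of modules per hemisphere.
#' @param homotopic_weight Weight given to every homotopic pair before
#'   normalization (keeps the graph connected across hemispheres).
#' @param within_between_ratio Mean weight ratio of within- to between-module
#'   edges.
#' @return A [connectome()].
#' @export
synthetic_connectome <- function(n_nodes, seed = 1L, density = 0.3,
                                 modules = 2L, homotopic_weight = 0.6,
                                 within_between_ratio = 4) {
  if (n_nodes < 4L || n_nodes %% 2L != 0L)
    stop("n_nodes must be an even integer >= 4")
  if (density <= 0 || density > 1) stop("density must lie in (0, 1]")
  nh <- n_nodes / 2L
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  mod_of <- sort(rep(seq_len(modules), length.out = nh))
  # within-hemisphere block (log-normal weights, modular structure)
  hemi <- matrix(0, nh, nh)
  for (i in seq_len(nh - 1)) {
    for (j in (i + 1):nh) {
      if (stats::runif(1) < density) {
        w <- stats::rlnorm(1, meanlog = 0, sdlog = 0.5)
        if (mod_of[i] == mod_of[j]) w <- w * within_between_ratio
        hemi[i, j] <- hemi[j, i] <- w
      }
    }
  }
  # chain so each hemisphere is a single component
  for (i in seq_len(nh - 1)) {
    if (hemi[i, i + 1] == 0)
      hemi[i, i + 1] <- hemi[i + 1, i] <- stats::rlnorm(1, -1, 0.25)
  }
  # cross-hemisphere block, written in mirrored coordinates so that
  # w[i, N+1-j] = cross[i, j] with cross symmetric (mirror symmetry holds)
  cross <- matrix(0, nh, nh)
  for (i in seq_len(nh)) {
    for (j in i:nh) {
      if (i != j && stats::runif(1) < density)
        cross[i, j] <- cross[j, i] <- 0.3 * stats::rlnorm(1, 0, 0.5)
    }
  }
  diag(cross) <- homotopic_weight * max(hemi)  # homotopic pairs
  w <- matrix(0, n_nodes, n_nodes)
  w[seq_len(nh), seq_len(nh)] <- hemi
  w[(nh + 1):n_nodes, (nh + 1):n_nodes] <- hemi[nh:1, nh:1]  # mirrored
  w[seq_len(nh), n_nodes:(nh + 1)] <- cross
  w[n_nodes:(nh + 1), seq_len(nh)] <- t(cross)
  connectome(w)
}

#' Nodal strength
#'
#' Sum of structural connectivity weights per region (row sums).
#'
#' @param c A [connectome()].
#' @return Named numeric vector of length N.
#' @export
nodal_strength <- function(c) {
  stopifnot(inherits(c, "connectome"))
  rowSums(unclass(c))
}

#' Inter-regional coupling input
#'
#' Entry i is `K * C * sum_j M_ij * pyr_rates[j]` (the diagonal of a valid
#' connectome is zero, so the self-term vanishes).
#'
#' @param pyr_rates Pyramidal firing rates S(x1 - x2) per region, 1/s.
#' @param c A [connectome()].
#' @param K Global coupling scale.
#' @param C Local connectivity scale (default 135).
#' @return Numeric vector of coupling inputs.
#' @export
coupling_input <- function(pyr_rates, c, K, C = 135) {
  stopifnot(inherits(c, "connectome"))
  if (length(pyr_rates) != nrow(c))
    stop("rate vector length does not match connectome size")
  as.numeric(K * C * (unclass(c) %*% pyr_rates))
}

#' Read / write a connectome as delimited text
#'
#' CSV with a header row of region labels; values are the weight matrix.
#'
#' @param path File path.
#' @param ... Passed to [connectome()] (e.g. `tol_asym`).
#' @return `read_connectome` returns a [connectome()]; `write_connectome`
#'   returns `path` invisibly.
#' @export
read_connectome <- function(path, ...) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  rownames(m) <- colnames(m)
  connectome(m, labels = colnames(m), ...)
}

#' @rdname read_connectome
#' @param c A [connectome()] to write.
#' @export
write_connectome <- function(c, path) {
  stopifnot(inherits(c, "connectome"))
  utils::write.csv(as.data.frame(unclass(c)), path, row.names = FALSE)
  invisible(path)
}
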