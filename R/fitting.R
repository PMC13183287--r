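# Goodness-of-fit metrics and sweep orchestration: global SSIM, Clarkson
# similarity, grid sweeps, power-masked dual fitting, Cohen's d and the
# strength-inhibition regression.

#' Structural similarity index (global form)
#'
#' SSIM computed once over the whole matrix (no sliding window), with the
#' standard stabilizing constants `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` where
#' the dynamic range `L = max - min` is taken jointly over both inputs.
#' Symmetric in its arguments; `ssim(a, a) = 1`.
#'
#' @param a,b Numeric matrices of identical shape (FC matrices should have
#'   their diagonals zeroed, as [eeg_band_fc()] and [bold_fc()] do).
#' @return SSIM score in \[-1, 1\].
#' @export
ssim <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("matrices must have identical shape")
  a <- as.numeric(a); b <- as.numeric(b)
  L <- max(a, b) - min(a, b)
  if (L == 0) {
    if (isTRUE(all.equal(a, b))) return(1)
    stop("zero dynamic range with unequal matrices")
  }
  C1 <- (0.01 * L)^2
  C2 <- (0.03 * L)^2
  mu_a <- mean(a); mu_b <- mean(b)
  va <- mean((a - mu_a)^2); vb <- mean((b - mu_b)^2)
  vab <- mean((a - mu_a) * (b - mu_b))
  ((2 * mu_a * mu_b + C1) * (2 * vab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
}

#' Clarkson similarity between power vectors
#'
#' `1 - 0.5 * || x/||x|| - y/||y|| ||` (Euclidean norms): 1 for collinear
#' vectors, scale-invariant in each argument.
#'
#' @param x,y Nonzero numeric vectors of equal length.
#' @return Similarity in \[0, 1\].
#' @export
clarkson_similarity <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("zero vector")
  1 - 0.5 * sqrt(sum((x / nx - y / ny)^2))
}

#' Run an objective over a parameter grid
#'
#' Evaluates `objective(cell, seed)` for every combination of the axis values
#' and every seed. Cells are independent, so results do not depend on
#' evaluation order; previously completed rows can be passed in `done` and
#' are skipped (resumability).
#'
#' @param axes Named list of numeric vectors (the grid axes).
#' @param objective `function(cell, seed)` returning a named numeric vector;
#'   `cell` is a named list of one value per axis.
#' @param seeds Integer vector of seeds.
#' @param done Optional data.frame from a previous partial run.
#' @return A data.frame with one row per cell x seed: the axis values, the
#'   seed, and the objective outputs (plus `error` for failed cells, which
#'   are recorded rather than fatal).
#' @export
grid_sweep <- function(axes, objective, seeds = 1L, done = NULL) {
  stopifnot(is.list(axes), !is.null(names(axes)), all(nzchar(names(axes))))
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  rows <- list()
  key <- function(cell, seed)
    paste(c(unlist(cell), seed), collapse = "|")
  done_keys <- character(0)
  if (!is.null(done) && nrow(done)) {
    done_keys <- apply(done[, c(names(axes), "seed"), drop = FALSE], 1,
                       paste, collapse = "|")
    rows <- split(done, seq_len(nrow(done)))
  }
  for (i in seq_len(nrow(grid))) {
    cell <- as.list(grid[i, , drop = FALSE])
    for (s in seeds) {
      if (key(cell, s) %in% done_keys) next
      res <- tryCatch(objective(cell, s), error = function(e)
        c(error = conditionMessage(e)))
      if (!is.null(names(res)) && "error" %in% names(res) &&
          is.character(res)) {
        row <- cbind(as.data.frame(cell), seed = s, error = unname(res))
      } else {
        row <- cbind(as.data.frame(cell), seed = s,
                     as.data.frame(as.list(res)), error = NA_character_)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}

#' Power-masked dual fit
#'
#' Among grid cells whose EEG power similarity is at least `threshold`,
#' returns the cell with maximal FC score (SSIM). Ties are broken by higher
#' power similarity and then by lexicographic order of the grid parameters.
#'
#' @param grid Data.frame with the grid parameters and the two score
#'   columns.
#' @param fc_col,power_col Names of the SSIM and power-similarity columns.
#' @param threshold Feasibility threshold on the power similarity (default
#'   0.85).
#' @return A list: `feasible` (logical), `best` (the selected row or `NULL`),
#'   and `n_feasible`.
#' @export
masked_dual_fit <- function(grid, fc_col = "ssim", power_col = "power_fit",
                            threshold = 0.85) {
  stopifnot(all(c(fc_col, power_col) %in% names(grid)))
  mask <- grid[[power_col]] >= threshold & !is.na(grid[[fc_col]])
  if (!any(mask))
    return(list(feasible = FALSE, best = NULL, n_feasible = 0L))
  sub <- grid[mask, , drop = FALSE]
  par_cols <- setdiff(names(grid), c(fc_col, power_col, "seed", "error"))
  ord <- do.call(order, c(list(-sub[[fc_col]], -sub[[power_col]]),
                          lapply(par_cols, function(cn) sub[[cn]])))
  list(feasible = TRUE, best = sub[ord[1], , drop = FALSE],
       n_feasible = sum(mask))
}

#' Cohen's d effect size
#'
#' `(mean(x) - mean(y)) / s_pooled` with the pooled standard deviation
#' weighted by degrees of freedom.
#'
#' @param x,y Numeric samples (each of size >= 2).
#' @return Cohen's d.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each sample needs at least 2 observations")
  sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
  if (sp == 0) stop("zero pooled standard deviation")
  (mean(x) - mean(y)) / sp
}

#' Verbal label for an effect size
#'
#' Conventional bins: very small (<0.2), small, moderate, large, very large
#' (1.2-2), huge (>2).
#'
#' @param d Cohen's d value.
#' @return Character label.
#' @export
effect_size_label <- function(d) {
  ad <- abs(d)
  if (ad < 0.2) "very small"
  else if (ad < 0.5) "small"
  else if (ad < 0.8) "moderate"
  else if (ad < 1.2) "large"
  else if (ad < 2) "very large"
  else "huge"
}

#' Regression of mean feedback inhibition on nodal strength
#'
#' Ordinary least squares of the time-averaged C4 per node on the nodal
#' strength of the structural matrix.
#'
#' @param strength Nodal strengths (length N >= 3, non-constant).
#' @param mean_c4 Time-averaged C4 per node.
#' @return List with `slope`, `intercept` and `r` (Pearson correlation).
#' @export
strength_inhibition_slope <- function(strength, mean_c4) {
  if (length(strength) != length(mean_c4)) stop("length mismatch")
  if (length(strength) < 3) stop("need at least 3 nodes")
  if (sd(strength) == 0) stop("constant strength vector")
  fit <- lm(mean_c4 ~ strength)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r = cor(strength, mean_c4))
}
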