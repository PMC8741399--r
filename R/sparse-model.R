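# Sparse representation of variant incidence and class-divergence (scatter)
# statistics. The L0 problem min ||x||_0 s.t. y = Ax is attacked with a greedy
# orthogonal-matching-pursuit solver; spark and the restricted-isometry
# constant are computed by exhaustive support enumeration at small n.

#' Binary variant-incidence matrix over genome regions
#'
#' Splits the analysed coordinate range into equal-length regions (rows) and
#' marks a 1 at every (region, offset) cell holding a variant. With SNV +
#' indel density below 0.1% of the sequence the matrix is extremely sparse,
#' which is what makes sparse recovery on it meaningful.
#'
#' @param positions Integer vector of 1-based variant positions (e.g.
#'   `truth$pos`).
#' @param genome_length Total length of the analysed sequence.
#' @param n_regions Number of equal-length regions partitioning
#'   `1:genome_length`; must divide `genome_length`.
#' @return A [Matrix::sparseMatrix()] of dimension
#'   `n_regions x (genome_length / n_regions)` with attribute `sparsity`
#'   (fraction of ones).
#' @export
build_variant_matrix <- function(positions, genome_length, n_regions) {
  if (genome_length %% n_regions != 0L) {
    stop("partition error: 'n_regions' must divide 'genome_length' ",
         "(equal-length regions)")
  }
  width <- genome_length %/% n_regions
  positions <- unique(as.integer(positions))
  if (any(positions < 1L | positions > genome_length)) {
    stop("variant positions outside [1, genome_length]")
  }
  row <- (positions - 1L) %/% width + 1L
  col <- (positions - 1L) %% width + 1L
  m <- Matrix::sparseMatrix(i = row, j = col, x = 1,
                            dims = c(n_regions, width))
  attr(m, "sparsity") <- length(positions) / (n_regions * width)
  m
}

#' Greedy L0 sparse recovery (orthogonal matching pursuit)
#'
#' Approximates `min ||x||_0 s.t. ||y - Ax||_2 <= epsilon` by iteratively
#' selecting the column most correlated (after normalisation) with the
#' current residual and re-fitting the coefficients on the selected support
#' by least squares. Greedy selection alone can overshoot the minimal
#' support, so on small dictionaries (`ncol(A) <= 25`) an exhaustive
#' fallback then searches all supports up to size `max_exhaustive` for a
#' sparser solution within tolerance and keeps the sparsest one. On
#' instances satisfying the spark uniqueness condition
#' `2 ||x||_0 <= spark(A)` (with the true sparsity within the fallback
#' range) the returned solution is therefore the exact L0 (and L1)
#' solution, which is what the test-suite asserts.
#'
#' @param A Dictionary matrix (m x n), full column rank on the supports it
#'   visits.
#' @param y Observation vector of length m.
#' @param epsilon Residual tolerance (>= 0); iteration stops once
#'   `||y - Ax||_2 <= epsilon`.
#' @param max_nonzero Sparsity cap for the greedy pass; default
#'   `min(m, n)`.
#' @param max_exhaustive Largest support size tried by the exhaustive
#'   fallback (default 3; set 0 to disable).
#' @return List with `x` (length-n coefficient vector), `support` (selected
#'   column indices), `residual_norm`, `iterations`, `converged` (logical;
#'   `FALSE` when the residual stalled or the cap was hit first).
#' @export
solve_sparse <- function(A, y, epsilon = 0, max_nonzero = min(dim(A)),
                         max_exhaustive = 3L) {
  A <- as.matrix(A)
  y <- as.numeric(y)
  stopifnot(nrow(A) == length(y), epsilon >= 0)
  n <- ncol(A)
  x <- numeric(n)
  support <- integer(0)
  resid <- y
  rnorm_prev <- sqrt(sum(resid^2))
  tol <- max(epsilon, 1e-10)
  it <- 0L
  converged <- sqrt(sum(resid^2)) <= tol
  col_norms <- sqrt(colSums(A^2))
  col_norms[col_norms == 0] <- Inf
  while (!converged && it < max_nonzero) {
    it <- it + 1L
    corr <- abs(crossprod(A, resid)) / col_norms
    corr[support] <- -Inf
    j <- which.max(corr)
    support <- c(support, j)
    fit <- qr.solve(A[, support, drop = FALSE], y)
    x <- numeric(n)
    x[support] <- fit
    resid <- y - A %*% x
    rnorm <- sqrt(sum(resid^2))
    if (rnorm <= tol) {
      converged <- TRUE
    } else if (rnorm > rnorm_prev - 1e-12) {
      warning("sparse solver stalled after ", it,
              " iteration(s); residual norm ", signif(rnorm, 4))
      break
    }
    rnorm_prev <- rnorm
  }
  # exhaustive fallback: look for a strictly sparser in-tolerance solution
  if (max_exhaustive > 0L && n <= 25L) {
    target <- if (converged) max(0L, length(support) - 1L) else max_exhaustive
    for (k in seq_len(min(max_exhaustive, target))) {
      found <- FALSE
      for (s in utils::combn(n, k, simplify = FALSE)) {
        As <- A[, s, drop = FALSE]
        fit <- tryCatch(qr.solve(As, y), error = function(e) NULL)
        if (is.null(fit)) next
        if (sqrt(sum((y - As %*% fit)^2)) <= tol) {
          x <- numeric(n)
          x[s] <- fit
          support <- s
          converged <- TRUE
          found <- TRUE
          break
        }
      }
      if (found) break
    }
  }
  list(x = x, support = sort(support),
       residual_norm = sqrt(sum((y - A %*% x)^2)),
       iterations = it, converged = converged)
}

# rank of a column submatrix, via QR with a fixed tolerance
.mat_rank <- function(M, tol = 1e-9) {
  if (length(M) == 0L) {
    return(0L)
  }
  qr(M, tol = tol)$rank
}

#' Spark of a matrix
#'
#' The smallest number of linearly dependent columns of `A`; governs
#' uniqueness of sparse solutions (`2 ||x||_0 <= spark(A)` implies the L0
#' solution is unique). Computed by exhaustive subset enumeration, so
#' intended for `ncol(A) <= 20`.
#'
#' @param A A numeric matrix with at most 20 columns.
#' @return Smallest `k` such that some `k` columns are dependent, or
#'   `ncol(A) + 1` when every column subset is independent (the
#'   no-dependent-set convention).
#' @export
spark <- function(A) {
  A <- as.matrix(A)
  n <- ncol(A)
  if (n > 20L) {
    stop("spark() enumerates column subsets exhaustively; ncol(A) <= 20 required")
  }
  for (k in seq_len(min(n, nrow(A) + 1L))) {
    combs <- utils::combn(n, k, simplify = FALSE)
    for (s in combs) {
      if (.mat_rank(A[, s, drop = FALSE]) < k) {
        return(k)
      }
    }
  }
  n + 1L
}

#' Restricted-isometry constant (two-sided bound form)
#'
#' Tightest constant `mu` with `(1 - mu) ||x||^2 <= ||Ax||^2 <= mu ||x||^2`
#' for every `x` with at most `N` nonzeros, computed from the extreme
#' singular values of all column submatrices of size `<= N`. For an
#' orthonormal `A` the constant is 1 (exact isometry); a value much larger
#' than 1, or a lower bound reaching 0 (`mu >= 1`), signals nearly dependent
#' columns.
#'
#' @param A Numeric matrix.
#' @param N Maximum support size; exhaustive enumeration, `N <= ncol(A)`
#'   and small `choose(ncol(A), N)` expected.
#' @return The constant `mu_N = max(sigma_max^2, 1 - sigma_min^2)` over all
#'   supports of size at most `N`.
#' @export
rip_constant <- function(A, N) {
  A <- as.matrix(A)
  n <- ncol(A)
  if (N > n) {
    stop("'N' must not exceed ncol(A)")
  }
  mu <- 0
  for (k in seq_len(N)) {
    for (s in utils::combn(n, k, simplify = FALSE)) {
      d <- svd(A[, s, drop = FALSE], nu = 0, nv = 0)$d
      mu <- max(mu, max(d)^2, 1 - min(d)^2)
    }
  }
  mu
}

#' Between/within-class scatter statistics
#'
#' Computes the between-class scatter `S_b = sum_j N_j (mu_j - mu)(mu_j -
#' mu)^T`, the within-class scatter `S_w = sum_j sum_i (x_ij - mu_j)(x_ij -
#' mu_j)^T`, their traces (equal to the sums of their eigenvalues), the
#' trace ratio `eta = trace(S_b) / trace(S_w)` and the adjusted matrix
#' `S_t = S_b - eta S_w`. Used to quantify how separated variant incidence
#' is across genome regions or classes.
#'
#' @param x Numeric matrix, one observation vector per row (a vector is
#'   treated as one-dimensional observations).
#' @param labels Class label per row; at least two non-empty classes.
#' @param eta_override Optional fixed value of the adjustment parameter
#'   `eta`; by default `eta` is the trace ratio.
#' @return Object of class `divergence_stats`: list with `c` (class count),
#'   `class_sizes`, `class_means`, `grand_mean`, `S_b`, `S_w`, `trace_b`,
#'   `trace_w`, `eta`, `S_t`.
#' @export
divergence_stats <- function(x, labels, eta_override = NULL) {
  if (is.vector(x)) {
    x <- matrix(x, ncol = 1L)
  }
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  classes <- unique(labels)
  if (length(classes) < 2L) {
    stop("at least two classes are required")
  }
  d <- ncol(x)
  mu <- colMeans(x)
  S_b <- matrix(0, d, d)
  S_w <- matrix(0, d, d)
  sizes <- integer(length(classes))
  means <- matrix(NA_real_, length(classes), d,
                  dimnames = list(classes, colnames(x)))
  for (j in seq_along(classes)) {
    xs <- x[labels == classes[j], , drop = FALSE]
    sizes[j] <- nrow(xs)
    mu_j <- colMeans(xs)
    means[j, ] <- mu_j
    dmu <- mu_j - mu
    S_b <- S_b + sizes[j] * tcrossprod(dmu)
    centred <- sweep(xs, 2L, mu_j)
    S_w <- S_w + crossprod(centred)
  }
  trace_b <- sum(diag(S_b))
  trace_w <- sum(diag(S_w))
  if (is.null(eta_override)) {
    if (trace_w <= 0) {
      zero <- classes[vapply(classes, function(cl) {
        xs <- x[labels == cl, , drop = FALSE]
        all(apply(xs, 2L, function(col) length(unique(col)) == 1L))
      }, logical(1))]
      stop("degenerate divergence: within-class scatter is zero (class ",
           paste(zero, collapse = ", "),
           " has identical members); supply eta_override")
    }
    eta <- trace_b / trace_w
  } else {
    eta <- eta_override
  }
  structure(
    list(c = length(classes), class_sizes = stats::setNames(sizes, classes),
         class_means = means, grand_mean = mu,
         S_b = S_b, S_w = S_w, trace_b = trace_b, trace_w = trace_w,
         eta = eta, S_t = S_b - eta * S_w),
    class = "divergence_stats"
  )
}

#' @export
print.divergence_stats <- function(x, ...) {
  cat("<divergence_stats> ", x$c, " classes (sizes ",
      paste(x$class_sizes, collapse = ", "), ")\n",
      "  trace(S_b) = ", signif(x$trace_b, 6),
      ", trace(S_w) = ", signif(x$trace_w, 6),
      ", eta = ", signif(x$eta, 6), "\n", sep = "")
  invisible(x)
}
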