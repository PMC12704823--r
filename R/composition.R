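#' Close a positive vector to a constant sum
#'
#' Rescales strictly positive parts so they sum to `kappa` (1440 minutes for a
#' day, or 1 for proportions). Accepts a single 4-part vector or a matrix with
#' one composition per row.
#'
#' @param x Positive numeric vector of length 4, or an n x 4 matrix.
#' @param kappa Closure constant (default 1440 minutes).
#' @return Vector or matrix of the same shape, rows summing to `kappa`.
#' @examples
#' closure(c(447.3, 583.7, 366.0, 42.6))
#' closure(c(1, 1, 1, 1), kappa = 1)
#' @export
closure <- function(x, kappa = 1440) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop_validation("compositions must be strictly positive and finite")
  }
  if (is.matrix(x)) {
    out <- kappa * x / rowSums(x)
    if (ncol(out) == 4L && is.null(colnames(out))) {
      colnames(out) <- time_use_behaviors
    }
    return(out)
  }
  out <- kappa * x / sum(x)
  if (length(out) == 4L && is.null(names(out))) names(out) <- time_use_behaviors
  out
}

#' Orthonormal ILR pivot-coordinate basis
#'
#' Builds the 3 x 4 contrast matrix of pivot coordinates from the sequential
#' binary partition that isolates the pivot behavior first and then splits the
#' remaining parts one at a time (in canonical behavior order). Rotating the
#' pivot across the four behaviors yields the four ILR coordinate systems; any
#' two are related by an orthogonal rotation, so model-level results do not
#' depend on the choice.
#'
#' The first row for pivot part j has coefficient `sqrt(3/4)` on part j and
#' `-sqrt(1/12)` on the other three, i.e. the first coordinate is
#' `sqrt(3/4) * log(x_j / gm(others))`.
#'
#' @param pivot Behavior isolated first: index 1..4 or name in
#'   [time_use_behaviors].
#' @return An `ilr_basis`: 3 x 4 matrix, rows orthonormal and orthogonal to
#'   the all-ones vector.
#' @examples
#' V <- pivot_basis("mvpa")
#' V %*% t(V)  # identity
#' @export
pivot_basis <- function(pivot = 1) {
  p <- match_behavior(pivot)
  D <- 4L
  ord <- c(p, setdiff(seq_len(D), p))
  V <- matrix(0, D - 1L, D)
  for (i in seq_len(D - 1L)) {
    r <- D - i
    V[i, ord[i]] <- sqrt(r / (r + 1))
    V[i, ord[(i + 1L):D]] <- -sqrt(1 / (r * (r + 1)))
  }
  dimnames(V) <- list(paste0("z", 1:3), time_use_behaviors)
  structure(V, pivot = time_use_behaviors[p], class = c("ilr_basis", "matrix"))
}

as_comp_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1)
}

#' Isometric log-ratio transform
#'
#' Maps a 4-part composition to 3 real ILR coordinates, `z = V log(x)`. The
#' map is scale invariant: closure to 1440, to 1, or no closure at all give
#' identical coordinates.
#'
#' @param x Positive 4-vector or n x 4 matrix of compositions.
#' @param basis An [pivot_basis()] object (default: sleep pivot).
#' @return Numeric 3-vector, or n x 3 matrix for matrix input.
#' @export
ilr <- function(x, basis = pivot_basis(1)) {
  xm <- as_comp_matrix(x)
  if (ncol(xm) != 4L) stop_validation("expected a 4-part composition")
  if (any(!is.finite(xm)) || any(xm <= 0)) {
    stop_validation("compositions must be strictly positive and finite")
  }
  z <- log(xm) %*% t(basis)
  colnames(z) <- rownames(basis)
  if (is.matrix(x)) z else drop(z)
}

#' Inverse ILR transform
#'
#' @param z Numeric 3-vector or n x 3 matrix of ILR coordinates.
#' @param basis The basis `z` is expressed in.
#' @param kappa Closure constant for the returned composition.
#' @return Composition (4-vector or n x 4 matrix) closed to `kappa`.
#' @export
ilr_inverse <- function(z, basis = pivot_basis(1), kappa = 1440) {
  zm <- if (is.matrix(z)) z else matrix(z, nrow = 1)
  if (ncol(zm) != 3L) stop_validation("expected 3 ILR coordinates")
  if (any(!is.finite(zm))) stop_validation("ILR coordinates must be finite")
  e <- exp(zm %*% basis)
  if (any(!is.finite(e))) {
    stop_validation("ILR coordinates too large: exp() overflowed")
  }
  x <- closure(e, kappa)
  colnames(x) <- time_use_behaviors
  if (is.matrix(z)) x else drop(x)
}

#' Compositional (geometric) mean of a set of compositions
#'
#' Part-wise geometric mean followed by closure. Identical (to numerical
#' precision) to mapping to ILR coordinates, averaging there, and mapping
#' back — the compositional center used as the reference point for
#' time-reallocation estimates.
#'
#' @param x n x 4 matrix (or data frame) of positive compositions.
#' @param kappa Closure constant.
#' @return 4-vector closed to `kappa`.
#' @export
geometric_mean_composition <- function(x, kappa = 1440) {
  xm <- as.matrix(x)
  if (nrow(xm) < 1L) stop_validation("need at least one composition")
  if (any(!is.finite(xm)) || any(xm <= 0)) {
    stop_validation("compositions must be strictly positive and finite")
  }
  g <- exp(colMeans(log(xm)))
  out <- closure(g, kappa)
  names(out) <- time_use_behaviors
  out
}

#' Aitchison distance between two compositions
#'
#' Euclidean distance between ILR images; independent of the basis and of the
#' closure constant.
#'
#' @param x,y Positive 4-part compositions.
#' @export
aitchison_distance <- function(x, y) {
  sqrt(sum((ilr(x) - ilr(y))^2))
}

#' Feasibility of a minute reallocation
#'
#' A reallocation of `delta` minutes from one behavior to another is feasible
#' iff every part of the resulting composition remains strictly positive
#' (for negative `delta` the roles reverse, so the rule is symmetric).
#'
#' @param comp Composition in minutes (sums to 1440).
#' @param from,to Behaviors (index or name), distinct.
#' @param delta Minutes moved from `from` to `to`; may be negative.
#' @return Logical.
#' @export
reallocation_feasible <- function(comp, from, to, delta) {
  i <- match_behavior(from); j <- match_behavior(to)
  if (i == j) stop_validation("'from' and 'to' must differ")
  comp[i] - delta > 0 && comp[j] + delta > 0
}

#' Reallocate minutes between two behaviors
#'
#' Moves `delta` minutes from behavior `from` to behavior `to`, keeping all
#' remaining behaviors constant; the total stays at 1440. This is linear
#' arithmetic in minute space (not a compositional perturbation). Infeasible
#' reallocations — those driving a part to zero or below — raise an error of
#' class `coda24_infeasible`.
#'
#' @inheritParams reallocation_feasible
#' @return The reallocated 4-part composition (minutes).
#' @examples
#' ref <- closure(c(447.3, 583.7, 366.0, 42.6))
#' reallocate(ref, "sb", "mvpa", 15)
#' @export
reallocate <- function(comp, from, to, delta) {
  i <- match_behavior(from); j <- match_behavior(to)
  if (i == j) stop_validation("'from' and 'to' must differ")
  if (length(comp) != 4L || any(comp <= 0)) {
    stop_validation("comp must be a strictly positive 4-part composition")
  }
  out <- comp
  out[i] <- out[i] - delta
  out[j] <- out[j] + delta
  if (any(out[c(i, j)] <= 0)) {
    stop_validation(
      sprintf(
        "infeasible reallocation: %d min from %s leaves a non-positive part",
        delta, time_use_behaviors[i]
      ),
      class = "coda24_infeasible"
    )
  }
  out
}
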