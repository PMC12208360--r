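#' Behaviour part names
#'
#' The fixed part order used throughout the package: sedentary behaviour
#' (SB), light physical activity (LPA) and moderate-to-vigorous physical
#' activity (MVPA). All compositional operations assume this order; pivot
#' coordinate systems are expressed by rotation, never by re-declaring the
#' basis.
#'
#' @return Character vector `c("sb", "lpa", "mvpa")`.
#' @export
behaviourParts <- function() c("sb", "lpa", "mvpa")

.as_part_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, behaviourParts(), drop = FALSE])
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != 3L)
    stop("a behaviour composition has exactly 3 parts (sb, lpa, mvpa)")
  storage.mode(x) <- "double"
  colnames(x) <- behaviourParts()
  x
}

.drop_row <- function(m, vector_in) if (vector_in) m[1L, ] else m

#' Close a vector of behaviour durations to a composition
#'
#' Rescales non-negative durations (e.g. hours of SB, LPA and MVPA during
#' work) so the parts sum to 1, discarding the absolute total. Accepts a
#' single length-3 vector or a matrix/data frame with one row per
#' observation and columns `sb`, `lpa`, `mvpa`.
#'
#' Zeros are permitted here (closure of a zero stays zero); they must be
#' replaced with [replaceZeros()] before any log-ratio transformation.
#'
#' @param x Numeric vector of 3 non-negative durations, or a matrix/data
#'   frame of such rows.
#' @return A closed composition (rows sum to 1), same shape as the input.
#' @examples
#' closeComposition(c(3.17, 2.66, 0.82)) # behaviour hours -> shares
#' @export
closeComposition <- function(x) {
  vec <- is.null(dim(x))
  m <- .as_part_matrix(x)
  if (any(!is.finite(m)) || any(m < 0))
    stop("durations must be finite and non-negative")
  tot <- rowSums(m)
  if (any(tot <= 0))
    stop("degenerate input: all three durations are zero")
  .drop_row(m / tot, vec)
}

#' Multiplicative zero replacement for behaviour compositions
#'
#' Daily records can contain an exact zero in one part (typically MVPA)
#' which would make the log-ratios undefined. Each zero is replaced by
#' delta = half the smallest nonzero closed fraction observed for that part
#' across the dataset, and the nonzero parts of the affected row are
#' rescaled multiplicatively so the row still sums to 1.
#'
#' @param x Matrix/data frame of closed compositions (rows sum to 1), or a
#'   single composition vector.
#' @param delta Optional fixed replacement value per part (length 1 or 3).
#'   Defaults to half the smallest observed nonzero fraction, per part.
#' @return Strictly positive closed compositions of the same shape.
#' @export
replaceZeros <- function(x, delta = NULL) {
  vec <- is.null(dim(x))
  m <- .as_part_matrix(x)
  zero <- m == 0
  if (!any(zero)) return(.drop_row(m, vec))
  if (is.null(delta)) {
    delta <- vapply(seq_len(3L), function(j) {
      nz <- m[, j][m[, j] > 0]
      if (!length(nz))
        stop("part '", behaviourParts()[j],
             "' is zero in every row; cannot derive a replacement value")
      min(nz) / 2
    }, numeric(1))
  } else {
    delta <- rep_len(delta, 3L)
  }
  for (i in which(rowSums(zero) > 0)) {
    z <- zero[i, ]
    if (all(z)) stop("degenerate input: all three parts are zero")
    d <- delta[z]
    m[i, z] <- d
    m[i, !z] <- m[i, !z] * (1 - sum(d)) / sum(m[i, !z])
  }
  .drop_row(m, vec)
}

#' Geometric-mean composition of a sample
#'
#' The compositional centre of a set of compositions: the part-wise
#' geometric mean, re-closed to sum 1. Used to summarise average behaviour
#' distributions consistently with the relative nature of the data.
#'
#' @param x Matrix/data frame of strictly positive compositions (rows), or
#'   a list of length-3 vectors.
#' @return A single closed composition (named numeric vector).
#' @export
geometricMeanComposition <- function(x) {
  if (is.list(x) && !is.data.frame(x)) x <- do.call(rbind, x)
  m <- .as_part_matrix(x)
  if (nrow(m) == 0L) stop("cannot average an empty sample of compositions")
  if (any(m <= 0)) stop("all parts must be strictly positive")
  g <- exp(colMeans(log(m)))
  g / sum(g)
}

.sqrt23 <- sqrt(2 / 3)
.sqrt12 <- sqrt(1 / 2)

#' Isometric log-ratio coordinates of a behaviour composition
#'
#' Maps a three-part composition to two unconstrained real coordinates
#' under the sequential binary partition SB vs \{LPA, MVPA\}, then LPA vs
#' MVPA:
#' \deqn{ilr_1 = \sqrt{2/3}\,\ln\frac{SB}{\sqrt{LPA \cdot MVPA}}, \qquad
#'       ilr_2 = \sqrt{1/2}\,\ln\frac{LPA}{MVPA}.}
#' The first coordinate contrasts sedentary time against the geometric
#' mean of the two active behaviours; the second contrasts light against
#' moderate-to-vigorous activity. The map is scale invariant, so closure
#' of the input does not change the output.
#'
#' @param x Strictly positive composition vector, or matrix/data frame of
#'   rows (columns `sb`, `lpa`, `mvpa`).
#' @return Numeric vector `c(ilr1, ilr2)` or a matrix with those columns.
#' @seealso [inverseIlr()], [pivotCoordinates()]
#' @export
ilrTransform <- function(x) {
  vec <- is.null(dim(x))
  m <- .as_part_matrix(x)
  if (any(!is.finite(m)) || any(m <= 0))
    stop("ilr requires strictly positive parts; replace zeros first")
  z <- cbind(ilr1 = .sqrt23 * log(m[, 1] / sqrt(m[, 2] * m[, 3])),
             ilr2 = .sqrt12 * log(m[, 2] / m[, 3]))
  .drop_row(z, vec)
}

#' Inverse isometric log-ratio transformation
#'
#' Maps ilr coordinates back to the original three-part composition space,
#' yielding strictly positive parts that sum to 1. Exact inverse of
#' [ilrTransform()].
#'
#' @param z Numeric vector `c(ilr1, ilr2)` or a matrix with columns
#'   `ilr1`, `ilr2`.
#' @return A closed composition vector or matrix (columns `sb`, `lpa`,
#'   `mvpa`).
#' @export
inverseIlr <- function(z) {
  vec <- is.null(dim(z))
  if (vec) z <- matrix(z, nrow = 1L)
  z <- as.matrix(z)
  if (ncol(z) != 2L) stop("ilr coordinates have exactly 2 components")
  if (any(!is.finite(z))) stop("ilr coordinates must be finite")
  # log-contrasts: ln sb = sqrt(2/3) z1 (up to additive constant),
  # ln lpa = -z1/sqrt(6) + z2/sqrt(2), ln mvpa = -z1/sqrt(6) - z2/sqrt(2)
  lg <- cbind(.sqrt23 * z[, 1],
              -z[, 1] / sqrt(6) + z[, 2] * .sqrt12,
              -z[, 1] / sqrt(6) - z[, 2] * .sqrt12)
  lg <- lg - apply(lg, 1L, max) # guard overflow
  e <- exp(lg)
  m <- e / rowSums(e)
  colnames(m) <- behaviourParts()
  .drop_row(m, vec)
}

#' Pivot coordinates with a chosen behaviour in first position
#'
#' Rotates the chosen part into first position of the ilr basis so that
#' the first coordinate contrasts that behaviour against the geometric
#' mean of the other two:
#' \deqn{z_1 = \sqrt{2/3}\,\ln\frac{pivot}{\sqrt{other_1 \cdot other_2}}.}
#' The rotation is an isometry: the squared norm of the two coordinates
#' does not depend on the pivot choice. With `pivot = "sb"` the
#' coordinates coincide with [ilrTransform()].
#'
#' @param x Strictly positive composition vector or matrix of rows.
#' @param pivot One of `"sb"`, `"lpa"`, `"mvpa"`.
#' @return Numeric vector `c(z1, z2)` (or matrix) with attribute
#'   `"pivot"`; `z1` is the pivot contrast.
#' @export
pivotCoordinates <- function(x, pivot = c("sb", "lpa", "mvpa")) {
  pivot <- match.arg(pivot)
  vec <- is.null(dim(x))
  m <- .as_part_matrix(x)
  if (any(!is.finite(m)) || any(m <= 0))
    stop("pivot coordinates require strictly positive parts")
  ord <- c(pivot, setdiff(behaviourParts(), pivot))
  m <- m[, ord, drop = FALSE]
  z <- cbind(z1 = .sqrt23 * log(m[, 1] / sqrt(m[, 2] * m[, 3])),
             z2 = .sqrt12 * log(m[, 2] / m[, 3]))
  z <- .drop_row(z, vec)
  attr(z, "pivot") <- pivot
  z
}

#' Translate a pivot-coordinate coefficient into a percentage change
#'
#' A regression coefficient `beta` on a first pivot coordinate measures a
#' shift, per unit of the determinant, of the pivot behaviour relative to
#' the geometric mean of the remaining behaviours on the log-ratio scale.
#' On the original scale this corresponds to a relative change of
#' \deqn{100\,(e^{\beta \sqrt{D/(D-1)}} - 1)\ \%}
#' in the pivot part relative to the remaining parts, with `D` the number
#' of composition parts (3 here).
#'
#' @param beta Coefficient(s) on a first pivot coordinate, per unit of the
#'   determinant.
#' @param D Number of parts in the composition (default 3).
#' @return Percentage change(s); e.g. `percentChange(0.03)` is about +3.7.
#' @export
percentChange <- function(beta, D = 3) {
  if (!is.numeric(D) || length(D) != 1L || D < 2)
    stop("D must be a single number >= 2")
  if (any(!is.finite(beta))) stop("beta must be finite")
  100 * expm1(beta * sqrt(D / (D - 1)))
}

#' Aitchison distance between two compositions
#'
#' Equals the Euclidean distance between the ilr coordinates of the two
#' compositions (the defining isometry of the ilr map).
#'
#' @param x,y Strictly positive composition vectors.
#' @return Non-negative scalar distance.
#' @export
aitchisonDistance <- function(x, y) {
  sqrt(sum((ilrTransform(x) - ilrTransform(y))^2))
}
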