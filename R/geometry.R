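# Planar neighbour graphs used by the geo-prior (Delaunay linkage) and the
# posterior summaries (Gabriel graph). Both are computed by direct
# evaluation of their defining empty-circle predicates, which is exact and
# fast enough for the member-set sizes that occur here (areas of at most a
# few dozen languages).

#' Gabriel graph of a planar point set
#'
#' An edge `(a, b)` is present iff the open disc with diameter `ab` contains
#' no other point: `d^2(a, b) < d^2(a, c) + d^2(b, c)` for every other `c`
#' (strict inequality, so cocircular degenerate cases drop the edge). A
#' duplicate of an endpoint acts as a point at distance 0 and suppresses all
#' edges of that endpoint pair; duplicates trigger a warning.
#'
#' @param locations data frame or matrix with `x`/`y` columns (planar).
#' @return Integer matrix with columns `from`, `to` (row indices of
#'   `locations`, `from < to`), zero rows if no edge qualifies.
#' @export
#' @examples
#' sq <- data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
#' gabriel_graph(sq) # the four sides, no diagonals
gabriel_graph <- function(locations) {
  pts <- as.matrix(as.data.frame(locations)[, c("x", "y")])
  n <- nrow(pts)
  if (n < 2L) stop("gabriel_graph needs at least 2 points")
  if (anyDuplicated(pts)) {
    warning("duplicate coordinates; edges between duplicated points are suppressed")
  }
  d2 <- as.matrix(dist(pts))^2
  edges <- matrix(0L, nrow = 0L, ncol = 2L,
                  dimnames = list(NULL, c("from", "to")))
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      others <- setdiff(seq_len(n), c(a, b))
      if (!length(others) || all(d2[a, b] < d2[a, others] + d2[b, others])) {
        edges <- rbind(edges, c(a, b))
      }
    }
  }
  edges
}

# Delaunay triangulation edges of a planar point set, by the empty
# circumcircle test on every triple. Returns a 2-column index matrix, or
# NULL when all points are collinear (no triangulation exists). Points on a
# circumcircle (within tol) do not invalidate a triangle, so cotangent
# degenerate inputs still yield a triangulation. n = 2 gives the single edge.
delaunay_edges <- function(pts, tol = 1e-9) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 2L) {
    return(matrix(0L, 0L, 2L))
  }
  if (n == 2L) {
    return(matrix(c(1L, 2L), 1L, 2L))
  }
  x <- pts[, 1L]
  y <- pts[, 2L]
  scale2 <- max(diff(range(x)), diff(range(y)))^2
  edge_seen <- matrix(FALSE, n, n)
  any_triangle <- FALSE
  for (i in seq_len(n - 2L)) {
    for (j in (i + 1L):(n - 1L)) {
      for (k in (j + 1L):n) {
        cc <- circumcircle(x[i], y[i], x[j], y[j], x[k], y[k])
        if (is.null(cc)) next # collinear triple
        others <- setdiff(seq_len(n), c(i, j, k))
        r2 <- cc[3L]
        inside <- (x[others] - cc[1L])^2 + (y[others] - cc[2L])^2 <
          r2 - tol * max(r2, scale2)
        if (!any(inside)) {
          any_triangle <- TRUE
          edge_seen[i, j] <- TRUE
          edge_seen[i, k] <- TRUE
          edge_seen[j, k] <- TRUE
        }
      }
    }
  }
  if (!any_triangle) {
    return(NULL)
  }
  which(edge_seen, arr.ind = TRUE)
}

# Circumcenter and squared radius of a triangle; NULL if (near) collinear.
circumcircle <- function(ax, ay, bx, by, cx, cy) {
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  span <- max(abs(c(ax, ay, bx, by, cx, cy, 1)))
  if (abs(d) < 1e-12 * span^2) {
    return(NULL)
  }
  a2 <- ax^2 + ay^2
  b2 <- bx^2 + by^2
  c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
}
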