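#' Mean point-to-surface distance
#'
#' The segmentation-accuracy metric: for each query point, the minimum
#' Euclidean distance to any triangle of the mesh (faces treated as solid
#' triangles, not just vertices), averaged over points. Used to compare an
#' automated bone segmentation against a manual reference surface.
#'
#' @param points `n x 3` matrix of query points (mm).
#' @param mesh A list with `vertices` (`v x 3`) and `faces` (`m x 3`,
#'   1-based triangle indices), as returned by [readPly()].
#' @return Mean distance in mm.
#' @export
pointToSurfaceError <- function(points, mesh) {
  if (is.vector(points) && length(points) == 3L) points <- rbind(points)
  stopifnot(is.matrix(points), ncol(points) == 3L, nrow(points) >= 1L)
  if (is.null(mesh$vertices) || is.null(mesh$faces) || nrow(mesh$faces) < 1L)
    stop("mesh must have vertices and at least one triangular face")
  A <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  B <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  C <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  mean(vapply(seq_len(nrow(points)),
              function(i) sqrt(min(pointTriangleSq(points[i, ], A, B, C))),
              numeric(1)))
}

# Squared distance from one point to each triangle (a, b, c row-wise),
# vectorized over triangles. Voronoi-region closest-point algorithm.
pointTriangleSq <- function(p, A, B, C) {
  AB <- B - A; AC <- C - A
  AP <- sweep(-A, 2L, p, `+`)
  d1 <- rowSums(AB * AP); d2 <- rowSums(AC * AP)
  BP <- sweep(-B, 2L, p, `+`)
  d3 <- rowSums(AB * BP); d4 <- rowSums(AC * BP)
  CP <- sweep(-C, 2L, p, `+`)
  d5 <- rowSums(AB * CP); d6 <- rowSums(AC * CP)
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4

  n <- nrow(A)
  Q <- matrix(NA_real_, n, 3L)
  done <- rep(FALSE, n)
  setQ <- function(idx, pts) {
    Q[idx, ] <<- pts
    done[idx] <<- TRUE
  }
  r <- !done & d1 <= 0 & d2 <= 0                     # vertex A
  if (any(r)) setQ(r, A[r, , drop = FALSE])
  r <- !done & d3 >= 0 & d4 <= d3                    # vertex B
  if (any(r)) setQ(r, B[r, , drop = FALSE])
  r <- !done & d6 >= 0 & d5 <= d6                    # vertex C
  if (any(r)) setQ(r, C[r, , drop = FALSE])
  r <- !done & vc <= 0 & d1 >= 0 & d3 <= 0           # edge AB
  if (any(r)) {
    v <- d1[r] / (d1[r] - d3[r])
    setQ(r, A[r, , drop = FALSE] + AB[r, , drop = FALSE] * v)
  }
  r <- !done & vb <= 0 & d2 >= 0 & d6 <= 0           # edge AC
  if (any(r)) {
    w <- d2[r] / (d2[r] - d6[r])
    setQ(r, A[r, , drop = FALSE] + AC[r, , drop = FALSE] * w)
  }
  r <- !done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0  # edge BC
  if (any(r)) {
    w <- (d4[r] - d3[r]) / ((d4[r] - d3[r]) + (d5[r] - d6[r]))
    setQ(r, B[r, , drop = FALSE] + (C[r, , drop = FALSE] - B[r, , drop = FALSE]) * w)
  }
  r <- !done                                          # interior
  if (any(r)) {
    denom <- 1 / (va[r] + vb[r] + vc[r])
    v <- vb[r] * denom; w <- vc[r] * denom
    setQ(r, A[r, , drop = FALSE] + AB[r, , drop = FALSE] * v +
              AC[r, , drop = FALSE] * w)
  }
  D <- sweep(Q, 2L, p)
  rowSums(D * D)
}
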