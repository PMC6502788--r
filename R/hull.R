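## Convex-hull volume in 1-3 dimensions, the geometric core of FRic.
##
## 1-D: range. 2-D: shoelace area over the grDevices::chull polygon.
## 3-D: brute-force facet enumeration — every plane through three points
## with all remaining points on one side is a supporting plane; coplanar
## supporting triples are merged into a single facet whose polygon is
## triangulated from the hull centroid. Point sets here are small (species
## within a plot), so the O(n^4) enumeration is exact and fast enough.

#' Volume of the convex hull of a point set
#'
#' Returns the d-dimensional volume (length, area or volume for d = 1, 2, 3)
#' of the convex hull of the rows of `points`. Exact duplicate rows are
#' removed first. When the points do not span d dimensions (fewer than
#' d + 1 affinely independent points), the hull is degenerate and `NA` is
#' returned rather than zero, so callers can distinguish "flat" communities
#' from genuinely tiny hulls.
#'
#' @param points numeric matrix, one row per point, 1 to 3 columns.
#' @return hull volume, or `NA_real_` for degenerate inputs.
#' @examples
#' convexHullVolume(matrix(c(1, 3, 7)))                    # 1-D range = 6
#' convexHullVolume(rbind(c(0, 0), c(1, 0), c(0, 1)))      # triangle = 0.5
#' @export
convexHullVolume <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (anyNA(points) || any(!is.finite(points)))
    stop("points must be finite", call. = FALSE)
  d <- ncol(points)
  if (d < 1 || d > 3)
    stop("hull volume implemented for 1 to 3 dimensions, got ", d,
         call. = FALSE)
  points <- unique(points)
  n <- nrow(points)
  if (n < d + 1) return(NA_real_)
  scale <- max(1, max(abs(points)))
  tol <- 1e-10 * scale
  if (.affineRank(points, tol) < d) return(NA_real_)
  switch(d, .hullLength(points), .hullArea(points),
         .hullVolume3(points, tol))
}

.affineRank <- function(points, tol) {
  centered <- sweep(points, 2, colMeans(points))
  sv <- svd(centered, nu = 0, nv = 0)$d
  sum(sv > tol * max(1, sv[1]))
}

.hullLength <- function(points) max(points[, 1]) - min(points[, 1])

.hullArea <- function(points) {
  h <- grDevices::chull(points[, 1], points[, 2])
  x <- points[h, 1]; y <- points[h, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

.hullVolume3 <- function(P, tol) {
  n <- nrow(P)
  ctr <- colMeans(P)
  tri <- utils::combn(n, 3L)
  A <- P[tri[1L, ], , drop = FALSE]
  U <- P[tri[2L, ], , drop = FALSE] - A
  V <- P[tri[3L, ], , drop = FALSE] - A
  N <- cbind(U[, 2] * V[, 3] - U[, 3] * V[, 2],
             U[, 3] * V[, 1] - U[, 1] * V[, 3],
             U[, 1] * V[, 2] - U[, 2] * V[, 1])
  len <- sqrt(rowSums(N * N))
  ok <- len > tol * tol   # drop (near-)collinear triples
  if (!any(ok)) return(NA_real_)
  N <- N[ok, , drop = FALSE] / len[ok]
  d0 <- rowSums(N * A[ok, , drop = FALSE])
  # signed distance of every point from every candidate plane
  off <- N %*% t(P) - d0
  supporting <- (rowSums(off > tol) == 0L) | (rowSums(off < -tol) == 0L)
  if (!any(supporting)) return(NA_real_)
  N <- N[supporting, , drop = FALSE]
  d0 <- d0[supporting]
  # orient normals outward (centroid strictly inside the hull)
  flip <- (N %*% ctr - d0) > 0
  N[flip, ] <- -N[flip, , drop = FALSE]
  d0[flip] <- -d0[flip]
  # merge coplanar supporting triples into unique facets
  planes <- list()
  for (i in seq_len(nrow(N))) {
    found <- FALSE
    for (pl in planes)
      if (sum(pl$n * N[i, ]) > 1 - 1e-8 && abs(pl$d - d0[i]) <= tol) {
        found <- TRUE; break
      }
    if (!found) planes[[length(planes) + 1L]] <- list(n = N[i, ], d = d0[i])
  }
  vol <- 0
  for (pl in planes) {
    onPlane <- abs(P %*% pl$n - pl$d) <= tol
    facetPts <- P[onPlane, , drop = FALSE]
    if (nrow(facetPts) < 3L) next
    # orthonormal basis of the facet plane
    e1 <- if (abs(pl$n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- e1 - sum(e1 * pl$n) * pl$n
    e1 <- e1 / sqrt(sum(e1 * e1))
    e2 <- c(pl$n[2] * e1[3] - pl$n[3] * e1[2],
            pl$n[3] * e1[1] - pl$n[1] * e1[3],
            pl$n[1] * e1[2] - pl$n[2] * e1[1])
    uv <- cbind(facetPts %*% e1, facetPts %*% e2)
    area <- .hullArea(uv)
    height <- abs(sum(pl$n * ctr) - pl$d)
    vol <- vol + area * height / 3
  }
  vol
}
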