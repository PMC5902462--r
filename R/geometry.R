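# Low-level 2D computational geometry: Delaunay triangulation (Bowyer-Watson),
# Voronoi vertex graph, point-in-polygon, polyline utilities. These back the
# medial-axis morphometry; no triangulation library is assumed.

# Deterministic pseudo-random permutation / jitter via a local LCG so that the
# geometry never touches (or depends on) the user's RNG stream.
.gm_lcg <- function(n, seed = 20260909L) {
  state <- as.double(seed %% 2147483647L)
  if (state <= 0) state <- 1
  out <- numeric(n)
  for (i in seq_len(n)) {
    state <- (state * 16807) %% 2147483647
    out[i] <- state / 2147483647
  }
  out
}

#' Delaunay triangulation of a 2D point set
#'
#' Incremental Bowyer-Watson triangulation. Input coordinates are jittered by a
#' deterministic ~1e-9 relative amount to break cocircular degeneracies (pixel
#' grids produce many); the jitter is far below any physical tolerance used
#' downstream.
#'
#' @param x,y numeric vectors of point coordinates (equal length, >= 3 points).
#' @return list with `tri` (m x 3 integer matrix of point indices, one row per
#'   triangle), `cc` (m x 2 circumcenters), `r2` (squared circumradii),
#'   and the (unjittered) input `x`, `y`.
#' @keywords internal
gm_delaunay <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  dx <- diff(range(x)); dy <- diff(range(y))
  diam <- max(dx, dy, 1e-12)
  jit <- .gm_lcg(2L * n)
  xj <- x + (jit[seq_len(n)] - 0.5) * 2e-9 * diam
  yj <- y + (jit[n + seq_len(n)] - 0.5) * 2e-9 * diam

  # super-triangle enclosing everything by a wide margin
  cx <- mean(range(x)); cy <- mean(range(y))
  R <- 20 * diam
  sx <- cx + R * c(0, -0.866, 0.866) * 2
  sy <- cy + R * c(2, -1, -1)
  px <- c(xj, sx); py <- c(yj, sy)

  cap <- 12L * n + 64L
  tri <- matrix(0L, cap, 3)
  ccx <- numeric(cap); ccy <- numeric(cap); rr2 <- numeric(cap)
  alive <- logical(cap)

  circ <- function(ia, ib, ic) {
    ax <- px[ia]; ay <- py[ia]; bx <- px[ib]; by <- py[ib]
    gx <- px[ic]; gy <- py[ic]
    d <- 2 * (ax * (by - gy) + bx * (gy - ay) + gx * (ay - by))
    d[abs(d) < 1e-300] <- 1e-300
    a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- gx^2 + gy^2
    ux <- (a2 * (by - gy) + b2 * (gy - ay) + c2 * (ay - by)) / d
    uy <- (a2 * (gx - bx) + b2 * (ax - gx) + c2 * (bx - ax)) / d
    list(x = ux, y = uy, r2 = (ux - ax)^2 + (uy - ay)^2)
  }

  m <- 1L
  tri[1L, ] <- c(n + 1L, n + 2L, n + 3L)
  cc1 <- circ(n + 1L, n + 2L, n + 3L)
  ccx[1L] <- cc1$x; ccy[1L] <- cc1$y; rr2[1L] <- cc1$r2
  alive[1L] <- TRUE

  ord <- order(.gm_lcg(n, seed = 987654321L))
  big <- as.double(n + 4L)
  for (p in ord) {
    qx <- px[p]; qy <- py[p]
    idx <- seq_len(m)
    bad <- idx[alive[idx] & ((qx - ccx[idx])^2 + (qy - ccy[idx])^2) <= rr2[idx]]
    if (!length(bad)) next  # duplicate point inside no circumcircle: skip
    e1 <- tri[bad, 1L]; e2 <- tri[bad, 2L]; e3 <- tri[bad, 3L]
    ea <- c(e1, e2, e3); eb <- c(e2, e3, e1)
    lo <- pmin(ea, eb); hi <- pmax(ea, eb)
    key <- lo * big + hi
    once <- !(key %in% key[duplicated(key)])
    alive[bad] <- FALSE
    ba <- ea[once]; bb <- eb[once]
    k <- length(ba)
    if (m + k > cap) {
      grow <- cap
      tri <- rbind(tri, matrix(0L, grow, 3))
      ccx <- c(ccx, numeric(grow)); ccy <- c(ccy, numeric(grow))
      rr2 <- c(rr2, numeric(grow)); alive <- c(alive, logical(grow))
      cap <- cap + grow
    }
    rows <- m + seq_len(k)
    tri[rows, 1L] <- ba; tri[rows, 2L] <- bb; tri[rows, 3L] <- p
    cc <- circ(ba, bb, rep.int(p, k))
    ccx[rows] <- cc$x; ccy[rows] <- cc$y; rr2[rows] <- cc$r2
    alive[rows] <- TRUE
    m <- m + k
  }

  keep <- which(alive[seq_len(m)])
  trik <- tri[keep, , drop = FALSE]
  real <- rowSums(trik > n) == 0L  # drop triangles touching the super-triangle
  keep <- keep[real]
  list(tri = tri[keep, , drop = FALSE],
       cc = cbind(ccx[keep], ccy[keep]),
       r2 = rr2[keep], x = x, y = y)
}

#' Voronoi vertex adjacency from a Delaunay triangulation
#'
#' Voronoi vertices are the circumcenters of Delaunay triangles; two vertices
#' are adjacent when their triangles share an edge.
#'
#' @param del result of [gm_delaunay()].
#' @return 2-column integer matrix of adjacent triangle (row) indices.
#' @keywords internal
gm_voronoi_edges <- function(del) {
  tr <- del$tri
  m <- nrow(tr)
  if (m < 2) return(matrix(integer(0), 0, 2))
  ea <- c(tr[, 1], tr[, 2], tr[, 3])
  eb <- c(tr[, 2], tr[, 3], tr[, 1])
  lo <- pmin(ea, eb); hi <- pmax(ea, eb)
  key <- lo * as.double(max(hi) + 1L) + hi
  tid <- rep.int(seq_len(m), 3L)
  o <- order(key)
  key <- key[o]; tid <- tid[o]
  same <- which(key[-length(key)] == key[-1L])
  cbind(tid[same], tid[same + 1L])
}

#' Point-in-polygon test (even-odd ray casting)
#'
#' @param qx,qy query point coordinates.
#' @param vx,vy polygon vertex coordinates (closed implicitly).
#' @return logical vector, TRUE for strictly interior points.
#' @keywords internal
gm_in_polygon <- function(qx, qy, vx, vy) {
  n <- length(vx)
  inside <- logical(length(qx))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    crosses <- ((yi > qy) != (yj > qy))
    if (any(crosses)) {
      w <- which(crosses)
      xint <- xi + (qy[w] - yi) * (xj - xi) / (yj - yi)
      flip <- xint > qx[w]
      inside[w] <- xor(inside[w], flip)
    }
    j <- i
  }
  inside
}

# Cumulative arclength of a polyline given as n x 2 matrix.
gm_arclength <- function(xy) {
  seg <- sqrt(rowSums(diff(xy)^2))
  c(0, cumsum(seg))
}

#' Resample a polyline at uniform arclength
#'
#' @param xy n x 2 coordinate matrix.
#' @param n_out number of output samples (>= 2); mutually exclusive with `step`.
#' @param step arclength step; the actual step is adjusted so the full length
#'   is covered by an integer number of intervals.
#' @param closed if TRUE the polyline is treated as a closed ring (the first
#'   point is appended before resampling, and the duplicated end is dropped).
#' @return resampled m x 2 matrix.
#' @keywords internal
gm_resample <- function(xy, n_out = NULL, step = NULL, closed = FALSE) {
  if (closed) xy <- rbind(xy, xy[1, ])
  s <- gm_arclength(xy)
  keep <- c(TRUE, diff(s) > 0)
  xy <- xy[keep, , drop = FALSE]; s <- s[keep]
  L <- s[length(s)]
  if (is.null(n_out)) {
    stopifnot(!is.null(step), step > 0)
    n_out <- max(if (closed) 8L else 2L, as.integer(ceiling(L / step)) + 1L)
  }
  si <- seq(0, L, length.out = n_out)
  out <- cbind(stats::approx(s, xy[, 1], xout = si)$y,
               stats::approx(s, xy[, 2], xout = si)$y)
  if (closed) out <- out[-nrow(out), , drop = FALSE]
  out
}

# Minimum distance from each query point to a reference point cloud (chunked).
gm_nearest_dist <- function(qx, qy, rx, ry, chunk = 512L) {
  nq <- length(qx)
  out <- numeric(nq)
  for (i0 in seq(1L, nq, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nq)
    d2 <- outer(qx[i0:i1], rx, "-")^2 + outer(qy[i0:i1], ry, "-")^2
    out[i0:i1] <- sqrt(apply(d2, 1, min))
  }
  out
}

# Shoelace area of a polygon (positive for counter-clockwise orientation in a
# y-up frame; callers only rely on |area| and on the sign convention being
# applied consistently).
gm_polygon_area <- function(vx, vy) {
  n <- length(vx)
  j <- c(2:n, 1L)
  sum(vx * vy[j] - vx[j] * vy) / 2
}
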