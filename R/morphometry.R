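# Silhouette -> contour -> Voronoi medial axis -> midline length, diameter
# profile and solid-of-revolution volume; plus an independent Bezier
# axisymmetric reconstruction used as a cross-check of the Voronoi route.
#
# Coordinate convention: image row/col map to y/x in mm with the origin at the
# image top-left, y downward, pixel centers at integer coordinates (0-based):
# x = col * scale, y = row * scale.

#' Morphometry configuration
#'
#' @param scale_mm_per_px image scale (mm per pixel).
#' @param threshold fixed grey-level threshold, or `NULL` for Otsu's method.
#' @param contour_blur_px Gaussian sigma (px) applied to the binary mask
#'   before subpixel contour extraction (anti-aliasing of the pixel staircase).
#' @param contour_spacing_px target contour resampling spacing (px); at least
#'   `min_contour_points` points are always used.
#' @param min_contour_points minimum number of contour samples fed to the
#'   Voronoi diagram.
#' @param smooth_tol_px allowed RMS deviation of the smoothed midline from the
#'   raw Voronoi path, in px.
#' @param midline_step_px arclength step of the resampled midline (px).
#' @param tubular_aspect_min minimum length / mean-diameter ratio; below it the
#'   silhouette is rejected as non-tubular.
#' @param end_rule end handling of the midline. `"cap_trim"` (default):
#'   extend the medial axis along its end tangents to the contour tips, then
#'   trim each end at the arclength where distance-from-tip equals the local
#'   radius — for a tube with rounded (hemispherical) tips this is exactly the
#'   cap center, so reported length excludes the caps. `"tips"`: keep the
#'   tip-to-tip extension (length includes the caps, one diameter longer on a
#'   capped tube). `"raw"`: the untouched Voronoi path.
#' @return object of class `morph_config`.
#' @export
morph_config <- function(scale_mm_per_px = 0.02, threshold = NULL,
                         contour_blur_px = 1, contour_spacing_px = 2,
                         min_contour_points = 400, smooth_tol_px = 1,
                         midline_step_px = 2, tubular_aspect_min = 3,
                         end_rule = c("cap_trim", "tips", "raw")) {
  end_rule <- match.arg(end_rule)
  stopifnot(scale_mm_per_px > 0, contour_blur_px >= 0, contour_spacing_px > 0,
            min_contour_points >= 20, smooth_tol_px >= 0, midline_step_px > 0,
            tubular_aspect_min > 0)
  structure(list(scale_mm_per_px = scale_mm_per_px, threshold = threshold,
                 contour_blur_px = contour_blur_px,
                 contour_spacing_px = contour_spacing_px,
                 min_contour_points = min_contour_points,
                 smooth_tol_px = smooth_tol_px,
                 midline_step_px = midline_step_px,
                 tubular_aspect_min = tubular_aspect_min,
                 end_rule = end_rule),
            class = "morph_config")
}

# Otsu threshold on a 256-bin histogram.
.otsu <- function(image) {
  rng <- range(image)
  if (diff(rng) == 0) stop("no object: image is constant")
  h <- tabulate(pmin(256L, 1L + as.integer(255 * (image - rng[1]) / diff(rng))),
                nbins = 256L)
  w <- h / sum(h)
  omega <- cumsum(w)
  mu <- cumsum(w * seq_len(256L))
  mu_t <- mu[256L]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  rng[1] + diff(rng) * (k - 0.5) / 255
}

# Connected components of a logical matrix (4-connectivity), frontier BFS.
.label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- integer(nr * nc)
  fg <- which(mask)
  unvisited <- logical(nr * nc)
  unvisited[fg] <- TRUE
  cur <- 0L
  for (s in fg) {
    if (!unvisited[s]) next
    cur <- cur + 1L
    frontier <- s
    unvisited[s] <- FALSE
    lab[s] <- cur
    while (length(frontier)) {
      up <- frontier[(frontier - 1L) %% nr != 0L] - 1L
      dn <- frontier[frontier %% nr != 0L] + 1L
      lf <- frontier[frontier > nr] - nr
      rt <- frontier[frontier <= nr * (nc - 1L)] + nr
      nb <- c(up, dn, lf, rt)
      nb <- nb[unvisited[nb]]
      if (length(nb)) {
        nb <- unique(nb)
        unvisited[nb] <- FALSE
        lab[nb] <- cur
      }
      frontier <- nb
    }
  }
  matrix(lab, nr, nc)
}

#' Segment the organ silhouette from a grayscale image
#'
#' Thresholds the image (Otsu by default), keeps the largest connected
#' foreground component and fills interior holes.
#'
#' @param image numeric matrix of grey levels.
#' @param scale_mm_per_px image scale (validated, recorded downstream).
#' @param threshold optional fixed threshold overriding Otsu.
#' @return logical mask matrix.
#' @export
segment_silhouette <- function(image, scale_mm_per_px, threshold = NULL) {
  stopifnot(is.matrix(image), length(image) > 0, scale_mm_per_px > 0)
  thr <- if (is.null(threshold)) .otsu(image) else threshold
  mask <- image > thr
  if (!any(mask)) stop("no object: empty foreground after thresholding")
  lab <- .label_components(mask)
  counts <- tabulate(lab[lab > 0L])
  keep <- which.max(counts)
  mask <- lab == keep
  # fill holes: background not reachable from the border is interior
  inv <- !mask
  nr <- nrow(mask); nc <- ncol(mask)
  border <- unique(c(seq_len(nr), nr * (nc - 1L) + seq_len(nr),
                     (seq_len(nc) - 1L) * nr + 1L, seq_len(nc) * nr))
  border <- border[inv[border]]
  reach <- logical(nr * nc)
  frontier <- border
  reach[frontier] <- TRUE
  invv <- as.vector(inv)
  while (length(frontier)) {
    up <- frontier[(frontier - 1L) %% nr != 0L] - 1L
    dn <- frontier[frontier %% nr != 0L] + 1L
    lf <- frontier[frontier > nr] - nr
    rt <- frontier[frontier <= nr * (nc - 1L)] + nr
    nb <- c(up, dn, lf, rt)
    nb <- nb[invv[nb] & !reach[nb]]
    if (length(nb)) {
      nb <- unique(nb)
      reach[nb] <- TRUE
    }
    frontier <- nb
  }
  mask | (inv & !matrix(reach, nr, nc))
}

#' Extract the subpixel closed contour of a mask
#'
#' The binary mask is lightly Gaussian-blurred and the 0.5 iso-contour is
#' traced by marching squares, giving a subpixel boundary; the polygon is then
#' resampled at approximately uniform spacing and normalized to a fixed
#' (counter-clockwise shoelace) orientation.
#'
#' @param mask logical matrix from [segment_silhouette()].
#' @param scale_mm_per_px image scale.
#' @param blur_px Gaussian sigma of the pre-blur, in px.
#' @param spacing_px target resampling spacing, in px.
#' @return a `contour` object: matrix with columns `x`, `y` (mm), closed
#'   implicitly, oriented counter-clockwise.
#' @export
extract_contour <- function(mask, scale_mm_per_px, blur_px = 1,
                            spacing_px = 2) {
  stopifnot(is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  if (any(mask[1, ]) || any(mask[nr, ]) || any(mask[, 1]) || any(mask[, nc])) {
    stop("mask touches the image border: organ truncated")
  }
  z <- mask * 1
  if (blur_px > 0) {
    half <- max(1L, as.integer(ceiling(3 * blur_px)))
    kern <- stats::dnorm(seq(-half, half), sd = blur_px)
    kern <- kern / sum(kern)
    blur1 <- function(m) {
      out <- m * kern[half + 1L]
      for (o in seq_len(half)) {
        up <- rbind(m[-seq_len(o), , drop = FALSE],
                    matrix(0, o, ncol(m)))
        dnm <- rbind(matrix(0, o, ncol(m)),
                     m[seq_len(nrow(m) - o), , drop = FALSE])
        out <- out + kern[half + 1L + o] * up + kern[half + 1L - o] * dnm
      }
      out
    }
    z <- blur1(z)
    z <- t(blur1(t(z)))
  }
  cl <- grDevices::contourLines(x = (seq_len(nr) - 1L) * scale_mm_per_px,
                                y = (seq_len(nc) - 1L) * scale_mm_per_px,
                                z = z, levels = 0.5)
  if (!length(cl)) stop("no contour found at the 0.5 level")
  lens <- vapply(cl, function(cc) {
    gm_arclength(cbind(cc$y, cc$x))[length(cc$x)]
  }, numeric(1))
  cc <- cl[[which.max(lens)]]
  poly <- cbind(x = cc$y, y = cc$x)  # contourLines x == image rows
  if (all(poly[1, ] == poly[nrow(poly), ])) poly <- poly[-nrow(poly), , drop = FALSE]
  if (nrow(poly) < 20) stop("contour has fewer than 20 vertices")
  perim <- gm_arclength(rbind(poly, poly[1, ]))
  perim <- perim[length(perim)]
  spacing <- min(spacing_px * scale_mm_per_px, perim / 60)
  poly <- gm_resample(poly, step = spacing, closed = TRUE)
  if (gm_polygon_area(poly[, 1], poly[, 2]) < 0) poly <- poly[nrow(poly):1, , drop = FALSE]
  colnames(poly) <- c("x", "y")
  structure(poly, class = c("gut_contour", "matrix", "array"),
            scale_mm_per_px = scale_mm_per_px)
}

#' Voronoi medial axis of a tubular contour
#'
#' Computes the Voronoi diagram of (densely resampled) contour points; the
#' circumcenters of interior Delaunay triangles approximate the medial axis,
#' and the returned midline is the longest geodesic path through the interior
#' Voronoi vertex graph, smoothed by a deviation-bounded smoothing spline and
#' resampled at uniform arclength. The local radius at each sample is the
#' distance to the nearest contour point.
#'
#' @param contour a contour from [extract_contour()] (or an n x 2 matrix of
#'   closed-polygon coordinates in mm).
#' @param config a [morph_config()].
#' @return a [midline()].
#' @export
medial_axis_voronoi <- function(contour, config = morph_config()) {
  sc <- attr(contour, "scale_mm_per_px")
  if (is.null(sc)) sc <- config$scale_mm_per_px
  poly <- unclass(contour)
  perim <- gm_arclength(rbind(poly, poly[1, ]))
  perim <- perim[length(perim)]
  n_pts <- max(config$min_contour_points, ceiling(perim / sc))
  dense <- gm_resample(poly, n_out = n_pts + 1L, closed = TRUE)

  del <- gm_delaunay(dense[, 1], dense[, 2])
  inside <- gm_in_polygon(del$cc[, 1], del$cc[, 2], dense[, 1], dense[, 2])
  if (sum(inside) < 2) stop("aspect ratio below tubular threshold")
  ed <- gm_voronoi_edges(del)
  keep_e <- inside[ed[, 1]] & inside[ed[, 2]]
  ed <- ed[keep_e, , drop = FALSE]
  if (!nrow(ed)) stop("aspect ratio below tubular threshold")
  wts <- sqrt((del$cc[ed[, 1], 1] - del$cc[ed[, 2], 1])^2 +
              (del$cc[ed[, 1], 2] - del$cc[ed[, 2], 2])^2)
  g <- igraph::graph_from_edgelist(cbind(as.character(ed[, 1]),
                                         as.character(ed[, 2])),
                                   directed = FALSE)
  igraph::E(g)$weight <- wts
  comp <- igraph::components(g)
  main <- which.max(comp$csize)
  g <- igraph::induced_subgraph(g, which(comp$membership == main))

  # longest geodesic path: its endpoints are leaves of the (tree-like) graph
  deg <- igraph::degree(g)
  leaves <- which(deg <= 1)
  if (length(leaves) < 2) leaves <- order(deg)[1:2]
  dm <- igraph::distances(g, v = leaves, to = leaves)
  ij <- which(dm == max(dm), arr.ind = TRUE)[1, ]
  sp <- igraph::shortest_paths(g, from = leaves[ij[1]], to = leaves[ij[2]],
                               output = "vpath")$vpath[[1]]
  vid <- as.integer(igraph::V(g)$name[as.integer(sp)])
  path <- del$cc[vid, , drop = FALSE]
  r_raw <- sqrt(del$r2[vid])

  s_raw <- gm_arclength(path)
  keep <- c(TRUE, diff(s_raw) > 0)
  path <- path[keep, , drop = FALSE]
  s_raw <- s_raw[keep]; r_raw <- r_raw[keep]

  # pre-trim the cap regions: circumcenters generated by near-collinear
  # triples on the rounded tips scatter radially and would both wiggle the
  # path and defeat the deviation-bounded smoothing below. The trimmed span
  # is restored afterwards by tangent extension.
  pre <- .trim_caps(s_raw, path, r_raw)

  # deviation-bounded smoothing of x(s), y(s)
  tol <- config$smooth_tol_px * sc
  fit_xy <- .smooth_path(pre$s, pre$xy, tol)

  # uniform-arclength resample of the smoothed path
  step <- config$midline_step_px * sc
  sm <- gm_resample(fit_xy, step = step)
  if (config$end_rule != "raw") sm <- .extend_to_contour(sm, dense)
  sm <- gm_resample(sm, step = step)
  s <- gm_arclength(sm)
  if (config$end_rule == "cap_trim") {
    w <- .perp_halfwidth(sm, dense)
    w[is.na(w)] <- 0
    tr <- .trim_caps(s, sm, w)
    s <- tr$s; sm <- tr$xy
  }
  r <- gm_nearest_dist(sm[, 1], sm[, 2], dense[, 1], dense[, 2])
  L <- s[length(s)]
  aspect <- L / max(2 * mean(r), 1e-12)
  if (aspect < config$tubular_aspect_min) {
    stop(sprintf("aspect ratio below tubular threshold (%.2f < %g)",
                 aspect, config$tubular_aspect_min))
  }
  midline(s, sm[, 1], sm[, 2], r)
}

# Smoothing spline on x(s), y(s). The smoothness of each coordinate is chosen
# by generalized cross-validation (the raw Voronoi path is already clean, so
# GCV picks a mild penalty); if the smoothed path deviates from the raw path
# by more than tol anywhere, the penalty is bisected down until it complies.
.smooth_path <- function(s, path, tol) {
  n <- length(s)
  if (n < 10 || tol <= 0) return(path)
  eval_at <- function(spar) {
    fx <- if (is.null(spar)) stats::smooth.spline(s, path[, 1]) else
      stats::smooth.spline(s, path[, 1], spar = spar)
    fy <- if (is.null(spar)) stats::smooth.spline(s, path[, 2]) else
      stats::smooth.spline(s, path[, 2], spar = spar)
    xy <- cbind(stats::predict(fx, s)$y, stats::predict(fy, s)$y)
    list(xy = xy, dev = sqrt(max(rowSums((xy - path)^2))),
         spar = max(fx$spar, fy$spar))
  }
  best <- eval_at(NULL)
  if (best$dev <= tol) return(best$xy)
  lo <- 0; hi <- best$spar
  best <- eval_at(lo)
  if (best$dev > tol) return(path)
  for (it in 1:10) {
    mid <- (lo + hi) / 2
    cand <- eval_at(mid)
    if (cand$dev <= tol) {
      lo <- mid; best <- cand
    } else hi <- mid
  }
  best$xy
}

# Trim rounded end caps off a tip-to-tip midline: from each tip, cut at the
# first arclength where distance-from-tip >= local radius. For a tube with
# hemispherical caps this is exactly the cap center, so the trimmed midline
# spans the tube's own axis and excludes the caps.
.trim_caps <- function(s, xy, r) {
  n <- length(s)
  # first upward zero-crossing of g after g has actually gone negative
  # (entered the cap); samples at the very tip can sit at g >= 0 spuriously.
  up_crossing <- function(g, ss) {
    neg <- which(g < 0)[1]
    if (is.na(neg)) return(ss[1])
    i <- which(g >= 0 & seq_along(g) > neg)[1]
    if (is.na(i)) return(ss[1])
    a <- i - 1L
    ss[a] + (ss[i] - ss[a]) * (0 - g[a]) / (g[i] - g[a])
  }
  s_lo <- up_crossing(s - r, s)
  s_hi_rev <- up_crossing(rev(s[n] - s) - rev(r), rev(s[n] - s))
  s_hi <- s[n] - s_hi_rev
  if (s_hi - s_lo < sqrt(.Machine$double.eps)) return(list(s = s, xy = xy, r = r))
  si <- unique(sort(c(s_lo, s[s > s_lo & s < s_hi], s_hi)))
  list(s = si - s_lo,
       xy = cbind(stats::approx(s, xy[, 1], xout = si)$y,
                  stats::approx(s, xy[, 2], xout = si)$y),
       r = stats::approx(s, r, xout = si)$y)
}

# Perpendicular half-width of the silhouette at each polyline sample: mean of
# the two ray-cast distances from the sample to the polygon along +/- normal.
# Inside a hemispherical cap at depth u from the tip this is sqrt(2 r u - u^2),
# which equals u exactly at the cap center -- unlike the nearest-boundary
# distance (= u throughout the cap), it gives a transversal trim crossing.
.perp_halfwidth <- function(xy, poly) {
  n <- nrow(xy)
  tx <- numeric(n); ty <- numeric(n)
  tx[2:n] <- xy[2:n, 1] - xy[1:(n - 1), 1]
  ty[2:n] <- xy[2:n, 2] - xy[1:(n - 1), 2]
  tx[1] <- tx[2]; ty[1] <- ty[2]
  tl <- sqrt(tx^2 + ty^2); tl[tl == 0] <- 1
  nx <- -ty / tl; ny <- tx / tl
  m <- nrow(poly)
  j <- c(2:m, 1L)
  ax <- poly[, 1]; ay <- poly[, 2]
  ex <- poly[j, 1] - ax; ey <- poly[j, 2] - ay
  w <- numeric(n)
  for (i in seq_len(n)) {
    den <- nx[i] * ey - ny[i] * ex
    ok <- abs(den) > 1e-14
    t1 <- ((ax - xy[i, 1]) * ey - (ay - xy[i, 2]) * ex) / den
    u <- ((ax - xy[i, 1]) * ny[i] - (ay - xy[i, 2]) * nx[i]) / den
    hit <- ok & u >= 0 & u < 1
    pos <- t1[hit & t1 > 0]; neg <- t1[hit & t1 < 0]
    w[i] <- if (length(pos) && length(neg)) (min(pos) - max(neg)) / 2 else NA_real_
  }
  w
}

# Extend both path ends along their tangents until they cross the contour.
.extend_to_contour <- function(path, poly) {
  ext_one <- function(p_end, p_prev) {
    d <- p_end - p_prev
    d <- d / sqrt(sum(d^2))
    n <- nrow(poly)
    j <- c(2:n, 1L)
    ax <- poly[, 1]; ay <- poly[, 2]
    bx <- poly[j, 1]; by <- poly[j, 2]
    ex <- bx - ax; ey <- by - ay
    den <- d[1] * ey - d[2] * ex
    ok <- abs(den) > 1e-12
    t1 <- ((ax - p_end[1]) * ey - (ay - p_end[2]) * ex) / den
    u <- ((ax - p_end[1]) * d[2] - (ay - p_end[2]) * d[1]) / den
    hit <- ok & t1 > 0 & u >= 0 & u <= 1
    if (!any(hit)) return(NULL)
    tmin <- min(t1[hit])
    p_end + tmin * d
  }
  m <- nrow(path)
  a <- ext_one(path[1, ], path[min(5L, m), ])
  b <- ext_one(path[m, ], path[max(1L, m - 4L), ])
  if (!is.null(a)) path <- rbind(a, path)
  if (!is.null(b)) path <- rbind(path, b)
  path
}

#' Morphometry from a midline
#'
#' Length is the final arclength; volume is the trapezoidal integral of
#' `pi r(s)^2`; mean diameter is the arclength-weighted mean of `2 r(s)`.
#' The lumen is neglected (it occupies < 5% of the volume at these stages).
#'
#' @param ml a [midline()].
#' @return a [tube_morphometry()].
#' @export
morphometry_from_midline <- function(ml) {
  stopifnot(inherits(ml, "midline"), nrow(ml) >= 2)
  n <- nrow(ml)
  if (n > 2 && any(ml$r[2:(n - 1)] <= 0)) {
    stop("non-positive radius at an interior midline sample")
  }
  L <- ml$s[n]
  vol <- trapz(ml$s, pi * ml$r^2)
  mean_d <- trapz(ml$s, 2 * ml$r) / L
  tube_morphometry(L, mean_d, vol,
                   diameter_profile = data.frame(s_mm = ml$s,
                                                 diameter_mm = 2 * ml$r))
}

#' Measure a tube silhouette end to end
#'
#' Composition of [segment_silhouette()], [extract_contour()],
#' [medial_axis_voronoi()] and [morphometry_from_midline()]; the single entry
#' point used by the command line.
#'
#' @param image grayscale image matrix.
#' @param scale_mm_per_px image scale.
#' @param config a [morph_config()].
#' @return a [tube_morphometry()].
#' @export
measure_tube <- function(image, scale_mm_per_px = NULL, config = morph_config()) {
  if (!is.null(scale_mm_per_px)) config$scale_mm_per_px <- scale_mm_per_px
  sc <- config$scale_mm_per_px
  mask <- segment_silhouette(image, sc, threshold = config$threshold)
  ctr <- extract_contour(mask, sc, blur_px = config$contour_blur_px,
                         spacing_px = config$contour_spacing_px)
  ml <- medial_axis_voronoi(ctr, config)
  morphometry_from_midline(ml)
}

#' Relative discrepancy between two morphometry results
#'
#' @param a,b [tube_morphometry()] objects in the same units.
#' @return named numeric vector of `|a - b| / mean(a, b)` for length, mean
#'   diameter and volume.
#' @export
compare_methods <- function(a, b) {
  stopifnot(inherits(a, "tube_morphometry"), inherits(b, "tube_morphometry"))
  one <- function(x, y) {
    m <- (x + y) / 2
    if (m == 0) stop("zero denominator in method comparison")
    abs(x - y) / m
  }
  c(length = one(a$length_mm, b$length_mm),
    diameter = one(a$mean_diameter_mm, b$mean_diameter_mm),
    volume = one(a$volume_mm3, b$volume_mm3))
}
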