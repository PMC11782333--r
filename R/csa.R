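#' Centerline plus lumen surface geometry
#'
#' Pairs an ordered vessel centerline (from the anastomosis center toward
#' the vein) with the triangulated lumen surface it runs through, for
#' cross-sectional-area extraction.
#'
#' @param points Numeric `k x 3` matrix of ordered centerline coordinates
#'   (mm), k >= 2, consecutive points distinct.
#' @param vertices Numeric `n x 3` matrix of surface vertex coordinates (mm).
#' @param triangles Integer `m x 3` matrix of 1-based vertex indices.
#' @return A `centerline_geometry` object.
#' @export
centerline_geometry <- function(points, vertices, triangles) {
  points <- as.matrix(points); vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  if (ncol(points) != 3 || nrow(points) < 2)
    stop("centerline needs >= 2 points with 3 coordinates")
  if (any(sqrt(rowSums(diff(points)^2)) == 0))
    stop("consecutive centerline points must be distinct")
  if (ncol(vertices) != 3) stop("vertices must be n x 3")
  if (min(triangles) < 1 || max(triangles) > nrow(vertices))
    stop("triangle indices out of range")
  structure(list(points = points,
                 surface = list(vertices = vertices, triangles = triangles)),
            class = "centerline_geometry")
}

#' Cross-sectional-area profile along a centerline
#'
#' Resamples the centerline at a uniform arc-length spacing and, at each
#' station, cuts the lumen surface with the plane normal to the local
#' centerline tangent. Among the closed intersection contours, the one
#' whose centroid lies nearest the centerline point is kept (guarding
#' against grazing cuts through other vessel limbs near the anastomosis)
#' and its enclosed polygon area is reported. Stations where the plane
#' misses the surface, or where only open chains are found, get `NA`
#' rather than zero, so downstream remodeling statistics are not biased.
#'
#' @param geom A `centerline_geometry`.
#' @param spacing_mm Arc-length station spacing (mm), default 0.1.
#' @return A `csa_profile`: data.frame with `arc_length_mm` (starting at 0,
#'   uniform spacing) and `area_mm2` (`NA` where no section exists).
#' @export
csa_profile <- function(geom, spacing_mm = 0.1) {
  stopifnot(inherits(geom, "centerline_geometry"), spacing_mm > 0)
  cl <- .resample_centerline(geom$points, spacing_mm)
  V <- geom$surface$vertices
  Tm <- geom$surface$triangles
  scale <- max(apply(V, 2, function(z) diff(range(z))))
  areas <- vapply(seq_len(nrow(cl$points)), function(i) {
    .section_area(V, Tm, cl$points[i, ], cl$tangents[i, ], scale)
  }, numeric(1))
  out <- data.frame(arc_length_mm = cl$arc, area_mm2 = areas)
  class(out) <- c("csa_profile", "data.frame")
  out
}

# Uniform arc-length resampling with central-difference tangents.
.resample_centerline <- function(points, spacing) {
  seg <- sqrt(rowSums(diff(points)^2))
  s_in <- c(0, cumsum(seg))
  s_out <- seq(0, s_in[length(s_in)], by = spacing)
  P <- sapply(1:3, function(k) stats::approx(s_in, points[, k], s_out)$y)
  P <- matrix(P, ncol = 3)
  n <- nrow(P)
  Tg <- (P[pmin(seq_len(n) + 1, n), ] - P[pmax(seq_len(n) - 1, 1), ])
  Tg <- Tg / sqrt(rowSums(Tg^2))
  list(arc = s_out, points = P, tangents = Tg)
}

# Area of the closed plane-surface intersection contour nearest `p`,
# or NA when no closed contour exists.
.section_area <- function(V, Tm, p, nrm, scale) {
  d <- as.numeric(V %*% nrm) - sum(p * nrm)
  d[d == 0] <- scale * 1e-12          # nudge on-plane vertices off the plane
  s1 <- d[Tm[, 1]]; s2 <- d[Tm[, 2]]; s3 <- d[Tm[, 3]]
  cut <- (pmin(s1, s2, s3) < 0) & (pmax(s1, s2, s3) > 0)
  if (!any(cut)) return(NA_real_)
  tri <- Tm[cut, , drop = FALSE]
  # each cut triangle contributes a segment joining its two crossing edges
  edge_key <- function(i, j) paste0(pmin(i, j), "_", pmax(i, j))
  seg_a <- character(nrow(tri)); seg_b <- character(nrow(tri))
  pts <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(tri))) {
    vids <- tri[r, ]
    dv <- d[vids]
    cross <- which(c(dv[1] * dv[2], dv[2] * dv[3], dv[3] * dv[1]) < 0)
    e <- list(c(1, 2), c(2, 3), c(3, 1))[cross]
    keys <- vapply(e, function(ij) edge_key(vids[ij[1]], vids[ij[2]]), "")
    for (k in seq_along(e)) {
      if (is.null(pts[[keys[k]]])) {
        i <- vids[e[[k]][1]]; j <- vids[e[[k]][2]]
        tpar <- d[i] / (d[i] - d[j])
        pts[[keys[k]]] <- V[i, ] + tpar * (V[j, ] - V[i, ])
      }
    }
    seg_a[r] <- keys[1]; seg_b[r] <- keys[2]
  }
  # chain segments into loops: every crossing edge of a closed surface
  # borders exactly two cut triangles
  nbr <- new.env(parent = emptyenv())
  add <- function(a, b) assign(a, c(if (!is.null(nbr[[a]])) nbr[[a]], b), nbr)
  for (r in seq_along(seg_a)) { add(seg_a[r], seg_b[r]); add(seg_b[r], seg_a[r]) }
  visited <- new.env(parent = emptyenv())
  basis <- .plane_basis(nrm)
  best <- c(dist = Inf, area = NA_real_)
  for (start in ls(nbr)) {
    if (!is.null(visited[[start]])) next
    loop <- character(0)
    cur <- start; prev <- ""
    closed <- FALSE
    repeat {
      assign(cur, TRUE, visited)
      loop <- c(loop, cur)
      nxt <- setdiff(nbr[[cur]], prev)[1]
      if (is.na(nxt)) break                       # open chain (boundary cut)
      if (nxt == start) { closed <- TRUE; break }
      prev <- cur; cur <- nxt
    }
    if (!closed || length(loop) < 3) next
    P <- t(vapply(loop, function(k) pts[[k]], numeric(3)))
    uv <- cbind((P - matrix(p, nrow(P), 3, byrow = TRUE)) %*% basis$u,
                (P - matrix(p, nrow(P), 3, byrow = TRUE)) %*% basis$v)
    area <- abs(.shoelace(uv))
    ctr_dist <- sqrt(sum(colMeans(uv)^2))
    if (ctr_dist < best["dist"]) best <- c(dist = ctr_dist, area = area)
  }
  unname(best["area"])
}

.plane_basis <- function(nrm) {
  a <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * nrm) * nrm
  u <- u / sqrt(sum(u^2))
  v <- c(nrm[2] * u[3] - nrm[3] * u[2],
         nrm[3] * u[1] - nrm[1] * u[3],
         nrm[1] * u[2] - nrm[2] * u[1])
  list(u = u, v = v)
}

.shoelace <- function(uv) {
  x <- uv[, 1]; y <- uv[, 2]
  n <- nrow(uv)
  sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y) / 2
}

#' Per-station cross-sectional-area change between two profiles
#'
#' Signed per-station difference `b - a` (mm^2) after linearly resampling
#' profile `b` onto `a`'s arc-length grid, with a remodeling flag at
#' stations whose absolute change strictly exceeds `threshold_mm2`.
#' Venous remodeling larger than 5 mm^2 per cross-section between
#' consecutive visits marks either stenosis (shrinking) or dilatation
#' (growth).
#'
#' @param profile_a,profile_b `csa_profile` objects (earlier, later).
#' @param threshold_mm2 Remodeling threshold, default 5 (strict `>`).
#' @return data.frame with `arc_length_mm`, `delta_mm2`, `remodeled`
#'   (`NA` delta where either profile is missing).
#' @export
csa_change <- function(profile_a, profile_b, threshold_mm2 = 5) {
  ra <- range(profile_a$arc_length_mm); rb <- range(profile_b$arc_length_mm)
  if (ra[1] > rb[2] || rb[1] > ra[2])
    stop("profiles cover non-overlapping arc-length ranges")
  ok_b <- !is.na(profile_b$area_mm2)
  if (sum(ok_b) < 2) stop("profile_b has too few valid stations to resample")
  b_on_a <- stats::approx(profile_b$arc_length_mm[ok_b],
                          profile_b$area_mm2[ok_b],
                          xout = profile_a$arc_length_mm)$y
  delta <- b_on_a - profile_a$area_mm2
  data.frame(arc_length_mm = profile_a$arc_length_mm,
             delta_mm2 = delta,
             remodeled = ifelse(is.na(delta), NA, abs(delta) > threshold_mm2))
}

#' Triangulated tube surface for synthetic vessel geometry
#'
#' Builds an open-ended tube of circular sections along the z axis with an
#' arbitrary radius profile — the synthetic stand-in for a lumen surface
#' in geometry tests (straight cylinder, cone, stenosed vessel).
#'
#' @param radius_fun Function of axial position z (mm) returning the local
#'   radius (mm); a single number is accepted for a constant radius.
#' @param length_mm Tube length (mm).
#' @param n_theta Vertices around the circumference (default 64).
#' @param n_axial Vertex rings along the axis (default 81).
#' @return List with `vertices` (matrix) and `triangles` (matrix), plus a
#'   `centerline` matrix along the axis.
#' @export
tube_surface <- function(radius_fun, length_mm, n_theta = 64, n_axial = 81) {
  if (is.numeric(radius_fun)) {
    r0 <- radius_fun
    radius_fun <- function(z) rep(r0, length(z))
  }
  z <- seq(0, length_mm, length.out = n_axial)
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  r <- radius_fun(z)
  vertices <- cbind(
    x = as.vector(outer(cos(th), r)),
    y = as.vector(outer(sin(th), r)),
    z = rep(z, each = n_theta))
  tri <- vector("list", 2L * (n_axial - 1) * n_theta)
  k <- 0L
  for (i in seq_len(n_axial - 1)) {
    base <- (i - 1L) * n_theta
    for (j in seq_len(n_theta)) {
      jn <- if (j == n_theta) 1L else j + 1L
      a <- base + j; b <- base + jn
      c2 <- base + n_theta + j; d2 <- base + n_theta + jn
      tri[[k + 1L]] <- c(a, b, c2)
      tri[[k + 2L]] <- c(b, d2, c2)
      k <- k + 2L
    }
  }
  list(vertices = vertices,
       triangles = do.call(rbind, tri),
       centerline = cbind(0, 0, z))
}
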