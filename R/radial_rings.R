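#' Equal-area concentric ring analysis of nuclear localisation density
#'
#' A nuclear ROI is subdivided into `n` concentric rings of equal area by
#' scaling the contour about its centroid: the k-th ring lies between the
#' contour scaled by `sqrt((k-1)/n)` and by `sqrt(k/n)`. Because the area
#' of a scaled copy grows as the square of the scale, the rings have
#' exactly equal area whenever the scaled copies nest, which holds for any
#' contour that is star-shaped about its centroid (real nuclear outlines
#' are near-convex). Ring 1 is the nuclear centre, ring `n` the periphery.
#'
#' @name radial_rings
NULL

#' Build an equal-area ring set for a nuclear ROI
#'
#' @param roi a [roi_polygon()].
#' @param n_rings number of rings (default 6).
#' @return A `ring_set`: list with `roi`, `n_rings`,
#'   `scales` (`sqrt(k/n)`, k = 1..n), `ring_area_um2`
#'   (= `roi_area(roi)/n_rings`), `centroid` and `star_shaped`. If the
#'   polygon is not star-shaped about its centroid a warning is raised and
#'   recorded (ring areas are then only approximately equal).
#' @export
build_rings <- function(roi, n_rings = 6L) {
  stopifnot(inherits(roi, "roi_polygon"))
  n_rings <- as.integer(n_rings)
  if (is.na(n_rings) || n_rings < 2L)
    stop("parameter error: n_rings must be an integer >= 2")
  ctr <- polygon_centroid(roi)
  star <- .is_star_shaped(roi$vertices, ctr)
  if (!star)
    warning("ROI is not star-shaped about its centroid; ring areas are only approximately equal")
  structure(list(roi = roi,
                 n_rings = n_rings,
                 scales = sqrt(seq_len(n_rings) / n_rings),
                 ring_area_um2 = roi_area(roi) / n_rings,
                 centroid = ctr,
                 star_shaped = star),
            class = "ring_set")
}

# star-shaped about c <=> vertex angles about c are strictly monotone
# (mod one wrap); for a simple polygon this means every ray from c crosses
# the boundary exactly once
.is_star_shaped <- function(v, ctr) {
  ang <- atan2(v[, 2L] - ctr[2L], v[, 1L] - ctr[1L])
  d <- diff(c(ang, ang[1L]))
  d <- ((d + pi) %% (2 * pi)) - pi       # wrap to (-pi, pi]
  isTRUE(all(d > 0)) || isTRUE(all(d < 0))
}

#' Scale a ROI polygon about a point
#'
#' @param roi a [roi_polygon()].
#' @param s positive scale factor.
#' @param about length-2 centre of scaling (default the polygon centroid).
#' @return A new [roi_polygon()].
#' @export
scale_roi <- function(roi, s, about = polygon_centroid(roi)) {
  stopifnot(inherits(roi, "roi_polygon"), s > 0)
  v <- sweep(roi$vertices, 2L, about)
  roi_polygon(sweep(v * s, 2L, about, `+`))
}

#' Containing scale of points relative to a star-shaped contour
#'
#' For each point, the smallest s such that the contour scaled by s about
#' its centroid contains the point: the distance from the centroid to the
#' point divided by the distance from the centroid to the boundary along
#' the same ray. Values > 1 lie outside the ROI.
#'
#' @param points numeric matrix / data.frame with columns (x, y) in nm, or
#'   a length-2 vector for a single point.
#' @param rings a `ring_set` from [build_rings()] (or a [roi_polygon()],
#'   in which case the centroid is computed here).
#' @return Numeric vector of scales (0 at the centroid itself).
#' @export
containing_scale <- function(points, rings) {
  if (inherits(rings, "roi_polygon"))
    rings <- list(roi = rings, centroid = polygon_centroid(rings))
  v <- rings$roi$vertices
  ctr <- rings$centroid
  pts <- .as_xy_matrix(points)
  dx <- pts[, 1L] - ctr[1L]
  dy <- pts[, 2L] - ctr[2L]
  r <- sqrt(dx^2 + dy^2)
  ok <- r > 0
  ux <- ifelse(ok, dx / r, 1)
  uy <- ifelse(ok, dy / r, 0)
  n <- nrow(v)
  nxt <- c(2:n, 1L)
  tmin <- rep(Inf, nrow(pts))
  for (e in seq_len(n)) {
    ax <- v[e, 1L] - ctr[1L]; ay <- v[e, 2L] - ctr[2L]
    ex <- v[nxt[e], 1L] - v[e, 1L]; ey <- v[nxt[e], 2L] - v[e, 2L]
    den <- ux * ey - uy * ex
    # ray c + t*u meets segment a + w*e where t = cross(a, e)/den, w = cross(a, u)/den
    tt <- (ax * ey - ay * ex) / den
    ww <- (ax * uy - ay * ux) / den
    # w tolerance admits rays passing exactly through a vertex, which
    # floating point can otherwise exclude from both adjacent edges
    hit <- is.finite(tt) & tt > 0 & ww >= -1e-9 & ww < 1 + 1e-9
    tmin[hit] <- pmin(tmin[hit], tt[hit])
  }
  s <- r / tmin
  s[!ok] <- 0
  s
}

.as_xy_matrix <- function(points) {
  if (is.null(dim(points))) {
    stopifnot(length(points) == 2L)
    matrix(as.numeric(points), ncol = 2L)
  } else {
    pts <- as.matrix(as.data.frame(points)[, 1:2])
    storage.mode(pts) <- "double"
    pts
  }
}

#' Assign points to rings
#'
#' A point belongs to the smallest k such that it lies inside the contour
#' scaled by `sqrt(k/n)`: a point exactly on a shared ring boundary belongs
#' to the inner of the two rings, and a point on the ROI outline belongs to
#' ring n.
#'
#' @param points (x, y) matrix or single point, in nm.
#' @param rings a `ring_set`.
#' @return Integer vector of ring indices in `1..n_rings`, `NA` for points
#'   outside the ROI.
#' @export
assign_ring <- function(points, rings) {
  stopifnot(inherits(rings, "ring_set"))
  s <- containing_scale(points, rings)
  n <- rings$n_rings
  k <- ceiling(s^2 * n - 1e-9)
  k[k < 1L] <- 1L
  k[s > 1 + 1e-9] <- NA_integer_
  as.integer(k)
}

#' Radial ring profile of a localisation table
#'
#' Counts the in-ROI localisations per ring and converts them to densities
#' (localisations per um^2, each ring having area `roi_area/n`). Every
#' in-ROI localisation lands in exactly one ring, so the counts sum to the
#' in-ROI total.
#'
#' @param table a [loc_table()].
#' @param rings a `ring_set` from [build_rings()].
#' @return A `ring_profile`: list with `counts` (length `n_rings`,
#'   index 1 = centre), `densities_per_um2`, `n_inside` and `ring_area_um2`.
#' @export
ring_profile <- function(table, rings) {
  stopifnot(inherits(table, "loc_table"), inherits(rings, "ring_set"))
  inside <- filter_by_roi(table, rings$roi)
  n <- rings$n_rings
  if (nrow(inside) == 0L) {
    counts <- integer(n)
  } else {
    s <- containing_scale(cbind(inside$x_nm, inside$y_nm), rings)
    k <- ceiling(s^2 * n - 1e-9)
    # points admitted by the boundary-inclusive ROI test are clamped into
    # the valid ring range so the counts always partition the in-ROI total
    k <- pmin(pmax(k, 1), n)
    counts <- tabulate(k, nbins = n)
  }
  structure(list(counts = counts,
                 densities_per_um2 = counts / rings$ring_area_um2,
                 n_inside = nrow(inside),
                 ring_area_um2 = rings$ring_area_um2),
            class = "ring_profile")
}

#' Closed-form ring probabilities under a radial density law
#'
#' For points whose radial position follows density proportional to
#' s^gamma in the containing scale s (s in (0, 1]; gamma = 0 is uniform,
#' gamma > 0 periphery-weighted), the probability of ring k is
#' `(k/n)^(1 + gamma/2) - ((k-1)/n)^(1 + gamma/2)`.
#'
#' @param gamma radial gradient exponent, >= 0.
#' @param n_rings number of rings (default 6).
#' @return Numeric vector of ring probabilities summing to 1.
#' @export
expected_ring_probs <- function(gamma, n_rings = 6L) {
  stopifnot(gamma >= 0, n_rings >= 2L)
  k <- seq_len(n_rings)
  e <- 1 + gamma / 2
  (k / n_rings)^e - ((k - 1) / n_rings)^e
}

#' Write per-nucleus ring profiles as CSV
#'
#' One row per nucleus: id, per-ring counts, per-ring densities.
#'
#' @param profiles named list of `ring_profile` objects.
#' @param path output CSV path.
#' @return The assembled data.frame, invisibly.
#' @export
write_ring_table <- function(profiles, path) {
  rows <- lapply(seq_along(profiles), function(ix) {
    p <- profiles[[ix]]
    id <- if (!is.null(names(profiles))) names(profiles)[ix] else as.character(ix)
    n <- length(p$counts)
    row <- c(list(nucleus_id = id),
             stats::setNames(as.list(p$counts), paste0("ring", seq_len(n), "_count")),
             stats::setNames(as.list(p$densities_per_um2),
                             paste0("ring", seq_len(n), "_density_per_um2")))
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @export
print.ring_set <- function(x, ...) {
  cat(sprintf("Ring set: %d equal-area rings of %.4f um^2 each%s\n",
              x$n_rings, x$ring_area_um2,
              if (!x$star_shaped) " (approximate: contour not star-shaped)" else ""))
  invisible(x)
}

#' @export
print.ring_profile <- function(x, ...) {
  cat("Ring profile (centre -> periphery):\n")
  cat("  counts:   ", paste(x$counts, collapse = " "), "\n")
  cat("  per um^2: ", paste(sprintf("%.1f", x$densities_per_um2), collapse = " "), "\n")
  invisible(x)
}
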