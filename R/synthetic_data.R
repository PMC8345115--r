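#' Synthetic data with planted ground truth
#'
#' Generators for the three data kinds the analyses consume, each with a
#' machine-readable ground-truth record so every downstream stage can be
#' validated by parameter recovery without any external data:
#' localisation tables (nanoscale chromatin organised as small compacted
#' clusters interspersed in a low-density space, with an optional radial
#' bias towards the nuclear periphery), confocal nucleus images with a
#' plantable compact-chromatin fraction, and two-channel tissue fields
#' with a plantable fraction of miR+ cells on the 0-255 intensity scale.
#' Identical specs and seeds produce bit-identical outputs.
#'
#' @name synthetic_data
NULL

#' Specification for a simulated SMLM localisation table
#'
#' Cluster centres are placed inside the contour with radial weight
#' proportional to `s^gamma`, where `s` is the containing scale of the
#' position (0 at the centroid, 1 on the outline); `gamma = 0` is uniform,
#' `gamma > 0` periphery-weighted. Cluster points are Gaussian around
#' their centre (default sigma 25 nm, giving a cluster FWHM of about
#' 59 nm, in the 50-60 nm diameter range of compacted chromatin
#' clusters); points falling outside the contour are redrawn so the total
#' count is exact. Background points are uniform in the contour.
#'
#' @param contour a [roi_polygon()], star-shaped about its centroid.
#' @param total_count exact number of localisations to generate.
#' @param n_clusters number of compact clusters.
#' @param cluster_sigma_nm cluster spread in nm (default 25; 0 plants all
#'   cluster points exactly at their centres).
#' @param background_fraction fraction of points drawn uniformly in the
#'   contour rather than from clusters, in `[0, 1]`.
#' @param radial_gradient_gamma radial gradient exponent, >= 0.
#' @param seed integer RNG seed.
#' @return An `smlm_spec` list.
#' @export
smlm_spec <- function(contour, total_count, n_clusters,
                      cluster_sigma_nm = 25, background_fraction = 0,
                      radial_gradient_gamma = 0, seed = 1L) {
  stopifnot(inherits(contour, "roi_polygon"),
            total_count >= 0, n_clusters >= 0, cluster_sigma_nm >= 0,
            background_fraction >= 0, background_fraction <= 1,
            radial_gradient_gamma >= 0)
  structure(list(contour = contour,
                 total_count = as.integer(total_count),
                 n_clusters = as.integer(n_clusters),
                 cluster_sigma_nm = cluster_sigma_nm,
                 background_fraction = background_fraction,
                 radial_gradient_gamma = radial_gradient_gamma,
                 seed = as.integer(seed)),
            class = "smlm_spec")
}

#' Simulate a localisation table
#'
#' @param spec an [smlm_spec()].
#' @return List with `table` (a [loc_table()] of exactly
#'   `spec$total_count` records, all inside the contour) and `truth`
#'   (cluster centres, per-point cluster id -- 0 for background --,
#'   background count, and the closed-form [expected_ring_probs()] for
#'   the planted gradient).
#' @export
simulate_localisations <- function(spec) {
  stopifnot(inherits(spec, "smlm_spec"))
  ctr <- polygon_centroid(spec$contour)
  if (!.is_star_shaped(spec$contour$vertices, ctr))
    stop("geometry error: contour must be star-shaped about its centroid")
  set.seed(spec$seed)
  N <- spec$total_count
  n_bg <- round(spec$background_fraction * N)
  n_cl <- N - n_bg
  if (spec$n_clusters == 0L && n_cl > 0L) {
    n_bg <- N; n_cl <- 0L
  }
  centres <- if (n_cl > 0L)
    .sample_in_polygon(spec$n_clusters, spec$contour,
                       gamma = spec$radial_gradient_gamma)
  else matrix(numeric(0), ncol = 2L)
  pts <- matrix(numeric(0), ncol = 2L)
  labels <- integer(0)
  if (n_cl > 0L) {
    # near-equal deterministic split so every cluster holds its expected
    # share of points exactly (a 400-cluster spec of 40-point clusters
    # really gets 40 points per cluster)
    q <- n_cl %/% spec$n_clusters
    r <- n_cl %% spec$n_clusters
    sizes <- rep.int(q, spec$n_clusters) + c(rep.int(1L, r),
                                             rep.int(0L, spec$n_clusters - r))
    idx <- rep.int(seq_len(spec$n_clusters), sizes)
    cl_pts <- centres[idx, , drop = FALSE]
    if (spec$cluster_sigma_nm > 0) {
      cl_pts <- cl_pts + matrix(stats::rnorm(2L * n_cl, 0, spec$cluster_sigma_nm),
                                ncol = 2L)
      cl_pts <- .redraw_outside(cl_pts, centres[idx, , drop = FALSE],
                                spec$cluster_sigma_nm, spec$contour)
    }
    pts <- cl_pts
    labels <- idx
  }
  if (n_bg > 0L) {
    bg <- .sample_in_polygon(n_bg, spec$contour, gamma = 0)
    pts <- rbind(pts, bg)
    labels <- c(labels, integer(n_bg))
  }
  perm <- sample.int(N)
  pts <- pts[perm, , drop = FALSE]
  labels <- labels[perm]
  tab <- loc_table(data.frame(
    frame = seq_len(N),
    x_nm = pts[, 1L],
    y_nm = pts[, 2L],
    intensity = round(stats::rlnorm(N, meanlog = log(500), sdlog = 0.5))))
  list(table = tab,
       truth = list(cluster_centres = centres,
                    cluster_id = labels,
                    n_background = n_bg,
                    radial_gradient_gamma = spec$radial_gradient_gamma,
                    expected_ring_probs =
                      expected_ring_probs(spec$radial_gradient_gamma)))
}

# rejection sampling of points in a polygon with radial weight s^gamma
.sample_in_polygon <- function(n, roi, gamma = 0) {
  v <- roi$vertices
  ctr <- polygon_centroid(roi)
  rs <- list(roi = roi, centroid = ctr)
  xr <- range(v[, 1L]); yr <- range(v[, 2L])
  out <- matrix(numeric(0), ncol = 2L)
  while (nrow(out) < n) {
    batch <- max(256L, 2L * (n - nrow(out)))
    cx <- stats::runif(batch, xr[1L], xr[2L])
    cy <- stats::runif(batch, yr[1L], yr[2L])
    keep <- .in_polygon(cx, cy, v)
    cx <- cx[keep]; cy <- cy[keep]
    if (length(cx) == 0L) next
    if (gamma > 0) {
      s <- pmin(containing_scale(cbind(cx, cy), rs), 1)
      acc <- stats::runif(length(cx)) < s^gamma
      cx <- cx[acc]; cy <- cy[acc]
    }
    if (length(cx) > 0L)
      out <- rbind(out, cbind(cx, cy))
  }
  unname(out[seq_len(n), , drop = FALSE])
}

# redraw cluster points that fell outside the contour (rejection keeps the
# total count exact without truncating the Gaussian towards the boundary);
# only the still-outside points are retested each round
.redraw_outside <- function(pts, ctrs, sigma, roi) {
  v <- roi$vertices
  todo <- which(!.in_polygon(pts[, 1L], pts[, 2L], v))
  while (length(todo) > 0L) {
    k <- length(todo)
    pts[todo, ] <- ctrs[todo, , drop = FALSE] +
      matrix(stats::rnorm(2L * k, 0, sigma), ncol = 2L)
    todo <- todo[!.in_polygon(pts[todo, 1L], pts[todo, 2L], v)]
  }
  pts
}

#' Preset localisation-table simulations
#'
#' Named presets emulating the occupancy regimes of the tissue cell types:
#' `"carcinoma-like"` (few clusters, mostly diffuse background, the regime
#' in which most occupied bins hold a single event), `"normal-like"`
#' (many dense clusters over little background, the normal mucosa
#' epithelium regime), `"muscle-like"` and `"submucosa-like"`
#' (intermediate). Default total counts are the four exemplar per-nucleus
#' totals scaled down 100-fold to desk scale, and the default preset
#' contours are circles whose areas are the corresponding nuclear cross
#' sections scaled by the same factor (carcinoma nuclei being notably
#' larger than normal epithelial ones): scaling counts and area together
#' preserves the per-bin occupancy that defines each regime, whereas
#' scaling counts alone would collapse every regime into the sparse
#' one-event-per-bin limit. Pass `total_count` to override the total
#' (regime comparisons should use equal totals). All presets use a
#' periphery-weighted radial gradient (`gamma = 2`), matching the
#' observation that chromatin densities are highest in the outer rings.
#'
#' @param name preset name.
#' @param seed integer RNG seed.
#' @param total_count optional override of the preset total.
#' @param contour optional [roi_polygon()] overriding the preset contour.
#' @return An [smlm_spec()].
#' @export
smlm_preset <- function(name = c("carcinoma-like", "normal-like",
                                 "muscle-like", "submucosa-like"),
                        seed = 1L, total_count = NULL, contour = NULL) {
  name <- match.arg(name)
  p <- switch(name,
    "carcinoma-like" = list(total = 1600L, n_clusters = 50L, bg = 0.9,
                            area_um2 = 1.15),
    "normal-like" = list(total = 9800L, n_clusters = 400L, bg = 0.2,
                         area_um2 = 0.47),
    "muscle-like" = list(total = 13400L, n_clusters = 150L, bg = 0.5,
                         area_um2 = 0.40),
    "submucosa-like" = list(total = 5500L, n_clusters = 120L, bg = 0.4,
                            area_um2 = 0.30))
  if (is.null(contour)) {
    r <- sqrt(p$area_um2 * 1e6 / pi)
    th <- 2 * pi * (0:63) / 64
    contour <- roi_polygon(cbind(r + 50 + r * cos(th), r + 50 + r * sin(th)))
  }
  if (!is.null(total_count)) p$total <- as.integer(total_count)
  smlm_spec(contour, total_count = p$total, n_clusters = p$n_clusters,
            cluster_sigma_nm = 25, background_fraction = p$bg,
            radial_gradient_gamma = 2, seed = seed)
}

#' Specification for a simulated confocal nucleus image
#'
#' A disk nucleus with baseline chromatin intensity plus `n_domains`
#' non-overlapping bright circular patches whose union covers
#' `compact_fraction` of the nucleus pixels (within 1%; the common patch
#' radius is solved by bisection against the pixelated mask). The image
#' is mildly blurred and carries additive Gaussian noise.
#'
#' @param nucleus_radius_px nucleus radius in pixels.
#' @param compact_fraction target compact-chromatin fraction in `(0, 1)`.
#' @param n_domains number of planted domains.
#' @param noise_sigma additive noise SD (intensity units; default 4 on a
#'   baseline-90 / domain-200 intensity scale).
#' @param seed integer RNG seed.
#' @param pixel_size_um pixel pitch (default 0.1 um, a typical confocal
#'   sampling).
#' @return A `nucleus_image_spec` list.
#' @export
nucleus_image_spec <- function(nucleus_radius_px, compact_fraction, n_domains,
                               noise_sigma = 4, seed = 1L,
                               pixel_size_um = 0.1) {
  stopifnot(nucleus_radius_px >= 8, compact_fraction > 0, compact_fraction < 1,
            n_domains >= 1, noise_sigma >= 0)
  structure(list(nucleus_radius_px = as.integer(nucleus_radius_px),
                 compact_fraction = compact_fraction,
                 n_domains = as.integer(n_domains),
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed),
                 pixel_size_um = pixel_size_um),
            class = "nucleus_image_spec")
}

#' Simulate a confocal nucleus image
#'
#' @param spec a [nucleus_image_spec()].
#' @return List with `image` (a [nucleus_image()]) and `truth`
#'   (`domain_mask`, `nucleus_mask`, `centres`, `patch_radius_px`,
#'   `achieved_fraction`).
#' @export
simulate_nucleus_image <- function(spec) {
  stopifnot(inherits(spec, "nucleus_image_spec"))
  set.seed(spec$seed)
  R <- spec$nucleus_radius_px
  f <- spec$compact_fraction
  n <- spec$n_domains
  side <- max(16L, round(3.2 * R))
  cx <- (side + 1) / 2
  r0 <- R * sqrt(f / n)
  if (r0 < 2)
    stop("spec error: compact_fraction/n_domains gives patches below 2 px radius")
  centres <- .place_patch_centres(n, R, r0)  # relative to nucleus centre
  if (is.null(centres))
    stop("spec error: compact_fraction unreachable with ", n,
         " non-overlapping patches")
  gx <- matrix(seq_len(side), side, side)
  gy <- matrix(seq_len(side), side, side, byrow = TRUE)
  nucleus <- (gx - cx)^2 + (gy - cx)^2 <= R^2
  target <- f * sum(nucleus)
  min_gap <- if (n > 1L) min(stats::dist(centres)) else Inf
  s_max <- min(min_gap / (2 * r0), (R - max(sqrt(rowSums(centres^2)))) / r0)
  domain_at <- function(s) {
    dmask <- matrix(FALSE, side, side)
    for (k in seq_len(n)) {
      dmask <- dmask | ((gx - cx - centres[k, 1L])^2 +
                          (gy - cx - centres[k, 2L])^2 <= (s * r0)^2)
    }
    dmask & nucleus
  }
  lo <- 0.5; hi <- s_max
  if (sum(domain_at(hi)) < target * 0.99 || sum(domain_at(lo)) > target * 1.01)
    stop("spec error: compact_fraction unreachable with ", n,
         " non-overlapping patches")
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    if (sum(domain_at(mid)) < target) lo <- mid else hi <- mid
  }
  dmask <- domain_at(hi)
  base <- matrix(5, side, side)
  base[nucleus] <- 90
  base[dmask] <- 200
  px <- .smooth_px(base, 1)
  if (spec$noise_sigma > 0)
    px <- px + matrix(stats::rnorm(side * side, 0, spec$noise_sigma), side, side)
  px <- pmax(px, 0)
  list(image = nucleus_image(px, spec$pixel_size_um),
       truth = list(domain_mask = dmask,
                    nucleus_mask = nucleus,
                    centres = sweep(centres, 2L, c(cx, cx), `+`),
                    patch_radius_px = hi * r0,
                    achieved_fraction = sum(dmask) / sum(nucleus)))
}

# seeded repulsion relaxation of n patch centres inside a disk of radius R,
# pairwise separation >= 2*r0 + 2 and boundary clearance r0 + 1;
# returns NULL when the packing is infeasible
.place_patch_centres <- function(n, R, r0) {
  if (n == 1L) return(matrix(0, 1L, 2L))
  lim <- R - r0 - 1
  if (lim <= 0) return(NULL)
  sep <- 2 * r0 + 2
  golden <- pi * (3 - sqrt(5))
  k <- seq_len(n)
  rad <- lim * sqrt((k - 0.5) / n)
  ang <- k * golden + stats::runif(1L, 0, 2 * pi)
  pts <- cbind(rad * cos(ang), rad * sin(ang)) +
    matrix(stats::rnorm(2L * n, 0, 0.5), ncol = 2L)
  for (it in 1:600) {
    moved <- FALSE
    for (i in seq_len(n - 1L)) {
      d <- sweep(pts[(i + 1L):n, , drop = FALSE], 2L, pts[i, ])
      dist <- sqrt(rowSums(d^2))
      close <- which(dist < sep)
      for (jj in close) {
        j <- i + jj
        dir <- if (dist[jj] > 0) d[jj, ] / dist[jj] else c(1, 0)
        push <- (sep - dist[jj]) / 2 + 0.1
        pts[i, ] <- pts[i, ] - dir * push
        pts[j, ] <- pts[j, ] + dir * push
        moved <- TRUE
      }
    }
    rr <- sqrt(rowSums(pts^2))
    out <- rr > lim
    if (any(out)) {
      pts[out, ] <- pts[out, , drop = FALSE] * (lim / rr[out])
      moved <- TRUE
    }
    if (!moved) break
  }
  rr <- sqrt(rowSums(pts^2))
  if (any(rr > lim + 1e-6) || min(stats::dist(pts)) < sep - 1e-6) return(NULL)
  pts
}

#' Specification for a simulated two-channel tissue field
#'
#' Disk nuclei in the nuclear channel; each cell's cytoplasm annulus is
#' painted in the miR channel at `positive_mean` or `negative_mean`
#' according to its planted label, plus noise, clipped to the 8-bit
#' `[0, 255]` range. The number of planted positive cells is exactly
#' `round(positive_fraction * n_cells)`.
#'
#' @param n_cells number of cells.
#' @param positive_fraction planted miR+ fraction in `[0, 1]`.
#' @param positive_mean,negative_mean cytoplasm miR intensities on the
#'   0-255 scale (defaults 30 and 1, straddling the positivity threshold
#'   of 5 as stained versus scrambled-control tissue does).
#' @param noise_sigma additive noise SD (default 1).
#' @param seed integer RNG seed.
#' @param nucleus_radius_px nucleus radius in pixels (default 8).
#' @param cytoplasm_width_px cytoplasm annulus width in pixels (default 5).
#' @param pixel_size_um pixel pitch (default 0.5 um, a 20x-magnification
#'   scale).
#' @param dim optional `c(nx, ny)` field size; default sized to hold
#'   `n_cells` on a jittered grid. A field too small for the requested
#'   cells is a placement error.
#' @return A `tissue_field_spec` list.
#' @export
tissue_field_spec <- function(n_cells, positive_fraction,
                              positive_mean = 30, negative_mean = 1,
                              noise_sigma = 1, seed = 1L,
                              nucleus_radius_px = 8L, cytoplasm_width_px = 5L,
                              pixel_size_um = 0.5, dim = NULL) {
  stopifnot(n_cells >= 1, positive_fraction >= 0, positive_fraction <= 1,
            positive_mean >= 0, positive_mean <= 255,
            negative_mean >= 0, negative_mean <= 255, noise_sigma >= 0)
  structure(list(n_cells = as.integer(n_cells),
                 positive_fraction = positive_fraction,
                 positive_mean = positive_mean, negative_mean = negative_mean,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 nucleus_radius_px = as.integer(nucleus_radius_px),
                 cytoplasm_width_px = as.integer(cytoplasm_width_px),
                 pixel_size_um = pixel_size_um, dim = dim),
            class = "tissue_field_spec")
}

#' Simulate a two-channel tissue field
#'
#' @param spec a [tissue_field_spec()].
#' @return List with `field` (a [tissue_field()]) and `truth` (`centres`,
#'   `is_positive`, `n_positive`).
#' @export
simulate_tissue_field <- function(spec) {
  stopifnot(inherits(spec, "tissue_field_spec"))
  set.seed(spec$seed)
  R <- spec$nucleus_radius_px
  w <- spec$cytoplasm_width_px
  cell_pitch <- 2L * (R + w) + 8L
  g <- ceiling(sqrt(spec$n_cells))
  need <- g * cell_pitch + cell_pitch %/% 2L
  if (is.null(spec$dim)) {
    nx <- ny <- need
  } else {
    nx <- spec$dim[1L]; ny <- spec$dim[2L]
    gx_fit <- floor((nx - cell_pitch %/% 2L) / cell_pitch)
    gy_fit <- floor((ny - cell_pitch %/% 2L) / cell_pitch)
    if (gx_fit * gy_fit < spec$n_cells)
      stop("placement error: field of ", nx, " x ", ny,
           " px cannot hold ", spec$n_cells, " non-overlapping cells")
    g <- gx_fit
  }
  slots <- expand.grid(ix = seq_len(g), iy = seq_len(ceiling(spec$n_cells / g)))
  slots <- slots[seq_len(spec$n_cells), , drop = FALSE]
  jitter <- matrix(stats::runif(2L * spec$n_cells, -2, 2), ncol = 2L)
  centres <- cbind(
    (slots$ix - 0.5) * cell_pitch + cell_pitch %/% 4L + jitter[, 1L],
    (slots$iy - 0.5) * cell_pitch + cell_pitch %/% 4L + jitter[, 2L])
  n_pos <- round(spec$positive_fraction * spec$n_cells)
  is_pos <- rep(FALSE, spec$n_cells)
  if (n_pos > 0L) is_pos[sample.int(spec$n_cells, n_pos)] <- TRUE
  gx <- matrix(seq_len(nx), nx, ny)
  gy <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  nuc <- matrix(2, nx, ny)
  mir <- matrix(0, nx, ny)
  for (k in seq_len(spec$n_cells)) {
    d2 <- (gx - centres[k, 1L])^2 + (gy - centres[k, 2L])^2
    nuc[d2 <= R^2] <- 180
    annulus <- d2 > R^2 & d2 <= (R + w)^2
    mir[annulus] <- if (is_pos[k]) spec$positive_mean else spec$negative_mean
  }
  if (spec$noise_sigma > 0) {
    nuc <- nuc + matrix(stats::rnorm(nx * ny, 0, spec$noise_sigma), nx, ny)
    mir <- mir + matrix(stats::rnorm(nx * ny, 0, spec$noise_sigma), nx, ny)
  }
  nuc <- round(pmin(pmax(nuc, 0), 255))
  mir <- round(pmin(pmax(mir, 0), 255))
  list(field = tissue_field(nuc, mir, spec$pixel_size_um),
       truth = list(centres = centres, is_positive = is_pos,
                    n_positive = n_pos))
}

#' Write a simulation's ground truth as a JSON sidecar
#'
#' @param truth the `truth` component of a simulation result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_sidecar <- function(truth, path) {
  truth <- lapply(truth, function(x) if (is.matrix(x)) unname(x) else x)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
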