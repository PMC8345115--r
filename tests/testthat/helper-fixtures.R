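# Shared fixtures and independent oracles, all built in code.

# --- polygon builders (nm coordinates) --------------------------------------

make_square_roi <- function(side = 1000, origin = c(0, 0)) {
  roi_polygon(rbind(origin,
                    origin + c(side, 0),
                    origin + c(side, side),
                    origin + c(0, side)))
}

make_circle_roi <- function(radius = 4000, centre = c(5000, 5000), n = 64L) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  roi_polygon(cbind(centre[1L] + radius * cos(th),
                    centre[2L] + radius * sin(th)))
}

# concave C shape: outer square with a notch opening to the right
make_c_roi <- function() {
  roi_polygon(rbind(c(0, 0), c(3000, 0), c(3000, 1000), c(1000, 1000),
                    c(1000, 2000), c(3000, 2000), c(3000, 3000), c(0, 3000)))
}

# smooth random blob: Fourier-perturbed circle, star-shaped by construction
make_blob_roi <- function(seed, radius = 4000, centre = c(5000, 5000),
                          n = 64L, max_amp = 0.12) {
  set.seed(seed)
  amps <- runif(3L, 0.02, max_amp / 3)
  phis <- runif(3L, 0, 2 * pi)
  ks <- c(2L, 3L, 5L)
  th <- 2 * pi * (seq_len(n) - 1L) / n
  r <- radius * (1 + Reduce(`+`, lapply(1:3, function(i)
    amps[i] * cos(ks[i] * th + phis[i]))))
  roi_polygon(cbind(centre[1L] + r * cos(th), centre[2L] + r * sin(th)))
}

make_table <- function(x, y, frame = NULL) {
  n <- length(x)
  loc_table(data.frame(frame = if (is.null(frame)) seq_len(n) else frame,
                       x_nm = x, y_nm = y))
}

uniform_points_in_bbox <- function(n, roi) {
  v <- roi$vertices
  cbind(runif(n, min(v[, 1L]), max(v[, 1L])),
        runif(n, min(v[, 2L]), max(v[, 2L])))
}

# --- independent oracles ----------------------------------------------------

# textbook even-odd crossing-number point-in-polygon test (scalar loop,
# independent of the pracma-based implementation); boundary points are not
# handled and callers use interior/exterior points only
ray_cast_inside <- function(points, roi) {
  v <- roi$vertices
  n <- nrow(v)
  apply(points, 1L, function(p) {
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      if ((v[i, 2L] > p[2L]) != (v[j, 2L] > p[2L])) {
        xint <- v[i, 1L] + (p[2L] - v[i, 2L]) *
          (v[j, 1L] - v[i, 1L]) / (v[j, 2L] - v[i, 2L])
        if (p[1L] < xint) inside <- !inside
      }
      j <- i
    }
    inside
  })
}

# brute-force per-point floor-division bin assignment with an environment
# as hash map
brute_bin_counts <- function(table, bin_size, origin = c(0, 0)) {
  env <- new.env(hash = TRUE)
  for (r in seq_len(nrow(table))) {
    i <- floor((table$x_nm[r] - origin[1L]) / bin_size)
    j <- floor((table$y_nm[r] - origin[2L]) / bin_size)
    key <- paste(i, j)
    env[[key]] <- (if (is.null(env[[key]])) 0L else env[[key]]) + 1L
  }
  keys <- ls(env)
  parts <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
  data.frame(i = as.integer(parts[, 1L]), j = as.integer(parts[, 2L]),
             count = vapply(keys, function(k) env[[k]], integer(1L)),
             row.names = NULL)
}

sorted_bins <- function(df) {
  df <- df[order(df$i, df$j), c("i", "j", "count")]
  rownames(df) <- NULL
  df
}

# stratified (jittered-grid) Monte-Carlo estimate of the ring areas, in um^2
mc_ring_areas <- function(rings, grid_n = 400L) {
  v <- rings$roi$vertices
  xr <- range(v[, 1L]); yr <- range(v[, 2L])
  gx <- (rep(seq_len(grid_n), each = grid_n) - runif(grid_n^2)) / grid_n
  gy <- (rep(seq_len(grid_n), times = grid_n) - runif(grid_n^2)) / grid_n
  pts <- cbind(xr[1L] + gx * diff(xr), yr[1L] + gy * diff(yr))
  k <- assign_ring(pts, rings)
  bbox_um2 <- diff(xr) * diff(yr) / 1e6
  tabulate(k[!is.na(k)], nbins = rings$n_rings) / length(gx) * bbox_um2
}

# scalar bilinear interpolation oracle (pixel centres at integer coords)
bilinear_oracle <- function(px, u, v) {
  x0 <- min(max(floor(u), 1L), nrow(px) - 1L)
  y0 <- min(max(floor(v), 1L), ncol(px) - 1L)
  fx <- u - x0; fy <- v - y0
  (1 - fx) * (1 - fy) * px[x0, y0] + fx * (1 - fy) * px[x0 + 1L, y0] +
    (1 - fx) * fy * px[x0, y0 + 1L] + fx * fy * px[x0 + 1L, y0 + 1L]
}

# planted Gaussian blobs on a disk nucleus (for maxima/domain tests)
blob_nucleus <- function(side = 120L, R = 50, centres, amp = 150, sigma = 2,
                         baseline = 60, noise = 0.5, seed = 1L) {
  set.seed(seed)
  gx <- matrix(seq_len(side), side, side)
  gy <- matrix(seq_len(side), side, side, byrow = TRUE)
  c0 <- (side + 1) / 2
  px <- matrix(5, side, side)
  nucleus <- (gx - c0)^2 + (gy - c0)^2 <= R^2
  px[nucleus] <- baseline
  for (k in seq_len(nrow(centres))) {
    px <- px + amp * exp(-((gx - centres[k, 1L])^2 + (gy - centres[k, 2L])^2) /
                           (2 * sigma^2)) * nucleus
  }
  px <- px + matrix(rnorm(side^2, 0, noise), side, side)
  nucleus_image(pmax(px, 0), 0.1)
}
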