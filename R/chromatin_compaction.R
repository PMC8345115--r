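#' Confocal chromatin-compaction analysis
#'
#' A confocal image of a stained nucleus is segmented into compact
#' chromatin domains (regions around local intensity maxima) and dark
#' area (low chromatin density). The number of detected maxima is the
#' number of chromatin domains; the dark area is the nuclear area minus
#' the total domain area, and the compaction percentage is the domain
#' area as a percentage of the nuclear area. All thresholds are relative
#' to the in-mask intensity distribution, so the analysis is exactly
#' invariant to multiplying the image by a positive constant.
#'
#' @name chromatin_compaction
NULL

#' Construct a nucleus image
#'
#' @param pixels numeric matrix `[x, y]` of non-negative intensities, at
#'   least 16 x 16 pixels.
#' @param pixel_size_um pixel pitch in micrometres.
#' @return A `nucleus_image`.
#' @export
nucleus_image <- function(pixels, pixel_size_um) {
  px <- as.matrix(pixels)
  if (!is.numeric(px) || any(dim(px) < 16L))
    stop("nucleus image must be a numeric matrix of at least 16 x 16 pixels")
  if (!all(is.finite(px)) || any(px < 0))
    stop("nucleus image intensities must be finite and non-negative")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L || pixel_size_um <= 0)
    stop("pixel_size_um must be a positive number")
  structure(list(pixels = px, pixel_size_um = pixel_size_um),
            class = "nucleus_image")
}

#' Read a nucleus image from TIFF
#'
#' @param path single-channel TIFF path.
#' @param pixel_size_um pixel pitch in micrometres.
#' @return A [nucleus_image()].
#' @export
read_nucleus_image <- function(path, pixel_size_um) {
  nucleus_image(read_image_matrix(path), pixel_size_um)
}

#' Segment the nucleus from the background
#'
#' Gaussian pre-smoothing, global Otsu threshold, largest connected
#' component, holes filled. The nuclear area is the pixel count times the
#' pixel area. One nucleus per image crop is assumed (the largest
#' component); batch analysis iterates over crops. Because a stained
#' nucleus can itself show two chromatin intensity classes over the dark
#' background, the threshold is class-structure aware: when a
#' well-populated middle intensity class is present, the lower threshold
#' of a three-class Otsu split separates nucleus from background;
#' otherwise the standard two-class Otsu threshold is used.
#'
#' @param img a [nucleus_image()].
#' @param smoothing_sigma_px Gaussian smoothing sigma in pixels (default 1).
#' @return A `nucleus_segmentation`: list with `mask` (logical `[x, y]`),
#'   `nucleus_area_um2`, `smoothed` and `smoothing_sigma_px`.
#' @export
segment_nucleus <- function(img, smoothing_sigma_px = 1.0) {
  stopifnot(inherits(img, "nucleus_image"))
  sm <- .smooth_px(img$pixels, smoothing_sigma_px)
  if (diff(range(sm)) == 0)
    stop("segmentation error: image has no contrast, no foreground found")
  th <- .nucleus_threshold(as.vector(sm))
  fg <- sm > th
  if (!any(fg))
    stop("segmentation error: thresholding yields no foreground")
  mask <- .largest_component(fg)
  mask <- as.matrix(EBImage::fillHull(mask * 1L)) > 0L
  structure(list(mask = mask,
                 nucleus_area_um2 = sum(mask) * img$pixel_size_um^2,
                 smoothed = sm,
                 smoothing_sigma_px = smoothing_sigma_px),
            class = "nucleus_segmentation")
}

#' Detect chromatin domains as local intensity maxima
#'
#' Local maxima of the smoothed image inside the nuclear mask, mutually
#' separated by at least `min_separation_px` and rising at least
#' `prominence_fraction` of the in-mask intensity range above the in-mask
#' background level (the median of the dim intensity class). A perfectly
#' flat nucleus yields zero maxima. Plateaus contribute one maximum each.
#'
#' @param img a [nucleus_image()].
#' @param mask logical nucleus mask from [segment_nucleus()] (a
#'   `nucleus_segmentation` is also accepted).
#' @param min_separation_px minimum pairwise distance between maxima in
#'   pixels (default 3).
#' @param prominence_fraction minimum rise above background as a fraction
#'   of the in-mask intensity range (default 0.10).
#' @param smoothing_sigma_px smoothing applied before peak finding
#'   (default 1, matching [segment_nucleus()]).
#' @return data.frame with columns `x`, `y` (pixel indices) and `value`
#'   (smoothed peak intensity); `nrow` is the number of chromatin domains.
#' @export
detect_chromatin_domains <- function(img, mask, min_separation_px = 3L,
                                     prominence_fraction = 0.10,
                                     smoothing_sigma_px = 1.0) {
  stopifnot(inherits(img, "nucleus_image"))
  if (inherits(mask, "nucleus_segmentation")) mask <- mask$mask
  sm <- .smooth_px(img$pixels, smoothing_sigma_px)
  v <- sm[mask]
  none <- data.frame(x = integer(), y = integer(), value = numeric())
  rng <- diff(range(v))
  if (rng == 0) return(none)
  b <- .mask_background(v)
  win <- 2L * as.integer(min_separation_px) + 1L
  mx <- as.matrix(EBImage::dilate(EBImage::Image(sm), EBImage::makeBrush(win, "box")))
  cand <- mask & (sm >= mx - 1e-12) &
    (sm - b >= prominence_fraction * rng) & (sm > b)
  if (!any(cand)) return(none)
  # one representative pixel per connected plateau
  lab <- as.matrix(EBImage::bwlabel(cand))
  ids <- sort(unique(lab[lab > 0L]))
  pk <- t(vapply(ids, function(id) {
    w <- which(lab == id, arr.ind = TRUE)
    ctr <- colMeans(w)
    w[which.min((w[, 1L] - ctr[1L])^2 + (w[, 2L] - ctr[2L])^2), ]
  }, numeric(2L)))
  vals <- sm[pk]
  ord <- order(vals, decreasing = TRUE)
  keep <- integer(0)
  for (ix in ord) {
    if (length(keep) == 0L ||
        all((pk[keep, 1L] - pk[ix, 1L])^2 + (pk[keep, 2L] - pk[ix, 2L])^2 >=
              min_separation_px^2))
      keep <- c(keep, ix)
  }
  keep <- keep[order(keep)]
  data.frame(x = as.integer(pk[keep, 1L]), y = as.integer(pk[keep, 2L]),
             value = vals[keep])
}

#' Grow domains around detected maxima
#'
#' The nuclear mask is partitioned among the maxima by seeded region
#' growing on the smoothed image (a marker-based watershed analogue), and
#' each region is clipped to the pixels whose intensity reaches at least
#' `b + level_fraction * (peak - b)`, where `b` is the in-mask background
#' level. For an isolated peak with `level_fraction = 0.5` this reduces to
#' the half-rise (half-max above background) contour.
#'
#' @param img a [nucleus_image()].
#' @param mask logical nucleus mask (or a `nucleus_segmentation`).
#' @param maxima data.frame from [detect_chromatin_domains()].
#' @param level_fraction relative rise level in `(0, 1)` (default 0.5).
#' @param smoothing_sigma_px smoothing (default 1).
#' @return Integer label matrix `[x, y]`; 0 = non-domain, k = domain of the
#'   k-th maximum.
#' @export
grow_domains <- function(img, mask, maxima, level_fraction = 0.5,
                         smoothing_sigma_px = 1.0) {
  stopifnot(inherits(img, "nucleus_image"))
  if (inherits(mask, "nucleus_segmentation")) mask <- mask$mask
  lab0 <- matrix(0L, nrow(img$pixels), ncol(img$pixels))
  if (nrow(maxima) == 0L) return(lab0)
  sm <- .smooth_px(img$pixels, smoothing_sigma_px)
  b <- .mask_background(sm[mask])
  seeds <- lab0
  seeds[cbind(maxima$x, maxima$y)] <- seq_len(nrow(maxima))
  regions <- as.matrix(EBImage::propagate(EBImage::Image(sm),
                                          seeds = EBImage::Image(seeds),
                                          mask = EBImage::Image(mask * 1L)))
  regions <- matrix(as.integer(round(regions)), nrow(regions), ncol(regions))
  thr <- b + level_fraction * (maxima$value - b)
  out <- lab0
  sel <- regions > 0L
  sel[sel] <- sm[sel] >= thr[regions[sel]]
  out[sel] <- regions[sel]
  out
}

#' Full chromatin-compaction analysis of one nucleus image
#'
#' Chains [segment_nucleus()], [detect_chromatin_domains()],
#' [grow_domains()] and the compaction summary.
#'
#' @param img a [nucleus_image()].
#' @inheritParams detect_chromatin_domains
#' @inheritParams grow_domains
#' @return A `chromatin_segmentation`: list with `nucleus_mask`,
#'   `nucleus_area_um2`, `n_domains`, `maxima`, `domain_label_map`,
#'   `domain_total_area_um2`, `compact_percent`, `dark_area_um2` and
#'   `pixel_size_um`.
#' @export
analyze_chromatin_compaction <- function(img, smoothing_sigma_px = 1.0,
                                         min_separation_px = 3L,
                                         prominence_fraction = 0.10,
                                         level_fraction = 0.5) {
  seg <- segment_nucleus(img, smoothing_sigma_px)
  maxima <- detect_chromatin_domains(img, seg$mask, min_separation_px,
                                     prominence_fraction, smoothing_sigma_px)
  labels <- grow_domains(img, seg$mask, maxima, level_fraction,
                         smoothing_sigma_px)
  domain_area <- sum(labels > 0L) * img$pixel_size_um^2
  res <- structure(list(nucleus_mask = seg$mask,
                        nucleus_area_um2 = seg$nucleus_area_um2,
                        n_domains = nrow(maxima),
                        maxima = maxima,
                        domain_label_map = labels,
                        domain_total_area_um2 = domain_area,
                        pixel_size_um = img$pixel_size_um),
                   class = "chromatin_segmentation")
  res[c("compact_percent", "dark_area_um2")] <- compaction_summary(res)
  res
}

#' Compaction percentage and dark area of a segmentation
#'
#' The dark (low chromatin density) area is the nuclear area minus the
#' total area of all recognised domains; the compaction percentage is
#' `100 * domain_total / nucleus_area`.
#'
#' @param seg a `chromatin_segmentation` (at minimum a list with
#'   `nucleus_area_um2` and `domain_total_area_um2`, with the domain pixels
#'   inside the nucleus mask).
#' @return List with `compact_percent` and `dark_area_um2`.
#' @export
compaction_summary <- function(seg) {
  if (!is.null(seg$domain_label_map) && !is.null(seg$nucleus_mask) &&
      any(seg$domain_label_map > 0L & !seg$nucleus_mask))
    stop("internal consistency error: domain pixels outside the nucleus mask")
  if (seg$domain_total_area_um2 > seg$nucleus_area_um2 + 1e-9)
    stop("internal consistency error: domain area exceeds nuclear area")
  list(compact_percent = 100 * seg$domain_total_area_um2 / seg$nucleus_area_um2,
       dark_area_um2 = seg$nucleus_area_um2 - seg$domain_total_area_um2)
}

#' Mode +/- SD summary of a sample
#'
#' Reported central values follow the mode of the sample distribution: a
#' histogram with Freedman-Diaconis bin width is built and the mode is the
#' centre of the tallest bin (ties broken towards the lowest-valued bin).
#' The spread is the sample standard deviation (n - 1 denominator). A
#' count of prominent histogram peaks is included to flag multimodal
#' distributions, for which a single central value is not meaningful.
#'
#' @param values numeric vector, length >= 1.
#' @param bin_width optional histogram bin width override.
#' @return A `mode_summary`: list with `mode`, `sd`, `n`,
#'   `histogram_bin_width` and `n_peaks`.
#' @export
mode_sd_summary <- function(values, bin_width = NULL) {
  values <- as.numeric(values)
  if (length(values) == 0L || any(!is.finite(values)))
    stop("parameter error: values must be a non-empty finite numeric vector")
  n <- length(values)
  s <- stats::sd(values)
  if (n == 1L) s <- 0
  if (is.null(bin_width)) {
    iqr <- stats::IQR(values)
    bin_width <- if (iqr > 0) {
      2 * iqr * n^(-1 / 3)                       # Freedman-Diaconis
    } else if (isTRUE(s > 0)) {
      3.49 * s * n^(-1 / 3)                      # Scott fallback for IQR = 0
    } else 0
  }
  if (bin_width <= 0 || diff(range(values)) == 0) {
    # degenerate sample: all values equal (or forced single bin)
    return(structure(list(mode = values[1L], sd = if (is.na(s)) 0 else s,
                          n = n, histogram_bin_width = bin_width,
                          n_peaks = 1L),
                     class = "mode_summary"))
  }
  lo <- floor(min(values) / bin_width) * bin_width
  breaks <- seq(lo, max(values) + bin_width, by = bin_width)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  mode <- h$mids[which.max(h$counts)]   # which.max takes the first (lowest) tie
  structure(list(mode = mode, sd = if (is.na(s)) 0 else s, n = n,
                 histogram_bin_width = bin_width,
                 n_peaks = .count_peaks(h$counts)),
            class = "mode_summary")
}

# prominent peaks of a 1D histogram: local maxima whose rise above the
# deepest separating valley towards any taller peak is >= 25% of the
# tallest bin (small sampling wiggles within one mode do not count)
.count_peaks <- function(counts, min_prominence_frac = 0.25) {
  r <- rle(counts)
  vals <- r$values
  m <- length(vals)
  if (m == 1L) return(if (vals[1L] > 0) 1L else 0L)
  is_peak <- vapply(seq_len(m), function(i) {
    left <- if (i > 1L) vals[i - 1L] else -Inf
    right <- if (i < m) vals[i + 1L] else -Inf
    vals[i] > left && vals[i] > right
  }, logical(1L))
  peaks <- which(is_peak)
  tallest <- max(counts)
  n_prom <- 0L
  for (p in peaks) {
    higher <- peaks[vals[peaks] > vals[p]]
    if (length(higher) == 0L) { n_prom <- n_prom + 1L; next }
    valley <- Inf
    for (q in higher) {
      rng <- if (q < p) q:p else p:q
      valley <- min(valley, max(min(vals[rng]), 0))
    }
    if (vals[p] - valley >= min_prominence_frac * tallest)
      n_prom <- n_prom + 1L
  }
  n_prom
}

#' Write a domain label map as TIFF
#'
#' @param seg a `chromatin_segmentation`.
#' @param path output TIFF path (16-bit; pixel value = domain label).
#' @return `path`, invisibly.
#' @export
write_label_map <- function(seg, path) {
  stopifnot(inherits(seg, "chromatin_segmentation"))
  write_image_matrix(seg$domain_label_map, path)
}

#' @export
print.chromatin_segmentation <- function(x, ...) {
  cat(sprintf(
    "Chromatin segmentation: nucleus %.2f um^2, %d domains, %.1f%% compact, dark area %.2f um^2\n",
    x$nucleus_area_um2, x$n_domains, x$compact_percent, x$dark_area_um2))
  invisible(x)
}

#' @export
print.mode_summary <- function(x, ...) {
  cat(sprintf("mode %.4g +/- %.4g SD (n = %d%s)\n", x$mode, x$sd, x$n,
              if (x$n_peaks > 1L) sprintf(", %d peaks: possibly multimodal", x$n_peaks) else ""))
  invisible(x)
}
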