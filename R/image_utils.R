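# Internal image helpers shared by the confocal modules.
#
# Pixel convention throughout: matrices indexed [x, y] (first dimension =
# x, rightward; second = y, downward; origin at the top-left corner), the
# native orientation of EBImage. TIFF readers/writers transpose
# accordingly.

.smooth_px <- function(px, sigma) {
  if (sigma <= 0) return(px)
  as.matrix(EBImage::gblur(px, sigma = sigma))
}

# Otsu threshold of a numeric vector, computed on min-max normalised
# values so the split is exactly invariant to affine intensity rescaling.
# Returns a threshold on the original scale; foreground is `> threshold`.
.otsu_thresh <- function(v, levels = 256L) {
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1L])
  u <- (v - rng[1L]) / diff(rng)
  h <- tabulate(pmin(floor(u * levels) + 1L, levels), nbins = levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(levels) - 0.5) / levels)
  mu_t <- mu[levels]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- 0
  k <- which.max(sb2)
  rng[1L] + (k / levels) * diff(rng)
}

# three-class Otsu split (two thresholds maximising between-class
# variance on a 256-bin normalised histogram); returns thresholds and the
# class weights/means on the original scale
.otsu_multi3 <- function(v, levels = 256L) {
  rng <- range(v)
  if (diff(rng) == 0) return(NULL)
  u <- (v - rng[1L]) / diff(rng)
  h <- tabulate(pmin(floor(u * levels) + 1L, levels), nbins = levels)
  p <- h / sum(h)
  idx <- seq_len(levels)
  W <- cumsum(p)
  M <- cumsum(p * idx)
  mt <- M[levels]
  best <- -Inf
  bt <- c(NA_integer_, NA_integer_)
  for (t1 in 1:(levels - 2L)) {
    w1 <- W[t1]
    if (w1 == 0) next
    m1 <- M[t1] / w1
    t2 <- (t1 + 1L):(levels - 1L)
    w2 <- W[t2] - W[t1]
    w3 <- 1 - W[t2]
    ok <- w2 > 0 & w3 > 0
    if (!any(ok)) next
    m2 <- (M[t2] - M[t1]) / w2
    m3 <- (mt - M[t2]) / w3
    v2 <- w1 * (m1 - mt)^2 + w2 * (m2 - mt)^2 + w3 * (m3 - mt)^2
    v2[!ok] <- -Inf
    j <- which.max(v2)
    if (v2[j] > best) {
      best <- v2[j]
      bt <- c(t1, t2[j])
    }
  }
  if (anyNA(bt)) return(list(thresholds = bt, weights = rep(NA_real_, 3L),
                             means = rep(NA_real_, 3L)))
  w1 <- W[bt[1L]]; w2 <- W[bt[2L]] - W[bt[1L]]; w3 <- 1 - W[bt[2L]]
  means_norm <- c(M[bt[1L]] / w1,
                  (M[bt[2L]] - M[bt[1L]]) / w2,
                  (mt - M[bt[2L]]) / w3) / levels
  list(thresholds = rng[1L] + bt / levels * diff(rng),
       weights = c(w1, w2, w3),
       means = rng[1L] + means_norm * diff(rng))
}

# nucleus-versus-background threshold. A stained nucleus over a dark
# background can present three intensity classes (background, loose
# chromatin, compact domains); a plain two-class Otsu then cuts between
# the chromatin classes and truncates the nucleus. When a well-populated
# middle class exists (weight >= 5%, separated from both neighbours by
# >= 15% of the range) the lower threshold of a three-class Otsu split is
# used; otherwise the standard two-class threshold.
.nucleus_threshold <- function(v, min_mid_weight = 0.05, min_gap_frac = 0.15) {
  t2c <- .otsu_thresh(v)
  m3 <- .otsu_multi3(v)
  if (is.null(m3) || anyNA(m3$thresholds)) return(t2c)
  rng <- diff(range(v))
  if (m3$weights[2L] >= min_mid_weight &&
      (m3$means[2L] - m3$means[1L]) >= min_gap_frac * rng &&
      (m3$means[3L] - m3$means[2L]) >= min_gap_frac * rng)
    m3$thresholds[1L]
  else t2c
}

# background (dim-class) level of the in-mask intensities: median of the
# values at or below the in-mask Otsu split; reduces to the plain median
# when the mask holds a single intensity class
.mask_background <- function(v) {
  if (diff(range(v)) == 0) return(v[1L])
  th <- .otsu_thresh(v)
  lo <- v[v <= th]
  if (length(lo) == 0L) return(stats::median(v))
  stats::median(lo)
}

.largest_component <- function(binary) {
  lab <- EBImage::bwlabel(binary)
  lab <- as.matrix(lab)
  if (max(lab) == 0L) return(NULL)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

#' Read a single-channel image as a pixel matrix
#'
#' Reads an 8- or 16-bit single-channel TIFF into a matrix in the package's
#' `[x, y]` pixel convention, keeping native integer intensity values.
#'
#' @param path TIFF file path.
#' @return Numeric matrix `[nx, ny]`.
#' @export
read_image_matrix <- function(path) {
  px <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(px)) == 3L) {
    if (dim(px)[3L] != 1L)
      stop("input error: expected a single-channel image: ", path)
    px <- px[, , 1L]
  }
  t(px)  # readTIFF is [row = y, col = x]
}

#' Write a pixel matrix as a 16-bit TIFF
#'
#' @param px numeric matrix in the `[x, y]` convention, values >= 0.
#' @param path output path.
#' @param max_value full-scale value (defaults to 65535; intensities are
#'   divided by this before writing).
#' @return `path`, invisibly.
#' @export
write_image_matrix <- function(px, path, max_value = 65535) {
  m <- t(px) / max_value
  m[m < 0] <- 0; m[m > 1] <- 1
  tiff::writeTIFF(m, path, bits.per.sample = 16L)
  invisible(path)
}
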