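#' Occupancy binning of localisations on a nanometre grid
#'
#' Localisation signals are binned on a square grid (default 50 x 50 nm^2)
#' and the per-bin count distribution is summarised box-plot style. Only
#' occupied bins (count >= 1) enter the distribution: the count axis is
#' displayed on a log scale, which cannot represent zero, and statements
#' like "the majority of bins hold a single event" are only meaningful over
#' occupied bins.
#'
#' @name density_binning
NULL

#' Bin localisations on a square grid
#'
#' Point p is assigned to bin
#' `(floor((p.x - origin.x)/b), floor((p.y - origin.y)/b))` with half-open
#' bins `[k*b, (k+1)*b)`: a point exactly on a bin edge belongs to the
#' higher-index bin. Empty bins are not stored.
#'
#' @param table a [loc_table()].
#' @param bin_size_nm bin edge length in nm (default 50).
#' @param origin_nm length-2 numeric, grid origin in nm (default `c(0, 0)`;
#'   fixed rather than anchored to the data so results are reproducible).
#' @return A `bin_grid`: list with `bin_size_nm`, `origin_nm`,
#'   `bins` (data.frame `i`, `j`, `count`) and `total_count`.
#' @export
bin_localisations <- function(table, bin_size_nm = 50, origin_nm = c(0, 0)) {
  stopifnot(inherits(table, "loc_table"))
  if (!is.numeric(bin_size_nm) || length(bin_size_nm) != 1L || bin_size_nm <= 0)
    stop("parameter error: bin_size_nm must be a positive number")
  n <- nrow(table)
  if (n == 0L) {
    bins <- data.frame(i = integer(), j = integer(), count = integer())
    return(structure(list(bin_size_nm = bin_size_nm, origin_nm = origin_nm,
                          bins = bins, total_count = 0L),
                     class = "bin_grid"))
  }
  i <- floor((table$x_nm - origin_nm[1L]) / bin_size_nm)
  j <- floor((table$y_nm - origin_nm[2L]) / bin_size_nm)
  i0 <- min(i); j0 <- min(j)
  nj <- max(j) - j0 + 1
  key <- as.integer((i - i0) * nj + (j - j0) + 1)
  counts <- tabulate(key, nbins = max(key))
  occ <- which(counts > 0L)
  bins <- data.frame(i = as.integer(i0 + (occ - 1L) %/% nj),
                     j = as.integer(j0 + (occ - 1L) %% nj),
                     count = counts[occ])
  structure(list(bin_size_nm = bin_size_nm, origin_nm = origin_nm,
                 bins = bins, total_count = n),
            class = "bin_grid")
}

#' Box-plot summary of the per-bin count distribution
#'
#' Median and quartiles use linear-interpolation quantiles (the common
#' box-plot convention); whiskers sit at the most extreme counts within
#' `q1 - 1.5*IQR` and `q3 + 1.5*IQR`, and counts beyond the whiskers are
#' listed as outliers.
#'
#' @param grid a `bin_grid` from [bin_localisations()], or a bare numeric
#'   vector of occupied-bin counts.
#' @return A `bin_count_dist`: list with `counts`, `n_bins`, `median`,
#'   `q1`, `q3`, `whisker_low`, `whisker_high`, `outliers`.
#' @export
bin_count_distribution <- function(grid) {
  counts <- if (inherits(grid, "bin_grid")) grid$bins$count else as.numeric(grid)
  if (length(counts) == 0L)
    stop("empty-input error: no occupied bins")
  .summarise_counts(counts)
}

.summarise_counts <- function(counts) {
  qs <- stats::quantile(counts, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- qs[3L] - qs[1L]
  lo_fence <- qs[1L] - 1.5 * iqr
  hi_fence <- qs[3L] + 1.5 * iqr
  inside <- counts[counts >= lo_fence & counts <= hi_fence]
  structure(list(counts = counts,
                 n_bins = length(counts),
                 median = qs[2L], q1 = qs[1L], q3 = qs[3L],
                 whisker_low = min(inside),
                 whisker_high = max(inside),
                 outliers = counts[counts < lo_fence | counts > hi_fence]),
            class = "bin_count_dist")
}

#' Pool occupied-bin counts across replicate grids
#'
#' The per-cell-type distributions are combinations of replicate nuclei:
#' the occupied-bin counts of all grids are pooled into one multiset and
#' summarised as in [bin_count_distribution()].
#'
#' @param grids list of `bin_grid` objects (length >= 1).
#' @return A `bin_count_dist` over the pooled counts.
#' @export
merge_distributions <- function(grids) {
  if (!is.list(grids) || length(grids) == 0L || inherits(grids, "bin_grid"))
    stop("parameter error: supply a non-empty list of bin_grid objects")
  counts <- unlist(lapply(grids, function(g) {
    stopifnot(inherits(g, "bin_grid"))
    g$bins$count
  }))
  if (length(counts) == 0L)
    stop("empty-input error: no occupied bins in any grid")
  .summarise_counts(counts)
}

#' Write the per-bin table as CSV
#'
#' @param grid a `bin_grid`.
#' @param path output path; columns `i`, `j`, `count`.
#' @return `path`, invisibly.
#' @export
write_bin_table <- function(grid, path) {
  stopifnot(inherits(grid, "bin_grid"))
  utils::write.csv(grid$bins, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.bin_grid <- function(x, ...) {
  cat("Bin grid:", x$bin_size_nm, "nm bins,", nrow(x$bins),
      "occupied bins,", x$total_count, "localisations\n")
  invisible(x)
}

#' @export
print.bin_count_dist <- function(x, ...) {
  cat(sprintf(
    "Occupied-bin count distribution: n = %d bins, median %.4g [q1 %.4g, q3 %.4g], %d outlier(s)\n",
    x$n_bins, x$median, x$q1, x$q3, length(x$outliers)))
  invisible(x)
}
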