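#' Bin radiocarbon dates within sites
#'
#' Groups dates into site-phase bins so oversampled sites or phases do not
#' dominate the summed probability distribution. Within each site the
#' uncalibrated 14C ages are clustered by complete-linkage hierarchical
#' clustering and the tree is cut at `cut_height` (default 50 14C years);
#' dates from different sites are never merged.
#'
#' @param dates A `c14_dates` table.
#' @param cut_height Cut height in 14C years (default 50).
#' @return A `date_bins` object: the input table with an added `bin`
#'   column (`"<site>_<k>"`), plus attribute `n_bins`.
#' @export
bin_dates <- function(dates, cut_height = 50) {
  if (nrow(dates) == 0) stop("no dates to bin")
  bin <- character(nrow(dates))
  for (site in unique(dates$site_id)) {
    idx <- which(dates$site_id == site)
    if (length(idx) == 1) {
      cl <- 1L
    } else {
      hc <- stats::hclust(stats::dist(dates$age[idx]), method = "complete")
      cl <- stats::cutree(hc, h = cut_height)
    }
    bin[idx] <- paste(site, cl, sep = "_")
  }
  out <- dates
  out$bin <- bin
  structure(out, class = c("date_bins", "data.frame"),
            n_bins = length(unique(bin)), cut_height = cut_height)
}

#' Build a summed probability distribution
#'
#' Averages calibrated densities within each bin (arithmetic mean of
#' member densities, year by year), sums the bin densities on an annual
#' calendar grid over `window`, and applies a centered rolling mean of
#' width `rolling_window` years (symmetric windows that shrink at the
#' series edges).
#'
#' @param densities List of `cal_density` objects, one per date, in the
#'   same order as the rows of `bins` (as returned by [calibrate_dates()]).
#' @param bins A `date_bins` object from [bin_dates()]; `NULL` treats
#'   every date as its own bin.
#' @param window Calendar window in years AD, default `c(100, 1450)`.
#' @param rolling_window Rolling-mean width in years (default 100;
#'   `0` or `1` disables smoothing).
#' @return An `spd_series`: data frame with columns `year_ad`, `spd`;
#'   attributes `normalized` and `n_bins`.
#' @export
build_spd <- function(densities, bins = NULL, window = c(100, 1450),
                      rolling_window = 100) {
  if (length(densities) == 0) stop("no calibrated densities supplied")
  if (is.null(bins)) {
    bin_of <- as.character(seq_along(densities))
  } else {
    if (nrow(bins) != length(densities))
      stop("bins and densities refer to different numbers of dates")
    bin_of <- bins$bin
  }
  grid <- seq(window[1], window[2])
  spd <- numeric(length(grid))
  for (b in unique(bin_of)) {
    members <- which(bin_of == b)
    acc <- numeric(length(grid))
    for (i in members) {
      d <- densities[[i]]
      j <- d$year_ad - window[1] + 1L
      ok <- j >= 1L & j <= length(grid)
      acc[j[ok]] <- acc[j[ok]] + d$density[ok]
    }
    spd <- spd + acc / length(members)
  }
  if (rolling_window > 1) spd <- rolling_mean(spd, rolling_window)
  normalized <- if (length(densities))
    isTRUE(attr(densities[[1]], "normalized")) else NA
  structure(data.frame(year_ad = grid, spd = spd),
            class = c("spd_series", "data.frame"),
            normalized = normalized, n_bins = length(unique(bin_of)),
            rolling_window = rolling_window)
}

#' Centered rolling mean with shrinking edge windows
#'
#' Window of `width` points centered on each index (for even widths the
#' extra point falls on the trailing side), clipped at the series edges so
#' edge values average over the available points.
#'
#' @param x Numeric vector.
#' @param width Window width in points.
#' @return Numeric vector of the same length.
#' @export
rolling_mean <- function(x, width) {
  n <- length(x)
  if (width <= 1 || n == 0) return(x)
  h1 <- floor((width - 1) / 2)
  h2 <- width - 1 - h1
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h1, 1L)
  hi <- pmin(i + h2, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' @export
print.spd_series <- function(x, ...) {
  cat("SPD series: AD ", min(x$year_ad), "-", max(x$year_ad),
      ", ", attr(x, "n_bins"), " bins, ",
      if (isTRUE(attr(x, "normalized"))) "normalized" else "unnormalized",
      " calibration\n", sep = "")
  invisible(x)
}

#' @export
plot.spd_series <- function(x, ...) {
  graphics::plot(x$year_ad, x$spd, type = "l", xlab = "year AD",
                 ylab = "summed probability", ...)
  invisible(x)
}

#' Write an SPD series to CSV (`year_ad,spd`)
#' @param spd An `spd_series`.
#' @param path Output path.
#' @export
write_spd <- function(spd, path) {
  utils::write.csv(data.frame(year_ad = spd$year_ad, spd = spd$spd),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an SPD series from CSV (`year_ad,spd`)
#' @param path CSV path.
#' @param normalized Normalization flag to record on the object.
#' @export
read_spd <- function(path, normalized = NA) {
  d <- utils::read.csv(path)
  structure(data.frame(year_ad = d$year_ad, spd = d$spd),
            class = c("spd_series", "data.frame"),
            normalized = normalized, n_bins = NA_integer_)
}
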