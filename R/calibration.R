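#' Load an atmospheric radiocarbon calibration curve
#'
#' Reads a calibration curve in the standard `.14c` layout: comment lines
#' starting with `#`, then comma- or whitespace-separated columns
#' `cal BP, 14C age BP, error` (further columns, if present, are ignored).
#'
#' @param path Path to the curve file.
#' @return An object of class `cal_curve`: a data frame with columns
#'   `cal_bp`, `mu` (conventional radiocarbon age BP) and `sigma_curve`
#'   (1-sigma curve error, radiocarbon years), sorted by `cal_bp`.
#' @examples
#' f <- tempfile(fileext = ".14c")
#' writeLines(c("# toy curve", "0,5,1", "10,15,1", "20,25,1"), f)
#' crv <- load_calibration_curve(f)
#' curve_at(crv, 5) # mu = 10, sigma = 1
#' @export
load_calibration_curve <- function(path) {
  if (!file.exists(path)) stop("calibration curve file not found: ", path)
  raw <- readLines(path)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lineno <- which(keep)
  rows <- lapply(seq_along(lineno), function(i) {
    ln <- raw[lineno[i]]
    parts <- strsplit(trimws(ln), "[,[:space:]]+")[[1]]
    if (length(parts) < 3)
      stop("calibration curve parse error at line ", lineno[i],
           ": expected at least 3 columns")
    vals <- suppressWarnings(as.numeric(parts[1:3]))
    if (anyNA(vals))
      stop("calibration curve parse error at line ", lineno[i],
           ": non-numeric value in '", ln, "'")
    vals
  })
  m <- do.call(rbind, rows)
  curve <- data.frame(cal_bp = m[, 1], mu = m[, 2], sigma_curve = m[, 3])
  curve <- curve[order(curve$cal_bp), , drop = FALSE]
  rownames(curve) <- NULL
  validate_cal_curve(curve)
  class(curve) <- c("cal_curve", "data.frame")
  curve
}

#' Construct a calibration curve from vectors
#'
#' @param cal_bp Calendar years BP (strictly monotone after sorting;
#'   duplicates are an error).
#' @param mu Conventional radiocarbon age BP at each knot.
#' @param sigma_curve 1-sigma curve error (radiocarbon years), recycled.
#' @return A `cal_curve` object.
#' @export
calibration_curve <- function(cal_bp, mu, sigma_curve = 0) {
  curve <- data.frame(cal_bp = as.numeric(cal_bp), mu = as.numeric(mu),
                      sigma_curve = as.numeric(rep_len(sigma_curve, length(cal_bp))))
  curve <- curve[order(curve$cal_bp), , drop = FALSE]
  rownames(curve) <- NULL
  validate_cal_curve(curve)
  class(curve) <- c("cal_curve", "data.frame")
  curve
}

validate_cal_curve <- function(curve) {
  if (nrow(curve) < 2) stop("calibration curve needs at least 2 knots")
  if (any(diff(curve$cal_bp) <= 0))
    stop("calibration curve cal_bp values must be strictly monotone")
  if (any(curve$sigma_curve < 0))
    stop("calibration curve errors must be non-negative")
  invisible(curve)
}

#' Interpolate a calibration curve
#'
#' Linear interpolation of the curve mean and error at arbitrary calendar
#' years BP within the knot range.
#'
#' @param curve A `cal_curve`.
#' @param cal_bp Calendar years BP at which to evaluate.
#' @return A data frame with columns `cal_bp`, `mu`, `sigma_curve`.
#' @export
curve_at <- function(curve, cal_bp) {
  rng <- range(curve$cal_bp)
  if (any(cal_bp < rng[1] | cal_bp > rng[2]))
    stop("requested calendar years outside calibration curve coverage [",
         rng[1], ", ", rng[2], "] cal BP")
  data.frame(
    cal_bp = cal_bp,
    mu = stats::approx(curve$cal_bp, curve$mu, xout = cal_bp)$y,
    sigma_curve = stats::approx(curve$cal_bp, curve$sigma_curve, xout = cal_bp)$y
  )
}

#' @export
print.cal_curve <- function(x, ...) {
  cat("Calibration curve: ", nrow(x), " knots, ",
      min(x$cal_bp), "-", max(x$cal_bp), " cal BP\n", sep = "")
  invisible(x)
}

#' Radiocarbon date table
#'
#' Validates a table of radiocarbon determinations. Column conventions
#' follow the P3K14C layout: `LabID`, `Age` (conventional 14C age BP),
#' `Error` (1-sigma, 14C years), `SiteID`, and optionally `Material`.
#'
#' @param lab_id,age,error,site_id,material Vectors of equal length
#'   (material optional).
#' @return A data frame of class `c14_dates`.
#' @export
c14_dates <- function(lab_id, age, error, site_id, material = NA_character_) {
  d <- data.frame(lab_id = as.character(lab_id), age = as.numeric(age),
                  error = as.numeric(error), site_id = as.character(site_id),
                  material = as.character(rep_len(material, length(lab_id))),
                  stringsAsFactors = FALSE)
  if (any(!is.finite(d$age)) || any(d$age <= 0))
    stop("radiocarbon ages must be positive and finite")
  if (any(!is.finite(d$error)) || any(d$error <= 0))
    stop("radiocarbon errors must be positive and finite")
  if (any(is.na(d$site_id) | !nzchar(d$site_id)))
    stop("every date needs a non-empty site_id")
  class(d) <- c("c14_dates", "data.frame")
  d
}

#' Read a radiocarbon date table from CSV
#'
#' Expects a header with columns `LabID,Age,Error,SiteID[,Material,...]`
#' (case-insensitive; extra columns ignored).
#'
#' @param path CSV path.
#' @return A `c14_dates` data frame.
#' @export
read_c14_dates <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- tolower(names(raw))
  pick <- function(col) {
    i <- match(col, nm)
    if (is.na(i)) stop("date table is missing required column '", col, "'")
    raw[[i]]
  }
  mat <- if ("material" %in% nm) raw[[match("material", nm)]] else NA_character_
  c14_dates(pick("labid"), pick("age"), pick("error"), pick("siteid"), mat)
}

#' Write a radiocarbon date table to CSV
#' @param dates A `c14_dates` table.
#' @param path Output path.
#' @export
write_c14_dates <- function(dates, path) {
  out <- data.frame(LabID = dates$lab_id, Age = dates$age, Error = dates$error,
                    SiteID = dates$site_id, Material = dates$material)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Calibrate a single radiocarbon date
#'
#' Converts a conventional radiocarbon age with 1-sigma lab error into a
#' probability density over calendar years, using linear interpolation of
#' the calibration curve on an annual grid. At calendar year theta the
#' (pre-normalization) density is the Gaussian ordinate
#' `dnorm(age; mu(theta), sqrt(error^2 + sigma_curve(theta)^2))`.
#' With `normalize = TRUE` the density is rescaled to unit mass over its
#' support; with `normalize = FALSE` the raw ordinates are kept, so dates
#' lying on steep parts of the curve retain more mass (the distinction the
#' normalized/unnormalized SPD variants probe).
#'
#' Support is truncated where the cumulative mass in each tail falls below
#' `tail` (of the total), before any renormalization.
#'
#' @param age,error Conventional 14C age BP and its 1-sigma error.
#' @param curve A `cal_curve`.
#' @param normalize Rescale to unit mass? Default `TRUE`.
#' @param tail Per-tail cumulative mass cutoff (default `1e-5`).
#' @return A `cal_density`: data frame with columns `year_ad` (ascending)
#'   and `density`, plus attributes `normalized` and `cal_bp` range.
#' @export
calibrate_date <- function(age, error, curve, normalize = TRUE, tail = 1e-5) {
  if (!is.finite(age) || age <= 0) stop("age must be positive")
  if (!is.finite(error) || error <= 0) stop("error must be positive")
  grid_bp <- seq(ceiling(min(curve$cal_bp)), floor(max(curve$cal_bp)), by = 1)
  at <- curve_at(curve, grid_bp)
  sd_tot <- sqrt(error^2 + at$sigma_curve^2)
  max_sd <- max(sd_tot)
  if (age < min(at$mu) - 10 * max_sd || age > max(at$mu) + 10 * max_sd)
    stop("date ", age, " BP lies outside calibration curve coverage")
  dens <- stats::dnorm(age, mean = at$mu, sd = sd_tot)
  tot <- sum(dens)
  if (tot <= 0) stop("date ", age, " BP has no probability mass on the curve grid")
  # truncate tails at cumulative mass `tail` per side (relative to total)
  cum <- cumsum(dens) / tot
  keep <- cum > tail & (1 - cum + dens / tot) > tail
  if (!any(keep)) keep <- dens == max(dens)
  grid_bp <- grid_bp[keep]
  dens <- dens[keep]
  if (normalize) dens <- dens / sum(dens)
  out <- data.frame(year_ad = rev(1950 - grid_bp), density = rev(dens))
  structure(out, class = c("cal_density", "data.frame"),
            normalized = normalize)
}

#' Calibrate every date in a table
#'
#' @param dates A `c14_dates` table.
#' @param curve A `cal_curve`.
#' @inheritParams calibrate_date
#' @return A list of `cal_density` objects, one per date, named by lab ID.
#' @export
calibrate_dates <- function(dates, curve, normalize = TRUE, tail = 1e-5) {
  out <- lapply(seq_len(nrow(dates)), function(i)
    calibrate_date(dates$age[i], dates$error[i], curve,
                   normalize = normalize, tail = tail))
  names(out) <- dates$lab_id
  out
}
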