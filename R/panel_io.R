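#' Read a site table
#'
#' Reads a CSV describing the monitoring sites (cities or stations) that form
#' the node universe of a spatial correlation network. The file must have a
#' header with at least \code{site_id}, \code{latitude} and \code{longitude};
#' \code{name} and \code{category} (e.g. Urban/Suburban) are optional.
#'
#' Row order is preserved and becomes the canonical node order used by every
#' downstream matrix and ranking.
#'
#' @param path path to a CSV file.
#' @return A \code{sites_table}: a data frame with columns \code{site_id},
#'   \code{name}, \code{latitude}, \code{longitude}, \code{category}.
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) stop("sites file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "latitude", "longitude")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sites file missing column(s): ", paste(miss, collapse = ", "))
  if (!"name" %in% names(df)) df$name <- df$site_id
  if (!"category" %in% names(df)) df$category <- NA_character_
  sites_table(df$site_id, df$name, df$latitude, df$longitude, df$category)
}

#' Construct a validated site table
#'
#' @param site_id character vector of unique site identifiers.
#' @param name display names (defaults to \code{site_id}).
#' @param latitude decimal degrees in [-90, 90].
#' @param longitude decimal degrees in [-180, 180].
#' @param category optional site label (e.g. "Urban", "Suburban").
#' @return A data frame of class \code{sites_table}.
#' @export
sites_table <- function(site_id, name = site_id, latitude, longitude,
                        category = NA_character_) {
  site_id <- as.character(site_id)
  if (length(site_id) < 2L) stop("need >= 2 sites to build a network")
  dup <- site_id[duplicated(site_id)]
  if (length(dup)) stop("duplicate site_id: ", paste(unique(dup), collapse = ", "))
  latitude <- as.numeric(latitude)
  longitude <- as.numeric(longitude)
  bad_lat <- which(!is.finite(latitude) | latitude < -90 | latitude > 90)
  if (length(bad_lat))
    stop("latitude out of range [-90, 90] at row(s): ", paste(bad_lat, collapse = ", "))
  bad_lon <- which(!is.finite(longitude) | longitude < -180 | longitude > 180)
  if (length(bad_lon))
    stop("longitude out of range [-180, 180] at row(s): ", paste(bad_lon, collapse = ", "))
  out <- data.frame(site_id = site_id, name = as.character(name),
                    latitude = latitude, longitude = longitude,
                    category = rep_len(as.character(category), length(site_id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("sites_table", "data.frame")
  out
}

#' Write a site table to CSV
#' @param sites a \code{sites_table}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_sites <- function(sites, path) {
  utils::write.csv(as.data.frame(sites), path, row.names = FALSE)
  invisible(path)
}

#' Construct a readings panel
#'
#' A readings panel is a time-by-site grid of AQI values. Daily panels have a
#' contiguous calendar \code{Date} axis; hourly panels carry the observed
#' \code{POSIXct} timestamps.
#'
#' @param values numeric matrix, rows = time points, columns = sites; column
#'   names are site ids.
#' @param times \code{Date} (daily) or \code{POSIXct} (hourly) vector, one per row.
#' @param frequency "daily" or "hourly".
#' @return An object of class \code{readings_panel}: a list with elements
#'   \code{values}, \code{times}, \code{frequency}, \code{sites}.
#' @export
readings_panel <- function(values, times, frequency = c("daily", "hourly")) {
  frequency <- match.arg(frequency)
  values <- as.matrix(values)
  if (nrow(values) != length(times)) stop("length(times) must equal nrow(values)")
  if (is.null(colnames(values))) stop("values must have site ids as column names")
  if (any(values < 0, na.rm = TRUE)) stop("AQI values must be nonnegative")
  ord <- order(times)
  structure(list(values = values[ord, , drop = FALSE], times = times[ord],
                 frequency = frequency, sites = colnames(values)),
            class = "readings_panel")
}

#' @export
print.readings_panel <- function(x, ...) {
  cat(sprintf("readings_panel: %d %s time points x %d sites (%s)\n",
              nrow(x$values), x$frequency, ncol(x$values),
              if (panel_complete(x)) "complete" else
                sprintf("%d missing cells", sum(is.na(x$values)))))
  invisible(x)
}

#' Is a panel free of missing cells?
#' @param panel a \code{readings_panel}.
#' @return logical scalar.
#' @export
panel_complete <- function(panel) !anyNA(panel$values)

#' Read long-format AQI readings
#'
#' Reads a long CSV with columns \code{site_id}, \code{timestamp} (or
#' \code{date}) and \code{aqi}, and pivots it into a readings panel. For daily
#' data the date axis is expanded to the full calendar range, so interior
#' missing days appear as NA cells ready for \code{\link{impute_missing}}.
#'
#' @param path path to the readings CSV.
#' @param sites a \code{sites_table}; rows whose site id is not listed are a
#'   hard error. Column order of the panel follows the site table.
#' @param frequency "daily" or "hourly".
#' @return A \code{readings_panel}, possibly with missing cells.
#' @export
read_readings <- function(path, sites, frequency = c("daily", "hourly")) {
  frequency <- match.arg(frequency)
  if (!file.exists(path)) stop("readings file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tcol <- intersect(c("timestamp", "date"), names(df))[1]
  if (is.na(tcol)) stop("readings file needs a 'timestamp' or 'date' column")
  if (!all(c("site_id", "aqi") %in% names(df)))
    stop("readings file needs columns site_id and aqi")
  df$site_id <- as.character(df$site_id)
  unknown <- setdiff(unique(df$site_id), sites$site_id)
  if (length(unknown))
    stop("readings reference unknown site id(s): ", paste(unknown, collapse = ", "))
  if (any(df$aqi < 0, na.rm = TRUE)) stop("negative AQI value in readings")
  tt <- if (frequency == "hourly") {
    as.POSIXct(df[[tcol]], tz = "UTC")
  } else {
    as.Date(df[[tcol]])
  }
  if (anyNA(tt)) stop("unparseable timestamp(s) in readings")
  key <- paste(df$site_id, format(tt))
  if (anyDuplicated(key))
    stop("duplicate (site_id, timestamp) row(s), e.g. ", key[duplicated(key)][1])
  times <- if (frequency == "daily") {
    seq(min(tt), max(tt), by = "day")
  } else {
    sort(unique(tt))
  }
  values <- matrix(NA_real_, nrow = length(times), ncol = nrow(sites),
                   dimnames = list(NULL, sites$site_id))
  ri <- match(if (frequency == "daily") as.integer(tt) else as.numeric(tt),
              if (frequency == "daily") as.integer(times) else as.numeric(times))
  values[cbind(ri, match(df$site_id, sites$site_id))] <- df$aqi
  readings_panel(values, times, frequency)
}

#' Aggregate an hourly panel to daily means
#'
#' Each (site, date) cell becomes the arithmetic mean of that site's observed
#' hourly values on that date; cells with fewer than \code{min_hours}
#' observations are marked missing. The result covers the full calendar range.
#'
#' @param panel an hourly \code{readings_panel}.
#' @param min_hours minimum number of observed hours for a valid daily mean
#'   (default 1: any observed hour yields a mean).
#' @return A daily \code{readings_panel}.
#' @export
aggregate_daily <- function(panel, min_hours = 1L) {
  stopifnot(inherits(panel, "readings_panel"))
  if (panel$frequency != "hourly") stop("aggregate_daily expects an hourly panel")
  day <- as.Date(panel$times, tz = "UTC")
  days <- seq(min(day), max(day), by = "day")
  g <- match(day, days)
  vals <- matrix(NA_real_, length(days), ncol(panel$values),
                 dimnames = list(NULL, colnames(panel$values)))
  for (j in seq_len(ncol(vals))) {
    x <- panel$values[, j]
    ok <- !is.na(x)
    cnt <- tabulate(g[ok], nbins = length(days))
    sums <- vapply(seq_along(days), function(d) sum(x[ok & g == d]), numeric(1))
    vals[, j] <- ifelse(cnt >= min_hours & cnt > 0, sums / cnt, NA_real_)
  }
  readings_panel(vals, days, "daily")
}

#' Fill missing days in a daily panel
#'
#' Air quality evolves continuously, so a single missing day is replaced by
#' the mean of the previous and next day's values. Longer interior gaps are
#' filled by linear interpolation between the flanking observed days (which
#' reduces to the previous/next mean for one-day gaps); gaps at the start or
#' end of the series take the nearest observed value.
#'
#' @param panel a daily \code{readings_panel}.
#' @return A complete daily \code{readings_panel} with attribute
#'   \code{n_imputed}, the number of cells that were filled.
#' @export
impute_missing <- function(panel) {
  stopifnot(inherits(panel, "readings_panel"))
  if (panel$frequency != "daily") stop("impute_missing expects a daily panel")
  vals <- panel$values
  n_imp <- 0L
  for (j in seq_len(ncol(vals))) {
    x <- vals[, j]
    obs <- which(!is.na(x))
    if (length(obs) == 0L)
      stop("site '", colnames(vals)[j], "' has no observed values")
    gaps <- which(is.na(x))
    if (length(gaps)) {
      # rule = 2 extends the nearest observed value beyond the series ends
      x[gaps] <- stats::approx(obs, x[obs], xout = gaps, rule = 2)$y
      vals[, j] <- x
      n_imp <- n_imp + length(gaps)
    }
  }
  out <- readings_panel(vals, panel$times, "daily")
  attr(out, "n_imputed") <- n_imp
  out
}

#' Write a daily panel as wide CSV
#'
#' First column \code{date}, one column per site.
#' @param panel a \code{readings_panel}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_panel <- function(panel, path) {
  df <- data.frame(date = format(panel$times), panel$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a panel as long-format readings CSV
#'
#' Emits the same \code{site_id,date,aqi} (or \code{site_id,timestamp,aqi})
#' layout that \code{\link{read_readings}} consumes, so synthetic data can
#' exercise the real input path.
#' @param panel a \code{readings_panel}.
#' @param path output CSV path.
#' @param drop_na omit missing cells (default TRUE).
#' @return \code{path}, invisibly.
#' @export
write_readings <- function(panel, path, drop_na = TRUE) {
  tname <- if (panel$frequency == "daily") "date" else "timestamp"
  df <- data.frame(site_id = rep(colnames(panel$values), each = nrow(panel$values)),
                   t = rep(format(panel$times), ncol(panel$values)),
                   aqi = as.vector(panel$values), stringsAsFactors = FALSE)
  names(df)[2] <- tname
  if (drop_na) df <- df[!is.na(df$aqi), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
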