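#' Configuration for the synthetic AQI panel generator
#'
#' The generator emulates the structure of a daily AQI panel over an urban
#' agglomeration: a common seasonal cycle (winter pollution peaks), a shared
#' regional factor with day-to-day persistence (multi-day pollution
#' episodes), and site-level noise whose cross-site correlation decays with
#' geographic distance, so nearby sites co-vary more than distant ones.
#'
#' Defaults describe a one-year, 13-site panel on a region the size of a
#' large Chinese urban agglomeration (roughly 450 x 350 km): baseline AQI 75
#' (moderate), seasonal swing +/-25, regional-episode loading 20 AQI units
#' per site with AR(1) persistence 0.7, site noise sd 25, and a 300 km
#' correlation length for the distance-decay noise covariance. These levels
#' put the mean pairwise correlation of a one-year panel near 0.75, the level
#' observed in real urban-agglomeration AQI panels.
#'
#' @param n_sites number of sites (>= 2).
#' @param n_days number of daily observations.
#' @param seed integer seed; identical config + seed gives identical output.
#' @param layout "uniform_box" (random coordinates in \code{box}), "grid"
#'   (near-square lattice in \code{box}) or "explicit" (use \code{coords}).
#' @param box named numeric vector lat_min, lat_max, lon_min, lon_max.
#' @param coords data frame with latitude/longitude for layout = "explicit".
#' @param mean_level baseline AQI.
#' @param seasonal_amplitude amplitude (AQI units) of the annual sine cycle.
#' @param factor_loadings per-site nonnegative loadings on the shared
#'   regional factor; scalar is recycled.
#' @param factor_persistence AR(1) coefficient of the factor, in [0, 1).
#' @param noise_sd standard deviation of site noise (AQI units).
#' @param correlation_length_km e-folding distance of the noise covariance.
#' @param missing_rate fraction of cells blanked at random (for imputation
#'   tests).
#' @return A list of class \code{synth_config}.
#' @export
synth_config <- function(n_sites = 13, n_days = 365, seed = 1,
                         layout = c("uniform_box", "grid", "explicit"),
                         box = c(lat_min = 36, lat_max = 41,
                                 lon_min = 114, lon_max = 118),
                         coords = NULL,
                         mean_level = 75, seasonal_amplitude = 25,
                         factor_loadings = 20, factor_persistence = 0.7,
                         noise_sd = 25, correlation_length_km = 300,
                         missing_rate = 0) {
  layout <- match.arg(layout)
  stopifnot(n_sites >= 2, n_days >= 1, missing_rate >= 0, missing_rate < 1,
            factor_persistence >= 0, factor_persistence < 1,
            noise_sd >= 0, correlation_length_km > 0,
            all(factor_loadings >= 0))
  structure(list(n_sites = as.integer(n_sites), n_days = as.integer(n_days),
                 seed = as.integer(seed), layout = layout, box = box,
                 coords = coords, mean_level = mean_level,
                 seasonal_amplitude = seasonal_amplitude,
                 factor_loadings = rep_len(factor_loadings, n_sites),
                 factor_persistence = factor_persistence,
                 noise_sd = noise_sd,
                 correlation_length_km = correlation_length_km,
                 missing_rate = missing_rate),
            class = "synth_config")
}

#' Generate a synthetic site table
#'
#' @param config a \code{synth_config}.
#' @return A \code{sites_table} with sites "S01", "S02", ...
#' @export
generate_sites <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_sites
  b <- config$box
  if (config$layout == "explicit") {
    cd <- config$coords
    if (is.null(cd) || nrow(cd) != n)
      stop("layout 'explicit' needs coords with one row per site")
    lat <- cd$latitude; lon <- cd$longitude
    ids <- if ("site_id" %in% names(cd)) cd$site_id else sprintf("S%02d", seq_len(n))
    return(sites_table(ids, latitude = lat, longitude = lon))
  }
  set.seed(config$seed)
  if (config$layout == "grid") {
    ncol_ <- ceiling(sqrt(n))
    nrow_ <- ceiling(n / ncol_)
    gx <- seq(b["lon_min"], b["lon_max"], length.out = ncol_)
    gy <- seq(b["lat_min"], b["lat_max"], length.out = nrow_)
    grid <- expand.grid(lon = gx, lat = gy)[seq_len(n), ]
    lat <- grid$lat; lon <- grid$lon
  } else {
    lat <- stats::runif(n, b["lat_min"], b["lat_max"])
    lon <- stats::runif(n, b["lon_min"], b["lon_max"])
  }
  sites_table(sprintf("S%02d", seq_len(n)), latitude = lat, longitude = lon)
}

#' Generate a synthetic daily AQI panel
#'
#' Site i on day t takes the value
#' \deqn{X_i(t) = \mu + A \sin(2\pi t/365) + \lambda_i F(t) + \epsilon_i(t)}
#' with F a unit-variance AR(1) latent regional factor and epsilon drawn each
#' day from a zero-mean multivariate normal with covariance
#' \eqn{\sigma^2 \exp(-d_{ij}/\rho)}. Values are truncated at 0; if
#' \code{missing_rate > 0}, that fraction of cells is blanked at random.
#'
#' @param sites a \code{sites_table} (typically from
#'   \code{\link{generate_sites}}).
#' @param config a \code{synth_config}.
#' @return A daily \code{readings_panel} starting 2020-11-01.
#' @export
generate_panel <- function(sites, config) {
  stopifnot(inherits(config, "synth_config"), nrow(sites) == config$n_sites)
  set.seed(config$seed + 1L)
  n <- config$n_sites
  nd <- config$n_days
  phi <- config$factor_persistence
  # latent regional factor, stationary unit variance
  f <- numeric(nd)
  f[1] <- stats::rnorm(1)
  if (nd > 1) for (t in 2:nd)
    f[t] <- phi * f[t - 1] + sqrt(1 - phi^2) * stats::rnorm(1)
  # distance-decay noise covariance
  if (config$noise_sd > 0) {
    d <- site_distances(sites, model = "sphere")
    sigma <- config$noise_sd^2 * exp(-d / config$correlation_length_km)
    cl <- chol(sigma)
    eps <- matrix(stats::rnorm(nd * n), nd, n) %*% cl
  } else {
    eps <- matrix(0, nd, n)
  }
  t_ <- seq_len(nd)
  season <- config$mean_level +
    config$seasonal_amplitude * sin(2 * pi * t_ / 365)
  x <- season + outer(f, config$factor_loadings) + eps
  x <- pmax(x, 0)
  colnames(x) <- sites$site_id
  if (config$missing_rate > 0) {
    holes <- which(stats::runif(length(x)) < config$missing_rate)
    x[holes] <- NA_real_
  }
  readings_panel(x, seq(as.Date("2020-11-01"), by = "day", length.out = nd),
                 "daily")
}

#' Plant a dominant hub site
#'
#' Test scaffold for rank recovery: relocates one site to the geometric
#' center of the layout and boosts its loading on the shared regional factor,
#' making it both geographically central (short distances, hence heavy
#' edges) and most strongly coupled to the regional signal. A sound
#' influence ranking should place it first.
#'
#' @param sites a \code{sites_table}.
#' @param config a \code{synth_config}.
#' @param hub index or site id of the hub (default: first site).
#' @param boost multiplier on the hub's factor loading (default 2).
#' @return list with modified \code{sites} and \code{config}.
#' @export
plant_hub <- function(sites, config, hub = 1L, boost = 2) {
  stopifnot(inherits(config, "synth_config"))
  if (is.character(hub)) hub <- match(hub, sites$site_id)
  stopifnot(!is.na(hub), hub >= 1, hub <= nrow(sites))
  sites$latitude[hub] <- mean(sites$latitude[-hub])
  sites$longitude[hub] <- mean(sites$longitude[-hub])
  config$factor_loadings[hub] <- boost * max(config$factor_loadings[-hub])
  list(sites = sites, config = config)
}
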