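# Spherical-earth geodesy for migratory-trait extraction.
# Mean earth radius, km; fixed so results are deterministic across platforms.
EARTH_RADIUS_KM <- 6371.0088

deg2rad <- function(x) x * pi / 180

#' Rhumb-line (loxodrome) bearing and distance
#'
#' The constant-bearing path between two points: bearing is
#' `atan2(dlon, dpsi)` with `dpsi` the difference of meridional parts and
#' `dlon` wrapped to (-pi, pi], mapped to degrees clockwise from north in
#' `[0, 360)`; distance uses the loxodrome closed form with the mean earth
#' radius 6371.0088 km.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (vectorized).
#' @return Tibble with `bearing` (degrees) and `distance_km`.
#' @export
rhumb_bearing_distance <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90)) stop("latitude outside [-90, 90]")
  if (any(abs(c(lat1, lat2)) == 90)) stop("rhumb line undefined at the poles")
  if (any(lat1 == lat2 & normalize_lon(lon1) == normalize_lon(lon2))) {
    stop("bearing undefined for identical points")
  }
  phi1 <- deg2rad(lat1); phi2 <- deg2rad(lat2)
  dphi <- phi2 - phi1
  dlam <- deg2rad(normalize_lon(lon2 - lon1))
  dpsi <- log(tan(pi / 4 + phi2 / 2) / tan(pi / 4 + phi1 / 2))
  bearing <- (atan2(dlam, dpsi) * 180 / pi) %% 360
  q <- ifelse(abs(dpsi) < 1e-12, cos(phi1), dphi / dpsi)
  dist <- EARTH_RADIUS_KM * sqrt(dphi^2 + q^2 * dlam^2)
  tibble::tibble(bearing = bearing, distance_km = dist)
}

#' Great-circle (haversine) distance
#'
#' @inheritParams rhumb_bearing_distance
#' @return Distance in km (vectorized), mean earth radius 6371.0088 km.
#' @export
great_circle_distance <- function(lat1, lon1, lat2, lon2) {
  phi1 <- deg2rad(lat1); phi2 <- deg2rad(lat2)
  dphi <- phi2 - phi1
  dlam <- deg2rad(lon2 - lon1)
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

# initial great-circle bearing, radians
gc_bearing_rad <- function(lat1, lon1, lat2, lon2) {
  phi1 <- deg2rad(lat1); phi2 <- deg2rad(lat2)
  dlam <- deg2rad(lon2 - lon1)
  atan2(sin(dlam) * cos(phi2),
        cos(phi1) * sin(phi2) - sin(phi1) * cos(phi2) * cos(dlam))
}

#' Along-route fraction series for one migration season
#'
#' Projects each daily position onto the great circle from origin to
#' destination (cross-track / along-track construction) and expresses the
#' along-track distance as a fraction of the total route, clamped to
#' `[0, 1]`. A cumulative maximum is applied so the series is monotone even
#' when geolocator noise moves a bird backwards.
#'
#' @param track Tibble with `date`, `lat`, `lon` rows in date order.
#' @param origin,dest Numeric `c(lat, lon)` of the route endpoints (breeding
#'   and wintering sites in fall; reversed in spring).
#' @return Tibble with `date`, `fraction` (monotone non-decreasing) plus the
#'   route's `total_km` (great-circle) as an attribute.
#' @export
route_fraction_series <- function(track, origin, dest) {
  if (nrow(track) == 0) stop("track has no positions")
  total <- great_circle_distance(origin[1], origin[2], dest[1], dest[2])
  if (total <= 0) stop("origin and destination coincide")
  d13 <- great_circle_distance(origin[1], origin[2], track$lat, track$lon) /
    EARTH_RADIUS_KM
  th13 <- gc_bearing_rad(origin[1], origin[2], track$lat, track$lon)
  th12 <- gc_bearing_rad(origin[1], origin[2], dest[1], dest[2])
  dxt <- asin(pmin(1, pmax(-1, sin(d13) * sin(th13 - th12))))
  dat <- acos(pmin(1, pmax(-1, cos(d13) / cos(dxt))))
  dat <- dat * sign(cos(th13 - th12))
  frac <- pmin(1, pmax(0, dat * EARTH_RADIUS_KM / total))
  frac[d13 == 0] <- 0
  out <- tibble::tibble(date = track$date, fraction = cummax(frac))
  attr(out, "total_km") <- total
  out
}

#' Migration timing, duration and speed from a route-fraction series
#'
#' Timing is the first date at which the bird has covered at least half the
#' route; duration is the days between first reaching 30% and first reaching
#' 70%; speed is the rhumb-line migration distance divided by duration
#' (undefined, `NA`, for a zero-day duration). If the series never reaches
#' 70% the traits are returned as missing and flagged.
#'
#' @param fractions Output of [route_fraction_series()].
#' @param distance_km Migration distance (rhumb line) used for speed.
#' @return Tibble with `timing` (date), `duration_days`, `speed_km_day`,
#'   `complete` (logical flag).
#' @export
timing_and_duration <- function(fractions, distance_km = NA_real_) {
  f <- fractions$fraction
  if (max(f) < 0.7) {
    return(tibble::tibble(timing = as.Date(NA), duration_days = NA_real_,
                          speed_km_day = NA_real_, complete = FALSE))
  }
  first_at <- function(q) fractions$date[which(f >= q)[1]]
  timing <- first_at(0.5)
  duration <- as.numeric(first_at(0.7) - first_at(0.3))
  speed <- if (duration > 0) distance_km / duration else NA_real_
  tibble::tibble(timing = timing, duration_days = duration,
                 speed_km_day = speed, complete = TRUE)
}

#' Classify a bird's migratory group from its wintering location
#'
#' Longitude cutoffs follow the wintering-latitude rule: north of 37.5 deg N,
#' west of 5 deg E is SW and east of 20 deg E is SE; south of 37.5 deg N the
#' western cutoff drops to 0 deg E. Birds wintering at or north of
#' `nw_lat_min` with a rhumb bearing in the northwest quadrant are screened
#' off first as NW migrants (reverse migrants that the longitude rules alone
#' would mislabel). Boundary longitudes fall into S.
#'
#' @param breeding_lat,breeding_lon,wintering_lat,wintering_lon Coordinates
#'   in decimal degrees (vectorized).
#' @param nw_lat_min Minimum wintering latitude for the NW screen.
#' @return Character vector of group labels (NW, SW, SE or S).
#' @export
classify_group <- function(breeding_lat, breeding_lon, wintering_lat,
                           wintering_lon, nw_lat_min = 45) {
  wintering_lon <- normalize_lon(wintering_lon)
  bearing <- rhumb_bearing_distance(breeding_lat, breeding_lon,
                                    wintering_lat, wintering_lon)$bearing
  nw <- wintering_lat >= nw_lat_min & bearing > 270 & bearing <= 360
  west_cut <- ifelse(wintering_lat >= 37.5, 5, 0)
  out <- ifelse(wintering_lon < west_cut, "SW",
                ifelse(wintering_lon > 20, "SE", "S"))
  out[nw] <- "NW"
  out
}

#' Derive migratory traits for a cohort of tracked birds
#'
#' Computes, per bird: direction and distance (rhumb line breeding ->
#' wintering), wintering longitude, 50% timing and 30-70% duration of fall
#' and spring migration from the great-circle route-fraction series, fall
#' speed, and the migratory group label.
#'
#' @param birds Nested tibble from [read_tracked_birds()] (or the synthetic
#'   generator): per-bird coordinates plus a `track` list-column with
#'   `season`, `date`, `lat`, `lon`.
#' @return Tibble with one row per bird and the seven derived traits plus
#'   `group`.
#' @export
derive_phenotypes <- function(birds) {
  rh <- rhumb_bearing_distance(birds$breeding_lat, birds$breeding_lon,
                               birds$wintering_lat, birds$wintering_lon)
  season_traits <- function(i, season) {
    tr <- birds$track[[i]]
    tr <- tr[tr$season == season, ]
    if (nrow(tr) == 0) {
      return(tibble::tibble(timing = as.Date(NA), duration_days = NA_real_,
                            speed_km_day = NA_real_, complete = FALSE))
    }
    if (season == "fall") {
      origin <- c(birds$breeding_lat[i], birds$breeding_lon[i])
      dest <- c(birds$wintering_lat[i], birds$wintering_lon[i])
    } else {
      origin <- c(birds$wintering_lat[i], birds$wintering_lon[i])
      dest <- c(birds$breeding_lat[i], birds$breeding_lon[i])
    }
    fr <- route_fraction_series(tr, origin, dest)
    timing_and_duration(fr, rh$distance_km[i])
  }
  has_track <- "track" %in% names(birds)
  fall <- spring <- NULL
  if (has_track) {
    fall <- dplyr::bind_rows(lapply(seq_len(nrow(birds)), season_traits,
                                    season = "fall"))
    spring <- dplyr::bind_rows(lapply(seq_len(nrow(birds)), season_traits,
                                      season = "spring"))
  }
  out <- tibble::tibble(
    bird_id = birds$bird_id,
    sex = if ("sex" %in% names(birds)) birds$sex else NA_character_,
    direction = rh$bearing,
    distance_km = rh$distance_km,
    winter_longitude = normalize_lon(birds$wintering_lon),
    group = classify_group(birds$breeding_lat, birds$breeding_lon,
                           birds$wintering_lat, birds$wintering_lon)
  )
  if (has_track) {
    out$fall_timing <- fall$timing
    out$fall_duration <- fall$duration_days
    out$speed_km_day <- fall$speed_km_day
    out$spring_timing <- spring$timing
    out$spring_duration <- spring$duration_days
  }
  out
}
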