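test_that("rhumb bearing and distance match closed forms and geosphere", {
  eq <- rhumb_bearing_distance(0, 0, 0, 10)
  expect_equal(eq$bearing, 90)
  expect_equal(eq$distance_km, 6371.0088 * 10 * pi / 180, tolerance = 1e-9)
  expect_equal(rhumb_bearing_distance(50, 5, 40, 5)$bearing, 180)

  got <- rhumb_bearing_distance(52, 5, 36, -5)
  want <- oracle_rhumb(52, 5, 36, -5)
  expect_equal(got$bearing, want$bearing, tolerance = 1e-6)
  expect_equal(got$distance_km, want$distance, tolerance = 1e-6)

  skip_if_not_installed("geosphere")
  set.seed(41)
  lat1 <- runif(25, -60, 60); lon1 <- runif(25, -180, 180)
  lat2 <- runif(25, -60, 60); lon2 <- runif(25, -180, 180)
  rb <- rhumb_bearing_distance(lat1, lon1, lat2, lon2)
  for (i in 1:25) {
    expect_equal(rb$bearing[i],
                 geosphere::bearingRhumb(c(lon1[i], lat1[i]),
                                         c(lon2[i], lat2[i])) %% 360,
                 tolerance = 1e-6)
    expect_equal(rb$distance_km[i],
                 geosphere::distRhumb(c(lon1[i], lat1[i]),
                                      c(lon2[i], lat2[i]),
                                      r = 6371008.8) / 1000,
                 tolerance = 1e-6)
  }
  expect_error(rhumb_bearing_distance(10, 10, 10, 10), "identical")
  expect_error(rhumb_bearing_distance(90, 0, 50, 0), "pole")
})

test_that("great-circle distance has its closed-form values", {
  expect_equal(great_circle_distance(48, 13, 48, 13), 0)
  expect_equal(great_circle_distance(10, 0, -10, 180), pi * 6371.0088,
               tolerance = 1e-7)  # half-angle formula loses precision here
  expect_equal(great_circle_distance(0, 0, 0, 1), 2 * pi * 6371.0088 / 360,
               tolerance = 1e-9)
  skip_if_not_installed("geosphere")
  set.seed(42)
  lat1 <- runif(25, -80, 80); lon1 <- runif(25, -180, 180)
  lat2 <- runif(25, -80, 80); lon2 <- runif(25, -180, 180)
  gc <- great_circle_distance(lat1, lon1, lat2, lon2)
  ref <- geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                                  r = 6371008.8) / 1000
  expect_equal(gc, ref, tolerance = 1e-6)
})

test_that("rhumb distance dominates the great circle; bearings reverse", {
  set.seed(43)
  lat1 <- runif(40, -60, 60); lon1 <- runif(40, -170, 170)
  lat2 <- runif(40, -60, 60); lon2 <- runif(40, -170, 170)
  rb <- rhumb_bearing_distance(lat1, lon1, lat2, lon2)
  gc <- great_circle_distance(lat1, lon1, lat2, lon2)
  expect_true(all(rb$distance_km >= gc - 1e-6))
  back <- rhumb_bearing_distance(lat2, lon2, lat1, lon1)
  diff <- (rb$bearing - back$bearing) %% 360
  expect_equal(diff, rep(180, 40), tolerance = 1e-6)
})

test_that("route fractions are clamped, monotone and linear for constant speed", {
  routes <- tibble::tibble(bird_id = "b", origin_lat = 48, origin_lon = 13,
                           dest_lat = 38, dest_lon = -4,
                           departure = as.Date("2020-09-01"),
                           speed_km_day = 90)
  tr <- simulate_tracks(routes, "fall", position_noise_km = 0, seed = 1)
  fr <- route_fraction_series(tr[, c("date", "lat", "lon")], c(48, 13),
                              c(38, -4))
  expect_equal(fr$fraction[1], 0)
  expect_equal(fr$fraction[nrow(fr)], 1)
  total <- attr(fr, "total_km")
  expected <- pmin(1, (seq_len(nrow(fr)) - 1) * 90 / total)
  expect_equal(fr$fraction, expected, tolerance = 1e-6)
  expect_true(all(diff(fr$fraction) >= 0))

  # spring reversal mirrors the fall series
  rev_tr <- tr[nrow(tr):1, c("date", "lat", "lon")]
  rev_tr$date <- tr$date
  fr_rev <- route_fraction_series(rev_tr, c(38, -4), c(48, 13))
  expect_equal(fr_rev$fraction, cummax(1 - rev(fr$fraction)),
               tolerance = 1e-6)
})

test_that("timing, duration and speed follow the 50/30-70 rules", {
  dates <- as.Date("2020-09-01") + 0:10
  lin <- tibble::tibble(date = dates, fraction = seq(0, 1, 0.1))
  td <- timing_and_duration(lin, distance_km = 1000)
  expect_equal(td$timing, dates[6])          # first >= 0.5
  expect_equal(td$duration_days, 4)          # 0.7 at day 7, 0.3 at day 3
  expect_equal(td$speed_km_day, 250)

  jump <- tibble::tibble(date = dates[1:2], fraction = c(0, 1))
  tj <- timing_and_duration(jump, 1000)
  expect_equal(tj$duration_days, 0)
  expect_true(is.na(tj$speed_km_day))

  short <- tibble::tibble(date = dates[1:3], fraction = c(0, 0.2, 0.5))
  ts <- timing_and_duration(short, 1000)
  expect_false(ts$complete)
  expect_true(is.na(ts$timing))
})

test_that("group classification reproduces the latitude-longitude cutoffs", {
  b <- c(48, 13)
  expect_equal(classify_group(b[1], b[2], 40, 3), "SW")
  expect_equal(classify_group(b[1], b[2], 40, 25), "SE")
  expect_equal(classify_group(b[1], b[2], 36, 2), "S")
  expect_equal(classify_group(b[1], b[2], 36, -2), "SW")
  expect_equal(classify_group(b[1], b[2], 40, 10), "S")
  expect_equal(classify_group(b[1], b[2], 52, -2), "NW")
  # boundary longitudes fall into S
  expect_equal(classify_group(b[1], b[2], 40, 5), "S")
  expect_equal(classify_group(b[1], b[2], 40, 20), "S")
  # totality over a random grid
  set.seed(44)
  wl <- runif(200, -30, 65)
  wo <- runif(200, -30, 40)
  got <- classify_group(rep(48, 200), rep(13, 200), wl, wo)
  expect_true(all(got %in% c("NW", "SW", "SE", "S")))
})

test_that("derive_phenotypes assembles the seven traits per bird", {
  routes <- tibble::tibble(
    bird_id = c("b1", "b2"),
    origin_lat = 48, origin_lon = 13,
    dest_lat = c(38, 33), dest_lon = c(-4, 28),
    departure = as.Date("2020-09-01"), speed_km_day = c(90, 110))
  fall <- simulate_tracks(routes, "fall", 0, seed = 2)
  spring_routes <- routes
  spring_routes$origin_lat <- routes$dest_lat
  spring_routes$origin_lon <- routes$dest_lon
  spring_routes$dest_lat <- 48; spring_routes$dest_lon <- 13
  spring_routes$departure <- as.Date("2021-04-10")
  spring <- simulate_tracks(spring_routes, "spring", 0, seed = 3)
  tracks <- dplyr::bind_rows(fall, spring)
  birds <- tibble::tibble(
    bird_id = c("b1", "b2"), sex = c("M", "F"),
    breeding_lat = 48, breeding_lon = 13,
    wintering_lat = c(38, 33), wintering_lon = c(-4, 28),
    track = lapply(c("b1", "b2"), function(b)
      tracks[tracks$bird_id == b, c("season", "date", "lat", "lon")]))
  ph <- derive_phenotypes(birds)
  expect_equal(ph$group, c("SW", "SE"))
  expect_equal(ph$winter_longitude, c(-4, 28))
  rb <- rhumb_bearing_distance(48, 13, c(38, 33), c(-4, 28))
  expect_equal(ph$direction, rb$bearing)
  expect_equal(ph$distance_km, rb$distance_km)
  expect_false(any(is.na(ph$fall_timing)))
  expect_false(any(is.na(ph$spring_timing)))
  expect_true(all(ph$fall_duration >= 0))
})
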