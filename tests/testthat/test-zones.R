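test_that("haversine distance is a metric with the spherical-earth scale", {
  expect_equal(haversine_nm(10, -160, 10, -160), 0)
  # one degree of longitude at the equator: 2*pi*6371/360 km / 1.852
  expect_equal(haversine_nm(0, 0, 0, 1), 60.0405, tolerance = 1e-4)
  set.seed(1)
  a <- cbind(runif(100, -90, 90), runif(100, -180, 180))
  b <- cbind(runif(100, -90, 90), runif(100, -180, 180))
  d_ab <- haversine_nm(a[, 1], a[, 2], b[, 1], b[, 2])
  d_ba <- haversine_nm(b[, 1], b[, 2], a[, 1], a[, 2])
  expect_equal(d_ab, d_ba)
  expect_true(all(d_ab >= 0))
  expect_error(haversine_nm(95, 0, 0, 0), "latitude")
})

test_that("zone assignment puts feature centers inside active closures", {
  z <- zone_config()
  king <- z$features[z$features$name == "kingman", ]
  a <- assign_zone(king$lat, king$lon, "2009-01-06", z)
  expect_true(a$inside_active_closure)
  expect_true(a$kp50)
  expect_true(a$kp110)
  expect_true(is.na(a$control_label))
  # before the 50 nm designation the same point sat in the 12 nm closure
  # only when within 12 nm; at the center it is
  b <- assign_zone(king$lat, king$lon, "2005-06-01", z)
  expect_true(b$inside_active_closure)
  # once an open-ended closure starts it never reverts
  c1 <- assign_zone(king$lat, king$lon, "2012-01-01", z)
  c2 <- assign_zone(king$lat, king$lon, "2018-01-01", z)
  expect_true(c1$inside_active_closure && c2$inside_active_closure)
})

test_that("control zones split at the archipelago line and 150W meridian", {
  z <- zone_config()
  expect_equal(assign_zone(32, -175, "2000-01-01", z)$control_label,
               "northwest")
  expect_equal(assign_zone(10, -155, "2000-01-01", z)$control_label,
               "south")
  expect_equal(assign_zone(25, -148, "2000-01-01", z)$control_label,
               "northeast")
  # point exactly on the meridian, north of the line: east tie-break
  expect_equal(assign_zone(25, -150, "2000-01-01", z)$control_label,
               "northeast")
})

test_that("treatment/control assignment partitions random points once", {
  z <- zone_config()
  set.seed(7)
  n <- 2000
  pts <- data.frame(
    set_id = seq_len(n),
    lat = runif(n, 0, 40), lon = runif(n, -180, -145),
    date = as.Date("1994-03-04") + sample(0:9000, n, replace = TRUE)
  )
  a <- assign_zones(pts, z)
  n_treat <- rowSums(as.matrix(a[, c("kp50", "kp110", "j50", "j110",
                                     "j200", "j260")]))
  has_control <- !is.na(a$control_label)
  expect_true(all(xor(has_control, n_treat >= 1)))
  # nested buffers
  expect_true(all(!a$j110 | a$j260))
  expect_true(all(!a$kp50 | a$kp110))
  expect_true(all(!a$j50 | a$j110))
  expect_true(all(!a$j200 | a$j260))
})

test_that("confidentiality filter keeps aggregates with >= 3 vessels", {
  bins <- data.frame(
    bin = rep(c("a", "b", "c"), times = c(1, 3, 5)),
    vessel_id = c("v1", "v1", "v2", "v3", "v1", "v2", "v3", "v4", "v5")
  )
  out <- filter_confidential(bins)
  expect_setequal(out$bin, c("b", "c"))
  # all bins single-vessel -> empty
  solo <- data.frame(bin = c("a", "b"), vessel_id = c("v1", "v2"))
  expect_equal(nrow(filter_confidential(solo)), 0)
  # brute-force re-count oracle on random bins
  set.seed(11)
  big <- data.frame(
    bin = sample(1000, 5000, replace = TRUE),
    vessel_id = sample(paste0("v", 1:8), 5000, replace = TRUE)
  )
  out <- filter_confidential(big)
  oracle <- names(which(vapply(
    split(big$vessel_id, big$bin),
    function(v) length(unique(v)) >= 3, logical(1)
  )))
  expect_setequal(as.character(out$bin), oracle)
})

test_that("hexagonal binning conserves counts and maps points uniquely", {
  one <- data.frame(lat = 20, lon = -160)
  h1 <- hexbin_effort(one, min_sets = 50)
  expect_equal(nrow(h1), 1)
  expect_equal(h1$n_sets, 1)
  expect_false(h1$retained)

  set.seed(3)
  pts <- data.frame(lat = runif(4000, 0, 40), lon = runif(4000, -180, -145))
  h <- hexbin_effort(pts)
  expect_equal(sum(h$n_sets), 4000)

  same <- data.frame(lat = rep(17.2, 99), lon = rep(-163.4, 99))
  hs <- hexbin_effort(same)
  expect_equal(nrow(hs), 1)
  expect_equal(hs$n_sets, 99)
  expect_true(hs$retained)
})

test_that("zone buffers export as valid GeoJSON rings", {
  path <- tempfile(fileext = ".geojson")
  zones_to_geojson(zone_config(), path)
  gj <- jsonlite::read_json(path)
  expect_equal(gj$type, "FeatureCollection")
  expect_gt(length(gj$features), 3)
  ring <- gj$features[[1]]$geometry$coordinates[[1]]
  expect_equal(length(ring), 65) # 64 vertices, closed
  expect_equal(unlist(ring[[1]]), unlist(ring[[65]]))
})
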