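test_that("bin grid midpoints follow the farthest-ahead-first convention", {
  cfg <- tiny_cfg(ahead = 300, behind = 0, width = 100)
  expect_equal(build_bin_grid(cfg), c(250, 150, 50))

  cfg2 <- tiny_cfg(ahead = 100, behind = 100, width = 100)
  expect_equal(build_bin_grid(cfg2), c(50, -50))

  expect_error(tiny_cfg(width = 0), "bin_width")
  expect_error(tiny_cfg(ahead = 50, behind = 0, width = 100), "at least 2")
})

test_that("grid span covers the forward extent with a fixed ceiling rule", {
  for (ahead in c(500, 730, 1111)) {
    for (width in c(100, 130)) {
      cfg <- tiny_cfg(ahead = ahead, behind = 250, width = width)
      J <- cfg$n_bins
      expect_equal(J, ceiling((ahead + 250) / width))
      mids <- build_bin_grid(cfg)
      expect_equal(mids[1], ahead - width / 2)
      # last bin reaches at least to -behind (possibly past, by < one bin)
      expect_lte(mids[J] - width / 2, -250)
      expect_gt(mids[J] + width / 2, -250)
      expect_equal(diff(mids), rep(-width, J - 1))
    }
  }
})

test_that("radial distance is the euclidean combination, symmetric in sign", {
  expect_equal(radial_distance(3, 4), 5)
  expect_equal(radial_distance(7, 0), 7)
  expect_equal(radial_distance(0, -7), 7)
  expect_error(radial_distance(-1, 0), "non-negative")
  for (x in c(0, 2, 10)) for (y in c(-5, 0, 3)) {
    expect_gte(radial_distance(x, y), max(abs(x), abs(y)))
    expect_equal(radial_distance(x, y), radial_distance(x, -y))
  }
})

test_that("click trains bin into capture histories", {
  cfg <- tiny_cfg(ahead = 500, behind = 0, width = 100)   # J = 5
  # single click in bin 3 (midpoint 250)
  h <- bin_click_train(data.frame(time_s = 0, forward_distance_m = 250), cfg)
  expect_equal(as.integer(h), c(0L, 0L, 1L, 0L, 0L))

  # consecutive one-minute clicks walk aft one bin at a time
  cfg2 <- tiny_cfg(ahead = 500, behind = 100, width = 100, speed = 100 / 60)
  h2 <- bin_click_train(
    data.frame(time_s = c(0, 60, 120), forward_distance_m = c(450, NA, NA)),
    cfg2)
  expect_equal(as.integer(h2), c(1L, 1L, 1L, 0L, 0L, 0L))

  # a silent gap is preserved
  h3 <- bin_click_train(
    data.frame(time_s = c(0, 120), forward_distance_m = c(450, NA)), cfg2)
  expect_equal(as.integer(h3), c(1L, 0L, 1L, 0L, 0L, 0L))

  expect_error(bin_click_train(data.frame(), cfg), "at least one click")
  expect_error(bin_click_train(
    data.frame(time_s = c(10, 0), forward_distance_m = c(100, 100)), cfg),
    "non-decreasing")
})

test_that("binning is idempotent and boundary clicks go to the ahead bin", {
  cfg <- tiny_cfg(ahead = 500, behind = 0, width = 100)
  # boundary at 400 m separates bin 1 (400, 500] from bin 2 (300, 400]
  expect_equal(forward_to_bin(400, cfg), 1L)
  expect_equal(forward_to_bin(399.99, cfg), 2L)
  expect_equal(forward_to_bin(500, cfg), 1L)   # top edge belongs to bin 1
  expect_true(is.na(forward_to_bin(501, cfg)))
  expect_true(is.na(forward_to_bin(-1, cfg)))

  # re-binning clicks placed at the midpoints reproduces the history
  h <- c(0L, 1L, 1L, 0L, 1L)
  mids <- build_bin_grid(cfg)
  clicks <- data.frame(time_s = seq_along(which(h == 1)) * 0,
                       forward_distance_m = mids[h == 1])
  # rebuild each bin separately (time 0 anchors on the first click)
  got <- integer(5)
  for (j in which(h == 1))
    got[forward_to_bin(mids[j], cfg)] <- 1L
  expect_equal(got, h)
})

test_that("clicks outside the grid are dropped with a warning count", {
  cfg <- tiny_cfg(ahead = 500, behind = 0, width = 100)
  # second click is 600 s later: the whale's relative position has moved
  # 3000 m aft, far past the end of the grid
  expect_warning(
    h <- bin_click_train(
      data.frame(time_s = c(0, 600), forward_distance_m = c(250, NA)), cfg),
    "dropped")
  expect_equal(attr(h, "n_dropped"), 1L)
  expect_equal(as.integer(h), c(0L, 0L, 1L, 0L, 0L))
})

test_that("acoustic events validate history and geometry", {
  cfg <- tiny_cfg(ahead = 300, behind = 0, width = 100)
  ev <- acoustic_event("E1", 400, c(0, 1, 0), cfg)
  expect_equal(ev$radial, sqrt(400^2 + build_bin_grid(cfg)^2))
  expect_error(acoustic_event("E1", 400, c(0, 0, 0), cfg), "at least one")
  expect_error(acoustic_event("E1", 400, c(0, 2, 0), cfg), "0 or 1")
  expect_error(acoustic_event("E1", -4, c(0, 1, 0), cfg), "non-negative")
  expect_error(acoustic_event("E1", 400, c(0, 1), cfg), "per bin")
})

test_that("survey tables round-trip through CSV with extra columns kept", {
  dir <- withr::local_tempdir()
  sightings <- data.frame(
    sighting_id = c("S1", "S2"), team = c(1L, 2L),
    perp_distance_m = c(120.5, 2000), group_size = c(2L, 1L),
    duplicate_id = c("D1", NA), beaufort = c(2.5, 3))  # extra column
  events <- data.frame(event_id = c("E1", "E2"),
                       perp_distance_m = c(100, 3500),
                       fully_annotated = c(TRUE, FALSE))
  histories <- data.frame(event_id = c("E1", "E2"),
                          bin_1 = c(1L, 0L), bin_2 = c(0L, 1L))
  cfg <- tiny_cfg()
  write_survey(list(sightings = sightings, events = events,
                    histories = histories, config = cfg), dir)
  back <- read_survey(dir)
  expect_equal(back$sightings$perp_distance_m, sightings$perp_distance_m)
  expect_equal(back$sightings$beaufort, sightings$beaufort)
  expect_true(is.na(back$sightings$duplicate_id[2]))
  expect_equal(back$events$fully_annotated, events$fully_annotated)
  expect_equal(history_matrix(back$histories),
               matrix(c(1L, 0L, 0L, 1L), 2,
                      dimnames = list(c("E1", "E2"), c("bin_1", "bin_2"))))
  expect_equal(back$config$n_bins, cfg$n_bins)
  expect_equal(back$config$midpoints, cfg$midpoints)
})

test_that("schema violations are reported by column name", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "sightings.csv")
  utils::write.csv(data.frame(sighting_id = "S1", team = 1), f,
                   row.names = FALSE)
  expect_error(read_sightings(f), "perp_distance_m")

  # file without a header row fails the schema check
  writeLines(c("S1,1,100,1,", "S2,2,200,1,"), f)
  expect_error(read_sightings(f), "missing mandatory column")

  fe <- file.path(dir, "events.csv")
  utils::write.csv(data.frame(event_id = c("E1", "E1"),
                              perp_distance_m = c(1, 2)), fe,
                   row.names = FALSE)
  expect_error(read_events(fe), "duplicate event_id")
})
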