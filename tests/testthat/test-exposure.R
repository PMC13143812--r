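# Diary, residential, ABM, known-workplace and GPS exposures, track merging,
# and the convexity/missingness properties.

test_that("any diary on a uniform surface yields the surface value", {
  hset <- uniform_hset(20)
  res <- build_diary(list(kind = "residential"), "a", c(150, 150))
  expect_equal(diary_exposure(res, hset), 20, tolerance = 1e-12)
  set.seed(1)
  hm <- build_diary(list(kind = "homemaker", homemaker_buffer_km = 1), "a",
                    c(200, 200))
  # excursions may leave the extent of this small grid; keep ones inside
  if (!is.na(diary_exposure(hm, hset)))
    expect_equal(diary_exposure(hm, hset), 20, tolerance = 1e-12)
  coords <- rbind(c(50, 50), c(350, 350))
  net <- make_network(coords, rbind(c(1, 2)))
  rt <- shortest_route(net, coords[1, ], coords[2, ], "walk")
  cm <- build_diary(list(kind = "commuter", commuter_subcategory = "all"),
                    "a", coords[1, ], coords[2, ], rt)
  expect_equal(diary_exposure(cm, hset), 20, tolerance = 1e-12)
})

test_that("residential exposure equals the explicit 48-term sum", {
  set.seed(7)
  g <- matrix(runif(16, 5, 40), 4, 4)
  wd <- rep(1, 24) + 0.3 * sin(2 * pi * (0:23) / 24)
  we <- rep(1, 24) - 0.1 * cos(2 * pi * (0:23) / 24)
  shp <- normalize_diurnal_shapes(list(weekday = wd, weekend = we))
  st <- profile_station("s", 10 * shp$weekday, 10 * shp$weekend)
  hset <- apply_diurnal_ratios(tiny_surface(g), compute_diurnal_ratios(list(st)))
  home <- c(250, 250)  # inside cell (2, 3)
  rec <- residential_exposure(
    data.frame(id = "a", x = home[1], y = home[2]), hset)
  # oracle: explicit 48-term weighted sum at the home cell
  base <- g[2, 3]
  oracle <- 0
  for (h in 0:23) {
    oracle <- oracle + (5 / 7) / 24 * base * hset$ratios$ratio["weekday", h + 1] +
      (2 / 7) / 24 * base * hset$ratios$ratio["weekend", h + 1]
  }
  expect_equal(rec$mean, unname(oracle), tolerance = 1e-12)
  expect_equal(rec$metric, "RES")
  # two agents in the same cell get identical records
  rec2 <- residential_exposure(
    data.frame(id = "b", x = 299, y = 201), hset)
  expect_equal(rec2$mean, rec$mean)
})

test_that("a diary leg crossing a nodata region makes the exposure missing", {
  g <- matrix(20, 4, 4)
  g[2, 2] <- NA
  hset <- apply_diurnal_ratios(tiny_surface(g), flat_ratios())
  d <- build_diary(list(kind = "residential"), "a", c(150, 250))  # nodata cell
  expect_true(is.na(diary_exposure(d, hset)))
  rec <- residential_exposure(data.frame(id = "a", x = 150, y = 250), hset)
  expect_true(is.na(rec$mean))
  expect_equal(rec$reason, "out_of_extent")
})

test_that("ABM exposure aggregates realizations with the n-1 SD convention", {
  # two stationary 'realizations' parked on cells with values 10 and 20
  g <- matrix(c(10, 20), 1, 2)
  hset <- apply_diurnal_ratios(tiny_surface(g), flat_ratios())
  mk <- function(x) list(diary = build_diary(list(kind = "residential"),
                                             "a", c(x, 50)))
  sim <- structure(list(agent_id = "a", profile = list(kind = "commuter"),
                        realizations = list(mk(50), mk(150))),
                   class = "agent_realizations")
  rec <- abm_exposure(sim, hset)
  expect_equal(rec$mean, 15)
  expect_equal(rec$sd, stats::sd(c(10, 20)))  # sample convention
  expect_equal(rec$n_realizations, 2L)
  # identical realizations: SD 0
  sim2 <- structure(list(agent_id = "a", profile = list(kind = "commuter"),
                         realizations = rep(list(mk(50)), 5)),
                    class = "agent_realizations")
  expect_equal(abm_exposure(sim2, hset)$sd, 0)
  expect_error(abm_exposure(structure(list(agent_id = "a",
                                           realizations = list()),
                                      class = "agent_realizations"), hset),
               "at least one")
})

test_that("one out-of-extent realization voids the whole ABM record", {
  g <- matrix(c(10, 20), 1, 2)
  hset <- apply_diurnal_ratios(tiny_surface(g), flat_ratios())
  mk <- function(x) list(diary = build_diary(list(kind = "residential"),
                                             "a", c(x, 50)))
  sim <- structure(list(agent_id = "a", profile = list(kind = "commuter"),
                        realizations = list(mk(50), mk(150), mk(9999))),
                   class = "agent_realizations")
  rec <- abm_exposure(sim, hset)
  expect_true(is.na(rec$mean))
  expect_equal(rec$reason, "realization_out_of_extent")
})

test_that("a failed realization annotates the record instead of aborting", {
  g <- matrix(c(10, 20), 1, 2)
  hset <- apply_diurnal_ratios(tiny_surface(g), flat_ratios())
  mk <- function(x) list(diary = build_diary(list(kind = "residential"),
                                             "a", c(x, 50)))
  sim <- structure(list(agent_id = "a", profile = list(kind = "commuter"),
                        realizations = list(
                          mk(50),
                          list(index = 1L, diary = NULL,
                               error = "agent a: no walk-permitted path"))),
                   class = "agent_realizations")
  rec <- abm_exposure(sim, hset)
  expect_true(is.na(rec$mean))
  expect_equal(rec$reason, "realization_error")
})

test_that("RES and ABM are bit-identical for residential profiles", {
  w <- test_world(37L)
  hset <- apply_diurnal_ratios(w$surfaces$NO2,
                               compute_diurnal_ratios(w$stations$NO2))
  demo <- demographics_config(
    employment = c(fulltime = 0, parttime = 0, homemaker = 0, retired = 1,
                   other = 0), known_work_frac = 0)
  ag <- generate_population(w, demo, 30L, 5L)
  sims <- simulate_population(ag, w, n_realizations = 50L, seed = 5L)
  for (i in seq_len(nrow(ag))) {
    res <- residential_exposure(ag[i, ], hset)
    abm <- abm_exposure(sims[[ag$id[i]]], hset)
    expect_identical(res$mean, abm$mean)
  }
})

test_that("known-workplace exposure is deterministic and uses no RNG", {
  w <- test_world(37L)
  hset <- apply_diurnal_ratios(w$surfaces$NO2,
                               compute_diurnal_ratios(w$stations$NO2))
  ag <- agent_row <- data.frame(
    id = "a", x = 3000, y = 3000, municipality = "m01", sex = "female",
    age = 40, ses = "high", employment = "fulltime",
    known_work_x = 4500, known_work_y = 4200, stringsAsFactors = FALSE)
  set.seed(123); state <- .Random.seed
  r1 <- known_workplace_exposure(ag, hset, w)
  expect_identical(state, .Random.seed)  # no RNG consumed
  r2 <- known_workplace_exposure(ag, hset, w)
  expect_identical(r1$mean, r2$mean)
  expect_equal(r1$metric, "ABMkWP")
  expect_false(is.na(r1$mean))
  # absent workplace: skipped with a message
  ag$known_work_x <- NA_real_
  expect_message(out <- known_workplace_exposure(ag, hset, w), "skipped")
  expect_null(out)
})

test_that("commuting into the urban plume raises exposure above RES", {
  # monotone west-to-east gradient field
  g <- matrix(rep(seq(10, 50, length.out = 40), each = 40), 40, 40)
  hset <- apply_diurnal_ratios(tiny_surface(g), flat_ratios())
  coords <- rbind(c(200, 2000), c(3800, 2000))
  net <- make_network(coords, rbind(c(1, 2)))
  w_stub <- list(network = net)
  ag <- data.frame(id = "a", x = 200, y = 2000, municipality = "m01",
                   sex = "male", age = 30, ses = "middle",
                   employment = "fulltime",
                   known_work_x = 3800, known_work_y = 2000,
                   stringsAsFactors = FALSE)
  kwp <- known_workplace_exposure(ag, hset, w_stub)
  res <- residential_exposure(ag, hset)
  expect_gt(kwp$mean, res$mean)
  # zero-length commute: ABMkWP collapses to RES
  ag2 <- ag
  ag2$known_work_x <- ag2$x; ag2$known_work_y <- ag2$y
  kwp2 <- known_workplace_exposure(ag2, hset, w_stub)
  expect_equal(kwp2$mean, res$mean, tolerance = 1e-12)
})

test_that("merge_tracks keeps tracker points and stays strictly increasing", {
  app <- data.frame(t = c(5, 100, 250), x = 1:3, y = 1:3)
  tracker <- data.frame(t = c(0, 20, 40, 95), x = 11:14, y = 11:14)
  m <- merge_tracks(app, tracker)
  expect_true(all(diff(m$t) > 0))
  # app points at 5 (within 10 s of 0) and 100 (within 10 s of 95) dropped
  expect_equal(m$t, c(0, 20, 40, 95, 250))
  expect_equal(m$source, c(rep("tracker", 4), "app"))
  # duplicate timestamp: tracker survives
  m2 <- merge_tracks(data.frame(t = 20, x = 9, y = 9), tracker)
  expect_equal(m2$x[m2$t == 20], 12)
  # empty app stream passes tracker through
  m3 <- merge_tracks(data.frame(t = numeric(0), x = numeric(0),
                                y = numeric(0)), tracker)
  expect_equal(m3$t, tracker$t)
  expect_error(merge_tracks(data.frame(t = numeric(0), x = numeric(0),
                                       y = numeric(0)),
                            data.frame(t = numeric(0), x = numeric(0),
                                       y = numeric(0))), "empty")
})

test_that("merged interleaved streams match a sort-and-dedupe oracle", {
  set.seed(11)
  for (k in 1:20) {
    app <- data.frame(t = sort(runif(30, 0, 3000)), x = runif(30),
                      y = runif(30))
    tracker <- data.frame(t = sort(runif(80, 0, 3000)), x = runif(80),
                          y = runif(80))
    m <- merge_tracks(app, tracker)
    # oracle: brute-force double loop
    keep <- vapply(app$t, function(ta)
      all(abs(tracker$t - ta) > 10), logical(1))
    oracle <- rbind(cbind(app[keep, ], source = "app"),
                    cbind(tracker, source = "tracker"))
    oracle <- oracle[order(oracle$t), ]
    expect_equal(m$t, oracle$t)
    expect_equal(m$x, oracle$x)
  }
})

test_that("two-point tracks weight both endpoints equally", {
  g <- matrix(c(10, 30), 1, 2)
  hset <- apply_diurnal_ratios(tiny_surface(g), flat_ratios())
  tr <- structure(data.frame(t = c(0, 3600), x = c(50, 150), y = c(50, 50),
                             source = "tracker"),
                  class = c("merged_track", "data.frame"))
  rec <- track_exposure(tr, hset, "a", min_coverage = 0)
  expect_equal(rec$mean, 20)
})

test_that("GPS exposure on a uniform surface is the surface value", {
  hset <- uniform_hset(17, n = 10)
  set.seed(12)
  tr <- structure(data.frame(t = sort(runif(500, 0, 86400 * 2)),
                             x = runif(500, 0, 900), y = runif(500, 0, 900),
                             source = "tracker"),
                  class = c("merged_track", "data.frame"))
  rec <- track_exposure(tr, hset, "a")
  expect_equal(rec$mean, 17, tolerance = 1e-12)
})

test_that("a stationary zero-noise track reproduces RES exactly", {
  w <- test_world(41L)
  hset <- apply_diurnal_ratios(w$surfaces$NO2,
                               compute_diurnal_ratios(w$stations$NO2))
  home <- c(5100, 4300)
  diary <- build_diary(list(kind = "residential"), "a1", home)
  agents <- data.frame(id = "a1", stringsAsFactors = FALSE)
  tr <- generate_tracks(agents, list(a1 = diary), sampling_config(),
                        noise_sd = 0, dropout_rate = 0, seed = 2L)[["a1"]]
  m <- merge_tracks(tr$app, tr$tracker)
  gps <- track_exposure(m, hset, "a1", span = c(0, 14 * 86400))
  res <- residential_exposure(data.frame(id = "a1", x = home[1],
                                         y = home[2]), hset)
  expect_equal(gps$mean, res$mean, tolerance = 1e-6)
})

test_that("out-of-extent track time is dropped and coverage enforced", {
  g <- matrix(20, 2, 2)
  hset <- apply_diurnal_ratios(tiny_surface(g), flat_ratios())
  # half the points far outside the grid
  tr <- structure(data.frame(t = seq(0, 1900, by = 100),
                             x = c(rep(50, 10), rep(1e6, 10)),
                             y = 50, source = "tracker"),
                  class = c("merged_track", "data.frame"))
  rec <- track_exposure(tr, hset, "a", min_coverage = 0.3)
  expect_equal(rec$mean, 20)
  rec2 <- track_exposure(tr, hset, "a", min_coverage = 0.8)
  expect_true(is.na(rec2$mean))
  expect_equal(rec2$reason, "insufficient_coverage")
  # all points out of extent
  tr$x <- 1e6
  rec3 <- track_exposure(tr, hset, "a")
  expect_true(is.na(rec3$mean))
})

test_that("every exposure lies within the visited concentration range", {
  w <- test_world(43L)
  hset <- apply_diurnal_ratios(w$surfaces$NO2,
                               compute_diurnal_ratios(w$stations$NO2))
  rng <- range(hset$annual$grid, na.rm = TRUE) *
    range(hset$ratios$ratio)
  ag <- generate_population(w, demographics_config(known_work_frac = 0.5),
                            15L, 6L)
  sims <- simulate_population(ag, w, n_realizations = 5L, seed = 6L)
  for (i in seq_len(nrow(ag))) {
    for (r in sims[[ag$id[i]]]$realizations) {
      v <- diary_exposure(r$diary, hset)
      if (!is.na(v)) {
        expect_gte(v, rng[1] - 1e-9)
        expect_lte(v, rng[2] + 1e-9)
      }
    }
  }
})
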