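# Profile assignment, work-location sampling, mode choice, shortest routing
# against a brute-force oracle, diary construction and Monte Carlo simulation.

agent_row <- function(sex = "female", ses = "high", employment = "fulltime",
                      x = 0, y = 0, municipality = "m01", id = "a1") {
  data.frame(id = id, x = x, y = y, municipality = municipality, sex = sex,
             age = 40, ses = ses, employment = employment,
             known_work_x = NA_real_, known_work_y = NA_real_,
             stringsAsFactors = FALSE)
}

test_that("profile assignment maps the demographic rule table", {
  cases <- list(
    list(agent_row("female", "high", "fulltime"), "commuter", "female_highSES"),
    list(agent_row("male", "low", "parttime"), "commuter", "male_lowSES"),
    list(agent_row("male", "middle", "fulltime"), "commuter", "male_midSES"),
    list(agent_row("other", "high", "fulltime"), "commuter", "all"),
    list(agent_row("female", "low", "retired"), "residential", NULL),
    list(agent_row("male", "middle", "other"), "residential", NULL),
    list(agent_row("female", "middle", "homemaker"), "homemaker", NULL))
  for (cs in cases) {
    p <- assign_profile(cs[[1]])
    expect_equal(p$kind, cs[[2]])
    if (!is.null(cs[[3]])) expect_equal(p$commuter_subcategory, cs[[3]])
  }
  expect_equal(assign_profile(agent_row(employment = "homemaker"),
                              homemaker_buffer_km = 10)$homemaker_buffer_km, 10)
})

test_that("work locations follow the O-D row distribution", {
  w <- test_world(17L)
  munis <- w$municipalities
  # degenerate row: all mass on one destination
  od1 <- od_matrix("m01", c("m01", "m05"), matrix(c(0, 1), 1))
  ag <- agent_row()
  set.seed(1)
  for (k in 1:20) {
    pt <- sample_work_location(ag, od1, munis)
    expect_true(point_in_polygon(pt[1], pt[2],
                                 munis[[5]]$polygon))
  }
  # binomial oracle on a (0.3, 0.7) row
  od2 <- od_matrix("m01", c("m02", "m03"), matrix(c(0.3, 0.7), 1))
  set.seed(2)
  hits <- replicate(10000, {
    pt <- sample_work_location(ag, od2, munis)
    point_in_polygon(pt[1], pt[2], munis[[2]]$polygon)
  })
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(mean(hits) - 0.3), 3 * se)
  # one-municipality world: destination is the origin
  od3 <- od_matrix("m01", "m01", matrix(1, 1))
  pt <- sample_work_location(ag, od3, munis)
  expect_true(point_in_polygon(pt[1], pt[2], munis[[1]]$polygon))
  expect_error(sample_work_location(agent_row(municipality = "zz"), od3, munis),
               "not an O-D origin")
})

test_that("mode choice respects distance bands and boundaries", {
  mt <- default_mode_table()
  set.seed(3)
  # forced band: walk-only below 1 km
  mt1 <- mt; mt1[1, -1] <- c(1, 0, 0, 0)
  expect_equal(assign_mode(500, mt1), "walk")
  # boundary distances fall in the upper band
  mt2 <- mt
  mt2[1, -1] <- c(1, 0, 0, 0); mt2[2, -1] <- c(0, 1, 0, 0)
  expect_equal(assign_mode(2000, mt2), "bike")
  expect_equal(assign_mode(1999.999, mt2), "walk")
  # beyond the last finite bound: the open-ended band applies
  mt3 <- mt; mt3[4, -1] <- c(0, 0, 1, 0)
  expect_equal(assign_mode(250000, mt3), "car")
  # binomial oracle at 5 km with P(bike) = 0.6, P(car) = 0.4
  mt4 <- mt; mt4[2, -1] <- c(0, 0.6, 0.4, 0)
  set.seed(4)
  draws <- replicate(10000, assign_mode(5000, mt4))
  se <- sqrt(0.6 * 0.4 / 10000)
  expect_lt(abs(mean(draws == "bike") - 0.6), 3 * se)
  expect_true(all(draws %in% c("bike", "car")))
})

test_that("modal mode is the band's highest-probability mode", {
  expect_equal(modal_mode(500), "walk")
  expect_equal(modal_mode(5000), "bike")
  expect_equal(modal_mode(20000), "car")
})

test_that("a 3-4-5 triangle picks the direct edge", {
  # network lengths 5000 (direct) vs 3000 + 4000 (detour via n03); road
  # lengths exceed straight-line distances as real roads do
  coords <- rbind(c(0, 0), c(3000, 0), c(0, 2500))
  d32 <- sqrt(3000^2 + 2500^2)
  net <- make_network(coords, rbind(c(1, 2), c(1, 3), c(3, 2)),
                      stretch = c(5000 / 3000, 3000 / 2500, 4000 / d32))
  r <- shortest_route(net, c(0, 0), c(3000, 0), "car")
  expect_equal(r$nodes, c("n01", "n02"))
  expect_equal(r$length_m, 5000)
  expect_equal(r$travel_time_h, 5 / 45)
})

test_that("a square with a diagonal matches exhaustive enumeration", {
  coords <- rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000))
  net <- make_network(coords,
                      rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1), c(1, 3)))
  r <- shortest_route(net, c(0, 0), c(1000, 1000), "car")
  oracle <- brute_force_route(net, "n01", "n03")
  expect_equal(r$nodes, oracle$path)
  expect_equal(r$length_m, oracle$len)
  expect_equal(r$nodes, c("n01", "n03"))  # diagonal beats the two sides
})

test_that("equal-length alternatives break ties lexicographically", {
  coords <- rbind(c(0, 0), c(0, 1000), c(1000, 0), c(1000, 1000))
  net <- make_network(coords, rbind(c(1, 2), c(2, 4), c(1, 3), c(3, 4)))
  r <- shortest_route(net, c(0, 0), c(1000, 1000), "walk")
  expect_equal(r$nodes, c("n01", "n02", "n04"))
})

test_that("zero-length and impossible routes behave per contract", {
  coords <- rbind(c(0, 0), c(1000, 0))
  edges <- rbind(c(1, 2))
  net <- make_network(coords, edges)
  r <- shortest_route(net, c(10, 10), c(-5, 0), "car")
  expect_equal(r$length_m, 0)
  expect_equal(r$nodes, "n01")
  # a mode not permitted on the only edge
  net2 <- net
  net2$edges$modes <- "car"
  net2 <- transport_network(net2$nodes, net2$edges, net2$speeds)
  expect_error(shortest_route(net2, c(0, 0), c(1000, 0), "walk"),
               "no walk-permitted path")
  expect_error(shortest_route(net, c(0, 0), c(1000, 0), "hovercraft"),
               "unknown mode")
})

test_that("routing matches the brute-force oracle on random small graphs", {
  for (seed in 1:40) {
    net <- random_small_network(sample(c(3:8), 1), seed)
    ids <- net$nodes$id
    from <- ids[1]
    to <- ids[length(ids)]
    got <- shortest_route(net,
                          unlist(net$nodes[net$nodes$id == from, c("x", "y")]),
                          unlist(net$nodes[net$nodes$id == to, c("x", "y")]),
                          "bike")
    oracle <- brute_force_route(net, from, to)
    expect_equal(got$length_m, oracle$len, tolerance = 1e-9)
    expect_equal(got$nodes, oracle$path)
  }
})

test_that("diaries partition the day for every profile", {
  home <- c(100, 200)
  res <- build_diary(list(kind = "residential"), "a", home)
  expect_length(res$weekday, 1L)
  expect_equal(res$weekday[[1]][c("start", "end", "activity")],
               list(start = 0, end = 24, activity = "home"))
  expect_identical(res$weekday, res$weekend)

  set.seed(5)
  hm <- build_diary(list(kind = "homemaker", homemaker_buffer_km = 1), "a",
                    home)
  expect_silent(validate_diary(hm))
  # same pattern weekday and weekend
  expect_identical(hm$weekday, hm$weekend)

  coords <- rbind(c(0, 0), c(3000, 4000))
  net <- make_network(coords, rbind(c(1, 2)))
  rt <- shortest_route(net, c(0, 0), c(3000, 4000), "bike")
  cm <- build_diary(list(kind = "commuter", commuter_subcategory = "all"),
                    "a", c(0, 0), c(3000, 4000), rt)
  expect_silent(validate_diary(cm))
  acts <- vapply(cm$weekday, `[[`, character(1), "activity")
  expect_equal(acts, c("home", "travel", "work", "travel", "home"))
  # commute duration is the travel time rounded up to whole minutes
  t_cm <- cm$weekday[[2]]$end - cm$weekday[[2]]$start
  expect_equal(t_cm, ceiling(rt$travel_time_h * 60) / 60)
  expect_equal(vapply(cm$weekend, `[[`, character(1), "activity"), "home")
  expect_error(build_diary(list(kind = "commuter"), "a", home), "require")
})

test_that("homemaker excursions stay within the buffer radius", {
  home <- c(5000, 5000)
  set.seed(6)
  for (buffer in c(1, 5)) {
    max_d <- 0
    for (k in 1:500) {
      d <- build_diary(list(kind = "homemaker",
                            homemaker_buffer_km = buffer), "a", home)
      pts <- do.call(rbind, lapply(d$weekday, function(e)
        if (e$activity == "excursion") c(e$x, e$y)))
      dd <- sqrt((pts[, 1] - home[1])^2 + (pts[, 2] - home[2])^2)
      expect_true(all(dd <= buffer * 1000))
      max_d <- max(max_d, dd)
    }
    # a larger buffer is actually exercised
    expect_gt(max_d, buffer * 1000 * 0.8)
  }
})

test_that("realization counts follow the profile and runs are reproducible", {
  w <- test_world(23L)
  ag <- generate_population(w, demographics_config(known_work_frac = 0),
                            30L, 3L)
  commuter <- ag[ag$employment %in% c("fulltime", "parttime"), ][1, ]
  retired <- ag[ag$employment == "retired", ]
  s1 <- simulate_agent(commuter, w, n_realizations = 50L, seed = 9L)
  expect_length(s1$realizations, 50L)
  expect_true(all(vapply(s1$realizations,
                         function(r) r$mode %in% c("walk", "bike", "car",
                                                   "public_transport"),
                         logical(1))))
  s2 <- simulate_agent(commuter, w, n_realizations = 50L, seed = 9L)
  expect_identical(
    lapply(s1$realizations, function(r) r$work),
    lapply(s2$realizations, function(r) r$work))
  if (nrow(retired) > 0) {
    sr <- simulate_agent(retired[1, ], w, n_realizations = 50L, seed = 9L)
    expect_length(sr$realizations, 1L)
    expect_equal(sr$realizations[[1]]$diary$weekday[[1]]$activity, "home")
  }
})

test_that("route endpoints equal the snapped home and work nodes", {
  w <- test_world(23L)
  ag <- generate_population(w, demographics_config(known_work_frac = 0),
                            20L, 4L)
  commuter <- ag[ag$employment %in% c("fulltime", "parttime"), ][1, ]
  s <- simulate_agent(commuter, w, n_realizations = 5L, seed = 2L)
  nd <- w$network$nodes
  for (r in s$realizations) {
    home_node <- nd$id[which.min((nd$x - commuter$x)^2 +
                                   (nd$y - commuter$y)^2)]
    work_node <- nd$id[which.min((nd$x - r$work[1])^2 +
                                   (nd$y - r$work[2])^2)]
    expect_equal(r$route$nodes[1], home_node)
    expect_equal(r$route$nodes[length(r$route$nodes)], work_node)
  }
})

test_that("work-location marginal over many draws matches the O-D row", {
  w <- test_world(29L)
  ag <- agent_row(municipality = "m05")
  od <- w$od$all
  set.seed(8)
  n <- 10000
  dest <- character(n)
  for (k in seq_len(n)) {
    pt <- sample_work_location(ag, od, w$municipalities)
    for (m in w$municipalities) {
      if (point_in_polygon(pt[1], pt[2], m$polygon)) { dest[k] <- m$id; break }
    }
  }
  obs <- table(factor(dest, levels = od$destinations))
  expected <- od$prob["m05", ]
  keep <- expected > 1e-6
  chi <- suppressWarnings(
    stats::chisq.test(obs[keep], p = expected[keep] / sum(expected[keep])))
  expect_gt(chi$p.value, 0.01)
})
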