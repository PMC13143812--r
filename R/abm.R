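# Agent-based mobility model: profile assignment, work-location sampling from
# origin-destination matrices, Euclidean-distance mode choice, shortest-route
# computation on the transport network, activity-diary construction and the
# 50-realization Monte Carlo simulation per agent.

#' Assign a mobility profile to an agent
#'
#' Maps demographics to one of three profiles: employed (fulltime/parttime)
#' agents become commuters with a subcategory from (sex, SES); homemakers get
#' the homemaker profile with a configurable buffer radius; everyone else
#' (retired, other) is residential. Agents with sex `other` and employment
#' fall back to the pooled `all` commuter subcategory.
#'
#' @param agent one-row agent data frame (columns `sex`, `ses`, `employment`).
#' @param homemaker_buffer_km homemaker activity-space radius: 1, 5 or 10 km.
#' @return A list of class `mobility_profile` with `kind` and, as applicable,
#'   `commuter_subcategory` or `homemaker_buffer_km`.
#' @export
assign_profile <- function(agent, homemaker_buffer_km = 5) {
  stopifnot(homemaker_buffer_km %in% c(1, 5, 10))
  kind <- if (agent$employment %in% c("fulltime", "parttime")) "commuter"
  else if (agent$employment == "homemaker") "homemaker"
  else "residential"
  p <- list(kind = kind)
  if (kind == "commuter") {
    p$commuter_subcategory <- if (agent$sex %in% c("male", "female")) {
      ses_tag <- c(low = "lowSES", middle = "midSES", high = "highSES")[[agent$ses]]
      paste0(agent$sex, "_", ses_tag)
    } else "all"
  }
  if (kind == "homemaker") p$homemaker_buffer_km <- homemaker_buffer_km
  structure(p, class = "mobility_profile")
}

#' Sample a work location from an origin-destination matrix
#'
#' Draws a destination municipality from the O-D row of the agent's home
#' municipality, then a point uniformly inside the destination polygon
#' (rejection sampling). Consumes the current RNG stream; wrap in a seeded
#' stream for reproducibility.
#'
#' @param agent one-row agent data frame (`municipality` used).
#' @param od an [od_matrix()].
#' @param municipalities list of municipality objects (id, polygon).
#' @return Numeric `c(x, y)` work location.
#' @export
sample_work_location <- function(agent, od, municipalities) {
  row <- match(agent$municipality, od$origins)
  if (is.na(row))
    stop(sprintf("home municipality %s is not an O-D origin",
                 agent$municipality), call. = FALSE)
  j <- sample.int(length(od$destinations), 1L, prob = od$prob[row, ])
  dest_id <- od$destinations[j]
  poly <- NULL
  for (m in municipalities) if (m$id == dest_id) poly <- m$polygon
  if (is.null(poly))
    stop(sprintf("destination municipality %s not found", dest_id),
         call. = FALSE)
  sample_point_in_polygon(poly)
}

# ---- mode choice ----------------------------------------------------------

#' Default distance-band mode-choice table
#'
#' P(mode | Euclidean home-work distance band): short trips walk/bike
#' dominant, medium trips bike dominant, long trips car/public transport.
#' Bands are `[lower, upper)` with a boundary distance assigned to the upper
#' band; the last band is open-ended. Fully overridable.
#'
#' @return Data frame with `upper_m` (band upper bound, m) and one probability
#'   column per mode; rows sum to 1.
#' @export
default_mode_table <- function() {
  data.frame(
    upper_m = c(2000, 10000, 40000, Inf),
    walk = c(0.50, 0.05, 0.00, 0.00),
    bike = c(0.35, 0.45, 0.05, 0.00),
    car = c(0.10, 0.30, 0.60, 0.65),
    public_transport = c(0.05, 0.20, 0.35, 0.35)
  )
}

mode_band <- function(distance_m, mode_table) {
  # boundary distances go to the upper band: band i covers [upper_{i-1}, upper_i)
  findInterval(distance_m, mode_table$upper_m[-nrow(mode_table)]) + 1L
}

#' Draw a commuting mode from the distance-band table
#'
#' @param distance_m Euclidean home-work distance (m), >= 0.
#' @param mode_table a [default_mode_table()]-shaped table.
#' @return One of `"walk"`, `"bike"`, `"car"`, `"public_transport"`.
#' @export
assign_mode <- function(distance_m, mode_table = default_mode_table()) {
  stopifnot(distance_m >= 0)
  modes <- setdiff(names(mode_table), "upper_m")
  p <- as.numeric(mode_table[mode_band(distance_m, mode_table), modes])
  if (abs(sum(p) - 1) > 1e-8)
    stop("mode table rows must sum to 1", call. = FALSE)
  modes[sample.int(length(modes), 1L, prob = p)]
}

# deterministic modal (highest-probability) mode of the band; ties go to the
# first mode column
modal_mode <- function(distance_m, mode_table = default_mode_table()) {
  modes <- setdiff(names(mode_table), "upper_m")
  p <- as.numeric(mode_table[mode_band(distance_m, mode_table), modes])
  modes[which.max(p)]
}

# ---- routing --------------------------------------------------------------

nearest_node <- function(network, point) {
  d2 <- (network$nodes$x - point[1])^2 + (network$nodes$y - point[2])^2
  network$nodes$id[which.min(d2)]
}

#' Shortest route between two points across the transport network
#'
#' Snaps origin and destination to their nearest network nodes and returns
#' the minimum-total-length path over edges allowing the mode. When several
#' paths tie on length, the lexicographically smallest node-id sequence is
#' returned, making the result deterministic.
#'
#' @param network a [transport_network()].
#' @param origin,destination numeric `c(x, y)` points (m).
#' @param mode travel mode (must be permitted on the edges used).
#' @return A `route` object: node sequence, polyline coordinates, cumulative
#'   and total length (m), mode and travel time (h) at the mode speed.
#' @export
shortest_route <- function(network, origin, destination, mode = "car") {
  if (!mode %in% names(network$speeds))
    stop(sprintf("unknown mode '%s'", mode), call. = FALSE)
  allowed <- vapply(strsplit(network$edges$modes, "|", fixed = TRUE),
                    function(m) mode %in% m, logical(1))
  g <- if (all(allowed)) network$graph else
    igraph::subgraph_from_edges(network$graph, which(allowed),
                                delete.vertices = FALSE)
  from <- nearest_node(network, origin)
  to <- nearest_node(network, destination)
  node_xy <- as.matrix(network$nodes[, c("x", "y")])
  rownames(node_xy) <- network$nodes$id
  if (from == to) {
    return(make_route(from, node_xy[from, , drop = FALSE], numeric(0),
                      mode, network$speeds[[mode]]))
  }
  paths <- suppressWarnings(igraph::all_shortest_paths(
    g, from = from, to = to,
    weights = igraph::E(g)$length_m))$vpaths
  if (length(paths) == 0L)
    stop(sprintf("no %s-permitted path from %s to %s", mode, from, to),
         call. = FALSE)
  seqs <- lapply(paths, function(p) names(p))
  keys <- vapply(seqs, paste, character(1), collapse = " ")
  nodes <- seqs[[order(keys)[1L]]]
  coords <- node_xy[nodes, , drop = FALSE]
  # recover per-edge lengths from the graph (exact, not Euclidean)
  eids <- igraph::get_edge_ids(g, rep(nodes, each = 2)[-c(1, 2 * length(nodes))])
  edge_lengths <- igraph::E(g)$length_m[eids]
  make_route(nodes, coords, edge_lengths, mode, network$speeds[[mode]])
}

# ---- diary construction ---------------------------------------------------

#' Default commuter schedule
#'
#' Home until 08:00, commute, work until 17:00, commute home. The commute
#' duration is the route travel time rounded up to whole minutes.
#'
#' @param ... named overrides (`leave_home_h`, `leave_work_h`,
#'   `homemaker_excursions`, `homemaker_excursion_hours`).
#' @return A list of schedule parameters.
#' @export
schedule_config <- function(...) {
  cfg <- list(leave_home_h = 8, leave_work_h = 17,
              homemaker_excursions = 2L, homemaker_excursion_hours = 2)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Build an activity diary for a profile
#'
#' Residential: 24 h at home on both daytypes. Homemaker: home except
#' excursions at points uniform in the buffer disc around home, with the same
#' pattern on weekdays and weekend days. Commuter: on weekdays home / commute
#' / work / commute / home with commute duration equal to the route travel
#' time rounded up to whole minutes; at home all weekend. Homemaker excursion
#' points consume the current RNG stream.
#'
#' @param profile a [assign_profile()] result.
#' @param agent_id agent identifier.
#' @param home numeric `c(x, y)` home point.
#' @param work optional work point (commuters).
#' @param route optional `route` (commuters).
#' @param schedule a [schedule_config()].
#' @return An [activity_diary()].
#' @export
build_diary <- function(profile, agent_id, home, work = NULL, route = NULL,
                        schedule = schedule_config()) {
  home_entry <- function(s, e) diary_entry(s, e, "home", home[1], home[2])
  all_home <- list(home_entry(0, 24))
  if (profile$kind == "residential") {
    return(activity_diary(agent_id, all_home, all_home))
  }
  if (profile$kind == "homemaker") {
    r_m <- profile$homemaker_buffer_km * 1000
    k <- schedule$homemaker_excursions
    len <- schedule$homemaker_excursion_hours
    # uniform points in the buffer disc
    theta <- runif(k, 0, 2 * pi)
    rad <- r_m * sqrt(runif(k))
    pts <- cbind(home[1] + rad * cos(theta), home[2] + rad * sin(theta))
    entries <- list(home_entry(0, 10))
    t <- 10
    for (i in seq_len(k)) {
      entries <- c(entries, list(
        diary_entry(t, t + len, "excursion", pts[i, 1], pts[i, 2])))
      t <- t + len
      gap_end <- if (i < k) t + 2 else 24
      entries <- c(entries, list(home_entry(t, gap_end)))
      t <- gap_end
    }
    return(activity_diary(agent_id, entries, entries))
  }
  # commuter
  if (is.null(work) || is.null(route))
    stop("commuter diaries require a work point and a route", call. = FALSE)
  t_commute <- ceiling(route$travel_time_h * 60) / 60  # whole minutes, up
  s <- schedule
  if (s$leave_home_h + t_commute >= s$leave_work_h ||
      s$leave_work_h + t_commute >= 24)
    stop("commute too long for the configured schedule", call. = FALSE)
  weekday <- if (t_commute == 0) {
    # degenerate zero-length commute (work snaps to the home node)
    list(home_entry(0, s$leave_home_h),
         diary_entry(s$leave_home_h, s$leave_work_h, "work",
                     work[1], work[2]),
         home_entry(s$leave_work_h, 24))
  } else {
    speed_mps <- network_speed_mps(route)
    list(
      home_entry(0, s$leave_home_h),
      diary_entry(s$leave_home_h, s$leave_home_h + t_commute, "travel",
                  route = route, speed_mps = speed_mps),
      diary_entry(s$leave_home_h + t_commute, s$leave_work_h, "work",
                  work[1], work[2]),
      diary_entry(s$leave_work_h, s$leave_work_h + t_commute, "travel",
                  route = reverse_route(route), speed_mps = speed_mps),
      home_entry(s$leave_work_h + t_commute, 24))
  }
  activity_diary(agent_id, weekday, all_home)
}

network_speed_mps <- function(route) {
  if (route$travel_time_h <= 0) return(0)
  route$length_m / (route$travel_time_h * 3600)
}

reverse_route <- function(route) {
  k <- nrow(route$coords)
  speed_kmh <- if (route$travel_time_h > 0)
    route$length_m / route$travel_time_h / 1000 else 1
  make_route(rev(route$nodes), route$coords[k:1, , drop = FALSE],
             rev(diff(route$cumlen)), route$mode, speed_kmh)
}

# ---- Monte Carlo simulation ----------------------------------------------

#' Simulate mobility realizations for one agent
#'
#' Commuters receive `n_realizations` independent draws of (work location,
#' mode, shortest route, diary); homemakers receive `n_realizations` diaries
#' with freshly drawn excursion points; residential agents are deterministic
#' and receive a single realization. The RNG substream is derived from
#' (seed, agent id), so batch order never affects results.
#'
#' @param agent one-row agent data frame.
#' @param world a `mobair_world`.
#' @param n_realizations Monte Carlo draws for commuters (default 50).
#' @param seed integer root seed.
#' @param mode_table distance-band mode probabilities.
#' @param schedule a [schedule_config()].
#' @param homemaker_buffer_km buffer passed to [assign_profile()].
#' @return List of class `agent_realizations`: `agent_id`, `profile`, and
#'   `realizations`, each with `index`, `work`, `mode`, `route`, `diary`.
#' @export
simulate_agent <- function(agent, world, n_realizations = 50L, seed = 1L,
                           mode_table = default_mode_table(),
                           schedule = schedule_config(),
                           homemaker_buffer_km = 5) {
  profile <- assign_profile(agent, homemaker_buffer_km)
  home <- c(agent$x, agent$y)
  n <- switch(profile$kind, residential = 1L, n_realizations)
  reals <- with_seed(derive_seed(seed, paste0("abm:", agent$id)), {
    lapply(seq_len(n), function(i) {
      if (profile$kind == "commuter") {
        work <- sample_work_location(agent,
                                     world$od[[profile$commuter_subcategory]],
                                     world$municipalities)
        dist <- sqrt(sum((work - home)^2))
        mode <- assign_mode(dist, mode_table)
        # a routing failure annotates the realization but never aborts the
        # Monte Carlo batch
        tryCatch({
          route <- shortest_route(world$network, home, work, mode)
          diary <- build_diary(profile, agent$id, home, work, route,
                               schedule)
          list(index = i - 1L, work = work, mode = mode, route = route,
               diary = diary)
        }, error = function(e) {
          list(index = i - 1L, work = work, mode = mode, route = NULL,
               diary = NULL,
               error = sprintf("agent %s: %s", agent$id,
                               conditionMessage(e)))
        })
      } else {
        diary <- build_diary(profile, agent$id, home, schedule = schedule)
        list(index = i - 1L, work = NULL, mode = NULL, route = NULL,
             diary = diary)
      }
    })
  })
  structure(list(agent_id = agent$id, profile = profile,
                 realizations = reals),
            class = "agent_realizations")
}

#' @export
print.agent_realizations <- function(x, ...) {
  cat(sprintf("<agent_realizations> agent %s (%s): %d realization(s)\n",
              x$agent_id, x$profile$kind, length(x$realizations)))
  invisible(x)
}

#' Simulate all agents
#'
#' @param agents agent roster data frame.
#' @param world a `mobair_world`.
#' @inheritParams simulate_agent
#' @return Named list (by agent id) of [simulate_agent()] results.
#' @export
simulate_population <- function(agents, world, n_realizations = 50L,
                                seed = 1L,
                                mode_table = default_mode_table(),
                                schedule = schedule_config(),
                                homemaker_buffer_km = 5) {
  out <- lapply(seq_len(nrow(agents)), function(i)
    simulate_agent(agents[i, ], world, n_realizations, seed,
                   mode_table, schedule, homemaker_buffer_km))
  stats::setNames(out, agents$id)
}
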