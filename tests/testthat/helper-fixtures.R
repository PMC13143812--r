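# Shared fixtures: tiny surfaces, flat ratio sets, small transport networks,
# and the hand-rolled brute-force routing oracle (independent of igraph).

flat_ratios <- function(pollutant = "NO2", value = 1) {
  ratio <- matrix(value, 2, 24,
                  dimnames = list(c("weekday", "weekend"),
                                  sprintf("h%02d", 0:23)))
  structure(list(pollutant = pollutant, ratio = ratio),
            class = "diurnal_ratio_set")
}

# surface from a matrix, cells of 100 m anchored at (0, 0)
tiny_surface <- function(grid, pollutant = "NO2", cell_size = 100) {
  conc_surface(grid, 0, 0, cell_size, pollutant)
}

uniform_hset <- function(value = 20, n = 4, pollutant = "NO2") {
  apply_diurnal_ratios(tiny_surface(matrix(value, n, n), pollutant),
                       flat_ratios(pollutant))
}

# station with explicit weekday/weekend 24-h profiles, no noise
profile_station <- function(id, weekday, weekend, pollutant = "NO2",
                            location = c(0, 0)) {
  dt <- ifelse((seq_len(364) - 1) %% 7 < 5, "weekday", "weekend")
  hourly <- t(vapply(dt, function(d)
    if (d == "weekday") weekday else weekend, numeric(24)))
  station_series(id, pollutant, hourly, location)
}

# network from explicit node coordinates and edge index pairs; lengths may be
# inflated above Euclidean by `stretch` per edge
make_network <- function(coords, edge_idx, stretch = NULL,
                         speeds = c(walk = 5, bike = 15, car = 45,
                                    public_transport = 30)) {
  nodes <- data.frame(id = sprintf("n%02d", seq_len(nrow(coords))),
                      x = coords[, 1], y = coords[, 2],
                      stringsAsFactors = FALSE)
  eu <- sqrt((coords[edge_idx[, 1], 1] - coords[edge_idx[, 2], 1])^2 +
               (coords[edge_idx[, 1], 2] - coords[edge_idx[, 2], 2])^2)
  if (is.null(stretch)) stretch <- rep(1, nrow(edge_idx))
  edges <- data.frame(from = nodes$id[edge_idx[, 1]],
                      to = nodes$id[edge_idx[, 2]],
                      length_m = eu * stretch,
                      modes = "walk|bike|car|public_transport",
                      stringsAsFactors = FALSE)
  transport_network(nodes, edges, speeds)
}

# brute-force shortest path by exhaustive enumeration of all simple paths
# (depth-first), ties broken by lexicographic node-id sequence
brute_force_route <- function(network, from_id, to_id) {
  edges <- network$edges
  adj <- list()
  for (i in seq_len(nrow(edges))) {
    adj[[edges$from[i]]] <- rbind(adj[[edges$from[i]]],
                                  data.frame(to = edges$to[i],
                                             len = edges$length_m[i]))
    adj[[edges$to[i]]] <- rbind(adj[[edges$to[i]]],
                                data.frame(to = edges$from[i],
                                           len = edges$length_m[i]))
  }
  best <- list(len = Inf, path = NULL)
  walk <- function(node, visited, len) {
    if (node == to_id) {
      key <- paste(visited, collapse = " ")
      if (len < best$len - 1e-9 ||
          (abs(len - best$len) <= 1e-9 &&
           key < paste(best$path, collapse = " "))) {
        best <<- list(len = len, path = visited)
      }
      return(invisible())
    }
    nb <- adj[[node]]
    if (is.null(nb)) return(invisible())
    for (i in seq_len(nrow(nb))) {
      if (!(nb$to[i] %in% visited)) {
        walk(nb$to[i], c(visited, nb$to[i]), len + nb$len[i])
      }
    }
  }
  walk(from_id, from_id, 0)
  best
}

# random connected small graph: random tree plus extra random edges
random_small_network <- function(n_nodes, seed) {
  stopifnot(n_nodes >= 2, n_nodes <= 8)
  set.seed(seed)
  coords <- cbind(runif(n_nodes, 0, 1000), runif(n_nodes, 0, 1000))
  edge_idx <- cbind(2:n_nodes, vapply(2:n_nodes, function(i)
    sample.int(i - 1L, 1L), integer(1)))
  n_extra <- sample(0:2, 1)
  for (k in seq_len(n_extra)) {
    pair <- sort(sample.int(n_nodes, 2))
    if (!any(edge_idx[, 1] == pair[2] & edge_idx[, 2] == pair[1]) &&
        !any(edge_idx[, 1] == pair[1] & edge_idx[, 2] == pair[2])) {
      edge_idx <- rbind(edge_idx, pair)
    }
  }
  stretch <- 1 + runif(nrow(edge_idx), 0, 0.5)
  make_network(coords, edge_idx, stretch)
}

# small world for integration-style tests
test_world <- function(seed = 42L, grid_n = 60L, pm_margin = 600,
                       n_stations = 6L) {
  generate_world(world_config(
    grid_n = grid_n, n_municipalities_side = 3L, network_n = 8L,
    pollutants = list(
      NO2 = list(background = 12, amplitude = 22, noise_sd = 1.5,
                 n_stations = n_stations, edge_nodata_m = 0),
      PM25 = list(background = 12.5, amplitude = 6, noise_sd = 0.4,
                  n_stations = max(2L, n_stations %/% 2L),
                  edge_nodata_m = pm_margin))), seed)
}
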