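# Synthetic study world: pollution surfaces, background stations, transport
# network, municipalities, origin-destination matrices, agents and GPS tracks.
# Every generator is a pure function of (config, seed), so the whole world is
# reproducible bit-for-bit from a manifest.

#' Default synthetic-world configuration
#'
#' The defaults emulate an urban-gradient study region of 12 x 12 km on a
#' 100 m grid, with NO2 and PM2.5 annual surfaces built as background plus
#' Gaussian urban plumes plus spatially smoothed noise; concentration levels
#' are calibrated to typical central-European urban values (NO2 around
#' 12-35 ug/m3, PM2.5 around 12-19 ug/m3). NO2 uses 63 background stations and
#' PM2.5 uses 9. The PM2.5 surface carries a nodata margin inside the common
#' extent, so mobility can carry agents outside the PM2.5 modelling extent
#' while remaining inside the NO2 extent.
#'
#' @param ... named overrides of any default element.
#' @return A list of configuration values.
#' @export
world_config <- function(...) {
  cfg <- list(
    grid_n = 120L,            # cells per side
    cell_size = 100,          # m
    origin = c(0, 0),         # lower-left corner (projected m)
    crs = "EPSG:2056",
    n_centers = 3L,           # urban plume centres
    centers = NULL,           # optional explicit k x 2 matrix of centres
    plume_sigma_m = 2200,
    noise_range_m = 500,      # correlation range of the smoothed noise
    pollutants = list(
      NO2 = list(background = 12, amplitude = 22, noise_sd = 1.5,
                  n_stations = 63L, edge_nodata_m = 0),
      PM25 = list(background = 12.5, amplitude = 6, noise_sd = 0.4,
                  n_stations = 9L, edge_nodata_m = 0,
                  corner_nodata_m = 900)
    ),
    n_municipalities_side = 4L,
    gravity_lambda_m = 5000,
    network_n = 15L,          # lattice nodes per side
    network_diag_prob = 0.3,
    speeds = c(walk = 5, bike = 15, car = 45, public_transport = 30),  # km/h
    station_noise_sdlog = 0.15,
    urbanicity_power = 1.5
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Generate a complete synthetic world
#'
#' Builds every input the exposure pipeline needs: annual concentration
#' surfaces per pollutant, hourly background-station series, a connected
#' transport network, rectangular municipalities tiling the extent, and
#' gravity-model origin-destination matrices per commuter subcategory.
#' Identical (config, seed) pairs give bit-identical worlds.
#'
#' @param config a [world_config()] list.
#' @param seed integer seed.
#' @return An object of class `mobair_world` with elements `surfaces`
#'   (named list of [conc_surface()]), `stations` (named list of lists of
#'   [station_series()]), `network`, `municipalities`, `od`, `diurnal_shapes`,
#'   `crs`, `seed`, `config`.
#' @export
generate_world <- function(config = world_config(), seed = 1L) {
  if (config$grid_n <= 0 || config$cell_size <= 0)
    stop("grid_n and cell_size must be positive", call. = FALSE)
  with_seed(derive_seed(seed, "world"), {
    extent_m <- config$grid_n * config$cell_size
    centers <- config$centers
    if (is.null(centers)) {
      centers <- cbind(
        runif(config$n_centers, 0.2, 0.8) * extent_m + config$origin[1],
        runif(config$n_centers, 0.2, 0.8) * extent_m + config$origin[2])
    }
    surfaces <- list()
    for (pol in names(config$pollutants)) {
      surfaces[[pol]] <- generate_surface(config, pol, centers)
    }
    shapes <- default_diurnal_shapes()
    stations <- list()
    for (pol in names(config$pollutants)) {
      pc <- config$pollutants[[pol]]
      stations[[pol]] <- generate_station_series(
        surfaces[[pol]],
        diurnal_params = list(weekday = shapes$weekday,
                              weekend = shapes$weekend,
                              noise_sdlog = config$station_noise_sdlog),
        n_stations = pc$n_stations,
        seed = derive_seed(seed, paste0("stations:", pol)))
    }
    network <- generate_network(config, seed = derive_seed(seed, "network"))
    munis <- generate_municipalities(config, surfaces[[1L]])
    od <- generate_od_matrices(config, munis)
    world <- structure(
      list(surfaces = surfaces, stations = stations, network = network,
           municipalities = munis, od = od, diurnal_shapes = shapes,
           crs = config$crs, seed = seed, config = config),
      class = "mobair_world")
    world
  })
}

#' @export
print.mobair_world <- function(x, ...) {
  cat(sprintf("<mobair_world> seed %d, crs %s\n", x$seed, x$crs))
  cat(sprintf("  pollutants: %s\n", paste(names(x$surfaces), collapse = ", ")))
  cat(sprintf("  %d municipalities, %d network nodes, %d O-D matrices\n",
              length(x$municipalities), nrow(x$network$nodes), length(x$od)))
  invisible(x)
}

# background + Gaussian urban plumes + smoothed noise, floored at 0.01
generate_surface <- function(config, pollutant, centers) {
  pc <- config$pollutants[[pollutant]]
  n <- config$grid_n
  cs <- config$cell_size
  # cell centres; row 1 is the top row
  xc <- config$origin[1] + (seq_len(n) - 0.5) * cs
  yc <- config$origin[2] + (n - seq_len(n) + 0.5) * cs
  X <- matrix(xc, n, n, byrow = TRUE)
  Y <- matrix(yc, n, n)
  field <- matrix(pc$background, n, n)
  if (pc$amplitude > 0) {
    amp <- pc$amplitude * runif(nrow(centers), 0.5, 1)
    amp[1] <- pc$amplitude
    for (k in seq_len(nrow(centers))) {
      d2 <- (X - centers[k, 1])^2 + (Y - centers[k, 2])^2
      field <- field + amp[k] * exp(-d2 / (2 * config$plume_sigma_m^2))
    }
  }
  if (pc$noise_sd > 0) {
    field <- field + pc$noise_sd * smooth_noise(n, config$noise_range_m / cs)
  }
  field <- pmax(field, 0.01)
  if (pc$edge_nodata_m > 0) {
    margin <- abs(X - config$origin[1]) < pc$edge_nodata_m |
      abs(X - (config$origin[1] + n * cs)) < pc$edge_nodata_m |
      abs(Y - config$origin[2]) < pc$edge_nodata_m |
      abs(Y - (config$origin[2] + n * cs)) < pc$edge_nodata_m
    field[margin] <- NA_real_
  }
  corner <- pc$corner_nodata_m
  if (!is.null(corner) && corner > 0) {
    # a border-corner block outside this pollutant's modelling extent,
    # emulating a study region touching the edge of the national surface
    field[X < config$origin[1] + corner &
            Y < config$origin[2] + corner] <- NA_real_
  }
  conc_surface(field, config$origin[1], config$origin[2], cs, pollutant)
}

# unit-sd spatially correlated noise: box-blurred white noise, rescaled
smooth_noise <- function(n, range_cells) {
  z <- matrix(rnorm(n * n), n, n)
  w <- max(1L, round(range_cells))
  if (w > 1L) {
    k <- rep(1 / w, w)
    blur <- function(m) {
      m <- apply(m, 2, function(col) stats::filter(col, k, circular = TRUE))
      t(apply(t(m), 2, function(col) stats::filter(col, k, circular = TRUE)))
    }
    z <- blur(z)
    z <- z / stats::sd(as.vector(z))
  }
  z
}

# ---- diurnal shape curves -------------------------------------------------

#' Default weekday/weekend diurnal shape curves
#'
#' Weekday curve has morning and evening rush-hour peaks; weekend curve a
#' single flatter midday maximum at a lower level — the traffic-driven
#' patterns that motivate diurnal rescaling. Both curves are jointly scaled so
#' their (5/7, 2/7) time-weighted annual mean is exactly 1, which makes the
#' annual average of the rescaled hourly surfaces equal the annual surface.
#'
#' @return List with numeric `weekday` and `weekend` vectors of length 24.
#' @export
default_diurnal_shapes <- function() {
  h <- 0:23
  wd <- 0.8 + 0.55 * exp(-(h - 8)^2 / 8) + 0.5 * exp(-(h - 18)^2 / 10) -
    0.25 * exp(-(h - 3)^2 / 10)
  we <- 0.85 + 0.35 * exp(-(h - 14)^2 / 24) - 0.2 * exp(-(h - 4)^2 / 10)
  normalize_diurnal_shapes(list(weekday = wd, weekend = we))
}

#' Scale shape curves to unit time-weighted annual mean
#'
#' @param shapes list with `weekday` and `weekend` length-24 vectors.
#' @return The same list, jointly divided by its (5/7, 2/7)-weighted mean.
#' @export
normalize_diurnal_shapes <- function(shapes) {
  w <- WEEKDAY_WEIGHT * mean(shapes$weekday) +
    WEEKEND_WEIGHT * mean(shapes$weekend)
  shapes$weekday <- shapes$weekday / w
  shapes$weekend <- shapes$weekend / w
  shapes
}

#' Generate hourly background-station series
#'
#' Each station gets an annual base concentration read from the annual
#' surface at a random in-extent location, and 364 x 24 hourly values equal
#' to base x shape(daytype, hour) x multiplicative lognormal noise (unit
#' mean). The shape curves must have (5/7, 2/7) time-weighted mean 1, so the
#' diurnal ratios are recoverable by [compute_diurnal_ratios()] (exactly so
#' at zero noise).
#'
#' @param surface annual [conc_surface()] the stations sample.
#' @param diurnal_params list with length-24 `weekday` and `weekend` shape
#'   curves and `noise_sdlog` (sdlog of the lognormal noise; 0 = noiseless).
#' @param n_stations number of stations (>= 1).
#' @param seed integer seed.
#' @return List of [station_series()].
#' @export
generate_station_series <- function(surface, diurnal_params, n_stations,
                                    seed = 1L) {
  if (n_stations < 1L)
    stop("n_stations must be >= 1", call. = FALSE)
  shp <- diurnal_params
  wmean <- WEEKDAY_WEIGHT * mean(shp$weekday) + WEEKEND_WEIGHT * mean(shp$weekend)
  if (abs(wmean - 1) > 1e-6)
    stop("shape curves must have time-weighted mean 1; ",
         "see normalize_diurnal_shapes()", call. = FALSE)
  sdlog <- if (is.null(shp$noise_sdlog)) 0 else shp$noise_sdlog
  e <- surface_extent(surface)
  dt <- day_type(seq_len(DAYS_PER_YEAR))
  shape_mat <- rbind(weekday = shp$weekday, weekend = shp$weekend)[dt, ]
  dimnames(shape_mat) <- NULL
  with_seed(seed, {
    lapply(seq_len(n_stations), function(i) {
      repeat {
        loc <- c(runif(1, e["xmin"], e["xmax"]), runif(1, e["ymin"], e["ymax"]))
        base <- surface_lookup(surface, loc[1], loc[2])
        if (!is.na(base)) break
      }
      noise <- if (sdlog > 0) {
        matrix(exp(rnorm(DAYS_PER_YEAR * 24, -sdlog^2 / 2, sdlog)),
               DAYS_PER_YEAR, 24)
      } else 1
      station_series(sprintf("bs%03d", i), surface$pollutant,
                     base * shape_mat * noise, loc)
    })
  })
}

# ---- municipalities and O-D matrices --------------------------------------

# Rectangles tiling the extent; `size` is the mean concentration of the first
# pollutant over the rectangle, a proxy for urban mass used by the gravity
# model and by home sampling.
generate_municipalities <- function(config, size_surface) {
  m <- config$n_municipalities_side
  extent_m <- config$grid_n * config$cell_size
  step <- extent_m / m
  munis <- list()
  k <- 0L
  for (iy in seq_len(m)) {
    for (ix in seq_len(m)) {
      k <- k + 1L
      x0 <- config$origin[1] + (ix - 1) * step
      y0 <- config$origin[2] + (iy - 1) * step
      poly <- cbind(c(x0, x0 + step, x0 + step, x0, x0),
                    c(y0, y0, y0 + step, y0 + step, y0))
      centroid <- c(x0 + step / 2, y0 + step / 2)
      # average of surface cells inside the rectangle
      cs <- size_surface$cell_size
      cols <- which(config$origin[1] + (seq_len(config$grid_n) - 0.5) * cs > x0 &
                      config$origin[1] + (seq_len(config$grid_n) - 0.5) * cs < x0 + step)
      ycs <- config$origin[2] + (config$grid_n - seq_len(config$grid_n) + 0.5) * cs
      rows <- which(ycs > y0 & ycs < y0 + step)
      size <- mean(size_surface$grid[rows, cols], na.rm = TRUE)
      munis[[k]] <- list(id = sprintf("m%02d", k), polygon = poly,
                         centroid = centroid, size = size)
    }
  }
  munis
}

# commuter subcategories of the ABM's commuter profile
COMMUTER_SUBCATS <- c("all", "male", "female",
                      "male_lowSES", "male_midSES", "male_highSES",
                      "female_lowSES", "female_midSES", "female_highSES")

#' Origin-destination matrix
#'
#' @param origins,destinations character ids of municipalities.
#' @param prob row-stochastic matrix of destination probabilities.
#' @return An object of class `od_matrix`.
#' @export
od_matrix <- function(origins, destinations, prob) {
  prob <- as.matrix(prob)
  if (any(prob < 0))
    stop("O-D probabilities must be non-negative", call. = FALSE)
  prob <- prob / rowSums(prob)
  dimnames(prob) <- list(origins, destinations)
  structure(list(origins = origins, destinations = destinations, prob = prob),
            class = "od_matrix")
}

# gravity model: P(j | i) proportional to size_j * exp(-d_ij / lambda);
# subcategories differ by a fixed lambda multiplier (commuting-range contrast)
generate_od_matrices <- function(config, munis) {
  ids <- vapply(munis, `[[`, character(1), "id")
  cent <- do.call(rbind, lapply(munis, `[[`, "centroid"))
  size <- vapply(munis, `[[`, numeric(1), "size")
  d <- as.matrix(stats::dist(cent))
  mult <- c(all = 1, male = 1.15, female = 0.9,
            male_lowSES = 0.85, male_midSES = 1.1, male_highSES = 1.35,
            female_lowSES = 0.7, female_midSES = 0.9, female_highSES = 1.1)
  od <- lapply(COMMUTER_SUBCATS, function(sc) {
    lambda <- config$gravity_lambda_m * mult[[sc]]
    w <- sweep(exp(-d / lambda), 2, size, `*`)
    od_matrix(ids, ids, w)
  })
  names(od) <- COMMUTER_SUBCATS
  od
}

# ---- transport network ----------------------------------------------------

# jittered lattice; edge lengths are exact Euclidean distances, so every edge
# satisfies length >= straight-line distance (with equality)
generate_network <- function(config, seed = 1L) {
  with_seed(seed, {
    n <- config$network_n
    extent_m <- config$grid_n * config$cell_size
    step <- extent_m / (n + 1)
    gx <- config$origin[1] + step * seq_len(n)
    gy <- config$origin[2] + step * seq_len(n)
    nodes <- expand.grid(x = gx, y = gy)
    nodes$x <- nodes$x + runif(nrow(nodes), -0.25, 0.25) * step
    nodes$y <- nodes$y + runif(nrow(nodes), -0.25, 0.25) * step
    nodes$id <- sprintf("n%03d", seq_len(nrow(nodes)))
    idx <- function(ix, iy) (iy - 1L) * n + ix
    from <- integer(0); to <- integer(0)
    for (iy in seq_len(n)) {
      for (ix in seq_len(n)) {
        if (ix < n) { from <- c(from, idx(ix, iy)); to <- c(to, idx(ix + 1L, iy)) }
        if (iy < n) { from <- c(from, idx(ix, iy)); to <- c(to, idx(ix, iy + 1L)) }
        if (ix < n && iy < n && runif(1) < config$network_diag_prob) {
          from <- c(from, idx(ix, iy)); to <- c(to, idx(ix + 1L, iy + 1L))
        }
      }
    }
    len <- sqrt((nodes$x[from] - nodes$x[to])^2 + (nodes$y[from] - nodes$y[to])^2)
    edges <- data.frame(from = nodes$id[from], to = nodes$id[to],
                        length_m = len,
                        modes = "walk|bike|car|public_transport",
                        stringsAsFactors = FALSE)
    transport_network(nodes[, c("id", "x", "y")], edges, config$speeds)
  })
}

#' Construct a transport network
#'
#' @param nodes data frame with columns `id`, `x`, `y` (projected m).
#' @param edges data frame with columns `from`, `to`, `length_m`, `modes`
#'   (pipe-separated allowed modes); each length must be >= the Euclidean
#'   distance between its endpoints.
#' @param speeds named km/h vector for walk, bike, car, public_transport.
#' @return An object of class `transport_network` carrying an igraph graph.
#' @export
transport_network <- function(nodes, edges, speeds) {
  stopifnot(all(c("walk", "bike", "car", "public_transport") %in% names(speeds)),
            all(speeds > 0))
  xy <- stats::setNames(seq_len(nrow(nodes)), nodes$id)
  eu <- sqrt((nodes$x[xy[edges$from]] - nodes$x[xy[edges$to]])^2 +
               (nodes$y[xy[edges$from]] - nodes$y[xy[edges$to]])^2)
  if (any(edges$length_m <= 0) || any(edges$length_m < eu - 1e-6))
    stop("edge lengths must be positive and >= Euclidean distance",
         call. = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  structure(list(nodes = nodes, edges = edges, speeds = speeds, graph = g),
            class = "transport_network")
}

#' @export
print.transport_network <- function(x, ...) {
  cat(sprintf("<transport_network> %d nodes, %d edges, connected: %s\n",
              nrow(x$nodes), nrow(x$edges),
              igraph::is_connected(x$graph)))
  invisible(x)
}

# ---- population -----------------------------------------------------------

#' Default demographic marginals
#'
#' Marginal probabilities shaped like an urban tracking-campaign roster:
#' female-majority sex split, a 40-60 age mode, a high-SES majority and a
#' mostly employed population.
#'
#' @param ... named overrides (`sex`, `age`, `ses`, `employment`,
#'   `known_work_frac`).
#' @return A list of marginals; each probability vector sums to 1.
#' @export
demographics_config <- function(...) {
  cfg <- list(
    sex = c(male = 0.398, female = 0.6, other = 0.002),
    age = c("18-40" = 0.18, "40-60" = 0.55, "60+" = 0.27),
    ses = c(low = 0.048, middle = 0.189, high = 0.763),
    employment = c(fulltime = 0.60, parttime = 0.237, homemaker = 0.055,
                   retired = 0.09, other = 0.018),
    known_work_frac = 0.55
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Generate an agent roster
#'
#' Homes are sampled over municipalities with probability proportional to
#' municipality size raised to `urbanicity_power` (urban oversampling),
#' uniformly within the municipality. Demographics are drawn independently
#' from the configured marginals. A `known_work_frac` fraction of employed
#' agents receives a fixed known workplace drawn once from their O-D row.
#'
#' @param world a `mobair_world`.
#' @param demographics a [demographics_config()] list.
#' @param n number of agents.
#' @param seed integer seed.
#' @return Data frame with one row per agent: id, home coordinates,
#'   municipality, sex, age, ses, employment, known workplace (NA if none).
#' @export
generate_population <- function(world, demographics = demographics_config(),
                                n = 500L, seed = 1L) {
  for (m in c("sex", "age", "ses", "employment")) {
    if (abs(sum(demographics[[m]]) - 1) > 1e-8)
      stop(sprintf("demographic marginal '%s' must sum to 1", m),
           call. = FALSE)
  }
  if (n == 0L) {
    return(data.frame(id = character(0), x = numeric(0), y = numeric(0),
                      municipality = character(0), sex = character(0),
                      age = numeric(0), ses = character(0),
                      employment = character(0),
                      known_work_x = numeric(0), known_work_y = numeric(0),
                      stringsAsFactors = FALSE))
  }
  munis <- world$municipalities
  size <- vapply(munis, `[[`, numeric(1), "size")
  w <- size^world$config$urbanicity_power
  with_seed(derive_seed(seed, "population"), {
    mi <- sample.int(length(munis), n, replace = TRUE, prob = w)
    homes <- t(vapply(mi, function(i)
      sample_point_in_polygon(munis[[i]]$polygon), numeric(2)))
    draw <- function(marg) names(marg)[
      sample.int(length(marg), n, replace = TRUE, prob = marg)]
    band <- draw(demographics$age)
    age <- ifelse(band == "18-40", runif(n, 18, 40),
                  ifelse(band == "40-60", runif(n, 40, 60), runif(n, 60, 85)))
    agents <- data.frame(
      id = sprintf("a%04d", seq_len(n)),
      x = homes[, 1], y = homes[, 2],
      municipality = vapply(munis, `[[`, character(1), "id")[mi],
      sex = draw(demographics$sex), age = age,
      ses = draw(demographics$ses), employment = draw(demographics$employment),
      known_work_x = NA_real_, known_work_y = NA_real_,
      stringsAsFactors = FALSE)
    employed <- agents$employment %in% c("fulltime", "parttime")
    gets_work <- employed & runif(n) < demographics$known_work_frac
    for (i in which(gets_work)) {
      prof <- assign_profile(agents[i, ])
      wp <- sample_work_location(agents[i, ],
                                 world$od[[prof$commuter_subcategory]],
                                 munis)
      agents$known_work_x[i] <- wp[1]
      agents$known_work_y[i] <- wp[2]
    }
    agents
  })
}

# ---- geometry helpers -----------------------------------------------------

# ray-casting point-in-polygon; poly is a closed (first == last) k x 2 matrix
point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly) - 1L
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# uniform point inside a polygon by rejection from its bounding box
sample_point_in_polygon <- function(poly) {
  bx <- range(poly[, 1]); by <- range(poly[, 2])
  repeat {
    p <- c(runif(1, bx[1], bx[2]), runif(1, by[1], by[2]))
    if (point_in_polygon(p[1], p[2], poly)) return(p)
  }
}

# ---- GPS tracks -----------------------------------------------------------

#' Default GPS sampling configuration
#'
#' Two acquisition cadences: a high-precision tracker logging every 20 s and
#' a phone app logging every 3-4 min, over a 14-day campaign.
#'
#' @param ... named overrides (`tracker_interval_s`, `app_interval_range_s`,
#'   `duration_days`).
#' @return A list of sampling parameters.
#' @export
sampling_config <- function(...) {
  cfg <- list(tracker_interval_s = 20,
              app_interval_range_s = c(180, 240),
              duration_days = 14)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Generate GPS tracks from ground-truth diaries
#'
#' Samples each agent's true diary trajectory at the tracker cadence (exact
#' 20 s grid) and the app cadence (random 3-4 min intervals), adds isotropic
#' Gaussian positional noise of `noise_sd` metres to each point, and gives a
#' `dropout_rate` fraction of agents an empty tracker stream (device failure;
#' the app stream is retained). The campaign starts on a Monday at 00:00;
#' timestamps are seconds since campaign start.
#'
#' @param agents agent roster (rows used: `id`).
#' @param diaries named list (by agent id) of [activity_diary()] ground truth.
#' @param sampling a [sampling_config()].
#' @param noise_sd positional noise standard deviation per axis (m), >= 0.
#' @param dropout_rate fraction of agents losing their tracker stream.
#' @param seed integer seed.
#' @return Named list (by agent id) of objects of class `gps_track`: lists
#'   with `agent_id`, `duration_days`, and `app`/`tracker` data frames of
#'   (t, x, y).
#' @export
generate_tracks <- function(agents, diaries, sampling = sampling_config(),
                            noise_sd = 10, dropout_rate = 0, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  n <- nrow(agents)
  dropped <- with_seed(derive_seed(seed, "dropout"), {
    sample.int(n, round(dropout_rate * n))
  })
  total_s <- sampling$duration_days * 86400
  tracks <- vector("list", n)
  for (i in seq_len(n)) {
    id <- agents$id[i]
    diary <- diaries[[id]]
    if (is.null(diary)) stop("no diary for agent ", id, call. = FALSE)
    tracks[[i]] <- with_seed(derive_seed(seed, paste0("track:", id)), {
      n_tr <- ceiling(total_s / sampling$tracker_interval_s)
      t_tracker <- (seq_len(n_tr) - 1) * sampling$tracker_interval_s
      t_tracker <- t_tracker[t_tracker < total_s]
      gaps <- runif(ceiling(total_s / sampling$app_interval_range_s[1]),
                    sampling$app_interval_range_s[1],
                    sampling$app_interval_range_s[2])
      t_app <- cumsum(gaps)
      t_app <- c(0, t_app[t_app < total_s])
      sample_points <- function(t) {
        pos <- matrix(NA_real_, length(t), 2)
        dt <- time_daytype(t)
        for (d in unique(dt)) {
          sel <- dt == d
          pos[sel, ] <- diary_position(diary, d, t[sel] %% 86400)
        }
        if (noise_sd > 0) {
          pos <- pos + matrix(rnorm(2 * length(t), 0, noise_sd), ncol = 2)
        }
        data.frame(t = t, x = pos[, 1], y = pos[, 2])
      }
      app <- sample_points(t_app)
      tracker <- if (i %in% dropped) {
        data.frame(t = numeric(0), x = numeric(0), y = numeric(0))
      } else sample_points(t_tracker)
      structure(list(agent_id = id, duration_days = sampling$duration_days,
                     app = app, tracker = tracker),
                class = "gps_track")
    })
  }
  stats::setNames(tracks, agents$id)
}

#' @export
print.gps_track <- function(x, ...) {
  cat(sprintf("<gps_track> agent %s: %d app + %d tracker points over %g days\n",
              x$agent_id, nrow(x$app), nrow(x$tracker), x$duration_days))
  invisible(x)
}
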