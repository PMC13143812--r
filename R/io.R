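# File interchange: ESRI ASCII grids for rasters, CSV for tables and tracks,
# GeoJSON for network and municipalities, GPX for tracks, JSON for manifests.
# All writers are deterministic (fixed number formatting), so identical
# objects produce byte-identical files.

fmt_num <- function(x) {
  out <- sprintf("%.12g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write a concentration surface as an ESRI ASCII grid
#'
#' @param surface a [conc_surface()].
#' @param path output file path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(surface, path) {
  g <- surface$grid
  g[is.na(g)] <- -9999
  header <- c(
    sprintf("ncols %d", ncol(g)),
    sprintf("nrows %d", nrow(g)),
    sprintf("xllcorner %.12g", surface$xmin),
    sprintf("yllcorner %.12g", surface$ymin),
    sprintf("cellsize %.12g", surface$cell_size),
    "NODATA_value -9999")
  body <- apply(g, 1, function(r) paste(sprintf("%.12g", r), collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @param pollutant pollutant code to attach.
#' @return A [conc_surface()].
#' @export
read_esri_ascii <- function(path, pollutant = "NO2") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[k]]))
      stop(sprintf("malformed ESRI ASCII grid: missing header '%s' in %s",
                   k, path), call. = FALSE)
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop(sprintf("malformed ESRI ASCII grid: expected %d values, found %d",
                 hdr$ncols * hdr$nrows, length(vals)), call. = FALSE)
  g <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) g[g == hdr$nodata_value] <- NA_real_
  conc_surface(g, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, pollutant)
}

# ---- CSV tables -----------------------------------------------------------

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L)
    stop(sprintf("%s: missing mandatory column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}

write_csv_det <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- fmt_num(df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Write / read an agent roster CSV
#'
#' @param agents agent roster data frame.
#' @param path CSV path.
#' @return The path (write) or the roster (read).
#' @export
write_agents_csv <- function(agents, path) write_csv_det(agents, path)

#' @rdname write_agents_csv
#' @export
read_agents_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("id", "x", "y", "municipality", "sex", "age",
                        "ses", "employment"), basename(path))
  df
}

#' Write / read origin-destination matrices as CSV
#'
#' Long format: one row per (subcategory, origin, destination) with its
#' probability.
#'
#' @param od named list of [od_matrix()] by commuter subcategory.
#' @param path CSV path.
#' @return The path (write) or the named list (read).
#' @export
write_od_csv <- function(od, path) {
  rows <- lapply(names(od), function(sc) {
    m <- od[[sc]]
    data.frame(subcategory = sc,
               origin_id = rep(m$origins, times = length(m$destinations)),
               destination_id = rep(m$destinations, each = length(m$origins)),
               probability = as.vector(m$prob),
               stringsAsFactors = FALSE)
  })
  write_csv_det(do.call(rbind, rows), path)
}

#' @rdname write_od_csv
#' @export
read_od_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("subcategory", "origin_id", "destination_id",
                        "probability"), basename(path))
  out <- list()
  for (sc in unique(df$subcategory)) {
    sub <- df[df$subcategory == sc, ]
    origins <- sort(unique(sub$origin_id))
    dests <- sort(unique(sub$destination_id))
    prob <- matrix(0, length(origins), length(dests),
                   dimnames = list(origins, dests))
    prob[cbind(sub$origin_id, sub$destination_id)] <- sub$probability
    out[[sc]] <- od_matrix(origins, dests, prob)
  }
  out
}

#' Write / read station series as CSV
#'
#' Long format: station_id, x, y, day (1-364), hour (0-23), value.
#'
#' @param stations list of [station_series()].
#' @param path CSV path.
#' @param pollutant pollutant code (read).
#' @return The path (write) or the station list (read).
#' @export
write_stations_csv <- function(stations, path) {
  rows <- lapply(stations, function(s) {
    data.frame(station_id = s$station_id, x = s$location[1],
               y = s$location[2],
               day = rep(seq_len(DAYS_PER_YEAR), times = 24),
               hour = rep(0:23, each = DAYS_PER_YEAR),
               value = as.vector(s$hourly), stringsAsFactors = FALSE)
  })
  write_csv_det(do.call(rbind, rows), path)
}

#' @rdname write_stations_csv
#' @export
read_stations_csv <- function(path, pollutant = "NO2") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("station_id", "x", "y", "day", "hour", "value"),
                  basename(path))
  lapply(split(df, df$station_id), function(sub) {
    hourly <- matrix(NA_real_, DAYS_PER_YEAR, 24)
    hourly[cbind(sub$day, sub$hour + 1L)] <- sub$value
    station_series(sub$station_id[1], pollutant, hourly,
                   c(sub$x[1], sub$y[1]))
  })
}

# ---- tracks: CSV and GPX --------------------------------------------------

# campaign epoch: a Monday, so timestamp day-of-week matches the synthetic
# calendar (day 1 = Monday)
TRACK_EPOCH <- "2023-01-02T00:00:00Z"

track_time_iso <- function(t_sec) {
  format(as.POSIXct(TRACK_EPOCH, tz = "UTC",
                    format = "%Y-%m-%dT%H:%M:%OSZ") + t_sec,
         "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

track_time_seconds <- function(iso) {
  as.numeric(difftime(
    as.POSIXct(iso, tz = "UTC", format = "%Y-%m-%dT%H:%M:%OSZ"),
    as.POSIXct(TRACK_EPOCH, tz = "UTC", format = "%Y-%m-%dT%H:%M:%OSZ"),
    units = "secs"))
}

#' Write / read merged GPS tracks as CSV
#'
#' Columns: agent_id, timestamp (ISO-8601 UTC), x, y, source.
#'
#' @param tracks named list of [merge_tracks()] results by agent id.
#' @param path CSV path.
#' @return The path (write) or a named list of merged tracks (read).
#' @export
write_tracks_csv <- function(tracks, path) {
  if (length(tracks) == 0L) {
    return(write_csv_det(
      data.frame(agent_id = character(0), timestamp = character(0),
                 x = numeric(0), y = numeric(0), source = character(0)),
      path))
  }
  rows <- lapply(names(tracks), function(id) {
    tr <- tracks[[id]]
    data.frame(agent_id = id, timestamp = track_time_iso(tr$t),
               x = tr$x, y = tr$y, source = tr$source,
               stringsAsFactors = FALSE)
  })
  write_csv_det(do.call(rbind, rows), path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("agent_id", "timestamp", "x", "y", "source"),
                  basename(path))
  df$t <- track_time_seconds(df$timestamp)
  lapply(split(df, df$agent_id), function(sub) {
    out <- sub[order(sub$t), c("t", "x", "y", "source")]
    rownames(out) <- NULL
    structure(out, class = c("merged_track", "data.frame"))
  })
}

#' Write / read one track as GPX
#'
#' The synthetic world lives on a projected metric plane, so the projected
#' x/y coordinates are stored verbatim in the GPX `lon`/`lat` attributes
#' (documented convention for synthetic data; no geodetic meaning).
#'
#' @param track data frame with `t`, `x`, `y`.
#' @param path GPX path.
#' @return The path (write) or a t/x/y data frame sorted by time (read).
#' @export
write_gpx <- function(track, path) {
  doc <- xml2::xml_new_root("gpx", version = "1.1", creator = "mobair")
  trk <- xml2::xml_add_child(doc, "trk")
  seg <- xml2::xml_add_child(trk, "trkseg")
  iso <- track_time_iso(track$t)
  for (i in seq_len(nrow(track))) {
    pt <- xml2::xml_add_child(seg, "trkpt",
                              lat = sprintf("%.12g", track$y[i]),
                              lon = sprintf("%.12g", track$x[i]))
    xml2::xml_add_child(pt, "time", iso[i])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname write_gpx
#' @export
read_gpx <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  pts <- xml2::xml_find_all(doc, ".//trkpt")
  out <- data.frame(
    t = track_time_seconds(xml2::xml_text(xml2::xml_find_all(pts, "time"))),
    x = as.numeric(xml2::xml_attr(pts, "lon")),
    y = as.numeric(xml2::xml_attr(pts, "lat")))
  out[order(out$t), , drop = FALSE]
}

# ---- GeoJSON --------------------------------------------------------------

#' Write / read the transport network as GeoJSON
#'
#' Node features are Points (property `id`); edge features are LineStrings
#' with properties `from`, `to`, `length_m`, `modes`. Mode speeds are stored
#' in the top-level `properties`.
#'
#' @param network a [transport_network()].
#' @param path GeoJSON path.
#' @return The path (write) or a [transport_network()] (read).
#' @export
write_network_geojson <- function(network, path) {
  node_feats <- lapply(seq_len(nrow(network$nodes)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(network$nodes$x[i],
                                         network$nodes$y[i])),
         properties = list(id = network$nodes$id[i]))
  })
  xy <- stats::setNames(seq_len(nrow(network$nodes)), network$nodes$id)
  edge_feats <- lapply(seq_len(nrow(network$edges)), function(i) {
    e <- network$edges[i, ]
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = list(
                           c(network$nodes$x[xy[e$from]],
                             network$nodes$y[xy[e$from]]),
                           c(network$nodes$x[xy[e$to]],
                             network$nodes$y[xy[e$to]]))),
         properties = list(from = e$from, to = e$to,
                           length_m = e$length_m, modes = e$modes))
  })
  obj <- list(type = "FeatureCollection",
              properties = list(speeds = as.list(network$speeds)),
              features = c(node_feats, edge_feats))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network_geojson
#' @export
read_network_geojson <- function(path) {
  obj <- jsonlite::read_json(path)
  is_node <- vapply(obj$features,
                    function(f) f$geometry$type == "Point", logical(1))
  nodes <- do.call(rbind, lapply(obj$features[is_node], function(f) {
    data.frame(id = f$properties$id,
               x = f$geometry$coordinates[[1]],
               y = f$geometry$coordinates[[2]], stringsAsFactors = FALSE)
  }))
  edges <- do.call(rbind, lapply(obj$features[!is_node], function(f) {
    data.frame(from = f$properties$from, to = f$properties$to,
               length_m = f$properties$length_m, modes = f$properties$modes,
               stringsAsFactors = FALSE)
  }))
  speeds <- unlist(obj$properties$speeds)
  transport_network(nodes, edges, speeds)
}

#' Write / read municipalities as GeoJSON
#'
#' Polygon features with properties `id` and `size`.
#'
#' @param municipalities list of municipality objects.
#' @param path GeoJSON path.
#' @return The path (write) or the municipality list (read).
#' @export
write_municipalities_geojson <- function(municipalities, path) {
  feats <- lapply(municipalities, function(m) {
    ring <- lapply(seq_len(nrow(m$polygon)),
                   function(i) c(m$polygon[i, 1], m$polygon[i, 2]))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = list(id = m$id, size = m$size))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_municipalities_geojson
#' @export
read_municipalities_geojson <- function(path) {
  obj <- jsonlite::read_json(path)
  lapply(obj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    poly <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    list(id = f$properties$id, polygon = poly,
         centroid = c(mean(poly[-nrow(poly), 1]),
                      mean(poly[-nrow(poly), 2])),
         size = f$properties$size)
  })
}

#' Write a run manifest
#'
#' Records the configuration, seed and package version so any artifact can
#' be reproduced bit-identically.
#'
#' @param config pipeline or world configuration list.
#' @param seed root seed.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, seed, path) {
  jsonlite::write_json(
    list(package = "mobair",
         version = as.character(utils::packageVersion("mobair")),
         seed = seed, config = config),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
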