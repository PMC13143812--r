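# Activity diaries and routes.
#
# A diary holds, per daytype (weekday/weekend), an ordered list of entries
# that partition [0, 24) hours exactly. Stationary entries (home, work,
# excursion) carry a point; travel entries carry a route polyline and a speed,
# so the agent's position at any time of day is defined.

diary_entry <- function(start, end, activity, x = NA_real_, y = NA_real_,
                        route = NULL, speed_mps = NA_real_) {
  list(start = start, end = end, activity = activity,
       x = x, y = y, route = route, speed_mps = speed_mps)
}

#' Construct an activity diary
#'
#' @param agent_id agent identifier.
#' @param weekday,weekend ordered lists of diary entries; each entry has
#'   `start`/`end` hours, an `activity` in home/work/travel/excursion, and a
#'   point or route. Entries must partition `[0, 24)` with no gaps/overlaps.
#' @return An object of class `activity_diary`.
#' @export
activity_diary <- function(agent_id, weekday, weekend) {
  d <- structure(list(agent_id = agent_id,
                      weekday = weekday, weekend = weekend),
                 class = "activity_diary")
  validate_diary(d)
  d
}

#' Check the partition invariant of a diary
#'
#' Errors unless, for both daytypes, entries are ordered, start at 0, end at
#' 24, and each entry starts exactly where the previous one ends.
#'
#' @param diary an [activity_diary()].
#' @return The diary, invisibly.
#' @export
validate_diary <- function(diary) {
  for (dt in c("weekday", "weekend")) {
    entries <- diary[[dt]]
    if (length(entries) == 0L)
      stop(sprintf("diary %s has no %s entries", diary$agent_id, dt),
           call. = FALSE)
    starts <- vapply(entries, `[[`, numeric(1), "start")
    ends <- vapply(entries, `[[`, numeric(1), "end")
    if (abs(starts[1]) > 1e-9 || abs(ends[length(ends)] - 24) > 1e-9 ||
        any(abs(starts[-1] - ends[-length(ends)]) > 1e-9) ||
        any(ends <= starts))
      stop(sprintf("diary %s: %s entries do not partition [0, 24)",
                   diary$agent_id, dt), call. = FALSE)
  }
  invisible(diary)
}

#' @export
print.activity_diary <- function(x, ...) {
  cat(sprintf("<activity_diary> agent %s\n", x$agent_id))
  for (dt in c("weekday", "weekend")) {
    acts <- vapply(x[[dt]], function(e)
      sprintf("%.2f-%.2f %s", e$start, e$end, e$activity), character(1))
    cat(sprintf("  %s: %s\n", dt, paste(acts, collapse = ", ")))
  }
  invisible(x)
}

# ---- routes ---------------------------------------------------------------

# A route is a polyline over network nodes: coords (k x 2), cumulative network
# distance at each vertex, total length, mode and travel time at mode speed.
make_route <- function(nodes, coords, edge_lengths, mode, speed_kmh) {
  cumlen <- c(0, cumsum(edge_lengths))
  length_m <- cumlen[length(cumlen)]
  structure(list(nodes = nodes, coords = coords, cumlen = cumlen,
                 length_m = length_m, mode = mode,
                 travel_time_h = length_m / (speed_kmh * 1000)),
            class = "route")
}

#' @export
print.route <- function(x, ...) {
  cat(sprintf("<route> %d nodes, %.0f m by %s (%.1f min)\n",
              length(x$nodes), x$length_m, x$mode, x$travel_time_h * 60))
  invisible(x)
}

# Position along a route at network distance d (vectorised, clamped to ends).
route_point <- function(route, d) {
  d <- pmin(pmax(d, 0), route$length_m)
  if (nrow(route$coords) == 1L)
    return(cbind(rep(route$coords[1, 1], length(d)),
                 rep(route$coords[1, 2], length(d))))
  seg <- findInterval(d, route$cumlen, rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1L), nrow(route$coords) - 1L)
  seg_len <- route$cumlen[seg + 1L] - route$cumlen[seg]
  frac <- ifelse(seg_len > 0, (d - route$cumlen[seg]) / seg_len, 0)
  route$coords[seg, , drop = FALSE] +
    frac * (route$coords[seg + 1L, , drop = FALSE] -
              route$coords[seg, , drop = FALSE])
}

#' True position of an agent at given times of day
#'
#' Evaluates the diary's ground-truth trajectory: stationary entries return
#' their point, travel entries interpolate along the route polyline at the
#' entry's travel speed.
#'
#' @param diary an [activity_diary()].
#' @param daytype `"weekday"` or `"weekend"`.
#' @param tod_sec numeric vector of times of day in seconds `[0, 86400)`.
#' @return A 2-column matrix of x/y coordinates (m).
#' @export
diary_position <- function(diary, daytype, tod_sec) {
  entries <- diary[[daytype]]
  starts <- vapply(entries, `[[`, numeric(1), "start") * 3600
  idx <- findInterval(tod_sec, starts)
  idx[idx < 1L] <- 1L
  out <- matrix(NA_real_, length(tod_sec), 2)
  for (i in unique(idx)) {
    e <- entries[[i]]
    sel <- idx == i
    if (e$activity == "travel") {
      d <- e$speed_mps * (tod_sec[sel] - e$start * 3600)
      out[sel, ] <- route_point(e$route, d)
    } else {
      out[sel, 1] <- e$x
      out[sel, 2] <- e$y
    }
  }
  out
}
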