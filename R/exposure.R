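# Long-term average exposure per agent, pollutant and metric:
#   RES    - residential address only
#   ABM    - agent-based mobility, mean/SD over Monte Carlo realizations
#   ABMkWP - agent-based mobility with the known workplace (deterministic)
#   GPS    - time-weighted mean over the merged GPS track
# All metrics are annual (5/7 weekday + 2/7 weekend) time-weighted means of
# concentrations sampled from the long-term hourly surfaces.

#' Exposure record
#'
#' @param agent_id,pollutant,metric identifiers; metric one of RES, ABM,
#'   ABMkWP, GPS.
#' @param mean long-term mean exposure (micrograms/m^3) or `NA` (missing).
#' @param sd SD across realizations (ABM with > 1 realizations), else `NA`.
#' @param n_realizations realizations used (0 where not applicable).
#' @param reason missingness reason code (`""` when not missing).
#' @return One-row data frame of class `exposure_record`.
#' @export
exposure_record <- function(agent_id, pollutant, metric, mean,
                            sd = NA_real_, n_realizations = 0L,
                            reason = "") {
  stopifnot(metric %in% c("RES", "ABM", "ABMkWP", "GPS"))
  structure(data.frame(agent_id = agent_id, pollutant = pollutant,
                       metric = metric, mean = mean, sd = sd,
                       n_realizations = n_realizations, reason = reason,
                       stringsAsFactors = FALSE),
            class = c("exposure_record", "data.frame"))
}

#' Long-term exposure of an activity diary
#'
#' Integrates the diary against the hourly surfaces. Stationary entries
#' contribute duration x concentration at their point for each hour they
#' cover; travel entries are discretised at 1-minute steps along the route at
#' the entry's speed, each step contributing its duration x the concentration
#' at the step position and hour. The annual value is the (5/7, 2/7) weighted
#' mean of the weekday and weekend 24-h time-weighted means. Any missing
#' lookup (out of extent or nodata) makes the whole diary exposure `NA`.
#'
#' @param diary an [activity_diary()].
#' @param hset an `hourly_surface_set`.
#' @return Exposure (micrograms/m^3) or `NA`.
#' @export
diary_exposure <- function(diary, hset) {
  validate_diary(diary)
  day_mean <- function(daytype) {
    total <- 0
    for (e in diary[[daytype]]) {
      if (e$activity == "travel") {
        # 1-minute steps, evaluated at step midpoints
        n_steps <- ceiling((e$end - e$start) * 60 - 1e-9)
        step_ends <- e$start + pmin(seq_len(n_steps) / 60, e$end - e$start)
        step_starts <- e$start + (seq_len(n_steps) - 1) / 60
        mid <- (step_starts + step_ends) / 2
        pos <- route_point(e$route, e$speed_mps * (mid - e$start) * 3600)
        conc <- sample_concentration(hset, pos[, 1], pos[, 2], daytype,
                                     floor(mid) %% 24)
        total <- total + sum((step_ends - step_starts) * conc)
      } else {
        hours <- seq(floor(e$start), ceiling(e$end - 1e-9) - 1)
        dur <- pmin(e$end, hours + 1) - pmax(e$start, hours)
        conc <- sample_concentration(hset, e$x, e$y, daytype, hours %% 24)
        total <- total + sum(dur * conc)
      }
    }
    total / 24
  }
  WEEKDAY_WEIGHT * day_mean("weekday") + WEEKEND_WEIGHT * day_mean("weekend")
}

#' Residential (RES) exposure
#'
#' Exposure of the 24-h at-home diary: the time-weighted mean of the 48
#' hourly surface values at the home address. Identical, by construction, to
#' the ABM exposure of a residential-profile agent.
#'
#' @param agent one-row agent data frame.
#' @param hset an `hourly_surface_set`.
#' @return An [exposure_record()] with metric `RES`; missing (with reason
#'   `out_of_extent`) if the home cell has no data.
#' @export
residential_exposure <- function(agent, hset) {
  diary <- build_diary(list(kind = "residential"), agent$id,
                       c(agent$x, agent$y))
  val <- diary_exposure(diary, hset)
  exposure_record(agent$id, hset$pollutant, "RES", val,
                  reason = if (is.na(val)) "out_of_extent" else "")
}

#' ABM (simulated-workplace) exposure
#'
#' Mean and SD of the diary exposures of the agent's Monte Carlo
#' realizations. If any realization's exposure is missing (a route or work
#' location out of the modelling extent), the whole record is missing — the
#' out-of-extent exclusion behaviour.
#'
#' @param sim an `agent_realizations` from [simulate_agent()].
#' @param hset an `hourly_surface_set`.
#' @return An [exposure_record()] with metric `ABM`; `sd` is the sample
#'   (n-1) SD when more than one realization is used.
#' @export
abm_exposure <- function(sim, hset) {
  if (length(sim$realizations) < 1L)
    stop("at least one realization is required", call. = FALSE)
  vals <- vapply(sim$realizations, function(r) {
    if (!is.null(r$error)) NA_real_ else diary_exposure(r$diary, hset)
  }, numeric(1))
  n <- length(vals)
  if (anyNA(vals)) {
    failed <- any(vapply(sim$realizations,
                         function(r) !is.null(r$error), logical(1)))
    return(exposure_record(sim$agent_id, hset$pollutant, "ABM", NA_real_,
                           n_realizations = n,
                           reason = if (failed) "realization_error"
                           else "realization_out_of_extent"))
  }
  exposure_record(sim$agent_id, hset$pollutant, "ABM", mean(vals),
                  sd = if (n > 1L) stats::sd(vals) else NA_real_,
                  n_realizations = n)
}

#' Known-workplace (ABMkWP) exposure
#'
#' A single deterministic realization built from the agent's reported work
#' location: the mode is the modal (highest-probability) mode of the
#' distance band, the route the shortest path, the diary the standard
#' commuter diary. No RNG is consumed.
#'
#' @param agent one-row agent data frame with `known_work_x`/`known_work_y`.
#' @param hset an `hourly_surface_set`.
#' @param world a `mobair_world` (network used).
#' @param mode_table distance-band mode probabilities.
#' @param schedule a [schedule_config()].
#' @return An [exposure_record()] with metric `ABMkWP`, or `NULL` (with a
#'   message) when no known workplace is present.
#' @export
known_workplace_exposure <- function(agent, hset, world,
                                     mode_table = default_mode_table(),
                                     schedule = schedule_config()) {
  if (is.na(agent$known_work_x)) {
    message("agent ", agent$id, " has no known workplace; skipped")
    return(NULL)
  }
  home <- c(agent$x, agent$y)
  work <- c(agent$known_work_x, agent$known_work_y)
  dist <- sqrt(sum((work - home)^2))
  mode <- modal_mode(dist, mode_table)
  route <- shortest_route(world$network, home, work, mode)
  diary <- build_diary(list(kind = "commuter", commuter_subcategory = "all"),
                       agent$id, home, work, route, schedule)
  val <- diary_exposure(diary, hset)
  exposure_record(agent$id, hset$pollutant, "ABMkWP", val,
                  n_realizations = 1L,
                  reason = if (is.na(val)) "out_of_extent" else "")
}

# ---- GPS tracks -----------------------------------------------------------

#' Merge app and tracker point streams
#'
#' Union of both streams sorted by timestamp. When an app point falls within
#' 10 s of a tracker point, the tracker point (higher precision) is kept and
#' the app point dropped; the result has strictly increasing timestamps.
#'
#' @param app_points,tracker_points data frames with columns `t` (seconds),
#'   `x`, `y`.
#' @return Data frame (t, x, y, source) of class `merged_track`.
#' @export
merge_tracks <- function(app_points, tracker_points) {
  if (nrow(app_points) + nrow(tracker_points) == 0L)
    stop("both point streams are empty", call. = FALSE)
  keep_app <- rep(TRUE, nrow(app_points))
  if (nrow(tracker_points) > 0L && nrow(app_points) > 0L) {
    ts <- sort(tracker_points$t)
    i <- findInterval(app_points$t, ts)
    d_lo <- ifelse(i >= 1L, app_points$t - ts[pmax(i, 1L)], Inf)
    d_hi <- ifelse(i < length(ts), ts[pmin(i + 1L, length(ts))] - app_points$t,
                   Inf)
    keep_app <- pmin(d_lo, d_hi) > 10
  }
  out <- rbind(
    if (any(keep_app))
      cbind(app_points[keep_app, c("t", "x", "y")], source = "app"),
    if (nrow(tracker_points) > 0L)
      cbind(tracker_points[, c("t", "x", "y")], source = "tracker"))
  out <- out[order(out$t, out$source != "tracker"), , drop = FALSE]
  out <- out[!duplicated(out$t), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("merged_track", "data.frame"))
}

#' GPS-track exposure
#'
#' Time-weighted mean concentration over a merged track. Each inter-point
#' interval contributes its duration, capped at `cap_min` minutes to guard
#' against device gaps, times the mean of its two endpoint concentrations;
#' each concentration is looked up at its point for its own timestamp's
#' (daytype, hour). For a two-point track this reduces to the equal-weight
#' mean of the two points. When the campaign `span` is supplied, leading and
#' trailing stubs (before the first and after the last point) are carried at
#' the nearest point's concentration, also capped, so a complete-coverage
#' track weights every hour of the campaign exactly. Intervals with an
#' out-of-extent endpoint are dropped from numerator and denominator; the
#' record is missing when less than `min_coverage` of the capped track time
#' remains.
#'
#' @param track a [merge_tracks()] result (or any t/x/y data frame).
#' @param hset an `hourly_surface_set`.
#' @param agent_id agent identifier for the record.
#' @param cap_min interval cap in minutes (default 30).
#' @param min_coverage minimum covered time fraction for a valid record.
#' @param span optional `c(start, end)` campaign window in seconds.
#' @return An [exposure_record()] with metric `GPS`.
#' @export
track_exposure <- function(track, hset, agent_id = "?", cap_min = 30,
                           min_coverage = 0.5, span = NULL) {
  if (nrow(track) < 1L) stop("track is empty", call. = FALSE)
  if (nrow(track) < 2L && is.null(span)) {
    return(exposure_record(agent_id, hset$pollutant, "GPS", NA_real_,
                           reason = "track_too_short"))
  }
  cap <- cap_min * 60
  n <- nrow(track)
  ann <- surface_lookup(hset$annual, track$x, track$y)
  # capped intervals [a, b): mean of the two endpoint annual values; span
  # stubs carry the nearest point's value alone
  a <- track$t[-n]
  b <- pmin(track$t[-1], a + cap)
  v <- (ann[-n] + ann[-1]) / 2
  if (!is.null(span)) {
    a <- c(max(span[1], track$t[1] - cap), a, track$t[n])
    b <- c(track$t[1], b, min(span[2], track$t[n] + cap))
    v <- c(ann[1], v, ann[n])
  }
  keep <- b > a
  a <- a[keep]; b <- b[keep]; v <- v[keep]
  # split every interval at hour boundaries so each piece is scaled by its
  # own (daytype, hour) diurnal ratio
  first_slot <- floor(a / 3600)
  last_slot <- ceiling(b / 3600) - 1
  n_pieces <- last_slot - first_slot + 1
  idx <- rep(seq_along(a), n_pieces)
  slot <- first_slot[idx] + (sequence(n_pieces) - 1)
  pa <- pmax(a[idx], slot * 3600)
  pb <- pmin(b[idx], (slot + 1) * 3600)
  slot_sec <- slot * 3600
  cval <- v[idx] * ratio_at(hset$ratios, time_daytype(slot_sec),
                            time_hour(slot_sec))
  w <- pb - pa
  ok <- !is.na(cval)
  coverage <- if (sum(w) > 0) sum(w[ok]) / sum(w) else 0
  if (!any(ok) || coverage < min_coverage) {
    return(exposure_record(agent_id, hset$pollutant, "GPS", NA_real_,
                           reason = "insufficient_coverage"))
  }
  exposure_record(agent_id, hset$pollutant, "GPS",
                  sum(w[ok] * cval[ok]) / sum(w[ok]))
}

#' Exposure records for a whole cohort
#'
#' Convenience wrapper assembling RES / ABM / ABMkWP / GPS records per agent
#' and pollutant into one long data frame.
#'
#' @param agents agent roster.
#' @param sims [simulate_population()] result (or `NULL` to skip ABM).
#' @param hsets named list (by pollutant) of `hourly_surface_set`s.
#' @param world a `mobair_world` (needed for ABMkWP).
#' @param tracks [generate_tracks()] result (or `NULL` to skip GPS).
#' @return Data frame of exposure records.
#' @export
cohort_exposures <- function(agents, sims, hsets, world, tracks = NULL) {
  rows <- list()
  for (pol in names(hsets)) {
    hset <- hsets[[pol]]
    for (i in seq_len(nrow(agents))) {
      ag <- agents[i, ]
      rows[[length(rows) + 1L]] <- residential_exposure(ag, hset)
      if (!is.null(sims))
        rows[[length(rows) + 1L]] <- abm_exposure(sims[[ag$id]], hset)
      if (!is.na(ag$known_work_x)) {
        rows[[length(rows) + 1L]] <-
          known_workplace_exposure(ag, hset, world)
      }
      if (!is.null(tracks)) {
        tr <- tracks[[ag$id]]
        merged <- merge_tracks(tr$app, tr$tracker)
        rows[[length(rows) + 1L]] <-
          track_exposure(merged, hset, ag$id,
                         span = c(0, tr$duration_days * 86400))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}
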