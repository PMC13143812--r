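#' Gridded annual-average concentration surface
#'
#' Constructs a regular raster of annual-average pollutant concentrations on a
#' projected (metric) coordinate system. The grid is stored row-major from the
#' top row, i.e. `grid[1, 1]` is the north-west cell; the raster origin
#' (`xmin`, `ymin`) is the lower-left corner of the extent. Cells with no data
#' (outside the modelling extent) are `NA`.
#'
#' @param grid numeric matrix of concentrations (micrograms/m^3); `NA` = nodata.
#' @param xmin,ymin coordinates (m) of the lower-left corner of the extent.
#' @param cell_size cell edge length in metres (> 0).
#' @param pollutant pollutant code, e.g. `"NO2"` or `"PM25"`.
#' @return An object of class `conc_surface`.
#' @export
conc_surface <- function(grid, xmin, ymin, cell_size, pollutant) {
  if (!is.matrix(grid) || !is.numeric(grid))
    stop("`grid` must be a numeric matrix", call. = FALSE)
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number", call. = FALSE)
  if (any(grid <= 0, na.rm = TRUE))
    stop("all non-nodata concentrations must be > 0", call. = FALSE)
  structure(
    list(grid = grid, xmin = xmin, ymin = ymin,
         cell_size = cell_size, pollutant = pollutant),
    class = "conc_surface"
  )
}

#' Image plot of a concentration surface
#'
#' @param x a [conc_surface()].
#' @param ... passed to [graphics::image()].
#' @export
plot.conc_surface <- function(x, ...) {
  e <- surface_extent(x)
  xs <- seq(e["xmin"], e["xmax"], length.out = ncol(x$grid) + 1)
  ys <- seq(e["ymin"], e["ymax"], length.out = nrow(x$grid) + 1)
  graphics::image(xs, ys, t(x$grid[nrow(x$grid):1, , drop = FALSE]),
                  xlab = "x (m)", ylab = "y (m)",
                  main = sprintf("%s annual mean (ug/m3)", x$pollutant),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  invisible(x)
}

#' Extent of a concentration surface
#'
#' @param surface a [conc_surface()].
#' @return Named numeric vector `c(xmin, ymin, xmax, ymax)` in metres.
#' @export
surface_extent <- function(surface) {
  c(xmin = surface$xmin,
    ymin = surface$ymin,
    xmax = surface$xmin + ncol(surface$grid) * surface$cell_size,
    ymax = surface$ymin + nrow(surface$grid) * surface$cell_size)
}

#' @export
print.conc_surface <- function(x, ...) {
  e <- surface_extent(x)
  cat(sprintf("<conc_surface> %s: %d x %d cells of %g m\n",
              x$pollutant, nrow(x$grid), ncol(x$grid), x$cell_size))
  cat(sprintf("  extent: [%g, %g] x [%g, %g] m\n", e["xmin"], e["xmax"],
              e["ymin"], e["ymax"]))
  v <- x$grid[!is.na(x$grid)]
  cat(sprintf("  values: %.2f - %.2f ug/m3 (%d nodata cells)\n",
              min(v), max(v), sum(is.na(x$grid))))
  invisible(x)
}

# Vectorised nearest-cell lookup. Returns NA for out-of-extent points and for
# nodata cells; never interpolates. Points exactly on the top/right edge are
# outside (cells are [x0, x0 + cs) x [y0, y0 + cs)).
surface_lookup <- function(surface, x, y) {
  cs <- surface$cell_size
  col <- floor((x - surface$xmin) / cs) + 1L
  row_from_bottom <- floor((y - surface$ymin) / cs) + 1L
  row <- nrow(surface$grid) + 1L - row_from_bottom
  ok <- col >= 1L & col <= ncol(surface$grid) &
    row >= 1L & row <= nrow(surface$grid)
  out <- rep(NA_real_, length(x))
  if (any(ok)) out[ok] <- surface$grid[cbind(row[ok], col[ok])]
  out
}

# ---- synthetic 364-day calendar -------------------------------------------
# Day 1 is a Monday; days 1-5 of each 7-day block are weekdays. 52 exact weeks
# give 260 weekdays and 104 weekend days, so the weekday/weekend annual time
# weights are exactly 5/7 and 2/7.

DAYS_PER_YEAR <- 364L
WEEKDAY_WEIGHT <- 5 / 7
WEEKEND_WEIGHT <- 2 / 7

day_type <- function(day) {
  ifelse((day - 1L) %% 7L < 5L, "weekday", "weekend")
}

# daytype/hour of a timestamp in seconds since year start (hour 0-23)
time_daytype <- function(t_sec) day_type(floor(t_sec / 86400) + 1L)
time_hour <- function(t_sec) floor((t_sec %% 86400) / 3600)

#' Background-station hourly concentration series
#'
#' One synthetic year (364 days = 52 exact weeks) of hourly concentrations at
#' a background monitoring station.
#'
#' @param station_id station identifier.
#' @param pollutant pollutant code.
#' @param hourly numeric 364 x 24 matrix (day x hour) of concentrations
#'   (micrograms/m^3), all > 0; `NA` entries mark missing hours.
#' @param location numeric `c(x, y)` in projected metres.
#' @return An object of class `station_series`.
#' @export
station_series <- function(station_id, pollutant, hourly, location) {
  if (!is.matrix(hourly) || nrow(hourly) != DAYS_PER_YEAR || ncol(hourly) != 24L)
    stop("`hourly` must be a 364 x 24 matrix", call. = FALSE)
  if (any(hourly <= 0, na.rm = TRUE))
    stop("all concentrations must be > 0", call. = FALSE)
  structure(
    list(station_id = station_id, pollutant = pollutant,
         hourly = hourly, location = location),
    class = "station_series"
  )
}

#' Diurnal ratios from background-station series
#'
#' Computes the 48 hour-by-daytype ratios that rescale an annual-average
#' surface to long-term hourly weekday/weekend surfaces. For each (daytype,
#' hour) cell the ratio is the grand mean, pooled over all stations and all
#' matching calendar hours, of the measured concentration, divided by the
#' grand annual mean over all stations and all hours:
#' \deqn{Ratio_{annual-hr} = C_{BS-hr} / C_{BS-annual}}
#' Missing hours (`NA`) are excluded from both numerator and denominator.
#'
#' For a complete 364-day calendar the time-weighted mean of the 48 ratios is
#' identically 1: `(5/7) * mean(weekday) + (2/7) * mean(weekend) == 1`.
#'
#' @param stations list of [station_series()] sharing one pollutant.
#' @return An object of class `diurnal_ratio_set`: list with `pollutant` and
#'   `ratio`, a 2 x 24 matrix with rows `weekday`, `weekend`.
#' @export
compute_diurnal_ratios <- function(stations) {
  if (length(stations) < 1L)
    stop("at least one station series is required", call. = FALSE)
  pol <- unique(vapply(stations, function(s) s$pollutant, character(1)))
  if (length(pol) != 1L)
    stop("all station series must share one pollutant", call. = FALSE)
  dt <- day_type(seq_len(DAYS_PER_YEAR))
  stacked <- do.call(rbind, lapply(stations, `[[`, "hourly"))
  dt_all <- rep(dt, times = length(stations))
  annual <- mean(stacked, na.rm = TRUE)
  if (!is.finite(annual) || annual == 0)
    stop("annual mean of station series is zero or undefined", call. = FALSE)
  ratio <- rbind(
    weekday = colMeans(stacked[dt_all == "weekday", , drop = FALSE], na.rm = TRUE),
    weekend = colMeans(stacked[dt_all == "weekend", , drop = FALSE], na.rm = TRUE)
  ) / annual
  colnames(ratio) <- sprintf("h%02d", 0:23)
  structure(list(pollutant = pol, ratio = ratio), class = "diurnal_ratio_set")
}

#' @export
print.diurnal_ratio_set <- function(x, ...) {
  cat(sprintf("<diurnal_ratio_set> %s\n", x$pollutant))
  cat(sprintf("  weekday: %.3f - %.3f, weekend: %.3f - %.3f\n",
              min(x$ratio["weekday", ]), max(x$ratio["weekday", ]),
              min(x$ratio["weekend", ]), max(x$ratio["weekend", ])))
  w <- WEEKDAY_WEIGHT * mean(x$ratio["weekday", ]) +
    WEEKEND_WEIGHT * mean(x$ratio["weekend", ])
  cat(sprintf("  time-weighted mean: %.9f\n", w))
  invisible(x)
}

#' Rescale an annual surface to hourly weekday/weekend surfaces
#'
#' Applies the diurnal ratios to an annual-average surface: the long-term
#' hourly surface for (daytype, hour) is the annual grid multiplied cell-wise
#' by the scalar ratio for that (daytype, hour)
#' (\eqn{C_{P,t} = C_{P,annual} \cdot Ratio_{annual,t}}). Nodata cells are
#' preserved. The 48 grids are an exact scalar family of the annual grid, so
#' the set is stored as (annual surface, ratio set); [hourly_surface()]
#' materialises any member grid and [sample_concentration()] looks up points.
#'
#' @param annual a [conc_surface()] of annual averages.
#' @param ratios a `diurnal_ratio_set` for the same pollutant.
#' @return An object of class `hourly_surface_set`.
#' @export
apply_diurnal_ratios <- function(annual, ratios) {
  stopifnot(inherits(annual, "conc_surface"),
            inherits(ratios, "diurnal_ratio_set"))
  if (!identical(annual$pollutant, ratios$pollutant))
    stop(sprintf("pollutant mismatch: surface is %s, ratios are %s",
                 annual$pollutant, ratios$pollutant), call. = FALSE)
  if (any(ratios$ratio <= 0))
    stop("all diurnal ratios must be > 0", call. = FALSE)
  structure(list(pollutant = annual$pollutant, annual = annual,
                 ratios = ratios),
            class = "hourly_surface_set")
}

#' Materialise one member surface of an hourly set
#'
#' @param hset an `hourly_surface_set` from [apply_diurnal_ratios()].
#' @param daytype `"weekday"` or `"weekend"`.
#' @param hour integer hour 0-23.
#' @return A [conc_surface()] whose grid is annual x ratio(daytype, hour).
#' @export
hourly_surface <- function(hset, daytype, hour) {
  r <- ratio_at(hset$ratios, daytype, hour)
  s <- hset$annual
  s$grid <- s$grid * r
  s
}

ratio_at <- function(ratios, daytype, hour) {
  if (!all(daytype %in% c("weekday", "weekend")))
    stop("daytype must be 'weekday' or 'weekend'", call. = FALSE)
  if (any(hour < 0 | hour > 23 | hour != floor(hour)))
    stop("hour must be an integer in 0..23", call. = FALSE)
  ratios$ratio[cbind(daytype, sprintf("h%02d", hour))]
}

#' Space-time point lookup in an hourly surface set
#'
#' Nearest-cell (containing-cell) lookup, no interpolation: the value returned
#' is the annual value of the containing cell times the (daytype, hour) ratio.
#' Points outside the extent or on nodata cells yield `NA` (missing); the
#' function never extrapolates. All arguments are vectorised and recycled to a
#' common length.
#'
#' @param hset an `hourly_surface_set`.
#' @param x,y coordinates in projected metres.
#' @param daytype `"weekday"`/`"weekend"` (vectorised).
#' @param hour integer hour(s) 0-23.
#' @return Numeric vector of concentrations (micrograms/m^3), `NA` = missing.
#' @export
sample_concentration <- function(hset, x, y, daytype, hour) {
  n <- max(length(x), length(y), length(daytype), length(hour))
  x <- rep_len(x, n); y <- rep_len(y, n)
  daytype <- rep_len(daytype, n); hour <- rep_len(hour, n)
  surface_lookup(hset$annual, x, y) * ratio_at(hset$ratios, daytype, hour)
}
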