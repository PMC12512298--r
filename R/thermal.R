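# Hourly ambient temperature reconstruction. Observations carry only a date,
# an hour, and coordinates; climate tables carry daily minima/maxima per
# 25-km grid cell. The diel model is the classic sine/log-decay
# formulation (Linvill 1990): daytime warming follows a sine whose period is
# stretched by 4 hours past the daylength, nighttime cooling follows a
# logarithmic decay from the sunset temperature toward the next morning's
# minimum. Local clock hour is treated as local solar hour; the bias from
# ignoring position-in-timezone is under an hour and identical across
# comparisons.

EARTH_RADIUS_M <- 6371000

#' Specify a regular square grid for climate lookup
#'
#' Coordinates are projected with a local equirectangular projection about
#' `reference_latitude`; cells are half-open squares `[edge, edge + size)`
#' of side `cell_size` meters anchored at `origin` (projected meters).
#'
#' @param origin numeric length 2: projected (x, y) of the grid anchor, in
#'   meters (conventionally the data bounding-box minimum).
#' @param reference_latitude latitude (degrees) at which east-west meters
#'   are measured.
#' @param cell_size cell side in meters (default 25 km).
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(origin, reference_latitude, cell_size = 25000) {
  stopifnot(length(origin) == 2L, is.finite(origin), cell_size > 0,
            is.finite(reference_latitude))
  structure(list(origin = as.numeric(origin),
                 reference_latitude = as.numeric(reference_latitude),
                 cell_size = as.numeric(cell_size)),
            class = "grid_spec")
}

#' Build a grid spec from observed coordinates
#'
#' Uses the data centroid latitude as projection reference and the
#' projected bounding-box minimum as origin. The origin is floored to a
#' whole meter and moved 1 m further out so that the extreme records --
#' which would otherwise sit exactly on a cell edge -- keep a stable cell
#' id under round-trips of the coordinates through text formats.
#'
#' @param latitude,longitude coordinate vectors (degrees).
#' @param cell_size cell side in meters.
#' @return a [grid_spec()].
#' @export
make_grid_spec <- function(latitude, longitude, cell_size = 25000) {
  ref <- mean(range(latitude))
  p <- project_equirect(latitude, longitude, ref)
  grid_spec(origin = floor(c(min(p$x), min(p$y))) - 1,
            reference_latitude = ref, cell_size = cell_size)
}

project_equirect <- function(latitude, longitude, reference_latitude) {
  list(x = EARTH_RADIUS_M * (longitude * pi / 180) *
         cos(reference_latitude * pi / 180),
       y = EARTH_RADIUS_M * (latitude * pi / 180))
}

#' Assign coordinates to grid cells
#'
#' @param latitude,longitude coordinate vectors (degrees).
#' @param grid a [grid_spec()].
#' @return a data frame with integer columns `cell_col`, `cell_row`.
#' @export
assign_grid_cell <- function(latitude, longitude, grid) {
  stopifnot(inherits(grid, "grid_spec"),
            all(is.finite(latitude)), all(is.finite(longitude)))
  p <- project_equirect(latitude, longitude, grid$reference_latitude)
  data.frame(
    cell_col = as.integer(floor((p$x - grid$origin[1]) / grid$cell_size)),
    cell_row = as.integer(floor((p$y - grid$origin[2]) / grid$cell_size)))
}

#' Latitude of a grid row's cell centers
#' @param cell_row integer row index (as from [assign_grid_cell()]).
#' @param grid a [grid_spec()].
#' @return latitude in degrees.
#' @export
cell_center_latitude <- function(cell_row, grid) {
  y <- (cell_row + 0.5) * grid$cell_size + grid$origin[2]
  y / EARTH_RADIUS_M * 180 / pi
}

#' Sunrise, sunset and daylength from solar geometry
#'
#' Declination `delta = 23.45 deg * sin(2*pi*(284 + doy)/365)`; the hour
#' angle `acos(-tan(lat) tan(delta))` is clamped so polar day/night return
#' 24 h/0 h daylength instead of NaN. Times are local solar hours, centered
#' on solar noon at 12.
#'
#' @param latitude degrees.
#' @param day_of_year 1--365 (366 is mapped to 365).
#' @return a data frame with `sunrise`, `sunset`, `daylength` (hours).
#' @export
solar_times <- function(latitude, day_of_year) {
  doy <- pmin(day_of_year, 365)
  decl <- 23.45 * pi / 180 * sin(2 * pi * (284 + doy) / 365)
  arg <- pmin(pmax(-tan(latitude * pi / 180) * tan(decl), -1), 1)
  omega <- acos(arg)
  daylength <- 24 * omega / pi
  data.frame(sunrise = 12 - daylength / 2,
             sunset = 12 + daylength / 2,
             daylength = daylength)
}

#' Construct a diel temperature profile for one day and place
#'
#' @param latitude degrees (used for solar times).
#' @param day_of_year 1--365.
#' @param tmin,tmax daily minimum/maximum temperature (deg C) for the day.
#' @param tmin_next next day's minimum (deg C); may be `NA` when only
#'   daytime hours will be evaluated.
#' @return an object of class `diel_profile`.
#' @export
diel_profile <- function(latitude, day_of_year, tmin, tmax, tmin_next = NA) {
  if (!is.na(tmin) && !is.na(tmax) && tmin > tmax) {
    stop("tmin must not exceed tmax", call. = FALSE)
  }
  st <- solar_times(latitude, day_of_year)
  structure(list(tmin = tmin, tmax = tmax, tmin_next = tmin_next,
                 sunrise = st$sunrise, sunset = st$sunset,
                 daylength = st$daylength),
            class = "diel_profile")
}

day_temp <- function(tmin, tmax, sunrise, daylength, hour) {
  tmin + (tmax - tmin) * sin(pi * (hour - sunrise) / (daylength + 4))
}

night_temp <- function(t_sunset, tmin_next, daylength, hours_after_sunset) {
  t_sunset - (t_sunset - tmin_next) / log(24 - daylength) *
    log(pmax(hours_after_sunset, 1))
}

#' Hourly temperature from a diel profile
#'
#' Daytime (`sunrise <= hour <= sunset`):
#' `T = tmin + (tmax - tmin) * sin(pi * (hour - sunrise) / (daylength + 4))`.
#' After sunset: logarithmic decay from the sunset temperature toward
#' `tmin_next`, `T = T_s - (T_s - tmin_next)/log(24 - daylength) *
#' log(hour - sunset)`, with `hour - sunset` floored at 1 so the first
#' post-sunset hour holds the sunset temperature. Pre-dawn hours
#' (`hour < sunrise`) continue the previous night's decay and therefore
#' require `prev_profile`, the previous day's profile (whose `tmin_next`
#' is this day's `tmin`).
#'
#' @param profile a [diel_profile()].
#' @param hour local solar hour in `[0, 24)`.
#' @param prev_profile previous day's [diel_profile()], needed only for
#'   `hour < sunrise`.
#' @return temperature in deg C.
#' @export
hourly_temperature <- function(profile, hour, prev_profile = NULL) {
  stopifnot(inherits(profile, "diel_profile"), hour >= 0, hour < 24)
  if (hour >= profile$sunrise && hour <= profile$sunset) {
    return(day_temp(profile$tmin, profile$tmax, profile$sunrise,
                    profile$daylength, hour))
  }
  if (hour > profile$sunset) {
    if (profile$daylength >= 23) {
      stop("night formula degenerates for daylength >= 23 h", call. = FALSE)
    }
    if (is.na(profile$tmin_next)) {
      stop("tmin_next is required for hours after sunset", call. = FALSE)
    }
    t_s <- day_temp(profile$tmin, profile$tmax, profile$sunrise,
                    profile$daylength, profile$sunset)
    return(night_temp(t_s, profile$tmin_next, profile$daylength,
                      hour - profile$sunset))
  }
  # pre-dawn: previous night's decay evaluated at hour + 24
  if (is.null(prev_profile)) {
    stop("pre-dawn hours need the previous day's profile", call. = FALSE)
  }
  stopifnot(inherits(prev_profile, "diel_profile"))
  if (prev_profile$daylength >= 23) {
    stop("night formula degenerates for daylength >= 23 h", call. = FALSE)
  }
  t_s <- day_temp(prev_profile$tmin, prev_profile$tmax, prev_profile$sunrise,
                  prev_profile$daylength, prev_profile$sunset)
  night_temp(t_s, prev_profile$tmin_next, prev_profile$daylength,
             hour + 24 - prev_profile$sunset)
}

# Vectorized hourly temperature used by the generator and the join stage.
# tmin/tmax/tmin_next/tmin_prev-tmax_prev are aligned vectors; latitude and
# doy give solar times. Returns NA where a needed input is NA.
hourly_temp_vec <- function(latitude, day_of_year, hour,
                            tmin, tmax, tmin_next,
                            tmin_prev, tmax_prev) {
  st <- solar_times(latitude, day_of_year)
  out <- rep(NA_real_, length(hour))

  is_day <- !is.na(tmin) & !is.na(tmax) &
    hour >= st$sunrise & hour <= st$sunset
  out[is_day] <- day_temp(tmin[is_day], tmax[is_day], st$sunrise[is_day],
                          st$daylength[is_day], hour[is_day])

  is_night <- !is.na(tmin) & !is.na(tmax) & !is.na(tmin_next) &
    hour > st$sunset
  if (any(is_night)) {
    t_s <- day_temp(tmin[is_night], tmax[is_night], st$sunrise[is_night],
                    st$daylength[is_night], st$sunset[is_night])
    out[is_night] <- night_temp(t_s, tmin_next[is_night],
                                st$daylength[is_night],
                                hour[is_night] - st$sunset[is_night])
  }

  is_dawn <- !is.na(tmin_prev) & !is.na(tmax_prev) & !is.na(tmin) &
    hour < st$sunrise
  if (any(is_dawn)) {
    doy_prev <- ifelse(day_of_year - 1 >= 1, day_of_year - 1, 365)
    stp <- solar_times(latitude[is_dawn], doy_prev[is_dawn])
    t_s <- day_temp(tmin_prev[is_dawn], tmax_prev[is_dawn], stp$sunrise,
                    stp$daylength, stp$sunset)
    out[is_dawn] <- night_temp(t_s, tmin[is_dawn], stp$daylength,
                               hour[is_dawn] + 24 - stp$sunset)
  }
  out
}

#' Attach reconstructed hourly temperatures to observation records
#'
#' Assigns each record to its grid cell, looks up the cell's daily min/max
#' for the record's date (plus the next day for post-sunset hours and the
#' previous day for pre-dawn hours), and evaluates the diel model at the
#' record's hour. Records whose required daily entries are missing are
#' dropped; the drop count and ids are attached as the `"drop_log"`
#' attribute.
#'
#' @param records data frame with `id`, `latitude`, `longitude`, `date`
#'   (Date), `hour`.
#' @param daily data frame with `cell_col`, `cell_row`, `date`, `tmin`,
#'   `tmax`.
#' @param grid a [grid_spec()].
#' @return `records` with columns `cell_col`, `cell_row`, `hourly_temp`,
#'   missing-data rows removed.
#' @export
attach_temperatures <- function(records, daily, grid) {
  if (nrow(daily) == 0L) stop("daily temperature table is empty", call. = FALSE)
  stopifnot(all(c("cell_col", "cell_row", "date", "tmin", "tmax") %in%
                  names(daily)))
  cells <- assign_grid_cell(records$latitude, records$longitude, grid)
  lat_c <- cell_center_latitude(cells$cell_row, grid)
  date <- as.Date(records$date)

  dkey <- function(col, row, d) paste(col, row, as.character(d), sep = "|")
  daily_key <- dkey(daily$cell_col, daily$cell_row, as.Date(daily$date))
  look <- function(d) {
    i <- match(dkey(cells$cell_col, cells$cell_row, d), daily_key)
    list(tmin = daily$tmin[i], tmax = daily$tmax[i])
  }
  d0 <- look(date)
  d1 <- look(date + 1)
  dm <- look(date - 1)

  doy <- pmin(as.POSIXlt(date)$yday + 1L, 365L)
  temp <- hourly_temp_vec(lat_c, doy, records$hour,
                          d0$tmin, d0$tmax, d1$tmin,
                          dm$tmin, dm$tmax)
  keep <- !is.na(temp)
  out <- records[keep, , drop = FALSE]
  out$cell_col <- cells$cell_col[keep]
  out$cell_row <- cells$cell_row[keep]
  out$hourly_temp <- temp[keep]
  attr(out, "drop_log") <- list(
    n_input = nrow(records),
    n_dropped_missing_daily = sum(!keep),
    dropped_ids = records$id[!keep],
    n_retained = nrow(out))
  out
}
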