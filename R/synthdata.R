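# Synthetic-data generation with known ground truth. The generator states a
# world with the statistical structure the downstream models assume:
#   * organisms are uniformly colored elliptical blobs (plus clipped
#     channel noise) on differently colored backgrounds;
#   * green/brown outcomes follow a logistic model with a temperature
#     effect only outside a fixed Apr-Sep breeding window, plus a cyclic
#     seasonal term whose amplitude grows with latitude and which is
#     active only in the non-breeding season (its cosine is phased to
#     vanish exactly at the season boundaries, so the breeding-season
#     temperature null stays exact);
#   * daily temperatures vary sinusoidally with day of year and decrease
#     linearly with latitude.
# Default effect sizes are configuration for a plausible world, not claims
# about the real system.

#' Configuration of the synthetic world
#'
#' @param n_records number of observation records.
#' @param lat_range,lon_range coordinate ranges (degrees).
#' @param date_range two `Date`s spanning at least one full year.
#' @param hour_range local-hour range observations are drawn from.
#' @param beta0 logit intercept (non-breeding season).
#' @param beta_temp_nonbreeding temperature slope (logit/deg C) outside the
#'   breeding season.
#' @param beta_breeding logit offset of the breeding season.
#' @param beta_temp_breeding temperature slope within the breeding season
#'   (0 in the default world: summer green is temperature-independent).
#' @param season_amp_base amplitude (logit) of the non-breeding seasonal
#'   cosine at the lowest latitude.
#' @param season_amp_per_lat amplitude growth (logit per degree latitude).
#' @param noise_sd_image per-channel pixel noise SD.
#' @param organism_color_green,organism_color_brown,organism_color_unclear
#'   RGB triples planted for each intended label; each must classify to its
#'   intended label.
#' @param background_color mean background RGB.
#' @param bg_color_jitter_sd per-record SD of the background color draw
#'   (gives the crypsis regression a varying predictor).
#' @param unclear_frac fraction of records planted with the unclear color.
#' @param missing_temp_frac fraction of records whose same-day temperature
#'   entry is withheld from the daily table.
#' @param image_size frame side in pixels (square images, >= 32).
#' @param cell_size climate grid cell side in meters.
#' @param seed RNG seed governing every draw.
#' @return a validated list of class `synth_config`.
#' @export
synth_config <- function(n_records = 1000L,
                         lat_range = c(25, 36),
                         lon_range = c(-98, -77),
                         date_range = as.Date(c("2022-01-01", "2023-12-31")),
                         hour_range = c(7, 19),
                         beta0 = -2.5,
                         beta_temp_nonbreeding = 0.12,
                         beta_breeding = 3.5,
                         beta_temp_breeding = 0,
                         season_amp_base = 0.3,
                         season_amp_per_lat = 0.15,
                         noise_sd_image = 8,
                         organism_color_green = c(60, 140, 50),
                         organism_color_brown = c(135, 85, 55),
                         organism_color_unclear = c(100, 100, 100),
                         background_color = c(150, 150, 120),
                         bg_color_jitter_sd = 25,
                         unclear_frac = 0,
                         missing_temp_frac = 0,
                         image_size = 32L,
                         cell_size = 25000,
                         seed = 1L) {
  cfg <- list(n_records = as.integer(n_records), lat_range = lat_range,
              lon_range = lon_range, date_range = as.Date(date_range),
              hour_range = hour_range, beta0 = beta0,
              beta_temp_nonbreeding = beta_temp_nonbreeding,
              beta_breeding = beta_breeding,
              beta_temp_breeding = beta_temp_breeding,
              season_amp_base = season_amp_base,
              season_amp_per_lat = season_amp_per_lat,
              noise_sd_image = noise_sd_image,
              organism_color_green = organism_color_green,
              organism_color_brown = organism_color_brown,
              organism_color_unclear = organism_color_unclear,
              background_color = background_color,
              bg_color_jitter_sd = bg_color_jitter_sd,
              unclear_frac = unclear_frac,
              missing_temp_frac = missing_temp_frac,
              image_size = as.integer(image_size),
              cell_size = cell_size, seed = as.integer(seed))
  if (cfg$n_records < 1L) stop("n_records must be >= 1", call. = FALSE)
  for (rg in list(cfg$lat_range, cfg$lon_range, cfg$hour_range)) {
    if (length(rg) != 2L || rg[2] <= rg[1]) {
      stop("ranges must be non-empty (min < max)", call. = FALSE)
    }
  }
  if (as.numeric(diff(cfg$date_range)) < 364) {
    stop("date_range must span at least one full year", call. = FALSE)
  }
  if (cfg$noise_sd_image < 0) stop("noise_sd_image must be >= 0",
                                   call. = FALSE)
  if (cfg$unclear_frac < 0 || cfg$unclear_frac > 1 ||
      cfg$missing_temp_frac < 0 || cfg$missing_temp_frac > 1) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  check <- c(green = classify_color(cfg$organism_color_green),
             brown = classify_color(cfg$organism_color_brown),
             unclear = classify_color(cfg$organism_color_unclear))
  if (!identical(unname(check), names(check))) {
    stop("organism colors must classify to their intended labels (got: ",
         paste(names(check), check, sep = "=", collapse = ", "), ")",
         call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

#' Deterministic synthetic daily min/max temperatures
#'
#' `tmax = a0 - a1 * (lat - 25) + A * cos(2*pi*(doy - 200)/365)` and
#' `tmin = tmax - r`: a seasonal sinusoid peaking around day 200 (mid
#' July), cooling with latitude, with a fixed 10 deg C diurnal range.
#'
#' @param latitude degrees.
#' @param day_of_year 1--365 (366 mapped to 365).
#' @param a0 peak-season sea-level maximum at 25 deg N (default 33).
#' @param a1 lapse per degree latitude (default 0.5).
#' @param amplitude seasonal amplitude (default 10).
#' @param daily_range `tmax - tmin` (default 10).
#' @return a data frame with `tmin`, `tmax`.
#' @export
gen_daily_temps <- function(latitude, day_of_year,
                            a0 = 33, a1 = 0.5, amplitude = 10,
                            daily_range = 10) {
  stopifnot(all(latitude >= -66 & latitude <= 66))
  doy <- pmin(day_of_year, 365)
  tmax <- a0 - a1 * (latitude - 25) + amplitude * cos(2 * pi * (doy - 200) / 365)
  data.frame(tmin = tmax - daily_range, tmax = tmax)
}

#' Generate one synthetic segment image
#'
#' An axis-aligned elliptical blob of the base color covering roughly
#' 22--45% of the frame, on the background color, with independent
#' per-channel Gaussian noise clipped to `[0, 255]` and rounded to 8-bit.
#' The returned mask covers the blob exactly and the planted base color is
#' attached as the `planted_color` element.
#'
#' @param base_color organism RGB triple.
#' @param background_color background RGB triple.
#' @param noise_sd per-channel noise SD (`>= 0`).
#' @param size frame side in pixels (`>= 32`).
#' @param seed RNG seed.
#' @param id sample identifier.
#' @return a [segment_sample()] with an extra `planted_color` element.
#' @export
gen_segment_image <- function(base_color, background_color, noise_sd = 0,
                              size = 48L, seed = 1L, id = "synthetic") {
  base_color <- as_rgb(base_color)
  background_color <- as_rgb(background_color)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  size <- as.integer(size)
  if (size < 32L) stop("frame must be at least 32 x 32", call. = FALSE)

  withr::with_seed(as.integer(seed), {
    frac <- stats::runif(1, 0.22, 0.45)
    rho <- stats::runif(1, 0.8, 1.25)
    a <- min(sqrt(frac * size^2 / pi) * sqrt(rho), 0.49 * size)
    b <- min(frac * size^2 / pi / a, 0.49 * size)
    cx <- (size + 1) / 2
    cy <- (size + 1) / 2
    col_idx <- matrix(rep(seq_len(size), each = size), size, size)
    row_idx <- matrix(rep(seq_len(size), times = size), size, size)
    mask <- ((col_idx - cx) / a)^2 + ((row_idx - cy) / b)^2 <= 1

    img <- array(0, c(size, size, 3L))
    for (ch in 1:3) {
      plane <- ifelse(mask, base_color[ch], background_color[ch])
      if (noise_sd > 0) {
        plane <- plane + stats::rnorm(size * size, 0, noise_sd)
      }
      img[, , ch] <- round(pmin(pmax(plane, 0), 255))
    }
    s <- segment_sample(img, mask * 1L, id = id)
    s$planted_color <- round_rgb(base_color)
    s
  })
}

season_amplitude <- function(cfg, latitude) {
  cfg$season_amp_base + cfg$season_amp_per_lat * (latitude - cfg$lat_range[1])
}

# Seasonal cosine, phased to peak at week 26 (midsummer) so that it crosses
# zero exactly at the breeding-season boundaries (weeks ~13 and ~39); gated
# to the non-breeding season, where it is negative (less green midwinter).
seasonal_term <- function(cfg, latitude, week, season) {
  season_amplitude(cfg, latitude) * cos(2 * pi * (week - 26) / 52) *
    (season == "nonbreeding")
}

synthetic_linear_predictor <- function(cfg, latitude, week, season, temp) {
  breeding <- season == "breeding"
  cfg$beta0 +
    ifelse(breeding,
           cfg$beta_breeding + cfg$beta_temp_breeding * temp,
           cfg$beta_temp_nonbreeding * temp) +
    seasonal_term(cfg, latitude, week, season)
}

#' Generate a synthetic observation table with ground truth
#'
#' Draws latitude, longitude, date and hour uniformly from the configured
#' ranges; reconstructs the hourly temperature at each record's grid-cell
#' center through the same diel model the pipeline applies
#' ([hourly_temp_vec] on [gen_daily_temps()] output); forms the linear
#' predictor of the logistic world model; and draws green(1)/brown(0)
#' labels. The companion truth table records the label, linear predictor,
#' temperature, and which records were planted as unclear-colored or had
#' their same-day temperature entry withheld.
#'
#' @param config a [synth_config()].
#' @return a list: `records` (id, latitude, longitude, date, hour, week,
#'   season), `truth` (record_id, true_label, true_linear_predictor,
#'   true_hourly_temp, planted_unclear, planted_missing_temp), `daily`
#'   (cell_col, cell_row, date, tmin, tmax, with withheld rows removed),
#'   `grid` (the [grid_spec()]), and `meta` (bookkeeping: unclear ids,
#'   removed daily keys, and the ids expected to be dropped at the
#'   temperature stage).
#' @export
gen_observation_table <- function(config) {
  cfg <- if (inherits(config, "synth_config")) config else
    do.call(synth_config, config)
  n <- cfg$n_records

  withr::with_seed(cfg$seed, {
    latitude <- stats::runif(n, cfg$lat_range[1], cfg$lat_range[2])
    longitude <- stats::runif(n, cfg$lon_range[1], cfg$lon_range[2])
    span <- as.integer(cfg$date_range[2] - cfg$date_range[1])
    date <- cfg$date_range[1] + sample.int(span + 1L, n, replace = TRUE) - 1L
    hour <- stats::runif(n, cfg$hour_range[1], cfg$hour_range[2])

    grid <- make_grid_spec(latitude, longitude, cfg$cell_size)
    cells <- assign_grid_cell(latitude, longitude, grid)
    lat_c <- cell_center_latitude(cells$cell_row, grid)
    doy <- pmin(as.POSIXlt(date)$yday + 1L, 365L)
    doy_next <- ifelse(doy + 1 > 365, 1, doy + 1)
    doy_prev <- ifelse(doy - 1 < 1, 365, doy - 1)

    d0 <- gen_daily_temps(lat_c, doy)
    d1 <- gen_daily_temps(lat_c, doy_next)
    dm <- gen_daily_temps(lat_c, doy_prev)
    temp <- hourly_temp_vec(lat_c, doy, hour, d0$tmin, d0$tmax, d1$tmin,
                            dm$tmin, dm$tmax)

    week <- week_of_year(date)
    season <- assign_season(date)
    eta <- synthetic_linear_predictor(cfg, latitude, week, season, temp)
    label01 <- stats::rbinom(n, 1L, stats::plogis(eta))
    true_label <- ifelse(label01 == 1L, "green", "brown")

    id <- sprintf("rec%05d", seq_len(n))
    n_unclear <- floor(cfg$unclear_frac * n)
    unclear_ids <- if (n_unclear > 0) sort(sample(id, n_unclear)) else character(0)
    n_missing <- floor(cfg$missing_temp_frac * n)
    missing_ids <- if (n_missing > 0) sort(sample(id, n_missing)) else character(0)

    records <- data.frame(id = id, latitude = latitude, longitude = longitude,
                          date = date, hour = hour, week = week,
                          season = season, stringsAsFactors = FALSE)
    truth <- data.frame(record_id = id, true_label = true_label,
                        true_linear_predictor = eta,
                        true_hourly_temp = temp,
                        planted_unclear = id %in% unclear_ids,
                        planted_missing_temp = id %in% missing_ids,
                        stringsAsFactors = FALSE)

    # daily table: every (cell, date - 1 .. date + 1) a record could need,
    # minus the withheld same-day keys of the planted-missing records
    key <- function(col, row, d) paste(col, row, as.character(d), sep = "|")
    all_keys <- unique(c(key(cells$cell_col, cells$cell_row, date - 1),
                         key(cells$cell_col, cells$cell_row, date),
                         key(cells$cell_col, cells$cell_row, date + 1)))
    removed <- unique(key(cells$cell_col, cells$cell_row, date)[id %in% missing_ids])
    keep_keys <- setdiff(all_keys, removed)
    parts <- do.call(rbind, strsplit(keep_keys, "|", fixed = TRUE))
    dcol <- as.integer(parts[, 1]); drow <- as.integer(parts[, 2])
    ddate <- as.Date(parts[, 3])
    dlat <- cell_center_latitude(drow, grid)
    ddoy <- pmin(as.POSIXlt(ddate)$yday + 1L, 365L)
    dt <- gen_daily_temps(dlat, ddoy)
    daily <- data.frame(cell_col = dcol, cell_row = drow, date = ddate,
                        tmin = dt$tmin, tmax = dt$tmax)
    daily <- daily[order(daily$cell_col, daily$cell_row, daily$date), ]
    rownames(daily) <- NULL

    # expected temperature-stage drops: any record one of whose required
    # keys was removed, excluding records already planted unclear (those
    # leave the pipeline at the color stage)
    st <- solar_times(lat_c, doy)
    need_next <- hour > st$sunset
    need_prev <- hour < st$sunrise
    k0 <- key(cells$cell_col, cells$cell_row, date)
    k1 <- key(cells$cell_col, cells$cell_row, date + 1)
    km <- key(cells$cell_col, cells$cell_row, date - 1)
    hit <- k0 %in% removed | (need_next & k1 %in% removed) |
      (need_prev & km %in% removed)
    expected_drop_ids <- setdiff(id[hit], unclear_ids)

    list(records = records, truth = truth, daily = daily, grid = grid,
         meta = list(unclear_ids = unclear_ids,
                     removed_daily_keys = removed,
                     expected_temp_drop_ids = sort(expected_drop_ids)))
  })
}

#' Flatten a generated observation table into a model-ready data frame
#'
#' Joins the ground-truth label and temperature onto the records,
#' bypassing the image and temperature-join stages. Convenient for testing
#' the model layer directly against the world model.
#'
#' @param obs the list returned by [gen_observation_table()].
#' @return a data frame with `label` and `hourly_temp` columns added.
#' @export
as_model_table <- function(obs) {
  d <- obs$records
  stopifnot(identical(d$id, obs$truth$record_id))
  d$label <- obs$truth$true_label
  d$hourly_temp <- obs$truth$true_hourly_temp
  d
}

#' Generate a complete synthetic fixture bundle
#'
#' [gen_observation_table()] plus one synthetic segment image per record:
#' green- or brown-colored per the drawn label (or the unclear color for
#' planted-unclear records) on a per-record jittered background.
#'
#' @param config a [synth_config()].
#' @param with_images generate segment images (set `FALSE` for model-only
#'   work at large `n_records`).
#' @return the [gen_observation_table()] list with an added `images`
#'   element (a list of [segment_sample()]s keyed by record id) and
#'   `config`.
#' @export
gen_synth_bundle <- function(config, with_images = TRUE) {
  cfg <- if (inherits(config, "synth_config")) config else
    do.call(synth_config, config)
  obs <- gen_observation_table(cfg)
  obs$config <- cfg
  if (!with_images) return(obs)

  n <- nrow(obs$records)
  draws <- withr::with_seed(cfg$seed + 1L, {
    list(image_seeds = sample.int(.Machine$integer.max - 1L, n),
         bg_jitter = matrix(stats::rnorm(3L * n, 0, cfg$bg_color_jitter_sd),
                            nrow = n))
  })
  planted <- ifelse(obs$truth$planted_unclear, "unclear", obs$truth$true_label)
  color_of <- list(green = cfg$organism_color_green,
                   brown = cfg$organism_color_brown,
                   unclear = cfg$organism_color_unclear)
  obs$images <- lapply(seq_len(n), function(i) {
    bg <- pmin(pmax(cfg$background_color + draws$bg_jitter[i, ], 0), 255)
    gen_segment_image(color_of[[planted[i]]], bg,
                      noise_sd = cfg$noise_sd_image, size = cfg$image_size,
                      seed = draws$image_seeds[i], id = obs$records$id[i])
  })
  names(obs$images) <- obs$records$id
  obs
}

#' Write a synthetic bundle to disk
#'
#' Layout: `images/<id>.png`, `masks/<id>.png`, `records.csv`,
#' `truth.csv`, `daily_temps.csv`, `config.yaml` (configuration, grid
#' parameters and bookkeeping metadata).
#'
#' @param bundle a [gen_synth_bundle()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth_bundle <- function(bundle, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (s in bundle$images) {
    write_image(s$image, file.path(dir, "images", paste0(s$id, ".png")))
    write_mask(s$mask, file.path(dir, "masks", paste0(s$id, ".png")))
  }
  utils::write.csv(bundle$records, file.path(dir, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$daily, file.path(dir, "daily_temps.csv"),
                   row.names = FALSE)
  cfg <- bundle$config
  cfg$date_range <- as.character(cfg$date_range)
  yaml::write_yaml(list(config = unclass(cfg),
                        grid = unclass(bundle$grid),
                        meta = bundle$meta),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a synthetic bundle written by [write_synth_bundle()]
#' @param dir bundle directory.
#' @return a list shaped like a [gen_synth_bundle()] result.
#' @export
read_synth_bundle <- function(dir) {
  records <- utils::read.csv(file.path(dir, "records.csv"),
                             stringsAsFactors = FALSE)
  records$date <- as.Date(records$date)
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path)) {
    utils::read.csv(truth_path, stringsAsFactors = FALSE)
  } else NULL
  daily <- utils::read.csv(file.path(dir, "daily_temps.csv"),
                           stringsAsFactors = FALSE)
  daily$date <- as.Date(daily$date)
  y <- yaml::read_yaml(file.path(dir, "config.yaml"))
  grid <- grid_spec(unlist(y$grid$origin), y$grid$reference_latitude,
                    y$grid$cell_size)
  images <- lapply(records$id, function(id) {
    img <- read_image(file.path(dir, "images", paste0(id, ".png")))
    msk <- read_mask(file.path(dir, "masks", paste0(id, ".png")))
    segment_sample(img, msk, id = id)
  })
  names(images) <- records$id
  list(records = records, truth = truth, daily = daily, grid = grid,
       meta = y$meta, config = y$config, images = images)
}
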