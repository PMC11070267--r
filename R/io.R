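#' Read and validate radar echo tables
#'
#' Echo tables are RFC-4180 CSV with header
#' `site_id,timestamp_utc,altitude_agl_m,p_insect,p_bird,p_nonbio,rcs_max_cm2`
#' (an optional `truth_label` column is kept when present, e.g. from the
#' synthetic generator). Timestamps are ISO-8601 and interpreted as UTC;
#' altitude is metres above the radar.
#'
#' @param path file path.
#' @return A tibble, one row per echo, with `timestamp_utc` as `POSIXct`
#'   (UTC) and numeric measurement columns; row order preserved.
#' @seealso [write_echo_table()]
#' @export
read_echo_table <- function(path) {
  stopifnot(file.exists(path))
  required <- c("site_id", "timestamp_utc", "altitude_agl_m",
                "p_insect", "p_bird", "p_nonbio", "rcs_max_cm2")
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("echo table ", path, ": missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::mutate(
    x,
    timestamp_utc = parse_utc(.data$timestamp_utc),
    dplyr::across(dplyr::all_of(c("altitude_agl_m", "p_insect", "p_bird",
                                  "p_nonbio", "rcs_max_cm2")), as.numeric)
  )
  validate_echoes(out, path = path)
  out
}

#' Write a radar echo table
#'
#' @param echoes tibble as returned by [read_echo_table()] or
#'   [simulate_site()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_echo_table <- function(echoes, path) {
  validate_echoes(echoes, path = "(in memory)")
  out <- dplyr::mutate(echoes, timestamp_utc = format_utc(.data$timestamp_utc))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# shared echo validation; errors cite 1-based data row numbers
validate_echoes <- function(echoes, path) {
  bad_row <- function(ok, what) {
    if (any(!ok)) {
      stop("echo table ", path, ": ", what, " at data row(s) ",
           paste(head(which(!ok), 5), collapse = ", "), call. = FALSE)
    }
  }
  bad_row(!is.na(echoes$timestamp_utc), "unparseable timestamp")
  bad_row(!is.na(echoes$altitude_agl_m) & echoes$altitude_agl_m >= 0,
          "altitude_agl_m must be >= 0")
  for (p in c("p_insect", "p_bird", "p_nonbio")) {
    bad_row(!is.na(echoes[[p]]) & echoes[[p]] >= 0 & echoes[[p]] <= 1,
            paste0(p, " outside [0, 1]"))
  }
  psum <- echoes$p_insect + echoes$p_bird + echoes$p_nonbio
  bad_row(psum <= 1 + 1e-6, "class probabilities sum to more than 1")
  bad_row(!is.na(echoes$rcs_max_cm2) & echoes$rcs_max_cm2 > 0,
          "rcs_max_cm2 must be > 0")
  invisible(echoes)
}

#' Read a site configuration table
#'
#' CSV with header `site_id,name,lat_deg,lon_deg,elev_m`. Latitude must lie
#' in \[-90, 90\], longitude (east positive) in \[-180, 180\], and site ids
#' must be unique.
#'
#' @param path file path.
#' @return tibble, one row per site.
#' @export
read_sites <- function(path) {
  stopifnot(file.exists(path))
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("site_id", "name", "lat_deg", "lon_deg", "elev_m")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("sites table ", path, ": missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(x$site_id)) {
    stop("sites table ", path, ": duplicate site_id", call. = FALSE)
  }
  if (any(x$lat_deg < -90 | x$lat_deg > 90)) {
    stop("sites table ", path, ": latitude outside [-90, 90]", call. = FALSE)
  }
  if (any(x$lon_deg < -180 | x$lon_deg > 180)) {
    stop("sites table ", path, ": longitude outside [-180, 180]", call. = FALSE)
  }
  x
}

#' Read, validate and normalize an interval table
#'
#' CSV with header `site_id,kind,start_utc,end_utc`; `kind` is
#' `protocol_shortpulse` (times the radar ran the short-pulse protocol) or
#' `rain`. Per site and kind, overlapping or abutting intervals are merged,
#' so the result is a normalized disjoint set.
#'
#' @param path file path.
#' @return tibble `site_id, kind, start_utc, end_utc` with `POSIXct` UTC
#'   bounds, disjoint per site/kind, sorted by start.
#' @export
read_intervals <- function(path) {
  stopifnot(file.exists(path))
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  required <- c("site_id", "kind", "start_utc", "end_utc")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("interval table ", path, ": missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- dplyr::mutate(x,
                     start_utc = parse_utc(.data$start_utc),
                     end_utc = parse_utc(.data$end_utc))
  bad <- which(is.na(x$start_utc) | is.na(x$end_utc) | x$end_utc <= x$start_utc)
  if (length(bad) > 0) {
    stop("interval table ", path, ": end <= start (or unparseable) at data row(s) ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  merge_intervals(x)
}

#' Write an interval table
#' @param intervals tibble with `site_id, kind, start_utc, end_utc`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  out <- dplyr::mutate(intervals,
                       start_utc = format_utc(.data$start_utc),
                       end_utc = format_utc(.data$end_utc))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Merge overlapping or abutting intervals
#'
#' Per `site_id` and `kind`, unions intervals that overlap or touch, yielding
#' a minimal disjoint set. Idempotent; total covered duration is preserved up
#' to overlap removal.
#'
#' @param intervals tibble with `site_id, kind, start_utc, end_utc`
#'   (`POSIXct`).
#' @return normalized tibble, sorted by site, kind, start.
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0) {
    return(tibble::tibble(site_id = character(), kind = character(),
                          start_utc = utc_time(character()),
                          end_utc = utc_time(character())))
  }
  intervals |>
    dplyr::group_by(.data$site_id, .data$kind) |>
    dplyr::arrange(.data$start_utc, .by_group = TRUE) |>
    dplyr::mutate(
      run = cumsum(dplyr::lag(cummax(as.numeric(.data$end_utc)),
                              default = -Inf) < as.numeric(.data$start_utc))
    ) |>
    dplyr::group_by(.data$run, .add = TRUE) |>
    dplyr::summarise(start_utc = min(.data$start_utc),
                     end_utc = max(.data$end_utc), .groups = "drop") |>
    dplyr::select("site_id", "kind", "start_utc", "end_utc") |>
    dplyr::arrange(.data$site_id, .data$kind, .data$start_utc)
}

#' Cross-check a network's inputs for consistency
#'
#' Report-only validation: flags echoes at unknown sites, echoes outside the
#' configured analysis period, and the fraction of echoes outside the
#' configured altitude band. Never errors.
#'
#' @param sites tibble from [read_sites()].
#' @param echoes tibble from [read_echo_table()].
#' @param intervals tibble from [read_intervals()].
#' @param config a [dielflux_config()].
#' @return list with `issues` (tibble `type, detail, n`) and
#'   `frac_outside_band` (numeric).
#' @export
validate_network <- function(sites, echoes, intervals,
                             config = dielflux_config()) {
  issues <- list()
  unknown <- setdiff(unique(c(echoes$site_id, intervals$site_id)),
                     sites$site_id)
  if (length(unknown) > 0) {
    issues[[length(issues) + 1]] <- tibble::tibble(
      type = "unknown_site_id",
      detail = unknown,
      n = vapply(unknown, function(s) {
        sum(echoes$site_id == s) + sum(intervals$site_id == s)
      }, integer(1))
    )
  }
  d <- as.Date(echoes$timestamp_utc, tz = "UTC")
  n_outside <- sum(d < config$period[1] | d > config$period[2])
  if (n_outside > 0) {
    issues[[length(issues) + 1]] <- tibble::tibble(
      type = "echo_outside_period",
      detail = paste(format(config$period[1]), "to", format(config$period[2])),
      n = n_outside
    )
  }
  frac_outside_band <- if (nrow(echoes) == 0) 0 else {
    mean(echoes$altitude_agl_m < config$altitude_band[1] |
           echoes$altitude_agl_m > config$altitude_band[2])
  }
  list(
    issues = if (length(issues) > 0) dplyr::bind_rows(issues) else
      tibble::tibble(type = character(), detail = character(), n = integer()),
    frac_outside_band = frac_outside_band
  )
}

# ---- internal time helpers ---------------------------------------------

parse_utc <- function(x) {
  if (inherits(x, "POSIXct")) return(lubridate::with_tz(x, "UTC"))
  out <- lubridate::ymd_hms(x, tz = "UTC", quiet = TRUE)
  # accept date-only strings as midnight UTC
  only_date <- is.na(out) & !is.na(lubridate::ymd(x, quiet = TRUE))
  out[only_date] <- lubridate::ymd_hms(paste(x[only_date], "00:00:00"),
                                       tz = "UTC", quiet = TRUE)
  out
}

format_utc <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

utc_time <- function(x = numeric()) {
  as.POSIXct(x, tz = "UTC", origin = "1970-01-01")
}
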