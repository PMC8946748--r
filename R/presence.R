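# Seasonal, effort-normalized, FPR-scaled acoustic presence aggregation and
# correlation with visual sighting records.

#' Geographic / seasonal configuration
#'
#' @param bbox_lon_w Study-area longitude limits, degrees West (63-82 W).
#' @param bbox_lat_n Latitude limits, degrees North (24-46 N).
#' @param match_radius_km Estimated recording radius used to match sightings
#'   to mooring sites (~2 km).
#' @return A list of class `geo_config`. Seasons partition the twelve
#'   months: Spring Mar-May, Summer Jun-Aug, Fall Sep-Nov, Winter Dec-Feb.
#' @export
geo_config <- function(bbox_lon_w = c(63, 82), bbox_lat_n = c(24, 46),
                       match_radius_km = 2) {
  stopifnot(match_radius_km > 0)
  structure(list(bbox_lon_w = sort(bbox_lon_w),
                 bbox_lat_n = sort(bbox_lat_n),
                 match_radius_km = match_radius_km), class = "geo_config")
}

.season_levels <- c("Spring", "Summer", "Fall", "Winter")

#' Season of a date
#'
#' Spring: March-May; Summer: June-August; Fall: September-November;
#' Winter: December-February. Every month maps to exactly one season.
#'
#' @param date Date, POSIXt, or anything `as.Date()` accepts.
#' @return Factor with levels Spring, Summer, Fall, Winter.
#' @export
season_of <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  s <- c("Winter", "Winter", "Spring", "Spring", "Spring", "Summer",
         "Summer", "Summer", "Fall", "Fall", "Fall", "Winter")[m]
  factor(s, levels = .season_levels)
}

# Season-year convention: December counts toward the following year's
# winter, so each Dec-Feb block is one season instance.
.season_year <- function(date) {
  d <- as.Date(date)
  y <- as.integer(format(d, "%Y"))
  m <- as.integer(format(d, "%m"))
  y + (m == 12L)
}

# Hours (as POSIXct floored to the hour) covered by [start, end] intervals.
.effort_hours <- function(start, end) {
  out <- list()
  for (k in seq_along(start)) {
    h0 <- as.POSIXct(trunc(as.POSIXct(start[k], tz = "UTC"), "hours"),
                     tz = "UTC")
    h1 <- as.POSIXct(trunc(as.POSIXct(end[k], tz = "UTC"), "hours"),
                     tz = "UTC")
    out[[k]] <- seq(h0, h1, by = 3600)
  }
  unique(do.call(c, out))
}

#' Seasonal effort-normalized acoustic presence
#'
#' An hour counts as present for a class when at least one retained bin of
#' that class starts within it. Present hours are summed within each
#' (site, class, season, year), divided by the recorded fraction of that
#' season (normalizing for gaps between deployments), averaged across
#' years, and finally scaled by `1 - FPR` when false-positive-rate
#' estimates are supplied. Seasons with zero recording effort are flagged
#' `no_effort` rather than reported as zero presence.
#'
#' @param labels data.frame of retained bin labels: `bin_start` (POSIXct),
#'   `class`, `site`.
#' @param effort data.frame of recording intervals: `site`, `start`, `end`.
#' @param fpr Optional data.frame (class, site, fpr) from [estimate_fpr()].
#' @param cfg [geo_config()] (unused fields tolerated; kept for interface
#'   symmetry).
#' @return data.frame (site, class, season, mean_hours, n_years,
#'   fpr_scaled, no_effort).
#' @export
presence_hours <- function(labels, effort, fpr = NULL, cfg = geo_config()) {
  stopifnot(all(c("bin_start", "class", "site") %in% names(labels)),
            all(c("site", "start", "end") %in% names(effort)))
  labels$bin_start <- as.POSIXct(labels$bin_start, tz = "UTC")
  # effort hours per site/season/season-year
  eff <- list()
  for (site in unique(effort$site)) {
    es <- effort[effort$site == site, ]
    hours <- .effort_hours(es$start, es$end)
    eff[[site]] <- data.frame(hour = hours, season = season_of(hours),
                              syear = .season_year(hours))
  }
  season_total_hours <- function(season, syear) {
    months <- switch(as.character(season), Spring = 3:5, Summer = 6:8,
                     Fall = 9:11, Winter = c(12, 1, 2))
    yrs <- ifelse(months == 12, syear - 1, syear)
    sum(mapply(function(m, y) {
      as.integer(difftime(as.Date(sprintf("%d-%02d-01", y + (m == 12),
                                          ifelse(m == 12, 1, m + 1))),
                          as.Date(sprintf("%d-%02d-01", y, m)),
                          units = "hours"))
    }, months, yrs))
  }
  cells <- list()
  for (site in unique(labels$site)) {
    ls <- labels[labels$site == site, ]
    ls$hour <- as.POSIXct(trunc(ls$bin_start, "hours"), tz = "UTC")
    esite <- eff[[site]]
    for (cls in unique(ls$class)) {
      lc <- ls[ls$class == cls, ]
      for (season in .season_levels) {
        if (is.null(esite)) {
          cells[[length(cells) + 1L]] <- data.frame(
            site = site, class = cls, season = season, mean_hours = NA_real_,
            n_years = 0L, fpr_scaled = FALSE, no_effort = TRUE)
          next
        }
        es <- esite[esite$season == season, ]
        per_year <- vapply(unique(es$syear), function(sy) {
          tot <- season_total_hours(season, sy)
          rec <- sum(es$syear == sy)
          present <- length(unique(lc$hour[season_of(lc$hour) == season &
                                             .season_year(lc$hour) == sy]))
          present / (rec / tot)
        }, numeric(1))
        no_eff <- length(per_year) == 0
        cells[[length(cells) + 1L]] <- data.frame(
          site = site, class = cls, season = season,
          mean_hours = if (no_eff) NA_real_ else mean(per_year),
          n_years = length(per_year), fpr_scaled = FALSE, no_effort = no_eff)
      }
    }
  }
  out <- do.call(rbind, c(cells, make.row.names = FALSE))
  if (!is.null(fpr)) {
    m <- merge(out, fpr[c("class", "site", "fpr")],
               by = c("class", "site"), all.x = TRUE)
    m$mean_hours <- ifelse(is.na(m$fpr), m$mean_hours,
                           m$mean_hours * (1 - m$fpr))
    m$fpr_scaled <- !is.na(m$fpr)
    out <- m
  }
  out$season <- factor(out$season, levels = .season_levels)
  out
}

#' Pool sightings by season
#'
#' Sightings outside the study-area bounding box are excluded; the two
#' Kogia species are pooled by genus (hard to tell apart at sea); seasonal
#' sightings are pooled across all years (not averaged) because interannual
#' survey effort varies widely. Unparseable rows are dropped with a
#' message, never silently.
#'
#' @param sightings data.frame: `species`, `lat`, `lon` (decimal degrees,
#'   negative West or see `lon_west`), `datetime`, `group_size` (NA
#'   allowed).
#' @param species Optional filter (applied after Kogia pooling).
#' @param cfg [geo_config()].
#' @param lon_west If TRUE, `lon` is in positive degrees West.
#' @return data.frame (species, season, n_sightings, individuals,
#'   n_with_group_size).
#' @export
pool_sightings <- function(sightings, species = NULL, cfg = geo_config(),
                           lon_west = FALSE) {
  s <- sightings
  s$datetime <- as.POSIXct(s$datetime, tz = "UTC")
  bad <- is.na(s$datetime) | is.na(s$lat) | is.na(s$lon) |
    abs(s$lat) > 90 | abs(s$lon) > 360
  if (any(bad)) {
    message(sum(bad), " sighting row(s) dropped: unparseable datetime or ",
            "implausible coordinates")
    s <- s[!bad, , drop = FALSE]
  }
  lw <- if (lon_west) s$lon else -s$lon
  inbox <- lw >= cfg$bbox_lon_w[1] & lw <= cfg$bbox_lon_w[2] &
    s$lat >= cfg$bbox_lat_n[1] & s$lat <= cfg$bbox_lat_n[2]
  s <- s[inbox, , drop = FALSE]
  s$species[grepl("^Kogia", s$species)] <- "Kogia spp."
  if (!is.null(species)) s <- s[s$species %in% species, , drop = FALSE]
  s$season <- season_of(s$datetime)
  if (nrow(s) == 0) {
    return(data.frame(species = character(0), season = character(0),
                      n_sightings = integer(0), individuals = numeric(0),
                      n_with_group_size = integer(0)))
  }
  agg <- lapply(split(s, list(s$species, s$season), drop = TRUE), function(g) {
    data.frame(species = g$species[1], season = g$season[1],
               n_sightings = nrow(g),
               individuals = sum(g$group_size, na.rm = TRUE),
               n_with_group_size = sum(!is.na(g$group_size)))
  })
  out <- do.call(rbind, c(agg, make.row.names = FALSE))
  out[order(out$species, out$season), ]
}

#' Match sightings to acoustic mooring sites
#'
#' Great-circle (haversine) distance; sightings within the estimated
#' recording radius of a site are matched, carrying the sighting time for
#' acoustic cross-reference.
#'
#' @param sightings data.frame with `lat`, `lon` (signed decimal degrees,
#'   negative West).
#' @param sites data.frame with `site`, `lat`, `lon`.
#' @param cfg [geo_config()].
#' @return data.frame of matches (sighting row index, site, distance_km,
#'   plus the sighting columns).
#' @export
match_sightings_to_sites <- function(sightings, sites, cfg = geo_config()) {
  out <- list()
  for (k in seq_len(nrow(sites))) {
    d <- geosphere::distHaversine(
      cbind(sightings$lon, sightings$lat),
      c(sites$lon[k], sites$lat[k]))
    hit <- which(d <= cfg$match_radius_km * 1000)
    if (length(hit)) {
      out[[length(out) + 1L]] <- cbind(
        data.frame(sighting = hit, site = sites$site[k],
                   distance_km = d[hit] / 1000),
        sightings[hit, , drop = FALSE])
    }
  }
  if (length(out) == 0) {
    return(data.frame(sighting = integer(0), site = character(0),
                      distance_km = numeric(0)))
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res[order(res$distance_km), ]
}

#' Seasonal presence bubble map for one class
#'
#' Bubble area is proportional to effort-normalized mean hours (so radius
#' scales with the square root); classifier error (FPR) is encoded as the
#' bubble fill; sighting positions may be overlaid. Cells with zero or
#' no-effort presence draw no bubble. One panel per season.
#'
#' @param cells Output of [presence_hours()] for one class.
#' @param sites data.frame with `site`, `lat`, `lon`.
#' @param sightings Optional sighting data.frame (`lat`, `lon`, `datetime`).
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
render_presence_map <- function(cells, sites, sightings = NULL, path,
                                width = 8, height = 7) {
  d <- merge(cells, sites, by = "site")
  d <- d[!is.na(d$mean_hours) & d$mean_hours > 0, , drop = FALSE]
  d$fpr_band <- if ("fpr" %in% names(d)) {
    cut(d$fpr, c(-Inf, 0.25, 0.5, 0.75, Inf),
        labels = c("<0.25", "0.25-0.5", "0.5-0.75", ">0.75"))
  } else factor("n/a")
  p <- ggplot2::ggplot() +
    ggplot2::geom_point(data = sites, ggplot2::aes(x = lon, y = lat),
                        shape = 8, color = "red") +
    ggplot2::geom_point(data = d,
                        ggplot2::aes(x = lon, y = lat,
                                     size = sqrt(mean_hours),
                                     fill = fpr_band),
                        shape = 21, alpha = 0.7) +
    ggplot2::scale_size_area() +
    ggplot2::labs(x = "Longitude", y = "Latitude",
                  size = "sqrt(hours)", fill = "FPR")
  if (!is.null(sightings) && nrow(sightings) > 0) {
    sightings$season <- season_of(sightings$datetime)
    p <- p + ggplot2::geom_point(
      data = sightings, ggplot2::aes(x = lon, y = lat),
      color = "blue", size = 0.8)
  }
  p <- p + ggplot2::facet_wrap(~season, drop = FALSE)
  ggplot2::ggsave(path, p, width = width, height = height, dpi = 100)
  invisible(path)
}
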