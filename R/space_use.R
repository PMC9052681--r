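# Space use: centres of activity (detection-weighted mean receiver
# positions in fixed time bins) and monthly kernel utilisation
# distributions with reference-bandwidth smoothing, evaluated on a local
# planar projection centred on the array centroid (the bay spans well under
# a degree, so projection distortion is negligible and contour areas are
# well-defined in km^2).

#' Centres of activity
#'
#' Per animal and time bin, the detection-count-weighted mean of the
#' detecting receivers' coordinates. Bins tile the study window aligned to
#' local midnight; empty bins yield no row.
#'
#' @param detections filtered detection table.
#' @param stations station table.
#' @param bin_minutes bin width (360 for analysis, 720 for the geolocation
#'   fusion).
#' @param tz_offset local-day offset, hours.
#' @return data.frame: `animal_id, bin_start, lat, lon, n_detections`.
#' @export
compute_coas <- function(detections, stations, bin_minutes = 360,
                         tz_offset = DEFAULT_TZ_OFFSET) {
  if (!nrow(detections)) {
    return(data.frame(animal_id = character(),
                      bin_start = as.POSIXct(character(), tz = "UTC"),
                      lat = numeric(), lon = numeric(),
                      n_detections = integer()))
  }
  pos <- station_positions(stations)
  i <- match(detections$receiver_id, pos$receiver_id)
  w <- bin_minutes * 60
  shift <- tz_offset * 3600
  bin <- floor((as.numeric(detections$timestamp) + shift) / w) * w - shift
  key <- paste(detections$tag_id, bin, sep = "\r")
  lat <- tapply(pos$lat[i], key, mean)
  lon <- tapply(pos$lon[i], key, mean)
  n <- tapply(rep(1L, nrow(detections)), key, sum)
  parts <- strsplit(names(lat), "\r", fixed = TRUE)
  out <- data.frame(
    animal_id = vapply(parts, `[`, "", 1L),
    bin_start = as.POSIXct(as.numeric(vapply(parts, `[`, "", 2L)),
                           origin = "1970-01-01", tz = "UTC"),
    lat = as.numeric(lat), lon = as.numeric(lon),
    n_detections = as.integer(n), stringsAsFactors = FALSE)
  out <- out[order(out$animal_id, out$bin_start), ]
  rownames(out) <- NULL
  out
}

# Reference (plug-in) bandwidth: mean of the coordinate SDs times n^(-1/6),
# the bivariate normal-reference rule with a shared isotropic bandwidth.
href_bandwidth <- function(xy) {
  n <- nrow(xy)
  mean(c(sd(xy[, 1]), sd(xy[, 2]))) * n^(-1 / 6)
}

#' Kernel utilisation distribution of a COA cloud
#'
#' Bivariate Gaussian product-kernel density on a planar projection,
#' evaluated on a regular grid covering the points padded by three
#' bandwidths, normalized to unit mass. Contour level for q% is the largest
#' density threshold whose superlevel set holds at least q% of the mass.
#'
#' @param coas COA table (uses `lat`, `lon`).
#' @param h bandwidth in metres; default the reference rule.
#' @param grid_n grid cells per axis.
#' @param levels utilisation levels for contour areas.
#' @param origin projection centre `c(lat, lon)`; default the COA centroid.
#' @return `kud` list: grid coordinates (m), `density` matrix (1/m^2,
#'   integrating to 1), `h_m`, contour `areas_km2`, `thresholds`, cell
#'   membership masks, origin.
#' @export
kud_fit <- function(coas, h = NULL, grid_n = 100, levels = c(0.5, 0.95),
                    origin = NULL) {
  stopifnot(nrow(coas) >= 5)
  if (is.null(origin)) origin <- c(mean(coas$lat), mean(coas$lon))
  xy <- project_local(coas$lat, coas$lon, origin[1], origin[2])
  if (is.null(h)) h <- href_bandwidth(xy)
  if (!is.finite(h) || h <= 0) {
    stop("zero reference bandwidth (all COAs identical); jitter the input",
         call. = FALSE)
  }
  pad <- 3 * h
  gx <- seq(min(xy[, 1]) - pad, max(xy[, 1]) + pad, length.out = grid_n)
  gy <- seq(min(xy[, 2]) - pad, max(xy[, 2]) + pad, length.out = grid_n)
  # product Gaussian kernel, separable evaluation
  Kx <- outer(gx, xy[, 1], function(g, x) dnorm(g, x, h))
  Ky <- outer(gy, xy[, 2], function(g, y) dnorm(g, y, h))
  dens <- (Kx %*% t(Ky)) / nrow(xy)
  cell <- diff(gx)[1] * diff(gy)[1]
  dens <- dens / (sum(dens) * cell)   # unit mass on the grid
  thr <- numeric(length(levels)); names(thr) <- paste0(levels * 100, "%")
  areas <- numeric(length(levels)); names(areas) <- names(thr)
  masks <- list()
  o <- order(dens, decreasing = TRUE)
  cum <- cumsum(dens[o]) * cell
  for (j in seq_along(levels)) {
    m <- which(cum >= levels[j])[1]
    thr[j] <- dens[o[m]]
    masks[[names(thr)[j]]] <- dens >= thr[j]
    areas[j] <- sum(masks[[j]]) * cell / 1e6
  }
  structure(list(x = gx, y = gy, density = dens, h_m = h, cell_m2 = cell,
                 thresholds = thr, areas_km2 = areas, masks = masks,
                 origin = origin, n = nrow(xy)),
            class = "kud")
}

#' Monthly kernel utilisation distributions
#'
#' Pools COAs from all animals by calendar month (both study years pooled),
#' fitting a KUD per month with at least `min_coas` points; sparser months
#' are skipped with a warning. A common projection origin (the pooled COA
#' centroid) keeps monthly areas comparable.
#'
#' @param coas COA table.
#' @param min_coas minimum COAs per month (default 5).
#' @param ... passed to [kud_fit()].
#' @return named list of `kud` objects ("01".."12"), missing months NULL.
#' @export
kud_monthly <- function(coas, min_coas = 5, ...) {
  origin <- c(mean(coas$lat), mean(coas$lon))
  mon <- format(coas$bin_start, "%m")
  out <- setNames(vector("list", 12L), sprintf("%02d", 1:12))
  for (m in sort(unique(mon))) {
    sub <- coas[mon == m, ]
    if (nrow(sub) < min_coas) {
      warning("month ", m, " has fewer than ", min_coas, " COAs; skipped")
      next
    }
    out[[m]] <- kud_fit(sub, origin = origin, ...)
  }
  out
}

#' Seasonal contour-area series
#'
#' @param uds list from [kud_monthly()].
#' @return data.frame: month, n COAs, 50% and 95% areas (km^2); missing
#'   months flagged.
#' @export
seasonal_area_series <- function(uds) {
  rows <- lapply(names(uds), function(m) {
    u <- uds[[m]]
    if (is.null(u)) {
      data.frame(month = m, n_coas = 0L, area50_km2 = NA_real_,
                 area95_km2 = NA_real_, missing = TRUE)
    } else {
      data.frame(month = m, n_coas = u$n,
                 area50_km2 = unname(u$areas_km2["50%"]),
                 area95_km2 = unname(u$areas_km2["95%"]), missing = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Export KUD contours as GeoJSON
#'
#' Traces the contour polygons at the stored utilisation thresholds and
#' writes a GeoJSON FeatureCollection in geographic coordinates.
#'
#' @param kud a `kud` object.
#' @param path output file.
#' @export
write_contours_geojson <- function(kud, path) {
  feats <- list()
  for (nm in names(kud$thresholds)) {
    cl <- grDevices::contourLines(kud$x, kud$y, kud$density,
                                  levels = kud$thresholds[[nm]])
    for (poly in cl) {
      ll <- unproject_local(poly$x, poly$y, kud$origin[1], kud$origin[2])
      coords <- paste(sprintf("[%.6f,%.6f]", ll[, "lon"], ll[, "lat"]),
                      collapse = ",")
      feats[[length(feats) + 1L]] <- sprintf(
        '{"type":"Feature","properties":{"level":"%s"},"geometry":{"type":"Polygon","coordinates":[[%s]]}}',
        nm, coords)
    }
  }
  writeLines(sprintf('{"type":"FeatureCollection","features":[%s]}',
                     paste(unlist(feats), collapse = ",")), path)
  invisible(path)
}
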