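`%||%` <- function(a, b) if (is.null(a)) b else a

# Local tangent-plane projection (equidistant in both axes) centred on
# (lat0, lon0): x east, y north, metres. Adequate for extents under ~1 degree;
# used for kernel density estimation and the movement simulator.
project_local <- function(lat, lon, lat0, lon0) {
  rad <- pi / 180
  cbind(x = EARTH_RADIUS_M * rad * (lon - lon0) * cos(lat0 * rad),
        y = EARTH_RADIUS_M * rad * (lat - lat0))
}

unproject_local <- function(x, y, lat0, lon0) {
  rad <- pi / 180
  cbind(lat = lat0 + y / (EARTH_RADIUS_M * rad),
        lon = lon0 + x / (EARTH_RADIUS_M * rad * cos(lat0 * rad)))
}
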