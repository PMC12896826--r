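#' Great-circle displacement between GPS fixes
#'
#' Haversine distance between two positions on a sphere. Used to turn a
#' pair of GPS fixes recorded at the ends of a sensor window into the
#' displacement feature of a behavior frame: grazing and resting cattle
#' move metres per window, walking cattle tens of metres, so displacement
#' is the single most discriminative feature for locomotor behaviors.
#'
#' @param lat1,lon1 coordinates of the first fix, decimal degrees.
#' @param lat2,lon2 coordinates of the second fix, decimal degrees.
#' @param radius_km sphere radius in kilometres. Default 6371.393 (Earth).
#' @return distance in kilometres; vectorized over coordinates.
#' @examples
#' haversine_km(49.33, 119.95, 49.33, 119.95)   # 0
#' haversine_km(0, 0, 0, 180)                   # half the circumference
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2, radius_km = 6371.393) {
  stopifnot(radius_km > 0)
  if (!all(is.finite(c(lat1, lon1, lat2, lon2))))
    stop("non-finite GPS coordinates")
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180))
    stop("GPS coordinates out of range: |lat| <= 90, |lon| <= 180 required")
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad
  phi2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  h <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  # clamp guards rounding just above 1 for near-antipodal points
  2 * radius_km * asin(sqrt(pmin(1, h)))
}

#' Construct a GPS fix
#'
#' @param lat,lon position in decimal degrees.
#' @param t timestamp, seconds since epoch.
#' @return a `gps_fix` list.
#' @export
gps_fix <- function(lat, lon, t = 0) {
  if (!all(is.finite(c(lat, lon, t)))) stop("non-finite GPS fix fields")
  if (abs(lat) > 90) stop("latitude out of [-90, 90]")
  if (lon <= -180 || lon > 180) stop("longitude out of (-180, 180]")
  structure(list(lat = lat, lon = lon, t = t), class = "gps_fix")
}

#' Construct a sensor window
#'
#' One observation window: 1 Hz IMU samples (accelerometer, gyroscope,
#' magnetometer, 9 components per sample) bracketed by a GPS fix at each
#' end. The default window is 10 s, i.e. 10 samples.
#'
#' @param imu numeric matrix, one row per second, 9 columns
#'   (ax, ay, az, gx, gy, gz, mx, my, mz).
#' @param fix_start,fix_end [gps_fix()] at the window ends.
#' @return a `sensor_window` list.
#' @export
sensor_window <- function(imu, fix_start, fix_end) {
  imu <- as.matrix(imu)
  if (ncol(imu) != 9) stop("IMU samples must have 9 components")
  if (nrow(imu) < 1) stop("sensor window holds no IMU samples")
  stopifnot(inherits(fix_start, "gps_fix"), inherits(fix_end, "gps_fix"))
  if (fix_end$t - fix_start$t != nrow(imu))
    warning("window length (", fix_end$t - fix_start$t,
            " s) does not match number of 1 Hz samples (", nrow(imu), ")")
  structure(list(imu = imu, fix_start = fix_start, fix_end = fix_end),
            class = "sensor_window")
}

#' Assemble a 10-feature frame from a sensor window
#'
#' The first nine features are the arithmetic means of the 1 Hz IMU
#' samples over the window; the tenth is the haversine displacement (km)
#' between the window's two GPS fixes.
#'
#' @param w a [sensor_window()].
#' @param radius_km Earth radius passed to [haversine_km()].
#' @return named numeric vector of length 10
#'   (`ax,ay,az,gx,gy,gz,mx,my,mz,d`), unlabeled.
#' @export
assemble_frame <- function(w, radius_km = 6371.393) {
  stopifnot(inherits(w, "sensor_window"))
  if (nrow(w$imu) == 0) stop("empty sensor window")
  feats <- c(colMeans(w$imu),
             haversine_km(w$fix_start$lat, w$fix_start$lon,
                          w$fix_end$lat, w$fix_end$lon, radius_km))
  names(feats) <- hp_feature_names()
  feats
}

hp_feature_names <- function() {
  c("ax", "ay", "az", "gx", "gy", "gz", "mx", "my", "mz", "d")
}
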