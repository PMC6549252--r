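# Coordinate parsing and great-circle distances between sampling sites.
#
# Published site tables in this field give coordinates in degree /
# decimal-minute notation ("N37°46.385'W025°18.21'"); all internal
# computation is on decimal degrees and a spherical Earth.

# mean Earth radius, km (IUGG mean radius R1)
EARTH_RADIUS_KM <- 6371.0088

DEG_SIGN <- "\u00b0"
PRIME <- "\u2032"

normalize_lon <- function(lon) {
  w <- (lon + 180) %% 360
  ifelse(w == 0, 180, w - 180)
}

#' Parse a degree/decimal-minute coordinate string
#'
#' Accepts strings of the form `<N|S><deg>°<decimal minutes>′<E|W><deg>°
#' <decimal minutes>′`, the notation used for published sampling sites
#' (e.g. `"N63°53.278′W022°03.405′"`). The ASCII apostrophe is accepted in
#' place of the prime mark, leading zeros are allowed (`"W025°..."`), and
#' whitespace may separate the two halves.
#'
#' @param text a single coordinate string.
#' @return named numeric vector `c(lat = , lon = )` in decimal degrees:
#'   `deg + minutes/60`, negated for S and W. Longitude is normalized to
#'   (-180, 180].
#' @export
#' @examples
#' parse_coordinate("N14°8.191′E121°13.262′")
parse_coordinate <- function(text) {
  if (length(text) != 1 || is.na(text))
    gv_stop("coordinate must be a single non-missing string")
  txt <- trimws(text)
  half <- paste0("([NSEW])(\\d+)", DEG_SIGN,
                 "(\\d+(?:\\.\\d+)?)(?:", PRIME, "|')")
  rx <- paste0("^", half, "\\s*", half, "$")
  m <- regmatches(txt, regexec(rx, txt, perl = TRUE))[[1]]
  if (!length(m))
    gv_stop("unparseable coordinate string: '", text,
            "' (expected e.g. N37", DEG_SIGN, "46.385", PRIME,
            "W025", DEG_SIGN, "18.21", PRIME, ")")
  hemi1 <- m[2]; deg1 <- as.numeric(m[3]); min1 <- as.numeric(m[4])
  hemi2 <- m[5]; deg2 <- as.numeric(m[6]); min2 <- as.numeric(m[7])
  if (!(hemi1 %in% c("N", "S")))
    gv_stop("coordinate '", text, "': first half must be N or S, got '",
            hemi1, "'")
  if (!(hemi2 %in% c("E", "W")))
    gv_stop("coordinate '", text, "': second half must be E or W, got '",
            hemi2, "'")
  if (min1 >= 60)
    gv_stop("coordinate '", text, "': minutes out of [0, 60): '", m[4], "'")
  if (min2 >= 60)
    gv_stop("coordinate '", text, "': minutes out of [0, 60): '", m[7], "'")
  lat <- (deg1 + min1 / 60) * if (hemi1 == "S") -1 else 1
  lon <- (deg2 + min2 / 60) * if (hemi2 == "W") -1 else 1
  if (abs(lat) > 90)
    gv_stop("coordinate '", text, "': latitude degrees out of range: '",
            m[3], "'")
  if (abs(lon) > 180)
    gv_stop("coordinate '", text, "': longitude degrees out of range: '",
            m[6], "'")
  c(lat = lat, lon = normalize_lon(lon))
}

#' Format decimal degrees as a degree/decimal-minute string
#'
#' Inverse of [parse_coordinate()]; formatting then re-parsing reproduces
#' the input to well below 1e-9 degrees.
#'
#' @param lat,lon decimal degrees.
#' @return a coordinate string such as `"N63°53.278′W022°03.405′"`.
#' @export
format_coordinate <- function(lat, lon) {
  lon <- normalize_lon(lon)
  fmt_half <- function(value, pos, neg) {
    hemi <- if (value < 0) neg else pos
    a <- abs(value)
    deg <- floor(a)
    mins <- (a - deg) * 60
    # guard against 59.9999... rounding up to 60
    mtxt <- formatC(mins, digits = 10, format = "f")
    if (as.numeric(mtxt) >= 60) {
      deg <- deg + 1
      mtxt <- "0"
    }
    mtxt <- sub("0+$", "", mtxt)
    mtxt <- sub("\\.$", "", mtxt)
    paste0(hemi, deg, DEG_SIGN, mtxt, PRIME)
  }
  paste0(fmt_half(lat, "N", "S"), fmt_half(lon, "E", "W"))
}

#' Great-circle distance between two points, in km
#'
#' Haversine distance on a sphere of radius 6371.0088 km (the mean Earth
#' radius). The deviation from a true ellipsoidal geodesic is below 0.5%,
#' immaterial for site separations of tens to thousands of km.
#'
#' @param a,b points as named numeric vectors `c(lat = , lon = )` in
#'   decimal degrees (as returned by [parse_coordinate()]).
#' @return distance in km; 0 for identical points, at most `pi * R`
#'   (half the circumference, ~20015.087 km) for antipodes.
#' @export
#' @examples
#' great_circle_km(c(lat = 0, lon = 0), c(lat = 0, lon = 180))
great_circle_km <- function(a, b) {
  for (p in list(a, b)) {
    if (anyNA(p) || !all(is.finite(p[c("lat", "lon")])))
      gv_stop("great_circle_km: points need finite 'lat' and 'lon'")
  }
  geosphere::distHaversine(c(a[["lon"]], a[["lat"]]),
                           c(b[["lon"]], b[["lat"]]),
                           r = EARTH_RADIUS_KM)
}

#' Pairwise great-circle distance matrix for a site table
#'
#' @param sites a [site_table()]. Every site must carry coordinates; sites
#'   without them (strains known only from similarity matrices) raise an
#'   error naming them, so the caller must subset explicitly rather than
#'   have rows vanish.
#' @return a [labeled_matrix()] of kind `distance_km`.
#' @export
geographic_distance_matrix <- function(sites) {
  if (!inherits(sites, "site_table")) gv_stop("'sites' must be a site_table")
  if (nrow(sites) < 2) gv_stop("need at least 2 sites")
  missing <- sites_without_coords(sites)
  if (length(missing))
    gv_stop("sites lack coordinates: ", paste(missing, collapse = ", "),
            " (subset the table to coordinate-bearing sites first)")
  n <- nrow(sites)
  pts <- cbind(sites$lon, sites$lat)
  v <- matrix(0, n, n, dimnames = list(sites$name, sites$name))
  for (i in seq_len(n - 1)) {
    d <- geosphere::distHaversine(pts[i, , drop = FALSE],
                                  pts[(i + 1):n, , drop = FALSE],
                                  r = EARTH_RADIUS_KM)
    v[i, (i + 1):n] <- d
    v[(i + 1):n, i] <- d
  }
  labeled_matrix(v, kind = "distance_km")
}
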