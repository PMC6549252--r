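#' Construct a site table of sampling locations
#'
#' A site table records, per isolate, its short strain label, the raw
#' coordinate string it was parsed from (if any), decimal-degree latitude
#' and longitude, the tectonic plate the sampling site sits on, and
#' optional habitat metadata (temperature, pH). Strains known only from
#' published similarity matrices may appear without coordinates
#' (`lat`/`lon` = `NA`); geographic analyses then refuse them explicitly
#' rather than dropping them silently.
#'
#' @param name character vector of unique strain labels.
#' @param lat,lon decimal degrees (may be `NA` for strains without a
#'   published sampling location). Latitude in \[-90, 90\]; longitude is
#'   normalized to (-180, 180\].
#' @param plate tectonic-plate label per strain (may be `NA`).
#' @param coordinate_text raw degree/decimal-minute strings, if the
#'   coordinates came from text.
#' @param temperature_c,ph optional habitat descriptors, kept verbatim
#'   (published values are often ranges such as "62-64").
#'
#' @return a `data.frame` of class `site_table`.
#' @export
site_table <- function(name, lat = NA_real_, lon = NA_real_,
                       plate = NA_character_, coordinate_text = NA_character_,
                       temperature_c = NA_character_, ph = NA_character_) {
  name <- as.character(name)
  n <- length(name)
  if (n < 1) gv_stop("site table needs at least one row")
  if (anyDuplicated(name))
    gv_stop("duplicate strain names: ",
            paste(unique(name[duplicated(name)]), collapse = ", "))
  df <- data.frame(
    name = name,
    coordinate_text = rep_len(as.character(coordinate_text), n),
    lat = rep_len(as.numeric(lat), n),
    lon = rep_len(as.numeric(lon), n),
    plate = rep_len(as.character(plate), n),
    temperature_c = rep_len(as.character(temperature_c), n),
    ph = rep_len(as.character(ph), n),
    stringsAsFactors = FALSE
  )
  ok <- !is.na(df$lat)
  if (any(ok & (df$lat < -90 | df$lat > 90)))
    gv_stop("latitude out of [-90, 90] for: ",
            paste(df$name[ok & (df$lat < -90 | df$lat > 90)], collapse = ", "))
  df$lon[!is.na(df$lon)] <- normalize_lon(df$lon[!is.na(df$lon)])
  if (any(is.na(df$lat) != is.na(df$lon)))
    gv_stop("lat and lon must be both present or both absent for: ",
            paste(df$name[is.na(df$lat) != is.na(df$lon)], collapse = ", "))
  class(df) <- c("site_table", "data.frame")
  df
}

#' @export
print.site_table <- function(x, ...) {
  cat(sprintf("<site_table> %d sites\n", nrow(x)))
  NextMethod()
}

# names of sites lacking coordinates
sites_without_coords <- function(sites) sites$name[is.na(sites$lat)]
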