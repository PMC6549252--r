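# TSV readers/writers for site tables and labeled matrices, plus the
# packaged fixtures: the published six-site sampling table and the
# nine-strain pairwise DDH / 16S rRNA identity matrices.

#' Read a site table from TSV
#'
#' The file must have a header with a `name` column plus either a
#' `coordinate` column (degree/decimal-minute strings, parsed with
#' [parse_coordinate()]) or numeric `lat` and `lon` columns. Optional
#' columns: `plate`, `temperature_c`, `ph` (kept verbatim). A blank
#' coordinate cell yields a coordinate-less strain.
#'
#' @param path TSV file path.
#' @return a [site_table()].
#' @export
read_site_table <- function(path) {
  if (!file.exists(path)) gv_stop("no such file: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE, fileEncoding = "UTF-8",
                   colClasses = "character", na.strings = NULL)
  if (!"name" %in% names(df)) gv_stop(path, ": missing 'name' column")
  if (anyDuplicated(df$name))
    gv_stop(path, ": duplicate strain names: ",
            paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  n <- nrow(df)
  if ("coordinate" %in% names(df)) {
    lat <- lon <- rep(NA_real_, n)
    ctext <- df$coordinate
    for (i in seq_len(n)) {
      if (!nzchar(trimws(ctext[i]))) next
      pt <- tryCatch(parse_coordinate(ctext[i]), geovar_error = function(e) {
        gv_stop(path, " row ", i, " ('", df$name[i], "'): ",
                conditionMessage(e))
      })
      lat[i] <- pt[["lat"]]; lon[i] <- pt[["lon"]]
    }
  } else if (all(c("lat", "lon") %in% names(df))) {
    ctext <- rep(NA_character_, n)
    num <- function(col) {
      x <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(nzchar(trimws(df[[col]])) & is.na(x))
      if (length(bad))
        gv_stop(path, " row ", bad[1], " ('", df$name[bad[1]],
                "'): non-numeric ", col, " '", df[[col]][bad[1]], "'")
      x
    }
    lat <- num("lat"); lon <- num("lon")
  } else {
    gv_stop(path, ": need a 'coordinate' column or 'lat' + 'lon' columns")
  }
  opt <- function(col) if (col %in% names(df)) df[[col]] else NA_character_
  site_table(name = df$name, lat = lat, lon = lon,
             plate = opt("plate"), coordinate_text = ctext,
             temperature_c = opt("temperature_c"), ph = opt("ph"))
}

#' Write a site table to TSV
#'
#' Coordinates are written as degree/decimal-minute strings (the original
#' text when the row was parsed from text, otherwise formatted with
#' [format_coordinate()]); [read_site_table()] round-trips the result.
#'
#' @param sites a [site_table()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  ctext <- sites$coordinate_text
  for (i in seq_len(nrow(sites))) {
    if ((is.na(ctext[i]) || !nzchar(ctext[i])) && !is.na(sites$lat[i]))
      ctext[i] <- format_coordinate(sites$lat[i], sites$lon[i])
  }
  out <- data.frame(name = sites$name,
                    coordinate = ifelse(is.na(ctext), "", ctext),
                    plate = ifelse(is.na(sites$plate), "", sites$plate),
                    temperature_c = ifelse(is.na(sites$temperature_c), "",
                                           sites$temperature_c),
                    ph = ifelse(is.na(sites$ph), "", sites$ph),
                    stringsAsFactors = FALSE)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labeled square matrix from TSV
#'
#' Expects row and column labels (first header cell is ignored), numeric
#' cells, and optionally a blank upper triangle: published pairwise
#' tables are printed lower-triangular, and the upper triangle is then
#' filled by mirroring. When both triangles are present they must agree
#' to within `tol`.
#'
#' @param path TSV file path.
#' @param kind matrix kind, see [labeled_matrix()].
#' @param tol absolute symmetry/diagonal tolerance.
#' @return a [labeled_matrix()].
#' @export
read_matrix <- function(path, kind = c("similarity_percent", "distance_km",
                                       "distance_percent", "sympatry_binary"),
                        tol = 1e-9) {
  kind <- match.arg(kind)
  if (!file.exists(path)) gv_stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) gv_stop(path, ": not a labeled matrix (too few rows)")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]][-1]
  n <- length(header)
  if (length(cells) - 1 != n)
    gv_stop(path, ": not square: ", n, " columns vs ", length(cells) - 1,
            " rows")
  v <- matrix(NA_real_, n, n, dimnames = list(character(n), header))
  row_labels <- character(n)
  for (i in seq_len(n)) {
    row <- cells[[i + 1]]
    row_labels[i] <- row[1]
    vals <- row[-1]
    if (length(vals) > n)
      gv_stop(path, " row '", row[1], "': ", length(vals),
              " cells for ", n, " columns")
    vals <- c(vals, rep("", n - length(vals)))  # trailing blanks may be trimmed
    filled <- nzchar(trimws(vals))
    num <- suppressWarnings(as.numeric(vals[filled]))
    if (anyNA(num))
      gv_stop(path, " row '", row[1], "': non-numeric cell '",
              vals[filled][which(is.na(num))[1]], "'")
    v[i, filled] <- num
  }
  if (!identical(row_labels, header))
    gv_stop(path, ": row labels do not match column labels")
  rownames(v) <- row_labels
  # mirror blanks; check agreement where both triangles are present
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (is.na(v[i, j]) && !is.na(v[j, i])) v[i, j] <- v[j, i]
  }
  if (anyNA(v))
    gv_stop(path, ": cells missing from both triangles")
  labeled_matrix(v, kind = kind, tol = tol)
}

#' Write a labeled matrix to TSV
#'
#' Cells are written so that [read_matrix()] reproduces the matrix
#' exactly: the short decimal form is used whenever it round-trips to the
#' same double, otherwise full (17 significant digit) precision.
#'
#' @param m a [labeled_matrix()].
#' @param path output TSV path.
#' @param digits significant digits, or `NA` (default) for exact
#'   round-trip formatting.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, digits = NA) {
  validate_labeled_matrix(m)
  n <- length(m$labels)
  rows <- character(n + 1)
  rows[1] <- paste(c("strain", m$labels), collapse = "\t")
  for (i in seq_len(n)) {
    rows[i + 1] <- paste(c(m$labels[i], format_exact(m$values[i, ], digits)),
                         collapse = "\t")
  }
  writeLines(rows, path, useBytes = FALSE)
  invisible(path)
}

#' Packaged published fixtures: site table and pairwise identity matrices
#'
#' Returns the published data this package is validated against:
#' * `site_table` — the six newly sampled acidic hot-spring sites (strains
#'   Fur, Rib, Fdl, Yel, Ice, Phi) with degree/decimal-minute coordinates
#'   and tectonic-plate labels;
#' * `ddh_matrix` — 9x9 pairwise in silico DNA-DNA hybridization values
#'   (%), strains SolV, Fur, Rib, Fdl, Ice, Yel, Phi, V4, Kam1;
#' * `s16_matrix` — 9x9 pairwise 16S rRNA sequence identities (%), same
#'   strains;
#' * `plates` — named character vector of tectonic-plate labels for all
#'   nine strains (SolV, V4 and Kam1 appear in the matrices but have no
#'   published coordinates, so they are absent from the site table).
#'
#' @return a list with elements `site_table`, `ddh_matrix`, `s16_matrix`,
#'   `plates`.
#' @export
#' @examples
#' fx <- packaged_fixtures()
#' fx$ddh_matrix$values["Kam1", "Yel"]   # 50.4
packaged_fixtures <- function() {
  ext <- function(f) system.file("extdata", f, package = "geovar",
                                 mustWork = TRUE)
  sites <- read_site_table(ext("sites_table1.tsv"))
  plates_df <- read.delim(ext("plates_nine.tsv"), sep = "\t",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  plates <- stats::setNames(plates_df$plate, plates_df$name)
  list(
    site_table = sites,
    ddh_matrix = read_matrix(ext("ddh_table2.tsv"), "similarity_percent"),
    s16_matrix = read_matrix(ext("s16_table2.tsv"), "similarity_percent"),
    plates = plates
  )
}

#' Dump the packaged fixtures to a directory
#'
#' Copies the packaged fixture TSVs (site table, DDH matrix, 16S matrix,
#' nine-strain plate labels) into `dir`, creating it if needed.
#'
#' @param dir output directory.
#' @return character vector of the written paths, invisibly.
#' @export
dump_fixtures <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c("sites_table1.tsv", "ddh_table2.tsv", "s16_table2.tsv",
             "plates_nine.tsv")
  out <- file.path(dir, files)
  for (i in seq_along(files)) {
    src <- system.file("extdata", files[i], package = "geovar",
                       mustWork = TRUE)
    file.copy(src, out[i], overwrite = TRUE)
  }
  invisible(out)
}
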