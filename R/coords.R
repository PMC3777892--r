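#' Build a sample coordinate table
#'
#' Locations are held in planar kilometres throughout the package: the
#' interpolation grids are planar and all distances are Euclidean km.
#' Longitude/latitude input is projected once on construction with an
#' equirectangular projection about the data centroid (adequate at the
#' few-hundred-km extent of a regional study; supply pre-projected km for
#' anything larger).
#'
#' @param df data frame with `sample_id` and either `x`, `y` (planar km)
#'   or `lon`, `lat` (decimal degrees).
#' @return a `sample_geo` tibble with columns `sample_id`, `x`, `y` (km).
#' @export
sample_geo <- function(df) {
  df <- as_tibble(df)
  if (!"sample_id" %in% names(df)) abort("sample_geo needs a sample_id column")
  if (all(c("lon", "lat") %in% names(df)) && !all(c("x", "y") %in% names(df))) {
    xy <- lonlat_to_planar(df$lon, df$lat)
    df$x <- xy$x
    df$y <- xy$y
  }
  if (!all(c("x", "y") %in% names(df))) {
    abort("sample_geo needs x/y (km) or lon/lat columns")
  }
  df <- df %>%
    mutate(sample_id = as.character(.data$sample_id),
           x = as.numeric(.data$x), y = as.numeric(.data$y)) %>%
    select("sample_id", "x", "y")
  if (anyDuplicated(df$sample_id)) {
    abort(paste0("duplicate sample_id in coordinates: ",
                 df$sample_id[duplicated(df$sample_id)][1]))
  }
  if (any(!is.finite(df$x)) || any(!is.finite(df$y))) {
    bad <- df$sample_id[!is.finite(df$x) | !is.finite(df$y)][1]
    abort(paste0("non-finite coordinate for sample '", bad, "'"))
  }
  structure(df, class = c("sample_geo", class(tibble())))
}

#' Equirectangular projection to planar kilometres
#'
#' Projects lon/lat about a reference point (default: centroid), with
#' `x = R cos(lat0) (lon - lon0)`, `y = R (lat - lat0)` in radians and
#' `R = 6371` km.
#'
#' @param lon,lat decimal degrees.
#' @param lon0,lat0 reference point; defaults to the mean of the data.
#' @return list with numeric vectors `x`, `y` in km.
#' @export
lonlat_to_planar <- function(lon, lat, lon0 = mean(lon), lat0 = mean(lat)) {
  r_earth <- 6371
  to_rad <- pi / 180
  list(x = r_earth * cos(lat0 * to_rad) * (lon - lon0) * to_rad,
       y = r_earth * (lat - lat0) * to_rad)
}

#' Read sample coordinates from CSV
#'
#' @param path CSV with `sample_id` and `x`,`y` (km) or `lon`,`lat`.
#' @return a [sample_geo()] tibble.
#' @export
read_coords <- function(path) {
  sample_geo(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}
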