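#' Define a regular interpolation grid
#'
#' A rectangular lattice of points `(x0 + i*s, y0 + j*s)` for
#' `i = 0..nx-1`, `j = 0..ny-1`, spacing `s` in km (default 5, the
#' conventional resolution for regional landscape-genetic surfaces). An
#' optional polygon mask restricts the analysed area (e.g. land only);
#' masked-out points are dropped from all outputs and coverage tallies.
#'
#' @param x0,y0 origin (km).
#' @param spacing grid spacing in km, `> 0`.
#' @param nx,ny number of points along each axis, `>= 1`.
#' @param mask optional polygon as a data frame/matrix with columns
#'   `x`, `y` (vertices in order, implicitly closed); only grid points
#'   inside it are retained.
#' @return a `grid_spec` object.
#' @export
grid_spec <- function(x0, y0, spacing = 5, nx, ny, mask = NULL) {
  if (spacing <= 0) abort("grid spacing must be > 0")
  if (nx < 1 || ny < 1) abort("nx and ny must be >= 1")
  if (!is.null(mask)) {
    mask <- as.data.frame(mask)
    if (!all(c("x", "y") %in% names(mask)) || nrow(mask) < 3) {
      abort("mask must be a polygon with columns x, y and >= 3 vertices")
    }
  }
  spec <- structure(
    list(x0 = x0, y0 = y0, spacing = spacing,
         nx = as.integer(nx), ny = as.integer(ny), mask = mask),
    class = "grid_spec"
  )
  if (nrow(grid_points(spec)) < 1) abort("mask retains no grid point")
  spec
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("<grid_spec> ", x$nx, " x ", x$ny, " points, spacing ", x$spacing,
      " km, origin (", x$x0, ", ", x$y0, ")",
      if (!is.null(x$mask)) ", masked" else "", "\n", sep = "")
  invisible(x)
}

#' Materialise the grid points of a grid_spec
#'
#' @param spec a [grid_spec()].
#' @return tibble `point_id`, `x`, `y` (masked points omitted).
#' @export
grid_points <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  g <- tidyr::expand_grid(
    j = seq_len(spec$ny) - 1L,
    i = seq_len(spec$nx) - 1L
  ) %>%
    mutate(x = spec$x0 + .data$i * spec$spacing,
           y = spec$y0 + .data$j * spec$spacing,
           point_id = .data$j * spec$nx + .data$i + 1L) %>%
    select("point_id", "x", "y")
  if (!is.null(spec$mask)) {
    keep <- point_in_polygon(g$x, g$y, spec$mask$x, spec$mask$y)
    g <- g[keep, , drop = FALSE]
  }
  g
}

#' Grid covering a set of samples
#'
#' Bounding box of the sample locations padded by one spacing on each
#' side, snapped to multiples of the spacing.
#'
#' @param geo a [sample_geo()] tibble.
#' @param spacing km, default 5.
#' @param mask optional polygon (see [grid_spec()]).
#' @return a [grid_spec()].
#' @export
grid_from_samples <- function(geo, spacing = 5, mask = NULL) {
  x0 <- floor((min(geo$x) - spacing) / spacing) * spacing
  y0 <- floor((min(geo$y) - spacing) / spacing) * spacing
  nx <- ceiling((max(geo$x) + spacing - x0) / spacing) + 1
  ny <- ceiling((max(geo$y) + spacing - y0) / spacing) + 1
  grid_spec(x0, y0, spacing, nx, ny, mask = mask)
}

# Even-odd ray-casting point-in-polygon; vertices implicitly closed.
# Boundary points count as inside on left/bottom edges (half-open rule),
# which keeps the test deterministic for lattice points on mask edges.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Write an interpolated grid field
#'
#' One record per (retained) grid point with `x`, `y` and all value
#' columns. CSV output carries the coordinate reference in a `# crs:`
#' header comment and full double precision, so a write -> read round
#' trip is exact to better than 1e-9. GeoJSON output is a
#' FeatureCollection of Point features with the remaining columns as
#' properties.
#'
#' @param field tibble with `x`, `y` and value column(s).
#' @param path output path.
#' @param format `"csv"` or `"geojson"`.
#' @param crs free-text coordinate reference tag (default `"planar_km"`).
#' @return `path`, invisibly.
#' @export
write_grid_field <- function(field, path, format = c("csv", "geojson"),
                             crs = "planar_km") {
  format <- match.arg(format)
  if (!all(c("x", "y") %in% names(field))) abort("field needs x and y columns")
  if (format == "csv") {
    body <- readr::format_csv(field)
    writeLines(c(paste0("# crs: ", crs), sub("\n$", "", body)), path)
  } else {
    props <- setdiff(names(field), c("x", "y"))
    features <- purrr::map(seq_len(nrow(field)), function(k) {
      list(
        type = "Feature",
        geometry = list(type = "Point",
                        coordinates = c(field$x[k], field$y[k])),
        properties = as.list(field[k, props, drop = FALSE])
      )
    })
    obj <- list(type = "FeatureCollection", crs = crs, features = features)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  }
  invisible(path)
}

#' Read a grid field written by [write_grid_field()] (CSV only)
#'
#' @param path CSV path.
#' @return tibble with the original columns; the `crs` tag is attached as
#'   an attribute.
#' @export
read_grid_field <- function(path) {
  first <- readLines(path, n = 1)
  crs <- if (startsWith(first, "# crs:")) trimws(sub("# crs:", "", first)) else NA
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  attr(df, "crs") <- crs
  df
}
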