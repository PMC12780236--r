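# Readers and writers for the pipeline's on-disk artifacts. Rasters use the
# ESRI ASCII grid format (plain text, georeferenced, readable by any GIS),
# tables use CSV, zone sets a JSON document, configs YAML.

#' Write a raster layer as an ESRI ASCII grid
#'
#' @param layer Numeric matrix (`NA` = nodata).
#' @param grid A [grid_spec()].
#' @param path Output path (conventionally `.asc`).
#' @param nodata Nodata sentinel written to file (default -9999).
#' @export
write_ascii_grid <- function(layer, grid, path, nodata = -9999) {
  stopifnot(is.matrix(layer), nrow(layer) == grid$n_rows, ncol(layer) == grid$n_cols)
  ext <- grid_extent(grid)
  hdr <- c(sprintf("ncols %d", grid$n_cols),
           sprintf("nrows %d", grid$n_rows),
           sprintf("xllcorner %.10g", ext["xmin"]),
           sprintf("yllcorner %.10g", ext["ymin"]),
           sprintf("cellsize %.10g", grid$resolution),
           sprintf("NODATA_value %g", nodata))
  body <- layer
  body[is.na(body)] <- nodata
  lines <- apply(body, 1, function(r) paste(formatC(r, format = "g", digits = 9),
                                            collapse = " "))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File written by [write_ascii_grid()] (or any conforming
#'   ASCII grid).
#' @param crs_id CRS token to attach (the format does not carry one).
#' @return List with `layer` (matrix, `NA` = nodata) and `grid`.
#' @export
read_ascii_grid <- function(path, crs_id = "synthetic-equal-area-m") {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  kv <- stats::setNames(vapply(hdr, `[`, character(1), 2),
                        tolower(vapply(hdr, `[`, character(1), 1)))
  n_cols <- as.integer(kv[["ncols"]]); n_rows <- as.integer(kv[["nrows"]])
  res <- as.numeric(kv[["cellsize"]])
  nodata <- as.numeric(kv[["nodata_value"]])
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != n_rows * n_cols) {
    stop("malformed ASCII grid: expected ", n_rows * n_cols, " values, got ",
         length(vals), call. = FALSE)
  }
  layer <- matrix(vals, n_rows, n_cols, byrow = TRUE)
  layer[layer == nodata] <- NA_real_
  grid <- grid_spec(origin_x = as.numeric(kv[["xllcorner"]]),
                    origin_y = as.numeric(kv[["yllcorner"]]) + n_rows * res,
                    n_rows = n_rows, n_cols = n_cols, resolution = res,
                    crs_id = crs_id)
  list(layer = layer, grid = grid)
}

#' Write telemetry to CSV
#'
#' Columns: `individual_id, sex, region, timestamp` (ISO-8601 date),
#' `x, y`.
#'
#' @param telemetry Telemetry tibble.
#' @param path Output path.
#' @export
write_telemetry_csv <- function(telemetry, path) {
  out <- telemetry[, c("individual_id", "sex", "region", "timestamp", "x", "y")]
  out$timestamp <- format(as.Date(out$timestamp), "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read telemetry from CSV
#'
#' Validates the schema and timestamps; a malformed timestamp is rejected
#' with its line number.
#'
#' @param path CSV with columns `individual_id, sex, region, timestamp, x, y`.
#' @return Telemetry tibble with `timestamp` parsed as `Date`.
#' @export
read_telemetry_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "sex", "region", "timestamp", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("telemetry CSV lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", df$timestamp)
  if (!all(ok)) {
    stop("non-ISO timestamp at line(s): ",
         paste(utils::head(which(!ok) + 1L, 10), collapse = ", "), call. = FALSE)
  }
  ts <- as.Date(df$timestamp)
  if (anyNA(ts)) {
    stop("unparseable timestamp at line(s): ",
         paste(utils::head(which(is.na(ts)) + 1L, 10), collapse = ", "), call. = FALSE)
  }
  df$timestamp <- ts
  tibble::as_tibble(df)
}

#' Write a zone set to JSON
#'
#' Serializes the grid, every zone's type, name, attributes and member
#' cells to a plain JSON document.
#'
#' @param zones A `zone_set`.
#' @param path Output path.
#' @export
write_zones_json <- function(zones, path) {
  doc <- list(
    grid = zones$grid[c("origin_x", "origin_y", "n_rows", "n_cols",
                        "resolution", "crs_id")],
    zones = lapply(zones$zones, function(z) {
      list(zone_id = z$zone_id, zone_type = z$zone_type, name = z$name,
           attrs = z$attrs[!vapply(z$attrs, is.null, logical(1))],
           cells = z$cells)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Read a zone set from JSON
#'
#' @param path File written by [write_zones_json()].
#' @return A `zone_set`.
#' @export
read_zones_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  g <- doc$grid
  grid <- grid_spec(origin_x = g$origin_x, origin_y = g$origin_y,
                    n_rows = g$n_rows, n_cols = g$n_cols,
                    resolution = g$resolution, crs_id = g$crs_id)
  zs <- lapply(doc$zones, function(z) {
    zz <- zone(z$zone_id, z$zone_type, z$name, unlist(z$cells), grid,
               max_elevation_m = z$attrs$max_elevation_m %||% NA_real_,
               country = z$attrs$country %||% NA_character_)
    extra <- setdiff(names(z$attrs), names(zz$attrs))
    zz$attrs[extra] <- z$attrs[extra]
    zz
  })
  zone_set(grid, zs)
}

#' Write a use/available design to CSV
#' @param table Use/available tibble.
#' @param path Output path.
#' @export
write_design_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a use/available design from CSV
#' @param path File written by [write_design_csv()].
#' @return Tibble.
#' @export
read_design_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                    check.names = FALSE))
}
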