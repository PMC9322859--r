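# Raster data model: integer class grids, continuous driver grids, driver
# stacks, ESRI ASCII I/O and the exact Euclidean distance transform.
#
# Conventions (fixed for the whole package):
#   * matrices are row-major conceptually: row 1 is the top of the map,
#     (row, col) indexing, one value per cell
#   * nodata is NA in the stored matrix
#   * all rasters taking part in one analysis must share shape and cell_size;
#     mixed resolutions are rejected, never resampled

#' Land-use class codes and labels
#'
#' The six first-level land classes used throughout the package, in code
#' order 1..6: cultivated land, woodland, grassland, waters, construction
#' land, unused land.
#'
#' @return Character vector of length 6 (names of codes 1..6).
#' @export
land_classes <- function() {
  c("cultivated", "woodland", "grassland", "waters", "construction", "unused")
}

N_CLASS <- 6L

#' Construct a categorical land-use raster
#'
#' @param values Integer matrix of class codes in `1..6`; `NA` marks nodata.
#' @param cell_size Cell edge length in metres (scalar > 0).
#' @param class_labels Ordered labels for codes 1..6.
#' @return A `cat_raster` object (an integer matrix with attributes).
#' @export
cat_raster <- function(values, cell_size, class_labels = land_classes()) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (nrow(values) < 3L || ncol(values) < 3L)
    stop("categorical raster must be at least 3x3, got ",
         nrow(values), "x", ncol(values))
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a positive scalar (metres)")
  bad <- setdiff(unique(values[!is.na(values)]), seq_len(N_CLASS))
  if (length(bad) > 0L)
    stop("invalid land-class codes outside {1..6}: ",
         paste(sort(bad), collapse = ", "))
  if (length(class_labels) != N_CLASS)
    stop("class_labels must have length 6")
  structure(values, class = "cat_raster", cell_size = as.numeric(cell_size),
            class_labels = as.character(class_labels))
}

#' Construct a continuous raster
#'
#' @param values Numeric matrix; `NA` marks nodata.
#' @param cell_size Cell edge length in metres.
#' @return A `cont_raster` object.
#' @export
cont_raster <- function(values, cell_size) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a positive scalar (metres)")
  structure(values, class = "cont_raster", cell_size = as.numeric(cell_size))
}

#' @export
print.cat_raster <- function(x, ...) {
  cat(sprintf("<cat_raster> %d x %d cells, %.6g m cells, %d nodata\n",
              nrow(x), ncol(x), attr(x, "cell_size"), sum(is.na(x))))
  tab <- tabulate(x[!is.na(x)], nbins = N_CLASS)
  names(tab) <- attr(x, "class_labels")
  print(tab)
  invisible(x)
}

#' @export
print.cont_raster <- function(x, ...) {
  v <- x[!is.na(x)]
  cat(sprintf("<cont_raster> %d x %d cells, %.6g m cells, range [%.4g, %.4g]\n",
              nrow(x), ncol(x), attr(x, "cell_size"),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

cell_size_of <- function(r) attr(r, "cell_size")

values_of <- function(r) {
  v <- unclass(r)
  attributes(v) <- list(dim = dim(r))
  v
}

# stop unless a and b share shape and cell size
check_aligned <- function(a, b, what = "rasters") {
  if (!identical(dim(a), dim(b)))
    stop(what, " have mismatched shapes: ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"))
  if (!isTRUE(all.equal(cell_size_of(a), cell_size_of(b))))
    stop(what, " have mismatched cell sizes: ", cell_size_of(a), " vs ",
         cell_size_of(b), " (mixed resolutions are rejected, not resampled)")
  invisible(TRUE)
}

#' Class counts of a categorical raster
#'
#' @param lu A `cat_raster`.
#' @return Named integer vector of per-class cell counts (length 6).
#' @export
class_counts <- function(lu) {
  stats::setNames(tabulate(lu[!is.na(lu)], nbins = N_CLASS),
                  attr(lu, "class_labels"))
}

# ---------------------------------------------------------------------------
# Driver stacks

#' Canonical driver layer names
#' @return Character vector of the nine driver layer names.
#' @export
driver_names <- function() {
  c("dem", "slope", "gdp_density", "pop_density", "dist_town", "dist_river",
    "dist_national_road", "dist_provincial_road", "dist_railway")
}

#' Bundle continuous rasters into a driver stack
#'
#' All layers must share shape and cell size. Min-max normalised copies
#' (computed over non-nodata cells) are stored alongside the raw layers;
#' cells that are nodata in ANY layer are nodata in every normalised layer,
#' so downstream sampling and allocation see one common valid mask.
#'
#' @param layers Named list of `cont_raster` objects.
#' @return A `driver_stack` with elements `layers`, `normalized` (matrices in
#'   `[0,1]`), `valid` (logical matrix), `cell_size`.
#' @export
driver_stack <- function(layers) {
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    stop("driver layers must be named")
  if (length(layers) < 1L) stop("empty driver stack")
  ref <- layers[[1L]]
  for (nm in names(layers)) check_aligned(ref, layers[[nm]],
                                          paste0("driver layers (", nm, ")"))
  valid <- Reduce(`&`, lapply(layers, function(l) !is.na(l)))
  normalized <- lapply(layers, function(l) {
    v <- values_of(l)
    v[!valid] <- NA_real_
    rng <- range(v, na.rm = TRUE)
    if (diff(rng) == 0) v[] <- ifelse(is.na(v), NA_real_, 0) else
      v <- (v - rng[1L]) / diff(rng)
    v
  })
  structure(list(layers = layers, normalized = normalized, valid = valid,
                 cell_size = cell_size_of(ref)),
            class = "driver_stack")
}

#' @export
print.driver_stack <- function(x, ...) {
  cat(sprintf("<driver_stack> %d layers, %d x %d cells, %.6g m cells\n",
              length(x$layers), nrow(x$valid), ncol(x$valid), x$cell_size))
  cat(" layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# ESRI ASCII grid I/O

#' Read a raster from an ESRI ASCII grid file
#'
#' @param path File path.
#' @param kind `"categorical"` or `"continuous"`.
#' @return A `cat_raster` or `cont_raster`.
#' @export
read_raster <- function(path, kind = c("categorical", "continuous")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    stop("GeoTIFF is not supported in this build (no GDAL-backed R package ",
         "available); use the ESRI ASCII grid format")
  lines <- readLines(path, n = 6L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(parts) == 2L && !is.na(suppressWarnings(as.numeric(parts[2L]))) &&
        grepl("^[A-Za-z_]+$", parts[1L])) {
      hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
      n_hdr <- n_hdr + 1L
    } else break
  }
  for (key in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[key]])) stop("malformed ESRI ASCII header: missing ", key)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(path, what = double(), skip = n_hdr, quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("expected ", nr * nc, " values, found ", length(vals))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  if (kind == "categorical") cat_raster(m, hdr$cellsize)
  else cont_raster(m, hdr$cellsize)
}

#' Write a raster to an ESRI ASCII grid file
#'
#' @param raster A `cat_raster` or `cont_raster`.
#' @param path Output file path.
#' @param format Only `"ascii"` is supported in this build.
#' @param nodata Value used to encode nodata cells.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path, format = c("ascii", "geotiff"),
                         nodata = -9999) {
  format <- match.arg(format)
  if (format == "geotiff")
    stop("GeoTIFF is not supported in this build (no GDAL-backed R package ",
         "available); use format = \"ascii\"")
  m <- values_of(raster)
  m[is.na(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(m)),
               paste("nrows", nrow(m)),
               paste("xllcorner", 0),
               paste("yllcorner", 0),
               paste("cellsize", format(cell_size_of(raster), digits = 15)),
               paste("NODATA_value", nodata)), con)
  write.table(format(m, digits = 15, trim = TRUE, scientific = FALSE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Exact Euclidean distance transform (Felzenszwalb & Huttenlocher two-pass)

# 1D squared distance transform by lower envelope of parabolas; infinite
# entries (no source anywhere in this line yet) carry no parabola
dt_1d <- function(f) {
  n <- length(f)
  idx <- which(is.finite(f))
  if (length(idx) == 0L) return(f)
  d <- numeric(n)
  v <- integer(n)
  z <- numeric(n + 1L)
  k <- 1L
  v[1L] <- idx[1L]
  z[1L] <- -Inf
  z[2L] <- Inf
  if (length(idx) > 1L) for (q in idx[-1L]) {
    repeat {
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
      if (k > 1L && s <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Euclidean distance to the nearest source cell
#'
#' Exact centre-to-centre Euclidean distance, in metres, from every cell to
#' the nearest `TRUE` cell of the mask. Source cells read 0.
#'
#' @param mask Logical matrix (or 0/1 matrix) of source cells.
#' @param cell_size Cell edge length in metres.
#' @return A `cont_raster` of distances.
#' @export
distance_transform <- function(mask, cell_size) {
  m <- as.matrix(mask)
  storage.mode(m) <- "logical"
  if (!any(m, na.rm = TRUE))
    stop("distance_transform: mask has no TRUE cell; distance is undefined")
  m[is.na(m)] <- FALSE
  f <- matrix(Inf, nrow(m), ncol(m))
  f[m] <- 0
  # pass 1: columns; pass 2: rows of the column result
  for (j in seq_len(ncol(f))) f[, j] <- dt_1d(f[, j])
  for (i in seq_len(nrow(f))) f[i, ] <- dt_1d(f[i, ])
  cont_raster(sqrt(f) * cell_size, cell_size)
}

# restore-on-exit seeded evaluation; all package randomness goes through this
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}
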