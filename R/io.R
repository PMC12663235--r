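# Raster and box-list readers/writers. Images and masks are exchanged as
# 8-bit PNG/TIFF; instance masks as 16-bit TIFF (or 16-bit PNG on read).
# Box lists are whitespace-delimited text with 0-based inclusive
# coordinates (x = column, y = row), one box per line.

read_raster_raw <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    list(data = img, scale = 2^depth - 1)
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    info <- attributes(img)
    depth <- if (!is.null(info$bits.per.sample)) info$bits.per.sample else 8L
    list(data = img, scale = 2^depth - 1)
  } else {
    abort(sprintf("Unsupported raster format '%s' (use PNG or TIFF).", ext))
  }
}

#' Read an RGB image
#'
#' Reads an 8-bit 3-channel PNG or TIFF as an H x W x 3 array on the
#' 0-255 scale. A trailing alpha channel is dropped.
#'
#' @param path file path.
#' @return H x W x 3 numeric array.
#' @export
read_image <- function(path) {
  r <- read_raster_raw(path)
  img <- r$data
  if (length(dim(img)) != 3L || !(dim(img)[3] %in% c(3L, 4L))) {
    abort(sprintf("%s is not a 3-channel RGB image; convert it to RGB first.", path))
  }
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  array(round(img * 255), dim(img))
}

#' Write an RGB image
#'
#' @param image H x W x 3 array, 0-255 scale.
#' @param path output path (`.png`, `.tif` or `.tiff`).
#' @return the path, invisibly.
#' @export
write_image <- function(image, path) {
  assert_rgb_image(image)
  ext <- tolower(tools::file_ext(path))
  scaled <- image / 255
  if (ext == "png") {
    png::writePNG(scaled, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(scaled, path, bits.per.sample = 8L)
  } else {
    abort("Use a .png, .tif or .tiff extension.")
  }
  invisible(path)
}

#' Read a mask raster
#'
#' Reads a single-channel PNG or TIFF. With `type = "binary"` nonzero
#' values become 1; with `type = "instance"` the integer labels are
#' preserved (16-bit rasters supported).
#'
#' @param path file path.
#' @param type `"binary"` (default) or `"instance"`.
#' @return a 0/1 matrix or an integer instance matrix.
#' @export
read_mask <- function(path, type = c("binary", "instance")) {
  type <- match.arg(type)
  r <- read_raster_raw(path)
  if (length(dim(r$data)) != 2L) {
    abort(sprintf(
      "%s has %d channels but masks must be single-channel; export the mask as a grayscale raster.",
      path, dim(r$data)[3]))
  }
  vals <- round(r$data * r$scale)
  if (type == "binary") {
    matrix(as.numeric(vals > 0), nrow(vals), ncol(vals))
  } else {
    m <- matrix(as.integer(vals), nrow(vals), ncol(vals))
    m
  }
}

#' Write a mask raster
#'
#' Binary masks are written as 8-bit rasters (0/255); instance masks as
#' 16-bit TIFF preserving the integer labels.
#'
#' @param mask 0/1 matrix or integer instance matrix.
#' @param path output path; instance masks require `.tif`/`.tiff`.
#' @param type `"binary"` (default) or `"instance"`.
#' @return the path, invisibly.
#' @export
write_mask <- function(mask, path, type = c("binary", "instance")) {
  type <- match.arg(type)
  ext <- tolower(tools::file_ext(path))
  storage.mode(mask) <- "double"
  if (type == "binary") {
    assert_binary_mask(mask)
    if (ext == "png") {
      png::writePNG(mask, path)
    } else if (ext %in% c("tif", "tiff")) {
      tiff::writeTIFF(mask, path, bits.per.sample = 8L)
    } else {
      abort("Use a .png, .tif or .tiff extension.")
    }
  } else {
    if (max(mask) > 65535) abort("Instance IDs exceed the 16-bit range.")
    if (!ext %in% c("tif", "tiff")) {
      abort("Instance masks are written as 16-bit TIFF; use a .tif/.tiff extension.")
    }
    tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  }
  invisible(path)
}

#' Read a box list
#'
#' Reads a whitespace-delimited text file with one `x_min y_min x_max
#' y_max instance_id` line per box (0-based inclusive coordinates;
#' `#` lines are comments).
#'
#' @param path file path.
#' @return a tibble with the five box columns.
#' @export
read_boxes <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) {
    return(tibble(x_min = integer(0), y_min = integer(0),
                  x_max = integer(0), y_max = integer(0),
                  instance_id = integer(0)))
  }
  vals <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.integer))
  tibble(x_min = vals[, 1], y_min = vals[, 2],
         x_max = vals[, 3], y_max = vals[, 4], instance_id = vals[, 5])
}

#' Write a box list
#'
#' @param boxes tibble/data.frame with `x_min`, `y_min`, `x_max`,
#'   `y_max`, `instance_id` (0-based inclusive).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_boxes <- function(boxes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# x_min y_min x_max y_max instance_id (0-based, inclusive; x = column, y = row)", con)
  if (nrow(boxes) > 0L) {
    apply(boxes[, c("x_min", "y_min", "x_max", "y_max", "instance_id")], 1,
          function(r) writeLines(paste(r, collapse = " "), con))
  }
  invisible(path)
}

#' Default run configuration
#'
#' The shipped defaults: `lambda = 2`, `theta = 25`, `grid_k = 5`,
#' `n_components = 2`, `min_area = 20`, `solver = "maxflow"`,
#' `seed = 0`.
#'
#' @param ... named overrides of any default.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(lambda = 2, theta = 25, grid_k = 5L, n_components = 2L,
              min_area = 20L, solver = "maxflow", seed = 0L)
  dots <- list(...)
  unknown <- setdiff(names(dots), c(names(cfg),
    "image", "mask_d", "mask_s", "itd_instances", "boxes", "gt", "out_dir"))
  if (length(unknown)) {
    abort(sprintf("Unknown config field(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Read a run configuration from JSON
#'
#' Accepts the same keys as [run_config()].
#'
#' @param path JSON file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(run_config, as.list(vals))
}
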