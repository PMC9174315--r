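# Slide-image abstraction: a pyramidal image addressed by magnification
# (5, 10, 20, 40), with three backends — procedural synthetic slides,
# multi-page TIFF pyramids, and a directory-of-PNG-tiles layout.
# These readers target desk-scale images (whole levels fit in memory);
# they are not a gigapixel virtual-slide driver.

MAGNIFICATIONS <- c(5, 10, 20, 40)
PATCH_SIZE <- 512L

#' Pyramid level dimensions of a slide
#'
#' @param slide A `slide_image` object.
#' @param magnification One of 5, 10, 20, 40.
#' @return Named integer vector `c(width, height)` in pixels.
#' @export
slide_dims <- function(slide, magnification) UseMethod("slide_dims")

#' Read one 512x512 patch from a slide
#'
#' Patches are non-overlapping grid cells: the patch at 0-based
#' `(grid_row, grid_col)` covers pixels
#' `[512*grid_col, 512*grid_col + 512) x [512*grid_row, ...)` of the
#' requested level.
#'
#' @param slide A `slide_image` object.
#' @param magnification One of 5, 10, 20, 40.
#' @param grid_row,grid_col 0-based patch grid coordinates.
#' @return A 512 x 512 x 3 numeric array in `[0, 1]`.
#' @export
read_patch <- function(slide, magnification, grid_row, grid_col)
  UseMethod("read_patch")

#' Read a whole pyramid level
#'
#' @inheritParams read_patch
#' @return A height x width x 3 numeric array in `[0, 1]`.
#' @export
read_level <- function(slide, magnification) UseMethod("read_level")

check_magnification <- function(magnification) {
  if (!magnification %in% MAGNIFICATIONS)
    stop(sprintf("magnification must be one of %s (got %s)",
                 paste(MAGNIFICATIONS, collapse = "/"), magnification),
         call. = FALSE)
  magnification
}

# ---- synthetic backend -------------------------------------------------

#' @export
slide_dims.synthetic_slide <- function(slide, magnification) {
  check_magnification(magnification)
  level_dims_synthetic(slide, magnification)
}

#' @export
read_patch.synthetic_slide <- function(slide, magnification, grid_row,
                                       grid_col) {
  check_magnification(magnification)
  render_region(slide, magnification,
                x0 = PATCH_SIZE * grid_col, y0 = PATCH_SIZE * grid_row,
                w = PATCH_SIZE, h = PATCH_SIZE)
}

#' @export
read_level.synthetic_slide <- function(slide, magnification) {
  check_magnification(magnification)
  d <- slide_dims(slide, magnification)
  w <- d[["width"]]; h <- d[["height"]]
  out <- array(0, c(h, w, 3L))
  nr <- h %/% PATCH_SIZE; nc <- w %/% PATCH_SIZE
  for (r in seq_len(nr) - 1L) {
    for (c in seq_len(nc) - 1L) {
      out[r * PATCH_SIZE + 1:PATCH_SIZE, c * PATCH_SIZE + 1:PATCH_SIZE, ] <-
        read_patch(slide, magnification, r, c)
    }
  }
  # remainder strips (right, bottom) rendered with their own substreams
  if (nc * PATCH_SIZE < w)
    out[, (nc * PATCH_SIZE + 1L):w, ] <-
      render_region(slide, magnification, nc * PATCH_SIZE, 0L,
                    w - nc * PATCH_SIZE, h)
  if (nr * PATCH_SIZE < h && nc > 0L)
    out[(nr * PATCH_SIZE + 1L):h, 1:(nc * PATCH_SIZE), ] <-
      render_region(slide, magnification, 0L, nr * PATCH_SIZE,
                    nc * PATCH_SIZE, h - nr * PATCH_SIZE)
  out
}

# ---- multi-page TIFF backend ------------------------------------------

#' Write a slide as a multi-page pyramidal TIFF
#'
#' Page k holds the level at `magnifications[k]`; a JSON sidecar
#' (`<path>.json`) records slide id and the magnification of each page.
#'
#' @param slide A `slide_image`.
#' @param path Output `.tiff` path.
#' @param magnifications Levels to materialise (default all four).
#' @return `path`, invisibly.
#' @export
write_slide_tiff <- function(slide, path,
                             magnifications = MAGNIFICATIONS) {
  levels <- lapply(magnifications, function(m) read_level(slide, m))
  tiff::writeTIFF(levels, path, compression = "deflate")
  meta <- list(slide_id = slide$slide_id,
               patient_id = slide$patient_id %||% NA,
               magnifications = magnifications)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Open a multi-page TIFF pyramid as a slide
#'
#' Levels are loaded into memory. If a requested magnification has no
#' page, it is synthesised by area-averaging the nearest higher level.
#'
#' @param path `.tiff` file written by [write_slide_tiff()] (or any
#'   multi-page TIFF with the matching JSON sidecar).
#' @return A `tiff_slide` object.
#' @export
read_slide_tiff <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read slide image '%s'", path), call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stop(sprintf("unreadable slide image '%s': %s",
                                   path, conditionMessage(e)), call. = FALSE))
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    mags <- as.numeric(meta$magnifications)
    slide_id <- meta$slide_id
    patient_id <- meta$patient_id
  } else {
    # assume pages ordered base-first, powers-of-two pyramid from 40x
    mags <- 40 / 2^(seq_along(pages) - 1L)
    slide_id <- tools::file_path_sans_ext(basename(path))
    patient_id <- NA
  }
  levels <- stats::setNames(pages, as.character(mags))
  structure(list(slide_id = slide_id, patient_id = patient_id,
                 levels = levels, base_magnification = max(mags)),
            class = c("tiff_slide", "slide_image"))
}

get_or_synthesize_level <- function(slide, magnification) {
  key <- as.character(magnification)
  lv <- slide$levels[[key]]
  if (!is.null(lv)) return(lv)
  have <- as.numeric(names(slide$levels))
  higher <- sort(have[have > magnification])
  if (length(higher) == 0L)
    stop(sprintf("slide %s has no level at or above %gx",
                 slide$slide_id, magnification), call. = FALSE)
  src <- slide$levels[[as.character(higher[1L])]]
  factor <- higher[1L] / magnification
  if (factor != round(factor))
    stop(sprintf("cannot synthesize %gx from %gx", magnification,
                 higher[1L]), call. = FALSE)
  downsample_mean(src, as.integer(factor))
}

#' @export
slide_dims.tiff_slide <- function(slide, magnification) {
  check_magnification(magnification)
  lv <- get_or_synthesize_level(slide, magnification)
  c(width = ncol(lv), height = nrow(lv))
}

#' @export
read_patch.tiff_slide <- function(slide, magnification, grid_row, grid_col) {
  check_magnification(magnification)
  lv <- get_or_synthesize_level(slide, magnification)
  r0 <- grid_row * PATCH_SIZE; c0 <- grid_col * PATCH_SIZE
  if (r0 + PATCH_SIZE > nrow(lv) || c0 + PATCH_SIZE > ncol(lv))
    stop(sprintf("patch (%d,%d) outside slide %s at %gx",
                 grid_row, grid_col, slide$slide_id, magnification),
         call. = FALSE)
  lv[r0 + 1:PATCH_SIZE, c0 + 1:PATCH_SIZE, 1:3, drop = FALSE]
}

#' @export
read_level.tiff_slide <- function(slide, magnification) {
  check_magnification(magnification)
  get_or_synthesize_level(slide, magnification)
}

# ---- directory-of-tiles backend ---------------------------------------

#' Write a slide as a directory of PNG tiles
#'
#' Layout: `<dir>/meta.json` plus
#' `<dir>/mag<m>/tile_r<row>_c<col>.png` for every full 512x512 grid
#' cell of each level (edge remainders are not stored).
#'
#' @param slide A `slide_image`.
#' @param dir Output directory (created).
#' @param magnifications Levels to materialise.
#' @return `dir`, invisibly.
#' @export
write_slide_tiles <- function(slide, dir,
                              magnifications = MAGNIFICATIONS) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dims <- list()
  for (m in magnifications) {
    d <- slide_dims(slide, m)
    dims[[as.character(m)]] <- as.integer(d)
    sub <- file.path(dir, paste0("mag", m))
    dir.create(sub, showWarnings = FALSE)
    for (r in seq_len(d[["height"]] %/% PATCH_SIZE) - 1L)
      for (c in seq_len(d[["width"]] %/% PATCH_SIZE) - 1L)
        png::writePNG(read_patch(slide, m, r, c),
                      file.path(sub, sprintf("tile_r%d_c%d.png", r, c)))
  }
  meta <- list(slide_id = slide$slide_id,
               patient_id = slide$patient_id %||% NA,
               magnifications = magnifications, level_dims = dims)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Open a directory-of-tiles slide
#'
#' @param dir Directory written by [write_slide_tiles()].
#' @return A `tile_dir_slide` object.
#' @export
read_slide_tiles <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path))
    stop(sprintf("cannot read slide directory '%s': missing meta.json", dir),
         call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  structure(list(slide_id = meta$slide_id, patient_id = meta$patient_id,
                 dir = dir,
                 level_dims = lapply(meta$level_dims, as.integer),
                 magnifications = as.numeric(meta$magnifications)),
            class = c("tile_dir_slide", "slide_image"))
}

#' @export
slide_dims.tile_dir_slide <- function(slide, magnification) {
  check_magnification(magnification)
  d <- slide$level_dims[[as.character(magnification)]]
  if (is.null(d))
    stop(sprintf("slide %s has no stored level at %gx", slide$slide_id,
                 magnification), call. = FALSE)
  c(width = d[1L], height = d[2L])
}

#' @export
read_patch.tile_dir_slide <- function(slide, magnification, grid_row,
                                      grid_col) {
  check_magnification(magnification)
  path <- file.path(slide$dir, paste0("mag", magnification),
                    sprintf("tile_r%d_c%d.png", grid_row, grid_col))
  if (!file.exists(path))
    stop(sprintf("missing tile (%d,%d) at %gx for slide %s",
                 grid_row, grid_col, magnification, slide$slide_id),
         call. = FALSE)
  img <- png::readPNG(path)
  img[, , 1:3, drop = FALSE]
}

#' @export
read_level.tile_dir_slide <- function(slide, magnification) {
  d <- slide_dims(slide, magnification)
  nr <- d[["height"]] %/% PATCH_SIZE; nc <- d[["width"]] %/% PATCH_SIZE
  out <- array(0, c(nr * PATCH_SIZE, nc * PATCH_SIZE, 3L))
  for (r in seq_len(nr) - 1L)
    for (c in seq_len(nc) - 1L)
      out[r * PATCH_SIZE + 1:PATCH_SIZE, c * PATCH_SIZE + 1:PATCH_SIZE, ] <-
        read_patch(slide, magnification, r, c)
  out
}
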