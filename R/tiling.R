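# Non-overlapping 512x512 patch grids with background filtering.

#' Background fraction of a patch
#'
#' A pixel counts as background (white glass) when its HSV saturation is
#' below `sat_max` and its brightness (value) is above `val_min`. The
#' thresholds are exposed because background appearance varies between
#' scanners and stains.
#'
#' @param pixels H x W x 3 numeric array in `[0, 1]`.
#' @param sat_max,val_min HSV thresholds of the white-glass detector.
#' @return Fraction of background pixels in `[0, 1]`.
#' @export
background_fraction <- function(pixels, sat_max = 0.08, val_min = 0.85) {
  v <- pmax(pixels[, , 1L], pixels[, , 2L], pixels[, , 3L])
  mn <- pmin(pixels[, , 1L], pixels[, , 2L], pixels[, , 3L])
  s <- (v - mn) / v
  s[!is.finite(s)] <- 0
  mean(s < sat_max & v > val_min)
}

#' Tile a slide into a non-overlapping 512x512 patch grid
#'
#' Enumerates the full grid in row-major order; partial edge tiles are
#' discarded, so the grid holds exactly
#' `floor(height/512) * floor(width/512)` patches, each covering the
#' half-open pixel block `[512*col, 512*col + 512) x [512*row, ...)`.
#'
#' @param slide A `slide_image`.
#' @param magnification One of 5, 10, 20, 40.
#' @param compute_background If `TRUE` (default) each patch is read and
#'   its [background_fraction()] recorded; set `FALSE` to enumerate
#'   geometry only (the column is then `NA`).
#' @param sat_max,val_min Passed to [background_fraction()].
#' @return A `patch_grid`: a data.frame with columns slide_id,
#'   magnification, grid_row, grid_col, origin_x, origin_y,
#'   background_fraction, kept, plus attributes `n_rows`, `n_cols`,
#'   `level_width`, `level_height`.
#' @export
tile_slide <- function(slide, magnification, compute_background = TRUE,
                       sat_max = 0.08, val_min = 0.85) {
  check_magnification(magnification)
  d <- slide_dims(slide, magnification)
  nr <- d[["height"]] %/% PATCH_SIZE
  nc <- d[["width"]] %/% PATCH_SIZE
  n <- nr * nc
  if (n == 0L) {
    grid <- data.frame(slide_id = character(), magnification = numeric(),
                       grid_row = integer(), grid_col = integer(),
                       origin_x = integer(), origin_y = integer(),
                       background_fraction = numeric(), kept = logical(),
                       stringsAsFactors = FALSE)
  } else {
    grid_row <- rep(seq_len(nr) - 1L, each = nc)   # row-major enumeration
    grid_col <- rep(seq_len(nc) - 1L, times = nr)
    bf <- rep(NA_real_, n)
    if (compute_background) {
      for (i in seq_len(n))
        bf[i] <- background_fraction(
          read_patch(slide, magnification, grid_row[i], grid_col[i]),
          sat_max = sat_max, val_min = val_min)
    }
    grid <- data.frame(
      slide_id = slide$slide_id, magnification = magnification,
      grid_row = grid_row, grid_col = grid_col,
      origin_x = PATCH_SIZE * grid_col, origin_y = PATCH_SIZE * grid_row,
      background_fraction = bf, kept = TRUE, stringsAsFactors = FALSE)
  }
  structure(grid, class = c("patch_grid", "data.frame"),
            n_rows = nr, n_cols = nc,
            level_width = d[["width"]], level_height = d[["height"]])
}

#' Filter background patches
#'
#' Keeps patches whose background coverage is at most `threshold`;
#' strictly more than `threshold` is excluded, so a patch at exactly
#' 50% background survives the default filter.
#'
#' @param grid A `patch_grid` with computed background fractions.
#' @param threshold Maximum tolerated background fraction (default 0.5).
#' @return The grid with its `kept` flags updated.
#' @export
filter_background <- function(grid, threshold = 0.5) {
  check_scalar_num(threshold, "threshold", 0, 1)
  if (nrow(grid) > 0L && anyNA(grid$background_fraction))
    stop("background_fraction has not been computed for this grid",
         call. = FALSE)
  grid$kept <- grid$kept & grid$background_fraction <= threshold
  grid
}

#' Kept patches of a grid
#'
#' @param grid A `patch_grid`.
#' @return The rows with `kept == TRUE`.
#' @export
kept_patches <- function(grid) grid[grid$kept, , drop = FALSE]

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("<patch_grid> %s at %gx: %d x %d grid, %d kept of %d\n",
              if (nrow(x)) x$slide_id[1L] else "?",
              if (nrow(x)) x$magnification[1L] else NA,
              attr(x, "n_rows"), attr(x, "n_cols"),
              sum(x$kept), nrow(x)))
  invisible(x)
}

#' Write / read a patch inventory CSV
#'
#' One row per enumerated patch with its grid coordinates, pixel origin,
#' background fraction and kept flag.
#'
#' @param grids A `patch_grid` or list of them.
#' @param path CSV path.
#' @return `read_patch_inventory` returns a data.frame.
#' @export
write_patch_inventory <- function(grids, path) {
  if (inherits(grids, "data.frame")) grids <- list(grids)
  df <- do.call(rbind, lapply(grids, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_patch_inventory
#' @export
read_patch_inventory <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
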