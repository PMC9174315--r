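#' @keywords internal
"_PACKAGE"

# ---- seeding -----------------------------------------------------------

# 32-bit FNV-1a over a string, kept exact in double arithmetic by
# splitting the running hash into 16-bit halves before multiplying.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(as.character(x)))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    h <- bitwXor32(h, b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- ((lo * p) %% 4294967296 + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  h
}

bitwXor32 <- function(a, b) {
  # bitwXor works on 32-bit signed ints; route through the two halves
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi <- bitwXor((a - a %% 65536) / 65536, (b - b %% 65536) / 65536)
  hi * 65536 + lo
}

#' Derive a reproducible sub-stream seed
#'
#' Mixes a base seed with an arbitrary sequence of identifiers (patient ids,
#' slide ids, magnifications, grid coordinates, ...) into a stable 31-bit
#' seed. The mapping is a pure function of its arguments, so any component
#' of the pipeline can reconstruct its random sub-stream from the run seed
#' and the identifiers alone.
#'
#' @param seed Integer base seed.
#' @param ... Identifiers coerced to character and hashed.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
mix_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "\x1f")
  (fnv1a32(key) %% 2147483645) + 1
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# ---- validation helpers ------------------------------------------------

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar_num <- function(x, field, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_field(field, "must be a single non-missing number")
  if (x < lo || x > hi)
    stop_field(field, sprintf("must be in [%s, %s]", lo, hi))
  invisible(x)
}

check_flag <- function(x, field) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_field(field, "must be TRUE or FALSE")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- image helpers -----------------------------------------------------

# Area-average downsample of an H x W x C array by an integer factor.
downsample_mean <- function(img, factor) {
  d <- dim(img)
  h <- d[1L]; w <- d[2L]; ch <- if (length(d) == 3L) d[3L] else 1L
  stopifnot(h %% factor == 0L, w %% factor == 0L)
  hh <- h %/% factor; ww <- w %/% factor
  # average row blocks first (one pass over the full array), then the
  # much smaller column blocks
  m1 <- colMeans(matrix(img, factor, hh * w * ch))       # (hh, w, ch)
  a <- aperm(array(m1, c(hh, factor, ww, ch)), c(2L, 1L, 3L, 4L))
  out <- colMeans(a, dims = 1L)                          # (hh, ww, ch)
  if (length(d) == 3L) array(out, c(hh, ww, ch)) else matrix(out, hh, ww)
}

# Nearest-neighbour upsample of a matrix to target dimensions.
upsample_nearest <- function(m, h, w) {
  ri <- pmin(nrow(m), pmax(1L, ceiling(seq_len(h) / h * nrow(m))))
  ci <- pmin(ncol(m), pmax(1L, ceiling(seq_len(w) / w * ncol(m))))
  m[ri, ci, drop = FALSE]
}

# Bilinear upsample of a matrix to target dimensions (used to blow small
# activation maps up to patch resolution).
upsample_bilinear <- function(m, h, w) {
  sr <- nrow(m); sc <- ncol(m)
  if (sr == 1L && sc == 1L) return(matrix(m[1L, 1L], h, w))
  yi <- (seq_len(h) - 0.5) / h * sr - 0.5
  xi <- (seq_len(w) - 0.5) / w * sc - 0.5
  y0 <- pmin(pmax(floor(yi), 0), sr - 1); y1 <- pmin(y0 + 1, sr - 1)
  x0 <- pmin(pmax(floor(xi), 0), sc - 1); x1 <- pmin(x0 + 1, sc - 1)
  fy <- pmin(pmax(yi - y0, 0), 1); fx <- pmin(pmax(xi - x0, 0), 1)
  a <- m[y0 + 1, x0 + 1, drop = FALSE] * outer(1 - fy, 1 - fx)
  a <- a + m[y1 + 1, x0 + 1, drop = FALSE] * outer(fy, 1 - fx)
  a <- a + m[y0 + 1, x1 + 1, drop = FALSE] * outer(1 - fy, fx)
  a + m[y1 + 1, x1 + 1, drop = FALSE] * outer(fy, fx)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

patch_key <- function(slide_id, magnification, grid_row, grid_col) {
  paste(slide_id, magnification, grid_row, grid_col, sep = "|")
}

split_patch_key <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)
  data.frame(
    slide_id = vapply(parts, `[`, "", 1L),
    magnification = as.numeric(vapply(parts, `[`, "", 2L)),
    grid_row = as.integer(vapply(parts, `[`, "", 3L)),
    grid_col = as.integer(vapply(parts, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
}
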