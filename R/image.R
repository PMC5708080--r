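#' @title N-dimensional images
#' @description
#' An image is an N-dimensional grid of samples of one [sample_type()], with
#' one of four storage layouts: `array` (one flat buffer), `planar` (one
#' buffer per 2D plane of the first two dimensions), `cell` (block-partitioned
#' with an LRU cache paging blocks to a backing store) and `function`
#' (samples computed on demand, read-only).  Coordinates are 0-based;
#' iteration order is row-major with the last dimension fastest.  All layouts
#' satisfy the same access contract, so algorithms are written once and run
#' on any of them.
#' @name images
NULL

# maximum samples materializable as one in-memory vector
.materialize_limit <- 2^26

is_ndimg <- function(x) inherits(x, "ndimg")

fmt_extent <- function(x) format(x, scientific = FALSE, trim = TRUE)

# normalize a shape given as numeric or exact decimal strings
normalize_shape <- function(shape) {
  if (is.character(shape)) {
    if (!all(grepl("^[0-9]+$", shape)))
      stop("shape strings must be decimal digit strings")
    chr <- sub("^0+(?=.)", "", shape, perl = TRUE)
    num <- as.numeric(chr)
  } else {
    stopifnot(is.numeric(shape))
    if (any(shape != floor(shape))) stop("extents must be integers")
    num <- as.numeric(shape)
    chr <- fmt_extent(num)
  }
  if (length(num) < 1L) stop("dimension count must be >= 1")
  if (any(num < 1)) stop("every extent must be >= 1")
  max63 <- "9223372036854775807"
  over <- nchar(chr) > nchar(max63) | (nchar(chr) == nchar(max63) & chr > max63)
  if (any(over)) stop("extent exceeds 2^63-1: ", chr[which(over)[1L]])
  list(num = num, chr = chr)
}

#' Create an image
#'
#' All samples are initialized to zero.  The `array` layout requires every
#' plane (product of the first two extents) to stay below 2^31 samples — a
#' 50,000 x 50,000 plane is rejected with advice to use the `cell` layout,
#' which pages blocks to disk, or the read-only `function` layout, whose
#' extents may go up to 2^63-1 (pass such extents as decimal strings).
#'
#' @param t a [sample_type()] (or its name, with `ctx`)
#' @param shape extent vector (numeric, or decimal strings for exact large
#'   extents); each extent in 1 .. 2^63-1
#' @param layout `"array"`, `"planar"`, `"cell"` or `"function"`
#' @param cell_opts for `layout = "cell"`: a list with `cell_shape`,
#'   `capacity` and optionally `backing` (see [create_cell_image()])
#' @param fn for `layout = "function"`: a vectorized function taking an
#'   n-by-d matrix of 0-based coordinates and returning n sample values
#' @param ctx optional context used to resolve a type name
#' @return an `ndimg`
#' @export
create_image <- function(t, shape, layout = c("array", "planar", "cell", "function"),
                         cell_opts = NULL, fn = NULL, ctx = NULL) {
  layout <- match.arg(layout)
  if (is.character(t)) {
    if (is.null(ctx)) stop("a context is required to resolve a type name")
    t <- get_sample_type(ctx, t)
  }
  stopifnot(inherits(t, "sample_type"))
  sh <- normalize_shape(shape)
  d <- length(sh$num)
  total <- prod(sh$num)
  if (layout != "function" && any(sh$num > 2^53))
    stop("extents beyond 2^53 require the function layout")
  if (layout %in% c("array", "planar")) {
    plane <- if (d >= 2L) sh$num[[1L]] * sh$num[[2L]] else sh$num[[1L]]
    if (plane >= 2^31)
      stop("capacity error: a plane of ", fmt_extent(plane),
           " samples cannot be held in one array; use layout = \"cell\"")
    if (layout == "array" && total >= 2^31)
      stop("capacity error: ", fmt_extent(total),
           " samples cannot be held in one array; use layout = \"cell\"")
  }
  img <- new.env(parent = emptyenv())
  class(img) <- "ndimg"
  img$type <- t
  img$shape <- sh$num
  img$shape_chr <- sh$chr
  img$ndim <- d
  img$layout <- layout
  if (layout == "array") {
    img$data <- numeric(total)
  } else if (layout == "planar") {
    plane <- if (d >= 2L) sh$num[[1L]] * sh$num[[2L]] else sh$num[[1L]]
    nplanes <- if (d > 2L) prod(sh$num[-(1:2)]) else 1
    if (nplanes * plane > .materialize_limit)
      stop("capacity error: planar image too large; use layout = \"cell\"")
    img$planes <- replicate(nplanes, numeric(plane), simplify = FALSE)
  } else if (layout == "cell") {
    if (is.null(cell_opts) || is.null(cell_opts$cell_shape) ||
        is.null(cell_opts$capacity))
      stop("cell layout requires cell_opts with cell_shape and capacity")
    init_cell_store(img, cell_opts$cell_shape, cell_opts$capacity,
                    cell_opts$backing)
  } else {
    if (is.null(fn)) fn <- function(coords) numeric(nrow(coords))
    img$fn <- fn
  }
  img
}

#' @export
print.ndimg <- function(x, ...) {
  cat("<image ", x$type$name, " [", paste(x$shape_chr, collapse = "x"),
      "] ", x$layout, ">\n", sep = "")
  invisible(x)
}

#' Image accessors
#'
#' @param img an `ndimg`
#' @return `img_shape()` the numeric extent vector; `img_shape_chr()` the
#'   exact decimal extents as strings (relevant beyond 2^53);
#'   `img_type()` the [sample_type()]; `img_layout()` the layout tag;
#'   `img_size()` the total sample count.
#' @export
img_shape <- function(img) img$shape

#' @rdname img_shape
#' @export
img_shape_chr <- function(img) img$shape_chr

#' @rdname img_shape
#' @export
img_type <- function(img) img$type

#' @rdname img_shape
#' @export
img_layout <- function(img) img$layout

#' @rdname img_shape
#' @export
img_size <- function(img) prod(img$shape)

# -- coordinate arithmetic (0-based, row-major, last dimension fastest) -------

as_coord_matrix <- function(coords, d) {
  if (is.matrix(coords)) {
    if (ncol(coords) != d) stop("coordinate matrix must have ", d, " columns")
    coords
  } else {
    if (length(coords) != d) stop("coordinate vector must have length ", d)
    matrix(coords, nrow = 1L)
  }
}

check_bounds <- function(coords, shape) {
  for (k in seq_along(shape)) {
    bad <- which(coords[, k] < 0 | coords[, k] >= shape[[k]] |
                   coords[, k] != floor(coords[, k]))
    if (length(bad))
      stop("coordinate out of bounds in dimension ", k, ": ",
           coords[bad[1L], k], " not in [0, ", fmt_extent(shape[[k]] - 1), "]")
  }
  invisible(TRUE)
}

# 0-based row-major linear index (last dimension fastest)
coords_to_linear <- function(coords, shape) {
  idx <- coords[, 1L]
  if (length(shape) > 1L)
    for (k in 2:length(shape)) idx <- idx * shape[[k]] + coords[, k]
  idx
}

linear_to_coords <- function(idx, shape) {
  d <- length(shape)
  out <- matrix(0, nrow = length(idx), ncol = d)
  rem <- idx
  for (k in d:1) {
    out[, k] <- rem %% shape[[k]]
    rem <- rem %/% shape[[k]]
  }
  out
}

# all coordinates of a shape in iteration order (guarded by size)
all_coords <- function(shape) {
  total <- prod(shape)
  if (total > .materialize_limit) stop("shape too large to enumerate")
  d <- length(shape)
  grids <- lapply(rev(shape), function(e) seq.int(0L, e - 1L))
  eg <- do.call(expand.grid, c(grids, KEEP.OUT.ATTRS = FALSE))
  m <- as.matrix(eg)[, d:1, drop = FALSE]
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  m
}

# planar helpers: plane over dims 1..2, plane index over trailing dims
planar_split <- function(coords, shape) {
  d <- length(shape)
  if (d == 1L) {
    list(plane = rep(1L, nrow(coords)), within = coords[, 1L])
  } else {
    within <- coords[, 1L] * shape[[2L]] + coords[, 2L]
    if (d == 2L) plane <- rep(1L, nrow(coords))
    else plane <- coords_to_linear(coords[, 3:d, drop = FALSE], shape[3:d]) + 1L
    list(plane = plane, within = within)
  }
}

# -- sample access ------------------------------------------------------------

#' Read or write individual samples
#'
#' `coords` may be a single 0-based coordinate vector or an n-by-d matrix for
#' vectorized access.  Reads return the last written value (0 initially);
#' writes are rejected on the immutable `function` layout and out-of-range
#' coordinates raise a bounds error naming the offending dimension.
#'
#' @param img an `ndimg`
#' @param coords coordinate vector or matrix (0-based)
#' @param values replacement values (recycled to the number of coordinates)
#' @return `img_get()` a numeric vector of sample values
#' @export
img_get <- function(img, coords) {
  coords <- as_coord_matrix(coords, img$ndim)
  check_bounds(coords, img$shape)
  switch(img$layout,
    array = img$data[coords_to_linear(coords, img$shape) + 1],
    planar = {
      ps <- planar_split(coords, img$shape)
      out <- numeric(nrow(coords))
      for (p in unique(ps$plane)) {
        sel <- ps$plane == p
        out[sel] <- img$planes[[p]][ps$within[sel] + 1]
      }
      out
    },
    cell = cell_get(img, coords),
    `function` = img$fn(coords)
  )
}

#' @rdname img_get
#' @export
img_set <- function(img, coords, values) {
  if (img$layout == "function")
    stop("immutability error: function-backed images are read-only")
  coords <- as_coord_matrix(coords, img$ndim)
  check_bounds(coords, img$shape)
  values <- rep_len(as.numeric(values), nrow(coords))
  switch(img$layout,
    array = { img$data[coords_to_linear(coords, img$shape) + 1] <- values },
    planar = {
      ps <- planar_split(coords, img$shape)
      for (p in unique(ps$plane)) {
        sel <- ps$plane == p
        buf <- img$planes[[p]]
        buf[ps$within[sel] + 1] <- values[sel]
        img$planes[[p]] <- buf
      }
    },
    cell = cell_set(img, coords, values)
  )
  invisible(img)
}

#' Bulk sample access in iteration order
#'
#' `img_values()` materializes every sample as one numeric vector in
#' row-major order (last dimension fastest); `set_img_values()` is the bulk
#' writer.  Cell images stream block by block; function-backed images are
#' evaluated (both guarded against absurd sizes — use [reduce_samples()] for
#' virtually large images).
#'
#' @param img an `ndimg`
#' @param values numeric vector of length `img_size(img)`
#' @return numeric vector of all samples
#' @export
img_values <- function(img) {
  total <- prod(img$shape)
  if (total > .materialize_limit)
    stop("image too large to materialize; use reduce_samples()")
  switch(img$layout,
    array = img$data,
    planar = {
      out <- numeric(total)
      cm <- all_coords(img$shape)
      ps <- planar_split(cm, img$shape)
      for (p in unique(ps$plane)) {
        sel <- ps$plane == p
        out[sel] <- img$planes[[p]][ps$within[sel] + 1]
      }
      out
    },
    cell = cell_values(img),
    `function` = img$fn(all_coords(img$shape))
  )
}

#' @rdname img_values
#' @export
set_img_values <- function(img, values) {
  total <- prod(img$shape)
  stopifnot(length(values) == total)
  if (img$layout == "function")
    stop("immutability error: function-backed images are read-only")
  values <- as.numeric(values)
  switch(img$layout,
    array = { img$data <- values },
    planar = {
      cm <- all_coords(img$shape)
      ps <- planar_split(cm, img$shape)
      for (p in unique(ps$plane)) {
        sel <- ps$plane == p
        buf <- img$planes[[p]]
        buf[ps$within[sel] + 1] <- values[sel]
        img$planes[[p]] <- buf
      }
    },
    cell = cell_set_values(img, values)
  )
  invisible(img)
}

#' Copy an image, optionally changing layout
#'
#' @param img an `ndimg`
#' @param layout target layout (default: same as `img`)
#' @param cell_opts cell options when the target layout is `"cell"`
#' @return a fresh image with identical samples
#' @export
img_copy <- function(img, layout = img$layout, cell_opts = NULL) {
  if (layout == "cell" && is.null(cell_opts)) {
    cs <- if (img$layout == "cell") img$store$cell_shape
          else pmin(img$shape, 32)
    cell_opts <- list(cell_shape = cs, capacity = 8L)
  }
  out <- create_image(img$type, img$shape, layout, cell_opts = cell_opts)
  set_img_values(out, img_values(img))
  out
}

# fresh image of the same geometry/type/layout (zero-filled)
img_like <- function(img, t = img$type) {
  if (img$layout == "cell")
    create_image(t, img$shape, "cell",
                 cell_opts = list(cell_shape = img$store$cell_shape,
                                  capacity = img$store$capacity))
  else if (img$layout == "function")
    create_image(t, img$shape, "array")
  else create_image(t, img$shape, img$layout)
}

# -- ROIs and iteration -------------------------------------------------------

#' Mask region of interest
#'
#' A ROI is a per-dimension closed bounding box `[min, max]` plus an optional
#' predicate over coordinates; the effective predicate is false outside the
#' bounding box.
#'
#' @param bbox_min,bbox_max integer vectors (0-based, closed interval)
#' @param predicate optional vectorized function over an n-by-d coordinate
#'   matrix returning a logical vector
#' @return a `mask_roi`
#' @export
mask_roi <- function(bbox_min, bbox_max, predicate = NULL) {
  stopifnot(length(bbox_min) == length(bbox_max), all(bbox_min <= bbox_max))
  structure(list(bbox_min = as.numeric(bbox_min),
                 bbox_max = as.numeric(bbox_max),
                 predicate = predicate),
            class = "mask_roi")
}

roi_test <- function(roi, coords) {
  inside <- rep(TRUE, nrow(coords))
  for (k in seq_along(roi$bbox_min))
    inside <- inside & coords[, k] >= roi$bbox_min[[k]] &
      coords[, k] <= roi$bbox_max[[k]]
  if (!is.null(roi$predicate) && any(inside))
    inside[inside] <- as.logical(roi$predicate(coords[inside, , drop = FALSE]))
  inside
}

#' Iterate samples in deterministic order
#'
#' Visits each sample exactly once in row-major order (last dimension
#' fastest); with a ROI, exactly the coordinates where the ROI predicate is
#' true, in the same order.
#'
#' @param img an `ndimg`
#' @param roi optional [mask_roi()]
#' @return a list with `coords` (n-by-d matrix, 0-based) and `values`
#' @export
iterate_samples <- function(img, roi = NULL) {
  cm <- all_coords(img$shape)
  if (!is.null(roi)) cm <- cm[roi_test(roi, cm), , drop = FALSE]
  list(coords = cm, values = if (nrow(cm)) img_get(img, cm) else numeric(0))
}

# -- blockwise reduction (virtually large images) -----------------------------

#' Blockwise sample reduction
#'
#' Streams an image in chunks of leading-dimension slabs (at most
#' `chunk_samples` samples resident at a time) and folds `f(acc, values,
#' coords)` over them.  This is how aggregate ops run on cell and
#' function-backed images far larger than memory.  The peak chunk size is
#' recorded on the result's `"peak_chunk"` attribute.
#'
#' @param img an `ndimg`
#' @param init initial accumulator
#' @param f fold function `(acc, values, coords) -> acc`
#' @param roi optional [mask_roi()]
#' @param chunk_samples resident-sample budget per chunk
#' @param need_coords set `FALSE` to skip building coordinate matrices when
#'   `f` ignores them (function layout still receives them)
#' @return the final accumulator, with attribute `peak_chunk`
#' @export
reduce_samples <- function(img, init, f, roi = NULL, chunk_samples = 4e6,
                           need_coords = TRUE) {
  shape <- img$shape
  d <- length(shape)
  rest <- if (d > 1L) prod(shape[-1L]) else 1
  rows_per <- max(1, floor(chunk_samples / rest))
  acc <- init
  peak <- 0
  r0 <- 0
  while (r0 < shape[[1L]]) {
    nr <- min(rows_per, shape[[1L]] - r0)
    sub_shape <- c(nr, if (d > 1L) shape[-1L])
    nsub <- prod(sub_shape)
    peak <- max(peak, nsub)
    coords <- NULL
    if (need_coords || img$layout != "array" || !is.null(roi))
      coords <- slab_coords(shape, r0, nr)
    vals <- switch(img$layout,
      `function` = img$fn(coords),
      array = img$data[(r0 * rest + 1):(r0 * rest + nsub)],
      img_get(img, coords))
    if (!is.null(roi)) {
      keep <- roi_test(roi, coords)
      vals <- vals[keep]
      coords <- coords[keep, , drop = FALSE]
    }
    acc <- f(acc, vals, coords)
    r0 <- r0 + nr
  }
  attr(acc, "peak_chunk") <- peak
  acc
}

# coordinates of the slab rows [r0, r0+nr) in iteration order, built with
# rep() arithmetic (expand.grid is too slow for multi-million-sample slabs)
slab_coords <- function(shape, r0, nr) {
  d <- length(shape)
  sub <- c(nr, if (d > 1L) shape[-1L])
  n <- prod(sub)
  out <- matrix(0, nrow = n, ncol = d)
  for (k in seq_len(d)) {
    each <- if (k < d) prod(shape[(k + 1L):d]) else 1
    vals <- if (k == 1L) seq.int(r0, r0 + nr - 1L) else seq.int(0L, shape[[k]] - 1L)
    times <- n / (each * length(vals))
    out[, k] <- rep(rep(vals, each = each), times = times)
  }
  out
}

# -- synthetic fixtures -------------------------------------------------------

#' Synthetic image fixtures
#'
#' Deterministic test patterns used throughout the test suite (no external
#' data): `constant` (all samples `value`), `gradient` (sample = row-major
#' index mod (type max + 1)), `impulse` (1 at `at`, else 0) and `noise`
#' (seeded uniform integers in `[min, max]` for bounded integer types,
#' uniform reals in `[0, 1)` for real types; identical for equal seeds).
#'
#' @param pattern `"constant"`, `"gradient"`, `"impulse"` or `"noise"`
#' @param t a [sample_type()]
#' @param shape extent vector
#' @param layout storage layout
#' @param value constant value (pattern `"constant"`)
#' @param at 0-based impulse coordinate (pattern `"impulse"`)
#' @param seed RNG seed (pattern `"noise"`)
#' @param cell_opts options for `layout = "cell"` (defaulted when absent)
#' @return an `ndimg`
#' @export
make_fixture <- function(pattern = c("constant", "gradient", "impulse", "noise"),
                         t, shape, layout = "array", value = 0,
                         at = NULL, seed = 1L, cell_opts = NULL) {
  pattern <- match.arg(pattern)
  sh <- normalize_shape(shape)$num
  total <- prod(sh)
  if (pattern == "constant" && (value < t$min || value > t$max))
    stop("constant ", value, " out of range for ", t$name)
  if (layout == "function") {
    fn <- switch(pattern,
      constant = local({ v <- as.numeric(value)
        function(coords) rep(v, nrow(coords)) }),
      gradient = local({ m <- t$max; s <- sh
        function(coords) {
          idx <- coords_to_linear(coords, s)
          if (is.finite(m)) idx %% (m + 1) else idx
        } }),
      impulse = local({ a <- if (is.null(at)) rep(0, length(sh)) else at
        function(coords) {
          hit <- rep(TRUE, nrow(coords))
          for (k in seq_along(a)) hit <- hit & coords[, k] == a[[k]]
          as.numeric(hit)
        } }),
      stop("noise pattern is not available for the function layout"))
    return(create_image(t, shape, "function", fn = fn))
  }
  vals <- switch(pattern,
    constant = rep(as.numeric(value), total),
    gradient = {
      if (!is.finite(t$max)) seq.int(0L, total - 1L)
      else (seq.int(0L, total - 1L)) %% (t$max + 1)
    },
    impulse = {
      if (is.null(at)) at <- rep(0, length(sh))
      v <- numeric(total)
      v[coords_to_linear(matrix(at, nrow = 1L), sh) + 1] <- 1
      v
    },
    noise = with_seed(seed, {
      if (type_is_bounded_int(t)) {
        lo <- max(t$min, -2^31); hi <- min(t$max, 2^31 - 1)
        floor(stats::runif(total, lo, hi + 1))
      } else stats::runif(total)
    })
  )
  if (layout == "cell" && is.null(cell_opts))
    cell_opts <- list(cell_shape = pmin(sh, 16), capacity = 4L)
  img <- create_image(t, sh, layout, cell_opts = cell_opts)
  set_img_values(img, vals)
  img
}

# evaluate expr under a seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
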