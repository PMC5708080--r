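#' @title Cell-cached images
#' @description
#' A cell image partitions the sample grid into fixed-shape blocks ("cells").
#' At most `capacity` cells are resident in memory; least-recently-used cells
#' are evicted, and dirty cells are packed with the sample type's bit codec
#' and written back to a raw block store on disk, from which they reload on
#' the next access.  The image therefore behaves as a writeable virtual
#' stack: its full extent may exceed memory while reads always observe the
#' last written values.
#' @name cell-images
NULL

init_cell_store <- function(img, cell_shape, capacity, backing = NULL) {
  shape <- img$shape
  cell_shape <- as.numeric(cell_shape)
  if (length(cell_shape) != length(shape))
    stop("cell_shape must have one extent per dimension")
  if (any(cell_shape < 1) || any(cell_shape > shape))
    stop("cell extents must be in [1, shape]")
  capacity <- as.integer(capacity)
  if (capacity < 1L) stop("capacity must be >= 1")
  if (is.null(backing)) backing <- tempfile("ndops-cells-")
  store <- new.env(parent = emptyenv())
  store$cell_shape <- cell_shape
  store$cell_size <- prod(cell_shape)
  store$grid <- ceiling(shape / cell_shape)
  store$n_cells <- prod(store$grid)
  store$capacity <- capacity
  store$backing <- backing
  store$blocks <- NULL          # lazily initialized block store
  store$resident <- list()      # "<idx>" -> numeric buffer (padded cell)
  store$dirty <- logical(0)
  store$lru <- character(0)     # most recent last
  store$max_resident <- 0L
  store$evictions <- 0L
  store$saves <- 0L
  store$loads <- 0L
  img$store <- store
  invisible(img)
}

#' Create a cell-cached image
#'
#' @param t a [sample_type()]
#' @param shape extent vector
#' @param cell_shape per-dimension block extents (<= shape)
#' @param capacity maximum resident cells (>= 1)
#' @param backing directory for evicted blocks; created on first eviction.
#'   Defaults to a temporary directory.
#' @return an `ndimg` with layout `"cell"`
#' @export
create_cell_image <- function(t, shape, cell_shape, capacity, backing = NULL) {
  create_image(t, shape, "cell",
               cell_opts = list(cell_shape = cell_shape, capacity = capacity,
                                backing = backing))
}

#' Cell-cache instrumentation
#'
#' @param img a cell-layout image
#' @return list with `resident` (current resident cells), `max_resident`
#'   (peak residency), `capacity`, `evictions`, `saves`, `loads` and the
#'   `backing` path
#' @export
cell_stats <- function(img) {
  stopifnot(img$layout == "cell")
  s <- img$store
  list(resident = length(s$resident), max_resident = s$max_resident,
       capacity = s$capacity, evictions = s$evictions,
       saves = s$saves, loads = s$loads, backing = s$backing)
}

cell_blocks <- function(store, type) {
  if (is.null(store$blocks))
    store$blocks <- block_store_init(store$backing, type, store$cell_shape)
  store$blocks
}

evict_one <- function(store, type) {
  key <- store$lru[[1L]]
  store$lru <- store$lru[-1L]
  if (isTRUE(store$dirty[[key]])) {
    bs <- cell_blocks(store, type)
    buf <- store$resident[[key]]
    block_store_save(bs, as.numeric(key), pack_block(buf, type))
    store$saves <- store$saves + 1L
  }
  store$resident[[key]] <- NULL
  store$dirty <- store$dirty[names(store$dirty) != key]
  store$evictions <- store$evictions + 1L
}

pack_block <- function(values, type) {
  if (type_is_bounded_int(type)) pack_samples(values, type)
  else writeBin(values, raw(), size = 8, endian = "big")
}

unpack_block <- function(bytes, type, n) {
  if (type_is_bounded_int(type)) unpack_samples(bytes, type, n)
  else readBin(bytes, "double", n = n, size = 8, endian = "big")
}

# make cell `idx` (0-based linear index over the cell grid) resident
touch_cell <- function(img, idx) {
  store <- img$store
  key <- fmt_extent(idx)
  if (!is.null(store$resident[[key]])) {
    # refresh LRU position
    store$lru <- c(store$lru[store$lru != key], key)
    return(store$resident[[key]])
  }
  while (length(store$resident) >= store$capacity) evict_one(store, img$type)
  buf <- NULL
  if (!is.null(store$blocks)) {
    bytes <- block_store_load(store$blocks, idx, missing_ok = TRUE)
    if (!is.null(bytes)) {
      buf <- unpack_block(bytes, img$type, store$cell_size)
      store$loads <- store$loads + 1L
    }
  }
  if (is.null(buf)) buf <- numeric(store$cell_size)
  store$resident[[key]] <- buf
  store$dirty[[key]] <- FALSE
  store$lru <- c(store$lru, key)
  store$max_resident <- max(store$max_resident, length(store$resident))
  buf
}

# split coordinates into (cell linear index, within-cell linear index)
cell_split <- function(coords, store) {
  cc <- sweep(coords, 2L, store$cell_shape, `%/%`)
  wc <- sweep(coords, 2L, store$cell_shape, `%%`)
  list(cell = coords_to_linear(cc, store$grid),
       within = coords_to_linear(wc, store$cell_shape))
}

cell_get <- function(img, coords) {
  store <- img$store
  sp <- cell_split(coords, store)
  out <- numeric(nrow(coords))
  for (idx in unique(sp$cell)) {
    sel <- sp$cell == idx
    buf <- touch_cell(img, idx)
    out[sel] <- buf[sp$within[sel] + 1]
  }
  out
}

cell_set <- function(img, coords, values) {
  store <- img$store
  sp <- cell_split(coords, store)
  for (idx in unique(sp$cell)) {
    sel <- sp$cell == idx
    buf <- touch_cell(img, idx)
    buf[sp$within[sel] + 1] <- values[sel]
    key <- fmt_extent(idx)
    store$resident[[key]] <- buf
    store$dirty[[key]] <- TRUE
  }
  invisible(img)
}

# global row-major linear indices (1-based) covered by cell `idx`,
# plus the matching within-cell positions (1-based) for padded edge cells
cell_index_map <- function(img, idx) {
  store <- img$store
  cc <- linear_to_coords(idx, store$grid)[1L, ]
  offset <- cc * store$cell_shape
  wcoords <- all_coords(store$cell_shape)
  gcoords <- sweep(wcoords, 2L, offset, `+`)
  valid <- rep(TRUE, nrow(gcoords))
  for (k in seq_along(img$shape))
    valid <- valid & gcoords[, k] < img$shape[[k]]
  list(global = coords_to_linear(gcoords[valid, , drop = FALSE], img$shape) + 1,
       within = which(valid))
}

cell_values <- function(img) {
  out <- numeric(prod(img$shape))
  for (idx in seq.int(0L, img$store$n_cells - 1L)) {
    buf <- touch_cell(img, idx)
    map <- cell_index_map(img, idx)
    out[map$global] <- buf[map$within]
  }
  out
}

cell_set_values <- function(img, values) {
  store <- img$store
  for (idx in seq.int(0L, store$n_cells - 1L)) {
    buf <- touch_cell(img, idx)
    map <- cell_index_map(img, idx)
    buf[map$within] <- values[map$global]
    key <- fmt_extent(idx)
    store$resident[[key]] <- buf
    store$dirty[[key]] <- TRUE
  }
  invisible(img)
}
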