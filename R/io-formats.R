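#' @title Data access and image formats
#' @description
#' Pluggable I/O: a location descriptor (file path or named in-memory byte
#' buffer), random-access data handles over either, magic-byte/suffix format
#' detection, Netpbm codecs (PGM P2/P5 grayscale, PPM P6 color) with
#' row-chunked reading, and the raw block store backing cell images.
#' Written files use a canonical header (single `\n` separators, no
#' comments), so re-writing a dataset is byte-identical.
#' @name io-formats
NULL

# shared in-memory buffers for the bytes: scheme
.bytes_buffers <- new.env(parent = emptyenv())

#' Resolve a location spec
#'
#' Plain paths give `file` locations; `bytes:<id>` names a shared in-memory
#' buffer (created on first write).  Other URI schemes are unsupported.
#'
#' @param spec nonempty location string
#' @return an `nd_location`
#' @export
resolve_location <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1L, nzchar(spec))
  if (grepl("^bytes:", spec)) {
    id <- sub("^bytes:", "", spec)
    return(structure(list(scheme = "bytes", ref = id), class = "nd_location"))
  }
  if (grepl("^[A-Za-z][A-Za-z0-9+.-]*://", spec))
    stop("location error: unsupported scheme in '", spec, "'")
  structure(list(scheme = "file", ref = spec), class = "nd_location")
}

as_location <- function(loc) {
  if (inherits(loc, "nd_location")) loc else resolve_location(loc)
}

bytes_buffer <- function(id, create = FALSE) {
  if (!exists(id, envir = .bytes_buffers, inherits = FALSE)) {
    if (!create) return(NULL)
    buf <- new.env(parent = emptyenv())
    buf$data <- raw(0)
    assign(id, buf, envir = .bytes_buffers)
  }
  get(id, envir = .bytes_buffers)
}

#' Open a random-access data handle
#'
#' Handles expose seek/read/write over a location's raw bytes.  Two handles
#' on one `bytes:` location share the buffer and see each other's writes.
#'
#' @param loc an `nd_location` or location spec string
#' @param writable open for writing (file handles: the file is created if
#'   absent; its parent directory must exist)
#' @return an `nd_handle`
#' @export
open_handle <- function(loc, writable = FALSE) {
  loc <- as_location(loc)
  h <- new.env(parent = emptyenv())
  class(h) <- "nd_handle"
  h$location <- loc
  h$writable <- writable
  h$position <- 0
  if (loc$scheme == "file") {
    if (!writable && !file.exists(loc$ref))
      stop("not-found error: no file at '", loc$ref, "'")
    if (writable) {
      if (!dir.exists(dirname(loc$ref)))
        stop("not-found error: parent directory of '", loc$ref,
             "' does not exist")
      if (!file.exists(loc$ref)) file.create(loc$ref)
    }
    h$con <- file(loc$ref, if (writable) "r+b" else "rb")
    h$length <- file.size(loc$ref)
  } else {
    buf <- bytes_buffer(loc$ref, create = writable)
    if (is.null(buf))
      stop("not-found error: no bytes buffer '", loc$ref, "'")
    h$buf <- buf
    h$length <- length(buf$data)
  }
  h
}

#' @rdname open_handle
#' @param h an `nd_handle`
#' @export
handle_length <- function(h) {
  if (!is.null(h$buf)) length(h$buf$data) else h$length
}

#' @rdname open_handle
#' @param pos byte offset (0-based)
#' @export
handle_seek <- function(h, pos) {
  stopifnot(pos >= 0)
  h$position <- pos
  invisible(h)
}

#' @rdname open_handle
#' @param n maximum bytes to read
#' @return `handle_read()`: a raw vector (shorter than `n` at end of data)
#' @export
handle_read <- function(h, n) {
  len <- handle_length(h)
  if (h$position >= len) return(raw(0))   # end-of-data signal
  n <- min(n, len - h$position)
  out <- if (!is.null(h$buf)) {
    h$buf$data[(h$position + 1):(h$position + n)]
  } else {
    seek(h$con, where = h$position, origin = "start", rw = "read")
    readBin(h$con, "raw", n = n)
  }
  h$position <- h$position + length(out)
  out
}

#' @rdname open_handle
#' @param bytes raw vector to write at the current position
#' @export
handle_write <- function(h, bytes) {
  if (!h$writable) stop("permission error: handle is read-only")
  if (!is.null(h$buf)) {
    end <- h$position + length(bytes)
    if (end > length(h$buf$data))
      h$buf$data <- c(h$buf$data, raw(end - length(h$buf$data)))
    if (length(bytes)) h$buf$data[(h$position + 1):end] <- bytes
  } else {
    seek(h$con, where = h$position, origin = "start", rw = "write")
    writeBin(bytes, h$con)
    flush(h$con)
    h$length <- max(h$length, h$position + length(bytes))
  }
  h$position <- h$position + length(bytes)
  invisible(h)
}

#' @rdname open_handle
#' @export
handle_close <- function(h) {
  if (!is.null(h$con)) close(h$con)
  invisible(NULL)
}

# -- format registry ----------------------------------------------------------

#' Construct a format descriptor
#'
#' @param name format name
#' @param suffixes file suffixes (without dot)
#' @param magic character vector of leading byte signatures
#' @param priority tie-breaking priority
#' @param reader function `(ctx, handle) -> nd_dataset`
#' @param writer function `(ctx, ds, handle) -> bytes written`, or `NULL`
#' @return a `format_descriptor`
#' @export
format_descriptor <- function(name, suffixes, magic, priority = 0,
                              reader, writer = NULL) {
  if (length(suffixes) == 0L && length(magic) == 0L)
    stop("a format needs at least one suffix or magic pattern")
  structure(list(name = name, suffixes = suffixes, magic = magic,
                 priority = as.numeric(priority), reader = reader,
                 writer = writer),
            class = "format_descriptor")
}

registered_formats <- function(ctx) plugin_payloads(ctx, "format")

#' Detect the format of a location
#'
#' Magic bytes are matched first; suffix matches are the fallback; ties are
#' broken by (priority descending, name ascending).
#'
#' @param ctx a context
#' @param loc an `nd_location` or spec string
#' @return the winning `format_descriptor`
#' @export
detect_format <- function(ctx, loc) {
  loc <- as_location(loc)
  formats <- registered_formats(ctx)
  if (length(formats) == 0L) stop("unknown-format error: no formats registered")
  head <- tryCatch({
    h <- open_handle(loc, writable = FALSE)
    on.exit(handle_close(h))
    handle_read(h, 16L)
  }, error = function(e) raw(0))
  magic_hit <- function(m) {
    mb <- charToRaw(m)
    length(head) >= length(mb) && identical(head[seq_along(mb)], mb)
  }
  pick <- function(cand) {
    pri <- vapply(cand, function(f) f$priority, numeric(1))
    nm <- vapply(cand, function(f) f$name, character(1))
    cand[[order(-pri, nm)[1L]]]
  }
  by_magic <- Filter(function(f)
    any(vapply(f$magic, magic_hit, logical(1))), formats)
  if (length(by_magic)) return(pick(by_magic))
  suffix <- tolower(sub("^.*\\.", "", loc$ref))
  by_suffix <- Filter(function(f) suffix %in% f$suffixes, formats)
  if (length(by_suffix)) return(pick(by_suffix))
  stop("unknown-format error: no format matches '", loc$ref, "'; registered: ",
       paste(vapply(formats, function(f) f$name, character(1)), collapse = ", "))
}

#' Read an image dataset
#'
#' The format is detected by magic bytes/suffix; Netpbm bodies are read in
#' row chunks (`ctx$config$chunk_rows`), so chunk size never changes the
#' result.  PGM yields a 2D dataset with axes X, Y (uint8 for maxval <= 255,
#' big-endian uint16 above); PPM yields X, Y, CHANNEL with extent 3.
#'
#' @param ctx a context
#' @param loc an `nd_location` or spec string
#' @return an `nd_dataset`
#' @export
read_image <- function(ctx, loc) {
  loc <- as_location(loc)
  fmt <- detect_format(ctx, loc)
  h <- open_handle(loc, writable = FALSE)
  on.exit(handle_close(h))
  ds <- fmt$reader(ctx, h)
  ds$name <- if (loc$scheme == "file") basename(loc$ref) else loc$ref
  ds
}

#' Write an image dataset
#'
#' @param ctx a context
#' @param ds an `nd_dataset` (or bare image; default axes are attached)
#' @param loc target `nd_location` or spec string
#' @param format optional format name; defaults to the location suffix, else
#'   the dataset geometry (2D gray -> PGM, 3-channel -> PPM)
#' @return bytes written
#' @export
write_image <- function(ctx, ds, loc, format = NULL) {
  if (is_ndimg(ds)) ds <- wrap_dataset(ds)
  loc <- as_location(loc)
  formats <- registered_formats(ctx)
  fmt <- NULL
  if (!is.null(format)) {
    for (f in formats) if (f$name == format) fmt <- f
    if (is.null(fmt)) stop("unknown-format error: '", format, "'")
  } else {
    suffix <- tolower(sub("^.*\\.", "", loc$ref))
    for (f in formats) if (suffix %in% f$suffixes) { fmt <- f; break }
    if (is.null(fmt))
      fmt <- if (ds$image$ndim == 3L) Filter(function(f) f$name == "ppm",
                                             formats)[[1L]]
             else Filter(function(f) f$name == "pgm", formats)[[1L]]
  }
  if (is.null(fmt$writer)) stop("format '", fmt$name, "' is read-only")
  h <- open_handle(loc, writable = TRUE)
  on.exit(handle_close(h))
  if (loc$scheme == "bytes") h$buf$data <- raw(0)   # truncate canonical file
  fmt$writer(ctx, ds, h)
}

# -- Netpbm codecs ------------------------------------------------------------

# read whitespace-separated header tokens, skipping '#' comments
netpbm_tokens <- function(h, n_tokens) {
  tokens <- character(0)
  cur <- ""
  in_comment <- FALSE
  while (length(tokens) < n_tokens ||
         (length(tokens) == n_tokens && nzchar(cur))) {
    b <- handle_read(h, 1L)
    if (length(b) == 0L) break
    ch <- rawToChar(b)
    if (in_comment) {
      if (ch == "\n") in_comment <- FALSE
      next
    }
    if (ch == "#") { in_comment <- TRUE; next }
    if (grepl("^[ \t\r\n]$", ch)) {
      if (nzchar(cur)) { tokens <- c(tokens, cur); cur <- "" }
      if (length(tokens) == n_tokens) break   # single whitespace ends header
    } else {
      cur <- paste0(cur, ch)
    }
  }
  if (length(tokens) < n_tokens)
    stop("format error at byte ", h$position, ": truncated header")
  tokens
}

netpbm_sample_type <- function(ctx, maxval) {
  if (maxval <= 255) get_sample_type(ctx, "uint8")
  else if (maxval <= 65535) get_sample_type(ctx, "uint16")
  else stop("format error: maxval ", maxval, " out of range")
}

# binary body reader in row chunks; returns samples in file order
netpbm_read_body <- function(ctx, h, w, ht, channels, bpp) {
  chunk_rows <- max(1L, as.integer(ctx$config$chunk_rows))
  per_row <- w * channels * bpp
  out <- numeric(w * ht * channels)
  r0 <- 0L
  while (r0 < ht) {
    nr <- min(chunk_rows, ht - r0)
    bytes <- handle_read(h, nr * per_row)
    if (length(bytes) < nr * per_row)
      stop("format error at byte ", h$position, ": truncated pixel data")
    b <- as.numeric(as.integer(bytes))
    vals <- if (bpp == 1L) b
            else b[seq(1, length(b), by = 2)] * 256 + b[seq(2, length(b), by = 2)]
    out[(r0 * w * channels + 1):((r0 + nr) * w * channels)] <- vals
    r0 <- r0 + nr
  }
  out
}

# file-order samples (y slow, x fast, channel fastest) -> image
netpbm_to_dataset <- function(ctx, vals, w, ht, channels, t) {
  if (channels == 1L) {
    img <- create_image(t, c(w, ht), "array")
    fx <- rep(seq.int(0L, w - 1L), times = ht)
    fy <- rep(seq.int(0L, ht - 1L), each = w)
    img$data[fx * ht + fy + 1] <- vals
    wrap_dataset(img, list(axis("X"), axis("Y")))
  } else {
    img <- create_image(t, c(w, ht, channels), "array")
    fx <- rep(rep(seq.int(0L, w - 1L), each = channels), times = ht)
    fy <- rep(seq.int(0L, ht - 1L), each = w * channels)
    fc <- rep(seq.int(0L, channels - 1L), times = w * ht)
    img$data[(fx * ht + fy) * channels + fc + 1] <- vals
    wrap_dataset(img, list(axis("X"), axis("Y"), axis("CHANNEL")))
  }
}

netpbm_reader <- function(kind) {
  function(ctx, h) {
    magic <- rawToChar(handle_read(h, 2L))
    header <- netpbm_tokens(h, 3L)
    w <- as.integer(header[[1]]); ht <- as.integer(header[[2]])
    maxval <- as.integer(header[[3]])
    if (anyNA(c(w, ht, maxval)) || w < 1L || ht < 1L)
      stop("format error: bad header dimensions")
    t <- netpbm_sample_type(ctx, maxval)
    channels <- if (magic == "P6") 3L else 1L
    vals <- if (magic == "P2") {
      n <- w * ht
      txt <- rawToChar(handle_read(h, handle_length(h) - h$position))
      nums <- suppressWarnings(as.numeric(strsplit(trimws(txt), "[ \t\r\n]+")[[1]]))
      if (length(nums) < n || anyNA(nums[seq_len(n)]))
        stop("format error at byte ", h$position, ": truncated ASCII data")
      nums[seq_len(n)]
    } else {
      netpbm_read_body(ctx, h, w, ht, channels, if (maxval > 255) 2L else 1L)
    }
    if (any(vals > maxval))
      stop("format error: sample above declared maxval")
    netpbm_to_dataset(ctx, vals, w, ht, channels, t)
  }
}

# gather image samples into file order
netpbm_file_order <- function(img, channels) {
  vals <- img_values(img)
  w <- img$shape[[1L]]; ht <- img$shape[[2L]]
  if (channels == 1L) {
    fx <- rep(seq.int(0L, w - 1L), times = ht)
    fy <- rep(seq.int(0L, ht - 1L), each = w)
    vals[fx * ht + fy + 1]
  } else {
    fx <- rep(rep(seq.int(0L, w - 1L), each = channels), times = ht)
    fy <- rep(seq.int(0L, ht - 1L), each = w * channels)
    fc <- rep(seq.int(0L, channels - 1L), times = w * ht)
    vals[(fx * ht + fy) * channels + fc + 1]
  }
}

netpbm_writer <- function(kind) {
  function(ctx, ds, h) {
    img <- ds$image
    channels <- if (kind == "ppm") 3L else 1L
    if (kind == "ppm") {
      if (img$ndim != 3L || img$shape[[3L]] != 3L)
        stop("format error: PPM needs a [X, Y, 3] image")
    } else {
      if (img$ndim != 2L)
        stop("format error: PGM needs a 2D grayscale image, got ",
             img$ndim, " dimensions")
    }
    maxval <- if (img$type$bits <= 8) 255L else 65535L
    if (!type_is_bounded_int(img$type) || img$type$bits > 16)
      stop("format error: Netpbm supports integer samples up to 16 bits")
    magic <- if (kind == "ppm") "P6" else if (kind == "pgm-ascii") "P2" else "P5"
    header <- paste0(magic, "\n", fmt_extent(img$shape[[1L]]), " ",
                     fmt_extent(img$shape[[2L]]), "\n", maxval, "\n")
    handle_write(h, charToRaw(header))
    vals <- netpbm_file_order(img, channels)
    if (magic == "P2") {
      w <- img$shape[[1L]]
      rows <- vapply(seq_len(img$shape[[2L]]), function(r)
        paste(fmt_extent(vals[((r - 1) * w + 1):(r * w)]), collapse = " "),
        character(1))
      handle_write(h, charToRaw(paste0(paste(rows, collapse = "\n"), "\n")))
    } else if (maxval == 255L) {
      handle_write(h, as.raw(vals))
    } else {
      hi <- vals %/% 256; lo <- vals %% 256
      bytes <- as.raw(as.vector(rbind(hi, lo)))
      handle_write(h, bytes)
    }
    h$position
  }
}

# format plugin entry points (manifest kind "format")
fmtdef_pgm <- function(ctx) {
  format_descriptor("pgm", suffixes = "pgm", magic = c("P5", "P2"),
                    priority = 0, reader = netpbm_reader("pgm"),
                    writer = netpbm_writer("pgm"))
}

fmtdef_ppm <- function(ctx) {
  format_descriptor("ppm", suffixes = "ppm", magic = "P6",
                    priority = 0, reader = netpbm_reader("ppm"),
                    writer = netpbm_writer("ppm"))
}

# -- raw cell-block store -----------------------------------------------------

#' Raw block store for cell images
#'
#' One file per cell (`cell_<linear-index>.blk`, contents =
#' [pack_samples()] of the padded cell in row-major order) plus a key=value
#' sidecar (`index.txt`) recording the sample type and cell shape.  Loading
#' a never-saved block yields `NULL` (interpreted as all-zero).
#'
#' @param dir store directory (created if needed)
#' @param type the cell [sample_type()]
#' @param cell_shape per-dimension block extents
#' @return a `block_store`
#' @export
block_store_init <- function(dir, type, cell_shape) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop("storage error: cannot create '", dir, "'")
  sidecar <- file.path(dir, "index.txt")
  meta <- c(paste0("type=", type$name),
            paste0("cell_shape=", paste(fmt_extent(cell_shape), collapse = ",")))
  if (file.exists(sidecar)) {
    old <- readLines(sidecar, warn = FALSE)
    if (!identical(sort(old), sort(meta)))
      stop("storage error: sidecar mismatch in '", dir, "' (",
           paste(old, collapse = "; "), " vs ", paste(meta, collapse = "; "), ")")
  } else {
    writeLines(meta, sidecar)
  }
  structure(list(dir = dir, type = type, cell_shape = cell_shape),
            class = "block_store")
}

block_path <- function(store, idx) {
  file.path(store$dir, paste0("cell_", fmt_extent(idx), ".blk"))
}

#' @rdname block_store_init
#' @param store a `block_store`
#' @param idx 0-based linear cell index
#' @param bytes packed block bytes
#' @export
block_store_save <- function(store, idx, bytes) {
  writeBin(bytes, block_path(store, idx))
  invisible(TRUE)
}

#' @rdname block_store_init
#' @param missing_ok return `NULL` for a never-saved block instead of zeros
#' @return `block_store_load()`: raw vector (zero-filled when never saved,
#'   or `NULL` with `missing_ok = TRUE`)
#' @export
block_store_load <- function(store, idx, missing_ok = FALSE) {
  p <- block_path(store, idx)
  if (!file.exists(p)) {
    if (missing_ok) return(NULL)
    n <- prod(store$cell_shape)
    nb <- if (type_is_bounded_int(store$type)) bytes_required(store$type, n)
          else 8 * n
    return(raw(nb))
  }
  readBin(p, "raw", n = file.size(p))
}

#' @rdname block_store_init
#' @return `block_store_blocks()`: number of block files present
#' @export
block_store_blocks <- function(store) {
  length(list.files(store$dir, pattern = "^cell_.*\\.blk$"))
}
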