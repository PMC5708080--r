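#' @title Pixel sample types
#' @description
#' A sample type describes a pixel value domain: bit width, numeric kind and
#' bounds.  The registry ships 21 built-in types — unsigned integers from 1
#' to 128 bits (including the sub-byte uint1/uint2/uint4 and the detector
#' friendly uint12), signed integers, IEEE floats, complex floats, a packed
#' ARGB composite, a 1-bit boolean and unbounded integer/decimal types — and
#' is extensible per context.  Bounded integer types come with bit-level
#' packing codecs (big-endian, MSB-first) so that, e.g., 12-bit data is
#' stored without wasted bits.
#' @name sample-types
NULL

#' Construct a sample type descriptor
#'
#' @param name unique string id
#' @param bits bits per sample (positive integer) or `NA` for unbounded types
#' @param kind one of `"unsigned-int"`, `"signed-int"`, `"real"`,
#'   `"complex"`, `"argb-composite"`, `"boolean"`, `"unbounded-int"`,
#'   `"unbounded-decimal"`
#' @param min,max value bounds; for bounded integer kinds
#'   `max - min + 1 = 2^bits`
#' @return a `sample_type`
#' @export
sample_type <- function(name, bits, kind, min = -Inf, max = Inf) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  kinds <- c("unsigned-int", "signed-int", "real", "complex",
             "argb-composite", "boolean", "unbounded-int", "unbounded-decimal")
  if (!kind %in% kinds) stop("unknown sample kind '", kind, "'")
  structure(list(name = name, bits = bits, kind = kind,
                 min = min, max = max),
            class = "sample_type")
}

#' @export
print.sample_type <- function(x, ...) {
  cat("<sample type ", x$name, ": ", x$kind,
      if (!is.na(x$bits)) paste0(", ", x$bits, " bits") else ", unbounded",
      ">\n", sep = "")
  invisible(x)
}

type_is_bounded_int <- function(t) {
  t$kind %in% c("unsigned-int", "signed-int", "boolean", "argb-composite") &&
    !is.na(t$bits)
}

uint_type <- function(bits) {
  sample_type(paste0("uint", bits), bits, "unsigned-int", 0, 2^bits - 1)
}
int_type <- function(bits) {
  sample_type(paste0("int", bits), bits, "signed-int", -(2^(bits - 1)), 2^(bits - 1) - 1)
}

builtin_sample_types <- function() {
  list(
    uint_type(1), uint_type(2), uint_type(4), uint_type(8), uint_type(12),
    uint_type(16), uint_type(32), uint_type(64), uint_type(128),
    int_type(8), int_type(16), int_type(32), int_type(64),
    sample_type("float32", 32, "real"),
    sample_type("float64", 64, "real"),
    sample_type("complex-float32", 64, "complex"),
    sample_type("complex-float64", 128, "complex"),
    sample_type("argb32", 32, "argb-composite", 0, 2^32 - 1),
    sample_type("boolean-bit", 1, "boolean", 0, 1),
    sample_type("unbounded-int", NA, "unbounded-int"),
    sample_type("unbounded-decimal", NA, "unbounded-decimal")
  )
}

# service factory (manifest kind "sample_type_service")
new_sample_type_service <- function(ctx) {
  svc <- new.env(parent = emptyenv())
  svc$types <- list()
  for (t in builtin_sample_types()) svc$types[[t$name]] <- t
  class(svc) <- "sample_type_service"
  svc
}

#' Register a sample type in a context
#'
#' @param ctx a context
#' @param t a [sample_type()]
#' @return registry size after registration
#' @export
register_sample_type <- function(ctx, t) {
  stopifnot(inherits(t, "sample_type"))
  svc <- get_service(ctx, "sample_type_service")
  if (!is.null(svc$types[[t$name]]))
    stop("sample type '", t$name, "' is already registered")
  svc$types[[t$name]] <- t
  length(svc$types)
}

#' Look up a sample type by name
#'
#' @param ctx a context
#' @param name type name, e.g. `"uint12"`
#' @return the `sample_type`
#' @export
get_sample_type <- function(ctx, name) {
  svc <- get_service(ctx, "sample_type_service")
  t <- svc$types[[name]]
  if (is.null(t)) stop("unknown sample type '", name, "'")
  t
}

#' @rdname get_sample_type
#' @return `sample_type_names()`: character vector of registered names
#' @export
sample_type_names <- function(ctx) {
  names(get_service(ctx, "sample_type_service")$types)
}

# coerce a type-or-name argument
as_sample_type <- function(ctx, t) {
  if (inherits(t, "sample_type")) t else get_sample_type(ctx, t)
}

#' Saturating cast between sample types
#'
#' Values are clamped to the target bounds; real-to-integer casts round
#' half-to-even.  Casting a complex value with nonzero imaginary part to a
#' non-complex type is a domain error.  Idempotent: casting a cast value to
#' the same target is the identity.
#'
#' @param value numeric (or complex) vector
#' @param from,to `sample_type`s
#' @return numeric vector in the target domain
#' @export
clamp_cast <- function(value, from, to) {
  if (is.complex(value)) {
    if (to$kind == "complex") return(value)
    if (any(Im(value) != 0))
      stop("cannot cast complex value with nonzero imaginary part to ", to$name)
    value <- Re(value)
  }
  if (to$kind == "complex") return(complex(real = value, imaginary = 0))
  out <- value
  if (to$kind %in% c("unsigned-int", "signed-int", "boolean", "argb-composite",
                     "unbounded-int")) {
    out <- round(out)   # IEC 60559: round half to even
  }
  if (is.finite(to$min)) out <- pmax(out, to$min)
  if (is.finite(to$max)) out <- pmin(out, to$max)
  out
}

#' Bytes needed to store packed samples
#'
#' `ceil(n * bits / 8)`: samples are concatenated at the bit level, so five
#' uint12 samples need 8 bytes, not 10.
#'
#' @param t a bounded `sample_type`
#' @param n sample count (>= 0)
#' @return byte count
#' @export
bytes_required <- function(t, n) {
  if (is.na(t$bits)) stop("bytes_required: '", t$name, "' is unbounded")
  stopifnot(n >= 0)
  ceiling(n * t$bits / 8)
}

#' Pack integer samples into a bit-packed byte buffer
#'
#' Samples are written MSB-first in big-endian bit order and concatenated
#' without padding between samples; the final byte is zero-padded.  The
#' buffer length is exactly [bytes_required()].  `unpack_samples()` is the
#' exact inverse for in-range sequences.
#'
#' @param values integer-valued numeric vector, each within `[t$min, t$max]`
#' @param t a bounded integer `sample_type`
#' @return a raw vector
#' @export
pack_samples <- function(values, t) {
  if (!type_is_bounded_int(t))
    stop("pack_samples: '", t$name, "' is not a bounded integer type")
  n <- length(values)
  if (n == 0L) return(raw(0))
  bad <- which(values < t$min | values > t$max | values != floor(values))
  if (length(bad))
    stop("pack_samples: value ", values[bad[1L]], " at index ", bad[1L],
         " out of range for ", t$name, " [", t$min, ", ", t$max, "]")
  if (any(abs(values) > 2^53))
    stop("pack_samples: magnitude above 2^53 is not exactly representable")
  v <- values - t$min   # store offset-binary for signed types
  bits <- t$bits
  if (bits == 8L) return(as.raw(v))
  if (bits %% 8 == 0) {
    nb <- bits %/% 8
    bytes <- matrix(0, nrow = nb, ncol = n)
    rem <- v
    for (k in nb:1) {           # least significant byte last in big-endian
      bytes[k, ] <- rem %% 256
      rem <- rem %/% 256
    }
    return(as.raw(as.vector(bytes)))
  }
  # general sub-byte / unaligned path: explicit bit string, MSB-first
  powers <- 2^((bits - 1):0)
  bitmat <- vapply(powers, function(p) (v %/% p) %% 2, numeric(n))
  bitvec <- as.vector(t(matrix(bitmat, nrow = n)))  # sample-major, MSB first
  total <- bytes_required(t, n) * 8
  if (length(bitvec) < total) bitvec <- c(bitvec, rep(0, total - length(bitvec)))
  bytes <- colSums(matrix(bitvec, nrow = 8) * 2^(7:0))
  as.raw(bytes)
}

#' @rdname pack_samples
#' @param buffer raw vector from `pack_samples()` (or a block store)
#' @param n number of samples to decode
#' @return `unpack_samples()`: numeric vector of length `n`
#' @export
unpack_samples <- function(buffer, t, n) {
  if (!type_is_bounded_int(t))
    stop("unpack_samples: '", t$name, "' is not a bounded integer type")
  need <- bytes_required(t, n)
  if (length(buffer) < need)
    stop("unpack_samples: buffer has ", length(buffer), " bytes, need ", need)
  if (n == 0L) return(numeric(0))
  bits <- t$bits
  b <- as.numeric(as.integer(buffer[seq_len(need)]))
  if (bits == 8L) return(b + t$min)
  if (bits %% 8 == 0) {
    nb <- bits %/% 8
    m <- matrix(b, nrow = nb)
    v <- numeric(n)
    for (k in 1:nb) v <- v * 256 + m[k, ]
    return(v + t$min)
  }
  # expand to bits, MSB-first per byte
  bitmat <- vapply(2^(7:0), function(p) (b %/% p) %% 2, numeric(length(b)))
  bitvec <- as.vector(t(bitmat))
  idx <- matrix(seq_len(n * bits), nrow = bits)  # columns = samples
  powers <- 2^((bits - 1):0)
  v <- colSums(matrix(bitvec[idx], nrow = bits) * powers)
  v + t$min
}
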