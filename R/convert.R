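#' @title Converter framework
#' @description
#' A prioritized registry of type-to-type converters.  Converters let a
#' value of one semantic type serve where another is expected — directly via
#' [convert()], and automatically during op matching and module input
#' harvesting ("sensible defaults": a parsable string works where a number
#' is declared, a file path where an image is declared).  Conversion is
#' strictly single-hop: registered converters are never chained, so cost and
#' priority stay well defined.  Image/dataset conversions wrap by reference.
#' @name converters
NULL

#' Construct a converter descriptor
#'
#' @param id unique string
#' @param from,to semantic type labels (see [type_of()])
#' @param priority real; among applicable converters the highest priority
#'   wins, ties broken by registration order
#' @param apply function `(ctx, value) -> converted value`
#' @param accepts optional predicate on the value (e.g. "string parses as a
#'   number"); defaults to accepting everything of the `from` type
#' @return a `converter_descriptor`
#' @export
converter_descriptor <- function(id, from, to, priority = 0, apply,
                                 accepts = NULL) {
  structure(list(id = id, from = from, to = to,
                 priority = as.numeric(priority), apply = apply,
                 accepts = accepts),
            class = "converter_descriptor")
}

# service: ordered converter registry (manifest kind "convert_service";
# converter plugins of kind "converter" are collected at instantiation)
new_convert_service <- function(ctx) {
  svc <- new.env(parent = emptyenv())
  svc$converters <- list()
  svc$seq <- 0L
  for (c in plugin_payloads(ctx, "converter")) convert_service_add(svc, c)
  class(svc) <- "convert_service"
  svc
}

convert_service_add <- function(svc, c) {
  stopifnot(inherits(c, "converter_descriptor"))
  svc$seq <- svc$seq + 1L
  c$order <- svc$seq
  svc$converters[[length(svc$converters) + 1L]] <- c
  length(svc$converters)
}

#' Register a converter in a context
#'
#' @param ctx a context
#' @param c a [converter_descriptor()]
#' @return registry size after registration
#' @export
register_converter <- function(ctx, c) {
  convert_service_add(get_service(ctx, "convert_service"), c)
}

# applicable converters for a value -> target type, best first
applicable_converters <- function(ctx, from_type, to_type, value = NULL) {
  svc <- get_service(ctx, "convert_service")
  cand <- Filter(function(c) {
    type_is(from_type, c$from, ctx) && type_is(c$to, to_type, ctx) &&
      (is.null(value) || is.null(c$accepts) || isTRUE(c$accepts(value)))
  }, svc$converters)
  if (length(cand) == 0L) return(cand)
  pri <- vapply(cand, function(c) c$priority, numeric(1))
  ord <- vapply(cand, function(c) c$order, integer(1))
  cand[order(-pri, ord)]
}

#' Can a value be converted to a target type?
#'
#' True when the value is already assignable (identity / hierarchy), a
#' numeric widening applies, or some registered single-hop converter accepts
#' the value.
#'
#' @param ctx a context
#' @param from_value the value
#' @param to_type target semantic type label
#' @return logical
#' @export
can_convert <- function(ctx, from_value, to_type) {
  ft <- type_of(from_value)
  if (type_is(ft, to_type, ctx)) return(TRUE)
  if (ft == "integer" && to_type %in% c("real", "number")) return(TRUE)
  length(applicable_converters(ctx, ft, to_type, from_value)) > 0L
}

#' Convert a value to a target type
#'
#' Identity when the value is already assignable; otherwise the
#' highest-priority applicable converter is applied (exactly one — no
#' chaining).  Repeated calls with equal inputs pick the same converter.
#'
#' @param ctx a context
#' @param value the value
#' @param to_type target semantic type label
#' @return the converted value
#' @export
convert <- function(ctx, value, to_type) {
  ft <- type_of(value)
  if (type_is(ft, to_type, ctx)) return(value)
  cand <- applicable_converters(ctx, ft, to_type, value)
  if (length(cand) == 0L) {
    tried <- applicable_converters(ctx, ft, to_type)  # type-level candidates
    stop("conversion error: no converter from '", ft, "' to '", to_type,
         "' accepts the value",
         if (length(tried)) paste0(" (tried: ",
           paste(vapply(tried, function(c) c$id, character(1)), collapse = ", "),
           ")") else "")
  }
  cand[[1L]]$apply(ctx, value)
}

# convert via a specific registered converter id (used by op-match plans)
convert_with <- function(ctx, id, value) {
  svc <- get_service(ctx, "convert_service")
  for (c in svc$converters) if (c$id == id) return(c$apply(ctx, value))
  stop("unknown converter id '", id, "'")
}

# -- built-in converters (manifest kind "converter") --------------------------

string_is_number <- function(s) {
  length(s) == 1L && !is.na(suppressWarnings(as.numeric(s)))
}

conv_string_to_number <- function(ctx) {
  # canonical parser: outranks the integer/real refinements so a "number"
  # target converts with zero residual hierarchy distance
  converter_descriptor("convert.string-number", "string", "number",
    priority = 20,
    apply = function(ctx, v) as.numeric(v),
    accepts = string_is_number)
}

conv_integer_widen <- function(ctx) {
  converter_descriptor("convert.integer-real", "integer", "real",
    priority = 100,
    apply = function(ctx, v) as.numeric(v))
}

conv_string_to_integer <- function(ctx) {
  converter_descriptor("convert.string-integer", "string", "integer",
    priority = 10,
    apply = function(ctx, v) as.numeric(v),
    accepts = function(v) string_is_number(v) &&
      as.numeric(v) == floor(as.numeric(v)))
}

conv_string_to_real <- function(ctx) {
  converter_descriptor("convert.string-real", "string", "real",
    priority = 10,
    apply = function(ctx, v) as.numeric(v),
    accepts = string_is_number)
}

conv_number_to_string <- function(ctx) {
  converter_descriptor("convert.number-string", "number", "string",
    priority = 10,
    apply = function(ctx, v) render_value(v))
}

conv_image_to_dataset <- function(ctx) {
  converter_descriptor("convert.image-dataset", "image", "dataset",
    priority = 10,
    apply = function(ctx, v) wrap_dataset(v))   # by-reference wrap
}

conv_dataset_to_image <- function(ctx) {
  converter_descriptor("convert.dataset-image", "dataset", "image",
    priority = 10,
    apply = function(ctx, v) v$image)           # by-reference unwrap
}

conv_path_to_dataset <- function(ctx) {
  converter_descriptor("convert.path-dataset", "string", "dataset",
    priority = 5,
    apply = function(ctx, v) read_image(ctx, v),
    accepts = function(v) length(v) == 1L && file.exists(v))
}

conv_path_to_image <- function(ctx) {
  converter_descriptor("convert.path-image", "string", "image",
    priority = 5,
    apply = function(ctx, v) read_image(ctx, v)$image,
    accepts = function(v) length(v) == 1L && file.exists(v))
}

# canonical textual rendering of values (module outputs, CLI echo)
render_value <- function(v) {
  if (is_ndimg(v))
    return(paste0("<image ", v$type$name, " [",
                  paste(v$shape_chr, collapse = "x"), "] ", v$layout, ">"))
  if (is_dataset(v))
    return(paste0("<dataset '", v$name, "' [",
                  paste(v$image$shape_chr, collapse = "x"), "]>"))
  if (is.numeric(v) && length(v) == 1L) {
    if (is.finite(v) && v == floor(v) && abs(v) < 2^53)
      return(format(v, scientific = FALSE, trim = TRUE))
    return(format(v, digits = 15))
  }
  if (is.character(v) && length(v) == 1L) return(v)
  paste(utils::capture.output(print(v)), collapse = " ")
}
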