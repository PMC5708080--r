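#' @title Semantic type labels
#' @description
#' Operation matching and the converter framework reason about values through
#' a small hierarchy of semantic type labels rather than R classes.  The
#' built-in hierarchy is:
#'
#' ```
#' any
#' +- number
#' |  +- integer
#' |  +- real
#' +- image
#' |  +- array_image
#' |  +- planar_image
#' |  +- cell_image
#' |  +- function_image
#' +- dataset
#' +- string
#' +- logical
#' +- sample_type
#' +- op
#' ```
#'
#' Contexts may extend the hierarchy with [register_type_parent()]; custom
#' labels default to children of `any`.
#' @name type-system
NULL

.builtin_type_parents <- c(
  number = "any", integer = "number", real = "number",
  image = "any", array_image = "image", planar_image = "image",
  cell_image = "image", function_image = "image",
  dataset = "any", string = "any", logical = "any",
  sample_type = "any", op = "any", location = "any", roi = "any"
)

type_parents_of <- function(ctx) {
  extra <- if (!is.null(ctx)) ctx$type_parents else character()
  c(extra, .builtin_type_parents)
}

#' Register a parent link in a context's semantic type hierarchy
#'
#' @param ctx a context from [build_context()]
#' @param type,parent type labels; `type` becomes a direct child of `parent`
#' @return the context, invisibly
#' @export
register_type_parent <- function(ctx, type, parent) {
  stopifnot(is.character(type), is.character(parent))
  ctx$type_parents[type] <- parent
  invisible(ctx)
}

# chain of ancestors from `type` up to "any" (inclusive of `type`)
type_ancestry <- function(type, ctx = NULL) {
  parents <- type_parents_of(ctx)
  chain <- type
  cur <- type
  repeat {
    if (identical(cur, "any")) break
    nxt <- if (cur %in% names(parents)) unname(parents[[cur]]) else "any"
    chain <- c(chain, nxt)
    cur <- nxt
    if (length(chain) > 64) stop("type hierarchy cycle at '", type, "'")
  }
  chain
}

#' Test / measure assignability between semantic type labels
#'
#' `type_is(sub, sup)` is `TRUE` when a value labelled `sub` may be used
#' where `sup` is expected.  `type_distance()` returns the number of
#' hierarchy steps from `sub` up to `sup` (0 = exact), or `NA` when not
#' assignable.
#'
#' @param sub,sup type labels
#' @param ctx optional context carrying hierarchy extensions
#' @return logical / integer
#' @export
type_is <- function(sub, sup, ctx = NULL) {
  !is.na(type_distance(sub, sup, ctx))
}

#' @rdname type_is
#' @export
type_distance <- function(sub, sup, ctx = NULL) {
  chain <- type_ancestry(sub, ctx)
  i <- match(sup, chain)
  if (is.na(i)) NA_integer_ else i - 1L
}

#' Semantic type label of a value
#'
#' Whole numbers are labelled `integer`, other numerics `real`; images carry
#' their layout-specific label (`array_image`, ...).
#'
#' @param value any R value
#' @return a type label string
#' @export
type_of <- function(value) {
  if (is_ndimg(value)) return(paste0(value$layout, "_image"))
  if (is_dataset(value)) return("dataset")
  if (inherits(value, "sample_type")) return("sample_type")
  if (inherits(value, "nd_op")) return("op")
  if (inherits(value, "nd_location")) return("location")
  if (inherits(value, "mask_roi")) return("roi")
  if (is.character(value)) return("string")
  if (is.logical(value)) return("logical")
  if (is.numeric(value)) {
    if (length(value) >= 1 && all(is.finite(value)) && all(value == floor(value)))
      return("integer")
    return("real")
  }
  "any"
}
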