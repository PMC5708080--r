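#' @title Op registry and matching engine
#' @description
#' An op is a named, typed, prioritized operation registered as a plugin.
#' Callers request an op by name and arguments, not by implementation: the
#' engine scores every candidate whose name (or alias) and arity fit, and
#' picks the best by the total order (conversion penalty ascending,
#' specificity ascending, priority descending, id ascending).  Conversions
#' are penalized above specificity, so an exact-type op always beats a
#' converter-assisted one, and among direct matches the most specific
#' implementation wins.  Special op instances ([op_instance()]) freeze a
#' match so it can be applied to varying primary inputs with no further
#' matching.  Ops of the `function` kind are pure: they never modify their
#' inputs, which permits optional result memoization.
#' @name ops-engine
NULL

#' Declare an op parameter
#'
#' @param name parameter name
#' @param type semantic type label
#' @param primary is this a primary input (varies across calls of a special
#'   op instance)?  The count of primary parameters is the op's arity.
#' @param optional may be omitted (trailing parameters only)
#' @param default value used when an optional parameter is omitted
#' @return a parameter spec for [op_descriptor()]
#' @export
op_param <- function(name, type, primary = TRUE, optional = FALSE,
                     default = NULL) {
  list(name = name, type = type, primary = primary, optional = optional,
       default = default)
}

#' Construct an op descriptor
#'
#' @param id unique descriptor id (e.g. `"math.add.image-image"`)
#' @param name op name, `"namespace.op"`
#' @param params list of [op_param()]s, in call order
#' @param output semantic type label of the result
#' @param body function `(ctx, args) -> result`; must be pure (no
#'   modification of inputs) — the engine realizes the computer/inplace
#'   execution kinds by copying the computed values into the target
#' @param aliases alternative names matched like `name`
#' @param priority real, higher preferred (after penalty and specificity)
#' @param kinds nonempty subset of `"function"`, `"computer"`, `"inplace"`;
#'   the inplace kind requires a mutable primary input of the output type
#' @return an `op_descriptor`
#' @export
op_descriptor <- function(id, name, params, output, body, aliases = character(),
                          priority = 0, kinds = "function") {
  stopifnot(is.function(body), length(kinds) >= 1L,
            all(kinds %in% c("function", "computer", "inplace")))
  arity <- sum(vapply(params, function(p) isTRUE(p$primary), logical(1)))
  if ("inplace" %in% kinds) {
    prim <- Filter(function(p) isTRUE(p$primary), params)
    if (length(prim) == 0L || !identical(prim[[1L]]$type, output))
      stop("inplace kind requires a mutable primary input of the output type")
  }
  structure(list(id = id, name = name, aliases = aliases, params = params,
                 output = output, priority = as.numeric(priority),
                 kinds = kinds, arity = arity, body = body),
            class = "op_descriptor")
}

# service: op registry (manifest kind "op_service"; op plugins kind "op")
new_op_service <- function(ctx) {
  svc <- new.env(parent = emptyenv())
  svc$ops <- list()
  for (d in plugin_payloads(ctx, "op")) op_service_add(svc, d)
  class(svc) <- "op_service"
  svc
}

op_service_add <- function(svc, d) {
  stopifnot(inherits(d, "op_descriptor"))
  ids <- vapply(svc$ops, function(o) o$id, character(1))
  if (d$id %in% ids) stop("duplicate op id '", d$id, "'")
  svc$ops[[length(svc$ops) + 1L]] <- d
  length(svc$ops)
}

#' Register an op in a context
#'
#' @param ctx a context
#' @param d an [op_descriptor()]
#' @return registry size after registration
#' @export
register_op <- function(ctx, d) {
  op_service_add(get_service(ctx, "op_service"), d)
}

#' @rdname register_op
#' @return `ops_registered()`: all descriptors in registration order
#' @export
ops_registered <- function(ctx) get_service(ctx, "op_service")$ops

# score one candidate against argument types; NULL when incompatible
score_candidate <- function(ctx, d, arg_types) {
  nreq <- sum(!vapply(d$params, function(p) isTRUE(p$optional), logical(1)))
  n <- length(arg_types)
  if (n < nreq || n > length(d$params)) return(NULL)
  plan <- vector("list", n)
  penalty <- 0L
  dist <- 0L
  for (i in seq_len(n)) {
    pt <- d$params[[i]]$type
    at <- arg_types[[i]]
    dd <- type_distance(at, pt, ctx)
    if (!is.na(dd)) {
      plan[[i]] <- list(how = "direct")
      dist <- dist + dd
    } else {
      conv <- applicable_converters(ctx, at, pt)
      if (length(conv) == 0L) return(NULL)
      plan[[i]] <- list(how = "convert", id = conv[[1L]]$id)
      penalty <- penalty + 1L
      dist <- dist + type_distance(conv[[1L]]$to, pt, ctx)
    }
  }
  list(descriptor = d, conversion_plan = plan, penalty = penalty,
       specificity = dist)
}

#' Resolve an op request to the best match
#'
#' @param ctx a context
#' @param name op name or alias
#' @param arg_types semantic type labels of the intended arguments (see
#'   [type_of()])
#' @param out_type optional required output type
#' @return an `op_match`: list with `descriptor`, `conversion_plan` (one
#'   `"direct"` or converter-id entry per argument), `penalty` (count of
#'   converted arguments) and `specificity` (summed hierarchy distance)
#' @export
resolve_op <- function(ctx, name, arg_types, out_type = NULL) {
  arg_types <- as.list(arg_types)
  ops <- ops_registered(ctx)
  named <- Filter(function(d) name == d$name || name %in% d$aliases, ops)
  if (length(named) == 0L)
    stop("unknown op '", name, "'")
  if (!is.null(out_type))
    named <- Filter(function(d) type_is(d$output, out_type, ctx), named)
  scored <- Filter(Negate(is.null),
                   lapply(named, function(d) score_candidate(ctx, d, arg_types)))
  if (length(scored) == 0L) {
    near <- paste(vapply(named, function(d) {
      paste0(d$id, "(", paste(vapply(d$params, function(p) p$type, character(1)),
                              collapse = ", "), ")")
    }, character(1)), collapse = "; ")
    stop("no-match error: no '", name, "' candidate accepts (",
         paste(unlist(arg_types), collapse = ", "), "); near misses: ", near)
  }
  key <- data.frame(
    penalty = vapply(scored, function(m) m$penalty, integer(1)),
    spec = vapply(scored, function(m) m$specificity, integer(1)),
    pri = vapply(scored, function(m) m$descriptor$priority, numeric(1)),
    id = vapply(scored, function(m) m$descriptor$id, character(1)))
  ord <- order(key$penalty, key$spec, -key$pri, key$id, method = "radix")
  if (length(ord) > 1L) {
    a <- key[ord[1L], ]; b <- key[ord[2L], ]
    if (a$penalty == b$penalty && a$spec == b$spec && a$pri == b$pri)
      ctx_log(ctx, "WARN", "ambiguous op match for '", name,
              "': chose '", a$id, "' over '", b$id, "' by id order")
  }
  ctx_count(ctx, "op_matches")
  best <- scored[[ord[1L]]]
  class(best) <- "op_match"
  best
}

# apply a conversion plan to raw arguments
apply_plan <- function(ctx, plan, args) {
  for (i in seq_along(plan)) {
    if (identical(plan[[i]]$how, "convert"))
      args[[i]] <- convert_with(ctx, plan[[i]]$id, args[[i]])
  }
  args
}

# fill trailing optional parameters with defaults
fill_defaults <- function(d, args) {
  if (length(args) < length(d$params)) {
    for (i in (length(args) + 1L):length(d$params))
      args[i] <- list(d$params[[i]]$default)   # keeps NULL defaults in place
  }
  args
}

#' Run an op by name
#'
#' Resolves the best match for the argument types, applies the match's
#' converters, and executes the op in one of its kinds:
#' * default (`function` kind): a fresh output is returned, inputs untouched;
#' * `out =` (`computer` kind): the computed values are written into the
#'   preallocated output object, which is returned;
#' * `inplace = TRUE` (`inplace` kind): the first primary input is
#'   overwritten with the result and returned.
#'
#' With context memoization enabled, function-kind results are cached by
#' (op id, content digest of arguments) and returned without re-execution.
#'
#' @param ctx a context
#' @param name op name or alias
#' @param args list of arguments, in parameter order
#' @param out optional preallocated output image (computer kind)
#' @param inplace mutate the first input (inplace kind)
#' @return the op result
#' @export
run_op <- function(ctx, name, args, out = NULL, inplace = FALSE) {
  stopifnot(is.list(args))
  while (length(args) && is.null(args[[length(args)]]))
    args <- args[-length(args)]          # trailing NULLs = omitted optionals
  match <- resolve_op(ctx, name, lapply(args, type_of))
  execute_match(ctx, match, args, out = out, inplace = inplace)
}

execute_match <- function(ctx, match, args, out = NULL, inplace = FALSE) {
  d <- match$descriptor
  if (inplace && !("inplace" %in% d$kinds))
    stop("op '", d$id, "' has no inplace kind")
  if (!is.null(out) && !("computer" %in% d$kinds))
    stop("op '", d$id, "' has no computer kind")
  target <- if (inplace) args[[1L]] else out
  conv <- fill_defaults(d, apply_plan(ctx, match$conversion_plan, args))
  memo_key <- NULL
  if (isTRUE(ctx$config$memoize) && is.null(target)) {
    memo_key <- paste0(d$id, "|",
                       paste(vapply(conv, content_digest, character(1)),
                             collapse = "|"))
    if (exists(memo_key, envir = ctx$memo, inherits = FALSE)) {
      ctx_count(ctx, "memo_hits")
      return(get(memo_key, envir = ctx$memo))
    }
  }
  result <- tryCatch(d$body(ctx, conv), error = function(e) {
    stop("execution error in op '", d$id, "': ", conditionMessage(e),
         call. = FALSE)
  })
  ctx_count(ctx, "op_runs")
  if (!is.null(target)) {
    if (!is_ndimg(target) || !is_ndimg(result))
      stop("computer/inplace kinds require image outputs")
    if (!identical(target$shape, result$shape))
      stop("shape error: target shape differs from result shape")
    set_img_values(target, img_values(result))
    return(target)
  }
  if (!is.null(memo_key)) assign(memo_key, result, envir = ctx$memo)
  result
}

# content digest for memoization / purity checks (md5 over serialization)
content_digest <- function(value) {
  payload <- if (is_ndimg(value))
    list(t = value$type$name, s = value$shape_chr, v = img_values(value))
  else if (is_dataset(value))
    list(n = value$name, i = content_digest(value$image))
  else value
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(payload, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Create a special op instance
#'
#' Resolves the match once and returns a callable applying the matched
#' implementation to varying primary inputs with zero further matching; the
#' non-primary parameters are bound to `fixed` values at creation.  The
#' instance's arity equals the descriptor's count of primary parameters
#' (nullary, unary, binary).  Primary inputs are type-checked against the
#' bound types on every call.
#'
#' @param ctx a context
#' @param name op name or alias
#' @param fixed named (or positional) list of values for the non-primary
#'   parameters
#' @param primary_types optional type labels for the primary inputs;
#'   defaults to the declared parameter types
#' @return a function of class `nd_op`; call it with the primary inputs
#' @export
op_instance <- function(ctx, name, fixed = list(), primary_types = NULL) {
  # provisional resolve: named fixed values may bind any parameter (a bound
  # primary stops varying); positional fixed values fill the declared
  # non-primary parameters in order; remaining primaries take primary_types
  probe <- function(d) {
    pn <- vapply(d$params, function(p) p$name, character(1))
    declared_prim <- vapply(d$params, function(p) isTRUE(p$primary), logical(1))
    prim <- declared_prim
    bound_vals <- vector("list", length(d$params))
    bound_has <- logical(length(d$params))
    fx <- fixed
    nms <- names(fx)
    if (is.null(nms)) nms <- rep("", length(fx))
    for (j in seq_along(fx)) {
      if (nzchar(nms[[j]])) {
        i <- match(nms[[j]], pn)
        if (is.na(i)) return(NULL)
        bound_vals[[i]] <- fx[[j]]
        bound_has[[i]] <- TRUE
        prim[[i]] <- FALSE
      }
    }
    unnamed <- fx[!nzchar(nms)]
    slots <- which(!declared_prim & !bound_has)
    if (length(unnamed) > length(slots)) return(NULL)
    for (j in seq_along(unnamed)) {
      i <- slots[[j]]
      bound_vals[[i]] <- unnamed[[j]]
      bound_has[[i]] <- TRUE
    }
    if (!is.null(primary_types) && sum(prim) != length(primary_types))
      return(NULL)
    types <- character(length(d$params))
    types[prim] <- if (is.null(primary_types))
      vapply(d$params[prim], function(p) p$type, character(1))
    else unlist(primary_types)
    for (i in which(!prim))
      types[[i]] <- if (bound_has[[i]]) type_of(bound_vals[[i]])
                    else d$params[[i]]$type
    list(types = types, prim = prim, bound_vals = bound_vals,
         bound_has = bound_has)
  }
  ops <- ops_registered(ctx)
  named <- Filter(function(d) name == d$name || name %in% d$aliases, ops)
  if (length(named) == 0L) stop("unknown op '", name, "'")
  probes <- lapply(named, probe)
  keep <- !vapply(probes, is.null, logical(1))
  scored <- list()
  for (i in which(keep)) {
    s <- score_candidate(ctx, named[[i]], as.list(probes[[i]]$types))
    if (!is.null(s)) { s$probe <- probes[[i]]; scored[[length(scored) + 1L]] <- s }
  }
  if (length(scored) == 0L)
    stop("no-match error: no '", name, "' candidate fits the bound signature")
  ord <- order(vapply(scored, function(m) m$penalty, integer(1)),
               vapply(scored, function(m) m$specificity, integer(1)),
               -vapply(scored, function(m) m$descriptor$priority, numeric(1)),
               vapply(scored, function(m) m$descriptor$id, character(1)),
               method = "radix")
  m <- scored[[ord[1L]]]
  ctx_count(ctx, "op_matches")
  d <- m$descriptor
  prim <- m$probe$prim
  bound_types <- m$probe$types[prim]
  # pre-convert fixed arguments once
  np_idx <- which(!prim)
  fixed_conv <- vector("list", length(np_idx))
  for (j in seq_along(np_idx)) {
    i <- np_idx[[j]]
    v <- if (m$probe$bound_has[[i]]) m$probe$bound_vals[[i]]
         else d$params[[i]]$default
    if (!is.null(v) && identical(m$conversion_plan[[i]]$how, "convert"))
      v <- convert_with(ctx, m$conversion_plan[[i]]$id, v)
    fixed_conv[j] <- list(v)
  }
  prim_idx <- which(prim)
  fn <- function(...) {
    primaries <- list(...)
    if (length(primaries) != length(prim_idx))
      stop("op instance '", d$id, "' expects ", length(prim_idx),
           " primary input(s)")
    args <- vector("list", length(d$params))
    args[np_idx] <- fixed_conv
    for (j in seq_along(prim_idx)) {
      v <- primaries[[j]]
      if (!type_is(type_of(v), bound_types[[j]], ctx))
        stop("type error: primary input ", j, " is ", type_of(v),
             ", bound type is ", bound_types[[j]])
      i <- prim_idx[[j]]
      if (identical(m$conversion_plan[[i]]$how, "convert"))
        v <- convert_with(ctx, m$conversion_plan[[i]]$id, v)
      args[[i]] <- v
    }
    result <- d$body(ctx, args)
    ctx_count(ctx, "op_runs")
    result
  }
  structure(fn, class = c("nd_op", "function"), descriptor = d,
            arity = length(prim_idx), bound_types = bound_types)
}

#' @export
print.nd_op <- function(x, ...) {
  d <- attr(x, "descriptor")
  cat("<op instance ", d$id, ", arity ", attr(x, "arity"), ">\n", sep = "")
  invisible(x)
}
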