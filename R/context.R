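#' @title Application context
#' @description
#' A context is the application container: it holds prioritized plugin
#' registries, lazily instantiated per-context singleton services, a
#' synchronous publish/subscribe event bus, an object index, a persistent
#' preference store and a log sink.  Two contexts share no mutable state, so
#' several independently configured instances can coexist in one session.
#' @name context
NULL

#' Create a plugin descriptor
#'
#' Descriptors are the unit of extensibility: every service, sample type
#' provider, converter, op, format, pre-/post-processor and console action is
#' registered as a descriptor of the corresponding kind.  Within a kind,
#' descriptors are totally ordered by (priority descending, id ascending).
#'
#' @param kind plugin-category label (e.g. `"service"`, `"op"`, `"format"`)
#' @param id unique string within its kind in a context
#' @param priority finite real; larger wins
#' @param attrs named character vector of free-form attributes
#' @param factory zero- or one-argument function producing the plugin payload;
#'   called with the context when it accepts an argument
#' @return a `plugin_descriptor`
#' @export
plugin_descriptor <- function(kind, id, priority = 0, attrs = character(), factory) {
  stopifnot(is.character(kind), length(kind) == 1L, nzchar(kind),
            is.character(id), length(id) == 1L, nzchar(id),
            is.numeric(priority), length(priority) == 1L, is.finite(priority),
            is.function(factory))
  structure(list(kind = kind, id = id, priority = as.numeric(priority),
                 attrs = attrs, factory = factory),
            class = "plugin_descriptor")
}

default_manifest_path <- function() {
  system.file("plugins", "manifest.txt", package = "ndops", mustWork = TRUE)
}

resolve_entry_point <- function(entry) {
  if (grepl("::", entry, fixed = TRUE)) {
    parts <- strsplit(entry, "::", fixed = TRUE)[[1]]
    return(getExportedValue(parts[[1]], parts[[2]]))
  }
  ns <- asNamespace("ndops")
  if (exists(entry, envir = ns, inherits = FALSE)) return(get(entry, envir = ns))
  if (exists(entry, envir = globalenv())) return(get(entry, envir = globalenv()))
  stop("unknown plugin entry point '", entry, "'")
}

#' Load plugin descriptors from a manifest
#'
#' The manifest is UTF-8 text with one descriptor per line:
#' `kind<TAB>id<TAB>priority<TAB>entry`.  `entry` names a function (optionally
#' `pkg::fun`) returning the plugin payload.  `#` starts a comment.
#' In-process descriptors made with [plugin_descriptor()] may be appended to
#' the result; duplicates (same kind + id) are rejected by [build_context()].
#'
#' @param source path to a manifest file; defaults to the shipped manifest of
#'   built-in plugins
#' @return a list of `plugin_descriptor`s, in deterministic (file) order
#' @export
load_plugin_index <- function(source = default_manifest_path()) {
  if (!file.exists(source)) stop("manifest not readable: ", source)
  lines <- readLines(source, encoding = "UTF-8", warn = FALSE)
  out <- list()
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[[i]])
    if (!nzchar(trimws(line))) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    if (length(fields) != 4L || !all(nzchar(fields)))
      stop("malformed manifest line ", i, " in ", source,
           ": expected kind<TAB>id<TAB>priority<TAB>entry")
    pri <- suppressWarnings(as.numeric(fields[[3]]))
    if (is.na(pri)) stop("malformed manifest line ", i, ": bad priority '", fields[[3]], "'")
    entry <- fields[[4]]
    out[[length(out) + 1L]] <- plugin_descriptor(
      kind = fields[[1]], id = fields[[2]], priority = pri,
      attrs = c(entry = entry),
      factory = local({
        e <- entry
        function(ctx) {
          f <- resolve_entry_point(e)
          if (length(formals(f)) >= 1L) f(ctx) else f()
        }
      }))
  }
  out
}

#' Build an application context
#'
#' Descriptors are indexed by kind and sorted by (priority descending, id
#' ascending).  Services are instantiated lazily on first [get_service()]
#' request.  Each context is fully isolated: registries, services, the object
#' index, event subscriptions and preferences are all per-context.
#'
#' @param descriptors list of [plugin_descriptor()]s; defaults to the shipped
#'   manifest of built-in plugins
#' @param prefs_file optional path for the persistent preference store; when
#'   `NULL` a per-context temporary file is used
#' @param memoize enable op result caching (off by default)
#' @return a context environment of class `ndctx`
#' @export
build_context <- function(descriptors = load_plugin_index(),
                          prefs_file = NULL, memoize = FALSE) {
  ctx <- new.env(parent = emptyenv())
  class(ctx) <- "ndctx"
  ctx$plugins <- list()              # kind -> list of descriptors (sorted)
  ctx$services <- new.env(parent = emptyenv())
  ctx$instantiating <- character()   # service cycle detection
  ctx$objects <- list()              # object index, insertion order
  ctx$subscribers <- list()          # topic -> list(fun)
  ctx$prefs <- list()
  ctx$prefs_file <- if (is.null(prefs_file))
    tempfile("ndops-prefs-", fileext = ".txt") else prefs_file
  ctx$log <- character()
  ctx$counters <- new.env(parent = emptyenv())
  ctx$type_parents <- character()
  ctx$config <- list(memoize = isTRUE(memoize),
                     chunk_rows = 256L,
                     reduce_chunk = 4e6)
  ctx$memo <- new.env(parent = emptyenv())
  ctx$out <- function(...) cat(...)   # text sink for headless display

  for (d in descriptors) register_plugin(ctx, d)
  if (file.exists(ctx$prefs_file)) ctx$prefs <- read_prefs_file(ctx$prefs_file)
  ctx
}

#' @export
print.ndctx <- function(x, ...) {
  kinds <- names(x$plugins)
  cat("<ndops context: ", sum(lengths(x$plugins)), " plugins in ",
      length(kinds), " kinds>\n", sep = "")
  invisible(x)
}

sort_descriptors <- function(ds) {
  if (length(ds) == 0L) return(ds)
  pri <- vapply(ds, function(d) d$priority, numeric(1))
  ids <- vapply(ds, function(d) d$id, character(1))
  ds[order(-pri, ids, method = "radix")]
}

#' Register a descriptor in a context
#'
#' @param ctx a context
#' @param desc a [plugin_descriptor()]
#' @return the context, invisibly
#' @export
register_plugin <- function(ctx, desc) {
  stopifnot(inherits(ctx, "ndctx"), inherits(desc, "plugin_descriptor"))
  existing <- ctx$plugins[[desc$kind]]
  if (!is.null(existing)) {
    ids <- vapply(existing, function(d) d$id, character(1))
    if (desc$id %in% ids)
      stop("duplicate plugin id '", desc$id, "' of kind '", desc$kind,
           "': already registered as '", desc$id, "'")
  }
  ctx$plugins[[desc$kind]] <- sort_descriptors(c(existing, list(desc)))
  invisible(ctx)
}

#' List descriptors of one kind
#'
#' @param ctx a context
#' @param kind plugin-category label
#' @return descriptors sorted by (priority descending, id ascending); empty
#'   list for an unknown kind
#' @export
plugins_of <- function(ctx, kind) {
  ds <- ctx$plugins[[kind]]
  if (is.null(ds)) list() else ds
}

call_factory <- function(d, ctx) {
  if (length(formals(d$factory)) >= 1L) d$factory(ctx) else d$factory()
}

# instantiated plugin payloads of a kind, in registry order
plugin_payloads <- function(ctx, kind) {
  lapply(plugins_of(ctx, kind), call_factory, ctx = ctx)
}

#' Obtain the singleton service of a kind
#'
#' The highest-priority descriptor of the kind is instantiated on first
#' request and cached: repeated calls within one context return the identical
#' instance; distinct contexts get distinct instances.  Service factories may
#' themselves request other services; instantiation cycles are an error.
#'
#' @param ctx a context
#' @param kind service kind label
#' @return the service instance
#' @export
get_service <- function(ctx, kind) {
  if (exists(kind, envir = ctx$services, inherits = FALSE))
    return(get(kind, envir = ctx$services))
  ds <- plugins_of(ctx, kind)
  if (length(ds) == 0L) stop("no service of kind '", kind, "' registered")
  if (kind %in% ctx$instantiating)
    stop("service instantiation cycle: ",
         paste(c(ctx$instantiating, kind), collapse = " -> "))
  ctx$instantiating <- c(ctx$instantiating, kind)
  on.exit(ctx$instantiating <- setdiff(ctx$instantiating, kind))
  inst <- call_factory(ds[[1L]], ctx)
  assign(kind, inst, envir = ctx$services)
  inst
}

#' Publish an event on the context's bus
#'
#' Events are plain R objects whose `class()` vector declares their type
#' ancestry, most-derived first.  Subscribers of the event's type and of all
#' ancestor types are invoked synchronously, most-derived topics first; a
#' failing subscriber is logged and the remaining subscribers still run.
#'
#' @param ctx a context
#' @param event an object; `class(event)` is its type ancestry
#' @return number of subscriber invocations attempted
#' @export
publish_event <- function(ctx, event) {
  n <- 0L
  for (topic in class(event)) {
    for (fun in ctx$subscribers[[topic]]) {
      n <- n + 1L
      ok <- tryCatch({ fun(event); TRUE },
                     error = function(e) {
                       ctx_log(ctx, "ERROR", "event subscriber on '", topic,
                               "' failed: ", conditionMessage(e))
                       FALSE
                     })
      invisible(ok)
    }
  }
  n
}

#' Subscribe to an event topic
#'
#' @param ctx a context
#' @param topic event class name
#' @param fun one-argument handler
#' @return the context, invisibly
#' @export
subscribe_event <- function(ctx, topic, fun) {
  ctx$subscribers[[topic]] <- c(ctx$subscribers[[topic]], list(fun))
  invisible(ctx)
}

ctx_log <- function(ctx, level = "INFO", ...) {
  ctx$log <- c(ctx$log, paste0("[", level, "] ", paste0(..., collapse = "")))
  invisible(ctx)
}

ctx_count <- function(ctx, key, inc = 1L) {
  cur <- if (exists(key, envir = ctx$counters, inherits = FALSE))
    get(key, envir = ctx$counters) else 0L
  assign(key, cur + inc, envir = ctx$counters)
  invisible(cur + inc)
}

ctx_counter <- function(ctx, key) {
  if (exists(key, envir = ctx$counters, inherits = FALSE))
    get(key, envir = ctx$counters) else 0L
}

ctx_count_set <- function(ctx, key, value) {
  assign(key, value, envir = ctx$counters)
  invisible(value)
}

# -- object index -------------------------------------------------------------

#' Object index
#'
#' The object index tracks data objects (images, datasets, results) known to
#' the context; the most recently registered image or dataset is the "active
#' image" used by input harvesting.
#'
#' @param ctx a context
#' @param obj any value
#' @return `register_object()` the context, invisibly; `objects_of()` a list;
#'   `active_image()` an image/dataset or `NULL`
#' @export
register_object <- function(ctx, obj) {
  ctx$objects <- c(ctx$objects, list(obj))
  invisible(ctx)
}

#' @rdname register_object
#' @param type optional semantic type label filter (assignability, see
#'   [type_is()])
#' @export
objects_of <- function(ctx, type = NULL) {
  if (is.null(type)) return(ctx$objects)
  Filter(function(o) type_is(type_of(o), type, ctx), ctx$objects)
}

#' @rdname register_object
#' @export
active_image <- function(ctx) {
  imgs <- objects_of(ctx, "image")
  ds <- objects_of(ctx, "dataset")
  all <- c(imgs, ds)
  if (length(all) == 0L) return(NULL)
  # most recently registered wins
  idx <- vapply(all, function(o) {
    Position(function(x) identical(x, o), ctx$objects)
  }, integer(1))
  all[[which.max(idx)]]
}

# -- preference store ---------------------------------------------------------

read_prefs_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  prefs <- list()
  for (line in lines) {
    eq <- regexpr("=", line, fixed = TRUE)
    if (eq < 1L) next
    key <- substr(line, 1L, eq - 1L)
    prefs[[key]] <- substr(line, eq + 1L, nchar(line))
  }
  prefs
}

write_prefs_file <- function(prefs, path) {
  keys <- sort(names(prefs))
  lines <- vapply(keys, function(k) paste0(k, "=", prefs[[k]]), character(1))
  tmp <- paste0(path, ".tmp")
  writeLines(lines, tmp, useBytes = TRUE)
  file.rename(tmp, path)   # atomic on one filesystem
  invisible(path)
}

#' Persistent per-context preferences
#'
#' Flat key=value text, written atomically on every change.  Keys are
#' namespaced by module id (`<module>.<param>`) by the module runtime.
#'
#' @param ctx a context
#' @param key preference key
#' @param value character value to store
#' @param default value returned when the key is absent
#' @return `pref_get()` the stored string or `default`
#' @export
pref_set <- function(ctx, key, value) {
  ctx$prefs[[key]] <- as.character(value)
  write_prefs_file(ctx$prefs, ctx$prefs_file)
  invisible(ctx)
}

#' @rdname pref_set
#' @export
pref_get <- function(ctx, key, default = NULL) {
  if (!is.null(ctx$prefs[[key]])) ctx$prefs[[key]] else default
}
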