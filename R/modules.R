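#' @title Parameterized modules
#' @description
#' A module is an executable unit with declared typed inputs and outputs: a
#' command (an R callable) or a script whose header declares parameters with
#' `#@ <type> <name>` / `#@output <type> <name>` lines.  The framework — not
#' the module — is responsible for resolving inputs ("input harvesting",
#' through a priority-ordered preprocessor chain: provided values with
#' automatic conversion, persisted last-used values, the active image,
#' declared defaults, required-check) and for routing outputs (the
#' postprocessor chain; headless, outputs are echoed to the text sink and
#' registered in the object index).  Modules therefore run identically from
#' the CLI, from scripts and from R code.
#' @name modules
NULL

#' Declare a module parameter
#'
#' @param name identifier
#' @param type semantic type label
#' @param direction `"in"` or `"out"`
#' @param required must be resolved for `direction = "in"`; out-params are
#'   never required inputs
#' @param default optional declared default
#' @param persist persist the resolved value and reuse it as default on later
#'   runs (keyed `<module id>.<name>` in the preference store)
#' @return a `param_spec`
#' @export
param_spec <- function(name, type, direction = c("in", "out"),
                       required = TRUE, default = NULL, persist = FALSE) {
  direction <- match.arg(direction)
  if (direction == "out") required <- FALSE
  structure(list(name = name, type = type, direction = direction,
                 required = required, default = default, persist = persist),
            class = "param_spec")
}

#' Construct a module
#'
#' @param id module id (used to namespace persisted values)
#' @param params list of [param_spec()]s; names must be unique
#' @param body either a function `(ctx, inputs) -> named output list`
#'   (a command), or a script: `list(language = "ndo", text = ...)`
#' @return a `module_info`
#' @export
module_info <- function(id, params, body) {
  nm <- vapply(params, function(p) p$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate parameter name '",
                              nm[duplicated(nm)][1L], "'")
  structure(list(id = id, params = params, body = body),
            class = "module_info")
}

module_inputs <- function(info) {
  Filter(function(p) p$direction == "in", info$params)
}
module_outputs <- function(info) {
  Filter(function(p) p$direction == "out", info$params)
}

# script parameter type tokens -> semantic labels
.script_types <- c(string = "string", str = "string",
                   int = "integer", integer = "integer",
                   real = "real", double = "real", number = "number",
                   image = "image", dataset = "dataset", logical = "logical")

#' Parse a script with a typed parameter header
#'
#' Header lines `#@ <type> <name>` declare inputs and `#@output <type>
#' <name>` declare outputs; the remaining lines are the script body.  Type
#' tokens: `string`, `int`/`integer`, `real`/`double`, `number`, `image`,
#' `dataset`, `logical`.  Script inputs persist by default (last-used values
#' become defaults on subsequent runs).
#'
#' @param text script text (or character vector of lines)
#' @param id module id; defaults to `"script"`
#' @return a [module_info()] whose body is an `"ndo"` script
#' @export
parse_script_header <- function(text, id = "script") {
  lines <- if (length(text) == 1L && grepl("\n", text))
    strsplit(text, "\n", fixed = TRUE)[[1]] else text
  params <- list()
  body <- character(0)
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (grepl("^#@", line)) {
      is_out <- grepl("^#@output\\b", line)
      rest <- trimws(sub("^#@(output)?", "", line))
      fields <- strsplit(rest, "[ \t]+")[[1]]
      if (length(fields) != 2L)
        stop("parse error at line ", i, ": expected '#@ <type> <name>'")
      if (!fields[[1]] %in% names(.script_types))
        stop("parse error at line ", i, ": unknown type label '",
             fields[[1]], "'")
      tt <- .script_types[[fields[[1]]]]
      nm <- fields[[2]]
      if (nm %in% vapply(params, function(p) p$name, character(1)))
        stop("parse error at line ", i, ": duplicate parameter '", nm, "'")
      params[[length(params) + 1L]] <-
        param_spec(nm, tt, if (is_out) "out" else "in",
                   persist = !is_out)
    } else {
      body <- c(body, line)
    }
  }
  module_info(id, params, list(language = "ndo", text = body))
}

#' Read a `.ndo` script file into a module
#'
#' @param path script file path
#' @return a [module_info()] with id = the file's base name
#' @export
read_script_module <- function(path) {
  if (!file.exists(path)) stop("script not found: ", path)
  parse_script_header(readLines(path, encoding = "UTF-8", warn = FALSE),
                      id = sub("\\.[^.]*$", "", basename(path)))
}

# -- preprocessing chain (input harvesting) -----------------------------------

# each preprocessor: function(ctx, info, state); state env has
# $provided (named list), $resolved (named list), $trace (character)

pp_state_unresolved <- function(info, state) {
  setdiff(vapply(module_inputs(info), function(p) p$name, character(1)),
          names(state$resolved))
}

preproc_provided_binder <- function(ctx) {
  list(id = "preprocess.provided", fun = function(ctx, info, state) {
    for (p in module_inputs(info)) {
      if (p$name %in% names(state$provided)) {
        v <- state$provided[[p$name]]
        if (!type_is(type_of(v), p$type, ctx)) v <- convert(ctx, v, p$type)
        state$resolved[[p$name]] <- v
      }
    }
  })
}

preproc_persisted_loader <- function(ctx) {
  list(id = "preprocess.persisted", fun = function(ctx, info, state) {
    for (p in module_inputs(info)) {
      if (p$name %in% pp_state_unresolved(info, state) && isTRUE(p$persist)) {
        stored <- pref_get(ctx, paste0(info$id, ".", p$name))
        if (!is.null(stored)) {
          v <- tryCatch(convert(ctx, stored, p$type), error = function(e) NULL)
          if (!is.null(v)) state$resolved[[p$name]] <- v
        }
      }
    }
  })
}

preproc_active_image <- function(ctx) {
  list(id = "preprocess.active-image", fun = function(ctx, info, state) {
    unres <- pp_state_unresolved(info, state)
    imgish <- Filter(function(p) p$name %in% unres &&
                       p$type %in% c("image", "dataset"),
                     module_inputs(info))
    if (length(imgish) != 1L) return()   # only the unambiguous single case
    act <- active_image(ctx)
    if (is.null(act)) return()
    p <- imgish[[1L]]
    if (!type_is(type_of(act), p$type, ctx)) act <- convert(ctx, act, p$type)
    state$resolved[[p$name]] <- act
  })
}

preproc_default_filler <- function(ctx) {
  list(id = "preprocess.defaults", fun = function(ctx, info, state) {
    for (p in module_inputs(info)) {
      if (p$name %in% pp_state_unresolved(info, state) && !is.null(p$default))
        state$resolved[[p$name]] <- p$default
    }
  })
}

preproc_required_check <- function(ctx) {
  list(id = "preprocess.required", fun = function(ctx, info, state) {
    for (p in module_inputs(info)) {
      if (isTRUE(p$required) && !(p$name %in% names(state$resolved)))
        stop("harvest error: required input '", p$name, "' is unresolved")
    }
  })
}

#' Run a module's preprocessing chain
#'
#' Executes every registered preprocessor plugin in priority order (the
#' provided-values binder, the persisted-defaults loader, the active-image
#' injector, the declared-default filler and the required-input check ship
#' built in) and returns the resolved input map.
#'
#' @param ctx a context
#' @param info a [module_info()]
#' @param provided named list of caller-supplied input values (converted to
#'   the declared types automatically)
#' @return named list of resolved inputs
#' @export
preprocess_chain <- function(ctx, info, provided = list()) {
  state <- new.env(parent = emptyenv())
  state$provided <- provided
  state$resolved <- list()
  state$trace <- character(0)
  for (d in plugins_of(ctx, "preprocessor")) {
    pp <- call_factory(d, ctx)
    state$trace <- c(state$trace, pp$id)
    pp$fun(ctx, info, state)
  }
  attr(state$resolved, "trace") <- state$trace
  state$resolved
}

# -- script body execution ----------------------------------------------------

# built-in "ndo" script language: each nonblank statement is
# `name = expression` in the expression grammar (strings + `+` concat);
# assignments extend the binding environment in order.
run_ndo_script <- function(ctx, text, inputs) {
  bindings <- inputs
  for (line in text) {
    line <- trimws(sub("#.*$", "", line))
    if (!nzchar(line)) next
    eq <- regexpr("=", line, fixed = TRUE)
    if (eq < 1L) stop("script error: statement is not 'name = expression': ",
                      line)
    nm <- trimws(substr(line, 1L, eq - 1L))
    if (!grepl("^[A-Za-z_][A-Za-z0-9_.]*$", nm))
      stop("script error: bad assignment target '", nm, "'")
    bindings[[nm]] <- op_eval(ctx, substr(line, eq + 1L, nchar(line)), bindings)
  }
  bindings
}

# registered script languages (plugin kind "script_language"); payload:
# list(id, run = function(ctx, text, inputs) -> bindings)
lang_ndo <- function(ctx) {
  list(id = "ndo", run = run_ndo_script)
}

# -- postprocessing chain -----------------------------------------------------

postproc_display <- function(ctx) {
  list(id = "postprocess.display", fun = function(ctx, name, value) {
    ctx$out(paste0(name, " = ", render_value(value), "\n"))
    TRUE
  })
}

postproc_object_index <- function(ctx) {
  list(id = "postprocess.object-index", fun = function(ctx, name, value) {
    if (is_ndimg(value) || is_dataset(value)) {
      register_object(ctx, value)   # becomes the active image
      TRUE
    } else FALSE
  })
}

#' Run a module's postprocessing chain
#'
#' Each output is offered to every postprocessor plugin in priority order;
#' headless, the display postprocessor prints `name = value` on the
#' context's text sink and images are registered in the object index.
#'
#' @param ctx a context
#' @param outputs named list of output values
#' @return handled-output report: named list of handler-id vectors
#' @export
postprocess_chain <- function(ctx, outputs) {
  report <- list()
  pps <- lapply(plugins_of(ctx, "postprocessor"), call_factory, ctx = ctx)
  for (nm in names(outputs)) {
    handled <- character(0)
    for (pp in pps) {
      if (isTRUE(pp$fun(ctx, nm, outputs[[nm]]))) handled <- c(handled, pp$id)
    }
    if (length(handled) == 0L)
      ctx_log(ctx, "WARN", "no handler for output '", nm, "'")
    report[[nm]] <- handled
  }
  report
}

#' Run a module
#'
#' Harvests inputs through the preprocessing chain, executes the body
#' (command callable or script), persists inputs of persist-flagged
#' parameters, routes outputs through the postprocessing chain and returns
#' the output map.  The result depends only on the context state and the
#' provided values — no display state is consulted.
#'
#' @param ctx a context
#' @param info a [module_info()] (or a script path)
#' @param provided named list of input values
#' @return named list of outputs
#' @export
run_module <- function(ctx, info, provided = list()) {
  if (is.character(info)) info <- read_script_module(info)
  inputs <- preprocess_chain(ctx, info, provided)
  outspecs <- module_outputs(info)
  outputs <-
    if (is.function(info$body)) {
      tryCatch(info$body(ctx, inputs), error = function(e)
        stop("module error in '", info$id, "': ", conditionMessage(e),
             call. = FALSE))
    } else {
      langs <- lapply(plugins_of(ctx, "script_language"), call_factory,
                      ctx = ctx)
      ids <- vapply(langs, function(l) l$id, character(1))
      li <- match(info$body$language, ids)
      if (is.na(li)) stop("unknown script language '", info$body$language, "'")
      lang <- langs[[li]]
      bindings <- tryCatch(lang$run(ctx, info$body$text, inputs),
                           error = function(e)
        stop("module error in '", info$id, "': ", conditionMessage(e),
             call. = FALSE))
      out <- list()
      for (p in outspecs) {
        if (!p$name %in% names(bindings))
          stop("module error in '", info$id, "': output '", p$name,
               "' was never assigned")
        out[[p$name]] <- bindings[[p$name]]
      }
      out
    }
  for (p in module_inputs(info)) {
    v <- inputs[[p$name]]
    # only plain values round-trip through the text preference store
    if (isTRUE(p$persist) && !is.null(v) &&
        (is.character(v) || is.numeric(v) || is.logical(v)))
      pref_set(ctx, paste0(info$id, ".", p$name), render_value(v))
  }
  postprocess_chain(ctx, outputs)
  outputs
}
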