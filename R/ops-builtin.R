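#' @title Built-in ops
#' @description
#' The shipped op library: element-wise `math.add/sub/mul/div/sqrt` (image
#' with constant, image with image, and scalar variants, plus an
#' array-specialized `math.sqrt`), the separable Gaussian filter
#' `filter.gauss`, the chained difference-of-Gaussians `image.dog`
#' (two Gaussian blurs and a subtraction), the `stats.*` aggregates
#' (`mean` decomposed as `sum / size`), the element-wise `map`, image
#' creation/identity, and the expression `eval` op.  Arithmetic on integer
#' images saturates to the sample-type bounds (the same rule as
#' [clamp_cast()]); integer division rounds half-to-even after real division.
#' @name builtin-ops
NULL

# finalize computed real values into a fresh image like `img`
finish_image <- function(img, raw_values) {
  out <- img_like(img)
  set_img_values(out, clamp_cast(raw_values, img$type, img$type))
  out
}

math_scalar_fun <- function(family) {
  switch(family,
    add = `+`, sub = `-`, mul = `*`,
    div = `/`,
    sqrt = function(a, b = NULL) sqrt(a))
}

math_image_values <- function(family, img, va, vb) {
  f <- math_scalar_fun(family)
  if (family == "div" && type_is_bounded_int(img$type)) {
    z <- which(vb == 0)
    if (length(z)) {
      co <- linear_to_coords(z[1L] - 1, img$shape)
      stop("domain error: integer division by zero sample at (",
           paste(co[1L, ], collapse = ", "), ")")
    }
  }
  if (family == "sqrt" && type_is_bounded_int(img$type) && any(va < 0))
    stop("domain error: square root of negative integer sample")
  f(va, vb)
}

make_math_descriptor <- function(family, variant) {
  fname <- paste0("math.", family)
  alias <- family
  if (variant == "ii") {
    body <- function(ctx, args) {
      a <- args[[1L]]; b <- args[[2L]]
      if (!identical(a$shape, b$shape))
        stop("shape error: operand shapes [",
             paste(a$shape_chr, collapse = "x"), "] and [",
             paste(b$shape_chr, collapse = "x"), "] differ")
      finish_image(a, math_image_values(family, a, img_values(a), img_values(b)))
    }
    op_descriptor(paste0(fname, ".image-image"), fname,
                  list(op_param("a", "image"), op_param("b", "image")),
                  "image", body, aliases = alias,
                  kinds = c("function", "computer", "inplace"))
  } else if (variant == "ic") {
    body <- function(ctx, args) {
      a <- args[[1L]]; b <- args[[2L]]
      finish_image(a, math_image_values(family, a, img_values(a), b))
    }
    op_descriptor(paste0(fname, ".image-constant"), fname,
                  list(op_param("a", "image"),
                       op_param("b", "number", primary = FALSE)),
                  "image", body, aliases = alias,
                  kinds = c("function", "computer", "inplace"))
  } else {  # scalar-scalar; division is real-valued
    body <- function(ctx, args) math_scalar_fun(family)(args[[1L]], args[[2L]])
    op_descriptor(paste0(fname, ".number-number"), fname,
                  list(op_param("a", "number"), op_param("b", "number")),
                  "number", body, aliases = alias)
  }
}

# one manifest entry point per math descriptor
for (.fam in c("add", "sub", "mul", "div")) {
  for (.var in c("ii", "ic", "ss")) {
    assign(paste0("opdef_math_", .fam, "_", .var),
           local({
             f <- .fam; v <- .var
             function(ctx) make_math_descriptor(f, v)
           }))
  }
}
rm(.fam, .var)

opdef_math_sqrt_image <- function(ctx) {
  body <- function(ctx, args) {
    a <- args[[1L]]
    finish_image(a, math_image_values("sqrt", a, img_values(a), NULL))
  }
  op_descriptor("math.sqrt.image", "math.sqrt", list(op_param("a", "image")),
                "image", body, aliases = "sqrt",
                kinds = c("function", "computer", "inplace"))
}

# array-specialized sqrt: same semantics, narrower parameter type, so the
# matcher prefers it for array images ("the most specific wins")
opdef_math_sqrt_array <- function(ctx) {
  body <- function(ctx, args) {
    a <- args[[1L]]
    if (type_is_bounded_int(a$type) && any(a$data < 0))
      stop("domain error: square root of negative integer sample")
    out <- img_like(a)
    out$data <- clamp_cast(sqrt(a$data), a$type, a$type)   # direct buffer path
    out
  }
  op_descriptor("math.sqrt.array", "math.sqrt",
                list(op_param("a", "array_image")),
                "array_image", body, aliases = "sqrt", priority = 10,
                kinds = c("function", "computer", "inplace"))
}

opdef_math_sqrt_number <- function(ctx) {
  op_descriptor("math.sqrt.number", "math.sqrt", list(op_param("a", "number")),
                "number", function(ctx, args) sqrt(args[[1L]]),
                aliases = "sqrt")
}

# -- Gaussian filter and difference of Gaussians ------------------------------

# reflect 0-based indices into [0, n-1], single (non-repeating) boundary
mirror_index <- function(i, n) {
  if (n == 1L) return(rep(0, length(i)))
  period <- 2 * n - 2
  j <- i %% period
  ifelse(j >= n, period - j, j)
}

# sampled normalized Gaussian kernel, radius max(1, ceil(3*sigma))
gauss_kernel <- function(sigma) {
  r <- max(1, ceiling(3 * sigma))
  x <- (-r):r
  w <- exp(-(x^2) / (2 * sigma^2))
  w / sum(w)
}

# separable convolution along every dimension, mirror boundary
gauss_filter_values <- function(values, shape, sigma) {
  d <- length(shape)
  arr <- array(values, dim = rev(shape))   # R dim k <-> our dim d+1-k
  w <- gauss_kernel(sigma)
  r <- (length(w) - 1L) / 2L
  for (k in seq_len(d)) {
    n <- dim(arr)[[k]]
    perm <- c(k, setdiff(seq_len(d), k))
    m <- aperm(arr, perm)
    dm <- dim(m)
    m <- matrix(m, nrow = n)
    out <- matrix(0, nrow = n, ncol = ncol(m))
    base <- seq.int(0L, n - 1L)
    for (tap in seq_along(w)) {
      src <- mirror_index(base + (tap - 1L - r), n) + 1
      out <- out + w[[tap]] * m[src, , drop = FALSE]
    }
    dim(out) <- dm
    arr <- aperm(out, order(perm))
  }
  as.vector(arr)
}

#' Gaussian blur of an image
#'
#' Separable convolution per dimension with a sampled Gaussian kernel
#' normalized to sum 1, radius `max(1, ceil(3*sigma))`, mirror (reflective,
#' non-edge-repeating) boundary.  `sigma = 0` returns an identical copy.
#' Integer images are filtered in real arithmetic and cast back with
#' [clamp_cast()].
#'
#' @param ctx a context
#' @param img an `ndimg`
#' @param sigma standard deviation in samples, `>= 0`
#' @return a fresh blurred image
#' @export
filter_gauss <- function(ctx, img, sigma) {
  img <- as_image(img)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("domain error: sigma must be a nonnegative real, got ", sigma)
  if (sigma == 0) return(img_copy(img))
  finish_image(img, gauss_filter_values(img_values(img), img$shape, sigma))
}

opdef_filter_gauss <- function(ctx) {
  op_descriptor("filter.gauss", "filter.gauss",
                list(op_param("img", "image"),
                     op_param("sigma", "number", primary = FALSE)),
                "image",
                function(ctx, args) filter_gauss(ctx, args[[1L]], args[[2L]]),
                aliases = "gauss", kinds = c("function", "computer"))
}

#' Difference of Gaussians
#'
#' Chained op: `dog(img, s1, s2) = sub(gauss(img, s1), gauss(img, s2))`,
#' executed as a tree of `filter.gauss` and `math.sub` op calls — the result
#' is exactly equal to composing those ops by hand, and `dog(img, s, s)` is
#' the zero image.
#'
#' @param ctx a context
#' @param img an `ndimg`
#' @param sigma1,sigma2 Gaussian standard deviations, `>= 0`
#' @return a fresh image
#' @export
image_dog <- function(ctx, img, sigma1, sigma2) {
  g1 <- run_op(ctx, "filter.gauss", list(img, sigma1))
  g2 <- run_op(ctx, "filter.gauss", list(img, sigma2))
  run_op(ctx, "math.sub", list(g1, g2))
}

opdef_image_dog <- function(ctx) {
  op_descriptor("image.dog", "image.dog",
                list(op_param("img", "image"),
                     op_param("sigma1", "number", primary = FALSE),
                     op_param("sigma2", "number", primary = FALSE)),
                "image",
                function(ctx, args)
                  image_dog(ctx, args[[1L]], args[[2L]], args[[3L]]),
                aliases = "dog", kinds = c("function", "computer"))
}

# -- statistics ---------------------------------------------------------------

stats_reduce <- function(ctx, img, roi, init, f) {
  img <- as_image(img)
  acc <- reduce_samples(img, c(init, 0), function(acc, vals, coords) {
    c(f(acc[[1L]], vals), acc[[2L]] + length(vals))
  }, roi = roi, chunk_samples = ctx$config$reduce_chunk,
    need_coords = !is.null(roi))
  peak <- attr(acc, "peak_chunk")
  ctx_count_set(ctx, "reduce_peak_chunk",
                max(ctx_counter(ctx, "reduce_peak_chunk"), peak))
  if (!is.null(roi) && acc[[2L]] == 0)
    stop("domain error: ROI selects no samples")
  acc[[1L]]
}

opdef_stats_sum <- function(ctx) {
  op_descriptor("stats.sum", "stats.sum",
    list(op_param("img", "image"),
         op_param("roi", "roi", primary = FALSE, optional = TRUE)),
    "number",
    function(ctx, args)
      stats_reduce(ctx, args[[1L]], args[[2L]], 0,
                   function(a, v) a + sum(v)),
    aliases = "sum")
}

opdef_stats_size <- function(ctx) {
  op_descriptor("stats.size", "stats.size",
    list(op_param("img", "image"),
         op_param("roi", "roi", primary = FALSE, optional = TRUE)),
    "number",
    function(ctx, args) {
      if (is.null(args[[2L]])) return(prod(as_image(args[[1L]])$shape))
      stats_reduce(ctx, args[[1L]], args[[2L]], 0, function(a, v) a + length(v))
    },
    aliases = "size")
}

opdef_stats_min <- function(ctx) {
  op_descriptor("stats.min", "stats.min",
    list(op_param("img", "image"),
         op_param("roi", "roi", primary = FALSE, optional = TRUE)),
    "number",
    function(ctx, args)
      stats_reduce(ctx, args[[1L]], args[[2L]], Inf,
                   function(a, v) min(a, if (length(v)) min(v) else Inf)))
}

opdef_stats_max <- function(ctx) {
  op_descriptor("stats.max", "stats.max",
    list(op_param("img", "image"),
         op_param("roi", "roi", primary = FALSE, optional = TRUE)),
    "number",
    function(ctx, args)
      stats_reduce(ctx, args[[1L]], args[[2L]], -Inf,
                   function(a, v) max(a, if (length(v)) max(v) else -Inf)))
}

# mean is deliberately built from sum, size and div (op chaining)
opdef_stats_mean <- function(ctx) {
  op_descriptor("stats.mean", "stats.mean",
    list(op_param("img", "image"),
         op_param("roi", "roi", primary = FALSE, optional = TRUE)),
    "number",
    function(ctx, args) {
      s <- run_op(ctx, "stats.sum", args)
      n <- run_op(ctx, "stats.size", args)
      run_op(ctx, "math.div", list(s, n))
    },
    aliases = "mean")
}

# -- map, creation, identity --------------------------------------------------

opdef_map <- function(ctx) {
  body <- function(ctx, args) {
    img <- as_image(args[[1L]])
    op <- args[[2L]]
    if (!inherits(op, "nd_op")) stop("type error: map needs a special op instance")
    bt <- attr(op, "bound_types")
    st <- if (type_is_bounded_int(img$type)) "integer" else "real"
    if (!type_is(st, bt[[1L]])) {
      # also allow ops bound to the image's own sample domain label "number"
      stop("type error: unary op is bound to ", bt[[1L]],
           ", image samples are ", st)
    }
    vals <- img_values(img)
    res <- vapply(vals, function(x) as.numeric(op(x)), numeric(1))
    finish_image(img, res)
  }
  op_descriptor("map.unary", "map",
                list(op_param("img", "image"),
                     op_param("op", "op", primary = FALSE)),
                "image", body, kinds = c("function", "computer"))
}

opdef_create_img <- function(ctx) {
  op_descriptor("create.img", "create.img",
    list(op_param("t", "sample_type", primary = FALSE),
         op_param("shape", "number", primary = FALSE)),
    "image",
    function(ctx, args) create_image(args[[1L]], args[[2L]], "array"),
    aliases = "create")
}

opdef_identity_image <- function(ctx) {
  op_descriptor("identity.image", "identity", list(op_param("x", "image")),
                "image", function(ctx, args) img_copy(args[[1L]]),
                aliases = "copy.img", kinds = c("function", "computer"))
}

opdef_identity_number <- function(ctx) {
  op_descriptor("identity.number", "identity", list(op_param("x", "number")),
                "number", function(ctx, args) args[[1L]])
}

opdef_eval <- function(ctx) {
  op_descriptor("eval.expr", "eval",
    list(op_param("expr", "string"),
         op_param("bindings", "any", primary = FALSE, optional = TRUE)),
    "any",
    function(ctx, args) {
      b <- args[[2L]]
      op_eval(ctx, args[[1L]], if (is.null(b)) list() else b)
    })
}
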