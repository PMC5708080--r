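# shared test helpers: fixtures are always generated in code, never stored.

# context whose text sink collects instead of printing
silent_ctx <- function(...) {
  ctx <- build_context(...)
  ctx$cli_text <- character(0)
  ctx$out <- function(...) ctx$cli_text <- c(ctx$cli_text, paste0(...))
  ctx
}

counter_of <- function(ctx, key) ndops:::ctx_counter(ctx, key)

u8 <- function(ctx) get_sample_type(ctx, "uint8")
f64 <- function(ctx) get_sample_type(ctx, "float64")

# --- independent dense convolution oracle (direct sum, mirror boundary) ------

oracle_mirror <- function(i, n) {
  if (n == 1) return(0)
  while (i < 0 || i >= n) {
    if (i < 0) i <- -i
    if (i >= n) i <- 2 * n - 2 - i
  }
  i
}

oracle_kernel <- function(sigma) {
  r <- max(1, ceiling(3 * sigma))
  w <- exp(-((-r):r)^2 / (2 * sigma^2))
  w / sum(w)
}

# dense separable gaussian on a 2D value matrix vals[x+1, y+1]
oracle_gauss_2d <- function(vals, sigma) {
  w <- oracle_kernel(sigma)
  r <- (length(w) - 1) / 2
  nx <- nrow(vals); ny <- ncol(vals)
  tmp <- matrix(0, nx, ny)
  for (x in seq_len(nx)) for (y in seq_len(ny)) {
    s <- 0
    for (k in seq_along(w))
      s <- s + w[k] * vals[oracle_mirror(x - 1 + k - 1 - r, nx) + 1, y]
    tmp[x, y] <- s
  }
  out <- matrix(0, nx, ny)
  for (x in seq_len(nx)) for (y in seq_len(ny)) {
    s <- 0
    for (k in seq_along(w))
      s <- s + w[k] * tmp[x, oracle_mirror(y - 1 + k - 1 - r, ny) + 1]
    out[x, y] <- s
  }
  out
}

# image values as a [x, y] matrix (2D images)
img_matrix <- function(img) {
  sh <- img_shape(img)
  matrix(img_values(img), nrow = sh[1], ncol = sh[2], byrow = TRUE)
}

# --- independent brute-force op-matching oracle ------------------------------

# scores candidates with its own arithmetic over an explicit parent map;
# converters given as list(from, to, priority, order)
brute_force_match <- function(ops, arg_types, parents, converters = list()) {
  dist_to <- function(sub, sup) {
    d <- 0
    cur <- sub
    repeat {
      if (identical(cur, sup)) return(d)
      nxt <- parents[[cur]]
      if (is.null(nxt)) return(NA_integer_)
      cur <- nxt
      d <- d + 1
    }
  }
  best <- NULL
  for (op in ops) {
    if (length(op$types) != length(arg_types)) next
    pen <- 0; spec <- 0; ok <- TRUE
    for (i in seq_along(arg_types)) {
      dd <- dist_to(arg_types[[i]], op$types[[i]])
      if (!is.na(dd)) { spec <- spec + dd; next }
      conv_ok <- NULL
      for (cv in converters) {
        if (!is.na(dist_to(arg_types[[i]], cv$from)) &&
            !is.na(dist_to(cv$to, op$types[[i]]))) {
          if (is.null(conv_ok) || cv$priority > conv_ok$priority ||
              (cv$priority == conv_ok$priority && cv$order < conv_ok$order))
            conv_ok <- cv
        }
      }
      if (is.null(conv_ok)) { ok <- FALSE; break }
      pen <- pen + 1
      spec <- spec + dist_to(conv_ok$to, op$types[[i]])
    }
    if (!ok) next
    key <- list(pen = pen, spec = spec, pri = op$priority, id = op$id)
    better <- is.null(best) ||
      key$pen < best$pen ||
      (key$pen == best$pen && key$spec < best$spec) ||
      (key$pen == best$pen && key$spec == best$spec && key$pri > best$pri) ||
      (key$pen == best$pen && key$spec == best$spec && key$pri == best$pri &&
         key$id < best$id)
    if (better) best <- c(key, list(op = op))
  }
  best
}

# write a tiny mean-of-image command module
mean_module <- function() {
  module_info("meanimg",
              list(param_spec("image", "image"),
                   param_spec("value", "real", direction = "out")),
              function(ctx, inputs)
                list(value = run_op(ctx, "stats.mean", list(inputs$image))))
}

greet_script_path <- function() {
  system.file("extdata", "greet.ndo", package = "ndops")
}
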