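# op matching: specificity, penalties, tie rules, brute-force equivalence

test_that("math.add resolves by argument types like the documented examples", {
  ctx <- build_context()
  m1 <- resolve_op(ctx, "math.add", list("planar_image", "real"))
  expect_identical(m1$descriptor$id, "math.add.image-constant")
  m2 <- resolve_op(ctx, "math.add", list("planar_image", "planar_image"))
  expect_identical(m2$descriptor$id, "math.add.image-image")
  m3 <- resolve_op(ctx, "math.add", list("integer", "integer"))
  expect_identical(m3$descriptor$id, "math.add.number-number")
})

test_that("the most specific implementation wins for array images", {
  ctx <- build_context()
  m <- resolve_op(ctx, "math.sqrt", list("array_image"))
  expect_identical(m$descriptor$id, "math.sqrt.array")
  expect_identical(m$specificity, 0L)
  m2 <- resolve_op(ctx, "math.sqrt", list("planar_image"))
  expect_identical(m2$descriptor$id, "math.sqrt.image")
})

test_that("a zero-penalty match always beats converter-assisted candidates", {
  ctx <- build_context()
  m <- resolve_op(ctx, "math.add", list("array_image", "string"))
  expect_identical(m$descriptor$id, "math.add.image-constant")
  expect_identical(m$penalty, 1L)
  expect_identical(m$conversion_plan[[2]]$how, "convert")
  direct <- resolve_op(ctx, "math.add", list("array_image", "integer"))
  expect_identical(direct$penalty, 0L)
  expect_true(all(vapply(direct$conversion_plan, function(p)
    identical(p$how, "direct"), logical(1))))
})

test_that("unknown names and incompatible signatures fail with useful errors", {
  ctx <- build_context()
  expect_error(resolve_op(ctx, "nosuch.op", list("integer")), "unknown op")
  expect_error(resolve_op(ctx, "math.add", list("sample_type", "sample_type")),
               "no-match error.*near misses")
})

test_that("full-key ties resolve by id ascending with a logged warning", {
  ctx <- build_context(list())
  mk <- function(id) plugin_descriptor("op", id, 0, factory = local({
    i <- id
    function(ctx) op_descriptor(i, "tied.op", list(op_param("x", "number")),
                                "number", function(ctx, args) args[[1L]])
  }))
  for (d in list(mk("tied.b"), mk("tied.a"),
                 plugin_descriptor("op_service", "svc", 0,
                                   factory = ndops:::new_op_service)))
    register_plugin(ctx, d)
  m <- resolve_op(ctx, "tied.op", list("integer"))
  expect_identical(m$descriptor$id, "tied.a")
  expect_true(any(grepl("ambiguous", ctx$log)))
})

test_that("resolve_op equals brute-force scoring over generated registries", {
  # independent oracle: enumerate and score every candidate with its own
  # arithmetic over an explicit hierarchy, with and without converters
  parents <- list(sub_a = "base_a", base_a = "any", sub_b = "base_b",
                  base_b = "any", any = NULL)
  arg_pool <- c("sub_a", "base_a", "sub_b")
  param_pool <- c("sub_a", "base_a", "sub_b", "base_b", "any")
  set.seed(2024)
  for (trial in 1:120) {
    n_ops <- sample(1:8, 1)
    n_args <- sample(1:3, 1)
    use_conv <- trial %% 2 == 0
    ops <- lapply(seq_len(n_ops), function(i) list(
      id = paste0("gen.op", i),
      types = sample(param_pool, n_args, replace = TRUE),
      priority = sample(0:2, 1)))
    converters <- if (use_conv)
      list(list(id = "gen.conv-a2b", from = "base_a", to = "sub_b",
                priority = 1, order = 1))
    else list()
    args <- sample(arg_pool, n_args, replace = TRUE)

    expected <- brute_force_match(ops, args, parents, converters)

    ctx <- build_context(list())
    register_plugin(ctx, plugin_descriptor("op_service", "svc", 0,
                                           factory = ndops:::new_op_service))
    register_plugin(ctx, plugin_descriptor("convert_service", "csvc", 0,
                                           factory = ndops:::new_convert_service))
    for (ty in setdiff(names(parents), "any"))
      register_type_parent(ctx, ty, parents[[ty]])
    for (op in ops) {
      local({
        o <- op
        register_op(ctx, op_descriptor(
          o$id, "gen.target",
          lapply(seq_along(o$types), function(j) op_param(paste0("p", j),
                                                          o$types[[j]])),
          "any", function(ctx, a) NULL, priority = o$priority))
      })
    }
    for (cv in converters)
      register_converter(ctx, converter_descriptor(
        cv$id, cv$from, cv$to, priority = cv$priority,
        apply = function(ctx, v) v))

    if (is.null(expected)) {
      expect_error(resolve_op(ctx, "gen.target", as.list(args)),
                   "no-match error")
    } else {
      got <- suppressWarnings(resolve_op(ctx, "gen.target", as.list(args)))
      info <- paste("trial", trial, ":", paste(args, collapse = ","))
      expect_identical(got$descriptor$id, expected$id, info = info)
      expect_identical(got$penalty, as.integer(expected$pen), info = info)
      expect_identical(got$specificity, as.integer(expected$spec), info = info)
    }
  }
})

test_that("aliases resolve to the same descriptors as full names", {
  ctx <- build_context()
  expect_identical(resolve_op(ctx, "gauss", list("array_image", "real"))$descriptor$id,
                   resolve_op(ctx, "filter.gauss", list("array_image", "real"))$descriptor$id)
  expect_identical(resolve_op(ctx, "dog", list("array_image", "real", "real"))$descriptor$id,
                   "image.dog")
})
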