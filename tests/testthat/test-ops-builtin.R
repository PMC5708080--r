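# built-in ops: math semantics, gauss/dog, stats, map, eval, special ops

test_that("element-wise math follows the documented examples and saturates", {
  ctx <- build_context()
  g <- make_fixture("gradient", u8(ctx), c(2, 2))
  expect_identical(img_values(run_op(ctx, "math.add", list(g, 10))),
                   c(10, 11, 12, 13))
  hot <- make_fixture("constant", u8(ctx), c(2, 2), value = 250)
  expect_identical(img_values(run_op(ctx, "math.add", list(hot, 10))),
                   rep(255, 4))   # clamp at the uint8 bound
  two <- make_fixture("constant", u8(ctx), c(2, 2), value = 2)
  expect_identical(img_values(run_op(ctx, "math.add", list(two, 10))),
                   rep(12, 4))
  expect_identical(img_values(run_op(ctx, "math.add", list(g, g))),
                   c(0, 2, 4, 6))
  # string constant is parsed through the converter framework
  expect_identical(img_values(run_op(ctx, "math.add", list(g, "3"))),
                   c(3, 4, 5, 6))
  other <- make_fixture("gradient", u8(ctx), c(3, 2))
  expect_error(run_op(ctx, "math.add", list(g, other)), "shape error")
})

test_that("integer image division rounds half-to-even and rejects zero divisors", {
  ctx <- build_context()
  img <- create_image(u8(ctx), c(1, 4), "array")
  set_img_values(img, c(3, 5, 7, 9))
  out <- run_op(ctx, "math.div", list(img, 2))
  expect_identical(img_values(out), c(2, 2, 4, 4))   # 1.5->2 2.5->2 3.5->4 4.5->4
  zero <- create_image(u8(ctx), c(1, 4), "array")
  expect_error(run_op(ctx, "math.div", list(img, zero)),
               "division by zero sample at \\(0, 0\\)")
  # scalar division is real-valued
  expect_identical(run_op(ctx, "math.div", list(5, 2)), 2.5)
})

test_that("function kind never mutates inputs and all kinds agree", {
  ctx <- build_context()
  for (seed in 1:8) {
    a <- make_fixture("noise", u8(ctx), c(6, 5), seed = seed)
    b <- make_fixture("noise", u8(ctx), c(6, 5), seed = seed + 100)
    before_a <- img_values(a); before_b <- img_values(b)
    for (fam in c("math.add", "math.sub", "math.mul")) {
      fresh <- run_op(ctx, fam, list(a, b))
      expect_identical(img_values(a), before_a)   # purity
      expect_identical(img_values(b), before_b)
      pre <- create_image(u8(ctx), c(6, 5), "array")
      filled <- run_op(ctx, fam, list(a, b), out = pre)
      expect_identical(filled, pre)               # preallocated output filled
      expect_identical(img_values(pre), img_values(fresh))
      mut <- img_copy(a)
      got <- run_op(ctx, fam, list(mut, b), inplace = TRUE)
      expect_identical(got, mut)                  # input object overwritten
      expect_identical(img_values(mut), img_values(fresh))
    }
  }
})

test_that("gaussian blur preserves constants, matches the dense oracle, and sigma 0 copies", {
  ctx <- build_context()
  const <- make_fixture("constant", f64(ctx), c(7, 6), value = 7)
  blurred <- run_op(ctx, "filter.gauss", list(const, 2))
  expect_true(all(abs(img_values(blurred) - 7) <= 1e-9))

  imp <- make_fixture("impulse", f64(ctx), c(9, 11), at = c(4, 5))
  got <- img_matrix(run_op(ctx, "filter.gauss", list(imp, 1)))
  want <- oracle_gauss_2d(img_matrix(imp), 1)
  expect_lt(max(abs(got - want)), 1e-12)
  # near the center this equals the outer product of the 1D kernel
  w <- oracle_kernel(1)
  expect_lt(max(abs(got[2:8, 3:9] - outer(w, w))), 1e-12)

  noise <- make_fixture("noise", f64(ctx), c(8, 8), seed = 4)
  copy <- run_op(ctx, "filter.gauss", list(noise, 0))
  expect_identical(img_values(copy), img_values(noise))
  expect_false(identical(copy, noise))   # a fresh container
  expect_error(run_op(ctx, "filter.gauss", list(noise, -1)), "domain error")
})

test_that("difference of gaussians is exactly the chained sub(gauss, gauss)", {
  ctx <- build_context()
  img <- make_fixture("noise", f64(ctx), c(10, 9), seed = 11)
  d <- run_op(ctx, "image.dog", list(img, 2, 1))
  manual <- run_op(ctx, "math.sub",
                   list(run_op(ctx, "filter.gauss", list(img, 2)),
                        run_op(ctx, "filter.gauss", list(img, 1))))
  expect_identical(img_values(d), img_values(manual))
  expect_identical(img_values(run_op(ctx, "image.dog", list(img, 1.5, 1.5))),
                   rep(0, 90))
  imp <- make_fixture("impulse", f64(ctx), c(13, 13), at = c(6, 6))
  got <- img_matrix(run_op(ctx, "image.dog", list(imp, 2, 1)))
  want <- oracle_gauss_2d(img_matrix(imp), 2) - oracle_gauss_2d(img_matrix(imp), 1)
  expect_lt(max(abs(got - want)), 1e-12)
})

test_that("stats aggregate whole images and ROIs; mean decomposes as sum/size", {
  ctx <- build_context()
  g <- make_fixture("gradient", u8(ctx), c(2, 2))
  expect_identical(run_op(ctx, "stats.mean", list(g)), 1.5)
  noise <- make_fixture("noise", u8(ctx), c(9, 7), seed = 21)
  expect_identical(run_op(ctx, "stats.mean", list(noise)),
                   run_op(ctx, "stats.sum", list(noise)) /
                     run_op(ctx, "stats.size", list(noise)))
  expect_identical(run_op(ctx, "stats.size", list(noise)), 63)
  expect_identical(run_op(ctx, "stats.min", list(noise)),
                   min(img_values(noise)))
  expect_identical(run_op(ctx, "stats.max", list(noise)),
                   max(img_values(noise)))
  roi <- mask_roi(c(0, 0), c(0, 6))
  expect_identical(run_op(ctx, "stats.sum", list(noise, roi)),
                   sum(img_values(noise)[1:7]))
  expect_identical(run_op(ctx, "stats.size", list(noise, roi)), 7)
  empty <- mask_roi(c(0, 0), c(8, 6), function(co) rep(FALSE, nrow(co)))
  expect_error(run_op(ctx, "stats.sum", list(noise, empty)), "domain error")
})

test_that("map applies a unary special op per sample and preserves layout", {
  ctx <- build_context()
  img <- create_image(u8(ctx), c(2, 2), "array")
  set_img_values(img, c(0, 1, 4, 9))
  sq <- op_instance(ctx, "math.sqrt", primary_types = list("number"))
  expect_identical(img_values(run_op(ctx, "map", list(img, sq))),
                   c(0, 1, 2, 3))
  ident <- op_instance(ctx, "identity", primary_types = list("number"))
  noise <- make_fixture("noise", u8(ctx), c(6, 6), seed = 8, layout = "planar")
  mapped <- run_op(ctx, "map", list(noise, ident))
  expect_identical(img_values(mapped), img_values(noise))
  expect_identical(img_layout(mapped), "planar")
  # per-sample loop oracle
  twice <- op_instance(ctx, "math.mul", fixed = list(b = 2),
                       primary_types = list("number"))
  got <- img_values(run_op(ctx, "map", list(noise, twice)))
  want <- vapply(img_values(noise), function(x) min(2 * x, 255), numeric(1))
  expect_identical(got, want)
})

test_that("eval parses precedence, dispatches ops and reports positions", {
  ctx <- build_context()
  expect_identical(op_eval(ctx, "2+3*4"), 14)
  expect_identical(op_eval(ctx, "(2+3)*4"), 20)
  expect_identical(op_eval(ctx, "a/b", list(a = 5, b = 2)), 2.5)
  expect_identical(op_eval(ctx, "-3+10"), 7)
  expect_identical(op_eval(ctx, "2-3-4"), -5)            # left associative
  expect_identical(op_eval(ctx, '"x" + 1 + 2'), "x12")   # string concat
  img <- make_fixture("noise", f64(ctx), c(7, 7), seed = 31)
  viaeval <- op_eval(ctx, "sub(gauss(image,2),gauss(image,1))",
                     list(image = img))
  expect_identical(img_values(viaeval),
                   img_values(run_op(ctx, "image.dog", list(img, 2, 1))))
  plus <- op_eval(ctx, "image + 3", list(image = make_fixture("gradient",
                                                              u8(ctx), c(2, 2))))
  expect_identical(img_values(plus), c(3, 4, 5, 6))
  expect_error(op_eval(ctx, "2 +"), "parse error")
  expect_error(op_eval(ctx, "2 @ 3"), "position 3")
  expect_error(op_eval(ctx, "nope + 1"), "unbound identifier 'nope'")
})

test_that("special op instances skip matching and reproduce run_op results", {
  ctx <- build_context()
  gi <- op_instance(ctx, "filter.gauss", fixed = list(sigma = 2))
  base <- counter_of(ctx, "op_matches")
  imgs <- lapply(1:10, function(s) make_fixture("noise", f64(ctx), c(6, 6),
                                                seed = s))
  for (img in imgs) {
    expect_identical(img_values(gi(img)),
                     img_values(run_op(ctx, "filter.gauss", list(img, 2))))
  }
  # run_op re-matches each call; the instance itself never did
  expect_identical(counter_of(ctx, "op_matches") - base, 10L)
  only_instance <- op_instance(ctx, "filter.gauss", fixed = list(sigma = 1))
  base2 <- counter_of(ctx, "op_matches")
  for (img in imgs) invisible(only_instance(img))
  expect_identical(counter_of(ctx, "op_matches") - base2, 0L)

  addi <- op_instance(ctx, "math.add",
                      primary_types = list("array_image", "array_image"))
  a <- make_fixture("noise", u8(ctx), c(5, 5), seed = 1)
  b <- make_fixture("noise", u8(ctx), c(5, 5), seed = 2)
  expect_identical(img_values(addi(a, b)),
                   pmin(img_values(a) + img_values(b), 255))  # elementwise oracle
  expect_error(addi(a, 3), "type error")

  zero <- op_instance(ctx, "create.img",
                      fixed = list(t = u8(ctx), shape = c(2, 3)))
  i1 <- zero(); i2 <- zero()
  expect_false(identical(i1, i2))            # fresh container each call
  expect_identical(img_values(i1), rep(0, 6))
  expect_identical(img_values(i2), rep(0, 6))
})

test_that("memoization returns cached results without re-execution", {
  ctx <- build_context(memoize = TRUE)
  img <- make_fixture("noise", u8(ctx), c(8, 8), seed = 2)
  r1 <- run_op(ctx, "stats.sum", list(img))
  hits0 <- counter_of(ctx, "memo_hits")
  r2 <- run_op(ctx, "stats.sum", list(img))
  expect_identical(r1, r2)
  expect_identical(counter_of(ctx, "memo_hits") - hits0, 1L)
  # distinct inputs do not share cache entries
  other <- make_fixture("noise", u8(ctx), c(8, 8), seed = 3)
  expect_false(identical(run_op(ctx, "stats.sum", list(other)), NULL))
  expect_identical(counter_of(ctx, "memo_hits") - hits0, 1L)
})

test_that("built-in ops are layout transparent", {
  ctx <- build_context()
  for (seed in 1:5) {
    ref <- make_fixture("noise", u8(ctx), c(6, 5), seed = seed)
    layouts <- list(array = ref,
                    planar = img_copy(ref, "planar"),
                    cell = img_copy(ref, "cell",
                                    cell_opts = list(cell_shape = c(2, 2),
                                                     capacity = 2)))
    for (opname in c("math.sqrt", "filter.gauss")) {
      args <- if (opname == "filter.gauss") list(1.2) else list()
      res <- lapply(layouts, function(img)
        img_values(run_op(ctx, opname, c(list(img), args))))
      expect_identical(res$planar, res$array)
      expect_identical(res$cell, res$array)
    }
    expect_identical(run_op(ctx, "stats.mean", list(layouts$cell)),
                     run_op(ctx, "stats.mean", list(layouts$array)))
  }
})
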