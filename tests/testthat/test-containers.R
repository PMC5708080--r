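# image containers: layouts, access, iteration, cell cache, datasets, fixtures

test_that("new images are zero-filled and report their geometry", {
  ctx <- build_context()
  img <- create_image(u8(ctx), c(2, 2), "array")
  expect_identical(img_values(img), rep(0, 4))
  expect_identical(img_shape(img), c(2, 2))
  expect_identical(img_layout(img), "array")
})

test_that("oversized planes are rejected for arrays but fine as cells or functions", {
  ctx <- build_context()
  expect_error(create_image(u8(ctx), c(50000, 50000), "array"),
               "capacity error.*cell")
  big <- create_image(u8(ctx), c(50000, 50000), "cell",
                      cell_opts = list(cell_shape = c(1024, 1024), capacity = 1))
  expect_identical(img_shape(big), c(50000, 50000))
  virt <- create_image(u8(ctx), c("9223372036854775807"), "function")
  expect_identical(img_shape_chr(virt), "9223372036854775807")   # 2^63-1 exact
})

test_that("write-then-read roundtrips at a coordinate on every writable layout", {
  ctx <- build_context()
  for (layout in c("array", "planar", "cell")) {
    img <- create_image(u8(ctx), c(4, 4), layout,
                        cell_opts = list(cell_shape = c(2, 2), capacity = 2))
    img_set(img, c(1, 1), 7)
    expect_identical(img_get(img, c(1, 1)), 7)
    expect_identical(img_get(img, c(0, 0)), 0)
  }
  img <- create_image(u8(ctx), c(2, 2), "array")
  expect_error(img_get(img, c(5, 0)), "bounds in dimension 1")
  fi <- create_image(u8(ctx), c(2, 2), "function")
  expect_error(img_set(fi, c(0, 0), 1), "immutability")
})

test_that("a seeded random access script transcribes identically across layouts", {
  ctx <- build_context()
  mk <- function(layout) create_image(u8(ctx), c(6, 5, 3), layout,
    cell_opts = list(cell_shape = c(2, 2, 2), capacity = 3))
  imgs <- list(array = mk("array"), planar = mk("planar"), cell = mk("cell"))
  set.seed(77)
  script <- data.frame(x = sample(0:5, 200, TRUE), y = sample(0:4, 200, TRUE),
                       z = sample(0:2, 200, TRUE),
                       write = sample(c(TRUE, FALSE), 200, TRUE),
                       val = sample(0:255, 200, TRUE))
  transcripts <- lapply(imgs, function(img) {
    out <- numeric(0)
    for (i in seq_len(nrow(script))) {
      co <- c(script$x[i], script$y[i], script$z[i])
      if (script$write[i]) img_set(img, co, script$val[i])
      else out <- c(out, img_get(img, co))
    }
    out
  })
  expect_identical(transcripts$planar, transcripts$array)   # array = oracle
  expect_identical(transcripts$cell, transcripts$array)
  expect_identical(img_values(imgs$planar), img_values(imgs$array))
  expect_identical(img_values(imgs$cell), img_values(imgs$array))
})

test_that("iteration is row-major (last dimension fastest) and ROI-filtered", {
  ctx <- build_context()
  img <- make_fixture("gradient", u8(ctx), c(2, 3))
  it <- iterate_samples(img)
  expect_identical(nrow(it$coords), 6L)
  expect_identical(it$coords,
    matrix(c(0,0, 0,1, 0,2, 1,0, 1,1, 1,2), ncol = 2, byrow = TRUE))
  expect_identical(it$values, as.numeric(0:5))

  roi <- mask_roi(c(0, 0), c(0, 2))
  expect_identical(iterate_samples(img, roi)$values, as.numeric(0:2))

  # checkerboard predicate matches a brute-force filter of the full walk
  board <- make_fixture("gradient", u8(ctx), c(4, 4))
  pred <- function(co) (co[, 1] + co[, 2]) %% 2 == 0
  got <- iterate_samples(board, mask_roi(c(0, 0), c(3, 3), pred))
  full <- iterate_samples(board)
  keep <- pred(full$coords)
  expect_identical(sum(keep), 8L)
  expect_identical(got$coords, full$coords[keep, , drop = FALSE])
  expect_identical(got$values, full$values[keep])
})

test_that("cell images page through a bounded LRU cache with write-back", {
  ctx <- build_context()
  img <- create_cell_image(u8(ctx), c(24, 24), c(8, 8), 2)
  vals <- as.numeric((0:575) %% 256)
  set_img_values(img, vals)
  expect_identical(img_values(img), vals)
  st <- cell_stats(img)
  expect_lte(st$max_resident, 2L)          # residency bound under capacity
  expect_gt(st$saves, 0L)                  # dirty cells hit the backing store
  expect_gt(block_store_blocks(block_store_init(st$backing, u8(ctx), c(8, 8))), 0L)

  # capacity >= total cells: no eviction, backing never written
  lazy <- create_cell_image(u8(ctx), c(8, 8), c(4, 4), 4)
  set_img_values(lazy, as.numeric(1:64 %% 256))
  expect_identical(img_values(lazy), as.numeric(1:64 %% 256))
  expect_identical(cell_stats(lazy)$saves, 0L)
  expect_false(dir.exists(cell_stats(lazy)$backing))
})

test_that("interleaved writes across many cells match the array oracle", {
  ctx <- build_context()
  cellimg <- create_cell_image(u8(ctx), c(9, 9), c(3, 3), 2)   # 9 cells, cap 2
  arrimg <- create_image(u8(ctx), c(9, 9), "array")
  set.seed(5)
  for (i in 1:300) {
    co <- c(sample(0:8, 1), sample(0:8, 1))
    v <- sample(0:255, 1)
    img_set(cellimg, co, v)
    img_set(arrimg, co, v)
  }
  expect_identical(img_values(cellimg), img_values(arrimg))
  expect_lte(cell_stats(cellimg)$max_resident, 2L)
})

test_that("datasets validate axes and expose physical calibration", {
  ctx <- build_context()
  img <- create_image(u8(ctx), c(10, 20), "array")
  ds <- wrap_dataset(img, list(axis("X", "um", 0.5), axis("Y", "um", 0.5)),
                     name = "cal")
  expect_identical(physical_extent(ds), c(5, 10))
  expect_error(wrap_dataset(img, list(axis("X"), axis("Y"), axis("Z"))),
               "metadata error")
  rgb <- create_image(u8(ctx), c(4, 4, 3), "array")
  axs <- list(axis("X"), axis("Y"), axis("CHANNEL"))
  expect_silent(wrap_dataset(rgb, axs, channel_luts = c("red", "green", "blue")))
  expect_error(wrap_dataset(rgb, axs, channel_luts = c("red", "green")),
               "metadata error")
  expect_error(axis("X", scale = 0), "scale")
})

test_that("fixture patterns are exact and reproducible", {
  ctx <- build_context()
  expect_identical(sum(img_values(make_fixture("constant", u8(ctx), c(2, 2),
                                               value = 5))), 20)
  imp <- make_fixture("impulse", u8(ctx), c(3, 3), at = c(1, 1))
  expect_identical(sum(img_values(imp) != 0), 1L)
  expect_identical(img_get(imp, c(1, 1)), 1)
  n1 <- make_fixture("noise", u8(ctx), c(8, 8), seed = 42)
  n2 <- make_fixture("noise", u8(ctx), c(8, 8), seed = 42)
  expect_identical(img_values(n1), img_values(n2))
  expect_false(identical(img_values(n1),
                         img_values(make_fixture("noise", u8(ctx), c(8, 8),
                                                 seed = 43))))
  expect_error(make_fixture("constant", u8(ctx), c(2, 2), value = 300),
               "out of range")
})

test_that("gradient values are the row-major index mod (max+1)", {
  ctx <- build_context()
  g <- make_fixture("gradient", u8(ctx), c(16, 17))
  expect_identical(img_values(g), as.numeric((0:(16 * 17 - 1)) %% 256))
})

test_that("function-backed images stream blockwise without materializing", {
  ctx <- build_context()
  virt <- make_fixture("constant", u8(ctx), c(5000, 5000), layout = "function",
                       value = 3)
  s <- reduce_samples(virt, 0, function(acc, v, co) acc + sum(v),
                      chunk_samples = 1e6)
  expect_identical(as.numeric(s), 3 * 25e6)
  expect_lte(attr(s, "peak_chunk"), 1e6)
})
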