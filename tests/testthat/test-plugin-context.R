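# application container: registries, services, events, prefs, isolation

test_that("an empty context has zero plugins of every kind", {
  ctx <- build_context(list())
  expect_identical(plugins_of(ctx, "op"), list())
  expect_identical(plugins_of(ctx, "no-such-kind"), list())
})

test_that("the default context lists every descriptor in the shipped manifest", {
  lines <- readLines(system.file("plugins", "manifest.txt", package = "ndops"))
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  expected <- vapply(strsplit(lines, "\t"), function(f) trimws(f[[2]]),
                     character(1))
  ctx <- build_context()
  got <- unlist(lapply(names(ctx$plugins), function(k)
    vapply(plugins_of(ctx, k), function(d) d$id, character(1))))
  expect_setequal(got, expected)
  expect_length(got, length(expected))
})

test_that("contexts are fully isolated from each other", {
  ctx1 <- build_context()
  ctx2 <- build_context()
  register_object(ctx1, "payload")
  expect_length(objects_of(ctx1), 1L)
  expect_length(objects_of(ctx2), 0L)
  register_plugin(ctx2, plugin_descriptor("custom", "only-in-2", 1,
                                          factory = function() "x"))
  expect_length(plugins_of(ctx1, "custom"), 0L)
  expect_length(plugins_of(ctx2, "custom"), 1L)
})

test_that("duplicate descriptor ids are a configuration error naming the id", {
  ctx <- build_context(list())
  d <- plugin_descriptor("svc", "dup", 1, factory = function() "a")
  register_plugin(ctx, d)
  expect_error(register_plugin(ctx, d), "duplicate plugin id 'dup'")
})

test_that("services are per-context singletons and the top priority wins", {
  mk <- function(id, pri, tag) plugin_descriptor("widget", id, pri,
    factory = function() new.env())
  ctx <- build_context(list(
    plugin_descriptor("widget", "low", 0, factory = function() {
      e <- new.env(); e$tag <- "low"; e
    }),
    plugin_descriptor("widget", "high", 10, factory = function() {
      e <- new.env(); e$tag <- "high"; e
    })))
  s1 <- get_service(ctx, "widget")
  s2 <- get_service(ctx, "widget")
  expect_identical(s1, s2)             # same instance, same context
  expect_identical(s1$tag, "high")     # priority-10 descriptor won
  ctx2 <- build_context(list(
    plugin_descriptor("widget", "high", 10, factory = function() new.env())))
  expect_false(identical(get_service(ctx2, "widget"), s1))
  expect_error(get_service(ctx, "absent"), "no service of kind")
})

test_that("service instantiation cycles are detected", {
  ctx <- build_context(list(
    plugin_descriptor("a", "a", 0, factory = function(ctx) get_service(ctx, "b")),
    plugin_descriptor("b", "b", 0, factory = function(ctx) get_service(ctx, "a"))))
  expect_error(get_service(ctx, "a"), "cycle")
})

test_that("plugins_of sorts by priority descending then id ascending", {
  mk <- function(id, pri) plugin_descriptor("k", id, pri, factory = function() id)
  ctx <- build_context(list(mk("a", 1), mk("b", 3), mk("c", 2)))
  expect_identical(vapply(plugins_of(ctx, "k"), `[[`, character(1), "id"),
                   c("b", "c", "a"))
  # exhaustive tie rule check: equal priorities resolve by id ascending
  perms <- list(c("x", "y", "z"), c("z", "y", "x"), c("y", "x", "z"),
                c("y", "z", "x"), c("z", "x", "y"), c("x", "z", "y"))
  for (p in perms) {
    ctx <- build_context(lapply(p, mk, pri = 5))
    expect_identical(vapply(plugins_of(ctx, "k"), `[[`, character(1), "id"),
                     c("x", "y", "z"))
  }
})

test_that("plugins_of returns a sorted permutation of random registrations", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(1:8, 1)
    ids <- paste0("p", sample(100, n))
    pris <- sample(0:3, n, replace = TRUE)
    ctx <- build_context(Map(function(i, p)
      plugin_descriptor("k", i, p, factory = function() NULL), ids, pris))
    got <- plugins_of(ctx, "k")
    expect_setequal(vapply(got, `[[`, character(1), "id"), ids)
    key <- data.frame(pri = vapply(got, `[[`, numeric(1), "priority"),
                      id = vapply(got, `[[`, character(1), "id"))
    expect_identical(order(-key$pri, key$id), seq_len(n))
  }
})

test_that("events deliver hierarchically, most-derived first, surviving failures", {
  ctx <- build_context(list())
  expect_identical(publish_event(ctx, structure(list(), class = "lonely")), 0L)

  seen <- character(0)
  subscribe_event(ctx, "parent", function(e) seen <<- c(seen, "parent"))
  subscribe_event(ctx, "child", function(e) seen <<- c(seen, "child"))
  n <- publish_event(ctx, structure(list(), class = c("child", "parent")))
  expect_identical(n, 2L)
  expect_identical(seen, c("child", "parent"))   # most-derived first

  # parent-type subscriber alone still receives a child-type event
  ctx2 <- build_context(list())
  hits <- 0L
  subscribe_event(ctx2, "parent", function(e) hits <<- hits + 1L)
  expect_identical(publish_event(ctx2,
    structure(list(), class = c("child", "parent"))), 1L)
  expect_identical(hits, 1L)

  # a raising subscriber is logged; the other still runs; count is 2
  ctx3 <- build_context(list())
  ran <- 0L
  subscribe_event(ctx3, "ev", function(e) stop("boom"))
  subscribe_event(ctx3, "ev", function(e) ran <<- ran + 1L)
  expect_identical(publish_event(ctx3, structure(list(), class = "ev")), 2L)
  expect_identical(ran, 1L)
  expect_true(any(grepl("boom", ctx3$log)))
})

test_that("the preference store persists key=value pairs atomically", {
  pf <- tempfile()
  ctx <- build_context(list(), prefs_file = pf)
  expect_null(pref_get(ctx, "greet.age"))
  pref_set(ctx, "greet.age", "30")
  expect_identical(pref_get(ctx, "greet.age"), "30")
  expect_true(file.exists(pf))
  ctx2 <- build_context(list(), prefs_file = pf)   # reload from disk
  expect_identical(pref_get(ctx2, "greet.age"), "30")
})

test_that("manifest parsing counts entries, rejects malformed lines, unions with in-process", {
  mf <- tempfile()
  writeLines(c("# comment",
               "op\tx.one\t1\topdef_map",
               "op\tx.two\t0\topdef_map",
               "format\tx.fmt\t0\tfmtdef_pgm"), mf)
  idx <- load_plugin_index(mf)
  expect_length(idx, 3L)
  expect_identical(idx[[1]]$id, "x.one")

  bad <- tempfile()
  writeLines(c("op\tx.one\t1\topdef_map", "missing-fields-line"), bad)
  expect_error(load_plugin_index(bad), "line 2")

  # union with an in-process registration; duplicate kind+id rejected
  extra <- plugin_descriptor("op", "x.three", 0, factory = function() NULL)
  ctx <- build_context(c(idx, list(extra)))
  expect_length(plugins_of(ctx, "op"), 3L)
  expect_error(build_context(c(idx, idx[1])), "duplicate plugin id")
})
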