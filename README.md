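# ndops

**ndops** is a headless framework for N-dimensional scientific image
processing in R, built for pipelines that must outlive any single tool:
microscopy facilities batch-processing acquisitions on servers, method
developers who need one algorithm to run unchanged on 8-bit, 12-bit or
floating-point data of any dimensionality, and anyone whose images no longer
fit in memory.

Everything is a plugin in an application context:

* **Sample types** — 21 built-in pixel domains (`uint1` … `uint128`,
  signed, float, complex, ARGB, boolean, unbounded), extensible per
  context, with bit-level packing codecs.  12-bit detector data is stored
  without wasted bits: `ceil(12n/8)` bytes for *n* samples, a 33% gain in
  samples per byte over 16-bit storage.
* **Containers** — one access contract over four storage layouts: flat
  `array`, per-plane `planar`, disk-cached `cell` (an LRU block cache with
  write-back: a writeable virtual stack) and computed-on-demand `function`
  images with extents up to 2⁶³−1.  A 50,000 × 50,000 image sums exactly,
  one block resident at a time.
* **Op matching** — operations are requested by name and arguments, never
  by implementation.  Candidates are scored by
  (conversion penalty ↑, specificity ↑, priority ↓, id ↑): exact-type ops
  beat converter-assisted ones, and the most specific implementation wins.
  *Special op* instances freeze a match and apply it to varying inputs with
  zero further matching (nullary/unary/binary arities).
* **Chained ops** — the difference of Gaussians is literally its op tree,
  `dog(img, σ₁, σ₂) = sub(gauss(img, σ₁), gauss(img, σ₂))`, and
  `stats.mean = stats.sum / stats.size`; an `eval` op runs the same trees
  from expression strings.
* **Modules** — scripts declare typed inputs/outputs in `#@` headers;
  the framework harvests inputs (provided values, persisted last-used
  values, the active image, defaults) and routes outputs, identically from
  R or the command line.
* **I/O** — pluggable formats with magic-byte detection; Netpbm PGM/PPM
  codecs with chunked, chunk-size-independent reading and byte-stable
  canonical writing.

## A worked example

```r
library(ndops)
ctx <- build_context()

# a seeded 12-bit noise image, 64 x 48
img <- make_fixture("noise", get_sample_type(ctx, "uint12"), c(64, 48), seed = 7)

run_op(ctx, "stats.mean", list(img))      # 2031.201
run_op(ctx, "stats.max",  list(img))      # 4092

# band-pass it: difference of Gaussians, resolved and chained by the engine
d <- run_op(ctx, "image.dog", list(img, 2, 1))
range(img_values(d))                      # 0 805   (uint12 output, clamped)

# the same computation from an expression string
e <- op_eval(ctx, "sub(gauss(image,2),gauss(image,1))", list(image = img))
identical(img_values(e), img_values(d))   # TRUE

# 12-bit packing: bytes for the 3072 samples above
bytes_required(get_sample_type(ctx, "uint12"), 64 * 48)   # 4608
bytes_required(get_sample_type(ctx, "uint16"), 64 * 48)   # 6144
```

The mean is the op tree `sum/size`; the DoG output equals composing
`filter.gauss` and `math.sub` by hand, exactly.

From a shell, the same engine drives the CLI (`inst/bin/ndops`):

```sh
$ ndops op math.add 2 3
5
$ ndops run greet.ndo --name Alice --age 30
greeting = Hello Alice! You are 30
$ ndops run greet.ndo --name Bob          # age persisted from the last run
greeting = Hello Bob! You are 30
```

## Package layout

```
R/                  implementation (context, types, containers, converters,
                    ops engine, modules, I/O, CLI)
inst/plugins/       built-in plugin manifest
inst/bin/ndops      command-line launcher
inst/extdata/       example script module (greet.ndo)
tests/testthat/     unit, property and acceptance suites
vignettes/          design and methods vignette
scripts/            acceptance script
```
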