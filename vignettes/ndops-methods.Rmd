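---
title: "ndops: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ndops: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndops)
```

`ndops` is a headless, extensible framework for N-dimensional scientific
image processing.  Everything — sample types, storage layouts, converters,
operations, image formats, module pre-/post-processors, console flags — is a
plugin registered in an application context, and operations are selected by
a typed matching engine rather than called by implementation name.  This
vignette explains the model behind each subsystem, the tunable parameters,
the numerical choices, and what the synthetic fixtures do and do not
demonstrate.

## The application context

A context (`build_context()`) owns all mutable state: the plugin index, one
lazily created singleton service per service kind, an object index, a
synchronous event bus and a persistent key=value preference store.  Two
contexts share nothing, so independent pipelines can run side by side in one
R session.  Plugins are discovered from a tab-separated text manifest (one
descriptor per line: kind, id, priority, entry point) plus in-process
registration; within a kind, descriptors are totally ordered by priority
descending, then id ascending.  The id tie-break is this package's choice:
it makes registry listings, service selection and op matching reproducible
when priorities collide.  Service factories may request other services
during construction; cycles are detected and refused rather than deadlocked.

Event delivery walks the event object's `class()` vector, so a subscriber
to a base class receives derived events, most-derived subscribers first.
Delivery is synchronous and single-threaded by design; subscriber failures
are logged and do not stop delivery.

## Sample types and bit packing

A sample type records a pixel value domain: bit width, kind (unsigned or
signed integer, real, complex, ARGB composite, boolean, unbounded integer or
decimal) and bounds.  Twenty-one types ship built in, from `uint1` to
`uint128`, and new ones can be registered per context.  The 12-bit unsigned
type matters in practice because many scientific detectors produce 12-bit
samples: storing them in 16-bit words wastes a quarter of the space, whereas
the bit-level codec here packs samples back to back — `bytes_required(uint12,
n) = ceil(12n/8)`, a 33% gain in samples per byte over 16-bit storage.

Packing order is big-endian, MSB-first, with the final byte zero-padded.
This was an open choice (nothing forces one bit order) and is fixed and
documented because the cell-image block files on disk depend on it.  Signed
types are stored offset-binary (value − min).  Two numerical caveats are
deliberate: bounds of 64- and 128-bit integer types are represented as R
doubles, so they are exact only up to 2^53, and the packing codec refuses
values whose magnitude exceeds 2^53 rather than silently losing precision.
The shipped type list is an approximation of the full family of types such a
framework can carry; the registry is the extension point, not the list.

Real-to-integer casts round half to even (the IEEE default, matching R's
`round()`), and all casts saturate to the target bounds rather than wrap.
Saturation was chosen over wrapping or error because it composes: chained
arithmetic on uint8 images behaves like clamped pixel arithmetic, which is
what imaging users expect of 8-bit pipelines.

## Images, layouts, and the cell cache

An image is a grid of samples of one type with 0-based coordinates and a
fixed iteration order: row-major, last dimension fastest.  The order is
arbitrary but must be fixed, or op results on the same data would differ
between layouts.  Four layouts satisfy one access contract:

* `array` — one flat buffer; planes (the product of the first two extents)
  must stay below 2^31 samples, so a 50,000 × 50,000 plane is refused with
  advice to use the cell layout;
* `planar` — one buffer per 2D plane of the first two dimensions;
* `cell` — the image is partitioned into fixed-shape blocks; at most
  `capacity` blocks are memory-resident, the least-recently-used block is
  evicted, dirty blocks are bit-packed and written to a raw block store
  (`cell_<index>.blk` files plus a key=value sidecar), and reload on next
  access.  LRU was chosen over FIFO because interleaved write patterns
  (common in tiled processing) revisit recent blocks;
* `function` — samples are computed on demand from a coordinate function;
  read-only; extents may reach 2^63−1.  Extents beyond 2^53 are passed as
  decimal strings and reported exactly via `img_shape_chr()`, since R
  doubles cannot represent them.

Aggregate ops never materialize cell or function images: `reduce_samples()`
streams leading-dimension slabs of at most `chunk_samples` samples (default
4 × 10^6, chosen so a slab of coordinates plus values stays around 100 MB)
and folds over them.  The acceptance suite sums a constant-1
50,000 × 50,000 function-backed image this way: 2.5 × 10^9 samples, exact
result, one slab resident at a time, about 1–2 minutes in pure R.

Regions of interest are bounding boxes plus an optional coordinate
predicate; the predicate is only consulted inside the box, so the invariant
"false outside the bounding box" holds by construction.  Intervals are
closed and coordinates 0-based throughout.

## Converters

Converters let a value of one semantic type stand in where another is
expected: parsable strings as numbers, file paths as datasets, images as
datasets (wrapped by reference, so no pixels are copied and edits remain
visible).  Conversion is strictly single-hop.  Allowing chains would make
the cost of a match ill-defined (is one high-priority chain better than one
low-priority direct converter?) and could loop; every use site composes at
most one converter.  Among applicable converters the highest priority wins,
ties broken by registration order.  The generic string-to-number parser
outranks its integer/real refinements so that a `number`-typed target
converts with zero residual hierarchy distance.

## The op matching engine

An op request is a name plus argument types.  Every registered descriptor
whose name or alias matches and whose parameter count fits is scored:

1. **penalty** — the number of arguments that need a converter;
2. **specificity** — the summed hierarchy distance from each argument type
   to its parameter type (0 = exact);
3. **priority** — descending;
4. **descriptor id** — ascending, with a logged warning when reached.

Penalty dominates specificity, so an exact-type implementation always beats
a converter-assisted one; among direct matches the most specific
implementation wins (an `array_image`-specialized `math.sqrt` beats the
generic image variant for array inputs).  The numeric total order is this
package's design: "best fit" needs a concrete tie-break chain, and a
deterministic id-ascending final rule with a warning was preferred over a
hard ambiguity error so that scripted pipelines keep running.  The test
suite checks the engine against a brute-force enumeration oracle over
generated registries of up to 8 ops, 3 argument types, with and without
converters.

Ops are pure functions of their inputs.  The engine realizes three
execution kinds from one body: `function` (fresh output), `computer` (the
computed values are copied into a caller-preallocated output) and `inplace`
(copied into the first input).  In R, copying value vectors into the target
container is semantically faithful even though it is not a memory
optimization; the kinds exist for contract parity, and the test suite
asserts that all three produce identical values and that function-kind
execution leaves input digests untouched.  Purity is what makes optional
memoization safe: with `build_context(memoize = TRUE)`, function-kind
results are cached by op id plus an MD5 digest of the serialized arguments.

Special op instances (`op_instance()`) freeze a resolved match: non-primary
parameters are bound (and converted) once, and the returned callable applies
the implementation to varying primary inputs with zero further matching —
the instrumented match counter is the test for this.  Arity is the number
of unbound primary inputs: nullary (e.g. an image creator), unary (e.g.
Gaussian blur with σ fixed), binary (e.g. element-wise add).

## Built-in ops and numerical choices

* **Element-wise math** (`math.add/sub/mul/div/sqrt`) exists in
  image∘image, image∘constant and scalar variants.  Integer image results
  are clamped to the sample-type bounds; integer division divides in real
  arithmetic and then rounds half to even; a zero divisor sample in integer
  images is a domain error naming the coordinate (real images produce
  infinities, as IEEE arithmetic does).
* **`filter.gauss`** is a separable convolution with a sampled Gaussian
  kernel normalized to sum 1, radius `max(1, ceil(3σ))`, and mirror
  (reflective, non-edge-repeating) boundary.  Sampling (rather than
  integrating) the Gaussian, the 3σ radius and the mirror rule are standard
  but not forced; they are fixed here and tested against a dense direct
  convolution oracle.  σ = 0 returns an identical copy.
* **`image.dog`** is deliberately implemented as a tree of ops — two
  `filter.gauss` calls and one `math.sub` — not as its own kernel, so
  `dog ≡ sub(gauss, gauss)` holds exactly and `dog(img, σ, σ)` is exactly
  zero.  Likewise **`stats.mean`** is `math.div(stats.sum, stats.size)`.
* **`map`** applies a unary special op per sample, preserving layout.
* **`eval`** parses a small left-associative expression grammar (numbers,
  strings, identifiers, unary minus, `+ - * /`, calls) and dispatches calls
  and image operators through the matching engine, so
  `eval("sub(gauss(image,2),gauss(image,1))")` runs the same op tree as
  `image.dog`.

## Modules and harvesting

A module declares typed inputs and outputs; scripts declare them in `#@
<type> <name>` / `#@output <type> <name>` header lines.  Input harvesting is
a priority-ordered preprocessor chain: provided values (with automatic
conversion), persisted last-used values, the active image (only when exactly
one image input is unresolved — injecting into several would be ambiguous),
declared defaults, and finally a required-input check that fails naming the
parameter.  Outputs flow through the postprocessor chain; headless, strings
are echoed as `name = value` and images are registered in the object index,
becoming the next active image.  Persisted values are stored as
`<module id>.<parameter>` keys in the context preference file; only plain
values (numbers, strings, logicals) are persisted, since containers do not
round-trip through text.

One script language ships built in: the `eval` expression grammar extended
with string literals and `+` concatenation, one `name = expression`
statement per line.  Other languages are a plugin point (`script_language`
kind), not an attempt to embed interpreters.

## I/O

Locations are `file` paths or named in-memory `bytes:` buffers (the latter
mainly for tests; buffers are shared between handles, which is itself part
of the contract).  Formats are plugins detected by magic bytes first, then
suffix, ties by priority then name.  The shipped codecs are Netpbm PGM
(P2/P5) and PPM (P6): 2D grayscale up to 16 bits (big-endian) and 3-channel
8-bit color, read in row chunks of a configurable size so results are
independent of chunking.  Written files use a canonical header — single
newline separators, no comments — so rewriting a dataset is byte-identical.
Datasets read as shape `[width, height(, 3)]` with axes X, Y(, CHANNEL); the
codec maps Netpbm's row-major file order onto this package's iteration
order.

## The fixture generator

All test data is generated in code: `constant`, `gradient` (row-major index
modulo the type's range), `impulse`, and `noise` (seeded uniform integers
across the type's bounds, or uniform reals in [0, 1)).  These patterns
exercise exactness, symmetry and reproducibility, which is what the
framework's contracts are about — layout transparency, codec identity,
composition laws are all bitwise or 10^−12-level statements.  What they do
not emulate is real microscopy data: no optics, no Poisson photon
statistics, no spatial correlation, no metadata quirks of instrument
formats.  A green suite therefore certifies the framework's algebra, not
the scientific fitness of any particular filter parameter on real images.

## Problem sizes

The test and acceptance workloads were sized for exactness-first coverage
on a single CPU: fixture images of 5 × 5 to 31 × 17 for per-op laws (50 to
100 seeded fixtures per property), a 1024 × 1024 image through 64 × 64
cells at capacity 4 for the paging roundtrip, and one 50,000 × 50,000
function-backed constant image (2.5 × 10^9 samples) summed blockwise for
the virtual-scale demonstration.

## Known limitations

* No rendering, LUT application, color-space math or coordinate transforms;
  LUT names are metadata only.
* ROI algebra (union/intersection) and ROI serialization are out of scope;
  only mask ROIs with bounding boxes exist.
* The op library is a compact core (about forty registrations), an
  extension surface rather than a complete image-processing library.
* Integer bounds above 2^53 are inexact (R doubles); the packing codec
  refuses such values instead of corrupting them.
* `bytes:` buffers live in a process-wide registry keyed by name — unlike
  everything else they are not context-isolated, mirroring how shared
  memory behaves.
* Performance is pure-R vectorized; the cell cache and blockwise reductions
  bound memory, not CPU.
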