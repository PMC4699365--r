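---
title: "Mining high-content screens with property graphs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining high-content screens with property graphs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenminer)
```

## The data model

High-content screens produce a layered data set: a top layer of perturbed
entities (genes, strains, conditions) and a detail layer of quantitative
measurements, usually one record per segmented cell, with metadata such as
source images in between. `screenminer` represents this as a property
graph. Each node has a *kind* with one of three roles:

* **grouping** — the single top-level kind (e.g. `Gene`). Exactly one kind
  per graph has this role; in single-layer screens it can be flagged
  `self_descriptive` and then also carries the features.
* **descriptive** — the kind carrying the numeric features (e.g. `Cell`).
* **metadata** — everything else (e.g. `Image`); stored and traversable but
  not directly queryable as features.

A node's external identity is its kind plus the ordered values of its
ID-typed properties; the internal node id is a surrogate. Properties are
typed `TEXT`, `NUMBER`, `ID` or `URL`; only `NUMBER` properties enter the
per-kind *feature catalog* and are queryable. Labels are binary
annotations attached to grouping nodes (`1` attaches, `0` detaches; any
other value is an error). Every descriptive node must reach exactly one
grouping node through the edge set — `owning_group()` verifies this by
breadth-first search and treats zero or multiple reachable grouping nodes
as a graph-integrity failure.

The store is in-memory with JSON-lines file serialization
(`write_graph()` / `read_graph()`). A graph database would add
transactional and query-language machinery that is incidental to the
method; the store here is deliberately a plain, backend-agnostic
container with O(1) identity lookup and adjacency lists. Serialization is
ordered (kinds, then nodes sorted by ID values, then edges sorted by key)
so that equal graphs produce byte-identical files, and numbers are written
in round-trip decimal form so `NUMBER` properties survive a
serialize–deserialize cycle exactly.

## The import format

Screens are imported from CSV (RFC 4180, UTF-8, decimal point, no
thousands separators) with three header rows: property names, owning
object names, property types. Every row after the third is one
descriptive-object instance. Rows referring to an already-seen
(object, ID-tuple) pair *merge* into the existing node — this is the only
semantics under which the format works, since many cell rows share one
gene — and a merged row that would change an already-known property value
raises a conflict error. Empty `NUMBER` cells become missing values; they
are excluded from queries and never coerced to 0.

Two points the format itself leaves open, and how this package resolves
them:

* **Which object is grouping/descriptive.** The format does not mark
  roles, so they are operator-supplied; when unspecified, the object
  owning the first ID column is taken as grouping and the object owning
  the most NUMBER columns as descriptive.
* **Edges.** The importer creates one membership edge per descriptive row
  and referenced object: `MEMBER_OF` to the grouping node, `DERIVED_FROM`
  to each metadata node. This is a reconstruction of the natural semantics
  (cells belong to a gene's population, derive from an image); duplicate
  edges collapse (set semantics).

The label file has one header row; the leading columns whose names match
the grouping object's ID property names are the ID columns, all remaining
columns are labels. This header convention is itself a reconstruction and
is documented as such. Label rows referencing unknown grouping IDs warn
rather than fail, because screens routinely annotate genes absent from an
imported subset; warnings carry the unmatched tuples.

`validate_screen_file()` reports every problem (missing header rows,
ragged rows, unknown type tokens, unparseable numbers) with 1-based file
coordinates, and returns an empty report exactly when import would
succeed.

## Query semantics

A query is a complete, serializable state: level, axis features,
aggregation, filters, transforms, selection. Evaluation order is fixed
and is the contract the tests enforce:

1. descriptive-level filter clauses (numeric ranges on cell features,
   cell-label presence/absence);
2. aggregation to grouping level (if requested) — mean, median, count,
   min or max over the *surviving* descriptive members, skipping missing
   values; a grouping object with no surviving non-missing member yields
   no record;
3. grouping-level filter clauses. Label clauses test the grouping node's
   labels. Numeric-range clauses test the grouping node's own `NUMBER`
   property when it has one, otherwise the named descriptive feature
   aggregated with the query's aggregation method — the feature catalog at
   grouping level is the post-aggregation one;
4. axis transforms (`linear` or `log10`; `log10` fails loudly, listing the
   offending entities, if any value is non-positive);
5. the area selection, a closed axis-aligned rectangle (boundary points
   included), mirroring plot gating.

Filters combine conjunctively, so they are order-independent and adding a
clause can never grow the result. Records missing a requested axis value
are dropped pairwise-complete and the dropped count is reported in the
result's provenance. Records are sorted by entity ID values, which makes
every downstream export deterministic.

Two choices here were genuinely open. The original description never
states how gene-level values derive from cell-level data, so the
aggregation method is an explicit, visible field of the query state
(default `mean`) rather than a hidden convention. It also does not state
whether cell-level filters apply before or after gene-level aggregation;
this package fixes *before*, because a gene-level summary of "cells
passing the gate" is the quantity a screener gates on, and the sequential
oracle in the test suite pins that order down.

`drill_down()` is the inverse motion: a set of grouping IDs expands to all
member descriptive records, tagged with the owner's IDs, so a gene-level
selection becomes a cell-level point set in one call.

## Analytics defaults

The rendering layer of the original tool does not document its numeric
conventions, so the following are this package's own, all overridable:

* **Histogram**: equal-width bins over the data range; right-open bins
  except the last (right-closed), so all values are counted exactly once;
  default bin count by Sturges' rule `ceiling(log2(n)) + 1`; a constant
  sample gets one unit-width bin centred on the value. Multi-histograms
  share one set of edges computed over the pooled range, so series are
  directly comparable.
* **KDE**: Gaussian kernel, evaluated exactly (no binned/FFT
  approximation) on a 256-point grid spanning the data range extended by
  three bandwidths; automatic bandwidth is Silverman's rule of thumb
  `0.9 · min(sd, IQR/1.34) · n^(-1/5)`, which requires at least two
  distinct values — otherwise an explicit bandwidth must be supplied. The
  exact evaluation (chunked to bound memory) keeps the single-kernel
  closed form `1/(h√(2π))` and shift-equivariance true to near machine
  precision; `stats::density()` is used in the tests only as an
  independent cross-check at looser tolerance.
* **Regression**: ordinary least squares of `y ~ x` on the coordinates as
  displayed (i.e. after axis transforms), via R's QR-based `lm()`; the
  test oracle solves the normal equations directly, so implementation and
  oracle are distinct routes. `r² = 1 − SS_res/SS_tot`; a constant
  response (`SS_tot = 0`) is flagged degenerate with `r²` reported as 0,
  and constant `x` (a vertical line) is an error. Median ties are resolved
  as the average of the middle two values.
* **Comparison**: `compare_plots()` returns data (shared axis ranges as
  the union of per-set ranges, per-axis summaries, mean differences
  `b − a`), not rendered images, and deliberately performs no hypothesis
  test — comparison is a visual-analytics operation here, not an
  inferential one.

## Sharing and the service

A share token is the complete query state serialized to *canonical JSON*
(byte-sorted keys, no whitespace, round-trip decimal numbers), deflate
compressed, base64url encoded and version-prefixed (`v1.`). Tokens are
self-contained — no server-side state table — so a link replays anywhere
the instance file is available; a tampered token or a newer version fails
loudly rather than degrading. Canonical JSON uses shortest-of-15/16/17
significant-digit formatting, chosen so that equal states are
byte-identical and every double survives text round trips exactly
(standard JSON writers truncate at 15 significant digits, which does
not round-trip all doubles).

The HTTP service is a thin, read-only wrapper over the same functions:
`POST /query` takes the query-state JSON and returns the point set;
`/histogram`, `/kde`, `/regression`, `/compare` run the analytics on a
query result; `GET /share/{token}` replays a token. The route structure is
a reconstruction (the original's is undocumented). Malformed bodies are
HTTP 400, semantically invalid queries (unknown features or labels, failed
transforms) are 422. A pure in-process handler (`handle_request()`)
backs the socket server, which is how the test suite proves transport
transparency: over-HTTP numbers equal in-process numbers after the JSON
round trip, and the instance file hash is invariant under request traffic.
Instance building is CLI-only; no endpoint mutates the graph.

## The synthetic-screen generator

`generate_screen()` emulates a miniature knockout screen: genes × cells ×
independent Gaussian features, with images as metadata carrying
placeholder URLs. Hit genes receive a planted mean shift expressed in
within-gene standard-deviation units (default effect size 2 on the first
feature, baseline mean 10 and sd 2 per feature — values in the range of
z-scored or scaled morphology features); the label file marks them `1`.
An optional paired-feature mode plants `pair_y = a·pair_x + ε` at the cell
level to give regression a known slope. Generation is fully deterministic:
one seed drives hit selection and all draws, and files are byte-identical
across runs.

The reference configuration used by the acceptance checks is 50 genes ×
100 cells × 10 features with 5 hit genes — large enough that per-gene
standard errors make planted effects detectable, small enough that the
whole suite runs in minutes on one core. The generator emulates the
*structure* of a screen, not its pathologies: features are independent
Gaussians with no plate/batch effects, no correlated features, no
heavy-tailed or zero-inflated measurements, and equal cell counts per
gene. Passing tests therefore demonstrate correctness of the data path
(import → graph → query → analytics → export/serve), not robustness of
any statistical inference to real-data messiness.

## Degenerate inputs and numerical tolerances

* Empty data section: a valid graph with registered kinds and zero nodes.
* Corrupted files: the generator can inject exactly one defect
  (missing type row, unparseable number cell, ragged row, unknown label
  ID) at a recorded coordinate, and the importer/validator must report
  that coordinate — this is tested, not assumed.
* Aggregation equality against brute force is exact for count/min/max and
  within 1e-12 relative for mean; query-versus-oracle agreement is held to
  1e-9 relative; HTTP round trips to 1e-12 relative; share replay must be
  byte-identical.

## Limitations

* Single-writer, in-memory store: no concurrency or transactions, and
  instances must fit in RAM. Screens of ~10⁶ cells are the intended upper
  scale of the original system; this implementation targets the method,
  not that scale.
* Filters are conjunctive only; disjunction is deferred.
* Axis transforms are limited to linear/log10; selections to axis-aligned
  rectangles.
* URL properties are opaque link-outs; no image fetching or OMERO
  integration.
* The browser GUI of the original system is out of scope; the service
  returns plot-ready JSON and SVG instead.
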