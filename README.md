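# screenminer

Share and interactively mine image-derived feature data from
high-throughput / high-content microscopy screens (HT/HCS).

A finished screen typically holds millions of single-cell measurements —
hundreds of numeric features per cell, for cell populations perturbed one
gene (or condition) at a time. Accessing that data usually requires the
original analysis pipeline; `screenminer` instead turns a plain CSV export
of the screen into a queryable, shareable instance that both experimental
and computational biologists can work with.

## The model

A screen is stored as a **property graph**: nodes are the objects of
interest and carry tuples of typed properties plus categorical labels;
edges record how objects relate.

- **Grouping object** — the top-level entity (a gene, strain or condition).
- **Descriptive object** — the entity carrying the quantitative features
  (typically a cell); each belongs to exactly one grouping object.
- **Metadata objects** — e.g. images, holding URLs for click-through to raw
  data.
- **Labels** — binary annotations on grouping objects (e.g. `hit` for a
  phenotype), imported from a 0/1 matrix.

Screens are imported from a three-header-row CSV dialect (row 1 property
names, row 2 object names, row 3 property types `TEXT`/`NUMBER`/`ID`/`URL`;
every following row is one descriptive-object instance). On top of the
graph sits a multi-level query engine (grouping level with mean / median /
count / min / max roll-up, or descriptive level), conjunctive label and
numeric-range filters at either level, `log10` axis transforms, rectangular
area selection (gating) and one-call drill-down from a gene-level selection
to its member cells. Results feed an analytics toolkit — histograms and
multi-histograms, Gaussian KDE with Silverman's bandwidth
`0.9·min(sd, IQR/1.34)·n^(-1/5)`, OLS regression with
`r² = 1 − SS_res/SS_tot`, plot comparison — and export as CSV, SVG,
URL-safe share tokens encoding the complete query state, or JSON over a
read-only HTTP API.

## Worked example

```r
library(screenminer)

# A miniature synthetic screen with known ground truth: 4 genes x 6 cells,
# 3 Gaussian features, 1 planted hit gene.
dir   <- tempfile()
truth <- screen_truth(n_genes = 4, cells_per_gene = 6, n_features = 3,
                      n_hits = 1, seed = 7)
paths <- generate_screen(truth, dir)

graph <- read_screen(paths$data)
import_labels_file(graph, paths$labels)
graph
#> <property_graph>
#>   Gene (grouping): 4 nodes, 0 features, 1 labels
#>   Image (metadata): 4 nodes, 0 features, 0 labels
#>   Cell (descriptive): 24 nodes, 3 features, 0 labels
#>   edges: 48

# Gene-level scatter of mean f01 vs mean f02, restricted to hit genes:
st <- query_state("grouping", "f01", "f02",
                  filters = list(label_filter("Gene", "hit")))
run_query(graph, st)
#> <point_set> level=grouping records=1 dropped=0
#> # A tibble: 1 x 3
#>   geneID      x     y
#>   <chr>   <dbl> <dbl>
#> 1 gene002  12.4  10.3
```

The single record is the planted hit gene; `x` and `y` are its per-gene
mean feature values (the planted effect shifts `f01` by two within-gene
standard deviations, so ~12.4 against a baseline mean of 10).

```r
agg <- aggregate_feature(graph, "f01", "median")   # per-gene medians
cells <- drill_down(graph, "gene002", "f01", "f02") # its 6 member cells
fit <- fit_regression(run_query(graph, query_state("descriptive", "f01", "f02")))
fit
#> <regression_fit> y = -0.09417 x + 11.11  (r^2 = 0.0136, n = 24)

tok <- encode_share(st)          # URL-safe token, e.g. "v1.eJxtjUE..."
identical(state_to_json(decode_share(tok)), state_to_json(st))
#> [1] TRUE

export_csv(run_query(graph, st)) # RFC 4180, exact numeric round trip
#> geneID,f01,f02
#> gene002,12.415396697086585,10.31591385265806
```

Serve the instance as a read-only JSON API (routes: `GET /health`,
`GET /catalog/{kind}`, `POST /query|/histogram|/kde|/regression|/compare`,
`GET /share/{token}`):

```r
write_graph(graph, "instance.jsonl")
serve_screen("instance.jsonl", port = 8080)
```

or from a shell via the bundled CLI:

```sh
Rscript inst/cli/screenminer.R build --data screen.csv --labels labels.csv --out instance.jsonl
Rscript inst/cli/screenminer.R serve --instance instance.jsonl --port 8080
```

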