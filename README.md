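# dnawalkr

Two-dimensional walk visualization of DNA sequences, for anyone who needs an
annotation-free visual overview of sequence structure: a raw sequence is
mapped base by base into a polyline in the plane whose shape exposes
composition bias, repeats and local structure at a glance. The package
implements five *non-degenerate* transforms — every walk can be decoded back
into the exact sequence that produced it — together with the plumbing a
practical tool needs: FASTA input with capacity validation, compressed
columnar storage with range queries, extrema-preserving downsampling to a
fixed point budget, time-based cache expiry, publication-format plot export,
and a command-line interface.

## The transforms

For a sequence $s_1 s_2 \dots s_n$ over $\{A, C, G, T\}$:

| Method | Rule | Points |
|---|---|---|
| `gates` | cumulative sum of unit vectors T=(0,1), A=(0,−1), C=(−1,0), G=(1,0) | n + 1 |
| `yau` | cumulative sum of unit-circle vectors A=(½,−√3/2), G=(√3/2,−½), C=(√3/2,½), T=(½,√3/2) | n + 1 |
| `squiggle` | two bits per base (A=10, T=01, G=11, C=00), each bit a half-step Δx=0.5, Δy=±0.5 | 2n + 1 |
| `randic` | tablature: point *i* is (*i*, level(sᵢ)) with A=3, T=2, G=1, C=0 | n |
| `qi` | tablature over overlapping dinucleotides, y = alphabetical rank (AA=0 … TT=15) | max(n − 1, 0) |

Each transform is invertible: `decode_walk(transform(s)) == s` (the one
provable exception — a single-base `qi` walk has zero points — raises an
explicit error instead of guessing). Useful identities follow, e.g. the
`gates` endpoint is (#G − #C, #T − #A).

Batches are validated against capacity limits of 30 sequences, 4.5 Mb per
sequence and 135 Mb total (configurable via `walk_limits()`). Stored walks
live one Snappy-compressed Parquet table per `(file, sequence, method)` key;
zoom queries retrieve the closed x-interval through the Arrow engine and are
downsampled to a static budget of 1000 points per sequence by min-max
decimation, which always retains the global y-extrema. Cached walks expire
24 hours after submission.

## Worked example

```r
library(dnawalkr)

# three synthetic 2 kb sequences, GC fraction 0.6, fixed seed
synth_fasta("demo.fasta", n_sequences = 3, length = 2000, seed = 42,
            gc_fraction = 0.6)

# parse, validate, transform and store every (sequence, method) pair
entries <- cmd_transform("demo.fasta", c("squiggle", "gates"), "walks")
entries[c("seq_id", "method", "n_points")]
#> # A tibble: 6 × 3
#>   seq_id  method   n_points
#>   <chr>   <chr>       <int>
#> 1 synth_1 squiggle     4001
#> 2 synth_1 gates        2001
#> ...
```

Six walks are stored: the point counts follow the method laws above
(2·2000 + 1 squiggle points, 2000 + 1 gates points per sequence). A zoom
query retrieves the stored points in a closed x-interval, in walk order:

```r
store <- walk_store("walks")
query_region(store, "demo.fasta", "synth_1", "squiggle", xmin = 100, xmax = 110)
#>   idx     x    y
#> 1 200 100.0 -2.0
#> 2 201 100.5 -2.5
#> 3 202 101.0 -2.0
#> ...
```

At x = 100 the walk sits at y = −2: up to base 200 this sequence has two
more C than G (squiggle height is #G − #C). One-line summaries and plots:

```r
glance(squiggle_walk("GATTACA"))
#> # A tibble: 1 × 9
#>   method   seq_id source_file n_bases n_points x_min x_max y_min y_max
#> 1 squiggle seq    ""                7       15     0     7     0   1.5

spec <- plot_spec(store_keys(store)[c("source_file", "seq_id", "method")],
                  legend_mode = "by_sequence")
render_walks(store, spec, file = "walks.svg")  # also: .pdf, .png, .jpg
```

The same pipeline is scriptable from a shell via the `dnawalk` CLI
(installed under `inst/cli/`):

```sh
dnawalk synth --out demo.fasta --n 3 --length 2000 --gc 0.6 --seed 42
dnawalk transform --store walks --method squiggle --method gates demo.fasta
dnawalk query --store walks --file demo.fasta --seq synth_1 \
        --method squiggle --xmin 100 --xmax 110 --format csv
dnawalk plot --store walks --legend by-sequence --out walks.svg
dnawalk expire --store walks --ttl-hours 24
```

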