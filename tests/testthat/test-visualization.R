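make_demo_store <- function(env = parent.frame()) {
  store <- local_store(env)
  recs <- synth_sequences(3, c(40, 60, 80), seed = 14, source_file = "a.fa")
  recs$source_file <- c("a.fa", "a.fa", "b.fa")
  for (i in 1:3) put_walk(walk_transform(recs[i, ], "gates"), store)
  list(store = store, batch = recs)
}

test_that("autoscale_bounds applies a 2% margin to the union box", {
  b <- autoscale_bounds(tibble::tibble(x_min = 0, x_max = 4, y_min = 0, y_max = 3))
  expect_equal(unlist(b), c(x_min = -0.08, x_max = 4.08,
                            y_min = -0.06, y_max = 3.06))

  two <- tibble::tibble(x_min = c(0, 0), x_max = c(4, 100),
                        y_min = c(0, -1), y_max = c(3, 1))
  b2 <- autoscale_bounds(two, margin = 0)
  expect_equal(c(b2$x_min, b2$x_max), c(0, 100))
  expect_equal(c(b2$y_min, b2$y_max), c(-1, 3))

  # toggling the longer walk off recomputes bounds from the shorter alone
  b3 <- autoscale_bounds(two[1, ], margin = 0)
  expect_equal(b3$x_max, 4)

  expect_error(autoscale_bounds(two[0, ]), class = "dnawalkr_argument_error")
})

test_that("assign_colors groups by sequence or by file, deterministically", {
  batch <- tibble::tibble(
    seq_id = c("s1", "s2", "s3"),
    source_file = c("f1.fa", "f1.fa", "f1.fa")
  )
  by_seq <- assign_colors(batch, "by_sequence")
  expect_equal(by_seq$color_index, 0:2)
  by_file <- assign_colors(batch, "by_file")
  expect_equal(by_file$color_index, c(0L, 0L, 0L))
  expect_equal(unique(by_file$label), "f1.fa")

  four <- tibble::tibble(
    seq_id = c("a", "b", "c", "d"),
    source_file = c("f1.fa", "f1.fa", "f2.fa", "f2.fa")
  )
  expect_equal(assign_colors(four, "by_file")$color_index, c(0L, 0L, 1L, 1L))

  # toggling modes and back restores the original mapping
  expect_identical(assign_colors(batch, "by_sequence"), by_seq)
})

test_that("the palette is a fixed >= 30-color set that cycles", {
  p30 <- walk_palette(30)
  expect_equal(length(unique(p30)), 30L)
  p40 <- walk_palette(40)
  expect_equal(p40[37], p40[1]) # cycles past 36
  expect_identical(walk_palette(30), p30)
})

test_that("render draws one polyline per visible walk with grouped legend", {
  demo <- make_demo_store()
  keys <- store_keys(demo$store)[c("source_file", "seq_id", "method")]

  p <- render_walks(demo$store, plot_spec(keys, legend_mode = "by_file"))
  built <- ggplot2::ggplot_build(p)
  layer <- built$data[[1]]
  expect_equal(length(unique(layer$group)), 3L) # one polyline per walk
  expect_equal(length(unique(layer$colour)), 2L) # one color per file

  p2 <- render_walks(demo$store, plot_spec(keys, legend_mode = "by_sequence"))
  layer2 <- ggplot2::ggplot_build(p2)$data[[1]]
  expect_equal(length(unique(layer2$colour)), 3L)

  # default dynamic title: comma-joined source files; subtitle: method
  expect_equal(p$labels$title, "a.fa, b.fa")
  expect_equal(p$labels$subtitle, "gates")
})

test_that("vector export produces a parsable document; formats are enforced", {
  skip_if_not_installed("xml2")
  demo <- make_demo_store()
  keys <- store_keys(demo$store)[c("source_file", "seq_id", "method")]
  spec <- plot_spec(keys)

  svg_path <- withr::local_tempfile(fileext = ".svg")
  render_walks(demo$store, spec, file = svg_path)
  doc <- xml2::read_xml(svg_path)
  expect_equal(xml2::xml_name(doc), "svg")
  expect_gt(length(xml2::xml_find_all(doc, "//*[local-name()='path']")), 0L)

  pdf_path <- withr::local_tempfile(fileext = ".pdf")
  render_walks(demo$store, spec, file = pdf_path)
  expect_identical(readBin(pdf_path, "raw", 4), charToRaw("%PDF"))

  err <- expect_error(
    export_plot(ggplot2::ggplot(), "x.tiff"),
    class = "dnawalkr_argument_error"
  )
  for (f in c("svg", "pdf", "png", "jpg")) {
    expect_match(conditionMessage(err), f)
  }
})

test_that("zoom returns per-key downsampled points with reset semantics", {
  demo <- make_demo_store()
  keys <- store_keys(demo$store)[c("source_file", "seq_id", "method")]
  spec <- plot_spec(keys, point_budget = 1000)

  # zooming to the full extent reproduces the initial render's data
  full <- zoom_walks(demo$store, spec)
  for (i in seq_len(nrow(full))) {
    expect_identical(
      full$points[[i]],
      query_region(demo$store, keys$source_file[i], keys$seq_id[i],
                   keys$method[i], max_points = 1000)
    )
  }

  # a narrow region returns the stored points exactly (base-pair resolution)
  narrow <- zoom_walks(demo$store, spec, xmin = 2, xmax = 5)
  for (i in seq_len(nrow(narrow))) {
    w <- query_region(demo$store, keys$source_file[i], keys$seq_id[i],
                      keys$method[i], max_points = 1e6)
    expect_identical(narrow$points[[i]],
                     naive_region_filter(w, 2, 5),
                     label = sprintf("key %d", i))
  }

  # a disjoint region yields an empty table but keeps the key's row
  far <- zoom_walks(demo$store, spec, xmin = 1e6, xmax = 2e6)
  expect_equal(nrow(far), 3L)
  expect_true(all(vapply(far$points, nrow, integer(1)) == 0L))
})
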