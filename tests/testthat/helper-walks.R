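# Shared fixtures: all inputs are generated in code, under fixed seeds.

random_seq <- function(len) {
  if (len == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Independent oracle: count-based gates endpoint, (#G - #C, #T - #A).
gates_endpoint_by_counts <- function(s) {
  counts <- table(factor(strsplit(s, "")[[1]], levels = c("A", "C", "G", "T")))
  c(counts[["G"]] - counts[["C"]], counts[["T"]] - counts[["A"]])
}

# Independent oracle: naive in-memory closed-interval filter in walk order.
naive_region_filter <- function(points, xmin, xmax) {
  points[points$x >= xmin & points$x <= xmax, , drop = FALSE]
}

walk_fn <- function(method) {
  switch(method,
    squiggle = squiggle_walk, gates = gates_walk, yau = yau_walk,
    randic = randic_walk, qi = qi_walk
  )
}

local_store <- function(env = parent.frame()) {
  walk_store(withr::local_tempdir(.local_envir = env))
}
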