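#' Min-max (extrema-preserving) downsampling to a point budget
#'
#' If the input holds at most `max_points` rows it is returned unchanged.
#' Otherwise the rows are partitioned into `max_points / 2` equal contiguous
#' buckets (by position in the series, not by x — walks whose x revisits
#' values, like gates walks, still bucket correctly) and each bucket
#' contributes its minimum-y point (first occurrence) and its maximum-y point
#' (last occurrence); if those coincide, the bucket's last point is added
#' instead. Selected points are emitted in series order, so the output is a
#' subsequence of the input and redraws correctly as a polyline. The global
#' y-extrema are always retained, preserving the visual envelope.
#'
#' @param points A tibble of points ordered as stored (columns `idx`, `x`,
#'   `y`; only `y` is inspected).
#' @param max_points Even integer budget, at least 2.
#' @return A tibble with at most `max_points` of the input rows, in order;
#'   exactly `max_points` whenever every bucket holds at least 2 points.
#' @examples
#' pts <- tidy(squiggle_walk(strrep("ACGT", 300)))
#' nrow(downsample(pts, 100))
#' @export
downsample <- function(points, max_points) {
  if (length(max_points) != 1L || is.na(max_points) || max_points < 2 ||
      max_points %% 2 != 0) {
    stop_arg("`max_points` must be a single even integer >= 2")
  }
  n <- nrow(points)
  if (n <= max_points) return(points)
  k <- max_points / 2
  bucket <- floor(k * (seq_len(n) - 1) / n)
  y <- points$y
  pick <- unlist(lapply(split(seq_len(n), bucket), function(rows) {
    ys <- y[rows]
    i_min <- rows[which.max(ys == min(ys))]          # first occurrence of min
    i_max <- rows[max(which(ys == max(ys)))]         # last occurrence of max
    if (i_min == i_max) i_max <- rows[length(rows)]  # degenerate single point
    sort(unique(c(i_min, i_max)))
  }), use.names = FALSE)
  points[pick, , drop = FALSE]
}

#' Open (or create) a walk store
#'
#' A walk store is a directory holding one Parquet table per stored walk
#' (columns `idx`, `x`, `y`, Snappy-compressed) and a JSON manifest mapping
#' each key — `(source_file, seq_id, method)` — to its table's path, creation
#' time and point count. There is no resident server process: expiry runs
#' only when requested (see [expire_walks()]).
#'
#' @param path Directory for the store; created if absent.
#' @return A `walk_store` handle.
#' @export
walk_store <- function(path) {
  dir.create(file.path(path, "walks"), recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(path, "manifest.json")
  if (!file.exists(manifest_path)) write_manifest(path, empty_manifest())
  structure(list(path = path), class = "walk_store")
}

#' @export
print.walk_store <- function(x, ...) {
  m <- read_manifest(x$path)
  cat(sprintf("<walk_store> %s (%d stored walk%s)\n",
              x$path, nrow(m), if (nrow(m) == 1L) "" else "s"))
  invisible(x)
}

empty_manifest <- function() {
  tibble(source_file = character(), seq_id = character(),
         method = character(), path = character(),
         created_at = numeric(), n_points = integer())
}

read_manifest <- function(store_path) {
  p <- file.path(store_path, "manifest.json")
  if (!file.exists(p)) return(empty_manifest())
  entries <- jsonlite::fromJSON(p)$entries
  if (is.null(entries) || length(entries) == 0L) return(empty_manifest())
  as_tibble(entries) |>
    mutate(created_at = as.numeric(.data$created_at),
           n_points = as.integer(.data$n_points))
}

write_manifest <- function(store_path, manifest) {
  jsonlite::write_json(list(entries = manifest),
                       file.path(store_path, "manifest.json"),
                       dataframe = "rows", digits = NA)
  invisible(manifest)
}

key_slug <- function(source_file, seq_id, method) {
  raw <- paste(source_file, seq_id, method, sep = "__")
  gsub("[^A-Za-z0-9._-]", "_", raw)
}

manifest_match <- function(manifest, source_file, seq_id, method) {
  which(manifest$source_file == source_file &
          manifest$seq_id == seq_id &
          manifest$method == method)
}

#' Persist a walk in a store
#'
#' Writes the walk's points as a Snappy-compressed Parquet table and records
#' the key in the manifest. Re-putting an existing key overwrites it (the
#' cache-refresh contract), updating `created_at`.
#'
#' @param walk A `dna_walk`.
#' @param store A [walk_store()].
#' @param now Timestamp recorded as `created_at` (defaults to the current
#'   time); exposed so expiry can be tested against a simulated clock.
#' @return A one-row tibble describing the stored walk (`source_file`,
#'   `seq_id`, `method`, `path`, `created_at`, `n_points`).
#' @export
put_walk <- function(walk, store, now = Sys.time()) {
  stopifnot(inherits(store, "walk_store"), inherits(walk, "dna_walk"))
  manifest <- read_manifest(store$path)
  key <- list(source_file = attr(walk, "source_file"),
              seq_id = attr(walk, "seq_id"),
              method = attr(walk, "method"))
  hit <- manifest_match(manifest, key$source_file, key$seq_id, key$method)

  if (length(hit) > 0L) {
    rel <- manifest$path[hit[1L]]
  } else {
    # slug collisions between distinct keys are resolved with a numeric suffix
    slug <- key_slug(key$source_file, key$seq_id, key$method)
    rel <- file.path("walks", paste0(slug, ".parquet"))
    suffix <- 1L
    while (rel %in% manifest$path) {
      suffix <- suffix + 1L
      rel <- file.path("walks", paste0(slug, "-", suffix, ".parquet"))
    }
  }

  tbl <- tibble(idx = as.integer(walk$idx), x = as.numeric(walk$x),
                y = as.numeric(walk$y))
  arrow::write_parquet(tbl, file.path(store$path, rel), compression = "snappy")

  entry <- tibble(source_file = key$source_file, seq_id = key$seq_id,
                  method = key$method, path = rel,
                  created_at = as.numeric(now), n_points = nrow(tbl))
  manifest <- bind_rows(
    if (length(hit) > 0L) manifest[-hit, , drop = FALSE] else manifest,
    entry
  )
  write_manifest(store$path, manifest)
  entry
}

#' List the keys stored in a walk store
#'
#' @param store A [walk_store()].
#' @return The manifest as a tibble: one row per stored walk with its key,
#'   path, creation time (epoch seconds) and point count.
#' @export
store_keys <- function(store) {
  stopifnot(inherits(store, "walk_store"))
  read_manifest(store$path)
}

#' Query a stored walk for points in an x-range
#'
#' Retrieves exactly the stored points whose x falls in the closed interval
#' `[xmin, xmax]` (mirroring a SQL `BETWEEN` predicate), ordered by `idx` —
#' walk order, which is what a polyline redraw needs — and then downsampled
#' to `max_points` (see [downsample()]). The filter is executed by the Arrow
#' engine against the compressed Parquet table, the local analogue of
#' query-in-place retrieval. Results for a key never depend on what other
#' keys exist.
#'
#' @param store A [walk_store()].
#' @param source_file,seq_id,method The key of the stored walk.
#' @param xmin,xmax Closed query interval; `xmin <= xmax`. Defaults cover
#'   the full extent.
#' @param max_points Even downsampling budget, at least 2. Default 1000.
#' @return A tibble of points (`idx`, `x`, `y`) in walk order.
#' @export
query_region <- function(store, source_file, seq_id, method,
                         xmin = -Inf, xmax = Inf, max_points = 1000) {
  stopifnot(inherits(store, "walk_store"))
  if (length(xmin) != 1L || length(xmax) != 1L || is.na(xmin) || is.na(xmax) ||
      xmin > xmax) {
    stop_arg("invalid region: `xmin` must be <= `xmax`")
  }
  if (length(max_points) != 1L || is.na(max_points) || max_points < 2 ||
      max_points %% 2 != 0) {
    stop_arg("`max_points` must be a single even integer >= 2")
  }
  manifest <- read_manifest(store$path)
  hit <- manifest_match(manifest, source_file, seq_id, method)
  if (length(hit) == 0L) {
    stop_not_found(sprintf(
      "no stored walk for key (source_file='%s', seq_id='%s', method='%s')",
      source_file, seq_id, method
    ))
  }
  file <- file.path(store$path, manifest$path[hit[1L]])
  pts <- arrow::open_dataset(file) |>
    filter(.data$x >= xmin, .data$x <= xmax) |>
    collect() |>
    arrange(.data$idx)
  downsample(as_tibble(pts), max_points)
}

#' Remove stored walks older than a time-to-live
#'
#' Deletes every stored walk whose age `now - created_at` strictly exceeds
#' `ttl_hours` and returns the removed keys. An entry exactly at the
#' boundary is retained. Missing Parquet files are logged as messages, not
#' fatal.
#'
#' @param store A [walk_store()].
#' @param ttl_hours Time-to-live in hours; default 24.
#' @param now The current time (a `POSIXct` or epoch seconds); injectable for
#'   testing against a simulated clock.
#' @return A tibble of the removed keys (`source_file`, `seq_id`, `method`).
#' @export
expire_walks <- function(store, ttl_hours = 24, now = Sys.time()) {
  stopifnot(inherits(store, "walk_store"))
  manifest <- read_manifest(store$path)
  age_h <- (as.numeric(now) - manifest$created_at) / 3600
  drop <- which(age_h > ttl_hours)
  if (length(drop) == 0L) {
    return(tibble(source_file = character(), seq_id = character(),
                  method = character()))
  }
  removed <- manifest[drop, c("source_file", "seq_id", "method")]
  for (rel in manifest$path[drop]) {
    f <- file.path(store$path, rel)
    if (file.exists(f)) unlink(f) else inform(sprintf("missing walk file: %s", f))
  }
  write_manifest(store$path, manifest[-drop, , drop = FALSE])
  removed
}

#' Serialize query results
#'
#' @param points A tibble of points (`idx`, `x`, `y`).
#' @param seq_id,method Key fields echoed into JSON output.
#' @param format `"json"` (an object with `seq_id`, `method` and a `points`
#'   array of `[idx, x, y]` triples) or `"csv"` (header `idx,x,y`).
#' @return A single string.
#' @export
format_points <- function(points, seq_id, method, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    body <- sprintf("%d,%s,%s", as.integer(points$idx),
                    format(points$x, trim = TRUE, digits = 15),
                    format(points$y, trim = TRUE, digits = 15))
    return(paste(c("idx,x,y", body), collapse = "\n"))
  }
  triples <- unname(purrr::pmap(points[c("idx", "x", "y")], function(idx, x, y) {
    c(idx, x, y)
  }))
  jsonlite::toJSON(
    list(seq_id = seq_id, method = method, points = triples),
    auto_unbox = TRUE, digits = NA
  ) |> as.character()
}
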