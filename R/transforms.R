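# Fixed encoding tables. These are part of the on-disk format contract: a
# stored walk is only decodable because every run uses the same tables.
#
# Base order everywhere: A, C, G, T (alphabetical).
.bases <- c("A", "C", "G", "T")

# Gates: T up, A down, C left, G right, all unit length.
.gates_dx <- c(A = 0, C = -1, G = 1, T = 0)
.gates_dy <- c(A = -1, C = 0, G = 0, T = 1)

# Yau: unit vectors with positive x-components so the walk never doubles back;
# purines (A, G) below the x-axis, pyrimidines (C, T) above.
.yau_dx <- c(A = 1 / 2, C = sqrt(3) / 2, G = sqrt(3) / 2, T = 1 / 2)
.yau_dy <- c(A = -sqrt(3) / 2, C = 1 / 2, G = -1 / 2, T = sqrt(3) / 2)

# Squiggle: two-bit code per base, one up/down half-step per bit.
# Complementary bases are bit complements: A=10/T=01, G=11/C=00.
.squiggle_bits <- list(A = c(1, 0), C = c(0, 0), G = c(1, 1), T = c(0, 1))

# Randic tablature y-levels.
.randic_level <- c(A = 3, C = 0, G = 1, T = 2)

#' The five walk methods
#'
#' @return The method registry: a character vector of the five supported
#'   transform names.
#' @examples
#' walk_methods()
#' @export
walk_methods <- function() {
  c("squiggle", "gates", "yau", "randic", "qi")
}

# Map a residue string to integer codes 1..4 (A,C,G,T). Errors on anything
# else; unreachable after normalize_residues() but kept as a guard.
base_codes <- function(residues) {
  if (nchar(residues) == 0L) return(integer(0))
  codes <- match(as.integer(charToRaw(residues)),
                 as.integer(charToRaw("ACGT")))
  if (anyNA(codes)) {
    i <- which(is.na(codes))[1L]
    stop_arg(sprintf("non-ACGT residue '%s' at position %d",
                     substr(residues, i, i), i))
  }
  codes
}

new_dna_walk <- function(x, y, method, seq_id, source_file, n_bases) {
  pts <- tibble(idx = seq_along(x) - 1L, x = as.numeric(x), y = as.numeric(y))
  structure(pts,
            class = c("dna_walk", class(pts)),
            method = method, seq_id = seq_id,
            source_file = source_file, n_bases = as.integer(n_bases))
}

#' @export
print.dna_walk <- function(x, ...) {
  cat(sprintf("<dna_walk> method=%s seq_id=%s source_file=%s n_bases=%d n_points=%d\n",
              attr(x, "method"), attr(x, "seq_id"), attr(x, "source_file"),
              attr(x, "n_bases"), nrow(x)))
  NextMethod()
}

#' Gates walk
#'
#' Cumulative walk from the origin using the four cardinal unit vectors:
#' T = (0, +1), A = (0, -1), C = (-1, 0), G = (+1, 0). A sequence of `n`
#' bases yields `n + 1` points, and the endpoint is
#' (#G - #C, #T - #A). The x-coordinate may revisit values.
#'
#' @param residues A string over `{A, C, G, T}`.
#' @param seq_id,source_file Provenance carried on the walk.
#' @return A `dna_walk` tibble with columns `idx`, `x`, `y`.
#' @examples
#' gates_walk("ATGC")
#' @export
gates_walk <- function(residues, seq_id = "seq", source_file = "") {
  codes <- base_codes(residues)
  new_dna_walk(
    x = c(0, cumsum(.gates_dx[codes])),
    y = c(0, cumsum(.gates_dy[codes])),
    method = "gates", seq_id = seq_id, source_file = source_file,
    n_bases = length(codes)
  )
}

#' Yau walk
#'
#' Cumulative walk from the origin using unit vectors on the unit circle:
#' A = (1/2, -sqrt(3)/2), G = (sqrt(3)/2, -1/2), C = (sqrt(3)/2, 1/2),
#' T = (1/2, sqrt(3)/2). Purines point below the x-axis and pyrimidines
#' above; every x-step is positive, so x is strictly increasing and the walk
#' never self-overlaps. `n` bases yield `n + 1` points.
#'
#' @inheritParams gates_walk
#' @return A `dna_walk` tibble.
#' @examples
#' yau_walk("AT") # endpoint (1, 0): the A and T y-components cancel
#' @export
yau_walk <- function(residues, seq_id = "seq", source_file = "") {
  codes <- base_codes(residues)
  new_dna_walk(
    x = c(0, cumsum(.yau_dx[codes])),
    y = c(0, cumsum(.yau_dy[codes])),
    method = "yau", seq_id = seq_id, source_file = source_file,
    n_bases = length(codes)
  )
}

#' Squiggle walk
#'
#' Each base is encoded as two bits (A = 10, T = 01, G = 11, C = 00) and each
#' bit as a half-step of dx = 0.5 with dy = +0.5 for a 1 and dy = -0.5 for a
#' 0. `n` bases yield `2n + 1` points; A and T return y to an integer after
#' each base while G climbs and C falls.
#'
#' @inheritParams gates_walk
#' @return A `dna_walk` tibble.
#' @examples
#' squiggle_walk("A") # (0,0), (0.5, 0.5), (1, 0)
#' @export
squiggle_walk <- function(residues, seq_id = "seq", source_file = "") {
  codes <- base_codes(residues)
  n <- length(codes)
  bit1 <- c(1, 0, 1, 0)[codes]
  bit2 <- c(0, 0, 1, 1)[codes]
  bits <- as.vector(rbind(bit1, bit2))
  dy <- ifelse(bits == 1, 0.5, -0.5)
  new_dna_walk(
    x = 0.5 * (0:(2 * n)),
    y = c(0, cumsum(dy)),
    method = "squiggle", seq_id = seq_id, source_file = source_file,
    n_bases = n
  )
}

#' Randic tablature walk
#'
#' Tablature plot: point `i` (0-based) is `(i, level(base_i))` with fixed
#' levels A = 3, T = 2, G = 1, C = 0. `n` bases yield `n` points.
#'
#' @inheritParams gates_walk
#' @return A `dna_walk` tibble.
#' @examples
#' randic_walk("AT") # (0, 3), (1, 2)
#' @export
randic_walk <- function(residues, seq_id = "seq", source_file = "") {
  codes <- base_codes(residues)
  n <- length(codes)
  new_dna_walk(
    x = if (n > 0L) 0:(n - 1L) else numeric(0),
    y = .randic_level[codes],
    method = "randic", seq_id = seq_id, source_file = source_file,
    n_bases = n
  )
}

#' Qi dinucleotide tablature walk
#'
#' Tablature over overlapping dinucleotides: point `i` (0-based) is
#' `(i, rank(residues[i..i+1]))` where rank is the alphabetical index of the
#' dinucleotide over `{A, C, G, T}^2` (AA = 0, AC = 1, ..., TT = 15). `n`
#' bases yield `max(n - 1, 0)` points. Consecutive points overlap in one
#' base, which is what makes the walk decodable for `n >= 2`; a single-base
#' sequence produces no points and is the one input no walk can represent.
#'
#' @inheritParams gates_walk
#' @return A `dna_walk` tibble.
#' @examples
#' qi_walk("ATG") # (0, 3), (1, 14): AT has rank 3, TG rank 14
#' @export
qi_walk <- function(residues, seq_id = "seq", source_file = "") {
  codes <- base_codes(residues)
  n <- length(codes)
  if (n >= 2L) {
    y <- (codes[-n] - 1L) * 4L + (codes[-1L] - 1L)
    x <- 0:(n - 2L)
  } else {
    y <- numeric(0)
    x <- numeric(0)
  }
  new_dna_walk(x = x, y = y, method = "qi", seq_id = seq_id,
               source_file = source_file, n_bases = n)
}

#' Transform a sequence record into a walk
#'
#' Dispatches to the method-specific transform and stamps the walk with the
#' record's provenance (`seq_id`, `source_file`, `n_bases`).
#'
#' @param record A one-row tibble with columns `seq_id`, `residues`,
#'   `source_file` (as produced by [parse_fasta()]).
#' @param method One of [walk_methods()].
#' @return A `dna_walk` tibble.
#' @examples
#' rec <- parse_fasta(">s1\nACGT\n")[1, ]
#' walk_transform(rec, "gates")
#' @export
walk_transform <- function(record, method) {
  if (length(method) != 1L || !method %in% walk_methods()) {
    stop_arg(sprintf(
      "unknown method '%s'; valid methods are: %s",
      paste(method, collapse = ", "), paste(walk_methods(), collapse = ", ")
    ))
  }
  if (nrow(record) != 1L) stop_arg("`record` must be a single record (one row)")
  fn <- switch(method,
    squiggle = squiggle_walk, gates = gates_walk, yau = yau_walk,
    randic = randic_walk, qi = qi_walk
  )
  fn(record$residues, seq_id = record$seq_id, source_file = record$source_file)
}

#' Expected point count of a walk
#'
#' The deterministic point-count law per method: squiggle `2n + 1`; gates and
#' yau `n + 1`; randic `n`; qi `max(n - 1, 0)`.
#'
#' @param method One of [walk_methods()].
#' @param n_bases Sequence length in bases.
#' @return Integer point count.
#' @export
walk_point_count <- function(method, n_bases) {
  n <- as.integer(n_bases)
  switch(method,
    squiggle = 2L * n + 1L,
    gates = n + 1L,
    yau = n + 1L,
    randic = n,
    qi = max(n - 1L, 0L),
    stop_arg(sprintf("unknown method '%s'; valid methods are: %s",
                     method, paste(walk_methods(), collapse = ", ")))
  )
}

#' One-row summary of a walk
#'
#' @param x A `dna_walk`.
#' @param ... Unused.
#' @return A one-row tibble with the walk's method, provenance, point count
#'   and coordinate extents.
#' @export
glance.dna_walk <- function(x, ...) {
  tibble(
    method = attr(x, "method"),
    seq_id = attr(x, "seq_id"),
    source_file = attr(x, "source_file"),
    n_bases = attr(x, "n_bases"),
    n_points = nrow(x),
    x_min = if (nrow(x)) min(x$x) else NA_real_,
    x_max = if (nrow(x)) max(x$x) else NA_real_,
    y_min = if (nrow(x)) min(x$y) else NA_real_,
    y_max = if (nrow(x)) max(x$y) else NA_real_
  )
}

#' Walk points with provenance columns
#'
#' @param x A `dna_walk`.
#' @param ... Unused.
#' @return The walk's points as a plain tibble with `source_file`, `seq_id`
#'   and `method` columns prepended.
#' @export
tidy.dna_walk <- function(x, ...) {
  pts <- as_tibble(unclass(x)[c("idx", "x", "y")])
  tibble(
    source_file = attr(x, "source_file"),
    seq_id = attr(x, "seq_id"),
    method = attr(x, "method")
  )[rep(1L, nrow(pts)), ] |>
    dplyr::bind_cols(pts)
}

#' Summarise an object
#'
#' Generic for one-row summaries; see [glance.dna_walk()].
#'
#' @param x An object.
#' @param ... Passed to methods.
#' @return A one-row tibble.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Tidy an object into a tibble
#'
#' Generic for flat tabular views; see [tidy.dna_walk()].
#'
#' @param x An object.
#' @param ... Passed to methods.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")
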