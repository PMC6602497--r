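#' Decode a walk back into its DNA sequence
#'
#' Every supported transform is non-degenerate: the originating sequence can
#' be recovered exactly from the walk's points. Cumulative walks (gates, yau,
#' squiggle) are decoded from their step vectors — yau steps are matched to
#' the nearest candidate vector within a tolerance of 1e-6 — and tablature
#' walks (randic, qi) from their y-levels. For qi, consecutive dinucleotides
#' must overlap in one base; any inconsistency, or any step or level matching
#' no base, raises a corrupt-walk error naming the first bad point.
#'
#' The single exception is a qi walk of one base: it has zero points, so the
#' base is unrecoverable, and decoding raises a corrupt-walk error.
#'
#' @param walk A `dna_walk`, or a tibble of points with columns `x`, `y`
#'   plus a `method` supplied via attribute or argument.
#' @param method Override for the walk's method attribute.
#' @return The residue string over `{A, C, G, T}` such that re-transforming
#'   it reproduces `walk` exactly.
#' @examples
#' decode_walk(gates_walk("ACGT"))
#' decode_walk(squiggle_walk("GATTACA"))
#' @export
decode_walk <- function(walk, method = attr(walk, "method")) {
  if (is.null(method) || !method %in% walk_methods()) {
    stop_arg(sprintf("unknown method '%s'; valid methods are: %s",
                     method %||% "<missing>",
                     paste(walk_methods(), collapse = ", ")))
  }
  switch(method,
    gates = decode_steps(walk, .gates_dx, .gates_dy, tol = 1e-9),
    yau = decode_steps(walk, .yau_dx, .yau_dy, tol = 1e-6),
    squiggle = decode_squiggle(walk),
    randic = decode_randic(walk),
    qi = decode_qi(walk)
  )
}

codes_to_string <- function(codes) {
  if (length(codes) == 0L) return("")
  rawToChar(charToRaw("ACGT")[codes])
}

# Cumulative walks: match each step vector to the nearest of the four base
# vectors; reject anything farther than `tol` in either component.
decode_steps <- function(walk, dx_tab, dy_tab, tol) {
  n_pts <- nrow(walk)
  if (n_pts == 0L) stop_corrupt("cumulative walk has no points (expected at least the origin)")
  if (n_pts == 1L) return("")
  dx <- diff(walk$x)
  dy <- diff(walk$y)
  d2 <- vapply(seq_along(dx_tab), function(k) {
    (dx - dx_tab[k])^2 + (dy - dy_tab[k])^2
  }, numeric(length(dx)))
  d2 <- matrix(d2, ncol = length(dx_tab))
  codes <- max.col(-d2, ties.method = "first")
  best <- d2[cbind(seq_along(codes), codes)]
  bad <- which(best > tol^2 * 2)
  if (length(bad) > 0L) {
    stop_corrupt(sprintf(
      "step into point idx=%d matches no base vector", as.integer(bad[1L])
    ), point = bad[1L])
  }
  codes_to_string(codes)
}

decode_squiggle <- function(walk) {
  n_pts <- nrow(walk)
  if (n_pts == 0L) stop_corrupt("squiggle walk has no points (expected at least the origin)")
  if (n_pts %% 2L == 0L) {
    stop_corrupt(sprintf("squiggle walk has %d points; expected an odd count (2n + 1)", n_pts))
  }
  if (n_pts == 1L) return("")
  dx <- diff(walk$x)
  dy <- diff(walk$y)
  ok <- abs(dx - 0.5) < 1e-9 & abs(abs(dy) - 0.5) < 1e-9
  if (!all(ok)) {
    stop_corrupt(sprintf(
      "step into point idx=%d is not a half-unit squiggle step",
      which(!ok)[1L]
    ), point = which(!ok)[1L])
  }
  bits <- as.integer(dy > 0)
  two_bit <- bits[c(TRUE, FALSE)] * 2L + bits[c(FALSE, TRUE)]
  # 00=C, 01=T, 10=A, 11=G
  codes <- c(2L, 4L, 1L, 3L)[two_bit + 1L]
  codes_to_string(codes)
}

decode_randic <- function(walk) {
  if (nrow(walk) == 0L) return("")
  codes <- match(walk$y, .randic_level)
  if (anyNA(codes)) {
    i <- which(is.na(codes))[1L]
    stop_corrupt(sprintf(
      "point idx=%d has y=%s, matching no nucleotide level",
      as.integer(walk$idx[i]), format(walk$y[i])
    ), point = i)
  }
  codes_to_string(codes)
}

decode_qi <- function(walk) {
  n_pts <- nrow(walk)
  if (n_pts == 0L) {
    n_bases <- attr(walk, "n_bases")
    if (!is.null(n_bases) && n_bases == 1L) {
      stop_corrupt(paste0(
        "qi walk of a single base has no points; ",
        "the base cannot be recovered"
      ))
    }
    return("")
  }
  y <- walk$y
  if (any(y != round(y) | y < 0 | y > 15)) {
    i <- which(y != round(y) | y < 0 | y > 15)[1L]
    stop_corrupt(sprintf(
      "point idx=%d has y=%s, matching no dinucleotide rank (0..15)",
      as.integer(walk$idx[i]), format(y[i])
    ), point = i)
  }
  first <- y %/% 4 + 1L
  second <- y %% 4 + 1L
  if (n_pts > 1L) {
    mismatch <- which(second[-n_pts] != first[-1L])
    if (length(mismatch) > 0L) {
      i <- mismatch[1L]
      stop_corrupt(sprintf(
        "dinucleotides at idx=%d and idx=%d do not overlap",
        as.integer(walk$idx[i]), as.integer(walk$idx[i + 1L])
      ), point = i)
    }
  }
  codes_to_string(c(first[1L], second))
}
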