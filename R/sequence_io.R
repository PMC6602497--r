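#' Capacity limits for a sequence batch
#'
#' A batch submitted for visualization is capped at `max_sequences` records,
#' each at most `max_length_bases` bases, with at most `max_total_bases` in
#' total. The defaults (30 sequences of up to 4.5 Mb, 135 Mb overall) are the
#' capacities the transform-and-store pipeline is sized for; all three can be
#' overridden.
#'
#' @param max_sequences Maximum number of records in a batch.
#' @param max_length_bases Maximum length of any single record, in bases.
#' @param max_total_bases Maximum summed length of all records, in bases.
#' @return A `walk_limits` list with the three components.
#' @examples
#' walk_limits()
#' walk_limits(max_sequences = 5)
#' @export
walk_limits <- function(max_sequences = 30,
                        max_length_bases = 4.5e6,
                        max_total_bases = 135e6) {
  if (max_sequences < 1 || max_length_bases < 1 || max_total_bases < 1) {
    stop_arg("all limits must be strictly positive")
  }
  if (max_total_bases < max_length_bases) {
    stop_arg("`max_total_bases` must be >= `max_length_bases`")
  }
  structure(
    list(
      max_sequences = as.numeric(max_sequences),
      max_length_bases = as.numeric(max_length_bases),
      max_total_bases = as.numeric(max_total_bases)
    ),
    class = "walk_limits"
  )
}

#' Normalize raw residues to the DNA alphabet
#'
#' Folds lowercase to uppercase and RNA `U` to `T`. Any character then outside
#' `{A, C, G, T}` is handled according to `policy`: `"error"` (the default)
#' aborts, reporting the first offending 1-based position and character;
#' `"strip"` silently removes all such characters. The operation is idempotent
#' under both policies.
#'
#' @param raw A character vector of residue strings.
#' @param policy `"error"` or `"strip"`.
#' @return A character vector over the alphabet `{A, C, G, T}`.
#' @examples
#' normalize_residues("acgu")
#' normalize_residues("ACNGT", policy = "strip")
#' @export
normalize_residues <- function(raw, policy = c("error", "strip")) {
  policy <- match.arg(policy)
  out <- chartr("u", "T", toupper(raw))
  out <- chartr("U", "T", out)
  bad <- regexpr("[^ACGT]", out)
  if (any(bad > 0L)) {
    if (policy == "error") {
      i <- which(bad > 0L)[1L]
      pos <- as.integer(bad[i])
      ch <- substr(out[i], pos, pos)
      stop_parse(sprintf(
        "non-ACGT residue '%s' at position %d%s (use policy = \"strip\" to drop ambiguous bases)",
        ch, pos, if (length(raw) > 1L) sprintf(" of sequence %d", i) else ""
      ), position = pos, character = ch)
    }
    out <- gsub("[^ACGT]", "", out)
  }
  out
}

#' Parse FASTA-formatted text into sequence records
#'
#' Accepts standard multi-record FASTA: `>`-prefixed headers followed by
#' sequence lines of arbitrary wrapping. Blank lines are ignored; LF and CRLF
#' line endings are both accepted. The record id is the first
#' whitespace-delimited token after `>`; the remainder of the header becomes
#' the description. Residues are passed through [normalize_residues()].
#'
#' @param text FASTA text (a single string, or a character vector of lines).
#' @param source_file Label recorded as the provenance of every record.
#' @param policy Ambiguous-residue policy, see [normalize_residues()].
#' @return A tibble with one row per record and columns `seq_id`,
#'   `description`, `residues`, `source_file`, `length`.
#' @examples
#' parse_fasta(">s1 demo\nACGT\nTT\n", source_file = "demo.fasta")
#' @export
parse_fasta <- function(text, source_file = "input.fasta",
                        policy = c("error", "strip")) {
  policy <- match.arg(policy)
  if (length(text) == 0L || all(!nzchar(text))) {
    stop_parse("empty FASTA input")
  }
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1L]] else text
  lines <- sub("\r$", "", lines)

  is_header <- startsWith(lines, ">")
  is_blank <- !nzchar(trimws(lines))
  first_content <- which(!is_blank)
  if (length(first_content) == 0L) stop_parse("empty FASTA input")
  if (!is_header[first_content[1L]]) {
    stop_parse(sprintf(
      "sequence data before any '>' header at line %d", first_content[1L]
    ), line = first_content[1L])
  }

  rec <- cumsum(is_header)
  keep <- !is_header & !is_blank
  seqs <- vapply(
    split(lines[keep], factor(rec[keep], levels = seq_len(sum(is_header)))),
    paste0, character(1), collapse = ""
  )
  header_lines <- which(is_header)
  empty <- which(!nzchar(seqs))
  if (length(empty) > 0L) {
    stop_parse(sprintf(
      "header at line %d has no sequence lines", header_lines[empty[1L]]
    ), line = header_lines[empty[1L]])
  }

  headers <- sub("^>", "", lines[header_lines])
  seq_id <- sub("\\s.*$", "", headers)
  description <- trimws(sub("^\\S*\\s?", "", headers))
  if (any(!nzchar(seq_id))) {
    bad <- which(!nzchar(seq_id))[1L]
    stop_parse(sprintf("empty sequence id at line %d", header_lines[bad]),
               line = header_lines[bad])
  }
  if (anyDuplicated(seq_id)) {
    dup <- seq_id[duplicated(seq_id)][1L]
    stop_parse(sprintf("duplicate sequence id '%s' in '%s'", dup, source_file))
  }

  residues <- normalize_residues(unname(seqs), policy = policy)
  tibble(
    seq_id = seq_id,
    description = description,
    residues = residues,
    source_file = source_file,
    length = nchar(residues)
  )
}

#' Read one or more FASTA files
#'
#' @param paths Paths to FASTA files; each file's basename becomes the
#'   `source_file` label of its records.
#' @param policy Ambiguous-residue policy, see [normalize_residues()].
#' @return A tibble of records from all files, in file order.
#' @export
read_fasta <- function(paths, policy = c("error", "strip")) {
  policy <- match.arg(policy)
  purrr::map(paths, function(p) {
    parse_fasta(readLines(p, warn = FALSE), source_file = basename(p),
                policy = policy)
  }) |>
    bind_rows()
}

#' Write sequence records to a FASTA file
#'
#' Headers are `>seq_id description`; sequence lines are wrapped at 60
#' columns.
#'
#' @param records A tibble with columns `seq_id`, `residues` and optionally
#'   `description`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  desc <- if ("description" %in% names(records)) records$description else ""
  header <- paste0(">", records$seq_id,
                   ifelse(nzchar(desc), paste0(" ", desc), ""))
  body <- purrr::map(records$residues, function(s) {
    n <- nchar(s)
    if (n == 0L) return(character(0))
    starts <- seq(1L, n, by = 60L)
    substring(s, starts, pmin(starts + 59L, n))
  })
  lines <- unlist(purrr::map2(header, body, c), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Validate a batch of sequence records against capacity limits
#'
#' Checks the batch-level invariants: at most `max_sequences` records, no
#' record longer than `max_length_bases`, total length at most
#' `max_total_bases`, and unique `(seq_id, source_file)` pairs. A batch that
#' already satisfies the invariants passes through unchanged (record order is
#' preserved).
#'
#' @param records A tibble of records as returned by [parse_fasta()].
#' @param limits A [walk_limits()] object.
#' @return The validated batch as a `sequence_batch` tibble.
#' @examples
#' batch <- parse_fasta(">a\nACGT\n>b\nTTGA\n")
#' validate_batch(batch)
#' @export
validate_batch <- function(records, limits = walk_limits()) {
  stopifnot(inherits(limits, "walk_limits"))
  required <- c("seq_id", "residues", "source_file", "length")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop_arg(paste0("records are missing column(s): ",
                    paste(missing_cols, collapse = ", ")))
  }
  n_rec <- nrow(records)
  if (n_rec > limits$max_sequences) {
    stop_limit(sprintf(
      "batch has %d sequences; the limit is %d",
      n_rec, as.integer(limits$max_sequences)
    ), count = n_rec, limit = limits$max_sequences)
  }
  over <- which(records$length > limits$max_length_bases)
  if (length(over) > 0L) {
    i <- over[1L]
    stop_limit(sprintf(
      "sequence '%s' (%s) is %d bases; the per-sequence limit is %s",
      records$seq_id[i], records$source_file[i], records$length[i],
      format(limits$max_length_bases, big.mark = ",", scientific = FALSE)
    ), seq_id = records$seq_id[i])
  }
  total <- sum(as.numeric(records$length))
  if (total > limits$max_total_bases) {
    stop_limit(sprintf(
      "batch totals %s bases; the total limit is %s",
      format(total, big.mark = ",", scientific = FALSE),
      format(limits$max_total_bases, big.mark = ",", scientific = FALSE)
    ), total = total, limit = limits$max_total_bases)
  }
  key <- paste(records$seq_id, records$source_file, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    stop_limit(sprintf(
      "duplicate (seq_id, source_file) pair: ('%s', '%s')",
      records$seq_id[i], records$source_file[i]
    ))
  }
  if (any(records$length != nchar(records$residues))) {
    stop_arg("`length` column disagrees with `residues`")
  }
  structure(as_tibble(records),
            class = c("sequence_batch", class(as_tibble(records))))
}
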