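#' Construct a table of sequence records
#'
#' The package represents reads and reference sequences as a tibble with one
#' row per record: `id` (label), `seq` (nucleotide string over A/C/G/T/N,
#' uppercased on ingest), `qual` (list column of integer Phred scores, or
#' `NULL` entries when qualities are absent) and `sample` (optional sample
#' label, `NA` when unassigned). All downstream stages consume and return
#' this shape.
#'
#' @param id Character vector of record identifiers.
#' @param seq Character vector of nucleotide sequences. Lowercase letters are
#'   uppercased; characters outside `A,C,G,T,N` are rejected.
#' @param qual Optional list of integer vectors of Phred scores, one per
#'   record, each the same length as its sequence. `NULL` means no qualities.
#' @param sample Optional character vector of sample labels (recycled).
#'
#' @return A tibble with columns `id`, `seq`, `qual`, `sample`.
#' @examples
#' seq_tbl(c("a", "b"), c("acgt", "GGNN"))
#' @export
seq_tbl <- function(id, seq, qual = NULL, sample = NA_character_) {
  seq <- normalize_seq(seq)
  n <- length(seq)
  if (length(id) != n) {
    stop("`id` and `seq` must have the same length", call. = FALSE)
  }
  if (is.null(qual)) {
    qual <- rep(list(NULL), n)
  }
  if (!is.list(qual) || length(qual) != n) {
    stop("`qual` must be NULL or a list with one entry per record", call. = FALSE)
  }
  ok <- purrr::map2_lgl(qual, seq, function(q, s) {
    is.null(q) || (is.numeric(q) && length(q) == nchar(s) && all(q >= 0))
  })
  if (!all(ok)) {
    stop(
      "quality vectors must be non-negative and match sequence length (records: ",
      paste(utils::head(id[!ok], 5), collapse = ", "), ")",
      call. = FALSE
    )
  }
  qual <- purrr::map(qual, function(q) if (is.null(q)) NULL else as.integer(q))
  tibble::tibble(
    id = as.character(id),
    seq = seq,
    qual = qual,
    sample = rep_len(as.character(sample), n)
  )
}

#' @keywords internal
normalize_seq <- function(seq) {
  seq <- toupper(as.character(seq))
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    offender <- seq[bad][1]
    ch <- regmatches(offender, regexpr("[^ACGTN]", offender))
    stop(
      "sequence contains characters outside the A/C/G/T/N alphabet ",
      "(first offending character: '", ch, "')",
      call. = FALSE
    )
  }
  seq
}

#' Read a FASTA file into a record table
#'
#' Multi-line sequences are concatenated and record order is preserved.
#' Malformed input (a sequence line before any header, or a header with an
#' empty sequence) raises an error naming the offending line.
#'
#' @param path Path to a FASTA file.
#' @return A record tibble (see [seq_tbl()]); `qual` entries are all `NULL`.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "AC", "GT"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- trimws(lines[keep])
  if (length(lines) == 0) {
    return(seq_tbl(character(), character()))
  }
  is_header <- startsWith(lines, ">")
  if (!is_header[1]) {
    stop("FASTA parse error at line ", lineno[1],
      ": sequence data before any '>' header",
      call. = FALSE
    )
  }
  rec <- cumsum(is_header)
  ids <- sub("^>", "", lines[is_header])
  seqs <- vapply(
    split(lines[!is_header], rec[!is_header]),
    paste0,
    character(1),
    collapse = ""
  )
  # records with no sequence lines are absent from `seqs`
  missing <- setdiff(as.character(seq_along(ids)), names(seqs))
  if (length(missing) > 0) {
    bad <- as.integer(missing[1])
    stop("FASTA parse error at line ", lineno[is_header][bad],
      ": record '", ids[bad], "' has an empty sequence",
      call. = FALSE
    )
  }
  seq_tbl(ids, unname(seqs[as.character(seq_along(ids))]))
}

#' Read a four-line FASTQ file into a record table
#'
#' @param path Path to a FASTQ file (4 lines per record).
#' @param phred_offset ASCII offset used to decode qualities; 33 for modern
#'   Illumina (default), 64 for legacy encodings.
#' @return A record tibble with decoded integer Phred scores in `qual`.
#' @examples
#' f <- tempfile(fileext = ".fastq")
#' writeLines(c("@a", "AC", "+", "II"), f)
#' read_fastq(f)
#' @export
read_fastq <- function(path, phred_offset = 33) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(lines)), 0))]
  if (length(lines) == 0) {
    return(seq_tbl(character(), character()))
  }
  if (length(lines) %% 4 != 0) {
    stop("FASTQ parse error: ", length(lines),
      " lines is not a multiple of 4 (truncated record at end of file?)",
      call. = FALSE
    )
  }
  idx <- seq(1, length(lines), by = 4)
  heads <- lines[idx]
  bad_head <- !startsWith(heads, "@")
  if (any(bad_head)) {
    at <- idx[bad_head][1]
    stop("FASTQ parse error at line ", at, ": expected '@' header", call. = FALSE)
  }
  seqs <- lines[idx + 1]
  quals <- lines[idx + 3]
  len_bad <- nchar(seqs) != nchar(quals)
  if (any(len_bad)) {
    at <- idx[len_bad][1]
    stop("FASTQ parse error at line ", at + 3,
      ": quality string length (", nchar(quals[len_bad][1]),
      ") differs from sequence length (", nchar(seqs[len_bad][1]), ")",
      call. = FALSE
    )
  }
  ids <- sub("^@", "", heads)
  qual <- purrr::map(quals, function(q) utf8ToInt(q) - phred_offset)
  neg <- purrr::map_lgl(qual, function(q) length(q) > 0 && min(q) < 0)
  if (any(neg)) {
    stop(
      "negative Phred score after decoding record '", ids[neg][1],
      "' with offset ", phred_offset,
      "; the file may use a different quality encoding (try phred_offset = 33)",
      call. = FALSE
    )
  }
  seq_tbl(ids, seqs, qual)
}

#' Write records to FASTA
#'
#' Sequences are wrapped at `width` columns; ids are written verbatim after
#' `>`. Round-trips through [read_fasta()] preserve `id` and `seq`.
#'
#' @param records A record tibble.
#' @param path Output path.
#' @param width Line width for sequence wrapping (default 80).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 80) {
  stopifnot(is.data.frame(records))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$seq[i]
    starts <- seq(1, max(nchar(s), 1), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Write records to four-line FASTQ
#'
#' Records lacking qualities are written with a uniform placeholder score
#' (`default_qual`), with a warning.
#'
#' @param records A record tibble.
#' @param path Output path.
#' @param phred_offset ASCII offset for quality encoding (default 33).
#' @param default_qual Phred score used for records without qualities.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path, phred_offset = 33, default_qual = 40L) {
  stopifnot(is.data.frame(records))
  no_qual <- purrr::map_lgl(records$qual, is.null)
  if (any(no_qual)) {
    warning(sum(no_qual), " record(s) lack qualities; writing Phred ",
      default_qual, " placeholders",
      call. = FALSE
    )
  }
  lines <- purrr::pmap(
    list(records$id, records$seq, records$qual),
    function(id, seq, q) {
      if (is.null(q)) q <- rep(default_qual, nchar(seq))
      c(paste0("@", id), seq, "+", intToUtf8(q + phred_offset))
    }
  )
  writeLines(unlist(lines), path)
  invisible(path)
}
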