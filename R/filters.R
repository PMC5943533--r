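#' Quality-filter reads by Phred score
#'
#' Keeps reads whose mean (default) or minimum Phred score is at or above
#' `threshold`; the boundary is kept (a read at exactly the threshold
#' survives). Records without qualities — e.g. Sanger clone-library FASTA —
#' bypass the filter with a message rather than an error, so clone data flow
#' through the same downstream stages.
#'
#' @param records Record tibble (see [seq_tbl()]).
#' @param threshold Phred threshold (default 25).
#' @param stat `"mean"` (default) or `"min"` summary of per-base scores.
#' @return A list of class `mcp_quality_filter`: `$kept` (record tibble),
#'   `$n_discarded`, `$n_input`.
#' @export
quality_filter <- function(records, threshold = 25, stat = c("mean", "min")) {
  stat <- match.arg(stat)
  f <- if (stat == "mean") mean else min
  no_qual <- purrr::map_lgl(records$qual, is.null)
  if (any(no_qual)) {
    message(
      sum(no_qual),
      " record(s) have no quality scores and bypass the quality filter"
    )
  }
  score <- purrr::map_dbl(records$qual, function(q) {
    if (is.null(q) || length(q) == 0) Inf else f(q)
  })
  keep <- score >= threshold
  structure(
    list(
      kept = records[keep, , drop = FALSE],
      n_discarded = sum(!keep),
      n_input = nrow(records)
    ),
    class = "mcp_quality_filter"
  )
}

#' @export
print.mcp_quality_filter <- function(x, ...) {
  cat(
    "Quality filter:", nrow(x$kept), "of", x$n_input, "reads kept (",
    x$n_discarded, "discarded )\n"
  )
  invisible(x)
}

#' Translate nucleotide sequences with the standard genetic code
#'
#' Vectorised. The trailing partial codon is ignored; codons containing `N`
#' translate to `X`; stop codons are rendered `*`.
#'
#' @param seq Character vector over `A,C,G,T,N`.
#' @param frame_offset 0, 1 or 2 bases skipped before the first codon.
#' @return Character vector of amino-acid strings.
#' @examples
#' translate_dna(c("ATGGCC", "ATGTAA")) # "MA" "M*"
#' @export
translate_dna <- function(seq, frame_offset = 0) {
  stopifnot(frame_offset %in% 0:2)
  seq <- normalize_seq(seq)
  code <- Biostrings::GENETIC_CODE
  vapply(seq, function(s) {
    s <- substring(s, frame_offset + 1)
    n_codons <- nchar(s) %/% 3
    if (n_codons == 0) {
      return("")
    }
    starts <- 3 * (seq_len(n_codons) - 1) + 1
    codons <- substring(s, starts, starts + 2)
    aa <- unname(code[codons])
    aa[is.na(aa)] <- "X" # codons containing N
    paste0(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Configuration for the frame-aware length filter
#'
#' The amplified capsid-gene fragment is protein-coding, so admissible read
#' lengths differ from the canonical amplicon length by whole codons:
#' `canonical_length + 3n` within `length_window`. With the defaults
#' (145, window 136–154) the admissible set is
#' `{136, 139, 142, 145, 148, 151, 154}`.
#'
#' @param canonical_length Canonical amplicon length in nt (default 145,
#'   primer-inclusive).
#' @param length_window Inclusive `[min, max]` length bounds (default
#'   `c(136, 154)`).
#' @param frame_offset Reading-frame offset 0–2 used for the stop-codon
#'   screen (default 0).
#' @param quality_threshold Mean-Phred threshold carried for pipeline use
#'   (default 25).
#' @return A list of class `mcp_frame_config`.
#' @export
frame_filter_config <- function(canonical_length = 145,
                                length_window = c(136, 154),
                                frame_offset = 0,
                                quality_threshold = 25) {
  stopifnot(
    length(length_window) == 2, length_window[1] <= length_window[2],
    frame_offset %in% 0:2
  )
  if (canonical_length < length_window[1] || canonical_length > length_window[2]) {
    stop("canonical_length must lie within length_window", call. = FALSE)
  }
  structure(
    list(
      canonical_length = as.integer(canonical_length),
      length_window = as.integer(length_window),
      frame_offset = as.integer(frame_offset),
      quality_threshold = quality_threshold
    ),
    class = "mcp_frame_config"
  )
}

#' Admissible read lengths under a frame-filter configuration
#'
#' @param config An [frame_filter_config()] object.
#' @return Integer vector of lengths within the window congruent to the
#'   canonical length modulo 3.
#' @examples
#' admissible_lengths(frame_filter_config()) # 136 139 142 145 148 151 154
#' @export
admissible_lengths <- function(config = frame_filter_config()) {
  w <- config$length_window
  lens <- w[1]:w[2]
  lens[lens %% 3 == config$canonical_length %% 3]
}

#' Frame-aware length and stop-codon filter
#'
#' Applies, per read and in order: the length window; the whole-codon rule
#' (length congruent to the canonical length mod 3); and a stop-codon screen
#' on the translation at `frame_offset` (or, with
#' `stop_mode = "any-frame-open"`, a read survives if *any* of the three
#' frames is stop-free). Each discarded read is counted under exactly one
#' reason: `out_of_window`, `non_codon_length` or `stop_codon`. The filter
#' is idempotent and conserves reads (kept + discarded = input, per sample).
#'
#' @param records Record tibble (already quality-filtered and
#'   barcode-trimmed).
#' @param config An [frame_filter_config()].
#' @param stop_mode `"frame"` (default: screen the configured frame only) or
#'   `"any-frame-open"`.
#' @return An object of class `mcp_readset`: `$records` (survivors),
#'   `$length_histogram` (tibble `sample`, `length`, `n` over survivors),
#'   `$discarded` (tibble `sample`, `reason`, `n`), `$n_input`.
#' @export
frame_filter <- function(records, config = frame_filter_config(),
                         stop_mode = c("frame", "any-frame-open")) {
  stop_mode <- match.arg(stop_mode)
  stopifnot(inherits(config, "mcp_frame_config"))
  len <- nchar(records$seq)
  w <- config$length_window
  in_window <- len >= w[1] & len <= w[2]
  codon_ok <- (len %% 3) == (config$canonical_length %% 3)

  reason <- rep(NA_character_, nrow(records))
  reason[!in_window] <- "out_of_window"
  reason[is.na(reason) & !codon_ok] <- "non_codon_length"

  candidate <- is.na(reason)
  if (any(candidate)) {
    has_stop <- function(offset) {
      grepl("*", translate_dna(records$seq[candidate], offset), fixed = TRUE)
    }
    stopped <- if (stop_mode == "frame") {
      has_stop(config$frame_offset)
    } else {
      has_stop(0) & has_stop(1) & has_stop(2)
    }
    reason[which(candidate)[stopped]] <- "stop_codon"
  }

  keep <- is.na(reason)
  survivors <- records[keep, , drop = FALSE]
  sample_of <- function(x) dplyr::coalesce(x, "unassigned")
  hist <- survivors |>
    dplyr::mutate(sample = sample_of(.data$sample), length = nchar(.data$seq)) |>
    dplyr::count(.data$sample, .data$length, name = "n")
  discarded <- tibble::tibble(
    sample = sample_of(records$sample[!keep]),
    reason = factor(reason[!keep],
      levels = c("quality", "out_of_window", "non_codon_length", "stop_codon")
    )
  ) |>
    dplyr::count(.data$sample, .data$reason, name = "n", .drop = FALSE)

  structure(
    list(
      records = survivors,
      length_histogram = hist,
      discarded = discarded,
      n_input = nrow(records),
      config = config
    ),
    class = "mcp_readset"
  )
}

#' @export
print.mcp_readset <- function(x, ...) {
  n_disc <- sum(x$discarded$n)
  cat(
    "Frame-filtered read set:", nrow(x$records), "of", x$n_input,
    "reads kept;", n_disc, "discarded",
    sprintf("(%.1f%%)\n", 100 * n_disc / max(x$n_input, 1))
  )
  by_reason <- dplyr::count(x$discarded, .data$reason,
    wt = .data$n, name = "n"
  )
  by_reason <- by_reason[by_reason$n > 0, ]
  if (nrow(by_reason)) {
    cat(paste0("  ", by_reason$reason, ": ", by_reason$n, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Overall discard fraction of a filtered read set
#'
#' @param readset An `mcp_readset`.
#' @param reasons Discard reasons to count (default: all).
#' @return Fraction of input reads discarded for the given reasons.
#' @export
discard_fraction <- function(readset, reasons = NULL) {
  stopifnot(inherits(readset, "mcp_readset"))
  d <- readset$discarded
  if (!is.null(reasons)) d <- d[d$reason %in% reasons, ]
  sum(d$n) / max(readset$n_input, 1)
}

#' Length-class composition of surviving reads
#'
#' Per sample, the proportion of surviving reads in each focal length class
#' (default 142/145/148 nt), with everything else pooled as `"other"`.
#' Proportions sum to 1 within each sample.
#'
#' @param readset An `mcp_readset` (or its `$length_histogram` tibble).
#' @param classes Focal lengths (default `c(142, 145, 148)`).
#' @return Tibble `sample`, `class` (factor with levels classes + "other"),
#'   `n`, `proportion`.
#' @export
length_class_composition <- function(readset, classes = c(142, 145, 148)) {
  hist <- if (inherits(readset, "mcp_readset")) readset$length_histogram else readset
  if (nrow(hist) == 0 || sum(hist$n) == 0) {
    stop("empty read set: length-class proportions are undefined", call. = FALSE)
  }
  lv <- c(as.character(classes), "other")
  hist |>
    dplyr::mutate(
      class = factor(
        ifelse(.data$length %in% classes, as.character(.data$length), "other"),
        levels = lv
      )
    ) |>
    dplyr::count(.data$sample, .data$class, wt = .data$n, name = "n", .drop = FALSE) |>
    dplyr::group_by(.data$sample) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}

#' 142/145 length-class read ratio
#'
#' The ratio of 142-nt to 145-nt surviving reads, used as a relative index
#' of terrestrial (non-cyanophage) input versus in-situ cyanophage
#' production when comparing samples.
#'
#' @param readset An `mcp_readset` (or its `$length_histogram`).
#' @param numerator,denominator Length classes (defaults 142 and 145).
#' @return Tibble `sample`, `ratio`. A sample with zero denominator reads is
#'   an error, not an infinity.
#' @export
source_ratio <- function(readset, numerator = 142, denominator = 145) {
  hist <- if (inherits(readset, "mcp_readset")) readset$length_histogram else readset
  out <- hist |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(
      num = sum(.data$n[.data$length == numerator]),
      den = sum(.data$n[.data$length == denominator])
    )
  if (any(out$den == 0)) {
    stop(
      "no ", denominator, "-nt reads in sample(s): ",
      paste(out$sample[out$den == 0], collapse = ", "),
      "; ratio undefined",
      call. = FALSE
    )
  }
  dplyr::transmute(out, sample = .data$sample, ratio = .data$num / .data$den)
}
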