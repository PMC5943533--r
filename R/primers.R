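# IUPAC ambiguity codes plus inosine (I), which base-pairs with all four
# nucleotides. N in a *reference* is treated as matching any primer code
# (absence of information, not evidence of mismatch).
IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"), I = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N", I = "I"
)

# lookup matrix: rows = primer codes, cols = reference bases A,C,G,T,N
.iupac_lut <- local({
  codes <- names(IUPAC_EXPANSION)
  m <- matrix(FALSE, length(codes), 5, dimnames = list(codes, c("A", "C", "G", "T", "N")))
  for (cd in codes) m[cd, IUPAC_EXPANSION[[cd]]] <- TRUE
  m[, "N"] <- TRUE
  m
})

#' The study's degenerate MCP primer pair
#'
#' mcp-821F (`CTKGCDGARATYAACMGIGAART`) and mcp-966R
#' (`ADDAGWCCYTTGAAYTTYTCAAC`) target a short (~145 bp, primer-inclusive)
#' fragment of the T4-like cyanophage g23 major capsid protein gene. The `I`
#' in the forward primer is inosine, a universal base.
#'
#' @return A named character vector of the two primer patterns.
#' @examples
#' mcp_primers()
#' expansion_count(mcp_primers()[["mcp-821F"]])
#' @export
mcp_primers <- function() {
  c(
    "mcp-821F" = "CTKGCDGARATYAACMGIGAART",
    "mcp-966R" = "ADDAGWCCYTTGAAYTTYTCAAC"
  )
}

#' @keywords internal
check_pattern <- function(pattern) {
  pattern <- toupper(as.character(pattern))
  if (length(pattern) != 1 || is.na(pattern) || !nzchar(pattern)) {
    stop("primer pattern must be a single non-empty string", call. = FALSE)
  }
  chars <- strsplit(pattern, "")[[1]]
  bad <- setdiff(chars, names(IUPAC_EXPANSION))
  if (length(bad) > 0) {
    stop("unknown IUPAC code(s) in primer pattern: ",
      paste(unique(bad), collapse = ", "),
      call. = FALSE
    )
  }
  pattern
}

#' Does a degenerate code match a concrete base?
#'
#' Vectorised over both arguments. `I` (inosine) and `N` match all four
#' bases; a base of `N` matches every code.
#'
#' @param code Character vector of IUPAC codes (plus `I`).
#' @param base Character vector of bases in `A,C,G,T,N`.
#' @return Logical vector.
#' @examples
#' iupac_match("K", c("G", "A")) # TRUE FALSE
#' @export
iupac_match <- function(code, base) {
  code <- toupper(code)
  base <- toupper(base)
  if (!all(code %in% rownames(.iupac_lut))) {
    stop("unknown IUPAC code: ",
      paste(setdiff(unique(code), rownames(.iupac_lut)), collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(base %in% colnames(.iupac_lut))) {
    stop("base must be one of A, C, G, T, N", call. = FALSE)
  }
  n <- max(length(code), length(base))
  .iupac_lut[cbind(rep_len(code, n), rep_len(base, n))]
}

#' Number of concrete sequences a degenerate pattern represents
#'
#' The product over positions of the per-position degeneracy, with inosine
#' counted as 4.
#'
#' @param pattern IUPAC pattern string.
#' @return Integer count.
#' @examples
#' expansion_count("ACGT") # 1
#' expansion_count("CTKGCDGARATYAACMGIGAART") # 384
#' @export
expansion_count <- function(pattern) {
  pattern <- check_pattern(pattern)
  chars <- strsplit(pattern, "")[[1]]
  prod(vapply(IUPAC_EXPANSION[chars], length, integer(1)))
}

#' Enumerate all concrete expansions of a degenerate pattern
#'
#' @param pattern IUPAC pattern string.
#' @param max_expansions Guard against combinatorial blow-up.
#' @return Character vector of concrete sequences.
#' @export
expand_pattern <- function(pattern, max_expansions = 65536) {
  pattern <- check_pattern(pattern)
  n <- expansion_count(pattern)
  if (n > max_expansions) {
    stop("pattern has ", n, " expansions, above max_expansions = ",
      max_expansions,
      call. = FALSE
    )
  }
  chars <- strsplit(pattern, "")[[1]]
  grid <- expand.grid(rev(IUPAC_EXPANSION[chars]),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  apply(grid[, rev(seq_along(chars)), drop = FALSE], 1, paste0, collapse = "")
}

#' Reverse-complement a degenerate pattern
#'
#' Complements each IUPAC code (R<->Y, K<->M, B<->V, D<->H; W, S, N map to
#' themselves) and reverses the string. Inosine complements to inosine
#' (universal pairing). Works on concrete sequences too.
#'
#' @param pattern IUPAC pattern string.
#' @return The reverse-complemented pattern.
#' @examples
#' revcomp_pattern("KDR") # "YHM"
#' @export
revcomp_pattern <- function(pattern) {
  pattern <- check_pattern(pattern)
  chars <- rev(strsplit(pattern, "")[[1]])
  paste0(IUPAC_COMPLEMENT[chars], collapse = "")
}

# mismatch count of `pattern` against every window of `refchars`
# (character vector); returns integer vector of length L - k + 1
.window_mismatches <- function(pchars, refchars) {
  k <- length(pchars)
  L <- length(refchars)
  nw <- L - k + 1
  if (nw < 1) {
    return(integer(0))
  }
  mm <- integer(nw)
  for (j in seq_len(k)) {
    mm <- mm + as.integer(!.iupac_lut[pchars[j], refchars[j:(j + nw - 1)]])
  }
  unname(mm)
}

#' Find degenerate-primer binding sites in reference sequences
#'
#' Scans every window of each reference on the requested strand(s) and
#' reports sites with at most `max_mismatches` positions failing
#' [iupac_match()]. Minus-strand sites are located by scanning the
#' reverse-complemented pattern along the plus strand; coordinates are always
#' reported 1-based inclusive on the plus strand.
#'
#' @param primer IUPAC pattern string (optionally named).
#' @param refs A record tibble (see [seq_tbl()]) or named character vector of
#'   reference sequences.
#' @param max_mismatches Maximum tolerated mismatches (default 0).
#' @param strand `"both"` (default), `"+"` or `"-"`.
#' @return A tibble with columns `ref_id`, `start`, `end`, `strand`,
#'   `mismatches`, sorted by (mismatches, start). Zero rows when no site
#'   qualifies.
#' @examples
#' find_primer_matches("ACGT", c(r = "TTACGTTT"))
#' @export
find_primer_matches <- function(primer, refs, max_mismatches = 0,
                                strand = c("both", "+", "-")) {
  strand <- match.arg(strand)
  primer <- check_pattern(primer)
  refs <- as_ref_vector(refs)
  k <- nchar(primer)
  fwd <- strsplit(primer, "")[[1]]
  rev_ <- strsplit(revcomp_pattern(primer), "")[[1]]
  out <- purrr::imap(refs, function(seq, id) {
    refchars <- strsplit(toupper(seq), "")[[1]]
    res <- list()
    if (strand %in% c("both", "+")) {
      mm <- .window_mismatches(fwd, refchars)
      hit <- which(mm <= max_mismatches)
      if (length(hit)) {
        res$plus <- tibble::tibble(
          ref_id = id, start = hit, end = hit + k - 1L,
          strand = "+", mismatches = mm[hit]
        )
      }
    }
    if (strand %in% c("both", "-")) {
      mm <- .window_mismatches(rev_, refchars)
      hit <- which(mm <= max_mismatches)
      if (length(hit)) {
        res$minus <- tibble::tibble(
          ref_id = id, start = hit, end = hit + k - 1L,
          strand = "-", mismatches = mm[hit]
        )
      }
    }
    dplyr::bind_rows(res)
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble::tibble(
      ref_id = character(), start = integer(), end = integer(),
      strand = character(), mismatches = integer()
    ))
  }
  dplyr::arrange(out, .data$mismatches, .data$start)
}

#' @keywords internal
as_ref_vector <- function(refs) {
  if (is.data.frame(refs)) {
    stats::setNames(refs$seq, refs$id)
  } else if (is.character(refs)) {
    if (is.null(names(refs))) names(refs) <- paste0("ref", seq_along(refs))
    refs
  } else {
    stop("`refs` must be a record tibble or a named character vector", call. = FALSE)
  }
}

#' In-silico PCR with a degenerate primer pair
#'
#' Pairs each plus-strand forward-primer site with every downstream
#' minus-strand reverse-primer binding site and reports amplicons whose
#' primer-inclusive length falls within `[min_len, max_len]`. The reported
#' span runs from the first base of the forward match to the last base of
#' the reverse binding site (1-based inclusive); `insert_seq` is the
#' sequence strictly between the two binding sites, so
#' `length == nchar(forward) + nchar(insert_seq) + nchar(reverse)`.
#'
#' @param refs Record tibble or named character vector of references.
#' @param forward,reverse IUPAC pattern strings (the reverse primer is given
#'   5'->3' as ordered, as primers are written).
#' @param max_mismatches Per-primer mismatch tolerance (default 0).
#' @param min_len,max_len Amplicon length bounds (primer-inclusive).
#' @return Tibble with `ref_id`, `span_start`, `span_end`, `length`,
#'   `insert_seq`, `mismatches` (forward + reverse), sorted by mismatches
#'   then span length. All qualifying pairs are reported; there is no silent
#'   "best hit".
#' @examples
#' insilico_pcr(c(r = "GGAAAACCCCCAAAAGG"), "AAAA", "TTTT",
#'   min_len = 1, max_len = 50
#' )
#' @export
insilico_pcr <- function(refs, forward, reverse, max_mismatches = 0,
                         min_len = 1, max_len = 10000) {
  if (min_len > max_len) stop("min_len must be <= max_len", call. = FALSE)
  refs <- as_ref_vector(refs)
  f_hits <- find_primer_matches(forward, refs, max_mismatches, strand = "+")
  r_hits <- find_primer_matches(reverse, refs, max_mismatches, strand = "-")
  if (nrow(f_hits) == 0 || nrow(r_hits) == 0) {
    return(tibble::tibble(
      ref_id = character(), span_start = integer(), span_end = integer(),
      length = integer(), insert_seq = character(), mismatches = integer()
    ))
  }
  pairs <- dplyr::inner_join(
    dplyr::rename(f_hits, f_start = "start", f_end = "end", f_mm = "mismatches"),
    dplyr::rename(r_hits, r_start = "start", r_end = "end", r_mm = "mismatches"),
    by = "ref_id", relationship = "many-to-many"
  )
  pairs <- dplyr::filter(pairs, .data$r_start > .data$f_end)
  pairs <- dplyr::mutate(pairs,
    span_start = .data$f_start,
    span_end = .data$r_end,
    length = .data$span_end - .data$span_start + 1L,
    mismatches = .data$f_mm + .data$r_mm
  )
  pairs <- dplyr::filter(pairs, .data$length >= min_len, .data$length <= max_len)
  pairs <- dplyr::mutate(pairs,
    insert_seq = unname(substring(
      refs[.data$ref_id], .data$f_end + 1L, .data$r_start - 1L
    ))
  )
  out <- dplyr::select(
    pairs, "ref_id", "span_start", "span_end", "length", "insert_seq", "mismatches"
  )
  dplyr::arrange(out, .data$mismatches, .data$length, .data$span_start)
}

#' Demultiplex barcoded reads and trim barcodes/primers
#'
#' Assumes the single-index read layout with the barcode at the 5' end of
#' the read, immediately followed by the forward primer and the amplicon.
#' Each read is assigned to the unique sample whose barcode matches the read
#' prefix within `barcode_mismatches`; reads matching no barcode, or more
#' than one (ambiguity), go to the `"undetermined"` bin. The barcode is
#' always removed from assigned reads; with `trim_primers = TRUE` the
#' forward primer prefix and the reverse-primer binding-site suffix are also
#' removed when found within `primer_mismatches`.
#'
#' @param records Record tibble.
#' @param barcode_map Tibble/data frame with columns `sample`, `barcode`
#'   (uniform barcode length), or a named character vector
#'   `c(sample = barcode)`.
#' @param forward,reverse Primer patterns (used when `trim_primers = TRUE`).
#' @param barcode_mismatches Barcode mismatch tolerance (default 0).
#' @param primer_mismatches Primer-trimming mismatch tolerance (default 1).
#' @param trim_primers Remove primer sequences as well (default FALSE, the
#'   primer-inclusive length convention).
#' @return A list of class `mcp_demux`: `$reads` (record tibble with
#'   `sample` filled in; undetermined reads carry `"undetermined"`),
#'   `$counts` (tibble of per-bin read counts). Demultiplexing is a
#'   partition: bin sizes sum to the input size.
#' @export
demultiplex <- function(records, barcode_map,
                        forward = mcp_primers()[["mcp-821F"]],
                        reverse = mcp_primers()[["mcp-966R"]],
                        barcode_mismatches = 0, primer_mismatches = 1,
                        trim_primers = FALSE) {
  if (!is.data.frame(barcode_map)) {
    barcode_map <- tibble::tibble(
      sample = names(barcode_map), barcode = unname(barcode_map)
    )
  }
  barcodes <- toupper(barcode_map$barcode)
  if (length(unique(nchar(barcodes))) != 1) {
    stop("barcodes must all have the same length", call. = FALSE)
  }
  if (anyDuplicated(barcodes)) stop("duplicate barcodes in map", call. = FALSE)
  blen <- nchar(barcodes[1])
  bmat <- do.call(rbind, strsplit(barcodes, ""))

  prefixes <- substring(records$seq, 1, blen)
  assign_one <- function(prefix) {
    if (nchar(prefix) < blen) {
      return(NA_character_)
    }
    pc <- strsplit(prefix, "")[[1]]
    mm <- rowSums(bmat != matrix(pc, nrow(bmat), blen, byrow = TRUE))
    hit <- which(mm <= barcode_mismatches)
    if (length(hit) == 1) barcode_map$sample[hit] else NA_character_
  }
  assigned <- vapply(prefixes, assign_one, character(1), USE.NAMES = FALSE)

  reads <- records
  reads$sample <- ifelse(is.na(assigned), "undetermined", assigned)
  ok <- !is.na(assigned)
  # strip barcode from assigned reads
  reads$seq[ok] <- substring(reads$seq[ok], blen + 1)
  reads$qual[ok] <- purrr::map(reads$qual[ok], function(q) {
    if (is.null(q)) NULL else q[-seq_len(min(blen, length(q)))]
  })

  if (trim_primers) {
    fpat <- strsplit(check_pattern(forward), "")[[1]]
    rpat <- strsplit(revcomp_pattern(reverse), "")[[1]]
    for (i in which(ok)) {
      s <- strsplit(reads$seq[i], "")[[1]]
      from <- 1L
      to <- length(s)
      if (to >= length(fpat) &&
        sum(!.iupac_lut[cbind(fpat, s[seq_along(fpat)])]) <= primer_mismatches) {
        from <- length(fpat) + 1L
      }
      if (to - from + 1 >= length(rpat)) {
        tail_idx <- (to - length(rpat) + 1L):to
        if (sum(!.iupac_lut[cbind(rpat, s[tail_idx])]) <= primer_mismatches) {
          to <- to - length(rpat)
        }
      }
      reads$seq[i] <- paste0(s[from:to], collapse = "")
      if (!is.null(reads$qual[[i]])) {
        reads$qual[[i]] <- reads$qual[[i]][from:to]
      }
    }
  }

  counts <- dplyr::count(reads, .data$sample, name = "n")
  structure(list(reads = reads, counts = counts), class = "mcp_demux")
}

#' @export
print.mcp_demux <- function(x, ...) {
  cat("Demultiplexed reads:", nrow(x$reads), "reads in",
    nrow(x$counts), "bins\n"
  )
  print(x$counts)
  invisible(x)
}
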