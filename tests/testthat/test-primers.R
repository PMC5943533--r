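test_that("IUPAC code semantics: ambiguity sets, inosine, N", {
  expect_true(iupac_match("K", "G"))
  expect_false(iupac_match("K", "A"))
  expect_true(iupac_match("I", "C"))
  expect_false(iupac_match("D", "C"))
  expect_true(all(iupac_match("N", c("A", "C", "G", "T"))))
  expect_true(all(iupac_match(c("A", "K", "D"), "N"))) # reference N matches anything
  expect_error(iupac_match("Z", "A"), "unknown")
})

test_that("expansion counts match exhaustive enumeration, including the MCP pair", {
  expect_equal(expansion_count("ACGT"), 1)
  # oracle: enumerate every concrete expansion and count the distinct strings
  for (pat in c("CTKGCDGARATYAACMGIGAART", "ADDAGWCCYTTGAAYTTYTCAAC", "KDR", "NIA")) {
    n_enum <- length(expand_pattern(pat))
    expect_equal(expansion_count(pat), n_enum)
  }
  expect_equal(expansion_count(mcp_primers()[["mcp-821F"]]), 384)
  expect_equal(expansion_count(mcp_primers()[["mcp-966R"]]), 144)
})

test_that("pattern reverse complement is an involution and maps expansion sets", {
  expect_equal(revcomp_pattern("ACGT"), "ACGT")
  expect_equal(revcomp_pattern("KDR"), "YHM")
  pats <- c("KDR", "ACGT", "NIWS", mcp_primers()[["mcp-966R"]])
  for (p in pats) {
    expect_equal(revcomp_pattern(revcomp_pattern(p)), p)
  }
  # expansion set of the revcomp pattern == revcomp of each expansion
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  for (p in c("KDR", "BHVI")) {
    expect_setequal(
      expand_pattern(revcomp_pattern(p)),
      vapply(expand_pattern(p), rc, character(1), USE.NAMES = FALSE)
    )
  }
})

test_that("find_primer_matches agrees with expansion-enumeration brute force", {
  set.seed(21)
  codes <- c("A", "C", "G", "T", "R", "Y", "K", "M", "W", "S", "I", "D")
  for (rep in 1:15) {
    pat <- paste0(sample(codes, sample(4:7, 1), replace = TRUE), collapse = "")
    if (expansion_count(pat) > 512) next
    ref <- random_dna(1, 150)
    got <- find_primer_matches(pat, c(r = ref), max_mismatches = 0, strand = "+")
    expect_equal(got$start, oracle_find_sites(pat, ref), info = pat)
    if (nrow(got) > 0) {
      expect_true(all(got$end - got$start + 1 == nchar(pat)))
    }
  }
})

test_that("mismatch tolerance and strand reporting behave as specified", {
  expect_equal(
    find_primer_matches("ACGT", c(r = "TTACGTTT"), strand = "+")[, c("start", "end")],
    tibble::tibble(start = 3L, end = 6L)
  )
  m <- find_primer_matches("ACGT", c(r = "TTACGATT"), max_mismatches = 1, strand = "+")
  expect_equal(m$start[1], 3L)
  expect_equal(m$mismatches[1], 1L)
  # a primer matches its own concrete expansions exactly once at position 1
  for (e in expand_pattern("AKDCG")) {
    m <- find_primer_matches("AKDCG", c(x = e), strand = "+")
    expect_equal(m$start, 1L)
    expect_equal(m$mismatches, 0L)
  }
  # minus-strand coordinates are plus-strand positions of the binding site
  m <- find_primer_matches("AAAA", c(r = "GGTTTTGG"), strand = "-")
  expect_equal(m$start, 3L)
  expect_equal(m$strand, "-")
})

test_that("in-silico PCR reports span, insert and length conservation", {
  hit <- insilico_pcr(c(r = "GGAAAACCCCCAAAAGG"), "AAAA", "TTTT",
    min_len = 1, max_len = 50
  )
  expect_equal(nrow(hit), 1)
  expect_equal(hit$span_start, 3L)
  expect_equal(hit$span_end, 15L)
  expect_equal(hit$length, 13L)
  expect_equal(hit$insert_seq, "CCCCC")
  expect_equal(hit$length, 4L + nchar(hit$insert_seq) + 4L)
  # no downstream reverse site -> empty
  expect_equal(nrow(insilico_pcr(c(r = "GGAAAAGGGGG"), "AAAA", "TTTT",
    min_len = 1, max_len = 50
  )), 0)
})

test_that("the MCP primer pair amplifies the bundled stand-in g23 at 748-893", {
  # synthetic stand-in for the S-PM2 g23 coding sequence, with the two
  # primer-binding sites planted at the coordinates the primers were
  # designed against
  ref <- read_fasta(system.file("extdata", "spm2_g23_synthetic.fasta",
    package = "cyanomcp"
  ))
  hits <- insilico_pcr(ref, mcp_primers()[["mcp-821F"]], mcp_primers()[["mcp-966R"]],
    max_mismatches = 0, min_len = 100, max_len = 200
  )
  expect_equal(nrow(hits), 1)
  expect_equal(hits$span_start, 748L)
  expect_equal(hits$span_end, 893L)
  expect_equal(hits$length, 146L)
})

test_that("demultiplexing is a partition and recovers generator ground truth", {
  study <- generate_study(
    design = study_design(reads_per_sample = 40),
    decorate = TRUE, seed = 5
  )
  dmx <- demultiplex(study$reads, study$design[, c("sample", "barcode")])
  # partition: bin sizes sum to input
  expect_equal(sum(dmx$counts$n), nrow(study$reads))
  expect_equal(nrow(dmx$reads), nrow(study$reads))
  # zero barcode errors -> 100% correct assignment
  truth <- study$truth$sample[match(dmx$reads$id, study$truth$id)]
  expect_equal(dmx$reads$sample, truth)
  # barcode stripped: lengths back to the amplicon classes
  expect_true(all(nchar(dmx$reads$seq) %in% c(142, 145, 148)))
})

test_that("unknown and ambiguous barcodes are routed to undetermined", {
  reads <- seq_tbl(c("r1", "r2"), c("GGGGGGGGACGTACGT", "ACACACACACGTACGT"))
  map <- tibble::tibble(sample = c("S1", "S2"), barcode = c("ACACACAC", "ACACACAT"))
  dmx <- demultiplex(reads, map, barcode_mismatches = 1)
  # r1 matches nothing; r2 is within 1 mismatch of both barcodes -> ambiguous
  expect_equal(dmx$reads$sample, c("undetermined", "undetermined"))
  dmx0 <- demultiplex(reads, map, barcode_mismatches = 0)
  expect_equal(dmx0$reads$sample, c("undetermined", "S1"))
})

test_that("primer trimming removes the forward prefix and reverse suffix", {
  f <- "ACGTACGT"
  r_site <- "TTTTAAAA" # reverse-binding site on the plus strand
  insert <- "CCCGGGCCC"
  reads <- seq_tbl("r1", paste0("ACACACAC", f, insert, r_site))
  map <- c(S1 = "ACACACAC")
  dmx <- demultiplex(reads, map,
    forward = f, reverse = revcomp_pattern(r_site),
    trim_primers = TRUE, primer_mismatches = 0
  )
  expect_equal(dmx$reads$seq, insert)
})
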