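make_reads <- function(seqs, quals = NULL, sample = "S1") {
  seq_tbl(paste0("r", seq_along(seqs)), seqs, quals, sample = sample)
}

test_that("quality filter keeps by mean Phred with an inclusive boundary", {
  reads <- make_reads(
    rep("ACGTACGT", 3),
    list(rep(30L, 8), rep(20L, 8), rep(c(40L, 10L), 4)) # means 30, 20, 25
  )
  qf <- quality_filter(reads, threshold = 25)
  expect_equal(qf$kept$id, c("r1", "r3")) # exact boundary kept
  expect_equal(qf$n_discarded, 1)
  expect_equal(nrow(qf$kept) + qf$n_discarded, qf$n_input)
})

test_that("raising the quality threshold never increases the kept count", {
  set.seed(31)
  reads <- make_reads(random_dna(50, 30))
  reads$qual <- purrr::map(seq_len(50), function(i) sample(5:40, 30, replace = TRUE))
  kept <- vapply(c(10, 20, 25, 30, 35), function(th) {
    nrow(quality_filter(reads, threshold = th)$kept)
  }, numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("records without qualities bypass the quality filter with a message", {
  reads <- make_reads(c("ACGT", "GGGG"))
  expect_message(qf <- quality_filter(reads), "bypass")
  expect_equal(nrow(qf$kept), 2)
})

test_that("translation follows the standard code, drops partial codons, flags N", {
  expect_equal(translate_dna("ATGGCC"), "MA")
  expect_equal(translate_dna("ATGTAA"), "M*")
  expect_equal(translate_dna("ATGGC"), "M")
  expect_equal(translate_dna("ATGANC"), "MX")
  expect_equal(translate_dna("AATGGCC", frame_offset = 1), "MA")
})

test_that("the admissible-length set under the 145 +/- 3n rule is exact", {
  expect_equal(
    admissible_lengths(frame_filter_config()),
    c(136L, 139L, 142L, 145L, 148L, 151L, 154L)
  )
})

test_that("frame filter discards by window, codon rule and stop codons with a ledger", {
  set.seed(41)
  haps <- generate_haplotypes(6, c(142, 145, 148), seed = 41)
  spec <- community_spec("S1",
    length_class_probs = c("142" = 0.3, "145" = 0.4, "148" = 0.3),
    reads_per_sample = 100, substitution_error_rate = 0, seed = 41
  )
  reads <- generate_reads(haps, spec)$reads
  # plant 5 frame-shifts (1-base deletion) and 3 in-frame stops
  shift <- 1:5
  stopped <- 6:8
  reads$seq[shift] <- substring(reads$seq[shift], 2)
  reads$qual[shift] <- purrr::map(reads$qual[shift], function(q) q[-1])
  for (i in stopped) {
    s <- reads$seq[i]
    substr(s, 31, 33) <- "TAG" # codon 11, inside the insert
    reads$seq[i] <- s
  }
  rs <- frame_filter(reads)
  expect_equal(nrow(rs$records), 92)
  ledger <- dplyr::count(rs$discarded, reason, wt = n, name = "n")
  expect_equal(ledger$n[ledger$reason == "non_codon_length"], 5)
  expect_equal(ledger$n[ledger$reason == "stop_codon"], 3)
  # conservation
  expect_equal(nrow(rs$records) + sum(rs$discarded$n), rs$n_input)
})

test_that("each discard carries exactly one reason, window checked first", {
  reads <- make_reads(c(
    strrep("A", 120), # out of window (and wrong codon class)
    strrep("A", 144), # in window, 144 = 145-1: not a whole-codon variant
    paste0(strrep("A", 30), "TAG", strrep("A", 112)) # 145 with a stop
  ))
  rs <- frame_filter(reads)
  d <- rs$discarded[rs$discarded$n > 0, ]
  expect_setequal(as.character(d$reason), c("out_of_window", "non_codon_length", "stop_codon"))
  expect_equal(sum(d$n), 3)
})

test_that("every survivor length is congruent to 145 mod 3 and the filter is idempotent", {
  set.seed(43)
  lens <- sample(130:160, 200, replace = TRUE)
  reads <- make_reads(vapply(lens, function(L) {
    paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1)))
  rs <- frame_filter(reads)
  survivor_len <- nchar(rs$records$seq)
  expect_true(all(survivor_len %% 3 == 145 %% 3))
  expect_true(all(survivor_len >= 136 & survivor_len <= 154))
  rs2 <- frame_filter(rs$records)
  expect_equal(sum(rs2$discarded$n), 0)
  expect_equal(nrow(rs2$records), nrow(rs$records))
})

test_that("any-frame-open mode keeps reads with one open frame", {
  # stop in frame 0, but frames 1/2 are open
  s <- paste0("TAG", strrep("CCA", 47), "C") # length 145
  rs_strict <- frame_filter(make_reads(s))
  rs_any <- frame_filter(make_reads(s), stop_mode = "any-frame-open")
  expect_equal(nrow(rs_strict$records), 0)
  expect_equal(nrow(rs_any$records), 1)
})

test_that("length-class composition sums to one and recovers generator proportions", {
  # arithmetic on a fixed histogram
  hist <- tibble::tibble(
    sample = "S1", length = c(145L, 142L, 148L), n = c(97L, 2L, 1L)
  )
  comp <- length_class_composition(hist)
  expect_equal(sum(comp$proportion), 1)
  expect_equal(comp$proportion[comp$class == "145"], 0.97)
  expect_equal(comp$proportion[comp$class == "other"], 0)

  # parameter recovery at n = 10,000: KS-like mixture (142, 145, 148)
  probs <- c("142" = 0.176, "145" = 0.301, "148" = 0.52, "other" = 0.003)
  haps <- generate_haplotypes(8, c(142, 145, 148, 151), seed = 47)
  haps$class[8] <- 151L # one out-of-focal admissible length
  spec <- community_spec("KS",
    length_class_probs = c("142" = 0.176, "145" = 0.301, "148" = 0.52, "151" = 0.003),
    reads_per_sample = 10000, substitution_error_rate = 0, seed = 47
  )
  rs <- frame_filter(generate_reads(haps, spec)$reads)
  expect_equal(nrow(rs$records), 10000) # error-free reads lose nothing
  comp <- length_class_composition(rs)
  for (cl in c("142", "145", "148")) {
    p <- probs[[cl]]
    se <- sqrt(p * (1 - p) / 10000)
    expect_lt(
      abs(comp$proportion[comp$class == cl] - p), 3 * se
    )
  }
})

test_that("empty read sets have undefined composition", {
  expect_error(
    length_class_composition(tibble::tibble(
      sample = character(), length = integer(), n = integer()
    )),
    "empty"
  )
})

test_that("source ratio divides 142 by 145 counts and refuses a zero denominator", {
  hist <- tibble::tibble(sample = "S1", length = c(142L, 145L), n = c(10L, 100L))
  expect_equal(source_ratio(hist)$ratio, 0.1)
  hist0 <- tibble::tibble(sample = "S1", length = c(142L, 145L), n = c(0L, 50L))
  expect_equal(source_ratio(hist0)$ratio, 0)
  hist_bad <- tibble::tibble(sample = "S1", length = 142L, n = 10L)
  expect_error(source_ratio(hist_bad), "undefined")
})

test_that("planted 142/145 ratio ordering is recovered from reads", {
  haps <- generate_haplotypes(6, c(142, 145, 148), seed = 53)
  mk <- function(name, p142, p145, p148, seed) {
    spec <- community_spec(name,
      length_class_probs = c("142" = p142, "145" = p145, "148" = p148),
      reads_per_sample = 3000, substitution_error_rate = 0, seed = seed
    )
    generate_reads(haps, spec)$reads
  }
  # deep KS-like sample planted with the higher terrestrial-input ratio
  reads <- dplyr::bind_rows(
    mk("KS1like", 0.12, 0.35, 0.53, 61), # planted ratio 0.34
    mk("KS2like", 0.21, 0.27, 0.52, 62) # planted ratio 0.78
  )
  ratios <- source_ratio(frame_filter(reads))
  expect_gt(
    ratios$ratio[ratios$sample == "KS2like"],
    ratios$ratio[ratios$sample == "KS1like"]
  )
})
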