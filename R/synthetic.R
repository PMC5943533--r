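# Synthetic amplicon generator: ground-truth haplotypes with the 142/145/148
# length-class structure, codon-aware and stop-free in the canonical frame,
# log-skewed abundances, per-base substitution errors with Phred-style
# quality strings, and optional barcode decoration for demultiplex tests.

.random_bases <- function(n) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE)
}

# pick one concrete expansion of a degenerate pattern, uniformly per position
.sample_expansion <- function(pattern) {
  chars <- strsplit(check_pattern(pattern), "")[[1]]
  paste0(
    vapply(IUPAC_EXPANSION[chars], function(b) b[sample.int(length(b), 1)], character(1)),
    collapse = ""
  )
}

# build one stop-free amplicon of total length L: concrete forward primer +
# random insert + concrete reverse-primer binding site, repaired until the
# frame-0 translation is stop-free
.build_haplotype <- function(L, fwd_pat, rev_pat, max_tries = 200) {
  for (outer in seq_len(20)) {
    f <- .sample_expansion(fwd_pat)
    r <- revcomp_pattern(.sample_expansion(rev_pat))
    m <- L - nchar(f) - nchar(r)
    if (m < 0) stop("amplicon length ", L, " shorter than the two primers", call. = FALSE)
    chars <- c(strsplit(f, "")[[1]], .random_bases(m), strsplit(r, "")[[1]])
    insert_idx <- seq(nchar(f) + 1, length.out = m)
    for (try in seq_len(max_tries)) {
      aa <- translate_dna(paste0(chars, collapse = ""))
      stops <- which(strsplit(aa, "")[[1]] == "*")
      if (length(stops) == 0) {
        return(paste0(chars, collapse = ""))
      }
      fixable <- FALSE
      for (k in stops) {
        pos <- (3 * (k - 1) + 1):(3 * k)
        free <- intersect(pos, insert_idx)
        if (length(free) > 0) {
          chars[free] <- .random_bases(length(free))
          fixable <- TRUE
        }
      }
      if (!fixable) break # stop sits wholly in a primer region: redraw expansions
    }
  }
  stop("could not build a stop-free amplicon of length ", L,
    "; check primer patterns",
    call. = FALSE
  )
}

#' Generate ground-truth amplicon haplotypes
#'
#' Builds `n` distinct amplicon haplotypes whose lengths follow the
#' 142/145/148 class convention (all congruent to 145 mod 3, so the
#' canonical frame is preserved), each consisting of a concrete expansion of
#' the forward primer, a random insert, and the reverse-complemented
#' expansion of the reverse primer, constructed to be stop-free in frame 0.
#' All pairs are kept below `1 - min_pairwise_divergence` identity by
#' rejection; an unsatisfiable request errors with a parameter hint.
#'
#' @param n Number of haplotypes.
#' @param classes Amplicon lengths per haplotype, recycled to length `n`
#'   (default all 145).
#' @param min_pairwise_divergence Minimum pairwise divergence
#'   (`1 - identity`), default 0.2.
#' @param forward,reverse Degenerate primer patterns (defaults:
#'   [mcp_primers()]).
#' @param seed Optional RNG seed; fixed seed gives identical output.
#' @param max_rounds Rejection rounds per haplotype before giving up.
#' @return Tibble `haplotype`, `seq`, `class`.
#' @export
generate_haplotypes <- function(n, classes = 145,
                                min_pairwise_divergence = 0.2,
                                forward = mcp_primers()[["mcp-821F"]],
                                reverse = mcp_primers()[["mcp-966R"]],
                                seed = NULL, max_rounds = 50) {
  stopifnot(n >= 1, min_pairwise_divergence >= 0, min_pairwise_divergence < 1)
  if (!is.null(seed)) set.seed(seed)
  classes <- rep_len(as.integer(classes), n)
  max_ident <- 1 - min_pairwise_divergence
  seqs <- character(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (round in seq_len(max_rounds)) {
      cand <- .build_haplotype(classes[i], forward, reverse)
      if (length(seqs) == 0 ||
        max(pairwise_identity(seqs, cand)) <= max_ident) {
        seqs <- c(seqs, cand)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place haplotype ", i, " below ",
        sprintf("%.0f%%", 100 * max_ident),
        " identity to the existing set; lower `min_pairwise_divergence` or `n`",
        call. = FALSE
      )
    }
  }
  tibble::tibble(
    haplotype = sprintf("H%03d", seq_len(n)),
    seq = seqs,
    class = classes
  )
}

#' Specification of one synthetic sample community
#'
#' Bundles and validates the per-sample generator parameters: the mixture of
#' 142/145/148-nt length classes, the abundance model over haplotypes, the
#' sequencing effort, the per-base substitution error rate, and the quality
#' model for Phred strings.
#'
#' @param sample Sample label.
#' @param length_class_probs Named probabilities for classes `"142"`,
#'   `"145"`, `"148"` (must sum to 1). Default: the marine-like profile
#'   `c(0.02, 0.97, 0.01)`.
#' @param abundance_model `list(model = "lognormal", meanlog, sdlog)` or
#'   `list(model = "geometric", prob)`; haplotype weights are drawn from it.
#' @param reads_per_sample Number of reads to emit (default 2000).
#' @param substitution_error_rate Per-base substitution probability in
#'   `[0, 1)` (default 0.01).
#' @param quality_mean,quality_sd Normal model for per-base Phred scores
#'   (defaults 30.8 and 3), rounded and clamped to `[2, 41]`.
#' @param barcode Optional barcode prepended to every read.
#' @param seed Optional RNG seed used by [generate_reads()].
#' @return A validated list of class `mcp_community_spec`.
#' @export
community_spec <- function(sample,
                           length_class_probs = c("142" = 0.02, "145" = 0.97, "148" = 0.01),
                           abundance_model = list(model = "lognormal", meanlog = 1, sdlog = 1.5),
                           reads_per_sample = 2000,
                           substitution_error_rate = 0.01,
                           quality_mean = 30.8, quality_sd = 3,
                           barcode = NULL, seed = NULL) {
  if (abs(sum(length_class_probs) - 1) > 1e-8) {
    stop("length_class_probs must sum to 1", call. = FALSE)
  }
  if (is.null(names(length_class_probs))) {
    stop("length_class_probs must be named by class length", call. = FALSE)
  }
  if (substitution_error_rate < 0 || substitution_error_rate >= 1) {
    stop("substitution_error_rate must lie in [0, 1)", call. = FALSE)
  }
  if (reads_per_sample <= 0) stop("reads_per_sample must be > 0", call. = FALSE)
  if (!abundance_model$model %in% c("lognormal", "geometric")) {
    stop("abundance model must be 'lognormal' or 'geometric'", call. = FALSE)
  }
  structure(
    list(
      sample = sample,
      length_class_probs = length_class_probs,
      abundance_model = abundance_model,
      reads_per_sample = as.integer(reads_per_sample),
      substitution_error_rate = substitution_error_rate,
      quality_mean = quality_mean, quality_sd = quality_sd,
      barcode = barcode, seed = seed
    ),
    class = "mcp_community_spec"
  )
}

.draw_weights <- function(model, n) {
  switch(model$model,
    lognormal = stats::rlnorm(n, meanlog = model$meanlog, sdlog = model$sdlog),
    geometric = model$prob * (1 - model$prob)^(seq_len(n) - 1)
  )
}

.mutate_read <- function(seq, rate) {
  L <- nchar(seq)
  k <- stats::rbinom(1, L, rate)
  if (k == 0) {
    return(seq)
  }
  chars <- strsplit(seq, "")[[1]]
  pos <- sample.int(L, k)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste0(chars, collapse = "")
}

#' Emit reads from haplotypes under a community specification
#'
#' Each read picks a length class from the spec's class probabilities, then
#' a haplotype of that class in proportion to its drawn abundance weight;
#' per-base substitutions are planted at the stated rate and a Phred-style
#' quality string is drawn from the quality model. The full ground truth
#' (read to haplotype mapping) is returned.
#'
#' @param haplotypes Tibble from [generate_haplotypes()]. Every class with
#'   positive probability must be represented by at least one haplotype.
#' @param spec An [community_spec()].
#' @return List with `$reads` (record tibble; barcode-decorated if the spec
#'   has one) and `$truth` (tibble `id`, `haplotype`, `class`, `sample`).
#' @export
generate_reads <- function(haplotypes, spec) {
  stopifnot(inherits(spec, "mcp_community_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  probs <- spec$length_class_probs
  active <- names(probs)[probs > 0]
  missing <- setdiff(active, as.character(haplotypes$class))
  if (length(missing) > 0) {
    stop("no haplotypes available for length class(es): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  n <- spec$reads_per_sample
  w <- .draw_weights(spec$abundance_model, nrow(haplotypes))
  cls <- sample(names(probs), n, replace = TRUE, prob = probs)
  pick <- integer(n)
  for (cl in unique(cls)) {
    idx <- which(as.character(haplotypes$class) == cl)
    sel <- which(cls == cl)
    pick[sel] <- if (length(idx) == 1) {
      idx
    } else {
      sample(idx, length(sel), replace = TRUE, prob = w[idx])
    }
  }
  seqs <- haplotypes$seq[pick]
  if (spec$substitution_error_rate > 0) {
    seqs <- vapply(seqs, .mutate_read,
      character(1),
      rate = spec$substitution_error_rate, USE.NAMES = FALSE
    )
  }
  if (!is.null(spec$barcode)) {
    seqs <- paste0(toupper(spec$barcode), seqs)
  }
  qual <- purrr::map(nchar(seqs), function(L) {
    pmin(pmax(as.integer(round(stats::rnorm(L, spec$quality_mean, spec$quality_sd))), 2L), 41L)
  })
  ids <- sprintf("%s_read%05d", spec$sample, seq_len(n))
  list(
    reads = seq_tbl(ids, seqs, qual, sample = spec$sample),
    truth = tibble::tibble(
      id = ids,
      haplotype = haplotypes$haplotype[pick],
      class = haplotypes$class[pick],
      sample = spec$sample
    )
  )
}

#' Default eight-sample study design
#'
#' Two biome groups of four samples each — a marine-like group dominated by
#' the 145-nt class and a lake-like group containing two "KS-like"
#' sediment samples in which the 148-nt class dominates and the 142/145
#' ratio is elevated (more strongly in the deeper `KS2`-like sample than in
#' `KS1`). Each group draws its dominant haplotypes from a group-private
#' pool; a rare tail is shared by all samples.
#'
#' @param reads_per_sample Sequencing effort per sample (default 2000).
#' @return Tibble `sample`, `group`, `p142`, `p145`, `p148`, `reads`,
#'   `barcode`.
#' @export
study_design <- function(reads_per_sample = 2000) {
  tibble::tibble(
    sample = c("NMC", "KS1", "KS2", "SSL", "B43", "B64", "DHa1", "DW03"),
    group = c("lake", "lake", "lake", "lake", "marine", "marine", "marine", "marine"),
    p142 = c(0.02, 0.15, 0.21, 0.02, 0.02, 0.02, 0.02, 0.02),
    p145 = c(0.96, 0.32, 0.27, 0.96, 0.97, 0.97, 0.97, 0.97),
    p148 = c(0.02, 0.53, 0.52, 0.02, 0.01, 0.01, 0.01, 0.01),
    reads = as.integer(reads_per_sample),
    barcode = c(
      "ACACACAC", "CGCGCGCG", "GTGTGTGT", "TATATATA",
      "AACCGGTT", "CCAATTGG", "GGTTAACC", "TTGGCCAA"
    )
  )
}

#' Generate a complete multi-sample synthetic study
#'
#' Generates a shared haplotype universe (per-group private dominant pools
#' plus a rare tail common to all samples, all mutually divergent), then
#' emits reads for every sample of the design. The planted structure gives
#' the two groups disjoint dominant OTU sets — a clean beta-diversity signal
#' — while the shared rare tail keeps the groups connected.
#'
#' @param design A [study_design()] tibble.
#' @param n_dominant Dominant haplotypes per group (default 12, spread over
#'   the three length classes).
#' @param n_shared_rare Shared rare-tail haplotypes (default 30).
#' @param dominance_boost Abundance multiplier for a group's own dominant
#'   haplotypes (default 60).
#' @param substitution_error_rate Per-base error rate (default 0.01).
#' @param quality_mean,quality_sd Quality model (defaults 30.8, 3).
#' @param min_pairwise_divergence Haplotype divergence floor (default 0.2).
#' @param decorate Prepend each sample's barcode (default FALSE).
#' @param seed RNG seed for the whole study (default 1).
#' @param dir Optional directory: per-sample FASTQ plus `truth_reads.tsv`,
#'   `truth_haplotypes.tsv`, `design.tsv` are written there.
#' @return List of class `mcp_study`: `$reads`, `$truth`, `$haplotypes`
#'   (with `group` pool labels), `$design`, `$dir`.
#' @export
generate_study <- function(design = study_design(), n_dominant = 12,
                           n_shared_rare = 30, dominance_boost = 60,
                           substitution_error_rate = 0.01,
                           quality_mean = 30.8, quality_sd = 3,
                           min_pairwise_divergence = 0.2,
                           decorate = FALSE, seed = 1, dir = NULL) {
  set.seed(seed)
  groups <- unique(design$group)
  class_cycle <- function(n) rep_len(c(145L, 148L, 142L), n)
  pools <- c(
    stats::setNames(
      lapply(groups, function(g) class_cycle(n_dominant)),
      groups
    ),
    list(shared = class_cycle(n_shared_rare))
  )
  all_classes <- unlist(pools, use.names = FALSE)
  haps <- generate_haplotypes(
    length(all_classes),
    classes = all_classes,
    min_pairwise_divergence = min_pairwise_divergence
  )
  haps$group <- rep(names(pools), lengths(pools))

  reads <- list()
  truth <- list()
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    pool <- haps[haps$group %in% c(row$group, "shared"), ]
    spec <- community_spec(
      sample = row$sample,
      length_class_probs = c(
        "142" = row$p142, "145" = row$p145, "148" = row$p148
      ),
      reads_per_sample = row$reads,
      substitution_error_rate = substitution_error_rate,
      quality_mean = quality_mean, quality_sd = quality_sd,
      barcode = if (decorate) row$barcode else NULL,
      seed = NULL
    )
    # weights drawn here (not in generate_reads) so the dominance structure
    # is planted: group-private dominants get boosted weights
    n_h <- nrow(pool)
    w <- stats::rlnorm(n_h, meanlog = 0, sdlog = 1)
    w[pool$group != "shared"] <- w[pool$group != "shared"] * dominance_boost
    out <- .generate_reads_weighted(pool, spec, w)
    reads[[row$sample]] <- out$reads
    truth[[row$sample]] <- out$truth
  }
  reads <- dplyr::bind_rows(reads)
  truth <- dplyr::bind_rows(truth)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (s in unique(reads$sample)) {
      write_fastq(reads[reads$sample == s, ], file.path(dir, paste0(s, ".fastq")))
    }
    utils::write.table(truth, file.path(dir, "truth_reads.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
    utils::write.table(haps, file.path(dir, "truth_haplotypes.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
    utils::write.table(design, file.path(dir, "design.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
  }
  structure(
    list(reads = reads, truth = truth, haplotypes = haps, design = design, dir = dir),
    class = "mcp_study"
  )
}

# generate_reads with externally supplied haplotype weights
#' @keywords internal
.generate_reads_weighted <- function(haplotypes, spec, w) {
  probs <- spec$length_class_probs
  n <- spec$reads_per_sample
  cls <- sample(names(probs), n, replace = TRUE, prob = probs)
  pick <- integer(n)
  for (cl in unique(cls)) {
    idx <- which(as.character(haplotypes$class) == cl)
    if (length(idx) == 0) {
      stop("no haplotypes for class ", cl, call. = FALSE)
    }
    sel <- which(cls == cl)
    pick[sel] <- if (length(idx) == 1) {
      idx
    } else {
      sample(idx, length(sel), replace = TRUE, prob = w[idx])
    }
  }
  seqs <- haplotypes$seq[pick]
  if (spec$substitution_error_rate > 0) {
    seqs <- vapply(seqs, .mutate_read,
      character(1),
      rate = spec$substitution_error_rate, USE.NAMES = FALSE
    )
  }
  if (!is.null(spec$barcode)) seqs <- paste0(toupper(spec$barcode), seqs)
  qual <- purrr::map(nchar(seqs), function(L) {
    pmin(pmax(as.integer(round(stats::rnorm(L, spec$quality_mean, spec$quality_sd))), 2L), 41L)
  })
  ids <- sprintf("%s_read%05d", spec$sample, seq_len(n))
  list(
    reads = seq_tbl(ids, seqs, qual, sample = spec$sample),
    truth = tibble::tibble(
      id = ids,
      haplotype = haplotypes$haplotype[pick],
      class = haplotypes$class[pick],
      sample = spec$sample
    )
  )
}

#' @export
print.mcp_study <- function(x, ...) {
  cat(
    "Synthetic amplicon study:", nrow(x$reads), "reads,",
    nrow(x$haplotypes), "haplotypes,",
    nrow(x$design), "samples in",
    length(unique(x$design$group)), "groups\n"
  )
  invisible(x)
}
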