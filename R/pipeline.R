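#' Validate a pipeline configuration
#'
#' Declarative configuration for [run_pipeline()]. Input is either
#' `input_files` (named per-sample FASTQ/FASTA paths; names become sample
#' labels) or a single `multiplexed` file plus a `barcode_map`. All
#' validation happens here, before any work.
#'
#' @param out_dir Output directory (created if needed).
#' @param input_files Named character vector of demultiplexed read files.
#' @param multiplexed Path to one multiplexed FASTQ/FASTA.
#' @param barcode_map Data frame with `sample`, `barcode` columns, or path
#'   to a TSV with those columns (required with `multiplexed`).
#' @param forward,reverse Primer patterns (defaults: [mcp_primers()]).
#' @param trim_primers Remove primers during demultiplexing (default FALSE;
#'   lengths stay primer-inclusive).
#' @param quality_threshold Mean-Phred filter threshold (default 25).
#' @param frame_config A [frame_filter_config()].
#' @param thresholds OTU identity thresholds (default 0.80/0.90/0.95/0.97).
#' @param main_threshold Threshold used for the diversity stages (default
#'   0.90); must be one of `thresholds`.
#' @param rarefaction_depths Optional depths for the rarefaction table.
#' @param jackknife_reps Jackknife replicates for the sample tree (default
#'   1000).
#' @param jackknife_depth_fraction Subsampling depth as a fraction of the
#'   smallest sample total (default 0.75).
#' @param seed RNG seed for all stochastic stages (default 1).
#' @return A validated list of class `mcp_pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            input_files = NULL, multiplexed = NULL,
                            barcode_map = NULL,
                            forward = mcp_primers()[["mcp-821F"]],
                            reverse = mcp_primers()[["mcp-966R"]],
                            trim_primers = FALSE,
                            quality_threshold = 25,
                            frame_config = frame_filter_config(),
                            thresholds = c(0.80, 0.90, 0.95, 0.97),
                            main_threshold = 0.90,
                            rarefaction_depths = NULL,
                            jackknife_reps = 1000,
                            jackknife_depth_fraction = 0.75,
                            seed = 1) {
  if (any(thresholds <= 0) || any(thresholds > 1)) {
    stop("clustering thresholds must lie in (0, 1]", call. = FALSE)
  }
  if (!main_threshold %in% thresholds) {
    stop("main_threshold must be one of `thresholds`", call. = FALSE)
  }
  if (is.null(input_files) == is.null(multiplexed)) {
    stop("provide exactly one of `input_files` or `multiplexed`", call. = FALSE)
  }
  if (!is.null(input_files)) {
    if (is.null(names(input_files)) || any(!nzchar(names(input_files)))) {
      stop("`input_files` must be named by sample", call. = FALSE)
    }
    gone <- input_files[!file.exists(input_files)]
    if (length(gone)) {
      stop("input file(s) not found: ", paste(gone, collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(multiplexed)) {
    if (!file.exists(multiplexed)) {
      stop("multiplexed input not found: ", multiplexed, call. = FALSE)
    }
    if (is.null(barcode_map)) {
      stop("`barcode_map` is required with a multiplexed input", call. = FALSE)
    }
  }
  if (is.character(barcode_map)) {
    if (!file.exists(barcode_map)) {
      stop("barcode map not found: ", barcode_map, call. = FALSE)
    }
    barcode_map <- utils::read.delim(barcode_map, stringsAsFactors = FALSE)
  }
  stopifnot(inherits(frame_config, "mcp_frame_config"))
  structure(
    list(
      out_dir = out_dir, input_files = input_files, multiplexed = multiplexed,
      barcode_map = barcode_map, forward = forward, reverse = reverse,
      trim_primers = trim_primers, quality_threshold = quality_threshold,
      frame_config = frame_config, thresholds = sort(thresholds),
      main_threshold = main_threshold,
      rarefaction_depths = rarefaction_depths,
      jackknife_reps = jackknife_reps,
      jackknife_depth_fraction = jackknife_depth_fraction,
      seed = seed
    ),
    class = "mcp_pipeline_config"
  )
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Run the full amplicon diversity pipeline
#'
#' Executes, in order: read loading, quality filtering, optional
#' demultiplexing/trimming, the frame-aware length and stop-codon filter,
#' greedy OTU clustering at every configured threshold, singleton removal at
#' the main threshold, alpha diversity (exact rarefaction and Good's
#' coverage), the representative-sequence tree, weighted and unweighted
#' UniFrac, PCoA and the jackknife-supported UPGMA sample tree. Every
#' intermediate is written under `config$out_dir` and a manifest (JSON)
#' records parameters, the seed, per-stage read counts and artifact
#' checksums. A stage failure halts the run with a stage-tagged error
#' message; the manifest is still written, with a `FAILED` marker.
#'
#' @param config An [pipeline_config()].
#' @return The manifest, invisibly, as a list (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "mcp_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  manifest <- list(
    package_version = as.character(utils::packageVersion("cyanomcp")),
    seed = config$seed,
    parameters = list(
      quality_threshold = config$quality_threshold,
      canonical_length = config$frame_config$canonical_length,
      length_window = config$frame_config$length_window,
      thresholds = config$thresholds,
      main_threshold = config$main_threshold,
      jackknife_reps = config$jackknife_reps,
      jackknife_depth_fraction = config$jackknife_depth_fraction
    ),
    stages = list(),
    artifacts = character(0),
    status = "RUNNING"
  )
  finish <- function(status) {
    manifest$status <<- status
    files <- manifest$artifacts
    manifest$checksums <<- as.list(tools::md5sum(files[file.exists(files)]))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
  }
  add_artifact <- function(path) {
    manifest$artifacts <<- c(manifest$artifacts, path)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "FAILED", error = conditionMessage(e))
      finish("FAILED")
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  out <- function(...) file.path(config$out_dir, ...)

  # -- load ------------------------------------------------------------
  reads <- stage("load", {
    read_one <- function(path, sample) {
      r <- if (grepl("\\.(fa|fasta)$", path, ignore.case = TRUE)) {
        read_fasta(path)
      } else {
        read_fastq(path)
      }
      r$sample <- sample
      r
    }
    if (!is.null(config$input_files)) {
      dplyr::bind_rows(purrr::imap(config$input_files, function(p, s) read_one(p, s)))
    } else {
      read_one(config$multiplexed, NA_character_)
    }
  })
  manifest$stages$load <- list(status = "OK", n_reads = nrow(reads))

  # -- quality filter ---------------------------------------------------
  qf <- stage("quality_filter", {
    quality_filter(reads, threshold = config$quality_threshold)
  })
  manifest$stages$quality_filter <- list(
    status = "OK", n_input = qf$n_input,
    n_kept = nrow(qf$kept), n_discarded = qf$n_discarded
  )
  reads <- qf$kept

  # -- demultiplex ------------------------------------------------------
  if (!is.null(config$barcode_map)) {
    dmx <- stage("demultiplex", {
      demultiplex(reads, config$barcode_map,
        forward = config$forward, reverse = config$reverse,
        trim_primers = config$trim_primers
      )
    })
    manifest$stages$demultiplex <- list(
      status = "OK",
      counts = stats::setNames(as.list(dmx$counts$n), dmx$counts$sample)
    )
    reads <- dmx$reads[dmx$reads$sample != "undetermined", , drop = FALSE]
  }

  # -- frame filter -----------------------------------------------------
  readset <- stage("frame_filter", frame_filter(reads, config$frame_config))
  manifest$stages$frame_filter <- list(
    status = "OK", n_input = readset$n_input,
    n_kept = nrow(readset$records),
    discard_fraction = discard_fraction(readset)
  )
  stage("filter_reports", {
    add_artifact(.write_tsv(readset$discarded, out("discard_ledger.tsv")))
    add_artifact(.write_tsv(readset$length_histogram, out("length_histogram.tsv")))
    comp <- length_class_composition(readset)
    add_artifact(.write_tsv(comp, out("length_class_composition.tsv")))
    hist145 <- readset$length_histogram |>
      dplyr::group_by(.data$sample) |>
      dplyr::filter(sum(.data$n[.data$length == 145]) > 0) |>
      dplyr::ungroup()
    if (nrow(hist145) > 0) {
      add_artifact(.write_tsv(source_ratio(hist145), out("source_ratio.tsv")))
    }
    for (s in unique(readset$records$sample)) {
      add_artifact(write_fasta(
        readset$records[readset$records$sample %in% s, ],
        out(paste0("filtered_", s, ".fasta"))
      ))
    }
  })

  # -- OTU clustering ---------------------------------------------------
  tables <- stage("otu_cluster", {
    purrr::map(
      stats::setNames(config$thresholds, paste0("t", config$thresholds * 100)),
      function(th) cluster_greedy(readset$records, threshold = th)
    )
  })
  manifest$stages$otu_cluster <- list(
    status = "OK",
    otus_per_threshold = purrr::map(tables, function(t) nrow(t$representatives))
  )
  for (nm in names(tables)) {
    add_artifact(.write_tsv(tables[[nm]]$counts, out(paste0("otu_table_", nm, ".tsv"))))
    reps <- tables[[nm]]$representatives
    add_artifact(write_fasta(
      tibble::tibble(id = reps$otu, seq = reps$seq, qual = list(NULL), sample = NA),
      out(paste0("otu_reps_", nm, ".fasta"))
    ))
    add_artifact(.write_tsv(tables[[nm]]$membership, out(paste0("otu_membership_", nm, ".tsv"))))
  }
  main_name <- paste0("t", config$main_threshold * 100)
  table_main <- remove_singletons(tables[[main_name]])
  manifest$stages$singleton_removal <- list(
    status = "OK",
    otus_before = nrow(tables[[main_name]]$representatives),
    otus_after = nrow(table_main$representatives)
  )
  add_artifact(.write_tsv(table_main$counts, out("otu_table_main_nosingletons.tsv")))

  # -- alpha diversity --------------------------------------------------
  alpha <- stage("alpha_diversity", {
    rarefaction(table_main, depths = config$rarefaction_depths)
  })
  manifest$stages$alpha_diversity <- list(status = "OK")
  add_artifact(.write_tsv(alpha, out("rarefaction.tsv")))
  m <- otu_matrix(table_main)
  coverage <- tibble::tibble(
    sample = rownames(m),
    depth = rowSums(m),
    goods_coverage = apply(m, 1, goods_coverage)
  )
  add_artifact(.write_tsv(coverage, out("goods_coverage.tsv")))

  # -- tree -------------------------------------------------------------
  tree <- stage("tree", build_tree(table_main$representatives))
  manifest$stages$tree <- list(status = "OK", n_tips = length(tree$tip.label))
  ape::write.tree(tree, out("otu_tree.nwk"))
  add_artifact(out("otu_tree.nwk"))

  # -- beta diversity ---------------------------------------------------
  beta <- stage("beta_diversity", {
    du <- unifrac(table_main, tree, weighted = FALSE)
    dw <- unifrac(table_main, tree, weighted = TRUE, normalized = TRUE)
    list(
      unweighted = du, weighted = dw,
      pcoa_unweighted = pcoa(du), pcoa_weighted = pcoa(dw)
    )
  })
  manifest$stages$beta_diversity <- list(status = "OK")
  add_artifact(.write_tsv(tidy_dist(beta$unweighted), out("unifrac_unweighted.tsv")))
  add_artifact(.write_tsv(tidy_dist(beta$weighted), out("unifrac_weighted.tsv")))
  add_artifact(.write_tsv(beta$pcoa_unweighted$coordinates, out("pcoa_unweighted.tsv")))
  add_artifact(.write_tsv(beta$pcoa_weighted$coordinates, out("pcoa_weighted.tsv")))

  jack <- stage("jackknife_tree", {
    if (nrow(m) >= 3 && config$jackknife_reps >= 0) {
      sample_upgma_with_jackknife(
        table_main, tree,
        reps = config$jackknife_reps,
        depth_fraction = config$jackknife_depth_fraction,
        seed = config$seed
      )
    } else {
      NULL
    }
  })
  if (!is.null(jack)) {
    manifest$stages$jackknife_tree <- list(
      status = "OK", reps = jack$reps, depth = jack$depth
    )
    ape::write.tree(jack$tree, out("sample_tree_jackknife.nwk"))
    add_artifact(out("sample_tree_jackknife.nwk"))
    add_artifact(.write_tsv(jack$support, out("jackknife_support.tsv")))
  }

  finish("OK")
  invisible(manifest)
}
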