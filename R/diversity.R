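#' Exact or Monte Carlo rarefaction for one community
#'
#' For a vector of per-OTU counts, computes the expected number of OTUs
#' observed in a subsample of each requested depth. Exact mode uses the
#' hypergeometric closed form
#' \eqn{E[S_n] = \sum_i (1 - {N-N_i \choose n}/{N \choose n})}
#' evaluated in log-gamma arithmetic (stable at deep-sequencing scale);
#' Monte Carlo mode averages over `reps` subsamples drawn without
#' replacement. Good's coverage at each depth is reported alongside: the
#' exact expectation \eqn{E[C_n] = 1 - E[F_1]/n} with
#' \eqn{E[F_1] = \sum_i N_i {N-N_i \choose n-1}/{N \choose n}}, or the
#' Monte Carlo average of \eqn{1 - F_1/n}.
#'
#' @param counts Non-negative integer vector of per-OTU counts (one sample).
#' @param depths Subsample sizes, each between 1 and `sum(counts)`.
#' @param mode `"exact"` (default) or `"montecarlo"`.
#' @param reps Number of Monte Carlo subsamples (default 100).
#' @param seed Optional RNG seed for Monte Carlo mode.
#' @return Tibble `depth`, `observed_otus`, `goods_coverage`.
#' @examples
#' rarefaction_curve(c(2, 2), depths = 2) # E[S] = 5/3
#' @export
rarefaction_curve <- function(counts, depths, mode = c("exact", "montecarlo"),
                              reps = 100, seed = NULL) {
  mode <- match.arg(mode)
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop("community has no reads", call. = FALSE)
  N <- sum(counts)
  depths <- as.integer(depths)
  if (any(depths < 1) || any(depths > N)) {
    stop("depths must lie in [1, ", N, "] (community size)", call. = FALSE)
  }
  if (mode == "exact") {
    res <- purrr::map(depths, function(n) {
      lchoose_N_n <- lchoose(N, n)
      p_absent <- exp(lchoose(N - counts, n) - lchoose_N_n)
      e_f1 <- sum(counts * exp(lchoose(N - counts, n - 1) - lchoose_N_n))
      tibble::tibble(
        depth = n,
        observed_otus = sum(1 - p_absent),
        goods_coverage = 1 - e_f1 / n
      )
    })
    return(dplyr::bind_rows(res))
  }
  if (!is.null(seed)) set.seed(seed)
  pool <- rep(seq_along(counts), counts)
  res <- purrr::map(depths, function(n) {
    draws <- purrr::map(seq_len(reps), function(r) {
      tab <- tabulate(sample(pool, n), nbins = length(counts))
      c(sum(tab > 0), 1 - sum(tab == 1) / n)
    })
    m <- do.call(rbind, draws)
    tibble::tibble(
      depth = n,
      observed_otus = mean(m[, 1]),
      goods_coverage = mean(m[, 2])
    )
  })
  dplyr::bind_rows(res)
}

#' Rarefaction and coverage across all samples of an OTU table
#'
#' @param table An `mcp_otu_table`.
#' @param depths Depths to evaluate; per sample, depths exceeding the sample
#'   total are dropped. Default: 10 depths evenly spaced up to each sample's
#'   total.
#' @param ... Passed to [rarefaction_curve()].
#' @return Tibble `sample`, `depth`, `observed_otus`, `goods_coverage`.
#' @export
rarefaction <- function(table, depths = NULL, ...) {
  stopifnot(inherits(table, "mcp_otu_table"))
  m <- otu_matrix(table)
  out <- purrr::imap(
    stats::setNames(seq_len(nrow(m)), rownames(m)),
    function(i, nm) {
      counts <- m[i, ]
      N <- sum(counts)
      d <- if (is.null(depths)) unique(pmax(1L, round(seq(N / 10, N, length.out = 10)))) else depths[depths <= N]
      if (length(d) == 0) {
        return(NULL)
      }
      dplyr::mutate(rarefaction_curve(counts, d, ...), sample = nm, .before = 1)
    }
  )
  dplyr::bind_rows(out)
}

#' Good's coverage of a community
#'
#' \eqn{C = 1 - F_1/n}: one minus the fraction of reads in singleton OTUs —
#' an estimate of the probability that one more read would fall in an
#' already-observed OTU. At a reduced depth the coverage of the subsampled
#' community is computed (exact expectation or Monte Carlo).
#'
#' @inheritParams rarefaction_curve
#' @param depth Subsample size (default: full depth).
#' @return A single numeric coverage in `[0, 1]`.
#' @examples
#' goods_coverage(c(5, 3, 1, 1)) # 1 - 2/10 = 0.8
#' @export
goods_coverage <- function(counts, depth = sum(counts),
                           mode = c("exact", "montecarlo"),
                           reps = 100, seed = NULL) {
  if (length(depth) != 1 || depth <= 0) {
    stop("`depth` must be a positive subsample size", call. = FALSE)
  }
  rarefaction_curve(counts, depth, mode = mode, reps = reps, seed = seed)$goods_coverage
}

#' Identity-based distance tree over representative sequences
#'
#' Pairwise distances are `1 - pairwise_identity()`; the tree is built by
#' UPGMA (average-linkage, yielding a rooted ultrametric tree; the default)
#' or neighbor joining (midpoint-rooted, negative branch lengths clamped to
#' zero so the tree is usable for UniFrac).
#'
#' @param representatives Tibble with columns `otu`, `seq` (e.g.
#'   `$representatives` of an `mcp_otu_table`) or a named character vector.
#' @param method `"upgma"` (default) or `"nj"`.
#' @param end_gaps End-gap policy for [pairwise_identity()].
#' @return A rooted `ape::phylo` with branch lengths.
#' @export
build_tree <- function(representatives, method = c("upgma", "nj"),
                       end_gaps = c("penalized", "free")) {
  method <- match.arg(method)
  end_gaps <- match.arg(end_gaps)
  seqs <- as_ref_vector(
    if (is.data.frame(representatives)) {
      stats::setNames(representatives$seq, representatives$otu)
    } else {
      representatives
    }
  )
  if (length(seqs) < 2) stop("need at least 2 sequences", call. = FALSE)
  if (anyDuplicated(names(seqs))) {
    stop("duplicate sequence labels: ",
      paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
      call. = FALSE
    )
  }
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    ident <- pairwise_identity(seqs[(i + 1):n], seqs[[i]], end_gaps = end_gaps)
    D[i, (i + 1):n] <- 1 - ident
    D[(i + 1):n, i] <- 1 - ident
  }
  if (method == "upgma") {
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    tr <- ape::as.phylo(hc)
  } else {
    tr <- ape::nj(stats::as.dist(D))
    tr$edge.length <- pmax(tr$edge.length, 0)
    tr <- phangorn::midpoint(tr)
  }
  tr
}

# Precompute per-edge tip incidence, edge lengths and tip depths for a
# rooted tree; the basis for all UniFrac computations.
#' @keywords internal
tree_branch_structure <- function(tree) {
  if (!inherits(tree, "phylo")) stop("`tree` must be an ape phylo object", call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    stop("branch lengths must be finite and >= 0", call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels in tree: ",
      paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "),
      call. = FALSE
    )
  }
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- tr$Nnode
  nedge <- nrow(tr$edge)
  inc <- matrix(0, nedge, ntip)
  acc <- matrix(0, ntip + nnode, ntip)
  acc[cbind(seq_len(ntip), seq_len(ntip))] <- 1
  for (e in seq_len(nedge)) {
    child <- tr$edge[e, 2]
    inc[e, ] <- acc[child, ]
    parent <- tr$edge[e, 1]
    acc[parent, ] <- acc[parent, ] + acc[child, ]
  }
  depths <- ape::node.depth.edgelength(tr)
  list(
    inc = inc,
    edge_length = tr$edge.length,
    tip_depth = depths[seq_len(ntip)],
    tip_label = tr$tip.label
  )
}

# Pairwise UniFrac over a samples-by-tips count matrix M aligned to the
# branch structure `bs`. Returns a dist object.
#' @keywords internal
unifrac_engine <- function(M, bs, weighted = FALSE, normalized = TRUE) {
  totals <- rowSums(M)
  if (any(totals == 0)) {
    stop("sample(s) with zero reads: ",
      paste(rownames(M)[totals == 0], collapse = ", "),
      call. = FALSE
    )
  }
  A <- M %*% t(bs$inc) # samples x edges descendant counts
  P <- A / totals
  Ptip <- M / totals
  bl <- bs$edge_length
  ns <- nrow(M)
  D <- matrix(0, ns, ns, dimnames = list(rownames(M), rownames(M)))
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      if (weighted) {
        raw <- sum(bl * abs(P[i, ] - P[j, ]))
        d <- if (normalized) {
          den <- sum(bs$tip_depth * (Ptip[i, ] + Ptip[j, ]))
          if (den > 0) raw / den else 0
        } else {
          raw
        }
      } else {
        bi <- A[i, ] > 0
        bj <- A[j, ] > 0
        den <- sum(bl[bi | bj])
        d <- if (den > 0) sum(bl[xor(bi, bj)]) / den else 0
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  stats::as.dist(D)
}

#' UniFrac beta diversity between samples
#'
#' Unweighted UniFrac is the fraction of branch length unique to one of the
#' two communities, over the branch length of their union; weighted UniFrac
#' sums branch lengths weighted by the absolute difference in the subtree
#' read proportions, normalized by default to `[0, 1]` by the
#' abundance-weighted tree depth (raw, unnormalized weighted distances are
#' available with `normalized = FALSE`).
#'
#' @param table An `mcp_otu_table` (or a samples-by-OTUs count matrix whose
#'   column names are tree tip labels).
#' @param tree Rooted `phylo` whose tips cover all OTU ids in the table;
#'   OTUs missing from the tree are an error listing the offenders.
#' @param weighted Use abundance-weighted UniFrac (default FALSE).
#' @param normalized Normalize weighted UniFrac (default TRUE; ignored for
#'   unweighted).
#' @return A `dist` over samples (symmetric, zero diagonal).
#' @export
unifrac <- function(table, tree, weighted = FALSE, normalized = TRUE) {
  M <- if (inherits(table, "mcp_otu_table")) otu_matrix(table) else as.matrix(table)
  bs <- tree_branch_structure(tree)
  missing <- setdiff(colnames(M), bs$tip_label)
  if (length(missing) > 0) {
    stop("OTU(s) absent from the tree: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  full <- matrix(0, nrow(M), length(bs$tip_label),
    dimnames = list(rownames(M), bs$tip_label)
  )
  full[, colnames(M)] <- M
  unifrac_engine(full, bs, weighted = weighted, normalized = normalized)
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric scaling: the squared distance matrix is double-centered
#' and eigendecomposed; axes with positive eigenvalues are retained as
#' coordinates, ordered by decreasing eigenvalue. Negative eigenvalues (a
#' non-Euclidean distance) are reported in `$eigenvalues`, never silently
#' dropped. When the input distances are Euclidean the embedding reproduces
#' them exactly.
#'
#' @param dm A `dist` or symmetric zero-diagonal matrix.
#' @return An object of class `mcp_pcoa`: `$coordinates` (tibble `sample`,
#'   `Axis1`, `Axis2`, ...), `$eigenvalues` (all, descending),
#'   `$proportion_explained` (positive-eigenvalue axes).
#' @export
pcoa <- function(dm) {
  if (!inherits(dm, "dist")) {
    dm <- as.matrix(dm)
    if (!isSymmetric(unname(dm), tol = 1e-8)) {
      stop("distance matrix must be symmetric", call. = FALSE)
    }
    if (any(abs(diag(dm)) > 1e-12)) {
      stop("distance matrix must have a zero diagonal", call. = FALSE)
    }
    dm <- stats::as.dist(dm)
  }
  n <- attr(dm, "Size")
  labels <- attr(dm, "Labels")
  if (is.null(labels)) labels <- paste0("s", seq_len(n))
  sc <- suppressWarnings(stats::cmdscale(dm, k = n - 1, eig = TRUE))
  eig <- sort(sc$eig, decreasing = TRUE)
  pos <- which(sc$eig[seq_len(ncol(sc$points))] > 1e-10 * max(abs(sc$eig), 1e-300))
  pts <- sc$points[, pos, drop = FALSE]
  colnames(pts) <- paste0("Axis", seq_along(pos))
  coords <- tibble::as_tibble(pts)
  coords <- dplyr::mutate(coords, sample = labels, .before = 1)
  prop <- sc$eig[pos] / sum(pmax(sc$eig, 0))
  structure(
    list(
      coordinates = coords,
      eigenvalues = eig,
      proportion_explained = prop
    ),
    class = "mcp_pcoa"
  )
}

#' @export
print.mcp_pcoa <- function(x, ...) {
  cat(
    "PCoA:", nrow(x$coordinates), "samples,",
    length(x$proportion_explained), "positive axes; axis 1 explains",
    sprintf("%.1f%%\n", 100 * x$proportion_explained[1])
  )
  invisible(x)
}

#' UPGMA sample clustering with jackknife support
#'
#' Clusters samples by UPGMA on their UniFrac distances, then estimates node
#' robustness to sequencing effort: in each of `reps` jackknife replicates,
#' every sample is subsampled without replacement to a common depth, the
#' UniFrac matrix and UPGMA tree recomputed, and each internal node of the
#' full-data tree is annotated with the percentage of replicates containing
#' the same leaf bipartition.
#'
#' @param table An `mcp_otu_table` with at least 3 samples.
#' @param tree Rooted OTU `phylo` (see [build_tree()]).
#' @param reps Number of jackknife replicates (default 1000; 0 skips support).
#' @param depth_fraction Common subsampling depth as a fraction of the
#'   smallest sample total (default 0.75); overridden by `depth`.
#' @param depth Explicit common depth; must not exceed any sample's total.
#' @param seed Optional RNG seed.
#' @param weighted,normalized UniFrac options (defaults: unweighted).
#' @return Object of class `mcp_jackknife_tree`: `$tree` (sample `phylo`,
#'   node labels = support percentages when `reps > 0`), `$support`
#'   (tibble `clade`, `support`), `$distance` (full-data `dist`), `$depth`,
#'   `$reps`.
#' @export
sample_upgma_with_jackknife <- function(table, tree, reps = 1000,
                                        depth_fraction = 0.75, depth = NULL,
                                        seed = NULL, weighted = FALSE,
                                        normalized = TRUE) {
  M <- if (inherits(table, "mcp_otu_table")) otu_matrix(table) else as.matrix(table)
  if (nrow(M) < 3) stop("need at least 3 samples", call. = FALSE)
  bs <- tree_branch_structure(tree)
  missing <- setdiff(colnames(M), bs$tip_label)
  if (length(missing) > 0) {
    stop("OTU(s) absent from the tree: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  full <- matrix(0, nrow(M), length(bs$tip_label),
    dimnames = list(rownames(M), bs$tip_label)
  )
  full[, colnames(M)] <- M

  totals <- rowSums(full)
  if (is.null(depth)) depth <- floor(depth_fraction * min(totals))
  depth <- as.integer(depth)
  if (depth < 1 || depth > min(totals)) {
    stop("jackknife depth ", depth, " exceeds the smallest sample total (",
      min(totals), ")",
      call. = FALSE
    )
  }

  upgma_of <- function(d) ape::as.phylo(stats::hclust(d, method = "average"))
  d_full <- unifrac_engine(full, bs, weighted = weighted, normalized = normalized)
  phy <- upgma_of(d_full)

  clade_keys <- function(p) {
    parts <- ape::prop.part(p)
    vapply(parts, function(idx) {
      paste(sort(attr(parts, "labels")[idx]), collapse = "|")
    }, character(1))
  }
  full_keys <- clade_keys(phy)

  support <- NULL
  if (reps > 0) {
    if (!is.null(seed)) set.seed(seed)
    pools <- lapply(seq_len(nrow(full)), function(i) {
      rep(seq_len(ncol(full)), full[i, ])
    })
    tally <- stats::setNames(numeric(length(full_keys)), full_keys)
    for (r in seq_len(reps)) {
      sub <- t(vapply(pools, function(p) {
        tabulate(sample(p, depth), nbins = ncol(full))
      }, integer(ncol(full))))
      dimnames(sub) <- dimnames(full)
      d_r <- unifrac_engine(sub, bs, weighted = weighted, normalized = normalized)
      hit <- intersect(clade_keys(upgma_of(d_r)), full_keys)
      tally[hit] <- tally[hit] + 1
    }
    support <- tibble::tibble(
      clade = full_keys,
      support = 100 * unname(tally) / reps
    )
    # prop.part lists clades in internal-node number order
    phy$node.label <- sprintf("%.0f", support$support)
  }

  structure(
    list(
      tree = phy, support = support, distance = d_full,
      depth = depth, reps = reps,
      weighted = weighted, normalized = normalized
    ),
    class = "mcp_jackknife_tree"
  )
}

#' @export
print.mcp_jackknife_tree <- function(x, ...) {
  cat(
    "UPGMA sample tree (", length(x$tree$tip.label), "samples );",
    if (x$reps > 0) paste(x$reps, "jackknife replicates at depth", x$depth) else "no jackknife",
    "\n"
  )
  print(x$tree)
  invisible(x)
}
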