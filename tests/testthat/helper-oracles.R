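# Independent oracles used to validate the implementation. These deliberately
# use naive enumeration / textbook dynamic programming, not the package's own
# code paths.

# --- degenerate matching: enumerate every concrete expansion and string-search
oracle_find_sites <- function(pattern, ref) {
  codes <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T"), I = c("A", "C", "G", "T")
  )
  chars <- strsplit(pattern, "")[[1]]
  grid <- expand.grid(codes[chars], KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  expansions <- unique(apply(grid, 1, paste0, collapse = ""))
  k <- nchar(pattern)
  windows <- substring(ref, 1:(nchar(ref) - k + 1), k:nchar(ref))
  sort(which(windows %in% expansions))
}

# --- global affine-gap alignment score (gap of length l costs open + ext*l,
# end gaps charged), textbook three-state DP
oracle_nw_score <- function(a, b, match = 1, mismatch = -1, open = 2, ext = 0.5) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a)
  m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1) # gap in b (consume a)
  Y <- matrix(NEG, n + 1, m + 1) # gap in a (consume b)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(open + ext * (i - 1))
  for (j in 2:(m + 1)) Y[1, j] <- -(open + ext * (j - 1))
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (a[i - 1] == b[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext, Y[i - 1, j] - open - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext, X[i, j - 1] - open - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# --- exact rarefaction / coverage by full subset enumeration (N <= 12)
oracle_rarefy_enumerate <- function(counts, n) {
  reads <- rep(seq_along(counts), counts)
  subsets <- utils::combn(length(reads), n)
  s_vals <- apply(subsets, 2, function(ix) length(unique(reads[ix])))
  f1_vals <- apply(subsets, 2, function(ix) {
    tab <- table(reads[ix])
    sum(tab == 1)
  })
  list(
    observed = mean(s_vals),
    coverage = mean(1 - f1_vals / n)
  )
}

# --- UniFrac by per-edge descendant enumeration via phangorn::Descendants
oracle_unifrac <- function(counts, tree, weighted = FALSE, normalized = TRUE) {
  tips <- tree$tip.label
  M <- counts[, tips, drop = FALSE]
  P <- M / rowSums(M)
  ns <- nrow(M)
  D <- matrix(0, ns, ns, dimnames = list(rownames(M), rownames(M)))
  desc <- phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
  depths <- ape::node.depth.edgelength(tree)[seq_along(tips)]
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      num <- 0
      den <- 0
      for (e in seq_len(nrow(tree$edge))) {
        bl <- tree$edge.length[e]
        under <- desc[[e]]
        ci <- sum(M[i, under])
        cj <- sum(M[j, under])
        if (weighted) {
          num <- num + bl * abs(ci / sum(M[i, ]) - cj / sum(M[j, ]))
        } else {
          if (ci > 0 || cj > 0) den <- den + bl
          if (xor(ci > 0, cj > 0)) num <- num + bl
        }
      }
      if (weighted) {
        if (normalized) {
          den <- sum(depths * (P[i, ] + P[j, ]))
          D[i, j] <- D[j, i] <- if (den > 0) num / den else 0
        } else {
          D[i, j] <- D[j, i] <- num
        }
      } else {
        D[i, j] <- D[j, i] <- if (den > 0) num / den else 0
      }
    }
  }
  stats::as.dist(D)
}

# random rooted tree with non-negative branch lengths and given tip labels
random_labeled_tree <- function(labels) {
  tr <- ape::rtree(length(labels), rooted = TRUE)
  tr$tip.label <- labels
  tr$edge.length <- abs(tr$edge.length)
  tr
}

random_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i) {
    paste0(sample(c("A", "C", "G", "T"), len[i], replace = TRUE), collapse = "")
  }, character(1))
}
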