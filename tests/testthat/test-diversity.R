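test_that("exact rarefaction matches full subset enumeration on tiny communities", {
  # counts [2,2], n=2: 6 subsets, 4 give 2 OTUs, 2 give 1 -> E[S] = 5/3
  expect_equal(rarefaction_curve(c(2, 2), 2)$observed_otus, 5 / 3)
  set.seed(91)
  for (i in 1:6) {
    counts <- sample(1:4, sample(2:4, 1), replace = TRUE)
    N <- sum(counts)
    if (N > 12) next
    n <- sample(seq_len(N), 1)
    oracle <- oracle_rarefy_enumerate(counts, n)
    got <- rarefaction_curve(counts, n)
    expect_equal(got$observed_otus, oracle$observed, tolerance = 1e-12)
    expect_equal(got$goods_coverage, oracle$coverage, tolerance = 1e-12)
  }
})

test_that("rarefaction at full depth returns observed richness; deeper depths error", {
  counts <- c(5, 3, 2, 1, 1)
  expect_equal(rarefaction_curve(counts, sum(counts))$observed_otus, 5)
  expect_error(rarefaction_curve(counts, sum(counts) + 1), "depth")
})

test_that("Monte Carlo rarefaction agrees with the exact expectation", {
  counts <- c(8, 5, 3, 2, 1, 1)
  exact <- rarefaction_curve(counts, 10)$observed_otus
  reps <- 4000
  mc <- rarefaction_curve(counts, 10, mode = "montecarlo", reps = reps, seed = 93)
  # binomial-scale guard: richness per draw varies by at most the OTU count
  expect_lt(abs(mc$observed_otus - exact), 3 * 6 / sqrt(reps) + 0.05)
})

test_that("rarefaction expectation is non-decreasing and concave in depth", {
  set.seed(95)
  for (i in 1:5) {
    counts <- sample(1:40, 12, replace = TRUE)
    depths <- seq(5, sum(counts), by = 13)
    s <- rarefaction_curve(counts, depths)$observed_otus
    expect_true(all(diff(s) >= -1e-9))
    if (length(s) >= 3) expect_true(all(diff(diff(s)) <= 1e-9))
  }
})

test_that("Good's coverage closed forms hold", {
  expect_equal(goods_coverage(c(5, 3, 1, 1)), 0.8)
  expect_equal(goods_coverage(c(4, 3, 2)), 1.0)
  expect_equal(goods_coverage(c(1, 1, 1)), 0.0)
  expect_error(goods_coverage(c(2, 2), depth = 0), "positive")
})

test_that("coverage expectation increases with subsampling depth", {
  set.seed(97)
  # log-skewed community with a singleton tail
  counts <- table(sample(1:120, 2500, replace = TRUE, prob = stats::rlnorm(120, 0, 1.5)))
  cov <- vapply(c(200, 800, 1600, 2500), function(d) {
    goods_coverage(as.numeric(counts), depth = d)
  }, numeric(1))
  expect_true(all(diff(cov) > 0))
})

test_that("UPGMA joins the closest pair at half its distance and is ultrametric", {
  D <- matrix(
    c(
      0, 0.2, 0.4,
      0.2, 0, 0.4,
      0.4, 0.4, 0
    ),
    3, 3,
    dimnames = list(c("A", "B", "C"), c("A", "B", "C"))
  )
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  tr <- ape::as.phylo(hc)
  # A,B join first; on the ultrametric tree they sit at height 0.1, so
  # their tip-to-tip path is 0.2 and each path to C is 0.4
  expect_equal(hc$merge[1, ], c(-1, -2))
  d_tree <- ape::cophenetic.phylo(tr)
  expect_equal(d_tree["A", "B"], 0.2)
  expect_equal(d_tree["A", "C"], 0.4)

  # ultrametricity of build_tree's UPGMA on random sequences
  set.seed(99)
  seqs <- stats::setNames(random_dna(6, 80), paste0("t", 1:6))
  tr <- build_tree(seqs, method = "upgma")
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  # identical sequences form a zero-length cherry
  tr2 <- build_tree(c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTAAAA"))
  expect_equal(ape::cophenetic.phylo(tr2)["a", "b"], 0)
  expect_error(build_tree(c(a = "ACGT", a = "AAAA")), "duplicate")
})

test_that("UniFrac hand values on a two-leaf star are exact", {
  tree <- ape::read.tree(text = "(t1:1,t2:1);")
  M <- matrix(c(5L, 0L, 0L, 7L), 2, 2,
    byrow = TRUE,
    dimnames = list(c("S1", "S2"), c("t1", "t2"))
  )
  expect_equal(as.numeric(unifrac(M, tree, weighted = FALSE)), 1.0)
  expect_equal(as.numeric(unifrac(M, tree, weighted = TRUE, normalized = FALSE)), 2.0)
  expect_equal(as.numeric(unifrac(M, tree, weighted = TRUE, normalized = TRUE)), 1.0)
  # identical communities -> 0
  M2 <- matrix(c(3L, 4L, 3L, 4L), 2, 2,
    byrow = TRUE,
    dimnames = list(c("S1", "S2"), c("t1", "t2"))
  )
  expect_equal(as.numeric(unifrac(M2, tree)), 0)
  expect_equal(as.numeric(unifrac(M2, tree, weighted = TRUE)), 0)
})

test_that("UniFrac agrees with a branch-enumeration oracle on random instances", {
  set.seed(101)
  for (i in 1:6) {
    ntip <- sample(4:8, 1)
    tree <- random_labeled_tree(paste0("O", seq_len(ntip)))
    ns <- sample(2:4, 1)
    M <- matrix(stats::rpois(ns * ntip, 2), ns, ntip,
      dimnames = list(paste0("S", seq_len(ns)), tree$tip.label)
    )
    M[rowSums(M) == 0, 1] <- 1L
    for (w in c(FALSE, TRUE)) {
      got <- unifrac(M, tree, weighted = w, normalized = TRUE)
      exp <- oracle_unifrac(M, tree, weighted = w, normalized = TRUE)
      expect_equal(as.numeric(got), as.numeric(exp), tolerance = 1e-12)
    }
    raw <- unifrac(M, tree, weighted = TRUE, normalized = FALSE)
    raw_o <- oracle_unifrac(M, tree, weighted = TRUE, normalized = FALSE)
    expect_equal(as.numeric(raw), as.numeric(raw_o), tolerance = 1e-12)
  }
})

test_that("UniFrac matches an independent published implementation", {
  set.seed(103)
  tree <- random_labeled_tree(paste0("O", 1:6))
  M <- matrix(stats::rpois(18, 3) + 1L, 3, 6,
    dimnames = list(paste0("S", 1:3), tree$tip.label)
  )
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(M, taxa_are_rows = FALSE),
    phyloseq::phy_tree(tree)
  )
  expect_equal(
    as.numeric(unifrac(M, tree, weighted = FALSE)),
    as.numeric(phyloseq::UniFrac(ps, weighted = FALSE)),
    tolerance = 1e-8
  )
  expect_equal(
    as.numeric(unifrac(M, tree, weighted = TRUE, normalized = TRUE)),
    as.numeric(phyloseq::UniFrac(ps, weighted = TRUE, normalized = TRUE)),
    tolerance = 1e-8
  )
})

test_that("UniFrac is bounded, symmetric and invariant to OTU relabeling", {
  set.seed(105)
  tree <- random_labeled_tree(paste0("O", 1:7))
  M <- matrix(stats::rpois(21, 2) + 1L, 3, 7,
    dimnames = list(paste0("S", 1:3), tree$tip.label)
  )
  for (w in c(FALSE, TRUE)) {
    d <- as.matrix(unifrac(M, tree, weighted = w))
    expect_true(all(d >= -1e-12 & d <= 1 + 1e-12))
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
  }
  # permute OTU columns: distances unchanged
  perm <- sample(ncol(M))
  expect_equal(
    as.numeric(unifrac(M[, perm], tree)),
    as.numeric(unifrac(M, tree))
  )
  # OTU missing from the tree errors and names it
  M2 <- cbind(M, OX = 1L)
  expect_error(unifrac(M2, tree), "OX")
})

test_that("PCoA recovers planar configurations and reports negative eigenvalues", {
  set.seed(107)
  pts <- cbind(stats::runif(4, 0, 10), stats::runif(4, 0, 10))
  rownames(pts) <- paste0("P", 1:4)
  d <- stats::dist(pts)
  ord <- pcoa(d)
  rec <- as.matrix(ord$coordinates[, c("Axis1", "Axis2")])
  expect_equal(
    as.numeric(stats::dist(rec)), as.numeric(d),
    tolerance = 1e-9
  )
  expect_true(all(diff(ord$eigenvalues) <= 1e-9)) # descending
  expect_true(all(ord$proportion_explained >= 0 & ord$proportion_explained <= 1))
  expect_lte(sum(ord$proportion_explained), 1 + 1e-12)

  # coincident samples get coincident coordinates
  m <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0), 3, 3,
    dimnames = list(c("a", "b", "c"), c("a", "b", "c"))
  )
  ord2 <- pcoa(m)
  co <- ord2$coordinates
  expect_equal(
    as.numeric(co[co$sample == "a", -1]),
    as.numeric(co[co$sample == "b", -1])
  )

  # non-Euclidean distances: negative eigenvalues are present in the report
  m4 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m4[lower.tri(m4)] <- c(1, 1, 1, 1, 1, 2.9) # near-violating quadruple
  m4 <- m4 + t(m4)
  ord3 <- pcoa(m4)
  expect_lt(min(ord3$eigenvalues), 0)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("jackknife support is 100% for planted biome separation and bounded", {
  set.seed(109)
  # two groups with disjoint OTU sets over one tree
  tree <- random_labeled_tree(paste0("O", 1:10))
  M <- rbind(
    A1 = c(30, 25, 20, 15, 10, 0, 0, 0, 0, 0),
    A2 = c(25, 30, 15, 20, 10, 0, 0, 0, 0, 0),
    B1 = c(0, 0, 0, 0, 0, 30, 25, 20, 15, 10),
    B2 = c(0, 0, 0, 0, 0, 25, 30, 15, 20, 10)
  )
  colnames(M) <- tree$tip.label
  jk <- sample_upgma_with_jackknife(M, tree, reps = 60, seed = 109)
  expect_true(all(jk$support$support >= 0 & jk$support$support <= 100))
  # the A|B bipartition must appear in every replicate
  ab <- jk$support$support[jk$support$clade %in% c("A1|A2", "B1|B2")]
  expect_true(all(ab == 100))
  expect_setequal(jk$tree$tip.label, rownames(M))

  # reps = 0: no support annotations
  jk0 <- sample_upgma_with_jackknife(M, tree, reps = 0)
  expect_null(jk0$tree$node.label)
  expect_equal(nrow(tidy(jk0)), 0)

  # depth exceeding a sample total errors
  expect_error(
    sample_upgma_with_jackknife(M, tree, reps = 5, depth = 1000),
    "depth"
  )
})

test_that("PCoA on UniFrac separates planted biomes on axis 1", {
  set.seed(111)
  tree <- random_labeled_tree(paste0("O", 1:12))
  M <- rbind(
    A1 = c(30, 25, 20, 15, 2, 1, 0, 0, 0, 0, 1, 1),
    A2 = c(25, 30, 15, 20, 1, 2, 0, 0, 0, 0, 1, 1),
    A3 = c(20, 25, 30, 15, 1, 1, 0, 0, 0, 0, 2, 1),
    B1 = c(0, 0, 0, 0, 1, 1, 30, 25, 20, 15, 1, 2),
    B2 = c(0, 0, 0, 0, 2, 1, 25, 30, 15, 20, 1, 1),
    B3 = c(0, 0, 0, 0, 1, 2, 20, 25, 30, 15, 1, 1)
  )
  colnames(M) <- tree$tip.label
  ord <- pcoa(unifrac(M, tree, weighted = TRUE))
  x <- ord$coordinates$Axis1
  g <- substr(ord$coordinates$sample, 1, 1)
  # positive silhouette between groups on the first axis
  sil <- vapply(seq_along(x), function(i) {
    own <- mean(abs(x[i] - x[g == g[i]][-match(i, which(g == g[i]))]))
    other <- mean(abs(x[i] - x[g != g[i]]))
    (other - own) / max(other, own)
  }, numeric(1))
  expect_true(all(sil > 0))
})
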