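test_that("NJ solves the worked additive 4-taxon example", {
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tree <- nj_tree(D)
  expect_equal(sort(tree$tip.label), letters[1:4])
  # branch lengths a:1, b:2, c:3, d:4, internal:1, recovered exactly
  co <- ape::cophenetic.phylo(tree)[letters[1:4], letters[1:4]]
  expect_equal(co, D, tolerance = 1e-12)
  tip_edge <- function(t, lab) t$edge.length[t$edge[, 2] ==
                                               match(lab, t$tip.label)]
  expect_equal(vapply(letters[1:4], tip_edge, numeric(1), t = tree),
               c(a = 1, b = 2, c = 3, d = 4), tolerance = 1e-12)
  internal <- tree$edge.length[tree$edge[, 2] > 4]
  expect_equal(internal, 1, tolerance = 1e-12)
})

test_that("three taxa resolve by the closed three-point formulas", {
  D <- matrix(c(0, 2, 3,
                2, 0, 5,
                3, 5, 0), 3, 3, dimnames = list(c("x", "y", "z"),
                                                c("x", "y", "z")))
  tree <- nj_tree(D)
  tip_edge <- function(lab) tree$edge.length[tree$edge[, 2] ==
                                               match(lab, tree$tip.label)]
  expect_equal(tip_edge("x"), 0)   # (2 + 3 - 5) / 2
  expect_equal(tip_edge("y"), 2)
  expect_equal(tip_edge("z"), 3)
})

test_that("NJ recovers random additive trees within 1e-9", {
  withr::local_seed(31)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    t0 <- ape::rtree(n)
    t0$edge.length <- runif(nrow(t0$edge), 0.05, 1)
    D <- ape::cophenetic.phylo(t0)
    t1 <- nj_tree(D)
    expect_lt(max(abs(ape::cophenetic.phylo(t1)[rownames(D), colnames(D)] -
                        D)), 1e-9)
    # topology agrees with the independent ape implementation
    t2 <- ape::nj(D)
    expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("NJ input errors are explicit", {
  m <- matrix(c(0, NA, NA, 0), 2, 2)
  expect_error(nj_tree(matrix(0, 2, 2)), "at least 3")
  m3 <- matrix(0.1, 3, 3)
  diag(m3) <- 0
  m3[1, 2] <- NA
  expect_error(nj_tree(m3), "undefined")
})

test_that("relabeling leaves permutes the tree consistently", {
  withr::local_seed(4)
  t0 <- ape::rtree(8)
  t0$edge.length <- runif(14, 0.1, 1)
  D <- ape::cophenetic.phylo(t0)
  perm <- sample(8)
  t1 <- nj_tree(D)
  t2 <- nj_tree(D[perm, perm])
  expect_equal(ape::cophenetic.phylo(t2)[rownames(D), colnames(D)],
               ape::cophenetic.phylo(t1)[rownames(D), colnames(D)],
               tolerance = 1e-12)
})

two_clade_aln <- function() {
  base <- strrep("ACGT", 15)
  other <- paste0("GGTTGG", substr(base, 7, 60))
  make_aln(c(base, base, other, other),
           species = c("A", "A", "B", "B"),
           ids = c("a1", "a2", "b1", "b2"))
}

test_that("bootstrap support is seeded, reproducible and label-stable", {
  aln <- two_clade_aln()
  t1 <- bootstrap_support(aln, replicates = 30, seed = 5)
  t2 <- bootstrap_support(aln, replicates = 30, seed = 5)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  # same seed, permuted input rows: identical splits and supports
  t3 <- bootstrap_support(aln[c(3, 1, 4, 2), ], replicates = 30, seed = 5)
  expect_identical(ape::write.tree(t3), ape::write.tree(t1))
})

test_that("diagnostic-column clades get near-certain support", {
  aln <- two_clade_aln()
  tree <- bootstrap_support(aln, replicates = 100, seed = 2)
  sup <- suppressWarnings(as.numeric(tree$node.label))
  expect_gte(min(sup, na.rm = TRUE), 99)
})

test_that("a single replicate gives all-or-nothing support", {
  aln <- two_clade_aln()
  tree <- bootstrap_support(aln, replicates = 1, seed = 3)
  sup <- suppressWarnings(as.numeric(tree$node.label))
  expect_true(all(sup[!is.na(sup)] %in% c(0, 100)))
})

test_that("monophyly is read off tree bipartitions", {
  t1 <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  sp <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  m1 <- monophyly(t1, sp)
  expect_true(all(m1$monophyletic))

  t2 <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  m2 <- monophyly(t2, sp)
  expect_false(any(m2$monophyletic))

  # singletons are trivially monophyletic, flagged
  t3 <- ape::read.tree(text = "((a1:1,a2:1):1,c1:1,b1:1);")
  m3 <- monophyly(t3, c(a1 = "A", a2 = "A", b1 = "B", c1 = "C"))
  expect_true(all(m3$monophyletic))
  expect_equal(sum(m3$is_singleton), 2)

  expect_error(monophyly(t1, c(a1 = "A")), "absent")
})

test_that("simulated species structure is recovered as monophyly", {
  cfg <- rehmannia_simulation_config(
    n_individuals = c(R_glutinosa = 3L, R_solanifolia = 2L, R_chingii = 2L,
                      R_henryi = 2L, R_piasezkii = 2L, R_elata = 2L),
    intraspecific_scale = 0.1  # interspecific >> intraspecific divergence
  )
  sim <- simulate_dataset(cfg, seed = 12)
  aln <- sim$alignments$ITS2
  tree <- nj_tree(suppressWarnings(k2p_distances(aln)))
  mono <- monophyly(tree, aln)
  expect_true(all(mono$monophyletic))
})
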