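k2p_table <- function(ids, species, mat) {
  pairs <- combn(length(ids), 2)
  structure(
    tibble::tibble(
      sample_i = ids[pairs[1, ]], sample_j = ids[pairs[2, ]],
      species_i = species[pairs[1, ]], species_j = species[pairs[2, ]],
      d = mat[cbind(pairs[1, ], pairs[2, ])]
    ),
    class = c("k2p_dist", class(tibble::tibble())), marker = "toy"
  )
}

test_that("forced two-species case yields the six textbook values", {
  ids <- c("a1", "a2", "b1", "b2")
  sp <- c("A", "A", "B", "B")
  m <- matrix(0.05, 4, 4)
  m[1, 2] <- m[2, 1] <- 0.01
  m[3, 4] <- m[4, 3] <- 0.01
  s <- divergence_summary(k2p_table(ids, sp, m))
  means <- setNames(s$mean, s$statistic)
  expect_equal(unname(means), c(0.05, 0.05, 0.05, 0.01, 0.01, 0.01))
})

test_that("single-species input defines only the intraspecific side", {
  ids <- c("x1", "x2", "x3")
  m <- matrix(0, 3, 3)
  m[1, 2] <- 0.01; m[1, 3] <- 0.02; m[2, 3] <- 0.03
  s <- divergence_summary(k2p_table(ids, rep("X", 3), m))
  means <- setNames(s$mean, s$statistic)
  expect_true(all(is.na(means[c("all_interspecific_distance",
                                "theta_prime",
                                "minimum_interspecific_distance")])))
  expect_equal(unname(means["all_intraspecific_distance"]), 0.02)
  expect_equal(unname(means["theta"]), 0.02)
  expect_equal(unname(means["coalescent_depth"]), 0.03)
})

test_that("summary equals a naive double-loop recomputation", {
  withr::local_seed(42)
  for (i in 1:40) {
    tab <- random_k2p_table(n_samples = sample(6:10, 1))
    ids <- unique(c(tab$sample_i, tab$sample_j))
    sp <- c(tab$species_i, tab$species_j)[match(ids, c(tab$sample_i,
                                                      tab$sample_j))]
    m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    m[cbind(tab$sample_i, tab$sample_j)] <- tab$d
    m[cbind(tab$sample_j, tab$sample_i)] <- tab$d
    want <- divergence_oracle(m, sp)
    s <- divergence_summary(structure(tab,
                                      class = c("k2p_dist",
                                                class(tibble::tibble()))))
    means <- setNames(s$mean, s$statistic)
    expect_equal(unname(means["all_interspecific_distance"]),
                 want$all_inter)
    expect_equal(unname(means["theta_prime"]), want$theta_prime)
    expect_equal(unname(means["minimum_interspecific_distance"]),
                 want$min_inter)
    expect_equal(unname(means["all_intraspecific_distance"]),
                 want$all_intra)
    expect_equal(unname(means["theta"]), want$theta)
    expect_equal(unname(means["coalescent_depth"]), want$depth)
    # internal consistency
    expect_lte(means["minimum_interspecific_distance"],
               means["theta_prime"] + 1e-12)
    expect_lte(means["theta"], means["coalescent_depth"] + 1e-12)
  }
})

test_that("scaling distances by c > 0 scales all six statistics by c", {
  withr::local_seed(8)
  tab <- random_k2p_table(10, 3)
  s1 <- divergence_summary(tab)
  tab2 <- tab
  tab2$d <- tab2$d * 3.5
  s2 <- divergence_summary(tab2)
  expect_equal(s2$mean, s1$mean * 3.5)
  # and leaves Wilcoxon p-values unchanged
  p1 <- wilcoxon_signed_rank(tab$d, rev(tab$d))$p_value
  p2 <- wilcoxon_signed_rank(tab$d * 3.5, rev(tab$d) * 3.5)$p_value
  expect_equal(p1, p2)
})

test_that("wilcoxon signed-rank matches hand examples", {
  r <- wilcoxon_signed_rank(c(1, 2, 3))
  expect_equal(r$statistic, 6)
  expect_equal(r$p_value, 0.25)
  expect_equal(r$method, "exact")

  # symmetric differences: p = 1
  expect_equal(wilcoxon_signed_rank(c(1, -1))$p_value, 1)

  # zero differences are dropped
  expect_equal(wilcoxon_signed_rank(c(0, 0, 1, 2, 3))$n, 3)
  expect_error(wilcoxon_signed_rank(c(0, 0)), "no non-zero")
})

test_that("exact p equals full sign enumeration (with ties)", {
  withr::local_seed(99)
  for (i in 1:60) {
    n <- sample(2:12, 1)
    d <- round(runif(n, -1, 1), 1)  # rounding induces ties and zeros
    d <- d[d != 0]
    if (length(d) == 0) next
    expect_equal(wilcoxon_signed_rank(d)$p_value, wilcoxon_enum_p(d),
                 tolerance = 1e-12)
  }
})

test_that("exact p agrees with stats::wilcox.test when tie-free", {
  withr::local_seed(13)
  for (i in 1:15) {
    d <- runif(sample(5:20, 1), -1, 1)
    got <- wilcoxon_signed_rank(d)
    ref <- wilcox.test(d, exact = TRUE)
    expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("exact and normal approximation agree near the size boundary", {
  withr::local_seed(77)
  for (i in 1:10) {
    d <- rnorm(25, mean = 0.3)
    exact <- wilcoxon_signed_rank(d, exact_limit = 25)
    approx <- wilcoxon_signed_rank(d, exact_limit = 10)
    expect_equal(approx$method, "normal_approximation")
    expect_lt(abs(exact$p_value - approx$p_value), 0.01)
  }
})

test_that("marker comparison pairs distances on shared sample pairs", {
  aln1 <- make_aln(c("ACGTACGTAC", "ACGAACGTAC", "TCGTACGGAC", "ACGTACTTAC"),
                   species = c("A", "A", "B", "B"), marker = "m1")
  aln2 <- make_aln(c("ACGTACGTAC", "ACGTACGTAC", "GGGTACGTAC", "ACCTACGTTT"),
                   species = c("A", "A", "B", "B"), marker = "m2")
  r <- compare_marker_divergence(k2p_distances(aln1), k2p_distances(aln2))
  expect_s3_class(r, "signed_rank_test")
  expect_equal(r$marker_a, "m1")
  expect_equal(r$n, 4)  # 4 interspecific pairs, none dropped
  td <- tidy(r)
  expect_named(td, c("marker_a", "marker_b", "statistic", "n", "p_value",
                     "method"))
})

test_that("rank_markers orders by interspecific mean, stable on ties", {
  mk <- function(name, inter) {
    structure(
      tibble::tibble(statistic = "all_interspecific_distance",
                     scope = "interspecific", mean = inter, sd = 0, se = 0,
                     n = 1L),
      class = c("divergence_summary", class(tibble::tibble())),
      marker = name
    )
  }
  r <- rank_markers(list(mk("slow", 0.001), mk("fast", 0.027)))
  expect_equal(r$marker, c("fast", "slow"))
  r2 <- rank_markers(list(mk("first", 0.01), mk("second", 0.01)))
  expect_equal(r2$marker, c("first", "second"))
})
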