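small_cfg <- function(n_columns = 500L, rate = 1, kappa = 2,
                      intraspecific_scale = 0.2, indel_rate = 0,
                      n_per_species = 3L, gc_target = 50) {
  simulation_config(
    species_tree = "(spA:0.025,spB:0.025);",
    n_individuals = c(spA = n_per_species, spB = n_per_species),
    markers = tibble::tibble(
      name = "mk", n_columns = n_columns, rate_multiplier = rate,
      kappa = kappa, gc_target = gc_target, indel_rate = indel_rate
    ),
    intraspecific_scale = intraspecific_scale
  )
}

test_that("configuration validation rejects broken inputs", {
  expect_error(simulation_config("not a tree", c(a = 2),
                                 rehmannia_markers()), "Newick")
  expect_error(
    simulation_config("(a:1,b:1);", c(a = 2, wrong = 2),
                      rehmannia_markers()),
    "tip labels"
  )
  mk <- rehmannia_markers()
  mk$kappa[1] <- -1
  expect_error(simulation_config("(a:1,b:1);", c(a = 2, b = 2), mk))
})

test_that("rate zero collapses everything to identical sequences", {
  sim <- simulate_dataset(small_cfg(rate = 0), seed = 4)
  aln <- sim$alignments$mk
  expect_equal(length(unique(aln$residues)), 1)
  expect_equal(classify_sites(aln)$counts$variable_sites, 0)
  d <- k2p_distances(aln)
  expect_true(all(d$d == 0))
})

test_that("simulation is reproducible from its seed", {
  s1 <- simulate_dataset(small_cfg(), seed = 9)
  s2 <- simulate_dataset(small_cfg(), seed = 9)
  s3 <- simulate_dataset(small_cfg(), seed = 10)
  expect_identical(s1$alignments$mk$residues, s2$alignments$mk$residues)
  expect_false(identical(s1$alignments$mk$residues,
                         s3$alignments$mk$residues))
})

test_that("root composition tracks the GC target", {
  cfg <- small_cfg(n_columns = 5000L, rate = 0, gc_target = 65)
  sim <- simulate_dataset(cfg, seed = 2)
  gc <- gc_content(sim$alignments$mk$residues[1])
  expect_lt(abs(gc - 65), 3)  # binomial noise at 5000 columns
})

test_that("transition bias follows kappa at small distances", {
  cfg <- small_cfg(n_columns = 20000L, kappa = 5, intraspecific_scale = 0)
  sim <- simulate_dataset(cfg, seed = 6)
  aln <- sim$alignments$mk
  d <- k2p_distances(aln)
  inter <- d[d$species_i != d$species_j, ]
  # expected count ratio ts:tv = kappa:2 = 5:2 at first order
  ratio <- sum(inter$P * inter$n) / sum(inter$Q * inter$n)
  expect_lt(abs(ratio - 2.5), 0.4)
})

test_that("indels produce whole-column gaps at about the configured rate", {
  cfg <- small_cfg(n_columns = 2000L, indel_rate = 0.05)
  sim <- simulate_dataset(cfg, seed = 3)
  cl <- classify_sites(sim$alignments$mk)$counts
  gap_frac <- cl$gap_containing_sites / cl$alignment_length
  expect_gt(gap_frac, 0.02)
  expect_lt(gap_frac, 0.09)
  # gap columns affect a strict subset of sequences
  m <- aln_matrix(sim$alignments$mk)
  gap_cols <- which(apply(m == "-", 2, any))
  expect_true(all(colSums(m[, gap_cols, drop = FALSE] == "-") < nrow(m)))
})

test_that("K2P estimates are nearly unbiased for the generating divergence", {
  cfg <- small_cfg(n_columns = 5000L, intraspecific_scale = 0)
  ds <- vapply(1:50, function(s) {
    sim <- simulate_dataset(cfg, seed = s)
    d <- k2p_distances(sim$alignments$mk)
    mean(d$d[d$species_i != d$species_j])
  }, numeric(1))
  expect_lt(abs(mean(ds) - 0.05) / 0.05, 0.02)
})

test_that("the truth table encodes branch-sum expectations", {
  cfg <- small_cfg(intraspecific_scale = 0.2)
  sim <- simulate_dataset(cfg, seed = 1)
  tr <- sim$truth$markers
  # inter: 0.05 species path + 2 * 0.2 * 0.025 individual branches
  expect_equal(tr$expected_interspecific, 0.06)
  expect_equal(tr$expected_intraspecific, 0.01)
  expect_true(tr$gap_expected)
  expect_true(all(sim$truth$monophyly$monophyletic))
})

test_that("well-separated species yield a gap; equal scales do not", {
  gap_hits <- vapply(1:10, function(s) {
    sim <- simulate_dataset(small_cfg(n_columns = 1000L,
                                      n_per_species = 5L), seed = s)
    gap_profile(k2p_distances(sim$alignments$mk))$gap_present
  }, logical(1))
  expect_gte(sum(gap_hits), 9)

  # intraspecific divergence ~ interspecific: gap mostly absent
  flat <- simulation_config(
    species_tree = "(spA:0.001,spB:0.001);",
    n_individuals = c(spA = 5L, spB = 5L),
    markers = tibble::tibble(name = "mk", n_columns = 1000L,
                             rate_multiplier = 1, kappa = 2,
                             gc_target = 50, indel_rate = 0),
    intraspecific_scale = 10
  )
  flat_hits <- vapply(1:10, function(s) {
    gap_profile(
      k2p_distances(simulate_dataset(flat, seed = s)$alignments$mk)
    )$gap_present
  }, logical(1))
  expect_lte(sum(flat_hits), 5)
})

test_that("NJ recovers the species partition at high divergence ratios", {
  # interspecific >= ~10x intraspecific and enough informative columns:
  # the fast markers of the planted design, concatenated, at a reduced
  # within-species scale
  mk <- rehmannia_markers()
  mk$rate_multiplier <- c(3.6, 1.65, 0.75, 0.27, 0.09)
  cfg <- simulation_config(
    rehmannia_species_tree(),
    setNames(rep(2L, 6), c("R_glutinosa", "R_solanifolia", "R_chingii",
                           "R_henryi", "R_piasezkii", "R_elata")),
    mk, intraspecific_scale = 0.1
  )
  hits <- vapply(1:10, function(s) {
    sim <- simulate_dataset(cfg, seed = s)
    aln <- suppressMessages(
      concatenate_markers(sim$alignments$ITS2,
                          sim$alignments[["psbA-trnH"]])
    )
    tree <- nj_tree(suppressWarnings(k2p_distances(aln)))
    all(monophyly(tree, aln)$monophyletic)
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("simulated datasets round-trip through files", {
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(small_cfg(n_columns = 100L), seed = 5)
  paths <- write_simulated_dataset(sim, dir)
  expect_true(file.exists(paths$mk))
  back <- read_marker_alignment(paths$mk, file.path(dir, "metadata.tsv"),
                                "mk")
  expect_equal(back$residues, sim$alignments$mk$residues)
  expect_equal(back$species, sim$alignments$mk$species)
})
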