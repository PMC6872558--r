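#' Simulation configuration for multi-marker barcode datasets
#'
#' Describes a synthetic study: a species tree with branch lengths in
#' expected substitutions/site (the "reference-marker" scale), the number
#' of individuals sampled per species, and one row per marker giving its
#' alignment length, rate multiplier relative to the species tree, its
#' transition/transversion rate ratio kappa, the target GC composition of
#' the root sequence, and a per-column gap (indel) probability.
#'
#' Within a species, individuals radiate independently from the species'
#' tip sequence (a star), each along a branch of length
#' `intraspecific_scale` times that species' terminal branch.  The expected
#' divergence between two conspecific individuals is therefore twice that
#' product (times the marker's rate multiplier).
#'
#' @param species_tree Newick string with branch lengths.
#' @param n_individuals Named integer vector: individuals per species.
#'   Names must match the tree's tip labels.
#' @param markers Data frame with columns `name`, `n_columns`,
#'   `rate_multiplier`, `kappa`, `gc_target`, `indel_rate`.
#' @param intraspecific_scale Individual branch length as a fraction of the
#'   species' terminal branch.
#' @return An object of class `simulation_config`.
#' @seealso [simulate_dataset()], [rehmannia_simulation_config()]
#' @export
simulation_config <- function(species_tree, n_individuals, markers,
                              intraspecific_scale = 0.25) {
  phy <- tryCatch(suppressWarnings(ape::read.tree(text = species_tree)),
                  error = function(e) NULL)
  if (is.null(phy) || is.null(phy$edge.length)) {
    abort("species_tree must be parseable Newick with branch lengths")
  }
  if (is.null(names(n_individuals)) ||
      !setequal(names(n_individuals), phy$tip.label)) {
    abort("n_individuals must be named by the species tree's tip labels")
  }
  if (any(n_individuals < 1)) {
    abort("each species needs at least 1 individual")
  }
  markers <- as_tibble(markers)
  needed <- c("name", "n_columns", "rate_multiplier", "kappa", "gc_target",
              "indel_rate")
  missing_cols <- setdiff(needed, names(markers))
  if (length(missing_cols) > 0) {
    abort(paste0("markers is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  stopifnot(
    all(markers$n_columns >= 1),
    all(markers$rate_multiplier >= 0),
    all(markers$kappa > 0),
    all(markers$gc_target > 0 & markers$gc_target < 100),
    all(markers$indel_rate >= 0 & markers$indel_rate < 1),
    intraspecific_scale >= 0
  )
  structure(
    list(
      species_tree = species_tree,
      phylo = phy,
      n_individuals = n_individuals[phy$tip.label],
      markers = markers,
      intraspecific_scale = intraspecific_scale
    ),
    class = "simulation_config"
  )
}

#' Marker profiles and species tree emulating a small plant genus survey
#'
#' `rehmannia_markers()` returns five marker profiles shaped like the
#' classic candidate plant barcodes: a short, fast, GC-rich nuclear spacer
#' (ITS2), its longer parent region (ITS), a fast AT-rich intergenic
#' spacer with indels (psbA-trnH), and two long, slow coding plastid
#' regions (matK, rbcL).  Alignment lengths and GC targets follow the
#' ranges typical for these loci in a single genus; rate multipliers are
#' spaced so the five markers' interspecific divergences are
#' distinguishable at those alignment lengths, in the order
#' ITS2 > ITS > psbA-trnH > matK > rbcL.
#'
#' `rehmannia_species_tree()` is a six-species tree whose pairwise paths,
#' on the reference (ITS2) scale, give mean interspecific distances of a
#' few percent -- the magnitude seen in congeneric barcode surveys.
#'
#' @return A tibble (`rehmannia_markers`), a Newick string
#'   (`rehmannia_species_tree`), or a [simulation_config()]
#'   (`rehmannia_simulation_config`).
#' @export
rehmannia_markers <- function() {
  tibble(
    name = c("ITS2", "ITS", "psbA-trnH", "matK", "rbcL"),
    n_columns = c(225L, 610L, 497L, 1560L, 1287L),
    rate_multiplier = c(1.0, 0.55, 0.28, 0.10, 0.03),
    kappa = c(4, 4, 2, 2, 2),
    gc_target = c(65, 61, 27, 33.4, 43.5),
    indel_rate = c(0, 0, 0.02, 0.015, 0)
  )
}

#' @rdname rehmannia_markers
#' @export
rehmannia_species_tree <- function() {
  paste0(
    "((R_glutinosa:0.010,R_solanifolia:0.008):0.006,",
    "((R_chingii:0.008,R_henryi:0.008):0.004,",
    "(R_piasezkii:0.007,R_elata:0.007):0.005):0.003);"
  )
}

#' @rdname rehmannia_markers
#' @param n_individuals Named integer vector of individuals per species;
#'   the default samples one species densely (as with a cultivated focal
#'   species) and the others sparsely.
#' @param intraspecific_scale See [simulation_config()].
#' @export
rehmannia_simulation_config <- function(
    n_individuals = c(R_glutinosa = 20L, R_solanifolia = 2L,
                      R_chingii = 3L, R_henryi = 2L,
                      R_piasezkii = 2L, R_elata = 2L),
    intraspecific_scale = 0.25) {
  simulation_config(
    species_tree = rehmannia_species_tree(),
    n_individuals = n_individuals,
    markers = rehmannia_markers(),
    intraspecific_scale = intraspecific_scale
  )
}

#' @rdname rehmannia_markers
#' @details `ranking_experiment_config()` is the planted-truth design used
#'   to validate marker ranking: the same five marker profiles, but with
#'   rate multipliers spaced so that every adjacent pair of markers is
#'   separated by roughly three standard errors of the mean-interspecific-
#'   distance estimator at these alignment lengths, and balanced sampling
#'   (4 individuals in each of the 6 species) so no single species
#'   dominates the pair average.  At the much smaller divergences typical
#'   of slow plastid markers in a single genus the full ranking is *not*
#'   reliably recoverable from one dataset of this size -- the per-column
#'   substitution noise exceeds the between-marker separation -- which is
#'   why the planted design uses wider spacing.
#' @export
ranking_experiment_config <- function() {
  mk <- rehmannia_markers()
  mk$rate_multiplier <- c(3.6, 1.65, 0.75, 0.27, 0.09)
  simulation_config(
    species_tree = rehmannia_species_tree(),
    n_individuals = c(R_glutinosa = 4L, R_solanifolia = 4L,
                      R_chingii = 4L, R_henryi = 4L,
                      R_piasezkii = 4L, R_elata = 4L),
    markers = mk,
    intraspecific_scale = 0.25
  )
}

# K2P per-site substitution probabilities after branch length t (expected
# substitutions/site), transition:transversion rate ratio kappa.  With the
# rate matrix normalized so alpha + 2 beta = 1:
#   P(transition)        = 1/4 + 1/4 e^{-4 beta t} - 1/2 e^{-2(alpha+beta)t}
#   P(each transversion) = 1/4 - 1/4 e^{-4 beta t}
k2p_site_probs <- function(t, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (alpha + beta) * t)
  p_ts <- 1 / 4 + e1 / 4 - e2 / 2
  p_tv <- 1 / 4 - e1 / 4
  c(same = 1 - p_ts - 2 * p_tv, ts = p_ts, tv = p_tv)
}

# Evolve integer-coded sequences (1=A, 2=C, 3=G, 4=T) along one branch.
evolve_branch <- function(seq, t, kappa) {
  if (t <= 0) return(seq)
  pr <- k2p_site_probs(t, kappa)
  # outcome per site: 0 same, 1 transition, 2/3 the two transversions
  u <- sample.int(4, length(seq), replace = TRUE,
                  prob = c(pr["same"], pr["ts"], pr["tv"], pr["tv"]))
  ts_partner <- c(3L, 4L, 1L, 2L)        # A<->G, C<->T
  tv1 <- c(2L, 1L, 2L, 1L)               # A->C, C->A, G->C, T->A
  tv2 <- c(4L, 3L, 4L, 3L)               # A->T, C->G, G->T, T->G
  out <- seq
  out[u == 2] <- ts_partner[seq[u == 2]]
  out[u == 3] <- tv1[seq[u == 3]]
  out[u == 4] <- tv2[seq[u == 4]]
  out
}

#' Simulate a multi-marker, species-labelled barcode dataset
#'
#' Draws a root sequence per marker with stationary composition matching
#' the marker's GC target, evolves it down the species tree under a
#' two-rate (transition/transversion) Markov substitution process scaled by
#' the marker's rate multiplier, radiates the configured number of
#' individuals from each species tip, and finally turns a random subset of
#' sequences to gaps in an `indel_rate` fraction of columns.  Everything is
#' reproducible from `seed`.
#'
#' The returned truth table records, per marker, the expected inter- and
#' intraspecific K2P divergence implied by the branch lengths (averaged
#' over sample pairs), and whether a barcoding gap is expected (smallest
#' expected interspecific divergence more than three times the largest
#' expected intraspecific divergence).
#'
#' @param cfg A [simulation_config()].
#' @param seed Integer seed.
#' @return A list of class `barcode_simulation` with elements `alignments`
#'   (named list of [marker_alignment()]), `metadata` (tibble), `truth`
#'   (list: `markers` tibble, `species_tree`, `monophyly` tibble), `config`
#'   and `seed`.
#' @export
simulate_dataset <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "simulation_config"))
  phy <- cfg$phylo
  n_tip <- length(phy$tip.label)
  terminal <- terminal_branch_lengths(phy)
  ids <- unlist(lapply(phy$tip.label, function(sp) {
    sprintf("%s_%02d", sp, seq_len(cfg$n_individuals[[sp]]))
  }))
  species_of <- rep(phy$tip.label, cfg$n_individuals[phy$tip.label])
  metadata <- tibble(sample_id = ids, species = species_of,
                     origin = "simulated")

  alignments <- withr::with_seed(seed, {
    setNames(lapply(seq_len(nrow(cfg$markers)), function(mi) {
      mk <- cfg$markers[mi, ]
      simulate_marker(cfg, phy, terminal, metadata, mk)
    }), cfg$markers$name)
  })

  truth <- simulation_truth(cfg, phy, terminal, metadata)
  structure(
    list(alignments = alignments, metadata = metadata, truth = truth,
         config = cfg, seed = seed),
    class = "barcode_simulation"
  )
}

simulate_marker <- function(cfg, phy, terminal, metadata, mk) {
  L <- mk$n_columns
  gc <- mk$gc_target / 100
  freqs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  root_seq <- sample.int(4, L, replace = TRUE, prob = freqs)
  # preorder traversal: parents are assigned before children
  phy2 <- ape::reorder.phylo(phy, "cladewise")
  node_seq <- vector("list", max(phy2$edge))
  root <- length(phy2$tip.label) + 1
  node_seq[[root]] <- root_seq
  for (e in seq_len(nrow(phy2$edge))) {
    parent <- phy2$edge[e, 1]
    child <- phy2$edge[e, 2]
    t <- phy2$edge.length[e] * mk$rate_multiplier
    node_seq[[child]] <- evolve_branch(node_seq[[parent]], t, mk$kappa)
  }
  seqs <- matrix(0L, nrow(metadata), L)
  for (k in seq_len(nrow(metadata))) {
    sp <- metadata$species[k]
    tip <- match(sp, phy2$tip.label)
    t_ind <- cfg$intraspecific_scale * terminal[[sp]] * mk$rate_multiplier
    seqs[k, ] <- evolve_branch(node_seq[[tip]], t_ind, mk$kappa)
  }
  chars <- matrix(.BASES[seqs], nrow(metadata), L)
  if (mk$indel_rate > 0) {
    gap_cols <- which(runif(L) < mk$indel_rate)
    for (col in gap_cols) {
      k <- sample.int(nrow(metadata) - 1, 1)
      rows <- sample.int(nrow(metadata), k)
      chars[rows, col] <- .GAP
    }
  }
  marker_alignment(
    sample_id = metadata$sample_id,
    species = metadata$species,
    residues = apply(chars, 1, paste, collapse = ""),
    marker = mk$name,
    origin = metadata$origin
  )
}

terminal_branch_lengths <- function(phy) {
  n_tip <- length(phy$tip.label)
  tip_edges <- match(seq_len(n_tip), phy$edge[, 2])
  setNames(phy$edge.length[tip_edges], phy$tip.label)
}

simulation_truth <- function(cfg, phy, terminal, metadata) {
  sp_dist <- ape::cophenetic.phylo(phy)
  n_ind <- cfg$n_individuals
  species <- phy$tip.label
  sc <- cfg$intraspecific_scale

  marker_truth <- purrr::map_dfr(seq_len(nrow(cfg$markers)), function(mi) {
    mk <- cfg$markers[mi, ]
    rate <- mk$rate_multiplier
    inter_sum <- 0
    inter_n <- 0
    inter_min <- Inf
    for (i in seq_along(species)) {
      for (j in seq_along(species)) {
        if (i >= j) next
        e <- rate * (sp_dist[species[i], species[j]] +
                       sc * terminal[[species[i]]] +
                       sc * terminal[[species[j]]])
        w <- n_ind[[species[i]]] * n_ind[[species[j]]]
        inter_sum <- inter_sum + e * w
        inter_n <- inter_n + w
        inter_min <- min(inter_min, e)
      }
    }
    intra_e <- 2 * sc * unlist(terminal[species]) * rate
    intra_w <- vapply(species, function(s) {
      choose(n_ind[[s]], 2)
    }, numeric(1))
    has_intra <- intra_w > 0
    expected_intra <- if (any(has_intra)) {
      sum(intra_e[has_intra] * intra_w[has_intra]) / sum(intra_w[has_intra])
    } else {
      NA_real_
    }
    max_intra <- if (any(has_intra)) max(intra_e[has_intra]) else 0
    tibble(
      marker = mk$name,
      expected_interspecific = inter_sum / inter_n,
      expected_intraspecific = expected_intra,
      min_expected_interspecific = inter_min,
      gap_expected = inter_min > 3 * max_intra
    )
  })

  list(
    markers = marker_truth,
    species_tree = cfg$species_tree,
    monophyly = tibble(species = species, monophyletic = TRUE)
  )
}

#' Write a simulated dataset to FASTA + TSV files
#'
#' @param sim A `barcode_simulation` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named list of written FASTA paths, invisibly; also writes
#'   `metadata.tsv` and `truth.tsv`.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- dplyr::bind_rows(lapply(names(sim$alignments), function(mk) {
    dplyr::mutate(
      dplyr::select(as_tibble(sim$metadata), "sample_id", "species",
                    "origin"),
      marker = mk, .after = "species"
    )
  }))
  readr::write_tsv(meta, file.path(dir, "metadata.tsv"))
  readr::write_tsv(sim$truth$markers, file.path(dir, "truth.tsv"))
  paths <- lapply(names(sim$alignments), function(mk) {
    safe <- gsub("[^A-Za-z0-9_+-]", "_", mk)
    path <- file.path(dir, paste0(safe, ".fasta"))
    write_marker_alignment(sim$alignments[[mk]], path)
    path
  })
  invisible(setNames(paths, names(sim$alignments)))
}
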