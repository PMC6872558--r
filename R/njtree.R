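#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining: repeatedly join the pair of
#' clusters minimizing the Q criterion
#' `Q(i, j) = (r - 2) d(i, j) - R(i) - R(j)`
#' (with `R` the row sums over the `r` active clusters), compute the two
#' branch lengths from the rate-corrected formulas, and replace the pair by
#' a new node with reduced distances.  Two choices make the result
#' deterministic for any input order: Q ties are broken by the
#' lexicographically smallest pair of cluster labels (a cluster is labelled
#' by its smallest leaf), and negative branch lengths are clamped to zero
#' with the deficit moved to the sibling branch (the number of clamped
#' branches is recorded in the `"n_clamped"` attribute).
#'
#' @param x A `k2p_dist` tibble from [k2p_distances()], a symmetric numeric
#'   matrix with dimnames, or a [stats::dist] object.
#' @return An unrooted `ape::phylo` tree with branch lengths in the input's
#'   units.
#' @examples
#' m <- matrix(c(0, 3, 5, 6,
#'               3, 0, 6, 7,
#'               5, 6, 0, 7,
#'               6, 7, 7, 0), 4, 4,
#'             dimnames = list(letters[1:4], letters[1:4]))
#' nj_tree(m)
#' @export
nj_tree <- function(x) {
  D <- dist_input_matrix(x)
  if (anyNA(D)) {
    abort(paste0(
      "distance matrix contains undefined entries; exclude or impute the ",
      "affected samples upstream before tree building"
    ))
  }
  labels <- rownames(D)
  n <- length(labels)
  if (n < 3) {
    abort("neighbor joining needs at least 3 samples")
  }
  # Each active cluster carries a newick fragment and its smallest leaf
  # label (the tie-break key).
  frag <- labels
  key <- labels
  n_clamped <- 0
  fmt <- function(v) sprintf("%.15g", v + 0)  # + 0 normalizes -0

  while (nrow(D) > 3) {
    r <- nrow(D)
    R <- rowSums(D)
    Qm <- (r - 2) * D - outer(R, R, "+")
    diag(Qm) <- Inf
    qmin <- min(Qm)
    cand <- which(Qm - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    kk <- paste(pmin(key[cand[, 1]], key[cand[, 2]]),
                pmax(key[cand[, 1]], key[cand[, 2]]), sep = "\r")
    pick <- cand[order(kk)[1], ]
    i <- pick[1]
    j <- pick[2]
    vi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    vj <- D[i, j] - vi
    if (vi < 0) {
      vj <- vj + vi
      vi <- 0
      n_clamped <- n_clamped + 1
    } else if (vj < 0) {
      vi <- vi + vj
      vj <- 0
      n_clamped <- n_clamped + 1
    }
    new_frag <- paste0("(", frag[i], ":", fmt(vi), ",",
                       frag[j], ":", fmt(vj), ")")
    new_key <- min(key[i], key[j])
    d_new <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], d_new[keep]),
               c(d_new[keep], 0))
    frag <- c(frag[keep], new_frag)
    key <- c(key[keep], new_key)
  }
  # Final three clusters joined at the unrooted trifurcation.
  va <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  vb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  vc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  for (v in c(va, vb, vc)) if (v < 0) n_clamped <- n_clamped + 1
  va <- max(va, 0)
  vb <- max(vb, 0)
  vc <- max(vc, 0)
  ord <- order(key[1:3])
  parts <- paste0(frag, ":", fmt(c(va, vb, vc)))[ord]
  newick <- paste0("(", paste(parts, collapse = ","), ");")
  tree <- ape::read.tree(text = newick)
  attr(tree, "n_clamped") <- n_clamped
  tree
}

dist_input_matrix <- function(x) {
  if (inherits(x, "k2p_dist") ||
      (is.data.frame(x) && all(c("sample_i", "sample_j", "d") %in% names(x)))) {
    return(as_dist_matrix(x))
  }
  if (inherits(x, "dist")) {
    return(as.matrix(x))
  }
  if (is.matrix(x)) {
    if (is.null(rownames(x))) {
      rownames(x) <- colnames(x) <- paste0("t", seq_len(nrow(x)))
    }
    return(x)
  }
  abort("cannot interpret input as a distance matrix")
}

# Canonical keys for the non-trivial bipartitions of a tree: each split is
# represented by the side that does NOT contain the alphabetically first
# tip, as a sorted comma-joined label string.
tree_split_keys <- function(tree) {
  tips <- tree$tip.label
  ref <- min(tips)
  pp <- ape::prop.part(tree)
  keys <- vapply(pp, function(part) {
    side <- tips[part]
    if (ref %in% side) side <- setdiff(tips, side)
    paste(sort(side), collapse = ",")
  }, character(1))
  # node numbers corresponding to each part (root first, per prop.part)
  names(keys) <- seq_along(keys) + length(tips)
  keys
}

#' Column-bootstrap support for the NJ tree of an alignment
#'
#' Builds the NJ tree of the alignment's K2P distances, then resamples
#' alignment columns with replacement `replicates` times, recomputes
#' distances and NJ per replicate, and attaches to each internal edge of
#' the original tree the percentage of replicate trees containing the same
#' bipartition (Felsenstein-style support on the original topology).
#'
#' Replicates whose resampled distance matrix has undefined (saturated or
#' no-overlap) entries are dropped and counted; if more than `max_dropped`
#' of replicates are dropped the run aborts, since the remaining supports
#' would not be trustworthy.  Support percentages use the number of
#' retained replicates as denominator.
#'
#' @param aln A [marker_alignment()].
#' @param replicates Number of bootstrap replicates (1000 is customary).
#' @param seed Integer seed; the run is fully reproducible from it.
#' @param deletion Passed to [k2p_distances()].
#' @param max_dropped Maximum tolerated fraction of dropped replicates.
#' @return The original NJ tree with `node.label` set to support
#'   percentages (root label empty) and attributes `replicates`,
#'   `n_dropped`.
#' @export
bootstrap_support <- function(aln, replicates = 1000, seed = 1,
                              deletion = c("pairwise", "complete"),
                              max_dropped = 0.1) {
  deletion <- match.arg(deletion)
  if (replicates < 1) {
    abort("replicates must be >= 1")
  }
  base_dist <- suppressWarnings(k2p_distances(aln, deletion = deletion))
  tree <- nj_tree(base_dist)
  keys <- tree_split_keys(tree)
  counts <- setNames(numeric(length(keys)), keys)
  n_cols <- n_columns(aln)
  n_dropped <- 0
  withr::with_seed(seed, {
    for (b in seq_len(replicates)) {
      idx <- sample.int(n_cols, n_cols, replace = TRUE)
      rep_aln <- aln
      rep_aln$residues <- resample_columns(aln, idx)
      rep_dist <- tryCatch(
        suppressWarnings(k2p_distances(rep_aln, deletion = deletion)),
        error = function(e) NULL
      )
      if (is.null(rep_dist) || anyNA(rep_dist$d)) {
        n_dropped <- n_dropped + 1
        next
      }
      rep_tree <- nj_tree(rep_dist)
      rep_keys <- tree_split_keys(rep_tree)
      hit <- keys %in% rep_keys
      counts[hit] <- counts[hit] + 1
    }
  })
  kept <- replicates - n_dropped
  if (n_dropped > max_dropped * replicates || kept == 0) {
    abort(paste0("bootstrap: ", n_dropped, " of ", replicates,
                 " replicates dropped (undefined distances); increase ",
                 "sequence quality or use fewer saturated samples"))
  }
  support <- round(100 * counts / kept, 1)
  labels <- as.character(support)
  # The root of the stored (trifurcating) tree is the trivial split.
  labels[1] <- ""
  tree$node.label <- labels
  attr(tree, "replicates") <- replicates
  attr(tree, "n_dropped") <- n_dropped
  tree
}

resample_columns <- function(aln, idx) {
  m <- aln_matrix(aln)[, idx, drop = FALSE]
  apply(m, 1, paste, collapse = "")
}

#' Assess species monophyly on a tree
#'
#' A species is monophyletic when some edge bipartition of the (unrooted)
#' tree isolates exactly its leaves.  Singleton species are trivially
#' monophyletic and flagged as such.  When the tree carries bootstrap node
#' labels, the support of the edge subtending the species' clade is
#' reported.
#'
#' @param tree An `ape::phylo`, e.g. from [nj_tree()] or
#'   [bootstrap_support()].
#' @param species_map Named character vector mapping tip label to species,
#'   or a data frame with `sample_id` and `species` columns (a
#'   [marker_alignment()] works).
#' @return A tibble with `species`, `n_tips`, `monophyletic`,
#'   `is_singleton` and `support`.
#' @export
monophyly <- function(tree, species_map) {
  if (is.data.frame(species_map)) {
    species_map <- setNames(species_map$species, species_map$sample_id)
  }
  missing_tips <- setdiff(tree$tip.label, names(species_map))
  if (length(missing_tips) > 0) {
    abort(paste0("tip(s) absent from species map: ",
                 paste(missing_tips, collapse = ", ")))
  }
  tip_species <- species_map[tree$tip.label]
  keys <- tree_split_keys(tree)
  supports <- if (!is.null(tree$node.label)) {
    setNames(suppressWarnings(as.numeric(tree$node.label)), keys)
  } else {
    setNames(rep(NA_real_, length(keys)), keys)
  }
  tips <- tree$tip.label
  ref <- min(tips)
  purrr::map_dfr(unique(tip_species), function(sp) {
    members <- tips[tip_species == sp]
    if (length(members) == length(tips)) {
      return(tibble(species = sp, n_tips = length(members),
                    monophyletic = TRUE, is_singleton = FALSE,
                    support = NA_real_))
    }
    if (length(members) == 1) {
      return(tibble(species = sp, n_tips = 1L, monophyletic = TRUE,
                    is_singleton = TRUE, support = NA_real_))
    }
    side <- if (ref %in% members) setdiff(tips, members) else members
    k <- paste(sort(side), collapse = ",")
    mono <- k %in% keys
    tibble(
      species = sp,
      n_tips = length(members),
      monophyletic = mono,
      is_singleton = FALSE,
      support = if (mono) unname(supports[k]) else NA_real_
    )
  })
}

#' Write a tree with bootstrap labels to Newick
#'
#' Thin wrapper over [ape::write.tree()] that keeps support values as
#' internal node labels; provided so pipeline outputs are one call.
#'
#' @param tree An `ape::phylo`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
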