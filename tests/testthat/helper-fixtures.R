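# Fixture builders and independent oracles.  The oracles are deliberately
# written in a different style from the package internals (explicit loops,
# set operations per column) so agreement is a real cross-check.

`%||%` <- function(x, y) if (is.null(x)) y else x

make_aln <- function(residues, species = NULL, marker = "test",
                     ids = NULL) {
  n <- length(residues)
  marker_alignment(
    sample_id = ids %||% sprintf("s%02d", seq_len(n)),
    species = species %||% rep("spA", n),
    residues = residues,
    marker = marker
  )
}

random_alignment <- function(n_seq, n_col, p_gap = 0.05, p_ambig = 0.03,
                             n_species = 2) {
  chars <- c("A", "C", "G", "T", "N", "R", "-")
  probs <- c(rep((1 - p_gap - p_ambig) / 4, 4), p_ambig / 2, p_ambig / 2,
             p_gap)
  res <- replicate(n_seq, paste(
    sample(chars, n_col, replace = TRUE, prob = probs), collapse = ""))
  make_aln(res, species = rep_len(paste0("sp", seq_len(n_species)), n_seq))
}

# Independent per-column recount of the site classification.
classify_oracle <- function(aln) {
  m <- aln_matrix(aln)
  bases <- c("A", "C", "G", "T")
  out <- list(conserved = 0, variable = 0, gap_containing = 0,
              all_missing = 0, informative = 0)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    unamb <- col[col %in% bases]
    if (length(unamb) == 0) {
      out$all_missing <- out$all_missing + 1
    } else if (length(unamb) < length(col)) {
      out$gap_containing <- out$gap_containing + 1
    } else {
      states <- unique(col)
      if (length(states) == 1) {
        out$conserved <- out$conserved + 1
      } else {
        out$variable <- out$variable + 1
        shared <- sum(table(col) >= 2)
        if (shared >= 2) out$informative <- out$informative + 1
      }
    }
  }
  out
}

# Brute-force transition/transversion recount for one pair.
pq_oracle <- function(a, b) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  bases <- c("A", "C", "G", "T")
  ts_pairs <- list(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
  n <- 0
  ts <- 0
  tv <- 0
  for (k in seq_along(a)) {
    if (!(a[k] %in% bases) || !(b[k] %in% bases)) next
    n <- n + 1
    if (a[k] == b[k]) next
    is_ts <- any(vapply(ts_pairs, function(p) {
      a[k] == p[1] && b[k] == p[2]
    }, logical(1)))
    if (is_ts) ts <- ts + 1 else tv <- tv + 1
  }
  list(P = ts / n, Q = tv / n, n = n)
}

# Exact two-sided signed-rank p by full enumeration of sign assignments.
wilcoxon_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% r)
  lo <- mean(ws <= W + 1e-9)
  hi <- mean(ws >= W - 1e-9)
  min(1, 2 * min(lo, hi))
}

# Naive double-loop recomputation of the six divergence statistics from a
# labelled distance matrix.
divergence_oracle <- function(mat, species) {
  n <- nrow(mat)
  inter <- c()
  intra <- c()
  sp <- unique(species)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (species[i] == species[j]) {
        intra <- c(intra, mat[i, j])
      } else {
        inter <- c(inter, mat[i, j])
      }
    }
  }
  per_sp_mean <- c()
  per_sp_min <- c()
  for (s in sp) {
    ds <- c()
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        if ((species[i] == s) && (species[j] != s)) ds <- c(ds, mat[i, j])
      }
    }
    if (length(ds) > 0) {
      per_sp_mean <- c(per_sp_mean, mean(ds))
      per_sp_min <- c(per_sp_min, min(ds))
    }
  }
  theta <- c()
  depth <- c()
  for (s in sp) {
    idx <- which(species == s)
    if (length(idx) < 2) next
    ds <- c()
    for (i in idx) {
      for (j in idx) if (i < j) ds <- c(ds, mat[i, j])
    }
    theta <- c(theta, mean(ds))
    depth <- c(depth, max(ds))
  }
  list(
    all_inter = mean(inter), theta_prime = mean(per_sp_mean),
    min_inter = mean(per_sp_min), all_intra = mean(intra),
    theta = mean(theta), depth = mean(depth)
  )
}

random_k2p_table <- function(n_samples = 8, n_species = 3) {
  species <- sample(paste0("sp", seq_len(n_species)), n_samples,
                    replace = TRUE)
  while (length(unique(species)) < 2 || max(table(species)) < 2) {
    species <- sample(paste0("sp", seq_len(n_species)), n_samples,
                      replace = TRUE)
  }
  ids <- sprintf("s%02d", seq_len(n_samples))
  pairs <- combn(n_samples, 2)
  tibble::tibble(
    sample_i = ids[pairs[1, ]],
    sample_j = ids[pairs[2, ]],
    species_i = species[pairs[1, ]],
    species_j = species[pairs[2, ]],
    d = runif(ncol(pairs), 0, 0.2)
  )
}
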