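#' Kimura two-parameter distance for one sequence pair
#'
#' Computes the transition proportion `P` (A<->G, C<->T), the transversion
#' proportion `Q`, and the K2P distance
#' `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`
#' over the pair's comparable columns (both residues unambiguous bases;
#' pairwise deletion of gaps and ambiguity codes).
#'
#' When the correction is undefined (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) the
#' pair is *saturated*: `d` is returned as `NA` with `saturated = TRUE` so
#' that downstream summaries can exclude it explicitly rather than receive
#' an arbitrary large value.
#'
#' @param a,b Aligned sequences of equal length (character strings, or
#'   character vectors of single residues).
#' @return A one-row tibble with columns `P`, `Q`, `n` (comparable columns),
#'   `d` and `saturated`.
#' @examples
#' k2p_pair("ACGTACGTAC", "ACGTACGTAC")
#' @export
k2p_pair <- function(a, b) {
  if (length(a) == 1) a <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  if (length(b) == 1) b <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  if (length(a) != length(b)) {
    abort("sequences must have equal aligned length")
  }
  comp <- a %in% .BASES & b %in% .BASES
  n <- sum(comp)
  if (n == 0) {
    abort("K2P distance undefined: no comparable columns")
  }
  a <- a[comp]
  b <- b[comp]
  diff <- a != b
  purine_a <- a %in% .PURINES
  purine_b <- b %in% .PURINES
  ts <- sum(diff & (purine_a == purine_b))
  tv <- sum(diff & (purine_a != purine_b))
  P <- ts / n
  Q <- tv / n
  d <- k2p_distance(P, Q)
  tibble(P = P, Q = Q, n = n, d = d, saturated = is.na(d))
}

#' @rdname k2p_pair
#' @param P,Q Transition and transversion proportions (vectorized).
#' @return `k2p_distance()` returns the closed-form distance, `NA` where the
#'   logarithm argument is non-positive (saturation).
#' @export
k2p_distance <- function(P, Q) {
  len <- max(length(P), length(Q))
  P <- rep_len(P, len)
  Q <- rep_len(Q, len)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- rep(NA_real_, len)
  ok <- !is.na(w1) & !is.na(w2) & w1 > 0 & w2 > 0
  d[ok] <- -0.5 * log(w1[ok] * sqrt(w2[ok]))
  unname(d)
}

#' All pairwise K2P distances of a marker alignment
#'
#' Computes the K2P distance for every sample pair and returns the long
#' table that the divergence, gap and tree stages consume: one row per
#' unordered pair with both sample ids, both species, `P`, `Q`, the number
#' of comparable columns `n`, the distance `d` and the `saturated` flag
#' (`d = NA`).
#'
#' @param aln A [marker_alignment()].
#' @param deletion Column-filtering policy: `"pairwise"` (default) drops
#'   gap/ambiguous columns per pair; `"complete"` first removes every column
#'   containing any gap or ambiguity code in any sequence.
#' @return A tibble of class `k2p_dist` with attributes `marker`,
#'   `deletion` and `n_columns`.
#' @seealso [as_dist_matrix()] to reshape into a square labelled matrix.
#' @export
k2p_distances <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  m <- aln_matrix(aln)
  ok <- matrix(m %in% .BASES, nrow = nrow(m))
  if (deletion == "complete") {
    keep <- colSums(ok) == nrow(m)
    if (!any(keep)) {
      abort("complete deletion removed every column")
    }
    m <- m[, keep, drop = FALSE]
    ok <- ok[, keep, drop = FALSE]
  }
  purine <- matrix(m %in% .PURINES, nrow = nrow(m))
  pairs <- combn(nrow(m), 2)
  res <- vapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]
    j <- pairs[2, k]
    comp <- ok[i, ] & ok[j, ]
    n <- sum(comp)
    if (n == 0) return(c(NA_real_, NA_real_, 0))
    diff <- comp & (m[i, ] != m[j, ])
    ts <- sum(diff & (purine[i, ] == purine[j, ]))
    tv <- sum(diff) - ts
    c(ts / n, tv / n, n)
  }, numeric(3))
  out <- tibble(
    sample_i = aln$sample_id[pairs[1, ]],
    sample_j = aln$sample_id[pairs[2, ]],
    species_i = aln$species[pairs[1, ]],
    species_j = aln$species[pairs[2, ]],
    P = res[1, ],
    Q = res[2, ],
    n = as.integer(res[3, ]),
    d = k2p_distance(res[1, ], res[2, ])
  )
  out$saturated <- is.na(out$d)
  n_bad <- sum(out$saturated)
  if (n_bad > 0) {
    warn(paste0(n_bad, " saturated/undefined pair(s) flagged (d = NA)"))
  }
  structure(out,
            class = c("k2p_dist", class(tibble())),
            marker = aln$marker[1],
            deletion = deletion,
            n_columns = ncol(m))
}

#' Reshape a long pairwise-distance table into a square matrix
#'
#' @param dist A `k2p_dist` tibble from [k2p_distances()].
#' @return A symmetric numeric matrix with a zero diagonal, sample ids as
#'   dimnames, and a `"species"` attribute giving the species of each label.
#' @export
as_dist_matrix <- function(dist) {
  labels <- unique(c(dist$sample_i, dist$sample_j))
  mat <- matrix(0, length(labels), length(labels),
                dimnames = list(labels, labels))
  mat[cbind(dist$sample_i, dist$sample_j)] <- dist$d
  mat[cbind(dist$sample_j, dist$sample_i)] <- dist$d
  sp <- c(dist$species_i, dist$species_j)[match(labels,
                                                c(dist$sample_i,
                                                  dist$sample_j))]
  attr(mat, "species") <- setNames(sp, labels)
  mat
}
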