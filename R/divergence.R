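DIVERGENCE_STATS <- c(
  "all_interspecific_distance", "theta_prime",
  "minimum_interspecific_distance",
  "all_intraspecific_distance", "theta", "coalescent_depth"
)

#' Inter- and intraspecific divergence summary
#'
#' Computes the six statistics conventionally used to characterize a
#' barcode marker's divergence structure from a pairwise distance table:
#'
#' * **all interspecific distance** -- mean distance over all heterospecific
#'   sample pairs;
#' * **theta prime** -- for each species, the mean distance from its
#'   individuals to all heterospecific individuals, averaged over species;
#' * **minimum interspecific distance** -- for each species, the smallest
#'   distance to any heterospecific individual, averaged over species;
#' * **all intraspecific distance** -- mean distance over all conspecific
#'   pairs;
#' * **theta** -- per-species mean conspecific distance (species with >= 2
#'   individuals only), averaged over qualifying species;
#' * **coalescent depth** -- per-species maximum conspecific distance,
#'   averaged over qualifying species.
#'
#' Saturated pairs (`d = NA`) are excluded with a message.  Dispersion is
#' reported as both SD and SE (over pairs for the "all" statistics, over
#' species for the per-species ones), since divergence tables in the
#' literature rarely say which their `±` is.
#'
#' @param dist A `k2p_dist` tibble from [k2p_distances()] (any tibble with
#'   `species_i`, `species_j`, `d` works).
#' @param theta_prime `"per_species"` (default; average of per-species mean
#'   heterospecific distances) or `"per_species_pair"` (average of
#'   species-pair mean distances).
#' @return A tibble of class `divergence_summary` with columns `statistic`,
#'   `scope`, `mean`, `sd`, `se`, `n`, and attributes `marker`, `n_species`,
#'   `n_samples`.
#' @export
divergence_summary <- function(dist,
                               theta_prime = c("per_species",
                                               "per_species_pair")) {
  theta_prime <- match.arg(theta_prime)
  marker <- attr(dist, "marker") %||% NA_character_
  d <- as_tibble(dist)
  n_na <- sum(is.na(d$d))
  if (n_na > 0) {
    inform(paste0("divergence_summary: excluding ", n_na,
                  " undefined pair(s)"))
    d <- d[!is.na(d$d), ]
  }
  species <- unique(c(d$species_i, d$species_j))
  samples <- unique(c(d$sample_i, d$sample_j))
  inter <- d[d$species_i != d$species_j, ]
  intra <- d[d$species_i == d$species_j, ]

  row <- function(statistic, scope, values, n = length(values)) {
    if (length(values) == 0 || all(is.na(values))) {
      return(tibble(statistic = statistic, scope = scope, mean = NA_real_,
                    sd = NA_real_, se = NA_real_, n = 0L))
    }
    tibble(
      statistic = statistic, scope = scope, mean = mean(values),
      sd = if (length(values) > 1) sd(values) else 0,
      se = if (length(values) > 1) sd(values) / sqrt(length(values)) else 0,
      n = as.integer(n)
    )
  }

  per_species_inter <- function(fun) {
    vapply(species, function(s) {
      sel <- (inter$species_i == s) != (inter$species_j == s)
      if (!any(sel)) return(NA_real_)
      fun(inter$d[sel])
    }, numeric(1))
  }
  tp_values <- if (theta_prime == "per_species") {
    per_species_inter(mean)
  } else {
    pair_key <- paste(pmin(inter$species_i, inter$species_j),
                      pmax(inter$species_i, inter$species_j))
    as.numeric(tapply(inter$d, pair_key, mean))
  }
  min_values <- per_species_inter(min)

  intra_species <- unique(intra$species_i)
  theta_values <- vapply(intra_species, function(s) {
    mean(intra$d[intra$species_i == s])
  }, numeric(1))
  depth_values <- vapply(intra_species, function(s) {
    max(intra$d[intra$species_i == s])
  }, numeric(1))

  out <- dplyr::bind_rows(
    row("all_interspecific_distance", "interspecific", inter$d),
    row("theta_prime", "interspecific", tp_values[!is.na(tp_values)]),
    row("minimum_interspecific_distance", "interspecific",
        min_values[!is.na(min_values)]),
    row("all_intraspecific_distance", "intraspecific", intra$d),
    row("theta", "intraspecific", theta_values),
    row("coalescent_depth", "intraspecific", depth_values)
  )
  structure(out,
            class = c("divergence_summary", class(tibble())),
            marker = marker,
            n_species = length(species),
            n_samples = length(samples))
}

#' @export
glance.divergence_summary <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    dplyr::select(as_tibble(x), "statistic", "mean"),
    names_from = "statistic", values_from = "mean"
  )
  dplyr::bind_cols(
    tibble(marker = attr(x, "marker"),
           n_species = attr(x, "n_species"),
           n_samples = attr(x, "n_samples")),
    wide
  )
}

#' Wilcoxon signed-rank test
#'
#' Paired two-sided signed-rank test implemented from first principles so
#' its exact small-sample behaviour is under the package's control.  Zero
#' differences are dropped; tied absolute differences receive midranks.
#' For `n <= exact_limit` the null distribution of the statistic is
#' computed exactly (dynamic programming over doubled midranks, equivalent
#' to enumerating all `2^n` sign assignments); beyond that a normal
#' approximation with tie and continuity corrections is used.
#'
#' @param x Numeric vector: differences, or first member of each pair when
#'   `y` is given.
#' @param y Optional numeric vector paired with `x`.
#' @param exact_limit Largest `n` for which the exact distribution is used.
#' @return An object of class `signed_rank_test`: list with `statistic`
#'   (`W`, sum of positive-signed ranks), `n` (pairs after dropping zeros),
#'   `p_value` (two-sided) and `method`.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3))   # two-sided exact p = 0.25
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_limit = 25) {
  if (!is.null(y)) {
    if (length(x) != length(y)) {
      abort("x and y must have equal length")
    }
    x <- x - y
  }
  x <- x[!is.na(x)]
  d <- x[x != 0]
  n <- length(d)
  if (n == 0) {
    abort("signed-rank test undefined: no non-zero differences")
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_limit) {
    p <- signed_rank_exact_p(r, W)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_counts <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_counts^3 - tie_counts) / 48
    cc <- if (W == mu) 0 else 0.5
    z <- (W - mu - sign(W - mu) * cc) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approximation"
  }
  structure(
    list(statistic = W, n = n, p_value = p, method = method,
         marker_a = NA_character_, marker_b = NA_character_,
         n_dropped_zero = length(x) - n),
    class = "signed_rank_test"
  )
}

# Exact two-sided p for the signed-rank statistic with midranks.
# Doubling the ranks makes them integers; the distribution of 2W over all
# sign assignments is built by convolution.
signed_rank_exact_p <- function(ranks, W) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  f <- numeric(total + 1)
  f[1] <- 1
  for (rr in r2) {
    g <- f
    g[(rr + 1):(total + 1)] <- g[(rr + 1):(total + 1)] + f[1:(total + 1 - rr)]
    f <- g
  }
  f <- f / sum(f)
  w2 <- round(2 * W)
  p_lo <- sum(f[seq_len(w2 + 1)])
  p_hi <- sum(f[(w2 + 1):(total + 1)])
  min(1, 2 * min(p_lo, p_hi))
}

#' @export
print.signed_rank_test <- function(x, ...) {
  cat("Wilcoxon signed-rank test (", x$method, ")\n", sep = "")
  if (!is.na(x$marker_a)) {
    cat("  markers: ", x$marker_a, " vs ", x$marker_b, "\n", sep = "")
  }
  cat("  W = ", x$statistic, ", n = ", x$n,
      ", two-sided p = ", format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.signed_rank_test <- function(x, ...) {
  tibble(
    marker_a = x$marker_a, marker_b = x$marker_b,
    statistic = x$statistic, n = x$n, p_value = x$p_value,
    method = x$method
  )
}

#' Paired divergence comparison of two markers
#'
#' Pairs the two markers' distance tables on shared unordered sample-pair
#' keys and applies the signed-rank test to the paired distances.  Sample
#' pairs present in only one marker (or undefined in either) are dropped
#' and counted.
#'
#' @param dist_a,dist_b `k2p_dist` tibbles from [k2p_distances()].
#' @param scope Restrict the comparison to `"interspecific"`,
#'   `"intraspecific"` or `"all"` (default `"interspecific"`, the usual
#'   marker-ranking comparison).
#' @return A `signed_rank_test` with marker names filled in and an
#'   `n_unmatched` element.
#' @export
compare_marker_divergence <- function(dist_a, dist_b,
                                      scope = c("interspecific",
                                                "intraspecific", "all")) {
  scope <- match.arg(scope)
  key <- function(d) paste(pmin(d$sample_i, d$sample_j),
                           pmax(d$sample_i, d$sample_j), sep = "\r")
  a <- as_tibble(dist_a)
  b <- as_tibble(dist_b)
  filt <- function(d) switch(scope,
    all = d,
    interspecific = d[d$species_i != d$species_j, ],
    intraspecific = d[d$species_i == d$species_j, ]
  )
  a <- filt(a)
  b <- filt(b)
  a$key <- key(a)
  b$key <- key(b)
  merged <- dplyr::inner_join(
    dplyr::select(a, "key", d_a = "d"),
    dplyr::select(b, "key", d_b = "d"),
    by = "key"
  )
  merged <- merged[!is.na(merged$d_a) & !is.na(merged$d_b), ]
  n_unmatched <- nrow(a) + nrow(b) - 2 * nrow(merged)
  if (nrow(merged) == 0) {
    abort("no shared, defined sample pairs between the two markers")
  }
  if (n_unmatched > 0) {
    inform(paste0("compare_marker_divergence: ", n_unmatched,
                  " unmatched/undefined pair record(s) dropped"))
  }
  res <- wilcoxon_signed_rank(merged$d_a, merged$d_b)
  res$marker_a <- attr(dist_a, "marker") %||% "a"
  res$marker_b <- attr(dist_b, "marker") %||% "b"
  res$n_unmatched <- n_unmatched
  res
}

#' Rank markers by interspecific divergence
#'
#' Orders markers by their mean interspecific distance (largest first,
#' stable for ties) and annotates each adjacent pair with the signed-rank
#' p-value for that comparison when supplied.
#'
#' @param summaries List of [divergence_summary()] objects (or a tibble with
#'   columns `marker` and `all_interspecific_distance`).
#' @param tests Optional list of `signed_rank_test` objects from
#'   [compare_marker_divergence()].
#' @return A tibble with `rank`, `marker`, `interspecific_mean`,
#'   `next_marker` and `p_vs_next`.
#' @export
rank_markers <- function(summaries, tests = NULL) {
  if (inherits(summaries, "data.frame")) {
    tab <- tibble(marker = summaries$marker,
                  interspecific_mean = summaries$all_interspecific_distance)
  } else {
    tab <- purrr::map_dfr(summaries, function(s) {
      tibble(
        marker = attr(s, "marker"),
        interspecific_mean =
          s$mean[s$statistic == "all_interspecific_distance"]
      )
    })
  }
  if (nrow(tab) < 2) {
    abort("rank_markers needs at least 2 markers")
  }
  ord <- order(-tab$interspecific_mean)
  tab <- tab[ord, ]
  tab$rank <- seq_len(nrow(tab))
  tab$next_marker <- c(tab$marker[-1], NA_character_)
  tab$p_vs_next <- NA_real_
  if (!is.null(tests)) {
    test_tab <- purrr::map_dfr(tests, tidy)
    for (i in seq_len(nrow(tab) - 1)) {
      hit <- which(
        (test_tab$marker_a == tab$marker[i] &
           test_tab$marker_b == tab$next_marker[i]) |
        (test_tab$marker_b == tab$marker[i] &
           test_tab$marker_a == tab$next_marker[i])
      )
      if (length(hit) > 0) tab$p_vs_next[i] <- test_tab$p_value[hit[1]]
    }
  }
  dplyr::select(tab, "rank", "marker", "interspecific_mean",
                "next_marker", "p_vs_next")
}
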