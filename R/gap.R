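#' Barcoding-gap profile of a marker
#'
#' Splits a marker's defined pairwise distances into conspecific
#' (intraspecific) and heterospecific (interspecific) sets and assesses the
#' barcoding gap with the distribution-extrema rule: a gap is present when
#' the smallest interspecific distance exceeds the largest intraspecific
#' distance.  The gap interval is reported in percent (`100 * d`), the
#' scale on which such distributions are conventionally plotted.  The
#' overlap fraction is the share of interspecific distances less than or
#' equal to the intraspecific maximum (so a tie counts as overlap and a
#' present gap implies overlap 0).
#'
#' Shared histogram bins of `bin_width` percent covering `[0, max distance]`
#' are included for plotting; distances are kept in substitutions/site
#' internally and converted to percent only at this reporting boundary.
#'
#' @param dist A `k2p_dist` tibble from [k2p_distances()].
#' @param bin_width Histogram bin width in percent (default 0.2).
#' @return An object of class `gap_profile`.
#' @export
gap_profile <- function(dist, bin_width = 0.2) {
  marker <- attr(dist, "marker") %||% NA_character_
  d <- as_tibble(dist)
  d <- d[!is.na(d$d), ]
  intra <- d$d[d$species_i == d$species_j]
  inter <- d$d[d$species_i != d$species_j]
  if (length(intra) == 0) {
    abort("gap profile undefined: no intraspecific distances")
  }
  if (length(inter) == 0) {
    abort("gap profile undefined: no interspecific distances")
  }
  max_intra <- max(intra)
  min_inter <- min(inter)
  gap_present <- min_inter > max_intra
  overlap_fraction <- mean(inter <= max_intra)

  top <- max(c(intra, inter)) * 100
  breaks <- seq(0, max(bin_width, ceiling(top / bin_width) * bin_width),
                by = bin_width)
  if (top >= breaks[length(breaks)]) breaks <- c(breaks, top + bin_width)
  histo <- tibble(
    bin_lo = breaks[-length(breaks)],
    bin_hi = breaks[-1],
    intra_count = as.integer(
      table(cut(intra * 100, breaks, right = FALSE,
                include.lowest = TRUE))),
    inter_count = as.integer(
      table(cut(inter * 100, breaks, right = FALSE,
                include.lowest = TRUE)))
  )
  structure(
    list(
      marker = marker,
      intra_distances = intra,
      inter_distances = inter,
      bin_width = bin_width,
      max_intra = max_intra,
      min_inter = min_inter,
      gap_present = gap_present,
      gap_interval = if (gap_present) {
        c(100 * max_intra, 100 * min_inter)
      } else {
        NULL
      },
      overlap_fraction = overlap_fraction,
      histogram = histo
    ),
    class = "gap_profile"
  )
}

#' @export
print.gap_profile <- function(x, ...) {
  cat("<gap_profile> ", x$marker, ": ", length(x$intra_distances),
      " intra / ", length(x$inter_distances), " inter distances\n", sep = "")
  if (x$gap_present) {
    cat(sprintf("  barcoding gap present: %.4g%% to %.4g%%\n",
                x$gap_interval[1], x$gap_interval[2]))
  } else {
    cat(sprintf("  no gap; overlap fraction %.3f\n", x$overlap_fraction))
  }
  invisible(x)
}

#' @export
tidy.gap_profile <- function(x, ...) {
  dplyr::mutate(x$histogram, marker = x$marker, .before = 1)
}

#' @export
glance.gap_profile <- function(x, ...) {
  tibble(
    marker = x$marker,
    n_intra = length(x$intra_distances),
    n_inter = length(x$inter_distances),
    max_intra = x$max_intra,
    min_inter = x$min_inter,
    gap_present = x$gap_present,
    gap_lo_percent = if (x$gap_present) x$gap_interval[1] else NA_real_,
    gap_hi_percent = if (x$gap_present) x$gap_interval[2] else NA_real_,
    gap_width_percent = if (x$gap_present) {
      x$gap_interval[2] - x$gap_interval[1]
    } else {
      NA_real_
    },
    overlap_fraction = x$overlap_fraction
  )
}

#' Ranked barcoding-gap report across markers
#'
#' Orders markers so the best-separated come first: gapped markers before
#' overlapping ones, overlapping markers by ascending overlap fraction, and
#' gapped markers by descending gap width.
#'
#' @param profiles List of [gap_profile()] objects.
#' @return A tibble, one row per marker (the [glance()] columns plus
#'   `rank`).
#' @export
gap_report <- function(profiles) {
  if (length(profiles) == 0) {
    abort("gap_report needs at least one profile")
  }
  tab <- purrr::map_dfr(profiles, glance)
  width <- ifelse(is.na(tab$gap_width_percent), -Inf, tab$gap_width_percent)
  ord <- order(-tab$gap_present, tab$overlap_fraction, -width)
  tab <- tab[ord, ]
  dplyr::mutate(tab, rank = dplyr::row_number(), .before = 1)
}

#' Plot a barcoding-gap profile
#'
#' Mirrored histogram of intraspecific (up) and interspecific (down)
#' K2P distances on the percent scale, with the gap interval shaded when
#' present.
#'
#' @param object A [gap_profile()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.gap_profile <- function(object, ...) {
  h <- object$histogram
  long <- dplyr::bind_rows(
    tibble(mid = (h$bin_lo + h$bin_hi) / 2, count = h$intra_count,
           scope = "intraspecific"),
    tibble(mid = (h$bin_lo + h$bin_hi) / 2, count = -h$inter_count,
           scope = "interspecific")
  )
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(x = .data$mid, y = .data$count,
                                    fill = .data$scope)) +
    ggplot2::geom_col(width = object$bin_width * 0.9) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(
      x = "K2P distance (%)",
      y = "pair count (intra up / inter down)",
      title = paste0(object$marker,
                     if (object$gap_present) " - barcoding gap present"
                     else " - no barcoding gap")
    ) +
    ggplot2::theme_minimal()
  if (object$gap_present) {
    p <- p + ggplot2::annotate(
      "rect", xmin = object$gap_interval[1], xmax = object$gap_interval[2],
      ymin = -Inf, ymax = Inf, alpha = 0.15
    )
  }
  p
}
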