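new_distribution <- function(df, lo, hi, bin_width, n_genes) {
  structure(as_tibble(df), lo = as.integer(lo), hi = as.integer(hi),
            bin_width = as.integer(bin_width), n_genes = as.integer(n_genes),
            class = c("phqs_distribution", class(as_tibble(df))))
}

#' Bin motif hits into a TSS-centred frequency distribution
#'
#' Hits are assigned to fixed-width bins of their TSS-relative first-guanine
#' coordinate: bin `k` covers `[lo + k*bin_width, lo + (k+1)*bin_width)`.
#' Frequencies are normalised to the number of genes and expressed as
#' occurrences per 100 sequences per bin
#' (`freq_per_100_genes = 100 * count / n_genes`). Hits outside `[lo, hi)`
#' and hits of excluded categories are dropped; single-tract (1G) hits are
#' excluded by default because their tract decomposition is ambiguous.
#'
#' @param hits Motif-hit tibble.
#' @param n_genes Number of genes scanned (normalisation denominator; kept
#'   at the full gene count even if some genes are shorter than the window).
#' @param lo,hi TSS-relative window, half-open; `hi - lo` must be a multiple
#'   of `bin_width`.
#' @param bin_width Bin width in nucleotides.
#' @param categories Categories to keep.
#' @return A `phqs_distribution`: a tibble with one row per
#'   (bin_start, strand, category) over the full grid, columns `count` and
#'   `freq_per_100_genes`, and attributes `lo`, `hi`, `bin_width`,
#'   `n_genes`.
#' @export
#' @examples
#' h <- tibble::tibble(strand = "non_template", category = "2G",
#'                     tss_rel_coord = c(5, 50, 150))
#' bin_hits(h, n_genes = 100, lo = 0, hi = 400, categories = "2G")
bin_hits <- function(hits, n_genes, lo = -4000L, hi = 4000L,
                     bin_width = 100L, categories = c("2G", "3G", "4G+")) {
  lo <- as.integer(lo); hi <- as.integer(hi); bin_width <- as.integer(bin_width)
  if (n_genes < 1L) abort("n_genes must be >= 1")
  if ((hi - lo) %% bin_width != 0L) {
    abort("window width (hi - lo) must be divisible by bin_width")
  }
  bins <- seq.int(lo, hi - bin_width, by = bin_width)
  strands <- c("non_template", "template")
  kept <- hits |>
    filter(.data$category %in% categories,
           .data$tss_rel_coord >= lo, .data$tss_rel_coord < hi) |>
    mutate(bin_start = lo +
             ((.data$tss_rel_coord - lo) %/% bin_width) * bin_width)
  grid <- tidyr::expand_grid(bin_start = bins, strand = strands,
                             category = categories)
  counts <- kept |>
    count(.data$bin_start, .data$strand, .data$category, name = "count") |>
    mutate(bin_start = as.integer(.data$bin_start))
  out <- grid |>
    left_join(counts, by = c("bin_start", "strand", "category")) |>
    mutate(count = as.integer(tidyr::replace_na(.data$count, 0L)),
           freq_per_100_genes = 100 * .data$count / n_genes) |>
    arrange(.data$strand == "template", .data$category, .data$bin_start)
  new_distribution(out, lo, hi, bin_width, n_genes)
}

#' Normalise a distribution to its background level
#'
#' Divides each (strand, category) curve by the mean of its frequencies over
#' the background window — by default the bins whose start lies in
#' `[3000, 4000)`, i.e. the far-downstream region where the TSS-proximal
#' enrichment has decayed. Adds a `normalized` column; the normalised curve
#' averages 1 over the background window by construction.
#'
#' @param dist A `phqs_distribution`.
#' @param bg_lo,bg_hi Background window on `bin_start` (half-open). Use
#'   negative bounds to take the upstream flank instead.
#' @return The distribution with a `normalized` column.
#' @export
normalize_to_background <- function(dist, bg_lo = 3000L, bg_hi = 4000L) {
  stopifnot(inherits(dist, "phqs_distribution"))
  lo <- attr(dist, "lo"); hi <- attr(dist, "hi")
  bw <- attr(dist, "bin_width"); ng <- attr(dist, "n_genes")
  if (bg_lo < lo || bg_hi > hi || bg_hi - bg_lo < bw) {
    abort("background window must lie inside the distribution range and contain at least one bin")
  }
  out <- dist |>
    group_by(.data$strand, .data$category) |>
    mutate(.bg = mean(.data$freq_per_100_genes[
      .data$bin_start >= bg_lo & .data$bin_start < bg_hi])) |>
    ungroup()
  zero <- out |>
    filter(.data$.bg == 0) |>
    distinct(.data$strand, .data$category)
  if (nrow(zero)) {
    abort(paste0("zero background mean for curve(s): ",
                 paste(paste(zero$strand, zero$category, sep = "/"),
                       collapse = ", ")))
  }
  out <- out |>
    mutate(normalized = .data$freq_per_100_genes / .data$.bg) |>
    select(-".bg")
  new_distribution(out, lo, hi, bw, ng)
}

#' Per-bin difference of two distributions (masked-motif contribution)
#'
#' Subtracts the masked-scan distribution from the unmasked one, bin by bin
#' and curve by curve; the result is the contribution of the masked motif.
#' Both inputs must share range, bin width, gene count and curve keys.
#'
#' @param unmasked,masked `phqs_distribution` objects from the same gene set.
#' @return A `phqs_distribution` of per-bin differences.
#' @export
subtract_distribution <- function(unmasked, masked) {
  stopifnot(inherits(unmasked, "phqs_distribution"),
            inherits(masked, "phqs_distribution"))
  for (a in c("lo", "hi", "bin_width", "n_genes")) {
    if (!identical(attr(unmasked, a), attr(masked, a))) {
      abort(paste0("distributions differ in ", a))
    }
  }
  key <- c("bin_start", "strand", "category")
  if (!identical(as.data.frame(unmasked[key]), as.data.frame(masked[key]))) {
    abort("distributions have different bin/strand/category keys")
  }
  out <- unmasked[key] |>
    mutate(count = unmasked$count - masked$count,
           freq_per_100_genes =
             unmasked$freq_per_100_genes - masked$freq_per_100_genes)
  new_distribution(out, attr(unmasked, "lo"), attr(unmasked, "hi"),
                   attr(unmasked, "bin_width"), attr(unmasked, "n_genes"))
}

#' @method tidy phqs_distribution
#' @export
tidy.phqs_distribution <- function(x, ...) {
  as_tibble(unclass_dist(x))
}

#' @method glance phqs_distribution
#' @export
glance.phqs_distribution <- function(x, ...) {
  tibble(
    n_genes = attr(x, "n_genes"),
    lo = attr(x, "lo"), hi = attr(x, "hi"),
    bin_width = attr(x, "bin_width"),
    n_bins = (attr(x, "hi") - attr(x, "lo")) %/% attr(x, "bin_width"),
    total_hits = sum(x$count),
    non_template_hits = sum(x$count[x$strand == "non_template"]),
    template_hits = sum(x$count[x$strand == "template"])
  )
}

unclass_dist <- function(x) {
  attr(x, "lo") <- NULL; attr(x, "hi") <- NULL
  attr(x, "bin_width") <- NULL; attr(x, "n_genes") <- NULL
  class(x) <- setdiff(class(x), "phqs_distribution")
  x
}

#' Plot a binned TSS-centred distribution
#'
#' Step curves of frequency (or background-normalised frequency, when
#' present) against TSS-relative position, coloured by strand and faceted by
#' category.
#'
#' @param object A `phqs_distribution`.
#' @param normalized Plot the `normalized` column if available.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phqs_distribution
#' @export
autoplot.phqs_distribution <- function(object, normalized = FALSE, ...) {
  y <- if (normalized && "normalized" %in% names(object)) {
    "normalized"
  } else {
    "freq_per_100_genes"
  }
  ylab <- if (y == "normalized") {
    "frequency / background"
  } else {
    "occurrences per 100 sequences"
  }
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$bin_start + attr(object, "bin_width") / 2,
                               y = .data[[y]], colour = .data$strand)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(~category) +
    ggplot2::labs(x = "position relative to TSS (nt)", y = ylab,
                  colour = "strand") +
    ggplot2::theme_minimal()
}
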