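#' Strand-bias statistic over a TSS-relative window
#'
#' Counts hits per category on the non-template (`N_N`) and template (`N_T`)
#' strands whose TSS-relative coordinate falls in the window — by default the
#' 1 kb region downstream of the TSS, where only non-template G-tracts can
#' join the nascent transcript in a hybrid G-quadruplex. Two bias formulas
#' are available:
#'
#' * `normalized_difference`: `(N_N - N_T) / (N_N + N_T)`, bounded in
#'   \[-1, 1\] and symmetric (the default);
#' * `relative_excess`: `(N_N - N_T) / N_T`, the excess of non-template over
#'   template occurrences.
#'
#' An empty denominator yields `NA` with a warning, never an error.
#'
#' @param hits Motif-hit tibble.
#' @param categories Categories to report (one result row each).
#' @param window Length-2 TSS-relative half-open window.
#' @param formula Bias formula id.
#' @return A tibble of class `strand_bias_result` with columns `category`,
#'   `window_lo`, `window_hi`, `N_N`, `N_T`, `bias`, `formula_id`.
#' @export
#' @examples
#' h <- tibble::tibble(strand = rep(c("non_template", "template"), c(150, 50)),
#'                     category = "2G", tss_rel_coord = 10)
#' strand_bias(h, categories = "2G")
strand_bias <- function(hits, categories = c("2G", "3G", "4G+"),
                        window = c(0L, 1000L),
                        formula = c("normalized_difference",
                                    "relative_excess")) {
  formula <- match.arg(formula)
  stopifnot(length(window) == 2L, window[1] < window[2])
  inw <- hits |>
    filter(.data$category %in% categories,
           .data$tss_rel_coord >= window[1], .data$tss_rel_coord < window[2])
  out <- purrr::map(categories, function(cat) {
    nn <- sum(inw$category == cat & inw$strand == "non_template")
    nt <- sum(inw$category == cat & inw$strand == "template")
    bias <- if (formula == "normalized_difference") {
      if (nn + nt == 0L) NA_real_ else (nn - nt) / (nn + nt)
    } else {
      if (nt == 0L) NA_real_ else (nn - nt) / nt
    }
    tibble(category = cat, window_lo = as.integer(window[1]),
           window_hi = as.integer(window[2]), N_N = nn, N_T = nt,
           bias = bias, formula_id = formula)
  }) |>
    purrr::list_rbind()
  if (anyNA(out$bias)) {
    warn(paste0("undefined strand bias (empty denominator) for category(s): ",
                paste(out$category[is.na(out$bias)], collapse = ", ")))
  }
  structure(out, class = c("strand_bias_result", class(out)))
}

#' @method tidy strand_bias_result
#' @export
tidy.strand_bias_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "strand_bias_result")
  as_tibble(out)
}

#' Plot strand-bias values by category
#'
#' @param object A `strand_bias_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot strand_bias_result
#' @export
autoplot.strand_bias_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$category, y = .data$bias)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = "motif category", y = "strand bias") +
    ggplot2::theme_minimal()
}

#' Gene-level motif prevalence and abundance
#'
#' For each scan pattern present in `hits`, reports the percentage of genes
#' carrying at least one qualifying hit (on either strand by default) and
#' the mean number of qualifying hits per gene, in one of two regions:
#'
#' * `tss_window`: hits whose TSS-relative coordinate lies in `tss_window`
#'   (default the +/- 1 kb region around the TSS);
#' * `transcribed`: hits whose sense span overlaps the transcribed region
#'   `[tss_offset, tss_offset + gene_length)`.
#'
#' @param hits Motif-hit tibble (may mix patterns, e.g. phqs and pqs).
#' @param records Gene-record tibble defining the gene universe and the
#'   transcribed regions.
#' @param region `"tss_window"` or `"transcribed"`.
#' @param tss_window Length-2 half-open TSS-relative window for
#'   `region = "tss_window"`.
#' @param nontemplate_only Count hits on the non-template strand only.
#' @return Tibble with columns `region`, `pattern`, `n_genes`,
#'   `pct_genes_positive`, `mean_hits_per_gene`.
#' @export
gene_summary <- function(hits, records,
                         region = c("tss_window", "transcribed"),
                         tss_window = c(-1000L, 1000L),
                         nontemplate_only = FALSE) {
  region <- match.arg(region)
  check_records(records)
  n_genes <- nrow(records)
  if (nontemplate_only) hits <- filter(hits, .data$strand == "non_template")
  qual <- if (region == "tss_window") {
    filter(hits, .data$tss_rel_coord >= tss_window[1],
           .data$tss_rel_coord < tss_window[2])
  } else {
    hits |>
      left_join(records[, c("gene_id", "tss_offset", "gene_length")],
                by = "gene_id") |>
      filter(.data$sense_start < .data$tss_offset + .data$gene_length,
             .data$sense_end > .data$tss_offset)
  }
  patterns <- unique(hits$pattern)
  purrr::map(patterns, function(p) {
    q <- filter(qual, .data$pattern == p)
    tibble(region = region, pattern = p, n_genes = n_genes,
           pct_genes_positive = 100 * length(unique(q$gene_id)) / n_genes,
           mean_hits_per_gene = nrow(q) / n_genes)
  }) |>
    purrr::list_rbind()
}

#' Expected strand bias implied by a planting probability
#'
#' For motifs planted on the non-template strand with probability `p`, the
#' normalised-difference bias converges to `2p - 1` and the relative excess
#' to `p / (1 - p) - 1`.
#'
#' @param p_nontemplate Probability in \[0, 1\].
#' @param formula Bias formula id.
#' @return Expected bias (`NA` for `relative_excess` at `p = 1`).
#' @export
#' @examples
#' expected_bias(0.75)  # 0.5
expected_bias <- function(p_nontemplate,
                          formula = c("normalized_difference",
                                      "relative_excess")) {
  formula <- match.arg(formula)
  stopifnot(p_nontemplate >= 0, p_nontemplate <= 1)
  if (formula == "normalized_difference") {
    2 * p_nontemplate - 1
  } else if (p_nontemplate == 1) {
    NA_real_
  } else {
    p_nontemplate / (1 - p_nontemplate) - 1
  }
}
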