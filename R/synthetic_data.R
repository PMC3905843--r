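#' Construct one synthetic motif of a requested category
#'
#' Builds `k` tracts of exactly `GGG` (k = 2, 3 or 4 for categories 2G, 3G,
#' 4G+) joined by loops of 1-7 nt drawn from `{A, C, T}`. Loops never contain
#' a `G`, so a planted motif always scans to exactly one hit of the requested
#' category; loops are additionally rejection-sampled to exclude `CC`, so the
#' reverse complement of a plant can never harbour a G-run of length >= 2 and
#' plants are invisible to the opposite-strand scan.
#'
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param category `"2G"`, `"3G"` or `"4G+"`.
#' @return A DNA string in motif (scanned) orientation.
#' @export
#' @examples
#' set.seed(1)
#' make_motif("2G")
make_motif <- function(category = c("2G", "3G", "4G+")) {
  category <- match.arg(category)
  k <- switch(category, "2G" = 2L, "3G" = 3L, "4G+" = 4L)
  loops <- vapply(seq_len(k - 1L), function(i) {
    repeat {
      loop <- paste(sample(c("A", "C", "T"), sample.int(7L, 1L),
                           replace = TRUE), collapse = "")
      if (!grepl("CC", loop, fixed = TRUE)) return(loop)
    }
  }, character(1))
  paste0("GGG", paste0(loops, "GGG", collapse = ""))
}

#' Simulate gene-like sequences with planted motifs and exact ground truth
#'
#' Generates `n_genes` sense-strand sequences of `flank_len` upstream bases
#' followed by `gene_len` transcribed bases (TSS at index `flank_len`),
#' background drawn i.i.d. from `base_probs`, and plants motifs with known
#' category, position and strand. Template-strand plants are stored as
#' reverse complements on the sense string, mirroring real FASTA input. Each
#' plant is flanked by 8 nt of `{A, T}` padding, so planted motifs can never
#' chain with background G-runs — the truth table is exact, a deliberate
#' difference from raw genomic sequence.
#'
#' The TSS-relative coordinate of a plant is the position of its first
#' guanine in motif orientation, drawn uniformly from the half-open
#' `position` window (default the 1 kb region downstream of the TSS, where
#' TSS-proximal enrichment is modelled). Placements are rejection-sampled to
#' keep padded plants disjoint; more than 1000 rejections for one motif is a
#' packing error.
#'
#' @param n_genes Number of genes.
#' @param flank_len Upstream flank length before the TSS (nt).
#' @param gene_len Transcribed length (nt).
#' @param base_probs Named probabilities for A/C/G/T. The default guanine
#'   fraction is 0.15, close to gene-body guanine content, and the default is
#'   strand-symmetric (G = C) so the background motif rate is identical on
#'   the two strands and cannot masquerade as planted strand bias.
#' @param planting Named list or vector giving plants per gene for each
#'   category (names among `2G`, `3G`, `4G+`). Non-integer values are
#'   treated as per-gene Poisson rates.
#' @param position Length-2 half-open TSS-relative window for plant
#'   coordinates.
#' @param p_nontemplate Probability a plant goes on the non-template strand;
#'   the expected normalised-difference strand bias is
#'   `2 * p_nontemplate - 1`.
#' @param seed Integer seed; the full output is deterministic given the
#'   seed, with per-gene substreams so gene `i` is reproducible in
#'   isolation.
#' @return A list of class `phqs_simulation` with elements `records` (gene
#'   records), `truth` (one row per plant: `gene_id`, `strand`,
#'   `sense_start`, `sense_end`, `tss_rel_coord`, `category`,
#'   `matched_seq`) and `config`.
#' @export
#' @examples
#' sim <- simulate_gene_set(n_genes = 3, flank_len = 200, gene_len = 500,
#'                          planting = list("2G" = 1), seed = 1)
#' sim$truth
simulate_gene_set <- function(n_genes = 100L,
                              flank_len = 4000L,
                              gene_len = 6000L,
                              base_probs = c(A = 0.35, C = 0.15,
                                             G = 0.15, T = 0.35),
                              planting = list("2G" = 2, "3G" = 1, "4G+" = 1),
                              position = c(0L, 1000L),
                              p_nontemplate = 0.5,
                              seed = 1L) {
  stopifnot(n_genes >= 1L, flank_len >= 0L, gene_len >= 1L,
            length(position) == 2L, position[1] < position[2],
            p_nontemplate >= 0, p_nontemplate <= 1)
  base_probs <- base_probs[c("A", "C", "G", "T")]
  if (anyNA(base_probs) || abs(sum(base_probs) - 1) > 1e-8 ||
      any(base_probs < 0)) {
    abort("base_probs must be named probabilities for A, C, G, T summing to 1")
  }
  planting <- unlist(planting)
  if (length(planting) &&
      !all(names(planting) %in% c("2G", "3G", "4G+"))) {
    abort("planting names must be among 2G, 3G, 4G+")
  }
  L <- flank_len + gene_len
  pad <- 8L
  gene_ids <- sprintf("synth_%04d", seq_len(n_genes))
  genes <- vector("list", n_genes)
  truths <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    # independent, reorder-stable substream per gene (< 2^31)
    set.seed((as.integer(seed) %% 100003L) * 10007L + i)
    chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                    prob = base_probs)
    reserved <- matrix(integer(), ncol = 2L)  # padded [start, end) spans
    rows <- list()
    for (cat in names(planting)) {
      k <- planting[[cat]]
      n_plant <- if (abs(k - round(k)) < 1e-9) as.integer(round(k)) else
        rpois(1L, k)
      for (j in seq_len(n_plant)) {
        motif <- make_motif(cat)
        mlen <- nchar(motif)
        placed <- FALSE
        for (try in seq_len(1000L)) {
          coord <- sample.int(position[2] - position[1], 1L) - 1L + position[1]
          on_nt <- stats::runif(1L) < p_nontemplate
          if (on_nt) {
            s <- flank_len + coord
            e <- s + mlen
          } else {
            e <- flank_len + coord + 1L
            s <- e - mlen
          }
          if (s - pad < 0L || e + pad > L) next
          if (nrow(reserved) &&
              any(s - pad < reserved[, 2] & e + pad > reserved[, 1])) next
          mchars <- strsplit(if (on_nt) motif else reverse_complement(motif),
                             "", fixed = TRUE)[[1]]
          chars[(s + 1L):e] <- mchars
          chars[(s - pad + 1L):s] <- sample(c("A", "T"), pad, replace = TRUE)
          chars[(e + 1L):(e + pad)] <- sample(c("A", "T"), pad,
                                              replace = TRUE)
          reserved <- rbind(reserved, c(s - pad, e + pad))
          rows[[length(rows) + 1L]] <- tibble(
            gene_id = gene_ids[i],
            strand = if (on_nt) "non_template" else "template",
            sense_start = s, sense_end = e,
            tss_rel_coord = coord, category = cat, matched_seq = motif
          )
          placed <- TRUE
          break
        }
        if (!placed) {
          abort(paste0("could not place a ", cat, " motif in gene ",
                       gene_ids[i],
                       " after 1000 tries; lower the planting density"))
        }
      }
    }
    genes[[i]] <- paste(chars, collapse = "")
    truths[[i]] <- purrr::list_rbind(rows)
  }
  truth <- purrr::list_rbind(truths)
  if (nrow(truth)) {
    truth <- arrange(truth, .data$gene_id,
                     .data$strand == "template", .data$sense_start)
  }
  records <- gene_records(gene_ids, unlist(genes),
                          rep(flank_len, n_genes), rep(gene_len, n_genes))
  structure(list(
    records = records,
    truth = truth,
    config = list(n_genes = n_genes, flank_len = flank_len,
                  gene_len = gene_len, base_probs = base_probs,
                  planting = planting, position = as.integer(position),
                  p_nontemplate = p_nontemplate, seed = as.integer(seed))
  ), class = "phqs_simulation")
}

#' @export
print.phqs_simulation <- function(x, ...) {
  cat(sprintf("phqs_simulation: %d genes (%d nt flank + %d nt gene), %d planted motifs\n",
              x$config$n_genes, x$config$flank_len, x$config$gene_len,
              nrow(x$truth)))
  invisible(x)
}

#' Write a simulation to FASTA + TSS sidecar + truth TSV
#'
#' @param sim A `phqs_simulation`.
#' @param dir Output directory (created if needed); writes `genes.fasta`,
#'   `tss.tsv` and `truth.tsv`.
#' @return The output paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "phqs_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("genes.fasta", "tss.tsv", "truth.tsv"))
  write_gene_fasta(sim$records, paths[1], paths[2])
  readr::write_tsv(sim$truth, paths[3], progress = FALSE)
  invisible(paths)
}
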