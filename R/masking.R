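#' Mask interval regions of gene sequences with N
#'
#' Every base inside the union of the supplied intervals is replaced by `N`;
#' metadata and all other bases are unchanged. Because `N` still acts as a
#' loop character in the scan patterns, masking a loop does not destroy a
#' motif — only masking G-tracts does.
#'
#' @param records Gene-record tibble.
#' @param masks Tibble with columns `gene_id`, `start`, `end` (0-based
#'   half-open, within the sequence; overlapping intervals allowed).
#' @return The records with masked sequences.
#' @export
#' @examples
#' r <- gene_records("g1", "GGGTGGG", 0, 7)
#' apply_interval_mask(r, tibble::tibble(gene_id = "g1", start = 0, end = 3))
apply_interval_mask <- function(records, masks) {
  check_records(records)
  if (!nrow(masks)) return(records)
  stopifnot(all(c("gene_id", "start", "end") %in% names(masks)))
  lens <- setNames(nchar(records$seq), records$gene_id)
  known <- masks$gene_id %in% records$gene_id
  if (!all(known)) {
    abort(paste0("mask intervals for unknown gene(s): ",
                 paste(unique(masks$gene_id[!known]), collapse = ", ")))
  }
  bad <- masks$start < 0L | masks$end > lens[masks$gene_id] |
    masks$start >= masks$end
  if (any(bad)) {
    abort(paste0("mask interval out of range for gene(s): ",
                 paste(unique(masks$gene_id[bad]), collapse = ", ")))
  }
  by_gene <- split(masks, masks$gene_id)
  seqs <- setNames(records$seq, records$gene_id)
  for (gid in names(by_gene)) {
    ch <- strsplit(seqs[[gid]], "", fixed = TRUE)[[1]]
    iv <- by_gene[[gid]]
    pos <- unique(unlist(Map(seq.int, iv$start + 1L, iv$end)))
    ch[pos] <- "N"
    seqs[[gid]] <- paste(ch, collapse = "")
  }
  mutate(records, seq = unname(seqs[.data$gene_id]))
}

#' Ordered literal-motif mask specification
#'
#' Defaults reproduce the hnRNP-site masking procedure: the G-rich hnRNP A/H
#' recognition motifs `TAGGGT`, `TAGGGA` and `GGGA`, masked in that order and
#' searched only on the non-template (sense) strand.
#'
#' @param motifs Ordered character vector of DNA literals (uppercase ACGT).
#' @param strand `"non_template_only"` to search the sense sequence only, or
#'   `"both"` to also mask occurrences on the template strand (i.e. reverse
#'   complements of the motifs on the sense sequence).
#' @return A list of class `literal_mask_spec`.
#' @export
literal_mask_spec <- function(motifs = c("TAGGGT", "TAGGGA", "GGGA"),
                              strand = c("non_template_only", "both")) {
  strand <- match.arg(strand)
  motifs <- toupper(as.character(motifs))
  if (!length(motifs) || any(!grepl("^[ACGT]+$", motifs))) {
    abort("literal mask motifs must be non-empty strings over ACGT")
  }
  structure(list(motifs = motifs, strand = strand),
            class = "literal_mask_spec")
}

#' Mask ordered literal motifs with N
#'
#' For each motif in order, all its left-to-right non-overlapping occurrences
#' in the current (possibly already partially masked) sense sequence are
#' replaced by `N`; the next motif then searches the updated sequence. The
#' masked sequence is shared by both strand scans, since `N` complements to
#' `N`.
#'
#' @param records Gene-record tibble.
#' @param spec A [literal_mask_spec()].
#' @return The records with masked sequences.
#' @export
#' @examples
#' r <- gene_records("g1", "TAGGGTAGGGA", 0, 11)
#' apply_literal_mask(r, literal_mask_spec())$seq  # "NNNNNNANNNN"
apply_literal_mask <- function(records, spec = literal_mask_spec()) {
  check_records(records)
  stopifnot(inherits(spec, "literal_mask_spec"))
  mask_one <- function(seq) {
    for (motif in spec$motifs) {
      pats <- motif
      if (spec$strand == "both") {
        pats <- unique(c(motif, reverse_complement(motif)))
      }
      for (p in pats) {
        m <- gregexpr(p, seq, fixed = TRUE)[[1]]
        if (m[1] == -1L) next
        ch <- strsplit(seq, "", fixed = TRUE)[[1]]
        for (s in as.integer(m)) ch[s:(s + nchar(p) - 1L)] <- "N"
        seq <- paste(ch, collapse = "")
      }
    }
    seq
  }
  mutate(records, seq = vapply(.data$seq, mask_one, character(1),
                               USE.NAMES = FALSE))
}

#' Scan before and after masking to isolate a motif's contribution
#'
#' Runs the same scan on the original records and on the masked records; the
#' downstream per-bin difference of the two distributions (see
#' [subtract_distribution()]) is the masked motif's contribution to the
#' curves.
#'
#' @param records Gene-record tibble.
#' @param mask Either an interval-mask tibble (`gene_id`, `start`, `end`) or
#'   a [literal_mask_spec()].
#' @inheritParams scan_genes
#' @return A list with motif-hit tibbles `unmasked` and `masked`.
#' @export
contribution_scan <- function(records, mask, pattern = "phqs", config = NULL,
                              template_coord = "first_g") {
  masked_records <- if (inherits(mask, "literal_mask_spec")) {
    apply_literal_mask(records, mask)
  } else {
    apply_interval_mask(records, mask)
  }
  list(
    unmasked = scan_genes(records, pattern, config = config,
                          template_coord = template_coord),
    masked = scan_genes(masked_records, pattern, config = config,
                        template_coord = template_coord)
  )
}
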