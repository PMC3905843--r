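#' Build a validated gene-record table
#'
#' A gene record stores the sense (non-template) strand of a gene, 5'->3',
#' optionally including an upstream flank, together with the 0-based index of
#' the transcription start site (TSS) within the sequence and the number of
#' transcribed bases from the TSS onwards. All downstream coordinates in the
#' package are TSS-relative: the TSS base itself is 0, upstream is negative.
#'
#' Sequences are normalised on construction: lowercase is either uppercased
#' (default, soft-masked bases kept) or hard-masked to `N`; any letter outside
#' `A`, `C`, `G`, `T` becomes `N`.
#'
#' @param gene_id Character vector of unique identifiers.
#' @param seq Character vector of DNA sequences (sense strand).
#' @param tss_offset Integer vector, 0-based index of the TSS base in `seq`.
#' @param gene_length Integer vector (>= 1), transcribed bases from the TSS.
#' @param lowercase `"uppercase"` to keep soft-masked bases, `"mask"` to turn
#'   lowercase letters into `N`.
#' @return A tibble with columns `gene_id`, `seq`, `tss_offset`, `gene_length`.
#' @export
#' @examples
#' gene_records("g1", "acgtn", 2, 3)
gene_records <- function(gene_id, seq, tss_offset, gene_length,
                         lowercase = c("uppercase", "mask")) {
  lowercase <- match.arg(lowercase)
  if (anyDuplicated(gene_id)) {
    abort("duplicated gene_id values in gene records")
  }
  seq <- normalize_seq(seq, lowercase = lowercase)
  tss_offset <- vctrs_int(tss_offset, "tss_offset")
  gene_length <- vctrs_int(gene_length, "gene_length")
  len <- nchar(seq)
  bad <- tss_offset < 0L | tss_offset >= len
  if (any(bad)) {
    abort(paste0("tss_offset out of range [0, seq length) for gene(s): ",
                 paste(gene_id[bad], collapse = ", ")))
  }
  bad <- gene_length < 1L | tss_offset + gene_length > len
  if (any(bad)) {
    abort(paste0("gene_length invalid (must satisfy 1 <= gene_length and ",
                 "tss_offset + gene_length <= seq length) for gene(s): ",
                 paste(gene_id[bad], collapse = ", ")))
  }
  tibble(gene_id = as.character(gene_id), seq = seq,
         tss_offset = tss_offset, gene_length = gene_length)
}

# uppercase (or hard-mask lowercase), then collapse non-ACGT letters to N
normalize_seq <- function(seq, lowercase = "uppercase") {
  seq <- as.character(seq)
  if (lowercase == "mask") {
    seq <- gsub("[a-z]", "N", seq)
  }
  seq <- toupper(seq)
  gsub("[^ACGT]", "N", seq)
}

vctrs_int <- function(x, what) {
  xi <- suppressWarnings(as.integer(x))
  if (any(is.na(xi) & !is.na(x)) || anyNA(xi)) {
    abort(paste0("`", what, "` must be a non-missing integer vector"))
  }
  xi
}

#' Read gene sequences from FASTA plus a TSS sidecar table
#'
#' The FASTA file holds one record per gene (sense strand, any line width).
#' The sidecar is a tab-separated table with columns `gene_id`, `tss_offset`
#' (0-based index of the TSS base) and `gene_length`; every FASTA record id
#' (the first whitespace-delimited word of the header) must have a sidecar
#' row. Record order follows the FASTA file.
#'
#' @param fasta_path Path to the FASTA file.
#' @param tss_table_path Path to the TSS sidecar TSV.
#' @inheritParams gene_records
#' @return A gene-record tibble (see [gene_records()]).
#' @export
read_gene_fasta <- function(fasta_path, tss_table_path,
                            lowercase = c("uppercase", "mask")) {
  lowercase <- match.arg(lowercase)
  # BStringSet keeps the original case so the hard-mask option can see it
  ss <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) abort("duplicated record ids in FASTA")
  tss <- readr::read_tsv(tss_table_path, col_types = readr::cols(
    gene_id = readr::col_character(),
    tss_offset = readr::col_integer(),
    gene_length = readr::col_integer()
  ), progress = FALSE)
  missing <- setdiff(ids, tss$gene_id)
  if (length(missing)) {
    abort(paste0("no TSS sidecar row for gene(s): ",
                 paste(missing, collapse = ", ")))
  }
  idx <- match(ids, tss$gene_id)
  gene_records(ids, as.character(ss), tss$tss_offset[idx],
               tss$gene_length[idx], lowercase = lowercase)
}

#' Write gene records to FASTA plus a TSS sidecar table
#'
#' Inverse of [read_gene_fasta()]; the pair round-trips losslessly.
#'
#' @param records Gene-record tibble.
#' @param fasta_path,tss_table_path Output paths.
#' @return `records`, invisibly.
#' @export
write_gene_fasta <- function(records, fasta_path, tss_table_path) {
  check_records(records)
  ss <- Biostrings::DNAStringSet(setNames(records$seq, records$gene_id))
  Biostrings::writeXStringSet(ss, fasta_path, width = 70L)
  readr::write_tsv(records[, c("gene_id", "tss_offset", "gene_length")],
                   tss_table_path, progress = FALSE)
  invisible(records)
}

#' Reverse-complement DNA sequences
#'
#' Vectorised over input; `N` complements to `N`.
#'
#' @param seq Character vector over the alphabet `A`, `C`, `G`, `T`, `N`.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' reverse_complement("GGGT")  # "ACCC"
reverse_complement <- function(seq) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
  unname(out)
}

#' Project genomic BED intervals into gene-relative mask coordinates
#'
#' Converts 0-based half-open genomic intervals (BED convention) into
#' intervals on the stored sense-strand sequence of each gene. For a `+`
#' strand locus with 1-based genomic start `S`, a BED interval `[b0, b1)`
#' maps to `[b0 - (S - 1), b1 - (S - 1))`; for a `-` strand locus with
#' 1-based genomic end `E` it maps to `[E - b1, E - b0)`. Results are clipped
#' to the sequence and empty intervals dropped.
#'
#' @param bed Tibble/data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param loci Tibble with columns `gene_id`, `chrom`, `start_1based`,
#'   `end_1based`, `strand` (`+`/`-`) giving the genomic footprint of each
#'   stored sequence (flank included).
#' @param records Gene-record tibble (supplies sequence lengths for clipping).
#' @return Mask tibble with columns `gene_id`, `start`, `end` (gene-relative,
#'   0-based half-open).
#' @export
project_genomic_intervals <- function(bed, loci, records) {
  check_records(records)
  stopifnot(all(c("chrom", "start", "end") %in% names(bed)),
            all(c("gene_id", "chrom", "start_1based", "end_1based", "strand")
                %in% names(loci)))
  orphan_chrom <- setdiff(unique(bed$chrom), unique(loci$chrom))
  if (length(orphan_chrom)) {
    inform(paste0("skipping intervals on chromosome(s) without a locus: ",
                  paste(orphan_chrom, collapse = ", ")))
  }
  no_rec <- setdiff(loci$gene_id, records$gene_id)
  if (length(no_rec)) {
    warn(paste0("locus rows without a gene record ignored: ",
                paste(no_rec, collapse = ", ")))
    loci <- loci[loci$gene_id %in% records$gene_id, , drop = FALSE]
  }
  lens <- setNames(nchar(records$seq), records$gene_id)
  hits <- dplyr::inner_join(as_tibble(bed), as_tibble(loci), by = "chrom",
                            relationship = "many-to-many")
  if (!nrow(hits)) return(tibble(gene_id = character(),
                                 start = integer(), end = integer()))
  rel <- hits |>
    mutate(
      rel_start = if_else(.data$strand == "+",
                          .data$start - (.data$start_1based - 1L),
                          .data$end_1based - .data$end),
      rel_end = if_else(.data$strand == "+",
                        .data$end - (.data$start_1based - 1L),
                        .data$end_1based - .data$start),
      len = unname(lens[.data$gene_id]),
      start = pmax(.data$rel_start, 0L),
      end = pmin(.data$rel_end, .data$len)
    ) |>
    filter(.data$start < .data$end) |>
    select("gene_id", "start", "end") |>
    arrange(.data$gene_id, .data$start)
  mutate(rel, start = as.integer(.data$start), end = as.integer(.data$end))
}

#' Read a gene-relative mask table or a BED3 file
#'
#' @param path Path to a TSV with header `gene_id`, `start`, `end`
#'   (gene-relative masks) or a headerless BED3 file (genomic intervals).
#' @return Tibble of intervals (0-based half-open).
#' @export
read_mask_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    start = readr::col_integer(),
    end = readr::col_integer()
  ), progress = FALSE)
}

#' @rdname read_mask_tsv
#' @export
read_bed3 <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                  col_types = "cii", progress = FALSE)
}

#' @rdname read_mask_tsv
#' @export
read_locus_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    chrom = readr::col_character(),
    start_1based = readr::col_integer(),
    end_1based = readr::col_integer(),
    strand = readr::col_character()
  ), progress = FALSE)
}

hit_cols <- c(gene_id = "c", strand = "c", sense_start = "i", sense_end = "i",
              tss_rel_coord = "i", n_tracts = "i", category = "c",
              matched_seq = "c", pattern = "c")

#' Write and read motif-hit tables
#'
#' Hit tables are TSVs with the fixed column set `gene_id`, `strand`,
#' `sense_start`, `sense_end` (0-based half-open, sense coordinates),
#' `tss_rel_coord` (first-guanine position relative to the TSS), `n_tracts`,
#' `category`, `matched_seq` (scanned orientation) and `pattern`. Writing then
#' reading returns identical records.
#'
#' @param hits Motif-hit tibble.
#' @param path File path.
#' @return `write_hits()` returns `hits` invisibly; `read_hits()` the tibble.
#' @export
write_hits <- function(hits, path) {
  check_hits(hits)
  readr::write_tsv(hits[, names(hit_cols)], path, progress = FALSE)
  invisible(hits)
}

#' @rdname write_hits
#' @export
read_hits <- function(path) {
  readr::read_tsv(path, col_types = paste(hit_cols, collapse = ""),
                  progress = FALSE)
}

#' Write and read binned frequency distributions
#'
#' Distribution TSVs carry `bin_start`, `strand`, `category`, `count`,
#' `freq_per_100_genes` and, when present, `normalized`; the file header line
#' `# n_genes=<n> lo=<lo> hi=<hi> bin_width=<w>` preserves the binning
#' metadata so the round-trip through [read_distribution()] is lossless.
#'
#' @param dist A `phqs_distribution` (see [bin_hits()]).
#' @param path File path.
#' @export
write_distribution <- function(dist, path) {
  meta <- sprintf("# n_genes=%d lo=%d hi=%d bin_width=%d",
                  attr(dist, "n_genes"), attr(dist, "lo"),
                  attr(dist, "hi"), attr(dist, "bin_width"))
  writeLines(meta, path)
  readr::write_tsv(as_tibble(dist), path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(dist)
}

#' @rdname write_distribution
#' @export
read_distribution <- function(path) {
  meta <- readLines(path, n = 1L)
  kv <- regmatches(meta, gregexpr("[a-z_]+=-?[0-9]+", meta))[[1]]
  vals <- setNames(as.integer(sub(".*=", "", kv)), sub("=.*", "", kv))
  body <- readr::read_tsv(path, skip = 1L, progress = FALSE,
                          col_types = readr::cols(
                            bin_start = readr::col_integer(),
                            strand = readr::col_character(),
                            category = readr::col_character(),
                            count = readr::col_integer(),
                            .default = readr::col_double()
                          ))
  new_distribution(body, lo = vals[["lo"]], hi = vals[["hi"]],
                   bin_width = vals[["bin_width"]], n_genes = vals[["n_genes"]])
}

check_records <- function(records) {
  need <- c("gene_id", "seq", "tss_offset", "gene_length")
  if (!all(need %in% names(records))) {
    abort(paste0("gene records need columns: ", paste(need, collapse = ", ")))
  }
  invisible(records)
}

check_hits <- function(hits) {
  if (!all(names(hit_cols) %in% names(hits))) {
    abort(paste0("hit table needs columns: ",
                 paste(names(hit_cols), collapse = ", ")))
  }
  invisible(hits)
}
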