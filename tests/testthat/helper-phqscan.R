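# Shared fixtures, built in code.

# random DNA with a given G fraction; remaining mass split over A/C/T
random_dna <- function(n, g_frac = 0.2) {
  p <- c(A = (1 - g_frac) / 3, C = (1 - g_frac) / 3, G = g_frac,
         T = (1 - g_frac) / 3)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# one-record gene set with TSS at the sequence start
one_gene <- function(seq, tss_offset = 0L, gene_length = NULL) {
  gene_records("g1", seq, tss_offset,
               gene_length %||% (nchar(seq) - tss_offset))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# spans as a plain data frame for comparison
spans <- function(x) as.data.frame(x[, c("start", "end")])

all_configs <- function() {
  list(phqs = scan_config("phqs"), pqs = scan_config("pqs"),
       prescan = scan_config("isolated_g3"))
}

# minimal synthetic hits table for distribution/bias unit tests
fake_hits <- function(strand, category, tss_rel_coord,
                      gene_id = "g1", pattern = "phqs") {
  tibble::tibble(
    gene_id = gene_id, strand = strand,
    sense_start = pmax(tss_rel_coord, 0L), sense_end = pmax(tss_rel_coord, 0L) + 7L,
    tss_rel_coord = as.integer(tss_rel_coord),
    n_tracts = 2L, category = category,
    matched_seq = "GGGTGGG", pattern = pattern
  )
}
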