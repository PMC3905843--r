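test_that("FASTA + sidecar reading normalises sequences and preserves order", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  tss <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(">g1 some description", "acgtn",
               ">g2", "GGGT", "GGG",
               ">g3", "acgRyt"), fa)
  readr::write_tsv(tibble::tibble(gene_id = c("g1", "g2", "g3"),
                                  tss_offset = c(2L, 0L, 1L),
                                  gene_length = c(3L, 7L, 5L)), tss)
  recs <- read_gene_fasta(fa, tss)
  expect_equal(recs$gene_id, c("g1", "g2", "g3"))
  expect_equal(recs$seq, c("ACGTN", "GGGTGGG", "ACGNNT"))
  expect_equal(recs$tss_offset, c(2L, 0L, 1L))

  # hard-mask option turns soft-masked (lowercase) bases into N
  masked <- read_gene_fasta(fa, tss, lowercase = "mask")
  expect_equal(masked$seq[1], "NNNNN")
  expect_equal(masked$seq[2], "GGGTGGG")
})

test_that("sidecar validation fails loudly", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  tss <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(">g1", "ACGTN"), fa)
  readr::write_tsv(tibble::tibble(gene_id = "gX", tss_offset = 0L,
                                  gene_length = 1L), tss)
  expect_error(read_gene_fasta(fa, tss), "g1")

  readr::write_tsv(tibble::tibble(gene_id = "g1", tss_offset = 5L,
                                  gene_length = 1L), tss)
  expect_error(read_gene_fasta(fa, tss), "tss_offset")

  readr::write_tsv(tibble::tibble(gene_id = "g1", tss_offset = 2L,
                                  gene_length = 4L), tss)
  expect_error(read_gene_fasta(fa, tss), "gene_length")
})

test_that("gene records round-trip through FASTA + sidecar", {
  set.seed(101)
  recs <- gene_records(c("a", "b", "c"),
                       vapply(c(80, 120, 55), random_dna, ""),
                       c(10L, 0L, 30L), c(50L, 100L, 20L))
  fa <- withr::local_tempfile(fileext = ".fasta")
  tss <- withr::local_tempfile(fileext = ".tsv")
  write_gene_fasta(recs, fa, tss)
  expect_equal(read_gene_fasta(fa, tss), recs)
})

test_that("reverse_complement follows the standard complement and is an involution", {
  expect_equal(reverse_complement("GGGT"), "ACCC")
  expect_equal(reverse_complement("N"), "N")
  set.seed(7)
  for (s in replicate(20, random_dna(200, runif(1, 0.1, 0.5)))) {
    expect_equal(reverse_complement(reverse_complement(s)), s)
  }
})

test_that("genomic intervals project to gene-relative coordinates per strand", {
  recs <- gene_records(c("plus", "minus"), strrep("A", c(50, 50)), 0L, 50L)
  loci <- tibble::tibble(
    gene_id = c("plus", "minus"), chrom = c("chr1", "chr2"),
    start_1based = c(101L, 151L), end_1based = c(150L, 200L),
    strand = c("+", "-"))
  bed <- tibble::tibble(chrom = c("chr1", "chr2"),
                        start = c(110L, 190L), end = c(120L, 195L))
  m <- project_genomic_intervals(bed, loci, recs)
  expect_equal(m[m$gene_id == "plus", ]$start, 10L)
  expect_equal(m[m$gene_id == "plus", ]$end, 20L)
  expect_equal(m[m$gene_id == "minus", ]$start, 5L)
  expect_equal(m[m$gene_id == "minus", ]$end, 10L)
})

test_that("projection clips to the sequence and drops empty or orphan intervals", {
  recs <- gene_records("g", strrep("A", 30), 0L, 30L)
  loci <- tibble::tibble(gene_id = "g", chrom = "chr1",
                         start_1based = 101L, end_1based = 130L, strand = "+")
  bed <- tibble::tibble(chrom = c("chr1", "chr1", "chrX"),
                        start = c(90L, 95L, 10L), end = c(95L, 110L, 20L))
  expect_message(m <- project_genomic_intervals(bed, loci, recs), "chrX")
  # entirely-upstream interval dropped; straddling one clipped to [0, 10)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(0L, 10L))
})

test_that("minus-strand projection equals projecting the mirrored interval on plus", {
  len <- 40L
  recs <- gene_records(c("p", "m"), strrep("A", c(len, len)), 0L, len)
  S <- 201L; E <- S + len - 1L
  loci <- tibble::tibble(gene_id = c("p", "m"), chrom = c("cp", "cm"),
                         start_1based = S, end_1based = E,
                         strand = c("+", "-"))
  set.seed(5)
  for (i in 1:20) {
    b0 <- sample((S - 1L):(E - 2L), 1L); b1 <- sample((b0 + 1L):E, 1L)
    plus <- project_genomic_intervals(
      tibble::tibble(chrom = "cp", start = b0, end = b1), loci, recs)
    # mirror [b0, b1) within the locus footprint, then project on minus
    mb0 <- S - 1L + (E - b1); mb1 <- S - 1L + (E - b0)
    minus <- project_genomic_intervals(
      tibble::tibble(chrom = "cm", start = mb0, end = mb1), loci, recs)
    expect_equal(unname(unlist(plus[, c("start", "end")])),
                 unname(unlist(minus[, c("start", "end")])))
  }
})

test_that("hit and distribution tables round-trip through TSV", {
  recs <- one_gene("GGGTGGGAAAAAAAAAACCCACCC")
  hits <- scan_genes(recs, "phqs")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hits(hits, path)
  expect_equal(as.data.frame(read_hits(path)), as.data.frame(hits))

  # empty hit list gives a header-only file that reads back empty
  write_hits(hits[0, ], path)
  expect_equal(length(readLines(path)), 1L)
  expect_equal(nrow(read_hits(path)), 0L)

  dist <- bin_hits(hits, n_genes = 1, lo = 0, hi = 400, bin_width = 100)
  dpath <- withr::local_tempfile(fileext = ".tsv")
  write_distribution(dist, dpath)
  back <- read_distribution(dpath)
  expect_equal(as.data.frame(back), as.data.frame(dist))
  expect_equal(attr(back, "n_genes"), attr(dist, "n_genes"))
  expect_equal(attr(back, "bin_width"), attr(dist, "bin_width"))
})
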