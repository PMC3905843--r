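test_that("G-run finding and chaining follow maximality and the loop bound", {
  runs <- find_g_runs("GGGTGGT", 2L)
  expect_equal(spans(runs), data.frame(start = c(0L, 4L), end = c(3L, 6L)))
  expect_equal(nrow(find_g_runs("AAAA", 1L)), 0L)
  expect_equal(find_g_runs(strrep("G", 15), 3L)$length, 15L)

  chained <- chain_runs(find_g_runs("GGGTGGG", 3L), 7L)
  expect_equal(chained$chain, c(1L, 1L))
  far <- chain_runs(find_g_runs(paste0("GGG", strrep("T", 8), "GGG"), 3L), 7L)
  expect_equal(far$chain, c(1L, 2L))
  expect_equal(chain_runs(find_g_runs("GGG", 3L), 7L)$chain, 1L)
})

test_that("minimal pattern instances scan as expected", {
  phqs <- scan_config("phqs"); pqs <- scan_config("pqs")
  h <- scan_strand("GGGTGGG", phqs)
  expect_equal(as.data.frame(h),
               data.frame(start = 0L, end = 7L, n_tracts = 2L))

  # the G15 worked example: one PHQS hit (single long tract, 1G) and one
  # PQS hit (parses as four G3 tracts with single-G loops)
  g15 <- strrep("G", 15)
  h15 <- scan_strand(g15, phqs)
  expect_equal(nrow(h15), 1L)
  expect_equal(c(h15$start, h15$end), c(0L, 15L))
  expect_equal(motif_category(h15$n_tracts), "1G")
  p15 <- scan_strand(g15, pqs)
  expect_equal(as.data.frame(p15),
               data.frame(start = 0L, end = 15L, n_tracts = 1L))

  # a gap of 8 exceeds the loop bound
  expect_equal(nrow(scan_strand(paste0("GGG", strrep("T", 8), "GGG"), phqs)),
               1L * 0L)
  # three tracts make a PHQS 3G hit but no PQS hit
  s3 <- "GGGTGGGTGGG"
  expect_equal(nrow(scan_strand(s3, pqs)), 0L)
  h3 <- scan_strand(s3, phqs)
  expect_equal(h3$n_tracts, 3L)
  expect_equal(motif_category(h3$n_tracts), "3G")
})

test_that("lone G-runs hit PHQS iff L >= 7 and PQS iff L >= 15", {
  phqs <- scan_config("phqs"); pqs <- scan_config("pqs")
  runlen_hits <- function(L, cfg) nrow(scan_strand(strrep("G", L), cfg))
  expect_equal(runlen_hits(6, phqs), 0L)
  expect_equal(runlen_hits(7, phqs), 1L)
  expect_equal(motif_category(scan_strand(strrep("G", 7), phqs)$n_tracts), "1G")
  expect_equal(runlen_hits(14, pqs), 0L)
  expect_equal(runlen_hits(15, pqs), 1L)
  # closed-form floor((L+1)/4) >= 4 rule agrees with the oracle for all L
  for (L in 3:20) {
    expect_equal(runlen_hits(L, pqs) == 1L, (L + 1L) %/% 4L >= 4L)
    expect_equal(runlen_hits(L, pqs), nrow(regex_oracle(strrep("G", L), pqs)))
    expect_equal(runlen_hits(L, phqs), nrow(regex_oracle(strrep("G", L), phqs)))
  }
})

test_that("oracle handles hand-traced worked cases", {
  expect_equal(spans(regex_oracle("GGGTGGG", scan_config("phqs"))),
               data.frame(start = 0L, end = 7L))
  # G10 parses as G6-L1-G3 under the backtracking engine
  expect_equal(spans(regex_oracle(strrep("G", 10), scan_config("phqs"))),
               data.frame(start = 0L, end = 10L))
  expect_equal(nrow(regex_oracle("GGGTGG", scan_config("phqs"))), 0L)
})

test_that("chain scanner equals the backtracking oracle on random sequences", {
  set.seed(2024)
  cfgs <- all_configs()
  for (i in 1:150) {
    s <- random_dna(500, sample(c(0.1, 0.2, 0.3, 0.4), 1))
    for (cfg in cfgs) {
      expect_equal(spans(scan_strand(s, cfg)), spans(regex_oracle(s, cfg)))
    }
  }
})

test_that("hit spans are disjoint and concatenation shifts hits additively", {
  set.seed(31)
  cfg <- scan_config("phqs")
  for (i in 1:25) {
    a <- random_dna(300, 0.3); b <- random_dna(300, 0.3)
    ha <- scan_strand(a, cfg); hb <- scan_strand(b, cfg)
    expect_true(all(ha$start[-1] >= ha$end[-nrow(ha)]))
    spacer <- strrep("T", 8)
    hab <- scan_strand(paste0(a, spacer, b), cfg)
    shifted <- rbind(spans(ha), spans(hb) + nchar(a) + 8L)
    expect_equal(spans(hab), shifted, ignore_attr = TRUE)
  }
})

test_that("every PQS span lies inside exactly one PHQS span, and categories partition hits", {
  set.seed(77)
  phqs <- scan_config("phqs"); pqs <- scan_config("pqs")
  for (i in 1:20) {
    s <- random_dna(800, 0.35)
    hp <- scan_strand(s, phqs); hq <- scan_strand(s, pqs)
    if (nrow(hq)) {
      containing <- vapply(seq_len(nrow(hq)), function(k) {
        sum(hp$start <= hq$start[k] & hp$end >= hq$end[k])
      }, integer(1))
      expect_true(all(containing == 1L))
    }
    cats <- motif_category(hp$n_tracts)
    expect_equal(sum(table(factor(cats, c("1G", "2G", "3G", "4G+")))),
                 nrow(hp))
  }
})

test_that("both-strand gene scanning mirrors coordinates correctly", {
  # template-only motif: sense strand holds the reverse complement
  r <- one_gene("CCCACCC")
  h <- scan_genes(r, "phqs")
  expect_equal(h$strand, "template")
  expect_equal(c(h$sense_start, h$sense_end), c(0L, 7L))
  expect_equal(h$tss_rel_coord, 6L)  # first G of the motif = rightmost sense base
  expect_equal(h$matched_seq, "GGGTGGG")

  # span_start option reports the sense span start instead
  h2 <- scan_genes(r, "phqs", template_coord = "span_start")
  expect_equal(h2$tss_rel_coord, 0L)

  # one motif per strand, separated by a long A spacer
  r2 <- one_gene(paste0("GGGTGGG", strrep("A", 10), "CCCACCC"))
  h3 <- scan_genes(r2, "phqs")
  expect_equal(sort(h3$strand), c("non_template", "template"))
  expect_equal(h3$matched_seq, c("GGGTGGG", "GGGTGGG"))
})

test_that("scanning the reverse complement swaps strands and mirrors spans", {
  set.seed(12)
  for (i in 1:15) {
    s <- random_dna(400, 0.3)
    L <- nchar(s)
    fwd <- scan_genes(one_gene(s), "phqs")
    rev <- scan_genes(one_gene(reverse_complement(s)), "phqs")
    mirrored <- data.frame(
      strand = as.character(ifelse(rev$strand == "non_template", "template",
                                   "non_template")),
      sense_start = as.integer(L - rev$sense_end),
      sense_end = as.integer(L - rev$sense_start),
      stringsAsFactors = FALSE)
    key <- function(d) {
      d <- d[order(d$strand, d$sense_start),
             c("strand", "sense_start", "sense_end")]
      rownames(d) <- NULL
      d
    }
    expect_equal(key(as.data.frame(fwd[, c("strand", "sense_start", "sense_end")])),
                 key(mirrored))
  }
})

test_that("isolated-G3 keeps exactly lone G3 tracts far from any G>=2 run", {
  g3 <- function(s) isolated_g3_strand(s)
  expect_equal(spans(g3("AAAAGGGAAAA")), data.frame(start = 4L, end = 7L))
  expect_equal(nrow(g3("GGGTTGG")), 0L)   # GG run 2 nt away
  expect_equal(nrow(g3("AGGGGA")), 0L)    # run length 4, not 3
  expect_equal(nrow(g3(paste0("GGG", strrep("A", 8), "GG"))), 1L)  # 8 > 7 ok
  expect_equal(nrow(g3(paste0("GGG", strrep("A", 7), "GG"))), 0L)
  # a lone single G nearby does not break isolation (pre-scan ignores G1)
  expect_equal(nrow(g3("AAGGGAAGAA")), 1L)
})

test_that("isolated-G3 closed form equals the pre-scan oracle plus discard rules", {
  set.seed(99)
  pre <- scan_config("isolated_g3")
  for (i in 1:100) {
    s <- random_dna(500, sample(c(0.1, 0.2, 0.3, 0.4), 1))
    via_oracle <- regex_oracle(s, pre)
    keep <- vapply(seq_len(nrow(via_oracle)), function(k) {
      seg <- substr(s, via_oracle$start[k] + 1L, via_oracle$end[k])
      runs <- find_g_runs(seg, 2L)
      nrow(runs) == 1L && runs$length == 3L
    }, logical(1))
    expect_equal(spans(isolated_g3_strand(s)), spans(via_oracle[keep, ]))
  }
})
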