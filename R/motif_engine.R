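#' Scan configurations for the three G-tract patterns
#'
#' The scanner is parameterised by the minimum G-tract length, the loop
#' length bounds and the minimum number of outer repeats of the three backtracking
#' patterns the scanner reproduces:
#'
#' * **phqs** — `G{3,}(.{1,7}?G{3,}){1,}`: two or more tracts of >= 3 G,
#'   loops of 1-7 nt (any base, G included). Two DNA tracts suffice because
#'   the RNA transcript supplies the remaining tracts of the hybrid
#'   G-quadruplex.
#' * **pqs** — `G{3,}(.{1,7}?G{3,}){3,}`: four or more tracts, the classic
#'   intramolecular G-quadruplex pattern.
#' * **isolated_g3 pre-scan** — `G{2,}(.{1,7}?G{2,}){0,}`: any group of
#'   G>=2 tracts within loop distance; filtered afterwards down to isolated
#'   exact-G3 tracts.
#'
#' @param pattern One of `"phqs"`, `"pqs"`, `"isolated_g3"`.
#' @param tract_min,loop_min,loop_max,repeats_min Override individual fields
#'   of the preset (required tract count is `repeats_min + 1`).
#' @return A list of class `scan_config`.
#' @export
#' @examples
#' scan_config("pqs")
scan_config <- function(pattern = c("phqs", "pqs", "isolated_g3"),
                        tract_min = NULL, loop_min = NULL, loop_max = NULL,
                        repeats_min = NULL) {
  pattern <- match.arg(pattern)
  preset <- switch(pattern,
    phqs = list(tract_min = 3L, loop_min = 1L, loop_max = 7L, repeats_min = 1L),
    pqs = list(tract_min = 3L, loop_min = 1L, loop_max = 7L, repeats_min = 3L),
    isolated_g3 = list(tract_min = 2L, loop_min = 1L, loop_max = 7L,
                       repeats_min = 0L)
  )
  cfg <- list(
    pattern = pattern,
    tract_min = as.integer(tract_min %||% preset$tract_min),
    loop_min = as.integer(loop_min %||% preset$loop_min),
    loop_max = as.integer(loop_max %||% preset$loop_max),
    repeats_min = as.integer(repeats_min %||% preset$repeats_min)
  )
  stopifnot(cfg$tract_min >= 2L, cfg$loop_min >= 1L,
            cfg$loop_max >= cfg$loop_min, cfg$repeats_min >= 0L)
  structure(cfg, class = "scan_config")
}

#' Find maximal runs of consecutive guanines
#'
#' @param seq A single DNA string.
#' @param min_len Minimum run length to report.
#' @return Tibble with 0-based half-open `start`, `end` and `length`,
#'   left to right.
#' @export
find_g_runs <- function(seq, min_len = 1L) {
  m <- gregexpr("G+", seq)[[1]]
  if (m[1] == -1L) {
    return(tibble(start = integer(), end = integer(), length = integer()))
  }
  start <- as.integer(m) - 1L
  len <- as.integer(attr(m, "match.length"))
  keep <- len >= min_len
  start <- start[keep]
  len <- len[keep]
  tibble(start = start, end = start + len, length = len)
}

#' Group G-runs into chains linked by admissible loops
#'
#' Adjacent runs belong to the same chain when the gap between them is
#' between 1 and `loop_max` nucleotides; a larger gap starts a new chain.
#'
#' @param runs Output of [find_g_runs()] (sorted, maximal).
#' @param loop_max Maximum loop length.
#' @return `runs` with an integer `chain` column (1-based, left to right).
#' @export
chain_runs <- function(runs, loop_max = 7L) {
  n <- nrow(runs)
  if (n == 0L) return(mutate(runs, chain = integer()))
  gap <- runs$start[-1L] - runs$end[-n]
  mutate(runs, chain = cumsum(c(1L, as.integer(gap > loop_max))))
}

# tracts of exactly tract_min G separated by 1-G loops fit a run of length L
# floor((L + 1) / (tract_min + 1)) times; this is the run's tract capacity
run_capacity <- function(L, tract_min) (L + 1L) %/% (tract_min + 1L)

#' Scan one strand with the chain scanner
#'
#' Closed-form equivalent of leftmost non-overlapping matching of the
#' backtracking pattern (greedy tract and outer quantifiers, lazy
#' loop quantifier): each chain of G-runs (length >= `tract_min`, gaps
#' 1..`loop_max`) yields exactly one hit spanning the whole chain iff the sum
#' of per-run tract capacities reaches `repeats_min + 1`. Equivalence to
#' [regex_oracle()] is asserted in the test suite.
#'
#' @param seq A single DNA string in the orientation to be scanned.
#' @param config A [scan_config()].
#' @return Tibble with 0-based half-open `start`, `end` and `n_tracts` (the
#'   number of maximal qualifying G-runs in the span).
#' @export
#' @examples
#' scan_strand("GGGTGGG", scan_config("phqs"))
scan_strand <- function(seq, config = scan_config("phqs")) {
  runs <- chain_runs(find_g_runs(seq, config$tract_min), config$loop_max)
  if (!nrow(runs)) {
    return(tibble(start = integer(), end = integer(), n_tracts = integer()))
  }
  runs |>
    group_by(.data$chain) |>
    summarise(start = .data$start[1L], end = .data$end[n()],
              n_tracts = n(),
              capacity = sum(run_capacity(.data$length, config$tract_min)),
              .groups = "drop") |>
    filter(.data$capacity >= config$repeats_min + 1L) |>
    select("start", "end", "n_tracts")
}

#' Reference backtracking-pattern matcher
#'
#' Matches the literal backtracking pattern, e.g.
#' `G{3,}(.{1,7}?G{3,}){1,}`, globally (leftmost, non-overlapping) with a
#' PCRE backtracking engine in which the loop quantifier is lazy and the
#' rest greedy. Test-support oracle for [scan_strand()]; kept deliberately
#' independent of the chain scanner.
#'
#' @inheritParams scan_strand
#' @return Tibble with 0-based half-open `start` and `end` spans.
#' @export
regex_oracle <- function(seq, config = scan_config("phqs")) {
  pat <- sprintf("G{%d,}(.{%d,%d}?G{%d,}){%d,}",
                 config$tract_min, config$loop_min, config$loop_max,
                 config$tract_min, config$repeats_min)
  m <- gregexpr(pat, seq, perl = TRUE)[[1]]
  if (m[1] == -1L) return(tibble(start = integer(), end = integer()))
  start <- as.integer(m) - 1L
  tibble(start = start, end = start + attr(m, "match.length"))
}

#' Bucket tract counts into the 1G/2G/3G/4G+ categories
#'
#' @param n_tracts Integer vector of maximal-G-run counts per hit.
#' @return Character vector of categories.
#' @export
motif_category <- function(n_tracts) {
  dplyr::case_when(
    n_tracts >= 4L ~ "4G+",
    n_tracts == 3L ~ "3G",
    n_tracts == 2L ~ "2G",
    n_tracts == 1L ~ "1G"
  )
}

#' Scan gene records on both strands
#'
#' The non-template (sense) strand is scanned as stored; the template strand
#' is scanned as the reverse complement. Template spans are reported back in
#' sense coordinates. The TSS-relative coordinate of a hit is the position of
#' its first guanine in motif orientation: the sense span start on the
#' non-template strand and, by default, the rightmost sense base on the
#' template strand (`template_coord = "span_start"` uses the sense span start
#' instead).
#'
#' @param records Gene-record tibble (see [gene_records()]).
#' @param pattern Pattern preset passed to [scan_config()]; ignored when
#'   `config` is given. `"isolated_g3"` dispatches to [scan_isolated_g3()].
#' @param config Optional explicit [scan_config()].
#' @param template_coord `"first_g"` (default) or `"span_start"`.
#' @return Motif-hit tibble (see [write_hits()] for the column contract).
#'   Per gene, non-template hits are listed first, then template hits, each
#'   block left to right by sense start.
#' @export
#' @examples
#' recs <- gene_records("g1", "GGGTGGGAAACCCACCC", 0, 17)
#' scan_genes(recs, "phqs")
scan_genes <- function(records, pattern = c("phqs", "pqs", "isolated_g3"),
                       config = NULL,
                       template_coord = c("first_g", "span_start")) {
  pattern <- match.arg(pattern)
  template_coord <- match.arg(template_coord)
  check_records(records)
  if (is.null(config) && pattern == "isolated_g3") {
    return(scan_isolated_g3(records, template_coord = template_coord))
  }
  config <- config %||% scan_config(pattern)
  purrr::pmap(records[, c("gene_id", "seq", "tss_offset")],
              scan_one_gene, config = config,
              template_coord = template_coord, pattern_label = config$pattern) |>
    purrr::list_rbind()
}

scan_one_gene <- function(gene_id, seq, tss_offset, config, template_coord,
                          pattern_label) {
  L <- nchar(seq)
  nt <- scan_strand(seq, config)
  nt <- tibble(
    gene_id = gene_id, strand = "non_template",
    sense_start = nt$start, sense_end = nt$end,
    tss_rel_coord = nt$start - tss_offset,
    n_tracts = nt$n_tracts,
    matched_seq = stringr::str_sub(seq, nt$start + 1L, nt$end)
  )
  rc <- reverse_complement(seq)
  tm <- scan_strand(rc, config)
  tm <- tibble(
    gene_id = gene_id, strand = "template",
    sense_start = L - tm$end, sense_end = L - tm$start,
    tss_rel_coord = if (template_coord == "first_g") {
      (L - 1L) - tm$start - tss_offset
    } else {
      L - tm$end - tss_offset
    },
    n_tracts = tm$n_tracts,
    matched_seq = stringr::str_sub(rc, tm$start + 1L, tm$end)
  )
  tm <- arrange(tm, .data$sense_start)
  bind_rows(nt, tm) |>
    mutate(category = motif_category(.data$n_tracts),
           pattern = pattern_label) |>
    select("gene_id", "strand", "sense_start", "sense_end", "tss_rel_coord",
           "n_tracts", "category", "matched_seq", "pattern")
}

#' Isolated-G3 spans on one strand (closed form)
#'
#' Keeps exactly the maximal G-runs of length 3 that are separated from the
#' nearest other maximal G-run of length >= 2 by more than 7 nt on both
#' sides. Equivalent to matching `G{2,}(.{1,7}?G{2,}){0,}` and discarding
#' matches with more than one tract or a tract size other than 3.
#'
#' @param seq A single DNA string in the orientation to be scanned.
#' @param isolation_gap Minimum separating distance (exclusive), default 7.
#' @return Tibble of 0-based half-open `start`, `end` spans.
#' @export
isolated_g3_strand <- function(seq, isolation_gap = 7L) {
  runs <- find_g_runs(seq, 2L)
  n <- nrow(runs)
  if (!n) return(tibble(start = integer(), end = integer()))
  gap_prev <- c(Inf, runs$start[-1L] - runs$end[-n])
  gap_next <- c(runs$start[-1L] - runs$end[-n], Inf)
  keep <- runs$length == 3L & gap_prev > isolation_gap & gap_next > isolation_gap
  tibble(start = runs$start[keep], end = runs$end[keep])
}

#' Scan gene records for isolated G3 tracts
#'
#' Control motifs unable to form a hybrid G-quadruplex: single exact-G3
#' tracts more than 7 nt away from any G>=2 run. Emitted per strand with
#' `n_tracts = 1`, category `1G`, pattern `isolated_g3`.
#'
#' @inheritParams scan_genes
#' @return Motif-hit tibble.
#' @export
scan_isolated_g3 <- function(records,
                             template_coord = c("first_g", "span_start")) {
  template_coord <- match.arg(template_coord)
  check_records(records)
  purrr::pmap(records[, c("gene_id", "seq", "tss_offset")],
              function(gene_id, seq, tss_offset) {
    L <- nchar(seq)
    nt <- isolated_g3_strand(seq)
    nt <- tibble(gene_id = gene_id, strand = "non_template",
                 sense_start = nt$start, sense_end = nt$end,
                 tss_rel_coord = nt$start - tss_offset,
                 n_tracts = 1L,
                 matched_seq = stringr::str_sub(seq, nt$start + 1L, nt$end))
    rc <- reverse_complement(seq)
    tm <- isolated_g3_strand(rc)
    tm <- tibble(gene_id = gene_id, strand = "template",
                 sense_start = L - tm$end, sense_end = L - tm$start,
                 tss_rel_coord = if (template_coord == "first_g") {
                   (L - 1L) - tm$start - tss_offset
                 } else {
                   L - tm$end - tss_offset
                 },
                 n_tracts = 1L,
                 matched_seq = stringr::str_sub(rc, tm$start + 1L, tm$end))
    bind_rows(nt, arrange(tm, .data$sense_start)) |>
      mutate(category = "1G", pattern = "isolated_g3") |>
      select("gene_id", "strand", "sense_start", "sense_end",
             "tss_rel_coord", "n_tracts", "category", "matched_seq",
             "pattern")
  }) |>
    purrr::list_rbind()
}
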