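# Verification protocol: misassembly remapping, identity windows,
# pair spanning.

test_that("clean contigs produce no suspect flags", {
  ts <- generate_paralog_pair(small_spec(seed = 21))
  rs <- simulate_reads(ts, read_sim_spec(coverage = 50, error_rate = 0.01,
                                         seed = 21),
                       genes = c("sp1_H1", "sp1_H2"))
  fl <- remap_low_stringency(rs, ts$genes[c("sp1_H1", "sp1_H2")])
  expect_equal(nrow(fl), 0L)
  expect_gt(attr(fl, "n_anchored"), 0.9 * length(rs$r1) * 2)
  expect_error(remap_low_stringency(Biostrings::DNAStringSet(),
                                    ts$genes[["sp1_H1"]]), "empty")
})

test_that("a seeded chimera is flagged near its true breakpoint", {
  ts <- generate_paralog_pair(small_spec(seed = 22))
  rs <- simulate_reads(ts, read_sim_spec(coverage = 50, error_rate = 0.01,
                                         seed = 22),
                       genes = c("sp1_H1", "sp1_H2"))
  for (bp in c(1500, 3000)) {
    ch <- make_chimera(ts, bp)
    fl <- remap_low_stringency(rs, ch)
    expect_gte(nrow(fl), 1L)
    expect_lte(min(abs(fl$position - bp)), 200L)
    expect_true(all(fl$support >= 3))
  }
})

test_that("two chimeric junctions in one contig give two suspect clusters", {
  ts <- generate_paralog_pair(small_spec(seed = 23))
  rs <- simulate_reads(ts, read_sim_spec(coverage = 50, error_rate = 0.01,
                                         seed = 23),
                       genes = c("sp1_H1", "sp1_H2"))
  h1 <- as.character(ts$genes[["sp1_H1"]])
  h2 <- as.character(ts$genes[["sp1_H2"]])
  # both breakpoints upstream of the H2 insert so coordinates are colinear
  p1 <- 800; p2 <- 2000
  dbl <- paste0(substr(h1, 1, p1), substr(h2, p1 + 1, p2),
                substr(h1, p2 + 1, nchar(h1)))
  fl <- remap_low_stringency(rs, Biostrings::DNAStringSet(c(dbl = dbl)))
  expect_gte(nrow(fl), 2L)
  expect_lte(min(abs(fl$position - p1)), 200L)
  expect_lte(min(abs(fl$position - p2)), 200L)
})

test_that("identity windows flag identical and engineered-identical regions", {
  ts <- generate_paralog_pair(small_spec(seed = 24))
  h1 <- as.character(ts$genes[["sp1_H1"]])
  h2c <- h2_without_insert(ts)
  # identical sequences: every window flagged at identity 1
  rep1 <- scan_identity_windows(h1, h1)
  expect_true(all(rep1$flagged))
  expect_true(all(rep1$identity == 1))
  # ~30% divergent paralogs: no window reaches 95%
  rep2 <- scan_identity_windows(h1, h2c)
  expect_false(any(rep2$flagged))
  # symmetric in its arguments
  rep2b <- scan_identity_windows(h2c, h1)
  expect_equal(rep2$identity, rep2b$identity, tolerance = 1e-12)
  # engineer a 150-nt identical block mid-gene
  h2eng <- paste0(substr(h2c, 1, 1999), substr(h1, 2000, 2149),
                  substr(h2c, 2150, nchar(h2c)))
  rep3 <- scan_identity_windows(h1, h2eng)
  hit <- rep3[rep3$flagged, , drop = FALSE]
  expect_gte(nrow(hit), 1L)
  expect_true(any(hit$start_a <= 2149 & hit$end_a >= 2000))
  expect_error(scan_identity_windows("ACGT", h1), "window")
})

test_that("pair spanning passes long-fragment windows and fails impossible ones", {
  ts <- generate_paralog_pair(tiny_spec(seed = 25))
  g <- "sp1_H1"
  L <- length(ts$genes[[g]])
  rs <- simulate_reads(ts, read_sim_spec(read_length_nt = 100,
                                         fragment_mean_nt = 400,
                                         fragment_sd_nt = 20,
                                         coverage = 50, error_rate = 0,
                                         seed = 25), genes = g)
  # perfect placements straight from the origin table
  or <- rs$origin
  pl <- tibble::tibble(read_id = or$read_id, contig = g,
                       offset = or$start - 1L, strand = or$strand)
  win_ok <- tibble::tibble(contig = g, start = 600L, end = 699L)
  res <- check_pair_spanning(pl, rs, win_ok,
                             fragment_mean = 400, fragment_sd = 20)
  expect_true(res$pass[1])
  expect_gt(res$spanning_pairs[1], 0)
  # a window longer than the fragment cannot be spanned
  win_bad <- tibble::tibble(contig = g, start = 301L, end = 800L)
  res <- check_pair_spanning(pl, rs, win_bad,
                             fragment_mean = 400, fragment_sd = 20)
  expect_false(res$pass[1])
  expect_equal(res$spanning_pairs[1], 0L)
  # empty window set: empty pass report, not an error
  expect_equal(nrow(check_pair_spanning(pl, rs, win_ok[0, ])), 0L)
})

test_that("no pair spans a chimeric junction while parents are spanned", {
  ts <- generate_paralog_pair(small_spec(seed = 26))
  # mates can only sit wholly outside a 100-nt window when the fragment is
  # at least window + 2 * read_length
  rs <- simulate_reads(ts, read_sim_spec(coverage = 50, error_rate = 0,
                                         fragment_mean_nt = 460,
                                         fragment_sd_nt = 30, seed = 26),
                       genes = c("sp1_H1", "sp1_H2"))
  or <- rs$origin
  p <- 2000L
  # placements on the chimera: reads wholly on their parent's side only
  left <- or[or$gene == "sp1_H1" & or$end <= p, ]
  right <- or[or$gene == "sp1_H2" & or$start > p, ]
  pl_ch <- dplyr::bind_rows(
    tibble::tibble(read_id = left$read_id, contig = "chimera",
                   offset = left$start - 1L, strand = left$strand),
    tibble::tibble(read_id = right$read_id, contig = "chimera",
                   offset = right$start - 1L, strand = right$strand))
  win <- tibble::tibble(contig = "chimera", start = p - 49L, end = p + 50L)
  res <- check_pair_spanning(pl_ch, rs, win,
                             fragment_mean = 460, fragment_sd = 30)
  expect_false(res$pass[1])
  expect_equal(res$spanning_pairs[1], 0L)
  # the same window on the intact parent is spanned
  h1 <- or[or$gene == "sp1_H1", ]
  pl_h1 <- tibble::tibble(read_id = h1$read_id, contig = "sp1_H1",
                          offset = h1$start - 1L, strand = h1$strand)
  win1 <- tibble::tibble(contig = "sp1_H1", start = p - 49L, end = p + 50L)
  res1 <- check_pair_spanning(pl_h1, rs, win1,
                              fragment_mean = 460, fragment_sd = 30)
  expect_true(res1$pass[1])
})
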