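# Iterative mapping assembly: acceptance rule, seeding, extension,
# paralog separation.

test_that("accept_hit enforces the overlap, identity and mismatch thresholds", {
  p <- mapping_params()
  contig <- strrep("ACGT", 100)                      # 400 nt
  read <- substr(contig, 101, 250)                   # 150 nt, exact
  h <- accept_hit(read, contig, 100, p)
  expect_true(h$accepted)
  expect_equal(h$mismatches, 0L)
  expect_equal(h$overlap, 150L)
  # 59-nt clean overlap: below the 60-nt minimum
  h <- accept_hit(substr(contig, 1, 59), contig, 0, p)
  expect_false(h$accepted)
  expect_equal(h$overlap, 59L)
  # 60-nt clean overlap passes
  expect_true(accept_hit(substr(contig, 1, 60), contig, 0, p)$accepted)
  # 100-nt overlap with 2 mismatches: identity 98% < 99%
  r <- substr(contig, 1, 100)
  substr(r, 10, 10) <- "N"; substr(r, 50, 50) <- "N"
  h <- accept_hit(r, contig, 0, p)
  expect_false(h$accepted)
  expect_equal(h$mismatches, 2L)
  # 100-nt overlap with 1 mismatch: identity 99%, cap floor(1) = 1
  r <- substr(contig, 1, 100)
  substr(r, 10, 10) <- "N"
  expect_true(accept_hit(r, contig, 0, p)$accepted)
  # overhang beyond the contig end is allowed and unscored
  r <- paste0(substr(contig, 301, 400), strrep("A", 50))
  h <- accept_hit(r, contig, 300, p)
  expect_true(h$accepted)
  expect_equal(h$overlap, 100L)
  expect_equal(h$right_overhang, 50L)
})

test_that("mapper placements agree with the brute-force all-offset oracle", {
  ts <- generate_paralog_pair(tiny_spec(seed = 4))
  contig <- substr(as.character(ts$genes[["sp1_H1"]]), 101, 600)
  src <- Biostrings::DNAStringSet(c(frag = contig))
  rs <- simulate_reads(src, read_sim_spec(read_length_nt = 100,
                                          fragment_mean_nt = 200,
                                          coverage = 40, error_rate = 0.005,
                                          seed = 4))
  pool <- all_reads(rs)
  expect_lte(length(pool), 200)
  p <- mapping_params()
  for (rid in names(pool)) {
    r <- as.character(pool[[rid]])
    oracle <- brute_force_hits(r, contig, p)
    mapped <- assign_paralog(r, c(ctg = contig), p)
    oracle_acc <- oracle[oracle$accepted, , drop = FALSE]
    expect_equal(nrow(mapped) > 0 && any(mapped$accepted),
                 nrow(oracle_acc) > 0)
    if (nrow(oracle_acc) && any(mapped$accepted)) {
      # chosen placement is among the oracle's best accepted offsets
      best <- max(oracle_acc$overlap - oracle_acc$mismatches)
      best_off <- oracle_acc[oracle_acc$overlap - oracle_acc$mismatches ==
                               best, c("strand", "offset")]
      expect_true(any(best_off$offset == mapped$offset[1] &
                        best_off$strand == mapped$strand[1]))
    }
    # accept_hit agrees with the oracle row at random offsets
    for (off in sample(oracle$offset[oracle$strand == "+"], 5)) {
      row <- oracle[oracle$strand == "+" & oracle$offset == off, ]
      h <- accept_hit(r, contig, off, p)
      expect_equal(h$overlap, row$overlap)
      expect_equal(h$mismatches, row$mismatches)
      expect_equal(h$accepted, row$accepted)
    }
  }
})

test_that("self-mapping seeds recruit every read into one spanning contig", {
  ts <- generate_paralog_pair(tiny_spec(seed = 5))
  ref <- ts$genes[["sp1_H1"]]
  rs <- simulate_reads(Biostrings::DNAStringSet(c(gene = as.character(ref))),
                       read_sim_spec(read_length_nt = 100,
                                     fragment_mean_nt = 250, coverage = 30,
                                     error_rate = 0, seed = 5))
  st <- seed_map(rs, ref)
  expect_equal(length(st$recruited), length(rs$r1) * 2)
  expect_equal(length(st$contigs), 1L)
})

test_that("seed mapping at 70% recruits divergent reads but rejects 50% divergence", {
  ts <- generate_paralog_pair(tiny_spec(seed = 6))  # reference at ~25% divergence
  rs <- simulate_reads(ts, read_sim_spec(read_length_nt = 100,
                                         fragment_mean_nt = 250, coverage = 30,
                                         error_rate = 0, seed = 6),
                       genes = "sp1_H1")
  st <- seed_map(rs, ts$reference)
  expect_gt(length(st$recruited), 0)
  # same reads against a ~50%-divergent reference: nothing passes 70%
  far <- generate_paralog_pair(tiny_spec(seed = 6,
                                         seed_reference_divergence = 0.55))
  expect_error(seed_map(rs, far$reference), "no reads mapped")
  expect_error(seed_map(rs, Biostrings::DNAString("ACGTACGT")), "kmer_size")
})

test_that("reads from a single gene assemble into exactly that CDS", {
  ts <- generate_paralog_pair(tiny_spec(seed = 7))
  rs <- simulate_reads(ts, read_sim_spec(read_length_nt = 100,
                                         fragment_mean_nt = 250, coverage = 40,
                                         error_rate = 0, seed = 7),
                       genes = "sp1_H1")
  st <- assemble(rs, ts$reference)
  expect_true(st$converged)
  ctg <- assembled_contigs(st)
  expect_equal(length(ctg), 1L)
  expect_identical(as.character(ctg[[1]]),
                   as.character(ts$genes[["sp1_H1"]]))
})

test_that("a converged assembly is a fixed point of further iteration", {
  ts <- generate_paralog_pair(tiny_spec(seed = 8))
  rs <- simulate_reads(ts, read_sim_spec(read_length_nt = 100,
                                         fragment_mean_nt = 250, coverage = 40,
                                         error_rate = 0, seed = 8),
                       genes = "sp1_H1")
  st <- assemble(rs, ts$reference)
  before <- vapply(st$contigs, function(cc) cc$consensus, "")
  st2 <- extend_iterate(st, rs, max_iter = 3)
  expect_true(st2$converged)
  expect_identical(vapply(st2$contigs, function(cc) cc$consensus, ""), before)
  expect_identical(sort(st2$recruited), sort(st$recruited))
})

test_that("assign_paralog picks the strict best and flags equidistant ties", {
  set.seed(77)
  base <- paste(sample(c("A", "C", "G", "T"), 480, replace = TRUE),
                collapse = "")
  other <- base
  # contig B differs from A only in its first half
  for (i in seq(5, 200, by = 8)) substr(other, i, i) <- "T"
  contigs <- c(A = base, B = other)
  # read from the second half: identical on both -> ambiguous tie
  r <- substr(base, 301, 420)
  h <- assign_paralog(r, contigs)
  expect_equal(nrow(h), 2L)
  expect_true(all(h$ambiguous))
  expect_true(all(h$mismatches == 0))
  # read from the first half: 0 vs many mismatches -> A only
  r <- substr(base, 1, 120)
  h <- assign_paralog(r, contigs)
  expect_equal(h$contig, "A")
  expect_false(h$ambiguous[1])
  expect_equal(h$mismatches[1], 0L)
})

test_that("ambiguous-read fraction rises as paralogs approach identity", {
  frac_amb <- function(div) {
    ts <- generate_paralog_pair(tiny_spec(seed = 9, paralog = div))
    rs <- simulate_reads(ts, read_sim_spec(read_length_nt = 100,
                                           fragment_mean_nt = 250,
                                           coverage = 15, error_rate = 0,
                                           seed = 9))
    contigs <- setNames(as.character(ts$genes), names(ts$genes))
    pool <- all_reads(rs)
    amb <- vapply(seq_along(pool), function(i) {
      h <- assign_paralog(as.character(pool[[i]]), contigs)
      nrow(h) > 0 && any(h$ambiguous)
    }, TRUE)
    mean(amb)
  }
  a <- frac_amb(0.01); b <- frac_amb(0.08); c <- frac_amb(0.30)
  expect_gt(a, b)
  expect_gte(b, c)
  expect_gt(a, 0.1)
  expect_lt(c, 0.05)
})

test_that("paralog pair is recovered exactly and deterministically (error-free)", {
  ts <- generate_paralog_pair(small_spec(seed = 10))
  rs <- simulate_reads(ts, read_sim_spec(coverage = 30, error_rate = 0,
                                         seed = 10),
                       genes = c("sp1_H1", "sp1_H2"))
  st <- assemble(rs, ts$reference)
  ctg <- assembled_contigs(st)
  expect_equal(length(ctg), 2L)
  got <- sort(as.character(ctg))
  want <- sort(as.character(ts$genes[c("sp1_H1", "sp1_H2")]))
  expect_identical(unname(got), unname(want))
  sc <- score_assembly(ctg, ts, genes = c("sp1_H1", "sp1_H2"))
  expect_false(any(sc$chimeric))
  # determinism
  st2 <- assemble(rs, ts$reference)
  expect_identical(sort(as.character(assembled_contigs(st2))), got)
})

test_that("contig growth and read recruitment are monotone across iterations", {
  ts <- generate_paralog_pair(tiny_spec(seed = 12, paralog = 0.30))
  rs <- simulate_reads(ts, read_sim_spec(read_length_nt = 100,
                                         fragment_mean_nt = 250, coverage = 40,
                                         error_rate = 0.01, seed = 12))
  st <- seed_map(rs, ts$reference)
  prev_rec <- length(st$recruited)
  prev_len <- vapply(st$contigs, function(cc) nchar(cc$consensus), 0)
  for (i in 1:6) {
    st <- suppressWarnings(extend_iterate(st, rs, max_iter = 1))
    expect_gte(length(st$recruited), prev_rec)
    lens <- vapply(st$contigs, function(cc) nchar(cc$consensus), 0)
    common <- intersect(names(lens), names(prev_len))
    expect_true(all(lens[common] >= prev_len[common]))
    prev_rec <- length(st$recruited); prev_len <- lens
    if (st$converged) break
  }
})

test_that("assemblies serialize to FASTA, TSV placements and a JSON report", {
  ts <- generate_paralog_pair(tiny_spec(seed = 14))
  rs <- simulate_reads(ts, read_sim_spec(read_length_nt = 100,
                                         fragment_mean_nt = 250, coverage = 30,
                                         error_rate = 0, seed = 14),
                       genes = "sp1_H1")
  st <- assemble(rs, ts$reference)
  dir <- tempfile("asm")
  paths <- write_assembly(st, dir)
  fa <- Biostrings::readDNAStringSet(paths[1])
  expect_identical(sort(as.character(fa)),
                   sort(vapply(st$contigs, function(cc) cc$consensus, "")))
  pl <- utils::read.delim(paths[2])
  expect_equal(nrow(pl), nrow(st$placements))
  rep <- readLines(paths[3])
  expect_match(rep, '"converged":true')
})
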