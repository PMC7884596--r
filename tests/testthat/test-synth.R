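# Synthetic paralog/read generator: ground-truth guarantees.

test_that("zero divergence and no insert give identical paralogs", {
  sp <- paralog_pair_spec(architecture = small_arch(),
                          paralog_divergence = 0, species_divergence = NULL,
                          h2_insert = insert_spec(length_aa = 0),
                          seed_reference_divergence = NULL,
                          outgroup_divergence = NULL, seed = 3)
  ts <- generate_paralog_pair(sp)
  expect_identical(as.character(ts$genes[["sp1_H1"]]),
                   as.character(ts$genes[["sp1_H2"]]))
})

test_that("protein lengths and insert placement follow the architecture", {
  ts <- generate_paralog_pair(paralog_pair_spec(seed = 5))
  # 8 x 420 + 100 (+340 insert in H2)
  expect_equal(length(ts$proteins[["sp1_H1"]]), 3460L)
  expect_equal(length(ts$proteins[["sp1_H2"]]), 3800L)
  expect_equal(length(ts$genes[["sp1_H2"]]), 3L * 3800L + 3L)
  ins <- ts$insert[ts$insert$gene == "sp1_H2", ]
  expect_equal(ins$prot_end0 - ins$prot_start0, 340L)
  # insert coordinates exactly delimit the His/Asp-rich block
  p <- as.character(ts$proteins[["sp1_H2"]])
  block <- strsplit(substr(p, ins$prot_start0 + 1, ins$prot_end0), "")[[1]]
  expect_gte(mean(block %in% c("H", "D")), 0.68)
  flank <- strsplit(substr(p, ins$prot_start0 - 339, ins$prot_start0), "")[[1]]
  expect_lt(mean(flank %in% c("H", "D")), 0.3)
})

test_that("realized pairwise divergences match the spec within 0.02", {
  for (sd in 1:2) {
    ts <- generate_paralog_pair(paralog_pair_spec(seed = sd))
    par_div <- 1 - seq_identity(ts$genes[["sp1_H1"]], h2_without_insert(ts))
    sp_div <- 1 - seq_identity(ts$genes[["sp1_H1"]], ts$genes[["sp2_H1"]])
    ref_div <- 1 - seq_identity(ts$reference, ts$genes[["sp1_H1"]])
    expect_lt(abs(par_div - 0.30), 0.02)
    expect_lt(abs(sp_div - 0.15), 0.02)
    expect_lt(abs(ref_div - 0.25), 0.02)
  }
})

test_that("generation and simulation are deterministic given the seed", {
  a <- generate_paralog_pair(small_spec(seed = 11))
  b <- generate_paralog_pair(small_spec(seed = 11))
  expect_identical(as.character(a$genes), as.character(b$genes))
  ra <- simulate_reads(a, read_sim_spec(coverage = 5, seed = 4), genes = "sp1_H1")
  rb <- simulate_reads(b, read_sim_spec(coverage = 5, seed = 4), genes = "sp1_H1")
  expect_identical(as.character(ra$r1), as.character(rb$r1))
  expect_identical(as.character(ra$r2), as.character(rb$r2))
  rc <- simulate_reads(a, read_sim_spec(coverage = 5, seed = 5), genes = "sp1_H1")
  expect_false(identical(as.character(ra$r1), as.character(rc$r1)))
})

test_that("error-free reads are exact substrings in forward-reverse orientation", {
  ts <- generate_paralog_pair(tiny_spec(seed = 2))
  rs <- simulate_reads(ts, read_sim_spec(read_length_nt = 100,
                                         fragment_mean_nt = 250,
                                         coverage = 10, error_rate = 0,
                                         seed = 2))
  or <- rs$origin
  for (i in seq_len(nrow(or))) {
    g <- as.character(ts$genes[[or$gene[i]]])
    truth <- substr(g, or$start[i], or$end[i])
    mate <- if (or$mate[i] == 1) rs$r1 else rs$r2
    obs <- as.character(mate[[paste0(sub("/[12]$", "", or$read_id[i]), "/",
                                     or$mate[i])]])
    if (or$strand[i] == "-")
      obs <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(obs)))
    expect_identical(obs, truth)
  }
  # mate orientation: opposite strands within a pair
  pairs <- split(or$strand, sub("/[12]$", "", or$read_id))
  expect_true(all(vapply(pairs, function(x) length(unique(x)) == 2, TRUE)))
})

test_that("pair count follows coverage * length / (2 * read length)", {
  ts <- generate_paralog_pair(tiny_spec(seed = 3))
  L <- length(ts$genes[["sp1_H1"]])
  rs <- simulate_reads(ts, read_sim_spec(read_length_nt = 100,
                                         fragment_mean_nt = 250, coverage = 50,
                                         error_rate = 0, seed = 1),
                       genes = "sp1_H1")
  expected <- 50 * L / (2 * 100)
  expect_lt(abs(length(rs$r1) - expected) / expected, 0.1)
})

test_that("substitution errors occur at the configured rate", {
  ts <- generate_paralog_pair(paralog_pair_spec(seed = 4))
  rs <- simulate_reads(ts, read_sim_spec(coverage = 50, error_rate = 0.01,
                                         seed = 4),
                       genes = c("sp1_H1", "sp1_H2"))
  or <- rs$origin
  gs <- lapply(as.list(as.character(ts$genes)), identity)
  mm <- 0L; tot <- 0L
  pool <- all_reads(rs)
  for (i in seq_len(nrow(or))) {
    truth <- substr(gs[[or$gene[i]]], or$start[i], or$end[i])
    obs <- as.character(pool[[or$read_id[i]]])
    if (or$strand[i] == "-")
      obs <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(obs)))
    v <- utf8ToInt(obs) != utf8ToInt(truth)
    mm <- mm + sum(v); tot <- tot + length(v)
  }
  expect_gte(tot, 1e6)
  expect_lt(abs(mm / tot - 0.01), 0.001)
})

test_that("invalid read-simulation parameters error", {
  expect_error(read_sim_spec(read_length_nt = 150, fragment_mean_nt = 100),
               "fragment_mean_nt")
  expect_error(read_sim_spec(error_rate = 1))
  expect_error(read_sim_spec(coverage = 0))
})

test_that("make_chimera fuses at the breakpoint and handles degenerate cases", {
  ts <- generate_paralog_pair(small_spec(seed = 6))
  h1 <- as.character(ts$genes[["sp1_H1"]])
  h2 <- as.character(ts$genes[["sp1_H2"]])
  expect_identical(as.character(make_chimera(ts, 0)$seq), h2)
  expect_identical(as.character(make_chimera(ts, nchar(h1))$seq), h1)
  ch <- make_chimera(ts, 2000)
  cs <- as.character(ch$seq)
  expect_identical(substr(cs, 1, 2000), substr(h1, 1, 2000))
  expect_false(cs == h1)
  expect_false(cs == h2)
  expect_error(make_chimera(ts, -1))
  expect_error(make_chimera(ts, nchar(h1) + 1))
})

test_that("truth sets and read sets round-trip through their file formats", {
  ts <- generate_paralog_pair(tiny_spec(seed = 13))
  dir <- tempfile("truth")
  write_truth_set(ts, dir)
  back <- Biostrings::readDNAStringSet(file.path(dir, "genes.fasta"))
  expect_identical(as.character(back), as.character(ts$genes))
  ins <- utils::read.delim(file.path(dir, "insert.tsv"))
  expect_equal(nrow(ins), nrow(ts$insert))
  rs <- simulate_reads(ts, read_sim_spec(read_length_nt = 100,
                                         fragment_mean_nt = 250, coverage = 3,
                                         error_rate = 0, seed = 13))
  r1 <- tempfile(fileext = ".fastq"); r2 <- tempfile(fileext = ".fastq")
  write_read_set(rs, r1, r2)
  back1 <- Biostrings::readDNAStringSet(r1, format = "fastq")
  expect_identical(as.character(back1), as.character(rs$r1))
})
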