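# Protein characterization: ORF translation, mass, FU annotation, insertion
# calls, hydropathy, cysteine census.

test_that("find_orf_translate handles minimal, strandless and degenerate inputs", {
  p <- find_orf_translate("ATGGGTTAA", min_orf_nt = 9)
  expect_equal(p$seq, "MG")
  expect_equal(p$length_aa, 2L)
  expect_true(p$has_stop)
  expect_equal(nchar(p$cds) / 3 - 1, p$length_aa)
  expect_error(find_orf_translate("CCCGGGTTT", min_orf_nt = 9), "ORF")
  expect_error(find_orf_translate("ATGGGTTAA", min_orf_nt = 300), "min_orf_nt")
  expect_error(find_orf_translate("ATGQQQTAA"), "A,C,G,T,N")
  expect_warning(find_orf_translate("ATGGGTNNNGGGTAA", min_orf_nt = 9), "X")
})

test_that("the deduced CDS and protein match the generating truth on both strands", {
  ts <- generate_paralog_pair(small_spec(seed = 31))
  g <- ts$genes[["sp1_H2"]]
  orf <- find_orf_translate(g)
  expect_identical(orf$seq, as.character(ts$proteins[["sp1_H2"]]))
  expect_equal(orf$length_aa, nchar(orf$cds) / 3 - 1)
  orf2 <- find_orf_translate(Biostrings::reverseComplement(g))
  expect_identical(orf2$seq, orf$seq)
  expect_equal(orf2$strand, "-")
})

test_that("molecular weight uses average residue masses plus one water", {
  expect_equal(molecular_weight("G"), 75.07, tolerance = 1e-4)
  expect_equal(molecular_weight("GG"), 132.12, tolerance = 1e-4)
  expect_error(molecular_weight(""), "empty")
  expect_error(molecular_weight("GGB"), "positions")
  expect_lt(molecular_weight("G", monoisotopic = TRUE), molecular_weight("G"))
})

test_that("mass is additive over concatenation to 1e-6 Da", {
  set.seed(41)
  aas <- names(hemocyanr:::.AA_MASS_AVG)
  for (i in 1:20) {
    a <- paste(sample(aas, sample(5:50, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(5:50, 1), replace = TRUE), collapse = "")
    expect_equal(molecular_weight(paste0(a, b)),
                 molecular_weight(a) + molecular_weight(b) - 18.01524,
                 tolerance = 1e-6)
  }
})

test_that("composition fractions sum to one", {
  set.seed(42)
  aas <- names(hemocyanr:::.AA_MASS_AVG)
  for (i in 1:10) {
    s <- paste(sample(aas, sample(3:200, 1), replace = TRUE), collapse = "")
    expect_equal(sum(residue_composition(s)$fraction), 1, tolerance = 1e-9)
  }
})

test_that("FU boundaries project through alignment, inserts stay in their host FU", {
  ts <- generate_paralog_pair(small_spec(seed = 32))
  ref <- as.character(ts$proteins[["sp1_H1"]])
  fus <- ts$fu_map[ts$fu_map$gene == "sp1_H1", c("fu", "start_aa", "end_aa")]
  # identity projection
  ann <- annotate_fus(ref, ref, fus)
  expect_equal(ann$start_aa, fus$start_aa)
  expect_equal(ann$end_aa, fus$end_aa)
  # H2 with a 340-aa insert in FU-g: that segment grows by 340 +/- 2
  ann2 <- annotate_fus(ts$proteins[["sp1_H2"]], ref, fus)
  g_len <- ann2$end_aa[ann2$fu == "g"] - ann2$start_aa[ann2$fu == "g"]
  g_ref <- fus$end_aa[fus$fu == "g"] - fus$start_aa[fus$fu == "g"]
  expect_lte(abs((g_len - g_ref) - 340), 2)
  # truncated protein: trailing FUs reported absent
  part <- substr(ref, 1, fus$end_aa[fus$fu == "g"])
  ann3 <- annotate_fus(part, ref, fus)
  expect_setequal(ann3$fu, c("a", "b", "g"))
  # unrelated input errors
  expect_error(annotate_fus(strrep("M", 400), ref, fus), "50%")
})

test_that("call_insertion recovers the engineered insert and is empty on self", {
  ts <- generate_paralog_pair(small_spec(seed = 33))
  h1 <- ts$proteins[["sp1_H1"]]
  h2 <- ts$proteins[["sp1_H2"]]
  expect_equal(nrow(call_insertion(h1, h1)), 0L)
  fus <- ts$fu_map[ts$fu_map$gene == "sp1_H1", c("fu", "start_aa", "end_aa")]
  calls <- call_insertion(h2, h1, counterpart_fus = fus)
  expect_equal(nrow(calls), 1L)
  expect_lte(abs(calls$length_aa - 340), 2)
  expect_gte(calls$his_asp_fraction, 0.68)
  expect_equal(calls$his_asp_fraction,
               calls$his_fraction + calls$asp_fraction, tolerance = 1e-12)
  expect_lt(calls$mean_hydropathy, 0)
  expect_equal(calls$host_fu, "g")
  # coordinates match the generating truth
  ins <- ts$insert[ts$insert$gene == "sp1_H2", ]
  expect_lte(abs(calls$start_aa - (ins$prot_start0 + 1)), 2)
})

test_that("insertion length recovery is accurate across insert sizes", {
  errs <- c(); hd_called <- c(); hd_truth <- c(); kd <- c()
  for (len in c(50, 118, 150, 340)) {
    for (sd in 1:3) {
      ts <- generate_paralog_pair(small_spec(seed = 100 * sd + len,
                                             insert_len = len))
      calls <- call_insertion(ts$proteins[["sp1_H2"]], ts$proteins[["sp1_H1"]])
      expect_equal(nrow(calls), 1L)
      errs <- c(errs, abs(calls$length_aa - len))
      ins <- ts$insert[ts$insert$gene == "sp1_H2", ]
      p <- as.character(ts$proteins[["sp1_H2"]])
      block <- strsplit(substr(p, ins$prot_start0 + 1, ins$prot_end0), "")[[1]]
      hd_called <- c(hd_called, calls$his_asp_fraction)
      hd_truth <- c(hd_truth, mean(block %in% c("H", "D")))
      kd <- c(kd, calls$mean_hydropathy)
    }
  }
  expect_lte(mean(errs), 2)
  # boundary placement of a short divergent insert is ambiguous by a few
  # residues, so composition is compared in aggregate over replicates
  expect_lte(abs(mean(hd_called) - mean(hd_truth)), 0.02)
  expect_true(all(kd < 0))
})

test_that("hydropathy profile matches the KD scale and its symmetries", {
  expect_true(all(hydropathy_profile(strrep("I", 30))$hydropathy == 4.5))
  expect_true(all(hydropathy_profile(strrep("R", 30))$hydropathy == -4.5))
  set.seed(43)
  s <- paste(sample(names(hemocyanr:::.KD), 60, replace = TRUE), collapse = "")
  rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(rev(hydropathy_profile(s)$hydropathy),
               hydropathy_profile(rev_s)$hydropathy, tolerance = 1e-12)
  expect_error(hydropathy_profile(s, window = 8), "odd")
  expect_error(hydropathy_profile("MK", window = 9), "window")
})

test_that("cysteine census separates canonical from additional cysteines", {
  ts <- generate_paralog_pair(small_spec(seed = 34))
  ref <- as.character(ts$proteins[["sp1_H1"]])
  cys <- cysteine_census(ref, ref)
  expect_true(all(cys$status == "canonical"))
  # engineer: remove one reference Cys from the query, add a new one
  v <- strsplit(ref, "")[[1]]
  old_c <- which(v == "C")[1]
  v[old_c] <- "A"
  new_site <- old_c + 57
  v[new_site] <- "C"
  q <- paste(v, collapse = "")
  rep <- cysteine_census(q, ref)
  extra <- rep[rep$status == "additional", ]
  expect_equal(nrow(extra), 1L)
  expect_equal(extra$position_aa, new_site)
  expect_true(all(rep$status[rep$position_aa != new_site] == "canonical"))
})
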