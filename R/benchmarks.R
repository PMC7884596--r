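# End-to-end evaluation runs on synthetic data under the study conditions:
# eight 420-aa FUs plus a 100-aa tail, paralog divergence 0.30, species
# divergence 0.15, seed-reference divergence 0.25, 150-nt paired reads at
# 50x coverage with 1% substitution error. These functions back both the
# acceptance test suite and scripts/acceptance.R.

.derive_seeds <- function(seed, n) {
  .with_seed(seed, sample.int(1e6L, n))
}

#' Benchmark full-length paralog recovery by the iterative assembler
#'
#' For each replicate, generates a paralogous gene pair with ground truth,
#' simulates paired-end reads from one species' H1 and H2, assembles them
#' against the heterologous seed reference, and scores the best contig per
#' gene for identity and chimerism.
#'
#' @param n_seeds Number of replicates.
#' @param seed Master seed (per-replicate seeds derive from it).
#' @param error_rate Per-base substitution error of the simulated reads.
#' @param coverage Fold coverage per gene.
#' @param min_identity Identity a replicate must reach on both genes to pass.
#' @return Tibble: `seed`, `identity_h1`, `identity_h2`, `chimeric`,
#'   `n_contigs`, `pass`.
#' @export
benchmark_assembly_recovery <- function(n_seeds = 10, seed = 1,
                                        error_rate = 0.01, coverage = 50,
                                        min_identity = 0.999) {
  seeds <- .derive_seeds(seed, n_seeds)
  out <- lapply(seq_len(n_seeds), function(i) {
    ts <- generate_paralog_pair(paralog_pair_spec(seed = seeds[i]))
    rs <- simulate_reads(ts, read_sim_spec(coverage = coverage,
                                           error_rate = error_rate,
                                           seed = seeds[i]),
                         genes = c("sp1_H1", "sp1_H2"))
    st <- assemble(rs, ts$reference)
    sc <- score_assembly(assembled_contigs(st), ts,
                         genes = c("sp1_H1", "sp1_H2"))
    best <- function(g) {
      v <- sc$identity[sc$gene == g]
      if (length(v)) max(v) else 0
    }
    i1 <- best("sp1_H1"); i2 <- best("sp1_H2")
    tibble(seed = seeds[i], identity_h1 = i1, identity_h2 = i2,
           chimeric = any(sc$chimeric), n_contigs = nrow(sc),
           pass = i1 >= min_identity && i2 >= min_identity &&
             !any(sc$chimeric))
  })
  dplyr::bind_rows(out)
}

#' Benchmark chimera detection and clean-assembly specificity
#'
#' Each replicate pair generates a truth set and its reads, audits the two
#' TRUE coding sequences (the clean check), then fuses the paralogs at two
#' random breakpoints and audits each chimera with the low-stringency
#' remapping.
#'
#' @param n_pairs Truth sets to generate; each contributes 2 chimera
#'   replicates and (for the first `n_clean`) one clean two-contig check.
#' @param n_clean Clean assemblies audited for false positives.
#' @param seed Master seed.
#' @param max_error_nt Breakpoint localization tolerance.
#' @return List with `chimera` tibble (`pair`, `breakpoint`, `n_flags`,
#'   `best_error_nt`, `detected`) and `clean` tibble (`pair`, `n_flags`,
#'   `n_contigs`).
#' @export
benchmark_chimera_detection <- function(n_pairs = 25, n_clean = 20, seed = 1,
                                        max_error_nt = 200) {
  seeds <- .derive_seeds(seed, n_pairs)
  chim <- list(); clean <- list()
  for (i in seq_len(n_pairs)) {
    ts <- generate_paralog_pair(paralog_pair_spec(seed = seeds[i]))
    rs <- simulate_reads(ts, read_sim_spec(coverage = 50, error_rate = 0.01,
                                           seed = seeds[i]),
                         genes = c("sp1_H1", "sp1_H2"))
    if (i <= n_clean) {
      fl <- remap_low_stringency(rs, ts$genes[c("sp1_H1", "sp1_H2")])
      clean[[i]] <- tibble(pair = i, n_flags = nrow(fl), n_contigs = 2L)
    }
    L <- length(ts$genes[["sp1_H1"]])
    bps <- .with_seed(seeds[i] + 1L,
                      sample(seq(500L, L - 500L), 2))
    for (bp in bps) {
      ch <- make_chimera(ts, bp)
      fl <- remap_low_stringency(rs, ch)
      err <- if (nrow(fl)) min(abs(fl$position - bp)) else NA_integer_
      chim[[length(chim) + 1]] <- tibble(
        pair = i, breakpoint = bp, n_flags = nrow(fl),
        best_error_nt = err,
        detected = nrow(fl) > 0 && err <= max_error_nt)
    }
  }
  list(chimera = dplyr::bind_rows(chim), clean = dplyr::bind_rows(clean))
}

#' Benchmark insertion-call recovery across insert sizes
#'
#' Generates paralog pairs whose H2 carries a His/Asp-rich insertion of a
#' configured length (default grid spans the sizes observed in muricid
#' hemocyanins), calls insertions of H2 against H1, and compares length,
#' composition and hydropathy with the generative truth. A reduced four-FU
#' architecture keeps each replicate light without changing the insertion
#' geometry.
#'
#' @param lengths Insert lengths (aa) to sample.
#' @param n_replicates Total replicates, spread over `lengths`.
#' @param seed Master seed.
#' @return Tibble: `length_aa`, `seed`, `n_calls`, `called_length`,
#'   `abs_length_error`, `called_hd`, `truth_hd`, `mean_hydropathy`.
#' @export
benchmark_insertion_recovery <- function(lengths = c(50, 118, 150, 340),
                                         n_replicates = 50, seed = 1) {
  plan <- rep(lengths, length.out = n_replicates)
  seeds <- .derive_seeds(seed, n_replicates)
  arch <- fu_architecture(fu_names = c("a", "b", "g", "h"))
  out <- lapply(seq_len(n_replicates), function(i) {
    sp <- paralog_pair_spec(architecture = arch,
                            h2_insert = insert_spec(length_aa = plan[i]),
                            seed = seeds[i])
    ts <- generate_paralog_pair(sp)
    calls <- call_insertion(ts$proteins[["sp1_H2"]], ts$proteins[["sp1_H1"]])
    ins <- ts$insert[ts$insert$gene == "sp1_H2", ]
    p <- as.character(ts$proteins[["sp1_H2"]])
    block <- strsplit(substr(p, ins$prot_start0 + 1, ins$prot_end0), "")[[1]]
    main <- if (nrow(calls)) calls[which.max(calls$length_aa), ] else NULL
    tibble(length_aa = plan[i], seed = seeds[i], n_calls = nrow(calls),
           called_length = if (is.null(main)) 0L else main$length_aa,
           abs_length_error = abs((if (is.null(main)) 0L else
             main$length_aa) - plan[i]),
           called_hd = if (is.null(main)) NA_real_ else main$his_asp_fraction,
           truth_hd = mean(block %in% c("H", "D")),
           mean_hydropathy = if (is.null(main)) NA_real_ else
             main$mean_hydropathy)
  })
  dplyr::bind_rows(out)
}

#' Benchmark orthology recovery with bootstrap support
#'
#' Generates two species x two paralogs plus an outgroup, builds the NJ tree
#' with bootstrap support, and records the support of the two ortholog
#' clades (H1 of both species; H2 of both species). A reduced four-FU
#' architecture is used; divergences are the study defaults (0.30 / 0.15).
#'
#' @param n_runs Seeded runs.
#' @param replicates Bootstrap replicates per run.
#' @param seed Master seed.
#' @param min_support Support both clades need for a run to pass.
#' @return Tibble: `seed`, `support_h1`, `support_h2`, `correct_topology`,
#'   `pass`.
#' @export
benchmark_orthology <- function(n_runs = 10, replicates = 100, seed = 1,
                                min_support = 90) {
  seeds <- .derive_seeds(seed, n_runs)
  arch <- fu_architecture(fu_names = c("a", "b", "g", "h"))
  out <- lapply(seq_len(n_runs), function(i) {
    ts <- generate_paralog_pair(paralog_pair_spec(
      architecture = arch, h2_insert = insert_spec(length_aa = 340),
      seed = seeds[i]))
    prots <- setNames(as.character(ts$proteins), names(ts$proteins))
    prots <- c(prots, outgroup = as.character(ts$outgroup_protein))
    tr <- bootstrap_support(prots, replicates = replicates, seed = seeds[i],
                            outgroup = "outgroup")
    s1 <- clade_support(tr, c("sp1_H1", "sp2_H1"))
    s2 <- clade_support(tr, c("sp1_H2", "sp2_H2"))
    ok_topo <- !is.na(s1) && !is.na(s2)
    tibble(seed = seeds[i],
           support_h1 = ifelse(is.na(s1), 0, s1),
           support_h2 = ifelse(is.na(s2), 0, s2),
           correct_topology = ok_topo,
           pass = ok_topo && s1 >= min_support && s2 >= min_support)
  })
  dplyr::bind_rows(out)
}
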