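# Synthetic paralogous hemocyanin genes with ground truth.

# Average background residue frequencies (Robinson & Robinson style) used to
# draw ancestral protein sequence; C and W kept rare so engineered cysteine
# tests are not confounded by background Cys.
.AA_FREQ <- c(A = 0.078, R = 0.051, N = 0.045, D = 0.054, C = 0.010,
              Q = 0.043, E = 0.063, G = 0.074, H = 0.022, I = 0.051,
              L = 0.091, K = 0.057, M = 0.022, F = 0.039, P = 0.052,
              S = 0.071, T = 0.058, W = 0.013, Y = 0.032, V = 0.064)

.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  list(aa_of = gc, codons_of = split(names(gc), gc))
}

# run expr with a private RNG stream seeded by `seed`, restoring the caller's
# RNG state afterwards
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# per-lineage substitution probability so that two lineages diverging from a
# common ancestor show expected pairwise divergence D (Jukes-Cantor-like
# double-hit correction)
.rate_for_pairwise <- function(D) {
  if (D >= 0.75) stop("divergence >= 0.75 is saturated under this model")
  0.75 * (1 - sqrt(1 - (4 / 3) * D))
}

# extra per-lineage rate z so that a lineage with prior path factor `path`
# reaches total pairwise divergence D against the other end of the path
.rate_for_path <- function(D, path_factor) {
  f <- (1 - (4 / 3) * D) / path_factor
  if (f <= 0 || f > 1)
    stop("requested divergence unattainable given the rest of the gene tree")
  0.75 * (1 - f)
}

# substitution-only, codon-aware mutation of a CDS character vector; start
# and stop codons are protected, stop codons are never created, synonymous
# changes carry `syn_weight` relative to nonsynonymous ones. Sites inside
# `protect` (0-based half-open nt range) accept synonymous changes only —
# used to keep the His/Asp composition of the insert under purifying
# selection once the insert exists.
.mutate_cds <- function(nt, rate, syn_weight, ct, protect = NULL) {
  L <- length(nt)
  if (rate <= 0) return(nt)
  eligible <- 4:(L - 3)
  hit <- eligible[runif(length(eligible)) < rate]
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    ci <- (i - 1) %/% 3
    cpos <- i - 3 * ci
    codon <- nt[(3 * ci + 1):(3 * ci + 3)]
    aa0 <- ct$aa_of[[paste(codon, collapse = "")]]
    protected <- !is.null(protect) && i > protect[1] && i <= protect[2]
    alt <- setdiff(bases, nt[i])
    w <- numeric(3)
    for (j in 1:3) {
      cd <- codon
      cd[cpos] <- alt[j]
      aa1 <- ct$aa_of[[paste(cd, collapse = "")]]
      w[j] <- if (aa1 == "*") 0 else if (aa1 == aa0) syn_weight else
        if (protected) 0 else 1
    }
    if (all(w == 0)) next
    nt[i] <- sample(alt, 1L, prob = w)
  }
  nt
}

# mutate a protein character vector so two copies meet a target pairwise identity
.mutate_protein <- function(aa, identity) {
  if (identity >= 1) return(aa)
  q <- (19 / 20) * (1 - sqrt(max(0, 1 - (20 / 19) * (1 - identity))))
  hit <- which(runif(length(aa)) < q)
  for (i in hit) aa[i] <- sample(setdiff(names(.AA_FREQ), aa[i]), 1L)
  aa
}

.back_translate <- function(aa, ct) {
  unlist(lapply(aa, function(a) {
    cods <- ct$codons_of[[a]]
    strsplit(if (length(cods) == 1) cods else sample(cods, 1L), "")[[1]]
  }))
}

# His/Asp-rich repetitive insert with exact global composition:
# a base motif is tandem-repeated with per-copy variation that preserves
# which slots are His/Asp, then individual positions are flipped so the
# realized His+Asp count equals round(length * his_asp_fraction) exactly
.make_insert <- function(ins) {
  n <- ins$length_aa
  if (n == 0) return(character(0))
  period <- ins$motif_period
  hd <- c("H", "D")
  other <- setdiff(names(.AA_FREQ), c(hd, "C"))  # no spurious cysteines
  n_hd <- round(n * ins$his_asp_fraction)
  k_hd <- min(period, max(0, round(period * ins$his_asp_fraction)))
  motif_class <- rep(FALSE, period)
  if (k_hd > 0) motif_class[seq_len(k_hd)] <- TRUE
  motif <- ifelse(motif_class, sample(hd, period, replace = TRUE),
                  sample(other, period, replace = TRUE))
  slot <- ((seq_len(n) - 1) %% period) + 1
  res <- motif[slot]
  is_hd <- motif_class[slot]
  # per-position variation (30%) within the same His/Asp vs other class
  vary <- runif(n) < 0.3
  res[vary & is_hd] <- sample(hd, sum(vary & is_hd), replace = TRUE)
  res[vary & !is_hd] <- sample(other, sum(vary & !is_hd), replace = TRUE)
  # flip positions to hit the exact target count
  cur <- sum(is_hd)
  if (cur < n_hd) {
    idx <- sample(which(!is_hd), n_hd - cur)
    res[idx] <- sample(hd, length(idx), replace = TRUE)
  } else if (cur > n_hd) {
    idx <- sample(which(is_hd), cur - n_hd)
    res[idx] <- sample(other, length(idx), replace = TRUE)
  }
  res
}

#' Generate a ground-truthed pair of paralogous hemocyanin genes
#'
#' Simulates the gene family the assembler and annotation stages assume: an
#' ancestral multi-FU gene duplicates into paralogs H1 and H2; H2 acquires a
#' His/Asp-rich hydrophilic insertion in its host FU; both paralogs are
#' inherited by two species. Optionally a heterologous seed-reference gene
#' (for reference-guided assembly) and an outgroup protein (for tree rooting)
#' branch off the ancestor. Nucleotide divergence is applied per site with a
#' synonymous:nonsynonymous weighting and double-substitution correction, so
#' realized pairwise divergences match the spec values closely.
#'
#' @param spec A [paralog_pair_spec()].
#' @return An object of class `truth_set`: a list with elements
#'   `genes` (named [Biostrings::DNAStringSet] of CDSs including stop codon),
#'   `proteins` (named [Biostrings::AAStringSet]), `reference` /
#'   `reference_protein`, `outgroup_protein`, `insert` (tibble of 0-based
#'   half-open insert coordinates per gene, protein and CDS scale),
#'   `fu_map` (per-gene FU boundary tibble, 1-based inclusive), and `spec`.
#' @examples
#' ts <- generate_paralog_pair(paralog_pair_spec(seed = 7))
#' names(ts$genes)
#' ts$insert
#' @export
generate_paralog_pair <- function(spec) {
  stopifnot(inherits(spec, "paralog_pair_spec"))
  ct <- .codon_table()
  arch <- spec$architecture
  .with_seed(spec$seed, {
    aa_names <- names(.AA_FREQ)
    # ancestral FU prototype and per-FU derivation at the target intra-gene identity
    proto <- sample(aa_names, max(arch$fu_length_aa), replace = TRUE, prob = .AA_FREQ)
    fu_seqs <- lapply(seq_along(arch$fu_names), function(i) {
      .mutate_protein(proto[seq_len(arch$fu_length_aa[i])], arch$intra_gene_fu_identity)
    })
    tail_aa <- sample(aa_names, arch$terminal_tail_aa, replace = TRUE, prob = .AA_FREQ)
    anc_prot <- c(unlist(fu_seqs), tail_aa)
    anc_prot[1] <- "M"
    anc_cds <- c(.back_translate(anc_prot, ct), c("T", "A", "A"))

    # branch rates calibrated on expected pairwise divergences
    y <- if (is.null(spec$species_divergence)) 0 else
      .rate_for_pairwise(spec$species_divergence)
    fy <- (1 - (4 / 3) * y)
    # pairwise(H1, H2 | same species) spans two duplication branches and two
    # species branches: (1-4/3 x)^2 (1-4/3 y)^2 = 1 - 4/3 P
    fx2 <- (1 - (4 / 3) * spec$paralog_divergence) / fy^2
    if (fx2 <= 0) stop("paralog_divergence unattainable with this species_divergence")
    x <- 0.75 * (1 - sqrt(fx2))

    h1a <- .mutate_cds(anc_cds, x, spec$synonymous_weight, ct)
    h2a <- .mutate_cds(anc_cds, x, spec$synonymous_weight, ct)

    # insertion into the H2 ancestor, inherited by both species
    ins <- spec$h2_insert
    fb <- fu_boundaries(arch)
    host_start <- fb$start_aa[match(ins$host_fu, fb$fu)]
    ins_prot0 <- host_start - 1L + ins$offset_in_fu_aa     # 0-based protein coord
    ins_aa <- .make_insert(ins)
    ins_nt <- if (length(ins_aa)) .back_translate(ins_aa, ct) else character(0)
    if (length(ins_aa)) {
      at <- 3L * ins_prot0
      h2a <- c(h2a[seq_len(at)], ins_nt, h2a[(at + 1L):length(h2a)])
    }

    ins_protect <- if (length(ins_aa))
      c(3L * ins_prot0, 3L * (ins_prot0 + ins$length_aa)) else NULL
    n_species <- if (is.null(spec$species_divergence)) 1L else 2L
    genes <- list()
    for (s in seq_len(n_species)) {
      genes[[paste0("sp", s, "_H1")]] <-
        .mutate_cds(h1a, y, spec$synonymous_weight, ct)
      genes[[paste0("sp", s, "_H2")]] <-
        .mutate_cds(h2a, y, spec$synonymous_weight, ct, protect = ins_protect)
    }

    fxy <- (1 - (4 / 3) * x) * fy
    reference <- NULL
    if (!is.null(spec$seed_reference_divergence)) {
      z <- .rate_for_path(spec$seed_reference_divergence, fxy)
      reference <- .mutate_cds(anc_cds, z, spec$synonymous_weight, ct)
    }
    outgroup <- NULL
    if (!is.null(spec$outgroup_divergence)) {
      w <- .rate_for_path(spec$outgroup_divergence, fxy)
      outgroup <- .mutate_cds(anc_cds, w, spec$synonymous_weight, ct)
    }

    translate1 <- function(nt) {
      aa <- Biostrings::translate(Biostrings::DNAString(paste(nt, collapse = "")))
      as.character(Biostrings::subseq(aa, 1, length(aa) - 1))  # drop stop
    }
    gene_set <- Biostrings::DNAStringSet(vapply(genes, paste, "", collapse = ""))
    prot_set <- Biostrings::AAStringSet(vapply(genes, translate1, ""))
    names(prot_set) <- names(gene_set)

    ins_tbl <- tibble(gene = character(0), prot_start0 = integer(0),
                      prot_end0 = integer(0), nt_start0 = integer(0),
                      nt_end0 = integer(0))
    if (length(ins_aa)) {
      h2 <- grep("_H2$", names(genes), value = TRUE)
      ins_tbl <- tibble(gene = h2,
                        prot_start0 = ins_prot0,
                        prot_end0 = ins_prot0 + ins$length_aa,
                        nt_start0 = 3L * ins_prot0,
                        nt_end0 = 3L * (ins_prot0 + ins$length_aa))
    }

    fu_map <- dplyr::bind_rows(lapply(names(genes), function(g) {
      b <- fu_boundaries(arch)
      if (grepl("_H2$", g) && length(ins_aa)) {
        shift <- ins$length_aa
        after <- b$start_aa > ins_prot0 + 1L
        b$end_aa[b$start_aa <= ins_prot0 + 1L & b$end_aa > ins_prot0] <-
          b$end_aa[b$start_aa <= ins_prot0 + 1L & b$end_aa > ins_prot0] + shift
        b$start_aa[after] <- b$start_aa[after] + shift
        b$end_aa[after] <- b$end_aa[after] + shift
      }
      dplyr::mutate(b, gene = g, .before = 1)
    }))

    structure(list(
      genes = gene_set,
      proteins = prot_set,
      reference = if (is.null(reference)) NULL else
        Biostrings::DNAString(paste(reference, collapse = "")),
      reference_protein = if (is.null(reference)) NULL else
        Biostrings::AAString(translate1(reference)),
      outgroup = if (is.null(outgroup)) NULL else
        Biostrings::DNAString(paste(outgroup, collapse = "")),
      outgroup_protein = if (is.null(outgroup)) NULL else
        Biostrings::AAString(translate1(outgroup)),
      insert = ins_tbl,
      fu_map = fu_map,
      spec = spec
    ), class = "truth_set")
  })
}

#' @export
print.truth_set <- function(x, ...) {
  cat("<truth_set> ", length(x$genes), " genes (",
      paste(names(x$genes), collapse = ", "), "), CDS ",
      paste(Biostrings::width(x$genes), collapse = "/"), " nt",
      if (nrow(x$insert)) paste0("; H2 insert ",
        x$insert$prot_end0[1] - x$insert$prot_start0[1], " aa"), "\n", sep = "")
  invisible(x)
}

#' Fuse two paralogs into a chimeric ("hybrid") CDS
#'
#' Builds the misassembly artifact the verification protocol is designed to
#' catch: the 5' part of H1 joined to the 3' part of H2 at a chosen
#' breakpoint. Coordinates upstream of the H2 insert are shared between the
#' colinear paralogs; breakpoints downstream are shifted by the insert length
#' on the H2 side.
#'
#' @param truth A [generate_paralog_pair()] result.
#' @param breakpoint_nt 0-based H1 coordinate of the fusion point: the
#'   chimera is `H1[1..breakpoint] + H2[(breakpoint'+1)..]`. 0 returns H2
#'   unchanged; `nchar(H1)` returns H1 unchanged.
#' @param species Which species' paralogs to fuse.
#' @return A list of class `chimera_truth` with the fused `seq`
#'   ([Biostrings::DNAString]), the true `breakpoint_nt`, and parent ids.
#' @export
make_chimera <- function(truth, breakpoint_nt, species = "sp1") {
  stopifnot(inherits(truth, "truth_set"))
  h1_id <- paste0(species, "_H1"); h2_id <- paste0(species, "_H2")
  if (!all(c(h1_id, h2_id) %in% names(truth$genes)))
    stop("species '", species, "' not present in truth set")
  h1 <- as.character(truth$genes[[h1_id]])
  h2 <- as.character(truth$genes[[h2_id]])
  L1 <- nchar(h1)
  if (breakpoint_nt < 0 || breakpoint_nt > L1)
    stop("breakpoint must lie in [0, ", L1, "]")
  ins <- truth$insert[truth$insert$gene == h2_id, ]
  shift <- if (nrow(ins) && breakpoint_nt > ins$nt_start0[1])
    ins$nt_end0[1] - ins$nt_start0[1] else 0L
  bp2 <- breakpoint_nt + shift
  seq <- paste0(substr(h1, 1, breakpoint_nt), substr(h2, bp2 + 1, nchar(h2)))
  structure(list(seq = Biostrings::DNAString(seq),
                 breakpoint_nt = as.integer(breakpoint_nt),
                 breakpoint_h2_nt = as.integer(bp2),
                 parents = c(h1_id, h2_id), species = species),
            class = "chimera_truth")
}

#' Write a truth set to files
#'
#' Writes the simulated CDSs and proteins as FASTA plus TSV tables of the
#' insert coordinates (0-based half-open, protein and CDS scale) and the
#' per-gene FU boundaries (1-based inclusive).
#'
#' @param truth A [generate_paralog_pair()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_truth_set <- function(truth, dir) {
  stopifnot(inherits(truth, "truth_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genes = file.path(dir, "genes.fasta"),
             proteins = file.path(dir, "proteins.fasta"),
             insert = file.path(dir, "insert.tsv"),
             fu_map = file.path(dir, "fu_map.tsv"))
  Biostrings::writeXStringSet(truth$genes, paths[["genes"]])
  Biostrings::writeXStringSet(truth$proteins, paths[["proteins"]])
  utils::write.table(truth$insert, paths[["insert"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth$fu_map, paths[["fu_map"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(truth$reference))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(as.character(truth$reference),
                                        "seed_reference")),
      file.path(dir, "reference.fasta"))
  invisible(paths)
}
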