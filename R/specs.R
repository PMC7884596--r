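#' Functional-unit architecture of a hemocyanin subunit
#'
#' Describes the tandem domain layout of a gastropod hemocyanin polypeptide:
#' a series of paralogous functional units (FUs, ~420 aa each, one
#' oxygen-binding site per FU) labelled a..h by convention, with the last FU
#' carrying an additional C-terminal tail (~100 aa).
#'
#' @param fu_names Ordered character vector of domain labels.
#' @param fu_length_aa Integer length of each FU in amino acids; recycled to
#'   `length(fu_names)`.
#' @param terminal_tail_aa Integer tail appended after the last FU.
#' @param intra_gene_fu_identity Target pairwise amino-acid identity between
#'   the FU domains of one gene, in `[0, 1]`. Controls how internally
#'   repetitive the simulated gene is.
#' @return An object of class `fu_architecture`.
#' @examples
#' arch <- fu_architecture()
#' total_protein_length(arch)  # 8 * 420 + 100
#' @export
fu_architecture <- function(fu_names = letters[1:8], fu_length_aa = 420,
                            terminal_tail_aa = 100, intra_gene_fu_identity = 0.5) {
  stopifnot(length(fu_names) >= 1, !anyDuplicated(fu_names))
  fu_length_aa <- rep_len(as.integer(fu_length_aa), length(fu_names))
  if (any(fu_length_aa < 1)) stop("every FU must be at least 1 aa long")
  terminal_tail_aa <- as.integer(terminal_tail_aa)
  stopifnot(terminal_tail_aa >= 0,
            intra_gene_fu_identity >= 0, intra_gene_fu_identity <= 1)
  structure(list(fu_names = as.character(fu_names),
                 fu_length_aa = fu_length_aa,
                 terminal_tail_aa = terminal_tail_aa,
                 intra_gene_fu_identity = intra_gene_fu_identity),
            class = "fu_architecture")
}

#' Total protein length implied by an architecture
#' @param arch A [fu_architecture()].
#' @return Integer number of residues.
#' @export
total_protein_length <- function(arch) {
  stopifnot(inherits(arch, "fu_architecture"))
  sum(arch$fu_length_aa) + arch$terminal_tail_aa
}

#' FU boundary table for an architecture
#'
#' @param arch A [fu_architecture()].
#' @return Tibble with columns `fu`, `start_aa`, `end_aa` (1-based inclusive);
#'   the terminal tail is included in the last FU's span.
#' @export
fu_boundaries <- function(arch) {
  stopifnot(inherits(arch, "fu_architecture"))
  len <- arch$fu_length_aa
  len[length(len)] <- len[length(len)] + arch$terminal_tail_aa
  ends <- cumsum(len)
  tibble(fu = arch$fu_names, start_aa = c(1L, head(ends, -1) + 1L),
         end_aa = as.integer(ends))
}

#' Specification of a hydrophilic His/Asp-rich insertion
#'
#' The muricid H2-type hemocyanin subunits carry an extra hydrophilic segment
#' in the N-terminal region of FU-g, built from repetitive motifs dominated
#' by histidine and aspartate. This object parameterizes that insertion for
#' the synthetic generator.
#'
#' @param length_aa Insert length in residues (0 disables the insert).
#' @param host_fu Label of the FU that receives the insert.
#' @param offset_in_fu_aa 0-based residue offset of the insertion point within
#'   the host FU (default near the N-terminus).
#' @param his_asp_fraction Target combined His+Asp fraction of the insert.
#' @param motif_period Length of the repeated motif the insert is built from.
#' @return An object of class `insert_spec`.
#' @export
insert_spec <- function(length_aa = 340, host_fu = "g", offset_in_fu_aa = 30,
                        his_asp_fraction = 0.7, motif_period = 6) {
  length_aa <- as.integer(length_aa)
  stopifnot(length_aa >= 0, his_asp_fraction >= 0, his_asp_fraction <= 1,
            motif_period >= 1, offset_in_fu_aa >= 0)
  structure(list(length_aa = length_aa, host_fu = as.character(host_fu),
                 offset_in_fu_aa = as.integer(offset_in_fu_aa),
                 his_asp_fraction = his_asp_fraction,
                 motif_period = as.integer(motif_period)),
            class = "insert_spec")
}

#' Specification of a pair of paralogous hemocyanin genes
#'
#' Describes the generative model behind the synthetic data: a single
#' ancestral multi-FU gene duplicates into two paralogs (H1, H2); H2 acquires
#' a hydrophilic insertion; both paralogs are then inherited by two species.
#' Divergences are expected per-site nucleotide divergences between the
#' final sequences (double substitutions are corrected for), applied per
#' codon with a synonymous bias.
#'
#' @param architecture A [fu_architecture()].
#' @param paralog_divergence Expected per-site nucleotide divergence between
#'   H1 and H2 within one species, in `[0, 1)`.
#' @param species_divergence Expected divergence between orthologs of the two
#'   species; `NULL` generates a single species.
#' @param h2_insert An [insert_spec()] applied to the H2 paralog.
#' @param seed_reference_divergence Expected divergence between each paralog
#'   and the heterologous seed reference gene (no insert); `NULL` omits the
#'   reference.
#' @param outgroup_divergence Expected divergence between the ancestor and an
#'   outgroup hemocyanin used to root trees; `NULL` omits the outgroup.
#' @param synonymous_weight Relative weight of synonymous over nonsynonymous
#'   single-nucleotide changes when substituting (default 2, i.e. 2:1).
#' @param codon_table_id NCBI genetic code id (only 1, the standard code, is
#'   supported).
#' @param seed Integer seed; all randomness of the generator flows from it.
#' @return An object of class `paralog_pair_spec`.
#' @export
paralog_pair_spec <- function(architecture = fu_architecture(),
                              paralog_divergence = 0.30,
                              species_divergence = 0.15,
                              h2_insert = insert_spec(),
                              seed_reference_divergence = 0.25,
                              outgroup_divergence = 0.45,
                              synonymous_weight = 2,
                              codon_table_id = 1,
                              seed = 1L) {
  stopifnot(inherits(architecture, "fu_architecture"),
            inherits(h2_insert, "insert_spec"),
            paralog_divergence >= 0, paralog_divergence < 0.75,
            is.null(species_divergence) ||
              (species_divergence >= 0 && species_divergence < 0.75),
            synonymous_weight > 0)
  if (codon_table_id != 1) stop("only the standard genetic code (id 1) is supported")
  if (!h2_insert$host_fu %in% architecture$fu_names)
    stop("insert host FU '", h2_insert$host_fu, "' not in architecture")
  host_len <- architecture$fu_length_aa[match(h2_insert$host_fu, architecture$fu_names)]
  if (h2_insert$offset_in_fu_aa > host_len)
    stop("insert offset exceeds host FU length")
  if (!is.null(species_divergence) && paralog_divergence <= species_divergence)
    warning("paralog_divergence <= species_divergence: orthology topology ",
            "tests will not be meaningful")
  structure(list(architecture = architecture,
                 paralog_divergence = paralog_divergence,
                 species_divergence = species_divergence,
                 h2_insert = h2_insert,
                 seed_reference_divergence = seed_reference_divergence,
                 outgroup_divergence = outgroup_divergence,
                 synonymous_weight = synonymous_weight,
                 codon_table_id = as.integer(codon_table_id),
                 seed = as.integer(seed)),
            class = "paralog_pair_spec")
}

#' Specification of a paired-end read simulation
#'
#' Substitution-only short-read model with constant Q30 qualities and
#' forward-reverse mate orientation, emulating transcriptomic short-read
#' data. Fragments are drawn along the transcript with ragged ends (terminal
#' fragments are truncated at the sequence boundaries), so transcript termini
#' receive coverage as they do after random fragmentation of full-length
#' molecules.
#'
#' @param read_length_nt Read length.
#' @param fragment_mean_nt,fragment_sd_nt Normal fragment-length model.
#' @param coverage Target fold-coverage per gene.
#' @param error_rate Per-base substitution error probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return An object of class `read_sim_spec`.
#' @export
read_sim_spec <- function(read_length_nt = 150, fragment_mean_nt = 350,
                          fragment_sd_nt = 35, coverage = 50,
                          error_rate = 0.01, seed = 1L) {
  read_length_nt <- as.integer(read_length_nt)
  stopifnot(read_length_nt >= 1, coverage > 0,
            error_rate >= 0, error_rate < 1, fragment_sd_nt >= 0)
  if (fragment_mean_nt < read_length_nt)
    stop("fragment_mean_nt must be >= read_length_nt")
  structure(list(read_length_nt = read_length_nt,
                 fragment_mean_nt = fragment_mean_nt,
                 fragment_sd_nt = fragment_sd_nt,
                 coverage = coverage, error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "read_sim_spec")
}

#' @export
print.fu_architecture <- function(x, ...) {
  cat("<fu_architecture> ", length(x$fu_names), " FUs (",
      paste(x$fu_names, collapse = ","), "), ",
      sum(x$fu_length_aa), " aa + ", x$terminal_tail_aa, " aa tail\n", sep = "")
  invisible(x)
}

#' @export
print.paralog_pair_spec <- function(x, ...) {
  cat("<paralog_pair_spec> paralog divergence ", x$paralog_divergence,
      if (!is.null(x$species_divergence))
        paste0(", species divergence ", x$species_divergence),
      ", H2 insert ", x$h2_insert$length_aa, " aa in FU-",
      x$h2_insert$host_fu, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}
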