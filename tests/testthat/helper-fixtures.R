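# Shared fixture builders. Small architectures keep unit tests fast; the
# full eight-FU architecture is exercised in the acceptance tests.

small_arch <- function(intra = 0.5) {
  fu_architecture(fu_names = c("a", "b", "g", "h"), fu_length_aa = 420,
                  terminal_tail_aa = 100, intra_gene_fu_identity = intra)
}

small_spec <- function(seed = 1, insert_len = 340, paralog = 0.30,
                       species = 0.15, ...) {
  paralog_pair_spec(architecture = small_arch(),
                    paralog_divergence = paralog,
                    species_divergence = species,
                    h2_insert = insert_spec(length_aa = insert_len),
                    seed = seed, ...)
}

# a tiny two-domain gene family for mapping micro-tests (CDS ~1.2 kb)
tiny_spec <- function(seed = 1, paralog = 0.30, insert_len = 0,
                      species = NULL, ...) {
  paralog_pair_spec(
    architecture = fu_architecture(fu_names = c("a", "g"), fu_length_aa = 180,
                                   terminal_tail_aa = 40),
    paralog_divergence = paralog, species_divergence = species,
    h2_insert = insert_spec(length_aa = insert_len, host_fu = "g",
                            offset_in_fu_aa = 20),
    seed = seed, ...)
}

# fraction identity between two equal-length sequences
seq_identity <- function(a, b) {
  va <- strsplit(as.character(a), "")[[1]]
  vb <- strsplit(as.character(b), "")[[1]]
  n <- min(length(va), length(vb))
  mean(va[seq_len(n)] == vb[seq_len(n)])
}

# H2 CDS with the insert excised, for colinear comparison against H1
h2_without_insert <- function(ts, gene = "sp1_H2") {
  s <- as.character(ts$genes[[gene]])
  r <- ts$insert[ts$insert$gene == gene, ]
  if (!nrow(r)) return(s)
  paste0(substr(s, 1, r$nt_start0), substr(s, r$nt_end0 + 1, nchar(s)))
}
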