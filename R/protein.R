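# Protein-level characterization: ORF finding, translation, mass,
# composition, hydropathy.

# Average (and monoisotopic) residue masses, Da; water added once per chain.
.AA_MASS_AVG <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
                  C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
                  H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
                  M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
                  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.AA_MASS_MONO <- c(A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694,
                   C = 103.00919, E = 129.04259, Q = 128.05858, G = 57.02146,
                   H = 137.05891, I = 113.08406, L = 113.08406, K = 128.09496,
                   M = 131.04049, F = 147.06841, P = 97.05276, S = 87.03203,
                   T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841)
.WATER_AVG <- 18.01524
.WATER_MONO <- 18.010565

# Kyte-Doolittle hydropathy scale
.KD <- c(I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
         G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
         H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5)

.aa_chars <- function(p) {
  if (inherits(p, "protein_record")) p <- p$seq
  strsplit(.as_char_seq(p), "")[[1]]
}

#' Construct a protein record
#'
#' @param seq Residue sequence (character or AAString).
#' @param id Identifier.
#' @return A list of class `protein_record` with `id`, `seq`, `length_aa`
#'   and `mass_da` (average mass; `NA` with a warning when nonstandard
#'   residues are present).
#' @export
protein_record <- function(seq, id = "protein") {
  seq <- toupper(.as_char_seq(seq))
  if (!nchar(seq)) stop("empty protein sequence")
  mass <- tryCatch(molecular_weight(seq), error = function(e) NA_real_)
  structure(list(id = id, seq = seq, length_aa = nchar(seq), mass_da = mass),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record> ", x$id, ": ", x$length_aa, " aa",
      if (!is.na(x$mass_da)) paste0(", ", round(x$mass_da / 1000, 1), " kDa"),
      "\n", sep = "")
  invisible(x)
}

#' Find and translate the longest ORF
#'
#' Scans both strands of a nucleotide sequence for the longest ATG-initiated
#' open reading frame under the standard genetic code and translates it
#' without the terminal stop. ORFs may end at a stop codon or at the
#' sequence end. Internal `N`s translate to `X` and are flagged.
#'
#' @param x Nucleotide sequence (character, DNAString, or length-1
#'   DNAStringSet) over `A,C,G,T,N`.
#' @param min_orf_nt Minimum ORF length in nucleotides (including the stop
#'   codon); shorter ORFs cause an error.
#' @param id Identifier for the resulting record.
#' @return A `protein_record` with extra fields `cds` (the ORF nucleotides
#'   including the stop codon when present), `strand`, `cds_start` (1-based
#'   on the input strand given), and `has_stop`. For a stop-terminated ORF,
#'   `length_aa = nchar(cds) / 3 - 1`.
#' @examples
#' find_orf_translate("ATGGGTTAA", min_orf_nt = 9)$seq  # "MG"
#' @export
find_orf_translate <- function(x, min_orf_nt = 300, id = "orf") {
  if (is(x, "DNAStringSet")) x <- x[[1]]
  s <- toupper(.as_char_seq(x))
  if (grepl("[^ACGTN]", s)) stop("sequence must be over A,C,G,T,N")
  gc <- Biostrings::GENETIC_CODE
  best <- NULL
  for (strand in c("+", "-")) {
    seq <- if (strand == "+") s else .revcomp_chr(s)
    n <- nchar(seq)
    v <- strsplit(seq, "")[[1]]
    for (frame in 0:2) {
      idx <- seq(1 + frame, n - 2, by = 3)
      if (!length(idx)) next
      codons <- paste0(v[idx], v[idx + 1], v[idx + 2])
      aa <- unname(gc[codons])
      aa[is.na(aa)] <- "X"   # codons containing N
      stops <- which(aa == "*")
      starts <- which(codons == "ATG")
      if (!length(starts)) next
      seg_end <- c(stops, length(aa) + 1L)   # segment boundaries (exclusive)
      prev <- 0L
      for (e in seg_end) {
        cand <- starts[starts > prev & starts < e]
        if (length(cand)) {
          st <- cand[1]
          has_stop <- e <= length(aa)
          len_nt <- (e - st) * 3L + if (has_stop) 3L else 0L
          if (is.null(best) || len_nt > best$len_nt) {
            best <- list(strand = strand, frame = frame, start_codon = st,
                         end_codon = e, has_stop = has_stop, len_nt = len_nt,
                         aa = aa[st:(e - 1L)],
                         cds_start = idx[st])
          }
        }
        prev <- e
      }
    }
  }
  if (is.null(best)) stop("no ATG-initiated ORF found")
  if (best$len_nt < min_orf_nt)
    stop("longest ORF (", best$len_nt, " nt) is below min_orf_nt = ", min_orf_nt)
  seq_used <- if (best$strand == "+") s else .revcomp_chr(s)
  cds <- substr(seq_used, best$cds_start, best$cds_start + best$len_nt - 1L)
  prot <- paste(best$aa, collapse = "")
  if (grepl("X", prot))
    warning("ambiguous codons translated as X at ",
            paste(which(best$aa == "X"), collapse = ","))
  p <- protein_record(prot, id = id)
  p$cds <- cds
  p$strand <- best$strand
  p$cds_start <- best$cds_start
  p$has_stop <- best$has_stop
  p
}

#' Protein molecular weight
#'
#' Sum of residue masses plus one water. Average masses by default (matching
#' how subunit sizes of large multidomain proteins are usually reported);
#' monoisotopic masses behind a flag.
#'
#' @param p A `protein_record`, AAString or character sequence.
#' @param monoisotopic Use monoisotopic masses.
#' @return Mass in Da.
#' @examples
#' molecular_weight("G")   # 75.07
#' @export
molecular_weight <- function(p, monoisotopic = FALSE) {
  aa <- .aa_chars(p)
  if (!length(aa)) stop("empty protein sequence")
  tab <- if (monoisotopic) .AA_MASS_MONO else .AA_MASS_AVG
  bad <- which(!aa %in% names(tab))
  if (length(bad))
    stop("nonstandard residues at positions ",
         paste(head(bad, 10), collapse = ","),
         if (length(bad) > 10) " ...")
  sum(tab[aa]) + if (monoisotopic) .WATER_MONO else .WATER_AVG
}

#' Residue composition of a protein or segment
#'
#' @param p Sequence.
#' @return Tibble `residue`, `count`, `fraction` over the 20 standard
#'   residues plus any others present; fractions sum to 1.
#' @export
residue_composition <- function(p) {
  aa <- .aa_chars(p)
  if (!length(aa)) stop("empty protein sequence")
  tab <- table(factor(aa, levels = union(names(.AA_MASS_AVG), unique(aa))))
  tibble(residue = names(tab), count = as.integer(tab),
         fraction = as.integer(tab) / length(aa))
}

#' Kyte-Doolittle hydropathy profile
#'
#' Windowed mean hydropathy per residue position (centered window; ends are
#' truncated to the available residues). Negative values are hydrophilic;
#' His (-3.2) and Asp (-3.5) are both strongly hydrophilic, so the
#' His/Asp-rich hemocyanin insertions show as deep hydrophilic troughs.
#'
#' @param p Sequence.
#' @param window Odd window size, at most the sequence length.
#' @return Tibble of class `hydropathy_profile`: `position`, `residue`,
#'   `hydropathy`; window size in attribute `window`.
#' @export
hydropathy_profile <- function(p, window = 9) {
  aa <- .aa_chars(p)
  if (window %% 2 == 0) stop("window must be odd")
  if (window > length(aa)) stop("window larger than the sequence")
  if (any(!aa %in% names(.KD)))
    stop("nonstandard residues present; hydropathy undefined")
  v <- .KD[aa]
  half <- (window - 1) / 2
  n <- length(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(1, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  out <- tibble(position = seq_len(n), residue = aa,
                hydropathy = as.numeric((cs[hi + 1] - cs[lo]) / (hi - lo + 1)))
  attr(out, "window") <- as.integer(window)
  class(out) <- c("hydropathy_profile", class(out))
  out
}

#' Mean hydropathy of a sequence
#' @param p Sequence.
#' @return Mean Kyte-Doolittle value over all residues.
#' @export
mean_hydropathy <- function(p) {
  aa <- .aa_chars(p)
  mean(.KD[aa])
}
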