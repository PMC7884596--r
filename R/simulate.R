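# Paired-end read simulation with substitution errors and known origins.

.revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate paired-end reads from a truth set
#'
#' Substitution-only paired-end short-read simulator. Fragments are placed
#' with ragged ends: the fragment window may overhang the transcript and is
#' truncated to it, emulating random fragmentation of full-length molecules,
#' so terminal bases receive coverage. Mates are forward-reverse; R1 is the
#' 5' end of the fragment on the sequenced strand, R2 the reverse complement
#' of its 3' end. Qualities are constant Q30, Phred+33.
#'
#' @param truth A [generate_paralog_pair()] result, or any named
#'   [Biostrings::DNAStringSet] of source sequences.
#' @param spec A [read_sim_spec()].
#' @param genes Optional character vector restricting which sequences reads
#'   are drawn from (default: all).
#' @return An object of class `read_set`: list with `r1`, `r2`
#'   ([Biostrings::DNAStringSet], names `frag<i>/1`, `frag<i>/2`), an
#'   `origin` tibble (`read_id`, `gene`, `start`, `end` 1-based inclusive on
#'   the source gene, `strand` of the sequenced fragment, `mate`), and `spec`.
#'   The per-pair count per gene is `round(coverage * length / (2 * read_length))`.
#' @examples
#' ts <- generate_paralog_pair(paralog_pair_spec(seed = 1))
#' rs <- simulate_reads(ts, read_sim_spec(coverage = 5, seed = 1),
#'                      genes = "sp1_H1")
#' length(rs$r1)
#' @export
simulate_reads <- function(truth, spec, genes = NULL) {
  stopifnot(inherits(spec, "read_sim_spec"))
  src <- if (inherits(truth, "truth_set")) truth$genes else truth
  stopifnot(is(src, "DNAStringSet"), length(src) > 0)
  if (!is.null(genes)) {
    missing <- setdiff(genes, names(src))
    if (length(missing)) stop("unknown genes: ", paste(missing, collapse = ", "))
    src <- src[genes]
  }
  rl <- spec$read_length_nt
  .with_seed(spec$seed, {
    out <- vector("list", length(src))
    counter <- 0L
    for (gi in seq_along(src)) {
      gene <- names(src)[gi]
      gseq <- as.character(src[[gi]])
      L <- nchar(gseq)
      if (L < rl) stop("gene '", gene, "' shorter than the read length")
      n_pairs <- max(1L, round(spec$coverage * L / (2 * rl)))
      flen <- pmax(rl, round(rnorm(n_pairs, spec$fragment_mean_nt,
                                   spec$fragment_sd_nt)))
      # ragged-end placement: window start uniform over [2 - flen, L],
      # truncated to [1, L]; windows shorter than one read are redrawn inward
      fs <- floor(runif(n_pairs, min = 2 - flen, max = L + 1))
      fe <- pmin(L, fs + flen - 1L)
      fs <- pmax(1L, fs)
      short <- which(fe - fs + 1L < rl)
      for (i in short) {
        fs[i] <- sample.int(L - rl + 1L, 1L)
        fe[i] <- min(L, fs[i] + flen[i] - 1L)
      }
      strand <- ifelse(runif(n_pairs) < 0.5, "+", "-")
      ids <- sprintf("frag%06d", counter + seq_len(n_pairs))
      counter <- counter + n_pairs
      r1_plus <- substring(gseq, fs, fs + rl - 1L)
      r2_plus <- substring(gseq, fe - rl + 1L, fe)
      r1 <- ifelse(strand == "+", r1_plus, .revcomp_chr(r2_plus))
      r2 <- ifelse(strand == "+", .revcomp_chr(r2_plus), r1_plus)
      out[[gi]] <- tibble(
        id = ids, gene = gene, frag_start = fs, frag_end = fe,
        strand = strand, r1 = r1, r2 = r2,
        r1_start = ifelse(strand == "+", fs, fe - rl + 1L),
        r1_end = ifelse(strand == "+", fs + rl - 1L, fe),
        r2_start = ifelse(strand == "+", fe - rl + 1L, fs),
        r2_end = ifelse(strand == "+", fe, fs + rl - 1L))
    }
    tbl <- dplyr::bind_rows(out)
    if (spec$error_rate > 0) {
      tbl$r1 <- .add_errors(tbl$r1, spec$error_rate)
      tbl$r2 <- .add_errors(tbl$r2, spec$error_rate)
    }
    r1 <- Biostrings::DNAStringSet(setNames(tbl$r1, paste0(tbl$id, "/1")))
    r2 <- Biostrings::DNAStringSet(setNames(tbl$r2, paste0(tbl$id, "/2")))
    origin <- dplyr::bind_rows(
      tibble(read_id = paste0(tbl$id, "/1"), gene = tbl$gene,
             start = as.integer(tbl$r1_start), end = as.integer(tbl$r1_end),
             strand = tbl$strand, mate = 1L,
             frag_start = as.integer(tbl$frag_start),
             frag_end = as.integer(tbl$frag_end)),
      tibble(read_id = paste0(tbl$id, "/2"), gene = tbl$gene,
             start = as.integer(tbl$r2_start), end = as.integer(tbl$r2_end),
             strand = ifelse(tbl$strand == "+", "-", "+"), mate = 2L,
             frag_start = as.integer(tbl$frag_start),
             frag_end = as.integer(tbl$frag_end))) %>%
      arrange(.data$read_id)
    structure(list(r1 = r1, r2 = r2, origin = origin, spec = spec),
              class = "read_set")
  })
}

# substitution errors: each base replaced by a uniformly drawn different base
.add_errors <- function(reads, rate) {
  n <- nchar(reads[1])
  bases <- c("A", "C", "G", "T")
  vapply(reads, function(r) {
    hit <- which(runif(nchar(r)) < rate)
    if (!length(hit)) return(r)
    v <- strsplit(r, "")[[1]]
    for (i in hit) v[i] <- sample(setdiff(bases, v[i]), 1L)
    paste(v, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' @export
print.read_set <- function(x, ...) {
  cat("<read_set> ", length(x$r1), " pairs, ",
      x$spec$read_length_nt, " nt reads, error rate ",
      x$spec$error_rate, "\n", sep = "")
  invisible(x)
}

#' All reads of a read set as one oriented set
#'
#' @param rs A [simulate_reads()] result.
#' @return A [Biostrings::DNAStringSet] with both mates interleaved by name.
#' @export
all_reads <- function(rs) {
  stopifnot(inherits(rs, "read_set"))
  x <- c(rs$r1, rs$r2)
  x[order(names(x))]
}

#' Write a read set as a pair of FASTQ files
#'
#' @param rs A [simulate_reads()] result.
#' @param r1_path,r2_path Output FASTQ paths.
#' @return Invisibly, the two paths.
#' @export
write_read_set <- function(rs, r1_path, r2_path) {
  stopifnot(inherits(rs, "read_set"))
  q30 <- function(x) Biostrings::BStringSet(
    setNames(strrep("?", Biostrings::width(x)), names(x)))
  Biostrings::writeXStringSet(rs$r1, r1_path, format = "fastq",
                              qualities = q30(rs$r1))
  Biostrings::writeXStringSet(rs$r2, r2_path, format = "fastq",
                              qualities = q30(rs$r2))
  invisible(c(r1_path, r2_path))
}
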