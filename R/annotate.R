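# Alignment-based annotation: FU architecture projection, insertion calls,
# cysteine census.

# global affine-gap alignment of two proteins; returns per-column query and
# subject positions (NA at gaps)
.align_aa <- function(a, b) {
  a <- .as_char_seq(a); b <- .as_char_seq(b)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  qpos <- ifelse(pa == "-", NA_integer_, cumsum(pa != "-"))
  spos <- ifelse(pb == "-", NA_integer_, cumsum(pb != "-"))
  list(aln = aln, a = pa, b = pb, qpos = qpos, spos = spos)
}

#' Annotate functional units by projection from a reference architecture
#'
#' Globally aligns a protein to a reference whose FU boundaries are known and
#' projects the boundaries through the alignment. Insertions in the query
#' (residues aligned to reference gaps) stay inside the FU containing their
#' left flank. FUs with almost no aligned query residues (under 30% of the
#' reference FU) are reported absent.
#'
#' @param p Query protein (`protein_record`, AAString, character).
#' @param reference Reference protein sequence.
#' @param reference_fus Tibble with `fu`, `start_aa`, `end_aa` (1-based
#'   inclusive, on the reference), e.g. [fu_boundaries()].
#' @return Tibble of class `fu_annotation`: `fu`, `start_aa`, `end_aa` on
#'   the query, `ref_start`, `ref_end`, `aligned_aa`.
#' @export
annotate_fus <- function(p, reference, reference_fus) {
  stopifnot(all(c("fu", "start_aa", "end_aa") %in% names(reference_fus)))
  q <- if (inherits(p, "protein_record")) p$seq else .as_char_seq(p)
  r <- if (inherits(reference, "protein_record")) reference$seq else
    .as_char_seq(reference)
  al <- .align_aa(q, r)
  ref_aligned <- sum(!is.na(al$qpos) & !is.na(al$spos))
  if (ref_aligned < 0.5 * nchar(r))
    stop("alignment covers under 50% of the reference; ",
         "input does not look hemocyanin-like")
  # query position aligned at-or-after / at-or-before each reference position
  n <- length(al$a)
  qfill_fwd <- al$qpos
  for (i in 2:n) if (is.na(qfill_fwd[i])) qfill_fwd[i] <- qfill_fwd[i - 1]
  qfill_bwd <- al$qpos
  for (i in (n - 1):1) if (is.na(qfill_bwd[i])) qfill_bwd[i] <- qfill_bwd[i + 1]
  col_of_ref <- match(seq_len(nchar(r)), al$spos)
  out <- lapply(seq_len(nrow(reference_fus)), function(i) {
    rs <- reference_fus$start_aa[i]; re <- reference_fus$end_aa[i]
    cs <- col_of_ref[rs]; ce <- col_of_ref[re]
    qs <- qfill_bwd[cs]          # first query residue at/after FU start
    # FU end extends to just before the next FU's first aligned query residue,
    # so unaligned insertions attach to the FU on their left
    if (i < nrow(reference_fus)) {
      cn <- col_of_ref[reference_fus$start_aa[i + 1]]
      qe <- qfill_bwd[cn]
      qe <- if (is.na(qe)) nchar(q) else qe - 1L
    } else {
      qe <- nchar(q)
    }
    aligned <- sum(!is.na(al$qpos[cs:ce]) & !is.na(al$spos[cs:ce]))
    tibble(fu = reference_fus$fu[i],
           start_aa = as.integer(qs), end_aa = as.integer(qe),
           ref_start = rs, ref_end = re, aligned_aa = aligned)
  })
  out <- dplyr::bind_rows(out)
  out <- out[!is.na(out$start_aa) & !is.na(out$end_aa) &
               out$aligned_aa >= 0.3 * (out$ref_end - out$ref_start + 1L), ,
             drop = FALSE]
  class(out) <- c("fu_annotation", class(out))
  out
}

#' Call insertions relative to an insert-free counterpart
#'
#' Globally aligns a protein against a homolog lacking the insertion (the H1
#' paralog or another reference hemocyanin) and reports every maximal run of
#' at least `min_insert_aa` query residues aligned to counterpart gaps, with
#' its composition, mass and hydropathy. This is how the extra His/Asp-rich
#' FU-g segment of the H2 subunits is detected and measured.
#'
#' @param p Query protein.
#' @param counterpart Insert-free homolog.
#' @param min_insert_aa Minimum insertion length to report.
#' @param bridge_aa Gap runs separated by at most this many aligned columns
#'   are merged before length filtering: in a long divergent insertion the
#'   aligner occasionally pairs a couple of insert residues with the
#'   counterpart by chance, splitting one biological insertion into two gap
#'   runs.
#' @param counterpart_fus Optional FU boundary tibble for the counterpart;
#'   when given, each call is annotated with the host FU containing its left
#'   flank.
#' @return Tibble of class `insertion_calls`: `start_aa`, `end_aa` (query,
#'   1-based inclusive), `length_aa`, `mass_da` (sum of residue masses),
#'   `his_fraction`, `asp_fraction`, `his_asp_fraction`, `mean_hydropathy`,
#'   `host_fu`. Zero rows when no insertion qualifies.
#' @export
call_insertion <- function(p, counterpart, min_insert_aa = 20,
                           bridge_aa = 10, counterpart_fus = NULL) {
  q <- if (inherits(p, "protein_record")) p$seq else .as_char_seq(p)
  s <- if (inherits(counterpart, "protein_record")) counterpart$seq else
    .as_char_seq(counterpart)
  al <- .align_aa(q, s)
  gap <- is.na(al$spos) & !is.na(al$qpos)
  runs <- rle(gap)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  gi <- which(runs$values)
  # merge neighbouring gap runs across short aligned bridges
  spans <- list()
  for (k in gi) {
    if (length(spans) &&
        starts[k] - spans[[length(spans)]][2] - 1L <= bridge_aa) {
      spans[[length(spans)]][2] <- ends[k]
    } else {
      spans[[length(spans) + 1L]] <- c(starts[k], ends[k])
    }
  }
  keep <- Filter(function(sp) {
    sum(gap[sp[1]:sp[2]]) >= min_insert_aa
  }, spans)
  out <- lapply(keep, function(sp) {
    cols <- sp[1]:sp[2]
    qs <- al$qpos[cols[1]]; qe <- al$qpos[cols[length(cols)]]
    seg <- substr(q, qs, qe)
    aa <- strsplit(seg, "")[[1]]
    host <- NA_character_
    if (!is.null(counterpart_fus)) {
      left <- al$spos[seq_len(cols[1] - 1)]
      left <- left[!is.na(left)]
      if (length(left)) {
        lp <- max(left)
        hit <- counterpart_fus$start_aa <= lp & counterpart_fus$end_aa >= lp
        if (any(hit)) host <- counterpart_fus$fu[which(hit)[1]]
      }
    }
    tibble(start_aa = as.integer(qs), end_aa = as.integer(qe),
           length_aa = qe - qs + 1L,
           mass_da = sum(.AA_MASS_AVG[aa]),
           his_fraction = mean(aa == "H"),
           asp_fraction = mean(aa == "D"),
           his_asp_fraction = mean(aa %in% c("H", "D")),
           mean_hydropathy = mean(.KD[aa]),
           host_fu = host)
  })
  out <- if (length(out)) dplyr::bind_rows(out) else
    tibble(start_aa = integer(0), end_aa = integer(0), length_aa = integer(0),
           mass_da = numeric(0), his_fraction = numeric(0),
           asp_fraction = numeric(0), his_asp_fraction = numeric(0),
           mean_hydropathy = numeric(0), host_fu = character(0))
  class(out) <- c("insertion_calls", class(out))
  out
}

#' Cysteine census against a reference
#'
#' Partitions the cysteines of a protein into canonical (aligned to a
#' cysteine of the reference — the conserved intra-FU disulfide partners)
#' and additional (aligned to a non-cysteine or to a gap). Muricid H2
#' hemocyanins carry such an additional cysteine in the N-terminal region of
#' FU-d.
#'
#' @param p Query protein.
#' @param reference Reference protein.
#' @return Tibble of class `cysteine_report`: `position_aa` (query),
#'   `ref_position_aa` (NA when aligned to a gap), `ref_residue`, `status`
#'   (`"canonical"` / `"additional"`).
#' @export
cysteine_census <- function(p, reference) {
  q <- if (inherits(p, "protein_record")) p$seq else .as_char_seq(p)
  r <- if (inherits(reference, "protein_record")) reference$seq else
    .as_char_seq(reference)
  al <- .align_aa(q, r)
  qa <- strsplit(q, "")[[1]]
  cols <- which(!is.na(al$qpos))
  cys_cols <- cols[qa[al$qpos[cols]] == "C"]
  out <- lapply(cys_cols, function(cc) {
    rp <- al$spos[cc]
    rres <- if (is.na(rp)) NA_character_ else substr(r, rp, rp)
    tibble(position_aa = al$qpos[cc],
           ref_position_aa = rp,
           ref_residue = rres,
           status = if (!is.na(rres) && rres == "C") "canonical" else "additional")
  })
  out <- if (length(out)) dplyr::bind_rows(out) else
    tibble(position_aa = integer(0), ref_position_aa = integer(0),
           ref_residue = character(0), status = character(0))
  class(out) <- c("cysteine_report", class(out))
  out
}
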