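# Three-part verification against chimeric assemblies of paralogous,
# internally repetitive hemocyanin sequences: (i) low-stringency remapping
# for misassembly detection, (ii) identity-window scan between contigs,
# (iii) paired-mate spanning of repetitive/identical windows.

#' Verification parameters
#'
#' Defaults follow the low-sensitivity verification mapping settings: reads
#' need only a short anchoring overlap (25 nt) and may mismatch over up to
#' 60% of their total length beyond it, which lets reads reveal the position
#' where a chimeric consensus switches parent. The clustering fields are this
#' package's concrete detection statistic built on that mapping.
#'
#' @param low_min_overlap_nt Minimum anchoring overlap (nt).
#' @param max_offoverlap_mismatch_fraction Maximum fraction of the total read
#'   length allowed to mismatch beyond the anchor for the read to stay mapped.
#' @param identity_window_nt Window length of the identity scan.
#' @param identity_flag_threshold Windows at or above this identity between
#'   two contigs are flagged hybrid-risk.
#' @param min_spanning_pairs Pairs required to span a flagged window.
#' @param cluster_radius_nt Clip positions within this radius form one
#'   breakpoint cluster.
#' @param min_clip_disagreement Minimum off-anchor disagreement fraction (per
#'   side, of that side's length) for a read to emit a clip event.
#' @param min_clip_mismatches Minimum absolute number of disagreeing bases on
#'   the clipped side; keeps one or two sequencing errors in a short tail
#'   from counting as evidence.
#' @param min_clip_anchor_nt Minimum anchor length for a read to emit a clip
#'   event. Mapping anchors at `low_min_overlap_nt`, but a clip is only
#'   trusted from a confidently placed read: reads whose anchor is merely a
#'   short conserved block shared by both paralogs would otherwise pile up
#'   spurious clip clusters at the block edges.
#' @param min_support Minimum reads in a cluster for a suspect verdict.
#' @param support_fraction Additionally require support of at least this
#'   fraction of the local anchored depth (guards against scattered
#'   cross-paralog anchors at high coverage).
#' @param high_min_overlap_nt The high-stringency assembly overlap, used only
#'   to validate that `low_min_overlap_nt` is indeed lower.
#' @param kmer_size Seed k-mer for the remapping.
#' @return An object of class `verify_params`.
#' @export
verify_params <- function(low_min_overlap_nt = 25,
                          max_offoverlap_mismatch_fraction = 0.60,
                          identity_window_nt = 100,
                          identity_flag_threshold = 0.95,
                          min_spanning_pairs = 1,
                          cluster_radius_nt = 50,
                          min_clip_disagreement = 0.10,
                          min_clip_mismatches = 3,
                          min_clip_anchor_nt = 50,
                          min_support = 3,
                          support_fraction = 0.2,
                          high_min_overlap_nt = 60,
                          kmer_size = 13) {
  stopifnot(low_min_overlap_nt >= kmer_size,
            low_min_overlap_nt < high_min_overlap_nt,
            max_offoverlap_mismatch_fraction >= 0,
            max_offoverlap_mismatch_fraction <= 1,
            identity_window_nt >= 10,
            identity_flag_threshold > 0, identity_flag_threshold <= 1,
            min_spanning_pairs >= 1, min_support >= 3,
            min_clip_anchor_nt >= low_min_overlap_nt)
  structure(list(low_min_overlap_nt = as.integer(low_min_overlap_nt),
                 max_offoverlap_mismatch_fraction = max_offoverlap_mismatch_fraction,
                 identity_window_nt = as.integer(identity_window_nt),
                 identity_flag_threshold = identity_flag_threshold,
                 min_spanning_pairs = as.integer(min_spanning_pairs),
                 cluster_radius_nt = as.integer(cluster_radius_nt),
                 min_clip_disagreement = min_clip_disagreement,
                 min_clip_mismatches = as.integer(min_clip_mismatches),
                 min_clip_anchor_nt = as.integer(min_clip_anchor_nt),
                 min_support = as.integer(min_support),
                 support_fraction = support_fraction,
                 kmer_size = as.integer(kmer_size)),
            class = "verify_params")
}

.contig_char_set <- function(contigs) {
  if (inherits(contigs, "assembly_state"))
    contigs <- assembled_contigs(contigs)
  if (inherits(contigs, "chimera_truth")) {
    x <- setNames(as.character(contigs$seq), "chimera")
    return(x)
  }
  if (is(contigs, "DNAStringSet")) {
    nm <- names(contigs)
    if (is.null(nm)) nm <- paste0("contig", seq_along(contigs))
    return(setNames(as.character(contigs), nm))
  }
  if (is(contigs, "DNAString")) return(c(contig1 = as.character(contigs)))
  stopifnot(is.character(contigs))
  if (is.null(names(contigs))) names(contigs) <- paste0("contig", seq_along(contigs))
  contigs
}

#' Low-stringency remapping for misassembly detection
#'
#' Remaps the full read set to finished contigs with permissive settings:
#' each read is anchored by its longest perfect-match run (at least
#' `low_min_overlap_nt`) at its best ungapped placement; mismatches beyond
#' the anchor are tolerated up to `max_offoverlap_mismatch_fraction` of the
#' read length. Reads whose off-anchor part disagrees strongly on one side
#' emit a clip event at the anchor boundary; clip events that cluster at one
#' coordinate across many reads mark a candidate chimera breakpoint. The
#' breakpoint is reported as the median clip position of the cluster.
#'
#' @param reads A `read_set` or DNAStringSet (the total data set).
#' @param contigs Contigs to audit (`assembly_state`, DNAStringSet,
#'   `chimera_truth` or character).
#' @param params A [verify_params()].
#' @return Tibble of suspect breakpoint clusters: `contig`, `position`
#'   (1-based), `support`, `local_depth`, `mean_disagreement`, `verdict`
#'   (always `"suspect"`). Zero rows mean every contig is clean. The number
#'   of anchored reads is attached as attribute `n_anchored`.
#' @export
remap_low_stringency <- function(reads, contigs, params = verify_params()) {
  pool <- .read_pool(reads)
  if (!length(pool)) stop("empty read set")
  cset <- .contig_char_set(contigs)
  sc <- cpp_anchor_scan(unname(pool), unname(cset), params$kmer_size)
  sc <- as_tibble(sc)
  sc$anchor_len <- sc$anchor_end - sc$anchor_start
  sc <- sc[sc$anchor_len >= params$low_min_overlap_nt, , drop = FALSE]
  rl <- nchar(pool)[sc$read]
  off_mm <- sc$mm_left + sc$mm_right
  sc <- sc[off_mm <= params$max_offoverlap_mismatch_fraction * rl, , drop = FALSE]

  flags <- list()
  for (ci in sort(unique(sc$contig))) {
    s <- sc[sc$contig == ci, , drop = FALSE]
    fl <- ifelse(s$len_left > 0, s$mm_left / pmax(1, s$len_left), 0)
    fr <- ifelse(s$len_right > 0, s$mm_right / pmax(1, s$len_right), 0)
    # a clip needs a substantial disagreeing side (>= 10 informative nt)
    # and a confidently placed read (long anchor)
    conf <- s$anchor_len >= params$min_clip_anchor_nt
    clip_l <- conf & fl >= params$min_clip_disagreement & s$len_left >= 10 &
      s$mm_left >= params$min_clip_mismatches
    clip_r <- conf & fr >= params$min_clip_disagreement & s$len_right >= 10 &
      s$mm_right >= params$min_clip_mismatches
    clips <- tibble(
      pos = c(s$anchor_start[clip_l], s$anchor_end[clip_r]),  # 0-based
      dis = c(fl[clip_l], fr[clip_r]))
    if (!nrow(clips)) next
    clips <- clips[order(clips$pos), , drop = FALSE]
    gap <- c(TRUE, diff(clips$pos) > params$cluster_radius_nt)
    clips$cluster <- cumsum(gap)
    for (k in unique(clips$cluster)) {
      cl <- clips[clips$cluster == k, , drop = FALSE]
      pos <- as.integer(round(median(cl$pos)))
      depth <- sum(s$anchor_start <= pos & s$anchor_end >= pos)
      need <- max(params$min_support,
                  ceiling(params$support_fraction * depth))
      if (nrow(cl) >= need)
        flags[[length(flags) + 1]] <- tibble(
          contig = names(cset)[ci], position = pos + 1L,
          support = nrow(cl), local_depth = depth,
          mean_disagreement = mean(cl$dis), verdict = "suspect")
    }
  }
  out <- if (length(flags)) dplyr::bind_rows(flags) else
    tibble(contig = character(0), position = integer(0), support = integer(0),
           local_depth = integer(0), mean_disagreement = numeric(0),
           verdict = character(0))
  attr(out, "n_anchored") <- nrow(sc)
  out
}

#' Sliding-window identity scan between two contigs
#'
#' Globally aligns two sequences, then reports gapless identity in sliding
#' windows (step = window / 2) over the alignment; windows at or above the
#' flag threshold are hybrid-risk regions where reads cannot distinguish the
#' two sequences. Gap columns count as mismatches.
#'
#' @param contig_a,contig_b Sequences (character or DNAString).
#' @param params A [verify_params()].
#' @return Tibble of class `identity_window_report`: `start_a`, `end_a`,
#'   `start_b`, `end_b` (1-based in each input), `identity`, `flagged`.
#' @export
scan_identity_windows <- function(contig_a, contig_b,
                                  params = verify_params()) {
  a <- .as_char_seq(contig_a); b <- .as_char_seq(contig_b)
  w <- params$identity_window_nt
  if (nchar(a) < w || nchar(b) < w)
    stop("both sequences must be at least one window (", w, " nt) long")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                       Biostrings::DNAString(b),
                                       substitutionMatrix = mat,
                                       gapOpening = 4, gapExtension = 1,
                                       type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  match <- pa == pb & pa != "-"
  pos_a <- cumsum(pa != "-")
  pos_b <- cumsum(pb != "-")
  n <- length(pa)
  starts <- seq(1L, max(1L, n - w + 1L), by = max(1L, w %/% 2L))
  out <- tibble(
    start_a = pos_a[starts] + (pa[starts] == "-"),
    end_a = pos_a[pmin(n, starts + w - 1L)],
    start_b = pos_b[starts] + (pb[starts] == "-"),
    end_b = pos_b[pmin(n, starts + w - 1L)],
    identity = vapply(starts, function(s)
      mean(match[s:min(n, s + w - 1L)]), 0))
  out$flagged <- out$identity >= params$identity_flag_threshold
  class(out) <- c("identity_window_report", class(out))
  out
}

#' Check that flagged windows are spanned by read pairs
#'
#' For every flagged (repetitive / highly identical) window, counts read
#' pairs whose two mates sit wholly in unique sequence on opposite sides of
#' the window on the same contig with a consistent implied fragment length
#' (mean +/- 4 sd). Such pairs demonstrate that the window's placement is
#' supported across the repeat, not an artifact of merging indistinguishable
#' regions.
#'
#' @param placements Read placement tibble (`read_id`, `contig`, `offset`
#'   0-based, `strand`), e.g. `state$placements` from [assemble()].
#' @param reads The read set (for read lengths).
#' @param windows Tibble of flagged windows with `contig`, `start`, `end`
#'   (1-based inclusive); e.g. the flagged rows of a
#'   [scan_identity_windows()] report mapped onto one contig.
#' @param fragment_mean,fragment_sd Fragment-length model; estimated from
#'   the placements (median / mad of implied fragment lengths) when `NULL`.
#' @param params A [verify_params()].
#' @return Tibble `contig`, `start`, `end`, `spanning_pairs`, `pass`; zero
#'   rows when `windows` is empty.
#' @export
check_pair_spanning <- function(placements, reads, windows,
                                fragment_mean = NULL, fragment_sd = NULL,
                                params = verify_params()) {
  if (inherits(placements, "assembly_state")) placements <- placements$placements
  if (is.null(windows) || !nrow(windows))
    return(tibble(contig = character(0), start = integer(0), end = integer(0),
                  spanning_pairs = integer(0), pass = logical(0)))
  pool <- .read_pool(reads)
  pl <- placements
  pl$len <- nchar(pool[pl$read_id])
  pl$start <- pl$offset + 1L
  pl$end <- pl$offset + pl$len
  pl$pair <- sub("/[12]$", "", pl$read_id)
  pl$mate <- sub("^.*/", "", pl$read_id)

  both <- pl %>%
    group_by(.data$pair, .data$contig) %>%
    filter(n() == 2) %>%
    ungroup()
  if (nrow(both)) {
    sp <- split(both, paste(both$pair, both$contig))
    frag <- vapply(sp, function(h) max(h$end) - min(h$start) + 1L, 0L)
  } else frag <- integer(0)
  if (is.null(fragment_mean))
    fragment_mean <- if (length(frag)) median(frag) else NA_real_
  if (is.null(fragment_sd)) {
    fragment_sd <- if (length(frag)) mad(frag) else NA_real_
    if (!is.na(fragment_sd) && fragment_sd == 0) fragment_sd <- 1
  }

  out <- lapply(seq_len(nrow(windows)), function(i) {
    wct <- windows$contig[i]; ws <- windows$start[i]; we <- windows$end[i]
    wothers <- windows[windows$contig == wct, , drop = FALSE]
    unique_pos <- function(s, e) {
      # mate wholly outside every flagged window on this contig
      !any(s <= wothers$end & e >= wothers$start)
    }
    cand <- both[both$contig == wct, , drop = FALSE]
    count <- 0L
    if (nrow(cand)) {
      for (h in split(cand, cand$pair)) {
        if (nrow(h) != 2) next
        left <- h[which.min(h$start), ]; right <- h[which.max(h$start), ]
        if (left$end >= ws || right$start <= we) next
        if (!unique_pos(left$start, left$end)) next
        if (!unique_pos(right$start, right$end)) next
        implied <- right$end - left$start + 1L
        if (!is.na(fragment_mean) &&
            abs(implied - fragment_mean) > 4 * max(fragment_sd, 1)) next
        count <- count + 1L
      }
    }
    tibble(contig = wct, start = as.integer(ws), end = as.integer(we),
           spanning_pairs = count, pass = count >= params$min_spanning_pairs)
  })
  dplyr::bind_rows(out)
}
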