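# Iterative reference-guided, paralog-separating mapping assembly.

#' Mapping stringency parameters
#'
#' The acceptance rules of the iterative mapping assembler. The defaults are
#' the stringency settings used for muricid hemocyanin assembly: a
#' 70% nucleotide-identity heterologous seed mapping, then high-stringency
#' iterative extension requiring at least 60 overlapping nucleotides, 99%
#' overlap identity, and at most 1% mismatches of the overlap length. The
#' identity and mismatch caps are evaluated independently; at short overlaps
#' the floored mismatch count is the stricter of the two.
#'
#' @param min_overlap_nt Minimum read-contig overlap (nt) for acceptance.
#' @param min_overlap_identity Minimum identity over the overlap.
#' @param max_mismatch_fraction Mismatch cap as a fraction of overlap length;
#'   applied as `mismatches <= floor(fraction * overlap)`.
#' @param seed_identity Identity threshold for the initial heterologous
#'   reference mapping.
#' @param kmer_size Exact k-mer seed length for candidate placements.
#' @param min_extension_coverage Minimum reads supporting a base beyond a
#'   contig end for the consensus to extend over it.
#' @param min_extension_agreement Minimum agreement fraction at extended bases.
#' @param new_contig_max_identity A read whose best identity against all
#'   existing contigs is at or below this founds a new contig (it is evidence
#'   of a distinct paralog); reads between this and the acceptance threshold
#'   are deferred to later iterations.
#' @param merge_min_overlap_nt Minimum end overlap for merging two contig
#'   consensi. Contig ends are consensus sequences, not single reads, so a
#'   shorter overlap than the read-acceptance minimum is allowed; every
#'   merge must additionally be supported by reads spanning the junction
#'   (at least `min_extension_coverage` unambiguous reads covering 20 nt on
#'   both sides of the junction at the strict acceptance identity), which
#'   rejects coincidental identity between paralog contig tips.
#' @param seed_group_join_identity Identity for joining a seed-stage read
#'   group. Early group consensi are supported by one or two error-carrying
#'   reads, so joining uses this error-tolerant threshold (still far above
#'   between-paralog identity); all later recruitment against mature
#'   consensi uses the strict `min_overlap_identity`.
#' @return An object of class `mapping_params`.
#' @export
mapping_params <- function(min_overlap_nt = 60, min_overlap_identity = 0.99,
                           max_mismatch_fraction = 0.01, seed_identity = 0.70,
                           kmer_size = 13, min_extension_coverage = 3,
                           min_extension_agreement = 0.8,
                           new_contig_max_identity = 0.90,
                           merge_min_overlap_nt = 20,
                           seed_group_join_identity = 0.96) {
  stopifnot(min_overlap_identity > 0, min_overlap_identity <= 1,
            min_overlap_nt >= kmer_size, kmer_size >= 4, kmer_size <= 15,
            max_mismatch_fraction >= 0, seed_identity > 0, seed_identity <= 1,
            min_extension_coverage >= 1,
            min_extension_agreement > 0.5, min_extension_agreement <= 1,
            seed_group_join_identity > new_contig_max_identity,
            seed_group_join_identity <= 1)
  structure(list(min_overlap_nt = as.integer(min_overlap_nt),
                 min_overlap_identity = min_overlap_identity,
                 max_mismatch_fraction = max_mismatch_fraction,
                 seed_identity = seed_identity,
                 kmer_size = as.integer(kmer_size),
                 min_extension_coverage = as.integer(min_extension_coverage),
                 min_extension_agreement = min_extension_agreement,
                 new_contig_max_identity = new_contig_max_identity,
                 merge_min_overlap_nt = as.integer(merge_min_overlap_nt),
                 seed_group_join_identity = seed_group_join_identity),
            class = "mapping_params")
}

.as_char_seq <- function(x) {
  if (is.character(x)) x else as.character(x)
}

#' Evaluate one candidate read placement under the acceptance rule
#'
#' Ungapped comparison of a read placed at a fixed contig offset. The hit is
#' accepted iff the overlap is at least `min_overlap_nt`, identity over the
#' overlap is at least `min_overlap_identity`, and the mismatch count is at
#' most `floor(max_mismatch_fraction * overlap)`. Overhang beyond either
#' contig end is allowed and not scored. Ambiguous bases count as mismatches.
#'
#' @param read Read sequence (character or DNAString), already oriented.
#' @param contig Contig consensus sequence.
#' @param offset 0-based contig position of the first read base (may be
#'   negative for left overhang).
#' @param params A [mapping_params()].
#' @return A list of class `read_hit`: `accepted`, `overlap`, `mismatches`,
#'   `identity`, `left_overhang`, `right_overhang`, `offset`. Rejection is a
#'   value (`accepted = FALSE`), not an error.
#' @examples
#' p <- mapping_params()
#' accept_hit(strrep("A", 150), strrep("A", 200), 10, p)$accepted
#' @export
accept_hit <- function(read, contig, offset, params = mapping_params()) {
  read <- .as_char_seq(read); contig <- .as_char_seq(contig)
  v <- cpp_overlap_mm(read, contig, as.integer(offset))
  overlap <- v[["overlap"]]; mm <- v[["mismatches"]]
  identity <- if (overlap > 0) 1 - mm / overlap else NA_real_
  accepted <- overlap >= params$min_overlap_nt &&
    !is.na(identity) && identity >= params$min_overlap_identity &&
    mm <= floor(params$max_mismatch_fraction * overlap)
  structure(list(accepted = accepted, overlap = overlap, mismatches = mm,
                 identity = identity,
                 left_overhang = max(0L, -as.integer(offset)),
                 right_overhang = max(0L, as.integer(offset) + nchar(read) -
                                        nchar(contig)),
                 offset = as.integer(offset)),
            class = "read_hit")
}

#' Brute-force all-offset placement oracle
#'
#' Evaluates the ungapped overlap and mismatch count of a read at every
#' possible offset on a contig (both strands), independently of the k-mer
#' seeded mapper. Intended as a slow reference implementation for validating
#' [accept_hit()] and the mapper's placements on small inputs.
#'
#' @param read,contig Sequences.
#' @param params A [mapping_params()]; acceptance evaluated per offset.
#' @return Tibble with `strand`, `offset`, `overlap`, `mismatches`,
#'   `identity`, `accepted` for every offset.
#' @export
brute_force_hits <- function(read, contig, params = mapping_params()) {
  read <- .as_char_seq(read); contig <- .as_char_seq(contig)
  ci <- utf8ToInt(contig)
  one_strand <- function(r, strand) {
    ri <- utf8ToInt(r)
    rl <- length(ri); cl <- length(ci)
    offs <- (-(rl - 1)):(cl - 1)
    res <- lapply(offs, function(off) {
      rs <- max(1L, 1L - off); re <- min(rl, cl - off)
      if (re < rs) return(c(0L, 0L))
      idx <- rs:re
      c(length(idx), sum(ri[idx] != ci[idx + off]))
    })
    m <- do.call(rbind, res)
    tibble(strand = strand, offset = offs, overlap = m[, 1], mismatches = m[, 2])
  }
  out <- dplyr::bind_rows(
    one_strand(read, "+"),
    one_strand(.revcomp_chr(read), "-"))
  out$identity <- ifelse(out$overlap > 0, 1 - out$mismatches / out$overlap, NA)
  out$accepted <- out$overlap >= params$min_overlap_nt &
    !is.na(out$identity) & out$identity >= params$min_overlap_identity &
    out$mismatches <= floor(params$max_mismatch_fraction * out$overlap)
  out
}

# named character vector of all oriented input reads
.read_pool <- function(reads) {
  x <- if (inherits(reads, "read_set")) all_reads(reads) else reads
  setNames(as.character(x), names(x))
}

# majority consensus from a 5 x L count matrix; ties resolved to the
# lexicographically smallest base and flagged low-confidence
.consensus_from_counts <- function(counts) {
  acgt <- counts[1:4, , drop = FALSE]
  cov <- colSums(counts)
  maxc <- apply(acgt, 2, max)
  maj <- apply(acgt, 2, which.max)          # first max = lexicographic smallest
  ties <- colSums(acgt == rep(maxc, each = 4)) > 1 & maxc > 0
  seq <- c("A", "C", "G", "T")[maj]
  seq[cov == 0] <- "N"
  list(seq = seq, coverage = as.integer(cov),
       agreement = ifelse(cov > 0, maxc / cov, 0), low_conf = ties)
}

#' Seed a paralog-separated assembly from a heterologous reference
#'
#' Maps reads to the reference at the permissive seed identity (default 70%),
#' then builds initial contigs from the accepted reads themselves, not from
#' the reference bases: reads are processed in decreasing order of reference
#' identity and greedily grouped, joining a group only when they match its
#' current majority consensus under the high-stringency acceptance rule.
#' A read whose best group identity is at or below
#' `new_contig_max_identity` founds a new group — this is what separates the
#' paralogs from the first iteration on. Groups are cut into contigs at
#' uncovered reference columns.
#'
#' @param reads A [simulate_reads()] result or named DNAStringSet.
#' @param reference Reference CDS (DNAString/character/length-1 DNAStringSet).
#' @param params A [mapping_params()].
#' @return An object of class `assembly_state`; see [extend_iterate()].
#' @export
seed_map <- function(reads, reference, params = mapping_params()) {
  pool <- .read_pool(reads)
  if (!length(pool)) stop("empty read set")
  if (is(reference, "DNAStringSet")) reference <- reference[[1]]
  ref <- .as_char_seq(reference)
  if (nchar(ref) < params$kmer_size) stop("reference shorter than kmer_size")

  hits <- cpp_best_hits(unname(pool), ref, params$kmer_size,
                        params$min_overlap_nt, params$seed_identity)
  hits$identity <- ifelse(hits$overlap > 0, 1 - hits$mismatches / hits$overlap, 0)
  keep <- hits$qualified == 1
  hits <- hits[keep, , drop = FALSE]
  if (!nrow(hits)) stop("no reads mapped to the reference at the seed identity")

  rid <- names(pool)[hits$read]
  oriented <- ifelse(hits$strand == 1, unname(pool[hits$read]),
                     .revcomp_chr(unname(pool[hits$read])))
  ord <- order(-hits$identity, rid)
  grp <- cpp_seed_groups(oriented, hits$offset, order = ord,
                         ref_len = nchar(ref),
                         min_overlap = params$min_overlap_nt,
                         min_identity = params$seed_group_join_identity,
                         max_mismatch_fraction = 1,
                         founder_max_identity = params$new_contig_max_identity)

  placed <- tibble(read_id = rid, seq = oriented, offset = hits$offset,
                   strand = ifelse(hits$strand == 1, "+", "-"),
                   group = grp$group, ambiguous = grp$ambiguous == 1)
  placed$contrib <- grp$contrib
  placed <- placed[placed$group > 0, , drop = FALSE]

  # build contigs: one per contiguous covered segment per group
  contigs <- list(); placements <- list(); next_id <- 1L
  for (g in sort(unique(unlist(placed$contrib)))) {
    member <- vapply(placed$contrib, function(v) g %in% v, TRUE)
    sub <- placed[member, , drop = FALSE]
    lo <- min(sub$offset); hi <- max(sub$offset + nchar(sub$seq))
    counts <- cpp_pileup(sub$seq, sub$offset - lo, hi - lo)
    cons <- .consensus_from_counts(counts)
    covered <- cons$coverage > 0
    runs <- rle(covered)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
    for (ri in which(runs$values)) {
      s <- starts[ri]; e <- ends[ri]
      if (e - s + 1L < params$min_overlap_nt) next
      cid <- sprintf("contig%03d", next_id); next_id <- next_id + 1L
      contigs[[cid]] <- list(
        id = cid,
        consensus = paste(cons$seq[s:e], collapse = ""),
        coverage = cons$coverage[s:e],
        low_conf = cons$low_conf[s:e])
      inside <- sub$offset + nchar(sub$seq) > lo + s - 1L &
        sub$offset < lo + e
      pl <- sub[inside & sub$group == g, , drop = FALSE]
      if (nrow(pl))
        placements[[cid]] <- tibble(
          read_id = pl$read_id, contig = cid,
          offset = pl$offset - (lo + s - 1L),
          strand = pl$strand, ambiguous = pl$ambiguous)
    }
  }
  if (!length(contigs)) stop("seed mapping produced no contigs")
  placements <- dplyr::bind_rows(placements)
  state <- structure(list(contigs = contigs,
                          placements = placements,
                          recruited = unique(placements$read_id),
                          iteration = 0L, converged = FALSE,
                          params = params),
                     class = "assembly_state")
  # coalesce overlapping contigs of the same paralog right away (greedy
  # grouping can seed several overlapping fragments per gene)
  opool <- list(fwd = pool, rev = setNames(.revcomp_chr(unname(pool)),
                                           names(pool)))
  merged <- .merge_contigs(state, opool, params)
  state <- .refresh_ambiguity(merged$state)
  state$history <- tibble(
    iteration = 0L, n_contigs = length(state$contigs),
    n_recruited = length(state$recruited),
    total_length = sum(vapply(state$contigs, function(cc)
      nchar(cc$consensus), 0)))
  state
}

# collapse duplicate placements and recompute per-read ambiguity from the
# current contig memberships
.refresh_ambiguity <- function(state) {
  state$placements <- dplyr::distinct(
    state$placements, .data$read_id, .data$contig, .data$offset,
    .data$strand, .keep_all = TRUE)
  ncontig <- stats::ave(as.integer(factor(state$placements$contig)),
                        state$placements$read_id,
                        FUN = function(x) length(unique(x)))
  state$placements$ambiguous <- ncontig > 1
  state
}

#' @export
print.assembly_state <- function(x, ...) {
  cat("<assembly_state> ", length(x$contigs), " contigs, ",
      length(x$recruited), " reads recruited, iteration ", x$iteration,
      if (x$converged) " (converged)" else " (not converged)", "\n", sep = "")
  for (cc in x$contigs)
    cat("  ", cc$id, ": ", nchar(cc$consensus), " nt, mean coverage ",
        round(mean(cc$coverage), 1), "\n", sep = "")
  invisible(x)
}

# recompute one contig's consensus from its placements; extend ends using
# unambiguous reads only, requiring min coverage and agreement per new base.
# `pool` is an oriented-read lookup: list(fwd = named chr, rev = named chr).
.rebuild_contig <- function(cc, pl, pool, params) {
  seqs <- ifelse(pl$strand == "+", unname(pool$fwd[pl$read_id]),
                 unname(pool$rev[pl$read_id]))
  len <- nchar(cc$consensus)
  lo <- min(0L, min(pl$offset))
  hi <- max(len, max(pl$offset + nchar(seqs)))
  counts_all <- cpp_pileup(seqs, pl$offset - lo, hi - lo)
  unamb <- !pl$ambiguous
  counts_ext <- if (all(unamb)) counts_all else
    cpp_pileup(seqs[unamb], pl$offset[unamb] - lo, hi - lo)
  cons_all <- .consensus_from_counts(counts_all)
  cons_ext <- .consensus_from_counts(counts_ext)

  core <- (1L - lo):(len - lo)        # columns of the previous consensus
  ok_ext <- cons_ext$coverage >= params$min_extension_coverage &
    cons_ext$agreement >= params$min_extension_agreement &
    !cons_ext$low_conf
  # walk outward from the old ends
  left_cols <- integer(0)
  p <- core[1] - 1L
  while (p >= 1L && ok_ext[p]) { left_cols <- c(p, left_cols); p <- p - 1L }
  right_cols <- integer(0)
  p <- core[length(core)] + 1L
  while (p <= hi - lo && ok_ext[p]) { right_cols <- c(right_cols, p); p <- p + 1L }

  keep <- c(left_cols, core, right_cols)
  new_seq <- character(length(keep))
  new_cov <- integer(length(keep))
  new_low <- logical(length(keep))
  is_core <- keep %in% core
  new_seq[is_core] <- cons_all$seq[keep[is_core]]
  new_cov[is_core] <- cons_all$coverage[keep[is_core]]
  new_low[is_core] <- cons_all$low_conf[keep[is_core]]
  new_seq[!is_core] <- cons_ext$seq[keep[!is_core]]
  new_cov[!is_core] <- cons_all$coverage[keep[!is_core]]
  new_low[!is_core] <- cons_ext$low_conf[keep[!is_core]]
  # uncovered interior columns cannot occur: contigs are built over covered
  # segments and coverage never decreases
  shift <- (keep[1] + lo) - 1L   # 0-based coord of new first column
  list(contig = list(id = cc$id,
                     consensus = paste(new_seq, collapse = ""),
                     coverage = new_cov, low_conf = new_low),
       offset_shift = -shift)
}

#' Iteratively extend and merge contigs until convergence
#'
#' One iteration recruits unplaced reads against the current consensi under
#' the high-stringency acceptance rule (best contig by mismatch count; ties
#' are flagged ambiguous and add coverage to all tied contigs but never
#' extend any), rebuilds each consensus by majority vote, extends contig ends
#' over overhang columns passing the extension coverage/agreement gates, and
#' merges contigs whose consensi overlap under the same acceptance rule.
#' Iteration stops when no contig grew, no read was recruited and no merge
#' happened, or at `max_iter` (with a warning and `converged = FALSE`).
#'
#' @param state An [seed_map()] result.
#' @param reads The full read set (same object passed to [seed_map()]).
#' @param params A [mapping_params()].
#' @param max_iter Iteration cap.
#' @return The updated `assembly_state`.
#' @export
extend_iterate <- function(state, reads, params = state$params, max_iter = 40) {
  pool <- .read_pool(reads)
  rids <- names(pool)
  opool <- list(fwd = pool, rev = setNames(.revcomp_chr(unname(pool)), rids))
  for (it in seq_len(max_iter)) {
    state$iteration <- state$iteration + 1L
    changed <- FALSE

    # --- recruit unplaced reads against current consensi ---
    # Placements are sticky: once recruited, a read contributes to its
    # contig(s) for good (recruited set and contig lengths are monotone).
    # Ties at recruitment put the read on every tied contig, flagged
    # ambiguous; flags are refreshed structurally after merges.
    un <- setdiff(rids, state$recruited)
    consensi <- vapply(state$contigs, function(cc) cc$consensus, "")
    if (length(un)) {
      hits <- cpp_best_hits(unname(pool[un]), consensi, params$kmer_size,
                            params$min_overlap_nt, params$min_overlap_identity)
      if (nrow(hits)) {
        cap <- floor(params$max_mismatch_fraction * hits$overlap)
        hits$ok <- hits$qualified == 1 & hits$mismatches <= cap
        acc <- hits[hits$ok, , drop = FALSE]
        if (nrow(acc)) {
          acc$read_id <- un[acc$read]
          # best placement per read: most matching bases, then fewest
          # mismatches; remaining ties are ambiguous
          acc$matches <- acc$overlap - acc$mismatches
          best_m <- stats::ave(acc$matches, acc$read_id, FUN = max)
          acc <- acc[acc$matches == best_m, , drop = FALSE]
          best_mm <- stats::ave(acc$mismatches, acc$read_id, FUN = min)
          acc <- acc[acc$mismatches == best_mm, , drop = FALSE]
          n_tied <- stats::ave(acc$mismatches, acc$read_id, FUN = length)
          new_pl <- tibble(read_id = acc$read_id,
                           contig = names(consensi)[acc$contig],
                           offset = acc$offset,
                           strand = ifelse(acc$strand == 1, "+", "-"),
                           ambiguous = n_tied > 1)
          state$placements <- dplyr::bind_rows(state$placements, new_pl)
          state$recruited <- c(state$recruited, unique(new_pl$read_id))
          changed <- TRUE
        }
      }
    }

    # --- rebuild + extend ---
    for (cid in names(state$contigs)) {
      pl <- state$placements[state$placements$contig == cid, , drop = FALSE]
      if (!nrow(pl)) next
      old_len <- nchar(state$contigs[[cid]]$consensus)
      rb <- .rebuild_contig(state$contigs[[cid]], pl, opool, params)
      state$contigs[[cid]] <- rb$contig
      if (rb$offset_shift != 0) {
        sel <- state$placements$contig == cid
        state$placements$offset[sel] <- state$placements$offset[sel] +
          rb$offset_shift
      }
      if (nchar(rb$contig$consensus) > old_len) changed <- TRUE
    }

    # --- merge overlapping contigs ---
    merged <- .merge_contigs(state, opool, params)
    if (merged$changed) {
      # refresh ambiguity: a read is ambiguous iff it still sits on more
      # than one contig after merging
      state <- .refresh_ambiguity(merged$state)
      changed <- TRUE
    }

    state$history <- dplyr::bind_rows(state$history, tibble(
      iteration = state$iteration, n_contigs = length(state$contigs),
      n_recruited = length(state$recruited),
      total_length = sum(vapply(state$contigs, function(cc)
        nchar(cc$consensus), 0))))

    if (!changed) { state$converged <- TRUE; break }
  }
  if (!state$converged)
    warning("assembly did not converge within ", max_iter, " iterations")
  state
}

# Merge contigs whose consensi overlap end-to-end. Candidate overlaps are
# detected at the consensus-level join identity down to merge_min_overlap_nt;
# a trial merge is kept only when unambiguous reads span the junction (>= 20
# nt each side) at the strict acceptance identity against the rebuilt
# consensus, otherwise it is reverted. Read spanning is what distinguishes a
# true within-gene junction from coincidentally identical paralog tips.
.merge_contigs <- function(state, pool, params) {
  changed <- FALSE
  repeat {
    ids <- names(state$contigs)
    if (length(ids) < 2) break
    # batch candidate detection: every contig against every other in one call
    consensi <- vapply(state$contigs, function(cc) cc$consensus, "")
    hh <- cpp_best_hits(unname(consensi), unname(consensi), params$kmer_size,
                        params$merge_min_overlap_nt,
                        params$seed_group_join_identity)
    hh <- hh[hh$read != hh$contig & hh$qualified == 1, , drop = FALSE]
    if (!nrow(hh)) break
    hh$b_id <- ids[hh$read]; hh$a_id <- ids[hh$contig]
    # merge shorter into longer, largest overlaps first
    hh <- hh[nchar(consensi[hh$b_id]) <= nchar(consensi[hh$a_id]), , drop = FALSE]
    hh <- hh[order(-hh$overlap, hh$a_id, hh$b_id), , drop = FALSE]
    did <- FALSE
    for (ri in seq_len(nrow(hh))) {
      a <- hh$a_id[ri]; b <- hh$b_id[ri]
      if (!(a %in% names(state$contigs)) || !(b %in% names(state$contigs))) next
      {
        ca <- state$contigs[[a]]$consensus
        cb <- state$contigs[[b]]$consensus
        h <- hh[ri, ]
        snapshot <- state
        # rebase b's placements onto a
        sel <- state$placements$contig == b
        if (h$strand == 1) {
          state$placements$offset[sel] <- state$placements$offset[sel] + h$offset
        } else {
          rl <- nchar(unname(pool$fwd[state$placements$read_id[sel]]))
          state$placements$offset[sel] <- h$offset +
            (nchar(cb) - (state$placements$offset[sel] + rl))
          state$placements$strand[sel] <-
            ifelse(state$placements$strand[sel] == "+", "-", "+")
        }
        state$placements$contig[sel] <- a
        state$contigs[[b]] <- NULL
        pl <- state$placements[state$placements$contig == a, , drop = FALSE]
        rb <- .rebuild_contig(state$contigs[[a]], pl, pool, params)
        state$contigs[[a]] <- rb$contig
        if (rb$offset_shift != 0) {
          sel <- state$placements$contig == a
          state$placements$offset[sel] <- state$placements$offset[sel] +
            rb$offset_shift
        }
        # junction validation by read spanning
        ov_start <- max(0L, h$offset) + rb$offset_shift
        ov_end <- min(nchar(ca), h$offset + nchar(cb)) + rb$offset_shift
        jc <- as.integer((ov_start + ov_end) / 2)
        pl <- state$placements[state$placements$contig == a &
                                 !state$placements$ambiguous, , drop = FALSE]
        merged_seq <- state$contigs[[a]]$consensus
        span <- 0L
        if (nrow(pl)) {
          rlen <- nchar(pool$fwd[pl$read_id])
          cand <- which(pl$offset <= jc - 20L & pl$offset + rlen >= jc + 20L)
          for (ii in cand) {
            sq <- if (pl$strand[ii] == "+") pool$fwd[[pl$read_id[ii]]] else
              pool$rev[[pl$read_id[ii]]]
            v <- cpp_overlap_mm(sq, merged_seq, pl$offset[ii])
            if (v[["overlap"]] >= params$min_overlap_nt &&
                1 - v[["mismatches"]] / v[["overlap"]] >=
                  params$min_overlap_identity) {
              span <- span + 1L
              if (span >= params$min_extension_coverage) break
            }
          }
        }
        if (span < params$min_extension_coverage) {
          state <- snapshot
          next
        }
        did <- TRUE; changed <- TRUE
        break
      }
    }
    if (!did) break
  }
  list(state = state, changed = changed)
}

#' Classify one read against a set of contigs
#'
#' Best-hit paralog assignment: the read contributes only to the contig(s)
#' with the fewest mismatches at its best placement. Ties are flagged
#' ambiguous (such reads count toward coverage of every tied contig but are
#' excluded from end extension).
#'
#' @param read Read sequence.
#' @param contigs Named character vector / DNAStringSet of contig consensi.
#' @param params A [mapping_params()].
#' @return Tibble of the tied best contigs with `contig`, `offset`, `strand`,
#'   `overlap`, `mismatches`, `identity`, `accepted`, `ambiguous`; zero rows
#'   when the read has no seeded placement.
#' @export
assign_paralog <- function(read, contigs, params = mapping_params()) {
  if (is(contigs, "DNAStringSet")) contigs <- setNames(as.character(contigs),
                                                       names(contigs))
  stopifnot(length(contigs) >= 1)
  h <- cpp_best_hits(.as_char_seq(read), unname(contigs), params$kmer_size,
                     params$min_overlap_nt, params$min_overlap_identity)
  if (!nrow(h)) return(tibble(contig = character(0), offset = integer(0),
                              strand = character(0), overlap = integer(0),
                              mismatches = integer(0), identity = numeric(0),
                              accepted = logical(0), ambiguous = logical(0)))
  h$identity <- ifelse(h$overlap > 0, 1 - h$mismatches / h$overlap, 0)
  h$matches <- h$overlap - h$mismatches
  h <- h[h$matches == max(h$matches), , drop = FALSE]
  h <- h[h$mismatches == min(h$mismatches), , drop = FALSE]
  tibble(contig = names(contigs)[h$contig], offset = h$offset,
         strand = ifelse(h$strand == 1, "+", "-"), overlap = h$overlap,
         mismatches = h$mismatches, identity = h$identity,
         accepted = h$overlap >= params$min_overlap_nt &
           h$identity >= params$min_overlap_identity &
           h$mismatches <= floor(params$max_mismatch_fraction * h$overlap),
         ambiguous = nrow(h) > 1)
}

#' Run the full iterative assembly
#'
#' Convenience wrapper: [seed_map()] then [extend_iterate()].
#'
#' @inheritParams seed_map
#' @inheritParams extend_iterate
#' @return An `assembly_state`.
#' @export
assemble <- function(reads, reference, params = mapping_params(),
                     max_iter = 40) {
  state <- seed_map(reads, reference, params)
  extend_iterate(state, reads, params, max_iter = max_iter)
}

#' Extract assembled consensus sequences
#'
#' @param state An `assembly_state`.
#' @param min_length Drop contigs shorter than this.
#' @param min_mean_coverage Drop contigs with lower mean read depth.
#' @return A [Biostrings::DNAStringSet], longest first.
#' @export
assembled_contigs <- function(state, min_length = 300, min_mean_coverage = 3) {
  stopifnot(inherits(state, "assembly_state"))
  keep <- vapply(state$contigs, function(cc)
    nchar(cc$consensus) >= min_length && mean(cc$coverage) >= min_mean_coverage,
    TRUE)
  seqs <- vapply(state$contigs[keep], function(cc) cc$consensus, "")
  out <- Biostrings::DNAStringSet(seqs)
  out[order(-Biostrings::width(out))]
}

#' Score an assembly against the generating truth
#'
#' Tiles each contig, places every tile on each true CDS by ungapped best
#' hit, and reports per-contig identity to its majority gene plus a chimera
#' verdict: a contig is chimeric when any tile is confidently placed
#' (identity at least 0.9, margin at least 0.05) on a different gene than
#' the contig's majority gene. Whole-contig identity is computed from a
#' global alignment and normalized by the longer of contig and gene, so
#' missing ends count as errors.
#'
#' @param contigs DNAStringSet (e.g. [assembled_contigs()]).
#' @param truth A `truth_set`.
#' @param genes Which truth genes to score against (default all).
#' @param tile_nt Tile length.
#' @return Tibble with `contig`, `gene`, `identity`, `chimeric`, `n_tiles`.
#' @export
score_assembly <- function(contigs, truth, genes = NULL, tile_nt = 500) {
  stopifnot(inherits(truth, "truth_set"))
  if (inherits(contigs, "assembly_state")) contigs <- assembled_contigs(contigs)
  gset <- truth$genes
  if (!is.null(genes)) gset <- gset[genes]
  gseq <- setNames(as.character(gset), names(gset))
  out <- lapply(seq_along(contigs), function(i) {
    cseq <- as.character(contigs[[i]])
    cl <- nchar(cseq)
    starts <- seq(1L, max(1L, cl - tile_nt + 1L), by = tile_nt)
    tiles <- substring(cseq, starts, pmin(cl, starts + tile_nt - 1L))
    th <- cpp_best_hits(tiles, unname(gseq), 13L, 100L, 0.9)
    th$identity <- ifelse(th$overlap > 0, 1 - th$mismatches / th$overlap, 0)
    votes <- vapply(split(th, th$read), function(h) {
      names(gseq)[h$contig[which.max(h$identity)]][1]
    }, "")
    best_ident <- vapply(split(th, th$read), function(h) max(h$identity), 0)
    margin <- vapply(split(th, th$read), function(h) {
      s <- sort(h$identity, decreasing = TRUE)
      if (length(s) > 1) s[1] - s[2] else 1
    }, 0)
    maj <- names(sort(table(votes), decreasing = TRUE))[1]
    chim <- any(votes != maj & best_ident >= 0.9 & margin >= 0.05)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(cseq), gset[[maj]], type = "global")
    ident <- Biostrings::nmatch(aln) / max(cl, nchar(gseq[maj]))
    tibble(contig = if (!is.null(names(contigs))) names(contigs)[i] else
             paste0("contig", i),
           gene = maj, identity = ident, chimeric = chim,
           n_tiles = length(tiles))
  })
  dplyr::bind_rows(out)
}

#' Write assembly results to files
#'
#' Writes the consensus sequences as FASTA, the read placements as TSV
#' (1-based start coordinates), and a JSON run report (iterations, recruited
#' reads, convergence, per-contig length and mean coverage).
#'
#' @param state An `assembly_state`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, the paths written.
#' @export
write_assembly <- function(state, dir, prefix = "assembly") {
  stopifnot(inherits(state, "assembly_state"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, paste0(prefix, "_contigs.fasta"))
  tsv <- file.path(dir, paste0(prefix, "_placements.tsv"))
  js <- file.path(dir, paste0(prefix, "_report.json"))
  seqs <- Biostrings::DNAStringSet(vapply(state$contigs,
                                          function(cc) cc$consensus, ""))
  Biostrings::writeXStringSet(seqs, fa)
  pl <- state$placements
  pl$start <- pl$offset + 1L
  utils::write.table(pl[, c("read_id", "contig", "start", "strand",
                            "ambiguous")],
                     tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  report <- list(
    iterations = state$iteration,
    converged = state$converged,
    n_recruited = length(state$recruited),
    contigs = lapply(state$contigs, function(cc)
      list(id = cc$id, length = nchar(cc$consensus),
           mean_coverage = mean(cc$coverage))))
  writeLines(.to_json(report), js)
  invisible(c(fa, tsv, js))
}

# minimal JSON serializer for the run report (scalars, lists, named lists)
.to_json <- function(x) {
  if (is.null(x)) return("null")
  if (is.list(x)) {
    if (!is.null(names(x)) && all(nzchar(names(x)))) {
      paste0("{", paste0('"', names(x), '":',
                         vapply(x, .to_json, ""), collapse = ","), "}")
    } else {
      paste0("[", paste0(vapply(x, .to_json, ""), collapse = ","), "]")
    }
  } else if (is.character(x)) {
    paste0('"', x, '"')
  } else if (is.logical(x)) {
    tolower(as.character(x))
  } else {
    as.character(x)
  }
}
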