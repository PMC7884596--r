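# Distance-based phylogenetics: star alignment, Poisson-corrected protein
# distances, canonical neighbor joining, bootstrap support.

#' Poisson-corrected distance between two proteins
#'
#' Globally aligns the pair (affine gaps, BLOSUM62) and converts the
#' mismatch fraction p over aligned non-gap columns to substitutions/site by
#' the Poisson correction d = -ln(1 - p).
#'
#' @param a,b Protein sequences.
#' @return Distance in substitutions/site.
#' @examples
#' pairwise_distance("MKLV", "MKLV")  # 0
#' @export
pairwise_distance <- function(a, b) {
  al <- .align_aa(if (inherits(a, "protein_record")) a$seq else .as_char_seq(a),
                  if (inherits(b, "protein_record")) b$seq else .as_char_seq(b))
  both <- !is.na(al$qpos) & !is.na(al$spos)
  if (!any(both)) stop("sequences do not align")
  p <- mean(al$a[both] != al$b[both])
  if (p >= 1) stop("saturated distance (p >= 1)")
  -log(1 - p)
}

#' Star multiple alignment to the longest sequence
#'
#' Approximate multiple alignment: every sequence is globally aligned to the
#' longest (center) sequence and the pairwise gap patterns are merged
#' ("once a gap, always a gap"); residues falling in insertions relative to
#' the center are left-aligned within their block.
#'
#' @param proteins Named [Biostrings::AAStringSet] or character vector.
#' @return Character matrix (sequences x alignment columns) with `-` gaps,
#'   class `protein_msa`.
#' @export
star_alignment <- function(proteins) {
  if (is(proteins, "AAStringSet"))
    proteins <- setNames(as.character(proteins), names(proteins))
  stopifnot(is.character(proteins), length(proteins) >= 2,
            !is.null(names(proteins)))
  center <- which.max(nchar(proteins))
  L <- nchar(proteins[center])
  per <- lapply(seq_along(proteins), function(i) {
    if (i == center) {
      list(ins = integer(L + 1),
           res = lapply(0:L, function(k)
             if (k == 0) character(0) else substr(proteins[i], k, k)),
           direct = TRUE)
    } else {
      al <- .align_aa(proteins[i], proteins[center])
      # bucket query residues by the center position they follow
      bucket <- vector("list", L + 1)
      cur <- 0L
      for (cc in seq_along(al$a)) {
        if (!is.na(al$spos[cc])) cur <- al$spos[cc]
        if (!is.na(al$qpos[cc])) {
          ch <- substr(proteins[i], al$qpos[cc], al$qpos[cc])
          key <- cur + 1L
          bucket[[key]] <- c(bucket[[key]], ch)
        }
      }
      # residues aligned ON center position k are the last entry of bucket k;
      # simpler: re-walk to split "on" vs "after"
      on <- character(L); ins <- vector("list", L + 1)
      for (k in seq_len(L + 1)) ins[[k]] <- character(0)
      on[] <- "-"
      cur <- 0L
      for (cc in seq_along(al$a)) {
        sp <- al$spos[cc]; qp <- al$qpos[cc]
        if (!is.na(sp) && !is.na(qp)) {
          on[sp] <- substr(proteins[i], qp, qp); cur <- sp
        } else if (!is.na(sp)) {
          cur <- sp
        } else if (!is.na(qp)) {
          ins[[cur + 1L]] <- c(ins[[cur + 1L]],
                               substr(proteins[i], qp, qp))
        }
      }
      list(on = on, ins = ins, direct = FALSE)
    }
  })
  ins_len <- integer(L + 1)
  for (i in seq_along(per)) {
    if (!isTRUE(per[[i]]$direct)) {
      li <- lengths(per[[i]]$ins)
      ins_len <- pmax(ins_len, li)
    }
  }
  ncol_total <- L + sum(ins_len)
  rows <- matrix("-", nrow = length(proteins), ncol = ncol_total,
                 dimnames = list(names(proteins), NULL))
  for (i in seq_along(per)) {
    col <- 0L
    for (k in 0:L) {
      block <- ins_len[k + 1L]
      if (block > 0) {
        v <- if (isTRUE(per[[i]]$direct)) character(0) else per[[i]]$ins[[k + 1L]]
        if (length(v)) rows[i, col + seq_along(v)] <- v
        col <- col + block
      }
      if (k < L) {
        col <- col + 1L
        rows[i, col] <- if (isTRUE(per[[i]]$direct))
          substr(proteins[i], k + 1L, k + 1L) else per[[i]]$on[k + 1L]
      }
    }
  }
  class(rows) <- c("protein_msa", class(rows))
  rows
}

#' Poisson distance matrix from an alignment or sequences
#'
#' @param x A `protein_msa` matrix (from [star_alignment()]) or a named
#'   AAStringSet/character vector (star-aligned internally).
#' @return Symmetric distance matrix (substitutions/site), zero diagonal.
#' @export
distance_matrix <- function(x) {
  msa <- if (inherits(x, "protein_msa")) x else star_alignment(x)
  n <- nrow(msa)
  D <- matrix(0, n, n, dimnames = list(rownames(msa), rownames(msa)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- msa[i, ] != "-" & msa[j, ] != "-"
      if (!any(both)) stop("no shared columns between ", rownames(msa)[i],
                           " and ", rownames(msa)[j])
      p <- mean(msa[i, both] != msa[j, both])
      if (p >= 1) stop("saturated distance (p >= 1)")
      D[i, j] <- D[j, i] <- -log(1 - p)
    }
  }
  D
}

#' Canonical neighbor joining
#'
#' Saitou-Nei neighbor joining with deterministic behavior: the Q-matrix
#' minimum is taken with ties broken by lexicographic order of the joined
#' taxon-pair labels, and negative branch lengths are clamped to zero with
#' the deficit moved to the sister branch. Returns an unrooted `phylo` tree
#' (trifurcation at the last join).
#'
#' @param D Symmetric distance matrix with zero diagonal and taxon dimnames.
#' @return An [ape::ape-package] `phylo` object.
#' @export
neighbor_joining <- function(D) {
  if (!is.matrix(D) || !isSymmetric(unname(D), tol = 1e-8))
    stop("D must be a symmetric matrix")
  if (any(!is.finite(D)) || any(D < 0)) stop("distances must be finite and >= 0")
  n <- nrow(D)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # node bookkeeping: tips 1..n, internals n+1 .. 2n-2 (root = last)
  node_id <- seq_len(n)
  names(node_id) <- labels
  next_internal <- n + 1L
  edges <- matrix(0L, 0, 2); lens <- numeric(0)
  active <- labels
  Dm <- D
  while (length(active) > 3) {
    m <- length(active)
    r <- rowSums(Dm)
    best <- NULL
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        q <- (m - 2) * Dm[i, j] - r[i] - r[j]
        pair <- sort(c(active[i], active[j]))
        if (is.null(best) || q < best$q - 1e-12 ||
            (abs(q - best$q) <= 1e-12 &&
             (pair[1] < best$pair[1] ||
              (pair[1] == best$pair[1] && pair[2] < best$pair[2])))) {
          best <- list(q = q, i = i, j = j, pair = pair)
        }
      }
    }
    i <- best$i; j <- best$j
    li <- Dm[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- Dm[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0; li <- max(li, 0) }
    u <- next_internal; next_internal <- next_internal + 1L
    ulab <- paste0(".n", u)
    edges <- rbind(edges, c(u, node_id[active[i]]), c(u, node_id[active[j]]))
    lens <- c(lens, li, lj)
    duk <- (Dm[i, -c(i, j), drop = TRUE] + Dm[j, -c(i, j), drop = TRUE] -
              Dm[i, j]) / 2
    duk <- pmax(duk, 0)
    keep <- setdiff(seq_len(m), c(i, j))
    Dnew <- matrix(0, m - 1, m - 1)
    Dnew[seq_len(m - 2), seq_len(m - 2)] <- Dm[keep, keep, drop = FALSE]
    Dnew[m - 1, seq_len(m - 2)] <- duk
    Dnew[seq_len(m - 2), m - 1] <- duk
    newact <- c(active[keep], ulab)
    dimnames(Dnew) <- list(newact, newact)
    node_id[ulab] <- u
    active <- newact
    Dm <- Dnew
    r <- NULL
  }
  # final trifurcation
  a <- active[1]; b <- active[2]; c3 <- active[3]
  la <- (Dm[1, 2] + Dm[1, 3] - Dm[2, 3]) / 2
  lb <- (Dm[1, 2] + Dm[2, 3] - Dm[1, 3]) / 2
  lc <- (Dm[1, 3] + Dm[2, 3] - Dm[1, 2]) / 2
  root <- next_internal
  edges <- rbind(edges, c(root, node_id[a]), c(root, node_id[b]),
                 c(root, node_id[c3]))
  lens <- c(lens, max(la, 0), max(lb, 0), max(lc, 0))
  # renumber internals so the root is n+1 (ape convention: root first)
  n_int <- root - n
  remap <- c(seq_len(n), rep(NA_integer_, n_int))
  remap[root] <- n + 1L
  others <- setdiff((n + 1L):root, root)
  remap[others] <- n + 1L + seq_along(others)
  edges <- matrix(remap[edges], ncol = 2)
  tr <- structure(list(edge = edges, edge.length = unname(lens),
                       tip.label = labels, Nnode = n_int),
                  class = "phylo")
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}

# canonical bipartition strings of an unrooted tree: for each internal edge,
# the sorted tip set on the side not containing the first reference label
.bipartitions <- function(tree, ref_labels) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  out <- character(0)
  for (k in seq_along(pp)) {
    tips <- labs[pp[[k]]]
    if (length(tips) <= 1 || length(tips) >= length(ref_labels) - 1) next
    side <- if (ref_labels[1] %in% tips) setdiff(ref_labels, tips) else tips
    if (length(side) <= 1) next
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the NJ tree from the full star alignment, then resamples alignment
#' columns with replacement `replicates` times, recomputes distances and NJ
#' per replicate, and labels each internal bipartition of the main tree with
#' the percentage of replicates containing it.
#'
#' @param proteins Named AAStringSet/character of at least 4 sequences, or a
#'   `protein_msa`.
#' @param replicates Bootstrap replicates (default 100).
#' @param seed Integer seed; identical seeds give identical supports.
#' @param outgroup Optional tip label to root the returned tree on.
#' @return A `phylo` tree; `node.label` holds bootstrap percentages (root
#'   label empty). Attribute `support` is a tibble of bipartitions and
#'   supports.
#' @export
bootstrap_support <- function(proteins, replicates = 100, seed = 1,
                              outgroup = NULL) {
  if (replicates < 1) stop("replicates must be >= 1")
  msa <- if (inherits(proteins, "protein_msa")) proteins else
    star_alignment(proteins)
  if (nrow(msa) < 4) stop("bootstrap support needs at least 4 taxa")
  labels <- rownames(msa)
  main <- neighbor_joining(distance_matrix(msa))
  main_bip <- .bipartitions(main, labels)
  counts <- setNames(numeric(length(main_bip)), main_bip)
  .with_seed(seed, {
    for (b in seq_len(replicates)) {
      cols <- sample.int(ncol(msa), ncol(msa), replace = TRUE)
      rep_msa <- msa[, cols, drop = FALSE]
      class(rep_msa) <- c("protein_msa", "matrix", "array")
      tr <- neighbor_joining(distance_matrix(rep_msa))
      rb <- .bipartitions(tr, labels)
      hit <- main_bip %in% rb
      counts[hit] <- counts[hit] + 1
    }
  })
  support <- 100 * counts / replicates
  # attach as node labels: match each internal node's bipartition
  pp <- ape::prop.part(main)
  labs <- attr(pp, "labels")
  node_lab <- character(main$Nnode)
  for (k in seq_along(pp)) {
    tips <- labs[pp[[k]]]
    side <- if (labels[1] %in% tips) setdiff(labels, tips) else tips
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(support))
      node_lab[k] <- format(round(support[[key]], 1), trim = TRUE)
  }
  main$node.label <- node_lab
  if (!is.null(outgroup))
    main <- ape::root(main, outgroup = outgroup, resolve.root = FALSE,
                      edgelabel = TRUE)
  attr(main, "support") <- tibble(bipartition = names(support),
                                  support = unname(support))
  main
}

#' Bootstrap support of a specific clade
#'
#' @param tree A [bootstrap_support()] result.
#' @param tips Tip labels of the clade of interest.
#' @return Support percentage, or `NA` if the bipartition is not in the tree.
#' @export
clade_support <- function(tree, tips) {
  sup <- attr(tree, "support")
  if (is.null(sup)) stop("tree carries no bootstrap support attribute")
  all_tips <- sort(unique(unlist(strsplit(sup$bipartition, "\\|"))))
  universe <- if (!is.null(tree$tip.label)) tree$tip.label else all_tips
  side <- sort(tips)
  comp <- sort(setdiff(universe, tips))
  key1 <- paste(side, collapse = "|")
  key2 <- paste(comp, collapse = "|")
  hit <- sup$support[sup$bipartition %in% c(key1, key2)]
  if (length(hit)) hit[1] else NA_real_
}
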