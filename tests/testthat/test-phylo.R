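# Distance phylogenetics: Poisson distances, neighbor joining, bootstrap.

test_that("Poisson-corrected distance matches its closed form", {
  set.seed(51)
  aas <- names(hemocyanr:::.AA_MASS_AVG)
  a <- paste(sample(aas, 200, replace = TRUE), collapse = "")
  expect_equal(pairwise_distance(a, a), 0)
  # exactly 20 substitutions in 200 residues: p = 0.10, d = -ln(0.9)
  v <- strsplit(a, "")[[1]]
  idx <- sample(200, 20)
  for (i in idx) v[i] <- sample(setdiff(aas, v[i]), 1)
  b <- paste(v, collapse = "")
  expect_equal(pairwise_distance(a, b), -log(0.9), tolerance = 1e-9)
  expect_equal(pairwise_distance(a, b), pairwise_distance(b, a))
  # monotone in p
  p <- seq(0.05, 0.9, by = 0.05)
  expect_true(all(diff(-log(1 - p)) > 0))
})

test_that("neighbor joining reproduces additive trees exactly", {
  set.seed(52)
  for (n in 4:8) {
    rt <- ape::unroot(ape::rtree(n, br = function(k) runif(k, 0.05, 0.5)))
    D <- cophenetic(rt)
    D <- D[sort(rownames(D)), sort(rownames(D))]
    mine <- neighbor_joining(D)
    expect_equal(phangorn::RF.dist(mine, rt), 0)
    expect_equal(max(abs(cophenetic(mine)[rownames(D), rownames(D)] - D)), 0,
                 tolerance = 1e-8)
  }
})

test_that("three taxa give the closed-form star resolution", {
  D <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.4,
                0.5, 0.4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  expect_equal(ape::Ntip(tr), 3L)
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(lens["a"]), (0.3 + 0.5 - 0.4) / 2, tolerance = 1e-12)
  expect_equal(unname(lens["b"]), (0.3 + 0.4 - 0.5) / 2, tolerance = 1e-12)
  expect_equal(unname(lens["c"]), (0.5 + 0.4 - 0.3) / 2, tolerance = 1e-12)
})

test_that("neighbor joining agrees with the reference implementation on noisy matrices", {
  set.seed(53)
  for (i in 1:5) {
    n <- sample(5:9, 1)
    rt <- ape::unroot(ape::rtree(n, br = function(k) runif(k, 0.1, 0.6)))
    D <- cophenetic(rt)
    noise <- matrix(runif(n * n, 0, 0.03), n)
    D <- D + (noise + t(noise)) / 2
    diag(D) <- 0
    expect_equal(phangorn::RF.dist(neighbor_joining(D), ape::nj(D)), 0)
  }
  # invalid input
  D <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric|3 taxa")
  bad <- matrix(c(0, 1, 2, 1, 0, 1, 2.5, 1, 0), 3, 3)
  expect_error(neighbor_joining(bad), "symmetric")
})

test_that("negative NJ branch lengths are clamped to zero", {
  # a non-additive matrix known to produce a negative branch estimate
  D <- matrix(c(0, 0.1, 0.4, 0.45,
                0.1, 0, 0.42, 0.47,
                0.4, 0.42, 0, 0.02,
                0.45, 0.47, 0.02, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(D)
  expect_true(all(tr$edge.length >= 0))
})

test_that("newick serialization round-trips topology, lengths and supports", {
  ts <- generate_paralog_pair(tiny_spec(seed = 54, paralog = 0.3,
                                        species = 0.1, insert_len = 60,
                                        seed_reference_divergence = NULL))
  prots <- setNames(as.character(ts$proteins), names(ts$proteins))
  prots <- c(prots, outgroup = as.character(ts$outgroup_protein))
  tr <- bootstrap_support(prots, replicates = 25, seed = 9,
                          outgroup = "outgroup")
  path <- tempfile(fileext = ".nwk")
  ape::write.tree(tr, path)
  back <- ape::read.tree(path)
  expect_equal(phangorn::RF.dist(back, tr), 0)
  expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-9)
  expect_setequal(setdiff(back$node.label, ""), setdiff(tr$node.label, ""))
})

test_that("duplicate taxa get 100% bootstrap support and seeds are reproducible", {
  set.seed(55)
  aas <- names(hemocyanr:::.AA_MASS_AVG)
  base <- paste(sample(aas, 300, replace = TRUE), collapse = "")
  mut <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    for (i in sample(length(v), k)) v[i] <- sample(setdiff(aas, v[i]), 1)
    paste(v, collapse = "")
  }
  # serial mutation keeps the distances tree-like (near-additive)
  t3 <- mut(base, 90); t4 <- mut(t3, 80); t5 <- mut(t4, 80)
  prots <- c(t1 = base, t2 = base, t3 = t3, t4 = t4, t5 = t5)
  tr1 <- bootstrap_support(prots, replicates = 50, seed = 4)
  expect_equal(clade_support(tr1, c("t1", "t2")), 100)
  tr2 <- bootstrap_support(prots, replicates = 50, seed = 4)
  expect_identical(attr(tr1, "support"), attr(tr2, "support"))
  expect_error(bootstrap_support(prots, replicates = 0), "replicates")
})

test_that("orthologs group by gene, not species, with strong support", {
  tsp <- small_spec(seed = 56)
  ts <- generate_paralog_pair(tsp)
  prots <- setNames(as.character(ts$proteins), names(ts$proteins))
  prots <- c(prots, outgroup = as.character(ts$outgroup_protein))
  tr <- bootstrap_support(prots, replicates = 100, seed = 1,
                          outgroup = "outgroup")
  expect_gte(clade_support(tr, c("sp1_H1", "sp2_H1")), 90)
  expect_gte(clade_support(tr, c("sp1_H2", "sp2_H2")), 90)
  # and the species pairing is NOT a bipartition of the tree
  expect_true(is.na(clade_support(tr, c("sp1_H1", "sp1_H2"))))
})
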