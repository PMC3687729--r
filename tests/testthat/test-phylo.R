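test_that("three taxa give the unique topology with three-point lengths", {
  D <- matrix(c(0, 0.2, 0.3,
                0.2, 0, 0.5,
                0.3, 0.5, 0), 3L, 3L,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj(D)
  expect_s3_class(tr, "phylo")
  expect_identical(ape::Ntip(tr), 3L)
  expect_identical(tr$Nnode, 1L)
  len <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2L]])
  expect_equal(unname(len[c("a", "b", "c")]),
               c((0.2 + 0.3 - 0.5) / 2,
                 (0.2 + 0.5 - 0.3) / 2,
                 (0.3 + 0.5 - 0.2) / 2))
  expect_error(nj(D[1:2, 1:2]), "at least 3")
})

test_that("NJ exactly recovers random additive trees (n <= 8)", {
  set.seed(101)
  for (n in 4:8) {
    for (rep in 1:3) {
      true <- ape::rtree(n, rooted = FALSE,
                         br = function(k) runif(k, 0.05, 0.6))
      D <- ape::cophenetic.phylo(true)
      D <- D[sort(rownames(D)), sort(rownames(D))]
      est <- nj(D)
      expect_equal(as.numeric(ape::dist.topo(true, est)), 0)
      # additive consistency: path lengths on the estimate reproduce D
      est_D <- ape::cophenetic.phylo(est)
      expect_equal(est_D[rownames(D), colnames(D)], D, tolerance = 1e-8)
      # independent implementation agrees on the topology
      expect_equal(as.numeric(ape::dist.topo(est, ape::nj(stats::as.dist(D)))), 0)
    }
  }
})

test_that("the japonica clade is monophyletic on both default panel trees", {
  for (fix in list(list(its2_panel(), its2_dm()),
                   list(psba_panel(), psba_dm()))) {
    tr <- nj(fix[[2L]])
    expect_true(is_monophyletic(tr, JAPONICA, species_labels(fix[[1L]])))
  }
})

test_that("monophyly detection enumerates bipartitions correctly", {
  tr <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1,c:1);")
  lab <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", c = "C")
  expect_false(is_monophyletic(tr, "A", lab))  # a1/a2 interleaved
  expect_false(is_monophyletic(tr, "B", lab))
  expect_true(is_monophyletic(tr, "C", lab))   # single leaf: by convention
  tr2 <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1,c:1);")
  expect_true(is_monophyletic(tr2, "A", lab))
  expect_error(is_monophyletic(tr2, "Z", lab), "no tips")
})

test_that("bootstrap supports behave at the edges and are deterministic", {
  msa <- its2_msa()
  tr1 <- bootstrap_support(msa, replicates = 10L, seed = 5L)
  tr2 <- bootstrap_support(msa, replicates = 10L, seed = 5L)
  expect_identical(tr1$node.label, tr2$node.label)
  expect_identical(to_newick(tr1), to_newick(tr2))
  tr3 <- bootstrap_support(msa, replicates = 10L, seed = 6L)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr1), ape::unroot(tr3))),
               0)  # topology from the full data, not the seed

  one <- bootstrap_support(msa, replicates = 1L, seed = 9L)
  expect_true(all(as.numeric(one$node.label) %in% c(0, 100)))
  expect_error(bootstrap_support(msa, replicates = 0L), ">= 1")
})

test_that("well-separated clusters get full bootstrap support", {
  # two 4-tip clusters separated by 20 diagnostic sites out of 80, with
  # 1-2 private substitutions per tip to avoid zero-length branches
  set.seed(21)
  base <- strsplit(random_seq(80), "")[[1L]]
  flip <- function(ch) c(A = "G", G = "A", C = "T", T = "C")[[ch]]
  other <- base
  for (p in seq(3, 60, by = 3)) other[p] <- flip(other[p])
  seqs <- character(0L)
  for (i in 1:4) {
    a <- base; a[70 + i] <- flip(a[70 + i])
    b <- other; b[74 + i] <- flip(b[74 + i])
    seqs[paste0("A", i)] <- paste(a, collapse = "")
    seqs[paste0("B", i)] <- paste(b, collapse = "")
  }
  msa <- build_msa(seqs)
  tr <- bootstrap_support(msa, replicates = 50L, seed = 3L)
  lab <- stats::setNames(rep(c("A", "B"), 4L), names(seqs))
  expect_true(is_monophyletic(tr, "A", lab))
  # locate the internal node carrying the A-vs-B bipartition and check
  # its tallied support against the replicate count
  pp <- ape::prop.part(tr)
  a_idx <- sort(match(paste0("A", 1:4), tr$tip.label))
  n <- length(tr$tip.label)
  node <- which(vapply(pp, function(p) {
    identical(sort(as.integer(p)), a_idx) ||
      identical(sort(setdiff(seq_len(n), p)), a_idx)
  }, logical(1L)))
  expect_length(node, 1L)
  expect_equal(as.numeric(tr$node.label[node]), 100)
})

test_that("newick serialization round-trips topology, lengths and supports", {
  tr <- bootstrap_support(psba_msa(), replicates = 5L, seed = 2L)
  back <- from_newick(to_newick(tr))
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(back))), 0)
  expect_equal(sort(back$edge.length), sort(tr$edge.length),
               tolerance = 1e-9)
  expect_setequal(back$node.label, tr$node.label)
  tiny <- nj(matrix(c(0, .1, .2, .1, 0, .3, .2, .3, 0), 3L, 3L,
                    dimnames = list(letters[1:3], letters[1:3])))
  expect_match(to_newick(tiny), "^\\(a:[0-9.e+-]+,b:[0-9.e+-]+,c:[0-9.e+-]+\\);$")
})
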