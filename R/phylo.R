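#' Neighbor-joining tree from a K2P distance matrix
#'
#' Classic neighbor-joining (Saitou-Nei agglomeration with the
#' Q-criterion, standard branch-length and distance-update formulas),
#' returning an unrooted `ape::phylo` with an arbitrary trifurcating
#' root. Deterministic: Q-ties are broken by the first minimal pair in
#' column-major scan order. Negative branch lengths arising at a join are
#' clamped to zero with the deficit transferred to the sister branch, so
#' the pair's total length decomposition is preserved.
#'
#' @param dm A `k2p_dm`, or a plain symmetric numeric matrix with
#'   dimnames.
#' @return An unrooted `phylo` object whose tip labels are the matrix
#'   ids.
#' @export
nj <- function(dm) {
  D <- if (inherits(dm, "k2p_dm")) dm$d else dm
  stopifnot(is.matrix(D), nrow(D) == ncol(D),
            !is.null(rownames(D)))
  n <- nrow(D)
  if (n < 3L) stop("neighbor-joining needs at least 3 taxa")
  stopifnot(all(is.finite(D)), isTRUE(all.equal(D, t(D))))
  reps <- rownames(D)

  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    Q[lower.tri(Q)] <- Inf
    k <- which.min(Q)
    i <- (k - 1L) %% m + 1L
    j <- (k - 1L) %/% m + 1L
    li <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    if (li < 0) li <- 0  # total itself negative: clamp both
    new_rep <- sprintf("(%s:%.10g,%s:%.10g)", reps[i], li, reps[j], lj)
    others <- setdiff(seq_len(m), c(i, j))
    d_new <- 0.5 * (D[i, others] + D[j, others] - D[i, j])
    d_new <- pmax(d_new, 0)
    D <- rbind(cbind(D[others, others, drop = FALSE], d_new),
               c(d_new, 0))
    reps <- c(reps[others], new_rep)
    rownames(D) <- colnames(D) <- NULL
  }
  d1 <- max(0, (D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  d2 <- max(0, (D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  d3 <- max(0, (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 reps[1], d1, reps[2], d2, reps[3], d3)
  ape::read.tree(text = nwk)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Builds the NJ tree from the full alignment, then resamples alignment
#' columns with replacement (gap columns like any other), rebuilds the
#' distance matrix and NJ tree per replicate, and scores each internal
#' bipartition of the original tree by the percentage of replicate trees
#' containing it. Supports are stored in `node.label`; values below the
#' conventional 50% display threshold are retained, not blanked.
#'
#' @param msa A `barcode_msa`.
#' @param species Optional named species vector (defaults to the MSA's).
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed Seed for column resampling.
#' @return An unrooted `phylo` with `node.label` set to support
#'   percentages (the basal trifurcation is labelled 100 by convention)
#'   and attribute `replicates`.
#' @export
bootstrap_support <- function(msa, species = NULL, replicates = 1000L,
                              seed = 1L) {
  stopifnot(inherits(msa, "barcode_msa"))
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) stop("replicates must be >= 1")
  if (is.null(species)) species <- msa$species
  m <- msa_matrix(msa)
  main <- nj(distance_matrix(m, species))
  boot <- with_seed(seed, {
    lapply(seq_len(replicates), function(b) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      nj(distance_matrix(m[, cols, drop = FALSE], species))
    })
  })
  counts <- ape::prop.clades(main, boot, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / replicates, 1L)
  support[1L] <- 100  # basal trifurcation: trivial split
  main$node.label <- as.character(support)
  attr(main, "replicates") <- replicates
  main
}

# all nontrivial bipartitions of an unrooted tree, as tip-index sets
.bipartitions <- function(tree) {
  lapply(ape::prop.part(tree), function(p) sort(as.integer(p)))
}

#' Is a species monophyletic on a tree?
#'
#' TRUE when some edge of the (unrooted) tree bipartitions the leaves
#' into exactly that species' records versus everything else. Species
#' with a single record, or spanning all leaves, are monophyletic by
#' convention.
#'
#' @param tree A `phylo`.
#' @param species Species label to test.
#' @param labels Named character vector mapping tip labels to species.
#' @return Logical.
#' @export
is_monophyletic <- function(tree, species, labels) {
  stopifnot(inherits(tree, "phylo"), !is.null(names(labels)))
  tips <- names(labels)[labels == species]
  if (!length(tips)) stop("species '", species, "' has no tips on the tree")
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing)) {
    stop("tip(s) not on tree: ", paste(missing, collapse = ", "))
  }
  n <- length(tree$tip.label)
  target <- sort(match(tips, tree$tip.label))
  if (length(target) %in% c(1L, n - 1L, n)) return(TRUE)
  all_idx <- seq_len(n)
  for (p in .bipartitions(tree)) {
    if (identical(p, target)) return(TRUE)
    if (identical(sort(setdiff(all_idx, p)), target)) return(TRUE)
  }
  FALSE
}

#' Serialize a tree to newick
#'
#' Branch lengths are kept at full precision; bootstrap supports (if
#' present in `node.label`) are emitted as internal node labels readable
#' by standard tree viewers.
#'
#' @param tree A `phylo`.
#' @return A newick string (terminated by `;`).
#' @export
to_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, digits = 12)
}

#' Parse a newick string
#'
#' @param text A newick string.
#' @return A `phylo`.
#' @export
from_newick <- function(text) {
  ape::read.tree(text = text)
}
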