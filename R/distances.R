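#' Transition/transversion site counts for one aligned pair
#'
#' Sites where either row carries a gap or an ambiguity code are excluded
#' (pairwise deletion). Transitions are A<->G and C<->T; any other
#' difference between unambiguous bases is a transversion.
#'
#' @param a,b Equal-length (gapped) sequence strings.
#' @return List with `n_sites`, `n_transition`, `n_transversion`.
#' @export
site_pair_counts <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1L]]
  cb <- strsplit(toupper(b), "")[[1L]]
  if (length(ca) != length(cb)) stop("rows must have equal length")
  ok <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  ca <- ca[ok]; cb <- cb[ok]
  diff <- ca != cb
  purine <- c("A", "G")
  ts <- diff & ((ca %in% purine) == (cb %in% purine))
  list(n_sites = sum(ok), n_transition = sum(ts),
       n_transversion = sum(diff & !ts))
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` with `P` and `Q` the
#' transition and transversion proportions over the compared sites
#' (pairwise deletion of gapped/ambiguous sites).
#'
#' @param a,b Equal-length (gapped) sequence strings.
#' @return Nonnegative K2P distance.
#' @examples
#' a <- paste(rep("A", 228), collapse = "")
#' b <- paste(c(rep("A", 26), "G", rep("A", 201)), collapse = "")
#' round(k2p(a, b), 4)  # 0.0044: one transition in 228 sites
#' @export
k2p <- function(a, b) {
  cnt <- site_pair_counts(a, b)
  if (cnt$n_sites == 0L) stop("no comparable sites (all gapped/ambiguous)")
  k2p_from_counts(cnt$n_transition / cnt$n_sites,
                  cnt$n_transversion / cnt$n_sites)
}

#' K2P distance from transition/transversion proportions
#'
#' @param P Transition proportion.
#' @param Q Transversion proportion.
#' @return K2P distance.
#' @export
k2p_from_counts <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (any(w1 <= 0) || any(w2 <= 0)) {
    stop("K2P distance undefined: substitution saturation (1-2P-Q or ",
         "1-2Q not positive)")
  }
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Pairwise K2P distance matrix for an alignment
#'
#' All pairwise distances under pairwise deletion, computed with a
#' vectorized indicator-matrix formulation (exact, no approximation) and
#' species labels attached.
#'
#' @param msa A `barcode_msa`, or a character matrix of aligned rows.
#' @param species Named character vector of species labels per id;
#'   defaults to the labels stored in the MSA.
#' @return Object of class `k2p_dm`: list with `d` (symmetric numeric
#'   matrix, zero diagonal, dimnames = ids) and `species`.
#' @export
distance_matrix <- function(msa, species = NULL) {
  if (inherits(msa, "barcode_msa")) {
    m <- msa_matrix(msa)
    if (is.null(species)) species <- msa$species
  } else {
    m <- msa
  }
  n <- nrow(m)
  if (is.null(n) || n < 2L) stop("need at least 2 aligned sequences")
  ids <- rownames(m)
  X <- lapply(c("A", "C", "G", "T"), function(b) (m == b) * 1)
  names(X) <- c("A", "C", "G", "T")
  V <- X$A + X$C + X$G + X$T
  n_sites <- V %*% t(V)
  same <- Reduce(`+`, lapply(X, function(x) x %*% t(x)))
  ts <- X$A %*% t(X$G) + X$G %*% t(X$A) + X$C %*% t(X$T) + X$T %*% t(X$C)
  tv <- n_sites - same - ts
  off <- upper.tri(n_sites)
  if (any(n_sites[off] == 0)) {
    bad <- which(n_sites == 0 & off, arr.ind = TRUE)[1L, ]
    stop("no comparable sites between '", ids[bad[1L]], "' and '",
         ids[bad[2L]], "'")
  }
  P <- ts / n_sites
  Q <- tv / n_sites
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (any(w1[off] <= 0) || any(w2[off] <= 0)) {
    bad <- which((w1 <= 0 | w2 <= 0) & off, arr.ind = TRUE)[1L, ]
    stop("K2P saturation between '", ids[bad[1L]], "' and '",
         ids[bad[2L]], "'")
  }
  d <- -0.5 * log(w1) - 0.25 * log(w2)
  diag(d) <- 0
  d <- (d + t(d)) / 2  # remove floating asymmetry
  dimnames(d) <- list(ids, ids)
  if (!is.null(species)) species <- species[ids]
  structure(list(d = d, species = species), class = "k2p_dm")
}

#' @export
print.k2p_dm <- function(x, ...) {
  cat("K2P distance matrix:", nrow(x$d), "x", ncol(x$d))
  if (!is.null(x$species)) {
    cat(",", length(unique(x$species)), "species")
  }
  cat("\n  range:", sprintf("%.4f-%.4f", min(x$d), max(x$d)), "\n")
  invisible(x)
}

#' Export a distance matrix as TSV
#'
#' @param dm A `k2p_dm`.
#' @param path Output path.
#' @param format `"square"` (full matrix with header) or `"phylip"`
#'   (lower-triangle PHYLIP style).
#' @return Invisibly, `path`.
#' @export
write_distance_matrix <- function(dm, path, format = c("square", "phylip")) {
  stopifnot(inherits(dm, "k2p_dm"))
  format <- match.arg(format)
  if (format == "square") {
    write.table(format(dm$d, digits = 10), path, sep = "\t",
                quote = FALSE, col.names = NA)
  } else {
    n <- nrow(dm$d)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", n), con)
    for (i in seq_len(n)) {
      left <- if (i > 1L) {
        paste(sprintf("%.6f", dm$d[i, seq_len(i - 1L)]), collapse = " ")
      } else ""
      writeLines(trimws(paste(sprintf("%-12s", rownames(dm$d)[i]), left),
                        "right"), con)
    }
  }
  invisible(path)
}
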