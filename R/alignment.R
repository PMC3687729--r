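#' Default alignment scoring scheme
#'
#' Match +2, mismatch -3, gap opening -5, gap extension -2; a gap of
#' length L costs `gap_open + L * gap_extend`. These are the package
#' defaults for both global panel alignment and local best-hit scoring.
#'
#' @param match,mismatch,gap_open,gap_extend Scheme components; penalties
#'   are given as negative numbers.
#' @return A named list of class `align_scoring`.
#' @export
align_scoring <- function(match = 2, mismatch = -3, gap_open = -5,
                          gap_extend = -2) {
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_extend <= 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_scoring")
}

.subst_matrix <- function(scoring) {
  Biostrings::nucleotideSubstitutionMatrix(match = scoring$match,
                                           mismatch = scoring$mismatch,
                                           baseOnly = TRUE)
}

.pairwise <- function(pattern, subject, scoring, type = "global") {
  Biostrings::pairwiseAlignment(
    pattern, subject, type = type,
    substitutionMatrix = .subst_matrix(scoring),
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend)
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties.
#'
#' @param a,b Nonempty A/C/G/T sequences.
#' @param scoring An [align_scoring()] scheme.
#' @return A list with elements `a`, `b` (gapped strings of equal length)
#'   and `score`.
#' @examples
#' align_pair("ACGT", "ACT")$score  # -1: three matches, one 1-bp gap
#' @export
align_pair <- function(a, b, scoring = align_scoring()) {
  stopifnot(is.character(a), is.character(b), nzchar(a), nzchar(b))
  pa <- .pairwise(a, b, scoring)
  list(a = as.character(Biostrings::alignedPattern(pa)),
       b = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

#' Star multiple alignment of a barcode panel
#'
#' Aligns every sequence pairwise against the longest sequence (ties
#' broken by panel order) and merges the pairwise alignments into one
#' gapped matrix, propagating reference gaps ("once a gap, always a
#' gap"). For barcode panels this is exact in the sense that each row's
#' induced pairwise alignment to the reference is score-optimal; the
#' panels this package targets diverge by a few percent with at most one
#' indel event per sequence pair, which is the regime where star
#' alignment is adequate and progressive methods add nothing.
#'
#' @param panel A `barcode_panel`, or a named character vector of
#'   sequences (optionally with a `species` attribute).
#' @param scoring An [align_scoring()] scheme.
#' @return An object of class `barcode_msa`: list with `ids`, `seqs`
#'   (named gapped strings, all the same width), `species` (named vector
#'   or NULL) and `width`.
#' @export
build_msa <- function(panel, scoring = align_scoring()) {
  if (inherits(panel, "barcode_panel")) {
    if (length(unique(panel$records$locus)) > 1L) {
      stop("panel mixes loci; align one locus at a time")
    }
    seqs <- panel$records$sequence
    names(seqs) <- panel$records$id
    species <- panel$records$species
    names(species) <- panel$records$id
  } else {
    seqs <- panel
    stopifnot(is.character(seqs), !is.null(names(seqs)))
    species <- attr(panel, "species")
  }
  if (length(seqs) < 2L) stop("need at least 2 sequences to align")

  ref_i <- which.max(nchar(seqs))
  ref <- seqs[[ref_i]]
  L <- nchar(ref)
  others <- setdiff(seq_along(seqs), ref_i)

  # ins[[i]][k+1] = bases of row i inserted after reference position k
  pat_aln <- vector("list", length(seqs))
  ins_len <- matrix(0L, nrow = length(seqs), ncol = L + 1L)
  ins_txt <- vector("list", length(seqs))
  for (i in others) {
    pa <- .pairwise(seqs[[i]], ref, scoring)
    p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
    s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
    row_cols <- character(L)       # row char aligned to each ref base
    row_ins <- vector("list", L + 1L)
    k <- 0L
    for (j in seq_along(s)) {
      if (s[j] == "-") {
        row_ins[[k + 1L]] <- c(row_ins[[k + 1L]], p[j])
      } else {
        k <- k + 1L
        row_cols[k] <- p[j]
      }
    }
    stopifnot(k == L)
    pat_aln[[i]] <- row_cols
    ins_txt[[i]] <- row_ins
    ins_len[i, ] <- vapply(row_ins, length, integer(1L))
  }
  master_ins <- apply(ins_len, 2L, max)

  assemble <- function(cols, row_ins) {
    out <- character(0L)
    for (k in 0:L) {
      block <- if (is.null(row_ins)) character(0L) else row_ins[[k + 1L]]
      pad <- master_ins[k + 1L] - length(block)
      out <- c(out, block, rep("-", pad))
      if (k < L) out <- c(out, cols[k + 1L])
    }
    paste(out, collapse = "")
  }

  aligned <- character(length(seqs))
  ref_cols <- strsplit(ref, "")[[1L]]
  for (i in seq_along(seqs)) {
    aligned[i] <- if (i == ref_i) assemble(ref_cols, NULL)
                  else assemble(pat_aln[[i]], ins_txt[[i]])
  }
  names(aligned) <- names(seqs)
  stopifnot(length(unique(nchar(aligned))) == 1L)
  # invariant: ungapping recovers the inputs
  stopifnot(identical(unname(gsub("-", "", aligned)), unname(seqs)))
  structure(list(ids = names(seqs), seqs = aligned, species = species,
                 width = nchar(aligned[[1L]])),
            class = "barcode_msa")
}

#' @export
print.barcode_msa <- function(x, ...) {
  cat("MSA:", length(x$ids), "sequences x", x$width, "columns\n")
  invisible(x)
}

# character matrix view of an MSA (rows = sequences)
msa_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(unname(msa$seqs), ""))
  rownames(m) <- msa$ids
  m
}

#' Count variable (segregating) sites in an alignment
#'
#' A column is variable when at least two distinct unambiguous bases
#' (A/C/G/T) occur among the chosen rows. Gaps and ambiguity codes do not
#' contribute, so indel-only columns are not counted; indel events are
#' reported separately by [sequence_characteristics()].
#'
#' @param msa A `barcode_msa`.
#' @param ids Optional subset of sequence ids.
#' @return Integer count of variable columns.
#' @export
count_variable_sites <- function(msa, ids = NULL) {
  stopifnot(inherits(msa, "barcode_msa"))
  m <- msa_matrix(msa)
  if (!is.null(ids)) {
    unknown <- setdiff(ids, msa$ids)
    if (length(unknown)) {
      stop("unknown id(s): ", paste(unknown, collapse = ", "))
    }
    m <- m[ids, , drop = FALSE]
  }
  sum(apply(m, 2L, function(col) {
    length(unique(col[col %in% c("A", "C", "G", "T")])) >= 2L
  }))
}

# number of distinct indel events across the panel, counted as maximal
# runs of gap/base disagreement against the gap pattern consensus
count_indel_events <- function(msa) {
  m <- msa_matrix(msa) == "-"
  any_gap <- apply(m, 2L, any)
  if (!any(any_gap)) return(0L)
  runs <- rle(apply(m[, any_gap, drop = FALSE], 2L, paste, collapse = ""))
  # distinct gap columns blocks with identical row pattern = one event
  sum(rep(1L, length(runs$lengths)))
}

#' GC content
#'
#' Fraction (G+C)/(A+C+G+T); gaps and ambiguity codes are excluded from
#' both numerator and denominator. For a panel, the unweighted mean over
#' records is returned.
#'
#' @param x A character vector of sequences (gapped or not) or a
#'   `barcode_panel`.
#' @return For sequences, a numeric vector of per-sequence fractions; for
#'   a panel, a single mean fraction.
#' @examples
#' gc_content("ATGC")  # 0.5
#' @export
gc_content <- function(x) UseMethod("gc_content")

#' @export
gc_content.character <- function(x) {
  vapply(x, function(s) {
    ch <- strsplit(toupper(s), "")[[1L]]
    n_gc <- sum(ch %in% c("G", "C"))
    n_at <- sum(ch %in% c("A", "T"))
    if (n_gc + n_at == 0L) stop("sequence has no unambiguous bases")
    n_gc / (n_gc + n_at)
  }, numeric(1L))
}

#' @export
gc_content.barcode_panel <- function(x) {
  mean(unname(gc_content(x$records$sequence)))
}

#' Sequence characteristics of a panel
#'
#' Length range, mean GC content (percent, one decimal) and variable-site
#' counts for the focal species and for all taxa, plus the number of
#' indel-bearing column blocks in the alignment.
#'
#' @param panel A `barcode_panel`.
#' @param msa Optional precomputed [build_msa()] result.
#' @param focal Focal species label (default `"Lonicera japonica"`).
#' @return A data.frame with columns `characteristic` and `value`.
#' @export
sequence_characteristics <- function(panel, msa = NULL,
                                     focal = "Lonicera japonica") {
  stopifnot(inherits(panel, "barcode_panel"))
  r <- panel$records
  if (!nrow(r)) stop("empty panel")
  if (is.null(msa)) msa <- build_msa(panel)
  foc <- r$id[r$species == focal]
  if (!length(foc)) stop("focal species '", focal, "' absent from panel")
  rng <- function(x) if (min(x) == max(x)) as.character(min(x)) else
    paste0(min(x), "-", max(x))
  data.frame(
    characteristic = c(
      paste0("Length range in ", focal, " (bp)"),
      "Length in all taxa (bp)",
      paste0("Average of GC content in ", focal, " (%)"),
      "Average of GC content in all taxa (%)",
      paste0("No. of variable sites in ", focal),
      "No. of variable sites in all taxa",
      "No. of indel events in all taxa"),
    value = c(
      rng(nchar(r$sequence[r$species == focal])),
      rng(nchar(r$sequence)),
      sprintf("%.1f", 100 * mean(gc_content(r$sequence[r$species == focal]))),
      sprintf("%.1f", 100 * mean(gc_content(r$sequence))),
      count_variable_sites(msa, foc),
      count_variable_sites(msa),
      count_indel_events(msa)),
    stringsAsFactors = FALSE
  )
}

#' Write an alignment to gapped FASTA
#'
#' @param msa A `barcode_msa`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_msa <- function(msa, path) {
  stopifnot(inherits(msa, "barcode_msa"))
  write_fasta(msa$seqs, path)
}
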