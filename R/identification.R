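#' Rank reference sequences by local alignment score against a query
#'
#' Smith-Waterman local alignment with the package's default scoring
#' (match +2, mismatch -3, gap open -5, extend -2), the assignment rule
#' behind BLAST-style best-hit identification in a closed reference set:
#' raw scores suffice for ranking, so no E-values are computed.
#'
#' @param query A single (unaligned) sequence string.
#' @param references Named character vector of reference sequences.
#' @param scoring An [align_scoring()] scheme.
#' @return Data.frame with `id`, `score`, `rank` (ties share a rank),
#'   sorted by decreasing score then id.
#' @export
best_hit <- function(query, references, scoring = align_scoring()) {
  stopifnot(is.character(query), length(query) == 1L, nzchar(query))
  if (!length(references)) stop("empty reference set")
  stopifnot(!is.null(names(references)))
  pa <- .pairwise(Biostrings::DNAStringSet(references),
                  Biostrings::DNAString(query), scoring, type = "local")
  scores <- Biostrings::score(pa)
  ord <- order(-scores, names(references))
  out <- data.frame(id = names(references)[ord], score = scores[ord],
                    stringsAsFactors = FALSE)
  out$rank <- match(out$score, unique(out$score))
  out
}

#' Leave-one-out best-hit identification efficiency
#'
#' Each record is queried against all remaining records; the query is
#' assigned the species of its top-ranked hit(s) and counted as a success
#' only when every co-ranked top hit is conspecific with it (a top-score
#' tie spanning more than one species is a failure). Efficiency is the
#' success fraction over all assessable queries. Records of species with
#' a single record cannot be identified correctly by construction; they
#' are marked unassessable, excluded from the denominator, and a warning
#' is issued.
#'
#' @param panel A `barcode_panel`.
#' @param mode `"align"` (local-alignment scores, default) or `"k2p"`
#'   (nearest neighbor by K2P distance on the panel alignment).
#' @param scoring An [align_scoring()] scheme (align mode).
#' @param dm Optional precomputed `k2p_dm` (k2p mode).
#' @return Object of class `identification_report`: data.frame with one
#'   row per query (`id`, `species`, `best_hits`, `assigned`, `success`,
#'   `assessable`) and attribute `efficiency`.
#' @export
loo_efficiency <- function(panel, mode = c("align", "k2p"),
                           scoring = align_scoring(), dm = NULL) {
  stopifnot(inherits(panel, "barcode_panel"))
  mode <- match.arg(mode)
  r <- panel$records
  if (nrow(r) < 2L) stop("need at least 2 records")
  species <- r$species
  names(species) <- r$id
  lone <- names(table(species))[table(species) < 2L]
  if (length(lone)) {
    warning("species with a lone record are unassessable: ",
            paste(lone, collapse = ", "))
  }

  if (mode == "k2p") {
    if (is.null(dm)) dm <- distance_matrix(build_msa(panel, scoring))
    score_of <- function(qid) -dm$d[qid, setdiff(r$id, qid)]
  } else {
    seqs <- r$sequence
    names(seqs) <- r$id
    score_of <- function(qid) {
      hits <- best_hit(seqs[[qid]], seqs[names(seqs) != qid], scoring)
      s <- hits$score
      names(s) <- hits$id
      s
    }
  }

  rows <- lapply(r$id, function(qid) {
    s <- score_of(qid)
    top <- names(s)[s == max(s)]
    top_sp <- unique(species[top])
    data.frame(
      id = qid, species = species[[qid]],
      best_hits = paste(sort(top), collapse = ","),
      assigned = if (length(top_sp) == 1L) top_sp else
        paste(sort(top_sp), collapse = ","),
      success = length(top_sp) == 1L && top_sp == species[[qid]],
      assessable = !species[[qid]] %in% lone,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  eff <- sum(out$success[out$assessable]) / sum(out$assessable)
  attr(out, "efficiency") <- eff
  attr(out, "mode") <- mode
  class(out) <- c("identification_report", "data.frame")
  out
}

#' @export
print.identification_report <- function(x, ...) {
  cat("Leave-one-out identification (", attr(x, "mode"), " mode): ",
      sum(x$success[x$assessable]), "/", sum(x$assessable),
      " queries correct, efficiency ",
      sprintf("%.0f%%", 100 * attr(x, "efficiency")), "\n", sep = "")
  invisible(x)
}

#' Identification efficiency of a report
#'
#' @param report An `identification_report`.
#' @return Efficiency fraction in `[0, 1]`.
#' @export
efficiency <- function(report) {
  stopifnot(inherits(report, "identification_report"))
  attr(report, "efficiency")
}
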