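#' Haplotype specification
#'
#' Describes one haplotype as a set of edits relative to the locus
#' ancestor: zero or more single-base substitutions and at most one indel
#' event. All individuals carrying the haplotype receive the identical
#' realized sequence.
#'
#' @param label Short haplotype label, e.g. `"A1"`.
#' @param count Number of individuals carrying this haplotype (>= 1).
#' @param substitutions Two-column matrix-like input or a data.frame with
#'   columns `position` (1-based, within the ancestor) and `base` (the
#'   substituted base, one of A/C/G/T). `NULL` means no substitutions.
#' @param indel Optional list with fields `position` (1-based), `kind`
#'   (`"insertion"` or `"deletion"`) and `length` (>= 1). An insertion
#'   inserts after `position`; a deletion removes `position` to
#'   `position + length - 1`.
#' @param genbank Number of individuals (taken from the end of the count)
#'   flagged as public-database records rather than study vouchers.
#'
#' @return An object of class `haplotype_spec`.
#' @seealso [species_spec()], [panel_spec()]
#' @export
haplotype_spec <- function(label, count, substitutions = NULL, indel = NULL,
                           genbank = 0L) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  count <- as.integer(count)
  if (is.na(count) || count < 1L) {
    stop("haplotype '", label, "': count must be a positive integer")
  }
  genbank <- as.integer(genbank)
  if (is.na(genbank) || genbank < 0L || genbank > count) {
    stop("haplotype '", label, "': genbank count must lie in [0, count]")
  }
  if (!is.null(substitutions)) {
    substitutions <- as.data.frame(substitutions, stringsAsFactors = FALSE)
    if (!all(c("position", "base") %in% names(substitutions))) {
      stop("substitutions need columns 'position' and 'base'")
    }
    substitutions$position <- as.integer(substitutions$position)
    substitutions$base <- toupper(as.character(substitutions$base))
    if (anyDuplicated(substitutions$position)) {
      stop("haplotype '", label, "': duplicate substitution positions")
    }
    if (!all(substitutions$base %in% c("A", "C", "G", "T"))) {
      stop("haplotype '", label, "': substitution bases must be A/C/G/T")
    }
    if (any(substitutions$position < 1L)) {
      stop("haplotype '", label, "': substitution positions must be >= 1")
    }
  }
  if (!is.null(indel)) {
    stopifnot(is.list(indel))
    if (!all(c("position", "kind", "length") %in% names(indel))) {
      stop("indel needs fields 'position', 'kind', 'length'")
    }
    indel$position <- as.integer(indel$position)
    indel$length <- as.integer(indel$length)
    if (!indel$kind %in% c("insertion", "deletion")) {
      stop("indel kind must be 'insertion' or 'deletion'")
    }
    if (indel$position < 1L || indel$length < 1L) {
      stop("indel position and length must be >= 1")
    }
  }
  structure(
    list(label = label, count = count, substitutions = substitutions,
         indel = indel, genbank = genbank),
    class = "haplotype_spec"
  )
}

#' Species specification
#'
#' @param name Species label (e.g. `"Lonicera japonica"`).
#' @param haplotypes List of [haplotype_spec()] objects with unique labels.
#'
#' @return An object of class `species_spec`.
#' @export
species_spec <- function(name, haplotypes) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (inherits(haplotypes, "haplotype_spec")) haplotypes <- list(haplotypes)
  stopifnot(length(haplotypes) >= 1L,
            all(vapply(haplotypes, inherits, logical(1L), "haplotype_spec")))
  labs <- vapply(haplotypes, `[[`, character(1L), "label")
  if (anyDuplicated(labs)) {
    stop("species '", name, "': haplotype labels must be unique")
  }
  structure(list(name = name, haplotypes = haplotypes),
            class = "species_spec")
}

#' Panel specification
#'
#' A complete recipe for a synthetic barcode panel: a random ancestor of
#' given length and GC content, plus per-species haplotypes defined as
#' edits on that ancestor. The union of substituted positions across all
#' haplotypes must equal `n_variable_sites`, so that counting variable
#' sites on the realized panel recovers the configured value by
#' construction.
#'
#' @param locus `"ITS2"` or `"psbA-trnH"`.
#' @param ancestor_length Ancestor length in bp (> 0).
#' @param target_gc Target GC fraction in `[0, 1]`; realized exactly as
#'   `round(target_gc * ancestor_length)` G/C bases.
#' @param species List of [species_spec()] objects.
#' @param n_variable_sites Expected number of distinct substituted
#'   positions across all haplotypes.
#' @param seed Master seed; ancestor composition and indel fill bases are
#'   drawn from sub-seeds derived from it, so a spec realizes to a
#'   byte-identical panel every time.
#'
#' @return An object of class `panel_spec`.
#' @export
panel_spec <- function(locus, ancestor_length, target_gc, species,
                       n_variable_sites, seed = 1L) {
  locus <- match.arg(locus, c("ITS2", "psbA-trnH"))
  ancestor_length <- as.integer(ancestor_length)
  stopifnot(ancestor_length > 0L, target_gc >= 0, target_gc <= 1)
  if (inherits(species, "species_spec")) species <- list(species)
  stopifnot(length(species) >= 1L,
            all(vapply(species, inherits, logical(1L), "species_spec")))
  spp_names <- vapply(species, `[[`, character(1L), "name")
  if (anyDuplicated(spp_names)) stop("species names must be unique")

  sub_positions <- integer(0L)
  for (sp in species) {
    for (h in sp$haplotypes) {
      if (!is.null(h$substitutions)) {
        if (any(h$substitutions$position > ancestor_length)) {
          stop("haplotype '", h$label,
               "': substitution position beyond ancestor length")
        }
        sub_positions <- c(sub_positions, h$substitutions$position)
      }
      if (!is.null(h$indel)) {
        bad <- if (h$indel$kind == "deletion") {
          h$indel$position + h$indel$length - 1L > ancestor_length
        } else {
          h$indel$position > ancestor_length
        }
        if (bad) stop("haplotype '", h$label, "': indel out of range")
      }
    }
  }
  n_distinct <- length(unique(sub_positions))
  n_variable_sites <- as.integer(n_variable_sites)
  if (n_distinct != n_variable_sites) {
    stop("spec declares ", n_variable_sites, " variable sites but ",
         "haplotypes substitute ", n_distinct, " distinct positions")
  }
  structure(
    list(locus = locus, ancestor_length = ancestor_length,
         target_gc = target_gc, species = species,
         n_variable_sites = n_variable_sites, seed = as.integer(seed)),
    class = "panel_spec"
  )
}

#' @export
print.panel_spec <- function(x, ...) {
  n_rec <- sum(vapply(x$species, function(sp) {
    sum(vapply(sp$haplotypes, `[[`, integer(1L), "count"))
  }, integer(1L)))
  cat("Panel spec:", x$locus, "\n")
  cat("  ancestor:", x$ancestor_length, "bp, target GC",
      sprintf("%.1f%%", 100 * x$target_gc), "\n")
  cat("  species:", length(x$species), " records:", n_rec,
      " variable sites:", x$n_variable_sites, "\n")
  invisible(x)
}

# Interspecific substitution layout for the default ITS2 panel. The study
# reports 14 variable sites in all taxa (one of which is the C/T site at
# base 27 inside L. japonica) plus one 1-bp indel, but not their positions;
# the positions and per-haplotype subsets below are this package's fixed,
# documented choice. Subsets are chosen so that the focal interspecific
# divergence is realistic for congeneric ITS2 (~0.03) while the closest
# heterospecific pair (B3 vs B4) still differs at 2 sites, keeping the
# barcoding gap open (2/228 > the maximal intraspecific 1/228).
.its2_positions <- c(40L, 55L, 70L, 85L, 100L, 115L, 130L, 145L,
                     160L, 175L, 190L, 205L, 220L)
.its2_subsets <- list(
  B1 = c(1L, 2L, 3L, 4L, 5L, 6L, 7L),
  B2 = c(1L, 2L, 3L, 4L, 5L, 8L, 9L),
  B3 = c(1L, 2L, 3L, 10L, 11L, 12L),
  B4 = c(1L, 2L, 3L, 10L, 11L, 13L),
  B5 = c(4L, 5L, 10L, 12L, 13L),
  B6 = c(6L, 8L, 10L, 11L, 12L, 13L)
)

.psba_positions <- c(30L, 55L, 80L, 105L, 130L, 155L, 180L, 205L, 230L, 255L)
.psba_subsets <- list(
  B1 = c(1L, 2L, 3L, 4L),
  B2 = c(1L, 2L, 3L, 5L),
  B3 = c(1L, 2L, 6L, 7L),
  B4 = c(1L, 2L, 6L, 8L),
  B5 = c(3L, 6L, 9L),
  B6 = c(4L, 7L, 9L, 10L)
)

.lonicera_species <- c("Lonicera japonica", "Lonicera macranthoides",
                       "Lonicera fulvotomentosa", "Lonicera hypoglauca",
                       "Lonicera confusa", "Lonicera similis",
                       "Lonicera acuminata")

.subs_at <- function(idx, positions, base = "A") {
  data.frame(position = positions[idx], base = base,
             stringsAsFactors = FALSE)
}

#' Default ITS2 panel specification
#'
#' The 53-record ITS2 panel of the Flos Lonicerae Japonicae study: 32
#' \emph{L. japonica} individuals split into haplotypes A1 (4) and A2 (28,
#' of which 8 are public-database records), differing only by a C/T
#' transition at base 27, plus six congeneric species each carrying a
#' single haplotype (B1 x5, B2 x5, B3 x2, B4 x2, B5 x5, B6 x2). The
#' ancestor is 228 bp at GC 75.4%; substituted positions across all
#' haplotypes number exactly 14, and haplotype B6 (\emph{L. acuminata})
#' additionally carries a 1-bp insertion, so realized lengths are
#' 228-229 bp. All substitutions are transitions (ancestor C at base 27,
#' G at the 13 interspecific positions), which keeps small-distance
#' arithmetic exact.
#'
#' @param seed Master seed for ancestor realization.
#' @return A [panel_spec()].
#' @export
default_its2_spec <- function(seed = 20130549L) {
  pos <- .its2_positions
  japonica <- species_spec(.lonicera_species[1L], list(
    haplotype_spec("A1", 4L,
                   substitutions = data.frame(position = 27L, base = "T")),
    haplotype_spec("A2", 28L, genbank = 8L)
  ))
  counts <- c(B1 = 5L, B2 = 5L, B3 = 2L, B4 = 2L, B5 = 5L, B6 = 2L)
  others <- lapply(seq_along(.its2_subsets), function(i) {
    lab <- names(.its2_subsets)[i]
    indel <- if (lab == "B6") {
      list(position = 200L, kind = "insertion", length = 1L)
    }
    species_spec(.lonicera_species[i + 1L],
                 haplotype_spec(lab, counts[[lab]],
                                substitutions = .subs_at(.its2_subsets[[i]], pos),
                                indel = indel))
  })
  panel_spec("ITS2", ancestor_length = 228L, target_gc = 0.754,
             species = c(list(japonica), others),
             n_variable_sites = 14L, seed = seed)
}

#' Default psbA-trnH panel specification
#'
#' The 45-record psbA-trnH panel: 24 identical \emph{L. japonica}
#' sequences of exactly 339 bp (no within-species variation) and the six
#' congeners (5, 5, 2, 2, 5, 2 records), with 10 variable sites among all
#' taxa and per-haplotype indels sized so realized lengths span
#' 332-356 bp. Ancestor GC is 29.5%.
#'
#' @param seed Master seed for ancestor realization.
#' @return A [panel_spec()].
#' @export
default_psba_spec <- function(seed = 20130549L) {
  pos <- .psba_positions
  japonica <- species_spec(.lonicera_species[1L],
                           haplotype_spec("A", 24L))
  counts <- c(B1 = 5L, B2 = 5L, B3 = 2L, B4 = 2L, B5 = 5L, B6 = 2L)
  indels <- list(
    B1 = list(position = 280L, kind = "deletion", length = 7L),   # 332 bp
    B2 = list(position = 290L, kind = "deletion", length = 3L),   # 336 bp
    B3 = list(position = 300L, kind = "insertion", length = 5L),  # 344 bp
    B4 = list(position = 310L, kind = "deletion", length = 1L),   # 338 bp
    B5 = list(position = 270L, kind = "insertion", length = 10L), # 349 bp
    B6 = list(position = 320L, kind = "insertion", length = 17L)  # 356 bp
  )
  others <- lapply(seq_along(.psba_subsets), function(i) {
    lab <- names(.psba_subsets)[i]
    species_spec(.lonicera_species[i + 1L],
                 haplotype_spec(lab, counts[[lab]],
                                substitutions = .subs_at(.psba_subsets[[i]], pos),
                                indel = indels[[lab]]))
  })
  panel_spec("psbA-trnH", ancestor_length = 339L, target_gc = 0.295,
             species = c(list(japonica), others),
             n_variable_sites = 10L, seed = seed)
}

# Ancestor bases the default specs require at edited positions so every
# substitution is a transition: C at the ITS2 C/T site, G elsewhere.
.forced_ancestor_bases <- function(spec) {
  pos <- integer(0L); base <- character(0L)
  for (sp in spec$species) {
    for (h in sp$haplotypes) {
      s <- h$substitutions
      if (is.null(s)) next
      pos <- c(pos, s$position)
      base <- c(base, vapply(s$base, .transition_partner, character(1L)))
    }
  }
  keep <- !duplicated(pos)
  list(position = pos[keep], base = base[keep])
}

.transition_partner <- function(b) {
  switch(b, A = "G", G = "A", C = "T", T = "C",
         stop("no transition partner for '", b, "'"))
}
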