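# Lazily built, cached fixtures shared across test files. Everything is
# generated in code from the default specs; nothing is read from disk.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

its2_panel <- function() cached("its2_panel", function() {
  realize_panel(default_its2_spec())
})

its2_msa <- function() cached("its2_msa", function() build_msa(its2_panel()))

its2_dm <- function() cached("its2_dm", function() {
  distance_matrix(its2_msa())
})

psba_panel <- function() cached("psba_panel", function() {
  realize_panel(default_psba_spec())
})

psba_msa <- function() cached("psba_msa", function() build_msa(psba_panel()))

psba_dm <- function() cached("psba_dm", function() {
  distance_matrix(psba_msa())
})

species_labels <- function(panel) {
  stats::setNames(panel$records$species, panel$records$id)
}

JAPONICA <- "Lonicera japonica"

japonica_ids <- function(panel) {
  panel$records$id[panel$records$species == JAPONICA]
}

# small hand-made panel: species, haplotype sequences, copy counts
toy_panel <- function(species, haplotype, sequence, count) {
  rows <- do.call(rbind, lapply(seq_along(species), function(i) {
    data.frame(
      id = sprintf("%s-%s-%02d", gsub(" ", "", species[i]), haplotype[i],
                   seq_len(count[i])),
      species = species[i], locus = "ITS2", haplotype = haplotype[i],
      voucher = NA_character_, locality = "synthetic", source = "study",
      sequence = sequence[i], stringsAsFactors = FALSE
    )
  }))
  rownames(rows) <- NULL
  structure(list(locus = "ITS2", records = rows, ancestor = NULL,
                 spec = NULL), class = "barcode_panel")
}

# independent slow scorer for a gapped pair under the affine scheme:
# used as oracle against Biostrings-backed alignment scores
score_gapped_pair <- function(a, b, scoring = align_scoring()) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  stopifnot(length(ca) == length(cb))
  keep <- !(ca == "-" & cb == "-")
  ca <- ca[keep]; cb <- cb[keep]
  s <- 0
  in_gap_a <- FALSE; in_gap_b <- FALSE
  for (j in seq_along(ca)) {
    if (ca[j] == "-") {
      s <- s + scoring$gap_extend + if (!in_gap_a) scoring$gap_open else 0
      in_gap_a <- TRUE; in_gap_b <- FALSE
    } else if (cb[j] == "-") {
      s <- s + scoring$gap_extend + if (!in_gap_b) scoring$gap_open else 0
      in_gap_b <- TRUE; in_gap_a <- FALSE
    } else {
      s <- s + if (ca[j] == cb[j]) scoring$match else scoring$mismatch
      in_gap_a <- FALSE; in_gap_b <- FALSE
    }
  }
  s
}

# random A/C/G/T string helper for property-style tests
random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
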