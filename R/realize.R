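# Run an expression under a local RNG seed, restoring the caller's RNG
# state afterwards so panel realization never perturbs user code.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate a random ancestor sequence with exact GC composition
#'
#' Draws a uniformly shuffled nucleotide string whose G+C count is exactly
#' `round(gc * length)`; G vs C (and A vs T) are assigned uniformly at
#' random. Deterministic for a fixed seed.
#'
#' @param length Sequence length in bp (> 0).
#' @param gc Target GC fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @return A single uppercase A/C/G/T string.
#' @examples
#' generate_ancestor(228, 0.754, seed = 1)
#' @export
generate_ancestor <- function(length, gc, seed = 1L) {
  length <- as.integer(length)
  if (is.na(length) || length <= 0L) stop("length must be a positive integer")
  if (!is.numeric(gc) || length(gc) != 1L || is.na(gc) || gc < 0 || gc > 1) {
    stop("gc must be a fraction in [0, 1]")
  }
  n_gc <- round(gc * length)
  with_seed(seed, {
    strong <- sample(c("G", "C"), n_gc, replace = TRUE)
    weak <- sample(c("A", "T"), length - n_gc, replace = TRUE)
    paste(sample(c(strong, weak)), collapse = "")
  })
}

# Force specific bases at specific positions by swapping with a donor
# position elsewhere in the sequence, so base composition (hence GC) is
# preserved exactly. Donors are scanned left to right, skipping all forced
# positions; deterministic.
force_bases <- function(chars, positions, bases) {
  stopifnot(length(positions) == length(bases))
  protected <- positions
  for (k in seq_along(positions)) {
    p <- positions[k]; b <- bases[k]
    if (chars[p] == b) next
    donors <- which(chars == b)
    donors <- donors[!donors %in% protected]
    if (!length(donors)) {
      stop("cannot force base '", b, "' at position ", p,
           ": no donor position available")
    }
    d <- donors[1L]
    tmp <- chars[p]; chars[p] <- chars[d]; chars[d] <- tmp
  }
  chars
}

.species_code <- function(name) {
  gsub("[^A-Za-z0-9]", "", sub("^(\\w)\\w* ", "\\1", name))
}

#' Realize a panel specification into sequences
#'
#' Builds the ancestor with [generate_ancestor()], pins the ancestor base
#' at every substituted position to the transition partner of the target
#' base (composition-preserving swaps, so GC stays exact), then applies
#' each haplotype's substitutions and indel. Every individual carrying a
#' haplotype receives the identical sequence. Realization is fully
#' deterministic given the spec (which carries the master seed): the
#' ancestor uses the master seed and indel fill bases use master seed + 1.
#'
#' @param spec A [panel_spec()].
#' @return An object of class `barcode_panel`: a list with elements
#'   `locus`, `records` (data.frame with columns `id`, `species`, `locus`,
#'   `haplotype`, `voucher`, `locality`, `source`, `sequence`), `ancestor`
#'   and `spec`. Record ids follow `locus-species-haplotype-index`.
#' @examples
#' panel <- realize_panel(default_its2_spec())
#' nrow(panel$records)  # 53
#' @export
realize_panel <- function(spec) {
  if (!inherits(spec, "panel_spec")) stop("spec must be a panel_spec")
  anc <- generate_ancestor(spec$ancestor_length, spec$target_gc, spec$seed)
  chars <- strsplit(anc, "")[[1L]]
  forced <- .forced_ancestor_bases(spec)
  if (length(forced$position)) {
    chars <- force_bases(chars, forced$position, forced$base)
  }
  ancestor <- paste(chars, collapse = "")

  rows <- list()
  voucher_no <- 0L
  with_seed(spec$seed + 1L, {
    for (sp in spec$species) {
      code <- .species_code(sp$name)
      for (h in sp$haplotypes) {
        seq_chars <- chars
        if (!is.null(h$substitutions)) {
          s <- h$substitutions
          if (any(s$position > length(seq_chars))) {
            stop("haplotype '", h$label, "': edit position out of range")
          }
          same <- seq_chars[s$position] == s$base
          if (any(same)) {
            stop("haplotype '", h$label, "': substitution at position ",
                 s$position[same][1L], " equals the ancestor base")
          }
          seq_chars[s$position] <- s$base
        }
        if (!is.null(h$indel)) {
          id <- h$indel
          if (id$kind == "deletion") {
            seq_chars <- seq_chars[-(id$position:(id$position + id$length - 1L))]
          } else {
            gc_n <- round(spec$target_gc * id$length)
            fill <- sample(c(sample(c("G", "C"), gc_n, replace = TRUE),
                             sample(c("A", "T"), id$length - gc_n,
                                    replace = TRUE)))
            seq_chars <- append(seq_chars, fill, after = id$position)
          }
        }
        seq_str <- paste(seq_chars, collapse = "")
        for (i in seq_len(h$count)) {
          from_genbank <- i > h$count - h$genbank
          if (!from_genbank) voucher_no <- voucher_no + 1L
          rows[[length(rows) + 1L]] <- data.frame(
            id = sprintf("%s-%s-%s-%02d", gsub("-", "", spec$locus),
                         code, h$label, i),
            species = sp$name,
            locus = spec$locus,
            haplotype = h$label,
            voucher = if (from_genbank) NA_character_ else
              sprintf("SYN-%s-%03d", gsub("-", "", spec$locus), voucher_no),
            locality = if (from_genbank) "GenBank" else "synthetic",
            source = if (from_genbank) "genbank" else "study",
            sequence = seq_str,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  })
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  if (anyDuplicated(records$id)) stop("internal error: duplicate record ids")
  structure(list(locus = spec$locus, records = records,
                 ancestor = ancestor, spec = spec),
            class = "barcode_panel")
}

#' @export
print.barcode_panel <- function(x, ...) {
  r <- x$records
  cat("Barcode panel:", x$locus, "-", nrow(r), "records,",
      length(unique(r$species)), "species,",
      length(unique(paste(r$species, r$haplotype))), "haplotypes\n")
  cat("  lengths:", paste(range(nchar(r$sequence)), collapse = "-"), "bp\n")
  tab <- table(r$species)
  for (s in names(tab)) cat(sprintf("  %-26s %d\n", s, tab[[s]]))
  invisible(x)
}

#' Write a panel to FASTA plus metadata TSV
#'
#' @param panel A `barcode_panel`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths of the two files written
#'   (`<locus>.fasta`, `<locus>_metadata.tsv`).
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "barcode_panel"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- gsub("-", "", panel$locus)
  fasta <- file.path(dir, paste0(stem, ".fasta"))
  meta <- file.path(dir, paste0(stem, "_metadata.tsv"))
  seqs <- panel$records$sequence
  names(seqs) <- panel$records$id
  write_fasta(seqs, fasta)
  cols <- c("id", "species", "locus", "haplotype", "voucher", "locality")
  write.table(panel$records[, cols], meta, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fasta = fasta, metadata = meta))
}
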