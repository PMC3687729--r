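.iupac_dna <- c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K",
                "V", "H", "D", "B", "N")

#' Read a FASTA file of barcode sequences
#'
#' Sequences are uppercased and validated: ids must be unique and
#' nonempty, sequences nonempty, and the alphabet restricted to IUPAC DNA
#' codes. Line wrapping is ignored.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector (names are record ids, in file order).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("FASTA record with empty id in ", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  }
  empty <- ids[!nzchar(seqs)]
  if (length(empty)) {
    stop("empty sequence for record(s): ", paste(empty, collapse = ", "))
  }
  for (i in seq_along(seqs)) {
    bad <- setdiff(unique(strsplit(seqs[[i]], "")[[1L]]), .iupac_dna)
    if (length(bad)) {
      stop("record '", ids[i], "': non-IUPAC character(s) ",
           paste(bad, collapse = ", "))
    }
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

.meta_columns <- c("id", "species", "locus", "haplotype", "voucher",
                   "locality")

#' Read a sample-metadata table
#'
#' Expects a TSV with header columns `id`, `species`, `locus`,
#' `haplotype`, `voucher`, `locality` (one row per sequence record,
#' mirroring the study's voucher table).
#'
#' @param path Path to the TSV.
#' @return A data.frame keyed by `id`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- read.delim(path, stringsAsFactors = FALSE,
                     colClasses = "character", na.strings = "NA")
  missing <- setdiff(.meta_columns, names(meta))
  if (length(missing)) {
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(meta$id)) {
    stop("duplicate metadata id(s): ",
         paste(unique(meta$id[duplicated(meta$id)]), collapse = ", "))
  }
  blank <- meta$id[is.na(meta$species) | !nzchar(meta$species)]
  if (length(blank)) {
    stop("empty species label for id(s): ", paste(blank, collapse = ", "))
  }
  meta
}

#' Join FASTA sequences with their metadata into a panel
#'
#' The join must be total and unique: every FASTA id appears in exactly
#' one metadata row and vice versa.
#'
#' @param fasta Path to a FASTA file (or a named character vector as from
#'   [read_fasta()]).
#' @param metadata Path to a metadata TSV (or a data.frame as from
#'   [read_metadata()]).
#' @return A `barcode_panel` (without ancestor/spec provenance).
#' @export
read_panel <- function(fasta, metadata) {
  seqs <- if (is.character(fasta) && length(fasta) == 1L &&
              is.null(names(fasta))) read_fasta(fasta) else fasta
  meta <- if (is.character(metadata)) read_metadata(metadata) else metadata
  only_fasta <- setdiff(names(seqs), meta$id)
  only_meta <- setdiff(meta$id, names(seqs))
  if (length(only_fasta) || length(only_meta)) {
    stop("FASTA/metadata id mismatch",
         if (length(only_fasta)) paste0("; FASTA only: ",
                                        paste(only_fasta, collapse = ", ")),
         if (length(only_meta)) paste0("; metadata only: ",
                                       paste(only_meta, collapse = ", ")))
  }
  meta <- meta[match(names(seqs), meta$id), , drop = FALSE]
  records <- data.frame(
    id = meta$id, species = meta$species, locus = meta$locus,
    haplotype = meta$haplotype, voucher = meta$voucher,
    locality = meta$locality,
    source = if ("source" %in% names(meta)) meta$source else "study",
    sequence = unname(seqs), stringsAsFactors = FALSE
  )
  rownames(records) <- NULL
  locus <- unique(records$locus)
  structure(list(locus = if (length(locus) == 1L) locus else locus,
                 records = records, ancestor = NULL, spec = NULL),
            class = "barcode_panel")
}

#' Write the sequence-characteristics and divergence reports
#'
#' Emits two TSVs mirroring the study's summary tables: sequence
#' characteristics (length ranges, GC content to one decimal percent,
#' variable-site and indel counts) and the six divergence metrics with
#' spreads plus identification efficiency, numeric cells rounded to four
#' decimals.
#'
#' @param characteristics Data.frame from [sequence_characteristics()].
#' @param metrics A `divergence_summary` from [six_metrics()].
#' @param efficiency Identification efficiency fraction in `[0, 1]`
#'   (or `NA` to omit the row).
#' @param dir Output directory.
#' @return Invisibly, the paths written (`characteristics.tsv`,
#'   `divergence.tsv`).
#' @export
write_report <- function(characteristics, metrics, efficiency = NA, dir) {
  if (is.null(characteristics) || !nrow(characteristics)) {
    stop("empty characteristics table; refusing to write an empty report")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "characteristics.tsv")
  write.table(characteristics, p1, sep = "\t", quote = FALSE,
              row.names = FALSE)
  stopifnot(inherits(metrics, "divergence_summary"))
  tab <- data.frame(
    parameter = metrics$metric,
    value = sprintf("%.4f ± %.4f", metrics$mean, metrics$sd),
    stringsAsFactors = FALSE
  )
  if (!is.na(efficiency)) {
    tab <- rbind(tab, data.frame(
      parameter = "Identification efficiency (BLAST1)",
      value = sprintf("%.0f%%", 100 * efficiency)))
  }
  p2 <- file.path(dir, "divergence.tsv")
  write.table(tab, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(characteristics = p1, divergence = p2))
}
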