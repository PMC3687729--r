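.pairs_within <- function(ids) {
  n <- length(ids)
  if (n < 2L) return(matrix(character(0L), ncol = 2L))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  cbind(ids[idx[, 1L]], ids[idx[, 2L]])
}

#' Intraspecific distances of a focal species
#'
#' All pairwise distances among the focal species' records
#' (`choose(n, 2)` values).
#'
#' @param dm A `k2p_dm` with species labels.
#' @param focal Focal species label.
#' @return Numeric vector of distances.
#' @export
intra_distances <- function(dm, focal) {
  stopifnot(inherits(dm, "k2p_dm"), !is.null(dm$species))
  ids <- names(dm$species)[dm$species == focal]
  if (!length(ids)) stop("species '", focal, "' absent from matrix")
  if (length(ids) < 2L) {
    stop("species '", focal, "' has a single record; intraspecific ",
         "distance undefined")
  }
  p <- .pairs_within(ids)
  dm$d[cbind(p[, 1L], p[, 2L])]
}

#' Interspecific distances
#'
#' In `"focal"` mode (default), all distances between the focal species'
#' records and every heterospecific record; in `"global"` mode, all
#' heterospecific pairs over the whole panel.
#'
#' @param dm A `k2p_dm` with species labels.
#' @param focal Focal species label (ignored in global mode).
#' @param mode `"focal"` or `"global"`.
#' @return Numeric vector of distances.
#' @export
inter_distances <- function(dm, focal = NULL, mode = c("focal", "global")) {
  stopifnot(inherits(dm, "k2p_dm"), !is.null(dm$species))
  mode <- match.arg(mode)
  sp <- dm$species
  if (length(unique(sp)) < 2L) stop("need at least 2 species")
  if (mode == "focal") {
    if (is.null(focal)) stop("focal species required in focal mode")
    if (!focal %in% sp) stop("species '", focal, "' absent from matrix")
    foc <- names(sp)[sp == focal]
    het <- names(sp)[sp != focal]
    as.vector(dm$d[foc, het, drop = FALSE])
  } else {
    idx <- which(upper.tri(dm$d), arr.ind = TRUE)
    keep <- sp[idx[, 1L]] != sp[idx[, 2L]]
    dm$d[idx[keep, , drop = FALSE]]
  }
}

#' The six divergence metrics of a barcode panel
#'
#' Computes the standard intra/interspecific divergence summary used in
#' barcoding-gap studies:
#' \describe{
#'   \item{all intraspecific distance}{mean +/- SD over all conspecific
#'     pairs of the focal species (or of all species in global mode).}
#'   \item{theta}{mean over species (with >= 2 records) of the
#'     per-species mean intraspecific distance.}
#'   \item{coalescent depth}{mean over species (with >= 2 records) of the
#'     per-species maximum intraspecific distance.}
#'   \item{all interspecific distance}{mean +/- SD over focal-vs-other
#'     pairs (or all heterospecific pairs in global mode).}
#'   \item{theta prime}{mean over heterospecific species pairs of the
#'     pair's mean between-species distance.}
#'   \item{minimum interspecific distance}{mean +/- SD over species of
#'     each species' minimum distance to any heterospecific record.}
#' }
#' Spreads are sample standard deviations of the listed values. Species
#' with a single record are excluded from theta and coalescent depth with
#' a warning.
#'
#' @param dm A `k2p_dm` with species labels.
#' @param focal Focal species label; defaults to the most-sampled species.
#' @param convention `"focal"` (default) or `"global"` for the two
#'   all-intra / all-inter rows.
#' @return A data.frame of class `divergence_summary` with columns
#'   `metric`, `mean`, `sd`, and attributes `focal` and `convention`.
#' @export
six_metrics <- function(dm, focal = NULL,
                        convention = c("focal", "global")) {
  stopifnot(inherits(dm, "k2p_dm"), !is.null(dm$species))
  convention <- match.arg(convention)
  sp <- dm$species
  species <- unique(sp)
  if (length(species) < 2L) stop("need at least 2 species")
  counts <- table(sp)
  multi <- names(counts)[counts >= 2L]
  if (!length(multi)) stop("no species with >= 2 records")
  if (length(multi) < length(species)) {
    warning("species with a single record excluded from theta and ",
            "coalescent depth: ",
            paste(setdiff(species, multi), collapse = ", "))
  }
  if (is.null(focal)) focal <- names(counts)[which.max(counts)]

  per_sp_intra <- lapply(multi, function(s) intra_distances(dm, s))
  names(per_sp_intra) <- multi

  all_intra <- if (convention == "focal") intra_distances(dm, focal)
               else unlist(per_sp_intra, use.names = FALSE)
  all_inter <- inter_distances(dm, focal, mode = convention)

  theta_vals <- vapply(per_sp_intra, mean, numeric(1L))
  depth_vals <- vapply(per_sp_intra, max, numeric(1L))

  pair_means <- utils::combn(species, 2L, function(pr) {
    mean(dm$d[names(sp)[sp == pr[1L]], names(sp)[sp == pr[2L]]])
  })

  min_vals <- vapply(species, function(s) {
    min(dm$d[names(sp)[sp == s], names(sp)[sp != s]])
  }, numeric(1L))

  ms <- function(x) c(mean(x), if (length(x) > 1L) stats::sd(x) else 0)
  tab <- rbind(
    `All inter-specific distance` = ms(all_inter),
    `Theta prime` = ms(pair_means),
    `The minimum inter-specific distance` = ms(min_vals),
    `All intra-specific distance` = ms(all_intra),
    `Theta` = ms(theta_vals),
    `Coalescent depth` = ms(depth_vals)
  )
  out <- data.frame(metric = rownames(tab), mean = tab[, 1L],
                    sd = tab[, 2L], row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "focal") <- focal
  attr(out, "convention") <- convention
  class(out) <- c("divergence_summary", "data.frame")
  out
}

#' @export
print.divergence_summary <- function(x, ...) {
  cat("Divergence summary (focal:", attr(x, "focal"),
      "| convention:", attr(x, "convention"), ")\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-38s %.4f ± %.4f\n", x$metric[i], x$mean[i],
                x$sd[i]))
  }
  invisible(x)
}

#' Barcoding-gap histogram
#'
#' Bins all conspecific and all heterospecific pairwise distances into
#' half-open classes `[k*w, (k+1)*w)` of width `w` (default 0.010
#' distance units).
#'
#' @param dm A `k2p_dm` with species labels.
#' @param bin_width Positive bin width.
#' @return Object of class `gap_histogram`: data.frame with `bin_start`,
#'   `bin_end`, `intra_count`, `inter_count`.
#' @export
gap_histogram <- function(dm, bin_width = 0.010) {
  stopifnot(inherits(dm, "k2p_dm"), !is.null(dm$species))
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop("bin_width must be positive")
  }
  sp <- dm$species
  counts <- table(sp)
  multi <- names(counts)[counts >= 2L]
  if (!length(multi)) stop("no conspecific pairs to bin")
  intra <- unlist(lapply(multi, function(s) intra_distances(dm, s)),
                  use.names = FALSE)
  inter <- inter_distances(dm, mode = "global")
  if (!length(inter)) stop("no heterospecific pairs to bin")
  n_bins <- max(floor(c(intra, inter) / bin_width)) + 1L
  bins <- seq_len(n_bins) - 1L
  tab <- function(x) {
    tabulate(floor(x / bin_width) + 1L, nbins = n_bins)
  }
  out <- data.frame(bin_start = bins * bin_width,
                    bin_end = (bins + 1L) * bin_width,
                    intra_count = tab(intra), inter_count = tab(inter))
  stopifnot(sum(out$intra_count) == length(intra),
            sum(out$inter_count) == length(inter))
  class(out) <- c("gap_histogram", "data.frame")
  out
}

#' Does a barcoding gap exist?
#'
#' TRUE when the smallest heterospecific distance exceeds the largest
#' conspecific distance over the whole panel.
#'
#' @param dm A `k2p_dm` with species labels.
#' @return List with `gap` (logical), `max_intra`, `min_inter`.
#' @export
gap_exists <- function(dm) {
  stopifnot(inherits(dm, "k2p_dm"), !is.null(dm$species))
  sp <- dm$species
  counts <- table(sp)
  multi <- names(counts)[counts >= 2L]
  if (!length(multi)) stop("no conspecific pairs")
  intra <- unlist(lapply(multi, function(s) intra_distances(dm, s)),
                  use.names = FALSE)
  inter <- inter_distances(dm, mode = "global")
  if (!length(inter)) stop("no heterospecific pairs")
  list(gap = min(inter) > max(intra),
       max_intra = max(intra), min_inter = min(inter))
}
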