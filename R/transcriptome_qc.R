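# Post-assembly quality filters: the sporadic-vs-clustered error-correction
# filter (corrections packed into one k-mer window are suspected artifacts of
# iterating a k-spectrum corrector to exhaustion and are rejected), removal
# of contigs whose predicted protein sets are redundant, and the conservative
# expression noise filter.

#' Distribution of neighboring errors within a k-mer window
#'
#' Reads are grouped by their total number of identified errors. Within each
#' group, every error at position \eqn{p} is scored by how many other errors
#' \eqn{q} on the same read fall within the same k-mer window
#' (\eqn{|q - p| < window}), and the counts are tabulated.
#'
#' @param records Data.frame of error records with columns \code{read} and
#'   \code{position} (0-based within the read), one row per identified error.
#' @param window k-mer window size (default 13).
#' @return An integer matrix: rows are total-error groups, columns neighbor
#'   counts \code{0 .. window - 1}. Empty input gives a 0-row matrix.
#' @export
neighbor_distribution <- function(records, window = 13) {
  stopifnot(window >= 2)
  out_cols <- as.character(0:(window - 1L))
  if (nrow(records) == 0L) {
    return(matrix(0L, nrow = 0L, ncol = window,
                  dimnames = list(NULL, out_cols)))
  }
  ann <- annotate_neighbors(records, window)
  tab <- table(factor(ann$group), factor(ann$neighbors, levels = 0:(window - 1L)))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), out_cols))
  m[order(as.integer(rownames(m))), , drop = FALSE]
}

# per-error neighbor counts and total-error group sizes
annotate_neighbors <- function(records, window) {
  by_read <- split(records$position, records$read)
  res <- lapply(by_read, function(pos) {
    if (is.unsorted(pos, strictly = TRUE)) {
      if (anyDuplicated(pos)) stop("duplicate error positions within a read",
                                   call. = FALSE)
      pos <- sort(pos)
    }
    nb <- vapply(pos, function(p) sum(abs(pos - p) < window) - 1L, 1L)
    data.frame(position = pos, group = length(pos), neighbors = nb)
  })
  reads <- rep(names(by_read), vapply(res, nrow, 1L))
  out <- do.call(rbind, res)
  out$read <- reads
  rownames(out) <- NULL
  out[, c("read", "position", "group", "neighbors")]
}

#' Maximum allowable neighboring errors from a count distribution
#'
#' The cutoff is the neighbor count just before the distribution's secondary
#' increase: with counts indexed from 0 neighbors, the first index \eqn{i \ge
#' 1} with \code{counts[i] > counts[i - 1]} yields cutoff \eqn{i - 1}. If the
#' counts never increase there is no clustered regime and the last index is
#' returned.
#'
#' @param counts Numeric vector of error counts, element 1 corresponding to 0
#'   neighbors.
#' @return Integer cutoff (number of allowed neighbors).
#' @export
select_max_neighbors <- function(counts) {
  if (length(counts) == 0L) stop("counts must be non-empty", call. = FALSE)
  inc <- which(diff(counts) > 0)
  if (length(inc) == 0L) return(length(counts) - 1L)
  inc[1L] - 1L
}

#' Per-group neighbor cutoffs from a neighbor distribution
#'
#' Applies [select_max_neighbors()] to each total-error group of a
#' [neighbor_distribution()] matrix. Counts are truncated to the structurally
#' possible range (a read with g errors has at most g - 1 neighbors per
#' error).
#'
#' @param dist Matrix from [neighbor_distribution()].
#' @param window k-mer window size used to build the distribution.
#' @return Named integer vector of cutoffs, one per total-error group.
#' @export
group_cutoffs <- function(dist, window = 13) {
  groups <- as.integer(rownames(dist))
  cutoffs <- vapply(seq_along(groups), function(i) {
    upto <- min(groups[i], window)
    select_max_neighbors(dist[i, seq_len(upto)])
  }, 1L)
  stats::setNames(cutoffs, rownames(dist))
}

#' Accept or reject identified errors by their neighbor counts
#'
#' An error is accepted (corrected) when its neighbor count does not exceed
#' the cutoff of its read's total-error group.
#'
#' @inheritParams neighbor_distribution
#' @param cutoffs Named numeric vector: total-error group to maximum allowed
#'   neighbors (e.g. from [select_max_neighbors()] per group). Every observed
#'   group must have a cutoff.
#' @return The records annotated with \code{group}, \code{neighbors} and
#'   logical \code{accepted}.
#' @export
apply_error_filter <- function(records, cutoffs, window = 13) {
  if (nrow(records) == 0L) {
    return(cbind(records, group = integer(0), neighbors = integer(0),
                 accepted = logical(0)))
  }
  ann <- annotate_neighbors(records, window)
  have <- as.character(ann$group) %in% names(cutoffs)
  if (!all(have)) {
    stop("no cutoff for total-error group(s): ",
         paste(unique(ann$group[!have]), collapse = ", "), call. = FALSE)
  }
  ann$accepted <- ann$neighbors <= unname(cutoffs[as.character(ann$group)])
  ann
}

#' Remove contigs with redundant predicted protein sets
#'
#' A contig is dropped when its set of predicted proteins is a subset of (or
#' equal to) another retained contig's set; among contigs with identical
#' sets, the lexicographically smallest id is retained. The retained sets are
#' subset-free and the operation is idempotent.
#'
#' @param protein_sets Named list: contig id to character vector of predicted
#'   protein sequences (or their identifiers).
#' @return Character vector of retained contig ids.
#' @export
dedupe_predicted_proteins <- function(protein_sets) {
  if (length(protein_sets) == 0L) return(character(0))
  sets <- lapply(protein_sets, unique)
  ids <- names(sets)
  ord <- order(-lengths(sets), ids)
  retained_ids <- character(0)
  retained_sets <- list()
  for (i in ord) {
    s <- sets[[i]]
    absorbed <- any(vapply(retained_sets, function(r) all(s %in% r), TRUE))
    if (!absorbed) {
      retained_ids <- c(retained_ids, ids[i])
      retained_sets[[length(retained_sets) + 1L]] <- s
    }
  }
  sort(retained_ids)
}

#' Discard contigs below the expression noise threshold
#'
#' Contigs with FPKM below the threshold are treated as expression noise and
#' discarded; the boundary value itself is retained.
#'
#' @param fpkm Named numeric vector of FPKM values (contig ids as names).
#' @param threshold Noise threshold (default 0.01).
#' @return Character vector of retained contig ids.
#' @export
fpkm_noise_filter <- function(fpkm, threshold = 0.01) {
  if (any(fpkm < 0)) stop("FPKM values must be non-negative", call. = FALSE)
  names(fpkm)[fpkm >= threshold]
}

#' Read an eXpress-style FPKM table
#'
#' Accepts a TSV with \code{target_id} and \code{fpkm} columns (any other
#' columns are ignored) or a headerless two-column file.
#'
#' @param path Path to the table.
#' @return Named numeric vector of FPKM values.
#' @export
read_fpkm <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (all(c("target_id", "fpkm") %in% names(x))) {
    stats::setNames(as.numeric(x$fpkm), x$target_id)
  } else {
    stats::setNames(as.numeric(x[[2L]]), as.character(x[[1L]]))
  }
}
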