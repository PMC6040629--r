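# Cross-contamination filtering for co-multiplexed transcriptome assemblies.
# Near-identical contigs shared between two species are flagged as
# cross-contaminated, and the source species is resolved by the ratio of
# reads mapping to each copy: a contig is kept when it attracts at least ten
# times as many reads as its partner, or unconditionally when it has at least
# 10,000 reads mapping (highly expressed conserved genes legitimately match
# across species at read ratios near one).

#' Convert species-prefixed hits to contig match records
#'
#' Reinterprets a BLAST tabular table whose ids follow
#' \code{"species|contig"} as cross-species contig matches. Within-species
#' matches are dropped.
#'
#' @param hits A hit table from [read_blast_tab()].
#' @return A data.frame with columns \code{species_a}, \code{contig_a},
#'   \code{species_b}, \code{contig_b}, \code{percent_identity},
#'   \code{match_length}.
#' @export
as_contig_matches <- function(hits) {
  qs <- split_protein_ids(hits$query, "contig id")
  ss <- split_protein_ids(hits$subject, "contig id")
  keep <- qs$species != ss$species
  data.frame(species_a = qs$species[keep], contig_a = qs$protein[keep],
             species_b = ss$species[keep], contig_b = ss$protein[keep],
             percent_identity = hits$pident[keep],
             match_length = hits$length[keep], stringsAsFactors = FALSE)
}

#' Flag contig pairs as cross-contaminated
#'
#' A cross-species match is flagged when it reaches both the identity and
#' length thresholds (both inclusive).
#'
#' @param matches Data.frame of contig matches (see [as_contig_matches()]).
#' @param min_identity Minimum percent identity (default 96).
#' @param min_length Minimum match length in bases (default 90).
#' @return The flagged subset of \code{matches}.
#' @export
flag_contaminant_pairs <- function(matches, min_identity = 96, min_length = 90) {
  stopifnot(all(c("species_a", "contig_a", "species_b", "contig_b",
                  "percent_identity", "match_length") %in% names(matches)))
  if (any(matches$species_a == matches$species_b)) {
    stop("contig matches must involve two distinct species", call. = FALSE)
  }
  matches[matches$percent_identity >= min_identity &
            matches$match_length >= min_length, , drop = FALSE]
}

read_count_lookup <- function(reads) {
  stats::setNames(reads$count, paste(reads$species, reads$contig, sep = "\r"))
}

#' Resolve the source species of flagged contig pairs
#'
#' For every flagged pair, each contig is kept when its mapped-read count is
#' at least \code{ratio} times its partner's, or at least \code{floor}
#' regardless of ratio; otherwise it is discarded. Both contigs may be kept
#' (floor exception) and both may be discarded.
#'
#' @param flagged Flagged pairs from [flag_contaminant_pairs()].
#' @param reads Read-count table: data.frame with \code{species},
#'   \code{contig}, \code{count} (see [read_read_counts()]).
#' @param ratio Required read-mapping ratio (default 10).
#' @param floor Read count above which a contig is always kept
#'   (default 10,000).
#' @return A data.frame with one row per contig side of each pair: columns
#'   \code{species}, \code{contig}, \code{partner_species},
#'   \code{partner_contig}, \code{keep}, \code{reason} (one of
#'   \code{ratio-win}, \code{ratio-loss}, \code{floor-exception},
#'   \code{both-discarded}).
#' @export
resolve_sources <- function(flagged, reads, ratio = 10, floor = 10000) {
  lut <- read_count_lookup(reads)
  ka <- paste(flagged$species_a, flagged$contig_a, sep = "\r")
  kb <- paste(flagged$species_b, flagged$contig_b, sep = "\r")
  ca <- unname(lut[ka]); cb <- unname(lut[kb])
  if (anyNA(ca) || anyNA(cb)) {
    bad <- c(ka[is.na(ca)], kb[is.na(cb)])
    stop("missing read counts for flagged contigs: ",
         paste(gsub("\r", "|", utils::head(bad, 5L)), collapse = ", "),
         call. = FALSE)
  }
  decide <- function(mine, partner) {
    keep <- mine >= ratio * partner | mine >= floor
    reason <- ifelse(mine >= ratio * partner, "ratio-win",
                     ifelse(mine >= floor, "floor-exception", "ratio-loss"))
    list(keep = keep, reason = reason)
  }
  a <- decide(ca, cb); b <- decide(cb, ca)
  both_lost <- !a$keep & !b$keep
  a$reason[both_lost] <- "both-discarded"
  b$reason[both_lost] <- "both-discarded"
  data.frame(
    species = c(flagged$species_a, flagged$species_b),
    contig = c(flagged$contig_a, flagged$contig_b),
    partner_species = c(flagged$species_b, flagged$species_a),
    partner_contig = c(flagged$contig_b, flagged$contig_a),
    keep = c(a$keep, b$keep),
    reason = c(a$reason, b$reason),
    stringsAsFactors = FALSE
  )
}

#' Collapse per-pair decisions to one decision per contig
#'
#' A contig flagged against several partners can receive conflicting
#' decisions; a discard from any pair wins (conservative).
#'
#' @param decisions Data.frame from [resolve_sources()].
#' @return A data.frame with one row per flagged contig: \code{species},
#'   \code{contig}, \code{keep}, \code{reason}.
#' @export
contig_decisions <- function(decisions) {
  key <- paste(decisions$species, decisions$contig, sep = "\r")
  keep <- tapply(decisions$keep, key, all)
  reason <- vapply(names(keep), function(k) {
    rows <- decisions[key == k, ]
    if (all(rows$keep)) rows$reason[1L] else rows$reason[!rows$keep][1L]
  }, "")
  parts <- strsplit(names(keep), "\r", fixed = TRUE)
  data.frame(species = vapply(parts, `[[`, "", 1L),
             contig = vapply(parts, `[[`, "", 2L),
             keep = unname(keep), reason = unname(reason),
             stringsAsFactors = FALSE)
}

#' Remove discarded contigs and summarise per-species removal
#'
#' @param contig_sets Named list: species to character vector of contig ids.
#' @param decisions Per-pair decisions from [resolve_sources()] (collapsed
#'   internally with [contig_decisions()]).
#' @return A list with \code{cleaned} (the filtered contig sets) and
#'   \code{summary} (data.frame: species, n_contigs, n_removed,
#'   removal_frac).
#' @export
apply_decontamination <- function(contig_sets, decisions) {
  per_contig <- if (nrow(decisions) > 0L) contig_decisions(decisions) else
    data.frame(species = character(), contig = character(), keep = logical(),
               reason = character(), stringsAsFactors = FALSE)
  drop_key <- paste(per_contig$species[!per_contig$keep],
                    per_contig$contig[!per_contig$keep], sep = "\r")
  cleaned <- contig_sets
  n_removed <- integer(length(contig_sets))
  names(n_removed) <- names(contig_sets)
  for (sp in names(contig_sets)) {
    keys <- paste(sp, contig_sets[[sp]], sep = "\r")
    drop <- keys %in% drop_key
    cleaned[[sp]] <- contig_sets[[sp]][!drop]
    n_removed[sp] <- sum(drop)
  }
  n_total <- lengths(contig_sets)
  list(cleaned = cleaned,
       summary = data.frame(species = names(contig_sets),
                            n_contigs = unname(n_total),
                            n_removed = unname(n_removed),
                            removal_frac = unname(ifelse(n_total > 0,
                                                         n_removed / n_total, 0)),
                            stringsAsFactors = FALSE))
}
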