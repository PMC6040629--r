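# Probabilistic gene-family membership. A protein's support for belonging to
# its family is its average BLAST E-value to all other family members (a
# missing hit counts as the least-probable value e_max). Averages are mapped
# to probabilities through the empirical cumulative distribution of all
# E-values from the all-vs-all search, ordered from highest to lowest, so a
# protein with strong hits to most co-members scores near 1 and a protein
# with a few weak hits scores near 0.

#' Build an empirical E-value reference distribution
#'
#' Collects E-values into the reference used by [ecdf_probability()].
#' Reported E-values of exactly zero (or below the floor) are floored to the
#' smallest representable value so that rank comparisons stay well defined.
#'
#' @param evalues Numeric vector of E-values (>= 0).
#' @param floor Smallest representable E-value; zeros are raised to it.
#' @return An object of class \code{"ecdf_reference"}.
#' @export
ecdf_reference <- function(evalues, floor = 1e-200) {
  stopifnot(is.numeric(evalues), floor > 0)
  if (length(evalues) == 0L) stop("E-value reference must be non-empty", call. = FALSE)
  if (any(evalues < 0)) stop("E-values must be non-negative", call. = FALSE)
  v <- pmax(evalues, floor)
  structure(list(values = sort(v), floor = floor, n = length(v)),
            class = "ecdf_reference")
}

#' @export
print.ecdf_reference <- function(x, ...) {
  cat(sprintf("E-value ECDF reference: n = %d, range [%.3g, %.3g], floor %.3g\n",
              x$n, x$values[1L], x$values[x$n], x$floor))
  invisible(x)
}

#' Build the ECDF reference from a hit table
#'
#' Uses every non-self hit record from the all-vs-all search (self hits,
#' query equal to subject, are excluded).
#'
#' @param hits A hit table as returned by [read_blast_tab()].
#' @inheritParams ecdf_reference
#' @return An \code{"ecdf_reference"}.
#' @export
ecdf_reference_from_hits <- function(hits, floor = 1e-200) {
  keep <- hits$query != hits$subject
  ecdf_reference(hits$evalue[keep], floor = floor)
}

#' Rescale an E-value to a membership probability
#'
#' Returns the fraction of reference E-values strictly greater than \code{e}:
#' the empirical CDF with values ordered from highest (least probable) to
#' lowest. The result is monotone non-increasing in \code{e}, ties share a
#' probability, and the unique maximum of the reference maps to 0.
#'
#' @param e Numeric vector of E-values.
#' @param ref An \code{"ecdf_reference"}.
#' @return Probabilities in \eqn{[0, 1]}.
#' @export
ecdf_probability <- function(e, ref) {
  stopifnot(inherits(ref, "ecdf_reference"))
  e <- pmax(e, ref$floor)
  (ref$n - findInterval(e, ref$values)) / ref$n
}

# Best (minimum) E-value per unordered protein pair, as a named vector keyed
# by "a\rb" with a < b. Self hits are dropped.
best_pair_evalues <- function(hits, floor = 1e-200) {
  keep <- hits$query != hits$subject
  if (!any(keep)) return(stats::setNames(numeric(0), character(0)))
  dt <- data.table::data.table(
    a = pmin(hits$query[keep], hits$subject[keep]),
    b = pmax(hits$query[keep], hits$subject[keep]),
    e = pmax(hits$evalue[keep], floor)
  )
  e <- a <- b <- NULL # NSE bindings
  best <- dt[, list(e = min(e)), by = list(a, b)]
  stats::setNames(best$e, paste(best$a, best$b, sep = "\r"))
}

pair_key <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "\r")

#' Average E-value of a protein to its family co-members
#'
#' The arithmetic mean, on the raw E-value scale, of the protein's best hit
#' E-value to every other member of its family; a missing hit contributes the
#' maximum possible (least probable) value \code{e_max}. For a single-member
#' family the sentinel \code{e_max} is returned with attribute
#' \code{singleton = TRUE}.
#'
#' @param protein Full \code{"species|protein"} id; must be a family member.
#' @param members Character vector of the family's member ids.
#' @param hits Hit table (see [read_blast_tab()]).
#' @param e_max Maximum possible E-value, the search threshold.
#' @param floor Floor applied to reported E-values of zero.
#' @return The mean E-value (numeric scalar).
#' @export
mean_family_evalue <- function(protein, members, hits, e_max = 1e-5,
                               floor = 1e-200) {
  stopifnot(e_max > 0)
  if (!protein %in% members) {
    stop("protein '", protein, "' is not a member of the family", call. = FALSE)
  }
  pair_e <- best_pair_evalues(hits, floor = floor)
  others <- setdiff(members, protein)
  if (length(others) == 0L) {
    return(structure(e_max, singleton = TRUE))
  }
  e <- unname(pair_e[pair_key(protein, others)])
  e[is.na(e)] <- e_max
  mean(e)
}

#' Gene-family presence-probability matrix
#'
#' For every (family, species) pair: take the species' family member with the
#' lowest average E-value to its co-members and rescale that average through
#' the ECDF reference. Species with no member protein in a family get
#' probability 0; the sole member species of a singleton family gets
#' probability 1 (the family is defined by it).
#'
#' @param catalog A [family_catalog].
#' @param hits Hit table from the all-vs-all search.
#' @param species Character vector of all species (matrix columns). Defaults
#'   to the species present in the catalog.
#' @param e_max Search E-value threshold; substitutes for missing hits.
#' @param floor Floor for reported E-values of zero.
#' @param ref ECDF reference; defaults to all non-self hits in \code{hits}.
#' @return A numeric matrix (families x species) of probabilities in
#'   \eqn{[0, 1]}.
#' @export
presence_probabilities <- function(catalog, hits, species = NULL,
                                   e_max = 1e-5, floor = 1e-200, ref = NULL) {
  stopifnot(inherits(catalog, "family_catalog"))
  if (is.null(species)) species <- sort(unique(catalog$species))
  missing_sp <- setdiff(catalog$species, species)
  if (length(missing_sp) > 0L) {
    stop("catalog species absent from the species list: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  }
  if (is.null(ref)) ref <- ecdf_reference_from_hits(hits, floor = floor)
  pair_e <- best_pair_evalues(hits, floor = floor)

  fam_ids <- sort(unique(catalog$family))
  m <- matrix(0, nrow = length(fam_ids), ncol = length(species),
              dimnames = list(fam_ids, species))
  by_family <- split(catalog[, c("species", "protein")], catalog$family)
  for (f in fam_ids) {
    fam <- by_family[[f]]
    k <- nrow(fam)
    if (k == 1L) {
      m[f, fam$species] <- 1
      next
    }
    # mean E per member protein: k x k best-pair lookups, e_max where absent
    keys <- pair_key(rep(fam$protein, each = k), rep(fam$protein, times = k))
    emat <- matrix(unname(pair_e[keys]), nrow = k, ncol = k)
    emat[is.na(emat)] <- e_max
    diag(emat) <- NA
    means <- rowMeans(emat, na.rm = TRUE)
    best_by_species <- tapply(means, fam$species, min)
    m[f, names(best_by_species)] <- ecdf_probability(unname(best_by_species), ref)
  }
  m
}

#' Presence probabilities for additional species from best-reciprocal hits
#'
#' Scores gene-family presence for species added after the original analysis,
#' from a best-reciprocal-hit table (at most one hit per new protein per
#' original species). For each candidate family, a new protein's support is
#' the average over the family's original species of its best-hit E-value to
#' that species (missing species contribute \code{e_max}); each new protein
#' is assigned only to its single lowest-average family (ties broken towards
#' the lexicographically smallest family id, with a message), and the
#' family's probability for the new species is the lowest assigned average,
#' rescaled through the original ECDF reference.
#'
#' @param new_hits Data.frame with columns \code{query} (new-species protein,
#'   \code{"species|protein"}), \code{subject} (original protein id) and
#'   \code{evalue}; best-reciprocal only.
#' @param catalog The original [family_catalog].
#' @param ref The original \code{"ecdf_reference"}.
#' @inheritParams presence_probabilities
#' @return A numeric matrix (families x new species) of probabilities.
#' @export
posthoc_species_probabilities <- function(new_hits, catalog, ref,
                                          e_max = 1e-5, floor = 1e-200) {
  stopifnot(inherits(catalog, "family_catalog"), inherits(ref, "ecdf_reference"))
  fam_ids <- sort(unique(catalog$family))
  qs <- split_protein_ids(new_hits$query, "new-species query id")
  new_species <- sort(unique(qs$species))
  m <- matrix(0, nrow = length(fam_ids), ncol = length(new_species),
              dimnames = list(fam_ids, new_species))
  if (nrow(new_hits) == 0L) return(m)

  ss <- catalog$species[match(new_hits$subject, catalog$protein)]
  fam <- catalog$family[match(new_hits$subject, catalog$protein)]
  keep <- !is.na(fam)
  if (!any(keep)) return(m)
  dup <- duplicated(paste(new_hits$query, ss, sep = "\r")) & keep
  if (any(dup)) {
    stop("hits are not best-reciprocal: multiple hits for (",
         new_hits$query[dup][1L], ", ", ss[dup][1L], ")", call. = FALSE)
  }
  dt <- data.table::data.table(
    query = new_hits$query[keep], family = fam[keep],
    osp = ss[keep], e = pmax(new_hits$evalue[keep], floor)
  )
  fam_species <- lapply(split(catalog$species, catalog$family),
                        function(s) unique(s))
  e <- osp <- query <- family <- NULL # NSE bindings
  sums <- dt[, list(sum_e = sum(e), n_hit = data.table::uniqueN(osp)),
             by = list(query, family)]
  n_fam_sp <- vapply(fam_species[sums$family], length, 1L)
  sums$mean_e <- (sums$sum_e + (n_fam_sp - sums$n_hit) * e_max) / n_fam_sp

  # each new protein joins only its best (lowest-mean) family
  ord <- order(sums$query, sums$mean_e, sums$family)
  sums <- sums[ord, ]
  first <- !duplicated(sums$query)
  tied <- tapply(sums$mean_e, sums$query, function(v) sum(v == min(v)) > 1L)
  if (any(tied)) {
    message("posthoc assignment ties broken lexicographically for: ",
            paste(names(tied)[tied], collapse = ", "))
  }
  best <- sums[first, ]
  best$species <- sub("\\|.*$", "", best$query)
  agg <- tapply(best$mean_e, paste(best$family, best$species, sep = "\r"), min)
  keys <- strsplit(names(agg), "\r", fixed = TRUE)
  for (i in seq_along(agg)) {
    m[keys[[i]][1L], keys[[i]][2L]] <- ecdf_probability(agg[[i]], ref)
  }
  m
}
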