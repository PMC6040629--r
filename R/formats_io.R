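# Readers and writers for the external formats the pipeline consumes and
# produces: BLAST tabular hit tables, OrthoMCL-style groups files, Newick
# trees with a group-annotation sidecar, TSV presence matrices and
# Cluster 3.0 / TreeView CDT files.

#' Split species-tagged protein identifiers
#'
#' Protein identifiers follow the OrthoMCL convention
#' \code{"species|protein"}, with \code{"|"} reserved as the separator.
#'
#' @param ids Character vector of \code{"species|protein"} identifiers.
#' @param context Label used in error messages.
#' @return A data.frame with columns \code{species} and \code{protein}.
#' @export
split_protein_ids <- function(ids, context = "protein id") {
  bad <- !grepl("|", ids, fixed = TRUE)
  if (any(bad)) {
    stop(sprintf("%s without 'species|protein' prefix: %s",
                 context, paste(utils::head(ids[bad], 5L), collapse = ", ")),
         call. = FALSE)
  }
  data.frame(
    species = sub("\\|.*$", "", ids),
    protein = sub("^[^|]*\\|", "", ids),
    stringsAsFactors = FALSE
  )
}

#' Read a 12-column BLAST tabular hit file
#'
#' Parses standard BLAST \code{-outfmt 6} output. Only the query, subject,
#' percent identity, alignment length and E-value columns are used; the
#' remaining columns are read but ignored. Query and subject identifiers must
#' carry the \code{"species|protein"} prefix.
#'
#' @param path Path to a tab-separated hit file with at least 12 columns.
#' @return A data.frame of hit records with columns \code{query},
#'   \code{subject}, \code{qspecies}, \code{sspecies}, \code{pident},
#'   \code{length} and \code{evalue}.
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) stop("hit file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(query = character(), subject = character(),
                      qspecies = character(), sspecies = character(),
                      pident = numeric(), length = integer(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 12L)) {
    bad <- which(nf < 12L)[1L]
    stop(sprintf("malformed BLAST tabular row at line %d: expected >= 12 fields, found %d",
                 bad, nf[bad]), call. = FALSE)
  }
  query <- vapply(parts, `[[`, "", 1L)
  subject <- vapply(parts, `[[`, "", 2L)
  pident <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  len <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 4L)))
  evalue <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 11L)))
  for (col in list(list(pident, "percent identity"),
                   list(len, "alignment length"),
                   list(evalue, "E-value"))) {
    if (anyNA(col[[1L]])) {
      stop(sprintf("malformed BLAST tabular row at line %d: non-numeric %s",
                   which(is.na(col[[1L]]))[1L], col[[2L]]), call. = FALSE)
    }
  }
  if (any(evalue < 0)) {
    stop(sprintf("malformed BLAST tabular row at line %d: negative E-value",
                 which(evalue < 0)[1L]), call. = FALSE)
  }
  if (any(pident < 0 | pident > 100)) {
    stop(sprintf("malformed BLAST tabular row at line %d: percent identity outside [0, 100]",
                 which(pident < 0 | pident > 100)[1L]), call. = FALSE)
  }
  if (any(len < 1L)) {
    stop(sprintf("malformed BLAST tabular row at line %d: alignment length < 1",
                 which(len < 1L)[1L]), call. = FALSE)
  }
  qs <- split_protein_ids(query, "query id")
  ss <- split_protein_ids(subject, "subject id")
  data.frame(query = query, subject = subject,
             qspecies = qs$species, sspecies = ss$species,
             pident = pident, length = len, evalue = evalue,
             stringsAsFactors = FALSE)
}

#' Construct a validated family catalog
#'
#' A family catalog maps gene-family identifiers to member proteins, each
#' tagged with its species. Every protein may belong to at most one family
#' and every family must be non-empty.
#'
#' @param x A data.frame with columns \code{family}, \code{species},
#'   \code{protein} (full \code{"species|protein"} id).
#' @return The validated data.frame with class \code{"family_catalog"}.
#' @export
family_catalog <- function(x) {
  stopifnot(is.data.frame(x), all(c("family", "species", "protein") %in% names(x)))
  if (nrow(x) > 0L) {
    dup <- x$protein[duplicated(x$protein)]
    if (length(dup) > 0L) {
      offenders <- unique(dup)
      stop("proteins assigned to more than one family: ",
           paste(utils::head(offenders, 10L), collapse = ", "), call. = FALSE)
    }
  }
  x <- x[, c("family", "species", "protein")]
  class(x) <- c("family_catalog", "data.frame")
  x
}

#' Read an OrthoMCL-style groups file
#'
#' Each line has the form \code{"FAM123: sp1|pA sp2|pB ..."}. Membership is
#' validated: a protein occurring in two families is an error.
#'
#' @param path Path to the groups file.
#' @return A [family_catalog] data.frame.
#' @export
read_groups <- function(path) {
  if (!file.exists(path)) stop("groups file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(family_catalog(data.frame(family = character(), species = character(),
                                     protein = character(), stringsAsFactors = FALSE)))
  }
  colon <- regexpr(":", lines, fixed = TRUE)
  if (any(colon < 0L)) {
    stop(sprintf("malformed groups line %d: missing ':'", which(colon < 0L)[1L]),
         call. = FALSE)
  }
  fam <- trimws(substr(lines, 1L, colon - 1L))
  members <- strsplit(trimws(substring(lines, colon + 1L)), "[[:space:]]+")
  n <- lengths(members)
  if (any(n == 0L | vapply(members, function(m) any(!nzchar(m)), TRUE))) {
    stop(sprintf("malformed groups line %d: empty member list",
                 which(n == 0L)[1L]), call. = FALSE)
  }
  ids <- unlist(members, use.names = FALSE)
  sp <- split_protein_ids(ids, "group member id")
  family_catalog(data.frame(family = rep(fam, n), species = sp$species,
                            protein = ids, stringsAsFactors = FALSE))
}

#' Write a family catalog as an OrthoMCL-style groups file
#'
#' @param catalog A [family_catalog].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_groups <- function(catalog, path) {
  members <- split(catalog$protein, catalog$family)
  lines <- vapply(names(members), function(f) {
    paste0(f, ": ", paste(members[[f]], collapse = " "))
  }, "")
  writeLines(lines[sort(names(members))], path)
  invisible(path)
}

# ---- annotated species tree -------------------------------------------------

#' Construct an annotated species tree
#'
#' Wraps a rooted \code{ape::phylo} tree with the group structure the origin
#' inference needs: a partition of the leaves into major groups, optional
#' sub-groups of each major group (disjoint subsets that cover the group),
#' and named ancestral nodes of interest (each defined by the exact leaf set
#' of its clade).
#'
#' @param phy A rooted \code{phylo} object.
#' @param major_groups Named list of character vectors of species; must
#'   partition the tip labels.
#' @param subgroups Named list (by major group) of named lists of species
#'   subsets.
#' @param ancestor_nodes Named list of character vectors: each entry names an
#'   internal node by the exact leaf set of its clade.
#' @return An object of class \code{"annotated_tree"}.
#' @export
annotated_tree <- function(phy, major_groups, subgroups = list(),
                           ancestor_nodes = list()) {
  stopifnot(inherits(phy, "phylo"))
  if (!ape::is.rooted(phy)) stop("species tree must be rooted", call. = FALSE)
  tips <- phy$tip.label
  all_members <- unlist(major_groups, use.names = FALSE)
  if (anyDuplicated(all_members)) {
    stop("major groups overlap: ",
         paste(unique(all_members[duplicated(all_members)]), collapse = ", "),
         call. = FALSE)
  }
  if (!setequal(all_members, tips)) {
    stop("major groups must partition the leaf set; mismatched species: ",
         paste(utils::head(c(setdiff(tips, all_members),
                             setdiff(all_members, tips)), 10L), collapse = ", "),
         call. = FALSE)
  }
  for (g in names(subgroups)) {
    if (!g %in% names(major_groups)) {
      stop("subgroups declared for unknown major group: ", g, call. = FALSE)
    }
    sub <- subgroups[[g]]
    flat <- unlist(sub, use.names = FALSE)
    if (!all(flat %in% major_groups[[g]])) {
      stop("subgroup of '", g, "' not nested in its major group: ",
           paste(setdiff(flat, major_groups[[g]]), collapse = ", "), call. = FALSE)
    }
    if (anyDuplicated(flat)) {
      stop("subgroups of '", g, "' are not disjoint", call. = FALSE)
    }
    if (!setequal(flat, major_groups[[g]])) {
      stop("subgroups of '", g, "' do not cover the major group", call. = FALSE)
    }
  }
  clades <- clade_species_map(phy)
  nodes <- integer(0)
  for (nm in names(ancestor_nodes)) {
    leafset <- ancestor_nodes[[nm]]
    missing <- setdiff(leafset, tips)
    if (length(missing) > 0L) {
      stop("ancestor node '", nm, "' names unknown species: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    node <- if (length(leafset) == 1L) {
      match(leafset, tips)
    } else {
      ape::getMRCA(phy, leafset)
    }
    if (node <= length(tips)) {
      stop("ancestor node '", nm, "' must map to an internal node", call. = FALSE)
    }
    if (!setequal(clades[[node]], leafset)) {
      stop("ancestor node '", nm, "' leaf set is not a clade of the topology",
           call. = FALSE)
    }
    nodes[nm] <- node
  }
  parent <- integer(max(phy$edge))
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  structure(list(phy = phy, major_groups = major_groups, subgroups = subgroups,
                 ancestor_nodes = nodes, clades = clades, parent = parent),
            class = "annotated_tree")
}

# Leaf labels under every node, computed in one postorder sweep.
clade_species_map <- function(phy) {
  ntip <- length(phy$tip.label)
  nnode <- max(phy$edge)
  clades <- vector("list", nnode)
  for (i in seq_len(ntip)) clades[[i]] <- phy$tip.label[i]
  edge <- ape::reorder.phylo(phy, "postorder")$edge
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1L]; ch <- edge[i, 2L]
    clades[[p]] <- c(clades[[p]], clades[[ch]])
  }
  clades
}

#' @export
print.annotated_tree <- function(x, ...) {
  cat("Annotated species tree:", length(x$phy$tip.label), "species,",
      length(x$major_groups), "major groups,",
      length(x$ancestor_nodes), "named ancestral nodes\n")
  for (g in names(x$major_groups)) {
    subs <- if (g %in% names(x$subgroups)) {
      paste0(" (subgroups: ", paste(names(x$subgroups[[g]]), collapse = ", "), ")")
    } else ""
    cat(sprintf("  %s: %d species%s\n", g, length(x$major_groups[[g]]), subs))
  }
  if (length(x$ancestor_nodes)) {
    cat("  nodes:", paste(names(x$ancestor_nodes), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a species tree and its group-annotation config
#'
#' The Newick file provides the rooted topology; the sidecar config (YAML, or
#' JSON if the file ends in \code{.json}) provides \code{major_groups},
#' optional \code{subgroups} and \code{ancestor_nodes} (each ancestor given
#' as the leaf set of its clade).
#'
#' @param newick Path to a Newick tree file.
#' @param config Path to the YAML/JSON group configuration.
#' @return An [annotated_tree].
#' @export
read_tree_config <- function(newick, config) {
  phy <- ape::read.tree(newick)
  if (is.null(phy)) stop("could not parse Newick file: ", newick, call. = FALSE)
  cfg <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
    jsonlite::read_json(config, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(config)
  }
  if (is.null(cfg$major_groups)) {
    stop("config must define 'major_groups'", call. = FALSE)
  }
  annotated_tree(phy,
                 major_groups = lapply(cfg$major_groups, as.character),
                 subgroups = lapply(cfg$subgroups %||% list(),
                                    function(s) lapply(s, as.character)),
                 ancestor_nodes = lapply(cfg$ancestor_nodes %||% list(),
                                         as.character))
}

#' Write the tree and config files for an annotated tree
#'
#' @param tree An [annotated_tree].
#' @param newick,config Output paths for the Newick topology and YAML config.
#' @return Invisibly, a character vector of the two paths.
#' @export
write_tree_config <- function(tree, newick, config) {
  ape::write.tree(tree$phy, file = newick)
  cfg <- list(
    major_groups = tree$major_groups,
    subgroups = tree$subgroups,
    ancestor_nodes = lapply(as.list(tree$ancestor_nodes),
                            function(node) tree$clades[[node]])
  )
  yaml::write_yaml(cfg, config)
  invisible(c(newick, config))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- matrices ---------------------------------------------------------------

#' Write a presence matrix as TSV
#'
#' Rows are gene families, columns species. The round trip through
#' [read_matrix()] is lossless to full double precision.
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_matrix <- function(m, path) {
  stopifnot(is.matrix(m))
  header <- paste(c("family", colnames(m)), collapse = "\t")
  if (nrow(m) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], format(m[i, ], digits = 17, trim = TRUE,
                                   scientific = NA)), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a TSV presence matrix written by [write_matrix()]
#'
#' @param path Path to the TSV file.
#' @return A numeric matrix with families as rows and species as columns.
#' @export
read_matrix <- function(path) {
  x <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(x[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- x[[1L]]
  m
}

#' Write an ordered matrix as a Cluster 3.0 / Java TreeView CDT file
#'
#' The CDT dialect carries the row order chosen by [heatmap_order()]; the
#' GID, NAME and GWEIGHT bookkeeping columns and the EWEIGHT row are emitted
#' as Cluster 3.0 does.
#'
#' @param m Numeric matrix (families x species).
#' @param path Output path.
#' @param order Character vector of row names giving the row order; defaults
#'   to the current order.
#' @return Invisibly, \code{path}.
#' @export
write_cdt <- function(m, path, order = rownames(m)) {
  stopifnot(is.matrix(m))
  if (!is.null(order)) {
    stopifnot(all(order %in% rownames(m)))
    m <- m[order, , drop = FALSE]
  }
  header <- paste(c("GID", "NAME", "GWEIGHT", colnames(m)), collapse = "\t")
  eweight <- paste(c("EWEIGHT", "", "", rep("1", ncol(m))), collapse = "\t")
  lines <- c(header, eweight)
  if (nrow(m) > 0L) {
    body <- vapply(seq_len(nrow(m)), function(i) {
      id <- rownames(m)[i]
      paste(c(paste0("GENE", i, "X"), id, "1",
              format(m[i, ], digits = 17, trim = TRUE, scientific = NA)),
            collapse = "\t")
    }, "")
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- read counts ------------------------------------------------------------

#' Read a per-contig mapped-read count table
#'
#' Expects a TSV with columns \code{species}, \code{contig}, \code{count}
#' (header optional if in that order).
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns \code{species}, \code{contig},
#'   \code{count}.
#' @export
read_read_counts <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("species", "contig", "count") %in% names(x))) {
    if (ncol(x) < 3L) stop("read count table needs 3 columns", call. = FALSE)
    names(x)[1:3] <- c("species", "contig", "count")
  }
  x$count <- as.integer(x$count)
  if (anyNA(x$count) || any(x$count < 0L)) {
    stop("read counts must be non-negative integers", call. = FALSE)
  }
  x[, c("species", "contig", "count")]
}
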