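# Ancestral-origin inference. Group presence uses the 10% rule: a gene family
# is present in a group of species when the sum of its membership
# probabilities over the group is at least 10% of the group size (equivalent
# to a mean probability of at least 10%). Origins follow parsimony rules: a
# family present in two or more major groups existed in their last common
# ancestor; a family confined to one major group is placed on that group's
# stem only if at least two of the group's sub-groups pass the same rule.

# inclusive >= at floating-point tolerance, so that e.g. three species at
# probability 0.70 meet a 21-species group's 2.1 threshold exactly
geq <- function(x, y, tol = 1e-9) x >= y - tol

#' Group presence under the fractional-sum rule
#'
#' @param p Named numeric vector of membership probabilities for one family.
#' @param group Character vector of species in the group.
#' @param threshold_frac Required fraction of the group size; the comparison
#'   is inclusive (\code{>=}, evaluated at floating-point tolerance).
#' @return Logical scalar.
#' @export
group_presence <- function(p, group, threshold_frac = 0.10) {
  if (length(group) == 0L) stop("group must be non-empty", call. = FALSE)
  missing <- setdiff(group, names(p))
  if (length(missing) > 0L) {
    stop("species in group missing from the probability vector: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  geq(sum(p[group]), threshold_frac * length(group))
}

# family x group logical matrix of rule-based presence
group_presence_matrix <- function(m, groups, threshold_frac = 0.10) {
  out <- vapply(groups, function(sp) {
    geq(rowSums(m[, sp, drop = FALSE]), threshold_frac * length(sp))
  }, logical(nrow(m)))
  if (nrow(m) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(rownames(m), names(groups)))
  out
}

# nearest named ancestral node at or above `node`; NA_character_ if none
lift_to_named <- function(tree, node) {
  repeat {
    hit <- names(tree$ancestor_nodes)[match(node, tree$ancestor_nodes)]
    if (!is.na(hit)) return(hit)
    if (node == root_node(tree$phy)) return(NA_character_)
    node <- tree$parent[node]
  }
}

root_node <- function(phy) length(phy$tip.label) + 1L

# named node names strictly ancestral to a named node, nearest first
named_ancestors <- function(tree, name) {
  node <- tree$ancestor_nodes[[name]]
  out <- character(0)
  while (node != root_node(tree$phy)) {
    node <- tree$parent[node]
    hit <- names(tree$ancestor_nodes)[match(node, tree$ancestor_nodes)]
    if (!is.na(hit)) out <- c(out, hit)
  }
  out
}

# name of the named node whose clade equals the group's species set, or NA
group_ancestor <- function(tree, group) {
  sp <- tree$major_groups[[group]]
  for (nm in names(tree$ancestor_nodes)) {
    if (setequal(tree$clades[[tree$ancestor_nodes[[nm]]]], sp)) return(nm)
  }
  NA_character_
}

# major groups whose species all descend from `node`
groups_under <- function(tree, node) {
  clade <- tree$clades[[node]]
  names(tree$major_groups)[vapply(tree$major_groups,
                                  function(sp) all(sp %in% clade), TRUE)]
}

#' Assign a family's ancestral origin from group presences
#'
#' Applies the parsimony rules to precomputed presence booleans. With two or
#' more major groups present the origin is the named node at (or nearest
#' above) their last common ancestor. With exactly one group present, the
#' origin is that group's own ancestor node if at least two of its sub-groups
#' are present, and \code{"within-<group>"} otherwise. With no group present
#' the family is \code{"unassigned"}.
#'
#' @param major_present Named logical vector over major groups.
#' @param subgroup_present Named list (by major group) of named logical
#'   vectors over that group's sub-groups.
#' @param tree An [annotated_tree].
#' @return A single origin label.
#' @export
infer_origin <- function(major_present, subgroup_present, tree) {
  groups <- names(tree$major_groups)
  stopifnot(all(groups %in% names(major_present)))
  present <- groups[major_present[groups]]
  if (length(present) == 0L) return("unassigned")
  if (length(present) >= 2L) {
    sp <- unlist(tree$major_groups[present], use.names = FALSE)
    node <- ape::getMRCA(tree$phy, sp)
    nm <- lift_to_named(tree, node)
    if (is.na(nm)) {
      warning("no named node at or above the LCA of groups: ",
              paste(present, collapse = ", "))
      return("unassigned")
    }
    return(nm)
  }
  g <- present
  anc <- group_ancestor(tree, g)
  subs <- subgroup_present[[g]]
  if (is.null(subs) || length(subs) == 0L) {
    if (!is.na(anc)) {
      stop("group '", g, "' has a named ancestor node but no configured ",
           "sub-groups; cannot apply the single-group rule", call. = FALSE)
    }
    return(paste0("within-", g))
  }
  if (sum(subs) >= 2L) {
    if (is.na(anc)) {
      stop("group '", g, "' passes the sub-group rule but has no named ",
           "ancestor node", call. = FALSE)
    }
    return(anc)
  }
  paste0("within-", g)
}

#' Infer the origin of every family in a presence matrix
#'
#' @param m Presence-probability matrix (families x species).
#' @param tree An [annotated_tree].
#' @param threshold_frac Fractional-sum presence threshold (default 10%).
#' @return A data.frame with columns \code{family} and \code{origin}; every
#'   family receives exactly one assignment.
#' @export
infer_origins <- function(m, tree, threshold_frac = 0.10) {
  gp <- group_presence_matrix(m, tree$major_groups, threshold_frac)
  sub_p <- lapply(tree$subgroups, function(subs) {
    group_presence_matrix(m, subs, threshold_frac)
  })
  origin <- vapply(seq_len(nrow(m)), function(i) {
    subs_i <- lapply(sub_p, function(sp) sp[i, ])
    infer_origin(gp[i, ], subs_i, tree)
  }, "")
  data.frame(family = rownames(m), origin = origin, stringsAsFactors = FALSE)
}

#' Gene families present, gained and lost at each named ancestral node
#'
#' A family is counted present at a node when its origin is that node or one
#' of its named ancestors and at least one major group descending from the
#' node still passes the presence rule. Gains are families whose origin is
#' exactly the node. Losses on the branch to a node are families present at
#' the node's nearest named ancestor but absent from every major group below
#' the node.
#'
#' @param origins Data.frame from [infer_origins()].
#' @param m Presence-probability matrix.
#' @param tree An [annotated_tree].
#' @param threshold_frac Presence threshold fraction.
#' @return A data.frame with one row per named node (root first): columns
#'   \code{node}, \code{present}, \code{gained}, \code{lost}.
#' @export
node_gain_loss <- function(origins, m, tree, threshold_frac = 0.10) {
  stopifnot(identical(sort(origins$family), sort(rownames(m))))
  org <- stats::setNames(origins$origin, origins$family)[rownames(m)]
  gp <- group_presence_matrix(m, tree$major_groups, threshold_frac)

  nodes <- names(tree$ancestor_nodes)
  depth <- vapply(nodes, function(nm) length(named_ancestors(tree, nm)), 1L)
  nodes <- nodes[order(depth)]

  present_at <- function(nm) {
    chain <- c(nm, named_ancestors(tree, nm))
    gu <- groups_under(tree, tree$ancestor_nodes[[nm]])
    org %in% chain & rowSums(gp[, gu, drop = FALSE]) > 0L
  }
  pres <- vapply(nodes, present_at, logical(nrow(m)))
  if (nrow(m) == 1L) pres <- matrix(pres, nrow = 1L, dimnames = list(NULL, nodes))

  out <- data.frame(node = nodes,
                    present = colSums(pres)[nodes],
                    gained = vapply(nodes, function(nm) sum(org == nm), 1L),
                    lost = NA_integer_, stringsAsFactors = FALSE,
                    row.names = NULL)
  for (i in seq_along(nodes)) {
    nm <- nodes[i]
    parent <- named_ancestors(tree, nm)
    if (length(parent) == 0L) { out$lost[i] <- 0L; next }
    gu <- groups_under(tree, tree$ancestor_nodes[[nm]])
    absent_below <- rowSums(gp[, gu, drop = FALSE]) == 0L
    out$lost[i] <- sum(pres[, parent[1L]] & absent_below)
  }
  out
}

#' Summed retention of ancestral gene families per species
#'
#' For each set of families partitioned by ancestral origin, sums the
#' membership probabilities for each species. Species outside the descendants
#' of an origin accumulate only the small residual background of sub-threshold
#' probabilities.
#'
#' @param m Presence-probability matrix.
#' @param origins Data.frame from [infer_origins()].
#' @param origin_classes Character vector of origin labels to summarise;
#'   defaults to the named ancestral nodes occurring in \code{origins}.
#' @return A numeric matrix (species x origin class) of summed probabilities.
#' @export
retention_sums <- function(m, origins, origin_classes = NULL) {
  org <- stats::setNames(origins$origin, origins$family)[rownames(m)]
  if (is.null(origin_classes)) {
    origin_classes <- sort(unique(org[!grepl("^(within-|unassigned)", org)]))
  }
  out <- vapply(origin_classes, function(cl) {
    colSums(m[org == cl, , drop = FALSE])
  }, numeric(ncol(m)))
  if (ncol(m) == 1L) {
    out <- matrix(out, nrow = 1L, dimnames = list(colnames(m), origin_classes))
  }
  out
}

#' Group-specific core gene families
#'
#' Families whose membership probability passes the threshold (inclusive) in
#' every species of the group. Restrict \code{families} to those originating
#' at the group's stem to obtain group-specific cores.
#'
#' @param m Presence-probability matrix.
#' @param group Character vector of species.
#' @param families Candidate family ids (default: all rows).
#' @param threshold Per-species minimum probability (default 0.10).
#' @return Character vector of family ids.
#' @export
core_families <- function(m, group, families = rownames(m), threshold = 0.10) {
  near_core_families(m, group, max_missing = 0L, families = families,
                     threshold = threshold)
}

#' Near-core gene families missing from at most a few species
#'
#' @inheritParams core_families
#' @param max_missing Maximum number of group species allowed to fail the
#'   per-species threshold.
#' @return Character vector of family ids.
#' @export
near_core_families <- function(m, group, max_missing, families = rownames(m),
                               threshold = 0.10) {
  missing <- setdiff(group, colnames(m))
  if (length(missing) > 0L) {
    stop("species in group missing from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sub <- m[families, group, drop = FALSE]
  fails <- rowSums(sub < threshold)
  families[fails <= max_missing]
}

#' Fraction of one species set's families shared by all of them
#'
#' Given per-species retained family sets (families passing the per-species
#' probability threshold), reports how many families are retained in at least
#' one and in all of the species, and the percentage shared.
#'
#' @param m Presence-probability matrix.
#' @param species Character vector of species to intersect.
#' @param threshold Per-species presence threshold (default 0.10).
#' @param families Candidate family ids (default: all rows).
#' @return A list with \code{n_any}, \code{n_all} and \code{pct_shared}
#'   (100 * n_all / n_any).
#' @export
retention_overlap <- function(m, species, threshold = 0.10,
                              families = rownames(m)) {
  sub <- m[families, species, drop = FALSE] >= threshold
  n_any <- sum(rowSums(sub) > 0L)
  n_all <- sum(rowSums(sub) == length(species))
  list(n_any = n_any, n_all = n_all,
       pct_shared = if (n_any > 0L) 100 * n_all / n_any else NA_real_)
}

# ---- Dollo parsimony --------------------------------------------------------

#' Dollo parsimony reconstruction of family gains and losses
#'
#' Under Dollo parsimony each family is gained exactly once, at the most
#' recent common ancestor of all possessing leaves, and lost on the minimal
#' set of branches: the maximal subtrees under the gain node that contain no
#' possessing leaf.
#'
#' @param x Binary presence matrix (families x species), or a probability
#'   matrix which is binarised at \code{threshold}.
#' @param tree An [annotated_tree] or a rooted \code{phylo}.
#' @param threshold Binarisation threshold when \code{x} is not 0/1
#'   (default 0.10, the species-level presence criterion).
#' @return A list with \code{assignments} (data.frame: family, gain node id,
#'   gain label, number of losses) and \code{losses} (named list of child
#'   node ids whose subtrees were lost). Families absent everywhere are
#'   skipped with a warning.
#' @export
dollo_reconstruct <- function(x, tree, threshold = 0.10) {
  phy <- if (inherits(tree, "annotated_tree")) tree$phy else tree
  stopifnot(inherits(phy, "phylo"))
  if (!ape::is.rooted(phy)) stop("Dollo parsimony needs a rooted tree", call. = FALSE)
  bin <- x >= if (all(x %in% c(0, 1))) 0.5 else threshold
  missing <- setdiff(phy$tip.label, colnames(bin))
  if (length(missing) > 0L) {
    stop("species missing from the presence matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ntip <- length(phy$tip.label)
  kids <- split(phy$edge[, 2L], factor(phy$edge[, 1L], levels = seq_len(max(phy$edge))))
  clades <- clade_species_map(phy)
  node_label <- function(node) {
    if (node <= ntip) return(phy$tip.label[node])
    if (!is.null(phy$node.label)) {
      lbl <- phy$node.label[node - ntip]
      if (!is.na(lbl) && nzchar(lbl)) return(lbl)
    }
    paste0("node", node)
  }

  fams <- rownames(bin)
  gain_node <- integer(length(fams)); n_losses <- integer(length(fams))
  losses <- vector("list", length(fams)); names(losses) <- fams
  skip <- logical(length(fams))
  for (i in seq_along(fams)) {
    tips <- colnames(bin)[bin[i, ]]
    if (length(tips) == 0L) {
      warning("family '", fams[i], "' absent from every species; skipped")
      skip[i] <- TRUE
      next
    }
    gain <- if (length(tips) == 1L) match(tips, phy$tip.label) else ape::getMRCA(phy, tips)
    lost_nodes <- integer(0)
    if (gain > ntip) {
      # maximal empty subtrees below the gain node
      walk <- function(node) {
        for (ch in kids[[node]]) {
          if (!any(clades[[ch]] %in% tips)) {
            lost_nodes <<- c(lost_nodes, ch)
          } else if (ch > ntip) {
            walk(ch)
          }
        }
      }
      walk(gain)
    }
    gain_node[i] <- gain
    n_losses[i] <- length(lost_nodes)
    losses[[i]] <- lost_nodes
  }
  assignments <- data.frame(
    family = fams[!skip],
    gain_node = gain_node[!skip],
    gain_label = vapply(gain_node[!skip], node_label, ""),
    n_losses = n_losses[!skip],
    stringsAsFactors = FALSE
  )
  list(assignments = assignments, losses = losses[!skip])
}

# ---- heat-map ordering ------------------------------------------------------

#' Uncentered Pearson similarity between matrix rows
#'
#' \eqn{s(x, y) = \sum x_i y_i / \sqrt{\sum x_i^2 \sum y_i^2}}. Rows of all
#' zeros have similarity 0 to every row.
#'
#' @param m Numeric matrix.
#' @return A symmetric similarity matrix.
#' @export
uncentered_pearson <- function(m) {
  norms <- sqrt(rowSums(m^2))
  safe <- ifelse(norms > 0, norms, 1)
  s <- tcrossprod(m / safe)
  s[norms == 0, ] <- 0
  s[, norms == 0] <- 0
  s
}

#' Order families for heat-map display
#'
#' Families are first grouped by their pattern of presence across the major
#' groups (patterns sorted by group, present before absent, in the
#' configuration's group order) and then clustered within each pattern by
#' average-linkage hierarchical clustering on uncentered Pearson similarity.
#' All-zero rows are placed last within their pattern. Ties are broken by
#' family id.
#'
#' @param m Presence-probability matrix.
#' @param tree An [annotated_tree].
#' @param threshold_frac Presence threshold fraction for the patterns.
#' @return Character vector of family ids in display order.
#' @export
heatmap_order <- function(m, tree, threshold_frac = 0.10) {
  gp <- group_presence_matrix(m, tree$major_groups, threshold_frac)
  pattern <- apply(gp, 1L, function(b) paste(as.integer(!b), collapse = ""))
  out <- character(0)
  for (pat in sort(unique(pattern))) {
    ids <- sort(rownames(m)[pattern == pat])
    rows <- m[ids, , drop = FALSE]
    zero <- rowSums(rows^2) == 0
    live <- ids[!zero]
    if (length(live) > 2L) {
      s <- uncentered_pearson(rows[live, , drop = FALSE])
      h <- stats::hclust(stats::as.dist(1 - s), method = "average")
      live <- live[h$order]
    }
    out <- c(out, live, ids[zero])
  }
  out
}
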