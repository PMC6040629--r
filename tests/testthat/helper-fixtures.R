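# Shared fixtures and independent oracles.

# 4-leaf tree with two major groups, no subgroups, root named
tiny_tree4 <- function() {
  phy <- ape::read.tree(text = "((a,b)N1,(c,d)N2)Root;")
  annotated_tree(phy,
                 major_groups = list(G1 = c("a", "b"), G2 = c("c", "d")),
                 ancestor_nodes = list(Root = c("a", "b", "c", "d")))
}

# choanozoan-style mini tree: two annotated groups with subgroups + outgroup
mini_tree <- function() {
  phy <- ape::read.tree(text = paste0(
    "(((c1,c2,c3,c4)CHO,(s1,s2,m1,l1,l2,l3)ANI)CZ,o1)RT;"))
  annotated_tree(
    phy,
    major_groups = list(
      choanoflagellates = c("c1", "c2", "c3", "c4"),
      animals = c("s1", "s2", "m1", "l1", "l2", "l3"),
      outgroup = "o1"
    ),
    subgroups = list(
      choanoflagellates = list(craspedids = c("c1", "c2"),
                               loricates = c("c3", "c4")),
      animals = list(sponges = c("s1", "s2"), ctenophores = "m1",
                     later_branching = c("l1", "l2", "l3"))
    ),
    ancestor_nodes = list(
      Urchoanozoan = c("c1", "c2", "c3", "c4", "s1", "s2", "m1",
                       "l1", "l2", "l3"),
      Urchoanoflagellate = c("c1", "c2", "c3", "c4"),
      Urmetazoan = c("s1", "s2", "m1", "l1", "l2", "l3")
    )
  )
}

# one-row probability matrix over the given species
prob_row <- function(values, species, family = "f1") {
  matrix(values, nrow = 1, dimnames = list(family, species))
}

# independent oracle: ECDF rank by explicit counting
brute_force_ecdf <- function(e, ref_values, floor = 1e-200) {
  v <- pmax(ref_values, floor)
  vapply(pmax(e, floor), function(x) sum(v > x) / length(v), 1)
}

# independent oracle: minimal Dollo loss count by exhaustive enumeration over
# all ancestral state assignments with a single-gain constraint
dollo_oracle_min_losses <- function(phy, tips_present) {
  ntip <- length(phy$tip.label)
  nn <- max(phy$edge)
  internals <- (ntip + 1L):nn
  base <- integer(nn)
  base[seq_len(ntip)] <- as.integer(phy$tip.label %in% tips_present)
  root <- ntip + 1L
  best <- Inf
  for (mask in 0:(2^length(internals) - 1L)) {
    st <- base
    st[internals] <- as.integer(bitwAnd(mask, 2^(seq_along(internals) - 1L)) > 0)
    gains <- sum(st[phy$edge[, 1L]] == 0L & st[phy$edge[, 2L]] == 1L) + st[root]
    if (gains != 1L) next
    losses <- sum(st[phy$edge[, 1L]] == 1L & st[phy$edge[, 2L]] == 0L)
    best <- min(best, losses)
  }
  best
}

# write lines to a temp file, returning the path
tmp_lines <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# a valid 12-column BLAST tabular row
blast_row <- function(query, subject, pident = 97.0, len = 120, evalue = "1e-50") {
  paste(query, subject, pident, len, 0, 0, 1, len, 1, len, evalue, 200,
        sep = "\t")
}
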