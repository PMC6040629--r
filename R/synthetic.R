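# Synthetic-data generators. They emulate the statistical structure the
# analysis assumes -- gene-family gain on stem lineages with Bernoulli loss
# along descendant branches, hit tables in which true orthologs have strong
# hits to most co-members while false positives have near-threshold hits to
# one or two, cross-contamination scenarios with read counts, and per-read
# error-position records mixing sporadic and clustered errors -- so that
# every stage of the pipeline is testable without any sequencing data.

# run code under a fixed seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' The demonstration species tree
#'
#' A 55-species tree mirroring a realistic sampling design: 20
#' choanoflagellates (10 craspedids, 10 loricates), 20 animals (3 sponges, 1
#' ctenophore, 16 later-branching animals), one Capsaspora-like filasterean,
#' 5 fungi and 9 other eukaryotes. Within-group relationships are left as
#' polytomies -- the presence rules are deliberately independent of
#' within-group topology, and the branching order of early animals is
#' unresolved -- while the named ancestral nodes (Ureukaryote, Uropisthokont,
#' Urholozoan, Urchoanozoan, Urchoanoflagellate, Urmetazoan) are resolved.
#'
#' @return An [annotated_tree].
#' @export
paperlike_tree <- function() {
  cra <- sprintf("cra%02d", 1:10)
  lor <- sprintf("lor%02d", 1:10)
  spo <- sprintf("spo%02d", 1:3)
  cte <- "cte01"
  lat <- sprintf("lat%02d", 1:16)
  fun <- sprintf("fun%02d", 1:5)
  euk <- sprintf("euk%02d", 1:9)
  cap <- "capsaspora"
  poly <- function(tips) paste(tips, collapse = ",")
  nwk <- sprintf(
    "((%s),((%s),(((%s)Urchoanoflagellate,(%s)Urmetazoan)Urchoanozoan,%s)Urholozoan)Uropisthokont)Ureukaryote;",
    poly(euk), poly(fun), poly(c(cra, lor)), poly(c(spo, cte, lat)), cap)
  phy <- ape::read.tree(text = nwk)
  groups <- list(
    choanoflagellates = c(cra, lor),
    animals = c(spo, cte, lat),
    capsaspora = cap,
    fungi = fun,
    other_eukaryotes = euk
  )
  subgroups <- list(
    choanoflagellates = list(craspedids = cra, loricates = lor),
    animals = list(sponges = spo, ctenophores = cte, later_branching = lat)
  )
  ancestors <- list(
    Ureukaryote = phy$tip.label,
    Uropisthokont = c(fun, cap, cra, lor, spo, cte, lat),
    Urholozoan = c(cap, cra, lor, spo, cte, lat),
    Urchoanozoan = c(cra, lor, spo, cte, lat),
    Urchoanoflagellate = c(cra, lor),
    Urmetazoan = c(spo, cte, lat)
  )
  annotated_tree(phy, groups, subgroups, ancestors)
}

#' Default per-stem gain counts for the demonstration simulation
#'
#' Gains are spread over the six named nodes in rough proportion to the
#' relative sizes of the inferred ancestral gene complements (many ancient
#' families, substantial choanozoan- and animal-stem innovation).
#'
#' @return Named integer vector: node name to number of families gained.
#' @export
paperlike_gains <- function() {
  c(Ureukaryote = 60L, Uropisthokont = 20L, Urholozoan = 20L,
    Urchoanozoan = 50L, Urchoanoflagellate = 50L, Urmetazoan = 60L)
}

#' Simulate gene-family gain and loss along a species tree
#'
#' Each family is gained exactly once at its assigned stem node and then lost
#' independently with probability \code{loss_prob} on every descendant
#' branch; once lost on a branch it is absent from the entire subtree. The
#' result is bit-reproducible under a fixed seed.
#'
#' @param tree An [annotated_tree].
#' @param gains_per_stem Named integer vector: origin node name (a named
#'   ancestor of \code{tree}) to number of families gained there.
#' @param loss_prob Per-branch loss probability in \eqn{[0, 1)}.
#' @param seed Integer seed.
#' @return A \code{"sim_truth"} object: list with \code{origins} (data.frame
#'   family, origin), \code{presence} (binary matrix family x species),
#'   \code{loss_edges} (per family, the child nodes of branches where the
#'   family was lost) and the generating parameters.
#' @export
simulate_family_evolution <- function(tree, gains_per_stem = paperlike_gains(),
                                      loss_prob = 0.2, seed = 1) {
  stopifnot(inherits(tree, "annotated_tree"),
            loss_prob >= 0, loss_prob < 1)
  unknown <- setdiff(names(gains_per_stem), names(tree$ancestor_nodes))
  if (length(unknown) > 0L) {
    stop("gains assigned to unknown nodes: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  phy <- tree$phy
  species <- phy$tip.label
  ntip <- length(species)
  edge <- ape::reorder.phylo(phy, "postorder")$edge
  edge <- edge[rev(seq_len(nrow(edge))), , drop = FALSE] # preorder

  n_fam <- sum(gains_per_stem)
  fams <- sprintf("F%04d", seq_len(n_fam))
  origins <- rep(names(gains_per_stem), gains_per_stem)
  presence <- matrix(0L, nrow = n_fam, ncol = ntip,
                     dimnames = list(fams, species))
  loss_edges <- vector("list", n_fam)
  names(loss_edges) <- fams

  with_seed(seed, {
    for (i in seq_len(n_fam)) {
      origin_node <- tree$ancestor_nodes[[origins[i]]]
      state <- logical(max(phy$edge))
      state[origin_node] <- TRUE
      lost <- integer(0)
      for (j in seq_len(nrow(edge))) {
        p <- edge[j, 1L]; ch <- edge[j, 2L]
        if (!state[p]) next
        if (stats::runif(1) < loss_prob) {
          lost <- c(lost, ch)
        } else {
          state[ch] <- TRUE
        }
      }
      presence[i, ] <- as.integer(state[seq_len(ntip)])
      loss_edges[[i]] <- lost
    }
  })
  structure(list(origins = data.frame(family = fams, origin = origins,
                                      stringsAsFactors = FALSE),
                 presence = presence, loss_edges = loss_edges, tree = tree,
                 loss_prob = loss_prob, seed = seed),
            class = "sim_truth")
}

#' Check the internal consistency of a simulated truth
#'
#' Recomputes the presence of every family from its origin node and recorded
#' loss branches: a species possesses a family exactly when the family's
#' origin is ancestral to it and no loss occurred on its path.
#'
#' @param truth A \code{"sim_truth"}.
#' @return TRUE (invisibly) or an error describing the inconsistency.
#' @export
validate_sim_truth <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  tree <- truth$tree
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  for (i in seq_len(nrow(truth$presence))) {
    fam <- truth$origins$family[i]
    origin_node <- tree$ancestor_nodes[[truth$origins$origin[i]]]
    origin_clade <- tree$clades[[origin_node]]
    lost <- truth$loss_edges[[fam]]
    expected <- vapply(seq_len(ntip), function(tip) {
      if (!phy$tip.label[tip] %in% origin_clade) return(0L)
      node <- tip
      while (node != origin_node) {
        if (node %in% lost) return(0L)
        node <- tree$parent[node]
      }
      1L
    }, 1L)
    if (!identical(unname(truth$presence[i, ]), expected)) {
      stop("presence of family ", fam, " inconsistent with origin and losses",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("Simulated truth: %d families, %d species, per-branch loss %.2f, seed %d\n",
              nrow(x$presence), ncol(x$presence), x$loss_prob, x$seed))
  print(table(x$origins$origin))
  invisible(x)
}

#' Simulate an all-vs-all hit table and family catalog from a truth
#'
#' One protein per possessing (family, species) pair. True members hit each
#' co-member with probability \code{member_hit_prob} at a log10-uniform
#' E-value in \code{ortholog_logE_range}. False positives are injected into a
#' fraction \code{false_pos_rate} of the non-possessing (family, species)
#' pairs: a spurious protein joins the family's catalog entry but hits only
#' one or two members, near the search threshold. Background hits between
#' unrelated proteins (weak, near-threshold homology, the bulk of any real
#' all-vs-all search) populate the ECDF reference at
#' \code{background_ratio} records per within-family hit.
#'
#' @param truth A \code{"sim_truth"} from [simulate_family_evolution()].
#' @param ortholog_logE_range log10 E-value range for true ortholog hits.
#' @param member_hit_prob Probability a true member hits a given co-member.
#' @param false_pos_rate Fraction of absent (family, species) pairs that
#'   receive an injected false positive.
#' @param false_pos_logE_range log10 E-value range for false-positive hits.
#' @param fp_members_hit Candidate numbers of members a false positive hits.
#' @param background_ratio Background (cross-family) hits per within-family
#'   hit.
#' @param seed Integer seed.
#' @return A list with \code{catalog} (a [family_catalog], including injected
#'   proteins), \code{hits} (a hit-record data.frame), \code{injected}
#'   (data.frame of injected family/species/protein) and \code{truth}.
#' @export
simulate_hit_table <- function(truth, ortholog_logE_range = c(-200, -20),
                               member_hit_prob = 0.95, false_pos_rate = 0,
                               false_pos_logE_range = c(-10, -5),
                               fp_members_hit = c(1L, 2L),
                               background_ratio = 9, seed = 1) {
  stopifnot(inherits(truth, "sim_truth"),
            member_hit_prob >= 0, member_hit_prob <= 1,
            false_pos_rate >= 0, false_pos_rate <= 1)
  presence <- truth$presence
  keep <- rowSums(presence) > 0L
  presence <- presence[keep, , drop = FALSE]
  fams <- rownames(presence)
  species <- colnames(presence)

  cat_rows <- list(); hit_rows <- list(); injected <- list()
  with_seed(seed, {
    rle10 <- function(n, range) 10^stats::runif(n, range[1L], range[2L])
    for (f in fams) {
      sp <- species[presence[f, ] == 1L]
      prot <- paste0(sp, "|", f, ".", sp)
      cat_rows[[f]] <- data.frame(family = f, species = sp, protein = prot,
                                  stringsAsFactors = FALSE)
      k <- length(prot)
      if (k >= 2L) {
        pairs <- utils::combn(k, 2L)
        hit <- stats::runif(ncol(pairs)) < member_hit_prob
        if (any(hit)) {
          hit_rows[[f]] <- data.frame(
            query = prot[pairs[1L, hit]], subject = prot[pairs[2L, hit]],
            evalue = rle10(sum(hit), ortholog_logE_range),
            stringsAsFactors = FALSE)
        }
      }
    }
    catalog <- do.call(rbind, cat_rows)

    if (false_pos_rate > 0) {
      absent <- which(presence == 0L, arr.ind = TRUE)
      sizes <- rowSums(presence)[absent[, 1L]]
      absent <- absent[sizes >= 1L, , drop = FALSE]
      n_fp <- round(false_pos_rate * nrow(absent))
      if (n_fp > 0L) {
        pick <- sample(nrow(absent), n_fp)
        fp_rows <- list()
        for (i in pick) {
          f <- fams[absent[i, 1L]]; s <- species[absent[i, 2L]]
          prot <- paste0(s, "|", f, ".", s, ".fp")
          members <- cat_rows[[f]]$protein
          n_hit <- if (length(fp_members_hit) == 1L) fp_members_hit else
            sample(fp_members_hit, 1L)
          n_hit <- min(n_hit, length(members))
          targets <- sample(members, n_hit)
          fp_rows[[length(fp_rows) + 1L]] <- data.frame(
            query = prot, subject = targets,
            evalue = rle10(n_hit, false_pos_logE_range),
            stringsAsFactors = FALSE)
          injected[[length(injected) + 1L]] <- data.frame(
            family = f, species = s, protein = prot, stringsAsFactors = FALSE)
          catalog <- rbind(catalog, data.frame(family = f, species = s,
                                               protein = prot,
                                               stringsAsFactors = FALSE))
        }
        hit_rows <- c(hit_rows, fp_rows)
      }
    }

    hits <- do.call(rbind, hit_rows)
    n_bg <- round(background_ratio * nrow(hits))
    all_prot <- catalog$protein
    fam_of <- stats::setNames(catalog$family, catalog$protein)
    if (n_bg > 0L && length(unique(fam_of)) > 1L) {
      q <- character(0); s <- character(0)
      while (length(q) < n_bg) {
        draw <- 2L * (n_bg - length(q))
        qi <- sample(all_prot, draw, replace = TRUE)
        si <- sample(all_prot, draw, replace = TRUE)
        ok <- fam_of[qi] != fam_of[si]
        q <- c(q, qi[ok]); s <- c(s, si[ok])
      }
      bg <- data.frame(query = q[seq_len(n_bg)], subject = s[seq_len(n_bg)],
                       evalue = rle10(n_bg, c(-10, -5)),
                       stringsAsFactors = FALSE)
      hits <- rbind(hits, bg)
    }
    hits$pident <- round(stats::runif(nrow(hits), 25, 99), 1)
    hits$length <- sample(80:600, nrow(hits), replace = TRUE)
    hits$qspecies <- sub("\\|.*$", "", hits$query)
    hits$sspecies <- sub("\\|.*$", "", hits$subject)
    hits <- hits[, c("query", "subject", "qspecies", "sspecies",
                     "pident", "length", "evalue")]

    list(
      catalog = family_catalog(catalog),
      hits = hits,
      injected = if (length(injected)) do.call(rbind, injected) else
        data.frame(family = character(), species = character(),
                   protein = character(), stringsAsFactors = FALSE),
      truth = truth
    )
  })
}

#' Write a simulated hit table as 12-column BLAST tabular
#'
#' @param hits Hit-record data.frame (see [simulate_hit_table()]).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_blast_tab <- function(hits, path) {
  lines <- sprintf("%s\t%s\t%.1f\t%d\t0\t0\t1\t%d\t1\t%d\t%s\t0.0",
                   hits$query, hits$subject, hits$pident, hits$length,
                   hits$length, hits$length,
                   format(hits$evalue, digits = 17, trim = TRUE, scientific = NA))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a cross-contamination scenario
#'
#' Builds per-species contig sets with mapped-read counts, then copies a
#' fraction of contigs into another species' assembly as contaminants whose
#' read counts are \code{contaminant_read_fraction} of the source's, with
#' high-identity cross-species matches connecting each contaminant to its
#' source.
#'
#' @param n_species Number of co-multiplexed species.
#' @param contigs_per_species Contigs per species before contamination.
#' @param contam_rate Fraction of contigs copied into another species.
#' @param contaminant_read_fraction Contaminant read count as a fraction of
#'   the source contig's read count.
#' @param seed Integer seed.
#' @return A list with \code{contig_sets}, \code{matches} (contig match
#'   records), \code{reads} (read-count data.frame) and \code{truth}
#'   (data.frame with one row per contig: species, contig, is_contaminant,
#'   source_species, source_contig).
#' @export
simulate_decontam_scenario <- function(n_species = 6, contigs_per_species = 200,
                                       contam_rate = 0.02,
                                       contaminant_read_fraction = 0.01,
                                       seed = 1) {
  stopifnot(n_species >= 2, contam_rate >= 0, contam_rate < 1,
            contaminant_read_fraction > 0, contaminant_read_fraction <= 1)
  with_seed(seed, {
    species <- sprintf("sp%02d", seq_len(n_species))
    contig_sets <- lapply(species, function(sp) {
      sprintf("%s_c%04d", sp, seq_len(contigs_per_species))
    })
    names(contig_sets) <- species
    reads <- data.frame(
      species = rep(species, each = contigs_per_species),
      contig = unlist(contig_sets, use.names = FALSE),
      count = as.integer(round(10^stats::runif(n_species * contigs_per_species,
                                               2.7, 4.3))),
      stringsAsFactors = FALSE
    )
    truth <- data.frame(species = reads$species, contig = reads$contig,
                        is_contaminant = FALSE,
                        source_species = NA_character_,
                        source_contig = NA_character_,
                        stringsAsFactors = FALSE)
    n_cont <- round(contam_rate * nrow(reads))
    matches <- data.frame(species_a = character(), contig_a = character(),
                          species_b = character(), contig_b = character(),
                          percent_identity = numeric(),
                          match_length = integer(), stringsAsFactors = FALSE)
    if (n_cont > 0L) {
      src <- sample(nrow(reads), n_cont)
      tgt_sp <- vapply(reads$species[src], function(sp) {
        sample(setdiff(species, sp), 1L)
      }, "")
      cont_id <- paste0(reads$contig[src], "_xc")
      cont_count <- pmax(1L, as.integer(round(contaminant_read_fraction *
                                                reads$count[src])))
      for (i in seq_len(n_cont)) {
        contig_sets[[tgt_sp[i]]] <- c(contig_sets[[tgt_sp[i]]], cont_id[i])
      }
      reads <- rbind(reads, data.frame(species = tgt_sp, contig = cont_id,
                                       count = cont_count,
                                       stringsAsFactors = FALSE))
      truth <- rbind(truth, data.frame(species = tgt_sp, contig = cont_id,
                                       is_contaminant = TRUE,
                                       source_species = reads$species[src],
                                       source_contig = reads$contig[src],
                                       stringsAsFactors = FALSE))
      matches <- data.frame(
        species_a = reads$species[src], contig_a = reads$contig[src],
        species_b = tgt_sp, contig_b = cont_id,
        percent_identity = round(stats::runif(n_cont, 96, 100), 2),
        match_length = sample(90:1000, n_cont, replace = TRUE),
        stringsAsFactors = FALSE
      )
    }
    list(contig_sets = contig_sets, matches = matches, reads = reads,
         truth = truth)
  })
}

#' Simulate per-read error-position records
#'
#' Each read carries sporadic errors (pairwise separated by at least one
#' k-mer window, so each has zero neighbors) and, with probability
#' \code{cluster_rate}, one cluster of \code{cluster_size} errors packed into
#' a single k-mer window.
#'
#' @param n_reads Number of reads.
#' @param read_len Read length in bases.
#' @param sporadic_rate Expected number of sporadic errors per read
#'   (Poisson).
#' @param cluster_rate Probability a read carries an error cluster.
#' @param cluster_size Errors per cluster (at most \code{window}).
#' @param window k-mer window size.
#' @param seed Integer seed.
#' @return A list with \code{records} (data.frame read, position) and
#'   \code{labels} (data.frame read, position, label in
#'   \{sporadic, clustered\}).
#' @export
simulate_error_records <- function(n_reads = 400, read_len = 100,
                                   sporadic_rate = 2, cluster_rate = 0.3,
                                   cluster_size = 5, window = 13, seed = 1) {
  stopifnot(cluster_size >= 2, cluster_size <= window, read_len > 3 * window)
  with_seed(seed, {
    rows <- list()
    for (r in seq_len(n_reads)) {
      read_id <- sprintf("read%05d", r)
      pos <- integer(0); label <- character(0)
      if (stats::runif(1) < cluster_rate) {
        start <- sample.int(read_len - window + 1L, 1L) - 1L
        cl <- sort(sample(start:(start + window - 1L), cluster_size))
        pos <- cl; label <- rep("clustered", cluster_size)
      }
      n_spor <- stats::rpois(1L, sporadic_rate)
      tries <- 0L
      while (n_spor > 0L && tries < 200L) {
        cand <- sample.int(read_len, 1L) - 1L
        if (all(abs(pos - cand) >= window)) {
          pos <- c(pos, cand); label <- c(label, "sporadic")
          n_spor <- n_spor - 1L
        }
        tries <- tries + 1L
      }
      if (length(pos) > 0L) {
        ord <- order(pos)
        rows[[length(rows) + 1L]] <- data.frame(
          read = read_id, position = pos[ord], label = label[ord],
          stringsAsFactors = FALSE)
      }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(read = character(), position = integer(),
                 label = character(), stringsAsFactors = FALSE)
    list(records = out[, c("read", "position")],
         labels = out)
  })
}

#' Simulate the full demonstration data bundle
#'
#' Convenience wrapper: the demonstration tree, a family-evolution truth and
#' a matching hit table and catalog, all under one seed.
#'
#' @param seed Integer seed.
#' @param gains_per_stem Per-node gain counts (default [paperlike_gains()]).
#' @param loss_prob Per-branch loss probability.
#' @param false_pos_rate Injected false-positive rate.
#' @param ... Further arguments passed to [simulate_hit_table()].
#' @return A list with \code{tree}, \code{truth}, \code{catalog},
#'   \code{hits}, \code{injected}.
#' @export
simulate_paperlike <- function(seed = 1, gains_per_stem = paperlike_gains(),
                               loss_prob = 0.2, false_pos_rate = 0, ...) {
  tree <- paperlike_tree()
  truth <- simulate_family_evolution(tree, gains_per_stem,
                                     loss_prob = loss_prob, seed = seed)
  sim <- simulate_hit_table(truth, false_pos_rate = false_pos_rate,
                            seed = seed + 1L, ...)
  list(tree = tree, truth = truth, catalog = sim$catalog, hits = sim$hits,
       injected = sim$injected)
}
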