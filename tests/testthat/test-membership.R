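test_that("average family E-values follow the missing-hit penalty", {
  hits <- data.frame(query = c("a|p1", "a|p1"), subject = c("b|p2", "c|p3"),
                     qspecies = "a", sspecies = c("b", "c"),
                     pident = 90, length = 100, evalue = c(1e-50, 1e-30))
  members <- c("a|p1", "b|p2", "c|p3")
  expect_equal(mean_family_evalue("a|p1", members, hits), (1e-50 + 1e-30) / 2)

  # one hit to 1 of 3 co-members, the other two count as e_max
  hits1 <- hits[1, ]
  members4 <- c("a|p1", "b|p2", "c|p3", "d|p4")
  expect_equal(mean_family_evalue("a|p1", members4, hits1),
               (1e-40 * 0 + 1e-50 + 2 * 1e-5) / 3)

  # no hits at all -> e_max
  none <- hits[0, ]
  expect_equal(mean_family_evalue("a|p1", members4, none), 1e-5)

  # singleton family returns the sentinel, flagged
  v <- mean_family_evalue("a|p1", "a|p1", none)
  expect_equal(as.numeric(v), 1e-5)
  expect_true(attr(v, "singleton"))

  expect_error(mean_family_evalue("z|q", members, hits), "not a member")
})

test_that("ECDF probability counts strictly-greater reference values", {
  ref <- ecdf_reference(c(1e-3, 1e-6, 1e-9, 1e-12))
  expect_equal(ecdf_probability(1e-9, ref), 0.5)
  expect_equal(ecdf_probability(1e-3, ref), 0)    # unique maximum -> 0
  expect_equal(ecdf_probability(1e-15, ref), 1)   # below everything -> 1
  expect_error(ecdf_reference(numeric(0)), "non-empty")
})

test_that("ECDF probability equals a brute-force rank count", {
  set.seed(101)
  for (n in c(10L, 1000L, 10000L)) {
    ref_values <- 10^runif(n, -180, -2)
    ref_values[sample(n, n %/% 10)] <- 0  # exercise the floor
    ref <- ecdf_reference(ref_values)
    queries <- c(10^runif(50, -210, 0), sample(ref_values, min(20, n)), 0)
    expect_equal(ecdf_probability(queries, ref),
                 brute_force_ecdf(queries, ref_values))
    # monotone non-increasing and bounded
    sorted <- sort(queries)
    p <- ecdf_probability(sorted, ref)
    expect_true(all(diff(p) <= 0))
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("presence probabilities pick the best protein per species", {
  # one species with a strong and a weak protein: the strong one is chosen
  catalog <- family_catalog(data.frame(
    family = "F1",
    species = c("a", "a", "b", "c"),
    protein = c("a|good", "a|bad", "b|p", "c|p")))
  hits <- data.frame(
    query = c("a|good", "a|good", "a|bad", "b|p", "x|u", "x|u", "x|u"),
    subject = c("b|p", "c|p", "b|p", "c|p", "y|v", "y|w", "y|z"),
    qspecies = c("a", "a", "a", "b", "x", "x", "x"),
    sspecies = c("b", "c", "b", "c", "y", "y", "y"),
    pident = 90, length = 100,
    evalue = c(1e-30, 1e-30, 1e-8, 1e-30, 1e-4, 1e-4, 1e-4))
  m <- presence_probabilities(catalog, hits, species = c("a", "b", "c", "d"))
  # species a scores via a|good (mean over its 3 co-members incl. a|bad)
  ref <- ecdf_reference_from_hits(hits)
  mean_good <- mean_family_evalue("a|good", catalog$protein, hits)
  expect_equal(m["F1", "a"], ecdf_probability(mean_good, ref))
  mean_bad <- mean_family_evalue("a|bad", catalog$protein, hits)
  expect_true(ecdf_probability(mean_good, ref) >= ecdf_probability(mean_bad, ref))
  # absent species -> 0
  expect_equal(m["F1", "d"], 0)
  expect_true(all(m >= 0 & m <= 1))
})

test_that("singleton families score 1 for their sole species", {
  catalog <- family_catalog(data.frame(family = c("F1", "F2", "F2"),
                                       species = c("a", "b", "c"),
                                       protein = c("a|x", "b|y", "c|z")))
  hits <- data.frame(query = "b|y", subject = "c|z", qspecies = "b",
                     sspecies = "c", pident = 90, length = 100, evalue = 1e-20)
  m <- presence_probabilities(catalog, hits, species = c("a", "b", "c"))
  expect_equal(m["F1", "a"], 1)
})

test_that("probabilities are invariant to hit-table row order", {
  bundle <- simulate_paperlike(seed = 5, gains_per_stem = c(Urmetazoan = 6L,
                                                            Urchoanozoan = 6L),
                               loss_prob = 0.1)
  set.seed(99)
  shuffled <- bundle$hits[sample(nrow(bundle$hits)), ]
  sp <- bundle$tree$phy$tip.label
  m1 <- presence_probabilities(bundle$catalog, bundle$hits, species = sp)
  m2 <- presence_probabilities(bundle$catalog, shuffled, species = sp)
  expect_equal(m1, m2)
})

test_that("a family of tight orthologs scores at least 0.9 everywhere", {
  phy <- ape::read.tree(text = "((s1,s2,s3,s4,s5),(s6,s7,s8,s9,s10))Root;")
  tree <- annotated_tree(phy, list(G = phy$tip.label),
                         ancestor_nodes = list(Root = phy$tip.label))
  truth <- simulate_family_evolution(tree, c(Root = 3L), loss_prob = 0, seed = 3)
  sim <- simulate_hit_table(truth, ortholog_logE_range = c(-120, -80),
                            member_hit_prob = 1, seed = 4)
  m <- presence_probabilities(sim$catalog, sim$hits, species = phy$tip.label)
  expect_true(all(m >= 0.9))
})

test_that("a member with few near-threshold hits scores below 0.1", {
  # 40 tight members plus one member hitting only 2 of them near e_max
  species <- sprintf("s%02d", 1:41)
  prot <- paste0(species, "|p")
  catalog <- family_catalog(data.frame(family = "F1", species = species,
                                       protein = prot))
  pairs <- utils::combn(prot[1:40], 2)
  hits <- data.frame(query = c(pairs[1, ], prot[41], prot[41]),
                     subject = c(pairs[2, ], prot[1], prot[2]),
                     pident = 90, length = 100,
                     evalue = c(rep(1e-50, ncol(pairs)), 2e-6, 5e-6))
  hits$qspecies <- sub("\\|.*", "", hits$query)
  hits$sspecies <- sub("\\|.*", "", hits$subject)
  m <- presence_probabilities(catalog, hits, species = species)
  expect_lt(m["F1", "s41"], 0.1)
  expect_gt(min(m["F1", species[1:40]]), m["F1", "s41"])
})

test_that("post-hoc probabilities use best-hit means through the original ECDF", {
  # two stems with disjoint descendants, so one best-reciprocal hit per
  # (new protein, original species) can touch both families
  tree <- paperlike_tree()
  truth <- simulate_family_evolution(tree, c(Urmetazoan = 2L,
                                             Urchoanoflagellate = 2L),
                                     loss_prob = 0, seed = 2)
  sim <- simulate_hit_table(truth, member_hit_prob = 1, seed = 3)
  ref <- ecdf_reference_from_hits(sim$hits)
  cat_by_fam <- split(sim$catalog$protein, sim$catalog$family)
  fams <- names(cat_by_fam)
  f_ani <- fams[1]
  f_cho <- fams[3]
  members_ani <- cat_by_fam[[f_ani]]
  members_cho <- cat_by_fam[[f_cho]]

  # hits one family's members in all its species at 1e-60 -> high probability
  nh <- data.frame(query = "new|p1", subject = members_ani, evalue = 1e-60)
  pp <- posthoc_species_probabilities(nh, sim$catalog, ref)
  expect_equal(pp[f_ani, "new"], ecdf_probability(1e-60, ref))
  expect_gt(pp[f_ani, "new"], 0.85)

  # a protein hitting two families joins only the lower-mean one
  nh2 <- rbind(
    data.frame(query = "new|p2", subject = members_ani, evalue = 1e-80),
    data.frame(query = "new|p2", subject = members_cho[1], evalue = 1e-6))
  pp2 <- posthoc_species_probabilities(nh2, sim$catalog, ref)
  expect_gt(pp2[f_ani, "new"], 0)
  expect_equal(pp2[f_cho, "new"], 0)

  # duplicate hits to one (protein, species) violate the contract
  bad <- rbind(nh, nh[1, ])
  expect_error(posthoc_species_probabilities(bad, sim$catalog, ref),
               "best-reciprocal")

  # no hits -> all zero for that species
  pp3 <- posthoc_species_probabilities(nh[0, ], sim$catalog, ref)
  expect_equal(ncol(pp3), 0L)

  # equal-mean tie breaks to the lexicographically first family, with a note
  nh4 <- rbind(
    data.frame(query = "new|p4", subject = members_ani, evalue = 1e-50),
    data.frame(query = "new|p4", subject = members_cho, evalue = 1e-50))
  expect_message(pp4 <- posthoc_species_probabilities(nh4, sim$catalog, ref),
                 "tie")
  first <- min(f_ani, f_cho)
  other <- max(f_ani, f_cho)
  expect_gt(pp4[first, "new"], 0)
  expect_equal(pp4[other, "new"], 0)
})

test_that("true members separate from injected false positives", {
  bundle <- simulate_paperlike(
    seed = 11, gains_per_stem = c(Urchoanozoan = 10L, Urmetazoan = 10L),
    loss_prob = 0, false_pos_rate = 0.05)
  expect_gt(nrow(bundle$injected), 0L)
  m <- presence_probabilities(bundle$catalog, bundle$hits,
                              species = bundle$tree$phy$tip.label)
  fp_probs <- mapply(function(f, s) m[f, s],
                     bundle$injected$family, bundle$injected$species)
  true_cat <- bundle$catalog[!bundle$catalog$protein %in% bundle$injected$protein, ]
  true_probs <- mapply(function(f, s) m[f, s], true_cat$family, true_cat$species)
  expect_gt(min(true_probs), max(fp_probs))
  expect_lt(max(fp_probs), 0.1)
})
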