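test_that("group presence applies the fractional-sum rule inclusively", {
  species <- sprintf("s%02d", 1:21)
  p <- setNames(rep(0, 21), species)
  p[1:3] <- 0.70
  expect_true(group_presence(p, species))          # 3 x 0.70 = 2.1 >= 2.1
  p[] <- 0; p[1:6] <- 0.35
  expect_true(group_presence(p, species))          # 6 x 0.35 = 2.1 >= 2.1
  p[] <- 0; p[1:2] <- 0.70
  expect_false(group_presence(p, species))         # 1.4 < 2.1
  p[] <- 0
  expect_false(group_presence(p, species))

  # invariant to permutation of the group's species
  set.seed(7)
  p[] <- runif(21)
  expect_equal(group_presence(p, species), group_presence(p, sample(species)))

  expect_error(group_presence(p, c(species, "missing")), "missing")
})

test_that("origin rules place families at the right nodes", {
  tree <- mini_tree()
  sp <- tree$phy$tip.label
  gp <- function(vals) {
    m <- prob_row(vals[sp], sp)
    infer_origins(m, tree)$origin
  }
  # present in both choanoflagellates and animals -> their LCA
  v <- setNames(rep(0, length(sp)), sp); v[c("c1", "c2", "s1", "l1")] <- 1
  expect_equal(gp(v), "Urchoanozoan")

  # animal-only, in two subgroups (sponges + later-branching) -> Urmetazoan
  v[] <- 0; v[c("s1", "l1", "l2")] <- 1
  expect_equal(gp(v), "Urmetazoan")

  # animal-only, sponges only -> within-animals
  v[] <- 0; v[c("s1", "s2")] <- 1
  expect_equal(gp(v), "within-animals")

  # single-species ctenophore subgroup passes at probability >= 0.10
  v[] <- 0; v[c("s1", "s2")] <- 1; v["m1"] <- 0.10
  expect_equal(gp(v), "Urmetazoan")

  # outgroup only: no named ancestor, no subgroups -> within-outgroup
  v[] <- 0; v["o1"] <- 1
  expect_equal(gp(v), "within-outgroup")

  # nothing present -> unassigned
  v[] <- 0
  expect_equal(gp(v), "unassigned")
})

test_that("a group with a named ancestor but no subgroups is a config error", {
  phy <- ape::read.tree(text = "((a,b)N1,(c,d)N2)Root;")
  tree <- annotated_tree(phy,
                         major_groups = list(G1 = c("a", "b"), G2 = c("c", "d")),
                         ancestor_nodes = list(UrG1 = c("a", "b"),
                                               Root = c("a", "b", "c", "d")))
  m <- prob_row(c(a = 1, b = 1, c = 0, d = 0), c("a", "b", "c", "d"))
  expect_error(infer_origins(m, tree), "sub-group")
})

test_that("origin assignment conserves the family count", {
  bundle <- simulate_paperlike(seed = 21,
                               gains_per_stem = c(Ureukaryote = 10L,
                                                  Urchoanozoan = 10L,
                                                  Urmetazoan = 10L),
                               loss_prob = 0.2)
  m <- presence_probabilities(bundle$catalog, bundle$hits,
                              species = bundle$tree$phy$tip.label)
  origins <- infer_origins(m, bundle$tree)
  expect_equal(nrow(origins), nrow(m))
  expect_false(any(is.na(origins$origin)))
  gl <- node_gain_loss(origins, m, bundle$tree)
  n_named <- sum(gl$gained)
  n_other <- sum(grepl("^(within-|unassigned)", origins$origin))
  expect_equal(n_named + n_other, nrow(m))
})

test_that("gain/loss bookkeeping counts stem losses once, at the right node", {
  tree <- mini_tree()
  sp <- tree$phy$tip.label
  # origin Urchoanozoan, animals present, choanoflagellates absent
  v <- setNames(rep(0, length(sp)), sp); v[c("s1", "s2", "l1", "l2")] <- 1
  m <- prob_row(v, sp)
  origins <- data.frame(family = "f1", origin = "Urchoanozoan")
  gl <- node_gain_loss(origins, m, tree)
  row <- function(n) gl[gl$node == n, ]
  expect_equal(row("Urchoanozoan")$gained, 1L)
  expect_equal(row("Urchoanozoan")$present, 1L)
  expect_equal(row("Urchoanoflagellate")$lost, 1L)
  expect_equal(row("Urchoanoflagellate")$present, 0L)
  expect_equal(row("Urmetazoan")$present, 1L)
  # a gain at Urmetazoan is not counted at Urchoanozoan
  v[] <- 0; v[c("s1", "l1", "l2")] <- 1
  gl2 <- node_gain_loss(data.frame(family = "f1", origin = "Urmetazoan"),
                        prob_row(v, sp), tree)
  expect_equal(gl2[gl2$node == "Urchoanozoan", "present"], 0L)
  expect_equal(gl2[gl2$node == "Urmetazoan", "gained"], 1L)
})

test_that("gain/loss tables from inferred probabilities match the true pattern", {
  bundle <- simulate_paperlike(seed = 31, loss_prob = 0.2)
  tree <- bundle$tree
  m <- presence_probabilities(bundle$catalog, bundle$hits,
                              species = tree$phy$tip.label)
  origins <- infer_origins(m, tree)
  gl <- node_gain_loss(origins, m, tree)
  # tables computed from the true binary presence pattern
  mt <- bundle$truth$presence[rownames(m), , drop = FALSE] + 0
  origins_t <- infer_origins(mt, tree)
  gl_t <- node_gain_loss(origins_t, mt, tree)
  expect_equal(gl$node, gl_t$node)
  # counts agree within the small slack left by probability thresholds
  expect_true(all(abs(gl$gained - gl_t$gained) <= ceiling(0.05 * sum(gl_t$gained))))
  expect_true(all(gl$present >= 0 & gl$gained >= 0 & gl$lost >= 0))
})

test_that("probabilistic scoring yields fewer spurious shared origins than any-hit calls", {
  bundle <- simulate_paperlike(
    seed = 41, gains_per_stem = c(Urchoanoflagellate = 30L, Urmetazoan = 30L),
    loss_prob = 0.2, false_pos_rate = 0.05)
  tree <- bundle$tree
  m <- presence_probabilities(bundle$catalog, bundle$hits,
                              species = tree$phy$tip.label)
  origins_p <- infer_origins(m, tree)
  # binarized any-hit method: a species is present wherever it has a protein
  bin <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  idx <- cbind(match(bundle$catalog$family, rownames(bin)),
               match(bundle$catalog$species, colnames(bin)))
  bin[idx] <- 1
  origins_b <- infer_origins(bin, tree)
  true_origin <- setNames(bundle$truth$origins$origin,
                          bundle$truth$origins$family)[origins_p$family]
  spurious <- function(o) sum(o$origin == "Urchoanozoan" &
                                true_origin != "Urchoanozoan")
  expect_lt(spurious(origins_p), spurious(origins_b))
})

test_that("retention sums add probabilities per origin class", {
  m <- rbind(f1 = c(a = 1.0, b = 0), f2 = c(a = 0.5, b = 0),
             f3 = c(a = 0.05, b = 0))
  origins <- data.frame(family = c("f1", "f2", "f3"), origin = "Urmetazoan")
  ret <- retention_sums(m, origins)
  expect_equal(ret["a", "Urmetazoan"], 1.55)
  expect_equal(ret["b", "Urmetazoan"], 0)
})

test_that("retention ranking recovers a species that lost half its families", {
  tree <- paperlike_tree()
  truth <- simulate_family_evolution(tree, c(Urmetazoan = 40L), loss_prob = 0,
                                     seed = 51)
  # knock out half the families in one animal
  victim <- "lat01"
  pres <- truth$presence
  pres[1:20, victim] <- 0L
  m <- pres + 0
  origins <- data.frame(family = rownames(m), origin = "Urmetazoan")
  ret <- retention_sums(m, origins)
  animals <- tree$major_groups$animals
  expect_equal(names(which.min(ret[animals, "Urmetazoan"])), victim)
})

test_that("core and near-core families respect inclusive thresholds", {
  species <- sprintf("s%02d", 1:21)
  m <- rbind(
    allhigh = setNames(rep(1, 21), species),
    onelow = c(0.05, rep(1, 20)),
    boundary = c(0.10, rep(1, 20)),
    twolow = c(0.05, 0.05, rep(1, 19)),
    threelow = c(0.05, 0.05, 0.05, rep(1, 18)))
  colnames(m) <- species
  expect_equal(core_families(m, species), c("allhigh", "boundary"))
  expect_setequal(near_core_families(m, species, max_missing = 2),
                  c("allhigh", "boundary", "onelow", "twolow"))
  expect_false("threelow" %in% near_core_families(m, species, max_missing = 2))
  expect_equal(near_core_families(m, species, max_missing = 0),
               core_families(m, species))
})

test_that("retention overlap reports the shared fraction", {
  m <- rbind(matrix(1, 10, 3), cbind(rep(1, 5), 0, 0))
  rownames(m) <- paste0("f", 1:15); colnames(m) <- c("x", "y", "z")
  ov <- retention_overlap(m, c("x", "y", "z"))
  expect_equal(ov$n_any, 15L)
  expect_equal(ov$n_all, 10L)
  expect_equal(ov$pct_shared, 100 * 10 / 15)
})

test_that("Dollo reconstruction matches hand cases", {
  tree <- tiny_tree4()
  sp <- c("a", "b", "c", "d")
  all4 <- prob_row(c(1, 1, 1, 1), sp)
  d <- dollo_reconstruct(all4, tree)
  expect_equal(d$assignments$gain_label, "Root")
  expect_equal(d$assignments$n_losses, 0L)

  ac <- prob_row(c(1, 0, 1, 0), sp)
  d2 <- dollo_reconstruct(ac, tree)
  expect_equal(d2$assignments$gain_label, "Root")
  expect_equal(d2$assignments$n_losses, 2L)
  expect_setequal(tree$phy$tip.label[d2$losses$f1], c("b", "d"))

  single <- prob_row(c(0, 1, 0, 0), sp)
  d3 <- dollo_reconstruct(single, tree)
  expect_equal(d3$assignments$gain_label, "b")
  expect_equal(d3$assignments$n_losses, 0L)

  none <- prob_row(c(0, 0, 0, 0), sp)
  expect_warning(d4 <- dollo_reconstruct(none, tree), "absent")
  expect_equal(nrow(d4$assignments), 0L)
})

test_that("Dollo equals the exhaustive minimal-loss search on small trees", {
  trees <- list(
    ape::read.tree(text = "((a,b),(c,d));"),
    ape::read.tree(text = "((a,b,c),(d,e));"),
    ape::read.tree(text = "(((a,b),c),(d,(e,f)));"))
  for (phy in trees) {
    tips <- phy$tip.label
    n <- length(tips)
    for (mask in 1:(2^n - 1L)) {
      present <- tips[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0]
      bin <- matrix(as.numeric(tips %in% present), nrow = 1,
                    dimnames = list("f", tips))
      d <- dollo_reconstruct(bin, phy)
      expect_equal(d$assignments$n_losses,
                   dollo_oracle_min_losses(phy, present),
                   info = paste(phy$tip.label[seq_len(n)], collapse = ""),
                   label = paste("pattern", mask))
    }
  }
})

test_that("heat-map ordering groups patterns and clusters within them", {
  expect_equal(uncentered_pearson(rbind(c(1, 0), c(1, 1)))[1, 2], 1 / sqrt(2))

  tree <- mini_tree()
  sp <- tree$phy$tip.label
  base_cho <- setNames(rep(0, length(sp)), sp)
  base_cho[tree$major_groups$choanoflagellates] <- 0.9
  base_ani <- setNames(rep(0, length(sp)), sp)
  base_ani[tree$major_groups$animals] <- 0.9
  set.seed(8)
  rows <- rbind(
    do.call(rbind, replicate(5, base_cho + runif(length(sp), 0, 0.05),
                             simplify = FALSE)),
    do.call(rbind, replicate(5, base_ani + runif(length(sp), 0, 0.05),
                             simplify = FALSE)))
  rownames(rows) <- paste0("f", 1:10)
  # duplicate a row: identical rows must end up adjacent
  rows["f2", ] <- rows["f1", ]
  ord <- heatmap_order(rows, tree)
  expect_equal(abs(diff(match(c("f1", "f2"), ord))), 1)
  # the two presence patterns are not interleaved
  blocks <- ifelse(ord %in% paste0("f", 1:5), "cho", "ani")
  expect_equal(length(rle(blocks)$values), 2L)

  # zero rows go last within their pattern
  rows2 <- rbind(rows, f0 = setNames(rep(0, length(sp)), sp))
  ord2 <- heatmap_order(rows2, tree)
  expect_equal(ord2[length(ord2)], "f0")
})
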