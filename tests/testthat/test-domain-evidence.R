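lib <- default_rule_library()

test_that("canonical receptor architectures match their rules", {
  expect_true(match_architecture(c("EGF", "EGF", "Notch", "TM", "Ank"),
                                 lib$Notch[[1]]))
  # order matters: Ank before the TM breaks the Notch architecture
  expect_false(match_architecture(c("EGF", "Ank", "Notch", "TM"),
                                  lib$Notch[[1]]))
  # TIR + kinase without a transmembrane domain
  expect_true(match_architecture(c("Pkinase", "TIR"), lib$KinaseTIR[[1]]))
  expect_false(match_architecture(c("Pkinase", "TIR", "TM"),
                                  lib$KinaseTIR[[1]]))
  # empty domain list never matches
  expect_false(match_architecture(character(0), lib$TLR[[1]]))
})

test_that("LRR and TIR family variants are interchangeable", {
  for (lrr in c("LRR_1", "LRR_4", "LRR_8", "LRRNT")) {
    for (tir in c("TIR", "TIR_2")) {
      expect_true(match_architecture(c(lrr, "TM", tir), lib$TLR[[1]]),
                  label = paste(lrr, tir))
    }
  }
  expect_false(match_architecture(c("LRR_4", "TM"), lib$TLR[[1]]))
})

test_that("evidence levels fall back from strong to weak", {
  expect_equal(classify_evidence(c("Cadherin", "GPS", "7tm_2"), lib$Flamingo),
               "strong")
  expect_equal(classify_evidence(c("GPS", "7tm_2", "EGF"), lib$Flamingo),
               "moderate")
  expect_equal(classify_evidence(c("GPS", "7tm_2"), lib$Flamingo), "weak")
  expect_equal(classify_evidence(c("GPS"), lib$Flamingo), "none")
  expect_equal(classify_evidence(c("Dicer_dimer", "PAZ", "Ribonuclease_3"),
                                 lib$Dicer), "strong")
  expect_equal(classify_evidence("Dicer_dimer", lib$Dicer), "moderate")
})

test_that("matching survives interleaved irrelevant domains", {
  set.seed(29)
  base <- c("LRR_1", "TM", "TIR")
  foreign <- c("WD40", "PDZ", "SH3_1", "Ras")
  for (trial in 1:20) {
    padded <- base
    for (f in sample(foreign, 3)) {
      at <- sample(0:length(padded), 1)
      padded <- append(padded, f, after = at)
    }
    expect_true(match_architecture(padded, lib$TLR[[1]]),
                label = paste(padded, collapse = ","))
  }
})

test_that("adding domains never lowers the level of negation-free rules", {
  set.seed(31)
  domains <- c("EGF", "Notch", "TM", "Ank")
  lvl <- classify_evidence(domains, lib$Notch)
  rank <- c(none = 0, weak = 1, moderate = 2, strong = 3)
  for (trial in 1:20) {
    extended <- append(domains, sample(c("WD40", "EGF", "Ank"), 1),
                       after = sample(0:length(domains), 1))
    expect_gte(rank[classify_evidence(extended, lib$Notch)], rank[lvl])
  }
})

test_that("the species evidence table finds exactly the planted architectures", {
  ann <- rbind(
    data.frame(species = "spA", protein = "p1",
               domain = c("LRR_4", "TM", "TIR"), start = c(10, 200, 260),
               end = c(60, 220, 380)),
    data.frame(species = "spB", protein = "p2",
               domain = c("LRR_4", "TM"), start = c(10, 200),
               end = c(60, 220)),
    data.frame(species = "spB", protein = "p3",
               domain = c("MH1", "MH2"), start = c(5, 120), end = c(100, 220)))
  tab <- species_evidence_table(ann, genes = c("TLR", "SMAD"))
  expect_equal(tab["spA", "TLR"], "strong")
  expect_equal(tab["spB", "TLR"], "none")
  expect_equal(tab["spB", "SMAD"], "strong")
  expect_equal(tab["spA", "SMAD"], "none")
  expect_error(species_evidence_table(ann, genes = "NotAGene"), "unknown gene")
})

test_that("overlap resolution keeps the best-scoring non-overlapping hits", {
  ann <- data.frame(protein = "p1",
                    domain = c("LRR_4", "Junk", "TIR"),
                    start = c(10, 15, 100), end = c(60, 70, 180),
                    score = c(55.0, 12.0, 80.0))
  res <- resolve_overlaps(ann)
  expect_equal(res$domain, c("LRR_4", "TIR"))
})

test_that("pfam_scan and Phobius outputs parse into annotations", {
  pfam <- tmp_lines(c(
    "# pfam_scan.pl output",
    "spA|p1  10  60  8  62  PF13855  LRR_4  Repeat  1  55  60  55.2  1.2e-12  1  LRR",
    "spA|p1 260 380 255 382  PF01582  TIR    Domain  1 120 122  80.1  3e-25    1  TIR"))
  ann <- read_pfam_scan(pfam)
  expect_equal(ann$domain, c("LRR_4", "TIR"))
  expect_equal(ann$species, c("spA", "spA"))
  expect_equal(ann$start, c(10L, 260L))

  phob <- tmp_lines(c(
    "SEQENCE ID                     TM SP PREDICTION",
    "spA|p1                          1  0 i220-240o",
    "spA|p2                          0  Y n8-20c25/26o"))
  tm <- read_phobius(phob)
  expect_equal(tm$domain[tm$protein == "spA|p1"], "TM")
  expect_equal(tm$start[tm$protein == "spA|p1"], 220L)
  sp <- tm[tm$protein == "spA|p2", ]
  expect_equal(sp$domain, "SP")
  expect_equal(c(sp$start, sp$end), c(1L, 25L))

  # combined annotation supports TM-dependent rules
  comb <- rbind(ann[, c("protein", "domain", "start", "end")],
                tm[tm$protein == "spA|p1", ])
  comb <- comb[order(comb$start), ]
  expect_true(match_architecture(comb$domain, lib$TLR[[1]]))
})

test_that("rule libraries extend through YAML", {
  path <- tmp_lines(yaml::as.yaml(list(
    MyGene = list(list(level = "strong", order_matters = TRUE,
                       tokens = list(list(names = "DomA"),
                                     list(names = "DomB"),
                                     list(names = "TM", negated = TRUE)))))),
    ext = ".yaml")
  lib2 <- read_rule_library(path)
  expect_true("MyGene" %in% names(lib2))
  expect_true(match_architecture(c("DomA", "DomB"), lib2$MyGene[[1]]))
  expect_false(match_architecture(c("DomA", "DomB", "TM"), lib2$MyGene[[1]]))
  expect_true("TLR" %in% names(lib2))
})
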