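test_that("rarity is inclusive at the MAF threshold and treats absence as rare", {
  expect_true(is_rare(make_variant(population_maf = 0.01)))
  expect_true(is_rare(make_variant(population_maf = NA)))
  expect_false(is_rare(make_variant(population_maf = 0.05)))
  expect_true(is_rare(make_variant(population_maf = 0.04),
                      maf_threshold = 0.05))
})

test_that("protein-altering and LOF ontology sets are as defined", {
  pa <- c(missense = TRUE, stop_gain = TRUE, stop_loss = TRUE,
          frameshift = TRUE, inframe_indel = TRUE, splice_acceptor = TRUE,
          splice_donor = TRUE, synonymous = FALSE, other = FALSE)
  lof <- c(missense = FALSE, stop_gain = TRUE, stop_loss = TRUE,
           frameshift = TRUE, inframe_indel = FALSE, splice_acceptor = TRUE,
           splice_donor = TRUE, synonymous = FALSE, other = FALSE)
  for (cons in names(pa)) {
    v <- make_variant(consequence = cons)
    expect_identical(is_protein_altering(v), unname(pa[cons]), label = cons)
    expect_identical(is_lof(v), unname(lof[cons]), label = cons)
  }
})

test_that("deleteriousness policy matches an enumerated truth table", {
  sift_l <- c("deleterious", "tolerated", "unknown")
  pp2_l <- c("damaging", "benign", "unknown")
  mt_l <- c("disease_causing", "polymorphism", "unknown")
  for (cons in c("missense", "frameshift")) {
    for (s in sift_l) for (p in pp2_l) for (m in mt_l) {
      v <- make_variant(consequence = cons, sift = s, polyphen2 = p,
                        mutation_taster = m)
      hits <- c(s == "deleterious", p == "damaging", m == "disease_causing")
      lof <- cons == "frameshift"
      expect_identical(is_predicted_deleterious(v, "any_tool"),
                       lof || any(hits),
                       label = paste(cons, s, p, m, "any"))
      expect_identical(is_predicted_deleterious(v, "all_tools"),
                       lof || all(hits),
                       label = paste(cons, s, p, m, "all"))
    }
  }
})

test_that("the six-variant toy cascade filters as derived by hand", {
  v <- rbind(
    make_variant("S1", position = 1, population_maf = 0.2),     # common missense
    make_variant("S1", position = 2, consequence = "synonymous"),# rare synonymous
    make_variant("S1", position = 3, sift = "tolerated",
                 polyphen2 = "benign", mutation_taster = "polymorphism"),
                                                                 # rare benign missense
    make_variant("S1", position = 4, cadd_phred = 25),           # rare damaging missense
    make_variant("S1", position = 5, consequence = "frameshift",
                 alt_allele = "GT", sift = "unknown",
                 polyphen2 = "unknown", mutation_taster = "unknown",
                 cadd_phred = 35),                               # rare frameshift
    make_variant("S1", position = 6, consequence = "splice_donor",
                 population_maf = NA, sift = "unknown",
                 polyphen2 = "unknown", mutation_taster = "unknown",
                 cadd_phred = 18))                               # absent-MAF splice donor
  res <- run_cascade(v)
  expect_equal(unname(res$stage_counts),
               c(6L, 5L, 4L, 3L, 2L, 2L))  # total/rare/PA/deleterious/LOF/CADD>=20
  expect_setequal(res$surviving$predicted_deleterious$position, c(4, 5, 6))
  expect_setequal(res$surviving$lof$position, c(5, 6))
  expect_setequal(res$surviving$cadd_strict$position, c(4, 5))
})

test_that("empty input yields an all-zero cascade", {
  res <- run_cascade(make_variant()[0, ])
  expect_true(all(res$stage_counts == 0))
})

test_that("cascade is monotone and equals independent filter composition", {
  set.seed(21)
  for (rep in 1:10) {
    v <- random_variants(200)
    res <- run_cascade(v)
    sc <- res$stage_counts
    expect_true(all(diff(sc[c("total", "rare", "protein_altering",
                              "predicted_deleterious")]) <= 0))
    expect_lte(sc[["lof"]], sc[["predicted_deleterious"]])
    expect_lte(sc[["cadd_strict"]], sc[["predicted_deleterious"]])

    # oracle: apply the three predicates independently to the unique set
    u <- unique_variants(v)
    keep <- is_rare(u) & is_protein_altering(u) &
      is_predicted_deleterious(u)
    expect_equal(sc[["predicted_deleterious"]], sum(keep))
    expect_setequal(variant_key(res$surviving$predicted_deleterious),
                    variant_key(u[keep, ]))
    # every LOF survivor is protein-altering
    expect_true(all(is_protein_altering(res$surviving$lof)))
  }
})

test_that("CADD boundaries are inclusive at 20 (strict tier) and 10 (relevance)", {
  v20 <- make_variant(cadd_phred = 20)
  res <- run_cascade(v20)
  expect_equal(res$stage_counts[["cadd_strict"]], 1L)

  panel <- tiny_panel()
  expect_true(is_phenotype_relevant(make_variant(cadd_phred = 10), "FH",
                                    panel))
  expect_false(is_phenotype_relevant(make_variant(cadd_phred = 9.99), "FH",
                                     panel))
})

test_that("phenotype relevance requires the phenotype's gene set and all rules", {
  panel <- tiny_panel()
  # rare LDLR missense, CADD 25, SIFT deleterious, FH
  expect_true(is_phenotype_relevant(make_variant(), "FH", panel))
  # right variant, wrong gene set: LPL frameshift is not FH-relevant
  lpl <- make_variant(gene = "LPL", chromosome = "chr8", position = 250,
                      consequence = "frameshift", cadd_phred = 35)
  expect_false(is_phenotype_relevant(lpl, "FH", panel))
  expect_true(is_phenotype_relevant(lpl, "HTG", panel))
  # CADD below 10 fails
  expect_false(is_phenotype_relevant(make_variant(cadd_phred = 8), "FH",
                                     panel))
  # benign-by-all-tools non-LOF fails
  expect_false(is_phenotype_relevant(
    make_variant(sift = "tolerated", polyphen2 = "benign",
                 mutation_taster = "polymorphism"), "FH", panel))
  expect_error(is_phenotype_relevant(make_variant(), "nope", panel),
               "valid keys")
})
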