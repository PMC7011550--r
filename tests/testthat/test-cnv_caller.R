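test_that("normalization maps constant and half-depth samples to ratios 1 and 0.5", {
  panel <- tiny_panel()
  dm <- flat_depth(panel, sprintf("R%02d", 1:6), depth = 100)
  norm <- normalize_depth(dm)
  expect_true(all(norm$depth == 1))

  dm2 <- dm
  dm2$depth[, "R01"] <- 50  # half depth everywhere: pure library-size effect
  norm2 <- normalize_depth(dm2, reference_samples = sprintf("R%02d", 2:6))
  expect_true(all(abs(norm2$depth[, "R01"] - 1) < 1e-12))  # scaled away

  dm3 <- dm
  dm3$depth[1:3, "R01"] <- 50  # genuine half-ratio over 3 targets
  norm3 <- normalize_depth(dm3, reference_samples = sprintf("R%02d", 2:6))
  expect_true(all(abs(norm3$depth[1:3, "R01"] - 0.5) < 1e-12))
})

test_that("normalization rejects all-zero samples and flags dead targets", {
  panel <- tiny_panel()
  dm <- flat_depth(panel, c("A", "B", "C", "D"))
  dm$depth[, "A"] <- 0
  expect_error(normalize_depth(dm), "all-zero")

  dm2 <- flat_depth(panel, c("A", "B", "C", "D"))
  dm2$depth[5, ] <- 0
  norm <- normalize_depth(dm2)
  expect_true(norm$uncallable[5])
  expect_true(all(is.na(norm$depth[5, ])))
})

test_that("reference-mean ratios center at 1 on noisy negative-binomial depth", {
  set.seed(31)
  panel <- tiny_panel()
  tg <- panel_targets(panel)
  samples <- sprintf("R%02d", 1:20)
  eff <- exp(rnorm(nrow(tg), 0, 0.3))
  d <- matrix(rnbinom(nrow(tg) * 20, size = 1000, mu = 200 * eff),
              nrow(tg), 20, dimnames = list(NULL, samples))
  norm <- normalize_depth(depth_matrix(tg, d))
  expect_true(all(abs(rowMeans(norm$depth) - 1) < 1e-9))  # by construction
})

test_that("a spiked heterozygous deletion is recovered as one exact call", {
  panel <- tiny_panel()
  dm <- sim_depth_with_spike(panel, spike_gene = "LDLR",
                             spike_targets = 2:4, ratio = 0.5, seed = 32)
  calls <- call_cnvs(dm, "TEST", sprintf("R%02d", 1:20))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$gene, "LDLR")
  expect_equal(calls$state, "het_deletion")
  expect_equal(calls$region, "Exons 1-3")  # targets 2:4 of 5'UTR,E1..E3,3'UTR
  expect_equal(calls$n_targets, 3L)
})

test_that("a whole-gene duplication spans 5'UTR to 3'UTR", {
  panel <- tiny_panel()
  dm <- sim_depth_with_spike(panel, spike_gene = "PCSK9",
                             spike_targets = 1:3, ratio = 1.5, seed = 33,
                             depth = 400)
  calls <- call_cnvs(dm, "TEST", sprintf("R%02d", 1:20))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$state, "duplication")
  expect_equal(calls$region, "5'UTR - 3'UTR")
})

test_that("a flat sample produces no calls", {
  panel <- tiny_panel()
  dm <- sim_depth_with_spike(panel, seed = 34)
  expect_equal(nrow(call_cnvs(dm, "TEST", sprintf("R%02d", 1:20))), 0)
})

test_that("calling is invariant to uniform scaling of the test library", {
  panel <- tiny_panel()
  dm <- sim_depth_with_spike(panel, spike_gene = "LDLR",
                             spike_targets = 2:4, ratio = 0.5, seed = 35)
  calls1 <- call_cnvs(dm, "TEST", sprintf("R%02d", 1:20))
  dm$depth[, "TEST"] <- round(dm$depth[, "TEST"] * 3)
  calls2 <- call_cnvs(dm, "TEST", sprintf("R%02d", 1:20))
  expect_equal(calls1[, c("gene", "region", "state", "n_targets")],
               calls2[, c("gene", "region", "state", "n_targets")])
})

test_that("caller input contracts are enforced", {
  panel <- tiny_panel()
  dm <- flat_depth(panel, c("A", "B", "C", "D"))
  expect_error(call_cnvs(dm, "A", c("A", "B", "C")), "reference set")
  expect_error(call_cnvs(dm, "A", c("B", "C")), "at least 3")
})

test_that("aggregation groups lesions, keeps breakpoints distinct, sums totals", {
  one <- data.frame(sample_id = "S1", gene = "LDLR", region = "Exon 4",
                    state = "het_deletion", breakpoint_tag = NA)
  u1 <- aggregate_unique(one)
  expect_equal(attr(u1, "unique_count"), 1L)
  expect_equal(attr(u1, "instance_count"), 1L)
  expect_equal(u1$instances_observed, 1L)

  # same span, different breakpoints: two unique rows
  dups <- data.frame(sample_id = c("S1", "S2"), gene = "LDLR",
                     region = "Exons 11-12", state = "duplication",
                     breakpoint_tag = c("a", "b"))
  u2 <- aggregate_unique(dups)
  expect_equal(attr(u2, "unique_count"), 2L)

  # het and hom instances of the same deletion are one lesion
  mix <- data.frame(sample_id = c("S1", "S2", "S3"), gene = "MTTP",
                    region = "Exons 10-15",
                    state = c("hom_deletion", "hom_deletion",
                              "het_deletion"),
                    breakpoint_tag = NA)
  u3 <- aggregate_unique(mix)
  expect_equal(attr(u3, "unique_count"), 1L)
  expect_equal(attr(u3, "instance_count"), 3L)
  expect_equal(u3$zygosity, "hom x2, het")

  # totals invariant on random call sets
  set.seed(36)
  for (rep in 1:5) {
    n <- sample(1:40, 1)
    calls <- data.frame(
      sample_id = sprintf("S%d", seq_len(n)),
      gene = sample(c("LDLR", "LPL"), n, TRUE),
      region = sample(c("Exon 1", "Exons 2-6"), n, TRUE),
      state = sample(c("het_deletion", "hom_deletion", "duplication"), n,
                     TRUE),
      breakpoint_tag = NA)
    u <- aggregate_unique(calls)
    expect_equal(attr(u, "instance_count"), n)
    expect_equal(sum(u$instances_observed), n)
    expect_gte(attr(u, "instance_count"), attr(u, "unique_count"))
    if (all(u$instances_observed == 1)) {
      expect_equal(attr(u, "unique_count"), attr(u, "instance_count"))
    }
  }
})

test_that("depth matrices round-trip through TSV", {
  panel <- tiny_panel()
  dm <- sim_depth_with_spike(panel, n_ref = 4, seed = 37)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_depth_matrix(dm, path)
  back <- read_depth_matrix(path)
  expect_equal(back$targets, dm$targets)
  expect_equal(back$depth, dm$depth)
})
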