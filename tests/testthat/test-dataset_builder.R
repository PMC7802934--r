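# Dataset ingestion, reverse augmentation, conflict resolution,
# protein clustering and structure ranking.

write_csv_fixture <- function(df) {
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE, quote = FALSE)
  f
}

test_that("mutation tables ingest with correct signs and policies", {
  f <- write_csv_fixture(data.frame(
    protein = c("P1", "P1", "P2"), structure = "1ABC", chain = "A",
    pos = c(10, 11, 5), wt = c("L", "G", "K"), mut = c("A", "V", "E"),
    ddg = c(1.5, -0.3, 0)))
  d <- read_mutation_table(f)
  expect_s3_class(d, "ddg_dataset")
  expect_equal(nrow(d), 3)
  expect_equal(d$ddg_exp, c(1.5, -0.3, 0))
  expect_true(all(d$direction == "forward"))

  # opposite sign convention
  d_flip <- read_mutation_table(f, sign_flip = TRUE)
  expect_equal(d_flip$ddg_exp, c(-1.5, 0.3, 0))

  # duplicate keys: error by default, mean on request
  f2 <- write_csv_fixture(data.frame(
    protein = "P1", structure = "1ABC", chain = "A", pos = 10,
    wt = "L", mut = "A", ddg = c(1.0, 2.0)))
  expect_error(read_mutation_table(f2), class = "mutstab_schema_error")
  expect_equal(read_mutation_table(f2, duplicates = "mean")$ddg_exp, 1.5)

  # missing column
  f3 <- write_csv_fixture(data.frame(protein = "P1", chain = "A"))
  expect_error(read_mutation_table(f3), class = "mutstab_schema_error")
})

test_that("reverse augmentation doubles, links and negates", {
  d <- toy_dataset("P1", 5, paired = FALSE)
  a <- augment_with_reverse(d)
  expect_equal(nrow(a), 10)
  fwd <- a[a$direction == "forward", ]
  rev <- a[a$direction == "reverse", ]
  expect_equal(rev$wt, fwd$mut)
  expect_equal(rev$mut, fwd$wt)
  expect_equal(rev$ddg_exp, -fwd$ddg_exp)
  expect_equal(rev$pair_id, fwd$pair_id)
  # pair sums are exactly zero
  expect_true(all(tapply(a$ddg_exp, a$pair_id, sum) == 0))
  # involution: forward slice recovers the input
  expect_equal(fwd$ddg_exp, d$ddg_exp)
  expect_equal(fwd$wt, d$wt)
  # augmenting twice is a state error; empty input passes through
  expect_error(augment_with_reverse(a), class = "mutstab_state_error")
  expect_equal(nrow(augment_with_reverse(d[0, ])), 0)
})

test_that("sign split puts ddG = 0 in the destabilizing bin", {
  d <- toy_dataset("P1", 10, paired = FALSE)
  d$ddg_exp <- c(0, 1.2, -0.5, 3, -2, 0.01, -0.01, 0, 5, -4)
  sp <- split_by_sign(d)
  expect_equal(nrow(sp$destabilizing), sum(d$ddg_exp >= 0))
  expect_equal(nrow(sp$stabilizing), sum(d$ddg_exp < 0))
  expect_true(all(sp$destabilizing$ddg_exp >= 0))
  expect_true(all(sp$stabilizing$ddg_exp < 0))
  expect_equal(nrow(sp$destabilizing) + nrow(sp$stabilizing), nrow(d))
})

test_that("test-set merging averages, drops conflicts and overlaps", {
  mk <- function(pos, ddg, protein = "P1") {
    mutstab:::as_ddg_dataset(data.frame(
      protein_id = protein, structure_id = "S", chain = "A",
      position = pos, icode = "", wt = "L", mut = "A", ddg_exp = ddg,
      direction = "forward", pair_id = NA_integer_,
      stringsAsFactors = FALSE))
  }
  training <- mk(99, 1.0)
  # {1.0, 1.5}: range 0.5 < 1.0 -> mean 1.25
  # {0.0, 1.0}: range 1.0, not < 1.0 -> dropped (strict boundary)
  sets <- list(mk(c(1, 2), c(1.0, 0.0)), mk(c(1, 2), c(1.5, 1.0)),
               mk(99, 1.0))
  merged <- merge_test_sets(sets, training)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$position, 1)
  expect_equal(merged$ddg_exp, 1.25)
  # the training-overlap record (pos 99) is gone
  expect_false(99 %in% merged$position)
  expect_lte(nrow(merged), sum(vapply(sets, nrow, 1L)))
})

test_that("protein clustering is single-linkage over both thresholds", {
  set.seed(5)
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  rnd <- function(n) paste(sample(aa, n, replace = TRUE), collapse = "")

  # identical pair -> one cluster
  s <- rnd(120)
  cl <- cluster_proteins(c(p1 = s, p2 = s))
  expect_equal(length(unique(cl$cluster)), 1)

  # unrelated pair -> two clusters
  cl2 <- cluster_proteins(c(x = rnd(200), y = rnd(200)))
  expect_equal(length(unique(cl2$cluster)), 2)

  # transitive chain a~b, b~c, a!~c -> one cluster of three.
  # b = a + tail; c = unrelated head + the same tail; a and c share
  # no region, so only single linkage through b can join them.
  core <- rnd(120)
  tail_seq <- rnd(100)
  seqs <- c(a = core,
            b = paste0(core, tail_seq),
            c = paste0(rnd(120), tail_seq))
  cl3 <- cluster_proteins(seqs)
  expect_equal(length(unique(cl3$cluster)), 1)
  # a and c alone are not similar
  cl_ac <- cluster_proteins(seqs[c("a", "c")])
  expect_equal(length(unique(cl_ac$cluster)), 2)

  # partition is invariant to input order
  cl3p <- cluster_proteins(seqs[c("c", "a", "b")])
  expect_equal(cl3p[order(cl3p$protein), ], cl3[order(cl3$protein), ])

  expect_error(cluster_proteins(c(p = "")), class = "mutstab_value_error")
})

test_that("structure ranking follows the documented criteria", {
  cand <- data.frame(
    structure_id = c("het", "mut", "lig", "nmr", "lowres", "best"),
    multimer = c("heteromer", "monomer", "monomer", "monomer",
                 "monomer", "monomer"),
    is_wild_type = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
    n_ligands = c(0, 0, 2, 0, 0, 0),
    method = c("xray", "xray", "xray", "nmr", "xray", "xray"),
    resolution = c(1.0, 1.0, 1.0, NA, 2.8, 1.5),
    stringsAsFactors = FALSE)
  ranked <- rank_structures(cand)
  expect_equal(ranked$structure_id[1], "best")
  expect_equal(ranked$structure_id[nrow(ranked)], "het")
  # crystal structures worse than 3 A are excluded
  bad <- data.frame(structure_id = "worse", multimer = "monomer",
                    is_wild_type = TRUE, n_ligands = 0, method = "xray",
                    resolution = 3.5, stringsAsFactors = FALSE)
  expect_equal(nrow(rank_structures(bad)), 0)
})
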