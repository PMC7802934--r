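# PSSM parsing and the ten-feature computation.

test_that("synthetic PSSM round-trips through the reader, both dialects", {
  seq <- "MKVLAWGY"
  full <- read_psiblast_pssm(paste(
    make_synthetic_pssm(seq, 5, seed = 2, trailing = TRUE),
    collapse = "\n"))
  bare <- read_psiblast_pssm(paste(
    make_synthetic_pssm(seq, 5, seed = 2, trailing = FALSE),
    collapse = "\n"))
  expect_equal(full$sequence, seq)
  expect_equal(nrow(full$scores), nchar(seq))
  expect_identical(full$scores, bare$scores)
  expect_error(read_psiblast_pssm(""), class = "mutstab_format_error")
})

test_that("pssm_feature implements the mut-minus-wt difference", {
  p <- read_psiblast_pssm(paste(make_synthetic_pssm("ACDEF", 0, seed = 6),
                                collapse = "\n"))
  expect_equal(pssm_feature(p, 2, "C", "W"),
               unname(p$scores[2, "W"] - p$scores[2, "C"]))
  expect_equal(pssm_feature(p, 3, "D", "D"), 0)
  # hand-planted scores
  p$scores[4, "E"] <- 5L
  p$scores[4, "K"] <- -3L
  expect_equal(pssm_feature(p, 4, "E", "K"), -8)
  expect_equal(pssm_feature(p, 4, "E", "K", convention = "wt"), 5)
  expect_equal(pssm_feature(p, 4, "E", "K", convention = "mut"), -3)
  expect_error(pssm_feature(p, 2, "W", "A"),
               class = "mutstab_consistency_error")
})

test_that("delta_omh is antisymmetric over all 400 ordered pairs", {
  aa <- names(omh_scale())
  for (a in aa) for (b in aa) {
    expect_equal(delta_omh(a, b) + delta_omh(b, a), 0)
  }
  expect_equal(delta_omh("A", "A"), 0)
  sc <- omh_scale()
  expect_equal(delta_omh("A", "V"), sc[["V"]] - sc[["A"]])
  expect_error(delta_omh("A", "Z"), class = "mutstab_lookup_error")
})

test_that("burial composition counts buried residue classes", {
  st <- parse_pdb(paste(make_toy_structure(
    20, sequence = paste(rep("L", 20), collapse = "")), collapse = "\n"))
  prof <- sasa_profile(st)
  # synthetic profile: exactly 2 buried leucines
  prof$location <- c(rep("COR", 2), rep("SUR", 18))
  comp <- burial_composition(st, prof)
  expect_equal(comp$N_All, 20)
  expect_equal(comp$N_L, 2)
  expect_equal(comp$P_L, 0.1)
  expect_equal(comp$P_FWY, 0)
  expect_equal(comp$P_RKDE, 0)
  # all buried, all leucine
  prof$location <- rep("COR", 20)
  comp <- burial_composition(st, prof)
  expect_equal(comp$P_L, 1)
  expect_equal(comp$P_FWY + comp$P_RKDE, 0)
  # zero buried
  prof$location <- rep("SUR", 20)
  expect_equal(burial_composition(st, prof)$P_L, 0)
  expect_error(burial_composition(st, prof[-1, ]),
               class = "mutstab_coverage_error")
})

test_that("window counts scan 23 sites and truncate at termini", {
  expect_equal(unname(window_counts(strrep("A", 40), 20)), c(0, 0))
  expect_equal(unname(window_counts(strrep("L", 30), 15)), c(23, 0))
  set.seed(31)
  s40 <- paste(sample(names(omh_scale()), 40, replace = TRUE),
               collapse = "")
  wc <- window_counts(s40, 5)
  win <- strsplit(substring(s40, 1, 16), "")[[1]]  # [5-11, 5+11] clipped
  expect_equal(unname(wc["N_Hydro"]),
               sum(win %in% c("V","I","L","F","M","W","Y","C")))
  expect_equal(unname(wc["N_Charg"]), sum(win %in% c("R","K","D","E")))
  expect_lte(sum(wc), 23)
  expect_error(window_counts("ACD", 9), class = "mutstab_index_error")
})

test_that("naive mutator truncates the side chain and nothing else", {
  st <- parse_pdb(paste(make_toy_structure(
    12, sequence = "LLLLLLLLLLLL"), collapse = "\n"))
  mut <- mutate_structure_naive(st, "A", 5, wt = "L", mut = "A")
  at5 <- mut$atoms[mut$atoms$resno == 5, ]
  expect_setequal(at5$elety, c("N", "CA", "C", "O", "CB"))
  expect_equal(unique(at5$aa), "A")
  expect_equal(mut$atoms[mut$atoms$resno != 5, ],
               st$atoms[st$atoms$resno != 5, ])
  # glycine target loses the C-beta as well
  mutg <- mutate_structure_naive(st, "A", 5, wt = "L", mut = "G")
  expect_setequal(mutg$atoms$elety[mutg$atoms$resno == 5],
                  c("N", "CA", "C", "O"))
  # self-mutation is a no-op; absent site and wrong wt error
  expect_identical(mutate_structure_naive(st, "A", 5, "L", "L"), st)
  expect_error(mutate_structure_naive(st, "A", 99, "L", "A"),
               class = "mutstab_index_error")
  expect_error(mutate_structure_naive(st, "A", 5, "K", "A"),
               class = "mutstab_consistency_error")
})

test_that("the assembled vector equals its member-wise computation", {
  b <- small_bundle()
  pid <- b$dataset$protein_id[1]
  st <- b$structures[[pid]]
  prof <- sasa_profile(st, sphere_points = 480)
  rec <- b$dataset[1, ]
  fv <- build_feature_vector(rec, st, prof, b$pssms[[pid]],
                             b$conservation)
  expect_length(fv, 10)
  expect_true(all(is.finite(fv)))

  seq_pos <- mutstab:::sequence_position(st, rec$chain, rec$position)
  expect_equal(fv[["PSSM"]],
               pssm_feature(b$pssms[[pid]], seq_pos, rec$wt, rec$mut))
  expect_equal(fv[["dOMH"]], delta_omh(rec$wt, rec$mut))
  expect_equal(fv[["SASA_sol"]], unname(max_asa_reference()[rec$wt]))
  i <- which(prof$chain == rec$chain & prof$resno == rec$position)
  expect_equal(fv[["SASA_pro"]], prof$sasa_A2[i])
  comp <- burial_composition(st, prof)
  expect_equal(fv[["P_L"]], comp$P_L)
  wc <- window_counts(structure_sequence(st), seq_pos)
  expect_equal(fv[["N_Hydro"]], unname(wc["N_Hydro"]))

  # counts and fractions within their bounds for all records
  expect_true(all(b$features[, c("N_Hydro", "N_Charg")] <= 23))
  expect_true(all(b$features[, c("P_FWY", "P_RKDE", "P_L")] >= 0 &
                  b$features[, c("P_FWY", "P_RKDE", "P_L")] <= 1))
  expect_true(all(rowSums(b$features[, c("P_FWY", "P_RKDE", "P_L")]) <= 1))
})

test_that("reverse features negate the antisymmetric components exactly", {
  b <- small_bundle()
  n <- nrow(b$dataset) / 2
  expect_equal(b$features[1:n, "dOMH"] + b$features[n + 1:n, "dOMH"],
               rep(0, n))
  expect_equal(b$features[1:n, "PSSM"] + b$features[n + 1:n, "PSSM"],
               rep(0, n))
  expect_equal(b$features[1:n, "dCS"] + b$features[n + 1:n, "dCS"],
               rep(0, n))
})

test_that("missing providers raise named errors", {
  b <- small_bundle()
  pid <- b$dataset$protein_id[1]
  st <- b$structures[[pid]]
  prof <- sasa_profile(st, sphere_points = 480)
  rec <- b$dataset[1, ]
  expect_error(build_feature_vector(rec, st, prof, NULL, b$conservation),
               "pssm", class = "mutstab_missing_feature_error")
  empty_cons <- b$conservation[0, ]
  expect_error(build_feature_vector(rec, st, prof, b$pssms[[pid]],
                                    empty_cons),
               "conservation", class = "mutstab_missing_feature_error")
})
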