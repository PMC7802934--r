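# Agreement metrics, ROC/MCC, statistical comparisons and the five
# cross-validation protocols.

test_that("R, RMSE and slope match hand computation on a fixture", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 6)
  # frozen hand computation: cov = 10, var_x = 10, var_y = 14.8
  expect_equal(pearson_r(x, y), 10 / sqrt(10 * 14.8), tolerance = 1e-12)
  expect_equal(rmse(y, x), 1)
  expect_equal(fit_slope(y, x), 1)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(rmse(x, x), 0)
  expect_error(pearson_r(x, rep(1, 5)), class = "mutstab_value_error")
  expect_error(pearson_r(x, y[1:4]), class = "mutstab_shape_error")
})

test_that("MCC follows the printed formula with the 0 convention", {
  expect_equal(mcc(50, 50, 0, 0), 1)
  expect_equal(mcc(25, 25, 25, 25), 0)
  # arithmetic oracle: (40*30 - 10*20)/sqrt(50*60*40*50)
  expect_equal(mcc(40, 30, 10, 20), 1000 / sqrt(6e6), tolerance = 1e-12)
  expect_equal(mcc(0, 10, 0, 5), 0)  # zero denominator factor
  expect_error(mcc(0, 0, 0, 0), class = "mutstab_value_error")
  expect_error(mcc(-1, 2, 3, 4), class = "mutstab_value_error")
})

test_that("ROC analysis equals the concordant-pair statistic", {
  # 6-point enumerable fixture with a tie
  scores <- c(0.9, 0.8, 0.7, 0.7, 0.3, 0.1)
  labels <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  r <- roc_analysis(scores, labels)
  expect_equal(r$auc, auc_bruteforce(scores, labels), tolerance = 1e-12)
  # against the independent ROC implementation
  pr <- pROC::roc(labels, scores, levels = c(FALSE, TRUE),
                  direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)

  # perfect separation
  expect_equal(roc_analysis(c(3, 2, 1, 0), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  # null scores, large n
  set.seed(9)
  s <- rnorm(2000); l <- sample(c(TRUE, FALSE), 2000, replace = TRUE)
  expect_lt(abs(roc_analysis(s, l)$auc - 0.5), 0.05)
  expect_error(roc_analysis(1:3, c(TRUE, TRUE, TRUE)),
               class = "mutstab_class_error")

  # max-MCC agrees with a brute-force sweep on the fixture
  ms <- vapply(unique(scores), function(t) {
    pos <- scores >= t
    mcc(sum(pos & labels), sum(!pos & !labels),
        sum(pos & !labels), sum(!pos & labels))
  }, numeric(1))
  expect_equal(r$max_mcc, max(ms), tolerance = 1e-12)
})

test_that("extreme labelling uses inclusive 1.0 kcal/mol thresholds", {
  lab <- label_extremes(c(1.0, 0.99, -1.0, -0.99, 2.5, 0))
  expect_equal(lab$highly_destabilizing,
               c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(lab$highly_stabilizing,
               c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
})

test_that("anti-symmetry audit returns R_FR and mean pairwise bias", {
  pf <- c(1.2, -0.5, 2.2, 0.3, -1.8)
  expect_equal(antisymmetry_audit(pf, -pf), list(R_FR = -1, bias = 0))
  expect_equal(antisymmetry_audit(pf, pf)$R_FR, 1)
  set.seed(4)
  pr <- -pf + rnorm(5, 0, 0.1)
  a <- antisymmetry_audit(pf, pr)
  expect_equal(a$R_FR, cor(pf, pr))
  expect_equal(a$bias, mean(pf + pr))
  expect_error(antisymmetry_audit(pf, pf[1:3]),
               class = "mutstab_shape_error")
})

test_that("Fisher z comparison behaves at the null and far from it", {
  expect_equal(compare_correlations_independent(0.5, 100, 0.5, 80)$p_value,
               1)
  expect_lt(compare_correlations_independent(0.9, 500, 0.1, 500)$p_value,
            1e-6)
  a <- compare_correlations_independent(0.7, 120, 0.3, 90)
  b <- compare_correlations_independent(0.3, 90, 0.7, 120)
  expect_equal(a$p_value, b$p_value)
  # closed form check
  z <- (atanh(0.7) - atanh(0.3)) / sqrt(1 / 117 + 1 / 87)
  expect_equal(a$z, z)
  expect_error(compare_correlations_independent(1, 50, 0.2, 50),
               class = "mutstab_value_error")
})

test_that("DeLong test is consistent with the ROC AUCs", {
  set.seed(12)
  l <- rep(c(TRUE, FALSE), each = 60)
  s1 <- rnorm(120) + l
  s2 <- rnorm(120) + 0.5 * l
  d <- delong_auc_test(s1, s2, l)
  expect_equal(d$auc_a, roc_analysis(s1, l)$auc, tolerance = 1e-12)
  expect_equal(d$auc_b, roc_analysis(s2, l)$auc, tolerance = 1e-12)
  expect_true(d$p_value >= 0 && d$p_value <= 1)
  expect_equal(delong_auc_test(s1, s1, l)$p_value, 1)
  expect_error(delong_auc_test(s1, s2, rep(TRUE, 120)),
               class = "mutstab_class_error")
})

test_that("CV splits follow each protocol's structure", {
  d <- toy_dataset(c("P1", "P2", "P3"), 10, seed = 2)  # 20 records each

  # CV4: one round per protein, test = that protein's mutations
  sp4 <- cv_splits(d, cv_scheme("CV4"))
  expect_length(sp4, 3)
  for (s in sp4) {
    expect_equal(length(unique(d$protein_id[s$test])), 1)
    expect_setequal(c(s$train, s$test), seq_len(nrow(d)))
  }
  # coverage: every mutation tested exactly once
  tested <- unlist(lapply(sp4, `[[`, "test"))
  expect_setequal(tested, seq_len(nrow(d)))
  expect_equal(length(tested), nrow(d))

  # CV5 groups similar proteins; here give P1+P2 one cluster
  cl <- data.frame(protein = c("P1", "P2", "P3"), cluster = c(1, 1, 2))
  sp5 <- cv_splits(d, cv_scheme("CV5"), clusters = cl)
  expect_length(sp5, 2)
  expect_setequal(unique(d$protein_id[sp5[[1]]$test]), c("P1", "P2"))
  expect_setequal(unlist(lapply(sp5, `[[`, "test")), seq_len(nrow(d)))
  expect_error(cv_splits(d, cv_scheme("CV5")),
               class = "mutstab_config_error")

  # CV1 fractions
  sp1 <- cv_splits(d, cv_scheme("CV1", repeats = 5, seed = 7))
  for (s in sp1)
    expect_equal(length(s$train), 0.8 * nrow(d))
})

test_that("CV3 caps mutations per protein at min(n, cap)", {
  # protein sizes 30, 10, 25 mutations (25 = 12 pairs + 1 unpaired)
  d30 <- toy_dataset("P1", 15, seed = 3)
  d10 <- toy_dataset("P2", 5, seed = 4)
  d25p <- toy_dataset("P3", 12, seed = 5)
  solo <- mutstab:::as_ddg_dataset(data.frame(
    protein_id = "P3", structure_id = "P3", chain = "A", position = 99,
    icode = "", wt = "K", mut = "E", ddg_exp = 0.4,
    direction = "forward", pair_id = NA_integer_,
    stringsAsFactors = FALSE))
  d <- mutstab:::as_ddg_dataset(
    rbind(as.data.frame(d30), as.data.frame(d10), as.data.frame(d25p),
          as.data.frame(solo)))
  # re-key pair ids so they stay unique across the bind
  d$pair_id <- ifelse(is.na(d$pair_id), NA,
                      as.integer(factor(paste(d$protein_id, d$pair_id))))
  sp <- cv_splits(d, cv_scheme("CV3", repeats = 5, cap = 20, seed = 11))
  for (s in sp) {
    subset_n <- length(s$train) + length(s$test)
    expect_equal(subset_n, 20 + 10 + 20)
    per_prot <- table(d$protein_id[c(s$train, s$test)])
    expect_true(all(per_prot <= 20))
  }
})

test_that("no forward/reverse pair ever straddles a split", {
  d <- toy_dataset(c("P1", "P2"), 12, seed = 6)
  for (kind in c("CV1", "CV2", "CV3")) {
    sp <- cv_splits(d, cv_scheme(kind, repeats = 10, seed = 13))
    for (s in sp) {
      tr_pairs <- d$pair_id[s$train]
      te_pairs <- d$pair_id[s$test]
      expect_length(intersect(tr_pairs, te_pairs), 0)
    }
  }
})

test_that("run_cv reports per-round metrics and the pooled audit", {
  b <- small_bundle()
  cv <- run_cv(b$dataset, b$features,
               cv_scheme("CV4", seed = 5),
               ddg_model_params(n_trees = 80))
  expect_equal(nrow(cv$rounds), length(unique(b$dataset$protein_id)))
  expect_true(all(is.finite(cv$rounds$RMSE)))
  expect_true(all(!is.na(cv$predictions)))
  expect_true(cv$summary$pooled_R_FR < 0)  # anti-symmetric by training
  f <- tempfile()
  write_cv_report(cv, f)
  js <- jsonlite::read_json(paste0(f, "_summary.json"))
  expect_true(all(c("R", "RMSE", "R_FR") %in% names(js)))
  expect_true(file.exists(paste0(f, "_rounds.tsv")))
})
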