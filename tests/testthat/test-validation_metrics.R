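# brute-force comparison oracle: literal per-record loop over the joined
# tables, no grouping machinery
oracle_compare <- function(truth, test) {
  n_comp <- 0L; n_tot <- 0L; n_opp <- 0L
  for (i in seq_len(nrow(test))) {
    j <- which(truth$sample_id == test$sample_id[i] &
                 truth$rsid == test$rsid[i])
    if (length(j) != 1L) next
    if (truth$gt_class[j] == "MISSING") next
    n_comp <- n_comp + 1L
    if (test$gt_class[i] != truth$gt_class[j]) n_tot <- n_tot + 1L
    if ((truth$gt_class[j] == "HOMREF" && test$gt_class[i] == "HOMALT") ||
        (truth$gt_class[j] == "HOMALT" && test$gt_class[i] == "HOMREF")) {
      n_opp <- n_opp + 1L
    }
  }
  c(n_comp, n_tot, n_opp)
}

random_calls <- function(n_samples, n_markers, seed, missing_frac = 0.1) {
  set.seed(seed)
  grid <- expand.grid(sample_id = paste0("S", seq_len(n_samples)),
                      rsid = paste0("rs", seq_len(n_markers)),
                      stringsAsFactors = FALSE)
  grid$gt_class <- sample(c("HOMREF", "HET", "HOMALT", "MISSING"),
                          nrow(grid), replace = TRUE,
                          prob = c(0.4, 0.3, 0.3 - missing_frac, missing_frac))
  grid
}

test_that("error semantics: opposite errors increment both, HET errors only total", {
  truth <- calls_df("S1", c("rs1", "rs2", "rs3"),
                    c("HOMREF", "HOMREF", "HOMALT"))
  test <- calls_df("S1", c("rs1", "rs2", "rs3"),
                   c("HOMALT", "HET", "HOMREF"))
  s <- compare_genotypes(truth, test)
  expect_equal(s$n_compared, 3L)
  expect_equal(s$n_total_error, 3L)
  expect_equal(s$n_opposite_error, 2L)  # rs1 and rs3 flip homozygotes

  perfect <- compare_genotypes(truth, truth)
  expect_equal(perfect$frac_total, 0)
  expect_equal(perfect$frac_opposite, 0)
})

test_that("truth MISSING is excluded and unmatched test records are reported", {
  truth <- calls_df("S1", c("rs1", "rs2"), c("MISSING", "HOMREF"))
  test <- calls_df("S1", c("rs1", "rs2", "rs9"), c("HET", "HET", "HOMREF"))
  s <- compare_genotypes(truth, test)
  expect_equal(s$n_compared, 1L)  # rs1 excluded (truth MISSING), rs9 unmatched
  expect_equal(s$n_total_error, 1L)
  expect_equal(attr(s, "unmatched")$rsid, "rs9")
})

test_that("compare_genotypes matches the brute-force oracle on random tables", {
  for (seed in 1:10) {
    truth <- random_calls(4, 12, seed)
    test <- random_calls(4, 12, seed + 50)
    # add a replicate dimension on the test side
    test2 <- rbind(cbind(test, replicate = 1L),
                   cbind(random_calls(4, 12, seed + 100), replicate = 2L))
    s <- compare_genotypes(truth, test2)
    want <- oracle_compare(truth, test2)
    expect_equal(s$n_compared, want[1], label = paste("seed", seed))
    expect_equal(s$n_total_error, want[2])
    expect_equal(s$n_opposite_error, want[3])
    expect_true(s$n_opposite_error <= s$n_total_error)
    expect_true(s$n_total_error <= s$n_compared)

    # grouped totals equal the pooled totals
    g <- compare_genotypes(truth, test2, group_by = "replicate")
    expect_equal(sum(g$n_compared), s$n_compared)
    expect_equal(sum(g$n_total_error), s$n_total_error)

    # permutation of replicate order changes nothing
    shuf <- test2[sample(nrow(test2)), ]
    s2 <- compare_genotypes(truth, shuf)
    expect_equal(s2$n_total_error, s$n_total_error)
    expect_equal(s2$n_opposite_error, s$n_opposite_error)
  }
})

test_that("exact_match_fraction counts matching replicate phenotypes", {
  truth <- data.frame(eye = "blue", hair = "red", skin = "pale")
  reps <- data.frame(eye = c(rep("blue", 91), rep("brown", 9)))
  expect_equal(exact_match_fraction(truth, reps, "eye"), 0.91)
  expect_equal(exact_match_fraction(truth, reps[reps$eye == "blue", , drop = FALSE],
                                    "eye"), 1.0)
  expect_equal(exact_match_fraction(truth, data.frame(eye = rep("brown", 5)),
                                    "eye"), 0.0)
  truth_na <- data.frame(hair = "unavailable")
  expect_warning(out <- exact_match_fraction(truth_na,
                                             data.frame(hair = "red"), "hair"),
                 "unavailable")
  expect_true(is.na(out))
})

test_that("red-hair confusion reproduces the pooled-comparison semantics", {
  # 8 truth-red individuals x 10 replicates = 80 comparisons, 31 non-red
  truth <- data.frame(sample_id = c(paste0("R", 1:8), paste0("N", 1:5)),
                      hair = c(rep("red", 8), rep("blonde", 5)),
                      stringsAsFactors = FALSE)
  red_reps <- do.call(rbind, lapply(1:8, function(i) {
    data.frame(sample_id = paste0("R", i),
               hair = rep("red", 10), stringsAsFactors = FALSE)
  }))
  miss <- sample(seq_len(nrow(red_reps)), 31)
  red_reps$hair[miss] <- "blonde"
  nonred_reps <- do.call(rbind, lapply(1:5, function(i) {
    data.frame(sample_id = paste0("N", i),
               hair = rep("blonde", 10), stringsAsFactors = FALSE)
  }))
  conf <- red_hair_confusion(truth, rbind(red_reps, nonred_reps))
  expect_equal(conf$n_red_comparisons, 80L)
  expect_equal(conf$fn_rate, 31 / 80)  # 0.3875
  expect_equal(conf$fp_rate, 0)

  all_right <- red_hair_confusion(truth, data.frame(sample_id = truth$sample_id,
                                                    hair = truth$hair))
  expect_equal(all_right$fp_rate, 0)
  expect_equal(all_right$fn_rate, 0)

  no_red <- truth[truth$hair != "red", ]
  expect_warning(conf2 <- red_hair_confusion(no_red, no_red), "no truth-red")
  expect_true(is.na(conf2$fn_rate))
})

test_that("high-error combination flagging applies the mean high-coverage criterion", {
  combos <- expand.grid(sample_id = c("A", "B", "C"),
                        rsid = c("rs1", "rs2"),
                        coverage = c("original", "2x", "1x", "0.5x", "0.1x"),
                        stringsAsFactors = FALSE)
  combos$error_frac <- 0
  combos$n_errors <- 0L
  pick <- function(s, r, cv) combos$sample_id == s & combos$rsid == r &
    combos$coverage == cv
  # A/rs1: (0.30, 0.25, 0.20) at the high coverages -> mean 0.25, flagged
  combos$error_frac[pick("A", "rs1", "original")] <- 0.30
  combos$error_frac[pick("A", "rs1", "2x")] <- 0.25
  combos$error_frac[pick("A", "rs1", "1x")] <- 0.20
  # B/rs2: high only at low coverage -> not flagged
  combos$error_frac[pick("B", "rs2", "0.1x")] <- 0.9
  res <- flag_high_error_combinations(combos)
  expect_equal(nrow(res$flagged), 1L)
  expect_equal(res$flagged$sample_id, "A")
  expect_equal(res$flagged$rsid, "rs1")
  expect_equal(res$flagged$mean_high_error, 0.25)

  # all-zero combination is never flagged
  zeros <- combos; zeros$error_frac <- 0
  expect_equal(nrow(flag_high_error_combinations(zeros)$flagged), 0L)

  # attribution: engineer flagged combos holding 47% of all errors
  combos$n_errors[pick("A", "rs1", "original")] <- 20L
  combos$n_errors[pick("A", "rs1", "0.1x")] <- 27L
  combos$n_errors[pick("B", "rs2", "0.1x")] <- 40L
  combos$n_errors[pick("C", "rs2", "0.1x")] <- 13L
  res2 <- flag_high_error_combinations(combos)
  expect_equal(res2$attribution, 47 / 100)

  # a combination missing a high-coverage level is skipped with a warning
  dropped <- combos[!(pick("A", "rs1", "2x")), ]
  expect_warning(res3 <- flag_high_error_combinations(dropped), "skipped")
  expect_equal(nrow(res3$flagged), 0L)
})

test_that("imputation variability is one minus the modal genotype frequency", {
  reps <- calls_df("S1", "rs1", c(rep("HET", 7), rep("HOMREF", 3)))
  v <- imputation_variability(reps)
  expect_equal(v$minor_genotype_freq, 0.3)

  same <- calls_df("S1", "rs1", rep("HOMALT", 10))
  expect_equal(imputation_variability(same)$minor_genotype_freq, 0)

  # bound: value in [0, 1 - 1/k] for k observed classes
  set.seed(9)
  for (rep in 1:20) {
    g <- sample(c("HOMREF", "HET", "HOMALT"), 12, replace = TRUE)
    v <- imputation_variability(calls_df("S", "r", g))$minor_genotype_freq
    k <- length(unique(g))
    expect_gte(v, 0)
    expect_lte(v, 1 - 1 / k)
  }

  expect_error(imputation_variability(calls_df("S1", "rs1", "HET")),
               ">= 2 replicates")
})
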