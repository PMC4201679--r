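# Cross-validation design and evaluation statistics.

test_that("family folds keep whole half-sib families together, two per fold", {
  pop <- small_pop()
  plan <- make_family_folds(pop$pedigree, k = 4)
  expect_equal(plan$scenario, "family")
  expect_equal(sort(unname(table(plan$families))), rep(2L, 4),
               ignore_attr = TRUE)
  # no test individual shares a sire or dam with a training individual
  ped <- pop$pedigree
  f2 <- ped[ped$generation == "F2", ]
  for (fold in 1:4) {
    test_ids <- names(plan$assignment)[plan$assignment == fold]
    train_ids <- setdiff(f2$id, test_ids)
    ti <- f2[match(test_ids, f2$id), ]
    tr <- f2[match(train_ids, f2$id), ]
    expect_equal(length(intersect(ti$sire, tr$sire)), 0)
    expect_equal(length(intersect(ti$dam, tr$dam)), 0)
  }
})

test_that("eight equal families of 64 give four folds of 128", {
  ped <- data.frame(
    id = sprintf("f2_%03d", 1:512),
    sire = rep(sprintf("sire%d", 1:8), each = 64),
    dam = "d", sex = "F", generation = "F2", hatch = 1L)
  plan <- make_family_folds(ped, 4)
  expect_equal(plan$test_n, rep(128L, 4))
})

test_that("greedy family packing is near the exhaustive optimum on uneven families", {
  sizes <- c(70, 68, 66, 65, 64, 63, 60, 55)
  ped <- data.frame(
    id = sprintf("x%03d", seq_len(sum(sizes))),
    sire = rep(sprintf("s%d", 1:8), sizes),
    dam = "d", sex = "F", generation = "F2", hatch = 1L)
  plan <- make_family_folds(ped, 4)
  spread_greedy <- max(plan$test_n) - min(plan$test_n)

  # exhaustive oracle over all pairings of 8 families into 4 unordered pairs
  pairings <- function(v) {
    if (length(v) == 2) return(list(list(v)))
    first <- v[1]
    out <- list()
    for (j in 2:length(v)) {
      rest <- v[-c(1, j)]
      for (sub in pairings(rest))
        out[[length(out) + 1]] <- c(list(c(first, v[j])), sub)
    }
    out
  }
  spreads <- vapply(pairings(seq_along(sizes)), function(p) {
    tot <- vapply(p, function(ij) sum(sizes[ij]), 1)
    max(tot) - min(tot)
  }, 1)
  expect_equal(length(spreads), 105)   # 7!! pairings of 8 items
  expect_lte(min(spreads), spread_greedy)
  expect_lte(spread_greedy, 8)
})

test_that("family folds need at least as many families as folds", {
  ped <- data.frame(id = c("a", "b"), sire = c("s1", "s1"), dam = "d",
                    sex = "F", generation = "F2", hatch = 1L)
  expect_error(make_family_folds(ped, 4), "fewer")
})

test_that("random folds reproduce the study's 511/4 arithmetic", {
  ids <- sprintf("b%03d", 1:511)
  plan <- make_random_folds(ids, 4, seed = 6)
  expect_equal(plan$test_n, c(128L, 128L, 128L, 127L))
  expect_equal(plan$train_n, c(383L, 383L, 383L, 384L))
  # partition: disjoint and exhaustive
  expect_setequal(names(plan$assignment), ids)
  expect_equal(anyDuplicated(names(plan$assignment)), 0L)

  plan8 <- make_random_folds(letters[1:8], 4, seed = 7)
  expect_equal(plan8$test_n, rep(2L, 4))
  expect_error(make_random_folds(character(0), 4), "empty")
})

test_that("corrected phenotypes remove estimated fixed effects only", {
  ph <- data.frame(id = c("a", "b", "c", "d"),
                   y = c(10, 12, 9, 15),
                   sex = c("M", "F", "M", "F"),
                   hatch = c(1L, 1L, 2L, 2L))
  fit0 <- list(b = c("(Intercept)" = 3))
  expect_equal(unname(corrected_phenotypes(ph, fit0)), ph$y)

  fit <- list(b = c("(Intercept)" = 3, sexM = 2, hatch2 = -1))
  yc <- corrected_phenotypes(ph, fit)
  expect_equal(unname(yc), c(10 - 2, 12, 9 - 2 + 1, 15 + 1))

  # adding a constant to y shifts y_c by the same constant
  ph2 <- ph; ph2$y <- ph$y + 100
  expect_equal(unname(corrected_phenotypes(ph2, fit)), unname(yc) + 100)

  # unknown non-reference level errors
  ph3 <- ph; ph3$hatch[1] <- 9L; ph3$hatch[2] <- 3L
  expect_error(corrected_phenotypes(ph3, fit), "hatch level")
})

test_that("correcting for true nonzero fixed effects improves the correlation with genetic merit", {
  pop <- small_pop()
  ph <- pop$phenotypes$BW6
  A <- pedigree_a_matrix(pop$pedigree)
  des <- design_spec(ph$y, ph$id, ph$sex, ph$hatch, k_ids = rownames(A))
  fit <- solve_mme(des, A, ai_reml(des, A))
  y_c <- corrected_phenotypes(ph, fit)
  expect_gte(cor(y_c, ph$tbv), cor(ph$y, ph$tbv))
})

test_that("accuracy is the Pearson correlation with guarded degeneracies", {
  expect_equal(accuracy(1:5, 1:5), 1.0)
  expect_equal(accuracy(1:5, -(1:5)), -1.0)
  expect_equal(accuracy(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_error(accuracy(rep(1, 5), 1:5), "zero-variance")
  expect_error(accuracy(1:2, 1:2), "at least 3")
})

test_that("bias slope obeys its scale law", {
  set.seed(31)
  p <- rnorm(50); y <- p + rnorm(50, 0, 0.1)
  s1 <- bias_regression(y, p)
  expect_equal(bias_regression(p, p), 1.0)
  expect_equal(bias_regression(y, 2 * p), s1 / 2)
  expect_error(bias_regression(y, rep(1, 50)), "zero-variance")
})

test_that("paired t-test matches the hand-evaluated formula", {
  d <- c(0.02, 0.04, 0.01, 0.03)
  tt <- paired_t_test(d, rep(0, 4))
  expect_equal(tt$dbar, 0.025)
  expect_equal(tt$s_d, sqrt(sum((d - 0.025)^2) / 3))
  expect_equal(tt$s_d, 0.01290994, tolerance = 1e-6)
  expect_equal(tt$t, 0.025 / (tt$s_d / 2))
  expect_equal(tt$t, 3.872983, tolerance = 1e-6)
  expect_equal(tt$df, 3)

  # identical correlations: t = 0, p = 1
  same <- paired_t_test(c(0.4, 0.5, 0.6), c(0.4, 0.5, 0.6))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # antisymmetry
  a <- c(0.4, 0.45, 0.5, 0.42); b <- c(0.38, 0.47, 0.46, 0.40)
  t_ab <- paired_t_test(a, b); t_ba <- paired_t_test(b, a)
  expect_equal(t_ab$t, -t_ba$t)
  expect_equal(t_ab$p, t_ba$p)

  expect_error(paired_t_test(c(0.5, 0.75), c(0.25, 0.5)), "degenerate")
})

test_that("power of the correlation test behaves like its Monte-Carlo oracle", {
  expect_equal(power_correlation(0, 100), 0.05)
  # monotone in |r| and n
  expect_gt(power_correlation(0.4, 100), power_correlation(0.2, 100))
  expect_gte(power_correlation(0.3, 256), power_correlation(0.3, 128))

  # oracle: 50,000 simulated bivariate-normal datasets at r = 0.3, n = 128,
  # two-sided t-test of the sample correlation at alpha = 0.05
  set.seed(32)
  r <- 0.3; n <- 128; reps <- 50000
  x <- matrix(rnorm(reps * n), reps, n)
  y <- r * x + sqrt(1 - r^2) * matrix(rnorm(reps * n), reps, n)
  xc <- x - rowMeans(x); yc <- y - rowMeans(y)
  rhat <- rowSums(xc * yc) / sqrt(rowSums(xc^2) * rowSums(yc^2))
  tstat <- rhat * sqrt((n - 2) / (1 - rhat^2))
  reject <- abs(tstat) > qt(0.975, n - 2)
  expect_lt(abs(power_correlation(r, n) - mean(reject)), 0.02)

  expect_error(power_correlation(1, 100), "r must")
  expect_error(power_correlation(0.3, 3), "at least")
})

test_that("pooled correlation is computed on concatenated folds, not averaged", {
  # counterexample: two folds, each perfectly correlated within fold, but
  # with shifted scales so the pooled correlation is far from 1
  f1 <- data.frame(pred = c(1, 2, 3), y = c(11, 12, 13))
  f2 <- data.frame(pred = c(101, 102, 103), y = c(1, 2, 3))
  per_fold <- c(accuracy(f1$pred, f1$y), accuracy(f2$pred, f2$y))
  pooled <- accuracy(c(f1$pred, f2$pred), c(f1$y, f2$y))
  expect_equal(per_fold, c(1, 1))
  expect_lt(pooled, 0)
  expect_false(isTRUE(all.equal(pooled, mean(per_fold))))
})

study_fixture <- function() {
  if (is.null(.fixtures$study)) {
    .fixtures$study <- run_study(small_pop(), models = c("blup", "gblup"),
                                 scenarios = c("family", "random"), k = 4,
                                 full_data = TRUE, seed = 55)
  }
  .fixtures$study
}

test_that("the evaluation report pools over concatenated test sets and is reproducible", {
  rep1 <- study_fixture()
  # pooled accuracy equals the correlation over the stored concatenated
  # predictions
  for (sc in c("family", "random")) {
    pr <- rep1$predictions
    pr <- pr[pr$scenario == sc & pr$model == "gblup", ]
    pooled <- rep1$summary[rep1$summary$scenario == sc &
                             rep1$summary$model == "gblup" &
                             rep1$summary$statistic == "pooled_accuracy",
                           "value"]
    expect_equal(pooled, cor(pr$pred, pr$y_c))
  }
  rep2 <- run_study(small_pop(), models = c("blup", "gblup"),
                    scenarios = c("family", "random"), k = 4,
                    full_data = TRUE, seed = 55)
  expect_identical(rep1$summary, rep2$summary)
})

test_that("own-record (full-data) predictions beat cross-validated ones", {
  rep1 <- study_fixture()
  s <- rep1$summary
  for (mdl in c("blup", "gblup")) {
    full_acc <- s[s$scenario == "full_data" & s$model == mdl &
                    s$statistic == "accuracy", "value"]
    cv_acc <- s[s$scenario != "full_data" & s$model == mdl &
                  s$statistic == "pooled_accuracy", "value"]
    expect_true(all(full_acc > cv_acc))
  }
})

test_that("test-fold phenotypes are provably unused in training (masking integrity)", {
  pop <- small_pop()
  plan <- make_family_folds(pop$pedigree, 4)
  fold1 <- names(plan$assignment)[plan$assignment == 1]

  scrambled <- pop
  ph <- scrambled$phenotypes$BW6
  idx <- ph$id %in% fold1
  set.seed(66)
  ph$y[idx] <- sample(ph$y[idx]) + rnorm(sum(idx), 0, 50)
  scrambled$phenotypes$BW6 <- ph

  r1 <- run_study(pop, models = "gblup", scenarios = "family", seed = 77)
  r2 <- run_study(scrambled, models = "gblup", scenarios = "family", seed = 77)
  p1 <- r1$predictions[r1$predictions$fold == 1, ]
  p2 <- r2$predictions[r2$predictions$fold == 1, ]
  expect_equal(p1$pred, p2$pred, tolerance = 1e-10)
})

test_that("evaluation report exports as tidy CSV", {
  rep1 <- study_fixture()
  path <- tempfile(fileext = ".csv")
  write_eval_report(rep1, path)
  tab <- read.table(path, header = TRUE, sep = ",")
  expect_true(all(c("scenario", "fold", "trait", "model", "statistic",
                    "value") %in% names(tab)))
  expect_true(any(tab$statistic == "pooled_accuracy"))
})
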