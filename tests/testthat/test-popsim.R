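# Population simulator: founder lines, cross design, meiosis, phenotypes.

test_that("founder lines have the requested structure and divergence behaviour", {
  fnd <- simulate_founders(n_per_line = 10, n_snps = 200, n_chromosomes = 2,
                           divergence = 0, seed = 1)
  expect_equal(nrow(fnd$pedigree), 20)          # two lines of 10
  expect_setequal(unique(fnd$line), c("A", "B"))
  expect_equal(fnd$genotypes$dosage, fnd$hap1 + fnd$hap2)
  # divergence 0: line frequencies identical to the ancestral frequency
  expect_equal(fnd$p_line[, "A"], fnd$p_anc)
  expect_equal(mean(abs(fnd$p_line[, "A"] - fnd$p_line[, "B"])), 0)

  expect_error(simulate_founders(n_per_line = 0), "positive")
  expect_error(simulate_founders(divergence = 1), "divergence")
  expect_error(simulate_founders(divergence = -0.1), "divergence")
})

test_that("between-line FST matches a direct Monte-Carlo oracle of the frequency model", {
  n_per_line <- 200
  n_snps <- 10000
  div <- 0.3
  fnd <- simulate_founders(n_per_line = n_per_line, n_snps = n_snps,
                           n_chromosomes = 10, divergence = div, seed = 77)
  p_obs <- cbind(colMeans(fnd$genotypes$dosage[fnd$line == "A", ]) / 2,
                 colMeans(fnd$genotypes$dosage[fnd$line == "B", ]) / 2)
  fst_pkg <- hudson_fst(p_obs[, 1], p_obs[, 2], 2 * n_per_line, 2 * n_per_line)

  # oracle: resimulate the stated frequency-drawing rule directly (ancestral
  # uniform(0.05, 0.95); per-line Beta with F = divergence; binomial allele
  # counts), independent of the package's haplotype machinery
  set.seed(991)
  reps <- 30
  fst_oracle <- replicate(reps, {
    p <- runif(n_snps, 0.05, 0.95)
    pa <- rbeta(n_snps, p * (1 - div) / div, (1 - p) * (1 - div) / div)
    pb <- rbeta(n_snps, p * (1 - div) / div, (1 - p) * (1 - div) / div)
    ca <- rbinom(n_snps, 2 * n_per_line, pa) / (2 * n_per_line)
    cb <- rbinom(n_snps, 2 * n_per_line, pb) / (2 * n_per_line)
    hudson_fst(ca, cb, 2 * n_per_line, 2 * n_per_line)
  })
  expect_lt(abs(fst_pkg - mean(fst_oracle)), 3 * sd(fst_oracle))
})

test_that("cross design reproduces the study cohort and family arithmetic", {
  fnd <- simulate_founders(n_per_line = 10, n_snps = 50, n_chromosomes = 1,
                           seed = 2)
  pop <- make_cross_design(fnd, n_f1 = 51, n_sires_f1 = 8, n_f2 = 511, seed = 3)
  ped <- pop$pedigree
  expect_equal(nrow(ped), 20 + 51 + 511)
  expect_equal(as.vector(table(ped$generation)[c("F0", "F1", "F2")]),
               c(20L, 51L, 511L))
  fam_sizes <- sort(as.integer(table(pop$family)), decreasing = TRUE)
  expect_equal(fam_sizes, c(rep(64L, 7), 63L))   # 511 = 8*63 + 7
  expect_equal(length(unique(pop$family)), 8)
  # every F2 has both parents recorded, parents precede offspring
  f2 <- ped[ped$generation == "F2", ]
  expect_false(anyNA(f2$sire) || anyNA(f2$dam))
  idx <- setNames(seq_len(nrow(ped)), ped$id)
  expect_true(all(idx[f2$sire] < idx[f2$id] & idx[f2$dam] < idx[f2$id]))
  # hatch labels are round-robin within family
  expect_setequal(unique(f2$hatch), 1:4)
})

test_that("a single F1 sire gives one big half/full-sib family", {
  fnd <- simulate_founders(n_per_line = 4, n_snps = 20, n_chromosomes = 1,
                           seed = 4)
  pop <- make_cross_design(fnd, n_f1 = 10, n_sires_f1 = 1, n_f2 = 30, seed = 5)
  expect_equal(length(unique(pop$family)), 1)
})

test_that("infeasible cross designs error", {
  fnd <- simulate_founders(n_per_line = 4, n_snps = 20, n_chromosomes = 1,
                           seed = 6)
  expect_error(make_cross_design(fnd, n_f1 = 6, n_sires_f1 = 5, n_f2 = 20),
               "infeasible")
})

test_that("meiosis copies parental strands and matches the Haldane map function", {
  map1 <- data.frame(snp = c("a", "b"), chr = 1L, pos_cm = c(0, 20))
  h1 <- c(0L, 0L); h2 <- c(1L, 1L)
  set.seed(8)
  n_meioses <- 100000
  rec <- logical(n_meioses)
  for (i in seq_len(n_meioses)) {
    g <- drop_gamete(h1, h2, map1)
    rec[i] <- g[1] != g[2]
  }
  r_hat <- mean(rec)
  r_haldane <- (1 - exp(-0.4)) / 2
  se <- sqrt(r_haldane * (1 - r_haldane) / n_meioses)
  expect_lt(abs(r_hat - r_haldane), 3 * se)

  # zero map length: gamete is one intact parental strand
  map0 <- data.frame(snp = letters[1:5], chr = 1L, pos_cm = rep(0, 5))
  ha <- c(0L, 1L, 0L, 1L, 0L); hb <- c(1L, 0L, 1L, 0L, 1L)
  for (i in 1:20) {
    g <- drop_gamete(ha, hb, map0)
    expect_true(identical(g, ha) || identical(g, hb))
  }
  expect_error(drop_gamete(ha, hb, map0[0, ]), "empty map")
})

test_that("every offspring allele is inherited from a parent (Mendelian consistency)", {
  pop <- make_cross_design(
    simulate_founders(n_per_line = 5, n_snps = 120, n_chromosomes = 3, seed = 9),
    n_f1 = 12, n_sires_f1 = 3, n_f2 = 30, seed = 10)
  ped <- pop$pedigree
  for (i in which(ped$generation != "F0")) {
    s <- ped$sire[i]; d <- ped$dam[i]
    expect_true(all(pop$hap1[i, ] == pop$hap1[s, ] |
                    pop$hap1[i, ] == pop$hap2[s, ]))
    expect_true(all(pop$hap2[i, ] == pop$hap1[d, ] |
                    pop$hap2[i, ] == pop$hap2[d, ]))
  }
})

test_that("phenotype simulation hits the target architecture", {
  pop <- make_cross_design(
    simulate_founders(n_per_line = 10, n_snps = 400, n_chromosomes = 5,
                      seed = 11),
    n_f1 = 51, n_sires_f1 = 8, n_f2 = 5000, seed = 12)

  arch <- trait_architecture("T", h2 = 0.26, mean = 100, sd_p = 10,
                             n_qtl = 100, sex_effect = 4,
                             hatch_effects = c(0, 1, -1, 2))
  ph <- simulate_phenotypes(pop, arch, seed = 13)
  expect_equal(nrow(ph), 5000)            # F2 only
  expect_true(all(ph$id %in% pop$pedigree$id[pop$pedigree$generation == "F2"]))

  # regression of y on TBV has slope ~ 1, and the TBV share of the
  # fixed-effect-free variance is the target heritability
  fit <- lm(ph$y ~ ph$tbv)
  expect_lt(abs(coef(fit)[2] - 1), 0.05)
  fixed <- ifelse(ph$sex == "M", 4, 0) + c(0, 1, -1, 2)[ph$hatch]
  expect_lt(abs(var(ph$tbv) / var(ph$y - fixed) - 0.26), 0.02)

  # injected sex effect of +100 is recovered from sex-level means
  arch2 <- trait_architecture("S", h2 = 0, mean = 0, sd_p = 10,
                              sex_effect = 100, hatch_effects = 0)
  ph2 <- simulate_phenotypes(pop, arch2, seed = 14)
  expect_equal(var(ph2$tbv), 0)
  diff_sex <- mean(ph2$y[ph2$sex == "M"]) - mean(ph2$y[ph2$sex == "F"])
  expect_lt(abs(diff_sex - 100), 3 * 10 * sqrt(4 / 5000))
})

test_that("realized heritability is calibrated across replicates for all trait targets", {
  pop <- make_cross_design(
    simulate_founders(n_per_line = 10, n_snps = 500, n_chromosomes = 5,
                      seed = 21),
    n_f1 = 51, n_sires_f1 = 8, n_f2 = 2000, seed = 22)
  for (h2 in c(0.13, 0.26, 0.39, 0.44)) {
    realized <- vapply(1:20, function(r) {
      arch <- trait_architecture("T", h2 = h2, sd_p = 5, n_qtl = 150,
                                 sex_effect = 0, hatch_effects = 0)
      ph <- simulate_phenotypes(pop, arch, seed = 1000 * h2 + r)
      var(ph$tbv) / var(ph$y)
    }, 1)
    expect_lt(abs(mean(realized) - h2), 0.02)
  }
})

test_that("identical seeds reproduce identical populations", {
  p1 <- simulate_population(n_snps = 100, n_chromosomes = 2, n_f2 = 40,
                            traits = chicken_traits(10)["EP"], seed = 99)
  p2 <- simulate_population(n_snps = 100, n_chromosomes = 2, n_f2 = 40,
                            traits = chicken_traits(10)["EP"], seed = 99)
  expect_identical(p1$genotypes$dosage, p2$genotypes$dosage)
  expect_identical(p1$pedigree, p2$pedigree)
  expect_identical(p1$phenotypes$EP$y, p2$phenotypes$EP$y)
})

test_that("genotype container enforces its invariants", {
  d <- matrix(c(0, 1, 2, 3), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  map <- data.frame(snp = c("s1", "s2"), chr = 1L, pos_cm = c(1, 2))
  expect_error(genotypes(d, map), "dosages")
  d[2, 2] <- NA
  g <- genotypes(d, map)
  expect_s3_class(g, "genotypes")
  bad_map <- data.frame(snp = c("s1", "s2"), chr = 1L, pos_cm = c(2, 1))
  expect_error(genotypes(d, bad_map), "non-decreasing")
})
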