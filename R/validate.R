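# Cross-validation design and evaluation: family-sample and random-sample
# fold plans, corrected phenotypes, prediction accuracy, bias regression,
# paired t-tests between models, and power of pooled correlations.

#' Family-sample fold plan
#'
#' Whole half-sib sire families are assigned to folds by deterministic
#' greedy bin-packing: families sorted by decreasing size (ties by family
#' id) are placed one at a time into the currently smallest fold that still
#' has room (at most ceiling(#families / k) families per fold). Individuals
#' in a test fold therefore share no sire or dam with any training
#' individual.
#'
#' @param pedigree pedigree data.frame; only F2 rows (generation == "F2")
#'   are assigned to folds, grouped by sire.
#' @param k number of folds (default 4).
#' @return object of class \code{fold_plan}.
#' @export
make_family_folds <- function(pedigree, k = 4) {
  f2 <- pedigree[pedigree$generation == "F2", , drop = FALSE]
  fam <- split(f2$id, f2$sire)
  if (length(fam) < k) stop("fewer half-sib families than folds")
  sizes <- vapply(fam, length, 1L)
  ord <- order(-sizes, names(fam))
  cap <- ceiling(length(fam) / k)
  fold_of_family <- integer(length(fam))
  totals <- numeric(k)
  counts <- integer(k)
  for (fi in ord) {
    open <- which(counts < cap)
    target <- open[which.min(totals[open])]
    fold_of_family[fi] <- target
    totals[target] <- totals[target] + sizes[fi]
    counts[target] <- counts[target] + 1L
  }
  assignment <- setNames(rep(fold_of_family, sizes), unlist(fam))
  assignment <- assignment[f2$id]
  new_fold_plan("family", k, assignment,
                families = setNames(fold_of_family, names(fam)))
}

#' Random-sample fold plan
#'
#' Seeded uniform shuffle; the first \code{n mod k} folds get
#' \code{ceiling(n/k)} individuals, the rest \code{floor(n/k)}.
#'
#' @param ids individual ids to partition.
#' @param k number of folds (default 4).
#' @param seed integer seed.
#' @return object of class \code{fold_plan}.
#' @export
make_random_folds <- function(ids, k = 4, seed = NULL) {
  if (length(ids) == 0) stop("empty id list")
  if (length(ids) < k) stop("fewer individuals than folds")
  set_seed_if(seed)
  n <- length(ids)
  sizes <- rep(n %/% k, k)
  r <- n %% k
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  shuffled <- sample(ids)
  assignment <- setNames(rep(seq_len(k), sizes), shuffled)[ids]
  new_fold_plan("random", k, assignment)
}

new_fold_plan <- function(scenario, k, assignment, families = NULL) {
  n <- length(assignment)
  test_n <- as.integer(table(factor(assignment, levels = seq_len(k))))
  structure(list(scenario = scenario, k = k, assignment = assignment,
                 test_n = test_n, train_n = n - test_n,
                 families = families),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("%s-sample %d-fold plan over %d individuals\n",
              x$scenario, x$k, length(x$assignment)))
  cat(sprintf("  test sizes: %s; training sizes: %s\n",
              paste(x$test_n, collapse = "/"),
              paste(x$train_n, collapse = "/")))
  invisible(x)
}

#' Corrected phenotypes
#'
#' y_c = y - estimated sex effect - estimated hatch effect, with the fixed
#' effects taken from a conventional pedigree BLUP fitted on the full
#' dataset. The intercept is retained in y_c (a uniform shift that leaves
#' all downstream correlations unchanged).
#'
#' @param phenos phenotype data.frame with id, y, sex, hatch.
#' @param full_fit an \code{mme_fit} from the full-data pedigree BLUP whose
#'   fixed-effect design used the same factor coding.
#' @return named numeric of corrected phenotypes.
#' @export
corrected_phenotypes <- function(phenos, full_fit) {
  b <- full_fit$b
  known <- names(b)
  eff <- function(lev) ifelse(lev %in% known, b[lev], 0)
  sexlev <- paste0("sex", phenos$sex)
  hatchlev <- paste0("hatch", phenos$hatch)
  # when a factor was fitted (some of its levels appear in b), at most one
  # distinct level may be absent from b — the reference absorbed into the
  # intercept; more than one absent level means the fit cannot correct it
  check_levels <- function(lev, prefix, what) {
    if (!any(startsWith(known, prefix))) return(invisible(NULL))
    absent <- unique(lev[!(lev %in% known)])
    if (length(absent) > 1)
      stop(what, " level absent from the full-data fit")
  }
  check_levels(sexlev, "sex", "sex")
  check_levels(hatchlev, "hatch", "hatch")
  adj <- eff(sexlev) + eff(hatchlev)
  adj[is.na(adj)] <- 0
  setNames(phenos$y - adj, phenos$id)
}

#' Prediction accuracy (Pearson correlation)
#'
#' @param predictions,y_c paired numeric vectors (per fold or pooled).
#' @return the Pearson correlation.
#' @export
accuracy <- function(predictions, y_c) {
  if (length(predictions) != length(y_c)) stop("length mismatch")
  if (length(y_c) < 3) stop("need at least 3 paired values")
  if (sd(predictions) == 0 || sd(y_c) == 0)
    stop("zero-variance input: correlation undefined")
  cor(predictions, y_c)
}

#' Bias of predictions: regression slope of y_c on the prediction
#'
#' A slope of 1 indicates unbiased predictions; below 1, over-dispersed
#' (inflated) predictions.
#'
#' @param y_c corrected phenotypes.
#' @param predictions breeding-value predictions.
#' @return the OLS slope.
#' @export
bias_regression <- function(y_c, predictions) {
  if (length(predictions) != length(y_c)) stop("length mismatch")
  if (sd(predictions) == 0) stop("zero-variance predictions: slope undefined")
  unname(coef(lm(y_c ~ predictions))[2])
}

#' Paired t-test on per-fold correlations of two models
#'
#' Each fold is a subject; d is the per-fold difference of correlation
#' coefficients, t = dbar / (S_D / sqrt(n)) with n the fold count and
#' df = n - 1; two-sided p.
#'
#' @param corr_a,corr_b per-fold correlations of models A and B.
#' @return list with dbar, s_d, t, df, p, significant (at 0.05).
#' @export
paired_t_test <- function(corr_a, corr_b) {
  if (length(corr_a) != length(corr_b)) stop("fold counts differ")
  n <- length(corr_a)
  if (n < 2) stop("need at least 2 folds")
  d <- corr_a - corr_b
  dbar <- mean(d)
  s_d <- sd(d)
  if (s_d == 0) {
    if (dbar != 0) stop("degenerate paired differences: zero variance, nonzero mean")
    tval <- 0
  } else {
    tval <- dbar / (s_d / sqrt(n))
  }
  p <- 2 * pt(-abs(tval), df = n - 1)
  list(dbar = dbar, s_d = s_d, t = tval, df = n - 1, p = p,
       significant = p < 0.05)
}

#' Power of a correlation test (Fisher z approximation)
#'
#' Power of the two-sided test of rho = 0 at level alpha when the true
#' correlation is r and the sample size is n, via the normal approximation
#' to the Fisher z transform: z_r sqrt(n - 3) is compared against the
#' two-sided normal critical value.
#'
#' @param r hypothesised (observed) correlation, |r| < 1.
#' @param n sample size (>= 4).
#' @param alpha significance level (default 0.05).
#' @return power in [0, 1].
#' @export
power_correlation <- function(r, n, alpha = 0.05) {
  if (!is.finite(r) || abs(r) >= 1) stop("r must satisfy |r| < 1")
  if (n < 4) stop("n must be at least 4")
  zr <- atanh(abs(r)) * sqrt(n - 3)
  zc <- qnorm(1 - alpha / 2)
  pnorm(zr - zc) + pnorm(-zr - zc)
}

# ---------------------------------------------------------------------------
# full study driver

fit_fold_models <- function(trait_pheno, train_ids, test_ids, A, G, dosage,
                            models, mcmc, seed_stream) {
  ped_ids <- rownames(A)
  tr <- trait_pheno[trait_pheno$id %in% train_ids, , drop = FALSE]
  preds <- list()

  if (any(c("blup", "gblup") %in% models)) {
    for (mdl in intersect(c("blup", "gblup"), models)) {
      K <- if (mdl == "blup") A else G
      des <- design_spec(tr$y, tr$id, tr$sex, tr$hatch, k_ids = rownames(K))
      vc <- ai_reml(des, K)
      fit <- solve_mme(des, K, vc)
      preds[[mdl]] <- fit$u[test_ids]
    }
  }

  if (any(c("lasso", "mix4") %in% models)) {
    des <- design_spec(tr$y, tr$id, tr$sex, tr$hatch, k_ids = tr$id)
    Mtr <- dosage[tr$id, , drop = FALSE]
    if ("lasso" %in% models) {
      spec <- marker_model_spec(tr$y, des$X, Mtr, model = "lasso")
      cfg <- mcmc
      cfg$seed <- substream_seed(seed_stream, "lasso")
      fit <- run_bayes_lasso(spec, cfg)
      preds[["lasso"]] <- gebv_from_markers(dosage[test_ids, , drop = FALSE], fit)
    }
    if ("mix4" %in% models) {
      spec <- marker_model_spec(tr$y, des$X, Mtr, model = "mix4")
      cfg <- mcmc
      cfg$seed <- substream_seed(seed_stream, "mix4")
      fit <- run_bayes_mix4(spec, cfg)
      preds[["mix4"]] <- gebv_from_markers(dosage[test_ids, , drop = FALSE], fit)
    }
  }
  preds
}

#' Run the full cross-validation study
#'
#' For each scenario, fold, trait and model: fit on the training data (test
#' phenotypes masked), predict the test individuals, and assemble per-fold
#' and pooled accuracies, bias slopes, paired t-tests between all model
#' pairs and power of the pooled correlations. Corrected phenotypes come
#' from a conventional pedigree BLUP on the full dataset. Optionally also
#' fits every model on the full data (predictions use the individuals' own
#' records).
#'
#' @param population a \code{sim_population} with phenotypes (or a list with
#'   elements pedigree, genotypes, phenotypes of the same shape).
#' @param traits trait names to evaluate (default: all simulated).
#' @param models subset of c("blup", "gblup", "lasso", "mix4").
#' @param scenarios subset of c("family", "random").
#' @param k folds (default 4).
#' @param mcmc an \code{mcmc_config} for the Bayesian models.
#' @param qc_thresholds list(min_call_rate, min_maf) applied before analysis.
#' @param full_data also compute full-data (own-record) accuracies.
#' @param seed root seed for fold randomisation and the MCMC chains.
#' @return object of class \code{eval_report}: tidy \code{summary} and
#'   \code{fold_stats} data.frames, per-individual predictions, fold plans
#'   and the variance components of the full-data fits.
#' @export
run_study <- function(population, traits = NULL,
                      models = c("blup", "gblup", "lasso", "mix4"),
                      scenarios = c("family", "random"), k = 4,
                      mcmc = mcmc_config(),
                      qc_thresholds = list(min_call_rate = 0.95, min_maf = 0.01),
                      full_data = FALSE, seed = 1) {
  models <- match.arg(models, c("blup", "gblup", "lasso", "mix4"),
                      several.ok = TRUE)
  scenarios <- match.arg(scenarios, c("family", "random"), several.ok = TRUE)
  ped <- population$pedigree
  phenos <- population$phenotypes
  if (is.null(traits)) traits <- names(phenos)

  qc <- filter_snps(population$genotypes,
                    min_call_rate = qc_thresholds$min_call_rate,
                    min_maf = qc_thresholds$min_maf)
  geno <- impute_missing(qc$genotypes)
  A <- pedigree_a_matrix(ped)
  G <- genomic_g_matrix(geno)
  dosage <- geno$dosage

  plans <- list()
  if ("family" %in% scenarios) plans$family <- make_family_folds(ped, k)
  if ("random" %in% scenarios)
    plans$random <- make_random_folds(ped$id[ped$generation == "F2"], k,
                                      seed = substream_seed(seed, "random_folds"))

  fold_rows <- list()
  summary_rows <- list()
  pred_rows <- list()
  vc_full <- list()

  for (trait in traits) {
    ph <- phenos[[trait]]
    # full-data pedigree BLUP: fixed effects for y_c, and full-data EBV
    des_full <- design_spec(ph$y, ph$id, ph$sex, ph$hatch, k_ids = rownames(A))
    vc_a <- ai_reml(des_full, A)
    fit_full_blup <- solve_mme(des_full, A, vc_a)
    y_c <- corrected_phenotypes(ph, fit_full_blup)
    vc_full[[trait]] <- vc_a

    if (full_data) {
      fd_preds <- list(blup = fit_full_blup$u[ph$id])
      if ("gblup" %in% models) {
        des_g <- design_spec(ph$y, ph$id, ph$sex, ph$hatch, k_ids = rownames(G))
        vc_g <- ai_reml(des_g, G)
        fd_preds$gblup <- solve_mme(des_g, G, vc_g)$u[ph$id]
      }
      for (mdl in intersect(c("lasso", "mix4"), models)) {
        spec <- marker_model_spec(ph$y, des_full$X, dosage[ph$id, , drop = FALSE],
                                  model = mdl)
        cfg <- mcmc
        cfg$seed <- substream_seed(seed, paste0("full_", trait, "_", mdl))
        fit <- if (mdl == "lasso") run_bayes_lasso(spec, cfg)
               else run_bayes_mix4(spec, cfg)
        fd_preds[[mdl]] <- gebv_from_markers(dosage[ph$id, , drop = FALSE], fit)
      }
      for (mdl in intersect(models, names(fd_preds))) {
        summary_rows[[length(summary_rows) + 1L]] <- data.frame(
          scenario = "full_data", trait = trait, model = mdl,
          statistic = "accuracy",
          value = accuracy(fd_preds[[mdl]], y_c[ph$id]))
      }
    }

    for (sc in scenarios) {
      plan <- plans[[sc]]
      fold_corr <- matrix(NA_real_, k, length(models),
                          dimnames = list(NULL, models))
      pooled <- list()
      for (fold in seq_len(k)) {
        test_ids <- names(plan$assignment)[plan$assignment == fold]
        train_ids <- setdiff(ph$id, test_ids)
        preds <- fit_fold_models(ph, train_ids, test_ids, A, G, dosage,
                                 models, mcmc,
                                 seed_stream = substream_seed(
                                   seed, paste(sc, trait, fold, sep = "_")))
        for (mdl in models) {
          pr <- preds[[mdl]]
          fold_corr[fold, mdl] <- accuracy(pr, y_c[test_ids])
          pooled[[mdl]] <- rbind(pooled[[mdl]],
                                 data.frame(id = test_ids, fold = fold,
                                            pred = unname(pr),
                                            y_c = unname(y_c[test_ids])))
          fold_rows[[length(fold_rows) + 1L]] <- data.frame(
            scenario = sc, trait = trait, model = mdl, fold = fold,
            statistic = "accuracy", value = fold_corr[fold, mdl])
        }
      }
      for (mdl in models) {
        po <- pooled[[mdl]]
        acc <- accuracy(po$pred, po$y_c)
        slope <- bias_regression(po$y_c, po$pred)
        pw <- power_correlation(acc, nrow(po))
        summary_rows[[length(summary_rows) + 1L]] <- data.frame(
          scenario = sc, trait = trait, model = mdl,
          statistic = c("pooled_accuracy", "slope", "power"),
          value = c(acc, slope, pw))
        pred_rows[[length(pred_rows) + 1L]] <-
          cbind(scenario = sc, trait = trait, model = mdl, po)
      }
      if (length(models) > 1) {
        cmb <- utils::combn(models, 2)
        for (ci in seq_len(ncol(cmb))) {
          a <- cmb[1, ci]; b <- cmb[2, ci]
          tt <- paired_t_test(fold_corr[, a], fold_corr[, b])
          summary_rows[[length(summary_rows) + 1L]] <- data.frame(
            scenario = sc, trait = trait, model = paste(a, b, sep = "_vs_"),
            statistic = c("paired_t", "paired_t_p"),
            value = c(tt$t, tt$p))
        }
      }
    }
  }

  structure(list(
    summary = do.call(rbind, summary_rows),
    fold_stats = do.call(rbind, fold_rows),
    predictions = do.call(rbind, pred_rows),
    plans = plans,
    vc_full = vc_full,
    qc_report = qc$report,
    models = models, scenarios = scenarios, k = k, seed = seed
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Cross-validation evaluation report\n")
  acc <- x$summary[x$summary$statistic == "pooled_accuracy", , drop = FALSE]
  if (nrow(acc)) {
    tab <- stats::reshape(acc[, c("scenario", "trait", "model", "value")],
                          idvar = c("scenario", "trait"),
                          timevar = "model", direction = "wide")
    names(tab) <- sub("^value\\.", "", names(tab))
    print(tab, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Export an evaluation report as tidy CSV
#' @param report an \code{eval_report}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_eval_report <- function(report, path) {
  out <- rbind(
    cbind(report$summary, fold = NA_integer_)[,
      c("scenario", "fold", "trait", "model", "statistic", "value")],
    report$fold_stats[, c("scenario", "fold", "trait", "model",
                          "statistic", "value")]
  )
  write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
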