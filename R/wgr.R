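# Whole-genome regression front end: marker model specification, MCMC
# configuration, the BayesLASSO and BayesMix4 samplers, and GEBV assembly.

#' MCMC schedule
#'
#' Defaults are the desk-scale schedule (10,000 cycles, 4,000 burn-in, thin
#' 10); \code{mcmc_config_full()} gives the production schedule of 50,000
#' cycles, 20,000 burn-in and every 20th sample saved.
#'
#' @param n_iter chain length in cycles.
#' @param burnin burn-in cycles (discarded).
#' @param thin thinning interval.
#' @param seed integer seed for the chain.
#' @return object of class \code{mcmc_config}.
#' @export
mcmc_config <- function(n_iter = 10000, burnin = 4000, thin = 10, seed = NULL) {
  if (burnin >= n_iter) stop("burn-in must be shorter than the chain")
  if (thin < 1) stop("thinning interval must be >= 1")
  structure(list(n_iter = as.integer(n_iter), burnin = as.integer(burnin),
                 thin = as.integer(thin), seed = seed),
            class = "mcmc_config")
}

#' @rdname mcmc_config
#' @export
mcmc_config_full <- function(seed = NULL) {
  mcmc_config(50000, 20000, 20, seed)
}

#' Marker model specification
#'
#' Packages the response, fixed-effect incidence and the marker design
#' matrix. Marker columns are centred by their training means (twice the
#' allele frequency), which decouples markers from the intercept and makes
#' the SNP-BLUP/GBLUP equivalence exact; the centring constants are stored
#' so target individuals can be coded identically.
#'
#' @param y response vector (training individuals).
#' @param X fixed-effect incidence matrix (may have zero columns).
#' @param dosage dosage matrix (training individuals x SNPs, no missing).
#' @param model "lasso" or "mix4".
#' @param pi mixing proportions for mix4 (must sum to 1); ignored for lasso.
#' @return object of class \code{marker_model_spec} with centred \code{M}
#'   and \code{centers}.
#' @export
marker_model_spec <- function(y, X, dosage, model = c("lasso", "mix4"),
                              pi = c(0.889, 0.1, 0.01, 0.001)) {
  model <- match.arg(model)
  stopifnot(is.matrix(dosage), length(y) == nrow(dosage))
  if (anyNA(dosage)) stop("marker matrix has missing entries; impute first")
  if (model == "mix4") {
    if (length(pi) != 4 || any(pi <= 0)) stop("pi must be 4 positive proportions")
    if (abs(sum(pi) - 1) > 1e-12) stop("pi must sum to 1")
  }
  centers <- colMeans(dosage)
  M <- sweep(dosage, 2L, centers, "-")
  structure(list(y = as.numeric(y), X = X, M = M, centers = centers,
                 snp_ids = colnames(dosage), model = model,
                 pi = if (model == "mix4") pi else NULL),
            class = "marker_model_spec")
}

# shared runner
run_wgr <- function(spec, config, ctrl) {
  stopifnot(inherits(spec, "marker_model_spec"), inherits(config, "mcmc_config"))
  set_seed_if(config$seed)
  res <- wgr_gibbs_cpp(spec$y, spec$X, spec$M, spec$model,
                       config$n_iter, config$burnin, config$thin, ctrl)
  names(res$qhat) <- spec$snp_ids
  if (ncol(spec$X) > 0) names(res$bhat) <- colnames(spec$X)
  expected <- (config$n_iter - config$burnin) %/% config$thin
  stopifnot(res$n_saved == expected)
  structure(list(
    model = spec$model,
    qhat = res$qhat,
    bhat = res$bhat,
    sigma_e2_trace = res$sigma_e2_trace,
    sigma_e2 = mean(res$sigma_e2_trace),
    lambda_trace = res$lambda_trace,
    lambda = if (!is.null(res$lambda_trace)) mean(res$lambda_trace) else NULL,
    component_var_trace = res$component_var_trace,
    component_prob = res$component_prob,
    pi = spec$pi,
    n_saved = res$n_saved,
    centers = spec$centers,
    config = config
  ), class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("%s posterior summary: %d markers, %d saved samples\n",
              x$model, length(x$qhat), x$n_saved))
  cat(sprintf("  posterior mean sigma_e2 = %.4g\n", x$sigma_e2))
  if (!is.null(x$lambda)) cat(sprintf("  posterior mean lambda = %.4g\n", x$lambda))
  if (!is.null(x$component_var_trace))
    cat(sprintf("  posterior mean component variances: %s\n",
                paste(signif(colMeans(x$component_var_trace), 3), collapse = ", ")))
  invisible(x)
}

#' Bayesian LASSO whole-genome regression
#'
#' Gibbs sampler for marker effects under a double-exponential prior, using
#' its exponential scale-mixture representation: each marker carries a
#' latent variance with an inverse-Gaussian full conditional. The rate
#' parameter lambda has a uniform prior on (0, lambda_max]; its full
#' conditional is Gamma(k + 1, sum |q_j|) truncated to that support,
#' sampled by inverse CDF. The support is chosen on genetic grounds: the
#' default \code{lambda_max} is the rate at which the markers would jointly
#' explain only 2 percent of the phenotypic variance, so the uniform prior
#' spans every plausible shrinkage level for a heritable trait while
#' excluding the degenerate all-shrunk regime. (Under an unbounded uniform
#' the marginal posterior of lambda is flat at large lambda — the prior
#' factor lambda^k exactly offsets the collapsing prior mass — so an
#' overgenerous support hands most of the posterior to a model in which the
#' markers explain nothing.)
#'
#' @param spec a \code{marker_model_spec} with model "lasso".
#' @param config an \code{mcmc_config}.
#' Chains are warm-started: lambda is held at its data-informed initial
#' value for the first few hundred cycles (within burn-in) so marker
#' effects grow to data-supported magnitudes before the rate is released;
#' this keeps chains out of a degenerate, slowly-mixing all-shrunk regime
#' in which the marginal posterior of lambda under the uniform prior is
#' flat. The warm start does not alter the stationary distribution.
#'
#' @param lambda optional fixed value of lambda (disables its update).
#' @param lambda_max upper support of the uniform prior on lambda.
#' @param lambda_freeze cycles during which lambda is held at its initial
#'   value (default: half the burn-in, capped at 500).
#' @param sigma_e2 optional fixed residual variance (disables its update).
#' @return a \code{posterior_summary}.
#' @export
run_bayes_lasso <- function(spec, config, lambda = NULL, lambda_max = NULL,
                            lambda_freeze = NULL, sigma_e2 = NULL) {
  if (spec$model != "lasso") stop("spec is not a lasso model")
  vy <- var(spec$y)
  k <- ncol(spec$M)
  # lambda(f): the double-exponential rate at which the markers jointly
  # explain a fraction f of the phenotypic variance, i.e. E[q^2] = 2/lambda^2
  # = f vy / (k mbar), with mbar the mean per-marker sum of squares per
  # observation. The chain starts at f = 1/2 (markers explain half the
  # variance) and the uniform support extends down to f = 0.02.
  mbar <- max(mean(colSums(spec$M^2)) / length(spec$y), 1e-12)
  lambda_at <- function(f) sqrt(2 * k * mbar / max(f * vy, 1e-300))
  if (is.null(lambda_max)) lambda_max <- lambda_at(0.02)
  lambda_guess <- lambda_at(0.5)
  ctrl <- list(
    sigma_e2_init = if (is.null(sigma_e2)) vy / 2 else sigma_e2,
    update_sigma_e2 = is.null(sigma_e2),
    lambda_init = if (is.null(lambda)) min(lambda_guess, lambda_max) else lambda,
    lambda_max = lambda_max,
    update_lambda = is.null(lambda),
    lambda_freeze = as.integer(lambda_freeze %||%
                                 min(500L, config$burnin %/% 2L))
  )
  run_wgr(spec, config, ctrl)
}

#' Four-component Bayesian mixture whole-genome regression
#'
#' Gibbs sampler for marker effects under a mixture of four normal
#' distributions with fixed mixing proportions (default 0.889, 0.1, 0.01,
#' 0.001, ordered from the smallest to the largest component variance).
#' Per cycle: a component indicator per marker from its collapsed
#' multinomial conditional, marker effects from normal conditionals, the
#' four component variances from scaled-inverse-chi-square conditionals
#' (default 4.2 prior degrees of freedom with scale hyperparameters
#' spanning four orders of magnitude), with the variance ordering enforced
#' by sorting after each update.
#'
#' @param spec a \code{marker_model_spec} with model "mix4".
#' @param config an \code{mcmc_config}.
#' @param component_vars optional fixed component variances (disables their
#'   update; used e.g. to collapse the mixture to a single normal).
#' @param df0 prior degrees of freedom of the component variances.
#' @param scales optional prior scale hyperparameters (length 4, ascending).
#' @param sigma_e2 optional fixed residual variance (disables its update).
#' @return a \code{posterior_summary}.
#' @export
run_bayes_mix4 <- function(spec, config, component_vars = NULL, df0 = 4.2,
                           scales = NULL, sigma_e2 = NULL) {
  if (spec$model != "mix4") stop("spec is not a mix4 model")
  vy <- var(spec$y)
  mean_mtm <- mean(colSums(spec$M^2)) / length(spec$y)
  if (is.null(scales)) {
    # base so that the prior-mean genetic variance is about half of var(y)
    rel <- c(1e-3, 1e-2, 1e-1, 1)
    base <- 0.5 * vy / (sum(spec$pi * rel) * max(mean_mtm, 1e-12) * ncol(spec$M))
    scales <- base * rel
  }
  v0 <- if (is.null(component_vars)) scales else component_vars
  if (is.unsorted(v0)) stop("component variances must be ascending")
  ctrl <- list(
    sigma_e2_init = if (is.null(sigma_e2)) vy / 2 else sigma_e2,
    update_sigma_e2 = is.null(sigma_e2),
    pi = spec$pi,
    scale = scales,
    df0 = df0,
    update_component_vars = is.null(component_vars),
    var_init = v0
  )
  run_wgr(spec, config, ctrl)
}

#' Genomic breeding values from posterior-mean marker effects
#'
#' GEBV_i = sum_j m_ij qhat_j, with target dosages centred by the training
#' centring constants so coding matches the fitted model. Target individuals
#' need no phenotypes.
#'
#' @param dosage dosage matrix of the target individuals (SNP columns must
#'   match the fit).
#' @param fit a \code{posterior_summary} (or any list with \code{qhat} and
#'   \code{centers}).
#' @return named numeric vector of GEBV.
#' @export
gebv_from_markers <- function(dosage, fit) {
  qhat <- fit$qhat
  centers <- fit$centers
  if (ncol(dosage) != length(qhat) ||
      (!is.null(colnames(dosage)) && !is.null(names(qhat)) &&
       !identical(colnames(dosage), names(qhat))))
    stop("marker columns do not align with the fitted effects")
  M <- sweep(dosage, 2L, centers, "-")
  gebv <- drop(M %*% qhat)
  names(gebv) <- rownames(dosage)
  gebv
}
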