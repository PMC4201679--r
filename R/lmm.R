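# Linear mixed models for breeding-value prediction: design construction,
# AI-REML variance components (with an EM-type positivity fallback), the
# mixed-model equations, and the equivalent ridge SNP-BLUP.

#' Build a mixed-model design
#'
#' Response plus fixed-effect incidence (intercept, sex, hatch; treatment
#' coding with the first level absorbed into the intercept) and the mapping
#' of observations onto the individuals of a relationship matrix. Aliased
#' fixed-effect columns (e.g. a single-level factor) are dropped so X has
#' full column rank.
#'
#' @param y numeric response vector.
#' @param id character ids of the observations.
#' @param sex,hatch fixed-effect factors (vectors aligned with y); either
#'   may be NULL to omit the factor.
#' @param k_ids ids of the relationship matrix the observations map into.
#' @return object of class \code{design_spec}: y, X, zi (index of each
#'   observation in k_ids), ids, k_ids.
#' @export
design_spec <- function(y, id, sex = NULL, hatch = NULL, k_ids) {
  stopifnot(length(y) == length(id))
  zi <- match(id, k_ids)
  if (anyNA(zi)) stop("observation ids missing from the relationship matrix")
  df <- data.frame(row.names = seq_along(y))
  if (!is.null(sex)) df$sex <- factor(sex)
  if (!is.null(hatch)) df$hatch <- factor(hatch)
  X <- if (ncol(df) == 0) matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
       else model.matrix(~ ., droplevels(df))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) X <- X[, qr_x$pivot[seq_len(qr_x$rank)], drop = FALSE]
  structure(list(y = as.numeric(y), X = X, zi = zi,
                 ids = as.character(id), k_ids = as.character(k_ids)),
            class = "design_spec")
}

#' Variance components container
#' @param sigma_a2 additive (or genomic) variance.
#' @param sigma_e2 residual variance.
#' @param se named numeric of standard errors (optional).
#' @param h2_se standard error of h2 (optional).
#' @param converged,iterations,loglik fit diagnostics (optional).
#' @return object of class \code{var_comp} with computed \code{h2}.
#' @export
var_comp <- function(sigma_a2, sigma_e2, se = c(sigma_a2 = NA_real_, sigma_e2 = NA_real_),
                     h2_se = NA_real_, converged = NA, iterations = NA_integer_,
                     loglik = NA_real_) {
  if (sigma_a2 < 0 || sigma_e2 < 0) stop("variances must be non-negative")
  structure(list(sigma_a2 = sigma_a2, sigma_e2 = sigma_e2,
                 h2 = sigma_a2 / (sigma_a2 + sigma_e2),
                 se = se, h2_se = h2_se, converged = converged,
                 iterations = iterations, loglik = loglik),
            class = "var_comp")
}

#' @export
print.var_comp <- function(x, ...) {
  cat(sprintf("variance components: sigma_a2 = %.4g (SE %.3g), sigma_e2 = %.4g (SE %.3g)\n",
              x$sigma_a2, x$se[1], x$sigma_e2, x$se[2]))
  cat(sprintf("  h2 = %.3f (SE %.3f); converged: %s in %d iterations\n",
              x$h2, x$h2_se, x$converged, x$iterations))
  invisible(x)
}

# K restricted to observations (Z K Z'), as a plain matrix.
zkz <- function(design, K) {
  relmat_matrix(K)[design$zi, design$zi, drop = FALSE]
}

#' AI-REML variance components for a one-random-effect animal model
#'
#' Model y = Xb + Zu + e with u ~ N(0, K sigma_a2), e ~ N(0, I sigma_e2).
#' The observation-level covariance Z K Z' is eigendecomposed once, after
#' which each average-information update costs O(n p^2). When an AI step
#' would leave the parameter space the update falls back to a
#' positivity-preserving EM-type fixed-point step
#' sigma_i^2 <- sigma_i^2 * (y' P V_i P y) / tr(P V_i). Standard errors come
#' from the inverse of the average-information matrix; the heritability SE
#' uses the delta method.
#'
#' @param design a \code{design_spec}.
#' @param K a \code{relmat} covering all observed individuals.
#' @param init optional \code{var_comp} start values (default: half the
#'   phenotypic variance each).
#' @param tol convergence threshold on the parameter change relative to the
#'   total variance (default 1e-8).
#' @param max_iter iteration cap (default 200); non-convergence is flagged,
#'   not raised.
#' @return a \code{var_comp}.
#' @export
ai_reml <- function(design, K, init = NULL, tol = 1e-8, max_iter = 200) {
  y <- design$y
  X <- design$X
  n <- length(y)
  p <- ncol(X)
  if (n < p + 2) stop("too few observations for REML")
  W <- zkz(design, K)
  ev <- eigen(W, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  if (min(ev$values) < -1e-6 * max(abs(ev$values)))
    stop("relationship matrix is not positive semi-definite on the observations")
  ys <- drop(crossprod(ev$vectors, y))
  Xs <- crossprod(ev$vectors, X)

  th <- if (is.null(init)) rep(var(y) / 2, 2)
        else c(init$sigma_a2, init$sigma_e2)
  th <- pmax(th, 1e-8 * var(y))

  AI <- NULL
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    v <- th[1] * lam + th[2]
    Xv <- Xs / v
    C <- crossprod(Xs, Xv)
    Cinv <- solve(C)
    beta <- drop(Cinv %*% crossprod(Xv, ys))
    Py <- (ys - drop(Xs %*% beta)) / v

    Papply <- function(z) (z - drop(Xs %*% (Cinv %*% crossprod(Xs, z / v)))) / v
    XtLX <- crossprod(Xs, (lam / v^2) * Xs)
    XtIX <- crossprod(Xs, Xs / v^2)
    tr1 <- sum(lam / v) - sum(Cinv * XtLX)
    tr2 <- sum(1 / v) - sum(Cinv * XtIX)
    q1 <- sum(lam * Py^2)
    q2 <- sum(Py^2)
    score <- -0.5 * c(tr1 - q1, tr2 - q2)

    w1 <- lam * Py
    w2 <- Py
    Pw1 <- Papply(w1)
    Pw2 <- Papply(w2)
    AI <- 0.5 * matrix(c(sum(w1 * Pw1), sum(w1 * Pw2),
                         sum(w1 * Pw2), sum(w2 * Pw2)), 2, 2)

    step <- tryCatch(solve(AI, score), error = function(e) NULL)
    th_new <- if (is.null(step)) NULL else th + step
    if (is.null(th_new) || any(th_new <= 0)) {
      # EM-type fixed point: positive whenever the traces are
      th_new <- th * c(q1 / max(tr1, .Machine$double.eps),
                       q2 / max(tr2, .Machine$double.eps))
      th_new <- pmax(th_new, 1e-12 * var(y))
    }
    delta <- max(abs(th_new - th)) / sum(th_new)
    th <- th_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }

  # final quantities at the converged values
  v <- th[1] * lam + th[2]
  Xv <- Xs / v
  C <- crossprod(Xs, Xv)
  Cinv <- solve(C)
  beta <- drop(Cinv %*% crossprod(Xv, ys))
  Py <- (ys - drop(Xs %*% beta)) / v
  ll <- -0.5 * (sum(log(v)) + determinant(C, logarithm = TRUE)$modulus +
                  sum(Py * ys))

  cov_th <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, 2, 2))
  se <- sqrt(pmax(diag(cov_th), 0))
  s <- sum(th)
  g <- c(th[2], -th[1]) / s^2
  h2_se <- sqrt(max(drop(t(g) %*% cov_th %*% g), 0))

  var_comp(th[1], th[2],
           se = c(sigma_a2 = se[1], sigma_e2 = se[2]),
           h2_se = h2_se, converged = converged, iterations = it,
           loglik = as.numeric(ll))
}

#' Solve the mixed-model equations
#'
#' Builds and solves
#' \deqn{[X'X, X'Z; Z'X, Z'Z + K^{-1} \sigma_e^2/\sigma_a^2] [b; u] = [X'y; Z'y]}
#' over all individuals of K, so individuals without records receive
#' predictions through their relationships. The ridge recorded on K (for
#' genomic matrices) is added to its diagonal before inversion.
#'
#' @param design a \code{design_spec} whose \code{k_ids} match rownames(K).
#' @param K a \code{relmat}.
#' @param vc a \code{var_comp} with strictly positive variances.
#' @return object of class \code{mme_fit}: fixed effects \code{b}, random
#'   effects \code{u} (named by individual), the variance ratio
#'   \code{alpha}, and solver diagnostics.
#' @export
solve_mme <- function(design, K, vc) {
  stopifnot(inherits(design, "design_spec"), inherits(vc, "var_comp"))
  Km <- relmat_matrix(K)
  if (!identical(design$k_ids, rownames(Km)))
    stop("design k_ids do not match the relationship matrix")
  if (vc$sigma_e2 <= 0 || vc$sigma_a2 <= 0)
    stop("variances must be strictly positive to form the MME")
  y <- design$y; X <- design$X; zi <- design$zi
  n <- length(y); p <- ncol(X); q <- nrow(Km)
  alpha <- vc$sigma_e2 / vc$sigma_a2

  ridge <- attr(K, "ridge") %||% 0
  Kinv <- chol2inv(chol(Km + diag(ridge, q)))

  Z <- matrix(0, n, q)
  Z[cbind(seq_len(n), zi)] <- 1
  XtX <- crossprod(X)
  XtZ <- crossprod(X, Z)
  ZtZ <- crossprod(Z)
  C <- rbind(cbind(XtX, XtZ),
             cbind(t(XtZ), ZtZ + Kinv * alpha))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  sol <- tryCatch(solve(C, rhs), error = function(e)
    stop("mixed-model equations are singular: ", conditionMessage(e)))

  resid_rel <- sqrt(sum((C %*% sol - rhs)^2)) / max(sqrt(sum(rhs^2)), 1e-300)
  b <- setNames(sol[seq_len(p)], colnames(X))
  u <- setNames(sol[p + seq_len(q)], rownames(Km))
  structure(list(b = b, u = u, alpha = alpha, vc = vc,
                 kind = attr(K, "kind"), ridge = ridge,
                 resid_rel = resid_rel,
                 rcond = rcond(C)),
            class = "mme_fit")
}

#' @export
print.mme_fit <- function(x, ...) {
  cat(sprintf("MME solution (%s matrix): %d fixed effects, %d individuals\n",
              x$kind, length(x$b), length(x$u)))
  cat(sprintf("  alpha = %.4g, relative residual %.2g, rcond %.2g\n",
              x$alpha, x$resid_rel, x$rcond))
  invisible(x)
}

#' Predict breeding values for individuals outside a fitted MME
#'
#' Individuals present in the fit are returned as solved; individuals absent
#' from the fit but present in K receive the conditional-expectation
#' extension \code{K[new, fit] K[fit, fit]^{-1} u}, which equals the MME
#' solution that includes them with no records.
#'
#' @param fit an \code{mme_fit}.
#' @param K a \code{relmat} containing at least the fit individuals and the
#'   targets.
#' @param ids target individual ids.
#' @return named numeric of predictions.
#' @export
predict_unobserved <- function(fit, K, ids) {
  Km <- relmat_matrix(K)
  if (!all(ids %in% rownames(Km))) stop("target id absent from K")
  out <- setNames(rep(NA_real_, length(ids)), ids)
  have <- ids %in% names(fit$u)
  out[have] <- fit$u[ids[have]]
  if (any(!have)) {
    base <- intersect(names(fit$u), rownames(Km))
    if (length(base) == 0) stop("fit individuals absent from K")
    ridge <- attr(K, "ridge") %||% 0
    Kb <- Km[base, base] + diag(ridge, length(base))
    new <- ids[!have]
    out[!have] <- drop(Km[new, base, drop = FALSE] %*%
                         solve(Kb, fit$u[base]))
  }
  out
}

#' Ridge SNP-BLUP (equal-variance marker effects)
#'
#' Solves the marker-effect mixed-model equations
#' \code{[X'X, X'M; M'X, M'M + I sigma_e2/sigma_q2] [b; q] = [X'y; M'y]}.
#' With M column-centred by twice the allele frequency and
#' \code{sigma_q2 = sigma_u2 / (2 sum p (1-p))}, the resulting GEBV
#' \code{M q} are algebraically identical to GBLUP breeding values from the
#' corresponding genomic relationship matrix.
#'
#' @param y response vector.
#' @param X fixed-effect incidence (full column rank).
#' @param M centred marker matrix (observations x markers).
#' @param sigma_q2 per-marker effect variance.
#' @param sigma_e2 residual variance.
#' @return list with \code{b}, \code{q} (marker effects) and \code{gebv}
#'   (\code{M \%*\% q}, named by rownames of M).
#' @export
snp_blup <- function(y, X, M, sigma_q2, sigma_e2) {
  stopifnot(nrow(M) == length(y), nrow(X) == length(y),
            sigma_q2 > 0, sigma_e2 > 0)
  p <- ncol(X); k <- ncol(M)
  lambda <- sigma_e2 / sigma_q2
  C <- rbind(cbind(crossprod(X), crossprod(X, M)),
             cbind(crossprod(M, X), crossprod(M) + diag(lambda, k)))
  rhs <- c(crossprod(X, y), crossprod(M, y))
  sol <- solve(C, rhs)
  b <- setNames(sol[seq_len(p)], colnames(X))
  q <- sol[p + seq_len(k)]
  gebv <- drop(M %*% q)
  names(gebv) <- rownames(M)
  list(b = b, q = q, gebv = gebv)
}
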