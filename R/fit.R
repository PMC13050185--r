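# Maximum-likelihood fitting of the dyad-independent model: independent
# Bernoulli dyads with logistic link, estimated by iteratively reweighted
# least squares with step-halving. Dyads sharing a covariate pattern are
# pooled into binomial rows first, which leaves the likelihood, estimates and
# observed information identical while making the solve size independent of
# the number of dyads.

# Group identical design rows. Returns Xg (unique rows), g (row -> group),
# m (dyads per group).
.aggregate_design <- function(X) {
  key <- do.call(paste, c(as.data.frame(X), sep = "\r"))
  ug <- !duplicated(key)
  g <- match(key, key[ug])
  list(Xg = X[ug, , drop = FALSE], g = g, m = tabulate(g, nbins = sum(ug)))
}

# IRLS core on binomial rows: s successes out of m at covariate rows Xg.
# Bernoulli log-likelihood (no binomial coefficient), so it matches the
# per-dyad likelihood exactly.
.fit_core <- function(Xg, m, s, max_iter = 100L, grad_tol = 1e-8,
                      sep_threshold = 15) {
  k <- ncol(Xg)
  beta <- numeric(k)
  # intercept warm start at the empirical logit of density
  dens <- sum(s) / sum(m)
  if (colnames(Xg)[1] == "edges" && dens > 0 && dens < 1) {
    beta[1] <- stats::qlogis(dens)
  }
  loglik <- function(b) {
    eta <- drop(Xg %*% b)
    sum(s * eta - m * log1p(exp(eta)))
  }
  ll <- loglik(beta)
  converged <- FALSE
  grad <- rep(Inf, k)
  for (it in seq_len(max_iter)) {
    eta <- drop(Xg %*% beta)
    p <- stats::plogis(eta)
    grad <- drop(crossprod(Xg, s - m * p))
    if (max(abs(grad)) < grad_tol) {
      converged <- TRUE
      break
    }
    w <- pmax(m * p * (1 - p), 1e-12)
    XtWX <- crossprod(Xg * w, Xg)
    step <- tryCatch(solve(XtWX, grad),
                     error = function(e) {
                       drop(.pseudo_solve(XtWX) %*% grad)
                     })
    # step-halving: never accept a decrease in log-likelihood
    lam <- 1
    repeat {
      cand <- beta + lam * step
      llc <- loglik(cand)
      if (is.finite(llc) && llc >= ll - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) { cand <- beta; llc <- ll; break }
    }
    beta <- cand
    ll <- llc
  }
  eta <- drop(Xg %*% beta)
  p <- stats::plogis(eta)
  grad <- drop(crossprod(Xg, s - m * p))
  if (!converged && max(abs(grad)) < grad_tol) converged <- TRUE
  w <- pmax(m * p * (1 - p), 1e-12)
  XtWX <- crossprod(Xg * w, Xg)
  vcov <- tryCatch(solve(XtWX), error = function(e) .pseudo_solve(XtWX))
  separated <- abs(beta) > sep_threshold
  list(beta = beta, vcov = vcov, loglik = ll, converged = converged,
       separated = separated, grad = grad, iterations = it)
}

# Moore-Penrose pseudoinverse via SVD (used only when the weighted
# cross-product is numerically singular, e.g. under separation).
.pseudo_solve <- function(A, tol = 1e-10) {
  sv <- svd(A)
  d <- sv$d
  pos <- d > tol * max(d)
  sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / d[pos])
}

#' Fit a dyad-independent network model by maximum likelihood
#'
#' Treats each unordered dyad as an independent Bernoulli observation with
#' logistic link and maximises the likelihood by iteratively reweighted least
#' squares with step-halving. Convergence requires the gradient sup-norm to
#' fall below `grad_tol` (default `1e-8`) within `max_iter` iterations.
#' Standard errors come from the inverse observed information; Wald p-values
#' are two-sided normal. Perfect separation (a covariate cell whose dyads are
#' all connected or all unconnected) drives the affected coefficient towards
#' infinity; coefficients with `|estimate| > 15` are flagged `separated` and
#' reported with infinite standard error, while the remaining coefficients
#' are still usable.
#'
#' @param design a [build_design()] result.
#' @param max_iter maximum IRLS iterations.
#' @param grad_tol convergence tolerance on the gradient sup-norm.
#' @return A `kin_fit`: coefficient table (estimate, se, z, p, fold, odds
#'   ratio, separated flag), log-likelihood, parameter count `k`, dyad count
#'   `N`, information criteria and convergence flag.
#' @examples
#' nt <- node_table(data.frame(id = letters[1:3], sex = c("F", "F", "M")))
#' net <- kin_network(nt, data.frame(i = 1, j = 2))
#' fit_dyad_ergm(build_design(net, model_spec(term_edges())))
#' @export
fit_dyad_ergm <- function(design, max_iter = 100L, grad_tol = 1e-8) {
  stopifnot(inherits(design, "dyad_design"))
  X <- design$X
  k <- ncol(X)
  # guard: constant non-intercept column or exact collinearity
  qrX <- qr(X)
  if (qrX$rank < k) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):k]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  agg <- .aggregate_design(X)
  s <- drop(rowsum(design$y, agg$g))
  core <- .fit_core(agg$Xg, agg$m, s, max_iter = max_iter,
                    grad_tol = grad_tol)
  .as_kin_fit(core, design)
}

# Assemble the user-facing fit object from the IRLS core output.
.as_kin_fit <- function(core, design) {
  X <- design$X
  beta <- core$beta
  names(beta) <- colnames(X)
  se <- sqrt(pmax(diag(core$vcov), 0))
  se[core$separated] <- Inf
  z <- beta / se
  pval <- 2 * stats::pnorm(-abs(z))
  pval[core$separated] <- NA_real_
  N <- length(design$y)
  k <- length(beta)
  ic <- information_criteria(core$loglik, k, N)
  fold <- vapply(seq_along(beta), function(j)
    if (j == 1) NA_real_ else fold_change(beta[1], beta[j]), numeric(1))
  structure(list(
    coefficients = beta,
    se = se,
    z = z,
    p_value = pval,
    fold = fold,
    odds_ratio = c(NA_real_, exp(beta[-1])),
    separated = core$separated,
    loglik = core$loglik,
    deviance = -2 * core$loglik,
    k = k,
    n_dyads = N,
    bic = ic[["BIC"]], aic = ic[["AIC"]], aicc = ic[["AICc"]],
    converged = core$converged,
    iterations = core$iterations,
    vcov = core$vcov,
    term_of = design$term_of,
    spec = design$spec
  ), class = "kin_fit")
}

#' @export
print.kin_fit <- function(x, digits = 4, ...) {
  cat("Dyad-independent network model (", model_label(x$spec), ")\n", sep = "")
  cat(sprintf("N = %d dyads, k = %d, logLik = %.3f, BIC = %.2f, AIC = %.2f\n",
              x$n_dyads, x$k, x$loglik, x$bic, x$aic))
  if (!x$converged) cat("WARNING: IRLS did not converge\n")
  tab <- data.frame(
    estimate = round(x$coefficients, digits),
    se = round(x$se, digits),
    z = round(x$z, digits),
    p = signif(x$p_value, 3),
    fold = round(x$fold, 2)
  )
  if (any(x$separated)) tab$separated <- ifelse(x$separated, "*", "")
  print(tab)
  invisible(x)
}

#' Fold-increase in connection probability
#'
#' Converts a coefficient on the log-odds scale into the ratio of dyad
#' connection probabilities relative to the baseline cell:
#' `plogis(theta0 + theta) / plogis(theta0)`. For sparse networks (very
#' negative `theta0`) this approaches the odds ratio `exp(theta)` from below.
#'
#' @param theta0 baseline log-odds (the intercept).
#' @param theta coefficient of interest.
#' @return The fold-change, a positive scalar; 1 when `theta = 0`.
#' @examples
#' fold_change(-4, 0.35) # ~1.41
#' @export
fold_change <- function(theta0, theta) {
  stopifnot(is.finite(theta0), is.finite(theta))
  stats::plogis(theta0 + theta) / stats::plogis(theta0)
}

#' Information criteria for a fitted dyad model
#'
#' The observation count `N` is the number of dyads `n(n-1)/2` — the number
#' of potential edges, which grows quadratically with nodes, so `N >> k` even
#' for small networks (the regime in which BIC's stronger penalty is
#' preferred).
#'
#' @param loglik maximised log-likelihood.
#' @param k number of parameters (including the intercept).
#' @param N number of observations (dyads).
#' @return Named numeric vector `c(BIC, AIC, AICc)`; `AICc` is `NA` (with a
#'   warning) when `N <= k + 1`.
#' @examples
#' information_criteria(-100, 2, 44850)
#' @export
information_criteria <- function(loglik, k, N) {
  stopifnot(is.finite(loglik), k >= 0, N >= 1)
  bic <- -2 * loglik + k * log(N)
  aic <- -2 * loglik + 2 * k
  if (N > k + 1) {
    aicc <- aic + 2 * k * (k + 1) / (N - k - 1)
  } else {
    warning("AICc undefined: N <= k + 1", call. = FALSE)
    aicc <- NA_real_
  }
  c(BIC = bic, AIC = aic, AICc = aicc)
}

#' @export
logLik.kin_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, class = "logLik")
}

#' @export
coef.kin_fit <- function(object, ...) object$coefficients

#' @export
vcov.kin_fit <- function(object, ...) object$vcov
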