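#' Model specification for the triad log-linear model
#'
#' The model stratifies the 15 triad cells on the six unordered parental
#' mating types (intercepts mu1..mu6), always includes child-dose terms
#' (c1 for one copy, c2 for two), and optionally includes an imprinting
#' term alpha (log relative risk of a maternally versus paternally
#' inherited copy in heterozygous children) and maternal-effect terms
#' beta (mother carries two risk alleles) and gamma (one).
#'
#' The double-heterozygote cell (M = P = C = 1) cannot resolve parental
#' origin; its expected count is modelled as the sum of its two latent
#' transmission paths, exp(mu + c1 + gamma) * (exp(alpha) + 1), which
#' reduces to the usual 2x Mendelian multiplicity when alpha = 0.
#'
#' @param imprinting include the alpha term (default `TRUE`).
#' @param maternal include the beta and gamma terms (default `TRUE`).
#' @param alternative how the full model for each term's likelihood
#'   ratio test is formed: `"joint"` (default) drops the tested term
#'   from the model containing all included terms; `"marginal"` tests
#'   each term against a model with strata and child-dose terms only.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(imprinting = TRUE, maternal = TRUE,
                       alternative = c("joint", "marginal")) {
  structure(list(imprinting = isTRUE(imprinting),
                 maternal = isTRUE(maternal),
                 alternative = match.arg(alternative)),
            class = "model_spec")
}

# numerically safe log(1 + exp(x))
log1pexp <- function(x) ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))

#' Expected cell means of the triad log-linear model
#'
#' @param params named list with `mu` (numeric of length 6, mating-type
#'   intercepts for strata 2x2, 2x1, 2x0, 1x1, 1x0, 0x0), `c1`, `c2`
#'   (child-dose terms) and optional `alpha`, `beta`, `gamma`
#'   (defaulting to 0, i.e. no effect).
#' @return Numeric vector of 15 positive expected counts. For every
#'   cell except the double heterozygote, the mean is
#'   exp(mu_s + c1 I(C=1) + c2 I(C=2) + alpha I(origin maternal) +
#'   beta I(M=2) + gamma I(M=1)); the double-heterozygote mean is the
#'   sum of its maternal- and paternal-origin path means.
#' @export
expected_cell_means <- function(params) {
  p <- params
  for (nm in c("alpha", "beta", "gamma")) if (is.null(p[[nm]])) p[[nm]] <- 0
  vals <- c(p$mu, p$c1, p$c2, p$alpha, p$beta, p$gamma)
  if (any(!is.finite(vals) & !(is.infinite(vals) & vals < 0))) {
    stop("non-finite model parameter", call. = FALSE)
  }
  cl <- cells_tab()
  eta <- p$mu[cl$stratum] + p$c1 * cl$C1 + p$c2 * cl$C2 +
    p$alpha * (cl$origin == "maternal") + p$beta * cl$M2 + p$gamma * cl$M1
  m <- exp(eta)
  i9 <- which(cl$origin == "ambiguous")
  m[i9] <- exp(p$mu[cl$stratum[i9]] + p$c1 + p$gamma) * (exp(p$alpha) + 1)
  m
}

#' Poisson log-likelihood of a triad cell table
#'
#' Computes sum(n_i log m_i - m_i) over the 15 cells, dropping the
#' data-only log(n_i!) constant. With free mating-type intercepts this
#' Poisson likelihood is equivalent, for likelihood-ratio purposes, to
#' the 15-cell multinomial conditional on the total count. Returns
#' `-Inf` (rather than raising) when some cell has zero mean but a
#' positive count.
#'
#' @param x a [cell_table()].
#' @param params parameter list as in [expected_cell_means()].
#' @return A single numeric log-likelihood value.
#' @export
log_likelihood <- function(x, params) {
  stopifnot(inherits(x, "cell_table"))
  m <- expected_cell_means(params)
  n <- x$counts
  if (any(m == 0 & n > 0)) return(-Inf)
  term <- ifelse(n > 0, n * log(m), 0)
  sum(term) - sum(m)
}

# ---- internal fitting machinery -------------------------------------------

# design pieces for the non-stratum covariates, in canonical term order
.term_names <- c("c1", "c2", "alpha", "beta", "gamma")

term_design <- function() {
  cl <- cells_tab()
  X <- cbind(c1 = cl$C1, c2 = cl$C2,
             alpha = as.numeric(cl$origin == "maternal"),
             beta = cl$M2, gamma = cl$M1)
  # the ambiguous cell enters via a merged-path mean handled separately;
  # its linear part is c1 + gamma with alpha contributing log(e^a + 1)
  i9 <- which(cl$origin == "ambiguous")
  X[i9, ] <- c(1, 0, 0, 0, 1)
  list(X = X, i9 = i9, stratum = cl$stratum)
}

.design <- term_design()

get_design <- function() .design

# profile log-likelihood (mating-type intercepts maximized analytically)
# theta: named vector over `active` term names; inactive terms fixed at 0
profile_loglik <- function(theta, active, n, grad = FALSE) {
  d <- get_design()
  full <- stats::setNames(numeric(5), .term_names)
  full[active] <- theta
  logr <- as.vector(d$X %*% full)
  logr[d$i9] <- logr[d$i9] + log1pexp(full["alpha"])
  Ns <- as.vector(rowsum(n, d$stratum))       # totals per stratum 1..6
  use_s <- Ns > 0
  use_c <- use_s[d$stratum]
  r <- exp(logr)
  Rs <- as.vector(rowsum(r, d$stratum))
  ll <- sum(n[use_c] * logr[use_c]) +
    sum(Ns[use_s] * (log(Ns[use_s]) - log(Rs[use_s]))) - sum(Ns[use_s])
  if (!grad) return(ll)
  G <- d$X
  G[d$i9, "alpha"] <- stats::plogis(full["alpha"])
  g <- numeric(length(active))
  for (k in seq_along(active)) {
    gk <- G[, active[k]]
    wsum <- as.vector(rowsum(r * gk, d$stratum))
    g[k] <- sum(n[use_c] * gk[use_c]) -
      sum(Ns[use_s] * wsum[use_s] / Rs[use_s])
  }
  list(value = ll, gradient = g)
}

# which optional terms the data can estimate
estimable_terms <- function(n) {
  cl <- cells_tab()
  nz <- n > 0
  out <- list()
  het <- cl$C == 1L  # cells with a heterozygous child (incl. ambiguous)
  if (!any(nz & het)) {
    out$alpha <- "no heterozygous affected children observed"
  }
  for (trm in c("beta", "gamma")) {
    ind <- if (trm == "beta") cl$M2 else cl$M1
    if (length(unique(ind[nz])) < 2) {
      out[[trm]] <- sprintf("maternal indicator for %s constant across observed cells", trm)
    }
  }
  out
}

# crude data-driven starting values on the active terms
start_values <- function(active, n) {
  cl <- cells_tab()
  lr <- function(num, den) {
    v <- log((sum(n[num]) + 0.5) / (sum(n[den]) + 0.5))
    max(min(v, 6), -6)
  }
  s <- c(c1 = lr(cl$C == 1L, cl$C == 0L),
         c2 = lr(cl$C == 2L, cl$C == 0L),
         alpha = lr(cl$origin == "maternal", cl$origin == "paternal"),
         beta = lr(cl$M2 == 1L, cl$M == 0L),
         gamma = lr(cl$M1 == 1L, cl$M == 0L))
  s[active]
}

COEF_BOUND <- 12

fit_terms <- function(n, active, extra_starts = list()) {
  if (!length(active)) {
    ll <- profile_loglik(numeric(0), character(0), n)
    return(list(theta = stats::setNames(numeric(0), character(0)),
                loglik = ll, converged = TRUE, n_iterations = 0L))
  }
  starts <- c(list(stats::setNames(numeric(length(active)), active),
                   start_values(active, n)),
              extra_starts)
  best <- NULL
  for (s0 in starts) {
    opt <- stats::optim(
      par = s0,
      fn = function(th) profile_loglik(th, active, n),
      gr = function(th) profile_loglik(th, active, n, grad = TRUE)$gradient,
      method = "L-BFGS-B", lower = -COEF_BOUND, upper = COEF_BOUND,
      control = list(fnscale = -1, factr = 10, pgtol = 1e-10, maxit = 1000)
    )
    if (is.null(best) || opt$value > best$value) best <- opt
  }
  list(theta = stats::setNames(best$par, active),
       loglik = best$value,
       converged = best$convergence == 0,
       n_iterations = unname(best$counts[1]))
}

# stratum intercepts implied by the profile
profile_mu <- function(theta, active, n) {
  d <- get_design()
  full <- stats::setNames(numeric(5), .term_names)
  full[active] <- theta
  logr <- as.vector(d$X %*% full)
  logr[d$i9] <- logr[d$i9] + log1pexp(full["alpha"])
  Ns <- as.vector(rowsum(n, d$stratum))
  Rs <- as.vector(rowsum(exp(logr), d$stratum))
  mu <- ifelse(Ns > 0, log(Ns) - log(Rs), -Inf)
  stats::setNames(mu, paste0("mu", 1:6))
}

# ---- user-facing fitting ---------------------------------------------------

#' Fit the triad log-linear model
#'
#' Maximizes the Poisson (multinomial-equivalent) likelihood of the
#' 15-cell table by quasi-Newton optimization of the profile likelihood
#' in which each mating-type intercept is maximized analytically.
#' Optimization runs from an all-zero start and a count-ratio-matched
#' start (plus any estimates passed down from a nested fit) and keeps
#' the best. Coefficients are constrained to |coef| <= 12 so the
#' likelihood stays finite when a cell class is empty; fits on that
#' boundary are flagged. Mating types with zero total count have their
#' intercept reported as `-Inf` and contribute nothing. Terms the data
#' cannot estimate (indicator constant across observed cells, or no
#' heterozygous children for the imprinting term) are dropped and
#' reported in `inestimable_terms`.
#'
#' @param x a [cell_table()].
#' @param spec a [model_spec()].
#' @param drop optional character vector of terms to force out of the
#'   model (used for reduced fits in likelihood-ratio tests).
#' @param extra_starts list of additional named start vectors.
#' @return An object of class `poo_fit` with elements `coefficients`
#'   (mu1..mu6 plus estimated terms), `log_likelihood`, `converged`,
#'   `n_iterations`, `inestimable_terms`, `boundary`, `fitted_means`,
#'   `spec` and `cell_table`.
#' @export
fit_poo <- function(x, spec = model_spec(), drop = character(),
                    extra_starts = list()) {
  stopifnot(inherits(x, "cell_table"), inherits(spec, "model_spec"))
  n <- x$counts
  if (sum(n) == 0) stop("cell table has no counts", call. = FALSE)
  wanted <- c("c1", "c2",
              if (spec$imprinting) "alpha",
              if (spec$maternal) c("beta", "gamma"))
  wanted <- setdiff(wanted, drop)
  inest <- estimable_terms(n)
  inest <- inest[names(inest) %in% wanted]
  active <- setdiff(wanted, names(inest))

  extra_starts <- lapply(extra_starts, function(s) {
    out <- stats::setNames(numeric(length(active)), active)
    keep <- intersect(names(s), active)
    out[keep] <- pmax(pmin(s[keep], COEF_BOUND), -COEF_BOUND)
    out
  })
  res <- fit_terms(n, active, extra_starts)
  mu <- profile_mu(res$theta, active, n)
  theta_full <- stats::setNames(numeric(5), .term_names)
  theta_full[active] <- res$theta
  means <- expected_cell_means(list(mu = unname(mu),
                                    c1 = theta_full["c1"], c2 = theta_full["c2"],
                                    alpha = theta_full["alpha"],
                                    beta = theta_full["beta"],
                                    gamma = theta_full["gamma"]))
  structure(list(coefficients = c(mu, res$theta),
                 log_likelihood = res$loglik,
                 converged = res$converged,
                 n_iterations = res$n_iterations,
                 inestimable_terms = inest,
                 boundary = any(abs(res$theta) >= COEF_BOUND - 1e-3),
                 fitted_means = means,
                 terms = active,
                 spec = spec,
                 cell_table = x),
            class = "poo_fit")
}

#' @export
print.poo_fit <- function(x, digits = 4, ...) {
  cat("Triad log-linear model fit\n")
  cat(sprintf("  log-likelihood: %.6f  (converged: %s%s)\n",
              x$log_likelihood, x$converged,
              if (x$boundary) ", at coefficient bound" else ""))
  print(round(x$coefficients, digits))
  if (length(x$inestimable_terms)) {
    cat("  inestimable:",
        paste(sprintf("%s (%s)", names(x$inestimable_terms),
                      unlist(x$inestimable_terms)), collapse = "; "), "\n")
  }
  invisible(x)
}

#' Likelihood-ratio test of one parent-of-origin term
#'
#' Tests `alpha` (imprinting), `beta` or `gamma` (maternal effects) by
#' comparing the full model of `spec` with the model in which the term
#' is removed. The statistic 2 (logLik_full - logLik_reduced) is
#' referred to chi-square with 1 df; a statistic that is negative within
#' numerical noise (1e-8) is clamped to 0 (reported p = 1). The odds
#' ratio is the exponentiated coefficient from the full fit; for alpha,
#' OR > 1 means the risk allele is transmitted to affected children more
#' often by the mother.
#'
#' @param x a [cell_table()].
#' @param term one of `"alpha"`, `"beta"`, `"gamma"`.
#' @param spec a [model_spec()]; the term must be included in it.
#' @param full optional pre-computed full-model `poo_fit` to share
#'   across terms.
#' @return An object of class `term_test`: list with `term`,
#'   `lrt_statistic`, `df`, `p_value`, `odds_ratio`, `status`
#'   (`"ok"`/`"inestimable"`) and `boundary`.
#' @export
lrt_term <- function(x, term = c("alpha", "beta", "gamma"),
                     spec = model_spec(), full = NULL) {
  term <- match.arg(term)
  included <- switch(term, alpha = spec$imprinting,
                     beta = spec$maternal, gamma = spec$maternal)
  if (!included) stop(sprintf("term '%s' is not included in the model spec", term),
                      call. = FALSE)
  drop_base <- if (spec$alternative == "marginal") {
    setdiff(c("alpha", "beta", "gamma"), term)
  } else character()
  if (is.null(full)) full <- fit_poo(x, spec, drop = drop_base)
  if (term %in% names(full$inestimable_terms)) {
    return(structure(list(term = term, lrt_statistic = NA_real_, df = 1L,
                          p_value = NA_real_, odds_ratio = NA_real_,
                          status = "inestimable",
                          reason = full$inestimable_terms[[term]],
                          boundary = FALSE),
                     class = "term_test"))
  }
  start_red <- full$coefficients[intersect(names(full$coefficients), .term_names)]
  reduced <- fit_poo(x, spec, drop = c(drop_base, term),
                     extra_starts = list(start_red))
  stat <- 2 * (full$log_likelihood - reduced$log_likelihood)
  if (abs(stat) < 1e-8) stat <- 0  # numerically zero: report p = 1 exactly
  if (stat < 0) {
    # reduced fit beat the full fit beyond noise: retry full from reduced
    full2 <- fit_poo(x, spec, drop = drop_base,
                     extra_starts = list(reduced$coefficients[
                       intersect(names(reduced$coefficients), .term_names)]))
    if (full2$log_likelihood > full$log_likelihood) full <- full2
    stat <- max(0, 2 * (full$log_likelihood - reduced$log_likelihood))
  }
  structure(list(term = term,
                 lrt_statistic = stat,
                 df = 1L,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 odds_ratio = unname(exp(full$coefficients[term])),
                 status = "ok",
                 boundary = full$boundary || reduced$boundary),
            class = "term_test")
}

#' @export
print.term_test <- function(x, ...) {
  if (x$status == "inestimable") {
    cat(sprintf("%s: inestimable (%s)\n", x$term, x$reason))
  } else {
    cat(sprintf("%s: LRT = %.4f (df 1), p = %.4g, OR = %.4g%s\n",
                x$term, x$lrt_statistic, x$p_value, x$odds_ratio,
                if (x$boundary) " [boundary]" else ""))
  }
  invisible(x)
}

#' Test all three parent-of-origin terms
#'
#' Runs [lrt_term()] for alpha, beta and gamma, sharing a single
#' full-model fit.
#'
#' @param x a [cell_table()].
#' @param spec a [model_spec()] with both imprinting and maternal terms.
#' @return A list of class `poo_tests` with elements `alpha`, `beta`,
#'   `gamma` (each a `term_test`) and `fit` (the shared full `poo_fit`).
#' @export
test_all_terms <- function(x, spec = model_spec()) {
  stopifnot(spec$imprinting, spec$maternal)
  full <- if (spec$alternative == "joint") fit_poo(x, spec) else NULL
  out <- lapply(c(alpha = "alpha", beta = "beta", gamma = "gamma"),
                function(trm) lrt_term(x, trm, spec, full = full))
  out$fit <- if (is.null(full)) fit_poo(x, spec) else full
  class(out) <- "poo_tests"
  out
}

#' @export
print.poo_tests <- function(x, ...) {
  for (trm in c("alpha", "beta", "gamma")) print(x[[trm]])
  invisible(x)
}
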