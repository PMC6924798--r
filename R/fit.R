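#' Fit the interaction mixed logit by maximum simulated likelihood
#'
#' Maximises [mixl_loglik()] with BFGS and its analytic gradient.  Default
#' starting values are the conditional logit estimates for position and
#' mean terms and 0.1 for every SD term.  Standard errors come from the
#' sandwich of the numerical Hessian (finite differences of the analytic
#' gradient) and the outer product of respondent scores; p-values from
#' asymptotic normal t-ratios, with Holm's sequential Bonferroni
#' adjustment across all reported coefficients.  BIC uses the number of
#' respondents (the panel unit) as the sample size by default.
#'
#' @param data A `choice_data` data frame.
#' @param spec A `mixl_spec`.
#' @param scheme A `dce_scheme`.
#' @param n_draws Scrambled Halton draws per respondent (default 500).
#' @param seed Seed for draw scrambling; estimation is bit-reproducible
#'   given the seed and draw count.
#' @param start Optional start vector (order of [spec_labels()]).
#' @param maxit,reltol Passed to [stats::optim()].
#' @param bic_n Sample size used in the BIC (default: respondents).
#' @param antithetic Use antithetic draw pairs (default `TRUE` for even
#'   `n_draws`); see [halton_draws()].
#' @param draw_method `"halton"` (scrambled Halton, the default) or
#'   `"mlhs"` (per-respondent modified Latin hypercube, see
#'   [mlhs_draws()]; preferable at small draw counts).
#' @param optimizer `"bfgs"` (default) or `"bhhh"` (score-based
#'   Newton-type steps; far fewer likelihood evaluations, useful at large
#'   draw counts).
#' @return A `mixl_fit` object: coefficients, `se`, `tstat`, `p`,
#'   `p_holm`, `loglik`, `bic`, `k`, `n_respondents`, `n_draws`, `seed`,
#'   `vcov`, `converged`, plus the spec and scheme.
#' @export
fit_mixed_logit <- function(data, spec, scheme, n_draws = 500L, seed = 1L,
                            start = NULL, maxit = 500L, reltol = 1e-10,
                            bic_n = NULL, antithetic = TRUE,
                            draw_method = c("halton", "mlhs"),
                            optimizer = c("bfgs", "bhhh")) {
  draw_method <- match.arg(draw_method)
  optimizer <- match.arg(optimizer)
  mats <- build_mixl_matrices(data, spec, scheme)
  D <- length(mats$sd_sys)
  cube <- if (D > 0L) {
    z <- if (draw_method == "mlhs")
      mlhs_draws(mats$n_respondents, n_draws, D, seed = seed)
    else
      halton_draws(mats$n_respondents, n_draws, D, seed = seed,
                   antithetic = antithetic && n_draws %% 2L == 0L)
    draws_to_cube(z, mats$n_respondents, n_draws, seq_len(D))
  } else array(0, dim = c(1, 1, mats$n_respondents))

  if (is.null(start)) {
    cl <- clogit_newton(mats)
    start <- c(cl$coefficients, rep(0.1, mats$n_sd))
  }
  if (length(start) != mats$n_mean + mats$n_sd)
    stop("start vector has wrong length", call. = FALSE)

  if (optimizer == "bhhh") {
    opt <- bhhh_optim(start, function(th)
      eval_mixl(th, mats, cube, want_scores = TRUE),
      maxit = maxit, reltol = reltol)
    theta <- opt$par
    converged <- opt$converged
  } else {
    # fn and gr share one evaluation: optim calls gr at the point it has
    # just evaluated fn at, so cache the last joint result
    cache <- new.env(parent = emptyenv())
    joint <- function(th) {
      if (!is.null(cache$th) && identical(th, cache$th)) return(cache$res)
      res <- eval_mixl(th, mats, cube)
      cache$th <- th
      cache$res <- res
      res
    }
    negll <- function(th) -joint(th)$loglik
    neggr <- function(th) -joint(th)$gradient
    opt <- stats::optim(start, fn = negll, gr = neggr, method = "BFGS",
                        control = list(maxit = maxit, reltol = reltol))
    theta <- opt$par
    converged <- opt$convergence == 0L
  }
  final <- eval_mixl(theta, mats, cube, want_scores = TRUE)
  gnorm <- max(abs(final$gradient))

  H <- num_hessian(function(th) eval_mixl(th, mats, cube)$gradient, theta)
  B <- crossprod(final$scores)
  V <- tryCatch({
    Hinv <- solve(-(H + t(H)) / 2)
    Hinv %*% B %*% Hinv
  }, error = function(e) NULL)
  se <- if (is.null(V)) rep(NA_real_, length(theta)) else {
    dg <- diag(V)
    ifelse(dg > 0, sqrt(dg), NA_real_)
  }

  k <- length(theta)
  n_resp <- mats$n_respondents
  if (is.null(bic_n)) bic_n <- n_resp
  tstat <- theta / se
  p <- 2 * stats::pnorm(-abs(tstat))
  names(theta) <- names(se) <- names(tstat) <- names(p) <- mats$labels

  structure(list(coefficients = theta, se = se, tstat = tstat, p = p,
                 p_holm = holm_adjust(p),
                 loglik = final$loglik, k = k,
                 bic = bic(final$loglik, k, bic_n),
                 n_respondents = n_resp, n_tasks = mats$n_tasks,
                 n_draws = if (D > 0L) n_draws else 0L, seed = seed,
                 vcov = V, converged = converged,
                 gradient_norm = gnorm,
                 vcov_singular = is.null(V),
                 method = "maximum simulated likelihood",
                 n_mean = mats$n_mean, n_sd = mats$n_sd,
                 spec = spec, scheme = scheme),
            class = "mixl_fit")
}

#' Fit the conditional (multinomial) logit special case
#'
#' The fixed-coefficient model with closed-form choice probabilities; its
#' log-likelihood is globally concave, so Newton iterations converge to
#' the global maximum (stopping at gradient norm below `tol`).  Serves as
#' the analytic oracle for the sigma = 0 slice of the mixed logit.  Any SD
#' terms in `spec` are ignored.
#'
#' @inheritParams fit_mixed_logit
#' @param tol Gradient-norm convergence tolerance (default 1e-8).
#' @return A `mixl_fit` with `method = "conditional logit"`; a diverging
#'   coefficient path (separation) is flagged via `converged = FALSE`.
#' @export
fit_conditional_logit <- function(data, spec, scheme, tol = 1e-8,
                                  bic_n = NULL) {
  spec_cl <- spec
  spec_cl$sd[] <- FALSE
  mats <- build_mixl_matrices(data, spec_cl, scheme)
  cl <- clogit_newton(mats, tol = tol)
  theta <- cl$coefficients
  se <- cl$se
  k <- length(theta)
  n_resp <- mats$n_respondents
  if (is.null(bic_n)) bic_n <- n_resp
  tstat <- theta / se
  p <- 2 * stats::pnorm(-abs(tstat))
  names(theta) <- names(se) <- names(tstat) <- names(p) <- mats$labels

  structure(list(coefficients = theta, se = se, tstat = tstat, p = p,
                 p_holm = holm_adjust(p),
                 loglik = cl$loglik, k = k,
                 bic = bic(cl$loglik, k, bic_n),
                 n_respondents = n_resp, n_tasks = mats$n_tasks,
                 n_draws = 0L, seed = NA_integer_,
                 vcov = cl$vcov, converged = cl$converged,
                 gradient_norm = cl$gradient_norm,
                 vcov_singular = FALSE,
                 method = "conditional logit",
                 n_mean = mats$n_mean, n_sd = 0L,
                 spec = spec_cl, scheme = scheme),
            class = "mixl_fit")
}

# BHHH maximiser: Newton-type steps using the outer product of respondent
# scores as the information approximation, with backtracking line search.
# Each iteration costs a single likelihood + score evaluation, which makes
# large draw counts affordable.
bhhh_optim <- function(start, eval_fn, maxit = 200L, reltol = 1e-9) {
  th <- start
  cur <- eval_fn(th)
  K <- length(th)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    B <- crossprod(cur$scores)
    step <- tryCatch(solve(B + diag(1e-8, K), cur$gradient),
                     error = function(e) cur$gradient)
    lam <- 1
    new <- NULL
    while (lam > 1e-8) {
      cand <- tryCatch(eval_fn(th + lam * step), error = function(e) NULL)
      if (!is.null(cand) && is.finite(cand$loglik) &&
          cand$loglik > cur$loglik) { new <- cand; break }
      lam <- lam / 2
    }
    if (is.null(new)) break  # no uphill step found
    improvement <- new$loglik - cur$loglik
    th <- th + lam * step
    cur <- new
    if (improvement < reltol * (abs(cur$loglik) + 0.1)) {
      converged <- TRUE
      break
    }
  }
  if (!converged)  # accept a stall at a (numerically) stationary point
    converged <- max(abs(cur$gradient)) <
      1e-4 * max(1, abs(cur$loglik) / length(cur$gradient))
  list(par = th, loglik = cur$loglik, converged = converged,
       iterations = it)
}

# Newton-Raphson for the conditional logit on prebuilt matrices.
clogit_newton <- function(mats, tol = 1e-8, max_iter = 100L) {
  X <- mats$Xm
  tid <- mats$tid
  chosen <- mats$chosen_row + 1L
  K <- ncol(X)
  theta <- numeric(K)
  xch <- colSums(X[chosen, , drop = FALSE])
  ll_at <- function(th) {
    u <- drop(X %*% th)
    um <- tapply_max(u, tid)
    eu <- exp(u - um[tid])
    denom <- rowsum(eu, tid)
    p <- eu / denom[tid]
    list(ll = sum(u[chosen] - um - log(denom)), p = p)
  }
  cur <- ll_at(theta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    p <- cur$p
    g <- xch - colSums(X * p)
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    Xp <- rowsum(X * p, tid)
    info <- crossprod(X * sqrt(p)) - crossprod(Xp)
    step <- tryCatch(solve(info, g), error = function(e) NULL)
    if (is.null(step)) break
    new <- ll_at(theta + step)
    halvings <- 0L
    while (new$ll < cur$ll && halvings < 30L) {
      step <- step / 2
      new <- ll_at(theta + step)
      halvings <- halvings + 1L
    }
    theta <- theta + step
    cur <- new
  }
  separated <- any(abs(theta) > 15)
  p <- cur$p
  Xp <- rowsum(X * p, tid)
  info <- crossprod(X * sqrt(p)) - crossprod(Xp)
  vcov <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, K, K)
  })
  g <- xch - colSums(X * p)
  list(coefficients = theta, loglik = cur$ll, vcov = vcov,
       se = sqrt(pmax(diag(vcov), 0)),
       converged = converged && !separated,
       gradient_norm = max(abs(g)))
}

tapply_max <- function(x, g) {
  # max per contiguous group; g is a non-decreasing integer 1..T
  starts <- which(!duplicated(g))
  ends <- c(starts[-1] - 1L, length(g))
  vapply(seq_along(starts),
         function(i) max(x[starts[i]:ends[i]]), numeric(1))
}

# forward-difference Hessian of the log-likelihood from its gradient
num_hessian <- function(grad_fun, theta, h_scale = 1e-5) {
  K <- length(theta)
  g0 <- grad_fun(theta)
  H <- matrix(0, K, K)
  for (j in seq_len(K)) {
    h <- h_scale * max(1, abs(theta[j]))
    th <- theta
    th[j] <- th[j] + h
    H[, j] <- (grad_fun(th) - g0) / h
  }
  (H + t(H)) / 2
}

#' Bayesian Information Criterion
#'
#' `k * ln(n) - 2 * loglik`; lower is better.  For panel choice data `n`
#' is taken as the number of respondents (the independent sampling unit).
#'
#' @param loglik Maximised log-likelihood.
#' @param k Number of free parameters.
#' @param n Sample size.
#' @return A scalar.
#' @export
bic <- function(loglik, k, n) {
  stopifnot(n >= 1, k >= 0)
  k * log(n) - 2 * loglik
}

#' Holm's sequential Bonferroni adjustment
#'
#' Step-down familywise error control: sort the p-values ascending, set
#' `adj_(i) = max_{j <= i} min(1, (m - j + 1) * p_(j))`, and return the
#' adjusted values in the original order.  Implemented via
#' [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs are propagated).
#' @return Adjusted p-values, same order as the input.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))  # 0.03, 0.06, 0.06
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "holm")
}

#' Odds ratio for a system level under a given child vignette
#'
#' Exponentiated mean utility contrast for a non-baseline system level.
#' With `versus = "baseline_level"` (default) the contrast is against the
#' baseline level of the same attribute shown to the same vignette:
#' `exp(constant + sum of matching interaction means)`.  With
#' `versus = "baseline_vignette"` it is the interaction-only ratio — how
#' much the odds for that level change relative to choosing for the
#' all-baseline vignette: `exp(sum of matching interaction means)`.
#'
#' @param object A `mixl_fit` or `mixl_parameters`.
#' @param level A system dummy name, `"attribute.level"` (non-baseline).
#' @param vignette A one-row vignette data frame (see [child_vignette()]);
#'   defaults to the baseline vignette.
#' @param versus Contrast type, see above.
#' @param scheme Scheme; taken from the fit when available.
#' @return A scalar odds ratio.
#' @export
#' @examples
#' p <- reference_parameters()
#' odds_ratio(p, "size_of_vocabulary.over_1000")             # 0.395
#' odds_ratio(p, "vocabulary_organisation.taxonomic",
#'            child_vignette(aac_scheme(),
#'                           determination = "motivated_via_symbols"),
#'            versus = "baseline_vignette")                  # 2.03
odds_ratio <- function(object, level, vignette = NULL,
                       versus = c("baseline_level", "baseline_vignette"),
                       scheme = NULL) {
  versus <- match.arg(versus)
  if (is.null(scheme)) scheme <- object$scheme
  if (is.null(scheme)) scheme <- aac_scheme()
  mm <- mean_matrix(object, scheme)
  if (!level %in% rownames(mm))
    stop("'", level, "' is not a non-baseline system dummy", call. = FALSE)
  if (is.null(vignette)) vignette <- baseline_vignette(scheme)
  z <- drop(dummy_code(vignette, scheme, "child"))
  gam <- mm[level, ]
  contrib <- sum(gam[-1] * z)
  if (versus == "baseline_level") contrib <- contrib + gam[1]
  unname(exp(contrib))
}

# mean coefficient matrix (system dummy x (constant, child dummies)) from a
# fit or a parameter object
mean_matrix <- function(object, scheme) {
  if (inherits(object, "mixl_parameters")) return(object$mean)
  if (!inherits(object, "mixl_fit"))
    stop("expected a mixl_fit or mixl_parameters object", call. = FALSE)
  spec <- object$spec
  sys <- spec$system_dummies
  kid <- c("(constant)", spec$child_dummies)
  out <- matrix(0, length(sys), length(kid), dimnames = list(sys, kid))
  cells <- spec_cells(spec, "mean")
  for (i in seq_len(nrow(cells)))
    out[cells$sys[i], cells$child[i]] <- object$coefficients[cells$label[i]]
  out
}

#' @export
print.mixl_fit <- function(x, ...) {
  cat("Mixed logit fit (", x$method, ")\n", sep = "")
  cat(sprintf("  %d respondents, %d tasks, %d parameters",
              x$n_respondents, x$n_tasks, x$k))
  if (x$n_draws > 0) cat(sprintf(", %d draws (seed %s)", x$n_draws,
                                 format(x$seed)))
  cat("\n")
  cat(sprintf("  log-likelihood %.4f, BIC %.2f, %s\n", x$loglik, x$bic,
              if (x$converged) "converged" else "NOT CONVERGED"))
  invisible(x)
}

#' @export
coef.mixl_fit <- function(object, ...) object$coefficients

#' @export
vcov.mixl_fit <- function(object, ...) object$vcov

#' @export
logLik.mixl_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, class = "logLik")
}

#' @export
summary.mixl_fit <- function(object, ...) {
  d <- data.frame(term = names(object$coefficients),
                  estimate = unname(object$coefficients),
                  se = unname(object$se),
                  t = unname(object$tstat),
                  p = unname(object$p),
                  p_holm = unname(object$p_holm),
                  row.names = NULL)
  sd_rows <- startsWith(d$term, "sd.")
  d$estimate[sd_rows] <- abs(d$estimate[sd_rows])  # report |sigma|
  d
}
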