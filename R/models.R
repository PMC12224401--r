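#' Standardize columns to z-scores
#'
#' Centers and scales the named columns to mean 0, SD 1 (sample SD,
#' n - 1 denominator) within the supplied data, storing the transform
#' parameters so estimates can be mapped back to the raw scale.
#'
#' @param data data.frame.
#' @param columns character vector of numeric column names.
#' @return \code{data} with the columns replaced by z-scores and
#'   attributes \code{standardize_center} and \code{standardize_scale}
#'   (named vectors).
#' @export
standardize <- function(data, columns) {
  ctr <- numeric(0); scl <- numeric(0)
  for (cl in columns) {
    v <- data[[cl]]
    if (is.null(v)) stop("no such column: ", cl)
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) stop("column '", cl, "' is constant; cannot standardize")
    m <- mean(v)
    data[[cl]] <- (v - m) / s
    ctr[cl] <- m; scl[cl] <- s
  }
  attr(data, "standardize_center") <- ctr
  attr(data, "standardize_scale") <- scl
  data
}

#' Specification of a random-intercept logistic model
#'
#' @param exposure name of the (density) exposure column; z-scored
#'   before fitting.
#' @param covariates any of \code{"age"}, \code{"gender"},
#'   \code{"education"}, \code{"popdens"}, \code{"sei"}. The progressive
#'   strategy uses none (model 1), the three person-level confounders
#'   (model 2), and those plus the two area-level ones (model 3).
#' @param group grouping column (neighbourhood id).
#' @param outcome binary outcome column.
#' @param quadrature_nodes adaptive Gauss-Hermite node count (1 =
#'   Laplace approximation).
#' @param max_iter,tolerance quasi-Newton iteration cap and relative
#'   convergence tolerance.
#' @param fix_sigma_u optional non-negative value at which to fix the
#'   random-intercept SD instead of estimating it; 0 collapses the
#'   model to ordinary logistic regression exactly.
#' @return list of class \code{model_spec}.
#' @export
model_spec <- function(exposure, covariates = character(0),
                       group = "neighbourhood_id", outcome = "non_daily",
                       quadrature_nodes = 15, max_iter = 500,
                       tolerance = 1e-10, fix_sigma_u = NULL) {
  if (quadrature_nodes < 1) stop("quadrature_nodes must be >= 1")
  if (!is.null(fix_sigma_u) && fix_sigma_u < 0)
    stop("fix_sigma_u must be >= 0")
  structure(list(exposure = exposure, covariates = covariates,
                 group = group, outcome = outcome,
                 quadrature_nodes = as.integer(quadrature_nodes),
                 max_iter = max_iter, tolerance = tolerance,
                 fix_sigma_u = fix_sigma_u),
            class = "model_spec")
}

.log1pexp <- function(x) {
  out <- x
  lo <- x < 33
  out[lo] <- log1p(exp(x[lo]))
  out
}

# groupwise Bernoulli-logit log-likelihood at offset eta0 + u[group]
.group_loglik <- function(u, eta0, y, gi, ng) {
  eta <- eta0 + u[gi]
  as.numeric(rowsum(y * eta - .log1pexp(eta), gi, reorder = FALSE))
}

# conditional modes of the random effects: Newton on the strictly
# concave per-group objective loglik_j(u) - u^2/(2 sig2)
.cond_modes <- function(eta0, y, gi, ng, sig2, iter = 50, tol = 1e-11) {
  u <- numeric(ng)
  for (it in seq_len(iter)) {
    p <- stats::plogis(eta0 + u[gi])
    grad <- as.numeric(rowsum(y - p, gi, reorder = FALSE)) - u / sig2
    hess <- -as.numeric(rowsum(p * (1 - p), gi, reorder = FALSE)) - 1 / sig2
    step <- grad / hess
    u <- u - step
    if (max(abs(grad)) < tol) break
  }
  p <- stats::plogis(eta0 + u[gi])
  curv <- as.numeric(rowsum(p * (1 - p), gi, reorder = FALSE)) + 1 / sig2
  list(u = u, tau = 1 / sqrt(curv))
}

#' Marginal log-likelihood of the random-intercept logistic model
#'
#' For each group the Bernoulli-logit likelihood is integrated over the
#' Normal(0, sigma_u^2) random intercept by adaptive Gauss-Hermite
#' quadrature: nodes are centred at the group's conditional mode and
#' scaled by the curvature there, so few nodes suffice. One node is the
#' Laplace approximation.
#'
#' @param beta fixed-effect vector (conformable with \code{X}).
#' @param sigma_u random-intercept SD, >= 0 (0 collapses to the
#'   ordinary logistic likelihood).
#' @param y 0/1 outcome vector.
#' @param X design matrix (including intercept column).
#' @param group group id vector (factor or character).
#' @param nodes quadrature node count.
#' @return total marginal log-likelihood (scalar).
#' @export
marginal_loglik <- function(beta, sigma_u, y, X, group, nodes = 15) {
  gi <- as.integer(factor(group, levels = unique(group)))
  ng <- max(gi)
  eta0 <- as.numeric(X %*% beta)
  if (sigma_u <= 0)
    return(sum(y * eta0 - .log1pexp(eta0)))
  sig2 <- sigma_u^2
  gh <- pracma::gaussHermite(nodes)
  cm <- .cond_modes(eta0, y, gi, ng, sig2)
  # log integrand at node k, group j (log-normal-density part included)
  lse <- matrix(NA_real_, ng, nodes)
  const <- -0.5 * log(2 * pi) - log(sigma_u)
  for (k in seq_len(nodes)) {
    uk <- cm$u + sqrt(2) * cm$tau * gh$x[k]
    lse[, k] <- log(gh$w[k]) + gh$x[k]^2 +
      .group_loglik(uk, eta0, y, gi, ng) - uk^2 / (2 * sig2) + const
  }
  mx <- apply(lse, 1, max)
  sum(log(sqrt(2) * cm$tau) + mx + log(rowSums(exp(lse - mx))))
}

#' Fit a two-level random-intercept logistic regression
#'
#' Maximizes the adaptive Gauss-Hermite marginal likelihood by BFGS,
#' with the random-intercept SD parameterized on the log scale for
#' unconstrained optimization. Fixed effects are initialized from an
#' ordinary logistic fit and log sigma_u at log(0.5); the whole fit is
#' deterministic. Standard errors are Wald, from the numerically
#' differentiated Hessian at the optimum; odds ratios use
#' exp(coef +/- 1.96 SE).
#'
#' @param data analytic data.frame (participants joined with
#'   neighbourhood metrics); must contain the spec's exposure,
#'   covariate, group and outcome columns with no missing values.
#' @param spec a \code{\link{model_spec}}.
#' @return object of class \code{ri_logistic_fit}: list with
#'   \code{coefficients}, \code{se}, \code{sigma_u}, \code{loglik},
#'   \code{aic}, \code{or_table}, \code{converged}, \code{boundary},
#'   \code{n_obs}, \code{n_groups}, \code{spec}.
#' @export
fit_ri_logistic <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  mm <- .build_design(data, spec)
  y <- mm$y; X <- mm$X; group <- mm$group
  if (length(unique(group)) < 2) stop("need >= 2 groups")
  if (!all(y %in% c(0, 1))) stop("outcome must be binary")
  nodes <- spec$quadrature_nodes

  glm0 <- stats::glm.fit(X, y, family = stats::binomial())
  p <- ncol(X)
  fixed_sig <- spec$fix_sigma_u
  if (is.null(fixed_sig)) {
    par0 <- c(glm0$coefficients, log_sigma_u = log(0.5))
    nll <- function(par) {
      ll <- marginal_loglik(par[seq_len(p)], exp(par[p + 1]), y, X, group, nodes)
      if (!is.finite(ll)) return(1e10)
      -ll
    }
  } else {
    par0 <- glm0$coefficients
    nll <- function(par) {
      ll <- marginal_loglik(par, fixed_sig, y, X, group, nodes)
      if (!is.finite(ll)) return(1e10)
      -ll
    }
  }
  opt <- stats::optim(par0, nll, method = "BFGS",
                      control = list(maxit = spec$max_iter,
                                     reltol = spec$tolerance))
  npar <- length(par0)
  H <- stats::optimHess(opt$par, nll)
  se_all <- rep(NA_real_, npar)
  cv <- tryCatch(solve(H), error = function(e) NULL)
  if (!is.null(cv)) {
    d <- diag(cv)
    se_all[d > 0] <- sqrt(d[d > 0])
  }
  coefs <- opt$par[seq_len(p)]
  names(coefs) <- colnames(X)
  se <- se_all[seq_len(p)]
  names(se) <- colnames(X)
  sigma_u <- if (is.null(fixed_sig)) exp(opt$par[p + 1]) else fixed_sig
  loglik <- -opt$value
  # estimated parameters: fixed effects (incl. intercept) + variance
  # parameter when the latter is estimated
  k <- p + as.integer(is.null(fixed_sig))
  aic <- 2 * k - 2 * loglik
  or <- data.frame(term = names(coefs), or = exp(coefs),
                   ci_lo = exp(coefs - 1.96 * se),
                   ci_hi = exp(coefs + 1.96 * se),
                   stringsAsFactors = FALSE)
  rownames(or) <- NULL
  structure(list(coefficients = coefs, se = se, sigma_u = unname(sigma_u),
                 se_log_sigma_u = if (is.null(fixed_sig)) se_all[p + 1] else NA_real_,
                 loglik = loglik, aic = aic, k = k, or_table = or,
                 converged = opt$convergence == 0,
                 boundary = sigma_u < 1e-3,
                 n_obs = length(y), n_groups = length(unique(group)),
                 outcome_sum = sum(y), spec = spec),
            class = "ri_logistic_fit")
}

#' @export
print.ri_logistic_fit <- function(x, ...) {
  cat("Random-intercept logistic fit (AGHQ, ",
      x$spec$quadrature_nodes, " nodes)\n", sep = "")
  cat(sprintf("  n = %d in %d neighbourhoods; logLik = %.3f; AIC = %.2f\n",
              x$n_obs, x$n_groups, x$loglik, x$aic))
  cat(sprintf("  sigma_u = %.4f%s%s\n", x$sigma_u,
              if (x$boundary) " (boundary)" else "",
              if (!x$converged) " [NOT CONVERGED]" else ""))
  tab <- x$or_table
  tab$or <- sprintf("%.3f", tab$or)
  tab$ci <- sprintf("(%.3f, %.3f)", x$or_table$ci_lo, x$or_table$ci_hi)
  print(tab[, c("term", "or", "ci")], row.names = FALSE)
  invisible(x)
}

# design matrix for the progressive covariate sets; continuous
# variables (exposure, age, popdens, sei) are z-scored in-sample,
# gender enters as male vs female, education as the binary
# below-secondary recode
.build_design <- function(data, spec) {
  need <- c(spec$exposure, spec$group, spec$outcome)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("data missing column(s): ", paste(miss, collapse = ", "))
  cols <- list()
  zcols <- spec$exposure
  if ("age" %in% spec$covariates) zcols <- c(zcols, "age")
  if ("popdens" %in% spec$covariates) zcols <- c(zcols, "popdens")
  if ("sei" %in% spec$covariates) zcols <- c(zcols, "sei")
  dz <- standardize(data, zcols)
  X <- cbind("(Intercept)" = rep(1, nrow(data)))
  X <- cbind(X, stats::setNames(dz[zcols], zcols))
  if ("gender" %in% spec$covariates)
    X <- cbind(X, male = as.integer(data$gender == "male"))
  if ("education" %in% spec$covariates) {
    el <- if (!is.null(data$education_low)) data$education_low else
      data$education %in% c("<primary", "primary")
    X <- cbind(X, education_low = as.integer(el))
  }
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(data[[spec$outcome]]))
    stop("missing values in model columns; complete cases required")
  list(y = as.integer(data[[spec$outcome]]), X = X,
       group = as.character(data[[spec$group]]))
}

#' Progressive model sequence for one exposure
#'
#' Fits the three-model adjustment sequence on the identical analytic
#' sample: model 1 unadjusted (exposure only), model 2 adds the
#' person-level confounders (age, gender, education), model 3 adds the
#' area-level ones (population density, social environment index).
#'
#' @param data merged analytic data.frame.
#' @param exposure density column name.
#' @param quadrature_nodes passed to \code{\link{model_spec}}.
#' @return named list of three \code{ri_logistic_fit} objects
#'   (\code{model1}, \code{model2}, \code{model3}); a non-convergent
#'   member is kept, flagged by its \code{converged} field.
#' @export
progressive_fit <- function(data, exposure, quadrature_nodes = 15) {
  covs <- list(model1 = character(0),
               model2 = c("age", "gender", "education"),
               model3 = c("age", "gender", "education", "popdens", "sei"))
  lapply(covs, function(cv)
    fit_ri_logistic(data, model_spec(exposure, cv,
                                     quadrature_nodes = quadrature_nodes)))
}

#' Odds-ratio table across exposures and models
#'
#' One row per exposure density, one OR (95% CI) column per model in
#' the progressive sequence — the layout of a multilevel
#' food-environment association table.
#'
#' @param data merged analytic data.frame.
#' @param exposures character vector of density columns; default is the
#'   total plus all eight category densities.
#' @param quadrature_nodes node count.
#' @return list with \code{table} (data.frame: exposure, then
#'   or/ci_lo/ci_hi/converged per model) and \code{fits} (nested list).
#' @export
fit_all_exposures <- function(data,
                              exposures = c("density_total",
                                            paste0("density_", food_categories())),
                              quadrature_nodes = 15) {
  fits <- lapply(exposures, function(ex)
    progressive_fit(data, ex, quadrature_nodes))
  names(fits) <- exposures
  rows <- lapply(exposures, function(ex) {
    r <- data.frame(exposure = ex, stringsAsFactors = FALSE)
    for (m in names(fits[[ex]])) {
      f <- fits[[ex]][[m]]
      i <- match(ex, f$or_table$term)
      r[[paste0(m, "_or")]] <- f$or_table$or[i]
      r[[paste0(m, "_ci_lo")]] <- f$or_table$ci_lo[i]
      r[[paste0(m, "_ci_hi")]] <- f$or_table$ci_hi[i]
      r[[paste0(m, "_converged")]] <- f$converged
    }
    r
  })
  list(table = do.call(rbind, rows), fits = fits)
}

#' AIC comparison of fits on the same sample
#'
#' @param fits list of \code{ri_logistic_fit} objects fitted to the
#'   identical analytic sample.
#' @return data.frame ranked by AIC with \code{delta_aic} vs the best.
#' @export
compare_aic <- function(fits) {
  if (!length(fits)) stop("no fits supplied")
  n <- vapply(fits, function(f) f$n_obs, numeric(1))
  s <- vapply(fits, function(f) f$outcome_sum, numeric(1))
  if (length(unique(n)) > 1 || length(unique(s)) > 1)
    stop("fits are not on the identical sample; AIC comparison invalid")
  nm <- names(fits)
  if (is.null(nm)) nm <- paste0("fit", seq_along(fits))
  tab <- data.frame(model = nm,
                    k = vapply(fits, function(f) f$k, numeric(1)),
                    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
                    aic = vapply(fits, function(f) f$aic, numeric(1)),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$aic), ]
  tab$delta_aic <- tab$aic - tab$aic[1]
  rownames(tab) <- NULL
  tab
}
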