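# Statistical machinery ----------------------------------------------------
#
# Pearson chi-square, Welch's t, and a maximum-likelihood proportional-odds
# (cumulative-logit) regression of the error score, all implemented from the
# defining formulas. The ordinal fitter uses damped Newton-Raphson on a
# monotone reparameterization of the cutpoints, with the observed-information
# covariance at the maximum.

#' Pearson chi-square test of independence
#'
#' Expected counts from the margins, statistic \eqn{\sum (O-E)^2/E},
#' \eqn{(r-1)(c-1)} degrees of freedom, upper-tail p-value. No continuity
#' correction.
#'
#' @param table an r x c matrix (or table) of non-negative counts with
#'   strictly positive row and column sums.
#' @return an object of class `htest`.
#' @export
chi_square_test <- function(table) {
  O <- as.matrix(table)
  if (any(O < 0) || any(!is.finite(O))) stop("counts must be non-negative")
  rs <- rowSums(O); cs <- colSums(O)
  if (any(rs == 0) || any(cs == 0)) {
    stop("zero row/column margin; collapse categories before testing")
  }
  E <- outer(rs, cs) / sum(O)
  stat <- sum((O - E)^2 / E)
  df <- (nrow(O) - 1L) * (ncol(O) - 1L)
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = c("X-squared" = stat),
                 parameter = c(df = df), p.value = p,
                 method = "Pearson chi-square test of independence",
                 data.name = deparse(substitute(table)),
                 expected = E),
            class = "htest")
}

#' Welch's two-sample t-test
#'
#' Unequal-variance statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2 with nonzero
#'   variance.
#' @return an object of class `htest`.
#' @export
welch_t_test <- function(group_a, group_b) {
  a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 values")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) stop("both groups are degenerate (zero variance)")
  se2a <- va / length(a); se2b <- vb / length(b)
  stat <- (mean(a) - mean(b)) / sqrt(se2a + se2b)
  df <- (se2a + se2b)^2 /
    (se2a^2 / (length(a) - 1L) + se2b^2 / (length(b) - 1L))
  p <- 2 * stats::pt(-abs(stat), df)
  structure(list(statistic = c(t = stat), parameter = c(df = df),
                 p.value = p,
                 estimate = c("mean of a" = mean(a), "mean of b" = mean(b)),
                 method = "Welch two-sample t-test",
                 data.name = "group_a vs group_b"),
            class = "htest")
}

# Design specification ------------------------------------------------------

DEFAULT_REFERENCES <- list(
  arm = "pre_intervention",
  sex = "male",
  gbd_group = "ill_defined",
  seniority_years = "0-5",
  speciality = "general_medicine",
  facility_level = "I"
)

#' Design specification for the error-score regression
#'
#' Declares the covariates entering the ordinal regression of the error
#' score and the reference level of each categorical covariate. The defaults
#' mirror the published model: study arm (reference pre-intervention), age
#' in years as a continuous per-year covariate, sex (reference male), GBD
#' cause group (reference ill-defined), certifier seniority band (reference
#' 0-5 years), speciality (reference general medicine) and facility level
#' (reference I).
#'
#' @param covariates character vector of covariate names; `"age_years"` is
#'   continuous, all others are categorical certificate attributes.
#' @param references named list mapping each categorical covariate to its
#'   reference level; unnamed covariates keep the default reference.
#' @return an object of class `design_spec`.
#' @export
score_design <- function(covariates = c("arm", "age_years", "sex",
                                        "gbd_group", "seniority_years",
                                        "speciality", "facility_level"),
                         references = list()) {
  refs <- DEFAULT_REFERENCES
  for (nm in names(references)) refs[[nm]] <- references[[nm]]
  structure(list(covariates = covariates, references = refs),
            class = "design_spec")
}

# Build the (no-intercept) design matrix with reference-cell coding.
build_design_matrix <- function(data, design) {
  cols <- list()
  term_info <- list()
  for (cov in design$covariates) {
    if (cov == "age_years" && !"age_years" %in% names(data)) {
      data$age_years <- age_in_years(data$age_value, data$age_unit)
    }
    if (!cov %in% names(data)) stop("covariate not found in data: ", cov)
    if (is.numeric(data[[cov]])) { # continuous covariate, one column
      cols[[cov]] <- data[[cov]]
      term_info[[length(term_info) + 1L]] <- data.frame(
        term = cov, covariate = cov, level = "", continuous = TRUE,
        stringsAsFactors = FALSE)
      next
    }
    ref <- design$references[[cov]]
    lev <- unique(as.character(data[[cov]]))
    if (is.null(ref) || !ref %in% lev) {
      stop("reference level for '", cov, "' not present in the data: ",
           ref %||% "<none>")
    }
    ordered_lev <- c(ref, sort(setdiff(lev, ref)))
    f <- factor(as.character(data[[cov]]), levels = ordered_lev)
    for (l in ordered_lev[-1L]) {
      nm <- paste0(cov, ":", l)
      cols[[nm]] <- as.numeric(f == l)
      term_info[[length(term_info) + 1L]] <- data.frame(
        term = nm, covariate = cov, level = l, continuous = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  X <- do.call(cbind, cols)
  info <- do.call(rbind, term_info)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  list(X = X, info = info)
}

# Log-likelihood and analytic gradient of the cumulative-logit model in the
# natural (alpha, beta) parameterization. y is 1..K, alpha has length K-1.
po_loglik <- function(alpha, beta, X, y, K) {
  eta <- if (length(beta)) as.numeric(X %*% beta) else numeric(nrow(X))
  au <- c(alpha, Inf)[y] - eta
  al <- c(-Inf, alpha)[y] - eta
  p <- stats::plogis(au) - stats::plogis(al)
  sum(log(pmax(p, 1e-300)))
}

po_gradient <- function(alpha, beta, X, y, K) {
  n <- length(y)
  eta <- if (length(beta)) as.numeric(X %*% beta) else numeric(n)
  au <- c(alpha, Inf)[y] - eta
  al <- c(-Inf, alpha)[y] - eta
  p <- pmax(stats::plogis(au) - stats::plogis(al), 1e-300)
  fu <- ifelse(is.finite(au), stats::dlogis(au), 0)
  fl <- ifelse(is.finite(al), stats::dlogis(al), 0)
  ga <- numeric(K - 1L)
  ru <- fu / p
  rl <- fl / p
  for (k in seq_len(K - 1L)) {
    ga[k] <- sum(ru[y == k]) - sum(rl[y == k + 1L])
  }
  dldeta <- -(fu - fl) / p
  gb <- if (length(beta)) as.numeric(crossprod(X, dldeta)) else numeric(0)
  c(ga, gb)
}

# phi = (alpha_1, log diff(alpha), beta); keeps cutpoints strictly increasing
phi_to_alpha <- function(phi_cut) {
  if (length(phi_cut) == 1L) return(phi_cut)
  c(phi_cut[1L], phi_cut[1L] + cumsum(exp(phi_cut[-1L])))
}

alpha_to_phi <- function(alpha) {
  if (length(alpha) == 1L) return(alpha)
  c(alpha[1L], log(diff(alpha)))
}

phi_gradient <- function(phi, X, y, K, p_beta) {
  ncut <- K - 1L
  alpha <- phi_to_alpha(phi[seq_len(ncut)])
  beta <- phi[ncut + seq_len(p_beta)]
  g <- po_gradient(alpha, beta, X, y, K)
  ga <- g[seq_len(ncut)]
  gphi_cut <- numeric(ncut)
  gphi_cut[1L] <- sum(ga)
  if (ncut > 1L) {
    for (m in 2:ncut) {
      gphi_cut[m] <- sum(ga[m:ncut]) * exp(phi[m])
    }
  }
  c(gphi_cut, g[ncut + seq_len(p_beta)])
}

# central-difference Hessian of a gradient function
numeric_hessian <- function(grad_fn, x, h = 1e-5) {
  p <- length(x)
  H <- matrix(0, p, p)
  for (i in seq_len(p)) {
    step <- h * max(1, abs(x[i]))
    xp <- x; xp[i] <- xp[i] + step
    xm <- x; xm[i] <- xm[i] - step
    H[, i] <- (grad_fn(xp) - grad_fn(xm)) / (2 * step)
  }
  (H + t(H)) / 2
}

#' Fit a proportional-odds model of the error score
#'
#' Maximum-likelihood cumulative-logit regression
#' \eqn{\mathrm{logit}\,P(Y \le k \mid x) = \alpha_k - x'\beta}, so a
#' positive coefficient (odds ratio above one) means greater odds of a
#' *higher* error score than the reference category. Outcome levels with no
#' observations are collapsed away before fitting; levels with fewer than
#' five observations are retained with a warning. Optimisation is damped
#' Newton-Raphson on a monotone cutpoint transform; convergence is declared
#' when the gradient max-norm falls below `tol`. The covariance is the
#' inverse observed information at the maximum.
#'
#' @param data data.frame holding the outcome column and the design
#'   covariates; typically a certificate batch joined with
#'   [score_profiles()] output.
#' @param design a [score_design()].
#' @param outcome name of the ordinal outcome column (default `"score"`).
#' @param tol gradient max-norm convergence tolerance.
#' @param max_iter Newton iteration cap; if reached, the fit is returned
#'   with `converged = FALSE` and a warning.
#' @return an object of class `ordinal_fit`: cutpoints, coefficients,
#'   covariance, odds ratios with delta-method standard errors and two-sided
#'   Wald p-values, log-likelihood and convergence diagnostics.
#' @export
fit_ordinal_logit <- function(data, design = score_design(),
                              outcome = "score", tol = 1e-8,
                              max_iter = 100L) {
  y_raw <- data[[outcome]]
  if (is.null(y_raw)) stop("outcome column not found: ", outcome)
  levels_obs <- sort(unique(y_raw))
  K <- length(levels_obs)
  if (K < 2L) stop("outcome must have at least two observed levels")
  y <- match(y_raw, levels_obs)
  cnt <- tabulate(y, K)
  if (any(cnt < 5L)) {
    warning("outcome level(s) with fewer than 5 observations retained: ",
            paste(levels_obs[cnt < 5L], collapse = ", "))
  }
  dm <- build_design_matrix(data, design)
  X <- dm$X
  p_beta <- ncol(X)
  # centre columns for optimisation stability; cutpoints are shifted back
  x_centre <- colMeans(X)
  Xc <- sweep(X, 2L, x_centre)

  cum <- cumsum(cnt)[seq_len(K - 1L)] / length(y)
  alpha0 <- stats::qlogis(pmin(pmax(cum, 1e-4), 1 - 1e-4))
  alpha0 <- cummax(alpha0 + seq_len(K - 1L) * 1e-8) # strictly increasing
  phi <- c(alpha_to_phi(alpha0), rep(0, p_beta))

  ll_fn <- function(phi) {
    po_loglik(phi_to_alpha(phi[seq_len(K - 1L)]),
              phi[K - 1L + seq_len(p_beta)], Xc, y, K)
  }
  grad_fn <- function(phi) phi_gradient(phi, Xc, y, K, p_beta)

  ll <- ll_fn(phi)
  ll_trace <- ll
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    g <- grad_fn(phi)
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    H <- numeric_hessian(grad_fn, phi)
    step <- tryCatch(solve(H, -g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      ridge <- diag(ncol(H)) * (max(abs(diag(H))) * 1e-6 + 1e-8)
      step <- solve(H - ridge, -g)
    }
    # damping: halve until the log-likelihood does not decrease
    lambda <- 1
    repeat {
      cand <- phi + lambda * step
      ll_new <- ll_fn(cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) { cand <- phi; ll_new <- ll; break }
    }
    phi <- cand
    ll <- ll_new
    ll_trace <- c(ll_trace, ll)
  }
  if (!converged) {
    g <- grad_fn(phi)
    converged <- max(abs(g)) < tol
  }
  if (!converged) warning("ordinal fit did not converge in ",
                          max_iter, " iterations")

  alpha_c <- phi_to_alpha(phi[seq_len(K - 1L)])
  beta <- phi[K - 1L + seq_len(p_beta)]
  names(beta) <- colnames(X)
  alpha <- alpha_c + sum(x_centre * beta) # uncentred cutpoints

  # observed information in the natural (alpha, beta) parameterization
  grad_nat <- function(theta) {
    po_gradient(theta[seq_len(K - 1L)], theta[K - 1L + seq_len(p_beta)],
                X, y, K)
  }
  H_nat <- numeric_hessian(grad_nat, c(alpha, beta))
  vcov <- tryCatch(solve(-H_nat), error = function(e) {
    warning("observed information is singular; covariance unavailable")
    matrix(NA_real_, length(alpha) + p_beta, length(alpha) + p_beta)
  })
  idx_beta <- K - 1L + seq_len(p_beta)
  se_beta <- sqrt(pmax(diag(vcov)[idx_beta], 0))
  names(se_beta) <- names(beta)
  or <- exp(beta)
  z <- beta / se_beta
  pval <- 2 * stats::pnorm(-abs(z))

  structure(list(
    cutpoints = alpha,
    coefficients = beta,
    se = se_beta,
    vcov = vcov,
    odds_ratios = or,
    or_se = or * se_beta, # delta method; the scale the study tabulates
    z = z,
    p_values = pval,
    log_likelihood = po_loglik(alpha, beta, X, y, K),
    ll_trace = ll_trace,
    converged = converged,
    n_iterations = iter,
    n = length(y),
    outcome_levels = levels_obs,
    term_info = dm$info,
    design = design,
    outcome = outcome
  ), class = "ordinal_fit")
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat("Proportional-odds (cumulative logit) fit of '", x$outcome, "'\n",
      sep = "")
  cat("  n = ", x$n, ", outcome levels = ",
      length(x$outcome_levels), ", log-likelihood = ",
      formatC(x$log_likelihood, format = "f", digits = 3),
      if (!x$converged) "  [NOT CONVERGED]", "\n\n", sep = "")
  print(odds_ratio_table(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Odds-ratio report of an ordinal fit
#'
#' One row per covariate level, with reference rows marked "Ref.". Both the
#' standard error of the odds ratio (delta method; the published scale) and
#' of the log-odds coefficient are reported.
#'
#' @param fit an `ordinal_fit`.
#' @return data.frame with columns `covariate`, `level`, `reference`,
#'   `odds_ratio`, `std_error` (of the OR), `coef`, `coef_se`, `p_value`.
#' @export
odds_ratio_table <- function(fit) {
  stopifnot(inherits(fit, "ordinal_fit"))
  info <- fit$term_info
  rows <- list()
  for (cov in unique(info$covariate)) {
    if (!info$continuous[info$covariate == cov][1L]) {
      ref <- fit$design$references[[cov]]
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = cov, level = ref, reference = TRUE,
        odds_ratio = NA_real_, std_error = NA_real_, coef = NA_real_,
        coef_se = NA_real_, p_value = NA_real_, stringsAsFactors = FALSE)
    }
    sel <- info$covariate == cov
    terms <- info$term[sel]
    rows[[length(rows) + 1L]] <- data.frame(
      covariate = cov, level = info$level[sel], reference = FALSE,
      odds_ratio = unname(fit$odds_ratios[terms]),
      std_error = unname(fit$or_se[terms]),
      coef = unname(fit$coefficients[terms]),
      coef_se = unname(fit$se[terms]),
      p_value = unname(fit$p_values[terms]), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Refit with a different reference category
#'
#' Reparameterizes the model by switching the reference level of one
#' categorical covariate and refitting. The maximized log-likelihood is
#' invariant, and the odds ratio of level b against the new reference a
#' equals OR(b vs old reference) / OR(a vs old reference).
#'
#' @param data,design,outcome as in [fit_ordinal_logit()].
#' @param covariate name of the categorical covariate.
#' @param new_reference the level to use as the new reference (must occur in
#'   the data).
#' @param ... passed to [fit_ordinal_logit()].
#' @return an `ordinal_fit`.
#' @export
refit_with_reference <- function(data, design = score_design(), covariate,
                                 new_reference, outcome = "score", ...) {
  if (!new_reference %in% unique(as.character(data[[covariate]]))) {
    stop("new reference level '", new_reference,
         "' not present in the data for '", covariate, "'")
  }
  refs <- design$references
  refs[[covariate]] <- new_reference
  design$references <- refs
  fit_ordinal_logit(data, design, outcome = outcome, ...)
}

#' Simulate ordinal outcomes from a proportional-odds model
#'
#' Draws one ordinal response per linear-predictor value under
#' \eqn{\mathrm{logit}\,P(Y \le k) = \alpha_k - \eta}.
#'
#' @param eta numeric vector of linear predictors.
#' @param cutpoints strictly increasing cutpoints (K-1 values for K levels).
#' @param levels values to return (default `seq_len(K)`).
#' @return vector of sampled outcome levels, same length as `eta`.
#' @export
simulate_proportional_odds <- function(eta, cutpoints,
                                       levels = seq_len(length(cutpoints) + 1L)) {
  if (is.unsorted(cutpoints, strictly = TRUE)) {
    stop("cutpoints must be strictly increasing")
  }
  cum <- stats::plogis(outer(eta, cutpoints, function(e, a) a - e))
  u <- stats::runif(length(eta))
  idx <- rowSums(u > cum) + 1L
  levels[idx]
}
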