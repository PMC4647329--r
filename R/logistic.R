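# Multivariable logistic regression over screened factors, odds-ratio
# reporting, and backward elimination down to the retained predictors.

#' Fit a multivariable logistic regression
#'
#' Maximum-likelihood logistic regression of a binary outcome (coded
#' 1 = poor recovery, so positive coefficients mark risk factors for poor
#' outcome) on a design of category-coded predictors, fitted by iteratively
#' reweighted least squares via [stats::glm()].  Reports coefficients,
#' standard errors from the inverse observed information, odds ratios
#' `exp(beta)` with 95\% Wald intervals `exp(beta +/- 1.96 se)`, and
#' two-sided Wald p-values.
#'
#' @param design Numeric matrix or data frame of predictors (no intercept
#'   column; one is added).
#' @param outcome Binary vector (0/1 or logical), 1 = poor recovery.
#' @param max_iter Maximum IRLS iterations.
#' @param tol Convergence tolerance on the relative deviance change.
#' @return Object of class `logistic_fit` with `terms`, `beta`, `se`,
#'   `or_`, `ci95` (2-column matrix), `p`, `loglik`, `converged`, `n_iter`,
#'   `n`.
#' @export
fit_logistic <- function(design, outcome, max_iter = 50, tol = 1e-10) {
  X <- as.matrix(as.data.frame(design))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.integer(as_binary_labels(outcome))
  n <- length(y)
  if (nrow(X) != n) stop("design and outcome lengths differ", call. = FALSE)
  if (n <= ncol(X) + 1) stop("need more observations than terms",
                             call. = FALSE)
  Xi <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(Xi)
  if (qrX$rank < ncol(Xi)) {
    dropped <- colnames(Xi)[qrX$pivot[(qrX$rank + 1):ncol(Xi)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  df <- data.frame(.y = y, X, check.names = FALSE)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = tol,
                                            maxit = max_iter)))
  beta <- stats::coef(fit)
  if (any(abs(beta) > 15)) {
    stop("perfect separation detected: diverging coefficient(s) ",
         paste(names(beta)[abs(beta) > 15], collapse = ", "), call. = FALSE)
  }
  se <- sqrt(diag(stats::vcov(fit)))
  z <- beta / se
  structure(list(
    terms = names(beta),
    beta = unname(beta), se = unname(se),
    or_ = unname(exp(beta)),
    ci95 = cbind(low = unname(exp(beta - 1.96 * se)),
                 high = unname(exp(beta + 1.96 * se))),
    p = unname(2 * stats::pnorm(-abs(z))),
    loglik = as.numeric(stats::logLik(fit)),
    converged = fit$converged, n_iter = fit$iter, n = n),
    class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit: n = %d, log-likelihood = %.3f (%sconverged, %d iterations)\n",
              x$n, x$loglik, if (x$converged) "" else "NOT ", x$n_iter))
  tab <- data.frame(term = x$terms,
                    coef = sprintf("%.2f (%.2f)", x$beta, x$se),
                    OR = sprintf("%.2f (%.2f-%.2f)", x$or_,
                                 x$ci95[, "low"], x$ci95[, "high"]),
                    p = format.pval(x$p, digits = 3))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Odds ratio and 95% Wald confidence interval from a coefficient
#'
#' @param beta_j Log-odds coefficient.
#' @param se_j Positive standard error.
#' @return List with `or`, `ci_low`, `ci_high` (`exp(beta +/- 1.96 se)`).
#' @examples
#' odds_ratio(1.20, 0.34)  # OR 3.32
#' @export
odds_ratio <- function(beta_j, se_j) {
  if (any(se_j <= 0)) stop("se must be positive", call. = FALSE)
  list(or = exp(beta_j),
       ci_low = exp(beta_j - 1.96 * se_j),
       ci_high = exp(beta_j + 1.96 * se_j))
}

#' Build the category-coded design matrix for the multivariable model
#'
#' Maps screened factor names to numeric columns: binary factors to 0/1,
#' change factors to the ordinal disappear/keep/appear = 0/1/2 coding (a
#' single column each, matching a one-coefficient-per-change-variable
#' model), and continuous factors to their tree-derived category code when
#' a discretization is supplied (raw values otherwise).
#'
#' @param cohort A [cohort_table()].
#' @param factors Character vector of factor names as produced by
#'   [screen_candidates()]: `age`, `onset_hours`, `nihss_d1`,
#'   `delta_nihss`, `sex`, `hx_*`, `<symptom>_day1`, `<symptom>_change`.
#' @param discretizations Named list of [grow_thresholds()] results (or
#'   threshold vectors) keyed by continuous factor name.
#' @return Numeric matrix with one column per factor.
#' @export
build_design <- function(cohort, factors, discretizations = list()) {
  cols <- lapply(factors, function(f) {
    # accept the scale-item spellings of the same factors
    f <- sub("^history_", "hx_", f)
    if (grepl("_degree$", f)) {
      f <- sub("_degree$", "", f)
      if (f == "nihss_day1") f <- "nihss_d1"
    }
    if (f %in% c("age", "onset_hours", "nihss_d1", "delta_nihss")) {
      value <- if (f == "delta_nihss") {
        derive_delta_nihss(cohort$nihss_d1, cohort$nihss_d3)
      } else {
        cohort[[f]]
      }
      if (f %in% names(discretizations)) {
        bin_variable(value, discretizations[[f]])
      } else {
        value
      }
    } else if (f == "sex") {
      as.integer(cohort$sex == "male")
    } else if (f %in% paste0("hx_", HISTORY_FLAGS)) {
      cohort[[f]]
    } else if (grepl("_day1$", f)) {
      cohort[[paste0("sym_", sub("_day1$", "", f), "_d1")]]
    } else if (grepl("_change$", f)) {
      s <- sub("_change$", "", f)
      change_code(derive_change_status(cohort[[paste0("sym_", s, "_d1")]],
                                       cohort[[paste0("sym_", s, "_d3")]]))
    } else {
      stop("unknown factor: ", f, call. = FALSE)
    }
  })
  mat <- do.call(cbind, cols)
  colnames(mat) <- factors
  mat
}

#' Backward elimination of screened factors by Wald p-value
#'
#' Fits the multivariable logistic model on all candidates, then repeatedly
#' drops the term with the largest Wald p-value at or above `alpha` and
#' refits, until every retained term has `p < alpha` (or no terms remain).
#' The alternative strategy `"none"` keeps the full model.
#'
#' @param cohort A [cohort_table()].
#' @param candidates Character vector of factor names (see
#'   [build_design()]), or a [screen_candidates()] result, in which case the
#'   `selected` factors are used.
#' @param alpha Retention threshold on the Wald p-value.
#' @param discretizations Passed to [build_design()].
#' @param strategy `"backward"` (default) or `"none"`.
#' @return List with `fit` (the final [fit_logistic()]), `retained`
#'   (factor names), and `audit` (data frame of elimination steps).
#' @export
select_factors <- function(cohort, candidates, alpha = 0.05,
                           discretizations = list(),
                           strategy = c("backward", "none")) {
  strategy <- match.arg(strategy)
  if (is.data.frame(candidates)) {
    candidates <- candidates$factor[candidates$selected]
  }
  if (!length(candidates)) stop("empty model: no candidate factors",
                                call. = FALSE)
  outcome <- as.integer(derive_outcome(cohort$bi_d90) == "poor")
  current <- candidates
  audit <- data.frame(step = integer(), dropped = character(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  step <- 0
  repeat {
    X <- build_design(cohort, current, discretizations)
    fit <- fit_logistic(X, outcome)
    if (strategy == "none") break
    p_terms <- fit$p[-1]  # exclude intercept
    worst <- which.max(p_terms)
    if (p_terms[worst] < alpha) break
    step <- step + 1
    audit <- rbind(audit, data.frame(step = step, dropped = current[worst],
                                     p_value = p_terms[worst],
                                     stringsAsFactors = FALSE))
    current <- current[-worst]
    if (!length(current)) {
      return(list(fit = NULL, retained = character(), audit = audit))
    }
  }
  list(fit = fit, retained = current, audit = audit)
}
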