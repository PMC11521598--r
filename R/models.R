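#' Centre and scale continuous predictors
#'
#' z-scores the named columns (sample mean 0, sample SD 1), which makes
#' regression coefficients comparable and interpretable in models with
#' interaction terms. Categorical columns are left untouched (they are
#' treatment-coded by the model-fitting machinery).
#'
#' @param table A data frame.
#' @param columns Character vector of numeric columns to standardize.
#' @return The table with standardized columns.
#' @export
standardize_predictors <- function(table, columns) {
  for (col in columns) {
    if (!col %in% names(table)) stop("no column called `", col, "`")
    x <- table[[col]]
    if (!is.numeric(x)) stop("column `", col, "` is not numeric")
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      stop("column `", col, "` has zero variance and cannot be standardized")
    }
    table[[col]] <- (x - mean(x)) / s
  }
  table
}

#' Specify a linear mixed-effects model
#'
#' A declarative model specification: response, fixed-effect terms
#' (including `a:b` interactions), random intercepts (one grouping factor
#' each), random slopes, and the estimation criterion. Interactions listed
#' in `fixed` should have their main effects listed too (marginality).
#'
#' @param response Response column name.
#' @param fixed Character vector of fixed-effect terms.
#' @param random_intercepts Character vector of grouping-factor columns,
#'   each contributing a `(1 | g)` term (e.g. dyads crossed with video
#'   valence and video index are three crossed intercept terms).
#' @param random_slopes Named list: names are grouping factors, values are
#'   character vectors of slope terms, contributing `(0 + term | g)`.
#' @param estimation `"REML"` (default, for reporting) or `"ML"` (for
#'   comparing models with different fixed effects).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(response, fixed = character(),
                       random_intercepts = character(),
                       random_slopes = list(),
                       estimation = c("REML", "ML")) {
  estimation <- match.arg(estimation)
  structure(
    list(response = response, fixed = fixed,
         random_intercepts = random_intercepts,
         random_slopes = random_slopes, estimation = estimation),
    class = "model_spec"
  )
}

#' Read a model specification from YAML
#'
#' The declarative grammar mirrors [model_spec()]: keys `response`,
#' `fixed`, `random_intercepts`, `random_slopes` (a mapping from grouping
#' factor to slope terms), and `estimation`.
#'
#' @param path YAML file.
#' @return A `model_spec`.
#' @export
read_model_spec <- function(path) {
  y <- yaml::read_yaml(path)
  ok <- names(formals(model_spec))
  bad <- setdiff(names(y), ok)
  if (length(bad)) stop("unknown model spec keys: ", paste(bad, collapse = ", "))
  if (is.null(y$response)) stop("model spec must name a `response`")
  do.call(model_spec, y)
}

# Model formula from a spec.
spec_formula <- function(spec) {
  rhs <- if (length(spec$fixed)) paste(spec$fixed, collapse = " + ") else "1"
  for (g in spec$random_intercepts) {
    rhs <- paste0(rhs, " + (1 | ", g, ")")
  }
  for (g in names(spec$random_slopes)) {
    for (term in spec$random_slopes[[g]]) {
      rhs <- paste0(rhs, " + (0 + ", term, " | ", g, ")")
    }
  }
  stats::as.formula(paste(spec$response, "~", rhs))
}

has_random <- function(spec) {
  length(spec$random_intercepts) > 0 || length(spec$random_slopes) > 0
}

# Columns a spec touches (for complete-case filtering).
spec_columns <- function(spec) {
  vars <- unique(unlist(strsplit(spec$fixed, ":", fixed = TRUE)))
  unique(c(spec$response, vars, spec$random_intercepts,
           names(spec$random_slopes),
           unlist(spec$random_slopes, use.names = FALSE)))
}

#' Fit a linear (mixed-effects) model from a specification
#'
#' Fits with `lmerTest::lmer` (Satterthwaite coefficient tests) when the
#' specification has random terms, otherwise with `lm`. With zero random
#' variance the fixed effects coincide with ordinary least squares.
#' Singular or non-converged fits are reported through the `converged` and
#' `singular` flags, never silently.
#'
#' @param spec A [model_spec()].
#' @param table Data frame with the model columns.
#' @return A list of class `model_fit`: `coefficients` (data frame with
#'   estimate, SE, Wald 95% CI, p), `logLik`, `df` (number of model
#'   parameters), `sigma2`, `tau00` (named random-intercept variances),
#'   `icc` (for the single-intercept case), `r2_marginal`,
#'   `r2_conditional`, `converged`, `singular`, `spec`, and the underlying
#'   `fit` object.
#' @export
fit_lmm <- function(spec, table) {
  stopifnot(inherits(spec, "model_spec"))
  f <- spec_formula(spec)
  table <- table[stats::complete.cases(
    table[, intersect(spec_columns(spec), names(table)), drop = FALSE]), ,
    drop = FALSE]
  if (!has_random(spec)) {
    fit <- stats::lm(f, data = table)
    cf <- summary(fit)$coefficients
    ci <- cf[, 2] * stats::qnorm(0.975)
    coefs <- data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                        ci_lower = cf[, 1] - ci, ci_upper = cf[, 1] + ci,
                        p = cf[, 4], row.names = NULL)
    ll <- as.numeric(stats::logLik(fit))
    npar <- attr(stats::logLik(fit), "df")
    var_f <- stats::var(stats::fitted(fit))
    s2 <- summary(fit)$sigma^2
    out <- list(coefficients = coefs, logLik = ll, df = npar, sigma2 = s2,
                tau00 = numeric(0), icc = NA_real_,
                r2_marginal = var_f / (var_f + s2),
                r2_conditional = var_f / (var_f + s2),
                converged = TRUE, singular = FALSE, n_obs = nrow(table),
                spec = spec, fit = fit)
    class(out) <- "model_fit"
    return(out)
  }
  reml <- spec$estimation == "REML"
  converged <- TRUE
  fit <- withCallingHandlers(
    tryCatch(
      lmerTest::lmer(f, data = table, REML = reml,
                     control = lme4::lmerControl(check.conv.singular = "ignore",
                                                 calc.derivs = TRUE)),
      error = function(e) e),
    warning = function(w) {
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) {
        converged <<- FALSE
      }
      invokeRestart("muffleWarning")
    })
  if (inherits(fit, "error")) {
    stop("model failed to fit: ", conditionMessage(fit))
  }
  singular <- lme4::isSingular(fit, tol = 1e-4)
  cf <- stats::coef(summary(fit))
  pcol <- if ("Pr(>|t|)" %in% colnames(cf)) cf[, "Pr(>|t|)"] else {
    2 * stats::pnorm(-abs(cf[, "t value"]))
  }
  ci <- cf[, "Std. Error"] * stats::qnorm(0.975)
  coefs <- data.frame(term = rownames(cf), estimate = cf[, "Estimate"],
                      se = cf[, "Std. Error"],
                      ci_lower = cf[, "Estimate"] - ci,
                      ci_upper = cf[, "Estimate"] + ci,
                      p = pcol, row.names = NULL)
  vc <- lme4::VarCorr(fit)
  s2 <- stats::sigma(fit)^2
  tau <- vapply(vc, function(m) m[1, 1], numeric(1))
  icc <- if (length(tau) == 1L) tau[[1]] / (tau[[1]] + s2) else NA_real_
  # Nakagawa-style variance decomposition
  var_f <- stats::var(as.numeric(lme4::getME(fit, "X") %*% lme4::fixef(fit)))
  var_re <- sum(tau)
  denom <- var_f + var_re + s2
  out <- list(coefficients = coefs,
              logLik = as.numeric(stats::logLik(fit)),
              df = attr(stats::logLik(fit), "df"),
              sigma2 = s2, tau00 = tau, icc = icc,
              r2_marginal = var_f / denom,
              r2_conditional = (var_f + var_re) / denom,
              converged = converged, singular = singular,
              n_obs = stats::nobs(fit), spec = spec, fit = fit)
  class(out) <- "model_fit"
  out
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> %s (%s), logLik %.2f, R2m/R2c %.2f/%.2f%s%s\n",
              deparse(spec_formula(x$spec)), x$spec$estimation, x$logLik,
              x$r2_marginal, x$r2_conditional,
              if (!x$converged) ", NOT CONVERGED" else "",
              if (x$singular) ", singular" else ""))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Likelihood-ratio test between nested maximum-likelihood fits
#'
#' `chisq = 2 * (logLik_full - logLik_nested)` on `df` = difference in
#' parameter count, with the p-value from the upper chi-squared tail.
#' Refuses REML fits, whose log-likelihoods are not comparable across
#' fixed-effect structures.
#'
#' @param fit_nested,fit_full `model_fit` objects fitted by ML, the
#'   nested model's terms a subset of the full model's.
#' @return A list with `chisq`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(fit_nested, fit_full) {
  for (f in list(fit_nested, fit_full)) {
    if (inherits(f, "model_fit") && has_random(f$spec) &&
        f$spec$estimation != "ML") {
      stop("likelihood-ratio tests require ML fits (REML log-likelihoods are not comparable)")
    }
  }
  chisq <- max(0, 2 * (fit_full$logLik - fit_nested$logLik))
  df <- fit_full$df - fit_nested$df
  p <- if (df <= 0) 1 else stats::pchisq(chisq, df = df, lower.tail = FALSE)
  list(chisq = chisq, df = df, p = p)
}

#' Holm's step-down multiple-testing adjustment
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (same order), controlling the family-wise
#'   error rate.
#' @export
holm_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "holm")
}

#' Nonparametric post hoc tests with Holm correction
#'
#' Runs a declared family of pairwise Spearman correlations and two-tailed
#' Wilcoxon-Mann-Whitney group comparisons, reports effect sizes as
#' Pearson's r (from the normal approximation of the test statistic), and
#' adjusts the family's p-values with Holm's method. Ties are handled by
#' midranks.
#'
#' @param table A data frame.
#' @param comparisons A list; each element is a list with `type`
#'   (`"spearman"` or `"mann_whitney"`) plus `x`,`y` column names
#'   (spearman) or `value`,`group` column names (mann_whitney, exactly two
#'   groups).
#' @return A data frame with one row per comparison: `type`, `label`,
#'   `statistic` (rho or U), `p`, `effect_r`, `p_holm`.
#' @export
nonparametric_posthoc <- function(table, comparisons) {
  rows <- lapply(comparisons, function(cmp) {
    if (cmp$type == "spearman") {
      x <- table[[cmp$x]]; y <- table[[cmp$y]]
      ok <- stats::complete.cases(x, y)
      x <- x[ok]; y <- y[ok]
      if (length(x) < 4) stop("need n >= 4 for a Spearman correlation")
      ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                             exact = FALSE))
      data.frame(type = "spearman", label = paste(cmp$x, "~", cmp$y),
                 statistic = unname(ct$estimate), p = ct$p.value,
                 effect_r = unname(ct$estimate))
    } else if (cmp$type == "mann_whitney") {
      g <- factor(table[[cmp$group]])
      if (nlevels(g) != 2) stop("`mann_whitney` needs exactly two groups")
      v <- table[[cmp$value]]
      ok <- stats::complete.cases(v, g)
      v <- v[ok]; g <- g[ok]
      if (length(v) < 4) stop("need n >= 4 for a Mann-Whitney test")
      wt <- suppressWarnings(stats::wilcox.test(v ~ g, exact = FALSE,
                                                correct = FALSE))
      zval <- stats::qnorm(wt$p.value / 2)
      n1 <- sum(g == levels(g)[1]); n2 <- sum(g == levels(g)[2])
      direction <- sign(wt$statistic - n1 * n2 / 2)
      data.frame(type = "mann_whitney",
                 label = paste(cmp$value, "by", cmp$group),
                 statistic = unname(wt$statistic), p = wt$p.value,
                 effect_r = unname(direction * abs(zval) / sqrt(length(v))))
    } else stop("unknown comparison type: ", cmp$type)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- holm_adjust(out$p)
  rownames(out) <- NULL
  out
}
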