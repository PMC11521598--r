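# Terms that may be dropped from `fixed` while respecting marginality:
# a main effect stays while any interaction containing it remains.
droppable_terms <- function(fixed) {
  is_int <- grepl(":", fixed, fixed = TRUE)
  keep_main <- unique(unlist(strsplit(fixed[is_int], ":", fixed = TRUE)))
  fixed[is_int | !(fixed %in% keep_main)]
}

drop_term <- function(spec, term) {
  spec$fixed <- setdiff(spec$fixed, term)
  spec
}

as_ml <- function(spec) { spec$estimation <- "ML"; spec }

fit_or_null <- function(spec, table) {
  tryCatch(fit_lmm(spec, table), error = function(e) NULL)
}

usable <- function(fit) !is.null(fit) && fit$converged

#' Backward-stepwise fixed-effect elimination by likelihood-ratio test
#'
#' Implements the two-stage selection procedure for mixed models:
#' (1) candidate fixed effects are ranked by their single-term
#' likelihood-ratio contribution to the full model; (2) if the full model
#' does not converge, random slopes are simplified first and then the
#' least-contributing fixed terms are excluded until a converged fit is
#' obtained; (3) fixed effects are then discarded one at a time - always
#' the term whose removal gives the largest LRT p-value, respecting
#' marginality - until every remaining term is significant at
#' `alpha_keep`. All fits in the procedure use maximum likelihood so that
#' models with different fixed effects are comparable; the final model is
#' refitted by REML for reporting.
#'
#' @param full_spec A [model_spec()] with the complete candidate set.
#' @param table Data frame (complete cases for the model columns).
#' @param alpha_keep Significance level a term must beat to stay
#'   (default 0.05).
#' @return A list of class `selection_trace`: `trace` (data frame of
#'   steps: term, chisq, df, p, action), `final_spec`, `final_fit` (REML),
#'   `final_fit_ml`, `ranked_terms`.
#' @export
backward_stepwise <- function(full_spec, table, alpha_keep = 0.05) {
  stopifnot(inherits(full_spec, "model_spec"))
  spec <- as_ml(full_spec)
  table <- table[stats::complete.cases(
    table[, intersect(spec_columns(spec), names(table)), drop = FALSE]), ,
    drop = FALSE]
  trace <- list()
  note <- function(term, chisq, df, p, action) {
    trace[[length(trace) + 1L]] <<- data.frame(
      term = term, chisq = chisq, df = df, p = p, action = action)
  }

  full_fit <- fit_or_null(spec, table)

  # rank candidate terms by their LRT contribution to the full model
  ranked <- character(0)
  if (usable(full_fit)) {
    cand <- droppable_terms(spec$fixed)
    ps <- vapply(cand, function(tm) {
      f0 <- fit_or_null(drop_term(spec, tm), table)
      if (!usable(f0)) return(0)  # irreplaceable term
      likelihood_ratio_test(f0, full_fit)$p
    }, numeric(1))
    ranked <- cand[order(ps)]  # most significant contribution first
  }

  # convergence-driven simplification: random slopes first, then the
  # least-contributing fixed terms
  while (!usable(full_fit)) {
    if (length(spec$random_slopes) > 0) {
      g <- names(spec$random_slopes)[length(spec$random_slopes)]
      tm <- spec$random_slopes[[g]][length(spec$random_slopes[[g]])]
      spec$random_slopes[[g]] <- setdiff(spec$random_slopes[[g]], tm)
      if (length(spec$random_slopes[[g]]) == 0) spec$random_slopes[[g]] <- NULL
      note(paste0("(", tm, "|", g, ")"), NA, NA, NA, "dropped_for_convergence")
    } else {
      cand <- droppable_terms(spec$fixed)
      if (length(cand) == 0) {
        if (length(spec$random_intercepts) > 1) {
          g <- spec$random_intercepts[length(spec$random_intercepts)]
          spec$random_intercepts <- setdiff(spec$random_intercepts, g)
          note(paste0("(1|", g, ")"), NA, NA, NA, "dropped_for_convergence")
        } else {
          stop("intercept-only model failed to converge")
        }
      } else {
        tm <- if (length(ranked)) rev(intersect(ranked, cand))[1] else cand[length(cand)]
        ranked <- setdiff(ranked, tm)
        spec <- drop_term(spec, tm)
        note(tm, NA, NA, NA, "dropped_for_convergence")
      }
    }
    full_fit <- fit_or_null(spec, table)
  }

  # backward elimination: drop the weakest term until all are significant
  repeat {
    cand <- droppable_terms(spec$fixed)
    if (length(cand) == 0) break
    tests <- lapply(cand, function(tm) {
      f0 <- fit_or_null(drop_term(spec, tm), table)
      if (!usable(f0)) return(NULL)
      likelihood_ratio_test(f0, full_fit)
    })
    ok <- !vapply(tests, is.null, logical(1))
    if (!any(ok)) break
    cand <- cand[ok]; tests <- tests[ok]
    ps <- vapply(tests, `[[`, numeric(1), "p")
    worst <- which.max(ps)
    if (ps[worst] <= alpha_keep) {
      for (i in seq_along(cand)) {
        note(cand[i], tests[[i]]$chisq, tests[[i]]$df, tests[[i]]$p, "retained")
      }
      break
    }
    note(cand[worst], tests[[worst]]$chisq, tests[[worst]]$df,
         ps[worst], "dropped")
    spec <- drop_term(spec, cand[worst])
    full_fit <- fit_or_null(spec, table)
    if (!usable(full_fit)) stop("model lost convergence during elimination")
  }

  final_spec_reml <- spec
  final_spec_reml$estimation <- if (has_random(spec)) "REML" else "ML"
  out <- list(
    trace = if (length(trace)) do.call(rbind, trace) else
      data.frame(term = character(0), chisq = numeric(0), df = numeric(0),
                 p = numeric(0), action = character(0)),
    final_spec = spec,
    final_fit = fit_lmm(final_spec_reml, table),
    final_fit_ml = full_fit,
    ranked_terms = ranked)
  class(out) <- "selection_trace"
  out
}

#' @export
print.selection_trace <- function(x, ...) {
  dropped <- x$trace$term[x$trace$action %in%
                            c("dropped", "dropped_for_convergence")]
  cat(sprintf("<selection_trace> %d terms dropped (%s); final fixed effects: %s\n",
              length(dropped),
              if (length(dropped)) paste(dropped, collapse = ", ") else "none",
              paste(x$final_spec$fixed, collapse = " + ")))
  invisible(x)
}
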