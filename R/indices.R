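#' Dyadic mean of two members' values
#'
#' The within-dyad average of a rating or physiological measure, used as
#' an index of emotional intensity (e.g. dyadic mean valence, arousal,
#' IBI, respiratory rate, SC level).
#'
#' @param a,b The two members' values (same measure, same video).
#' @return `(a + b) / 2`; `NA` (never an imputed value) when a member is
#'   missing.
#' @export
dyadic_mean <- function(a, b) (a + b) / 2

#' Dyadic absolute difference
#'
#' The absolute difference between the two members' values, an index of
#' emotional dissimilarity within the dyad.
#'
#' @inheritParams dyadic_mean
#' @return `|a - b|` (>= 0, symmetric).
#' @export
dyadic_abs_difference <- function(a, b) abs(a - b)

#' Mutual (product) index
#'
#' The product of the two members' values. For a fixed sum the product is
#' maximal when the values are equal, so the index rewards both the
#' intensity and the reciprocity of the members' attitudes (mutual
#' connectedness, mutual identification, mutual desire). Multi-item scales
#' are averaged within members before multiplying.
#'
#' @inheritParams dyadic_mean
#' @return `a * b`.
#' @export
mutual_product <- function(a, b) a * b

#' Change score between two time points
#'
#' Subtracts the dyadic product at the start of the experiment from the
#' product at the end: positive values mean the intensity/reciprocity of
#' prosocial attitudes increased over the session.
#'
#' @param product_t1,product_t0 Dyadic products at the end and start.
#' @return `product_t1 - product_t0`.
#' @export
change_score <- function(product_t1, product_t0) product_t1 - product_t0

#' Build the per-dyad, per-video index table
#'
#' Aggregates an individual-level table (two members per dyad and video)
#' into dyad-level indices: dyadic means of valence, arousal and the
#' physiological levels; dyadic absolute differences of valence and
#' arousal; mutual connectedness (product of member connectedness scores);
#' and the change in mutual identification and mutual desire from t0 to
#' t1. The output is member-order invariant.
#'
#' @param individual A data frame with columns `dyad`, `member` (1/2),
#'   `video` (1-3), `valence`, `attention`, `valence_rating`,
#'   `arousal_rating`, `connectedness`, and optionally `mean_ibi_ms`,
#'   `rsp_rate`, `sc_level`, plus per-dyad columns `ident_t0`, `ident_t1`,
#'   `desire_t0`, `desire_t1` (constant within member).
#' @return A data frame of class `dyad_index_table`, one row per dyad and
#'   video.
#' @export
build_dyad_table <- function(individual) {
  need <- c("dyad", "member", "video", "valence", "attention",
            "valence_rating", "arousal_rating", "connectedness")
  miss <- setdiff(need, names(individual))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  rows <- list()
  for (d in unique(individual$dyad)) {
    di <- individual[individual$dyad == d, ]
    for (v in sort(unique(di$video))) {
      dv <- di[di$video == v, ]
      m1 <- dv[dv$member == 1, ]
      m2 <- dv[dv$member == 2, ]
      if (nrow(m1) != 1 || nrow(m2) != 1) {
        warning(sprintf("dyad %s video %s: missing member, row skipped", d, v))
        next
      }
      row <- data.frame(
        dyad = d, video = v, valence = m1$valence,
        attention = m1$attention,
        dyadic_mean_valence = dyadic_mean(m1$valence_rating, m2$valence_rating),
        dyadic_mean_arousal = dyadic_mean(m1$arousal_rating, m2$arousal_rating),
        dyadic_diff_valence = dyadic_abs_difference(m1$valence_rating, m2$valence_rating),
        dyadic_diff_arousal = dyadic_abs_difference(m1$arousal_rating, m2$arousal_rating),
        mutual_connectedness = mutual_product(m1$connectedness, m2$connectedness))
      for (col in c("mean_ibi_ms", "rsp_rate", "sc_level")) {
        if (col %in% names(dv)) {
          row[[paste0("dyadic_mean_", sub("_ms$", "", sub("^mean_", "", col)))]] <-
            dyadic_mean(m1[[col]], m2[[col]])
        }
      }
      if (all(c("ident_t0", "ident_t1") %in% names(dv))) {
        row$mutual_identification_change <- change_score(
          mutual_product(m1$ident_t1, m2$ident_t1),
          mutual_product(m1$ident_t0, m2$ident_t0))
      }
      if (all(c("desire_t0", "desire_t1") %in% names(dv))) {
        row$mutual_desire_change <- change_score(
          mutual_product(m1$desire_t1, m2$desire_t1),
          mutual_product(m1$desire_t0, m2$desire_t0))
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("dyad_index_table", class(out))
  out
}

#' Neutral-baseline correction of a dyad index table
#'
#' Subtracts each dyad's neutral-video row from its positive- and
#' negative-video rows for every numeric index column, so the corrected
#' variables measure changes relative to the neutral emotional baseline.
#' Attention and order metadata are carried through. Dyads without a
#' neutral-video row are dropped with a message.
#'
#' @param table A `dyad_index_table` with a `valence` column containing
#'   `"negative"`, `"neutral"`, `"positive"`.
#' @param columns Columns to correct; defaults to every numeric column
#'   except identifiers.
#' @return A data frame with two rows per complete dyad
#'   (`positive - neutral`, `negative - neutral`), valence labelling the
#'   valenced video of each row.
#' @export
neutral_baseline_correct <- function(table, columns = NULL) {
  stopifnot(is.data.frame(table), "valence" %in% names(table))
  if (is.null(columns)) {
    num <- vapply(table, is.numeric, logical(1))
    columns <- setdiff(names(table)[num], c("dyad", "video"))
  }
  rows <- list()
  dropped <- character(0)
  for (d in unique(table$dyad)) {
    dt <- table[table$dyad == d, ]
    neu <- dt[dt$valence == "neutral", ]
    if (nrow(neu) != 1) {
      dropped <- c(dropped, as.character(d))
      next
    }
    for (val in c("positive", "negative")) {
      dv <- dt[dt$valence == val, ]
      if (nrow(dv) != 1) {
        dropped <- c(dropped, as.character(d))
        next
      }
      row <- dv
      for (col in columns) row[[col]] <- dv[[col]] - neu[[col]]
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(dropped)) {
    message("dropped dyads lacking a complete video set: ",
            paste(unique(dropped), collapse = ", "))
  }
  if (length(rows) == 0L) stop("no complete dyads to correct")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Individual-level table from simulated sessions
#'
#' Convenience extractor that turns a list of [simulate_dyad_session()]
#' outputs into the individual-level table consumed by
#' [build_dyad_table()], using the generator's ratings and, when the
#' physiological channels were synthesized, the preprocessed physiological
#' summaries (mean IBI from ground-truth beats, detected expiration rate,
#' mean SC level).
#'
#' @param sessions List of `dyad_session` objects.
#' @param physio If `TRUE` (default), include physiological summaries.
#' @return A data frame, one row per member, video and dyad.
#' @export
sessions_to_individual_table <- function(sessions, physio = TRUE) {
  rows <- list()
  for (d in seq_along(sessions)) {
    s <- sessions[[d]]
    att <- s$attitudes
    for (m in 1:2) {
      am <- att[att$member == m, ]
      for (v in 1:3) {
        r <- s$ratings[s$ratings$member == m & s$ratings$video == v, ]
        row <- data.frame(
          dyad = d, member = m, video = v, valence = r$valence,
          attention = s$config$attention,
          valence_rating = r$valence_rating,
          arousal_rating = r$arousal_rating,
          connectedness = r$connectedness,
          ident_t0 = am$identification[am$time == "t0"],
          ident_t1 = am$identification[am$time == "t1"],
          desire_t0 = am$desire[am$time == "t0"],
          desire_t1 = am$desire[am$time == "t1"])
        if (physio) {
          vid <- s$members[[m]]$videos[[v]]
          if (!is.null(vid$ibi)) row$mean_ibi_ms <- vid$ibi$mean_ibi_ms
          if (!is.null(vid$rsp)) {
            row$rsp_rate <- detect_expirations(vid$rsp)$rate_per_min
          }
          if (!is.null(vid$sc)) row$sc_level <- mean(vid$sc$samples)
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  do.call(rbind, rows)
}
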