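#' Aggregate per-variable effect sizes into an Ecosystem Aggregated Impact
#'
#' The EAI of a treatment at a timepoint is the sum over the monitored
#' variables of the absolute value of Hedges' g against the control,
#' \eqn{EAI = \sum_v |g_v|}. Taking absolute values quantifies how much the
#' ecosystem changed without an a-priori direction of "better" or "worse".
#' Its variance is propagated as the sum of the per-variable effect-size
#' variances, \eqn{var(EAI) = \sum_v var(g_v)} (valid for approximately
#' normally distributed variables), and the 95% confidence interval is
#' \eqn{EAI \pm 1.96 \sqrt{var(EAI)}}. The lower bound is reported as
#' computed, which can be negative even though the index itself is
#' non-negative.
#'
#' @param estimates effect-size rows for a single treatment and timepoint,
#'   as returned by [effect_size_table()].
#' @param variables the full configured variable set; the estimates must
#'   cover exactly these variables, once each.
#' @return One-row data frame with columns \code{treatment},
#'   \code{timepoint}, \code{eai}, \code{var_eai}, \code{ci_low},
#'   \code{ci_high}, \code{n_variables}, \code{letter} (\code{NA} until
#'   [assign_letters()] is applied).
#' @examples
#' es <- data.frame(treatment = "H", timepoint = "T1",
#'                  variable = c("NO3", "PDA"),
#'                  g = c(1.5, -1.5), var_g = c(0.6, 0.6))
#' aggregate_eai(es, variables = c("NO3", "PDA"))
#' @export
aggregate_eai <- function(estimates, variables) {
  if (length(unique(estimates$treatment)) != 1 ||
      length(unique(estimates$timepoint)) != 1) {
    stop_("estimates mix treatments or timepoints; aggregate one cell at a time")
  }
  dup <- unique(estimates$variable[duplicated(estimates$variable)])
  if (length(dup)) stop_("duplicated variable(s) in estimates: %s", paste(dup, collapse = ", "))
  miss <- setdiff(variables, estimates$variable)
  if (length(miss)) stop_("missing variable(s) in estimates: %s", paste(miss, collapse = ", "))
  extra <- setdiff(estimates$variable, variables)
  if (length(extra)) stop_("unexpected variable(s) in estimates: %s", paste(extra, collapse = ", "))

  eai <- sum(abs(estimates$g))
  var_eai <- sum(estimates$var_g)
  half <- 1.96 * sqrt(var_eai)
  data.frame(treatment = estimates$treatment[1], timepoint = estimates$timepoint[1],
             eai = eai, var_eai = var_eai, ci_low = eai - half, ci_high = eai + half,
             n_variables = length(variables), letter = NA_character_)
}

#' EAI summaries for every treatment-by-timepoint cell
#'
#' Applies [aggregate_eai()] to each (treatment, timepoint) cell of an
#' effect-size table and, by default, assigns CI-overlap significance
#' letters within each timepoint.
#'
#' @param estimates full effect-size table from [effect_size_table()].
#' @param variables configured variable set (defaults to the variables
#'   present, which must be complete in every cell).
#' @param letters if \code{TRUE}, call [assign_letters()] on the result.
#' @return Data frame of EAI summaries, one row per treatment and timepoint.
#' @export
eai_table <- function(estimates, variables = NULL, letters = TRUE) {
  if (is.null(variables)) variables <- sort(unique(estimates$variable))
  cells <- unique(estimates[, c("treatment", "timepoint")])
  cells <- cells[order(cells$treatment, cells$timepoint), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- estimates$treatment == cells$treatment[i] &
      estimates$timepoint == cells$timepoint[i]
    aggregate_eai(estimates[sel, , drop = FALSE], variables)
  }))
  rownames(out) <- NULL
  if (letters) out <- assign_letters(out) else out
}

#' Assign compact significance letters from confidence-interval overlap
#'
#' Two EAI summaries are considered not significantly different when their
#' 95% confidence intervals overlap (closed intervals: touching endpoints
#' count as overlap). Letters are assigned so that two summaries share at
#' least one letter if and only if their intervals overlap, the usual
#' compact-letter display read off bar plots.
#'
#' Because confidence intervals are intervals on the real line, their
#' overlap graph is an interval graph: every maximal clique is the set of
#' intervals covering some interval's lower endpoint. The algorithm sweeps
#' the summaries in ascending EAI order, collects the clique at each lower
#' endpoint, absorbs cliques contained in another, and labels the surviving
#' cliques \code{a}, \code{b}, ... in sweep order, so the output is
#' deterministic.
#'
#' @param summaries data frame with \code{ci_low} and \code{ci_high}
#'   columns (rows from [eai_table()] or [aggregate_eai()]).
#' @param within optional column name; letters are assigned independently
#'   within each level (default \code{"timepoint"} when present, matching
#'   per-panel displays). Use \code{NULL} to compare all rows jointly.
#' @return The input with the \code{letter} column populated.
#' @export
assign_letters <- function(summaries, within = if ("timepoint" %in% names(summaries)) "timepoint" else NULL) {
  if (is.null(summaries) || nrow(summaries) == 0) stop_("no summaries to letter")
  if (!is.null(within)) {
    parts <- split(seq_len(nrow(summaries)), summaries[[within]])
    for (idx in parts) {
      summaries$letter[idx] <- letter_display(summaries$ci_low[idx], summaries$ci_high[idx],
                                              order_by = summaries$eai[idx])
    }
  } else {
    summaries$letter <- letter_display(summaries$ci_low, summaries$ci_high,
                                       order_by = summaries$eai)
  }
  summaries
}

# Compact letter display for closed intervals [lo, hi]: shared letter iff
# intervals intersect. order_by fixes the sweep order (ascending).
letter_display <- function(lo, hi, order_by = lo) {
  n <- length(lo)
  if (n == 0) stop_("no intervals")
  if (any(hi < lo)) stop_("interval with ci_high < ci_low")
  ord <- order(order_by, lo, hi)
  # maximal cliques of an interval graph: intervals covering each lo[i]
  cliques <- list()
  for (i in ord) {
    members <- which(lo <= lo[i] & hi >= lo[i])
    absorbed <- FALSE
    drop <- integer(0)
    for (k in seq_along(cliques)) {
      if (all(members %in% cliques[[k]])) { absorbed <- TRUE; break }
      if (all(cliques[[k]] %in% members)) drop <- c(drop, k)
    }
    if (!absorbed) {
      if (length(drop)) cliques[drop] <- NULL
      cliques[[length(cliques) + 1]] <- members
    }
  }
  if (length(cliques) > 26 * 27) stop_("too many letter groups to display")
  lab <- function(k) {
    if (k <= 26) letters[k] else paste0(letters[(k - 1) %/% 26], letters[(k - 1) %% 26 + 1])
  }
  out <- character(n)
  for (k in seq_along(cliques)) {
    out[cliques[[k]]] <- paste0(out[cliques[[k]]], lab(k))
  }
  out
}

#' Write an EAI summary table to a tab-separated file
#'
#' Rows are sorted by timepoint then descending EAI; values are written at
#' 6 significant digits, enough to round-trip the analysis.
#'
#' @param summaries lettered EAI table from [eai_table()].
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
eai_report <- function(summaries, path) {
  if (is.null(summaries) || nrow(summaries) == 0) stop_("no summaries to write")
  if (all(is.na(summaries$letter))) stop_("assign letters before writing the report")
  out <- summaries[order(summaries$timepoint, -summaries$eai), , drop = FALSE]
  num <- c("eai", "var_eai", "ci_low", "ci_high")
  out[num] <- lapply(out[num], signif, digits = 6)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
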