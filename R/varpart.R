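#' Sequential (Type-I) variance partitioning
#'
#' Decomposes the variance of a response into contributions of numeric
#' predictors entered in a fixed order, by sequential least squares: each
#' term's sum of squares is the reduction in residual SS when that
#' predictor is added after the preceding ones, so the attribution depends
#' on the order, which is part of the analysis configuration. Each single
#' degree-of-freedom term is tested against the residual mean square, and
#' its share of the total sum of squares is reported as a percentage.
#'
#' A predictor that is collinear with earlier terms contributes zero
#' degrees of freedom; its SS is reported as 0 with a warning.
#'
#' @param response numeric response vector (e.g. per-cell EAI values).
#' @param predictors named list or data frame of numeric predictors, in
#'   the order they should enter the model.
#' @return Data frame shaped like a sequential ANOVA table: one row per
#'   term plus a final \code{residual} row, with columns \code{term},
#'   \code{df}, \code{sum_sq}, \code{mean_sq}, \code{F}, \code{p},
#'   \code{percent}, \code{stars} (\code{*} p<0.05, \code{**} p<0.01,
#'   \code{***} p<0.001).
#' @export
variance_partition <- function(response, predictors) {
  predictors <- as.data.frame(predictors)
  if (ncol(predictors) == 0) stop_("no predictors supplied")
  if (nrow(predictors) != length(response)) {
    stop_("response and predictors differ in length")
  }
  if (length(response) < ncol(predictors) + 2) {
    stop_("need at least %d observations for %d terms",
          ncol(predictors) + 2, ncol(predictors))
  }
  terms <- names(predictors)
  dat <- cbind(data.frame(.response = response), predictors)
  fit <- lm(stats::reformulate(terms, response = ".response"), data = dat)
  av <- suppressWarnings(anova(fit))

  tab <- data.frame(term = rownames(av), df = av$Df, sum_sq = av[["Sum Sq"]],
                    mean_sq = av[["Mean Sq"]], F = av[["F value"]],
                    p = av[["Pr(>F)"]])
  # terms dropped by lm for collinearity carry zero SS and df
  dropped <- setdiff(terms, tab$term)
  if (length(dropped)) {
    warning(sprintf("collinear predictor(s) contribute zero df: %s",
                    paste(dropped, collapse = ", ")))
    add <- data.frame(term = dropped, df = 0L, sum_sq = 0, mean_sq = NA_real_,
                      F = NA_real_, p = NA_real_)
    resid_row <- tab$term == "Residuals"
    tab <- rbind(tab[!resid_row, , drop = FALSE], add, tab[resid_row, , drop = FALSE])
  }
  tab$term[tab$term == "Residuals"] <- "residual"
  ord <- match(c(terms, "residual"), tab$term)
  tab <- tab[ord, , drop = FALSE]

  ss_total <- sum(tab$sum_sq)
  tab$percent <- if (ss_total > 0) 100 * tab$sum_sq / ss_total else 0
  # an exact fit leaves only rounding noise in the residual mean square
  resid_ms <- tab$mean_sq[tab$term == "residual"]
  if (resid_ms <= 1e-12 * max(tab$mean_sq, na.rm = TRUE)) {
    tab$mean_sq[tab$term == "residual"] <- 0
    resid_ms <- 0
  }
  if (isTRUE(resid_ms == 0)) {
    is_term <- tab$term != "residual"
    tab$F[is_term] <- ifelse(tab$sum_sq[is_term] > 0, Inf, 0)
    tab$p[is_term] <- ifelse(tab$sum_sq[is_term] > 0, 0, 1)
  }
  tab$stars <- ifelse(is.na(tab$p), "",
               ifelse(tab$p < 0.001, "***",
               ifelse(tab$p < 0.01, "**",
               ifelse(tab$p < 0.05, "*", ""))))
  tab$stars[tab$term == "residual"] <- ""
  rownames(tab) <- NULL
  tab
}

#' Write a variance-partition table to a tab-separated file
#'
#' @param tab table from [variance_partition()].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_variance_partition <- function(tab, path) {
  out <- tab
  num <- c("sum_sq", "mean_sq", "F", "p", "percent")
  out[num] <- lapply(out[num], signif, digits = 6)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Per-cell predictors of the EAI from composition and effect-size shifts
#'
#' Builds the design matrix for [variance_partition()] with one row per
#' (treatment, timepoint) cell of an EAI table. A predictor named after a
#' measured variable contributes that cell's \eqn{|g|}; the special name
#' \code{"weighted_unifrac"} (or any metric name of [distance_matrix()])
#' contributes the mean distance between the cell's samples and the
#' control samples of the same timepoint.
#'
#' @param eai_tab EAI summaries from [eai_table()].
#' @param estimates effect-size table from [effect_size_table()].
#' @param dm optional distance matrix over community samples.
#' @param metadata optional data frame with \code{sample_id},
#'   \code{treatment}, \code{timepoint} describing the rows of \code{dm}.
#' @param control control treatment label (needed with \code{dm}).
#' @param predictors character vector of predictor names, in entry order.
#' @return List with \code{response} (EAI per cell) and \code{predictors}
#'   (data frame aligned with it), ready for [variance_partition()].
#' @export
eai_predictors <- function(eai_tab, estimates, dm = NULL, metadata = NULL,
                           control = NULL, predictors) {
  cells <- eai_tab[, c("treatment", "timepoint")]
  distance_names <- c("weighted_unifrac", "weighted_unifrac_normalized",
                      "unweighted_unifrac", "unweighted_unifrac_raw")
  cols <- lapply(predictors, function(p) {
    if (p %in% distance_names) {
      if (is.null(dm) || is.null(metadata) || is.null(control)) {
        stop_("distance predictor '%s' needs dm, metadata and control", p)
      }
      vapply(seq_len(nrow(cells)), function(i) {
        trt_s <- metadata$sample_id[metadata$treatment == cells$treatment[i] &
                                      metadata$timepoint == cells$timepoint[i]]
        ctl_s <- metadata$sample_id[metadata$treatment == control &
                                      metadata$timepoint == cells$timepoint[i]]
        trt_s <- intersect(trt_s, rownames(dm))
        ctl_s <- intersect(ctl_s, rownames(dm))
        if (!length(trt_s) || !length(ctl_s)) {
          stop_("no community samples for cell (%s, %s)", cells$treatment[i], cells$timepoint[i])
        }
        mean(dm[trt_s, ctl_s])
      }, numeric(1))
    } else {
      vapply(seq_len(nrow(cells)), function(i) {
        sel <- estimates$treatment == cells$treatment[i] &
          estimates$timepoint == cells$timepoint[i] & estimates$variable == p
        if (!any(sel)) stop_("no effect size for predictor '%s' in cell (%s, %s)",
                             p, cells$treatment[i], cells$timepoint[i])
        abs(estimates$g[sel][1])
      }, numeric(1))
    }
  })
  names(cols) <- predictors
  list(response = eai_tab$eai, predictors = as.data.frame(cols))
}
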