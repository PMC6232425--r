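#' One-way analysis of variance
#'
#' Fits the per-timepoint model \eqn{Y_{ij} = \mu + treatment_i +
#' residual_{ij}} and returns the F test of the treatment term. The
#' degenerate case of identical values within every group but different
#' group means is reported as an infinite F with p = 0.
#'
#' @param values numeric response vector.
#' @param groups group labels, same length; >= 2 groups with >= 2
#'   observations each.
#' @return List with \code{F}, \code{df_between}, \code{df_within},
#'   \code{p}.
#' @export
one_way_anova <- function(values, groups) {
  groups <- check_groups(values, groups)
  fit <- suppressWarnings(anova(lm(values ~ groups)))
  ms_b <- fit[["Mean Sq"]][1]
  ms_w <- fit[["Mean Sq"]][2]
  df_b <- fit[["Df"]][1]
  df_w <- fit[["Df"]][2]
  # an exact within-group fit leaves only rounding noise in MS_within
  if (ms_w <= 1e-12 * max(ms_b, .Machine$double.eps)) {
    if (ms_b <= .Machine$double.eps) {
      return(list(F = 0, df_between = df_b, df_within = df_w, p = 1))
    }
    return(list(F = Inf, df_between = df_b, df_within = df_w, p = 0))
  }
  list(F = fit[["F value"]][1], df_between = df_b, df_within = df_w,
       p = fit[["Pr(>F)"]][1])
}

#' Tukey honestly-significant-difference pairwise comparisons
#'
#' Studentized-range tests of all unordered group pairs at familywise
#' level \code{alpha}, using the within-group mean square and residual
#' degrees of freedom of the one-way fit. For unbalanced groups the
#' Tukey-Kramer standard error is used. With exactly two groups the q
#' statistic reduces to \eqn{\sqrt{2}\,|t|} of the pooled two-sample t.
#'
#' @inheritParams one_way_anova
#' @param alpha familywise significance level for the \code{significant}
#'   flag.
#' @return Data frame with one row per pair: \code{label_a},
#'   \code{label_b}, \code{diff} (mean of b minus mean of a), \code{q},
#'   \code{p} (familywise-adjusted), \code{significant}.
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  groups <- check_groups(values, groups)
  fit <- suppressWarnings(anova(lm(values ~ groups)))
  ms_w <- fit[["Mean Sq"]][2]
  df_w <- fit[["Df"]][2]
  lev <- levels(groups)
  k <- length(lev)
  means <- c(tapply(values, groups, mean))
  ns <- c(tapply(values, groups, length))
  pairs <- combn(lev, 2)
  out <- data.frame(label_a = pairs[1, ], label_b = pairs[2, ])
  out$diff <- unname(means[out$label_b] - means[out$label_a])
  se <- unname(sqrt(ms_w / 2 * (1 / ns[out$label_a] + 1 / ns[out$label_b])))
  out$q <- ifelse(se == 0, ifelse(out$diff == 0, 0, Inf), abs(out$diff) / se)
  out$p <- ifelse(is.infinite(out$q), 0, ptukey(out$q, nmeans = k, df = df_w, lower.tail = FALSE))
  out$p[out$q == 0] <- 1
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  out
}

check_groups <- function(values, groups) {
  if (length(values) != length(groups)) stop_("values and groups differ in length")
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop_("need >= 2 groups")
  sizes <- table(groups)
  if (any(sizes < 2)) {
    stop_("group(s) with < 2 observations: %s",
          paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  groups
}
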