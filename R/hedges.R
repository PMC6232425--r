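#' Hedges' g standardized mean difference between two replicate groups
#'
#' Computes the small-sample-corrected standardized mean difference of a
#' treated group relative to a control group, together with its large-sample
#' variance and a 95% confidence interval. The sign convention is treated
#' minus control, so positive \code{g} means the treatment increased the
#' variable.
#'
#' The estimate is \eqn{g = J (\bar{x}_T - \bar{x}_C) / s_p} with pooled
#' standard deviation
#' \eqn{s_p = \sqrt{((n_T-1)s_T^2 + (n_C-1)s_C^2) / (n_T+n_C-2)}} and
#' small-sample correction \eqn{J = 1 - 3/(4m - 1)}, \eqn{m = n_T+n_C-2}.
#' The variance is
#' \eqn{(n_T+n_C)/(n_T n_C) + g^2 / (2 (n_T+n_C))} and the confidence
#' interval \eqn{g \pm 1.96\sqrt{var(g)}}.
#'
#' When both groups have zero spread and equal means the effect is a
#' well-defined zero: \code{g = 0} is returned with the variance reduced to
#' its sample-size term. Zero pooled spread with unequal means has no finite
#' standardized difference and is an error.
#'
#' @param control numeric vector of control-group replicate values (>= 2).
#' @param treated numeric vector of treated-group replicate values (>= 2).
#' @return A one-row data frame with columns \code{g}, \code{var_g},
#'   \code{ci_low}, \code{ci_high}, \code{n_treated}, \code{n_control}.
#' @examples
#' hedges_g(control = c(10, 12, 11, 13), treated = c(14, 16, 15, 17))
#' @export
hedges_g <- function(control, treated) {
  control <- as.numeric(control)
  treated <- as.numeric(treated)
  if (length(control) < 2 || length(treated) < 2) {
    stop_("insufficient replicates: need >= 2 values per group (control %d, treated %d)",
          length(control), length(treated))
  }
  if (!all(is.finite(control)) || !all(is.finite(treated))) {
    stop_("non-finite values in input groups")
  }
  n_c <- length(control)
  n_t <- length(treated)
  m <- n_t + n_c - 2L
  s_p <- sqrt(((n_t - 1) * var(treated) + (n_c - 1) * var(control)) / m)
  diff <- mean(treated) - mean(control)
  n_term <- (n_t + n_c) / (n_t * n_c)
  if (s_p == 0) {
    if (abs(diff) > 0) {
      stop_("zero pooled variance with unequal means: standardized difference undefined")
    }
    g <- 0
    var_g <- n_term
  } else {
    J <- 1 - 3 / (4 * m - 1)
    g <- J * diff / s_p
    var_g <- n_term + g^2 / (2 * (n_t + n_c))
  }
  half <- 1.96 * sqrt(var_g)
  data.frame(g = g, var_g = var_g, ci_low = g - half, ci_high = g + half,
             n_treated = n_t, n_control = n_c)
}

#' Hedges' g for every treatment, timepoint and variable of an experiment
#'
#' Compares each non-control treatment to the control group within each
#' timepoint, variable by variable, after optionally log10-transforming
#' configured variables. Which variables are transformed is configuration
#' (typically those whose residuals need it, such as gene-copy abundances),
#' not something inferred from the data.
#'
#' @param measurements long-format measurement data frame with columns
#'   \code{sample_id}, \code{treatment}, \code{timepoint}, \code{replicate},
#'   \code{variable}, \code{value} (see [read_measurements()]).
#' @param control label of the control treatment.
#' @param variables character vector of variables to analyse; default all
#'   variables in the table.
#' @param transforms named character vector mapping variable names to
#'   \code{"none"} or \code{"log10"}; unnamed variables default to
#'   \code{"none"}.
#' @return Data frame with one row per (treatment, timepoint, variable),
#'   ordered lexicographically, with columns \code{treatment},
#'   \code{timepoint}, \code{variable}, \code{g}, \code{var_g},
#'   \code{ci_low}, \code{ci_high}, \code{n_treated}, \code{n_control},
#'   \code{transform}.
#' @seealso [hedges_g()], [eai_table()]
#' @export
effect_size_table <- function(measurements, control, variables = NULL,
                              transforms = NULL) {
  m <- validate_measurements(measurements)
  if (!control %in% m$treatment) stop_("control label '%s' not present", control)
  if (is.null(variables)) variables <- sort(unique(m$variable))
  missing_vars <- setdiff(variables, m$variable)
  if (length(missing_vars)) {
    stop_("variables absent from table: %s", paste(missing_vars, collapse = ", "))
  }
  m <- m[m$variable %in% variables, , drop = FALSE]

  timepoints <- sort(unique(m$timepoint))
  treatments <- sort(setdiff(unique(m$treatment), control))
  for (tp in timepoints) {
    if (!any(m$treatment == control & m$timepoint == tp)) {
      stop_("control group missing at timepoint '%s'", tp)
    }
  }

  trans_for <- function(v) {
    tr <- if (!is.null(transforms) && v %in% names(transforms)) transforms[[v]] else "none"
    if (!tr %in% c("none", "log10")) stop_("unknown transform '%s' for variable '%s'", tr, v)
    tr
  }
  apply_trans <- function(x, tr, who) {
    if (tr == "log10") {
      if (any(x <= 0)) {
        bad <- who[which(x <= 0)[1]]
        stop_("non-positive value under log10 transform (sample '%s')", bad)
      }
      log10(x)
    } else x
  }

  rows <- vector("list", length(treatments) * length(timepoints) * length(variables))
  k <- 0L
  for (tr_label in treatments) {
    for (tp in timepoints) {
      for (v in variables) {
        ctl <- m[m$treatment == control & m$timepoint == tp & m$variable == v, , drop = FALSE]
        trt <- m[m$treatment == tr_label & m$timepoint == tp & m$variable == v, , drop = FALSE]
        if (nrow(trt) == 0) {
          stop_("variable '%s' absent for treatment '%s' at timepoint '%s'", v, tr_label, tp)
        }
        if (nrow(ctl) == 0) {
          stop_("variable '%s' absent for control at timepoint '%s'", v, tp)
        }
        tf <- trans_for(v)
        est <- hedges_g(apply_trans(ctl$value, tf, ctl$sample_id),
                        apply_trans(trt$value, tf, trt$sample_id))
        k <- k + 1L
        rows[[k]] <- cbind(
          data.frame(treatment = tr_label, timepoint = tp, variable = v),
          est, data.frame(transform = tf))
      }
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  rownames(out) <- NULL
  out
}

validate_measurements <- function(m) {
  req <- c("sample_id", "treatment", "timepoint", "replicate", "variable", "value")
  missing_cols <- setdiff(req, names(m))
  if (length(missing_cols)) {
    stop_("measurement table missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  key <- paste(m$sample_id, m$variable, sep = "\r")
  if (anyDuplicated(key)) {
    d <- m[duplicated(key), , drop = FALSE][1, ]
    stop_("duplicate (sample_id, variable) pair: ('%s', '%s')", d$sample_id, d$variable)
  }
  if (!all(is.finite(m$value))) stop_("non-finite measurement values present")
  m
}
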