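#' Permutational multivariate analysis of variance (one factor)
#'
#' Tests whether community composition differs among groups using the
#' pseudo-F statistic computed directly from a dissimilarity matrix:
#' \eqn{SS_{total} = \frac{1}{N}\sum_{i<j} d_{ij}^2},
#' \eqn{SS_{within} = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2},
#' \eqn{F = \frac{(SS_{total}-SS_{within})/(a-1)}{SS_{within}/(N-a)}}.
#' Significance is assessed by free permutation of the group labels; the
#' Monte-Carlo p-value is \eqn{(b+1)/(m+1)} with \eqn{b} the number of
#' permuted statistics at or above the observed one, so p is never zero.
#' With \code{exhaustive = TRUE} all label permutations are enumerated and
#' the p-value is the exact proportion of permutations (identity included)
#' with \eqn{F_{perm} \ge F_{obs}}.
#'
#' @param dm square symmetric distance matrix, rows/columns aligned with
#'   \code{groups}.
#' @param groups group labels; >= 2 groups of >= 2 samples.
#' @param n_permutations number of random permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @param exhaustive enumerate all permutations (only sensible for small
#'   N; capped at N = 9).
#' @return List with \code{pseudo_F}, \code{p}, \code{df_between},
#'   \code{df_within}, \code{n_permutations}.
#' @export
permanova <- function(dm, groups, n_permutations = 999, seed = NULL,
                      exhaustive = FALSE) {
  dm <- as.matrix(dm)
  N <- nrow(dm)
  if (length(groups) != N) stop_("groups length must match distance matrix size")
  groups <- factor(groups)
  sizes <- table(groups)
  a <- nlevels(groups)
  if (a < 2) stop_("need >= 2 groups")
  if (any(sizes < 2)) {
    stop_("group(s) of size 1: %s", paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  D2 <- dm^2
  idx <- split(seq_len(N), groups)
  f_stat <- function(perm) {
    ss_w <- 0
    for (g in seq_along(idx)) {
      members <- perm[idx[[g]]]
      ss_w <- ss_w + sum(D2[members, members]) / (2 * length(members))
    }
    ss_t <- sum(D2) / (2 * N)
    ss_b <- ss_t - ss_w
    if (ss_w == 0) return(if (ss_b > 0) Inf else NaN)
    (ss_b / (a - 1)) / (ss_w / (N - a))
  }
  f_obs <- f_stat(seq_len(N))
  if (is.nan(f_obs)) f_obs <- 0

  if (exhaustive) {
    if (N > 9) stop_("exhaustive enumeration limited to N <= 9")
    perms <- all_permutations(N)
    f_perm <- apply(perms, 1, f_stat)
    p <- mean(f_perm >= f_obs)
    n_used <- nrow(perms)
  } else {
    f_perm <- with_seed(seed, {
      vapply(seq_len(n_permutations), function(i) f_stat(sample.int(N)), numeric(1))
    })
    p <- (sum(f_perm >= f_obs) + 1) / (n_permutations + 1)
    n_used <- n_permutations
  }
  list(pseudo_F = f_obs, p = p, df_between = a - 1, df_within = N - a,
       n_permutations = n_used)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Pairwise PERMANOVA between all group pairs
#'
#' Runs [permanova()] restricted to the samples of each unordered pair of
#' groups, optionally adjusting p-values with Benjamini-Hochberg.
#'
#' @inheritParams permanova
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @param alpha level for the \code{significant} flag, applied to the
#'   adjusted p when adjustment is requested.
#' @return Data frame with one row per pair: \code{label_a},
#'   \code{label_b}, \code{pseudo_F}, \code{p}, \code{adjusted_p} (when
#'   requested), \code{significant}.
#' @export
pairwise_permanova <- function(dm, groups, n_permutations = 999, seed = NULL,
                               adjust = c("none", "BH"), alpha = 0.05,
                               exhaustive = FALSE) {
  adjust <- match.arg(adjust)
  dm <- as.matrix(dm)
  groups <- factor(groups)
  lev <- levels(groups)
  if (length(lev) < 2) stop_("need >= 2 groups")
  pairs <- combn(lev, 2)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    sel <- groups %in% pairs[, i]
    r <- permanova(dm[sel, sel, drop = FALSE], droplevels(groups[sel]),
                   n_permutations = n_permutations,
                   seed = if (is.null(seed)) NULL else seed + i,
                   exhaustive = exhaustive)
    data.frame(label_a = pairs[1, i], label_b = pairs[2, i],
               pseudo_F = r$pseudo_F, p = r$p)
  })
  out <- do.call(rbind, res)
  if (adjust == "BH") {
    out$adjusted_p <- p.adjust(out$p, method = "BH")
    out$significant <- out$adjusted_p < alpha
  } else {
    out$significant <- out$p < alpha
  }
  rownames(out) <- NULL
  out
}
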