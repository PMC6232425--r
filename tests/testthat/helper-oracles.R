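# Independent oracles used across the suite. Each deliberately takes a
# different computational route than the package implementation.

# Hedges' g via the two-sample t statistic: d = t * sqrt(1/n1 + 1/n2),
# g = J * d (the package computes d from the pooled SD directly).
oracle_hedges_g <- function(control, treated) {
  n_c <- length(control); n_t <- length(treated)
  t_stat <- (mean(treated) - mean(control)) /
    sqrt((((n_t - 1) * var(treated) + (n_c - 1) * var(control)) / (n_t + n_c - 2)) *
           (1 / n_t + 1 / n_c))
  J <- 1 - 3 / (4 * (n_t + n_c - 2) - 1)
  g <- J * t_stat * sqrt(1 / n_t + 1 / n_c)
  list(g = g, var_g = (n_t + n_c) / (n_t * n_c) + g^2 / (2 * (n_t + n_c)))
}

# Leaf sets below every edge, via phangorn; the package instead
# accumulates counts in a single postorder pass.
edge_leaf_sets <- function(tree) {
  lapply(seq_len(nrow(tree$edge)), function(i) {
    node <- tree$edge[i, 2]
    tips <- unlist(phangorn::Descendants(tree, node, type = "tips"))
    tree$tip.label[tips]
  })
}

naive_faith_pd <- function(counts, tree) {
  observed <- names(counts)[counts > 0]
  sets <- edge_leaf_sets(tree)
  keep <- vapply(sets, function(s) length(intersect(s, observed)) > 0, logical(1))
  sum(tree$edge.length[keep])
}

naive_unifrac <- function(a, b, tree, weighted, normalized) {
  sets <- edge_leaf_sets(tree)
  bl <- tree$edge.length
  pa <- vapply(sets, function(s) sum(a[intersect(s, names(a))]) / sum(a), numeric(1))
  pb <- vapply(sets, function(s) sum(b[intersect(s, names(b))]) / sum(b), numeric(1))
  if (weighted) {
    raw <- sum(bl * abs(pa - pb))
    if (!normalized) return(raw)
    return(raw / sum(bl * (pa + pb)))
  }
  ia <- pa > 0; ib <- pb > 0
  uniq <- sum(bl[xor(ia, ib)])
  if (!normalized) return(uniq)
  uniq / sum(bl[ia | ib])
}

# Random named profile over a tree's tips (all tips present as names).
random_profile <- function(tree, max_count = 20) {
  n <- length(tree$tip.label)
  repeat {
    x <- setNames(rpois(n, lambda = 3), tree$tip.label)
    if (sum(x) > 0) return(x)
  }
}

# Brute-force pairwise closed-interval overlap relation.
overlap_relation <- function(lo, hi) {
  n <- length(lo)
  outer(seq_len(n), seq_len(n), Vectorize(function(i, j) lo[i] <= hi[j] && lo[j] <= hi[i]))
}

shared_letter_relation <- function(letter_strings) {
  split_letters <- function(s) {
    # letters are 1- or 2-char labels; single chars unless > 26 groups
    if (all(nchar(letter_strings) == 0)) return(character(0))
    strsplit(s, "")[[1]]
  }
  sets <- lapply(letter_strings, split_letters)
  n <- length(sets)
  outer(seq_len(n), seq_len(n),
        Vectorize(function(i, j) length(intersect(sets[[i]], sets[[j]])) > 0))
}

# One-way F from raw group sums of squares (no lm).
oracle_anova_f <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups); n <- length(values)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ss_b <- sum(ns * (means - gm)^2)
  ss_w <- sum((values - means[groups])^2)
  f <- (ss_b / (k - 1)) / (ss_w / (n - k))
  list(F = f, p = pf(f, k - 1, n - k, lower.tail = FALSE))
}

# PERMANOVA p by enumerating the distinct assignments of samples to the
# given group sizes (not label permutations).
oracle_permanova_exact_p <- function(dm, groups) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2)
  N <- nrow(dm)
  n1 <- sum(groups == levels(groups)[1])
  stat <- function(g1_idx) {
    lab <- rep(levels(groups)[2], N)
    lab[g1_idx] <- levels(groups)[1]
    eaimpact::permanova(dm, lab, n_permutations = 0, exhaustive = FALSE,
                        seed = 1)$pseudo_F
  }
  obs <- stat(which(groups == levels(groups)[1]))
  combos <- combn(N, n1)
  stats <- apply(combos, 2, stat)
  mean(stats >= obs)
}
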