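# Per-branch abundance fractions for each sample, by a single postorder
# accumulation over the edge matrix. Returns edge lengths, the edges x
# samples matrix of descending count fractions, and the presence indicator.
branch_profiles <- function(tree, otu) {
  if (!inherits(tree, "phylo")) stop_("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stop_("tree has no branch lengths")
  miss <- setdiff(colnames(otu)[colSums(otu) > 0], tree$tip.label)
  if (length(miss)) stop_("OTU(s) not in tree: %s", paste(miss, collapse = ", "))
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  ns <- nrow(otu)
  node_tot <- matrix(0, nrow = ntip + nnode, ncol = ns)
  shared <- intersect(tree$tip.label, colnames(otu))
  node_tot[match(shared, tree$tip.label), ] <- t(otu[, shared, drop = FALSE])
  E <- tree$edge
  edge_count <- matrix(0, nrow = nrow(E), ncol = ns)
  for (i in seq_len(nrow(E))) {
    child <- E[i, 2L]
    edge_count[i, ] <- node_tot[child, ]
    node_tot[E[i, 1L], ] <- node_tot[E[i, 1L], ] + node_tot[child, ]
  }
  totals <- rowSums(otu)
  if (any(totals == 0)) stop_("empty sample(s): %s", paste(rownames(otu)[totals == 0], collapse = ", "))
  list(lengths = tree$edge.length,
       prop = sweep(edge_count, 2, totals, "/"),
       present = edge_count > 0,
       samples = rownames(otu))
}

#' UniFrac dissimilarity between two community profiles
#'
#' Phylogeny-aware dissimilarity over the branches of a rooted tree. For
#' each branch let \eqn{p^A_i, p^B_i} be the fraction of each sample's
#' reads descending from it and \eqn{b_i} its length.
#'
#' \itemize{
#'   \item unweighted (default \code{normalized = TRUE}): branch length
#'     unique to one community's subtree divided by the branch length
#'     spanned by either, in \[0, 1\]; the raw (\code{normalized = FALSE})
#'     form is the unique branch length itself.
#'   \item weighted raw (default for \code{weighted = TRUE}):
#'     \eqn{\sum_i b_i |p^A_i - p^B_i|}, the form classically produced by
#'     QIIME-1 pipelines.
#'   \item weighted normalized: the raw value divided by
#'     \eqn{\sum_i b_i (p^A_i + p^B_i)}, in \[0, 1\].
#' }
#'
#' @param a,b named count vectors (OTU id -> count), non-empty.
#' @param tree rooted \code{ape::phylo} with branch lengths covering all
#'   observed OTUs.
#' @param weighted use abundance-weighted branch fractions.
#' @param normalized divide by the attainable maximum (see Details);
#'   defaults to the conventional form of each variant.
#' @return A single dissimilarity value.
#' @export
unifrac <- function(a, b, tree, weighted = FALSE, normalized = !weighted) {
  if (sum(a) == 0 || sum(b) == 0) stop_("empty profile: UniFrac undefined")
  otus <- union(names(a), names(b))
  m <- matrix(0, nrow = 2, ncol = length(otus), dimnames = list(c("A", "B"), otus))
  m["A", names(a)] <- a
  m["B", names(b)] <- b
  bp <- branch_profiles(tree, m)
  unifrac_from_profiles(bp, 1L, 2L, weighted, normalized)
}

unifrac_from_profiles <- function(bp, i, j, weighted, normalized) {
  b <- bp$lengths
  if (weighted) {
    raw <- sum(b * abs(bp$prop[, i] - bp$prop[, j]))
    if (!normalized) return(raw)
    denom <- sum(b * (bp$prop[, i] + bp$prop[, j]))
    if (denom == 0) stop_("no branch spanned by either profile")
    return(raw / denom)
  }
  pa <- bp$present[, i]
  pb <- bp$present[, j]
  unique_len <- sum(b[xor(pa, pb)])
  if (!normalized) return(unique_len)
  union_len <- sum(b[pa | pb])
  if (union_len == 0) stop_("no branch spanned by either profile")
  unique_len / union_len
}

#' Pairwise distance matrix over the samples of an OTU table
#'
#' @param otu samples-by-OTUs count matrix (>= 2 samples).
#' @param tree rooted phylogeny (required for UniFrac metrics).
#' @param metric one of \code{"unweighted_unifrac"},
#'   \code{"unweighted_unifrac_raw"}, \code{"weighted_unifrac"} (raw),
#'   \code{"weighted_unifrac_normalized"}.
#' @return Square symmetric labelled matrix with zero diagonal.
#' @export
distance_matrix <- function(otu, tree = NULL,
                            metric = c("weighted_unifrac", "weighted_unifrac_normalized",
                                       "unweighted_unifrac", "unweighted_unifrac_raw")) {
  supported <- c("weighted_unifrac", "weighted_unifrac_normalized",
                 "unweighted_unifrac", "unweighted_unifrac_raw")
  if (!is.character(metric) || !metric[1] %in% supported) {
    stop_("unknown metric '%s'; supported: %s", metric[1], paste(supported, collapse = ", "))
  }
  metric <- metric[1]
  if (nrow(otu) < 2) stop_("need >= 2 samples for a distance matrix")
  if (is.null(tree)) stop_("UniFrac metrics require a phylogeny")
  weighted <- startsWith(metric, "weighted")
  normalized <- if (weighted) endsWith(metric, "normalized") else metric == "unweighted_unifrac"
  bp <- branch_profiles(tree, otu)
  n <- nrow(otu)
  d <- matrix(0, n, n, dimnames = list(rownames(otu), rownames(otu)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- unifrac_from_profiles(bp, i, j, weighted, normalized)
    }
  }
  d
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric scaling: the squared distances are double-centred
#' (Gower) and eigendecomposed; axes are ordered by descending eigenvalue.
#' Axes with non-positive eigenvalues (which arise for non-Euclidean
#' dissimilarities such as UniFrac) are reported through their eigenvalues
#' but dropped from the coordinates; no Cailliez/Lingoes correction is
#' applied. The sign of each axis is fixed by making its largest-magnitude
#' coordinate positive.
#'
#' @param dm square symmetric distance matrix with zero diagonal.
#' @return List with \code{coordinates} (samples x retained axes, columns
#'   \code{PC1}, \code{PC2}, ...), \code{eigenvalues} (all, descending) and
#'   \code{relative_eig} (eigenvalues over the sum of positive ones).
#' @export
pcoa <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) != ncol(dm) || max(abs(dm - t(dm))) > 1e-9) {
    stop_("distance matrix must be square and symmetric")
  }
  n <- nrow(dm)
  fit <- suppressWarnings(cmdscale(as.dist(dm), k = n - 1, eig = TRUE))
  ev <- fit$eig
  tol <- max(abs(ev)) * 1e-9
  npos <- sum(ev > tol)
  coords <- fit$points[, seq_len(npos), drop = FALSE]
  if (npos > 0) {
    for (k in seq_len(npos)) {
      if (coords[which.max(abs(coords[, k])), k] < 0) coords[, k] <- -coords[, k]
    }
    colnames(coords) <- paste0("PC", seq_len(npos))
  }
  rownames(coords) <- rownames(dm)
  list(coordinates = coords,
       eigenvalues = ev,
       relative_eig = if (npos > 0) ev / sum(ev[ev > tol]) else ev)
}
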