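#' Rarefy a single community profile to a fixed depth
#'
#' Randomly subsamples reads without replacement so the sample totals
#' exactly \code{depth} counts, equalizing sequencing effort before
#' diversity comparisons. OTUs drawn down to zero are retained with count 0
#' so the OTU universe is unchanged. A single draw is made; given the same
#' seed the result is reproducible.
#'
#' @param counts named non-negative integer vector (OTU id -> count).
#' @param depth target total count (e.g. 2200, a typical minimum sample
#'   depth).
#' @param seed integer seed; \code{NULL} uses the current RNG stream.
#' @return Named integer vector with the same names, summing to
#'   \code{depth}.
#' @export
rarefy <- function(counts, depth, seed = NULL) {
  if (is.null(names(counts))) stop_("counts must be a named vector of OTU counts")
  if (any(counts < 0)) stop_("negative counts")
  if (depth <= 0) stop_("rarefaction depth must be positive")
  if (sum(counts) < depth) {
    stop_("sample below rarefaction depth (total %d < depth %d)",
          as.integer(sum(counts)), as.integer(depth))
  }
  m <- matrix(as.integer(counts), nrow = 1, dimnames = list("s", names(counts)))
  r <- with_seed(seed, suppressWarnings(vegan::rrarefy(m, as.integer(depth))))
  setNames(as.integer(r[1, ]), names(counts))
}

#' Rarefy every row of an OTU table
#'
#' Applies [rarefy()] to each sample (row) of a samples-by-OTUs count
#' matrix. Samples whose total is below the depth are dropped with a
#' warning naming them, mirroring the standard practice of excluding
#' under-sequenced samples.
#'
#' @param otu samples-by-OTUs integer matrix with dimnames.
#' @param depth rarefaction depth.
#' @param seed integer seed governing all draws.
#' @return Rarefied matrix (possibly fewer rows).
#' @export
rarefy_table <- function(otu, depth, seed = NULL) {
  totals <- rowSums(otu)
  low <- totals < depth
  if (any(low)) {
    warning(sprintf("dropping %d sample(s) below rarefaction depth: %s",
                    sum(low), paste(rownames(otu)[low], collapse = ", ")))
    otu <- otu[!low, , drop = FALSE]
    if (nrow(otu) == 0) stop_("all samples below rarefaction depth")
  }
  r <- with_seed(seed, suppressWarnings(vegan::rrarefy(otu, as.integer(depth))))
  storage.mode(r) <- "integer"
  r
}

#' Remove dataset-wide singleton OTUs
#'
#' An OTU whose summed count across all samples equals one is treated as a
#' likely artifact and deleted from every sample. An OTU seen once in each
#' of two samples (total two) is retained.
#'
#' @param otu samples-by-OTUs count matrix.
#' @return Matrix without singleton OTU columns.
#' @export
remove_singletons <- function(otu) {
  otu[, colSums(otu) != 1, drop = FALSE]
}

#' Observed species richness
#'
#' Number of OTUs with a positive count.
#'
#' @param counts named count vector for one sample.
#' @return Integer richness; 0 with a warning for an all-zero sample.
#' @export
observed_species <- function(counts) {
  if (any(counts < 0)) stop_("negative counts")
  if (sum(counts) == 0) {
    warning("all-zero sample: observed species is 0")
    return(0L)
  }
  as.integer(vegan::specnumber(counts))
}

#' Simpson's reciprocal diversity index
#'
#' Evenness measure \eqn{1 / \sum_i p_i^2} with \eqn{p_i} the relative
#' abundance of OTU i; equals the number of categories when all are equally
#' abundant. Plug-in form (no small-sample correction).
#'
#' @param counts named count vector with positive total.
#' @return The index (>= 1).
#' @export
simpson_reciprocal <- function(counts) {
  if (sum(counts) <= 0) stop_("Simpson's reciprocal undefined for zero total count")
  as.numeric(vegan::diversity(counts, index = "invsimpson"))
}

#' Faith's phylogenetic diversity
#'
#' Total branch length of the minimal subtree connecting all OTUs observed
#' in the sample and the root of the phylogeny (root-inclusive convention),
#' so a single-taxon sample has PD equal to its root-to-tip path length.
#'
#' @param counts named count vector; OTUs with positive count are "observed".
#' @param tree rooted \code{ape::phylo} with branch lengths whose tip labels
#'   cover all observed OTUs.
#' @return Faith's PD in branch-length units.
#' @export
faith_pd <- function(counts, tree) {
  present <- names(counts)[counts > 0]
  if (length(present) == 0) stop_("no observed OTUs in sample")
  miss <- setdiff(present, tree$tip.label)
  if (length(miss)) stop_("OTU(s) not in tree: %s", paste(miss, collapse = ", "))
  samp <- matrix(0L, nrow = 1, ncol = length(tree$tip.label),
                 dimnames = list("s", tree$tip.label))
  samp[1, present] <- 1L
  as.numeric(picante::pd(samp, tree, include.root = TRUE)$PD)
}

#' Alpha-diversity table for an OTU table
#'
#' Computes observed species, Simpson's reciprocal index and (when a tree
#' is supplied) Faith's PD for each sample of a (typically rarefied) OTU
#' table.
#'
#' @param otu samples-by-OTUs count matrix.
#' @param tree optional rooted phylogeny for Faith's PD.
#' @return Data frame with one row per sample.
#' @export
alpha_diversity <- function(otu, tree = NULL) {
  out <- data.frame(
    sample_id = rownames(otu),
    observed_species = apply(otu, 1, observed_species),
    simpson_reciprocal = apply(otu, 1, simpson_reciprocal))
  if (!is.null(tree)) {
    out$faith_pd <- apply(otu, 1, faith_pd, tree = tree)
  }
  rownames(out) <- NULL
  out
}
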