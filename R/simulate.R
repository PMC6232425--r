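#' Default response-variable set of the microcosm design
#'
#' Twenty-six variables covering N-cycle process rates (potential
#' nitrification and denitrification, potential N2O emissions and the N2O
#' emission ratio), mineral and total N pools, gene-copy abundances of the
#' total community and N-cycle guilds (with their 16S-normalized ratios),
#' and alpha-diversity indices. Gene-copy abundances are generated on the
#' raw copy scale and flagged for log10 transformation, where their
#' residuals are approximately normal.
#'
#' @return Data frame with columns \code{name}, \code{baseline_mean},
#'   \code{baseline_sd} (on the analysis scale) and \code{transform}.
#' @export
default_variables <- function() {
  v <- rbind(
    data.frame(name = "PNA",                baseline_mean = 1.2,  baseline_sd = 0.25, transform = "none"),
    data.frame(name = "PDA",                baseline_mean = 2.5,  baseline_sd = 0.50, transform = "none"),
    data.frame(name = "pN2O",               baseline_mean = 0.8,  baseline_sd = 0.20, transform = "none"),
    data.frame(name = "N2O_ratio",          baseline_mean = 0.30, baseline_sd = 0.06, transform = "none"),
    data.frame(name = "NH4",                baseline_mean = 5.0,  baseline_sd = 1.0,  transform = "none"),
    data.frame(name = "NO3",                baseline_mean = 20.0, baseline_sd = 4.0,  transform = "none"),
    data.frame(name = "total_N",            baseline_mean = 2.0,  baseline_sd = 0.30, transform = "none"),
    data.frame(name = "q16S",               baseline_mean = 5.5,  baseline_sd = 0.20, transform = "log10"),
    data.frame(name = "qAOA",               baseline_mean = 3.8,  baseline_sd = 0.25, transform = "log10"),
    data.frame(name = "qAOB",               baseline_mean = 3.2,  baseline_sd = 0.25, transform = "log10"),
    data.frame(name = "qnirK",              baseline_mean = 4.2,  baseline_sd = 0.20, transform = "log10"),
    data.frame(name = "qnirS",              baseline_mean = 4.0,  baseline_sd = 0.20, transform = "log10"),
    data.frame(name = "qnosZI",             baseline_mean = 4.1,  baseline_sd = 0.20, transform = "log10"),
    data.frame(name = "qnosZII",            baseline_mean = 3.6,  baseline_sd = 0.25, transform = "log10"),
    data.frame(name = "qAOA_16S",           baseline_mean = 0.020, baseline_sd = 0.004, transform = "none"),
    data.frame(name = "qAOB_16S",           baseline_mean = 0.005, baseline_sd = 0.001, transform = "none"),
    data.frame(name = "qnirK_16S",          baseline_mean = 0.050, baseline_sd = 0.010, transform = "none"),
    data.frame(name = "qnirS_16S",          baseline_mean = 0.032, baseline_sd = 0.007, transform = "none"),
    data.frame(name = "qnosZI_16S",         baseline_mean = 0.040, baseline_sd = 0.008, transform = "none"),
    data.frame(name = "qnosZII_16S",        baseline_mean = 0.013, baseline_sd = 0.003, transform = "none"),
    data.frame(name = "AOA_AOB_ratio",      baseline_mean = 4.0,  baseline_sd = 0.8,  transform = "none"),
    data.frame(name = "nirK_nirS_ratio",    baseline_mean = 1.6,  baseline_sd = 0.3,  transform = "none"),
    data.frame(name = "nosZI_nosZII_ratio", baseline_mean = 3.2,  baseline_sd = 0.6,  transform = "none"),
    data.frame(name = "observed_species",   baseline_mean = 1500, baseline_sd = 150,  transform = "none"),
    data.frame(name = "faith_pd",           baseline_mean = 80,   baseline_sd = 8,    transform = "none"),
    data.frame(name = "simpson_reciprocal", baseline_mean = 120,  baseline_sd = 15,   transform = "none"))
  rownames(v) <- NULL
  v
}

#' Describe a replicated disturbance-microcosm experiment
#'
#' The default mirrors a compounded-disturbance design: one undisturbed
#' control, three repeated single-disturbance treatments (freeze-thaw F,
#' heat H, anoxia A) and the six orderings of the three disturbances
#' (chronology treatments), with four replicate microcosms destructively
#' sampled at five timepoints T0-T4.
#'
#' @param treatments treatment labels; must include \code{control}.
#' @param control label of the undisturbed control.
#' @param timepoints ordered timepoint labels.
#' @param n_replicates replicate microcosms per treatment and timepoint
#'   (>= 2).
#' @param variables variable table as in [default_variables()].
#' @return An \code{experiment_design} list.
#' @export
experiment_design <- function(treatments = c("control", "F", "H", "A",
                                             "FHA", "FAH", "HFA", "HAF", "AFH", "AHF"),
                              control = "control",
                              timepoints = paste0("T", 0:4),
                              n_replicates = 4,
                              variables = default_variables()) {
  if (!control %in% treatments) stop_("control '%s' not among treatments", control)
  if (n_replicates < 2) stop_("need n_replicates >= 2")
  if (any(variables$baseline_sd <= 0)) stop_("baseline_sd must be positive")
  if (anyDuplicated(variables$name)) stop_("duplicated variable names")
  structure(list(treatments = treatments, control = control,
                 timepoints = timepoints, n_replicates = as.integer(n_replicates),
                 variables = variables),
            class = "experiment_design")
}

#' Declare true standardized effects for a simulation
#'
#' Builds the (treatment, timepoint, variable) -> delta table consumed by
#' [simulate_measurements()]; unlisted cells have delta = 0. Treated
#' values are drawn with mean shifted by \code{delta} baseline standard
#' deviations, so delta is the true Hedges'-g-scale effect.
#'
#' @param design an [experiment_design()].
#' @param treatments,timepoints,variables cells to set; \code{NULL} means
#'   all non-control treatments, all timepoints after the first, or all
#'   variables respectively.
#' @param delta true standardized effect (recycled).
#' @return Data frame with columns \code{treatment}, \code{timepoint},
#'   \code{variable}, \code{delta}.
#' @export
effect_spec <- function(design, treatments = NULL, timepoints = NULL,
                        variables = NULL, delta) {
  if (is.null(treatments)) treatments <- setdiff(design$treatments, design$control)
  if (is.null(timepoints)) {
    timepoints <- if (length(design$timepoints) > 1) design$timepoints[-1] else design$timepoints
  }
  if (is.null(variables)) variables <- design$variables$name
  if (design$control %in% treatments) stop_("control cannot carry an effect")
  g <- expand.grid(treatment = treatments, timepoint = timepoints,
                   variable = variables, stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  g$delta <- rep_len(delta, nrow(g))
  g
}

#' Simulate replicate-level measurements for a design
#'
#' Control replicates are drawn i.i.d. Normal(baseline_mean, baseline_sd)
#' on the analysis scale of each variable; treated replicates from
#' Normal(baseline_mean + delta * baseline_sd, baseline_sd). Variables
#' flagged \code{log10} are emitted as \code{10^x} so the raw table looks
#' like gene-copy data and the analysis must transform it back.
#'
#' @param design an [experiment_design()].
#' @param effects effect table from [effect_spec()] (or several
#'   \code{rbind}-ed ones); \code{NULL} means no effects anywhere.
#' @param seed integer seed; the table is a pure function of
#'   (design, effects, seed).
#' @return Long-format measurement data frame (see [read_measurements()]).
#' @export
simulate_measurements <- function(design, effects = NULL, seed = NULL) {
  stopifnot(inherits(design, "experiment_design"))
  if (!is.null(effects) && nrow(effects) > 0) {
    bad <- setdiff(effects$variable, design$variables$name)
    if (length(bad)) stop_("effects reference unknown variable(s): %s", paste(bad, collapse = ", "))
    key <- function(tr, tp, v) paste(tr, tp, v, sep = "\r")
    delta_map <- setNames(effects$delta, key(effects$treatment, effects$timepoint, effects$variable))
  } else delta_map <- character(0)

  with_seed(seed, {
    rows <- list()
    k <- 0L
    n <- design$n_replicates
    for (tr in design$treatments) {
      for (tp in design$timepoints) {
        for (i in seq_len(nrow(design$variables))) {
          v <- design$variables[i, ]
          delta <- 0
          if (tr != design$control && length(delta_map)) {
            d <- delta_map[paste(tr, tp, v$name, sep = "\r")]
            if (!is.na(d)) delta <- as.numeric(d)
          }
          x <- rnorm(n, mean = v$baseline_mean + delta * v$baseline_sd, sd = v$baseline_sd)
          if (v$transform == "log10") x <- 10^x
          k <- k + 1L
          rows[[k]] <- data.frame(
            sample_id = paste(tr, tp, seq_len(n), sep = "_"),
            treatment = tr, timepoint = tp, replicate = seq_len(n),
            variable = v$name, value = x)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out[, c("sample_id", "treatment", "timepoint", "replicate", "variable", "value")]
  })
}

#' Random rooted bifurcating phylogeny with OTU tip labels
#'
#' Topology by successive random joins, branch lengths i.i.d.
#' Exponential with mean 0.1; tips are labelled \code{OTU_1} ...
#' \code{OTU_n}.
#'
#' @param n_leaves number of tips (>= 2).
#' @param seed integer seed.
#' @return An \code{ape::phylo} tree.
#' @export
random_tree <- function(n_leaves, seed = NULL) {
  if (n_leaves < 2) stop_("need n_leaves >= 2")
  tr <- with_seed(seed, ape::rtree(n_leaves, rooted = TRUE,
                                   br = function(k) rexp(k, rate = 10)))
  tr$tip.label <- paste0("OTU_", seq_len(n_leaves))
  tr
}

#' Community-simulation settings
#'
#' Dirichlet-multinomial sampling scheme: each sample's OTU proportions
#' are a Dirichlet draw around shared base alphas (log-normally dispersed
#' across OTUs, total concentration \code{concentration}) and its depth is
#' uniform over \code{depth_range}. A shift entry multiplies the alphas of
#' a treatment-specific random subset of OTUs (a fraction of the
#' community) by \code{10^log_fold} at the given treatment and timepoint,
#' creating the composition displacement that UniFrac/PERMANOVA should
#' detect.
#'
#' @param n_otus number of OTUs (tree tips).
#' @param tree_seed seed for the tree and base alphas.
#' @param concentration total Dirichlet concentration (smaller = more
#'   overdispersed replicates).
#' @param depth_range integer (min, max) sequencing depth per sample;
#'   keep min at or above the rarefaction depth.
#' @param shifts data frame with columns \code{treatment},
#'   \code{timepoint}, \code{fraction}, \code{log_fold}; \code{NULL} for
#'   no composition shifts.
#' @return A \code{community_spec} list with the realized base alphas.
#' @export
community_spec <- function(n_otus = 300, tree_seed = 1, concentration = 50,
                           depth_range = c(2500, 6000), shifts = NULL) {
  if (n_otus < 2) stop_("need n_otus >= 2")
  if (depth_range[1] > depth_range[2] || depth_range[1] < 1) stop_("invalid depth_range")
  if (!is.null(shifts)) {
    req <- c("treatment", "timepoint", "fraction", "log_fold")
    if (!all(req %in% names(shifts))) stop_("shifts need columns %s", paste(req, collapse = ", "))
    if (any(shifts$fraction < 0 | shifts$fraction > 1)) stop_("shift fractions must be in [0, 1]")
  }
  alpha <- with_seed(tree_seed, {
    a <- rlnorm(n_otus, meanlog = 0, sdlog = 1)
    a / sum(a) * concentration
  })
  structure(list(n_otus = as.integer(n_otus), tree_seed = tree_seed,
                 base_alpha = setNames(alpha, paste0("OTU_", seq_len(n_otus))),
                 depth_range = as.integer(depth_range), shifts = shifts),
            class = "community_spec")
}

#' Simulate OTU tables with treatment-dependent composition shifts
#'
#' @param design an [experiment_design()] (treatments, timepoints,
#'   replicates define the sample set).
#' @param spec a [community_spec()].
#' @param seed integer seed; output is a pure function of
#'   (design, spec, seed).
#' @return List with \code{otu} (samples-by-OTUs integer matrix),
#'   \code{tree} (rooted phylogeny over the OTUs) and \code{metadata}
#'   (sample_id, treatment, timepoint, replicate).
#' @export
simulate_communities <- function(design, spec, seed = NULL) {
  stopifnot(inherits(design, "experiment_design"), inherits(spec, "community_spec"))
  tree <- random_tree(spec$n_otus, seed = spec$tree_seed)
  shift_key <- if (!is.null(spec$shifts)) {
    paste(spec$shifts$treatment, spec$shifts$timepoint, sep = "\r")
  } else character(0)

  with_seed(seed, {
    # one fixed random OTU ordering per treatment: a shift of fraction f
    # affects the first round(f * n) OTUs of that ordering, so nested
    # fractions are coherent across timepoints
    perms <- lapply(design$treatments, function(tr) sample.int(spec$n_otus))
    names(perms) <- design$treatments

    meta <- expand.grid(replicate = seq_len(design$n_replicates),
                        timepoint = design$timepoints,
                        treatment = design$treatments,
                        stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    meta <- meta[, c("treatment", "timepoint", "replicate")]
    meta$sample_id <- paste(meta$treatment, meta$timepoint, meta$replicate, sep = "_")

    otu <- matrix(0L, nrow = nrow(meta), ncol = spec$n_otus,
                  dimnames = list(meta$sample_id, names(spec$base_alpha)))
    for (s in seq_len(nrow(meta))) {
      alpha <- spec$base_alpha
      hit <- which(shift_key == paste(meta$treatment[s], meta$timepoint[s], sep = "\r"))
      if (length(hit)) {
        sh <- spec$shifts[hit[1], ]
        n_aff <- round(sh$fraction * spec$n_otus)
        if (n_aff > 0) {
          aff <- perms[[meta$treatment[s]]][seq_len(n_aff)]
          alpha[aff] <- alpha[aff] * 10^sh$log_fold
        }
      }
      depth <- sample(seq(spec$depth_range[1], spec$depth_range[2]), 1)
      p <- rgamma(spec$n_otus, shape = alpha, rate = 1)
      p <- p / sum(p)
      otu[s, ] <- as.integer(rmultinom(1, size = depth, prob = p))
    }
    list(otu = otu, tree = tree,
         metadata = meta[, c("sample_id", "treatment", "timepoint", "replicate")])
  })
}
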