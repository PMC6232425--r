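#' Read and normalize a run configuration
#'
#' YAML file describing either a simulation scenario or input files, plus
#' the analysis settings: control label, variable set, transforms,
#' rarefaction depth, UniFrac variant, permutation count, variance
#' partition predictors and seeds. Missing keys fall back to the defaults
#' documented in [run_pipeline()].
#'
#' @param path YAML file.
#' @return A named list of settings.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$mode)) cfg$mode <- if (!is.null(cfg$ingest)) "ingest" else "simulate"
  if (!cfg$mode %in% c("simulate", "ingest")) stop_("unknown mode '%s'", cfg$mode)
  if (is.null(cfg$control)) cfg$control <- "control"
  if (is.null(cfg$rarefaction_depth)) cfg$rarefaction_depth <- 2200
  if (is.null(cfg$unifrac)) cfg$unifrac <- "weighted_unifrac"
  if (is.null(cfg$permutations)) cfg$permutations <- 999
  if (is.null(cfg$seed)) cfg$seed <- 1
  if (cfg$mode == "ingest") {
    for (f in c("measurements", "otu_table", "tree")) {
      p <- cfg$ingest[[f]]
      if (!is.null(p) && !file.exists(p)) stop_("ingest path for '%s' not found: %s", f, p)
    }
  }
  cfg
}

#' Bundled configuration mirroring the study design
#'
#' A ready-to-run simulation scenario: control plus F/H/A repeated
#' disturbances and the six chronology treatments, 4 replicates, T0-T4,
#' the 26 default variables, 300 OTUs, composition shifts and planted
#' effect sizes that grow along the chronology treatments.
#'
#' @return Path to the installed YAML file.
#' @export
paper_like_config <- function() {
  system.file("extdata", "paper_like.yaml", package = "eaimpact", mustWork = TRUE)
}

build_design_from_config <- function(cfg) {
  sim <- cfg$simulate
  vars <- if (!is.null(sim$variables)) {
    do.call(rbind, lapply(sim$variables, as.data.frame))
  } else default_variables()
  experiment_design(
    treatments = if (!is.null(sim$treatments)) unlist(sim$treatments) else
      c("control", "F", "H", "A", "FHA", "FAH", "HFA", "HAF", "AFH", "AHF"),
    control = cfg$control,
    timepoints = if (!is.null(sim$timepoints)) unlist(sim$timepoints) else paste0("T", 0:4),
    n_replicates = if (!is.null(sim$n_replicates)) sim$n_replicates else 4,
    variables = vars)
}

effects_from_config <- function(cfg, design) {
  if (is.null(cfg$simulate$effects)) return(NULL)
  do.call(rbind, lapply(cfg$simulate$effects, function(e) {
    effect_spec(design,
                treatments = unlist(e$treatment),
                timepoints = if (is.null(e$timepoint)) NULL else unlist(e$timepoint),
                variables = if (is.null(e$variable)) NULL else unlist(e$variable),
                delta = e$delta)
  }))
}

shifts_from_config <- function(cfg) {
  if (is.null(cfg$simulate$shifts)) return(NULL)
  do.call(rbind, lapply(cfg$simulate$shifts, function(s) {
    tps <- if (is.null(s$timepoint)) stop_("shift entries need a timepoint") else unlist(s$timepoint)
    expand.grid(treatment = unlist(s$treatment), timepoint = tps,
                fraction = s$fraction, log_fold = s$log_fold,
                stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  }))
}

#' Run the full analysis pipeline and write a report bundle
#'
#' Stages, each writing tab-separated artifacts into \code{out_dir}:
#' \enumerate{
#'   \item data: simulate (per the config scenario) or ingest
#'     measurements, OTU table and tree;
#'   \item effect sizes: per-variable Hedges' g against the control at
#'     the post-baseline timepoints (\code{effect_sizes.tsv});
#'   \item EAI: aggregated index with CI-overlap letters per timepoint
#'     (\code{eai.tsv});
#'   \item univariate: per-timepoint ANOVA and Tukey HSD for every
#'     variable (\code{anova.tsv}, \code{tukey.tsv});
#'   \item community: singleton removal, rarefaction
#'     (\code{otu_rarefied.tsv}), alpha diversity
#'     (\code{alpha_diversity.tsv}), UniFrac distance matrices
#'     (\code{distance_*.tsv}), PCoA (\code{pcoa_*.tsv}) and per-timepoint
#'     pairwise PERMANOVA against all groups
#'     (\code{pairwise_permanova.tsv});
#'   \item variance partition of the per-cell EAI on configured
#'     predictors (\code{variance_partition.tsv});
#'   \item manifest: \code{manifest.json} echoing the configuration,
#'     seeds, package version and per-stage status.
#' }
#' All randomness derives from the configured seed, so a rerun with the
#' same configuration reproduces the bundle exactly.
#'
#' @param config path to a YAML configuration or a list from
#'   [read_run_config()].
#' @param out_dir output directory (created if needed).
#' @param seed optional override of the configured seed.
#' @param continue_on_error keep running later stages when one fails;
#'   failures are recorded in the manifest.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, continue_on_error = FALSE) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  outputs <- character(0)
  note <- function(name, status, error = NULL) {
    stages[[length(stages) + 1]] <<- list(stage = name, status = status,
                                          error = if (is.null(error)) NULL else conditionMessage(error))
  }
  run_stage <- function(name, fun) {
    res <- tryCatch({ out <- fun(); note(name, "ok"); out },
                    error = function(e) {
                      note(name, "failed", e)
                      if (!continue_on_error) {
                        write_manifest()
                        stop_("stage '%s' failed: %s", name, conditionMessage(e))
                      }
                      NULL
                    })
    res
  }
  write_manifest <- function() {
    manifest <- list(package = "eaimpact",
                     version = as.character(packageVersion("eaimpact")),
                     seed = cfg$seed, config = cfg,
                     stages = stages, outputs = outputs)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
    manifest
  }
  emit <- function(path) outputs <<- c(outputs, basename(path))

  # --- data -----------------------------------------------------------
  design <- NULL
  data <- run_stage("data", function() {
    if (cfg$mode == "simulate") {
      design <<- build_design_from_config(cfg)
      meas <- simulate_measurements(design, effects_from_config(cfg, design),
                                    seed = cfg$seed)
      sim <- cfg$simulate
      comm <- NULL
      if (is.null(sim$communities) || isTRUE(sim$communities)) {
        spec <- community_spec(
          n_otus = if (!is.null(sim$n_otus)) sim$n_otus else 300,
          tree_seed = cfg$seed + 1,
          depth_range = if (!is.null(sim$depth_range)) unlist(sim$depth_range) else c(2500, 6000),
          shifts = shifts_from_config(cfg))
        comm <- simulate_communities(design, spec, seed = cfg$seed + 2)
      }
      emit(write_measurements(meas, file.path(out_dir, "measurements.tsv")))
      if (!is.null(comm)) {
        emit(write_otu_table(comm$otu, file.path(out_dir, "otu_table.tsv")))
        ape::write.tree(comm$tree, file.path(out_dir, "tree.nwk"))
        emit(file.path(out_dir, "tree.nwk"))
      }
      list(measurements = meas, otu = comm$otu, tree = comm$tree,
           metadata = comm$metadata)
    } else {
      meas <- read_measurements(cfg$ingest$measurements)
      otu <- if (!is.null(cfg$ingest$otu_table)) read_otu_table(cfg$ingest$otu_table) else NULL
      tree <- if (!is.null(cfg$ingest$tree)) ape::read.tree(cfg$ingest$tree) else NULL
      meta <- unique(meas[, c("sample_id", "treatment", "timepoint", "replicate")])
      list(measurements = meas, otu = otu, tree = tree, metadata = meta)
    }
  })
  if (is.null(data)) { return(invisible(write_manifest())) }

  variables <- if (!is.null(cfg$variables)) unlist(cfg$variables) else
    sort(unique(data$measurements$variable))
  transforms <- if (!is.null(cfg$transforms)) unlist(cfg$transforms) else {
    if (cfg$mode == "simulate") setNames(design$variables$transform, design$variables$name)
    else NULL
  }
  all_tps <- sort(unique(data$measurements$timepoint))
  eai_tps <- if (!is.null(cfg$eai_timepoints)) unlist(cfg$eai_timepoints) else all_tps[-1]

  # --- effect sizes and EAI -------------------------------------------
  estimates <- run_stage("effect_sizes", function() {
    m <- data$measurements[data$measurements$timepoint %in% eai_tps, , drop = FALSE]
    es <- effect_size_table(m, control = cfg$control, variables = variables,
                            transforms = transforms)
    emit(write_effect_sizes(es, file.path(out_dir, "effect_sizes.tsv")))
    es
  })
  eai_tab <- if (!is.null(estimates)) run_stage("eai", function() {
    tab <- eai_table(estimates, variables = variables)
    emit(eai_report(tab, file.path(out_dir, "eai.tsv")))
    tab
  }) else NULL

  # --- univariate ANOVA / Tukey ---------------------------------------
  run_stage("univariate", function() {
    anova_rows <- list(); tukey_rows <- list()
    for (tp in all_tps) {
      for (v in variables) {
        sel <- data$measurements$timepoint == tp & data$measurements$variable == v
        d <- data$measurements[sel, , drop = FALSE]
        if (nrow(d) == 0) next
        x <- d$value
        if (!is.null(transforms) && v %in% names(transforms) &&
            transforms[[v]] == "log10") x <- log10(x)
        a <- one_way_anova(x, d$treatment)
        anova_rows[[length(anova_rows) + 1]] <-
          data.frame(timepoint = tp, variable = v, F = a$F,
                     df_between = a$df_between, df_within = a$df_within, p = a$p)
        tk <- tukey_hsd(x, d$treatment)
        tk <- cbind(data.frame(timepoint = tp, variable = v), tk)
        tukey_rows[[length(tukey_rows) + 1]] <- tk
      }
    }
    av <- do.call(rbind, anova_rows)
    av$p_adj_BH <- p.adjust(av$p, method = "BH")
    write.table(av, file.path(out_dir, "anova.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    emit(file.path(out_dir, "anova.tsv"))
    write.table(do.call(rbind, tukey_rows), file.path(out_dir, "tukey.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    emit(file.path(out_dir, "tukey.tsv"))
    NULL
  })

  # --- community composition ------------------------------------------
  dm_main <- NULL
  if (!is.null(data$otu)) {
    dm_main <- run_stage("community", function() {
      otu <- remove_singletons(data$otu)
      rar <- rarefy_table(otu, cfg$rarefaction_depth, seed = cfg$seed + 3)
      emit(write_otu_table(rar, file.path(out_dir, "otu_rarefied.tsv")))
      alpha <- alpha_diversity(rar, data$tree)
      write.table(alpha, file.path(out_dir, "alpha_diversity.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      emit(file.path(out_dir, "alpha_diversity.tsv"))

      metrics <- unique(c(cfg$unifrac, "unweighted_unifrac"))
      dms <- lapply(metrics, function(met) {
        dm <- distance_matrix(rar, data$tree, metric = met)
        emit(write_distance_matrix(dm, file.path(out_dir, paste0("distance_", met, ".tsv"))))
        emit(write_pcoa(pcoa(dm), file.path(out_dir, paste0("pcoa_", met, ".tsv"))))
        dm
      })
      dm <- dms[[1]]

      meta <- data$metadata[match(rownames(dm), data$metadata$sample_id), ]
      pp_rows <- list()
      for (tp in all_tps) {
        sel <- which(meta$timepoint == tp)
        if (length(sel) < 4) next
        pp <- pairwise_permanova(dm[sel, sel, drop = FALSE], meta$treatment[sel],
                                 n_permutations = cfg$permutations,
                                 seed = cfg$seed + 10 + match(tp, all_tps))
        pp_rows[[length(pp_rows) + 1]] <- cbind(data.frame(timepoint = tp), pp)
      }
      pp_tab <- do.call(rbind, pp_rows)
      write.table(pp_tab, file.path(out_dir, "pairwise_permanova.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      emit(file.path(out_dir, "pairwise_permanova.tsv"))
      dm
    })
  }

  # --- variance partition ---------------------------------------------
  if (!is.null(eai_tab)) {
    run_stage("variance_partition", function() {
      preds <- if (!is.null(cfg$varpart$predictors)) unlist(cfg$varpart$predictors) else {
        c(if (!is.null(dm_main)) cfg$unifrac,
          intersect(c("PNA", "qnosZI_16S", "qnosZII", "qnirK", "qnirK_16S",
                      "faith_pd", "simpson_reciprocal"), variables))
      }
      if (length(preds) == 0 || nrow(eai_tab) < length(preds) + 2) {
        stop_("variance partition needs predictors and enough EAI cells")
      }
      dat <- eai_predictors(eai_tab, estimates, dm = dm_main,
                            metadata = data$metadata, control = cfg$control,
                            predictors = preds)
      vp <- variance_partition(dat$response, dat$predictors)
      emit(write_variance_partition(vp, file.path(out_dir, "variance_partition.tsv")))
      NULL
    })
  }

  invisible(write_manifest())
}
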