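small_design <- function(n_rep = 4, n_var = 3) {
  experiment_design(treatments = c("control", "X", "Y"),
                    timepoints = c("T0", "T1"),
                    n_replicates = n_rep,
                    variables = default_variables()[seq_len(n_var), ])
}

test_that("generators are pure functions of their seed", {
  d <- small_design()
  eff <- effect_spec(d, treatments = "X", delta = 1)
  m1 <- simulate_measurements(d, eff, seed = 7)
  m2 <- simulate_measurements(d, eff, seed = 7)
  expect_identical(m1, m2)
  expect_false(identical(m1, simulate_measurements(d, eff, seed = 8)))

  t1 <- random_tree(12, seed = 5)
  t2 <- random_tree(12, seed = 5)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))

  spec <- community_spec(n_otus = 20, tree_seed = 3, depth_range = c(300, 500))
  c1 <- simulate_communities(d, spec, seed = 9)
  c2 <- simulate_communities(d, spec, seed = 9)
  expect_identical(c1$otu, c2$otu)
})

test_that("random trees have the right shape and labels", {
  t2 <- random_tree(2, seed = 1)
  expect_equal(length(t2$tip.label), 2)
  expect_equal(nrow(t2$edge), 2)
  expect_true(all(t2$edge.length > 0))
  t8 <- random_tree(8, seed = 2)
  expect_equal(nrow(t8$edge), 14)  # 2n - 2 edges for a rooted bifurcating tree
  expect_equal(sort(t8$tip.label), sort(paste0("OTU_", 1:8)))
  expect_true(ape::is.rooted(t8))
  expect_error(random_tree(1), "n_leaves")
})

test_that("planted effects are recovered at large replicate number", {
  d <- experiment_design(treatments = c("control", "X"), timepoints = "T1",
                         n_replicates = 50,
                         variables = default_variables()[1:2, ])
  eff <- effect_spec(d, treatments = "X", variables = "PNA", delta = 2)
  gs <- vapply(1:40, function(i) {
    m <- simulate_measurements(d, eff, seed = 100 + i)
    es <- effect_size_table(m, control = "control")
    es$g[es$variable == "PNA"]
  }, numeric(1))
  expect_gt(mean(gs), 1.9)
  expect_lt(mean(gs), 2.1)
})

test_that("log10-flagged variables are emitted on the raw scale", {
  d <- experiment_design(treatments = c("control", "X"), timepoints = "T1",
                         n_replicates = 4,
                         variables = default_variables()[8, , drop = FALSE])  # q16S
  m <- simulate_measurements(d, NULL, seed = 3)
  # baseline log10 mean 5.5: raw values are gene-copy sized
  expect_true(all(m$value > 1e4) && all(m$value < 1e7))
})

test_that("community totals stay inside depth_range and shifts move composition", {
  d <- small_design(n_rep = 4)
  spec <- community_spec(n_otus = 30, tree_seed = 11, depth_range = c(400, 600),
                         shifts = data.frame(treatment = "X", timepoint = "T1",
                                             fraction = 0.3, log_fold = 2))
  sim <- simulate_communities(d, spec, seed = 21)
  tot <- rowSums(sim$otu)
  expect_true(all(tot >= 400 & tot <= 600))
  expect_equal(dim(sim$otu), c(4 * 3 * 2, 30))
  expect_equal(sort(colnames(sim$otu)), sort(sim$tree$tip.label))

  # strongly shifted treatment is farther from control than control replicates
  # are from each other
  sel <- sim$metadata$timepoint == "T1" & sim$metadata$treatment %in% c("control", "X")
  otu <- sim$otu[sim$metadata$sample_id[sel], ]
  dm <- distance_matrix(otu, sim$tree, metric = "weighted_unifrac")
  meta <- sim$metadata[sel, ]
  ctl <- meta$sample_id[meta$treatment == "control"]
  trt <- meta$sample_id[meta$treatment == "X"]
  between <- mean(dm[trt, ctl])
  within <- mean(as.dist(dm[ctl, ctl]))
  expect_gt(between, within)
})

test_that("without composition shifts, between- and within-control distances match", {
  d <- experiment_design(treatments = c("control", "X"), timepoints = "T1",
                         n_replicates = 4,
                         variables = default_variables()[1, , drop = FALSE])
  spec <- community_spec(n_otus = 40, tree_seed = 13, depth_range = c(400, 600))
  ratios <- vapply(1:200, function(i) {
    sim <- simulate_communities(d, spec, seed = 3000 + i)
    dm <- distance_matrix(sim$otu, sim$tree, metric = "weighted_unifrac")
    meta <- sim$metadata
    ctl <- meta$sample_id[meta$treatment == "control"]
    trt <- meta$sample_id[meta$treatment == "X"]
    mean(dm[trt, ctl]) / mean(as.dist(dm[ctl, ctl]))
  }, numeric(1))
  expect_gt(mean(ratios), 0.8)
  expect_lt(mean(ratios), 1.2)
})

test_that("a strong composition shift is detected by pairwise PERMANOVA in >= 90% of runs", {
  d <- experiment_design(treatments = c("control", "X"), timepoints = "T1",
                         n_replicates = 4,
                         variables = default_variables()[1, , drop = FALSE])
  spec <- community_spec(n_otus = 40, tree_seed = 17, depth_range = c(400, 600),
                         shifts = data.frame(treatment = "X", timepoint = "T1",
                                             fraction = 0.3, log_fold = 2))
  rejected <- vapply(1:100, function(i) {
    sim <- simulate_communities(d, spec, seed = 8000 + i)
    dm <- distance_matrix(sim$otu, sim$tree, metric = "weighted_unifrac")
    pp <- pairwise_permanova(dm, sim$metadata$treatment, n_permutations = 199,
                             seed = i)
    pp$p[1] <= 0.05
  }, logical(1))
  expect_gte(mean(rejected), 0.9)
})

test_that("effect and design validation", {
  d <- small_design()
  expect_error(effect_spec(d, treatments = "control", delta = 1), "control")
  expect_error(simulate_measurements(d, data.frame(treatment = "X", timepoint = "T1",
                                                   variable = "nope", delta = 1),
                                     seed = 1), "unknown variable")
  expect_error(experiment_design(treatments = c("a", "b"), control = "c"), "control")
  expect_error(experiment_design(n_replicates = 1), "n_replicates")
  expect_error(community_spec(n_otus = 1), "n_otus")
  expect_error(community_spec(depth_range = c(50, 10)), "depth_range")
})
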