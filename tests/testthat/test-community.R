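test_that("rarefaction conserves depth exactly and is seed-deterministic", {
  counts <- c(OTU_1 = 500, OTU_2 = 1200, OTU_3 = 30, OTU_4 = 0, OTU_5 = 2000)
  r <- rarefy(counts, 800, seed = 5)
  expect_equal(sum(r), 800)
  expect_equal(names(r), names(counts))
  expect_equal(r, rarefy(counts, 800, seed = 5))
  expect_true(all(r <= counts))
  # a sample exactly at depth is unchanged
  expect_equal(rarefy(c(A = 2200), 2200, seed = 1), c(A = 2200L))
  expect_error(rarefy(c(A = 100), 2200, seed = 1), "below rarefaction depth")
})

test_that("rarefy_table drops under-sequenced samples with a warning", {
  otu <- rbind(s1 = c(A = 3000L, B = 500L), s2 = c(A = 10L, B = 5L))
  expect_warning(r <- rarefy_table(otu, 1000, seed = 2), "s2")
  expect_equal(rownames(r), "s1")
  expect_equal(unname(rowSums(r)), 1000)
})

test_that("per-OTU rarefied means follow the hypergeometric expectation", {
  counts <- c(A = 5000, B = 5000)
  draws <- vapply(1:300, function(i) rarefy(counts, 2200, seed = i)[["A"]], numeric(1))
  # hypergeometric: mean = n*K/N, var = n*(K/N)*(1-K/N)*(N-n)/(N-1)
  mu <- 2200 * 0.5
  v <- 2200 * 0.25 * (10000 - 2200) / (10000 - 1)
  expect_lt(abs(mean(draws) - mu), 3 * sqrt(v / length(draws)))
})

test_that("singletons are defined dataset-wide", {
  otu <- rbind(s1 = c(a = 1L, b = 1L, c = 5L, d = 0L),
               s2 = c(a = 0L, b = 1L, c = 2L, d = 0L))
  out <- remove_singletons(otu)
  expect_false("a" %in% colnames(out))  # total 1: removed everywhere
  expect_true("b" %in% colnames(out))   # 1 + 1 = 2: retained
  expect_true("d" %in% colnames(out))   # zero total is not a singleton
  none <- otu[, c("b", "c"), drop = FALSE]
  expect_identical(remove_singletons(none), none)
})

test_that("observed species counts positive OTUs; rarefaction only lowers it", {
  expect_equal(observed_species(c(A = 3, B = 0, C = 1)), 2L)
  expect_equal(observed_species(c(A = 1)), 1L)
  expect_warning(z <- observed_species(c(A = 0, B = 0)), "all-zero")
  expect_equal(z, 0L)
  set.seed(9)
  counts <- setNames(rpois(30, 40), paste0("OTU_", 1:30))
  expect_lte(observed_species(rarefy(counts, 100, seed = 3)), observed_species(counts))
})

test_that("Simpson's reciprocal equals k for k equal categories", {
  expect_equal(simpson_reciprocal(c(A = 50, B = 50)), 2.0)
  expect_equal(simpson_reciprocal(c(A = 100)), 1.0)
  expect_equal(simpson_reciprocal(c(A = 30, B = 30, C = 30)), 3.0)
  expect_error(simpson_reciprocal(c(A = 0)), "zero total")
})

test_that("faith_pd matches hand path-sums on the drawn tree", {
  tree <- ape::read.tree(text = "((A:1,B:2):0.5,C:3);")
  expect_equal(faith_pd(c(A = 5, C = 1), tree), 4.5)   # 1 + 0.5 + 3
  expect_equal(faith_pd(c(A = 5), tree), 1.5)          # leaf edge + edge to root
  expect_equal(faith_pd(c(A = 1, B = 1, C = 1), tree), sum(tree$edge.length))
  expect_error(faith_pd(c(Z = 1), tree), "Z")
})

test_that("alpha_diversity tabulates all samples with and without a tree", {
  tree <- random_tree(12, seed = 4)
  set.seed(10)
  otu <- rbind(s1 = setNames(rpois(12, 10), tree$tip.label),
               s2 = setNames(rpois(12, 10) + 1L, tree$tip.label))
  a <- alpha_diversity(otu, tree)
  expect_equal(a$sample_id, c("s1", "s2"))
  expect_named(a, c("sample_id", "observed_species", "simpson_reciprocal", "faith_pd"))
  expect_equal(a$faith_pd[2], faith_pd(otu["s2", ], tree))
  expect_false("faith_pd" %in% names(alpha_diversity(otu)))
})
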