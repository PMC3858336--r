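test_that("signal-to-noise follows the floored sd rule", {
  # constant gene: metric 0 despite zero sds
  m1 <- matrix(5, 1, 4, dimnames = list("g1", paste0("s", 1:4)))
  expect_equal(unname(signal_to_noise(m1, c("A", "A", "B", "B"))), 0)

  # hand-computed: A = (2, 2), B = (1, 1) -> floored sds 0.4, 0.2
  m2 <- matrix(c(2, 2, 1, 1), 1, 4, dimnames = list("g1", paste0("s", 1:4)))
  expect_equal(unname(signal_to_noise(m2, c("A", "A", "B", "B"))), 1 / 0.6)

  # antisymmetry under negation
  set.seed(2)
  m3 <- matrix(rnorm(10 * 6, 5), 10, 6,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  cls <- rep(c("A", "B"), each = 3)
  expect_equal(signal_to_noise(-m3, cls), -signal_to_noise(m3, cls))

  expect_error(signal_to_noise(m3, rep("A", 6)), "two classes")
  expect_error(signal_to_noise(m3[, 1:3], c("A", "A", "B")), ">= 2")
})

test_that("ranking is descending with stable ties", {
  metric <- c(g1 = 0.5, g2 = 2, g3 = 0.5, g4 = -1)
  r <- rank_genes(metric)
  expect_equal(r$ids, c("g2", "g1", "g3", "g4"))
  expect_true(all(diff(r$metric) <= 0))
})

test_that("a single top-ranked hit peaks the walk at 1", {
  metric <- c(g1 = 3, g2 = 2, g3 = 1, g4 = 0.5)
  res <- compute_es(rank_genes(metric), "g1", p_w = 1)
  expect_equal(res$ES, 1)
  expect_equal(res$hit_positions, 1L)
  expect_equal(res$running_sum[4], 0)
})

test_that("a single bottom-ranked hit with p_w = 0 gives the brute-force trough", {
  metric <- setNames(10:1, paste0("g", 1:10))
  ranked <- rank_genes(metric)
  res <- compute_es(ranked, "g10", p_w = 0)
  oracle <- oracle_es_walk(ranked$ids, ranked$metric, "g10", 0)
  expect_equal(res$ES, oracle$ES)
  expect_equal(res$ES, -(9 / 9) + 0)  # nine misses at -1/9 each, trough -1
})

test_that("ES equals an independent running-sum oracle on random instances", {
  set.seed(19)
  for (i in 1:100) {
    N <- sample(5:50, 1)
    metric <- setNames(rnorm(N), paste0("g", seq_len(N)))
    ranked <- rank_genes(metric)
    set <- sample(names(metric), sample(1:(N - 1), 1))
    p_w <- sample(c(0, 1, 2), 1)
    res <- compute_es(ranked, set, p_w)
    oracle <- oracle_es_walk(ranked$ids, ranked$metric, set, p_w)
    expect_equal(res$ES, oracle$ES, tolerance = 1e-12)
    expect_equal(res$running_sum, oracle$running_sum, tolerance = 1e-12)
    # conservation: the walk always returns to zero
    expect_equal(res$running_sum[N], 0, tolerance = 1e-12)
  }
})

test_that("with p_w = 0 the ES ignores monotone metric transforms", {
  set.seed(27)
  metric <- setNames(rnorm(30), paste0("g", 1:30))
  set <- sample(names(metric), 8)
  es1 <- compute_es(rank_genes(metric), set, p_w = 0)$ES
  es2 <- compute_es(rank_genes(metric * 100 + 5), set, p_w = 0)$ES
  es3 <- compute_es(rank_genes(sign(metric) * abs(metric)^3), set, p_w = 0)$ES
  expect_equal(es1, es2)
  expect_equal(es1, es3)
})

test_that("degenerate sets are rejected", {
  metric <- setNames(3:1, c("a", "b", "c"))
  ranked <- rank_genes(metric)
  expect_error(compute_es(ranked, "zzz"), "intersect")
  expect_error(compute_es(ranked, c("a", "b", "c")), "universe")
})

test_that("permutation machinery enumerates small designs and is seed-stable", {
  set.seed(55)
  m <- matrix(rnorm(60 * 8, 5), 60, 8,
              dimnames = list(paste0("g", 1:60), paste0("s", 1:8)))
  cls <- rep(c("A", "B"), each = 4)
  sets <- list(s1 = paste0("g", 1:20), s2 = paste0("g", 30:49))
  cfg <- permutation_config(n_permutations = 1000, min_size = 5, seed = 3)
  r1 <- permutation_significance(m, cls, sets, cfg)
  # C(8,4) = 70 distinct assignments < 1000: exhaustive enumeration
  expect_equal(attr(r1, "n_permutations_used"), 70)
  r2 <- permutation_significance(m, cls, sets, cfg)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  expect_true(all(r1$ES >= -1 & r1$ES <= 1))
  expect_true(all(r1$p_nominal >= 0 & r1$p_nominal <= 1, na.rm = TRUE))
  expect_true(all(r1$fdr_q >= 0 & r1$fdr_q <= 1, na.rm = TRUE))
  expect_true(all(r1$fwer_p >= 0 & r1$fwer_p <= 1))
})

test_that("sets outside the size limits are excluded, not fatal", {
  set.seed(56)
  m <- matrix(rnorm(50 * 12, 5), 50, 12,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:12)))
  cls <- rep(c("A", "B"), each = 6)
  sets <- list(tiny = "g1", ok = paste0("g", 1:20),
               alien = c("x1", "x2", "x3"))
  r <- permutation_significance(m, cls, sets,
                                permutation_config(n_permutations = 50,
                                                   min_size = 5, seed = 1))
  expect_equal(r$set, "ok")
  expect_setequal(attr(r, "excluded"), c("tiny", "alien"))
  expect_error(
    permutation_significance(m, cls, list(tiny = "g1"),
                             permutation_config(min_size = 5)),
    "size limits")
})

test_that("a planted coordinated set is called significant with positive NES", {
  cfg <- expr_sim_config(n_genes = 500, n_replicates = 6,
                         frac_activated = 0.06, frac_repressed = 0,
                         frac_kix_sensitive = 0, activation_log2fc = 1.5,
                         noise_sd = 0.2, seed = 8)
  e <- simulate_expression(cfg)
  wt <- e$samples$genotype == "WT"
  sub <- e$values[, wt]
  cls <- e$samples$treatment[wt]
  act <- e$truth$gene_id[e$truth$class == "activated"]  # 30 genes
  r <- permutation_significance(sub, cls, list(myb_act = act),
                                permutation_config(n_permutations = 500,
                                                   seed = 5),
                                positive_class = "myb")
  expect_gt(r$NES, 0)
  expect_lt(r$p_nominal, 0.01)
})

test_that("an empty permutation tail is displayed as below resolution", {
  set.seed(1)
  es_null <- matrix(c(runif(60, 0, 0.5), -runif(40, 0, 0.5)), nrow = 1)
  res <- hematrio:::summarize_permutations(0.9, es_null)
  expect_equal(res$p_nominal, 0)
  expect_match(res$p_nominal_label, "^<")
  res2 <- hematrio:::summarize_permutations(0.3, es_null)
  expect_gt(res2$p_nominal, 0)
  expect_no_match(res2$p_nominal_label, "^<")
})

test_that("a null comparison yields modest NES and non-degenerate q", {
  set.seed(91)
  m <- matrix(rnorm(200 * 12, 5), 200, 12,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:12)))
  cls <- rep(c("A", "B"), each = 6)
  sets <- lapply(1:5, function(i) sample(rownames(m), 25))
  names(sets) <- paste0("set", 1:5)
  r <- permutation_significance(m, cls, sets,
                                permutation_config(n_permutations = 300,
                                                   seed = 2))
  expect_true(all(abs(r$NES) < 2.5))
  expect_gt(mean(r$fdr_q, na.rm = TRUE), 0.05)
})

test_that("gene_set permutation mode also ranks a planted set first", {
  cfg <- expr_sim_config(n_genes = 300, n_replicates = 3,
                         frac_activated = 0.1, frac_repressed = 0,
                         frac_kix_sensitive = 0, noise_sd = 0.2, seed = 13)
  e <- simulate_expression(cfg)
  wt <- e$samples$genotype == "WT"
  act <- e$truth$gene_id[e$truth$class == "activated"]
  r <- permutation_significance(e$values[, wt], e$samples$treatment[wt],
                                list(act = act),
                                permutation_config(n_permutations = 200,
                                                   mode = "gene_set",
                                                   seed = 7),
                                positive_class = "myb")
  expect_gt(r$NES, 1)
  expect_lt(r$p_nominal, 0.05)
})
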