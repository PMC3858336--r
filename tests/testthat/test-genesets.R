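test_that("replicate averaging matches direct summation", {
  v <- matrix(c(4, 6), nrow = 1)
  e <- make_expr(cbind(v, v + 1, v + 2, v + 3),
                 genotypes = rep(c("WT", "WT", "KIX", "KIX"), each = 2),
                 treatments = rep(c("ctrl", "myb", "ctrl", "myb"), each = 2))
  m <- average_replicates(e)
  expect_equal(unname(m[1, "WT.ctrl"]), 5)

  set.seed(12)
  vals <- matrix(rnorm(20 * 6, 7), 20, 6)
  e2 <- make_expr(vals, genotypes = rep("WT", 6),
                  treatments = rep(c("ctrl", "myb"), each = 3))
  m2 <- average_replicates(e2)
  for (g in 1:20) {
    expect_equal(m2[g, "WT.ctrl"], sum(vals[g, 1:3]) / 3)
    expect_equal(m2[g, "WT.myb"], sum(vals[g, 4:6]) / 3)
  }
  expect_equal(unname(attr(m2, "n_replicates")), c(3L, 3L))

  # single replicate: condition mean is the replicate itself
  e3 <- make_expr(matrix(c(4.2, 5.5), 2, 1), "WT", "ctrl")
  expect_equal(unname(average_replicates(e3)[, 1]), c(4.2, 5.5))
})

test_that("linear-scale averaging differs from log-scale as documented", {
  vals <- matrix(c(2, 8), nrow = 1)  # log2 signals
  e <- make_expr(cbind(vals[, 1, drop = FALSE], vals[, 2, drop = FALSE]),
                 genotypes = c("WT", "WT"), treatments = c("ctrl", "ctrl"))
  expect_equal(unname(average_replicates(e)[1, 1]), 5)          # (2+8)/2
  expect_equal(unname(average_replicates(e, scale = "linear")[1, 1]),
               log2((2^2 + 2^8) / 2))
})

test_that("presence filter keeps the boundary and requires every condition", {
  m <- rbind(g1 = c(3.4, 5.0), g2 = c(3.3, 9.9), g3 = c(10, 2))
  colnames(m) <- c("WT.ctrl", "WT.myb")
  kept <- presence_filter(m, c("WT.ctrl", "WT.myb"), floor = 3.4)
  expect_equal(kept, "g1")
  expect_error(presence_filter(m, "nope"), "nope")

  set.seed(3)
  big <- matrix(runif(1000 * 2, 0, 8), 1000, 2,
                dimnames = list(sprintf("p%04d", 1:1000), c("a", "b")))
  kept2 <- presence_filter(big, c("a", "b"), floor = 3.4)
  brute <- rownames(big)[apply(big, 1, function(r) all(r >= 3.4))]
  expect_identical(kept2, brute)
})

test_that("fold-change classification is inclusive and matches enumeration", {
  m <- rbind(up_exact = c(3, 4), up_big = c(3, 6), down_exact = c(5, 4),
             flat = c(5, 5), down_big = c(8, 4))
  colnames(m) <- c("ctrl", "trt")
  sets <- classify_myb_response(m, "ctrl", "trt")
  expect_setequal(sets$activated, c("up_exact", "up_big"))   # ratio 2 kept
  expect_setequal(sets$repressed, c("down_exact", "down_big")) # ratio 0.5 kept
  expect_error(classify_myb_response(m, "ctrl", "ctrl"), "differ")

  # identical conditions: both sets empty
  m2 <- cbind(ctrl = c(a = 4, b = 7), trt = c(a = 4, b = 7))
  s2 <- classify_myb_response(m2, "ctrl", "trt")
  expect_length(s2$activated, 0)
  expect_length(s2$repressed, 0)
})

test_that("classification counts equal brute force on random matrices", {
  set.seed(21)
  for (i in 1:100) {
    n <- sample(20:200, 1)
    m <- matrix(rnorm(n * 4, 6, 2), n, 4,
                dimnames = list(sprintf("g%03d", 1:n),
                                c("c.ctrl", "c.trt", "w.trt", "k.trt")))
    pr <- filter_params(presence_floor = runif(1, 3, 6),
                        induce_ratio = runif(1, 1.2, 3),
                        repress_ratio = runif(1, 0.3, 0.8),
                        sensitivity_ratio = runif(1, 1, 2))
    kept <- presence_filter(m, c("c.ctrl", "c.trt"), pr$presence_floor)
    expect_identical(kept, rownames(m)[m[, "c.ctrl"] >= pr$presence_floor &
                                       m[, "c.trt"] >= pr$presence_floor])
    sets <- classify_myb_response(m, "c.ctrl", "c.trt", pr, genes = kept)
    ratio <- 2^(m[kept, "c.trt"] - m[kept, "c.ctrl"])
    expect_setequal(sets$activated, kept[ratio >= pr$induce_ratio])
    expect_setequal(sets$repressed, kept[ratio <= pr$repress_ratio])
    expect_length(intersect(sets$activated, sets$repressed), 0)

    gsr <- kix_sensitivity(sets, m, "w.trt", "k.trt", pr)
    rr <- 2^(m[, "w.trt"] - m[, "k.trt"])
    expect_setequal(gsr$kix_sensitive_activated,
                    sets$activated[rr[sets$activated] >= pr$sensitivity_ratio])
    expect_setequal(gsr$kix_sensitive_repressed,
                    sets$repressed[1 / rr[sets$repressed] >= pr$sensitivity_ratio])
    expect_true(all(gsr$kix_sensitive_activated %in% gsr$activated))
    expect_true(all(gsr$kix_sensitive_repressed %in% gsr$repressed))
  }
})

test_that("sensitivity boundary is inclusive and empty parents report NA", {
  m <- rbind(g1 = c(5, 5 - log2(1.5)), g2 = c(5, 5))
  colnames(m) <- c("wt", "mut")
  gsr <- kix_sensitivity(list(activated = c("g1", "g2"),
                              repressed = character()),
                         m, "wt", "mut")
  expect_equal(gsr$kix_sensitive_activated, "g1")   # ratio exactly 1.5 kept
  expect_equal(gsr$frac_sensitive_activated, 0.5)
  expect_true(is.na(gsr$frac_sensitive_repressed))
})

test_that("raising thresholds never grows a set; lowering the floor never shrinks", {
  set.seed(14)
  m <- matrix(rnorm(300 * 2, 6, 2), 300, 2,
              dimnames = list(sprintf("g%03d", 1:300), c("ctrl", "trt")))
  for (r in c(1.5, 2, 3, 5)) {
    a1 <- classify_myb_response(m, "ctrl", "trt",
                                filter_params(induce_ratio = r))$activated
    a2 <- classify_myb_response(m, "ctrl", "trt",
                                filter_params(induce_ratio = r + 0.5))$activated
    expect_true(all(a2 %in% a1))
  }
  for (f in c(3, 4, 5, 6)) {
    k1 <- presence_filter(m, c("ctrl", "trt"), f)
    k2 <- presence_filter(m, c("ctrl", "trt"), f - 0.5)
    expect_true(all(k1 %in% k2))
  }
})

test_that("planted truth is fully recovered without noise and degrades with it", {
  recov <- sapply(c(0, 0.3, 0.8), function(ns) {
    cfg <- expr_sim_config(n_genes = 2000, frac_activated = 0.1,
                           frac_repressed = 0.1, frac_kix_sensitive = 0.5,
                           noise_sd = ns, seed = 33)
    e <- simulate_expression(cfg)
    m <- average_replicates(e)
    sets <- classify_myb_response(m, "WT.ctrl", "WT.myb")
    truth_act <- e$truth$gene_id[e$truth$class == "activated"]
    mean(truth_act %in% sets$activated)
  })
  expect_equal(recov[1], 1)
  expect_true(all(diff(recov) <= 0))
  expect_lt(recov[3], 1)
})

test_that("high-noise-free recovery meets the planted-set standard at scale", {
  cfg <- expr_sim_config(n_genes = 5000, frac_activated = 0.1,
                         frac_repressed = 0.1, noise_sd = 0.3, seed = 4)
  e <- simulate_expression(cfg)
  m <- average_replicates(e)
  sets <- classify_myb_response(m, "WT.ctrl", "WT.myb")
  truth_act <- e$truth$gene_id[e$truth$class == "activated"]
  expect_gte(mean(truth_act %in% sets$activated), 0.95)
})

test_that("probe collapsing keeps the strongest probe with lexicographic ties", {
  vals <- matrix(c(5, 7, 7, 2), 4, 1,
                 dimnames = list(c("pB", "pA", "pC", "pD"), NULL))
  e <- make_expr(vals, "WT", "ctrl")
  p2g <- data.frame(probe_id = c("pB", "pA", "pC", "pD"),
                    gene_id = c("g1", "g1", "g1", "g2"))
  sel <- collapse_probes(e, p2g)
  expect_equal(unname(sel["g1"]), "pA")  # 7 beats 5; pA < pC
  expect_equal(unname(sel["g2"]), "pD")
})

test_that("direction concordance counts match pairwise enumeration", {
  a <- data.frame(gene_id = c("g1", "g2", "g3"),
                  direction = c("up", "down", "up"))
  expect_equal(direction_concordance(a, a)$n_same_direction, 3)
  b <- data.frame(gene_id = c("g4", "g5"), direction = c("up", "down"))
  expect_equal(direction_concordance(a, b)$n_overlap, 0)
  expect_equal(direction_concordance(a, b)$n_same_direction, 0)

  set.seed(6)
  universe <- sprintf("g%03d", 1:100)
  la <- data.frame(gene_id = sample(universe, 50),
                   direction = sample(c("up", "down"), 50, TRUE))
  lb <- data.frame(gene_id = sample(universe, 80),
                   direction = sample(c("up", "down"), 80, TRUE))
  res <- direction_concordance(la, lb)
  n_ov <- 0; n_same <- 0
  for (i in seq_len(nrow(la))) {
    j <- which(lb$gene_id == la$gene_id[i])
    if (length(j) == 1) {
      n_ov <- n_ov + 1
      if (lb$direction[j] == la$direction[i]) n_same <- n_same + 1
    }
  }
  expect_equal(res$n_overlap, n_ov)
  expect_equal(res$n_same_direction, n_same)
  expect_equal(res$frac_of_a, n_ov / 50)

  expect_error(direction_concordance(rbind(a, a), b), "once")
})

test_that("replicate-level t filter reproduces per-gene t-tests", {
  set.seed(44)
  vals <- rbind(matrix(rnorm(5 * 4, 5), 5, 4),
                cbind(matrix(rnorm(5 * 2, 5), 5, 2),
                      matrix(rnorm(5 * 2, 9), 5, 2)))
  e <- make_expr(vals, genotypes = rep("WT", 4),
                 treatments = rep(c("ctrl", "myb"), each = 2))
  res <- replicate_t_filter(e, "WT.ctrl", "WT.myb", p_threshold = 0.05)
  for (g in rownames(vals)) {
    expect_equal(res$p[[g]],
                 stats::t.test(e$values[g, 1:2], e$values[g, 3:4])$p.value)
  }
  expect_true(all(res$p[res$pass] < 0.05))
})
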