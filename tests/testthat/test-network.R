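test_that("PPMI matches closed forms and clips negatives to zero", {
  # perfectly co-occurring pair at p = 0.5: pmi = log2(0.5 / 0.25) = 1
  x <- rep(c(1L, 0L), 5000)
  m <- cbind(a = x, b = x, c = rep(c(0L, 1L), 5000))
  net <- compute_ppmi(m)
  expect_equal(net$weights["a", "b"], 1, tolerance = 1e-3)
  # a and c never co-occur: smoothing keeps pmi finite, clipping returns 0
  expect_equal(net$weights["a", "c"], 0)
  expect_true(all(net$weights >= 0))
  expect_equal(net$weights, t(net$weights))
  expect_true(all(diag(net$weights) == 0))
})

test_that("PPMI vanishes under independence", {
  set.seed(4)
  m <- cbind(a = rbinom(10000, 1, 0.5), b = rbinom(10000, 1, 0.3),
             c = rbinom(10000, 1, 0.6))
  net <- compute_ppmi(m)
  expect_lt(max(abs(net$weights)), 0.05)
})

test_that("Ising fit finds no edge between independent terms", {
  set.seed(5)
  m <- cbind(a = rbinom(500, 1, 0.4), b = rbinom(500, 1, 0.5),
             c = rbinom(500, 1, 0.3))
  net <- fit_ising(m)
  expect_true(all(net$weights == 0))
})

test_that("Ising fit recovers a strong pairwise coupling", {
  set.seed(6)
  a <- rbinom(500, 1, 0.5)
  b <- ifelse(runif(500) < 0.05, 1L - a, a)  # b = a with 5% flips
  m <- cbind(a = a, b = b, c = rbinom(500, 1, 0.4))
  net <- fit_ising(m)
  expect_gt(net$weights["a", "b"], 0)
  expect_equal(net$weights["a", "c"], 0)
})

test_that("planted two-cluster Ising model is recovered across seeds", {
  tc <- two_cluster_ising()
  metrics <- sapply(1:10, function(s) {
    set.seed(s)
    m <- sample_ising(1000, tc$J, tc$h)
    net <- fit_ising(m)
    true_edge <- tc$J != 0 & upper.tri(tc$J)
    est_edge <- net$weights != 0 & upper.tri(net$weights)
    part <- detect_communities(net)
    c(sens = sum(est_edge & true_edge) / sum(true_edge),
      fer = sum(est_edge & !true_edge) / sum(upper.tri(tc$J) & !true_edge),
      ari = adjusted_rand_index(part[colnames(tc$J)], tc$labels),
      signs_ok = all(sign(net$weights[est_edge & true_edge]) ==
                       sign(tc$J[est_edge & true_edge])))
  })
  expect_gte(mean(metrics["sens", ]), 0.8)
  expect_lte(mean(metrics["fer", ]), 0.1)
  expect_gte(mean(metrics["ari", ]), 0.7)
  expect_true(all(metrics["signs_ok", ] == 1))
})

test_that("AND-rule network is a subgraph of the OR-rule network", {
  tc <- two_cluster_ising(p_per = 3L, within = 0.8)
  set.seed(12)
  m <- sample_ising(400, tc$J, tc$h)
  net_and <- fit_ising(m, and_rule = TRUE)
  net_or <- fit_ising(m, and_rule = FALSE)
  expect_true(all(net_or$weights[net_and$weights != 0] != 0))
})

test_that("small or degenerate matrices are refused or repaired", {
  expect_error(fit_ising(matrix(0:1, 10, 4)), "too small")
  set.seed(8)
  m <- cbind(a = rbinom(100, 1, .5), b = rbinom(100, 1, .5),
             c = rbinom(100, 1, .5))
  m <- cbind(m, d = m[, "a"])  # perfect collinearity
  expect_warning(net <- fit_ising(m), "collinear")
  expect_false("d" %in% net$nodes)
})

test_that("walktrap communities match graph structure on cliques", {
  # two disconnected cliques -> exactly two communities
  W <- matrix(0, 6, 6, dimnames = list(sprintf("V%d", 1:6), sprintf("V%d", 1:6)))
  W[1:3, 1:3] <- 1; W[4:6, 4:6] <- 1; diag(W) <- 0
  net <- structure(list(nodes = rownames(W), weights = W, method = "ppmi",
                        n = 100L), class = "event_network")
  part <- detect_communities(net)
  expect_equal(length(unique(part)), 2L)
  expect_equal(length(unique(part[1:3])), 1L)
  # edgeless network: all singletons, with a warning
  W0 <- W * 0
  net0 <- structure(list(nodes = rownames(W), weights = W0, method = "ppmi",
                         n = 100L), class = "event_network")
  expect_warning(p0 <- detect_communities(net0), "edgeless")
  expect_equal(length(unique(p0)), 6L)
})

test_that("adjusted Rand index agrees with an external oracle", {
  skip_if_not_installed("mclust")
  set.seed(10)
  for (i in 1:20) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
  }
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
})

test_that("partition comparison handles identity, degeneracy and permutation", {
  p <- setNames(rep(1:2, each = 5), sprintf("V%d", 1:10))
  expect_equal(compare_partitions(p, p)$ari, 1)
  singletons <- setNames(1:10, names(p))
  oneblock <- setNames(rep(1L, 10), names(p))
  expect_equal(compare_partitions(singletons, oneblock)$ari, 0)
  expect_error(compare_partitions(p, setNames(p, sprintf("X%d", 1:10))),
               "different node sets")
  # random relabeling of items is near-zero on average
  set.seed(11)
  aris <- replicate(200, {
    q <- setNames(sample(p), names(p))
    compare_partitions(p, q)$ari
  })
  expect_lt(abs(mean(aris)), 0.05)
})

test_that("planted symptom clusters drive term selection and co-occurrence", {
  cl <- list(class_tag = "beta_blocker",
             pt_codes = c("PT0001", "PT0030", "PT0031", "PT0032"),
             p_on = 0.5, boost = 6)
  cfg <- sim_config(n_reports = 30000, seed = 41, symptom_clusters = list(cl))
  g <- generate_database(cfg)
  cases <- apply_exclusion(g$db, select_cases(g$db, "PT0001"))
  terms <- select_terms(g$db, "beta_blocker", cases,
                        exclude_pts = c("PT0001", "PT0002", "PT0003"))
  expect_true(all(c("PT0030", "PT0031", "PT0032") %in% terms$pt_code))
  m <- build_case_term_matrix(g$db, "beta_blocker", cases, terms$pt_code)
  expect_true(all(m %in% 0:1))
  expect_equal(sort(colnames(m)), sort(terms$pt_code))
  # cluster members co-occur positively in the PPMI network
  net <- compute_ppmi(m)
  expect_gt(net$weights["PT0030", "PT0031"], 0)
  # a term reported independently of case status is not selected
  expect_false("PT0005" %in% terms$pt_code)
})

test_that("select_terms warns and returns empty for a class without cases", {
  db <- toy_db()
  # dD (tki class) appears only in R08, which is not an index case
  expect_warning(t0 <- select_terms(db, "tki", c("R01", "R06", "R09")),
                 "no index-condition cases")
  expect_equal(nrow(t0), 0L)
})
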