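test_that("MAT standardization uses the population convention", {
  mat <- random_mat(N = 3, P = 4, E = 1)
  mat$Q[, 1, 1] <- c(0, 1, 2)
  mat$Q[, 2, 1] <- 5  # constant column
  st <- standardize_mat(mat)
  expect_equal(st$Q[, 1, 1], c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-10)
  expect_false(st$testable[2, 1])
  expect_equal(st$Q[, 2, 1], c(0, 0, 0))
  big <- standardize_mat(random_mat(N = 10, P = 30, E = 2, seed = 2))
  for (e in 1:2) {
    expect_lt(max(abs(colMeans(big$Q[, , e]))), 1e-10)
    v <- colMeans(big$Q[, , e]^2)
    expect_lt(max(abs(v[big$testable[, e]] - 1)), 1e-10)
  }
  flat <- random_mat(N = 4, P = 2, E = 1)
  flat$Q[] <- 1 / 2
  expect_error(standardize_mat(flat), "zero variance")
})

test_that("correlations hit the exact endpoints", {
  mat <- standardize_mat(random_mat(N = 8, P = 6, E = 1, seed = 3))
  y <- mat$Q[, 4, 1]
  C <- correlate(mat, y)
  expect_equal(C[1, 4], 1, tolerance = 1e-10)
  expect_equal(correlate(mat, -y)[1, 4], -1, tolerance = 1e-10)
  expect_true(all(abs(C) <= 1 + 1e-12))
  expect_error(correlate(mat, rep(1, 8)), "constant")
  # independent column, many samples: small correlation
  set.seed(4)
  matN <- standardize_mat(random_mat(N = 200, P = 10, E = 1, seed = 4))
  CN <- correlate(matN, rnorm(200))
  expect_lt(max(abs(CN)), 0.25)
})

test_that("moment-ratio meta-analysis matches direct arithmetic", {
  expect_equal(meta_local(matrix(c(0.7, 0.7, 0.7), 3, 1)), 0.7)
  expect_equal(meta_local(matrix(c(0.5, -0.5), 2, 1)), 0)
  expect_equal(meta_local(matrix(c(0.9, 0.1), 2, 1)),
               (0.729 + 0.001) / (0.81 + 0.01))
  expect_equal(meta_local(matrix(0, 2, 3)), c(0, 0, 0))
  # rho is bounded by the largest |C| entry per patch
  set.seed(5)
  C <- matrix(runif(50, -1, 1), 5, 10)
  rho <- meta_local(C)
  expect_true(all(abs(rho) <= apply(abs(C), 2, max) + 1e-12))
  expect_true(all(rho >= apply(C, 2, min) - 1e-12 &
                    rho <= apply(C, 2, max) + 1e-12))
})

test_that("global statistic identities hold", {
  expect_equal(global_stat(matrix(0.6, 4, 7)), 0.36)
  expect_equal(global_stat(matrix(0, 4, 7)), 0)
  set.seed(6)
  C1 <- matrix(runif(20, -1, 1), 1, 20)
  expect_equal(global_stat(C1), mean(C1^2))
  C <- matrix(runif(60, -1, 1), 6, 10)
  R <- global_stat(C)
  expect_gte(R, 0); expect_lte(R, 1)
})

test_that("donor-preserving permutation keeps donors intact and uniform", {
  md <- list(donor_id = c("d1", "d1", "d1", "d2", "d3"),
             phenotype = c(1, 1, 1, 0, 0.5))
  set.seed(7)
  for (i in 1:20) {
    p <- permute_phenotype(md)
    expect_length(unique(p[1:3]), 1)  # donor d1 samples share a value
    expect_setequal(p[c(1, 4, 5)], c(1, 0, 0.5))
  }
  # singleton donors: ordinary permutation, uniform over 3! arrangements
  md2 <- list(donor_id = c("a", "b", "c"), phenotype = c(1, 2, 3))
  set.seed(8)
  draws <- replicate(1200, paste(permute_phenotype(md2), collapse = ""))
  tab <- table(draws)
  expect_length(tab, 6)
  expect_gt(chisq.test(tab)$p.value, 0.001)
})

test_that("empirical FDR matches a brute-force recount and is monotone", {
  set.seed(9)
  P <- 20; n_perm <- 50
  rho <- rnorm(P, sd = 0.4)
  null_rho <- matrix(rnorm(P * n_perm, sd = 0.3), P, n_perm)
  thr <- sort(unique(rho[rho > 0]))
  curve <- vima:::.fdr_curve(rho, null_rho, thr)
  for (i in seq_along(thr)) {
    n_obs <- sum(rho >= thr[i])
    n_null <- mean(colSums(null_rho >= thr[i]))
    expect_equal(curve$n_observed[i], n_obs)
    expect_equal(curve$expected_null[i], n_null)
    expect_equal(curve$fdr_raw[i], n_null / n_obs)
    expect_equal(curve$fdr[i],
                 min(1, min(curve$fdr_raw[i:length(thr)])))
  }
  expect_true(all(diff(curve$fdr) <= 1e-12))
})

test_that("the local test calls planted signal and respects the null", {
  set.seed(10)
  N <- 20; P <- 60; E <- 2
  y <- rep(c(0, 1), each = N / 2)
  mat <- random_mat(N = N, P = P, E = E, seed = 10,
                    signal_cols = 1:10, y = y, effect = 1.5)
  md <- list(sample_id = mat$samples, donor_id = mat$samples,
             phenotype = y)
  mat <- standardize_mat(mat)
  res <- local_test(mat, md, n_perm = 200, fdr_level = 0.1)
  called <- c(res$significant_pos, res$significant_neg)
  expect_gt(length(intersect(called, 1:10)), 0)
  expect_gt(mean(called %in% 1:10), 0.5)  # planted columns dominate calls
  # degenerate case: all null coefficients below all observed
  obs <- c(0.9, 0.8)
  nullr <- matrix(0.01, 2, 10)
  cv <- vima:::.fdr_curve(obs, nullr, sort(obs))
  expect_equal(cv$fdr, c(0, 0))
})

test_that("global and local tests are sign-symmetric in the phenotype", {
  set.seed(11)
  mat <- standardize_mat(random_mat(N = 12, P = 25, E = 2, seed = 11))
  y <- rnorm(12)
  md1 <- list(sample_id = mat$samples, donor_id = mat$samples,
              phenotype = y)
  md2 <- md1; md2$phenotype <- -y
  set.seed(99); r1 <- vima_association(mat, md1, n_perm = 100)
  set.seed(99); r2 <- vima_association(mat, md2, n_perm = 100)
  expect_equal(r1$local$rho, -r2$local$rho, tolerance = 1e-12)
  expect_equal(r1$global$R, r2$global$R, tolerance = 1e-12)
  expect_equal(r1$global$p_value, r2$global$p_value)
})

test_that("the permutation P-value floor is the add-one estimator", {
  set.seed(12)
  mat <- standardize_mat(random_mat(N = 10, P = 15, E = 1, seed = 12))
  md <- list(sample_id = mat$samples, donor_id = mat$samples,
             phenotype = rep(c(0, 1), 5))
  g <- global_test(mat, md, n_perm = 99)
  expect_gte(g$p_value, 1 / 100)
  expect_lte(g$p_value, 1)
})

test_that("MAT PCA separates block-structured samples", {
  set.seed(13)
  N <- 10; P <- 30
  Q <- array(0.01, c(N, P, 2))
  Q[1:5, 1:15, ] <- Q[1:5, 1:15, ] + 1     # group 1 uses first microniches
  Q[6:10, 16:30, ] <- Q[6:10, 16:30, ] + 1
  for (e in 1:2) Q[, , e] <- Q[, , e] / rowSums(Q[, , e])
  mat <- structure(list(Q = Q, samples = sprintf("s%d", 1:N), s = 1,
                        projected = FALSE), class = "vima_mat")
  pc <- mat_pca(mat, n_pcs = 3)
  expect_true(all(pc$scores[1:5, 1] * pc$scores[6:10, 1] < 0) ||
                all(sign(pc$scores[1:5, 1]) != sign(pc$scores[6:10, 1])))
  expect_lt(abs(sum(pc$scores[, 1] * pc$scores[, 2])), 1e-8)
  # duplicate samples score identically
  mat$Q[2, , ] <- mat$Q[1, , ]
  pc2 <- mat_pca(mat)
  expect_equal(pc2$scores[1, ], pc2$scores[2, ], tolerance = 1e-10)
})

test_that("cluster comparator follows permutation and Bonferroni logic", {
  set.seed(14)
  # two well-separated embedding clusters whose abundance tracks y exactly
  N <- 10
  y <- rep(c(0, 1), each = 5)
  emb <- NULL; sids <- NULL
  for (n in 1:N) {
    n1 <- if (y[n] == 1) 18 else 2
    pts <- rbind(matrix(rnorm(n1 * 2), n1, 2),
                 matrix(rnorm((20 - n1) * 2, mean = 20), 20 - n1, 2))
    emb <- rbind(emb, pts)
    sids <- c(sids, rep(sprintf("s%02d", n), 20))
  }
  md <- list(sample_id = sprintf("s%02d", 1:N), donor_id = sprintf("d%d", 1:N),
             phenotype = y)
  res <- cluster_baseline_test(emb, sids, md, n_perm = 200, k = 10)
  expect_lte(min(res$per_cluster_p), 5 / 201)
  expect_equal(res$global_bonferroni_p,
               min(1, length(res$per_cluster_p) * min(res$per_cluster_p)))
  expect_lte(res$global_sumsq_p, 0.05)
  expect_length(res$patch_score, nrow(emb))
})

test_that("contingency log-odds match the asymptotic formulas", {
  r <- contingency_log_odds(10, 10, 10, 10)
  expect_equal(r$log_or, 0)
  expect_equal(r$se, sqrt(0.4))
  expect_equal(r$ci95, c(-1.96, 1.96) * sqrt(0.4))
  r2 <- contingency_log_odds(20, 10, 10, 20)
  expect_equal(r2$log_or, log(4))
  expect_error(contingency_log_odds(0, 1, 2, 3), "continuity")
  # CI contains 0 iff |log OR| < 1.96 se
  set.seed(15)
  for (i in 1:20) {
    cc <- sample(1:30, 4, replace = TRUE)
    r3 <- do.call(contingency_log_odds, as.list(cc))
    expect_equal(r3$ci95[1] < 0 && r3$ci95[2] > 0,
                 abs(r3$log_or) < 1.96 * r3$se)
  }
})
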