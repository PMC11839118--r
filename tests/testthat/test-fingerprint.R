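test_that("autoencoder loss decomposes into reconstruction and KL parts", {
  set.seed(1)
  p <- array(rnorm(40 * 40 * 2), c(40, 40, 2))
  # prior-matching posterior: KL term vanishes
  expect_equal(cvae_loss(p, p * 0, mu = rep(0, 5), log_var = rep(0, 5),
                         beta = 1e-3),
               mean(p^2))
  # perfect reconstruction and prior posterior: zero loss
  expect_equal(cvae_loss(p, p, rep(0, 5), rep(0, 5), 1e-3), 0)
  # mu = (1, 0, ...), sigma^2 = 1: KL magnitude is beta/2
  expect_equal(cvae_loss(p, p, c(1, rep(0, 4)), rep(0, 5), 1e-3),
               1e-3 / 2)
})

test_that("KL weight ramps linearly over the warm-up epochs", {
  cfg <- cvae_config(beta = 1e-4, kl_warmup_epochs = 5)
  expect_equal(kl_weight(cfg, 5), 1e-4)
  expect_equal(kl_weight(cfg, 2), 2e-4 / 5)
  expect_equal(kl_weight(cfg, 12), 1e-4)
})

test_that("model heads and conditioning have the specified shapes", {
  cfg <- tiny_cvae_config(latent_dim = 7)
  m <- build_model(cfg, K = 2, n_samples = 3)
  expect_equal(ncol(m$params$e_head.W), 14)  # mu ++ log sigma^2
  expect_equal(dim(m$params$e_emb), c(3, 4))  # 4 conditioning channels
  expect_equal(dim(m$params$d_emb), c(3, 4))
  x <- array(rnorm(2 * 40 * 40 * 2), c(2, 40, 40, 2))
  U <- diag(3)[, 1:2]
  wc <- crossprod(m$params$e_emb, U)
  enc <- vima:::.enc_fwd(m$params, cfg, x, wc)
  expect_equal(dim(enc$out), c(14, 2))

  cfg2 <- tiny_cvae_config(latent_dim = 5)
  cfg2$variant <- "convnet2_ae"
  m2 <- build_model(cfg2, K = 2, n_samples = 3)
  expect_equal(ncol(m2$params$e_c1.W), 3)   # first conv width
  expect_equal(ncol(m2$params$e_c2.W), 4)   # second conv width
  expect_equal(ncol(m2$params$e_head.W), 5) # plain bottleneck, no log-var
  expect_error(build_model(structure(c(cfg2, list()), class = "x"), 2, 3))
  # published widths are the convnet2 defaults
  expect_equal(cvae_config()$conv_widths, c(256, 512))
})

test_that("analytic gradients match finite differences off the ReLU kinks", {
  set.seed(42)
  for (variant in c("resnet_cvae", "convnet2_ae")) {
    cfg <- tiny_cvae_config()
    cfg$variant <- variant
    m <- build_model(cfg, K = 2, n_samples = 3)
    # jitter all parameters so no pre-activation sits exactly at zero
    p <- lapply(m$params, function(q) q + rnorm(length(q), sd = 0.05))
    x <- array(rnorm(2 * 40 * 40 * 2), c(2, 40, 40, 2))
    U <- if (variant == "resnet_cvae") diag(3)[, 1:2] else NULL
    noise <- matrix(rnorm(cfg$latent_dim * 2), cfg$latent_dim, 2)
    r <- vima:::.model_lossgrad(p, cfg, x, U, noise, 1e-3)
    eps <- 1e-6
    check <- sample(names(p), 6)
    for (nm in check) {
      j <- sample(length(p[[nm]]), 1)
      p1 <- p; p1[[nm]][j] <- p1[[nm]][j] + eps
      p2 <- p; p2[[nm]][j] <- p2[[nm]][j] - eps
      num <- (vima:::.model_lossgrad(p1, cfg, x, U, noise, 1e-3,
                                     want_grads = FALSE)$loss -
                vima:::.model_lossgrad(p2, cfg, x, U, noise, 1e-3,
                                       want_grads = FALSE)$loss) / (2 * eps)
      expect_lt(abs(num - r$grads[[nm]][j]),
                5e-4 * max(1, abs(num)))
    }
  }
})

test_that("with zero KL weight the objective is plain reconstruction MSE", {
  set.seed(5)
  cfg <- tiny_cvae_config()
  cfg$variant <- "resnet_ae_no_sid"
  m <- build_model(cfg, K = 2, n_samples = 2)
  x <- array(rnorm(2 * 40 * 40 * 2), c(2, 40, 40, 2))
  noise <- matrix(0, cfg$latent_dim, 2)
  r <- vima:::.model_lossgrad(m$params, cfg, x, NULL, noise, 0,
                              want_grads = FALSE)
  expect_equal(r$loss, r$recon)
  expect_equal(r$loss, mean((r$xhat - x)^2))
})

test_that("training is seed-deterministic and seed-sensitive", {
  ps <- random_patch_set(P = 40, K = 2, seed = 3)
  cfg <- tiny_cvae_config(epochs = 1, seed = 11)
  m1 <- train_cvae(ps, cfg)
  m2 <- train_cvae(ps, cfg)
  f1 <- encode(m1, ps)
  f2 <- encode(m2, ps)
  expect_identical(f1, f2)
  m3 <- train_cvae(ps, cfg, seed = 12)
  expect_false(isTRUE(all.equal(unclass(f1), unclass(encode(m3, ps)))))
})

test_that("encoding is deterministic and filters by tissue density", {
  ps <- random_patch_set(P = 20, K = 2, seed = 6)
  ps$patches[2, , , ] <- ps$patches[1, , , ]  # duplicate row
  ps$sample_ids[2] <- ps$sample_ids[1]
  ps$tissue_fraction <- c(0.9, 0.9, 0.4, rep(0.8, 17))
  cfg <- tiny_cvae_config(epochs = 1, seed = 2)
  m <- train_cvae(ps, cfg)
  f <- encode(m, ps)
  expect_equal(f[1, ], f[2, ])  # identical patches, same sample
  fa <- encode(m, ps, alpha = 0.5)
  expect_equal(attr(fa, "keep"), setdiff(1:20, 3))  # 0.4 excluded
  expect_error(encode(m, random_patch_set(P = 5, K = 3)), "channel")
})

test_that("ensemble members differ but share structure", {
  ps <- textured_patch_set(P = 60, K = 2, seed = 8)
  cfg <- tiny_cvae_config(epochs = 2, latent_dim = 4, seed = 21)
  ens <- train_ensemble(ps, cfg, E = 2)
  expect_s3_class(ens, "vima_ensemble")
  fp <- fingerprint_matrices(ens, ps, alpha = 0.5)
  expect_length(fp$fingerprints, 2)
  expect_false(isTRUE(all.equal(fp$fingerprints[[1]],
                                fp$fingerprints[[2]])))
  # k-NN graphs from different seeds share a majority of edges on
  # well-separated texture classes
  g1 <- build_graph(fp$fingerprints[[1]], k = 10)
  g2 <- build_graph(fp$fingerprints[[2]], k = 10)
  e1 <- which(as.matrix(g1$A) > 0)
  e2 <- which(as.matrix(g2$A) > 0)
  expect_gt(length(intersect(e1, e2)) / length(union(e1, e2)), 0.3)
})

test_that("reconstruction baselines follow the standardization contract", {
  ps <- random_patch_set(P = 30, K = 2, seed = 10)
  cfg <- tiny_cvae_config(epochs = 1, seed = 3)
  m <- train_cvae(ps, cfg)
  rm <- reconstruction_metrics(m, ps)
  expect_equal(rm$dataset_mean_mse, 1, tolerance = 1e-12)
  expect_lte(rm$patch_mean_mse, rm$dataset_mean_mse)

  # spatially constant patches: the patch-mean predictor is exact
  ps2 <- random_patch_set(P = 10, K = 2, seed = 11)
  for (i in 1:10) for (k in 1:2) ps2$patches[i, , , k] <- i + k
  rm2 <- reconstruction_metrics(m, ps2)
  expect_equal(rm2$patch_mean_mse, 0, tolerance = 1e-12)
})

test_that("a trained model beats the mean predictor on textured data", {
  ps <- textured_patch_set(P = 60, K = 2, seed = 12)
  # standardize channels so the mean-predictor MSE is 1
  for (k in 1:2) {
    v <- ps$patches[, , , k]
    ps$patches[, , , k] <- (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  }
  cfg <- tiny_cvae_config(epochs = 6, latent_dim = 4, widths = c(4, 6, 8),
                          seed = 5, lr = 2e-3)
  m <- train_cvae(ps, cfg)
  rm <- reconstruction_metrics(m, ps)
  expect_lt(rm$model_mse, rm$dataset_mean_mse)
})

test_that("sample-ID conditioning enters the encoder and decoder", {
  # mechanism check: encoding the same patch under different sample
  # identities must change the conditional fingerprint (the conditioning
  # channels are live), while the unconditioned variant ignores identity.
  ps <- random_patch_set(P = 24, K = 2, n_samples = 3, seed = 78)
  cfg <- tiny_cvae_config(latent_dim = 4, epochs = 2, seed = 9)
  m <- train_cvae(ps, cfg)
  ps2 <- ps
  ps2$sample_ids <- ps$sample_ids[c(2:24, 1)]  # relabel patches
  f1 <- unclass(encode(m, ps))
  f2 <- unclass(encode(m, ps2))
  expect_false(isTRUE(all.equal(f1, f2)))
  cfg$variant <- "resnet_ae_no_sid"
  m0 <- train_cvae(ps, cfg)
  expect_equal(unclass(encode(m0, ps)), unclass(encode(m0, ps2)),
               tolerance = 1e-12)
  # the learned conditioning embeddings move away from initialization
  expect_gt(sum((m$params$e_emb)^2), 0)
  expect_gt(sum((m$params$d_emb)^2), 0)
})
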