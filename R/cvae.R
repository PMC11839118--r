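#' Configuration for the patch autoencoders
#'
#' @param latent_dim latent dimension `C` (default 100).
#' @param beta weight of the variational (KL) penalty (default `1e-5`).
#'   If patches integrate poorly across samples, increase `beta` one order
#'   of magnitude at a time.
#' @param cond_embed_dim dimension of the learned per-sample conditioning
#'   embedding (default 4).
#' @param epochs training epochs before considering extension (default 20).
#' @param kl_warmup_epochs epochs over which the KL weight ramps linearly
#'   from 0 to `beta` (default 5).
#' @param batch_size minibatch size (default 256).
#' @param lr Adam learning rate (default `1e-3`).
#' @param lr_decay_per_epoch multiplicative learning-rate decay (default 0.9).
#' @param train_fraction fraction of patches used for training; the rest
#'   validate (default 0.8).
#' @param seed RNG seed for initialization, splits and minibatch noise.
#' @param variant `"resnet_cvae"` (conditional VAE with residual stages),
#'   `"resnet_ae_no_sid"` (same without sample-ID conditioning) or
#'   `"convnet2_ae"` (plain two-layer convolutional autoencoder).
#' @param widths channel widths of the three residual stages
#'   (default `c(64, 128, 256)`).
#' @param conv_widths channel widths of the two convolutional layers of
#'   the `convnet2_ae` variant (default `c(256, 512)`).
#' @param extend extend training in 5-epoch increments while the
#'   validation loss still improves by more than `extend_tol` per epoch.
#' @param extend_tol relative per-epoch improvement required to extend
#'   (default 0.005).
#' @param max_epochs hard cap on total epochs (default 60).
#' @return object of class `cvae_config`.
#' @export
cvae_config <- function(latent_dim = 100, beta = 1e-5, cond_embed_dim = 4,
                        epochs = 20, kl_warmup_epochs = 5, batch_size = 256,
                        lr = 1e-3, lr_decay_per_epoch = 0.9,
                        train_fraction = 0.8, seed = 1,
                        variant = c("resnet_cvae", "resnet_ae_no_sid",
                                    "convnet2_ae"),
                        widths = c(64, 128, 256), conv_widths = c(256, 512),
                        extend = TRUE, extend_tol = 0.005, max_epochs = 60) {
  variant <- match.arg(variant)
  stopifnot(beta > 0, latent_dim >= 1, train_fraction > 0,
            train_fraction < 1, length(widths) == 3, length(conv_widths) == 2)
  structure(list(latent_dim = latent_dim, beta = beta,
                 cond_embed_dim = cond_embed_dim, epochs = epochs,
                 kl_warmup_epochs = kl_warmup_epochs,
                 batch_size = batch_size, lr = lr,
                 lr_decay_per_epoch = lr_decay_per_epoch,
                 train_fraction = train_fraction, seed = seed,
                 variant = variant, widths = widths,
                 conv_widths = conv_widths, extend = extend,
                 extend_tol = extend_tol, max_epochs = max_epochs),
            class = "cvae_config")
}

#' KL weight during linear warm-up
#' @param config a [cvae_config()].
#' @param epoch 1-based epoch index.
#' @return the KL weight applied at that epoch.
#' @export
kl_weight <- function(config, epoch) {
  config$beta * min(1, epoch / config$kl_warmup_epochs)
}

#' Build an (untrained) patch autoencoder
#'
#' The default architecture is a compact residual convolutional network
#' for 40x40 inputs: a stem convolution followed by three residual stages
#' with stride-2 downsampling between them (40 -> 20 -> 10 -> 5), global
#' average pooling and a linear head producing the posterior mean and
#' log-variance.  The decoder mirrors it with nearest-neighbour
#' upsampling.  In the conditional variant a learned 4-dimensional
#' per-sample embedding is broadcast spatially and concatenated to the
#' representation at every stage of both encoder and decoder (the encoder
#' and decoder each learn their own embedding).
#'
#' @param config a [cvae_config()].
#' @param K number of meta-marker channels.
#' @param n_samples number of samples (size of the one-hot conditioning).
#' @param n_covariates number of additional conditioning covariates.
#' @return object of class `vima_cvae` (untrained).
#' @export
build_model <- function(config, K, n_samples, n_covariates = 0) {
  stopifnot(inherits(config, "cvae_config"))
  C <- config$latent_dim
  e4 <- if (config$variant == "resnet_cvae") config$cond_embed_dim else 0L
  du <- n_samples + n_covariates
  p <- list()
  if (config$variant == "convnet2_ae") {
    a <- config$conv_widths[1]; b <- config$conv_widths[2]
    p[c("e_c1.W", "e_c1.b")] <- .conv_init(K, a)
    p[c("e_c2.W", "e_c2.b")] <- .conv_init(a, b)
    p[c("e_head.W", "e_head.b")] <- .dense_init(b, C)
    p[c("d_head.W", "d_head.b")] <- .dense_init(C, b * 100)
    p[c("d_c1.W", "d_c1.b")] <- .conv_init(b, a)
    p[c("d_c2.W", "d_c2.b")] <- .conv_init(a, K)
    plan <- sprintf("convnet2_ae: conv%d/s2, conv%d/s2, gap, dense-%d", a, b, C)
  } else {
    w <- config$widths
    p[c("e_stem.W", "e_stem.b")] <- .conv_init(K + e4, w[1])
    p[c("e_r1a.W", "e_r1a.b")] <- .conv_init(w[1], w[1])
    p[c("e_r1b.W", "e_r1b.b")] <- .conv_init(w[1], w[1])
    p[c("e_d1.W", "e_d1.b")] <- .conv_init(w[1] + e4, w[2])
    p[c("e_r2a.W", "e_r2a.b")] <- .conv_init(w[2], w[2])
    p[c("e_r2b.W", "e_r2b.b")] <- .conv_init(w[2], w[2])
    p[c("e_d2.W", "e_d2.b")] <- .conv_init(w[2] + e4, w[3])
    p[c("e_r3a.W", "e_r3a.b")] <- .conv_init(w[3], w[3])
    p[c("e_r3b.W", "e_r3b.b")] <- .conv_init(w[3], w[3])
    p[c("e_d3.W", "e_d3.b")] <- .conv_init(w[3] + e4, w[3])
    p[c("e_head.W", "e_head.b")] <- .dense_init(w[3], 2 * C)
    p[c("d_head.W", "d_head.b")] <- .dense_init(C + e4, w[3] * 25)
    p[c("d_u1.W", "d_u1.b")] <- .conv_init(w[3] + e4, w[3])
    p[c("d_u2.W", "d_u2.b")] <- .conv_init(w[3] + e4, w[2])
    p[c("d_u3.W", "d_u3.b")] <- .conv_init(w[2] + e4, w[1])
    p[c("d_out.W", "d_out.b")] <- .conv_init(w[1], K)
    if (e4 > 0) {
      p$e_emb <- matrix(rnorm(du * e4, sd = 0.1), du, e4)
      p$d_emb <- matrix(rnorm(du * e4, sd = 0.1), du, e4)
    }
    plan <- sprintf(
      paste0("%s: encoder stem conv%d + res stages (%d,%d,%d), stride-2 ",
             "between, gap, dense-%d; decoder dense, 3x [upsample + conv] ",
             "(%d,%d,%d), conv-out%s"),
      config$variant, w[1], w[1], w[2], w[3], 2 * C, w[3], w[2], w[1],
      if (e4 > 0) sprintf("; %d conditioning channels per stage", e4) else "")
  }
  structure(list(params = p, config = config, K = K, C = C,
                 n_samples = n_samples, n_covariates = n_covariates,
                 sample_levels = NULL, cov_center = NULL, cov_scale = NULL,
                 trained = FALSE, arch_plan = plan, history = NULL),
            class = "vima_cvae")
}

#' @export
print.vima_cvae <- function(x, ...) {
  cat("vima_cvae (", if (x$trained) "trained" else "untrained", ")\n",
      sep = "")
  cat("  ", x$arch_plan, "\n", sep = "")
  cat(sprintf("  K = %d channels, C = %d latent dims\n", x$K, x$C))
  invisible(x)
}

.variational <- function(config) config$variant != "convnet2_ae"

## ---- forward / backward --------------------------------------------------

.enc_fwd <- function(p, cfg, x, wc) {
  ca <- list()
  if (cfg$variant == "convnet2_ae") {
    ca$x <- x
    ca$a1 <- .conv_f(p, "e_c1", x, 2L); h1 <- .relu(ca$a1); ca$h1 <- h1
    ca$a2 <- .conv_f(p, "e_c2", h1, 2L); h2 <- .relu(ca$a2); ca$h2 <- h2
    ca$g <- .gap(h2)
    return(list(out = .dense_f(p, "e_head", ca$g), cache = ca))
  }
  cc <- !is.null(wc)
  ca$x0 <- if (cc) .ccat(x, wc) else x
  ca$s <- .conv_f(p, "e_stem", ca$x0); h <- .relu(ca$s)
  ca$r1 <- .res_f(p, "e_r1", h)
  ca$h1c <- if (cc) .ccat(ca$r1$o, wc) else ca$r1$o
  ca$d1 <- .conv_f(p, "e_d1", ca$h1c, 2L); h <- .relu(ca$d1)
  ca$r2 <- .res_f(p, "e_r2", h)
  ca$h2c <- if (cc) .ccat(ca$r2$o, wc) else ca$r2$o
  ca$d2 <- .conv_f(p, "e_d2", ca$h2c, 2L); h <- .relu(ca$d2)
  ca$r3 <- .res_f(p, "e_r3", h)
  ca$h3c <- if (cc) .ccat(ca$r3$o, wc) else ca$r3$o
  ca$d3 <- .conv_f(p, "e_d3", ca$h3c, 2L); ca$h5 <- .relu(ca$d3)
  ca$g <- .gap(ca$h5)
  list(out = .dense_f(p, "e_head", ca$g), cache = ca)
}

.enc_bwd <- function(p, cfg, ca, dout, genv, cond) {
  if (cfg$variant == "convnet2_ae") {
    dg <- .dense_b(p, "e_head", ca$g, dout, genv)
    dh2 <- .relu_bwd(.gap_bwd(dg, dim(ca$h2)[2], dim(ca$h2)[3]), ca$a2)
    dh1 <- .relu_bwd(.conv_b(p, "e_c2", ca$h1, dh2, genv, 2L), ca$a1)
    .conv_b(p, "e_c1", ca$x, dh1, genv, 2L)
    return(NULL)
  }
  dwc <- NULL
  unc <- function(dxc) {
    if (!cond) return(dxc)
    sp <- .ccat_bwd(dxc, dim(dxc)[1] - cfg$cond_embed_dim)
    dwc <<- if (is.null(dwc)) sp$dwc else dwc + sp$dwc
    sp$dx
  }
  dg <- .dense_b(p, "e_head", ca$g, dout, genv)
  dh5 <- .relu_bwd(.gap_bwd(dg, dim(ca$h5)[2], dim(ca$h5)[3]), ca$d3)
  dh <- unc(.conv_b(p, "e_d3", ca$h3c, dh5, genv, 2L))
  dh <- .res_bwd(p, "e_r3", ca$r3, ca$r3$o, dh, genv)
  dh <- .relu_bwd(dh, ca$d2)
  dh <- unc(.conv_b(p, "e_d2", ca$h2c, dh, genv, 2L))
  dh <- .res_bwd(p, "e_r2", ca$r2, ca$r2$o, dh, genv)
  dh <- .relu_bwd(dh, ca$d1)
  dh <- unc(.conv_b(p, "e_d1", ca$h1c, dh, genv, 2L))
  dh <- .res_bwd(p, "e_r1", ca$r1, ca$r1$o, dh, genv)
  dh <- .relu_bwd(dh, ca$s)
  dx0 <- .conv_b(p, "e_stem", ca$x0, dh, genv)
  unc(dx0)
  dwc
}

.dec_fwd <- function(p, cfg, z, wc) {
  ca <- list()
  if (cfg$variant == "convnet2_ae") {
    b <- cfg$conv_widths[2]
    ca$z <- z
    ca$a0 <- .dense_f(p, "d_head", z)
    h <- .relu(array(ca$a0, c(b, 10, 10, ncol(z)))); ca$h0 <- h
    ca$u1 <- .up2(h)
    ca$a1 <- .conv_f(p, "d_c1", ca$u1); h <- .relu(ca$a1); ca$h1 <- h
    ca$u2 <- .up2(h)
    xhat <- .conv_f(p, "d_c2", ca$u2)
    return(list(xhat = xhat, cache = ca))
  }
  cc <- !is.null(wc)
  w <- cfg$widths
  zin <- if (cc) rbind(z, wc) else z
  ca$zin <- zin
  ca$a0 <- .dense_f(p, "d_head", zin)
  h <- .relu(array(ca$a0, c(w[3], 5, 5, ncol(z)))); ca$h0 <- h
  ca$x1 <- if (cc) .ccat(.up2(h), wc) else .up2(h)
  ca$a1 <- .conv_f(p, "d_u1", ca$x1); h1 <- .relu(ca$a1); ca$h1 <- h1
  ca$x2 <- if (cc) .ccat(.up2(h1), wc) else .up2(h1)
  ca$a2 <- .conv_f(p, "d_u2", ca$x2); h2 <- .relu(ca$a2); ca$h2 <- h2
  ca$x3 <- if (cc) .ccat(.up2(h2), wc) else .up2(h2)
  ca$a3 <- .conv_f(p, "d_u3", ca$x3); h3 <- .relu(ca$a3); ca$h3 <- h3
  xhat <- .conv_f(p, "d_out", ca$h3)
  list(xhat = xhat, cache = ca)
}

.dec_bwd <- function(p, cfg, ca, dxhat, genv, cond) {
  if (cfg$variant == "convnet2_ae") {
    du2 <- .conv_b(p, "d_c2", ca$u2, dxhat, genv)
    dh1 <- .relu_bwd(.up2_bwd(du2), ca$a1)
    du1 <- .conv_b(p, "d_c1", ca$u1, dh1, genv)
    dh0 <- .relu_bwd(.up2_bwd(du1), ca$h0)
    da0 <- matrix(dh0, length(dh0) / ncol(ca$z), ncol(ca$z))
    dz <- .dense_b(p, "d_head", ca$z, da0, genv)
    return(list(dz = dz, dwc = NULL))
  }
  dwc <- NULL
  unc <- function(dxc) {
    if (!cond) return(dxc)
    sp <- .ccat_bwd(dxc, dim(dxc)[1] - cfg$cond_embed_dim)
    dwc <<- if (is.null(dwc)) sp$dwc else dwc + sp$dwc
    sp$dx
  }
  B <- ncol(ca$a0)
  dh <- .conv_b(p, "d_out", ca$h3, dxhat, genv)
  dh <- .relu_bwd(dh, ca$a3)
  dh <- .up2_bwd(unc(.conv_b(p, "d_u3", ca$x3, dh, genv)))
  dh <- .relu_bwd(dh, ca$a2)
  dh <- .up2_bwd(unc(.conv_b(p, "d_u2", ca$x2, dh, genv)))
  dh <- .relu_bwd(dh, ca$a1)
  dh <- .up2_bwd(unc(.conv_b(p, "d_u1", ca$x1, dh, genv)))
  dh <- .relu_bwd(dh, ca$h0)
  da0 <- matrix(dh, length(dh) / B, B)
  dzin <- .dense_b(p, "d_head", ca$zin, da0, genv)
  if (cond) {
    C <- nrow(dzin) - cfg$cond_embed_dim
    dwc <- dwc + dzin[C + seq_len(cfg$cond_embed_dim), , drop = FALSE]
    dzin <- dzin[seq_len(C), , drop = FALSE]
  }
  list(dz = dzin, dwc = dwc)
}

## Full loss + gradients for one minibatch.
## x: (K, side, side, B); U: conditioning inputs (du x B) or NULL;
## noise: (C x B) reparameterization noise (0 for deterministic encoding);
## klw: current KL weight (beta after warm-up).
.model_lossgrad <- function(p, cfg, x, U, noise, klw, want_grads = TRUE) {
  cond <- cfg$variant == "resnet_cvae" && !is.null(U)
  vr <- .variational(cfg)
  B <- dim(x)[4]
  C <- cfg$latent_dim
  wc_e <- if (cond) crossprod(p$e_emb, U) else NULL
  wc_d <- if (cond) crossprod(p$d_emb, U) else NULL
  enc <- .enc_fwd(p, cfg, x, wc_e)
  if (vr) {
    mu <- enc$out[seq_len(C), , drop = FALSE]
    lvraw <- enc$out[C + seq_len(C), , drop = FALSE]
    lv <- pmin(pmax(lvraw, -10), 10)
    sdv <- exp(0.5 * lv)
    z <- mu + sdv * noise
    kl_b <- 0.5 * colSums(mu^2 + exp(lv) - 1 - lv)
    KL <- mean(kl_b)
  } else {
    z <- enc$out
    mu <- z; lv <- NULL; KL <- 0
  }
  dec <- .dec_fwd(p, cfg, z, wc_d)
  recon <- mean((dec$xhat - x)^2)
  loss <- recon + klw * KL
  if (!want_grads)
    return(list(loss = loss, recon = recon, kl = KL, mu = mu,
                xhat = dec$xhat))
  genv <- new.env(parent = emptyenv())
  genv$g <- list()
  dxhat <- 2 * (dec$xhat - x) / length(x)
  db <- .dec_bwd(p, cfg, dec$cache, dxhat, genv, cond)
  if (vr) {
    dmu <- db$dz + klw * mu / B
    dlv <- db$dz * (0.5 * noise * sdv) + klw * (exp(lv) - 1) / (2 * B)
    dlv[lvraw < -10 | lvraw > 10] <- 0
    dout <- rbind(dmu, dlv)
  } else {
    dout <- db$dz
  }
  dwc_e <- .enc_bwd(p, cfg, enc$cache, dout, genv, cond)
  if (cond) {
    .acc(genv, "e_emb", U %*% t(dwc_e))
    .acc(genv, "d_emb", U %*% t(db$dwc))
  }
  list(loss = loss, recon = recon, kl = KL, grads = genv$g)
}

#' Autoencoder training loss
#'
#' Mean squared reconstruction error per patch element plus `beta` times
#' the KL divergence of the encoder posterior from the standard-normal
#' prior.  With `mu = 0` and `log_var = 0` the KL term vanishes and the
#' loss reduces to the plain reconstruction MSE.
#'
#' @param patch original patch array (any shape).
#' @param reconstruction decoded patch, same shape.
#' @param mu,log_var posterior mean and log-variance vectors.
#' @param beta KL weight.
#' @return scalar loss.
#' @export
cvae_loss <- function(patch, reconstruction, mu, log_var, beta) {
  stopifnot(all(is.finite(patch)), all(is.finite(reconstruction)),
            all(is.finite(mu)), all(is.finite(log_var)))
  mean((patch - reconstruction)^2) +
    beta * 0.5 * sum(mu^2 + exp(log_var) - 1 - log_var)
}

## conditioning-input matrix (one-hot sample id ++ standardized covariates)
.cond_inputs <- function(model, sample_ids) {
  lev <- model$sample_levels
  j <- match(sample_ids, lev)
  if (anyNA(j)) stop("sample id(s) unseen during training: ",
                     paste(unique(sample_ids[is.na(j)]), collapse = ", "))
  U <- matrix(0, length(lev) + model$n_covariates, length(sample_ids))
  U[cbind(j, seq_along(j))] <- 1
  if (model$n_covariates > 0) {
    cv <- sweep(sweep(model$cov_by_sample[j, , drop = FALSE], 2,
                      model$cov_center), 2, model$cov_scale, "/")
    U[length(lev) + seq_len(model$n_covariates), ] <- t(cv)
  }
  U
}

#' Train one patch autoencoder
#'
#' Standard stochastic training: Adam, minibatches of
#' `config$batch_size`, learning rate decaying by
#' `config$lr_decay_per_epoch` each epoch, KL weight ramping linearly over
#' the first `config$kl_warmup_epochs` epochs, an 80/20 train/validation
#' split by patch, and optional extension in 5-epoch increments while the
#' validation loss keeps improving.
#'
#' @param patchset a [patch_set()].
#' @param config a [cvae_config()].
#' @param metadata optional [sample_metadata()] providing conditioning
#'   covariates.
#' @param seed RNG seed (defaults to `config$seed`).
#' @return a trained `vima_cvae`.
#' @export
train_cvae <- function(patchset, config = cvae_config(), metadata = NULL,
                       seed = config$seed) {
  K <- dim(patchset$patches)[4]
  lev <- sort(unique(patchset$sample_ids))
  ncov <- 0L
  cov_by_sample <- NULL
  if (!is.null(metadata) && !is.null(metadata$covariates)) {
    ncov <- ncol(metadata$covariates)
    cov_by_sample <- metadata$covariates[match(lev, metadata$sample_id), ,
                                         drop = FALSE]
  }
  set.seed(seed)
  model <- build_model(config, K, n_samples = length(lev),
                       n_covariates = ncov)
  model$sample_levels <- lev
  model$seed <- seed
  if (ncov > 0) {
    model$cov_by_sample <- cov_by_sample
    model$cov_center <- colMeans(cov_by_sample)
    s <- apply(cov_by_sample, 2, sd)
    model$cov_scale <- ifelse(s > 0, s, 1)
  }
  x_all <- aperm(patchset$patches, c(4, 2, 3, 1))
  P <- dim(x_all)[4]
  U_all <- if (config$variant == "resnet_cvae")
    .cond_inputs(model, patchset$sample_ids) else NULL
  C <- config$latent_dim
  ntr <- max(1L, floor(config$train_fraction * P))
  idx <- sample.int(P)
  tr <- idx[seq_len(ntr)]
  va <- if (ntr < P) idx[-seq_len(ntr)] else tr

  p <- model$params
  st <- .adam_init(p)
  target <- config$epochs
  hist <- NULL
  epoch <- 0L
  val_loss <- function(p) {
    tot <- 0
    for (chunk in split(va, ceiling(seq_along(va) / config$batch_size))) {
      r <- .model_lossgrad(p, config, x_all[, , , chunk, drop = FALSE],
                           if (is.null(U_all)) NULL else
                             U_all[, chunk, drop = FALSE],
                           matrix(0, C, length(chunk)), config$beta,
                           want_grads = FALSE)
      tot <- tot + r$loss * length(chunk)
    }
    tot / length(va)
  }
  while (epoch < target) {
    epoch <- epoch + 1L
    lr <- config$lr * config$lr_decay_per_epoch^(epoch - 1)
    klw <- kl_weight(config, epoch)
    ord <- sample(tr)
    tr_loss <- 0
    for (batch in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
      noise <- matrix(rnorm(C * length(batch)), C)
      r <- .model_lossgrad(p, config, x_all[, , , batch, drop = FALSE],
                           if (is.null(U_all)) NULL else
                             U_all[, batch, drop = FALSE],
                           noise, klw)
      if (!is.finite(r$loss))
        stop(sprintf("divergent loss (%.3g) at epoch %d; reduce lr", r$loss,
                     epoch))
      ad <- .adam_step(p, r$grads, st, lr)
      p <- ad$params
      st <- ad$state
      tr_loss <- tr_loss + r$loss * length(batch)
    }
    vl <- val_loss(p)
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = tr_loss / length(tr),
                                   val_loss = vl, lr = lr, kl_weight = klw))
    if (epoch == target && config$extend && target < config$max_epochs &&
        epoch > 5) {
      prev <- hist$val_loss[epoch - 5]
      rel <- (prev - vl) / abs(prev) / 5
      if (is.finite(rel) && rel > config$extend_tol)
        target <- min(target + 5L, config$max_epochs)
    }
  }
  model$params <- p
  model$trained <- TRUE
  model$history <- hist
  model$train_idx <- tr
  model$val_idx <- va
  model
}

#' Train an ensemble of patch autoencoders
#'
#' Trains `E` models with identical architecture but different seeds.
#'
#' @param patchset a [patch_set()].
#' @param config a [cvae_config()].
#' @param metadata optional [sample_metadata()].
#' @param E ensemble size (default 10).
#' @param seed base seed; model `e` uses `seed * 131 + e`.
#' @return object of class `vima_ensemble` (list of `vima_cvae` models).
#' @export
train_ensemble <- function(patchset, config = cvae_config(), metadata = NULL,
                           E = 10, seed = config$seed) {
  stopifnot(E >= 1, length(patchset) > 0)
  models <- lapply(seq_len(E), function(e)
    train_cvae(patchset, config, metadata,
               seed = (seed * 131 + e) %% .Machine$integer.max))
  structure(list(models = models, config = config, E = E, seed = seed),
            class = "vima_ensemble")
}

#' @export
print.vima_ensemble <- function(x, ...) {
  cat(sprintf("vima_ensemble: %d autoencoders (%s)\n", x$E,
              x$config$variant))
  invisible(x)
}

#' Encode patches into fingerprints
#'
#' The fingerprint of a patch is the posterior mean `mu(p)` of its latent
#' encoding (deterministic; no sampling).
#'
#' @param model a trained `vima_cvae`.
#' @param patchset a [patch_set()] with the same number of channels the
#'   model was trained on.
#' @param alpha optional tissue-density threshold: if given, only patches
#'   with `tissue_fraction > alpha` are encoded (rows of the result then
#'   correspond to `which(patchset$tissue_fraction > alpha)`, stored in
#'   the `"keep"` attribute).
#' @return P x C fingerprint matrix.
#' @export
encode <- function(model, patchset, alpha = NULL) {
  if (!model$trained) stop("model is not trained")
  if (dim(patchset$patches)[4] != model$K)
    stop("patch channel count (", dim(patchset$patches)[4],
         ") does not match model K (", model$K, ")")
  keep <- seq_len(length(patchset))
  if (!is.null(alpha)) keep <- which(patchset$tissue_fraction > alpha)
  x_all <- aperm(patchset$patches[keep, , , , drop = FALSE], c(4, 2, 3, 1))
  U_all <- if (model$config$variant == "resnet_cvae")
    .cond_inputs(model, patchset$sample_ids[keep]) else NULL
  C <- model$C
  out <- matrix(0, length(keep), C)
  for (chunk in split(seq_along(keep),
                      ceiling(seq_along(keep) / model$config$batch_size))) {
    r <- .model_lossgrad(model$params, model$config,
                         x_all[, , , chunk, drop = FALSE],
                         if (is.null(U_all)) NULL else
                           U_all[, chunk, drop = FALSE],
                         matrix(0, C, length(chunk)), model$config$beta,
                         want_grads = FALSE)
    out[chunk, ] <- t(r$mu)
  }
  attr(out, "keep") <- keep
  out
}

#' Fingerprint matrices for a whole ensemble
#'
#' @param ensemble a `vima_ensemble`.
#' @param patchset a [patch_set()].
#' @param alpha tissue-density threshold for inclusion in the analysis
#'   set (default 0.5; patches with `tissue_fraction > alpha` are kept).
#' @return list with `fingerprints` (list of P' x C matrices), `keep`
#'   (indices into the patch set) and `sample_ids`.
#' @export
fingerprint_matrices <- function(ensemble, patchset, alpha = 0.5) {
  fps <- lapply(ensemble$models, encode, patchset = patchset, alpha = alpha)
  keep <- attr(fps[[1]], "keep")
  list(fingerprints = lapply(fps, function(m) {
    attr(m, "keep") <- NULL
    m
  }), keep = keep, sample_ids = patchset$sample_ids[keep])
}

#' Reconstruction quality metrics
#'
#' Compares the model's reconstruction MSE against two analytic
#' baselines: predicting the dataset-wide per-channel mean everywhere
#' (exactly 1.0 when the channels are standardized with population
#' variance over these pixels) and predicting each patch's own
#' per-channel mean.
#'
#' @param model a trained `vima_cvae`.
#' @param patchset a [patch_set()].
#' @return list with `model_mse`, `dataset_mean_mse`, `patch_mean_mse`.
#' @export
reconstruction_metrics <- function(model, patchset) {
  x <- patchset$patches  # P x s x s x K
  d <- dim(x)
  flat <- matrix(aperm(x, c(2, 3, 1, 4)), d[2] * d[3] * d[1], d[4])
  ch_mean <- colMeans(flat)
  dataset_mean_mse <- mean(sweep(flat, 2, ch_mean)^2)
  pm <- apply(x, c(1, 4), mean)  # P x K patch means
  patch_mean_mse <- mean((x - aperm(array(pm, c(d[1], d[4], d[2], d[3])),
                                    c(1, 3, 4, 2)))^2)
  x_all <- aperm(x, c(4, 2, 3, 1))
  U_all <- if (model$config$variant == "resnet_cvae")
    .cond_inputs(model, patchset$sample_ids) else NULL
  se <- 0
  for (chunk in split(seq_len(d[1]),
                      ceiling(seq_len(d[1]) / model$config$batch_size))) {
    r <- .model_lossgrad(model$params, model$config,
                         x_all[, , , chunk, drop = FALSE],
                         if (is.null(U_all)) NULL else
                           U_all[, chunk, drop = FALSE],
                         matrix(0, model$C, length(chunk)),
                         model$config$beta, want_grads = FALSE)
    se <- se + mean((r$xhat - x_all[, , , chunk, drop = FALSE])^2) *
      length(chunk)
  }
  list(model_mse = se / d[1], dataset_mean_mse = dataset_mean_mse,
       patch_mean_mse = patch_mean_mse)
}
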