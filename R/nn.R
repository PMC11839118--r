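# Internal neural-network primitives for the patch autoencoders.
#
# Activations are arrays dim = c(channels, H, W, batch).  Parameters live
# in a flat named list; gradients accumulate in an environment so that
# layers shared across call sites (the conditioning embeddings) sum their
# contributions.

.conv_init <- function(cin, cout, k = 3) {
  fan <- cin * k * k
  list(W = matrix(rnorm(fan * cout, sd = sqrt(2 / fan)), fan, cout),
       b = numeric(cout))
}

.dense_init <- function(din, dout) {
  list(W = matrix(rnorm(din * dout, sd = sqrt(2 / din)), din, dout),
       b = numeric(dout))
}

.relu <- function(x) .relu_fwd(x)

## broadcast an (C x B) matrix to a (C x H x W x B) activation
.bcast <- function(m, H, W) {
  B <- ncol(m)
  array(m[, rep(seq_len(B), each = H * W), drop = FALSE],
        c(nrow(m), H, W, B))
}

## concatenate conditioning channels (wc: 4 x B) under an activation
.ccat <- function(x, wc) .ccat_cpp(x, wc)

## split gradient of a concatenated activation; returns list(dx, dwc)
.ccat_bwd <- function(dxc, n_main) .ccat_bwd_cpp(dxc, as.integer(n_main))

.up2 <- function(x) .up2_cpp(x)

.up2_bwd <- function(dy) .up2_bwd_cpp(dy)

.gap <- function(x) {
  d <- dim(x)
  matrix(apply(x, c(1, 4), mean), d[1], d[4])
}

.gap_bwd <- function(dg, H, W) .bcast(dg / (H * W), H, W)

.dense_f <- function(params, name, x) {
  # x: (din x B) -> (dout x B)
  crossprod(params[[paste0(name, ".W")]], x) + params[[paste0(name, ".b")]]
}

.dense_b <- function(params, name, x, dy, genv) {
  .acc(genv, paste0(name, ".W"), x %*% t(dy))
  .acc(genv, paste0(name, ".b"), rowSums(dy))
  params[[paste0(name, ".W")]] %*% dy
}

.conv_f <- function(params, name, x, stride = 1L) {
  .conv_fwd(x, params[[paste0(name, ".W")]], params[[paste0(name, ".b")]],
            as.integer(stride), 1L)
}

.conv_b <- function(params, name, x, dy, genv, stride = 1L) {
  r <- .conv_bwd(x, params[[paste0(name, ".W")]], dy, as.integer(stride), 1L)
  .acc(genv, paste0(name, ".W"), r$dW)
  .acc(genv, paste0(name, ".b"), r$db)
  r$dx
}

.acc <- function(genv, name, val) {
  cur <- genv$g[[name]]
  genv$g[[name]] <- if (is.null(cur)) val else cur + val
}

## residual block: out = relu(h + conv_b(relu(conv_a(h))))
.res_f <- function(params, pre, h) {
  a <- .conv_f(params, paste0(pre, "a"), h)
  ar <- .relu(a)
  bb <- .conv_f(params, paste0(pre, "b"), ar)
  o <- .relu(h + bb)
  list(o = o, a = a, ar = ar, h = h)
}

.res_bwd <- function(params, pre, cache, o, do, genv) {
  dm <- .relu_bwd(do, o)
  dar <- .relu_bwd(.conv_b(params, paste0(pre, "b"), cache$ar, dm, genv),
                   cache$a)
  dh <- .conv_b(params, paste0(pre, "a"), cache$h, dar, genv)
  dm + dh
}

## Adam with flat parameter lists
.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adam_step <- function(params, grads, st, lr, b1 = 0.9, b2 = 0.999,
                       eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - b1^st$t
  c2 <- 1 - b2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + eps)
  }
  list(params = params, state = st)
}
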