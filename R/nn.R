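## Internal 3D neural-network engine.
##
## Activations flow through two representations:
##   spatial: list(kind = "spatial", X = (B * nvox) x C matrix, sdim, B)
##            rows sample-major, voxels in array linear order within a sample
##   dense:   list(kind = "dense",   X = B x F matrix)
## Convolutions are evaluated as im2col matrix products; the index matrices
## that implement im2col depend only on (input dims, kernel, stride, padding,
## channels) and are memoized.

.nf_geom_cache <- new.env(parent = emptyenv())

conv_out_dim <- function(n, k, s, p) floor((n + 2 * p - k) / s) + 1L

## linear-index machinery for one (geometry, channels) pair
im2col_geometry <- function(sdim, k, stride, pad, n_ch) {
  key <- paste(c(sdim, k, stride, pad, n_ch), collapse = "_")
  hit <- .nf_geom_cache[[key]]
  if (!is.null(hit)) return(hit)
  od <- conv_out_dim(sdim, k, stride, pad)
  if (any(od < 1L))
    stop(sprintf(
      "input spatial dims %s too small for kernel %d / stride %d / padding %d",
      paste(sdim, collapse = "x"), k, stride, pad), call. = FALSE)
  pd <- sdim + 2L * pad
  starts <- lapply(1:3, function(a) (seq_len(od[a]) - 1L) * stride + 1L)
  start_lin <- as.vector(outer(
    outer(starts[[1]], (starts[[2]] - 1L) * pd[1], "+"),
    (starts[[3]] - 1L) * pd[1] * pd[2], "+"))
  koff <- as.vector(outer(
    outer(0:(k - 1L), (0:(k - 1L)) * pd[1], "+"),
    (0:(k - 1L)) * pd[1] * pd[2], "+"))
  idx1 <- outer(start_lin, koff, "+")           # nout x k^3, channel 1
  npad <- prod(pd)
  ## conv layout: columns grouped by channel -> nout x (k^3 * n_ch)
  idx_conv <- do.call(cbind, lapply(seq_len(n_ch) - 1L,
                                    function(c) idx1 + c * npad))
  ## pool layout: rows grouped by channel -> (nout * n_ch) x k^3
  idx_pool <- do.call(rbind, lapply(seq_len(n_ch) - 1L,
                                    function(c) idx1 + c * npad))
  g <- list(od = od, pd = pd, npad = npad, nout = prod(od),
            idx_conv = idx_conv, idx_pool = idx_pool,
            scatter_plan = make_scatter_plan(as.vector(idx_conv)),
            core = lapply(1:3, function(a) pad + seq_len(sdim[a])))
  .nf_geom_cache[[key]] <- g
  g
}

## precomputed plan for scatter-adding values with a FIXED index pattern:
## sort once, then each scatter is an O(L) gather + cumsum
make_scatter_plan <- function(gvec) {
  ord <- order(gvec, method = "radix")
  gs <- gvec[ord]
  L <- length(gs)
  ends <- c(which(gs[-1L] != gs[-L]), L)
  list(ord = ord, ends = ends, ids = gs[ends])
}

scatter_add_planned <- function(values, plan, n) {
  s <- cumsum(values[plan$ord])[plan$ends]
  out <- numeric(n)
  out[plan$ids] <- s - c(0, s[-length(s)])
  out
}

pad_sample <- function(xmat, sdim, pd, core, n_ch, fill = 0) {
  xpad <- array(fill, dim = c(pd, n_ch))
  xpad[core[[1]], core[[2]], core[[3]], ] <- array(xmat, c(sdim, n_ch))
  xpad
}

scatter_add <- function(values, index, n) {
  rs <- rowsum(values, index)
  out <- numeric(n)
  out[as.integer(rownames(rs))] <- rs
  out
}

## ---- layer constructors -------------------------------------------------

layer_conv3d <- function(in_ch, out_ch, kernel = 3L, stride = 2L,
                         padding = 1L) {
  fan_in <- kernel^3 * in_ch
  list(type = "conv3d", in_ch = in_ch, out_ch = out_ch,
       kernel = as.integer(kernel), stride = as.integer(stride),
       padding = as.integer(padding),
       W = matrix(stats::rnorm(fan_in * out_ch, sd = sqrt(2 / fan_in)),
                  fan_in, out_ch),
       b = numeric(out_ch))
}

layer_batchnorm <- function(ch, momentum = 0.1, eps = 1e-5) {
  list(type = "batchnorm", ch = ch, gamma = rep(1, ch), beta = numeric(ch),
       running_mean = numeric(ch), running_var = rep(1, ch),
       momentum = momentum, eps = eps)
}

layer_relu <- function() list(type = "relu")

layer_maxpool3d <- function(kernel = 3L, stride = 2L, padding = 1L) {
  list(type = "maxpool", kernel = as.integer(kernel),
       stride = as.integer(stride), padding = as.integer(padding))
}

layer_avgpool_global <- function() list(type = "avgpool_global")

layer_flatten <- function() list(type = "flatten")

layer_linear <- function(in_f, out_f) {
  list(type = "linear", in_f = in_f, out_f = out_f,
       W = matrix(stats::rnorm(in_f * out_f, sd = sqrt(2 / in_f)),
                  in_f, out_f),
       b = numeric(out_f))
}

layer_dropout <- function(p) list(type = "dropout", p = p)

## ---- forward ------------------------------------------------------------

layer_forward <- function(layer, rep, training) {
  switch(layer$type,
    conv3d = {
      g <- im2col_geometry(rep$sdim, layer$kernel, layer$stride,
                           layer$padding, layer$in_ch)
      B <- rep$B
      nvox <- prod(rep$sdim)
      P <- matrix(0, B * g$nout, ncol(g$idx_conv))
      for (b in seq_len(B)) {
        rows <- ((b - 1L) * nvox + 1L):(b * nvox)
        xpad <- pad_sample(rep$X[rows, , drop = FALSE], rep$sdim, g$pd,
                           g$core, layer$in_ch)
        P[((b - 1L) * g$nout + 1L):(b * g$nout), ] <-
          matrix(xpad[as.vector(g$idx_conv)], g$nout, ncol(g$idx_conv))
      }
      Y <- P %*% layer$W
      Y <- Y + rep(layer$b, each = nrow(Y))
      list(rep = list(kind = "spatial", X = Y, sdim = g$od, B = B),
           cache = list(P = P, in_sdim = rep$sdim, g = g))
    },
    batchnorm = {
      X <- rep$X
      if (training) {
        mu <- colMeans(X)
        xc <- X - rep(mu, each = nrow(X))
        v <- colMeans(xc * xc)
        n <- nrow(X)
        layer$running_mean <- (1 - layer$momentum) * layer$running_mean +
          layer$momentum * mu
        vu <- if (n > 1) v * n / (n - 1) else v
        layer$running_var <- (1 - layer$momentum) * layer$running_var +
          layer$momentum * vu
      } else {
        mu <- layer$running_mean
        v <- layer$running_var
        xc <- X - rep(mu, each = nrow(X))
      }
      invstd <- 1 / sqrt(v + layer$eps)
      xhat <- xc * rep(invstd, each = nrow(X))
      Y <- xhat * rep(layer$gamma, each = nrow(X)) +
        rep(layer$beta, each = nrow(X))
      out <- rep; out$X <- Y
      list(rep = out, cache = list(xhat = xhat, invstd = invstd),
           layer = layer)
    },
    relu = {
      Y <- pmax(rep$X, 0)
      out <- rep; out$X <- Y
      list(rep = out, cache = list(active = rep$X > 0))
    },
    maxpool = {
      g <- im2col_geometry(rep$sdim, layer$kernel, layer$stride,
                           layer$padding, ncol(rep$X))
      B <- rep$B
      nvox <- prod(rep$sdim)
      C <- ncol(rep$X)
      Y <- matrix(0, B * g$nout, C)
      sel <- matrix(0L, B * g$nout, C)   # padded linear index of the argmax
      for (b in seq_len(B)) {
        rows <- ((b - 1L) * nvox + 1L):(b * nvox)
        xpad <- pad_sample(rep$X[rows, , drop = FALSE], rep$sdim, g$pd,
                           g$core, C, fill = -Inf)
        vals <- matrix(xpad[as.vector(g$idx_pool)], nrow(g$idx_pool),
                       ncol(g$idx_pool))
        am <- max.col(vals, ties.method = "first")
        mx <- vals[cbind(seq_len(nrow(vals)), am)]
        pick <- g$idx_pool[cbind(seq_len(nrow(vals)), am)]
        orows <- ((b - 1L) * g$nout + 1L):(b * g$nout)
        Y[orows, ] <- matrix(mx, g$nout, C)
        sel[orows, ] <- matrix(pick, g$nout, C)
      }
      list(rep = list(kind = "spatial", X = Y, sdim = g$od, B = B),
           cache = list(g = g, in_sdim = rep$sdim, in_ch = C, sel = sel))
    },
    avgpool_global = {
      nvox <- prod(rep$sdim)
      grp <- rep(seq_len(rep$B), each = nvox)
      Y <- rowsum(rep$X, grp) / nvox
      list(rep = list(kind = "dense", X = Y),
           cache = list(sdim = rep$sdim, B = rep$B))
    },
    flatten = {
      nvox <- prod(rep$sdim)
      C <- ncol(rep$X)
      Y <- matrix(0, rep$B, nvox * C)
      for (b in seq_len(rep$B)) {
        rows <- ((b - 1L) * nvox + 1L):(b * nvox)
        Y[b, ] <- as.vector(rep$X[rows, , drop = FALSE])
      }
      list(rep = list(kind = "dense", X = Y),
           cache = list(sdim = rep$sdim, B = rep$B, C = C))
    },
    linear = {
      Y <- rep$X %*% layer$W
      Y <- Y + rep(layer$b, each = nrow(Y))
      list(rep = list(kind = "dense", X = Y), cache = list(Xin = rep$X))
    },
    dropout = {
      if (training && layer$p > 0) {
        keep <- matrix(stats::runif(length(rep$X)) >= layer$p,
                       nrow(rep$X), ncol(rep$X))
        Y <- rep$X * keep / (1 - layer$p)
        out <- rep; out$X <- Y
        list(rep = out, cache = list(keep = keep, p = layer$p))
      } else {
        list(rep = rep, cache = list(keep = NULL))
      }
    },
    stop("unknown layer type ", layer$type)
  )
}

net_forward <- function(layers, rep, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    st <- layer_forward(layers[[i]], rep, training)
    rep <- st$rep
    caches[[i]] <- st$cache
    if (!is.null(st$layer)) layers[[i]] <- st$layer  # BN running stats
  }
  list(out = rep$X, caches = caches, layers = layers)
}

## ---- backward -----------------------------------------------------------

layer_backward <- function(layer, cache, grad, guided = FALSE,
                           need_input = TRUE) {
  switch(layer$type,
    conv3d = {
      dW <- crossprod(cache$P, grad)
      db <- colSums(grad)
      if (!need_input) return(list(grad = NULL,
                                   grads = list(W = dW, b = db)))
      dP <- grad %*% t(layer$W)
      g <- cache$g
      B <- nrow(grad) / g$nout
      nvox <- prod(cache$in_sdim)
      dX <- matrix(0, B * nvox, layer$in_ch)
      npadtot <- g$npad * layer$in_ch
      for (b in seq_len(B)) {
        orows <- ((b - 1L) * g$nout + 1L):(b * g$nout)
        gp <- scatter_add_planned(as.vector(dP[orows, , drop = FALSE]),
                                  g$scatter_plan, npadtot)
        garr <- array(gp, dim = c(g$pd, layer$in_ch))
        dX[((b - 1L) * nvox + 1L):(b * nvox), ] <-
          matrix(garr[g$core[[1]], g$core[[2]], g$core[[3]], ],
                 nvox, layer$in_ch)
      }
      list(grad = dX, grads = list(W = dW, b = db))
    },
    batchnorm = {
      xhat <- cache$xhat
      n <- nrow(xhat)
      dxhat <- grad * rep(layer$gamma, each = n)
      dgamma <- colSums(grad * xhat)
      dbeta <- colSums(grad)
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * xhat)
      dX <- (dxhat - rep(s1 / n, each = n) - xhat * rep(s2 / n, each = n)) *
        rep(cache$invstd, each = n)
      list(grad = dX, grads = list(gamma = dgamma, beta = dbeta))
    },
    relu = {
      g <- grad * cache$active
      if (guided) g <- g * (g > 0)
      list(grad = g, grads = NULL)
    },
    maxpool = {
      g <- cache$g
      B <- nrow(grad) / g$nout
      nvox <- prod(cache$in_sdim)
      C <- cache$in_ch
      npadtot <- g$npad * C
      dX <- matrix(0, B * nvox, C)
      for (b in seq_len(B)) {
        orows <- ((b - 1L) * g$nout + 1L):(b * g$nout)
        gp <- scatter_add(as.vector(grad[orows, , drop = FALSE]),
                          as.vector(cache$sel[orows, , drop = FALSE]),
                          npadtot)
        garr <- array(gp, dim = c(g$pd, C))
        dX[((b - 1L) * nvox + 1L):(b * nvox), ] <-
          matrix(garr[g$core[[1]], g$core[[2]], g$core[[3]], ], nvox, C)
      }
      list(grad = dX, grads = NULL)
    },
    avgpool_global = {
      nvox <- prod(cache$sdim)
      dX <- grad[rep(seq_len(cache$B), each = nvox), , drop = FALSE] / nvox
      list(grad = dX, grads = NULL)
    },
    flatten = {
      nvox <- prod(cache$sdim)
      dX <- matrix(0, cache$B * nvox, cache$C)
      for (b in seq_len(cache$B)) {
        rows <- ((b - 1L) * nvox + 1L):(b * nvox)
        dX[rows, ] <- matrix(grad[b, ], nvox, cache$C)
      }
      list(grad = dX, grads = NULL)
    },
    linear = {
      list(grad = grad %*% t(layer$W),
           grads = list(W = crossprod(cache$Xin, grad), b = colSums(grad)))
    },
    dropout = {
      if (is.null(cache$keep)) list(grad = grad, grads = NULL)
      else list(grad = grad * cache$keep / (1 - cache$p), grads = NULL)
    },
    stop("unknown layer type ", layer$type)
  )
}

net_backward <- function(layers, caches, grad_out, guided = FALSE,
                         input_grad = TRUE) {
  grads <- vector("list", length(layers))
  grad <- grad_out
  for (i in rev(seq_along(layers))) {
    st <- layer_backward(layers[[i]], caches[[i]], grad, guided = guided,
                         need_input = input_grad || i > 1L)
    grad <- st$grad
    grads[i] <- list(st$grads)   # keep NULL slots (plain [[<- would drop them)
  }
  list(grad_input = grad, grads = grads)
}

## ---- batch assembly, loss, optimizer ------------------------------------

## stack a list of nf_model_input into the spatial representation
batch_to_rep <- function(inputs, n_channels) {
  B <- length(inputs)
  stopifnot(B >= 1L)
  for (inp in inputs) {
    stopifnot(inherits(inp, "nf_model_input"))
    if (length(inp$channels) != n_channels)
      stop(sprintf("model expects %d channels, input has %d",
                   n_channels, length(inp$channels)), call. = FALSE)
    if (!grid_equal(inputs[[1L]]$grid, inp$grid))
      stop("grid mismatch within batch", call. = FALSE)
  }
  sdim <- inputs[[1L]]$grid$dims
  nvox <- prod(sdim)
  X <- matrix(0, B * nvox, n_channels)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * nvox + 1L):(b * nvox)
    for (ch in seq_len(n_channels))
      X[rows, ch] <- as.vector(inputs[[b]]$channels[[ch]]$values)
  }
  list(kind = "spatial", X = X, sdim = sdim, B = B)
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

## mean cross-entropy and its gradient w.r.t. the logits
cross_entropy <- function(logits, y_idx) {
  B <- nrow(logits)
  p <- softmax_rows(logits)
  eps <- 1e-12
  loss <- -mean(log(pmax(p[cbind(seq_len(B), y_idx)], eps)))
  gr <- p
  gr[cbind(seq_len(B), y_idx)] <- gr[cbind(seq_len(B), y_idx)] - 1
  list(loss = loss, grad = gr / B)
}

adam_init <- function(layers) {
  lapply(layers, function(l) {
    nm <- intersect(c("W", "b", "gamma", "beta"), names(l))
    if (!length(nm)) return(NULL)
    stats::setNames(lapply(nm, function(p) {
      list(m = array(0, dim = dim(l[[p]]) %||% length(l[[p]])),
           v = array(0, dim = dim(l[[p]]) %||% length(l[[p]])))
    }), nm)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    gi <- grads[[i]]
    if (is.null(gi)) next
    for (p in names(gi)) {
      st <- state[[i]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * gi[[p]]
      st$v <- beta2 * st$v + (1 - beta2) * gi[[p]]^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[i]][[p]] <- layers[[i]][[p]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[p]] <- st
    }
  }
  list(layers = layers, state = state)
}

n_parameters <- function(layers) {
  sum(vapply(layers, function(l) {
    nm <- intersect(c("W", "b", "gamma", "beta"), names(l))
    sum(vapply(nm, function(p) length(l[[p]]), 0))
  }, 0))
}
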