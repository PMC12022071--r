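# Minimal convolutional-network engine on BLAS matrix operations.
#
# Activations for a batch of N samples are stored as (N * H * W) x C
# matrices with sample-major row blocks; 3x3 same-padding convolutions are
# evaluated as a single GEMM against an im2col gather, 2x2 max-pooling and
# batch normalization operate on the same layout. Everything is driven by
# R's RNG so training is reproducible under set.seed().

# neighbour map for 3x3 same-padding convolution on an H x W grid
# (column-major positions; 0 marks zero padding)
.conv_index <- function(H, W) {
  ii <- rep(seq_len(H), W); jj <- rep(seq_len(W), each = H)
  P <- matrix(0L, H * W, 9)
  k <- 0L
  for (dj in -1:1) for (di in -1:1) {
    k <- k + 1L
    ni <- ii + di; nj <- jj + dj
    ok <- ni >= 1 & ni <= H & nj >= 1 & nj <= W
    P[ok, k] <- (nj[ok] - 1L) * H + ni[ok]
  }
  P
}

# child map for 2x2/stride-2 max pooling
.pool_index <- function(H, W) {
  Ho <- H %/% 2L; Wo <- W %/% 2L
  oi <- rep(seq_len(Ho), Wo); oj <- rep(seq_len(Wo), each = Ho)
  cbind((2L * oj - 2L) * H + 2L * oi - 1L,
        (2L * oj - 2L) * H + 2L * oi,
        (2L * oj - 1L) * H + 2L * oi - 1L,
        (2L * oj - 1L) * H + 2L * oi)
}

.batch_index <- function(P, N, HW) {
  Pg <- P[rep(seq_len(nrow(P)), N), , drop = FALSE]
  offs <- rep((seq_len(N) - 1L) * HW, each = nrow(P))
  Pg + offs * (Pg > 0L)
}

.im2col <- function(A, Pg, Cin) {
  Xp <- matrix(0, nrow(Pg), 9L * Cin)
  for (k in 1:9) {
    rows <- Pg[, k]; ok <- rows > 0L
    Xp[ok, ((k - 1L) * Cin + 1L):(k * Cin)] <- A[rows[ok], , drop = FALSE]
  }
  Xp
}

.col2im <- function(dXp, Pg, Cin, nrow_A) {
  dA <- matrix(0, nrow_A, Cin)
  for (k in 1:9) {
    rows <- Pg[, k]; ok <- rows > 0L
    cols <- ((k - 1L) * Cin + 1L):(k * Cin)
    dA[rows[ok], ] <- dA[rows[ok], , drop = FALSE] + dXp[ok, cols, drop = FALSE]
  }
  dA
}


# column-wise scale / add without sweep()'s aperm overhead
.cs <- function(M, v) M * rep(v, each = nrow(M))
.ca <- function(M, v) M + rep(v, each = nrow(M))

.he_init <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
}

# Build network parameters. Architecture: n_blocks of
# {conv3x3 -> batchnorm -> relu -> maxpool2}, then dense -> relu ->
# dropout -> dense -> softmax.
.cnn_init <- function(input_dim = c(120L, 120L), filters = c(8L, 16L, 32L),
                      dense_units = 64L, n_classes = 3L) {
  H <- input_dim[1]; W <- input_dim[2]
  layers <- list()
  Cin <- 1L
  for (b in seq_along(filters)) {
    Cout <- filters[b]
    layers[[length(layers) + 1L]] <- list(
      type = "conv", H = H, W = W, Cin = Cin, Cout = Cout,
      P = .conv_index(H, W),
      W_ = .he_init(9L * Cin, Cout), b_ = rep(0, Cout),
      gamma = rep(1, Cout), beta = rep(0, Cout),
      run_mean = rep(0, Cout), run_var = rep(1, Cout)
    )
    layers[[length(layers) + 1L]] <- list(
      type = "pool", H = H, W = W, C = Cout, Q = .pool_index(H, W)
    )
    H <- H %/% 2L; W <- W %/% 2L
    Cin <- Cout
  }
  flat <- H * W * Cin
  net <- list(
    layers = layers, flat_dim = flat, flat_H = H, flat_W = W, flat_C = Cin,
    W1 = .he_init(flat, dense_units), b1 = rep(0, dense_units),
    W2 = .he_init(dense_units, n_classes), b2 = rep(0, n_classes),
    input_dim = input_dim, n_classes = n_classes
  )
  net
}

# forward pass; X is (N*H*W) x 1. Returns cache when train = TRUE.
.cnn_forward <- function(net, X, N, train = FALSE, dropout = 0.5,
                         bn_momentum = 0.7) {
  A <- X
  cache <- list(N = N)
  li <- 0L
  for (L in net$layers) {
    li <- li + 1L
    if (L$type == "conv") {
      HW <- L$H * L$W
      Pg <- .batch_index(L$P, N, HW)
      Xp <- .im2col(A, Pg, L$Cin)
      Z <- .ca(Xp %*% L$W_, L$b_)
      if (train) {
        mu <- colMeans(Z)
        zc <- .ca(Z, -mu)
        va <- colMeans(zc^2)
        net$layers[[li]]$run_mean <- bn_momentum * L$run_mean + (1 - bn_momentum) * mu
        net$layers[[li]]$run_var  <- bn_momentum * L$run_var + (1 - bn_momentum) * va
      } else {
        mu <- L$run_mean; va <- L$run_var
        zc <- .ca(Z, -mu)
      }
      inv_sd <- 1 / sqrt(va + 1e-5)
      xhat <- .cs(zc, inv_sd)
      out <- .ca(.cs(xhat, L$gamma), L$beta)
      relu_mask <- out > 0
      A2 <- out * relu_mask
      if (train) {
        cache[[paste0("L", li)]] <- list(Pg = Pg, Xp = Xp, zc = zc, inv_sd = inv_sd,
                            xhat = xhat, relu_mask = relu_mask,
                            nrow_A = nrow(A))
      }
      A <- A2
    } else {
      HW <- L$H * L$W
      Qg <- .batch_index(L$Q, N, HW)
      M1 <- A[Qg[, 1], , drop = FALSE]; M2 <- A[Qg[, 2], , drop = FALSE]
      M3 <- A[Qg[, 3], , drop = FALSE]; M4 <- A[Qg[, 4], , drop = FALSE]
      out <- pmax(M1, M2, M3, M4)
      if (train) cache[[paste0("L", li)]] <- list(Qg = Qg, Ms = list(M1, M2, M3, M4),
                                     out = out, nrow_A = nrow(A))
      A <- out
    }
  }
  # flatten: (N*hw) x C -> N x (hw*C)
  hw <- net$flat_H * net$flat_W
  arr <- array(A, c(hw, N, net$flat_C))
  Fmat <- t(matrix(aperm(arr, c(1, 3, 2)), hw * net$flat_C, N))
  H1 <- .ca(Fmat %*% net$W1, net$b1)
  relu1 <- H1 > 0
  H1 <- H1 * relu1
  if (train && dropout > 0) {
    dmask <- matrix(stats::runif(length(H1)) > dropout, nrow(H1), ncol(H1)) /
      (1 - dropout)
    H1d <- H1 * dmask
  } else {
    dmask <- NULL
    H1d <- H1
  }
  logits <- .ca(H1d %*% net$W2, net$b2)
  mx <- apply(logits, 1, max)
  ex <- exp(logits - mx)
  probs <- ex / rowSums(ex)
  list(net = net, probs = probs, logits = logits,
       cache = if (train) c(cache, list(Fmat = Fmat, H1 = H1, relu1 = relu1,
                                        dmask = dmask, H1d = H1d)) else NULL)
}

# backward pass; Y is N x K one-hot. Returns gradients mirroring net params.
.cnn_backward <- function(net, fw, Y) {
  N <- fw$cache$N
  dlogits <- (fw$probs - Y) / N
  grads <- list()
  grads$W2 <- crossprod(fw$cache$H1d, dlogits)
  grads$b2 <- colSums(dlogits)
  dH1 <- dlogits %*% t(net$W2)
  if (!is.null(fw$cache$dmask)) dH1 <- dH1 * fw$cache$dmask
  dH1 <- dH1 * fw$cache$relu1
  grads$W1 <- crossprod(fw$cache$Fmat, dH1)
  grads$b1 <- colSums(dH1)
  dF <- dH1 %*% t(net$W1)
  # unflatten
  hw <- net$flat_H * net$flat_W
  arr <- aperm(array(t(dF), c(hw, net$flat_C, N)), c(1, 3, 2))
  dA <- matrix(arr, hw * N, net$flat_C)
  grads$layers <- vector("list", length(net$layers))
  for (li in rev(seq_along(net$layers))) {
    L <- net$layers[[li]]
    cc <- fw$cache[[paste0("L", li)]]
    if (L$type == "pool") {
      dIn <- matrix(0, cc$nrow_A, L$C)
      claimed <- matrix(FALSE, nrow(dA), ncol(dA))
      for (k in 1:4) {
        sel <- (cc$Ms[[k]] == cc$out) & !claimed
        claimed <- claimed | sel
        dsel <- dA * sel
        rows <- cc$Qg[, k]
        dIn[rows, ] <- dIn[rows, , drop = FALSE] + dsel
      }
      dA <- dIn
    } else {
      dOut <- dA * cc$relu_mask
      m <- nrow(dOut)
      dgamma <- colSums(dOut * cc$xhat)
      dbeta <- colSums(dOut)
      dxhat <- .cs(dOut, L$gamma)
      # batch-norm backward (train-time statistics)
      inner <- dxhat - .cs(cc$xhat, colSums(dxhat * cc$xhat) / m)
      inner <- .ca(inner, -colSums(dxhat) / m)
      dZ <- .cs(inner, cc$inv_sd)
      gW <- crossprod(cc$Xp, dZ)
      gb <- colSums(dZ)
      dXp <- dZ %*% t(L$W_)
      dA <- .col2im(dXp, cc$Pg, L$Cin, cc$nrow_A)
      grads$layers[[li]] <- list(W_ = gW, b_ = gb, gamma = dgamma,
                                 beta = dbeta)
    }
  }
  grads
}

.adam_new <- function() list(t = 0)

.adam_update <- function(state, key, param, grad, lr,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  m <- state[[paste0(key, ".m")]]
  v <- state[[paste0(key, ".v")]]
  if (is.null(m)) { m <- param * 0; v <- param * 0 }
  m <- beta1 * m + (1 - beta1) * grad
  v <- beta2 * v + (1 - beta2) * grad^2
  mh <- m / (1 - beta1^state$t)
  vh <- v / (1 - beta2^state$t)
  state[[paste0(key, ".m")]] <- m
  state[[paste0(key, ".v")]] <- v
  list(state = state, param = param - lr * mh / (sqrt(vh) + eps))
}

.cnn_sgd_step <- function(net, grads, adam, lr) {
  adam$t <- adam$t + 1
  for (nm in c("W1", "b1", "W2", "b2")) {
    up <- .adam_update(adam, nm, net[[nm]], grads[[nm]], lr)
    adam <- up$state; net[[nm]] <- up$param
  }
  for (li in seq_along(net$layers)) {
    if (net$layers[[li]]$type != "conv") next
    for (nm in c("W_", "b_", "gamma", "beta")) {
      key <- paste0("L", li, ".", nm)
      up <- .adam_update(adam, key, net$layers[[li]][[nm]],
                         grads$layers[[li]][[nm]], lr)
      adam <- up$state; net$layers[[li]][[nm]] <- up$param
    }
  }
  list(net = net, adam = adam)
}

# stack a list of H x W patches into the (N*H*W) x 1 activation layout
.stack_patches <- function(patches) {
  matrix(unlist(patches, use.names = FALSE), ncol = 1)
}

# f x f average pooling of a matrix (network input downscaling)
.avg_pool_mat <- function(m, f) {
  if (f <= 1) return(m)
  n1 <- (nrow(m) %/% f) * f; n2 <- (ncol(m) %/% f) * f
  a <- array(m[seq_len(n1), seq_len(n2)], c(f, n1 / f, n2))
  s1 <- colMeans(a)                     # (n1/f) x n2
  a2 <- array(t(s1), c(f, n2 / f, n1 / f))
  t(colMeans(a2))
}

.one_hot <- function(labels, classes) {
  Y <- matrix(0, length(labels), length(classes))
  Y[cbind(seq_along(labels), match(labels, classes))] <- 1
  Y
}

# Train one network member. patches: list of 120x120 matrices (already
# preprocessed); labels: character; val_*: held-out fold.
.cnn_train <- function(patches, labels, classes, cfg,
                       val_patches = NULL, val_labels = NULL) {
  ds <- cfg$input_downscale
  if (is.null(ds)) ds <- 1L
  if (ds > 1) {
    patches <- lapply(patches, .avg_pool_mat, f = ds)
    if (!is.null(val_patches)) val_patches <- lapply(val_patches, .avg_pool_mat, f = ds)
  }
  net <- .cnn_init(input_dim = dim(patches[[1]]), filters = cfg$filters,
                   dense_units = cfg$dense_units, n_classes = length(classes))
  net$downscale <- ds
  adam <- .adam_new()
  n <- length(patches)
  best <- list(val_loss = Inf, net = net, epoch = 0)
  history <- data.frame()
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cfg$learning_rate * cfg$lr_decay^((epoch - 1) %/% cfg$decay_every)
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n)]
      bp <- patches[idx]
      if (isTRUE(cfg$augment)) bp <- lapply(bp, augment_patch)
      X <- .stack_patches(bp)
      Y <- .one_hot(labels[idx], classes)
      fw <- .cnn_forward(net, X, length(idx), train = TRUE,
                         dropout = cfg$dropout)
      net <- fw$net
      loss <- -mean(log(pmax(fw$probs[cbind(seq_along(idx),
                                            max.col(Y))], 1e-12)))
      if (!is.finite(loss)) {
        stop("training diverged (non-finite loss) at epoch ", epoch,
             "; reduce the learning rate")
      }
      grads <- .cnn_backward(net, fw, Y)
      st <- .cnn_sgd_step(net, grads, adam, lr)
      net <- st$net; adam <- st$adam
      ep_loss <- ep_loss + loss; nb <- nb + 1
    }
    val_loss <- NA_real_; val_acc <- NA_real_
    if (!is.null(val_patches)) {
      pv <- .cnn_predict(net, val_patches)
      val_loss <- -mean(log(pmax(pv[cbind(seq_along(val_labels),
                                          match(val_labels, classes))], 1e-12)))
      val_acc <- mean(classes[max.col(pv)] == val_labels)
      if (val_loss < best$val_loss) best <- list(val_loss = val_loss,
                                                 net = net, epoch = epoch)
    }
    history <- rbind(history, data.frame(epoch = epoch, lr = lr,
                                         train_loss = ep_loss / nb,
                                         val_loss = val_loss,
                                         val_acc = val_acc))
    if (!is.null(val_patches) && cfg$patience > 0 &&
        epoch - best$epoch >= cfg$patience) break
  }
  net <- if (cfg$patience > 0 && is.finite(best$val_loss)) best$net else net
  list(net = net, history = history)
}

.cnn_predict <- function(net, patches, batch = 64L) {
  if (!is.null(net$downscale) && net$downscale > 1 &&
      !all(dim(patches[[1]]) == net$input_dim)) {
    patches <- lapply(patches, .avg_pool_mat, f = net$downscale)
  }
  n <- length(patches)
  out <- matrix(0, n, net$n_classes)
  for (start in seq(1, n, by = batch)) {
    idx <- start:min(start + batch - 1, n)
    X <- .stack_patches(patches[idx])
    fw <- .cnn_forward(net, X, length(idx), train = FALSE)
    out[idx, ] <- fw$probs
  }
  out
}
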