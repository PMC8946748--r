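# Feed-forward softmax classifier implemented with base-R matrix ops:
# fully connected ReLU layers, inverted dropout between them, batch
# normalization after the last two dropout layers, Adam optimization with
# early stopping on validation loss.

#' Network architecture and optimizer specification
#'
#' Defaults are the published architecture: four 512-node fully connected
#' layers with ReLU activation, 50% dropout between fully connected layers,
#' batch normalization after the last two dropout layers, and a softmax
#' output layer. Optimizer settings (unpublished) default to Adam with
#' batch size 128, at most 100 epochs and early-stopping patience 10.
#'
#' @param hidden Hidden layer widths.
#' @param dropout Dropout probability between fully connected layers.
#' @param batchnorm_layers Indices of hidden layers followed by batch
#'   normalization (default: the last two).
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement).
#' @return A list of class `network_spec`.
#' @export
network_spec <- function(hidden = c(512, 512, 512, 512), dropout = 0.5,
                         batchnorm_layers = c(length(hidden) - 1, length(hidden)),
                         lr = 1e-3, batch_size = 128, max_epochs = 100,
                         patience = 10) {
  stopifnot(length(hidden) >= 1, dropout >= 0, dropout < 1)
  structure(list(hidden = hidden, dropout = dropout,
                 batchnorm_layers = batchnorm_layers, lr = lr,
                 batch_size = batch_size, max_epochs = max_epochs,
                 patience = patience), class = "network_spec")
}

.relu <- function(z) z * (z > 0)

.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass in evaluation mode (no dropout; batch norm uses running
# statistics). Returns the softmax probability matrix.
#' Evaluate a trained network
#' @param model A model from [train_network()].
#' @param x Feature matrix.
#' @return Softmax probabilities, one row per example (rows sum to 1).
#' @export
mlp_forward <- function(model, x) {
  a <- x
  L <- length(model$W) - 1L
  eps <- 1e-5
  for (l in seq_len(L)) {
    a <- .relu(sweep(a %*% model$W[[l]], 2, model$b[[l]], `+`))
    if (l %in% model$spec$batchnorm_layers) {
      bn <- model$bn[[as.character(l)]]
      a <- sweep(sweep(a, 2, bn$mean, `-`), 2, sqrt(bn$var + eps), `/`)
      a <- sweep(sweep(a, 2, bn$gamma, `*`), 2, bn$beta, `+`)
    }
  }
  .softmax(sweep(a %*% model$W[[L + 1L]], 2, model$b[[L + 1L]], `+`))
}

#' Train the feed-forward bin classifier
#'
#' @param partitions A `balanced_set` from [build_balanced_set()], or any
#'   list with `train$x`, `train$y`, `val$x`, `val$y`.
#' @param spec [network_spec()].
#' @param seed Optional seed (weight initialization, shuffling, dropout).
#' @param verbose Print per-epoch losses.
#' @return A model list (weights, batch-norm statistics, `classes`,
#'   `n_in`, training `log`) usable with [mlp_forward()] and
#'   [predict_bins()].
#' @export
train_network <- function(partitions, spec = network_spec(), seed = NULL,
                          verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  x <- partitions$train$x
  y <- partitions$train$y
  stopifnot(is.matrix(x), nrow(x) == length(y))
  classes <- levels(y)
  K <- length(classes)
  sizes <- c(ncol(x), spec$hidden, K)
  L <- length(spec$hidden)
  W <- list(); b <- list(); bn <- list()
  for (l in seq_len(L + 1)) {
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1],
                           sd = sqrt(2 / sizes[l])), sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  for (l in spec$batchnorm_layers) {
    bn[[as.character(l)]] <- list(gamma = rep(1, sizes[l + 1]),
                                  beta = numeric(sizes[l + 1]),
                                  mean = numeric(sizes[l + 1]),
                                  var = rep(1, sizes[l + 1]))
  }
  # Adam state
  zeros_like <- function(p) if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p))
  adam <- new.env()
  adam$t <- 0
  upd <- function(key, param, grad, lr) {
    m <- adam[[paste0("m", key)]]
    v <- adam[[paste0("v", key)]]
    if (is.null(m)) { m <- zeros_like(param); v <- zeros_like(param) }
    m <- 0.9 * m + 0.1 * grad
    v <- 0.999 * v + 0.001 * grad^2
    adam[[paste0("m", key)]] <- m
    adam[[paste0("v", key)]] <- v
    mh <- m / (1 - 0.9^adam$t)
    vh <- v / (1 - 0.999^adam$t)
    param - lr * mh / (sqrt(vh) + 1e-8)
  }
  Y <- diag(K)[as.integer(y), , drop = FALSE]
  eps <- 1e-5
  model <- list(W = W, b = b, bn = bn, spec = spec, classes = classes,
                n_in = ncol(x))
  ce_loss <- function(m, xx, yy) {
    p <- mlp_forward(m, xx)
    -mean(log(pmax(p[cbind(seq_along(yy), as.integer(yy))], 1e-12)))
  }
  best <- list(loss = Inf, model = model)
  stall <- 0
  n <- nrow(x)
  log_rows <- list()
  for (epoch in seq_len(spec$max_epochs)) {
    ord <- sample.int(n)
    for (b0 in seq(1, n, by = spec$batch_size)) {
      idx <- ord[b0:min(n, b0 + spec$batch_size - 1)]
      if (length(idx) < 2) next
      a <- x[idx, , drop = FALSE]
      yb <- Y[idx, , drop = FALSE]
      m_b <- length(idx)
      cache <- list()
      for (l in seq_len(L)) {
        z <- sweep(a %*% model$W[[l]], 2, model$b[[l]], `+`)
        h <- .relu(z)
        mask <- (matrix(runif(length(h)), nrow(h)) >= spec$dropout) /
          (1 - spec$dropout)
        hd <- h * mask
        st <- list(a_in = a, z = z, mask = mask)
        if (l %in% spec$batchnorm_layers) {
          key <- as.character(l)
          mu <- colMeans(hd)
          va <- colMeans(sweep(hd, 2, mu)^2)
          xc <- sweep(hd, 2, mu)
          istd <- 1 / sqrt(va + eps)
          xhat <- sweep(xc, 2, istd, `*`)
          a <- sweep(sweep(xhat, 2, model$bn[[key]]$gamma, `*`), 2,
                     model$bn[[key]]$beta, `+`)
          st$bn <- list(xc = xc, istd = istd, xhat = xhat)
          model$bn[[key]]$mean <- 0.9 * model$bn[[key]]$mean + 0.1 * mu
          model$bn[[key]]$var <- 0.9 * model$bn[[key]]$var + 0.1 * va
        } else {
          a <- hd
        }
        cache[[l]] <- st
      }
      logits <- sweep(a %*% model$W[[L + 1]], 2, model$b[[L + 1]], `+`)
      probs <- .softmax(logits)
      if (any(!is.finite(probs)))
        stop("training diverged (non-finite softmax) at epoch ", epoch)
      dz <- (probs - yb) / m_b
      adam$t <- adam$t + 1
      gW <- crossprod(a, dz)
      gb <- colSums(dz)
      da <- dz %*% t(model$W[[L + 1]])
      model$W[[L + 1]] <- upd(paste0("W", L + 1), model$W[[L + 1]], gW, spec$lr)
      model$b[[L + 1]] <- upd(paste0("b", L + 1), model$b[[L + 1]], gb, spec$lr)
      for (l in rev(seq_len(L))) {
        st <- cache[[l]]
        if (l %in% spec$batchnorm_layers) {
          key <- as.character(l)
          g <- model$bn[[key]]$gamma
          dgamma <- colSums(da * st$bn$xhat)
          dbeta <- colSums(da)
          dxhat <- sweep(da, 2, g, `*`)
          mb <- nrow(da)
          dhd <- sweep(dxhat, 2, st$bn$istd, `*`) -
            sweep(st$bn$xhat, 2, st$bn$istd * colMeans(dxhat * st$bn$xhat), `*`) -
            matrix(rep(st$bn$istd * colMeans(dxhat), each = mb), mb)
          model$bn[[key]]$gamma <- upd(paste0("g", l), g, dgamma, spec$lr)
          model$bn[[key]]$beta <- upd(paste0("be", l), model$bn[[key]]$beta,
                                      dbeta, spec$lr)
          da <- dhd
        }
        dh <- da * st$mask
        dzl <- dh * (st$z > 0)
        gW <- crossprod(st$a_in, dzl)
        gb <- colSums(dzl)
        da <- dzl %*% t(model$W[[l]])
        model$W[[l]] <- upd(paste0("W", l), model$W[[l]], gW, spec$lr)
        model$b[[l]] <- upd(paste0("b", l), model$b[[l]], gb, spec$lr)
      }
    }
    vloss <- if (!is.null(partitions$val) && length(partitions$val$y) > 0)
      ce_loss(model, partitions$val$x, partitions$val$y)
    else ce_loss(model, x, y)
    if (!is.finite(vloss)) stop("training diverged (non-finite loss)")
    log_rows[[epoch]] <- data.frame(epoch = epoch, val_loss = vloss)
    if (verbose) message("epoch ", epoch, " val loss ", round(vloss, 4))
    if (vloss < best$loss - 1e-6) {
      best <- list(loss = vloss, model = model)
      stall <- 0
    } else {
      stall <- stall + 1
      if (stall >= spec$patience) break
    }
  }
  out <- best$model
  out$log <- do.call(rbind, log_rows)
  out
}
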