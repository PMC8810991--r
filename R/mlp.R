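# Internal fully connected network engine.
#
# All learners in the package (ensemble members, the stage-two defer
# network, the LD baseline) are small multilayer perceptrons with a
# softmax head, trained by minibatch SGD (optionally Adam).  At the
# problem sizes this package targets (thousands of rows, tens of
# columns) vectorised base R matrix ops are fast and keep the gradient
# of the defer loss transparent, which is the point: the weighted defer
# loss is the method's core and its gradient must be auditable.

#' Weighted defer loss
#'
#' Cross-entropy over `C + 1` outputs (the `C` diagnostic classes plus a
#' final defer output) combining a target-class term and a defer term,
#' with relative weight `alpha`.  This is the training loss of both the
#' stage-two defer network and the LD baseline.
#'
#' With `alpha_on = "target"` (the default) the value is
#' `alpha * CE(target) + CE(defer)`, where `CE(j) = -log softmax(scores)[j]`.
#' Under this parameterisation *decreasing* `alpha` encourages deferral
#' and *increasing* it encourages automated diagnosis, which is the
#' direction all reported defer-rate sweeps follow.  `alpha_on = "defer"`
#' gives the transposed form `CE(target) + alpha * CE(defer)`.  The two
#' parameterisations coincide exactly at `alpha = 1`.  See the package
#' vignette for why `"target"` is the default.
#'
#' @param scores Numeric vector of `C + 1` raw (pre-softmax) scores, the
#'   defer output last; or a matrix with one such row per sample.
#' @param target Integer class index in `0 .. C-1` (scalar, or one per
#'   row of `scores`).
#' @param alpha Positive weight balancing diagnosis against deferral.
#' @param alpha_on Which term carries the weight; see Details.
#' @return Numeric loss value (one per row of `scores`).
#' @examples
#' defer_loss(c(0, 0, 0), target = 0, alpha = 1)   # 2 * log(3)
#' defer_loss(c(2, 0, -1), target = 1, alpha = 0.5)
#' @export
defer_loss <- function(scores, target, alpha, alpha_on = c("target", "defer")) {
  alpha_on <- match.arg(alpha_on)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0) {
    stop("`alpha` must be a single finite number > 0.", call. = FALSE)
  }
  if (is.vector(scores)) scores <- matrix(scores, nrow = 1L)
  if (!all(is.finite(scores))) {
    stop("`scores` must be finite.", call. = FALSE)
  }
  n_out <- ncol(scores)
  if (n_out < 2L) stop("`scores` needs at least two outputs.", call. = FALSE)
  n_classes <- n_out - 1L
  target <- as.integer(target)
  if (length(target) == 1L) target <- rep(target, nrow(scores))
  if (any(target < 0L | target >= n_classes)) {
    stop(sprintf("`target` must lie in 0 .. %d.", n_classes - 1L), call. = FALSE)
  }
  lp <- log_softmax(scores)
  ce_target <- -lp[cbind(seq_len(nrow(lp)), target + 1L)]
  ce_defer <- -lp[, n_out]
  if (alpha_on == "target") alpha * ce_target + ce_defer else ce_target + alpha * ce_defer
}

log_softmax <- function(z) {
  m <- apply(z, 1L, max)
  zs <- z - m
  zs - log(rowSums(exp(zs)))
}

softmax_rows <- function(z) {
  m <- apply(z, 1L, max)
  e <- exp(z - m)
  e / rowSums(e)
}

mlp_init <- function(n_in, hidden, n_out) {
  dims <- c(n_in, hidden, n_out)
  n_layers <- length(dims) - 1L
  w <- vector("list", n_layers)
  b <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    # He initialisation, suited to the ReLU hidden units
    w[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1L], sd = sqrt(2 / dims[l])),
                     nrow = dims[l], ncol = dims[l + 1L])
    b[[l]] <- numeric(dims[l + 1L])
  }
  list(w = w, b = b)
}

mlp_forward <- function(par, x) {
  n_layers <- length(par$w)
  a <- vector("list", n_layers + 1L)
  a[[1L]] <- x
  for (l in seq_len(n_layers)) {
    z <- a[[l]] %*% par$w[[l]]
    z <- sweep(z, 2L, par$b[[l]], "+")
    a[[l + 1L]] <- if (l < n_layers) pmax(z, 0) else z
  }
  a
}

# Soft-target distribution implied by the loss: plain CE uses the
# one-hot target; the defer loss (normalised by 1 + alpha so the
# gradient scale is comparable across the alpha grid) mixes the target
# class with the defer output.  The minimiser is unchanged by the
# positive normalisation.
mlp_soft_targets <- function(y, n_out, loss, alpha, alpha_on) {
  t_mat <- matrix(0, nrow = length(y), ncol = n_out)
  idx <- cbind(seq_along(y), y + 1L)
  if (loss == "ce") {
    t_mat[idx] <- 1
  } else {
    w_target <- if (alpha_on == "target") alpha else 1
    w_defer <- if (alpha_on == "target") 1 else alpha
    t_mat[idx] <- w_target / (w_target + w_defer)
    t_mat[, n_out] <- t_mat[, n_out] + w_defer / (w_target + w_defer)
  }
  t_mat
}

# mean loss and its gradients for one (mini)batch; the returned layout
# mirrors par ($w, $b).  delta is d(mean loss)/d(logits).
mlp_gradients <- function(par, xb, yb, n_out, loss, alpha, alpha_on,
                          weight_decay = 0) {
  n_layers <- length(par$w)
  a <- mlp_forward(par, xb)
  p <- softmax_rows(a[[n_layers + 1L]])
  t_mat <- mlp_soft_targets(yb, n_out, loss, alpha, alpha_on)
  loss_val <- -sum(t_mat * log(pmax(p, 1e-300))) / nrow(xb)
  delta <- (p - t_mat) / nrow(xb)
  gw <- vector("list", n_layers)
  gb <- vector("list", n_layers)
  for (l in rev(seq_len(n_layers))) {
    gw[[l]] <- crossprod(a[[l]], delta) + weight_decay * par$w[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1L) delta <- (delta %*% t(par$w[[l]])) * (a[[l]] > 0)
  }
  list(gw = gw, gb = gb, loss = loss_val)
}

mlp_train <- function(x, y, n_out, hidden = c(32L, 32L),
                      loss = c("ce", "defer"), alpha = 1,
                      alpha_on = c("target", "defer"),
                      epochs = 20L, learning_rate = 0.1, batch_size = 32L,
                      optimizer = c("sgd", "adam"), momentum = 0.9,
                      weight_decay = 0, seed = 1L, standardize = TRUE) {
  loss <- match.arg(loss)
  alpha_on <- match.arg(alpha_on)
  optimizer <- match.arg(optimizer)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.integer(y)
  n <- nrow(x)
  stopifnot(n >= 2L, length(y) == n, epochs >= 1L, learning_rate > 0)
  n_classes <- if (loss == "defer") n_out - 1L else n_out
  if (any(y < 0L | y >= n_classes)) {
    stop(sprintf("labels must lie in 0 .. %d.", n_classes - 1L), call. = FALSE)
  }

  center <- if (standardize) colMeans(x) else numeric(ncol(x))
  scale_ <- if (standardize) apply(x, 2L, stats::sd) else rep(1, ncol(x))
  scale_[!is.finite(scale_) | scale_ < 1e-12] <- 1
  xs <- sweep(sweep(x, 2L, center, "-"), 2L, scale_, "/")

  batch_size <- max(1L, min(as.integer(batch_size), n))
  epoch_loss <- numeric(epochs)

  par <- withr::with_seed(as.integer(seed), {
    par <- mlp_init(ncol(x), hidden, n_out)
    n_layers <- length(par$w)
    vel_w <- lapply(par$w, function(w) w * 0)
    vel_b <- lapply(par$b, function(b) b * 0)
    if (optimizer == "adam") {
      m_w <- lapply(par$w, function(w) w * 0); v_w <- m_w
      m_b <- lapply(par$b, function(b) b * 0); v_b <- m_b
      adam_t <- 0L
    }
    for (epoch in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = batch_size)
      running <- 0
      for (s in starts) {
        idx <- ord[s:min(s + batch_size - 1L, n)]
        g <- mlp_gradients(par, xs[idx, , drop = FALSE], y[idx], n_out,
                           loss, alpha, alpha_on, weight_decay)
        running <- running + g$loss * length(idx)
        for (l in seq_len(n_layers)) {
          if (optimizer == "sgd") {
            vel_w[[l]] <- momentum * vel_w[[l]] - learning_rate * g$gw[[l]]
            vel_b[[l]] <- momentum * vel_b[[l]] - learning_rate * g$gb[[l]]
            par$w[[l]] <- par$w[[l]] + vel_w[[l]]
            par$b[[l]] <- par$b[[l]] + vel_b[[l]]
          } else {
            if (l == 1L) adam_t <- adam_t + 1L
            m_w[[l]] <- 0.9 * m_w[[l]] + 0.1 * g$gw[[l]]
            v_w[[l]] <- 0.999 * v_w[[l]] + 0.001 * g$gw[[l]]^2
            m_b[[l]] <- 0.9 * m_b[[l]] + 0.1 * g$gb[[l]]
            v_b[[l]] <- 0.999 * v_b[[l]] + 0.001 * g$gb[[l]]^2
            mc <- 1 - 0.9^adam_t
            vc <- 1 - 0.999^adam_t
            par$w[[l]] <- par$w[[l]] -
              learning_rate * (m_w[[l]] / mc) / (sqrt(v_w[[l]] / vc) + 1e-8)
            par$b[[l]] <- par$b[[l]] -
              learning_rate * (m_b[[l]] / mc) / (sqrt(v_b[[l]] / vc) + 1e-8)
          }
        }
      }
      epoch_loss[epoch] <- running / n
      if (!is.finite(epoch_loss[epoch])) {
        stop(sprintf("training diverged (non-finite loss) at epoch %d.", epoch),
             call. = FALSE)
      }
    }
    par
  })

  structure(
    list(par = par, center = center, scale = scale_, hidden = hidden,
         n_in = ncol(x), n_out = n_out, loss = loss, alpha = alpha,
         alpha_on = alpha_on, seed = as.integer(seed),
         epoch_loss = epoch_loss),
    class = "deferral_mlp"
  )
}

mlp_scores <- function(net, x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != net$n_in) {
    stop(sprintf("feature dimension mismatch: model expects %d columns, got %d.",
                 net$n_in, ncol(x)), call. = FALSE)
  }
  if (nrow(x) == 0L) return(matrix(numeric(0), 0L, net$n_out))
  xs <- sweep(sweep(x, 2L, net$center, "-"), 2L, net$scale, "/")
  a <- mlp_forward(net$par, xs)
  a[[length(a)]]
}

mlp_prob <- function(net, x) {
  z <- mlp_scores(net, x)
  if (nrow(z) == 0L) return(z)
  softmax_rows(z)
}
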