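# ---------------------------------------------------------------------------
# Feature attention block and classifier, trained jointly by plain SGD.
#
# Attention: one small scalar subnetwork per feature column (1 -> hidden ->
# sigmoid), applied element-wise to every row of that column; this realizes
# one network evaluation per matrix entry while keeping parameter count
# O(g) so train and test batches of any size share weights. The gated
# matrix is F~ = E (*) M. Predictor: g -> hidden (ReLU) -> 2 neurons
# (sigmoid); the first neuron is the association probability entering the
# binary cross-entropy. All gradients are computed analytically (verified
# against central finite differences in the test suite).
# ---------------------------------------------------------------------------

.sigmoid <- function(x) 1 / (1 + exp(-x))

.glorot <- function(n_in, n_out, n) {
  lim <- sqrt(6 / (n_in + n_out))
  stats::runif(n, -lim, lim)
}

#' Training configuration
#'
#' Defaults: plain gradient descent with constant learning rate 0.9,
#' minibatch size 3000, 2000 epochs, L2 coefficient 2e-4; attention hidden
#' width 8 and predictor hidden width 64.
#'
#' @param learning_rate constant SGD step size
#' @param batch_size minibatch size (last batch may be smaller)
#' @param epochs number of passes over the training set
#' @param l2_lambda L2 regularization coefficient on all parameters
#' @param hidden_att attention subnetwork hidden width
#' @param hidden_pred predictor hidden width
#' @param seed RNG seed for initialization and shuffling
#' @param use_attention set `FALSE` for the M = 1 ablation
#' @param head `"sigmoid"` (independent output neurons; neuron 1 is the
#'   probability) or `"softmax"` (normalized two-neuron head)
#' @param eps probability clipping inside the loss
#' @return list of class `dmanet_train_config`
#' @export
train_config <- function(learning_rate = 0.9, batch_size = 3000L,
                         epochs = 2000L, l2_lambda = 2e-4,
                         hidden_att = 8L, hidden_pred = 64L, seed = 1L,
                         use_attention = TRUE,
                         head = c("sigmoid", "softmax"), eps = 1e-7) {
  head <- match.arg(head)
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1, l2_lambda >= 0,
            hidden_att >= 1, hidden_pred >= 1, eps > 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), l2_lambda = l2_lambda,
                 hidden_att = as.integer(hidden_att),
                 hidden_pred = as.integer(hidden_pred),
                 seed = as.integer(seed), use_attention = use_attention,
                 head = head, eps = eps),
            class = "dmanet_train_config")
}

#' Initialize an untrained model
#'
#' Glorot-style uniform initialization scaled by layer widths, fully
#' seeded through the R RNG.
#'
#' @param g embedding width (number of feature columns)
#' @param config a [train_config()]
#' @return object of class `dmanet_model`
#' @export
init_model <- function(g, config = train_config()) {
  h <- config$hidden_att; H <- config$hidden_pred
  att <- if (config$use_attention) list(
    W1 = matrix(.glorot(1, h, g * h), g, h),
    b1 = matrix(0, g, h),
    W2 = matrix(.glorot(h, 1, g * h), g, h),
    b2 = numeric(g)
  ) else NULL
  pred <- list(
    W1 = matrix(.glorot(g, H, g * H), g, H),
    b1 = numeric(H),
    W2 = matrix(.glorot(H, 2, H * 2), H, 2),
    b2 = numeric(2)
  )
  structure(list(g = as.integer(g), config = config, att = att, pred = pred,
                 trace = numeric()),
            class = "dmanet_model")
}

#' @export
print.dmanet_model <- function(x, ...) {
  cat(sprintf("<model: g=%d, attention %s, %d epochs trained>\n", x$g,
              if (is.null(x$att)) "off" else "on", length(x$trace)))
  invisible(x)
}

# forward pass with caches needed for backprop
.forward <- function(model, E) {
  n <- nrow(E); g <- model$g
  stopifnot(ncol(E) == g)
  cfg <- model$config
  Et <- t(E)                             # g x n: feature broadcasts recycle
  if (!is.null(model$att)) {
    # vectorized over rows and features; loop only over the (small) hidden
    # width: Z1[[k]][i, r] is hidden unit k of feature i's subnetwork at row r
    h <- cfg$hidden_att
    Z1 <- vector("list", h)
    S <- matrix(model$att$b2, g, n)
    for (k in seq_len(h)) {
      zk <- Et * model$att$W1[, k] + model$att$b1[, k]
      Z1[[k]] <- zk
      S <- S + (zk * (zk > 0)) * model$att$W2[, k]
    }
    M <- t(.sigmoid(S))
  } else {
    Z1 <- NULL
    M <- matrix(1, n, g)
  }
  Ft <- E * M
  Zp1 <- Ft %*% model$pred$W1 +
    rep(model$pred$b1, each = n)
  Hp <- Zp1 * (Zp1 > 0)
  Zp2 <- Hp %*% model$pred$W2 + rep(model$pred$b2, each = n)
  if (cfg$head == "softmax") {
    mx <- pmax(Zp2[, 1], Zp2[, 2])
    e1 <- exp(Zp2[, 1] - mx); e2 <- exp(Zp2[, 2] - mx)
    P <- e1 / (e1 + e2)
  } else {
    P <- .sigmoid(Zp2[, 1])
  }
  list(Z1 = Z1, M = M, Ft = Ft, Et = Et, Zp1 = Zp1, Hp = Hp, Zp2 = Zp2, P = P)
}

#' Attention forward pass
#'
#' Applies the per-feature attention subnetworks to every entry of `E` and
#' returns both the attention matrix `M` (entries strictly in (0,1)) and
#' the gated features `Ftilde = E * M`.
#'
#' @param model a `dmanet_model`
#' @param E embedding matrix (k x g)
#' @return list with `M` and `Ftilde`
#' @export
attend <- function(model, E) {
  fw <- .forward(model, E)
  list(M = fw$M, Ftilde = fw$Ft)
}

#' Association probabilities for embedded pairs
#' @param object a `dmanet_model`
#' @param E embedding matrix (k x g)
#' @param ... unused
#' @return numeric vector of probabilities in (0,1)
#' @export
predict.dmanet_model <- function(object, E, ...) {
  .forward(object, E)$P
}

.l2_sum <- function(model) {
  s <- sum(unlist(model$pred, use.names = FALSE)^2)
  if (!is.null(model$att)) s <- s + sum(unlist(model$att, use.names = FALSE)^2)
  s
}

#' Binary cross-entropy with L2 penalty
#'
#' Mean over samples of `-(Y log P + (1-Y) log(1-P))` with probabilities
#' clipped to `[eps, 1-eps]`, plus `lambda * ||theta||_2^2`. The returned
#' value is minimized during training.
#'
#' @param P predicted probabilities
#' @param Y 0/1 labels
#' @param lambda L2 coefficient
#' @param theta_sq sum of squared parameters (0 if no penalty wanted)
#' @param eps clipping constant
#' @return scalar loss
#' @export
bce_loss <- function(P, Y, lambda = 0, theta_sq = 0, eps = 1e-7) {
  stopifnot(length(P) == length(Y), all(Y %in% c(0, 1)))
  Pc <- pmin(pmax(P, eps), 1 - eps)
  -mean(Y * log(Pc) + (1 - Y) * log(1 - Pc)) + lambda * theta_sq
}

#' Full-model loss on an embedded batch
#' @param model a `dmanet_model`
#' @param E embedding matrix
#' @param Y labels
#' @return scalar loss including the configured L2 penalty
#' @export
model_loss <- function(model, E, Y) {
  fw <- .forward(model, E)
  bce_loss(fw$P, Y, model$config$l2_lambda, .l2_sum(model), model$config$eps)
}

# analytic gradients of the full loss; same shapes as model$att / model$pred
.backward <- function(model, E, Y, fw) {
  cfg <- model$config
  n <- nrow(E); g <- model$g
  lam2 <- 2 * cfg$l2_lambda
  P <- fw$P
  Pc <- pmin(pmax(P, cfg$eps), 1 - cfg$eps)
  inside <- (P > cfg$eps) & (P < 1 - cfg$eps)
  dP <- ((1 - Y) / (1 - Pc) - Y / Pc) / n * inside
  dZp2 <- matrix(0, n, 2)
  if (cfg$head == "softmax") {
    dZp2[, 1] <- dP * P * (1 - P)
    dZp2[, 2] <- -dP * P * (1 - P)
  } else {
    dZp2[, 1] <- dP * P * (1 - P)
  }
  gpred <- list(
    W1 = NULL, b1 = NULL,
    W2 = crossprod(fw$Hp, dZp2) + lam2 * model$pred$W2,
    b2 = .colSums(dZp2, n, 2) + lam2 * model$pred$b2
  )
  dHp <- dZp2 %*% t(model$pred$W2)
  dZp1 <- dHp * (fw$Zp1 > 0)
  gpred$W1 <- crossprod(fw$Ft, dZp1) + lam2 * model$pred$W1
  gpred$b1 <- .colSums(dZp1, n, ncol(dZp1)) + lam2 * model$pred$b1
  if (is.null(model$att)) return(list(att = NULL, pred = gpred))
  dFt <- dZp1 %*% t(model$pred$W1)
  h <- cfg$hidden_att
  gatt <- list(W1 = matrix(0, g, h), b1 = matrix(0, g, h),
               W2 = matrix(0, g, h), b2 = numeric(g))
  Mt <- t(fw$M)
  dSt <- t(dFt) * fw$Et * Mt * (1 - Mt)  # g x n, gradient at the sigmoid input
  gatt$b2 <- .rowSums(dSt, g, n)
  for (k in seq_len(h)) {
    zk <- fw$Z1[[k]]
    gatt$W2[, k] <- .rowSums((zk * (zk > 0)) * dSt, g, n)
    dZk <- (dSt * model$att$W2[, k]) * (zk > 0)
    gatt$W1[, k] <- .rowSums(dZk * fw$Et, g, n)
    gatt$b1[, k] <- .rowSums(dZk, g, n)
  }
  gatt$W1 <- gatt$W1 + lam2 * model$att$W1
  gatt$b1 <- gatt$b1 + lam2 * model$att$b1
  gatt$W2 <- gatt$W2 + lam2 * model$att$W2
  gatt$b2 <- gatt$b2 + lam2 * model$att$b2
  list(att = gatt, pred = gpred)
}

#' Analytic parameter gradients (exposed for verification)
#' @param model a `dmanet_model`
#' @param E embedding matrix
#' @param Y labels
#' @return list with the same shapes as `model$att` / `model$pred`
#' @export
model_gradients <- function(model, E, Y) {
  .backward(model, E, Y, .forward(model, E))
}

#' Train the attention block and predictor jointly
#'
#' Plain stochastic gradient descent with the configuration's constant
#' learning rate; one shuffle per epoch, fixed by the seed; the recorded
#' loss trace is the mean pre-update minibatch loss per epoch. Attention
#' and predictor parameters receive gradients from the same binary
#' cross-entropy, so they are optimized jointly.
#'
#' @param E training embedding matrix (k x g)
#' @param Y 0/1 labels, at least one of each class
#' @param config a [train_config()]
#' @return a trained `dmanet_model` with `$trace`
#' @export
train_model <- function(E, Y, config = train_config()) {
  stopifnot(nrow(E) == length(Y))
  if (length(unique(Y)) < 2) stop("training set needs both classes")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  model <- init_model(ncol(E), config)
  n <- nrow(E)
  trace <- numeric(config$epochs)
  lr <- config$learning_rate
  for (ep in seq_len(config$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    bl <- numeric(length(starts))
    for (s in seq_along(starts)) {
      idx <- perm[starts[s]:min(starts[s] + config$batch_size - 1L, n)]
      Eb <- E[idx, , drop = FALSE]; Yb <- Y[idx]
      fw <- .forward(model, Eb)
      bl[s] <- bce_loss(fw$P, Yb, config$l2_lambda, .l2_sum(model), config$eps)
      gr <- .backward(model, Eb, Yb, fw)
      for (nm in names(model$pred)) {
        model$pred[[nm]] <- model$pred[[nm]] - lr * gr$pred[[nm]]
      }
      if (!is.null(model$att)) {
        for (nm in names(model$att)) {
          model$att[[nm]] <- model$att[[nm]] - lr * gr$att[[nm]]
        }
      }
    }
    trace[ep] <- mean(bl)
    if (!is.finite(trace[ep])) {
      stop("training diverged (non-finite loss at epoch ", ep,
           "); try a lower learning rate")
    }
  }
  model$trace <- trace
  model
}

# save/restore the global RNG state so seeded training does not perturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
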