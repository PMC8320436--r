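#' Training configuration for the Bayesian-regularized network
#'
#' Levenberg-Marquardt damping schedule and stopping rules. Training stops at
#' `max_iter` iterations, when the damping exceeds `mu_max`, when the largest
#' gradient component falls below `grad_tol`, or when the relative decrease of
#' the data error is below `f_tol` for three consecutive accepted steps.
#'
#' @param max_iter Maximum LM iterations (default 300).
#' @param mu0 Initial damping (default 0.005).
#' @param mu_inc,mu_dec Damping multipliers on rejected/accepted steps
#'   (default 10 and 0.1).
#' @param mu_max Damping ceiling; exceeding it stops training (default 1e10).
#' @param grad_tol Infinity-norm gradient tolerance (default 1e-7).
#' @param f_tol Relative data-error improvement below which a step counts as
#'   a plateau (default 1e-9).
#' @param seed RNG seed for the weight initialization.
#' @return An object of class `bpnn_config`.
#' @export
bpnn_config <- function(max_iter = 300, mu0 = 5e-3, mu_inc = 10, mu_dec = 0.1,
                        mu_max = 1e10, grad_tol = 1e-7, f_tol = 1e-9,
                        seed = 1L) {
  stopifnot(max_iter >= 1, mu0 > 0, mu_inc > 1, mu_dec > 0, mu_dec < 1,
            mu_max > 0, grad_tol >= 0, f_tol >= 0)
  structure(list(max_iter = as.integer(max_iter), mu0 = mu0, mu_inc = mu_inc,
                 mu_dec = mu_dec, mu_max = mu_max, grad_tol = grad_tol,
                 f_tol = f_tol, seed = as.integer(seed)),
            class = "bpnn_config")
}

CLINICAL_SCALES <- list(
  FMA_SE = c(0, 42), FMA_WH = c(0, 24),
  MAS_elbow = c(0, 4), MAS_wrist = c(0, 4), MAS_finger = c(0, 4)
)

#' Score range of a clinical scale
#'
#' @param scale One of `"FMA_SE"` (0-42), `"FMA_WH"` (0-24), `"MAS_elbow"`,
#'   `"MAS_wrist"`, `"MAS_finger"` (0-4 each).
#' @return Numeric `c(min, max)`.
#' @export
clinical_scale_range <- function(scale) {
  r <- CLINICAL_SCALES[[scale]]
  if (is.null(r))
    abort_semg(paste0("unknown clinical scale: ", scale), "value")
  r
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# pack/unpack weights <-> flat vector; layout: W1 (by column), b1, W2, b2
unpack_weights <- function(w, n_in, n_hidden) {
  i1 <- n_hidden * n_in
  list(W1 = matrix(w[seq_len(i1)], n_hidden, n_in),
       b1 = w[i1 + seq_len(n_hidden)],
       W2 = w[i1 + n_hidden + seq_len(n_hidden)],
       b2 = w[i1 + 2 * n_hidden + 1])
}

# forward pass on scaled inputs X (n_in x N); returns activations for reuse
bpnn_forward_scaled <- function(w, X, n_hidden) {
  n_in <- nrow(X)
  p <- unpack_weights(w, n_in, n_hidden)
  A1 <- sigmoid(p$W1 %*% X + p$b1)            # n_hidden x N
  y <- drop(sigmoid(drop(p$W2 %*% A1) + p$b2)) # N
  list(A1 = A1, y = y, p = p)
}

# residuals e = y - t and Jacobian J = d e / d w  (N x N_w)
bpnn_residual_jacobian <- function(w, X, t, n_hidden) {
  fw <- bpnn_forward_scaled(w, X, n_hidden)
  N <- ncol(X)
  n_in <- nrow(X)
  e <- fw$y - t
  d2 <- fw$y * (1 - fw$y)                                  # N
  D1 <- (fw$p$W2 * fw$A1 * (1 - fw$A1)) * rep(d2, each = n_hidden) # n_h x N
  N_w <- n_hidden * (n_in + 1) + n_hidden + 1
  J <- matrix(0, N, N_w)
  for (i in seq_len(n_in))                                  # dW1[, i]
    J[, (i - 1) * n_hidden + seq_len(n_hidden)] <- t(D1) * X[i, ]
  J[, n_hidden * n_in + seq_len(n_hidden)] <- t(D1)         # db1
  J[, n_hidden * (n_in + 1) + seq_len(n_hidden)] <- t(fw$A1) * d2 # dW2
  J[, N_w] <- d2                                            # db2
  list(e = e, J = J, y = fw$y)
}

#' Train the three-layer sEMG-to-score network
#'
#' Fits a fully connected network with one sigmoid hidden layer and a sigmoid
#' output, mapping standardized epoch feature vectors to a clinical score
#' scaled into (0, 1). Training minimizes the regularized objective
#' `F = beta * E_D + alpha * E_W` (`E_D` the sum of squared errors on the
#' normalized targets, `E_W` the sum of squared weights) by
#' Levenberg-Marquardt steps with a Gauss-Newton Hessian. After each accepted
#' step the evidence-framework hyperparameters are re-estimated:
#' `gamma = N_w - 2 * alpha * tr(H^-1)`, `alpha = gamma / (2 * E_W)`,
#' `beta = (N - gamma) / (2 * E_D)`, with `H = 2 * beta * J'J + 2 * alpha * I`.
#' `gamma` is the effective number of parameters; on pure-noise targets the
#' regularizer drives it far below `N_w`, suppressing overfitting.
#'
#' Inputs are standardized (per-feature location/scale from the training data)
#' and targets min-max scaled by the clinical range, so mapped scores are
#' bounded by the scale by construction. Training is deterministic given the
#' data and `config$seed`.
#'
#' @param x Numeric matrix (cases by features) or data frame of features.
#' @param y Numeric target scores, one per case, on the clinical scale.
#' @param n_hidden Hidden-layer size (default 15).
#' @param target_range Numeric `c(min, max)` of the clinical scale, or a scale
#'   name accepted by [clinical_scale_range()].
#' @param config A [bpnn_config()].
#' @return An object of class `bpnn` with weights, scalers, and the training
#'   state (`alpha`, `beta`, `gamma`, `mu`, iteration count, stop reason).
#' @export
bpnn_train <- function(x, y, n_hidden = 15, target_range = "FMA_SE",
                       config = bpnn_config()) {
  if (is.character(target_range)) {
    scale_name <- target_range
    target_range <- clinical_scale_range(target_range)
  } else scale_name <- NA_character_
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) abort_semg("features contain non-finite values.", "input")
  if (!all(is.finite(y))) abort_semg("targets contain non-finite values.", "input")
  if (nrow(x) != length(y)) abort_semg("x and y sizes disagree.", "shape")
  if (length(unique(y)) < 2)
    abort_semg("targets are constant; nothing to map.", "degenerate_target")
  if (n_hidden < 1) abort_semg("`n_hidden` must be >= 1.", "parameter")
  stopifnot(inherits(config, "bpnn_config"))

  feature_names <- colnames(x)
  center <- colMeans(x)
  scale_sd <- apply(x, 2, stats::sd)
  scale_sd[scale_sd < 1e-12] <- 1
  Xs <- t((x - rep(center, each = nrow(x))) / rep(scale_sd, each = nrow(x)))
  tgt <- (y - target_range[1]) / diff(target_range)

  n_in <- nrow(Xs)
  N <- ncol(Xs)
  N_w <- n_hidden * (n_in + 1) + n_hidden + 1

  w <- with_local_seed(config$seed, {
    c(stats::runif(n_hidden * n_in, -0.5, 0.5) / sqrt(n_in),
      stats::runif(n_hidden, -0.5, 0.5),
      stats::runif(n_hidden, -0.5, 0.5) / sqrt(n_hidden),
      stats::runif(1, -0.5, 0.5))
  })

  alpha <- 0
  beta <- 1
  gamma <- N_w
  mu <- config$mu0
  rj <- bpnn_residual_jacobian(w, Xs, tgt, n_hidden)
  E_D <- sum(rj$e^2)
  E_W <- sum(w^2)
  F_obj <- beta * E_D + alpha * E_W
  plateau <- 0L
  n_iter <- 0L
  reason <- "max_iter"

  for (iter in seq_len(config$max_iter)) {
    n_iter <- iter
    G <- crossprod(rj$J)                      # J'J, N_w x N_w
    if (iter > 1) {
      # evidence-framework re-estimation after the previous accepted step
      if (alpha > 0) {
        H <- 2 * beta * G
        diag(H) <- diag(H) + 2 * alpha
        tr_Hinv <- tryCatch(sum(diag(chol2inv(chol(H)))), error = function(e) {
          diag(H) <- diag(H) + 1e-10 * max(diag(H))
          sum(diag(chol2inv(chol(H))))
        })
        gamma <- N_w - 2 * alpha * tr_Hinv
      } else gamma <- N_w
      gamma <- min(max(gamma, 0), min(N_w, 0.999 * N))
      alpha <- gamma / (2 * max(E_W, 1e-12))
      beta <- (N - gamma) / (2 * max(E_D, 1e-12))
      F_obj <- beta * E_D + alpha * E_W
    }
    g <- 2 * (beta * drop(crossprod(rj$J, rj$e)) + alpha * w)
    if (max(abs(g)) < config$grad_tol) { reason <- "grad_tol"; break }
    accepted <- FALSE
    repeat {
      A <- 2 * beta * G
      diag(A) <- diag(A) + 2 * alpha + mu
      delta <- tryCatch(-drop(chol2inv(chol(A)) %*% g),
                        error = function(e) -drop(solve(A, g)))
      w_new <- w + delta
      rj_new <- bpnn_residual_jacobian(w_new, Xs, tgt, n_hidden)
      E_D_new <- sum(rj_new$e^2)
      E_W_new <- sum(w_new^2)
      F_new <- beta * E_D_new + alpha * E_W_new
      if (is.finite(F_new) && F_new < F_obj) {
        rel_impr <- (E_D - E_D_new) / max(E_D, 1e-300)
        plateau <- if (abs(rel_impr) < config$f_tol) plateau + 1L else 0L
        w <- w_new; rj <- rj_new; E_D <- E_D_new; E_W <- E_W_new; F_obj <- F_new
        mu <- max(mu * config$mu_dec, 1e-20)
        accepted <- TRUE
        break
      }
      mu <- mu * config$mu_inc
      if (mu > config$mu_max) break
    }
    if (!accepted) { reason <- "mu_max"; break }
    if (plateau >= 3L) { reason <- "f_tol"; break }
  }

  p <- unpack_weights(w, n_in, n_hidden)
  structure(list(
    n_in = n_in, n_hidden = as.integer(n_hidden),
    W1 = p$W1, b1 = p$b1, W2 = p$W2, b2 = p$b2,
    input_center = stats::setNames(center, feature_names),
    input_scale = stats::setNames(scale_sd, feature_names),
    target_range = target_range, scale_name = scale_name,
    feature_names = feature_names,
    train_state = list(alpha = alpha, beta = beta, gamma = gamma, mu = mu,
                       E_D = E_D, E_W = E_W, n_iter = n_iter,
                       n_cases = N, n_params = N_w, stop_reason = reason),
    seed = config$seed
  ), class = "bpnn")
}

#' @export
print.bpnn <- function(x, ...) {
  cat(sprintf("<bpnn> %d-%d-1 sigmoid network (%s scale %g-%g)\n",
              x$n_in, x$n_hidden,
              if (is.na(x$scale_name)) "custom" else x$scale_name,
              x$target_range[1], x$target_range[2]))
  st <- x$train_state
  cat(sprintf("  trained %d iter (%s): gamma %.1f / %d params, alpha %.3g, beta %.3g\n",
              st$n_iter, st$stop_reason, st$gamma, st$n_params, st$alpha, st$beta))
  invisible(x)
}

#' Map feature vectors to clinical-scale scores
#'
#' @param object A fitted [bpnn_train()] model.
#' @param newdata Matrix or data frame of features. Data frames may carry
#'   extra columns; the model's feature columns are selected by name.
#' @param ... Unused.
#' @return Numeric vector of mapped scores in clinical-scale units, bounded
#'   by the scale range.
#' @export
predict.bpnn <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    if (!is.null(object$feature_names)) {
      absent <- setdiff(object$feature_names, names(newdata))
      if (length(absent))
        abort_semg(paste0("newdata lacks feature column(s): ",
                          paste(absent, collapse = ", ")), "shape")
      newdata <- newdata[object$feature_names]
    }
    newdata <- as.matrix(newdata)
  }
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != object$n_in)
    abort_semg(sprintf("expected %d features, got %d.", object$n_in,
                       ncol(newdata)), "shape")
  Xs <- t((newdata - rep(object$input_center, each = nrow(newdata))) /
            rep(object$input_scale, each = nrow(newdata)))
  A1 <- sigmoid(object$W1 %*% Xs + object$b1)
  y <- drop(sigmoid(drop(object$W2 %*% A1) + object$b2))
  object$target_range[1] + y * diff(object$target_range)
}

#' Final mapped score of one participant-session
#'
#' The mean of the epoch-wise mapped scores over all test epochs of a
#' participant-session is that participant's final mapped score.
#'
#' @param model A fitted [bpnn_train()] model.
#' @param epochs Feature matrix or data frame of the participant's test epochs.
#' @return Scalar mapped score in clinical-scale units.
#' @export
predict_participant <- function(model, epochs) {
  if ((is.data.frame(epochs) || is.matrix(epochs)) && nrow(epochs) == 0)
    abort_semg("no test epochs for this participant.", "empty_result")
  mean(predict(model, epochs))
}
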