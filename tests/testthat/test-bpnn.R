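test_that("forward pass maps the zero network to mid-scale", {
  zero_model <- function(scale) {
    m <- bpnn_train(matrix(rnorm(40), ncol = 2), rep(c(1, 2), 10),
                    n_hidden = 3, target_range = scale,
                    config = bpnn_config(max_iter = 1, seed = 1))
    m$W1[] <- 0; m$b1[] <- 0; m$W2[] <- 0; m$b2 <- 0
    m$input_center[] <- 0; m$input_scale[] <- 1
    m
  }
  # sigmoid(0) = 0.5 at both layers -> middle of the clinical scale
  expect_equal(predict(zero_model("FMA_SE"), matrix(rnorm(10), ncol = 2)),
               rep(21, 5))
  expect_equal(predict(zero_model("MAS_elbow"), matrix(0, 1, 2)), 2)
  # saturating logit pins the output at the scale maximum
  m <- zero_model("FMA_SE")
  m$W2[] <- 1e4; m$b2 <- 1e4
  expect_equal(predict(m, matrix(1, 1, 2)), 42, tolerance = 1e-9)
  expect_error(predict(m, matrix(1, 1, 5)), class = "semgmap_shape_error")
})

test_that("outputs are always inside the clinical scale", {
  withr::with_seed(10, {
    x <- matrix(rnorm(200), ncol = 4)
    y <- runif(50, 0, 42)
    m <- bpnn_train(x, y, n_hidden = 4, target_range = "FMA_SE",
                    config = fast_config())
    preds <- predict(m, matrix(rnorm(400, sd = 5), ncol = 4))
    expect_true(all(preds >= 0 & preds <= 42))
  })
})

test_that("analytic Jacobian matches central finite differences", {
  withr::with_seed(33, {
    n_in <- 4; n_hidden <- 3; N <- 12
    X <- matrix(rnorm(n_in * N), n_in, N)
    tgt <- runif(N)
    N_w <- n_hidden * (n_in + 1) + n_hidden + 1
    w <- rnorm(N_w, sd = 0.5)
    J <- semgmap:::bpnn_residual_jacobian(w, X, tgt, n_hidden)$J
    h <- 1e-6
    J_fd <- matrix(0, N, N_w)
    for (j in seq_len(N_w)) {
      wp <- w; wp[j] <- wp[j] + h
      wm <- w; wm[j] <- wm[j] - h
      ep <- semgmap:::bpnn_residual_jacobian(wp, X, tgt, n_hidden)$e
      em <- semgmap:::bpnn_residual_jacobian(wm, X, tgt, n_hidden)$e
      J_fd[, j] <- (ep - em) / (2 * h)
    }
    denom <- max(abs(J_fd))
    expect_lt(max(abs(J - J_fd)) / denom, 1e-5)
  })
})

test_that("network learns a smooth 1-D function", {
  withr::with_seed(8, {
    x <- matrix(runif(200), ncol = 1)
    y <- drop(x) * 42          # y = x on the normalized scale
    m <- bpnn_train(x, y, n_hidden = 15, target_range = "FMA_SE",
                    config = bpnn_config(max_iter = 100, seed = 2))
    x_new <- matrix(runif(50), ncol = 1)
    pred <- predict(m, x_new)
    mse_norm <- mean((pred / 42 - drop(x_new))^2)
    expect_lt(mse_norm, 1e-3)
  })
})

test_that("Bayesian regularization suppresses parameters on pure noise", {
  withr::with_seed(12, {
    x <- matrix(rnorm(300 * 4), ncol = 4)
    y <- runif(300, 0, 42)     # no feature dependence
    m <- bpnn_train(x, y, n_hidden = 10, target_range = "FMA_SE",
                    config = bpnn_config(max_iter = 50, seed = 3))
    g <- glance(m)
    expect_lt(g$gamma / g$n_params, 0.5)
    expect_true(g$gamma >= 0 && g$gamma <= g$n_params)
  })
})

test_that("training is deterministic and the objective decreases", {
  withr::with_seed(14, {
    x <- matrix(rnorm(200), ncol = 4)
    y <- 10 + rowSums(x) * 3 + rnorm(50, sd = 0.5)
  })
  cfg <- bpnn_config(max_iter = 25, seed = 9)
  m1 <- bpnn_train(x, y, n_hidden = 5, target_range = "FMA_SE", config = cfg)
  m2 <- bpnn_train(x, y, n_hidden = 5, target_range = "FMA_SE", config = cfg)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$train_state$gamma, m2$train_state$gamma)
  # a different seed gives a different fit
  m3 <- bpnn_train(x, y, n_hidden = 5, target_range = "FMA_SE",
                   config = bpnn_config(max_iter = 25, seed = 10))
  expect_false(identical(m1$W1, m3$W1))
  # the parameter count bookkeeping matches the architecture
  expect_equal(m1$train_state$n_params, 5 * (4 + 1) + 5 + 1)
})

test_that("degenerate training inputs are rejected", {
  x <- matrix(rnorm(40), ncol = 2)
  expect_error(bpnn_train(x, rep(7, 20), target_range = "FMA_SE"),
               class = "semgmap_degenerate_target_error")
  x[3, 1] <- NA
  expect_error(bpnn_train(x, 1:20, target_range = "FMA_SE"),
               class = "semgmap_input_error")
})

test_that("participant scores average the epoch outputs", {
  withr::with_seed(18, {
    x <- matrix(rnorm(100), ncol = 2)
    y <- runif(50, 0, 24)
    m <- bpnn_train(x, y, n_hidden = 3, target_range = "FMA_WH",
                    config = fast_config())
    eps <- matrix(rnorm(12), ncol = 2)
    expect_equal(predict_participant(m, eps), mean(predict(m, eps)))
    expect_equal(predict_participant(m, eps[1, , drop = FALSE]),
                 predict(m, eps[1, , drop = FALSE]))
    expect_true(predict_participant(m, eps) >= 0 &&
                  predict_participant(m, eps) <= 24)
    expect_error(predict_participant(m, eps[0, , drop = FALSE]),
                 class = "semgmap_empty_result_error")
  })
})

test_that("models round-trip exactly through JSON", {
  withr::with_seed(19, {
    x <- matrix(rnorm(160), ncol = 4)
    colnames(x) <- c("ED_MAV", "ED_RMS", "FD_MAV", "FD_RMS")
    y <- runif(40, 0, 42)
    m <- bpnn_train(x, y, n_hidden = 4, target_range = "FMA_SE",
                    config = bpnn_config(max_iter = 15, seed = 7))
    path <- withr::local_tempfile(fileext = ".json")
    bpnn_save(m, path)
    back <- bpnn_load(path)
    expect_identical(back$W1, m$W1)
    expect_identical(back$train_state$alpha, m$train_state$alpha)
    expect_identical(back$train_state$beta, m$train_state$beta)
    expect_identical(back$train_state$gamma, m$train_state$gamma)
    expect_identical(back$seed, m$seed)
    probe <- matrix(rnorm(40), ncol = 4)
    expect_identical(predict(back, probe), predict(m, probe))

    # truncated file fails to parse
    txt <- readLines(path)
    writeLines(txt[1:(length(txt) %/% 2)], path)
    expect_error(bpnn_load(path))

    # schema version mismatch is refused
    path2 <- withr::local_tempfile(fileext = ".json")
    bpnn_save(m, path2)
    doc <- jsonlite::read_json(path2, simplifyVector = TRUE)
    doc$schema_version <- "0.9"
    jsonlite::write_json(doc, path2, auto_unbox = TRUE)
    expect_error(bpnn_load(path2), class = "semgmap_version_error")
  })
})

test_that("tidy and glance expose the fitted network", {
  withr::with_seed(20, {
    x <- matrix(rnorm(60), ncol = 3)
    m <- bpnn_train(x, runif(20, 0, 4), n_hidden = 2,
                    target_range = "MAS_elbow", config = fast_config())
  })
  td <- tidy(m)
  expect_equal(nrow(td), 2 * 3 + 2 + 2 + 1)
  expect_equal(td$estimate[1], m$W1[1, 1])
  g <- glance(m)
  expect_equal(g$n_hidden, 2)
  expect_true(g$stop_reason %in% c("max_iter", "grad_tol", "mu_max", "f_tol"))
})
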