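test_that("losses match naive-loop oracles on random small tensors", {
  set.seed(1)
  for (rep in 1:20) {
    N <- sample(1:5, 1); T <- sample(1:5, 1); d <- sample(1:5, 1)
    C <- sample(2:5, 1)
    x <- array(rnorm(N * T * d), c(N, T, d))
    xh <- array(rnorm(N * T * d), c(N, T, d))
    expect_equal(reconstruction_loss(x, xh), rec_loss_loop(x, xh),
                 tolerance = 1e-10)
    p <- matrix(runif(N * C), N, C)
    y <- matrix(rbinom(N * C, 1, 0.5), N, C)
    y[rowSums(y) == 0, 1] <- 1
    expect_equal(classification_loss(p, y), cls_loss_loop(p, y),
                 tolerance = 1e-10)
    expect_equal(total_loss(0.2, 0.3, 1), 0.5)
  }
})

test_that("frozen loss examples hold", {
  # N=1, T=2, d=1, x=(0,0), x_hat=(1,1) -> 2
  expect_equal(reconstruction_loss(array(0, c(1, 2, 1)),
                                   array(1, c(1, 2, 1))), 2.0)
  # per-sample sums 2 and 4 -> mean 3
  x <- array(0, c(2, 2, 1)); xh <- x
  xh[1, , 1] <- 1; xh[2, , 1] <- sqrt(2)
  expect_equal(reconstruction_loss(x, xh), 3.0)
  # p = (1, 0) against y = (1, 1): p_hat = (0.5, 0.5), loss 0.5
  expect_equal(classification_loss(matrix(c(1, 0), 1), matrix(c(1, 1), 1)),
               0.5)
  # perfect prediction
  expect_equal(classification_loss(matrix(c(0.5, 0.5, 0), 1),
                                   matrix(c(1, 1, 0), 1)), 0)
})

test_that("all-zero label rows are excluded with a warning", {
  p <- matrix(0.5, 2, 2)
  y <- rbind(c(1, 0), c(0, 0))
  expect_warning(l <- classification_loss(p, y), "all-zero")
  expect_equal(l, sum((c(0.5, 0.5) - c(1, 0))^2)) # only row 1 counted, N = 1
})

test_that("total_loss is linear in l_rec with slope gamma", {
  for (gamma in c(0, 0.5, 2)) {
    l0 <- total_loss(0.3, 0, gamma)
    l1 <- total_loss(0.3, 1, gamma)
    l2 <- total_loss(0.3, 2, gamma)
    expect_equal(l1 - l0, gamma)
    expect_equal(l2 - l1, gamma)
  }
  expect_error(total_loss(0.1, 0.1, -1), "gamma")
})

test_that("encoder recurrence: zero params give zero states; T=1 degenerate", {
  params <- mlstm_init(2, 3, 2, seed = 1)
  for (grp in c("enc", "dec", "cls")) {
    for (nm in names(params[[grp]])) params[[grp]][[nm]][] <- 0
  }
  x <- array(0, c(2, 4, 2))
  enc <- mlstm_encode(params, x)
  expect_true(all(enc$h_all == 0))
  expect_true(all(enc$h_T == 0))
  # T = 1: final state equals the single step's state
  params2 <- mlstm_init(2, 3, 2, seed = 2)
  x1 <- array(rnorm(4), c(2, 1, 2))
  enc1 <- mlstm_encode(params2, x1)
  expect_equal(enc1$h_T, matrix(enc1$h_all[, 1, ], 2))
  # determinism
  enc2 <- mlstm_encode(params2, x1)
  expect_identical(enc1$h_T, enc2$h_T)
})

test_that("classification head gives 0.5 at zero weights and stays in [0,1]", {
  params <- mlstm_init(2, 3, 4, seed = 1)
  params$cls$Wc[] <- 0; params$cls$bc[] <- 0
  p <- mlstm_classify(params, matrix(rnorm(6), 2, 3))
  expect_equal(p, matrix(0.5, 2, 4)) # sigmoid(0)
  params2 <- mlstm_init(2, 3, 4, seed = 2)
  p2 <- mlstm_classify(params2, matrix(rnorm(30, sd = 10), 10, 3))
  expect_true(all(p2 >= 0 & p2 <= 1))
  expect_identical(dim(p2), c(10L, 4L))
})

test_that("reconstruction target is the time-flipped input; decoder shapes", {
  x <- array(seq_len(6), c(1, 3, 2))
  fx <- flip_time(x)
  expect_equal(fx[1, , 1], rev(x[1, , 1]))
  expect_equal(fx[1, , 2], rev(x[1, , 2]))
  x1 <- array(rnorm(4), c(2, 1, 2))
  expect_equal(flip_time(x1), x1) # length-1 flip is the identity
  params <- mlstm_init(2, 3, 2, seed = 1)
  dec <- mlstm_decode(params, matrix(rnorm(6), 2, 3), T = 5)
  expect_identical(dim(dec$x_hat), c(2L, 5L, 2L))
  expect_error(mlstm_decode(params, matrix(rnorm(6), 2, 3), T = 0),
               "positive")
})

test_that("analytic gradients match central finite differences", {
  set.seed(42)
  N <- 3; T <- 3; d <- 2; H <- 4; C <- 2; gamma <- 0.7
  x <- array(rnorm(N * T * d), c(N, T, d))
  y <- matrix(rbinom(N * C, 1, 0.6), N, C)
  y[rowSums(y) == 0, 1] <- 1
  params <- mlstm_init(d, H, C, seed = 1)
  g <- ssoddi:::mlstm_loss_grads(params, x, y, gamma)
  lossf <- function(p) ssoddi:::mlstm_loss_grads(p, x, y, gamma)$loss
  eps <- 1e-5
  for (grp in c("enc", "dec", "cls")) {
    for (nm in names(g$grads[[grp]])) {
      w <- params[[grp]][[nm]]
      for (k in sample(length(w), min(6, length(w)))) {
        p1 <- params; p1[[grp]][[nm]][k] <- w[k] + eps
        p2 <- params; p2[[grp]][[nm]][k] <- w[k] - eps
        num <- (lossf(p1) - lossf(p2)) / (2 * eps)
        # absolute error: fd truncation noise dominates near-zero entries
        expect_lt(abs(g$grads[[grp]][[nm]][k] - num), 1e-6)
      }
    }
  }
})

test_that("training is seeded, checkpointed, and learns the fixture", {
  ds <- small_synth(seed = 7)
  ctrl <- mlstm_control(epochs = 6, hidden = 12)
  fit1 <- mlstm_train(ds$x, ds$y, ctrl, seed = 7)
  fit2 <- mlstm_train(ds$x, ds$y, ctrl, seed = 7)
  expect_identical(fit1$history, fit2$history) # bitwise determinism
  expect_identical(nrow(fit1$history), 6L)
  expect_lt(tail(fit1$history$train_loss, 1), fit1$history$train_loss[1])
  # epochs = 0: empty history, params at initialization
  fit0 <- mlstm_train(ds$x, ds$y, mlstm_control(epochs = 0, hidden = 12),
                      seed = 7)
  expect_identical(nrow(fit0$history), 0L)
  init <- mlstm_init(dim(ds$x)[3], 12, ncol(ds$y),
                     seed = derive_seed(7, "init"))
  expect_identical(fit0$params$enc$Wx, init$enc$Wx)
})

test_that("predict_scores is bounded, row-aligned, and permutation-equivariant", {
  ds <- small_synth(seed = 7)
  fit <- mlstm_train(ds$x, ds$y, mlstm_control(epochs = 3, hidden = 10),
                     seed = 1)
  p <- predict_scores(fit, ds$x)
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(dim(p), c(dim(ds$x)[1], ncol(ds$y)))
  perm <- sample(dim(ds$x)[1])
  expect_equal(predict_scores(fit, ds$x[perm, , , drop = FALSE]), p[perm, ])
})

test_that("checkpoints round-trip through disk", {
  ds <- small_synth(seed = 7)
  fit <- mlstm_train(ds$x, ds$y, mlstm_control(epochs = 2, hidden = 8),
                     seed = 1)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(fit, path)
  expect_true(file.exists(paste0(path, ".json")))
  fit2 <- load_checkpoint(path)
  expect_equal(predict_scores(fit2, ds$x), predict_scores(fit, ds$x))
})
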