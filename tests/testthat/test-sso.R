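bounds1 <- matrix(c(-10, 10), 1, 2)

test_that("discoverer update matches direct evaluation of both branches", {
  ctrl <- sso_control(st = 0.8)
  # safe branch: X * exp(-i / (alpha * T_max)), i = 1, alpha = 1, T_max = 10
  X <- matrix(2.0, 1, 1)
  out <- sso_update_discoverers(X, t_max = 10, ctrl, bounds1,
                                draws = list(r2 = 0.1, alpha = 1, o = 0))
  expect_equal(out[1, 1], 2.0 * exp(-0.1), tolerance = 1e-12)
  # alarm branch with O = 0: position unchanged
  out2 <- sso_update_discoverers(X, t_max = 10, ctrl, bounds1,
                                 draws = list(r2 = 0.95, alpha = 1, o = 0))
  expect_equal(out2[1, 1], 2.0)
  # alarm branch adds O to every dimension (O * G with G all-ones)
  X3 <- matrix(c(1, 2, 3), 1, 3)
  out3 <- sso_update_discoverers(X3, t_max = 10, ctrl,
                                 matrix(c(-10, 10), 3, 2, byrow = TRUE),
                                 draws = list(r2 = 0.9, alpha = 1, o = 0.25))
  expect_equal(out3[1, ], c(1.25, 2.25, 3.25))
})

test_that("joiner update matches direct evaluation of both branches", {
  # converging branch (i <= n/2): X = Xb stays at Xb
  out <- sso_update_joiners(matrix(1.5, 1, 1), ranks = 2, n = 10, xb = 1.5,
                            xw = 9, bounds1, draws = list(o = 0, b = matrix(1)))
  expect_equal(out[1, 1], 1.5)
  # converging branch: Xb + |X - Xb| * B, d=1, Xb=1, X=3, B=+1 -> 3
  out2 <- sso_update_joiners(matrix(3, 1, 1), ranks = 2, n = 10, xb = 1,
                             xw = 9, bounds1, draws = list(o = 0,
                                                           b = matrix(1)))
  expect_equal(out2[1, 1], 3.0)
  # scattering branch (i > n/2) at X = Xw: exp(0) = 1 so result is O
  out3 <- sso_update_joiners(matrix(9, 1, 1), ranks = 8, n = 10, xb = 1,
                             xw = 9, bounds1, draws = list(o = 0.7,
                                                           b = matrix(1)))
  expect_equal(out3[1, 1], 0.7)
})

test_that("guarder update matches direct evaluation of both branches", {
  ctrl <- sso_control()
  # worse-than-best branch: Xbest + beta * |X - Xbest|, Xbest=1, X=3, beta=0.5
  out <- sso_update_guarders(matrix(3, 1, 1), f = 5, f_g = 1, f_w = 9,
                             xbest = 1, xworst = 8, ctrl, bounds1,
                             draws = list(beta = 0.5, k = 0))
  expect_equal(out[1, 1], 2.0)
  # worse-than-best branch at X = Xbest stays put
  out2 <- sso_update_guarders(matrix(1, 1, 1), f = 5, f_g = 1, f_w = 9,
                              xbest = 1, xworst = 8, ctrl, bounds1,
                              draws = list(beta = 0.5, k = 0))
  expect_equal(out2[1, 1], 1.0)
  # at-best branch with X = Xworst: zero numerator, unchanged
  out3 <- sso_update_guarders(matrix(8, 1, 1), f = 1, f_g = 1, f_w = 9,
                              xbest = 1, xworst = 8, ctrl, bounds1,
                              draws = list(beta = 0.5, k = 0.4))
  expect_equal(out3[1, 1], 8.0)
})

test_that("fitness_error_rate equals a per-sample comparison loop", {
  expect_equal(fitness_error_rate(matrix(0, 100, 3), matrix(0, 100, 3)), 0)
  expect_equal(fitness_error_rate(matrix(1, 100, 3), matrix(0, 100, 3)), 100)
  set.seed(3)
  for (rep in 1:10) {
    N <- sample(2:40, 1); C <- sample(1:4, 1)
    a <- matrix(rbinom(N * C, 1, 0.5), N, C)
    b <- matrix(rbinom(N * C, 1, 0.5), N, C)
    expect_equal(fitness_error_rate(a, b), error_rate_loop(a, b))
  }
  # 5 of 100 misclassified -> 5%
  a <- matrix(0, 100, 2); b <- a; b[1:5, 1] <- 1
  expect_equal(fitness_error_rate(a, b), 5.0)
  expect_error(fitness_error_rate(matrix(0, 0, 2), matrix(0, 0, 2)),
               "at least one")
})

test_that("population init is bounded, seeded, and correctly shaped", {
  b <- matrix(c(0, 1), 5, 2, byrow = TRUE)
  X1 <- sso_init_population(20, 5, b, seed = 4)
  X2 <- sso_init_population(20, 5, b, seed = 4)
  expect_identical(X1, X2)
  expect_identical(dim(X1), c(20L, 5L))
  expect_true(all(X1 >= 0 & X1 <= 1))
  expect_error(sso_init_population(3, 2, b[1:2, ]), "role split")
})

test_that("best-so-far trace is non-increasing and positions stay bounded", {
  set.seed(5)
  rugged <- function(x) sum(x^2) + 3 * sum(sin(5 * x)^2) # many local minima
  b <- matrix(c(-4, 4), 3, 2, byrow = TRUE)
  res <- sso_optimize(rugged, b, np = 12, t_max = 60, seed = 9)
  expect_false(is.unsorted(-res$trace$best_fitness)) # monotone non-increasing
  expect_true(all(res$population >= -4 & res$population <= 4))
  expect_identical(nrow(res$trace), 60L)
  # determinism: identical traces for identical seeds
  res2 <- sso_optimize(rugged, b, np = 12, t_max = 60, seed = 9)
  expect_identical(res$trace, res2$trace)
  expect_identical(res$best_position, res2$best_position)
})

test_that("NaN objectives are treated as +Inf with a warning", {
  bad <- function(x) if (x[1] > 0) NaN else sum(x^2)
  warns <- capture_warnings(res <- sso_optimize(bad, bounds1, np = 6,
                                                t_max = 5, seed = 2))
  expect_gt(length(warns), 0)
  expect_true(all(grepl("NaN", warns)))
  expect_true(is.finite(res$best_fitness))
})

test_that("2-D sphere: median final best over 10 seeds is < 1e-3", {
  b <- matrix(c(-5, 5), 2, 2, byrow = TRUE)
  finals <- vapply(1:10, function(s) {
    sso_optimize(function(x) sum(x^2), b, np = 30, t_max = 300,
                 seed = s)$best_fitness
  }, numeric(1))
  expect_lt(median(finals), 1e-3)
})

test_that("hyperparameter decoding respects types and scales", {
  box <- default_hyper_box()
  hp <- decode_hyperparams(c(-2, 15.6, 32.2, 0.8, 0.1), box)
  expect_equal(hp$lr, 0.01) # log10 scale
  expect_identical(hp$hidden, 16L) # rounded integer
  expect_identical(hp$batch_size, 32L)
  expect_equal(hp$gamma, 0.8)
  expect_error(decode_hyperparams(c(1, 2), box), "length")
})
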