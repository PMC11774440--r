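test_that("forward pass composes gated pathways", {
  net <- gated_network(p = 1, d_in = 4, d_out = 4, sigma0 = 0, seed = 1)
  net$weights[[1]] <- diag(4)
  net$gates <- 1
  x <- rnorm(4)
  expect_equal(predict(net, x), x)

  tc <- tiny_teachers()
  net2 <- tiny_network(sigma0 = 0)
  net2$weights <- list(tc$weights[[1]], tc$weights[[1]])
  net2$gates <- c(0.5, 0.5)
  x <- rnorm(16)
  expect_equal(predict(net2, x), drop(tc$weights[[1]] %*% x))

  net2$gates <- c(0, 0)
  expect_equal(predict(net2, x), rep(0, 4))
  expect_error(predict(net2, rnorm(7)), class = "gf_dim_error")
})

test_that("per-row gates act on individual output rows", {
  tc <- tiny_teachers(m = 2)
  net <- gated_network(p = 2, d_in = 16, d_out = 4, gate_mode = "per_row",
                       sigma0 = 0)
  net$weights <- tc$weights
  # odd rows from teacher 1, even rows from teacher 2
  net$gates <- rbind(c(1, 0, 1, 0), c(0, 1, 0, 1))
  x <- rnorm(16)
  y <- predict(net, x)
  y1 <- drop(tc$weights[[1]] %*% x)
  y2 <- drop(tc$weights[[2]] %*% x)
  expect_equal(y, ifelse(c(TRUE, FALSE, TRUE, FALSE), y1, y2))
  # and the row-composed teacher is matched exactly
  comp <- compose_teachers(tc, pairs = list(c(1, 2)), type = "rows")
  expect_equal(expected_task_loss(net, comp$weights[[1]]), 0)
})

test_that("task loss matches its closed-form expectation", {
  # exact cases
  tc <- tiny_teachers(m = 1)
  net <- tiny_network(p = 2, sigma0 = 0)
  net$weights <- list(tc$weights[[1]], tc$weights[[1]])
  net$gates <- c(0.5, 0.5)
  b <- sample_batch(tc$weights[[1]], n = 10, seed = 1)
  expect_equal(task_loss(net, b), 0)
  expect_equal(expected_task_loss(net, tc$weights[[1]]), 0)

  # single sample, hand-computed
  net1 <- gated_network(p = 1, d_in = 2, d_out = 2, sigma0 = 0)
  net1$gates <- 0
  expect_equal(task_loss(net1, list(x = matrix(c(1, 0)), y = matrix(c(1, 0)))),
               0.5)
  # closed gates on a unit-Frobenius teacher: loss = 0.5 * ||W*||^2
  wstar <- tc$weights[[1]] / sqrt(sum(tc$weights[[1]]^2))
  netz <- tiny_network(sigma0 = 0)
  netz$gates <- c(0, 0)
  expect_equal(expected_task_loss(netz, wstar), 0.5)

  # Monte-Carlo agreement at large n
  netr <- tiny_network(sigma0 = 0.5, seed = 8)
  b <- sample_batch(tc$weights[[1]], n = 1e5, seed = 3)
  expect_equal(task_loss(netr, b), expected_task_loss(netr, tc$weights[[1]]),
               tolerance = 0.02)
})

test_that("regularization losses follow the bounded nonnegative gate penalties", {
  net <- tiny_network()
  net$gates <- c(0.5, 0.5)
  expect_equal(reg_loss(net), list(norm = 0, nonneg = 0))
  net$gates <- c(1, 1)
  expect_equal(reg_loss(net)$norm, 0.5)
  net$gates <- c(-0.2, 1.0)
  expect_equal(reg_loss(net)$nonneg, 0.2)
  # permutation invariance
  net$gates <- c(0.9, -0.3)
  r1 <- reg_loss(net)
  net$gates <- c(-0.3, 0.9)
  expect_equal(reg_loss(net), r1)
  # L2 variant
  net2 <- tiny_network(norm_order = 2)
  net2$gates <- c(3, 4)
  expect_equal(reg_loss(net2)$norm, 0.5 * (5 - 1)^2)
})

test_that("expectation-mode gradients match the error-matrix expressions", {
  tc <- tiny_teachers(m = 1)
  net <- tiny_network(sigma0 = 0)
  net$weights <- list(tc$weights[[1]], 0 * tc$weights[[1]])
  net$gates <- c(1, 0.3)
  g <- loss_gradients(net, tc$weights[[1]])
  # students reproduce the teacher: task parts vanish
  expect_equal(g$dW[[1]], 0 * g$dW[[1]])
  expect_equal(g$components$task, c(0, 0))

  # for positive gates under the L1 bound, the norm-gradient is
  # lambda_norm * (sum(c) - 1) for every path
  net$gates <- c(0.8, 0.6)
  g2 <- loss_gradients(net, tc$weights[[1]])
  expect_equal(g2$components$reg,
               rep(net$lambda_norm * (0.8 + 0.6 - 1), 2))
})

test_that("minibatch gradients converge to the expectation gradients", {
  tc <- tiny_teachers(m = 1, d_in = 8, d_out = 2)
  net <- tiny_network(d_in = 8, d_out = 2, sigma0 = 0.5, seed = 4)
  net$gates <- c(0.7, 0.4)
  ge <- loss_gradients(net, tc$weights[[1]])
  b <- sample_batch(tc$weights[[1]], n = 4e5, seed = 11)
  gm <- loss_gradients(net, tc$weights[[1]], mode = "minibatch", batch = b)
  rel <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2))
  expect_lt(rel(gm$dW[[1]], ge$dW[[1]]), 0.01)
  expect_lt(rel(gm$dW[[2]], ge$dW[[2]]), 0.01)
  # relative Frobenius error of the full stacked gradient (the gate part
  # alone has a near-cancelling denominator, so it is checked stacked)
  stack <- function(g) c(unlist(g$dW), g$dc)
  expect_lt(rel(stack(gm), stack(ge)), 0.01)
  expect_error(loss_gradients(net, tc$weights[[1]], mode = "minibatch"),
               class = "gf_invalid_config")
})

test_that("analytic gradients match central finite differences", {
  # 10 random states, both gate modes, away from the hinge/sign kinks
  for (s in 1:5) {
    for (mode in c("scalar", "per_row")) {
      tc <- tiny_teachers(m = 1, d_in = 6, d_out = 3, seed = s)
      net <- gated_network(p = 2, d_in = 6, d_out = 3, gate_mode = mode,
                           sigma0 = 0.5, seed = s + 100)
      net$gates <- if (mode == "scalar") {
        withr::with_seed(s, runif(2, 0.2, 1.2))
      } else {
        withr::with_seed(s, matrix(runif(6, 0.2, 1.2), 2, 3))
      }
      g <- loss_gradients(net, tc$weights[[1]])
      dc <- if (mode == "scalar") matrix(g$dc, ncol = 1) else g$dc
      for (q in 1:2) {
        idx <- c(1, 9, 18)  # spot-check weight coordinates
        for (i in idx) {
          fd <- fd_total_loss(net, tc$weights[[1]], "w", q, i)
          expect_equal(g$dW[[q]][i], fd, tolerance = 1e-5)
        }
      }
      for (i in seq_along(net$gates)) {
        fd <- fd_total_loss(net, tc$weights[[1]], "c", NULL, i)
        expect_equal(unname(dc[i]), fd, tolerance = 1e-5)
      }
    }
  }
})

test_that("the forgetful baseline strips gate constraints and nothing else", {
  net <- gated_network(p = 2, d_in = 16, d_out = 4, tau_w = 1.3, tau_c = 0.03,
                       lambda_norm = 1, lambda_nonneg = 1, seed = 9)
  fb <- forgetful_baseline(net)
  expect_equal(fb$tau_c, 1.3)
  expect_equal(fb$lambda_norm, 0)
  expect_equal(fb$lambda_nonneg, 0)
  expect_identical(fb$weights, net$weights)
  expect_identical(fb$gates, net$gates)
  expect_identical(forgetful_baseline(fb), fb)
})
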