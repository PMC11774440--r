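test_that("alignment is the row-mean cosine with scale and sign symmetry", {
  tc <- tiny_teachers(m = 2)
  w <- tc$weights[[1]]
  expect_equal(alignment(w, w), 1)
  expect_equal(alignment(-w, w), -1)
  # rows orthogonal to the teacher rows align to zero
  expect_equal(alignment(tc$weights[[2]], w), 0, tolerance = 1e-10)
  # scale invariance up to sign
  withr::with_seed(1, {
    a <- matrix(rnorm(12), 3, 4)
    b <- matrix(rnorm(12), 3, 4)
  })
  expect_equal(alignment(2.7 * a, 0.3 * b), alignment(a, b))
  expect_equal(alignment(-2 * a, 5 * b), -alignment(a, b))
  # zero rows warn and contribute zero
  a0 <- a
  a0[2, ] <- 0
  expect_warning(al <- alignment(a0, b), "zero row")
  row_cos <- function(i) sum(a[i, ] * b[i, ]) /
    sqrt(sum(a[i, ]^2) * sum(b[i, ]^2))
  expect_equal(al, (row_cos(1) + 0 + row_cos(3)) / 3)
})

test_that("total alignment matches ensembles up to permutation", {
  tc <- tiny_teachers(m = 2)
  # swapped students still align perfectly
  expect_equal(total_alignment(rev(tc$weights), tc), 1)
  # small random initialization is near zero
  net <- gated_network(p = 2, d_in = 32, d_out = 8, sigma0 = 0.01, seed = 1)
  tc2 <- make_teachers(m = 2, d_in = 32, d_out = 8, seed = 2)
  expect_lt(abs(total_alignment(net, tc2)), 0.1)
  # forgetful collapse: both students on teacher 1 is strictly sub-par
  expect_lt(total_alignment(list(tc$weights[[1]], tc$weights[[1]]), tc),
            1 - 1e-6)
  # permutation invariance of the path order
  w <- list(tc$weights[[2]], 0.5 * tc$weights[[1]])
  expect_equal(total_alignment(w, tc), total_alignment(rev(w), tc))
  # equals 1 when the matched stack is a positive multiple of the teacher
  # stack; differing per-path scales strictly reduce the concatenated cosine
  expect_equal(total_alignment(list(2 * tc$weights[[1]], 2 * tc$weights[[2]]),
                               tc), 1, tolerance = 1e-9)
  expect_lt(total_alignment(list(2 * tc$weights[[1]], 0.1 * tc$weights[[2]]),
                            tc), 1 - 1e-3)
  expect_error(total_alignment(list(), tc), class = "gf_domain_error")
})

synthetic_traj <- function(loss_fun, n_blocks = 10, block_length = 1,
                           res = 200) {
  t <- seq(0, n_blocks * block_length - block_length / res,
           by = block_length / res)
  block <- floor(t / block_length) + 1L
  within <- t - (block - 1) * block_length
  as_trajectory(tibble::tibble(time = t, block = as.integer(block), task = 1L,
                               loss = loss_fun(within, block)),
                block_length = block_length)
}

test_that("time-to-criterion inverts loss curves per block", {
  # constant sub-threshold loss reaches criterion immediately
  tr <- synthetic_traj(function(w, b) rep(0.05, length(w)))
  expect_true(all(time_to_criterion(tr, 0.1)$t_crit == 0))
  # never below threshold: block length sentinel
  tr2 <- synthetic_traj(function(w, b) rep(0.5, length(w)))
  expect_true(all(time_to_criterion(tr2, 0.1)$t_crit == 1))
  # exponential decay exp(-t) within each 4-long block crosses 0.1 at ln(10)
  tr3 <- synthetic_traj(function(w, b) exp(-w), n_blocks = 3,
                        block_length = 4, res = 4000)
  expect_equal(time_to_criterion(tr3, 0.1)$t_crit, rep(log(10), 3),
               tolerance = 2e-3)
})

test_that("time-to-criterion is monotone under pointwise-lower losses", {
  f_hi <- function(w, b) exp(-2 * w)
  f_lo <- function(w, b) 0.5 * exp(-2 * w)
  hi <- time_to_criterion(synthetic_traj(f_hi, block_length = 4), 0.1)
  lo <- time_to_criterion(synthetic_traj(f_lo, block_length = 4), 0.1)
  expect_true(all(lo$t_crit <= hi$t_crit))
})

test_that("regime classification follows alignment and acceleration", {
  # hand-built: perfect alignment, criterion times decreasing -> flexible
  mk <- function(t_crit_fun, align) {
    tr <- synthetic_traj(function(w, b) ifelse(w >= t_crit_fun(b), 0.01, 1),
                         n_blocks = 12)
    tr$total_alignment <- rep(align, nrow(tr))
    tr
  }
  expect_equal(classify_regime(mk(function(b) 0.8 / b, 0.99)), "flexible")
  expect_equal(classify_regime(mk(function(b) 0.8 / b, 0.5)), "forgetful")
  expect_equal(classify_regime(mk(function(b) 0.2 + 0.05 * b, 0.99)),
               "forgetful")
  short <- synthetic_traj(function(w, b) w, n_blocks = 4)
  expect_error(classify_regime(short), class = "gf_insufficient_data")
})

test_that("switch-speed trends recover slope signs", {
  flat <- synthetic_traj(function(w, b) rep(0.3, length(w)), n_blocks = 10)
  expect_equal(switch_speed_trend(flat)$slope, 0, tolerance = 1e-12)
  rising <- synthetic_traj(function(w, b) 0.1 * b + 0 * w, n_blocks = 10)
  expect_gt(switch_speed_trend(rising)$slope, 0)
  expect_equal(switch_speed_trend(rising)$sign, 1)
  expect_error(switch_speed_trend(synthetic_traj(function(w, b) w,
                                                 n_blocks = 2)),
               class = "gf_insufficient_data")
})
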