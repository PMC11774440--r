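test_that("projection recovers reduced coordinates and specialization coords", {
  tc <- tiny_teachers(m = 2, d_in = 12, d_out = 3)
  # perfectly specialized students built from the teachers' singular triplets
  p_spec <- array(0, dim = c(2, 2, 3))
  for (q in 1:2) p_spec[q, q, ] <- 1
  net <- network_from_reduced(p_spec, gates = c(1, 0), teachers = tc)
  rs <- project_network(net, tc)
  expect_equal(rs$w, p_spec, tolerance = 1e-12)
  expect_equal(rs$coords$w_bar, 1)
  expect_equal(rs$coords$c_bar, 1)

  # identical students have zero specialization; zero students project to zero
  net2 <- tiny_network(seed = 4)
  net2$weights[[2]] <- net2$weights[[1]]
  rs2 <- project_network(net2, tiny_teachers())
  expect_equal(rs2$coords$w_bar1, 0)
  expect_equal(rs2$coords$w_bar2, 0)
  net3 <- tiny_network(sigma0 = 0)
  rs3 <- project_network(net3, tiny_teachers())
  expect_true(all(rs3$w == 0))

  expect_error(project_network(tiny_network(), tiny_teachers(m = 3, d_in = 16,
                                                             d_out = 4)),
               class = "gf_unsupported_config")
})

test_that("reduced derivatives vanish at fixed points and show the protection sign", {
  # perfect output at the regularization optimum: all derivatives zero
  rs <- gateflow:::new_reduced(diag(2), c(1, 0))
  d <- reduced_rhs(rs, target = 1, lambda_norm = 5, lambda_nonneg = 5)
  expect_equal(max(abs(d$dw)), 0)
  expect_equal(d$dc, c(0, 0), tolerance = 1e-12)

  # after a switch the specialized-but-wrong path's gate closes,
  # the newly-correct path's gate opens
  d2 <- reduced_rhs(rs, target = 2)
  expect_lt(d2$dc[1], 0)
  expect_gt(d2$dc[2], 0)
})

test_that("the gate decomposition is an exact identity and linear in the student", {
  for (s in 1:100) {
    rs <- random_reduced(seed = s)
    target <- 1 + s %% 2
    dec <- gate_decomposition(rs, target, lambda_norm = 0.7,
                              lambda_nonneg = 1.3)
    d <- reduced_rhs(rs, target, tau_c = 0.4, lambda_norm = 0.7,
                     lambda_nonneg = 1.3)
    total <- dec$term_teacher1 + dec$term_teacher2 + dec$reg_term
    expect_equal(total, 0.4 * d$dc, tolerance = 1e-12)
  }
  # a zero student contributes no error terms (small-init attenuation)...
  rs0 <- gateflow:::new_reduced(rbind(c(0, 0), c(0.3, 0.4)), c(0.5, 0.5))
  dec0 <- gate_decomposition(rs0, 1)
  expect_equal(dec0$term_teacher1[1], 0)
  expect_equal(dec0$term_teacher2[1], 0)
  # ...and the terms are linear in the student at fixed error (the scaled
  # path's gate is closed so the output, hence eps, is unchanged)
  rs1 <- gateflow:::new_reduced(rbind(c(0.2, 0.1), c(0.3, 0.4)), c(0, 0.5))
  rs2 <- gateflow:::new_reduced(rbind(c(0.4, 0.2), c(0.3, 0.4)), c(0, 0.5))
  d1 <- gate_decomposition(rs1, 1)
  d2 <- gate_decomposition(rs2, 1)
  expect_equal(d2$term_teacher1[1], 2 * d1$term_teacher1[1])
  expect_equal(d2$term_teacher2[1], 2 * d1$term_teacher2[1])
})

test_that("specialization derivatives match finite differences along a trajectory", {
  # trivial anchors
  rs <- gateflow:::new_reduced(rbind(c(0.8, 0.1), c(0.1, 0.7)), c(0.5, 0.5))
  expect_equal(specialization_rhs(rs, 2)$dw_bar, 0)  # c_bar = 0
  rs0 <- gateflow:::new_reduced(matrix(0.3, 2, 2), c(0.9, 0.2))
  expect_equal(specialization_rhs(rs0, 2)$dc_bar, 0)  # w_bar1 = w_bar2 = 0

  # numerical differentiation of integrated coordinates
  tr <- simulate_reduced(rbind(c(0.9, 0.05), c(0.1, 0.8)), c(0.8, 0.2),
                         targets = 2L, block_length = 1, tau_c = 0.3,
                         constrain_sum = TRUE, dt = 1e-3, method = "euler")
  # forward differences along an explicit-Euler path reproduce the rhs at
  # the step start exactly (the gate-sum projection cancels in c_bar)
  h <- tr$time[2] - tr$time[1]
  for (i in c(50, 200, 600)) {
    rs_i <- gateflow:::new_reduced(
      rbind(c(tr$w_p1_t1[i], tr$w_p1_t2[i]), c(tr$w_p2_t1[i], tr$w_p2_t2[i])),
      c(tr$gate_1[i], tr$gate_2[i]))
    d <- specialization_rhs(rs_i, 2, tau_w = 1, tau_c = 0.3)
    expect_equal((tr$w_bar[i + 1] - tr$w_bar[i]) / h, d$dw_bar,
                 tolerance = 1e-6)
    expect_equal((tr$c_bar[i + 1] - tr$c_bar[i]) / h, d$dc_bar,
                 tolerance = 1e-6)
  }
})

test_that("the closed-form symmetric solution matches its defining ODE", {
  # anchors at full separation: specialization is exactly 1 for any timescale
  for (ratio in c(0.05, 0.5, 1, 2)) {
    expect_equal(exact_symmetric_solution(1, tau_c = ratio, tau_w = 1), 1)
    expect_equal(exact_symmetric_solution(-1, tau_c = ratio, tau_w = 1), 1)
  }

  # independent oracle: integrate dw/dc = (tau_c/tau_w) * c / (2 w) from
  # (c, w) = (1, 1) down to c = 0 (equal timescales)
  sol <- deSolve::ode(y = c(w = 1), times = seq(1, 0, by = -0.01),
                      func = function(cbar, y, parms) {
                        list(parms * cbar / (2 * y[1]))
                      }, parms = 1, rtol = 1e-10, atol = 1e-12)
  oracle <- unname(sol[nrow(sol), "w"])
  expect_equal(oracle, 0.7071068, tolerance = 1e-6)  # frozen oracle value
  expect_equal(exact_symmetric_solution(0, tau_c = 1, tau_w = 1), oracle,
               tolerance = 1e-7)

  # domain errors
  expect_error(exact_symmetric_solution(1.5, 0.5), class = "gf_domain_error")
  expect_error(exact_symmetric_solution(0, tau_c = 3, tau_w = 1),
               class = "gf_domain_error")

  # even in c_bar, monotone increasing in |c_bar|
  cb <- seq(0, 1, by = 0.05)
  w <- exact_symmetric_solution(cb, tau_c = 0.8, tau_w = 1)
  expect_equal(w, exact_symmetric_solution(-cb, tau_c = 0.8, tau_w = 1))
  expect_true(all(diff(w) > 0))
})

test_that("full-model and reduced trajectories coincide on the teacher subspace", {
  tc <- make_teachers(m = 2, d_in = 8, d_out = 1, seed = 3)
  w0 <- withr::with_seed(42, matrix(rnorm(4, sd = 0.3), 2, 2))
  net <- network_from_reduced(w0, c(0.5, 0.5), tc, tau_w = 1, tau_c = 0.2,
                              lambda_norm = 1, lambda_nonneg = 1)
  cur <- make_curriculum(n_blocks = 5, block_length = 2, n_tasks = 2)
  dt <- net$tau_c / 50
  full <- simulate_dynamics(net, tc, cur, dt = dt, record_every = 1L)
  red <- simulate_reduced(w0, c(0.5, 0.5),
                          targets = active_task((0:4) * 2, cur),
                          block_length = 2, tau_w = 1, tau_c = 0.2,
                          lambda_norm = 1, lambda_nonneg = 1, dt = dt,
                          method = "euler")
  expect_lt(max(abs(full$loss - red$loss)), 1e-6)
  expect_lt(max(abs(full$gate_1 - red$gate_1)), 1e-6)
  expect_lt(max(abs(full$gate_2 - red$gate_2)), 1e-6)
  pr <- project_network(final_network(full), tc)
  expect_lt(max(abs(pr$w - attr(red, "final_state")$w)), 1e-6)
})

test_that("adaptation from the specialized state protects specialization", {
  ba <- block_adaptation(tau_c = 0.18, tau_w = 1)
  # strong-L1 setting: gates stay on the simplex within 1e-3
  expect_lt(max(abs(ba$gate_1 + ba$gate_2 - 1)), 1e-3)
  # complete adaptation to teacher 2
  expect_lt(ba$loss[nrow(ba)], 1e-2)
  # path matches the closed form pointwise
  pred <- exact_symmetric_solution(pmax(pmin(ba$c_bar, 1), -1),
                                   tau_c = 0.18, tau_w = 1)
  expect_lt(max(abs(ba$w_bar - pred)), 0.02)
  # protection limit: as tau_c/tau_w -> 0 the weights barely move
  ba_fast <- block_adaptation(tau_c = 0.01, tau_w = 1, block_length = 5)
  expect_gt(min(ba_fast$w_bar), 1 - 0.01)
})

test_that("the first integral of the symmetric flow is conserved", {
  tau_c <- 0.3
  tr <- simulate_reduced(diag(2), c(1, 0), targets = 2L, block_length = 6,
                         tau_w = 1, tau_c = tau_c, constrain_sum = TRUE,
                         dt = 0.003, rtol = 1e-11, atol = 1e-13)
  q <- tr$w_bar^2 - (tau_c / 2) * tr$c_bar^2
  expect_lt(max(abs(q - q[1])), 1e-6)
})
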