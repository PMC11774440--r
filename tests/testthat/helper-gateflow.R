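# Shared fixtures: everything is generated in code at test time.

tiny_teachers <- function(m = 2, d_in = 16, d_out = 4, seed = 1, ...) {
  make_teachers(m = m, d_in = d_in, d_out = d_out, seed = seed, ...)
}

tiny_network <- function(p = 2, d_in = 16, d_out = 4, tau_c = 0.1, seed = 2,
                         ...) {
  gated_network(p = p, d_in = d_in, d_out = d_out, tau_c = tau_c, seed = seed,
                ...)
}

# central finite difference of the total weighted loss at one coordinate
fd_total_loss <- function(net, teacher, what, q, i, h = 1e-6) {
  bump <- function(net, delta) {
    if (what == "w") {
      net$weights[[q]][i] <- net$weights[[q]][i] + delta
    } else {
      net$gates[i] <- net$gates[i] + delta
    }
    net
  }
  total <- function(net) {
    r <- reg_loss(net)
    expected_task_loss(net, teacher) + net$lambda_norm * r$norm +
      net$lambda_nonneg * r$nonneg
  }
  (total(bump(net, h)) - total(bump(net, -h))) / (2 * h)
}

# random reduced state for identity checks
random_reduced <- function(p = 2, seed = 1) {
  withr::with_seed(seed, {
    w <- matrix(rnorm(p * 2), p, 2)
    cc <- runif(p, -0.5, 1.5)
    gateflow:::new_reduced(w, cc)
  })
}
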