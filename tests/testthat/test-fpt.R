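test_that("sink reduction keeps sink escape in the diagonal and normalizes p0", {
  # 2-state chain with absorbing end
  net <- generate_two_state(2.0, 1.0)
  r <- build_rate_matrices(net)
  red <- reduce_to_sink(r, sink = 2, source = 1)
  expect_equal(dim(red$Q_tilde), c(1L, 1L))
  expect_equal(red$Q_tilde[1, 1], -r$K[2, 1])
  expect_equal(sum(red$p0), 1)

  # 3-state chain, sink at one end
  chain <- ktn(data.frame(id = 1:3, energy = c(-5, -5, -5)),
               data.frame(id = 1:2, energy = -3, min1 = 1:2, min2 = 2:3))
  rc <- build_rate_matrices(chain)
  redc <- reduce_to_sink(rc, sink = 3, source = 1)
  cs <- colSums(redc$Q_tilde)
  expect_equal(cs[["1"]], 0, tolerance = 1e-14)
  expect_lt(cs[["2"]], 0)

  # closed 5-ring: only sink-adjacent columns have strict deficit
  ring <- ktn(data.frame(id = 1:5, energy = rep(-5, 5)),
              data.frame(id = 1:5, energy = -3, min1 = 1:5,
                         min2 = c(2:5, 1L)))
  rr <- build_rate_matrices(ring)
  redr <- reduce_to_sink(rr, sink = 5, source = 1)
  cs <- colSums(redr$Q_tilde)
  expect_lt(max(abs(cs[c("2", "3")])), 1e-14)
  expect_true(all(cs[c("1", "4")] < 0))

  expect_error(reduce_to_sink(rc, sink = 1, source = 1), "disjoint")
  iso <- ktn(data.frame(id = 1:3, energy = c(-5, -5, -5)),
             data.frame(id = 1L, energy = -3, min1 = 1L, min2 = 2L))
  expect_warning(ri <- build_rate_matrices(iso), "connected")
  expect_error(reduce_to_sink(ri, sink = 2, source = 3), "unreachable")
})

test_that("eigenmodes reproduce single-state and symmetric two-state closed forms", {
  net <- generate_two_state(2.0, 1.0)
  r <- build_rate_matrices(net)
  em <- eigenmodes(reduce_to_sink(r, sink = 2, source = 1))
  expect_equal(em$lambda, -r$K[2, 1])
  expect_equal(em$A, 1)

  chain <- ktn(data.frame(id = 1:3, energy = c(-5, -5, -5)),
               data.frame(id = 1:2, energy = -3, min1 = 1:2, min2 = 2:3))
  rc <- build_rate_matrices(chain)
  em2 <- eigenmodes(reduce_to_sink(rc, sink = 3, source = 1))
  expect_true(all(em2$lambda < 0))
  expect_equal(sum(em2$A), 1, tolerance = 1e-10)
  # biorthogonality
  G <- em2$Y %*% em2$X
  expect_equal(G, diag(2), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("eigenvalues agree with a generic dense eigensolver on a synthetic funnel", {
  gen <- generate_funnel_ktn(1, 20, seed = 5)
  r <- build_rate_matrices(gen$ktn)
  sink <- gen$ktn$minima$id[which.max(gen$ktn$minima$energy)]
  src <- gen$representatives[1]
  red <- reduce_to_sink(r, sink = sink, source = src)
  em <- eigenmodes(red)
  dense <- sort(Re(eigen(red$Q_tilde, only.values = TRUE)$values))
  expect_equal(sort(em$lambda), dense, tolerance = 1e-8)
})

test_that("FPT distribution has the analytic log-time peak structure", {
  # one mode: exponential density, peak height 1/e at y = ln(1/k)
  net <- generate_two_state(2.0, 1.0)
  r <- build_rate_matrices(net)
  red <- reduce_to_sink(r, sink = 2, source = 1)
  em <- eigenmodes(red)
  k <- r$K[2, 1]
  fd <- fpt_distribution(em)
  expect_equal(fd$mode_peaks$y_star, log(1 / k), tolerance = 1e-8)
  expect_equal(fd$mode_peaks$height, 1 / exp(1), tolerance = 1e-8)
  expect_equal(max(fd$density), 1 / exp(1), tolerance = 1e-4)
  # quadrature normalization on a wide grid
  fd_wide <- fpt_distribution(em, y_range = log(1 / k) + c(-16, 6))
  integral <- sum(diff(fd_wide$y) *
                    (utils::head(fd_wide$density, -1) +
                       utils::tail(fd_wide$density, -1)) / 2)
  expect_equal(integral, 1, tolerance = 1e-6)

  # two synthetic well-separated modes superpose
  em2 <- structure(list(lambda = c(-1e-6, -1), A = c(0.5, 0.5),
                        X = diag(2), Y = diag(2), ids = 1:2,
                        p0 = c(1, 0)), class = "eigenmode_set")
  fd2 <- fpt_distribution(em2)
  expect_equal(fd2$mode_peaks$height, c(0.5, 0.5) / exp(1))
  expect_equal(nrow(fd2$empirical_peaks), 2)
  expect_equal(sort(fd2$empirical_peaks$height), rep(0.5 / exp(1), 2),
               tolerance = 1e-3)
})

test_that("MFPT: linear solve matches closed forms and the eigenmode sum", {
  net <- generate_two_state(2.0, 1.0)
  r <- build_rate_matrices(net)
  red <- reduce_to_sink(r, sink = 2, source = 1)
  expect_equal(mfpt(red), 1 / r$K[2, 1], tolerance = 1e-12)

  # uniform chain of n states + sink: MFPT = sum over k<=n of k = n(n+1)/2
  n <- 7
  chain <- ktn(data.frame(id = 1:(n + 1), energy = rep(-5, n + 1)),
               data.frame(id = 1:n, energy = -5 + 1e-12, min1 = 1:n,
                          min2 = 2:(n + 1)))
  rc <- build_rate_matrices(chain)   # all rates 1
  redc <- reduce_to_sink(rc, sink = n + 1, source = 1)
  expect_equal(mfpt(redc), n * (n + 1) / 2, tolerance = 1e-9)

  for (seed in 1:10) {
    gen <- random_funnel_net(seed)
    r <- build_rate_matrices(gen$ktn)
    ids <- gen$ktn$minima$id
    sink <- ids[which.max(gen$ktn$minima$energy)]
    src <- gen$representatives[1]
    if (src == sink) next
    red <- reduce_to_sink(r, sink = sink, source = src)
    expect_equal(mfpt_from_modes(eigenmodes(red)), mfpt(red),
                 tolerance = 1e-8)
  }
})

test_that("eigenmode FPT density matches stiff ODE propagation of the reduced master equation", {
  skip_if_not_installed("deSolve")
  gen <- generate_funnel_ktn(2, c(6, 6), inter_funnel_barrier = 6, seed = 9)
  r <- build_rate_matrices(gen$ktn)
  sink <- gen$representatives[2]
  src <- gen$ktn$minima$id[2]
  red <- reduce_to_sink(r, sink = sink, source = src)
  em <- eigenmodes(red)
  tm <- mfpt(red)
  times <- tm * c(0.01, 0.1, 0.5, 1, 2, 5)
  sol <- deSolve::ode(y = red$p0, times = c(0, times),
                      func = function(t, p, parms) list(as.numeric(red$Q_tilde %*% p)),
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  p_ode <- -colSums(red$Q_tilde) %*% t(sol[-1, -1, drop = FALSE]) # flux into sink
  p_eig <- vapply(times, function(t) sum(em$A * abs(em$lambda) * exp(em$lambda * t)), 1.0)
  expect_equal(as.numeric(p_ode), p_eig, tolerance = 1e-5)
})

test_that("a planted trap splits the FPT distribution into well-separated peaks", {
  tk <- generate_trap_ktn()
  r <- build_rate_matrices(tk$ktn)
  red <- reduce_to_sink(r, sink = tk$sink, source = tk$source)
  em <- eigenmodes(red)
  fd <- fpt_distribution(em, amplitude_cutoff = 0.05)
  expect_gte(nrow(fd$mode_peaks), 2)
  expect_gte(nrow(fd$empirical_peaks), 2)
  # raising the trap-escape barrier shifts the slow peak to larger y
  tk2 <- generate_trap_ktn(trap_depth = 14)
  r2 <- build_rate_matrices(tk2$ktn)
  em2 <- eigenmodes(reduce_to_sink(r2, sink = tk2$sink, source = tk2$source))
  expect_gt(-log(abs(em2$lambda[1])), -log(abs(em$lambda[1])))
})

test_that("mode attribution concentrates on the trapping basin and is permutation-equivariant", {
  net <- generate_two_state(2.0, 1.0)
  r <- build_rate_matrices(net)
  em <- eigenmodes(reduce_to_sink(r, sink = 2, source = 1))
  at <- mode_attribution(em, 1)
  expect_equal(at$weight, 1)

  tk <- generate_trap_ktn()
  r <- build_rate_matrices(tk$ktn)
  em <- eigenmodes(reduce_to_sink(r, sink = tk$sink, source = tk$source))
  at_slow <- mode_attribution(em, 1)
  expect_equal(at_slow$id[1], tk$trap)
  expect_gt(at_slow$weight[1], 0.99)

  # relabeling minima permutes ids but not weights
  relabel <- c(1L, 2L, 3L); new <- c(10L, 20L, 30L)
  mins <- tk$ktn$minima; mins$id <- new[match(mins$id, relabel)]
  ts <- tk$ktn$ts
  ts$min1 <- new[match(ts$min1, relabel)]; ts$min2 <- new[match(ts$min2, relabel)]
  net_p <- ktn(mins, ts)
  em_p <- eigenmodes(reduce_to_sink(build_rate_matrices(net_p),
                                    sink = 30, source = 10))
  at_p <- mode_attribution(em_p, 1)
  expect_equal(at_p$weight, at_slow$weight, tolerance = 1e-10)
  expect_equal(at_p$id, new[match(at_slow$id, relabel)])
})
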