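test_that("branching probabilities and waiting times follow their definitions", {
  # state 1 with two exits at rates 1 and 3 (plus reverse rates so no state
  # is isolated): branching 0.25 / 0.75, waiting time 0.25
  K <- matrix(0, 3, 3)
  K[2, 1] <- 1; K[3, 1] <- 3; K[1, 2] <- 0.5; K[1, 3] <- 0.5
  r <- structure(list(K = K, D = diag(colSums(K)), Q = K - diag(colSums(K)),
                      ids = 1:3, model = NULL), class = "rate_matrices")
  rep <- to_branching(r, sink = integer())
  expect_equal(rep$P[2, 1], 0.25)
  expect_equal(rep$P[3, 1], 0.75)
  expect_equal(rep$tau[1], 0.25)
  expect_equal(unname(colSums(rep$P)), rep_len(1, 3), tolerance = 1e-14)

  # sink-adjacent state: deficit 1
  two <- generate_two_state(2, 1)
  r2 <- build_rate_matrices(two)
  rep2 <- to_branching(r2, sink = 2L)
  expect_equal(dim(rep2$P), c(1L, 1L))
  expect_equal(rep2$P[1, 1], 0)
  expect_equal(rep2$tau[1], 1 / r2$K[2, 1])
})

test_that("to_rates inverts to_branching on arbitrary networks", {
  for (seed in 1:5) {
    gen <- random_funnel_net(seed)
    r <- build_rate_matrices(gen$ktn)
    back <- to_rates(to_branching(r, sink = integer()))
    expect_equal(back$K, r$K, tolerance = 1e-12)
    expect_equal(diag(back$D), diag(r$D), tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("state elimination preserves first-passage statistics exactly", {
  # irreversible linear chain 1 -> 2 -> 3 at rate k each, eliminate 2:
  # effective branching 1 with doubled waiting time
  k <- 0.37
  K <- matrix(0, 3, 3); K[2, 1] <- k; K[3, 2] <- k
  r <- structure(list(K = K, D = diag(colSums(K)), Q = K - diag(colSums(K)),
                      ids = 1:3, model = NULL), class = "rate_matrices")
  rep <- to_branching(r, sink = 3L)
  rep2 <- eliminate_state(rep, 2L)
  expect_equal(unname(rep2$tau), 2 / k)
  # deficit 1: everything reaches the sink
  expect_equal(unname(colSums(rep2$P)), 0)

  # eliminating a state unconnected to a column leaves it unchanged
  gen <- generate_funnel_ktn(2, c(4, 4), seed = 2)
  r <- build_rate_matrices(gen$ktn)
  rep <- to_branching(r, sink = 8L)
  far <- 5L   # funnel-2 member; column 1 (funnel-1 bottom) is not its neighbour
  if (rep$P[match(1L, rep$ids), match(far, rep$ids)] == 0 &&
      rep$P[match(far, rep$ids), match(1L, rep$ids)] == 0) {
    rep2 <- eliminate_state(rep, far)
    expect_equal(rep2$P[, match(1L, rep2$ids)],
                 rep$P[setdiff(seq_along(rep$ids), match(far, rep$ids)),
                       match(1L, rep$ids)],
                 tolerance = 1e-14)
  }
})

test_that("pGT reduction preserves MFPT to the sink for any elimination set", {
  for (seed in 1:20) {
    gen <- random_funnel_net(seed, max_funnels = 3, max_minima = 10)
    r <- build_rate_matrices(gen$ktn)
    ids <- gen$ktn$minima$id
    sink <- gen$representatives[length(gen$representatives)]
    src <- setdiff(ids, sink)[1]
    full <- mfpt(reduce_to_sink(r, sink = sink, source = src))
    pool <- setdiff(ids, c(sink, src))
    keep <- if (length(pool) > 1) sample(pool, sample.int(length(pool) - 1, 1)) else integer()
    red <- pgt_reduce(r, retain = c(src, keep), sink = sink)
    got <- mfpt(as_sink_reduction(red, source = src))
    expect_equal(got, full, tolerance = 1e-8)
  }
})

test_that("pGT reduced networks are independent of the elimination order", {
  gen <- generate_funnel_ktn(2, c(6, 6), seed = 13)
  r <- build_rate_matrices(gen$ktn)
  sink <- gen$representatives[2]
  retain <- c(1L, 3L)
  elim <- setdiff(r$ids, c(sink, retain))
  red_a <- pgt_reduce(r, retain, sink, order = elim)
  red_b <- pgt_reduce(r, retain, sink, order = rev(elim))
  red_c <- pgt_reduce(r, retain, sink)
  expect_equal(red_a$K, red_b$K, tolerance = 1e-10)
  expect_equal(red_a$K, red_c$K, tolerance = 1e-10)
  expect_equal(diag(red_a$D), diag(red_c$D), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("retaining everything is the identity and bottom-to-bottom MFPTs survive 2-state reduction", {
  gen <- generate_funnel_ktn(2, c(25, 25), inter_funnel_barrier = 7, seed = 21)
  r <- build_rate_matrices(gen$ktn)
  ident <- pgt_reduce(r, retain = setdiff(r$ids, 50L), sink = 50L)
  rep0 <- to_rates(to_branching(r, sink = 50L))
  expect_equal(ident$K, rep0$K, tolerance = 1e-12)

  bottoms <- gen$representatives
  full <- mfpt(reduce_to_sink(r, sink = bottoms[2], source = bottoms[1]))
  red <- pgt_reduce(r, retain = bottoms[1], sink = bottoms[2])
  expect_equal(1 / red$D[1, 1], full, tolerance = 1e-8)

  red2 <- pgt_reduce(r, retain = bottoms, sink = gen$ktn$minima$id[3])
  expect_equal(mfpt(as_sink_reduction(red2, source = bottoms[2])),
               mfpt(reduce_to_sink(r, sink = gen$ktn$minima$id[3],
                                   source = bottoms[2])),
               tolerance = 1e-8)
})

test_that("total sink-absorption probability is conserved by reduction", {
  gen <- generate_funnel_ktn(2, c(8, 8), seed = 31)
  r <- build_rate_matrices(gen$ktn)
  sink <- gen$representatives[2]
  red <- pgt_reduce(r, retain = c(1L, 2L), sink = sink)
  # absorption probability from any retained state is 1: column deficits of
  # the branching representation are the per-step sink probabilities, and the
  # reduced 2-state system must still absorb everything
  sr <- as_sink_reduction(red, source = 1L)
  em <- eigenmodes(sr)
  expect_equal(sum(em$A), 1, tolerance = 1e-10)
})

test_that("pGT recovers the slow eigenvalue that dense eigendecomposition loses", {
  dt <- generate_deep_trap_ktn(trap_rate = 1e-18, n_satellites = 8)
  r <- build_rate_matrices(dt$ktn)
  red <- reduce_to_sink(r, sink = dt$sink, source = dt$trap)

  # analytic oracle: the trap outflow is ~1e-18 against O(1) rates elsewhere,
  # so the slowest eigenvalue is -k_out * P(absorb at sink before returning
  # to the trap | hub) up to O(k_out^2); the splitting probability comes from
  # a well-conditioned solve on the fast subnetwork
  fast <- setdiff(r$ids, c(dt$trap, dt$sink))
  i_f <- match(fast, r$ids)
  q <- solve(t(r$Q[i_f, i_f]), -r$K[match(dt$sink, r$ids), i_f])
  lam_true <- unname(-r$D[match(dt$trap, r$ids), match(dt$trap, r$ids)] *
                       q[match(dt$hub, fast)])

  # generic dense (nonsymmetric) eigendecomposition cannot resolve it:
  # absolute eigenvalue error is ~eps * ||Q|| ~ 1e-16 >> |lambda_slow|
  ev <- eigen(red$Q_tilde)$values
  lam_direct <- Re(ev[which.min(abs(ev))])
  expect_gt(abs(lam_direct - lam_true) / abs(lam_true), 1e-3)

  # pGT reduction to the trap alone computes it from O(1) branching
  # probabilities: agreement to at least 6 significant figures
  pg <- pgt_reduce(r, retain = dt$trap, sink = dt$sink)
  expect_equal(-pg$D[1, 1], lam_true, tolerance = 1e-6)
})

test_that("numerically trapped states are reported", {
  K <- matrix(0, 2, 2); K[2, 1] <- 1; K[1, 2] <- 1
  r <- structure(list(K = K, D = diag(colSums(K)), Q = K - diag(colSums(K)),
                      ids = 1:2, model = NULL), class = "rate_matrices")
  rep <- to_branching(r, sink = integer())
  # both states only exchange with each other: eliminating one leaves the
  # other with unit self-loop
  rep2 <- eliminate_state(rep, 1L)
  expect_error(eliminate_state(rep2, 2L), "trapped")
})
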