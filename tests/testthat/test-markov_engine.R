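test_that("uniform transition matrix matches the hand-built toy matrix exactly", {
  expect_equal(unclass(toy_matrix())[, ], toy_matrix_expected(),
               tolerance = 1e-15, ignore_attr = TRUE)

  one <- build_transition(augment(directed_network("A")))
  expect_equal(unname(unclass(one)[, ]),
               rbind(c(0, 1, 0), c(1/2, 0, 1/2), c(1, 0, 0)),
               tolerance = 1e-15)
})

test_that("transition rows are uniform over the enumerated out-neighbors", {
  aug <- random_augmented(6, 0.4, seed = 3)
  M <- build_transition(aug)
  expect_equal(unname(rowSums(M)), rep(1, 8), tolerance = 1e-12)
  for (v in aug$ordering) {
    nb <- aug$out_neighbors[[v]]
    expect_setequal(names(which(M[v, ] > 0)), nb)
    expect_equal(unname(M[v, nb]), rep(1 / length(nb), length(nb)),
                 tolerance = 1e-15)
  }
})

test_that("loading a printed matrix renormalizes rounded rows and rejects bad input", {
  path <- system.file("extdata", "p53_regulators_matrix.csv",
                      package = "walkrank")
  M <- load_transition(path)
  expect_equal(dim(M), c(11L, 11L))
  expect_equal(unname(rowSums(M)), rep(1, 11), tolerance = 1e-12)
  expect_equal(rownames(M)[c(1, 6, 11)], c("S", "HDAC1", "T"))

  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,0", "0,0"), f)          # zero row cannot be renormalized
  expect_error(load_transition(f), "renormalization band")
  writeLines(c("1,0,0", "0,1,0"), f)      # non-square
  expect_error(load_transition(f), "not square")
  writeLines(c("0.5,0.2", "0,1"), f)      # row sum far from 1
  expect_error(load_transition(f), "renormalization band")
  writeLines(c("1.5,-0.5", "0,1"), f)     # negative entry
  expect_error(load_transition(f), "negative")
  expect_error(load_transition("no/such.csv"), "not found")
})

test_that("ergodicity check reproduces the cycle-length argument", {
  rep_toy <- check_ergodicity(toy_matrix())
  expect_true(rep_toy$strongly_connected)
  expect_equal(rep_toy$period, 1L)        # cycles of length 3 and 4 coexist
  expect_true(rep_toy$is_ergodic)

  # the raw (un-augmented) toy network is not strongly connected
  raw <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 0))
  rep_raw <- check_ergodicity(raw)
  expect_false(rep_raw$strongly_connected)
  expect_equal(rep_raw$period, 0L)
  expect_false(rep_raw$is_ergodic)

  rep_cyc <- check_ergodicity(cycle2_matrix())
  expect_true(rep_cyc$strongly_connected)
  expect_equal(rep_cyc$period, 2L)
  expect_equal(rep_cyc$period, brute_period(cycle2_matrix() > 0))
  expect_false(rep_cyc$is_ergodic)
})

test_that("BFS-level period agrees with brute-force cycle enumeration on small graphs", {
  checked <- 0L
  for (seed in 1:40) {
    n <- 2L + seed %% 5L
    net <- random_network(n, 0.35, seed = 1000 + seed)
    adj <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
    if (nrow(net$edges)) adj[net$edges] <- 1
    rep <- check_ergodicity(adj)
    if (rep$strongly_connected) {
      expect_equal(rep$period, brute_period(adj))
      checked <- checked + 1L
    }
    # directed k-cycles have period k
    k <- 2L + seed %% 4L
    cyc <- diag(k)[c(2:k, 1), ]
    expect_equal(check_ergodicity(cyc)$period, k)
    expect_equal(check_ergodicity(cyc)$period, brute_period(cyc))
  }
  expect_gt(checked, 5L)
})

test_that("direct solve reproduces the toy solution in exact rationals", {
  P <- stationary_direct(toy_matrix(), scaling = "initial-node-one")
  expect_equal(unname(P$p), c(1, 1/3, 1/3, 4/9, 1/2), tolerance = 1e-12)
  expect_lt(P$residual, 1e-8)

  # single-node network: balance equations p_A = p_S, p_T = p_A/2,
  # p_S = p_A/2 + p_T give (0.4, 0.4, 0.2) under sum-one scaling
  one <- build_transition(augment(directed_network("A")))
  expect_equal(unname(stationary_direct(one)$p), c(0.4, 0.4, 0.2),
               tolerance = 1e-12)
})

test_that("direct solve agrees with an independent linear-system oracle", {
  for (seed in 1:15) {
    M <- build_transition(random_augmented(3 + seed %% 8, 0.3,
                                           seed = 500 + seed))
    p <- stationary_direct(M)$p
    expect_equal(unname(p), unname(stationary_linear_oracle(M)),
                 tolerance = 1e-10)
  }
})

test_that("non-ergodic input is refused by the solver", {
  expect_error(stationary_direct(cycle2_matrix()), "not ergodic",
               class = "walkrank_method_error")
  raw <- rbind(c(0.5, 0.5), c(0, 1))     # absorbing, not irreducible
  expect_error(stationary_direct(raw), "not ergodic")
})

test_that("power iteration matches the direct solve and detects periodicity", {
  Pd <- stationary_direct(toy_matrix())
  Pp <- stationary_power(toy_matrix(), tol = 1e-12)
  expect_equal(Pp$p, Pd$p, tolerance = 1e-10)
  expect_lt(Pp$residual, 1e-8)

  # a period-2 chain oscillates forever from any asymmetric start (the
  # uniform start happens to sit exactly on the oscillation's average)
  expect_error(stationary_power(cycle2_matrix(), check = FALSE,
                                start = c(1, 0), max_iter = 1e4),
               "did not converge", class = "walkrank_method_error")

  # a doubly stochastic uniform matrix fixes the uniform start immediately
  U <- matrix(1/3, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(unname(stationary_power(U, check = FALSE)$p), rep(1/3, 3),
               tolerance = 1e-12)

  # the limit is independent of the starting distribution
  for (s in list(c(1, 0, 0, 0, 0), c(0.1, 0.2, 0.3, 0.2, 0.2))) {
    expect_equal(stationary_power(toy_matrix(), start = s)$p, Pd$p,
                 tolerance = 1e-10)
  }
})

test_that("S receives exactly twice the stationary mass of T on augmented chains", {
  for (seed in 1:30) {
    M <- build_transition(random_augmented(1 + seed %% 12, 0.4,
                                           seed = 7000 + seed))
    p <- stationary_direct(M)$p
    expect_equal(unname(p[1]), 2 * unname(p[length(p)]), tolerance = 1e-9)
  }
})

test_that("stationary distribution is equivariant under protein relabeling", {
  net <- random_network(7, 0.35, seed = 77)
  perm <- c(3, 1, 7, 5, 2, 6, 4)
  pnet <- directed_network(net$nodes[perm], net$edges)
  p1 <- stationary_direct(build_transition(augment(net)))$p
  p2 <- stationary_direct(build_transition(augment(pnet)))$p
  expect_equal(p2[names(p1)], p1, tolerance = 1e-10)
})

test_that("scaling conventions are consistent rescalings of one solution", {
  M <- toy_matrix()
  P <- stationary_direct(M)
  expect_equal(sum(P$p), 1, tolerance = 1e-12)
  l2 <- rescale(P, "unit-euclidean")
  expect_equal(sum(l2$p^2), 1, tolerance = 1e-12)
  s1 <- rescale(P, "initial-node-one")
  expect_equal(unname(s1$p[1]), 1, tolerance = 1e-15)
  expect_equal(unname(s1$p), unname(P$p / P$p[1]), tolerance = 1e-14)
  expect_equal(stationary_direct(M, scaling = "unit-euclidean")$p, l2$p,
               tolerance = 1e-12)
})
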