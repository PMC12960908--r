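test_that("position-specific convolution matches the worked examples", {
  # L=2, M=1, K=3, F=1; filters [1,1,1] at position 1: taps cover the zero
  # pad, d1=1, d2=2 -> 3
  D <- matrix(c(1, 2), 2, 1)
  bank <- array(0, c(2, 1, 3, 1))
  bank[1, 1, , 1] <- c(1, 1, 1)
  expect_equal(positionSpecificConv(D, bank)[1, 1], 3)

  # filters [0,0,1] at position 2: the third tap falls on the zero pad
  bank2 <- array(0, c(2, 1, 3, 1))
  bank2[2, 1, , 1] <- c(0, 0, 1)
  expect_equal(positionSpecificConv(D, bank2)[2, 1], 0)

  # all-zero bank
  expect_equal(positionSpecificConv(D, array(0, c(2, 1, 3, 1))),
               matrix(0, 2, 1))
})

test_that("position-specific convolution matches the nested-loop oracle", {
  set.seed(10)
  for (i in 1:20) {
    L <- sample(2:9, 1); M <- sample(1:4, 1)
    F <- sample(1:4, 1); K <- sample(c(1, 3, 5), 1)
    D <- matrix(rnorm(L * M), L, M)
    bank <- array(rnorm(L * F * K * M), c(L, F, K, M))
    expect_lt(max(abs(positionSpecificConv(D, bank) - oracleConv(D, bank))), 1e-10)
  }
})

test_that("tied per-position filters reduce to a shared cross-correlation", {
  set.seed(11)
  L <- 8; M <- 3; F <- 2; K <- 5
  shared <- array(rnorm(F * K * M), c(F, K, M))
  tied <- array(0, c(L, F, K, M))
  for (i in seq_len(L)) tied[i, , , ] <- shared
  D <- matrix(rnorm(L * M), L, M)
  got <- positionSpecificConv(D, tied)
  expect_lt(max(abs(got - oracleSharedConv(D, shared))), 1e-10)
  expect_lt(max(abs(positionSpecificConv(D, shared) - oracleSharedConv(D, shared))),
            1e-10)
})

test_that("zero-order-hold discretization follows the closed forms", {
  expect_equal(discretizeZoh(0, 1.7, 1)$Abar, 1)
  expect_equal(discretizeZoh(-1, log(2), 1)$Abar, 0.5)
  z <- discretizeZoh(c(-1, -2), 1e-9, c(3, 4))
  expect_equal(z$Abar, c(1, 1), tolerance = 1e-8)   # continuity limit
  expect_equal(z$Bbar, c(3e-9, 4e-9))
  expect_error(discretizeZoh(-1, 0, 1), "positive")
})

test_that("selective scan reproduces its limiting cases", {
  # memoryless: Abar=0, Bbar=1, C=2 -> z_t = 2 g_t
  G <- matrix(c(1, 3), 2, 1)
  expect_equal(selectiveScan(G, c(0, 0), c(1, 1), c(2, 2)),
               matrix(c(2, 6), 2, 1))
  # integrator: cumulative sum
  expect_equal(selectiveScan(matrix(1, 3, 1), rep(1, 3), rep(1, 3), rep(1, 3)),
               matrix(1:3, 3, 1))
})

test_that("selective scan matches the naive recurrence oracle and is causal", {
  set.seed(12)
  for (i in 1:20) {
    L <- sample(2:10, 1); F <- sample(1:4, 1); S <- sample(1:5, 1)
    G <- matrix(rnorm(L * F), L, F)
    Abar <- matrix(runif(L * S, 0, 1), L, S)
    Bbar <- matrix(rnorm(L * S), L, S)
    C <- matrix(rnorm(L * S), L, S)
    expect_lt(max(abs(selectiveScan(G, Abar, Bbar, C) -
                      oracleScan(G, Abar, Bbar, C))), 1e-10)
  }
  # causality: perturbing row t changes rows >= t only
  L <- 8; S <- 4
  G <- matrix(rnorm(L * 2), L, 2)
  Abar <- matrix(runif(L * S), L, S); Bbar <- matrix(rnorm(L * S), L, S)
  C <- matrix(rnorm(L * S), L, S)
  base <- selectiveScan(G, Abar, Bbar, C)
  G2 <- G; G2[5, ] <- G2[5, ] + 1
  pert <- selectiveScan(G2, Abar, Bbar, C)
  expect_equal(pert[1:4, ], base[1:4, ])
  expect_false(isTRUE(all.equal(pert[5, ], base[5, ])))
})

test_that("scale fusion is a softmax-weighted convex combination", {
  # symmetry: equal queries and equal inputs return the input
  Z <- matrix(rnorm(12), 4, 3)
  f <- fuseScales(list(Z, Z, Z), list(rep(1, 3), rep(1, 3), rep(1, 3)))
  expect_equal(f$Z, Z)
  expect_equal(f$weights[[1]], matrix(1 / 3, 4, 3))

  # worked example: pre-softmax (ln 2, 0, 0), values (4, 8, 8) -> 6
  f2 <- fuseScales(list(matrix(4), matrix(8), matrix(8)),
                   list(log(2) / 4, 0, 0))
  expect_equal(f2$weights[[1]][1, 1], 0.5)
  expect_equal(f2$Z[1, 1], 6)

  # random case: weights sum to one, fused value within scale range
  set.seed(13)
  zs <- replicate(3, matrix(rnorm(20), 5, 4), simplify = FALSE)
  qs <- replicate(3, rnorm(4), simplify = FALSE)
  f3 <- fuseScales(zs, qs)
  expect_equal(Reduce(`+`, f3$weights), matrix(1, 5, 4), tolerance = 1e-12)
  lo <- Reduce(pmin, zs); hi <- Reduce(pmax, zs)
  expect_true(all(f3$Z >= lo - 1e-12 & f3$Z <= hi + 1e-12))
})

test_that("embedding is a row lookup", {
  tab <- diag(4)
  out <- embedBatch(matrix(c(0L, 0L, 0L), 1, 3), tab)
  expect_equal(out[1, 1, ], out[1, 2, ])
  expect_equal(out[1, 3, ], c(1, 0, 0, 0))
  out2 <- embedBatch(matrix(0:3, 1, 4), tab)
  for (t in 1:4) expect_equal(out2[1, t, ], as.numeric(diag(4)[t, ]))
  expect_error(embedBatch(matrix(4L, 1, 1), tab), "0..3")
})
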