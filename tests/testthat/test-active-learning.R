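test_that("binary entropy matches its closed form", {
  expect_equal(binary_entropy(0.5), log(2))
  expect_equal(binary_entropy(0.75), -(0.75 * log(0.75) + 0.25 * log(0.25)))
  expect_equal(binary_entropy(0.75), 0.5623, tolerance = 1e-4)
  expect_lt(binary_entropy(1e-12), 1e-10)
  expect_equal(binary_entropy(c(0, 1)), c(0, 0))  # continuity convention
})

test_that("random initialization covers every drug and one full target column", {
  e1 <- init_random(3, 1, seed = 2)
  expect_equal(nrow(e1), 3)
  expect_true(all(e1[, 2] == 1))

  e <- init_random(50, 50, seed = 7)
  X <- matrix(0, 50, 50); X[e] <- 1
  expect_true(all(rowSums(X) >= 1))
  expect_equal(sum(colSums(X) == 50), 1)
  expect_true(nrow(e) >= 50 && nrow(e) <= 100)
  expect_identical(init_random(50, 50, seed = 7), e)
})

test_that("diversity initialization balances cluster pairs", {
  ## two obvious drug clusters and two target clusters
  Y <- two_block_matrix(12, 10)
  ks <- derive_perfect_kernels(Y)
  e <- init_diversity(ks$Kd, ks$Kt, budget = 4, seed = 1,
                      k_drugs = 2, k_targets = 2)
  expect_equal(nrow(e), 4)
  cell <- paste(e[, 1] <= 6, e[, 2] <= 5)
  expect_equal(sort(table(cell)), sort(table(c(1, 2, 3, 4))), ignore_attr = TRUE)

  ## one cluster each degenerates to a uniform sample
  e1 <- init_diversity(ks$Kd, ks$Kt, budget = 7, seed = 1,
                       k_drugs = 1, k_targets = 1)
  expect_equal(nrow(e1), 7)
  expect_false(any(duplicated(e1)))

  ## representation counts differ by at most one
  for (s in 1:3) {
    e <- init_diversity(ks$Kd, ks$Kt, budget = 11, seed = s,
                        k_drugs = 2, k_targets = 2)
    counts <- table(factor(paste(e[, 1] <= 6, e[, 2] <= 5),
                           levels = unique(paste(rep(c(TRUE, FALSE), each = 2),
                                                 c(TRUE, FALSE)))))
    expect_lte(diff(range(counts)), 1)
  }
  expect_error(init_diversity(ks$Kd, ks$Kt, budget = 3, seed = 1,
                              k_drugs = 2, k_targets = 2), "cluster pairs")
})

test_that("entry batches are the greedy top-K of the pool", {
  X <- matrix(0, 2, 5)
  U <- matrix(c(0.1, 0.2, 0.9, 0.3, 0.5, 0.45, 0.05, 0.6, 0.25, 0.15), 2, 5)
  b1 <- select_batch_entries(U, X, 1, seed = 1)
  expect_equal(U[b1], 0.9)

  b3 <- select_batch_entries(U, X, 3, seed = 1)
  expect_equal(sort(U[b3]), sort(sort(c(U), decreasing = TRUE)[1:3]))  # full-sort oracle

  ## selections always come from the pool
  X2 <- X; X2[1, 2] <- 1   # remove the maximum from the pool
  b <- select_batch_entries(U, X2, 3, seed = 1)
  expect_true(all(X2[b] == 0))
  expect_false(any(duplicated(paste(b[, 1], b[, 2]))))

  ## ties are broken reproducibly
  Ueq <- matrix(1, 2, 5)
  t1 <- select_batch_entries(Ueq, X, 2, seed = 9)
  t2 <- select_batch_entries(Ueq, X, 2, seed = 9)
  expect_identical(t1, t2)
  expect_error(select_batch_entries(U, X, 11, seed = 1), "exceeds pool")
})

test_that("drug batches rank drugs by mean pool uncertainty", {
  set.seed(3)
  X <- matrix(0, 6, 5)
  P <- matrix(stats::runif(30, 0.9, 0.99), 6, 5)
  P[4, ] <- 0.5                       # one fully uncertain drug
  U <- binary_entropy(P)
  expect_equal(select_batch_drugs(U, X, fraction = 1 / 6, seed = 1), 4L)

  ## oracle: explicit mean-entropy ranking
  X2 <- X; X2[2, c(1, 3)] <- 1
  meanU <- sapply(1:6, function(i) mean(U[i, X2[i, ] == 0]))
  got <- select_batch_drugs(U, X2, fraction = 0.5, seed = 1)
  expect_equal(sort(got), sort(order(-meanU)[1:3]))

  expect_equal(sort(select_batch_drugs(U, X, fraction = 1, seed = 1)), 1:6)
  expect_error(select_batch_drugs(U, X, fraction = 0), "positive")
})

test_that("the trace runner reveals truthfully and shrinks the pool batchwise", {
  sc <- quick_scenario(0.5, 0.3, seed = 21, N = 20, M = 20)
  ini <- init_random(20, 20, seed = 21)
  tr <- run_trace(sc$Y, sc$Kd, sc$Kt, "uncertainty", init = ini, batch = 60,
                  R = 6, iterations = 30, tol = 1e-3, seed = 21,
                  stop_fraction = 0.95)
  expect_s3_class(tr, "al_trace")
  expect_equal(tr$n_observed[1], nrow(ini))
  steps <- diff(tr$n_observed)
  expect_true(all(utils::head(steps, -1) == 60))   # full batches, capped last
  expect_true(all(steps >= 1 & steps <= 60))
  expect_true(all(tr$fraction > 0 & tr$fraction <= 1))
  expect_true(all(tr$accuracy >= 0 & tr$accuracy <= 1))
  expect_gte(tr$fraction[nrow(tr)], 0.95)
  ## accuracy at the final round is still scored on the reserve pool
  expect_lte(tr$fraction[nrow(tr)], 1 - floor(0.05 * 400) / 400 + 1e-9)

  ## one selection round when the first batch can swallow the pool
  tr1 <- run_trace(sc$Y, sc$Kd, sc$Kt, "uncertainty", init = ini,
                   batch = 400 - nrow(ini), R = 6, iterations = 20,
                   tol = 1e-3, seed = 21, stop_fraction = 1)
  expect_equal(nrow(tr1), 2)
})

test_that("uncertainty sampling beats random on high-uniqueness systems", {
  ## few duplicated profiles (the regime real drug-target panels resemble):
  ## greedy entropy batches query informative entries and dominate
  gaps <- vapply(1:3, function(s) {
    sc <- simulate_scenario(0.9, 0.3, 0, seed = 800 + s)
    ini <- init_random(50, 50, seed = 800 + s)
    auac(fast_trace(sc$Y, sc$Kd, sc$Kt, "uncertainty", seed = 800 + s, init = ini)) -
      auac(fast_trace(sc$Y, sc$Kd, sc$Kt, "random", seed = 800 + s, init = ini))
  }, numeric(1))
  expect_gt(mean(gaps), 0)
})

test_that("paired strategies share the first time-point, then diverge", {
  sc <- quick_scenario(0.5, 0.3, seed = 22, N = 20, M = 20)
  ini <- init_random(20, 20, seed = 22)
  tu <- run_trace(sc$Y, sc$Kd, sc$Kt, "uncertainty", init = ini, batch = 80,
                  R = 6, iterations = 30, tol = 1e-3, seed = 22,
                  stop_fraction = 0.9)
  tr <- run_trace(sc$Y, sc$Kd, sc$Kt, "random", init = ini, batch = 80,
                  R = 6, iterations = 30, tol = 1e-3, seed = 22,
                  stop_fraction = 0.9)
  expect_equal(tu$accuracy[1], tr$accuracy[1])
  expect_identical(run_trace(sc$Y, sc$Kd, sc$Kt, "random", init = ini,
                             batch = 80, R = 6, iterations = 30, tol = 1e-3,
                             seed = 22, stop_fraction = 0.9)$accuracy,
                   tr$accuracy)   # same seed, same trace
})
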