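test_that("bias-only fits recover closed-form logits", {
  L <- matrix(0, 100, 2)
  M <- cbind(rep(c(1, 0), each = 50),        # present in half -> A = 0
             rep(c(1, 1, 1, 0), 25))          # present in 75% -> A = log 3
  fit <- boltzmann_train(M, L)
  expect_equal(fit$A[1], 0, tolerance = 1e-4)
  expect_equal(fit$A[2], log(3), tolerance = 1e-4)
  # independent 1-D oracle: base-R logistic fit
  oracle <- stats::glm(M[, 2] ~ 1, family = stats::binomial())
  expect_equal(fit$A[2], unname(stats::coef(oracle)), tolerance = 1e-4)
})

test_that("the closed-form normalizer matches brute-force enumeration", {
  set.seed(21)
  for (K in c(3L, 8L, 12L)) {
    J <- 5L
    params <- structure(list(A = stats::rnorm(K),
                             C = matrix(stats::rnorm(K * J), K, J),
                             motif_ids = NULL, feature_names = NULL),
                        class = "boltzmann_params")
    l <- stats::rbinom(J, 1, 0.5)
    grid <- as.matrix(expand.grid(rep(list(0:1), K)))
    ll <- glycan_loglik(params, l, grid)
    theta <- params$A + as.numeric(params$C %*% l)
    brute_F <- log(sum(exp(grid %*% theta)))
    closed_F <- sum(log1p(exp(theta)))
    expect_equal(closed_F, brute_F, tolerance = 1e-9)
    expect_equal(sum(exp(ll)), 1, tolerance = 1e-9)
  }
})

test_that("uniform parameters give the uniform distribution over motif vectors", {
  K <- 6L
  params <- structure(list(A = rep(0, K), C = matrix(0, K, 2),
                           motif_ids = NULL, feature_names = NULL),
                      class = "boltzmann_params")
  grid <- as.matrix(expand.grid(rep(list(0:1), K)))
  ll <- glycan_loglik(params, c(0, 0), grid)
  expect_equal(ll, rep(-K * log(2), nrow(grid)))
})

test_that("posteriors follow the logistic form", {
  params <- structure(list(A = c(0, log(3)), C = matrix(c(2, -1), 2, 1),
                           motif_ids = c("m1", "m2"), feature_names = "f"),
                      class = "boltzmann_params")
  p0 <- motif_posterior(params, 0)
  expect_equal(unname(p0), c(0.5, 0.75))
  p1 <- motif_posterior(params, 1)
  # flipping feature bit j changes the logit by exactly C_ij
  expect_equal(stats::qlogis(p1) - stats::qlogis(p0), unname(params$C[, 1]),
               ignore_attr = TRUE)
  expect_error(motif_posterior(params, c(1, 0)), "schema")
})

test_that("training engines agree on the unique optimum", {
  set.seed(33)
  n <- 200; K <- 6; J <- 8
  L <- matrix(stats::rbinom(n * J, 1, 0.4), n, J)
  P <- stats::plogis(sweep(L %*% t(matrix(stats::rnorm(K * J, 0, 0.4), K, J)),
                           2, stats::rnorm(K), "+"))
  M <- matrix(stats::rbinom(n * K, 1, P), n, K)
  newton <- boltzmann_train(M, L, method = "newton")
  nesterov <- boltzmann_train(M, L, method = "nesterov", max_iter = 20000,
                              gtol = 1e-6)
  gd <- suppressWarnings(boltzmann_train(M, L, method = "gd",
                                         max_iter = 20000, gtol = 1e-6))
  expect_equal(nesterov$loss, newton$loss, tolerance = 1e-6)
  expect_equal(gd$loss, newton$loss, tolerance = 1e-4)
  expect_equal(max(abs(nesterov$A - newton$A)), 0, tolerance = 1e-2)
})

test_that("duplicate motif columns are trained exactly once and expanded", {
  set.seed(8)
  n <- 150; J <- 4
  L <- matrix(stats::rbinom(n * J, 1, 0.5), n, J)
  m <- stats::rbinom(n, 1, 0.5)
  M <- cbind(a = m, b = m, c = stats::rbinom(n, 1, 0.3))
  fit <- boltzmann_train(M, L, method = "newton")
  expect_identical(fit$A[1], fit$A[2])
  expect_identical(fit$C[1, ], fit$C[2, ])
  expect_identical(fit$motif_ids, c("a", "b", "c"))
})

test_that("permuting the catalog order permutes parameters consistently", {
  set.seed(13)
  n <- 120; K <- 5; J <- 6
  L <- matrix(stats::rbinom(n * J, 1, 0.5), n, J)
  M <- matrix(stats::rbinom(n * K, 1, 0.5), n, K)
  colnames(M) <- paste0("m", 1:K)
  perm <- c(3, 1, 5, 2, 4)
  f1 <- boltzmann_train(M, L, method = "newton")
  f2 <- boltzmann_train(M[, perm], L, method = "newton")
  expect_equal(f2$A, f1$A[perm], tolerance = 1e-6)
  # glycan log-likelihoods are invariant to catalog order
  l <- stats::rbinom(J, 1, 0.5)
  m_vec <- stats::rbinom(K, 1, 0.5)
  expect_equal(glycan_loglik(f2, l, m_vec[perm]),
               glycan_loglik(f1, l, m_vec), tolerance = 1e-6)
})

test_that("candidate ranking orders by likelihood with canonical tie-break", {
  corpus <- fixture_corpus()
  catalog <- build_catalog(corpus, max_size = 3, min_count = 2)
  K <- nrow(catalog); J <- 4
  zero <- structure(list(A = rep(0, K), C = matrix(0, K, J),
                         motif_ids = catalog$motif_id, feature_names = NULL),
                    class = "boltzmann_params")
  rk <- rank_candidates(zero, rep(0, J), corpus, catalog)
  # all tied -> canonical string ascending
  expect_identical(rk$structure, sort(corpus$structure))
  expect_true(all(diff(rk$loglik) <= 1e-12))
  expect_equal(nrow(rank_candidates(zero, rep(0, J), corpus, catalog,
                                    top_n = 3)), 3L)
  expect_error(rank_candidates(zero, rep(0, J), corpus[0, ], catalog), "empty")
})

test_that("candidates with identical motif vectors rank adjacently", {
  # two structures that differ only beyond the catalog's motif resolution
  corpus <- glycan_corpus(c(rep("Galb1-4GlcNAc", 6), rep("Galb1-3GlcNAc", 6)))
  catalog <- build_catalog(corpus, max_size = 1, min_count = 2)
  set.seed(2)
  K <- nrow(catalog)
  params <- structure(list(A = stats::rnorm(K), C = matrix(0, K, 2),
                           motif_ids = catalog$motif_id, feature_names = NULL),
                      class = "boltzmann_params")
  pool <- glycan_corpus(c("Galb1-4GlcNAc", "Galb1-3GlcNAc",
                          "Neua2-6Galb1-4GlcNAc"))
  M <- motif_matrix(pool, catalog)
  # size-1 motifs with open slots: the two LacNAc isomers share motif vectors
  expect_identical(M[1, ], M[2, ])
  rk <- rank_candidates(params, c(0, 0), pool, catalog, M = M)
  pos <- match(c("Galb1-3GlcNAc", "Galb1-4GlcNAc"), rk$structure)
  expect_equal(sort(pos), c(min(pos), min(pos) + 1L))
  expect_equal(pos[1], min(pos))   # canonical ascending among ties
})

test_that("recovered posteriors match generating posteriors on synthetic data", {
  set.seed(55)
  n <- 5000; K <- 10; J <- 12
  L <- matrix(stats::rbinom(n * J, 1, 0.3), n, J)
  A0 <- stats::rnorm(K, 0, 0.8)
  C0 <- matrix(stats::rnorm(K * J, 0, 0.5), K, J)
  P0 <- stats::plogis(sweep(L %*% t(C0), 2, A0, "+"))
  M <- matrix(stats::rbinom(n * K, 1, P0), n, K)
  fit <- boltzmann_train(M, L, method = "newton")
  Phat <- stats::plogis(sweep(L %*% t(fit$C), 2, fit$A, "+"))
  expect_lt(mean(abs(Phat - P0)), 0.02)
})

test_that("parameters round-trip through JSON", {
  set.seed(3)
  fit <- boltzmann_train(matrix(stats::rbinom(40, 1, 0.5), 20, 2),
                         matrix(stats::rbinom(60, 1, 0.5), 20, 3),
                         method = "newton")
  path <- withr::local_tempfile(fileext = ".json")
  write_params_json(fit, path, meta = list(seed = 3))
  back <- read_params_json(path)
  expect_equal(back$A, fit$A, tolerance = 1e-12)
  expect_equal(unname(back$C), unname(fit$C), tolerance = 1e-12)
})
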