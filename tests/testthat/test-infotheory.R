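test_that("entropy matches hand computations", {
  expect_equal(shannon_entropy(c(0, 1, 0, 1)), 1)
  expect_equal(shannon_entropy(rep(1, 7)), 0)
  expect_equal(shannon_entropy(c(1, 1, 1, 0)),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)))
})

test_that("mutual information matches the plug-in formula", {
  expect_equal(mutual_information(c(0, 1, 0, 1), c(0, 1, 0, 1)), 1)
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  # counts table [[4,1],[1,4]]
  x <- rep(c(0, 0, 1, 1), c(4, 1, 1, 4))
  y <- rep(c(0, 1, 0, 1), c(4, 1, 1, 4))
  H <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  expect_equal(mutual_information(x, y),
               2 * H(c(0.5, 0.5)) - H(c(0.4, 0.1, 0.1, 0.4)),
               tolerance = 1e-12)
  expect_error(mutual_information(c(0, 1), c(0, 1, 1)), "length")
})

test_that("MI respects its entropy bounds on random binary data", {
  set.seed(17)
  for (rep in 1:50) {
    n <- sample(5:40, 1)
    x <- stats::rbinom(n, 1, stats::runif(1))
    y <- stats::rbinom(n, 1, stats::runif(1))
    mi <- mutual_information(x, y)
    expect_gte(mi, 0)
    expect_lte(mi, min(shannon_entropy(x), shannon_entropy(y)) + 1e-12)
  }
})

test_that("joint variables are supported (matrix second argument)", {
  set.seed(4)
  m1 <- stats::rbinom(100, 1, 0.5); m2 <- stats::rbinom(100, 1, 0.5)
  lec <- as.integer(xor(m1, m2))
  expect_lt(mutual_information(lec, m1), 0.1)
  expect_equal(mutual_information(lec, cbind(m1, m2)), shannon_entropy(lec),
               tolerance = 1e-12)
})

test_that("mi_table identifies a deterministic planted lectin", {
  corpus <- fixture_corpus(3)
  catalog <- build_catalog(corpus, max_size = 3, min_count = 3)
  M <- motif_matrix(corpus, catalog)
  target <- which.max(apply(M, 2, shannon_entropy))
  rfu <- ifelse(M[, target] == 1, 15000, 100)
  tab <- tibble::tibble(glycan_id = corpus$glycan_id, spacer_id = "Sp0",
                        `LX@c1` = rfu)
  fm <- binarize(tab)
  mt <- mi_table(fm, M, min_bits = 0.3)
  expect_equal(mt$report$motif_id[1], colnames(M)[target])
  expect_equal(mt$report$mi_bits[1], shannon_entropy(M[, target]),
               tolerance = 1e-12)
  # filter and ordering contracts
  expect_true(all(mt$report$mi_bits >= 0.3))
  expect_true(all(diff(mt$raw$mi_bits) <= 1e-12))
})

test_that("an independent random lectin reports no information", {
  set.seed(23)
  n <- 500
  motifs <- matrix(stats::rbinom(n * 6, 1, 0.4), n, 6,
                   dimnames = list(sprintf("g%03d", 1:n), paste0("M", 1:6)))
  tab <- tibble::tibble(glycan_id = rownames(motifs), spacer_id = "Sp0",
                        `RND@c1` = exp(stats::runif(n, log(200), log(30000))))
  mt <- mi_table(binarize(tab), motifs, min_bits = 0.3)
  expect_equal(nrow(mt$report), 0L)
  expect_true(all(mt$raw$mi_bits < 0.3))
})

test_that("primary information fraction is exact in constructed cases", {
  set.seed(6)
  m1 <- stats::rbinom(300, 1, 0.5)
  others <- matrix(stats::rbinom(300 * 3, 1, 0.5), 300, 3)
  M <- cbind(p = m1, others)
  colnames(M) <- c("p", "q", "r", "s")
  # lectin identical to one motif, others independent -> fraction 1
  pif <- primary_information_fraction(m1, M)
  expect_identical(pif$primary, "p")
  expect_equal(pif$fraction, 1)
  # lectin = OR of two independent motifs: exact 8-outcome construction
  reps <- 40L
  grid <- expand.grid(a = 0:1, b = 0:1, c = 0:1)
  a <- rep(grid$a, reps); b <- rep(grid$b, reps); cc <- rep(grid$c, reps)
  lec <- as.integer(a | b)
  M2 <- cbind(a = a, b = b, c = cc)
  pif2 <- primary_information_fraction(lec, M2)
  expect_lt(pif2$fraction, 1)
  expect_gt(pif2$fraction, 0)
  expect_setequal(pif2$selected[1:2], c("a", "b"))
  # exact joint MI: the pair (a,b) determines the OR completely
  expect_equal(pif2$mi_total, shannon_entropy(lec), tolerance = 1e-12)
  # degenerate lectin -> undefined fraction
  expect_true(is.na(primary_information_fraction(rep(0, 300), M)$fraction))
})

test_that("order comparison saturates for a perfectly bound motif", {
  set.seed(9)
  l1 <- stats::rbinom(200, 1, 0.5); l2 <- stats::rbinom(200, 1, 0.5)
  oc <- order_comparison(l1, l1, l2)
  expect_equal(oc$dH1, oc$H, tolerance = 1e-6)
  expect_equal(oc$dH2, oc$H, tolerance = 1e-9)
})

test_that("only the interaction term can express XOR", {
  grid <- expand.grid(l1 = 0:1, l2 = 0:1)
  l1 <- rep(grid$l1, 25); l2 <- rep(grid$l2, 25)
  m <- as.integer(xor(l1, l2))
  oc <- order_comparison(m, l1, l2)
  expect_equal(oc$dH1, 0, tolerance = 1e-9)
  expect_equal(oc$dH2, oc$H, tolerance = 1e-12)
  expect_equal(oc$H, 1)
})

test_that("losses are nested and the saturated fit reproduces cell frequencies", {
  set.seed(31)
  for (rep in 1:20) {
    n <- 120
    l1 <- stats::rbinom(n, 1, stats::runif(1, 0.2, 0.8))
    l2 <- stats::rbinom(n, 1, stats::runif(1, 0.2, 0.8))
    m <- stats::rbinom(n, 1, stats::plogis(-0.5 + l1 + 0.5 * l2))
    oc <- order_comparison(m, l1, l2)
    expect_lte(oc$J1, oc$J0 + 1e-9)
    expect_lte(oc$J2, oc$J1 + 1e-9)
    expect_gte(oc$dH2, oc$dH1 - 1e-9)
    # saturated predictions equal empirical cell frequencies
    cells <- paste0(l1, l2)
    for (cl in unique(cells)) {
      expect_equal(unname(oc$p2_cells[cl]), mean(m[cells == cl]),
                   tolerance = 1e-6)
    }
  }
})

test_that("degenerate inputs yield zero information for all orders", {
  oc <- order_comparison(rep(1, 50), stats::rbinom(50, 1, 0.5),
                         stats::rbinom(50, 1, 0.5))
  expect_equal(oc$dH1, 0)
  expect_equal(oc$dH2, 0)
  oc2 <- order_comparison(stats::rbinom(50, 1, 0.5), rep(0, 50), rep(1, 50))
  expect_equal(oc2$dH2, 0)
})

test_that("order comparison can pick the two most predictive features", {
  set.seed(12)
  n <- 300
  m <- stats::rbinom(n, 1, 0.5)
  feats <- cbind(f_good = ifelse(stats::runif(n) < 0.9, m, 1 - m),
                 f_noise1 = stats::rbinom(n, 1, 0.5),
                 f_ok = ifelse(stats::runif(n) < 0.7, m, 1 - m),
                 f_noise2 = stats::rbinom(n, 1, 0.5))
  oc <- order_comparison(m, features = feats)
  expect_gt(oc$dH1, 0.2)
})
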