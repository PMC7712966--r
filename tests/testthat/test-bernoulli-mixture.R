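test_that("sufficient statistics count frames and contacts per category", {
  x <- matrix(c(1, 1, 0), ncol = 1)
  ss <- suff_stats(x, c(1, 1, 2), 2L)
  expect_equal(ss$Nk, c(2, 1))
  expect_equal(unname(ss$Nkj), rbind(2, 0))

  x2 <- matrix(rbinom(12, 1, 0.5), 4, 3)
  ss2 <- suff_stats(x2, rep(1, 4), 1L)
  expect_equal(ss2$Nk, 4)
  expect_equal(as.vector(ss2$Nkj), colSums(x2))

  ss3 <- suff_stats(x2, c(1, 1, 2, 2), 3L)   # category 3 empty is legal
  expect_equal(ss3$Nk[3], 0)
  expect_true(all(ss3$Nkj[3, ] == 0))
  expect_error(suff_stats(x2, c(1, 4, 1, 1), 3L), "out of range")
})

test_that("log_joint matches brute-force products and handles boundaries", {
  th <- model_params(c(1), matrix(0.5, 1, 1), alpha = 2)
  expect_equal(log_joint(matrix(1, 1, 1), 1L, th), log(0.5))

  x <- matrix(c(1, 1, 0, 1), 2, 2)
  th2 <- model_params(c(1), matrix(0.5, 1, 2), alpha = 3)
  expect_equal(log_joint(x, c(1L, 1L), th2), 4 * log(0.5))
  # brute force over entries for random theta
  set.seed(2)
  mu <- matrix(runif(2), 1, 2)
  th3 <- model_params(c(1), mu, alpha = 3)
  brute <- sum(log(ifelse(x == 1, mu[rep(1, 2), ], 1 - mu[rep(1, 2), ])))
  expect_equal(log_joint(x, c(1L, 1L), th3), brute)

  th0 <- model_params(c(1), matrix(0, 1, 1), alpha = 2)
  expect_equal(log_joint(matrix(1, 1, 1), 1L, th0), -Inf)
  expect_equal(log_joint(matrix(0, 1, 1), 1L, th0), 0)  # 0 log 0 = 0
})

test_that("responsibilities are normalized posteriors including pi", {
  th <- model_params(c(0.5, 0.5), rbind(c(0.9), c(0.1)))
  expect_equal(responsibilities(c(1), th), c(0.9, 0.1))
  # symmetric prototypes -> uniform for any datum
  ths <- model_params(c(0.5, 0.5), rbind(c(0.3, 0.7), c(0.3, 0.7)))
  expect_equal(responsibilities(c(1, 0), ths), c(0.5, 0.5))
  expect_equal(responsibilities(c(1), model_params(c(1), matrix(0.4, 1, 1))),
               1.0)
  # pi weighting can be dropped
  thw <- model_params(c(0.99, 0.01), rbind(c(0.9), c(0.9)))
  expect_equal(responsibilities(c(1), thw, use_pi = FALSE), c(0.5, 0.5))

  # agreement with direct evaluation on random instances, rows sum to 1
  set.seed(31)
  for (r in 1:20) {
    K <- sample(2:3, 1); M <- sample(1:3, 1)
    pi <- as.vector(stats::rgamma(K, 1)); pi <- pi / sum(pi)
    mu <- matrix(runif(K * M), K, M)
    th <- model_params(pi, mu)
    xi <- rbinom(M, 1, 0.5)
    direct <- pi * apply(mu^rep(xi, each = K) *
                           (1 - mu)^rep(1 - xi, each = K), 1, prod)
    expect_equal(responsibilities(xi, th), direct / sum(direct),
                 tolerance = 1e-12)
    expect_equal(sum(responsibilities(xi, th)), 1, tolerance = 1e-12)
  }
  expect_error(responsibilities(c(1), model_params(c(0.5, 0.5),
                                                   rbind(0, 0))),
               "impossible")
})

test_that("Bhattacharyya similarity matches exhaustive enumeration", {
  expect_equal(bhattacharyya(c(1), c(0)), 0)
  expect_equal(bhattacharyya(c(1), c(0.5)), sqrt(0.5))
  set.seed(5)
  for (r in 1:10) {
    M <- sample(1:6, 1)
    p <- runif(M); q <- runif(M)
    expect_equal(bhattacharyya(p, p), 1)
    expect_equal(bhattacharyya(p, q), bhattacharyya(q, p))
    b <- bhattacharyya(p, q)
    expect_true(b >= 0 && b <= 1)
    # oracle: sum over all 2^M bit vectors of sqrt(P(b) Q(b))
    bits <- as.matrix(expand.grid(rep(list(0:1), M)))
    pb <- apply(bits, 1, function(s) prod(p^s * (1 - p)^(1 - s)))
    qb <- apply(bits, 1, function(s) prod(q^s * (1 - q)^(1 - s)))
    expect_equal(b, sum(sqrt(pb * qb)), tolerance = 1e-12)
  }
})

test_that("log_prior combines Dirichlet and uniqueness terms", {
  expect_equal(log_prior(model_params(c(1), matrix(0.3, 1, 2), alpha = 3)), 0)
  expect_equal(log_prior(model_params(c(0.5, 0.5),
                                      rbind(c(0.4, 0.6), c(0.4, 0.6)))),
               -Inf)   # duplicate categories are forbidden
  expect_equal(log_prior(model_params(c(0.5, 0.5), rbind(1, 0), alpha = 2)),
               log(1.5))
})

test_that("conjugate draws have the right moments, shapes and determinism", {
  x <- matrix(rep(1, 10), ncol = 1)
  set.seed(9)
  draws <- replicate(10000, sample_theta_given_z(x, rep(1L, 10), 1L)$mu[1, 1])
  expect_equal(mean(draws), 11 / 12, tolerance = 0.005)  # Beta(11, 1) mean

  x2 <- matrix(rbinom(40, 1, 0.5), 10, 4)
  th <- sample_theta_given_z(x2, rep(1:2, 5), 2L)
  expect_equal(length(th$pi), 2L)
  expect_equal(dim(th$mu), c(2L, 4L))
  expect_equal(th$alpha, 5)                      # M + 1 default
  set.seed(77); a <- sample_theta_given_z(x2, rep(1:2, 5), 2L)
  set.seed(77); b <- sample_theta_given_z(x2, rep(1:2, 5), 2L)
  expect_identical(a, b)
})

test_that("collapsed marginal matches analytic and Monte-Carlo integrals", {
  expect_equal(log_marginal(matrix(1, 1, 1), 1L, 1L, alpha = 2), log(1 / 2))
  expect_equal(log_marginal(matrix(c(1, 0), 2, 1), c(1L, 1L), 1L, alpha = 2),
               log(1 / 6))
  # invariant under sample reordering
  x <- matrix(c(1, 0, 1, 1, 0, 0), 3, 2)
  z <- c(1L, 2L, 1L)
  perm <- c(3L, 1L, 2L)
  expect_equal(log_marginal(x, z, 2L), log_marginal(x[perm, ], z[perm], 2L))

  # Monte-Carlo oracle: average P(x, z | theta) over theta ~ P(theta | U)
  set.seed(123)
  xm <- matrix(c(1, 0, 1), 3, 1)
  zm <- c(1L, 2L, 1L)
  alpha <- 2
  n <- 200000
  g1 <- stats::rgamma(n, alpha); g2 <- stats::rgamma(n, alpha)
  pi1 <- g1 / (g1 + g2)
  mu1 <- runif(n); mu2 <- runif(n)
  vals <- pi1^2 * (1 - pi1) * mu1^2 * (1 - mu2)
  mc <- mean(vals)
  se <- stats::sd(vals) / sqrt(n)
  expect_lt(abs(exp(log_marginal(xm, zm, 2L, alpha)) - mc), 4 * se)
})

test_that("summing exp(log_joint) over assignments recovers the mixture likelihood", {
  set.seed(44)
  for (r in 1:5) {
    N <- sample(2:4, 1); M <- sample(1:3, 1); K <- sample(2:3, 1)
    x <- matrix(rbinom(N * M, 1, 0.5), N, M)
    pi <- as.vector(stats::rgamma(K, 1)); pi <- pi / sum(pi)
    th <- model_params(pi, matrix(runif(K * M), K, M))
    zz <- as.matrix(expand.grid(rep(list(1:K), N)))
    total <- sum(apply(zz, 1, function(z) exp(log_joint(x, z, th))))
    lik <- prod(vapply(seq_len(N), function(i)
      sum(pi * apply(th$mu^rep(x[i, ], each = K) *
                       (1 - th$mu)^rep(1 - x[i, ], each = K), 1, prod)),
      numeric(1)))
    expect_equal(total, lik, tolerance = 1e-10)
  }
})

test_that("prototype export round-trips through CSV", {
  fm <- block_fm(3L)
  th <- model_params(c(0.25, 0.75), rbind(c(0.9, 0.8, 0.1), c(0.1, 0.2, 0.9)))
  path <- tempfile(fileext = ".csv")
  export_prototypes(th, fm, path)
  df <- read.csv(path, check.names = FALSE)
  expect_equal(nrow(df), 2L)
  expect_equal(df$pi, th$pi)
  expect_equal(unname(as.matrix(df[, -(1:2)])), unname(th$mu))
  expect_equal(names(df)[3], sprintf("%d:%d", fm$pairs[1, 1] - 1L,
                                     fm$pairs[1, 2] - 1L))
})
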