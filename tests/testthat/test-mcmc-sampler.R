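test_that("chains are reproducible and ensembles pool them unchanged", {
  fm <- block_fm(10L)
  cfg <- sampler_config(n_steps = 60, n_chains = 3, burn_in = 20, thin = 5,
                        seed = 13)
  a <- run_chain(fm, cfg, chain_id = 2L)
  b <- run_chain(fm, cfg, chain_id = 2L)
  expect_identical(a, b)
  ens <- run_ensemble(fm, cfg)
  singles <- lapply(1:3, function(i) run_chain(fm, cfg, i))
  expect_identical(ens$samples, do.call(c, lapply(singles, `[[`, "samples")))
  # retention rule: steps >= burn_in, divisible by thin (0-based)
  expect_equal(vapply(a$samples, `[[`, numeric(1), "step"),
               c(20, 25, 30, 35, 40, 45, 50, 55))
})

test_that("recategorize is an exact Gibbs draw from the responsibilities", {
  fm <- toy_fm()
  # K = 1: nothing can change
  st1 <- chain_state(fm, rep(1L, 3))
  expect_identical(recategorize(st1, fm)$z, rep(1L, 3))

  # degenerate prototypes force deterministic labels
  thd <- model_params(c(0.5, 0.5), rbind(c(1 - 1e-12, 1 - 1e-12),
                                         c(1e-12, 1e-12)))
  std <- chain_state(fm, c(1L, 1L, 2L), theta = thd)
  set.seed(8)
  zz <- recategorize(std, fm)$z
  expect_equal(zz[3], 1L)   # row (1,1) must go to the all-ones category
  expect_equal(zz[1], 2L)   # row (0,0) to the all-zeros category

  # empirical label frequencies match the responsibilities
  th <- model_params(c(0.6, 0.4), rbind(c(0.8, 0.3), c(0.2, 0.9)))
  st <- chain_state(fm, c(1L, 1L, 2L), theta = th)
  want <- responsibilities(fm, th)
  set.seed(99)
  n <- 4000
  counts <- matrix(0, 3, 2)
  for (r in seq_len(n)) {
    z <- recategorize(st, fm)$z
    counts[cbind(1:3, z)] <- counts[cbind(1:3, z)] + 1
  }
  expect_true(all(abs(counts / n - want) < 0.035))
  expect_equal(recategorize(st, fm)$K, st$K)   # K never changes
})

test_that("reclassify accepts at the uniqueness-prior rate", {
  set.seed(21)
  x <- matrix(rbinom(20, 1, 0.5), 10, 2)
  fm <- fm_from_x(x)
  z <- rep(1:2, 5)
  st <- chain_state(fm, z)
  # independent Monte-Carlo oracle for E[ prod (1 - B) ] under P(theta|z,x,U)
  w <- mc_uniqueness_weight(fm, z, 2L, n_draw = 20000L)[["mean"]]
  n <- 3000
  acc <- 0
  for (r in seq_len(n)) {
    st2 <- reclassify(st, fm)
    if (attr(st2, "accepted")) acc <- acc + 1
  }
  se <- sqrt(w * (1 - w) / n)
  expect_lt(abs(acc / n - w), 4 * se + 0.01)

  st1 <- chain_state(fm, rep(1L, 10))
  st1b <- reclassify(st1, fm)
  expect_true(attr(st1b, "accepted"))   # K = 1: empty product, always accepted
})

test_that("split proposals follow the eta-biased partition law", {
  # two members, x_j = (1, 0), eta = 0.9: ordered partition L={1}, R={2}
  # has probability 0.9*0.9 / (1 - 0.9*0.1 - 0.1*0.9) = 0.81/0.82
  lp <- contactmix:::split_pair_logprob(c(1, 0), c(TRUE, FALSE), 0.9)
  expect_equal(exp(lp), 0.81)
  p_ordered <- exp(lp) / (1 - 0.9 * 0.1 - 0.1 * 0.9)
  expect_equal(p_ordered, 0.81 / 0.82)

  fm <- fm_from_x(matrix(c(1, 0), 2, 1))
  st <- chain_state(fm, c(1L, 1L))
  set.seed(3)
  n <- 2000
  hit <- 0
  for (r in seq_len(n)) {
    pr <- propose_split(st, fm, eta = 0.9)
    if (identical(pr$z_new, c(1L, 2L))) hit <- hit + 1
  }
  expect_lt(abs(hit / n - 0.81 / 0.82), 0.03)
  expect_equal(pr$K_new, 2L)

  # categories with no informative feature are never split
  fmc <- fm_from_x(matrix(c(1, 1, 0, 0), 2, 2))   # identical rows
  stc <- chain_state(fmc, c(1L, 1L))
  expect_null(propose_split(stc, fmc))
  # singletons are unsplittable too
  sts <- chain_state(fm, c(1L, 2L))
  expect_null(propose_split(sts, fm))
})

test_that("join proposals merge a uniform pair and keep labels contiguous", {
  fm <- block_fm(6L)
  z <- rep(1:3, each = 4)
  st <- chain_state(fm, z)
  expect_null(propose_join(chain_state(fm, rep(1L, 12)), fm))
  set.seed(14)
  pr <- propose_join(st, fm)
  expect_equal(pr$K_new, 2L)
  expect_equal(exp(pr$log_gen_prob), 1 / 3)   # 3 unordered pairs at K = 3
  expect_setequal(unique(pr$z_new), 1:2)      # contiguous after renumbering

  st2 <- chain_state(fm, rep(1:2, each = 6))
  pr2 <- propose_join(st2, fm)
  expect_equal(exp(pr2$log_gen_prob), 1)      # only one pair at K = 2
  expect_equal(pr2$z_new, rep(1L, 12))
})

test_that("a split separating two well-separated blocks is always accepted", {
  fm <- block_fm(25L, m = 6L)
  N <- nrow(fm$x)
  z1 <- rep(1L, N)
  zb <- rep(1:2, each = N / 2)
  d_m <- log_marginal(fm, zb, 2L) - log_marginal(fm, z1, 1L)
  # generation probabilities for this specific partition
  toL <- rep(c(TRUE, FALSE), each = N / 2)
  a <- colSums(fm$x[toL, , drop = FALSE])
  c1 <- colSums(fm$x[!toL, , drop = FALSE])
  lg_split <- contactmix:::split_partition_loggen(
    a, c1, N / 2, N / 2, 0.9)   # single splittable category
  lg_join <- log(2) - log(2 * 1)
  expect_gt(d_m + lg_join - lg_split, 0)   # Metropolis ratio > 1

  # and the sampler finds the block structure almost immediately
  cfg <- sampler_config(n_steps = 40, n_chains = 1, burn_in = 20, thin = 2,
                        seed = 5)
  res <- run_chain(fm, cfg)
  ks <- vapply(res$samples, function(s) length(unique(s$z)), integer(1))
  expect_true(all(ks >= 2))
  s <- res$samples[[length(res$samples)]]
  expect_equal(length(unique(s$z[1:(N / 2)])), 1L)
  expect_equal(length(unique(s$z[(N / 2 + 1):N])), 1L)
})

test_that("every move keeps the cached log posterior consistent", {
  set.seed(17)
  fm <- block_fm(8L, m = 4L)
  st <- chain_state(fm, rep(1L, 16))
  cfg <- sampler_config(n_steps = 10, burn_in = 5, thin = 1, seed = 2)
  recheck <- function(s)
    expect_equal(s$log_post, log_joint(fm, s$z, s$theta) + log_prior(s$theta),
                 tolerance = 1e-8)
  for (r in 1:15) {
    st <- recategorize(st, fm); recheck(st)
    st <- reclassify(st, fm); recheck(st)
    st <- split_join_step(st, fm, cfg); recheck(st)
  }
  expect_true(st$K >= 1L && st$K <= nrow(fm$x))
})

test_that("retained samples respect K bounds and category uniqueness", {
  fm <- toy_fm()
  cfg <- sampler_config(n_steps = 300, n_chains = 2, burn_in = 50, thin = 2,
                        seed = 23)
  res <- run_ensemble(fm, cfg)
  for (d in res$diagnostics) {
    expect_true(all(d$K_trace >= 1L & d$K_trace <= nrow(fm$x)))
  }
  for (s in res$samples) {
    K <- s$theta$K
    expect_true(K >= 1L && K <= nrow(fm$x))
    if (K >= 2L)
      for (k in 1:(K - 1L)) for (l in (k + 1L):K)
        expect_lt(bhattacharyya(s$theta$mu[k, ], s$theta$mu[l, ]), 1)
  }
})
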