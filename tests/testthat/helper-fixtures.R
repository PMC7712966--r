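## Small fixtures built in code; all randomness is locally seeded.

## feature matrix straight from a 0/1 matrix, with synthetic pair labels
fm_from_x <- function(x, cutoff = 2, pruned = TRUE) {
  M <- ncol(x)
  u <- rep.int(seq_len(M), 1L)
  feature_matrix(x, cbind(u, u + M), cutoff, pruned = pruned,
                 orig_index = seq_len(M))
}

## two well-separated feature blocks: 1110... then 0001...
block_fm <- function(n_per = 25L, m = 3L) {
  a <- c(rep(1, ceiling(m / 2)), rep(0, floor(m / 2)))
  x <- rbind(matrix(rep(a, n_per), ncol = m, byrow = TRUE),
             matrix(rep(1 - a, n_per), ncol = m, byrow = TRUE))
  fm_from_x(x)
}

## tiny instance used for exhaustive-enumeration checks
toy_fm <- function() fm_from_x(matrix(c(0, 0, 1,
                                        0, 1, 1), ncol = 2L))

## random small trajectory
rand_traj <- function(N = 3L, P = 4L, d = 2L, seed = 42L) {
  set.seed(seed)
  trajectory(array(stats::rnorm(N * P * d, sd = 2), c(N, P, d)))
}

## all set partitions of 1..n as canonical label vectors (first-appearance
## order), via restricted growth strings
set_partitions <- function(n) {
  out <- list()
  grow <- function(z, mx) {
    if (length(z) == n) {
      out[[length(out) + 1L]] <<- z
      return(invisible())
    }
    for (v in seq_len(mx + 1L)) grow(c(z, v), max(mx, v))
  }
  grow(1L, 1L)
  out
}

## canonical partition signature of a label vector
partition_sig <- function(z) {
  paste(as.integer(factor(z, levels = unique(z))), collapse = "")
}

## Monte-Carlo estimate (with standard error) of E[prod_{k<l}(1 - B_kl)]
## under theta ~ P(theta | z, x, U); vectorized over draws
mc_uniqueness_weight <- function(fm, z, K, n_draw = 20000L) {
  ss <- suff_stats(fm, z, K)
  M <- ncol(fm$x)
  mus <- lapply(seq_len(K), function(k)
    matrix(stats::rbeta(n_draw * M, rep(ss$Nkj[k, ] + 1, each = n_draw),
                        rep(ss$Nk[k] - ss$Nkj[k, ] + 1, each = n_draw)),
           n_draw, M))
  w <- rep(1, n_draw)
  if (K >= 2L)
    for (k in 1:(K - 1L)) for (l in (k + 1L):K) {
      b <- rep(1, n_draw)
      for (j in seq_len(M))
        b <- b * (sqrt(mus[[k]][, j] * mus[[l]][, j]) +
                    sqrt((1 - mus[[k]][, j]) * (1 - mus[[l]][, j])))
      w <- w * (1 - b)
    }
  c(mean = mean(w), se = stats::sd(w) / sqrt(n_draw))
}

## exhaustive collapsed posterior over set partitions (summing nominal K
## from the block count up to N), including the uniqueness prior weight;
## returns probabilities and their Monte-Carlo standard errors
enumerate_partition_posterior <- function(fm, alpha = ncol(fm$x) + 1,
                                          n_draw = 20000L) {
  N <- nrow(fm$x)
  parts <- set_partitions(N)
  sig <- vapply(parts, partition_sig, "")
  a <- va <- numeric(length(parts))
  for (i in seq_along(parts)) {
    z <- parts[[i]]
    B <- max(z)
    for (K in B:N) {
      m <- exp(log_marginal(fm, z, K, alpha))
      u <- mc_uniqueness_weight(fm, z, K, n_draw)
      a[i] <- a[i] + m * u[["mean"]]
      va[i] <- va[i] + (m * u[["se"]])^2
    }
  }
  S <- sum(a)
  p <- a / S
  ## delta method for p_c = a_c / sum(a) with independent MC errors
  pse <- vapply(seq_along(a), function(cc) {
    g <- -a[cc] / S^2 + ifelse(seq_along(a) == cc, 1 / S, 0)
    sqrt(sum(g^2 * va))
  }, numeric(1))
  list(p = stats::setNames(p, sig), se = stats::setNames(pse, sig))
}

## minimal multi-MODEL PDB writer for C-alpha fixtures
write_test_pdb <- function(path, frames, atom = "CA") {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(frames)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- frames[[m]]
    for (i in seq_len(nrow(xyz)))
      writeLines(sprintf("ATOM  %5d  %-3s ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
                         i, atom, i, xyz[i, 1], xyz[i, 2], xyz[i, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
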