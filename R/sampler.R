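## Markov chain Monte Carlo over (K, pi, mu, z) with four move types:
##
##   * recategorization -- every frame label redrawn from its
##     responsibilities (an exact Gibbs step at fixed theta);
##   * reclassification -- theta proposed from the conjugate conditional
##     P(theta | z, x, U) and accepted with probability prod_{k<l}(1 - B_kl),
##     which leaves P(theta | z, x, I) invariant;
##   * category split -- one category divided in two by eta-biased coin
##     flips on a single informative feature;
##   * category join -- two categories merged into one.
##
## Split and join are accepted by a Metropolis ratio of collapsed marginal
## likelihoods P(x, z | U) (pi and mu integrated out analytically) times the
## ratio of generation probabilities, and each dimension change carries a
## fresh conjugate draw of theta whose uniqueness factor enters the same
## acceptance decision.  With the generation probabilities below this leaves
## the joint distribution P(theta, z | x, I) invariant; the implied marginal
## over labelled assignments is proportional to
## exp(log_marginal) * E[prod(1 - B_kl) | z, U].

logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## deterministic 32-bit sub-seed for chain `chain_id` of run `seed`
derive_seed <- function(seed, chain_id) {
  ((seed %% 2147483647) * 48271 + chain_id * 1234567) %% 2147483647
}

#' Sampler protocol configuration
#'
#' Defaults follow the package's standard protocol: 5 independent chains of
#' 1000 steps each, samples retained every 10 steps from step 500 on (so 50
#' retained draws per chain), split bias `eta = 0.9`, and Dirichlet
#' concentration `alpha = M + 1` recomputed from the pruned feature count.
#'
#' @param n_steps steps per chain; one step = recategorize + reclassify +
#'   one split-or-join attempt.
#' @param n_chains number of independent chains.
#' @param burn_in first retained step (0-based).
#' @param thin retain every `thin`-th step at or after `burn_in`.
#' @param eta split-move bias in `(0.5, 1)`: a member with the chosen
#'   feature present moves to the new left set with probability `eta`.
#' @param split_join_prob probability that a dimension attempt is a split
#'   rather than a join.
#' @param seed integer seed; chain `i` uses a sub-seed derived from
#'   `(seed, i)`, so chains are reproducible regardless of scheduling.
#' @param alpha_override optional fixed Dirichlet concentration replacing
#'   the `M + 1` default.
#' @return an object of class `"sampler_config"`.
#' @export
sampler_config <- function(n_steps = 1000L, n_chains = 5L, burn_in = 500L,
                           thin = 10L, eta = 0.9, split_join_prob = 0.5,
                           seed = 1L, alpha_override = NULL) {
  if (burn_in >= n_steps) stop("'burn_in' must be smaller than 'n_steps'")
  if (thin < 1L) stop("'thin' must be at least 1")
  if (eta <= 0.5 || eta >= 1) stop("'eta' must lie in (0.5, 1)")
  if (split_join_prob < 0 || split_join_prob > 1)
    stop("'split_join_prob' must lie in [0, 1]")
  structure(list(n_steps = as.integer(n_steps),
                 n_chains = as.integer(n_chains),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 eta = eta, split_join_prob = split_join_prob,
                 seed = as.integer(seed), alpha_override = alpha_override),
            class = "sampler_config")
}

## immutable per-run context: double-precision data and lookup tables
make_ctx <- function(fm, alpha = NULL) {
  x <- as_x(fm)
  xd <- x + 0
  N <- nrow(xd); M <- ncol(xd)
  list(xd = xd, N = N, M = M,
       alpha = alpha %||% (M + 1),
       lf = logfact_table(N + 1))       # lf[n + 1] = log n!
}

## lgamma(K a) - lgamma(N + K a): the K-dependent Dirichlet factor
dir_dim_term <- function(K, ctx) {
  lgamma(K * ctx$alpha) - lgamma(ctx$N + K * ctx$alpha)
}

## sufficient statistics via an indicator cross-product (BLAS)
fast_stats <- function(xd, z, K) {
  N <- nrow(xd)
  Z <- matrix(0, N, K)
  Z[cbind(seq_len(N), z)] <- 1
  list(Nk = .colSums(Z, N, K), Nkj = crossprod(Z, xd))
}

## Dirichlet prior density term of the current theta
log_pi_prior <- function(th) {
  lgamma(th$K * th$alpha) - th$K * lgamma(th$alpha) +
    sum(xlogy(rep(th$alpha - 1, th$K), th$pi))
}

## complete-data log likelihood from cached counts (mu kept off boundaries)
stats_log_lik <- function(th, Nk, Nkj) {
  sum(xlogy(Nk, th$pi)) + sum(Nkj * log(th$mu)) +
    sum((Nk - Nkj) * log1p(-th$mu))
}

state_log_post <- function(state, ctx) {
  lu <- state$log_uniq %||% log_uniqueness(state$theta$mu)
  stats_log_lik(state$theta, state$Nk, state$Nkj) +
    log_pi_prior(state$theta) + lu
}

#' Construct a chain state
#'
#' Bundles the current parameters, assignment, cached sufficient statistics
#' and cached log posterior.  Mostly useful for driving the individual move
#' functions directly; [run_chain()] manages states internally.
#'
#' @param fm a pruned [feature_matrix()].
#' @param z integer assignment vector.
#' @param theta a [model_params()]; if `NULL`, drawn from the conjugate
#'   conditional given `z`.
#' @param K number of categories; defaults to `theta$K` or `max(z)`.
#' @param step step counter carried along by the sampler.
#' @return an object of class `"chain_state"` with fields `theta`, `z`,
#'   `K`, `Nk`, `Nkj`, `log_post`, `step`.
#' @export
chain_state <- function(fm, z, theta = NULL, K = NULL, step = 0L) {
  ctx <- make_ctx(fm)
  K <- K %||% (if (!is.null(theta)) theta$K else max(z))
  if (is.null(theta)) theta <- sample_theta_given_z(fm, z, K, ctx$alpha)
  ss <- fast_stats(ctx$xd, as.integer(z), K)
  st <- list(theta = theta, z = as.integer(z), K = K,
             Nk = ss$Nk, Nkj = ss$Nkj, step = as.integer(step),
             log_uniq = log_uniqueness(theta$mu))
  st$log_post <- state_log_post(st, ctx)
  class(st) <- "chain_state"
  st
}

#' @export
print.chain_state <- function(x, ...) {
  cat(sprintf("<chain_state> step %d: K = %d (%d occupied), log_post = %.3f\n",
              x$step, x$K, sum(x$Nk > 0), x$log_post))
  invisible(x)
}

## ---- moves ---------------------------------------------------------------

recategorize_impl <- function(state, ctx) {
  K <- state$K
  if (K > 1L) {
    lr <- log_resp_matrix(ctx$xd, state$theta)
    g <- matrix(-log(-log(stats::runif(ctx$N * K))), ctx$N, K)
    z <- max.col(lr + g, ties.method = "first")   # Gumbel-max categorical
    picked <- lr[cbind(seq_len(ctx$N), z)]
    if (any(!is.finite(picked)))
      stop("datum impossible under every category")
    chg <- which(z != state$z)
    if (length(chg) > ctx$N %/% 8L) {
      ss <- fast_stats(ctx$xd, z, K)
      state$Nk <- ss$Nk; state$Nkj <- ss$Nkj
    } else if (length(chg)) {          # few frames moved: update in place
      Nkj <- state$Nkj; Nk <- state$Nk
      for (i in chg) {
        xi <- ctx$xd[i, ]
        Nkj[state$z[i], ] <- Nkj[state$z[i], ] - xi
        Nkj[z[i], ] <- Nkj[z[i], ] + xi
        Nk[state$z[i]] <- Nk[state$z[i]] - 1L
        Nk[z[i]] <- Nk[z[i]] + 1L
      }
      state$Nkj <- Nkj; state$Nk <- Nk
    }
    state$z <- z
    ## sum_i [log pi_zi + log P(x_i | mu_zi)] is the complete-data log lik
    state$log_post <- sum(picked) + log_pi_prior(state$theta) +
      state$log_uniq
  }
  state
}

draw_theta <- function(Nk, Nkj, ctx) {
  K <- length(Nk)
  g <- stats::rgamma(K, shape = Nk + ctx$alpha)
  mu <- matrix(stats::rbeta(K * ctx$M, Nkj + 1, Nk - Nkj + 1), K, ctx$M)
  mu[mu < 1e-300] <- 1e-300
  mu[mu > 1 - 1e-16] <- 1 - 1e-16
  model_params(g / sum(g), mu, ctx$alpha)
}

reclassify_impl <- function(state, ctx) {
  cand <- draw_theta(state$Nk, state$Nkj, ctx)
  lu <- log_uniqueness(cand$mu)
  ok <- stats::runif(1) < exp(lu)
  if (ok) {
    state$theta <- cand
    state$log_uniq <- lu
    state$log_post <- state_log_post(state, ctx)
  }
  attr(state, "accepted") <- ok
  state
}

## log of the probability that eta-coin flips on feature column `col`
## send exactly the members flagged `toL` to L and the rest to R
split_pair_logprob <- function(col, toL, eta) {
  sum(ifelse(toL, ifelse(col == 1, log(eta), log1p(-eta)),
             ifelse(col == 1, log1p(-eta), log(eta))))
}

## lumped log generation probability of an (unordered) split partition,
## summed over every informative feature of the category and both L/R
## orientations, each renormalized for the all-one-side redraw rule;
## inputs are per-feature counts over the category's informative features:
## a = #[in L with feature], c1 = #[in R with feature]
split_partition_loggen <- function(a, c1, nL, nR, eta) {
  b <- nL - a; d <- nR - c1
  nk <- nL + nR
  le <- log(eta); l1e <- log1p(-eta)
  lpLR <- (a + d) * le + (b + c1) * l1e
  lpRL <- (b + c1) * le + (a + d) * l1e
  nkj <- a + c1
  pAllL <- exp(nkj * le + (nk - nkj) * l1e)
  pAllR <- exp(nkj * l1e + (nk - nkj) * le)
  terms <- pmax(lpLR, lpRL) + log1p(exp(-abs(lpLR - lpRL))) -
    log1p(-(pAllL + pAllR))
  logsumexp(terms) - log(length(a))
}

splittable_categories <- function(Nk, Nkj) {
  which(Nk >= 2L & rowSums(Nkj > 0 & Nkj < Nk) > 0)
}

propose_split_impl <- function(state, ctx, eta) {
  cand <- splittable_categories(state$Nk, state$Nkj)
  if (!length(cand)) return(NULL)
  k <- cand[sample.int(length(cand), 1L)]
  feats <- which(state$Nkj[k, ] > 0 & state$Nkj[k, ] < state$Nk[k])
  j <- feats[sample.int(length(feats), 1L)]
  members <- which(state$z == k)
  xk <- ctx$xd[members, feats, drop = FALSE]
  colj <- xk[, match(j, feats)]
  pL <- ifelse(colj == 1, eta, 1 - eta)
  repeat {
    toL <- stats::runif(length(members)) < pL
    nL <- sum(toL)
    if (nL > 0L && nL < length(members)) break
  }
  z2 <- state$z
  z2[members[!toL]] <- state$K + 1L
  NkjL_f <- .colSums(xk * toL, length(members), length(feats))
  NkjR_f <- state$Nkj[k, feats] - NkjL_f
  log_gen <- -log(length(cand)) +
    split_partition_loggen(NkjL_f, NkjR_f, nL, length(members) - nL, eta)
  list(z_new = z2, K_new = state$K + 1L, log_gen_prob = log_gen,
       k = k, j = j, members = members, toL = toL, feats = feats,
       NkjL_f = NkjL_f, NkjR_f = NkjR_f)
}

propose_join_impl <- function(state) {
  K <- state$K
  if (K < 2L) return(NULL)
  pr <- sort(sample.int(K, 2L))
  a <- pr[1L]; b <- pr[2L]
  z2 <- state$z
  z2[z2 == b] <- a
  z2[z2 > b] <- z2[z2 > b] - 1L
  list(z_new = z2, K_new = K - 1L, log_gen_prob = log(2) - log(K * (K - 1)),
       pair = pr)
}

#' Individual sampler moves
#'
#' These functions implement the four Monte Carlo move types on a
#' [chain_state()]; they are exposed mainly for testing and for building
#' custom sweeps.  `recategorize` redraws every frame label from its
#' responsibilities (always accepted); `reclassify` redraws `theta` from the
#' conjugate conditional and accepts with probability
#' `prod_{k<l}(1 - B_kl)`; `propose_split`/`propose_join` generate
#' dimension-change candidates together with the log of their generation
#' probability; `split_join_step` performs one complete dimension attempt
#' with its Metropolis acceptance.  All use R's global random number
#' generator.
#'
#' @param state a [chain_state()].
#' @param fm the pruned [feature_matrix()] the state refers to.
#' @param eta split bias in `(0.5, 1)`.
#' @param cfg a [sampler_config()].
#' @return an updated [chain_state()] (moves), or a candidate list with
#'   elements `z_new`, `K_new`, `log_gen_prob` (proposals; `NULL` when no
#'   such move is available).  Moves carry a logical `"accepted"` attribute.
#' @name sampler-moves
NULL

#' @rdname sampler-moves
#' @export
recategorize <- function(state, fm) {
  ctx <- make_ctx(fm, state$theta$alpha)
  st <- recategorize_impl(state, ctx)
  attr(st, "accepted") <- TRUE
  st
}

#' @rdname sampler-moves
#' @export
reclassify <- function(state, fm) {
  reclassify_impl(state, make_ctx(fm, state$theta$alpha))
}

#' @rdname sampler-moves
#' @export
propose_split <- function(state, fm, eta = 0.9) {
  propose_split_impl(state, make_ctx(fm, state$theta$alpha), eta)
}

#' @rdname sampler-moves
#' @export
propose_join <- function(state, fm) {
  propose_join_impl(state)
}

## collapsed-marginal contribution of categories `rows` of a stats pair
marg_rows <- function(Nk, Nkj, rows, ctx) {
  tot <- 0
  for (k in rows)
    tot <- tot + cat_marg_term(Nk[k], Nkj[k, ], ctx$alpha, ctx$lf)
  tot
}

## shared tail of an accepted or rejected dimension change: the Metropolis
## gate on the collapsed-marginal ratio comes first; only when it passes is
## the fresh conjugate theta drawn and gated on its uniqueness factor
dim_change_accept <- function(state, ctx, log_r, z_new, K_new, Nk2, Nkj2) {
  if (stats::runif(1) >= min(1, exp(log_r))) return(NULL)
  cand_theta <- draw_theta(Nk2, Nkj2, ctx)
  lu <- log_uniqueness(cand_theta$mu)
  if (stats::runif(1) >= exp(lu)) return(NULL)
  state$z <- z_new; state$K <- K_new
  state$Nk <- Nk2; state$Nkj <- Nkj2
  state$theta <- cand_theta
  state$log_uniq <- lu
  state$log_post <- state_log_post(state, ctx)
  state
}

split_join_impl <- function(state, ctx, cfg) {
  attempt_split <- stats::runif(1) < cfg$split_join_prob
  accepted <- FALSE
  if (attempt_split) {
    if (state$K < ctx$N) {             # keep K <= N
      prop <- propose_split_impl(state, ctx, cfg$eta)
      if (!is.null(prop)) {
        k <- prop$k
        nL <- sum(prop$toL); nR <- length(prop$members) - nL
        Nk_k <- state$Nk[k]
        lf <- ctx$lf
        ## features constant within k contribute a closed-form Beta ratio:
        ## log Beta splits as -log(n+1) for an all-0 or all-1 column
        n_const <- ctx$M - length(prop$feats)
        d_feats <-
          sum(lf[prop$NkjL_f + 1] + lf[nL - prop$NkjL_f + 1]) +
          sum(lf[prop$NkjR_f + 1] + lf[nR - prop$NkjR_f + 1]) -
          length(prop$feats) * (lf[nL + 2] + lf[nR + 2]) -
          sum(lf[state$Nkj[k, prop$feats] + 1] +
              lf[Nk_k - state$Nkj[k, prop$feats] + 1]) +
          length(prop$feats) * lf[Nk_k + 2]
        d_m <- dir_dim_term(state$K + 1L, ctx) - dir_dim_term(state$K, ctx) +
          lgamma(nL + ctx$alpha) + lgamma(nR + ctx$alpha) -
          lgamma(ctx$alpha) - lgamma(Nk_k + ctx$alpha) +
          n_const * (log(Nk_k + 1) - log(nL + 1) - log(nR + 1)) +
          d_feats
        log_gen_rev <- log(2) - log((state$K + 1) * state$K)
        log_r <- d_m + log_gen_rev - prop$log_gen_prob
        if (log(stats::runif(1)) < min(0, log_r)) {
          ## reconstitute full count rows only now that the ratio passed
          NkjL <- numeric(ctx$M)
          NkjL[state$Nkj[k, ] == Nk_k] <- nL
          NkjL[prop$feats] <- prop$NkjL_f
          NkjR <- state$Nkj[k, ] - NkjL
          Nk2 <- c(state$Nk, nR); Nk2[k] <- nL
          Nkj2 <- rbind(state$Nkj, NkjR); Nkj2[k, ] <- NkjL
          cand_theta <- draw_theta(Nk2, Nkj2, ctx)
          lu <- log_uniqueness(cand_theta$mu)
          if (stats::runif(1) < exp(lu)) {
            state$z <- prop$z_new; state$K <- state$K + 1L
            state$Nk <- Nk2; state$Nkj <- Nkj2
            state$theta <- cand_theta
            state$log_uniq <- lu
            state$log_post <- state_log_post(state, ctx)
            accepted <- TRUE
          }
        }
      }
    }
  } else if (state$K >= 2L) {
    prop <- propose_join_impl(state)
    a <- prop$pair[1L]; b <- prop$pair[2L]
    ## the reverse split must be able to regenerate the current state:
    ## both halves non-empty and the merged category informative
    if (state$Nk[a] > 0L && state$Nk[b] > 0L) {
      NkM <- state$Nk[a] + state$Nk[b]
      NkjM <- state$Nkj[a, ] + state$Nkj[b, ]
      featsM <- which(NkjM > 0 & NkjM < NkM)
      if (length(featsM)) {
        Nk2 <- state$Nk[-b]; Nk2[a] <- NkM
        Nkj2 <- state$Nkj[-b, , drop = FALSE]
        Nkj2[a, ] <- NkjM                          # a < b, index unshifted
        n_split2 <- length(splittable_categories(Nk2, Nkj2))
        log_gen_rev <- -log(n_split2) +
          split_partition_loggen(state$Nkj[a, featsM],
                                 state$Nkj[b, featsM],
                                 state$Nk[a], state$Nk[b], cfg$eta)
        d_m <- dir_dim_term(state$K - 1L, ctx) - dir_dim_term(state$K, ctx) +
          cat_marg_term(NkM, NkjM, ctx$alpha, ctx$lf) -
          marg_rows(state$Nk, state$Nkj, c(a, b), ctx)
        log_r <- d_m + log_gen_rev - prop$log_gen_prob
        st2 <- dim_change_accept(state, ctx, log_r, prop$z_new,
                                 state$K - 1L, Nk2, Nkj2)
        if (!is.null(st2)) { state <- st2; accepted <- TRUE }
      }
    }
  }
  attr(state, "accepted") <- accepted
  attr(state, "attempted_split") <- attempt_split
  state
}

#' @rdname sampler-moves
#' @export
split_join_step <- function(state, fm, cfg) {
  split_join_impl(state, make_ctx(fm, cfg$alpha_override), cfg)
}

## ---- chain drivers -------------------------------------------------------

#' Run one MCMC chain
#'
#' Starts from all frames in a single category with a conjugate draw of
#' `theta`, then performs `n_steps` sweeps of recategorize + reclassify +
#' one split-or-join attempt, retaining the state at every step `s >=
#' burn_in` with `s` divisible by `thin` (steps are counted from 0).  Fully
#' reproducible from `(cfg$seed, chain_id)`.
#'
#' @param fm a pruned [feature_matrix()] with at least one column.
#' @param cfg a [sampler_config()].
#' @param chain_id integer chain identifier (also seeds the chain).
#' @return a list with `samples` (list of retained draws, each holding
#'   `theta`, `z`, `log_post`, `chain_id`, `step`) and `diagnostics`
#'   (`K_trace`, `log_post_trace`, split/join attempt and acceptance
#'   counts, `sj_acceptance` fraction, reclassify acceptance fraction).
#' @export
run_chain <- function(fm, cfg = sampler_config(), chain_id = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!fm$pruned)
    stop("feature matrix must be pruned first (see prune_constant_features)")
  if (ncol(fm$x) < 1L) stop("no informative features")
  ctx <- make_ctx(fm, cfg$alpha_override)
  set.seed(derive_seed(cfg$seed, chain_id))
  z0 <- rep(1L, ctx$N)
  ss <- fast_stats(ctx$xd, z0, 1L)
  state <- list(theta = draw_theta(ss$Nk, ss$Nkj, ctx), z = z0, K = 1L,
                Nk = ss$Nk, Nkj = ss$Nkj, step = 0L)
  state$log_uniq <- 0
  state$log_post <- state_log_post(state, ctx)
  class(state) <- "chain_state"

  n_keep <- length(seq(cfg$burn_in, cfg$n_steps - 1L, by = cfg$thin))
  samples <- vector("list", n_keep)
  ki <- 0L
  K_trace <- integer(cfg$n_steps)
  lp_trace <- numeric(cfg$n_steps)
  sj_att <- 0L; sj_acc <- 0L; rc_att <- 0L; rc_acc <- 0L
  for (step in 0:(cfg$n_steps - 1L)) {
    state <- recategorize_impl(state, ctx)
    state <- reclassify_impl(state, ctx)
    rc_att <- rc_att + 1L
    if (attr(state, "accepted")) rc_acc <- rc_acc + 1L
    state <- split_join_impl(state, ctx, cfg)
    sj_att <- sj_att + 1L
    if (attr(state, "accepted")) sj_acc <- sj_acc + 1L
    state$step <- step
    K_trace[step + 1L] <- state$K
    lp_trace[step + 1L] <- state$log_post
    if (step >= cfg$burn_in && (step %% cfg$thin) == 0L) {
      ki <- ki + 1L
      samples[[ki]] <- list(theta = state$theta, z = state$z,
                            log_post = state$log_post,
                            chain_id = chain_id, step = step)
    }
  }
  list(samples = samples[seq_len(ki)],
       diagnostics = list(chain_id = chain_id, K_trace = K_trace,
                          log_post_trace = lp_trace,
                          sj_attempts = sj_att, sj_accepted = sj_acc,
                          sj_acceptance = sj_acc / max(1L, sj_att),
                          reclassify_acceptance = rc_acc / max(1L, rc_att)))
}

#' Run an ensemble of independent chains
#'
#' Runs `cfg$n_chains` chains with sub-seeds derived from
#' `(cfg$seed, chain_id)` and pools the retained samples.  Chains are
#' independent, so execution order cannot affect the result.
#'
#' @inheritParams run_chain
#' @return an object of class `"cmix_posterior"`: a list with pooled
#'   `samples`, per-chain `diagnostics`, and the `config` used.
#' @export
run_ensemble <- function(fm, cfg = sampler_config()) {
  chains <- lapply(seq_len(cfg$n_chains), function(i) run_chain(fm, cfg, i))
  structure(list(samples = do.call(c, lapply(chains, `[[`, "samples")),
                 diagnostics = lapply(chains, `[[`, "diagnostics"),
                 config = cfg),
            class = "cmix_posterior")
}

#' @export
print.cmix_posterior <- function(x, ...) {
  ks <- vapply(x$samples, function(s) sum(tabulate(s$z) > 0), integer(1))
  acc <- mean(vapply(x$diagnostics, `[[`, numeric(1), "sj_acceptance"))
  cat(sprintf(paste0("<cmix_posterior> %d samples from %d chains; ",
                     "occupied K in [%d, %d] (mode %d); ",
                     "split/join acceptance %.1f%%\n"),
              length(x$samples), length(x$diagnostics),
              min(ks), max(ks), as.integer(names(which.max(table(ks)))),
              100 * acc))
  invisible(x)
}

#' Save or load pooled posterior samples
#'
#' Serialized container holding the retained draws (`theta`, `z`,
#' `log_post`, chain and step tags), per-chain diagnostics and the sampler
#' configuration.
#'
#' @param post a `"cmix_posterior"` object from [run_ensemble()].
#' @param path file path (conventionally `.rds`).
#' @export
write_posterior <- function(post, path) {
  stopifnot(inherits(post, "cmix_posterior"))
  saveRDS(unclass(post), path)
  invisible(path)
}

#' @rdname write_posterior
#' @export
read_posterior <- function(path) {
  structure(readRDS(path), class = "cmix_posterior")
}
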