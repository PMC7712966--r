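## Scoring categorizations against time order.
##
## The benchmark motions are monotone in time, so a good categorization
## should assign contiguous runs of frames to each category: a perfect
## categorization with k categories has exactly k - 1 label transitions.
## Two scores are reported.  The "left" score charges every transition
## beyond the required k - 1.  The "right" score additionally excuses
## boundary oscillation: transitions between categories that are adjacent
## on the dominant category path (the maximum-weight simple path through
## the observed adjacent-frame transition graph) are not charged at all.

## maximum-weight Hamiltonian path edges by bitmask dynamic programming
max_path_edges_exact <- function(w) {
  k <- nrow(w)
  if (k == 1L) return(matrix(integer(0), 0L, 2L))
  bits <- bitwShiftL(1L, seq_len(k) - 1L)
  full <- bitwShiftL(1L, k) - 1L
  dp <- matrix(-Inf, full, k)       # dp[mask, last] = best weight
  parent <- matrix(0L, full, k)
  dp[cbind(bits, seq_len(k))] <- 0
  for (mask in seq_len(full)) {
    lasts <- which(is.finite(dp[mask, ]))
    if (!length(lasts)) next
    nxt <- which(bitwAnd(mask, bits) == 0L)
    if (!length(nxt)) next
    for (last in lasts) {
      m2 <- mask + bits[nxt]
      val <- dp[mask, last] + w[last, nxt]
      idx <- cbind(m2, nxt)
      better <- val > dp[idx]
      if (any(better)) {
        dp[idx[better, , drop = FALSE]] <- val[better]
        parent[idx[better, , drop = FALSE]] <- last
      }
    }
  }
  last <- which.max(dp[full, ])
  path <- integer(k)
  mask <- full
  for (i in k:1) {
    path[i] <- last
    prev <- parent[mask, last]
    mask <- mask - bits[last]
    last <- prev
  }
  cbind(path[-k], path[-1L])
}

## greedy fallback: insert heaviest edges that keep a single simple path
max_path_edges_greedy <- function(w) {
  k <- nrow(w)
  eu <- rep(seq_len(k), each = k); ev <- rep(seq_len(k), k)
  sel <- eu < ev
  ord <- order(w[cbind(eu[sel], ev[sel])], decreasing = TRUE)
  cand <- cbind(eu[sel], ev[sel])[ord, , drop = FALSE]
  deg <- integer(k)
  comp <- seq_len(k)
  edges <- matrix(integer(0), 0L, 2L)
  for (e in seq_len(nrow(cand))) {
    a <- cand[e, 1L]; b <- cand[e, 2L]
    if (deg[a] >= 2L || deg[b] >= 2L || comp[a] == comp[b]) next
    edges <- rbind(edges, cand[e, ])
    deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L
    comp[comp == comp[b]] <- comp[a]
    if (nrow(edges) == k - 1L) break
  }
  edges
}

#' Time-order accuracy of a categorization
#'
#' Given per-frame labels `z` in time order, computes the transition count
#' `T`, the number of distinct labels used `k`, and two accuracies: the
#' left score `100 (1 - (T - (k - 1)) / N)`, which charges every transition
#' beyond the `k - 1` required ones, and the right score, which instead
#' charges only transitions whose label pair is *not* an edge of the
#' maximum-weight simple path through the adjacent-frame transition graph
#' (boundary oscillation between path-adjacent categories is excused).  The
#' path is found exactly by dynamic programming for `k <= 12` and by greedy
#' edge insertion beyond that.
#'
#' @param z integer (or factor) vector of labels in frame order, `N >= 2`.
#' @return an object of class `"accuracy_report"`: list with `left_pct`,
#'   `right_pct`, `n_transitions`, `k_used`.
#' @export
time_order_accuracy <- function(z) {
  if (length(z) < 2L) stop("need at least 2 frames to count transitions")
  z <- as.integer(factor(z))
  N <- length(z)
  k <- max(z)
  a <- z[-N]; b <- z[-1L]
  chg <- which(a != b)
  Tn <- length(chg)
  left <- 100 * (1 - (Tn - (k - 1)) / N)
  w <- matrix(0, k, k)
  for (i in chg) {
    u <- min(a[i], b[i]); v <- max(a[i], b[i])
    w[u, v] <- w[u, v] + 1
    w[v, u] <- w[v, u] + 1
  }
  edges <- if (k <= 12L) max_path_edges_exact(w) else max_path_edges_greedy(w)
  onpath <- matrix(FALSE, k, k)
  if (nrow(edges)) {
    onpath[edges] <- TRUE
    onpath[edges[, 2:1, drop = FALSE]] <- TRUE
  }
  excused <- if (Tn) sum(onpath[cbind(a[chg], b[chg])]) else 0L
  right <- 100 * (1 - (Tn - excused) / N)
  structure(list(left_pct = left, right_pct = right,
                 n_transitions = Tn, k_used = k),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf(paste0("<accuracy_report> left %.2f%%, right %.2f%%, ",
                     "%d transitions over %d categories\n"),
              x$left_pct, x$right_pct, x$n_transitions, x$k_used))
  invisible(x)
}

as_sample_list <- function(samples) {
  if (inherits(samples, "cmix_posterior")) samples$samples else samples
}

occupied_k <- function(s) sum(tabulate(s$z) > 0L)

#' Summarize time-order accuracy over pooled posterior samples
#'
#' Applies [time_order_accuracy()] to every retained draw and summarizes
#' the left and right scores by their mean (reported alongside the
#' interquartile range).
#'
#' @param samples a `"cmix_posterior"` object or a list of posterior
#'   samples.
#' @return list with `per_sample` (data frame of left/right/k per draw) and
#'   `mean_left`, `mean_right`, `iqr_left`, `iqr_right`.
#' @export
accuracy_summary <- function(samples) {
  ss <- as_sample_list(samples)
  if (!length(ss)) stop("no posterior samples")
  rep_list <- lapply(ss, function(s) time_order_accuracy(s$z))
  left <- vapply(rep_list, `[[`, numeric(1), "left_pct")
  right <- vapply(rep_list, `[[`, numeric(1), "right_pct")
  k <- vapply(rep_list, `[[`, numeric(1), "k_used")
  list(per_sample = data.frame(left_pct = left, right_pct = right,
                               k_used = k),
       mean_left = mean(left), mean_right = mean(right),
       iqr_left = stats::IQR(left), iqr_right = stats::IQR(right))
}

#' Histogram of the number of categories across posterior samples
#'
#' Counts, for each retained draw, the number of *occupied* categories
#' (categories with at least one assigned frame; the sampler may carry
#' empty bookkeeping categories which are not meaningful states).
#'
#' @inheritParams accuracy_summary
#' @return a named integer vector mapping K to its sample count; counts sum
#'   to the number of pooled samples.
#' @export
k_histogram <- function(samples) {
  ss <- as_sample_list(samples)
  if (!length(ss)) stop("no posterior samples")
  ks <- vapply(ss, occupied_k, integer(1))
  tab <- table(ks)
  stats::setNames(as.integer(tab), names(tab))
}

#' Maximum-posterior sample at each category count
#'
#' For each observed number of occupied categories, returns the retained
#' draw with the largest log posterior (ties broken by earliest chain and
#' step).
#'
#' @inheritParams accuracy_summary
#' @return a named list mapping `K` to the winning sample (fields `theta`,
#'   `z`, `log_post`, `chain_id`, `step`).
#' @export
best_theta_per_k <- function(samples) {
  ss <- as_sample_list(samples)
  if (!length(ss)) stop("no posterior samples")
  ks <- vapply(ss, occupied_k, integer(1))
  out <- list()
  for (K in sort(unique(ks))) {
    idx <- which(ks == K)
    lp <- vapply(ss[idx], `[[`, numeric(1), "log_post")
    ch <- vapply(ss[idx], `[[`, numeric(1), "chain_id")
    stp <- vapply(ss[idx], `[[`, numeric(1), "step")
    best <- idx[order(-lp, ch, stp)[1L]]
    out[[as.character(K)]] <- ss[[best]]
  }
  out
}

#' Representative frame of each category
#'
#' For each category `k` of `theta`, the frame whose posterior membership
#' probability for `k` is highest (ties broken by the earliest frame).
#' These frames serve as representative conformations for their categories.
#'
#' @param fm a [feature_matrix()].
#' @param theta a [model_params()].
#' @return integer vector of frame indices, one per category.
#' @export
representative_frames <- function(fm, theta) {
  r <- responsibilities(fm, theta)
  apply(r, 2L, which.max)
}
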