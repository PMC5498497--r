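# Bayesian skyline: piecewise-constant coalescent likelihood on a fixed
# genealogy, Metropolis-Hastings over group Ne values (log-uniform
# prior) and group boundaries, summarized as a median trajectory with
# 95% HPD bounds.

#' Construct a genealogy (coalescent event times)
#'
#' @param coal_times Numeric vector of the `n_tips - 1` coalescent times
#'   in years before present.
#' @param samp_times Sampling times of the tips in years before present
#'   (default: all contemporaneous at 0).
#' @param n_tips Number of tips (default `length(coal_times) + 1`).
#' @return Object of class `genealogy`.
#' @export
genealogy <- function(coal_times, samp_times = NULL, n_tips = NULL) {
  coal_times <- sort(as.numeric(coal_times))
  if (is.null(n_tips)) n_tips <- length(coal_times) + 1L
  if (length(coal_times) != n_tips - 1L)
    stop("need exactly n_tips - 1 coalescent times")
  if (is.null(samp_times)) samp_times <- rep(0, n_tips)
  if (length(samp_times) != n_tips) stop("one sampling time per tip")
  if (any(coal_times < 0) || any(samp_times < 0))
    stop("times must be non-negative")
  # validate lineage counts: walking back in time, each coalescence
  # needs >= 2 active lineages
  ev <- rbind(data.frame(t = samp_times, d = 1L),
              data.frame(t = coal_times, d = -1L))
  ev <- ev[order(ev$t, -ev$d), ]
  kk <- cumsum(ev$d)
  if (any(kk[ev$d == -1L] < 1L))
    stop("coalescent event with fewer than 2 active lineages")
  structure(list(coal_times = coal_times, samp_times = sort(samp_times),
                 n_tips = n_tips), class = "genealogy")
}

#' Extract a genealogy from a dated ultrametric tree
#'
#' @param tree Rooted `phylo`.
#' @param node_ages Ages (years) of all nodes in `phylo` numbering
#'   (tips first); e.g. `1000 * fit$node_ages_ky` from a clock fit.
#' @param tips Optional tip subset: the genealogy of their induced
#'   subtree (MRCA-rooted clade).
#' @return A [genealogy()].
#' @export
genealogy_from_tree <- function(tree, node_ages, tips = NULL) {
  n <- length(tree$tip.label)
  if (!is.null(tips)) {
    keep_node <- ape::getMRCA(tree, tips)
    desc <- phylo_descendants(tree, keep_node)
    internal <- desc[desc > n]
    internal <- c(keep_node, internal)
    tip_idx <- match(tips, tree$tip.label)
    genealogy(node_ages[unique(internal)], node_ages[tip_idx])
  } else {
    genealogy(node_ages[(n + 1L):(n + tree$Nnode)], node_ages[1:n])
  }
}

phylo_descendants <- function(tree, node) {
  out <- integer(0)
  stack <- tree$edge[tree$edge[, 1] == node, 2]
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, v)
    stack <- c(stack, tree$edge[tree$edge[, 1] == v, 2])
  }
  out
}

#' Piecewise-constant coalescent log-likelihood
#'
#' For each inter-event interval with `k` active lineages the
#' contribution is `-k(k-1)/(2 Ne) * dtau` (times in generations), and
#' each coalescent event contributes `-log Ne` at its epoch.
#' Non-positive `Ne` yields `-Inf` rather than an error (so an MCMC can
#' simply reject).
#'
#' @param gen A [genealogy()] (times in years).
#' @param ne Vector of Ne values (effective females), one per epoch.
#' @param breaks Epoch boundaries in years (sorted, length
#'   `length(ne) - 1`); `ne[1]` applies on `[0, breaks[1]]` (an event
#'   falling exactly on a boundary belongs to the earlier epoch, the
#'   skyline grouping convention).
#' @param gen_time Generation time in years (default 6).
#' @return Log-likelihood (up to the constant `sum(log(k(k-1)/2))`).
#' @export
coalescent_loglik <- function(gen, ne, breaks = numeric(0), gen_time = 6) {
  if (any(ne <= 0)) return(-Inf)
  if (length(breaks) != length(ne) - 1L)
    stop("need length(ne) - 1 breaks")
  g <- gen_time
  ev <- rbind(data.frame(t = gen$samp_times / g, d = 1L),
              data.frame(t = gen$coal_times / g, d = -1L))
  ev <- ev[order(ev$t, -ev$d), ]
  br <- breaks / g
  ne_at <- function(tau) ne[findInterval(tau, br, left.open = TRUE) + 1L]
  ll <- 0
  k <- 0L
  for (i in seq_len(nrow(ev))) {
    if (i > 1L) {
      t0 <- ev$t[i - 1L]; t1 <- ev$t[i]
      if (t1 > t0 && k >= 2L) {
        cuts <- c(t0, br[br > t0 & br < t1], t1)
        for (j in seq_len(length(cuts) - 1L)) {
          mid <- (cuts[j] + cuts[j + 1L]) / 2
          ll <- ll - k * (k - 1) / (2 * ne_at(mid)) *
            (cuts[j + 1L] - cuts[j])
        }
      }
    }
    if (ev$d[i] == -1L) ll <- ll - log(ne_at(ev$t[i]))
    k <- k + ev$d[i]
  }
  ll
}

# integrated k(k-1)/2 * dtau between successive coalescent events
# (in generations), one entry per coalescent event; sampling events
# inside an interval are handled exactly
interval_intensities <- function(gen, gen_time) {
  g <- gen_time
  ev <- rbind(data.frame(t = gen$samp_times / g, d = 1L),
              data.frame(t = gen$coal_times / g, d = -1L))
  ev <- ev[order(ev$t, -ev$d), ]
  A <- numeric(length(gen$coal_times))
  idx <- 0L
  k <- 0L
  acc <- 0
  for (i in seq_len(nrow(ev))) {
    if (i > 1L) acc <- acc + k * (k - 1) / 2 * (ev$t[i] - ev$t[i - 1L])
    if (ev$d[i] == -1L) {
      idx <- idx + 1L
      A[idx] <- acc
      acc <- 0
    }
    k <- k + ev$d[i]
  }
  A
}

#' Bayesian skyline MCMC on a fixed genealogy
#'
#' Coalescent intervals are partitioned into `m_groups` contiguous
#' groups sharing one Ne each (classic skyline). The sampler uses scale
#' proposals on Ne (log-uniform prior within `ne_prior`) and single-event
#' boundary shifts on the group sizes, and returns the post-burn-in
#' median trajectory with 95% HPD bounds on a uniform time grid in
#' years. Convergence is monitored by the effective sample size of the
#' log-likelihood trace; a low ESS flags the result with a warning
#' (`attr(x, "converged")`).
#'
#' @param gen A [genealogy()].
#' @param m_groups Number of Ne groups (`1 <= m <= n_tips - 1`).
#' @param iters MCMC iterations.
#' @param thin Keep every `thin`-th sample.
#' @param seed Integer seed (fixed seed => identical trajectory).
#' @param gen_time Generation time in years (default 6).
#' @param burnin Fraction of iterations discarded (default 0.1).
#' @param grid_n Number of trajectory grid points.
#' @param ne_prior Bounds of the log-uniform Ne prior.
#' @return `data.frame` of class `skyline_trajectory` with columns
#'   `time_yr`, `median_nef`, `hpd_lo`, `hpd_hi`; attributes `gen_time`,
#'   `ess`, `converged`, `boundaries_yr` (posterior-median group
#'   boundaries) and `samples`.
#' @export
run_skyline_mcmc <- function(gen, m_groups = 10L, iters = 500000L,
                             thin = 100L, seed = 1L, gen_time = 6,
                             burnin = 0.1, grid_n = 100L,
                             ne_prior = c(1e-2, 1e9)) {
  n_ev <- length(gen$coal_times)
  if (m_groups < 1L || m_groups > n_ev)
    stop("m_groups must be between 1 and n_tips - 1")
  A <- interval_intensities(gen, gen_time)
  m <- m_groups
  with_seed(seed, {
    sizes <- diff(round(seq(0, n_ev, length.out = m + 1L)))
    bounds <- cumsum(sizes)                # event index of group ends
    grpA <- function(bounds) {
      lo <- c(1L, utils::head(bounds, -1L) + 1L)
      vapply(seq_len(m), function(j) sum(A[lo[j]:bounds[j]]), numeric(1))
    }
    gA <- grpA(bounds)
    gs <- sizes
    ne <- pmax(pmin(gA / pmax(gs, 1), ne_prior[2]), ne_prior[1])
    ne[ne <= 0] <- 1
    ll_parts <- -gA / ne - gs * log(ne)
    ll <- sum(ll_parts)
    n_keep <- floor(iters / thin)
    ne_samp <- matrix(NA_real_, n_keep, m)
    bd_samp <- matrix(NA_integer_, n_keep, m)
    ll_trace <- numeric(n_keep)
    ks <- 0L
    for (it in seq_len(iters)) {
      if (stats::runif(1) < 0.7 || m == 1L) {
        j <- sample.int(m, 1L)
        s <- exp(stats::runif(1, -0.8, 0.8))
        ne_new <- ne[j] * s
        if (ne_new >= ne_prior[1] && ne_new <= ne_prior[2]) {
          lp_new <- -gA[j] / ne_new - gs[j] * log(ne_new)
          # scale move on a log-uniform prior: Hastings and prior cancel
          if (log(stats::runif(1)) < lp_new - ll_parts[j]) {
            ne[j] <- ne_new
            ll <- ll - ll_parts[j] + lp_new
            ll_parts[j] <- lp_new
          }
        }
      } else {
        b <- sample.int(m - 1L, 1L)
        delta <- if (stats::runif(1) < 0.5) 1L else -1L
        new_bounds <- bounds
        new_bounds[b] <- bounds[b] + delta
        lo_ok <- new_bounds[b] >= b   # group sizes stay >= 1
        hi_ok <- new_bounds[b] < bounds[b + 1L] &&
          (b == 1L || new_bounds[b] > bounds[b - 1L])
        if (lo_ok && hi_ok) {
          gA2 <- grpA(new_bounds)
          gs2 <- diff(c(0L, new_bounds))
          lp_old <- ll_parts[b] + ll_parts[b + 1L]
          lp_new <- -gA2[b] / ne[b] - gs2[b] * log(ne[b]) -
            gA2[b + 1L] / ne[b + 1L] - gs2[b + 1L] * log(ne[b + 1L])
          if (log(stats::runif(1)) < lp_new - lp_old) {
            bounds <- new_bounds
            gA <- gA2; gs <- gs2
            ll_parts[b] <- -gA[b] / ne[b] - gs[b] * log(ne[b])
            ll_parts[b + 1L] <- -gA[b + 1L] / ne[b + 1L] -
              gs[b + 1L] * log(ne[b + 1L])
            ll <- sum(ll_parts)
          }
        }
      }
      if (it %% thin == 0L) {
        ks <- ks + 1L
        ne_samp[ks, ] <- ne
        bd_samp[ks, ] <- bounds
        ll_trace[ks] <- ll
      }
    }
    keep <- seq.int(floor(n_keep * burnin) + 1L, n_keep)
    ne_samp <- ne_samp[keep, , drop = FALSE]
    bd_samp <- bd_samp[keep, , drop = FALSE]
    ll_trace <- ll_trace[keep]

    tmax <- max(gen$coal_times)
    grid <- seq(0, tmax, length.out = grid_n)
    ct <- gen$coal_times
    traj <- matrix(NA_real_, length(keep), grid_n)
    for (s in seq_len(nrow(ne_samp))) {
      bt <- ct[bd_samp[s, ]]                  # group end times (years)
      gidx <- pmin(findInterval(grid, bt, left.open = TRUE) + 1L, m)
      traj[s, ] <- ne_samp[s, gidx]
    }
    med <- apply(traj, 2, stats::median)
    hpd <- apply(traj, 2, hpd_interval)
    ess <- ess_of(ll_trace)
    converged <- is.finite(ess) && ess >= 100
    if (!converged)
      warning("skyline MCMC: low effective sample size (",
              round(ess, 1), "); results may not have converged")
    out <- data.frame(time_yr = grid, median_nef = med,
                      hpd_lo = hpd[1, ], hpd_hi = hpd[2, ])
    class(out) <- c("skyline_trajectory", "data.frame")
    attr(out, "gen_time") <- gen_time
    attr(out, "ess") <- ess
    attr(out, "converged") <- converged
    attr(out, "boundaries_yr") <- ct[round(apply(bd_samp, 2, stats::median))]
    attr(out, "samples") <- list(ne = ne_samp, bounds = bd_samp,
                                 loglik = ll_trace)
    out
  })
}

# shortest interval containing `prob` of the sample
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  w <- max(1L, floor(prob * n))
  if (w >= n) return(c(x[1], x[n]))
  widths <- x[(w + 1L):n] - x[1:(n - w)]
  i <- which.min(widths)
  c(x[i], x[i + w])
}

# crude autocorrelation-based effective sample size (Geyer-style cutoff)
ess_of <- function(x) {
  n <- length(x)
  if (n < 10L || stats::sd(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1]
  neg <- which(rho <= 0)
  if (length(neg)) rho <- rho[seq_len(neg[1] - 1L)]
  n / (1 + 2 * sum(rho))
}

#' Classify trajectory trends across epochs
#'
#' For each epoch, compares the median trajectory at the older and the
#' more recent boundary and reports the forward-in-time change:
#' `"increase"`, `"decrease"`, or `"flat"` (relative change within
#' `flat_tol`).
#'
#' @param traj A `skyline_trajectory`.
#' @param epochs `data.frame` with columns `start`, `end` in years
#'   before present (order of the two does not matter).
#' @param flat_tol Relative-change tolerance for "flat" (default 0.1).
#' @return Character vector, one entry per epoch.
#' @export
detect_trend_phases <- function(traj, epochs, flat_tol = 0.1) {
  span <- range(traj$time_yr)
  vapply(seq_len(nrow(epochs)), function(i) {
    older <- max(epochs$start[i], epochs$end[i])
    recent <- min(epochs$start[i], epochs$end[i])
    if (older > span[2] || recent < span[1])
      stop("epoch ", i, " outside trajectory span")
    v_old <- stats::approx(traj$time_yr, traj$median_nef, older,
                           rule = 2)$y
    v_new <- stats::approx(traj$time_yr, traj$median_nef, recent,
                           rule = 2)$y
    ratio <- v_new / v_old
    if (ratio > 1 + flat_tol) "increase"
    else if (ratio < 1 / (1 + flat_tol)) "decrease"
    else "flat"
  }, character(1))
}

#' Write a skyline trajectory to TSV
#' @param traj A `skyline_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_skyline <- function(traj, path) {
  utils::write.table(as.data.frame(traj), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
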