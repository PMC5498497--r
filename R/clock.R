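# Calibrated Poisson molecular clock on branch mutation counts.
#
# Branch counts k_b are modelled as Poisson(r * L * dt_b) with dt_b the
# branch duration implied by node ages; calibrations either pin node
# ages (fixed) or contribute Gaussian log-density penalties. The rate r
# is profiled out analytically (r_hat = K / (L * T)); node ages are
# optimized on a constrained transform that keeps every child younger
# than its parent. Standard errors come from the observed information
# (numerical Hessian) at the optimum.

#' Define a clock calibration
#'
#' @param tips Character vector of tip labels: one label for a dated tip,
#'   several for the MRCA node of the set, or `"root"`.
#' @param age Age in years before present.
#' @param sd Standard deviation in years (required for
#'   `mode = "gaussian"`).
#' @param mode `"gaussian"` (penalty at the printed SD) or `"fixed"`
#'   (age pinned exactly).
#' @return A `calibration` object.
#' @export
calibration <- function(tips, age, sd = NA_real_,
                        mode = c("gaussian", "fixed")) {
  mode <- match.arg(mode)
  if (age <= 0) stop("calibration age must be positive")
  if (mode == "gaussian" && (is.na(sd) || sd <= 0))
    stop("gaussian calibration needs sd > 0")
  structure(list(tips = tips, age = age, sd = sd, mode = mode),
            class = "calibration")
}

#' Read a calibration table
#'
#' TSV with header `target age_yr sd_yr mode`; `target` is `root`, a tip
#' label, or comma-separated tip labels whose MRCA is calibrated.
#'
#' @param path TSV path.
#' @return List of [calibration()] objects.
#' @export
read_calibrations <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i)
    calibration(strsplit(tab$target[i], ",")[[1]], tab$age_yr[i],
                if (is.null(tab$sd_yr)) NA_real_ else tab$sd_yr[i],
                tab$mode[i]))
}

#' Fit the calibrated Poisson clock
#'
#' Maximum-likelihood substitution rate and node ages from per-branch
#' mutation counts under a strict clock. The model is
#' `k_b ~ Poisson(r * L * dt_b)`; Gaussian calibrations add their
#' log-density to the objective, fixed calibrations pin ages exactly.
#' Ages of dated (ancient) tips are fixed at their stated age.
#'
#' @param tree Rooted binary `phylo` with integer branch mutation counts
#'   in `edge.count` (as produced by [assign_branch_mutations()]) or
#'   `edge.length`.
#' @param calibrations List of [calibration()] objects (at least one).
#' @param site_count Number of sites `L` the counts were accumulated
#'   over (codons or nucleotides — the rate is per chosen unit).
#' @param tip_ages Optional named numeric vector of tip ages in years
#'   (default 0 = present-day).
#' @param n_starts Number of seeded optimizer starts.
#' @return Object of class `clock_fit`: list with `rate` (substitutions
#'   per site per Ky), `rate_se`, `site_count`, `node_ages_ky` (vector
#'   over all tree nodes), `node_se_ky`, `loglik` (penalized, at the
#'   optimum), `tree`, `calibrations`, `convergence`.
#' @export
fit_clock <- function(tree, calibrations, site_count, tip_ages = NULL,
                      n_starts = 5L) {
  if (!length(calibrations)) stop("at least one calibration is required")
  if (inherits(calibrations, "calibration")) calibrations <- list(calibrations)
  k <- branch_counts(tree)
  L <- site_count
  n <- length(tree$tip.label)
  nn <- tree$Nnode
  root <- n + 1L
  if (sum(k) == 0L) {
    warning("zero mutations: rate estimate 0, SEs undefined")
    ages <- numeric(n + nn)
    return(structure(list(rate = 0, rate_se = NA_real_,
                          site_count = L, node_ages_ky = ages,
                          node_se_ky = rep(NA_real_, n + nn),
                          loglik = 0, tree = tree,
                          calibrations = calibrations,
                          convergence = 0L), class = "clock_fit"))
  }
  ta <- rep(0, n)
  names(ta) <- tree$tip.label
  if (!is.null(tip_ages)) ta[names(tip_ages)] <- tip_ages
  ta_ky <- ta / 1000

  # resolve calibrations to node numbers (tips handled via fixed ages)
  pin <- rep(NA_real_, n + nn)       # fixed ages (Ky)
  gauss <- list()                    # list of (node, mean_ky, sd_ky)
  for (cal in calibrations) {
    node <- cal_node(tree, cal$tips)
    if (node <= n) {                 # dated tip: age is data
      ta_ky[node] <- cal$age / 1000
      next
    }
    if (cal$mode == "fixed") pin[node] <- cal$age / 1000
    else gauss[[length(gauss) + 1L]] <-
        list(node = node, mean = cal$age / 1000, sd = cal$sd / 1000)
  }
  if (all(is.na(pin)) && !length(gauss))
    stop("no usable calibration (all targets were present-day tips)")

  phy <- ape::reorder.phylo(tree, "postorder")
  kpost <- branch_counts(tree)[match(paste(phy$edge[, 1], phy$edge[, 2]),
                                     paste(tree$edge[, 1], tree$edge[, 2]))]
  # lower bound per node: max descendant tip age
  lb <- c(ta_ky, rep(0, nn))
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]; ch <- phy$edge[i, 2]
    lb[p] <- max(lb[p], lb[ch])
  }
  pre_edges <- phy$edge[nrow(phy$edge):1, , drop = FALSE]  # preorder
  internal <- (n + 1L):(n + nn)
  free <- internal[is.na(pin[internal])]
  root_free <- is.na(pin[root])

  ages_from_par <- function(par) {
    ages <- c(ta_ky, rep(NA_real_, nn))
    idx <- 1L
    if (root_free) {
      ages[root] <- lb[root] + exp(par[idx]); idx <- idx + 1L
    } else ages[root] <- pin[root]
    frac <- if (length(par) >= idx) stats::plogis(par[idx:length(par)])
      else numeric(0)
    j <- 1L
    for (i in seq_len(nrow(pre_edges))) {
      ch <- pre_edges[i, 2]
      if (ch <= n) next
      up <- ages[pre_edges[i, 1]]
      if (!is.na(pin[ch])) {
        ages[ch] <- pin[ch]
        if (ages[ch] > up) return(NULL)
      } else {
        ages[ch] <- lb[ch] + frac[j] * (up - lb[ch])
        j <- j + 1L
      }
    }
    ages
  }

  K <- sum(kpost)
  # gaussian calibrations are truncated at +/- 4 sd: the age of a
  # calibrated node may not wander arbitrarily far from its prior mean
  # (this excludes a degenerate mode where the whole tree collapses onto
  # a fixed ancient-tip age with an absurd rate)
  trunc_ok <- function(ages) {
    for (gz in gauss) {
      if (abs(ages[gz$node] - gz$mean) > 4 * gz$sd) return(FALSE)
    }
    TRUE
  }
  negll <- function(par) {
    ages <- ages_from_par(par)
    if (is.null(ages)) return(1e10)
    dt <- ages[phy$edge[, 1]] - ages[phy$edge[, 2]]
    if (any(dt <= 0)) return(1e10)
    if (!trunc_ok(ages)) return(1e10)
    Ttot <- sum(dt)
    r <- K / (L * Ttot)
    ll <- sum(kpost * log(r * L * dt)) - r * L * Ttot
    for (gz in gauss)
      ll <- ll + stats::dnorm(ages[gz$node], gz$mean, gz$sd, log = TRUE)
    -ll
  }

  npar <- as.integer(root_free) + length(free)
  # initial ages: proportional to mean mutation depth below each node
  depth <- node_mut_depth(phy, kpost, n, nn)
  root_guess <- init_root_age(gauss, pin, root, depth, lb)
  init_par <- function(jitter, seed) {
    with_seed(seed, {
      sc <- root_guess / max(depth[root], 1)
      ages0 <- pmax(lb + 1e-6, depth * sc)
      ages0[root] <- max(root_guess, lb[root] + 1e-3)
      par <- numeric(0)
      if (root_free) par <- log(max(ages0[root] - lb[root], 1e-3))
      for (i in seq_len(nrow(pre_edges))) {
        ch <- pre_edges[i, 2]
        if (ch <= n || !is.na(pin[ch])) next
        up <- ages0[pre_edges[i, 1]]
        f <- (ages0[ch] - lb[ch]) / max(up - lb[ch], 1e-9)
        f <- min(max(f, 0.02), 0.98)
        par <- c(par, stats::qlogis(f))
      }
      par + stats::rnorm(length(par), 0, jitter)
    })
  }

  if (npar == 0L) {
    best <- list(par = numeric(0), value = negll(numeric(0)),
                 convergence = 0L)
  } else {
    best <- NULL
    for (s in seq_len(n_starts)) {
      p0 <- init_par(if (s == 1) 0 else 0.5, seed = 1000L + s)
      method <- if (npar > 4L) "BFGS" else "Nelder-Mead"
      fit <- tryCatch(
        stats::optim(p0, negll, method = method,
                     control = list(maxit = 2000L)),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    if (is.null(best)) stop("clock optimization failed")
  }
  ages_hat <- ages_from_par(best$par)
  dt <- ages_hat[phy$edge[, 1]] - ages_hat[phy$edge[, 2]]
  r_hat <- K / (L * sum(dt))

  # observed information on the unconstrained scale (log r + transformed
  # ages, where the ordering constraints cannot be violated), mapped to
  # (rate, node ages) by the delta method
  free_nodes <- c(if (root_free) root, free)
  negll_full <- function(theta) {
    r <- exp(theta[1])
    ages <- ages_from_par(theta[-1])
    if (is.null(ages)) return(NA_real_)
    dtb <- ages[phy$edge[, 1]] - ages[phy$edge[, 2]]
    if (any(dtb <= 0) || !trunc_ok(ages)) return(NA_real_)
    ll <- sum(kpost * log(r * L * dtb)) - r * L * sum(dtb)
    for (gz in gauss)
      ll <- ll + stats::dnorm(ages[gz$node], gz$mean, gz$sd, log = TRUE)
    -ll
  }
  gmap <- function(theta) {
    c(exp(theta[1]), ages_from_par(theta[-1])[free_nodes])
  }
  theta0 <- c(log(r_hat), best$par)
  age_se <- rep(NA_real_, n + nn)
  age_se[!is.na(pin)] <- 0
  age_se[seq_len(n)] <- 0              # tip ages are data
  rate_se <- NA_real_
  H <- tryCatch(pracma::hessian(negll_full, theta0), error = function(e) NULL)
  if (!is.null(H) && !anyNA(H)) {
    V <- tryCatch(solve(H), error = function(e)
      tryCatch(pracma::pinv(H), error = function(e2) NULL))
    J <- tryCatch(pracma::jacobian(gmap, theta0), error = function(e) NULL)
    if (!is.null(V) && !is.null(J) && !anyNA(J)) {
      W <- J %*% V %*% t(J)
      d <- diag(W)
      d[d < 0] <- NA_real_
      rate_se <- sqrt(d[1])
      if (length(free_nodes)) age_se[free_nodes] <- sqrt(d[-1])
    }
  }
  se <- list(rate_se = rate_se, age_se = age_se)
  structure(list(rate = r_hat, rate_se = se$rate_se, site_count = L,
                 node_ages_ky = ages_hat, node_se_ky = se$age_se,
                 loglik = -best$value, tree = tree,
                 calibrations = calibrations,
                 convergence = best$convergence),
            class = "clock_fit")
}

branch_counts <- function(tree) {
  k <- tree$edge.count
  if (is.null(k)) k <- round(tree$edge.length)
  if (is.null(k)) stop("tree carries no branch mutation counts")
  if (any(k < 0)) stop("negative branch counts")
  as.numeric(k)
}

cal_node <- function(tree, tips) {
  n <- length(tree$tip.label)
  if (identical(tips, "root")) return(n + 1L)
  miss <- setdiff(tips, tree$tip.label)
  if (length(miss)) stop("calibration names unknown tips: ",
                         paste(miss, collapse = ", "))
  if (length(tips) == 1L) return(match(tips, tree$tip.label))
  ape::getMRCA(tree, tips)
}

node_mut_depth <- function(phy, kpost, n, nn) {
  # mean mutation count from each node down to its descendant tips
  depth <- numeric(n + nn)
  wt <- c(rep(1, n), rep(0, nn))
  acc <- numeric(n + nn)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]; ch <- phy$edge[i, 2]
    acc[p] <- acc[p] + acc[ch] + (depth[ch] + kpost[i]) * wt[ch]
    wt[p] <- wt[p] + wt[ch]
    depth[p] <- acc[p] / wt[p]
  }
  depth
}

init_root_age <- function(gauss, pin, root, depth, lb) {
  for (gz in gauss) if (gz$node == root) return(gz$mean)
  if (!is.na(pin[root])) return(pin[root])
  # scale from any calibrated node
  for (gz in gauss) {
    if (depth[gz$node] > 0)
      return(gz$mean * depth[root] / depth[gz$node])
  }
  pinned <- which(!is.na(pin))
  if (length(pinned) && depth[pinned[1]] > 0)
    return(pin[pinned[1]] * depth[root] / depth[pinned[1]])
  max(lb[root] * 2, 1)
}

#' @export
print.clock_fit <- function(x, ...) {
  cat("clock_fit: rate ", format(x$rate, digits = 4),
      " subs/site/Ky (SE ", format(x$rate_se, digits = 3), "), L = ",
      x$site_count, "\n", sep = "")
  n <- length(x$tree$tip.label)
  cat("  root age ", format(x$node_ages_ky[n + 1], digits = 5), " Ky\n",
      sep = "")
  invisible(x)
}

#' Likelihood-ratio test of the molecular clock
#'
#' Compares the free Poisson model (one expected count per branch,
#' maximized at the observed count) against the single-rate clock model
#' (shared rate, ultrametric node ages). The statistic is
#' `2 * (loglik_free - loglik_clock)` with `df = #branches - #clock
#' parameters`, referred to the chi-square upper tail. Requires
#' contemporaneous tips.
#'
#' @param tree Rooted binary `phylo` with branch mutation counts.
#' @return List `statistic`, `df`, `p`.
#' @export
clock_lrt <- function(tree) {
  n <- length(tree$tip.label)
  if (n < 4L) stop("clock LRT needs at least 4 tips")
  k <- branch_counts(tree)
  ll_free <- sum(ifelse(k > 0, k * log(k) - k, 0))
  # clock model: root pinned at an arbitrary scale (rate absorbs it)
  fit <- fit_clock(tree, list(calibration("root", 1000, mode = "fixed")),
                   site_count = 1, n_starts = 3L)
  # remove no gaussian penalty: loglik is the pure Poisson term
  ll_clock <- fit$loglik
  n_par_clock <- tree$Nnode        # (Nnode - 1) free ages + 1 rate
  df <- nrow(tree$edge) - n_par_clock
  if (df <= 0) stop("degenerate tree: non-positive degrees of freedom")
  stat <- max(2 * (ll_free - ll_clock), 0)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Expected waiting time between substitutions
#'
#' `1 / (rate * units)`: with a per-site rate and the number of sites,
#' the mean time separating successive substitutions across the whole
#' sequence.
#'
#' @param rate Substitution rate per site per time unit (> 0).
#' @param units Number of sites (> 0).
#' @return Waiting time in the rate's time unit.
#' @examples
#' waiting_time(3.75e-5, 3790)   # ~7.03 (Ky per synonymous substitution)
#' @export
waiting_time <- function(rate, units) {
  if (rate <= 0 || units <= 0) stop("rate and units must be positive")
  1 / (rate * units)
}

#' Tabulate clade ages from a clock fit
#'
#' One row per named clade: MRCA age (Ky), its SE and the 95% CI
#' computed as `age +/- 1.96 * SE`. Singleton clades are reported with
#' `NA` SE (no internal node of their own). Non-monophyletic clades are
#' flagged but their MRCA age is still reported.
#'
#' @param fit A `clock_fit`.
#' @param clade_defs Named list of tip-label vectors.
#' @return `data.frame` with columns `clade`, `n`, `age_ky`, `se_ky`,
#'   `ci_lo`, `ci_hi`, `monophyletic`.
#' @export
node_age_report <- function(fit, clade_defs) {
  tree <- fit$tree
  n <- length(tree$tip.label)
  rows <- lapply(names(clade_defs), function(nm) {
    tips <- clade_defs[[nm]]
    if (length(tips) == 1L) {
      idx <- match(tips, tree$tip.label)
      return(data.frame(clade = nm, n = 1L,
                        age_ky = fit$node_ages_ky[idx], se_ky = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_,
                        monophyletic = TRUE))
    }
    node <- ape::getMRCA(tree, tips)
    mono <- ape::is.monophyletic(tree, tips)
    if (!mono) warning("clade ", nm, " is not monophyletic; ",
                       "reporting its MRCA age")
    age <- fit$node_ages_ky[node]
    se <- fit$node_se_ky[node]
    data.frame(clade = nm, n = length(tips), age_ky = age, se_ky = se,
               ci_lo = age - 1.96 * se, ci_hi = age + 1.96 * se,
               monophyletic = mono)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a dated tree (ages in Ky as node depths)
#'
#' @param fit A `clock_fit`.
#' @param path Newick output path.
#' @return `path`, invisibly.
#' @export
write_dated_tree <- function(fit, path) {
  tree <- fit$tree
  ages <- fit$node_ages_ky
  tree$edge.length <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
  ape::write.tree(tree, path)
  invisible(path)
}
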