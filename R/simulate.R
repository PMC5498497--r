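# Synthetic data: piecewise-constant coalescent genealogies and
# HKY+Gamma+I sequence evolution with coding/control partitions and a
# tunable purifying-selection knob, giving every pipeline stage a
# known ground truth.

#' Define a piecewise-constant demographic model
#'
#' @param epochs `data.frame` with columns `start`, `end` (years before
#'   present; epochs must tile `[0, Inf)` — first start 0, each end
#'   equal to the next start, last end `Inf`) and `ne` (effective
#'   females, > 0).
#' @param gen_time Generation time in years (default 6).
#' @return Object of class `demographic_model`.
#' @export
demographic_model <- function(epochs, gen_time = 6) {
  stopifnot(all(c("start", "end", "ne") %in% names(epochs)))
  epochs <- epochs[order(epochs$start), , drop = FALSE]
  if (epochs$start[1] != 0) stop("epochs must start at 0")
  if (!is.infinite(epochs$end[nrow(epochs)])) stop("last epoch must end at Inf")
  if (nrow(epochs) > 1 &&
      any(abs(epochs$end[-nrow(epochs)] - epochs$start[-1]) > 1e-9))
    stop("epochs must tile [0, Inf) without gaps or overlap")
  if (any(epochs$ne <= 0)) stop("ne must be positive")
  structure(list(epochs = epochs, gen_time = gen_time),
            class = "demographic_model")
}

ne_at_gen <- function(model, tau) {
  # tau in generations
  yr <- tau * model$gen_time
  i <- findInterval(yr, model$epochs$start)
  model$epochs$ne[pmax(i, 1L)]
}

#' Simulate a coalescent genealogy under piecewise demography
#'
#' Standard backwards-in-time coalescent: with `k` active lineages the
#' coalescence rate is `k(k-1) / (2 Ne(tau))`, with `Ne` read from the
#' epoch active at `tau`; waiting times are drawn piecewise across epoch
#' boundaries. Dated (ancient) tips enter the active set at their ages.
#'
#' @param model A [demographic_model()].
#' @param n_tips Number of tips (>= 2).
#' @param tip_ages Tip ages in years before present (recycled; default
#'   0).
#' @param seed Integer seed.
#' @param labels Optional tip labels (default `t1 ... tn`).
#' @return List with `tree` (rooted `phylo`, branch lengths in years,
#'   element `ages_yr` giving all node ages) and `genealogy`
#'   (a [genealogy()]).
#' @export
simulate_genealogy <- function(model, n_tips, tip_ages = 0, seed = 1L,
                               labels = NULL) {
  if (n_tips < 2L) stop("need at least 2 tips")
  tip_ages <- rep_len(tip_ages, n_tips)
  if (is.null(labels)) labels <- paste0("t", seq_len(n_tips))
  g <- model$gen_time
  bounds_gen <- model$epochs$start / g     # epoch starts, generations
  with_seed(seed, {
    tau <- 0
    pend <- order(tip_ages)                # tips pending entry
    pend_t <- tip_ages[pend] / g
    active <- integer(0)
    nxt <- n_tips + 1L
    ages <- c(tip_ages / g, rep(NA_real_, n_tips - 1L))
    edges <- matrix(0L, 0, 2)
    repeat {
      # admit tips sampled at or before tau
      while (length(pend) && pend_t[1] <= tau + 1e-12) {
        active <- c(active, pend[1])
        pend <- pend[-1]; pend_t <- pend_t[-1]
      }
      k <- length(active)
      if (k <= 1L && !length(pend)) break
      if (k < 2L) {                        # jump to next tip entry
        tau <- pend_t[1]
        next
      }
      limit <- if (length(pend)) pend_t[1] else Inf
      # piecewise-exponential waiting time
      t_ev <- NA_real_
      tt <- tau
      repeat {
        ne <- ne_at_gen(model, tt + 1e-12)
        rate <- k * (k - 1) / (2 * ne)
        nb <- bounds_gen[bounds_gen > tt + 1e-12]
        seg_end <- min(c(nb, Inf)[1], limit)
        w <- stats::rexp(1, rate)
        if (tt + w <= seg_end) { t_ev <- tt + w; break }
        if (seg_end >= limit) break
        tt <- seg_end
      }
      if (is.na(t_ev)) {                   # tip entry reached first
        tau <- limit
        next
      }
      pair <- sample(seq_along(active), 2L)
      parent <- nxt; nxt <- nxt + 1L
      ages[parent] <- t_ev
      edges <- rbind(edges, c(parent, active[pair[1]]),
                     c(parent, active[pair[2]]))
      active <- c(active[-pair], parent)
      tau <- t_ev
    }
    ages_yr <- ages * g
    tree <- edges_to_phylo(edges, n_tips, labels, ages_yr)
    gen <- genealogy(ages_yr[(n_tips + 1L):(2L * n_tips - 1L)],
                     tip_ages, n_tips)
    list(tree = tree, genealogy = gen)
  })
}

# build an ape phylo from (parent, child) edges over ids 1..n (tips)
# and arbitrary internal ids; `ages_yr` indexed by those ids.
# Internal nodes are renumbered preorder from the root (= ape n+1).
edges_to_phylo <- function(edges, n, labels, ages_yr) {
  parents <- unique(edges[, 1])
  root <- setdiff(parents, edges[, 2])
  stopifnot(length(root) == 1L)
  maxid <- max(edges)
  kids <- vector("list", maxid)
  for (i in seq_len(nrow(edges)))
    kids[[edges[i, 1]]] <- c(kids[[edges[i, 1]]], edges[i, 2])
  remap <- integer(maxid)
  remap[seq_len(n)] <- seq_len(n)
  oedge <- matrix(0L, nrow(edges), 2)
  nxt <- n + 1L
  k <- 0L
  ages_new <- numeric(maxid)
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (remap[v] == 0L) { remap[v] <- nxt; nxt <- nxt + 1L }
    ages_new[remap[v]] <- ages_yr[v]
    for (ch in kids[[v]]) {
      if (ch > n && remap[ch] == 0L) { remap[ch] <- nxt; nxt <- nxt + 1L }
      ages_new[remap[ch]] <- ages_yr[ch]
      k <- k + 1L
      oedge[k, ] <- c(remap[v], remap[ch])
      stack <- c(stack, ch)
    }
  }
  phy <- list(edge = oedge, tip.label = labels, Nnode = nxt - n - 1L)
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  phy$edge.length <- ages_new[phy$edge[, 1]] - ages_new[phy$edge[, 2]]
  phy$ages_yr <- ages_new[seq_len(nxt - 1L)]
  phy
}

#' Define an HKY+Gamma+I evolution model
#'
#' @param kappa Transition/transversion rate ratio.
#' @param base_freqs Equilibrium base frequencies (A, C, G, T; sum 1).
#' @param gamma_shape Shape of the discretized Gamma rate heterogeneity.
#' @param n_cat Number of Gamma categories (default 8).
#' @param p_invariant Proportion of invariant sites in `[0, 1)`.
#' @param rate Substitutions per site per year (genome average).
#' @param partition_multipliers Named relative rates, `coding` and
#'   `control`.
#' @param nonsyn_suppression Fraction of attempted non-synonymous
#'   changes rejected (purifying selection knob, `[0, 1]`).
#' @return Object of class `evolution_model`.
#' @export
evolution_model <- function(kappa = 20, base_freqs = c(A = 0.33, C = 0.26,
                                                       G = 0.13, T = 0.28),
                            gamma_shape = 0.5, n_cat = 8L,
                            p_invariant = 0.3, rate = 2e-8,
                            partition_multipliers = c(coding = 1,
                                                      control = 5),
                            nonsyn_suppression = 0.9) {
  stopifnot(abs(sum(base_freqs) - 1) < 1e-8, gamma_shape > 0,
            p_invariant >= 0, p_invariant < 1, rate >= 0, kappa > 0)
  structure(list(kappa = kappa, base_freqs = base_freqs,
                 gamma_shape = gamma_shape, n_cat = as.integer(n_cat),
                 p_invariant = p_invariant, rate = rate,
                 partition_multipliers = partition_multipliers,
                 nonsyn_suppression = nonsyn_suppression),
            class = "evolution_model")
}

# HKY rate matrix normalized to mean rate 1 at equilibrium
hky_matrix <- function(kappa, freqs) {
  bases <- c("A", "C", "G", "T")
  Q <- matrix(0, 4, 4, dimnames = list(bases, bases))
  for (a in 1:4) for (b in 1:4) {
    if (a == b) next
    ts <- paste0(sort(bases[c(a, b)]), collapse = "") %in% c("AG", "CT")
    Q[a, b] <- ifelse(ts, kappa, 1) * freqs[b]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  Q / mu
}

# means of the k equal-probability categories of Gamma(shape, mean 1)
discrete_gamma_means <- function(shape, k) {
  if (k == 1L) return(1)
  q <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape, rate = shape)
  p <- stats::pgamma(q, shape + 1, rate = shape)
  k * diff(p)
}

#' Simulate sequence evolution along a tree
#'
#' Forward simulation of an HKY+Gamma+I process with coding/control
#' partitions on the genome layout given by `genemap`. Protein-coding
#' sites carry codon structure (honouring strand); a configurable
#' fraction of attempted non-synonymous changes is rejected, emulating
#' purifying selection. Substitutions are generated by exact thinning of
#' the per-site Markov jump process, so multiple hits, back mutations
#' and codon-context interactions all occur naturally. True per-branch
#' substitution counts are recorded.
#'
#' @param tree Rooted `phylo` with branch lengths in years.
#' @param evo An [evolution_model()].
#' @param genemap A [gene_map()] tiling positions `1..L`.
#' @param seed Integer seed.
#' @param root_seq Optional root genome (character vector); generated
#'   from the model (stop-free in frame) when `NULL`.
#' @return List with `records` (a [mitogenomes()] of the tip sequences),
#'   `truth` (per-edge data.frame `parent`, `child`, `n_subs`,
#'   `n_coding`, `n_control`), `root_seq`, and `site_info`.
#' @export
simulate_sequences <- function(tree, evo, genemap, seed = 1L,
                               root_seq = NULL) {
  L <- max(genemap$end)
  bases <- c("A", "C", "G", "T")
  info <- genome_site_info(genemap, L)
  with_seed(seed, {
    if (is.null(root_seq)) root_seq <- random_root_genome(genemap, L, evo)
    stopifnot(length(root_seq) == L)
    # per-site rate in subs/yr: partition multiplier x Gamma x invariant
    mult <- ifelse(info$region == "control",
                   evo$partition_multipliers[["control"]],
                   evo$partition_multipliers[["coding"]])
    gmeans <- discrete_gamma_means(evo$gamma_shape, evo$n_cat)
    cat_idx <- sample.int(evo$n_cat, L, replace = TRUE)
    inv <- stats::runif(L) < evo$p_invariant
    site_rate <- evo$rate * mult * gmeans[cat_idx] / (1 - evo$p_invariant)
    site_rate[inv] <- 0
    site_rate[info$is_stop_site] <- 0   # terminal stop codons conserved
    Q <- hky_matrix(evo$kappa, evo$base_freqs)
    leave <- -diag(Q)
    qmax <- max(leave)
    jump_prob <- Q
    diag(jump_prob) <- 0
    jump_prob <- sweep(jump_prob, 1, rowSums(jump_prob), "/")

    phy <- ape::reorder.phylo(tree, "postorder")
    pre <- nrow(phy$edge):1
    n <- length(tree$tip.label)
    maxid <- n + tree$Nnode
    seqs <- vector("list", maxid)
    root <- phy$edge[nrow(phy$edge), 1]
    seqs[[root]] <- root_seq
    n_subs <- integer(nrow(phy$edge))
    n_coding <- integer(nrow(phy$edge))
    n_control <- integer(nrow(phy$edge))
    for (i in pre) {
      p <- phy$edge[i, 1]; ch <- phy$edge[i, 2]
      t_b <- phy$edge.length[i]
      sq <- seqs[[p]]
      if (t_b > 0 && any(site_rate > 0)) {
        nev <- stats::rpois(L, site_rate * qmax * t_b)
        hot <- which(nev > 0L)
        if (length(hot) > 1L) hot <- sample(hot)
        for (s in hot) {
          for (e in seq_len(nev[s])) {
            cur <- match(sq[s], bases)
            if (stats::runif(1) > leave[cur] / qmax) next
            to <- sample.int(4L, 1L, prob = jump_prob[cur, ])
            if (info$is_coding[s]) {
              cls <- change_class(sq, s, bases[to], info)
              if (cls == "nonsense") next    # lethal, always rejected
              if (cls == "missense" &&
                  stats::runif(1) < evo$nonsyn_suppression) next
            }
            sq[s] <- bases[to]
            n_subs[i] <- n_subs[i] + 1L
            if (info$region[s] == "control")
              n_control[i] <- n_control[i] + 1L
            else n_coding[i] <- n_coding[i] + 1L
          }
        }
      }
      seqs[[ch]] <- sq
    }
    tipseqs <- do.call(rbind, seqs[seq_len(n)])
    rownames(tipseqs) <- tree$tip.label
    truth <- data.frame(parent = phy$edge[, 1], child = phy$edge[, 2],
                        n_subs = n_subs, n_coding = n_coding,
                        n_control = n_control)
    list(records = mitogenomes(tipseqs), truth = truth,
         root_seq = root_seq, site_info = info)
  })
}

# per-site annotation: region, coding codon structure
genome_site_info <- function(genemap, L) {
  region <- rep(NA_character_, L)
  is_coding <- logical(L)
  is_stop_site <- logical(L)
  codon_sites <- matrix(NA_integer_, L, 3)   # reading-order positions
  cpos <- integer(L)
  strand <- rep("+", L)
  for (i in seq_len(nrow(genemap))) {
    gm <- genemap[i, ]
    span <- gm$start:gm$end
    region[span] <- switch(gm$kind, protein = "coding",
                           control = "control", "RNA")
    if (gm$kind == "protein") {
      len <- gm$end - gm$start + 1L
      n_cod <- len %/% 3L           # includes the stop codon
      ord <- if (gm$strand == "+") span else rev(span)
      for (ci in seq_len(n_cod)) {
        trio <- ord[(ci - 1L) * 3L + 1:3]
        # the terminal (stop) codon is excluded from suppression
        last <- ci == n_cod
        for (w in 1:3) {
          s <- trio[w]
          if (!last) {
            is_coding[s] <- TRUE
            codon_sites[s, ] <- trio
            cpos[s] <- w
          } else is_stop_site[s] <- TRUE
          strand[s] <- gm$strand
        }
      }
    }
  }
  if (anyNA(region)) stop("gene map does not tile 1..", L)
  list(region = region, is_coding = is_coding, is_stop_site = is_stop_site,
       codon_sites = codon_sites, cpos = cpos, strand = strand)
}

# classify substituting `to` at genome position s: synonymous / missense
# / nonsense (stop gained or lost)
change_class <- function(sq, s, to, info) {
  trio <- info$codon_sites[s, ]
  b <- sq[trio]
  b2 <- b
  b2[info$cpos[s]] <- to
  if (info$strand[s] == "-") {
    b <- complement_base(b)
    b2 <- complement_base(b2)
  }
  aa1 <- translate_mt(paste(b, collapse = ""))
  aa2 <- translate_mt(paste(b2, collapse = ""))
  if (is.na(aa1) || is.na(aa2) || aa1 == "*" || aa2 == "*") return("nonsense")
  if (aa1 == aa2) "synonymous" else "missense"
}

# root genome honouring the map: stop-free codons in protein genes
# (strand aware), iid bases elsewhere, TAA-like stop at each gene end
random_root_genome <- function(genemap, L, evo) {
  bases <- c("A", "C", "G", "T")
  fr <- evo$base_freqs
  out <- sample(bases, L, replace = TRUE, prob = fr)
  codons <- names(mt_code())
  ok <- !is_stop_mt(codons)
  cw <- vapply(codons, function(cd) {
    b <- strsplit(cd, "")[[1]]
    prod(fr[b])
  }, numeric(1))
  sense <- codons[ok]; sw <- cw[ok] / sum(cw[ok])
  stops <- c("TAA", "TAG")
  for (i in which(genemap$kind == "protein")) {
    gm <- genemap[i, ]
    len <- gm$end - gm$start + 1L
    n_cod <- len %/% 3L
    gene_seq <- c(unlist(strsplit(sample(sense, n_cod - 1L, replace = TRUE,
                                         prob = sw), "")),
                  strsplit(sample(stops, 1L), "")[[1]])
    extra <- len - 3L * n_cod        # tolerate non-multiple-of-3 spans
    if (extra > 0L) gene_seq <- c(gene_seq, sample(bases, extra,
                                                   replace = TRUE, prob = fr))
    if (gm$strand == "-")
      gene_seq <- rev(complement_base(gene_seq))
    out[gm$start:gm$end] <- gene_seq
  }
  out
}

#' Generate a complete study-like fixture
#'
#' A self-contained data set shaped like a swamp-buffalo mitogenome
#' study: ~100 contemporary ingroup tips drawn from a
#' bottleneck-then-expansion demography, one divergent river-type
#' outgroup joining the ingroup stem, a distant outgroup pair — one
#' modern and one ancient dated tip — and a root age matching a deep
#' fossil calibration. Returns sequences, metadata, gene map,
#' calibrations and the full truth bundle.
#'
#' @param seed Integer seed; the full fixture is a deterministic
#'   function of it.
#' @param n_ingroup Number of ingroup (swamp-type) tips.
#' @param write_dir Optional directory: writes FASTA, metadata TSV,
#'   genemap TSV, calibration TSV and a truth JSON.
#' @return List with `records`, `genemap`, `calibrations`,
#'   `clade_defs`, `truth` (tree, node ages, per-branch counts, models,
#'   seed).
#' @export
make_study_like_dataset <- function(seed = 42L, n_ingroup = 100L,
                                    write_dir = NULL) {
  demo <- demographic_model(data.frame(
    start = c(0, 3e3, 11e3, 25e3, 130e3, 200e3),
    end = c(3e3, 11e3, 25e3, 130e3, 200e3, Inf),
    ne = c(30000, 1500, 6000, 12000, 15000, 15000)))
  evo <- evolution_model()
  genemap <- study_genemap()

  ing <- simulate_genealogy(demo, n_ingroup, seed = seed,
                            labels = sprintf("SW%03d", seq_len(n_ingroup)))
  t_in <- max(ing$tree$ages_yr)
  # graft: ((ingroup, river) @ 0.9 My, (bos, aurochs) @ 0.1 My) @ 8.8 My
  full <- graft_outgroups(ing$tree, t_river = 9e5, t_bos = 1e5,
                          t_root = 8.8e6, aurochs_age = 6.7e3)
  sim <- simulate_sequences(full$tree, evo, genemap, seed = seed + 1L)
  meta <- data.frame(id = full$tree$tip.label)
  meta$btype <- "swamp"
  meta$btype[meta$id == "RIV01"] <- "river"
  meta$btype[meta$id %in% c("BOS01", "AUR01")] <- "outgroup"
  regions <- c("Yangtze", "SW-China", "SE-China", "Laos", "Thailand",
               "Vietnam")
  meta$population <- NA_character_
  ingrows <- grepl("^SW", meta$id)
  meta$population[ingrows] <- with_seed(seed + 2L,
    sample(regions, sum(ingrows), replace = TRUE))
  meta$tip_age <- 0
  meta$tip_age[meta$id == "AUR01"] <- 6.7e3
  records <- mitogenomes(sim$records$seq, meta)

  calibrations <- list(
    calibration("root", 8.8e6, 1.1e6, "gaussian"),
    calibration("AUR01", 6.7e3, 0.2e3, "gaussian"))
  clade_defs <- list(
    ingroup = meta$id[ingrows],
    buffalo = meta$id[meta$btype %in% c("swamp", "river")])
  truth <- list(tree = full$tree, ages_yr = full$tree$ages_yr,
                branch_counts = sim$truth, demography = demo,
                evolution = evo, ingroup_tmrca_yr = t_in, seed = seed)
  out <- list(records = records, genemap = genemap,
              calibrations = calibrations, clade_defs = clade_defs,
              truth = truth)
  if (!is.null(write_dir)) {
    dir.create(write_dir, recursive = TRUE, showWarnings = FALSE)
    write_alignment(records, file.path(write_dir, "alignment.fa"))
    utils::write.table(meta, file.path(write_dir, "metadata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_genemap(genemap, file.path(write_dir, "genemap.tsv"))
    cal_df <- data.frame(
      target = c("root", "AUR01"), age_yr = c(8.8e6, 6.7e3),
      sd_yr = c(1.1e6, 0.2e3), mode = "gaussian")
    utils::write.table(cal_df, file.path(write_dir, "calibrations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed, ingroup_tmrca_yr = t_in,
           branch_counts = sim$truth,
           demography = demo$epochs),
      file.path(write_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

# 13 protein genes (one minus-strand, ND6-like) summing to 3790 sense
# codons after stop removal, an rRNA block and a control region
study_genemap <- function() {
  codons <- c(318, 346, 322, 434, 513, 227, 68, 95, 459, 98, 304, 475, 131)
  stopifnot(sum(codons) == 3790)
  names(codons) <- c("ND1", "ND2", "COX1", "COX2", "ATP6", "COX3", "ATP8",
                     "ND3", "ND4", "ND4L", "ND5", "CYTB", "ND6")
  lens <- (codons + 1L) * 3L       # + stop codon
  start <- cumsum(c(1L, lens[-length(lens)]))
  end <- start + lens - 1L
  strand <- rep("+", 13)
  strand[names(codons) == "ND6"] <- "-"
  prot <- data.frame(name = names(codons), start = start, end = end,
                     strand = strand, kind = "protein")
  rrna_start <- max(end) + 1L
  rrna <- data.frame(name = "rRNA", start = rrna_start,
                     end = rrna_start + 2499L, strand = "+", kind = "rRNA")
  ctl <- data.frame(name = "CR", start = rrna$end + 1L,
                    end = rrna$end + 900L, strand = "+", kind = "control")
  gene_map(rbind(prot, rrna, ctl), reference_id = "SW001")
}

# attach river + (bos, aurochs) outgroups above an ingroup tree
graft_outgroups <- function(ingroup, t_river, t_bos, t_root, aurochs_age) {
  n_in <- length(ingroup$tip.label)
  ages_in <- ingroup$ages_yr
  n <- n_in + 3L                     # + RIV01, BOS01, AUR01
  # rebuild edge list over temporary ids: tips 1..n, internals beyond
  shift <- function(v) ifelse(v <= n_in, v, v + 3L)
  edges <- cbind(shift(ingroup$edge[, 1]), shift(ingroup$edge[, 2]))
  ages <- c(ages_in[seq_len(n_in)], 0, 0, aurochs_age,
            ages_in[(n_in + 1L):length(ages_in)])
  riv <- n_in + 1L; bos <- n_in + 2L; aur <- n_in + 3L
  nxt <- n + ingroup$Nnode + 1L
  a_node <- nxt; b_node <- nxt + 1L; r_node <- nxt + 2L
  in_root <- n_in + 3L + 1L          # old root n_in+1 shifted by 3
  edges <- rbind(edges,
                 c(a_node, in_root), c(a_node, riv),
                 c(b_node, bos), c(b_node, aur),
                 c(r_node, a_node), c(r_node, b_node))
  ages <- c(ages, t_river, t_bos, t_root)
  labels <- c(ingroup$tip.label, "RIV01", "BOS01", "AUR01")
  tree <- edges_to_phylo(edges, n, labels, ages)
  list(tree = tree)
}
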