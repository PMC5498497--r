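# Maximum-parsimony machinery: Fitch scoring on bit-encoded states,
# exact branch-and-bound for small taxon sets, stepwise-addition +
# NNI/SPR hill climbing otherwise, and Fitch backtrace mutation mapping.

.BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L)

# encode base characters as bit sets; gap/N/anything else = wildcard 15
encode_bits <- function(mat) {
  b <- matrix(15L, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  for (nm in names(.BITS)) b[mat == nm] <- .BITS[[nm]]
  b
}

bit_to_base <- function(bit) {
  # deterministic representative: lowest set bit, alphabetical order
  c("A", "C", "A", "G", "A", "C", "A", "T", "A", "C", "A", "G", "A", "C",
    "A")[bit]
}

# ---- oriented Fitch up-pass -------------------------------------------------
# oedge: 2-column matrix (parent, child) in postorder (children before
# parents); bits: matrix with rows indexed by node id (tips filled).
# Sequential folding of children = exact Fitch on binary trees; on
# polytomies it is the usual soft-polytomy approximation.
fitch_up <- function(oedge, bits, maxid) {
  nc <- ncol(bits)
  state <- matrix(NA_integer_, maxid, nc)
  tip_rows <- seq_len(nrow(bits))
  state[tip_rows, ] <- bits
  changes <- numeric(nc)
  seen <- logical(maxid)
  for (i in seq_len(nrow(oedge))) {
    p <- oedge[i, 1]; ch <- oedge[i, 2]
    if (!seen[p]) {
      state[p, ] <- state[ch, ]
      seen[p] <- TRUE
    } else {
      inter <- bitwAnd(state[p, ], state[ch, ])
      z <- inter == 0L
      if (any(z)) {
        inter[z] <- bitwOr(state[p, z], state[ch, z])
        changes[z] <- changes[z] + 1L
      }
      state[p, ] <- inter
    }
  }
  list(state = state, changes = changes)
}

# ---- unrooted search trees --------------------------------------------------
# tips are ids 1..n_all (indices into the label vector); internal nodes
# get ids above n_all.
utree_init <- function(t1, t2, t3, n_all) {
  x <- n_all + 1L
  list(edge = rbind(c(x, t1), c(x, t2), c(x, t3)),
       n_all = n_all, next_node = x + 1L)
}

utree_add_tip <- function(ut, tip, edge_i) {
  u <- ut$edge[edge_i, 1]; v <- ut$edge[edge_i, 2]
  w <- ut$next_node
  ut$edge[edge_i, ] <- c(u, w)
  ut$edge <- rbind(ut$edge, c(w, v), c(w, tip))
  ut$next_node <- w + 1L
  ut
}

# orient edges away from `root` (an internal node id); returns postorder
# parent->child edge matrix
orient_utree <- function(edge, root) {
  maxid <- max(edge)
  # adjacency
  from <- c(edge[, 1], edge[, 2])
  to <- c(edge[, 2], edge[, 1])
  ord <- order(from)
  from_s <- from[ord]; to_s <- to[ord]
  starts <- c(1L, which(diff(from_s) > 0L) + 1L)
  idx_of <- integer(maxid)
  cnt <- integer(maxid)
  idx_of[from_s[starts]] <- starts
  tb <- tabulate(from_s, maxid)
  # iterative DFS
  n_edges <- nrow(edge)
  oedge <- matrix(0L, n_edges, 2)
  pos <- n_edges
  stack <- integer(maxid + 1L); sp <- 1L; stack[1] <- root
  parent <- integer(maxid)
  pre <- integer(maxid); np <- 0L
  while (sp > 0L) {
    v <- stack[sp]; sp <- sp - 1L
    np <- np + 1L; pre[np] <- v
    if (tb[v]) {
      nb <- to_s[idx_of[v] + 0:(tb[v] - 1L)]
      for (w in nb) {
        if (w != parent[v]) {
          parent[w] <- v
          sp <- sp + 1L; stack[sp] <- w
        }
      }
    }
  }
  # postorder edges = reverse preorder of non-root nodes
  k <- 0L
  for (i in np:1) {
    v <- pre[i]
    if (v != root) {
      k <- k + 1L
      oedge[k, ] <- c(parent[v], v)
    }
  }
  oedge
}


# any internal node, safe as a traversal root (tips can drift into
# edge[1,1] after NNI/SPR edits)
utree_root <- function(ut) {
  v <- as.vector(ut$edge)
  v[v > ut$n_all][1]
}
utree_fitch <- function(ut, bits) {
  root <- utree_root(ut)
  oedge <- orient_utree(ut$edge, root)
  sum(fitch_up(oedge, bits, max(ut$edge))$changes)
}

# tip-id set on the child side of every edge (unrooted splits)
utree_splits <- function(ut) {
  root <- utree_root(ut)
  oedge <- orient_utree(ut$edge, root)
  maxid <- max(ut$edge)
  below <- vector("list", maxid)
  for (i in seq_len(nrow(oedge))) {
    ch <- oedge[i, 2]
    if (is.null(below[[ch]])) below[[ch]] <- ch  # tip
  }
  for (i in seq_len(nrow(oedge))) {
    p <- oedge[i, 1]; ch <- oedge[i, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  lapply(seq_len(nrow(oedge)), function(i) sort(below[[oedge[i, 2]]]))
}

# are all constraints (lists of tip ids) monophyletic among present tips?
utree_constraints_ok <- function(ut, constraints, present) {
  active <- Filter(function(s) {
    s2 <- intersect(s, present)
    length(s2) >= 2L && length(s2) < length(present)
  }, constraints)
  if (!length(active)) return(TRUE)
  splits <- utree_splits(ut)
  splits <- lapply(splits, function(s) s[s <= ut$n_all])
  pres <- sort(present)
  for (s in active) {
    s2 <- sort(intersect(s, pres))
    comp <- setdiff(pres, s2)
    hit <- any(vapply(splits, function(sp)
      identical(sp, s2) || identical(sp, comp), logical(1)))
    if (!hit) return(FALSE)
  }
  TRUE
}

ut_to_phylo <- function(ut, labels) {
  n <- ut$n_all
  root_old <- utree_root(ut)
  oedge <- orient_utree(ut$edge, root_old)
  pre <- oedge[nrow(oedge):1, , drop = FALSE]   # preorder parent->child
  remap <- integer(max(ut$edge))
  remap[seq_len(n)] <- seq_len(n)
  remap[root_old] <- n + 1L
  nxt <- n + 2L
  for (i in seq_len(nrow(pre))) {
    ch <- pre[i, 2]
    if (ch > n) { remap[ch] <- nxt; nxt <- nxt + 1L }
  }
  phy <- list(edge = matrix(remap[pre], ncol = 2),
              tip.label = labels, Nnode = nxt - n - 1L)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

# ---- exported operations ----------------------------------------------------

#' Fitch parsimony length of a topology
#'
#' Minimal substitution count of an alignment on a fixed (rooted or
#' unrooted) topology via the Fitch algorithm; gaps and `N` are treated
#' as missing (full wildcard). Exact on binary trees; polytomies are
#' folded child-by-child (soft-polytomy approximation).
#'
#' @param tree A `phylo` whose tip labels appear as row names of `x`.
#' @param x Character matrix of aligned bases (rows = taxa), a
#'   [mitogenomes()] object, or a `coding_alignment`.
#' @return Integer substitution count.
#' @export
fitch_length <- function(tree, x) {
  mat <- sequence_matrix(x)
  miss <- setdiff(tree$tip.label, rownames(mat))
  if (length(miss)) stop("leaf without sequence: ",
                         paste(miss, collapse = ", "))
  mat <- mat[tree$tip.label, , drop = FALSE]
  bits <- encode_bits(mat)
  phy <- ape::reorder.phylo(tree, "postorder")
  up <- fitch_up(phy$edge, bits, max(phy$edge))
  as.integer(sum(up$changes))
}

sequence_matrix <- function(x) {
  if (inherits(x, "mitogenomes")) return(x$seq)
  if (inherits(x, "coding_alignment")) return(x$seq)
  if (is.matrix(x)) return(x)
  stop("cannot interpret sequences")
}

#' Maximum-parsimony tree search
#'
#' For up to `exact_max` taxa the optimum is found by branch-and-bound
#' over addition trees (ties resolved toward the lexicographically
#' smallest canonical newick). Larger problems use randomized stepwise
#' addition (seeded, outgroup taxa placed first) followed by NNI and
#' SPR hill climbing. Monophyly constraints are honoured throughout:
#' trees violating a constraint are rejected.
#'
#' @param x Sequences (see [fitch_length()]).
#' @param constraints List of character vectors of tip labels, each
#'   required to be monophyletic. Overlapping, non-nested constraints
#'   are an error.
#' @param outgroup Character vector of outgroup tip labels; the returned
#'   tree is rooted on them.
#' @param seed Integer seed controlling the stepwise addition order.
#' @param exact_max Maximum taxon count for exact branch-and-bound.
#' @param spr_rounds Maximum SPR improvement sweeps.
#' @return Rooted `phylo` with attribute `pscore` (tree length).
#' @export
mp_search <- function(x, constraints = list(), outgroup = NULL, seed = 1L,
                      exact_max = 8L, spr_rounds = 3L) {
  mat <- sequence_matrix(x)
  n <- nrow(mat)
  if (n < 3L) stop("need at least 3 sequences")
  labels <- rownames(mat)
  if (is.null(labels)) stop("sequences must be named")
  check_constraints(constraints, labels, outgroup)
  cons_ids <- lapply(constraints, function(s) match(s, labels))
  bits_full <- encode_bits(mat)
  varc <- which(apply(bits_full, 2, function(b) {
    obs <- b[b != 15L]
    length(obs) && length(unique(obs)) > 1L
  }))
  bits <- bits_full[, varc, drop = FALSE]
  if (ncol(bits) == 0L) bits <- matrix(1L, n, 1L)  # invariant data

  if (n <= exact_max) {
    res <- bb_search(bits, n, cons_ids, labels)
    ut <- res$ut
  } else {
    ut <- heuristic_search(bits, n, cons_ids, labels, outgroup, seed,
                           spr_rounds)
  }
  len <- utree_fitch(ut, bits)
  phy <- ut_to_phylo(ut, labels)
  if (!is.null(outgroup)) {
    phy <- tryCatch(
      ape::root(phy, outgroup = outgroup, resolve.root = TRUE),
      error = function(e) {
        warning("outgroup not monophyletic in the optimal tree; ",
                "rooting on '", outgroup[1], "'")
        ape::root(phy, outgroup = outgroup[1], resolve.root = TRUE)
      })
  }
  attr(phy, "pscore") <- len
  phy
}

check_constraints <- function(constraints, labels, outgroup = NULL) {
  for (s in constraints) {
    miss <- setdiff(s, labels)
    if (length(miss)) stop("constraint names unknown tips: ",
                           paste(miss, collapse = ", "))
  }
  k <- length(constraints)
  if (k > 1L) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      a <- constraints[[i]]; b <- constraints[[j]]
      inter <- intersect(a, b)
      if (length(inter) && !(all(a %in% b) || all(b %in% a)))
        stop("mutually inconsistent constraints: overlap without nesting")
    }
  }
  invisible(TRUE)
}

# exact branch-and-bound with canonical-newick tie-breaking; partial
# trees are pruned only when strictly worse than the incumbent so that
# all equally parsimonious completions are still visited
bb_search <- function(bits, n, cons_ids, labels) {
  present_all <- seq_len(n)
  best <- list(len = Inf, ut = NULL, canon = "~")
  recurse2 <- function(ut, next_tip) {
    len <- utree_fitch(ut, bits)
    if (len > best$len) return()
    if (next_tip > n) {
      if (!utree_constraints_ok(ut, cons_ids, present_all)) return()
      canon <- canonical_newick(ut, labels)
      if (len < best$len ||
          (len == best$len && canon < best$canon)) {
        best <<- list(len = len, ut = ut, canon = canon)
      }
      return()
    }
    for (i in seq_len(nrow(ut$edge))) {
      recurse2(utree_add_tip(ut, next_tip, i), next_tip + 1L)
    }
  }
  recurse2(utree_init(1L, 2L, 3L, n), 4L)
  if (is.null(best$ut)) stop("no tree satisfies the constraints")
  best
}

canonical_newick <- function(ut, labels) {
  root <- utree_root(ut)
  oedge <- orient_utree(ut$edge, root)
  maxid <- max(ut$edge)
  rep_str <- character(maxid)
  for (i in seq_len(nrow(oedge))) {
    ch <- oedge[i, 2]
    if (ch <= ut$n_all) rep_str[ch] <- labels[ch]
  }
  kids <- split(oedge[, 2], oedge[, 1])
  build <- function(v) {
    if (v <= ut$n_all) return(rep_str[v])
    parts <- sort(vapply(kids[[as.character(v)]], build, character(1)))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  build(root)
}

heuristic_search <- function(bits, n, cons_ids, labels, outgroup, seed,
                             spr_rounds) {
  og_ids <- if (is.null(outgroup)) integer() else match(outgroup, labels)
  with_seed(seed, {
    in_ids <- setdiff(seq_len(n), og_ids)
    order_ids <- c(og_ids, sample(in_ids))
    ut <- utree_init(order_ids[1], order_ids[2], order_ids[3], n)
    present <- order_ids[1:3]
    for (t in order_ids[-(1:3)]) {
      cand <- lapply(seq_len(nrow(ut$edge)), function(i)
        utree_add_tip(ut, t, i))
      lens <- vapply(cand, utree_fitch, numeric(1), bits = bits)
      present2 <- c(present, t)
      ok <- FALSE
      for (i in order(lens)) {
        if (utree_constraints_ok(cand[[i]], cons_ids, present2)) {
          ut <- cand[[i]]; ok <- TRUE; break
        }
      }
      if (!ok) stop("stepwise addition blocked by constraints")
      present <- present2
    }
    ut <- nni_climb(ut, bits, cons_ids, present)
    for (r in seq_len(spr_rounds)) {
      res <- spr_sweep(ut, bits, cons_ids, present)
      if (!res$improved) break
      ut <- nni_climb(res$ut, bits, cons_ids, present)
    }
    ut
  })
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  force(expr)
}

nni_neighbors <- function(ut) {
  n <- ut$n_all
  internal_rows <- which(ut$edge[, 1] > n & ut$edge[, 2] > n)
  out <- list()
  for (r in internal_rows) {
    u <- ut$edge[r, 1]; v <- ut$edge[r, 2]
    ur <- which((ut$edge[, 1] == u | ut$edge[, 2] == u) &
                  seq_len(nrow(ut$edge)) != r)
    vr <- which((ut$edge[, 1] == v | ut$edge[, 2] == v) &
                  seq_len(nrow(ut$edge)) != r)
    if (length(ur) < 1L || length(vr) < 1L) next
    swap <- function(row_a, node_a, row_b, node_b) {
      e <- ut$edge
      e[row_a, ][e[row_a, ] == node_a] <- node_b
      e[row_b, ][e[row_b, ] == node_b] <- node_a
      u2 <- ut; u2$edge <- e; u2
    }
    a_row <- ur[1]
    a_node <- setdiff(ut$edge[a_row, ], u)
    for (br in vr) {
      b_node <- setdiff(ut$edge[br, ], v)
      out[[length(out) + 1L]] <- swap(a_row, a_node, br, b_node)
    }
  }
  out
}

nni_climb <- function(ut, bits, cons_ids, present) {
  cur_len <- utree_fitch(ut, bits)
  repeat {
    nb <- nni_neighbors(ut)
    if (!length(nb)) break
    lens <- vapply(nb, utree_fitch, numeric(1), bits = bits)
    improved <- FALSE
    for (i in order(lens)) {
      if (lens[i] >= cur_len) break
      if (utree_constraints_ok(nb[[i]], cons_ids, present)) {
        ut <- nb[[i]]; cur_len <- lens[i]; improved <- TRUE; break
      }
    }
    if (!improved) break
  }
  ut
}

spr_sweep <- function(ut, bits, cons_ids, present) {
  cur_len <- utree_fitch(ut, bits)
  best <- list(ut = ut, len = cur_len)
  ne <- nrow(ut$edge)
  for (r in seq_len(ne)) {
    pr <- spr_prune(ut, r)
    if (is.null(pr)) next
    for (j in seq_len(nrow(pr$rest$edge))) {
      cand <- spr_regraft(pr, j)
      len <- utree_fitch(cand, bits)
      if (len < best$len &&
          utree_constraints_ok(cand, cons_ids, present)) {
        best <- list(ut = cand, len = len)
      }
    }
  }
  list(ut = best$ut, improved = best$len < cur_len)
}

# detach the subtree hanging below edge r (child side); returns the
# remaining tree (with the freed attachment node spliced out) plus the
# subtree edges and its root node id
spr_prune <- function(ut, r) {
  u <- ut$edge[r, 1]; v <- ut$edge[r, 2]
  ne <- nrow(ut$edge)
  # prune the v-side subtree; requires the attachment node u internal
  if (u <= ut$n_all) { tmp <- u; u <- v; v <- tmp }
  in_sub <- reachable_without(ut$edge, v, r)
  sub_rows <- which(apply(ut$edge, 1, function(e)
    all(e %in% in_sub)))
  rest_rows <- setdiff(seq_len(ne), c(sub_rows, r))
  rest_edge <- ut$edge[rest_rows, , drop = FALSE]
  # splice out u (now degree 2 in rest) unless u is a tip
  if (u <= ut$n_all) return(NULL)
  urows <- which(rest_edge[, 1] == u | rest_edge[, 2] == u)
  if (length(urows) != 2L) return(NULL)  # u was the basal node; skip
  nb <- c(setdiff(rest_edge[urows[1], ], u), setdiff(rest_edge[urows[2], ], u))
  rest_edge[urows[1], ] <- nb
  rest_edge <- rest_edge[-urows[2], , drop = FALSE]
  rest <- ut; rest$edge <- rest_edge
  list(rest = rest, sub_rows = sub_rows,
       sub_edge = ut$edge[sub_rows, , drop = FALSE],
       sub_root = v, attach = u, full = ut)
}

reachable_without <- function(edge, start, skip_row) {
  maxid <- max(edge)
  seen <- logical(maxid)
  seen[start] <- TRUE
  stack <- start
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    rows <- which((edge[, 1] == v | edge[, 2] == v))
    rows <- setdiff(rows, skip_row)
    for (rr in rows) {
      w <- setdiff(edge[rr, ], v)
      if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
    }
  }
  which(seen)
}

spr_regraft <- function(pr, rest_edge_row) {
  rest <- pr$rest
  u <- pr$attach   # reuse the freed internal node id
  p <- rest$edge[rest_edge_row, 1]; q <- rest$edge[rest_edge_row, 2]
  new_edge <- rest$edge
  new_edge[rest_edge_row, ] <- c(p, u)
  new_edge <- rbind(new_edge, c(u, q), c(u, pr$sub_root), pr$sub_edge)
  out <- rest
  out$edge <- new_edge
  out$next_node <- pr$full$next_node
  out
}

#' Map mutations onto tree branches by Fitch backtrace
#'
#' Runs the Fitch up-pass and a deterministic down-pass (final state =
#' the parent's state whenever it is contained in a node's state set;
#' root ties broken toward the supplied ancestral base, else
#' alphabetically) and records, per branch, the columns that change and
#' their from/to bases. The per-column assignment count always equals
#' the column's Fitch count, so the branch counts sum to the tree
#' length.
#'
#' @param tree Rooted `phylo` (tips matching rows of `x`).
#' @param x Sequences (see [fitch_length()]).
#' @param ancestral Optional `ancestral_assignment` (or character vector
#'   of bases, one per column) used to break root-state ties.
#' @return The tree with `edge.length` set to per-branch mutation counts
#'   and extra elements `edge.count` (integer vector) and `mutations`
#'   (list of data.frames `column`, `from`, `to` per edge row).
#' @export
assign_branch_mutations <- function(tree, x, ancestral = NULL) {
  mat <- sequence_matrix(x)
  mat <- mat[tree$tip.label, , drop = FALSE]
  bits <- encode_bits(mat)
  nc <- ncol(bits)
  if (inherits(ancestral, "ancestral_assignment")) ancestral <- ancestral$bases
  anc_bits <- if (is.null(ancestral)) rep(15L, nc) else {
    ab <- .BITS[ancestral]
    ab[is.na(ab)] <- 15L
    as.integer(ab)
  }
  phy <- ape::reorder.phylo(tree, "postorder")
  up <- fitch_up(phy$edge, bits, max(phy$edge))
  state <- up$state
  n <- length(tree$tip.label)
  root <- phy$edge[nrow(phy$edge), 1]
  final <- matrix(NA_integer_, max(phy$edge), nc)
  rs <- state[root, ]
  pref <- bitwAnd(rs, anc_bits)
  rs_final <- ifelse(pref > 0L, lowest_bit(pref), lowest_bit(rs))
  final[root, ] <- rs_final
  # preorder = reverse postorder
  for (i in nrow(phy$edge):1) {
    p <- phy$edge[i, 1]; ch <- phy$edge[i, 2]
    fs <- state[ch, ]
    pf <- final[p, ]
    keep <- bitwAnd(fs, pf) > 0L
    out <- integer(nc)
    out[keep] <- pf[keep]
    if (any(!keep)) {
      cand <- fs[!keep]
      prefc <- bitwAnd(cand, anc_bits[!keep])
      out[!keep] <- ifelse(prefc > 0L, lowest_bit(prefc), lowest_bit(cand))
    }
    final[ch, ] <- out
  }
  counts <- integer(nrow(phy$edge))
  muts <- vector("list", nrow(phy$edge))
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]; ch <- phy$edge[i, 2]
    d <- which(final[p, ] != final[ch, ])
    counts[i] <- length(d)
    muts[[i]] <- data.frame(column = d,
                            from = bit_to_base(final[p, d]),
                            to = bit_to_base(final[ch, d]))
  }
  # map back to the input tree's edge order
  key_in <- paste(tree$edge[, 1], tree$edge[, 2])
  key_post <- paste(phy$edge[, 1], phy$edge[, 2])
  m <- match(key_in, key_post)
  tree$edge.length <- as.numeric(counts[m])
  tree$edge.count <- counts[m]
  tree$mutations <- muts[m]
  tree$node.state <- final
  tree
}

lowest_bit <- function(b) {
  bitwAnd(b, bitwNot(b - 1L))
}

# Fitch root state per column for a whole alignment (used for ancestral
# inference); `prefer` breaks ties when it intersects the root set.
fitch_root_state <- function(tree, mat, prefer = NULL) {
  mat <- mat[tree$tip.label, , drop = FALSE]
  bits <- encode_bits(mat)
  phy <- ape::reorder.phylo(tree, "postorder")
  up <- fitch_up(phy$edge, bits, max(phy$edge))
  root <- phy$edge[nrow(phy$edge), 1]
  rs <- up$state[root, ]
  pref_bits <- if (is.null(prefer)) rep(0L, ncol(bits)) else {
    pb <- .BITS[prefer]
    pb[is.na(pb)] <- 0L
    as.integer(pb)
  }
  inter <- bitwAnd(rs, pref_bits)
  pick <- ifelse(inter > 0L, lowest_bit(inter), lowest_bit(rs))
  out <- bit_to_base(pick)
  out[rs == 15L] <- NA_character_   # wholly missing column
  out
}
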