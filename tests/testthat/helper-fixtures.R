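# shared fixture builders (all data generated in code)

# toy genome: gene g1 (+) = ATG GGA TAA, gene g2 (-) = revcomp of
# ATG CTA TAG, 4-base control region
toy_reference <- function() {
  g2 <- rev(c(A = "T", C = "G", G = "C", T = "A")[
    c("A", "T", "G", "C", "T", "A", "T", "A", "G")])
  c("A", "T", "G", "G", "G", "A", "T", "A", "A", unname(g2),
    "C", "C", "C", "C")
}

toy_genemap <- function() {
  gene_map(data.frame(name = c("g1", "g2", "cr"),
                      start = c(1, 10, 19), end = c(9, 18, 22),
                      strand = c("+", "-", "+"),
                      kind = c("protein", "protein", "control")),
           reference_id = "ref")
}

random_base_matrix <- function(n, L, with_names = TRUE) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
  if (with_names) rownames(m) <- paste0("t", seq_len(n))
  m
}

# independent brute-force piecewise coalescent log-likelihood:
# scalar time stepping over a merged, fully subdivided timeline
oracle_coalescent_loglik <- function(gen, ne, breaks, gen_time) {
  samp <- sort(gen$samp_times) / gen_time
  coal <- sort(gen$coal_times) / gen_time
  br <- breaks / gen_time
  ne_at <- function(tau) {
    i <- sum(br < tau)       # boundary events belong to the earlier epoch
    ne[i + 1L]
  }
  pts <- sort(unique(c(samp, coal, br)))
  ll <- 0
  for (j in seq_len(length(pts) - 1L)) {
    t0 <- pts[j]; t1 <- pts[j + 1L]
    k <- sum(samp <= t0 + 1e-12) - sum(coal <= t0 + 1e-12)
    if (k >= 2) {
      # integrate over [t0, t1]; Ne constant there by construction
      ll <- ll - k * (k - 1) / (2 * ne_at((t0 + t1) / 2)) * (t1 - t0)
    }
  }
  for (tc in coal) ll <- ll - log(ne_at(tc))
  ll
}

# compact genemap for sequence simulation: two plus-strand genes, one
# minus-strand gene (all with stop codons), and a control region
toy_study_genemap <- function() {
  gene_map(data.frame(
    name = c("gA", "gB", "gC", "cr"),
    start = c(1, 151, 301, 451),
    end = c(150, 300, 450, 600),
    strand = c("+", "+", "-", "+"),
    kind = c("protein", "protein", "protein", "control")),
    reference_id = "t1")
}

codon_strings <- function(v) {
  stopifnot(length(v) %% 3 == 0)
  paste0(v[c(TRUE, FALSE, FALSE)], v[c(FALSE, TRUE, FALSE)],
         v[c(FALSE, FALSE, TRUE)])
}

random_genealogy <- function(n_tips, serial = FALSE) {
  samp <- if (serial) c(0, sort(stats::runif(n_tips - 1L, 0, 50)))
    else rep(0, n_tips)
  coal <- numeric(n_tips - 1L)
  t <- max(samp)
  for (i in seq_len(n_tips - 1L)) {
    t <- t + stats::rexp(1, 1 / 30)
    coal[i] <- t
  }
  genealogy(coal, samp)
}
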