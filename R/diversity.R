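#' Haplotype diversity (Hd)
#'
#' `Hd = n/(n-1) * (1 - sum(p_i^2))` with `p_i` the sample frequency of
#' haplotype `i` — the probability that two randomly drawn records carry
#' different haplotypes, with the small-sample correction.
#'
#' @param table A `haplotype_table` from [collapse_haplotypes()], or an
#'   integer vector of haplotype member counts.
#' @return Hd in `[0, 1]`.
#' @export
haplotype_diversity <- function(table) {
  counts <- if (inherits(table, "haplotype_table"))
    table$haplotypes$n_members else as.integer(table)
  n <- sum(counts)
  if (n < 2L) stop("haplotype diversity undefined for n < 2")
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Pairwise difference statistics and nucleotide diversity
#'
#' Counts substitution differences over all record pairs with pairwise
#' deletion: for each pair, columns where either sequence carries a gap
#' or `N` are skipped. The effective length used for the per-site
#' diversity is the number of alignment columns whose consensus
#' (most frequent character) is a base, i.e. non-indel columns of the
#' consensus. `pi_percent` is `100 * mean_pairwise / effective_length`;
#' the raw per-site value is also returned.
#'
#' @param x A [mitogenomes()] object (or character matrix of bases).
#' @param mask Optional logical vector (length = alignment columns);
#'   `FALSE` columns are excluded throughout.
#' @return List with `mean_pairwise`, `sd_pairwise` (population SD over
#'   the C(n,2) pair values), `pi_percent`, `pi`, `S` (segregating
#'   sites), `effective_length`, `n_pairs`.
#' @export
pairwise_stats <- function(x, mask = NULL) {
  mat <- if (inherits(x, "mitogenomes")) x$seq else x
  n <- nrow(mat)
  if (n < 2L) stop("need at least two records")
  if (!is.null(mask)) {
    stopifnot(length(mask) == ncol(mat))
    mat <- mat[, mask, drop = FALSE]
  }
  if (ncol(mat) == 0L) stop("all columns masked")
  bases <- c("A", "C", "G", "T")
  # consensus-based effective length
  cons_is_base <- apply(mat, 2, function(cc) {
    tb <- sort(table(cc), decreasing = TRUE)
    names(tb)[1] %in% bases
  })
  eff_len <- sum(cons_is_base)
  if (eff_len == 0L) stop("no usable columns after masking")
  # segregating sites: >= 2 distinct bases among A/C/G/T
  nb <- apply(mat, 2, function(cc) length(unique(cc[cc %in% bases])))
  S <- sum(nb >= 2L)
  # pair differences only ever occur at variable columns
  var_cols <- which(nb >= 2L)
  vm <- mat[, var_cols, drop = FALSE]
  pairs <- utils::combn(n, 2)
  d <- apply(pairs, 2, function(pr) {
    a <- vm[pr[1], ]; b <- vm[pr[2], ]
    ok <- a %in% bases & b %in% bases
    sum(a[ok] != b[ok])
  })
  m <- mean(d)
  list(mean_pairwise = m,
       sd_pairwise = sqrt(mean((d - m)^2)),
       pi_percent = 100 * m / eff_len,
       pi = m / eff_len,
       S = S,
       effective_length = eff_len,
       n_pairs = ncol(pairs))
}

#' Per-site nucleotide diversity as a percentage
#'
#' Arithmetic helper: `100 * mean_pairwise / effective_length`.
#'
#' @param mean_pairwise Mean pairwise difference count.
#' @param effective_length Number of sites compared.
#' @return Percent per-site diversity.
#' @export
pi_percent <- function(mean_pairwise, effective_length) {
  if (effective_length <= 0) stop("effective_length must be positive")
  100 * mean_pairwise / effective_length
}

#' Synonymous / non-synonymous substitution ratio
#'
#' Counts distinct coding substitutions — distinct by `(position,
#' alternate allele)` — classified synonymous vs non-synonymous, and
#' returns their ratio. With zero non-synonymous changes the ratio is
#' `Inf` (with a warning).
#'
#' @param variant_sets A list of variant data.frames (e.g. the
#'   `variants` element of a `haplotype_table`), or a single data.frame.
#' @return List with `ratio`, `n_syn`, `n_nonsyn`.
#' @export
syn_nonsyn_ratio <- function(variant_sets) {
  if (is.data.frame(variant_sets)) variant_sets <- list(variant_sets)
  all_v <- do.call(rbind, variant_sets)
  cod <- all_v[!is.na(all_v$effect) &
                 all_v$effect %in% c("synonymous", "nonsynonymous"), ,
               drop = FALSE]
  if (nrow(cod) == 0L) stop("no classified coding variants")
  key <- paste0(cod$pos, ":", cod$alt)
  first <- !duplicated(key)
  n_syn <- sum(cod$effect[first] == "synonymous")
  n_non <- sum(cod$effect[first] == "nonsynonymous")
  if (n_non == 0L) {
    warning("no non-synonymous substitutions; ratio is Inf")
    return(list(ratio = Inf, n_syn = n_syn, n_nonsyn = 0L))
  }
  list(ratio = n_syn / n_non, n_syn = n_syn, n_nonsyn = n_non)
}

#' One-row summary of sequence variation
#'
#' Combines [haplotype_diversity()], [pairwise_stats()] and
#' [syn_nonsyn_ratio()] into the summary usually quoted for a mitogenome
#' data set: n, number of haplotypes, Hd, segregating sites, per-site
#' diversity (percent), mean and SD of pairwise differences, and the
#' syn/non-syn ratio.
#'
#' @param x A [mitogenomes()] object.
#' @param table Optional precomputed `haplotype_table` (computed if
#'   missing; a genemap is then required for the syn/non-syn ratio).
#' @param genemap Optional [gene_map()].
#' @param reference Reference record id for variant calling.
#' @return One-row `data.frame`.
#' @export
diversity_summary <- function(x, table = NULL, genemap = NULL,
                              reference = rownames(x$seq)[1]) {
  if (is.null(table))
    table <- collapse_haplotypes(x, reference = reference, genemap = genemap)
  ps <- pairwise_stats(x)
  ratio <- NA_real_
  if (!is.null(table$variants)) {
    r <- tryCatch(suppressWarnings(syn_nonsyn_ratio(table$variants)),
                  error = function(e) NULL)
    if (!is.null(r)) ratio <- r$ratio
  }
  data.frame(n_sequences = n_records(x),
             n_haplotypes = nrow(table$haplotypes),
             Hd = haplotype_diversity(table),
             S = ps$S,
             pi_percent = ps$pi_percent,
             mean_pairwise = ps$mean_pairwise,
             sd_pairwise = ps$sd_pairwise,
             syn_nonsyn_ratio = ratio)
}
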