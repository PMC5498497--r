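#' Build the concatenated in-frame coding alignment
#'
#' Extracts the protein-coding genes in genomic order, reverse
#' complementing minus-strand genes (ND6) so every gene reads in the same
#' direction, and trims terminal stop codons — complete (3 nt) or
#' incomplete (`T`/`TA`, completed by polyadenylation in vivo). The trim
#' is taken from the gene map's `trim3` column when present, otherwise
#' inferred from the reference: a trailing in-frame stop codon, or the
#' 1-2 leftover bases of a partial codon. After trimming, the reference
#' reading frame must be stop-free or the offending gene is reported as
#' an error.
#'
#' @param x A [mitogenomes()] object.
#' @param genemap A [gene_map()] with the protein entries.
#' @param reference Record id carrying the map's coordinate system
#'   (default: the map's `reference_id` if present among records,
#'   else the first record).
#' @return Object of class `coding_alignment`: list with `seq`
#'   (character matrix, rows = records), `codon_count`, `length_nt`, and
#'   `source_map` (`data.frame` per column: `gene`, `ref_pos`,
#'   `codon_pos`).
#' @export
extract_coding <- function(x, genemap, reference = NULL) {
  if (is.null(reference)) {
    reference <- attr(genemap, "reference_id")
    if (is.null(reference) || !reference %in% rownames(x$seq))
      reference <- rownames(x$seq)[1]
  }
  ref_aln <- record_seq(x, reference)
  col_of <- which(ref_aln != "-")      # alignment column of each ref pos
  refbases <- ref_aln[col_of]
  prot <- genemap[genemap$kind == "protein", , drop = FALSE]
  if (nrow(prot) == 0L) stop("gene map has no protein entries")
  prot <- prot[order(prot$start), , drop = FALSE]

  seq_parts <- vector("list", nrow(prot))
  map_parts <- vector("list", nrow(prot))
  for (i in seq_len(nrow(prot))) {
    g <- prot[i, ]
    pos <- g$start:g$end
    if (g$strand == "-") pos <- rev(pos)
    gene_ref <- refbases[pos]
    if (g$strand == "-") gene_ref <- complement_base(gene_ref)
    trim <- if (!is.null(g$trim3) && !is.na(g$trim3)) as.integer(g$trim3)
      else infer_trim3(gene_ref)
    keep <- seq_len(length(pos) - trim)
    if (length(keep) %% 3L != 0L)
      stop("frame violation in gene ", g$name,
           ": length ", length(keep), " after stop trimming")
    pos <- pos[keep]
    gr <- gene_ref[keep]
    codons <- paste0(gr[c(TRUE, FALSE, FALSE)], gr[c(FALSE, TRUE, FALSE)],
                     gr[c(FALSE, FALSE, TRUE)])
    if (any(is_stop_mt(codons)))
      stop("frame violation in gene ", g$name,
           ": internal stop codon in reference after trimming")
    block <- x$seq[, col_of[pos], drop = FALSE]
    if (g$strand == "-") block[] <- complement_base(block)
    seq_parts[[i]] <- block
    map_parts[[i]] <- data.frame(gene = g$name, ref_pos = pos,
                                 codon_pos = rep_len(1:3, length(pos)))
  }
  seqs <- do.call(cbind, seq_parts)
  smap <- do.call(rbind, map_parts)
  rownames(smap) <- NULL
  structure(list(seq = seqs, codon_count = ncol(seqs) %/% 3L,
                 length_nt = ncol(seqs), source_map = smap,
                 reference = reference),
            class = "coding_alignment")
}

# bases to drop from the 3' end: complete stop codon, or the 1-2 bases
# of an incomplete (polyadenylation-completed) stop
infer_trim3 <- function(gene_ref) {
  n <- length(gene_ref)
  r <- n %% 3L
  if (r != 0L) return(r)
  last <- paste(gene_ref[(n - 2):n], collapse = "")
  if (isTRUE(is_stop_mt(last))) 3L else 0L
}

#' @export
print.coding_alignment <- function(x, ...) {
  cat("coding_alignment: ", nrow(x$seq), " records x ", x$length_nt,
      " nt (", x$codon_count, " codons, ",
      length(unique(x$source_map$gene)), " genes)\n", sep = "")
  invisible(x)
}

#' Infer ancestral bases of the coding alignment
#'
#' Either from an outgroup consensus (default) or, when a rooted tree is
#' supplied, by Fitch reconstruction at the root with ties broken toward
#' the outgroup state. Columns where the outgroup carries a gap or `N`
#' and no tree is available are flagged unresolved (`NA`).
#'
#' @param coding A `coding_alignment`.
#' @param tree Optional rooted `phylo` whose tip labels match record ids.
#' @param outgroup_ids Character vector of outgroup record ids (at least
#'   one required when `tree` is `NULL`).
#' @return Object of class `ancestral_assignment`: list with `bases`
#'   (character vector, `NA` = unresolved) and `method`.
#' @export
infer_ancestral <- function(coding, tree = NULL, outgroup_ids = character()) {
  mat <- coding$seq
  bases4 <- c("A", "C", "G", "T")
  if (is.null(tree) && length(outgroup_ids) == 0L)
    stop("need outgroup ids or a rooted tree")
  og_state <- NULL
  if (length(outgroup_ids)) {
    miss <- setdiff(outgroup_ids, rownames(mat))
    if (length(miss)) stop("unknown outgroup ids: ",
                           paste(miss, collapse = ", "))
    og <- mat[outgroup_ids, , drop = FALSE]
    og_state <- apply(og, 2, function(cc) {
      cc <- cc[cc %in% bases4]
      if (!length(cc)) return(NA_character_)
      tb <- table(cc)
      names(tb)[which.max(tb)]       # ties: alphabetically first
    })
  }
  if (!is.null(tree)) {
    anc <- fitch_root_state(tree, mat, prefer = og_state)
    method <- "fitch"
  } else {
    anc <- og_state
    method <- "outgroup"
    # invariant columns need no outgroup information
    uni <- apply(mat, 2, function(cc) {
      u <- unique(cc[cc %in% bases4])
      if (length(u) == 1L) u else NA_character_
    })
    anc[is.na(anc) & !is.na(uni)] <- uni[is.na(anc) & !is.na(uni)]
  }
  structure(list(bases = unname(anc), method = method),
            class = "ancestral_assignment")
}

#' Replace non-synonymous substitutions with the ancestral base
#'
#' For every sequence and polymorphic coding column, the observed base is
#' evaluated in the ancestral codon context under the vertebrate
#' mitochondrial code. A codon is kept only if it encodes the same amino
#' acid as the ancestral codon *and* every single-base step from the
#' ancestral codon toward it is itself synonymous (multi-hit codons are
#' treated conservatively); otherwise the differing bases revert to the
#' ancestral state. After masking, every sequence translates identically
#' to the ancestral protein at all masked positions.
#'
#' @param coding A `coding_alignment`.
#' @param ancestral An `ancestral_assignment` resolved at every
#'   polymorphic column.
#' @return A `coding_alignment` with masked sequences and an `audit`
#'   attribute: data.frame (`record`, `column`, `gene`, `codon_pos`,
#'   `ancestral`, `observed`, `action`).
#' @export
mask_nonsynonymous <- function(coding, ancestral) {
  mat <- coding$seq
  anc <- ancestral$bases
  L <- ncol(mat)
  stopifnot(length(anc) == L)
  bases4 <- c("A", "C", "G", "T")
  poly <- apply(mat, 2, function(cc) length(unique(cc[cc %in% bases4])) > 1L)
  if (any(poly & is.na(anc)))
    stop("unresolved ancestral base at ", sum(poly & is.na(anc)),
         " polymorphic column(s)")
  diffm <- mat != matrix(anc, nrow(mat), L, byrow = TRUE)
  diffm[mat == "N" | mat == "-"] <- FALSE   # unclassifiable, left alone
  diffm[, is.na(anc)] <- FALSE
  cells <- which(diffm, arr.ind = TRUE)
  audit <- NULL
  if (nrow(cells)) {
    codon_idx <- (cells[, 2] - 1L) %/% 3L
    groups <- split(seq_len(nrow(cells)),
                    paste(cells[, 1], codon_idx, sep = "/"))
    recs <- list()
    for (g in groups) {
      r <- cells[g[1], 1]
      ci <- (cells[g[1], 2] - 1L) %/% 3L
      colr <- ci * 3L + 1:3
      anc_cod <- anc[colr]
      obs_cod <- mat[r, colr]
      dpos <- which(obs_cod != anc_cod & obs_cod %in% bases4)
      if (!length(dpos)) next
      keep <- joint_synonymous(anc_cod, obs_cod, dpos)
      action <- if (keep) "kept" else "masked"
      if (!keep) mat[r, colr[dpos]] <- anc_cod[dpos]
      recs[[length(recs) + 1L]] <- data.frame(
        record = rownames(mat)[r], column = colr[dpos],
        gene = coding$source_map$gene[colr[dpos]],
        codon_pos = dpos, ancestral = anc_cod[dpos],
        observed = obs_cod[dpos], action = action)
    }
    audit <- if (length(recs)) do.call(rbind, recs) else NULL
  }
  out <- coding
  out$seq <- mat
  attr(out, "audit") <- audit
  out
}

# keep the codon only if observed vs ancestral is synonymous jointly and
# through every single-base intermediate step
joint_synonymous <- function(anc_cod, obs_cod, dpos) {
  aa_anc <- translate_mt(paste(anc_cod, collapse = ""))
  aa_obs <- translate_mt(paste(obs_cod, collapse = ""))
  if (is.na(aa_anc) || is.na(aa_obs) || aa_obs != aa_anc) return(FALSE)
  for (p in dpos) {
    step <- anc_cod
    step[p] <- obs_cod[p]
    aa_s <- translate_mt(paste(step, collapse = ""))
    if (is.na(aa_s) || aa_s != aa_anc) return(FALSE)
  }
  TRUE
}

#' Write a masked coding alignment and its audit log
#'
#' @param coding A (masked) `coding_alignment`.
#' @param path FASTA output path.
#' @param audit_path Optional TSV path for the masking audit log.
#' @return `path`, invisibly.
#' @export
write_masked <- function(coding, path, audit_path = NULL) {
  seqs <- apply(coding$seq, 1, paste, collapse = "")
  write_alignment(stats::setNames(seqs, rownames(coding$seq)), path)
  if (!is.null(audit_path)) {
    a <- attr(coding, "audit")
    if (is.null(a)) a <- data.frame(record = character(), column = integer(),
                                    gene = character(), codon_pos = integer(),
                                    ancestral = character(),
                                    observed = character(),
                                    action = character())
    utils::write.table(a, audit_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
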