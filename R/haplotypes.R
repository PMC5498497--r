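#' Collapse aligned records into haplotypes
#'
#' Groups records that carry identical substitution patterns. Haplotype
#' identity uses substitutions only: alignment columns containing a gap
#' in any record are excluded, as are (in the default strict mode)
#' columns where records differ only by `N`. With `strict = FALSE`, `N`
#' matches any base and records are merged greedily in input order into
#' the first compatible haplotype.
#'
#' @param x A [mitogenomes()] object.
#' @param reference Id of the record used as the coordinate reference for
#'   the per-haplotype variant lists (default: first record).
#' @param genemap A [gene_map()] (used to annotate the defining
#'   variants); may be `NULL` to skip variant annotation.
#' @param strict Logical; treat sequences differing only by `N` as
#'   distinct haplotypes (default `TRUE`).
#' @return Object of class `haplotype_table`: list with `haplotypes`
#'   (data.frame `ht_id`, `n_members`, `haplogroup`), `members` (named
#'   list of record ids), and `variants` (named list of variant
#'   data.frames vs the reference, `NULL` when `genemap` is `NULL`).
#' @export
collapse_haplotypes <- function(x, reference = rownames(x$seq)[1],
                                genemap = NULL, strict = TRUE) {
  mat <- x$seq
  if (nrow(mat) < 1L) stop("need at least one record")
  no_indel <- colSums(mat == "-") == 0L
  cols <- which(no_indel)
  sub <- mat[, cols, drop = FALSE]
  # variable columns (across ACGT and, for strict identity, N)
  n_distinct <- apply(sub, 2, function(cc) length(unique(cc)))
  var_cols <- which(n_distinct > 1L)
  pat <- if (length(var_cols))
    apply(sub[, var_cols, drop = FALSE], 1, paste, collapse = "")
  else rep("", nrow(mat))

  ids <- rownames(mat)
  if (strict) {
    grp <- match(pat, unique(pat))
    if (any(grepl("N", pat, fixed = TRUE)))
      message("strict mode: sequences differing only by N are kept distinct")
  } else {
    reps <- list()   # consensus patterns with N filled as observed
    grp <- integer(length(ids))
    for (i in seq_along(ids)) {
      p <- strsplit(pat[i], "")[[1]]
      placed <- FALSE
      for (j in seq_along(reps)) {
        r <- reps[[j]]
        if (all(p == r | p == "N" | r == "N")) {
          fill <- r == "N" & p != "N"
          r[fill] <- p[fill]
          reps[[j]] <- r
          grp[i] <- j; placed <- TRUE; break
        }
      }
      if (!placed) { reps[[length(reps) + 1L]] <- p; grp[i] <- length(reps) }
    }
  }
  k <- max(grp)
  ht_ids <- sprintf("HT%02d", seq_len(k))
  members <- split(ids, grp)
  names(members) <- ht_ids
  variants <- NULL
  if (!is.null(genemap)) {
    ref_seq <- record_seq(x, reference)
    variants <- lapply(members, function(m)
      call_variants(mat[m[1], ], ref_seq, genemap))
    names(variants) <- ht_ids
  }
  structure(list(
    haplotypes = data.frame(ht_id = ht_ids,
                            n_members = vapply(members, length, 1L),
                            haplogroup = NA_character_,
                            row.names = NULL),
    members = members, variants = variants,
    reference = reference, strict = strict),
    class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("haplotype_table: ", nrow(x$haplotypes), " haplotypes, ",
      sum(x$haplotypes$n_members), " records\n", sep = "")
  invisible(x)
}

#' Read haplogroup diagnostic rules
#'
#' Tab-separated with header `label parent motif`; `motif` lists the full
#' diagnostic variant set of the haplogroup as semicolon-separated
#' `position:allele` pairs (derived alleles relative to the calling
#' reference); `parent` is empty/`NA` for top-level haplogroups. A child
#' motif must extend its parent's motif and the parent chain must be
#' acyclic.
#'
#' @param path TSV path.
#' @return `data.frame` of class `haplogroup_rules` with list-column
#'   `motif` (integer-named character vectors: names = positions,
#'   values = alleles).
#' @export
read_haplogroup_rules <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "", na.strings = c("NA", ""))
  haplogroup_rules(tab)
}

#' Construct haplogroup rules from a data.frame
#' @param tab data.frame with `label`, `parent`, `motif` (string
#'   `"pos:allele;pos:allele"`).
#' @return Validated `haplogroup_rules` object.
#' @export
haplogroup_rules <- function(tab) {
  stopifnot(all(c("label", "parent", "motif") %in% names(tab)))
  if (anyDuplicated(tab$label)) stop("duplicate haplogroup labels")
  parse_motif <- function(s) {
    if (is.na(s) || !nzchar(s)) return(stats::setNames(character(), character()))
    kv <- strsplit(strsplit(s, ";")[[1]], ":")
    stats::setNames(toupper(vapply(kv, `[`, "", 2)),
                    vapply(kv, `[`, "", 1))
  }
  motifs <- lapply(tab$motif, parse_motif)
  names(motifs) <- tab$label
  # acyclic parent chain + depth
  depth <- stats::setNames(rep(NA_integer_, nrow(tab)), tab$label)
  get_depth <- function(lab, seen = character()) {
    if (lab %in% seen) stop("cycle in haplogroup rule parents at ", lab)
    p <- tab$parent[tab$label == lab]
    if (is.na(p)) return(1L)
    if (!p %in% tab$label) stop("unknown parent '", p, "' for ", lab)
    1L + get_depth(p, c(seen, lab))
  }
  for (lab in tab$label) depth[lab] <- get_depth(lab)
  # child motif extends parent motif
  for (i in seq_len(nrow(tab))) {
    p <- tab$parent[i]
    if (is.na(p)) next
    pm <- motifs[[p]]; cm <- motifs[[i]]
    if (!all(names(pm) %in% names(cm)) ||
        !all(cm[names(pm)] == pm))
      stop("motif of ", tab$label[i], " does not extend parent ", p)
  }
  out <- data.frame(label = tab$label, parent = tab$parent,
                    depth = unname(depth[tab$label]),
                    stringsAsFactors = FALSE)
  out$motif <- motifs
  structure(out, class = c("haplogroup_rules", "data.frame"))
}

#' Assign a haplogroup label from a variant set
#'
#' Returns the label of the deepest rule whose full motif is contained in
#' the variant set; `"unassigned"` when no rule matches, and
#' `"conflict:<labels>"` when two equally deep rules on different
#' branches both match (never a silent tie-break).
#'
#' @param variants Variant `data.frame` (needs `pos`, `alt`) from
#'   [call_variants()], or a character vector of `"pos:allele"` strings.
#' @param rules A [haplogroup_rules()] object.
#' @return Single character label.
#' @export
assign_haplogroup <- function(variants, rules) {
  if (is.data.frame(variants)) {
    have <- paste0(variants$pos, ":", toupper(variants$alt))
  } else have <- as.character(variants)
  matches <- vapply(seq_len(nrow(rules)), function(i) {
    m <- rules$motif[[i]]
    length(m) > 0L && all(paste0(names(m), ":", m) %in% have)
  }, logical(1))
  if (!any(matches)) return("unassigned")
  md <- max(rules$depth[matches])
  top <- rules$label[matches & rules$depth == md]
  if (length(top) > 1L)
    return(paste0("conflict:", paste(sort(top), collapse = ",")))
  top
}

#' Label every haplotype in a table with its haplogroup
#'
#' @param table A `haplotype_table` with variant annotations.
#' @param rules A [haplogroup_rules()] object.
#' @return The table with the `haplogroup` column filled in.
#' @export
assign_haplogroups <- function(table, rules) {
  if (is.null(table$variants))
    stop("haplotype table lacks variant annotations (collapse with a genemap)")
  table$haplotypes$haplogroup <- vapply(
    table$haplotypes$ht_id,
    function(h) assign_haplogroup(table$variants[[h]], rules), character(1))
  table
}

#' Write a haplotype table to TSV
#' @param table A `haplotype_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(table, path) {
  df <- table$haplotypes
  df$members <- vapply(table$members[df$ht_id], paste, "", collapse = ",")
  df$variants <- vapply(df$ht_id, function(h) {
    v <- table$variants[[h]]
    if (is.null(v)) return("")
    paste0(v$pos, v$alt, collapse = ";")
  }, "")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
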