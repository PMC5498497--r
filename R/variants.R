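#' Call variants of a record against a reference
#'
#' Compares one aligned sequence with the reference sequence column by
#' column and reports differences in the reference coordinate system
#' (1-based). Alignment columns where the reference carries a gap
#' (insertions relative to the reference) are reported at the coordinate
#' of the preceding reference base with a positive `subpos` sub-index.
#' Columns where either sequence is `N` emit no substitution call.
#' Substitution effects in protein genes are computed under the
#' vertebrate mitochondrial code (translation table 2) against the
#' reference codon, honouring strand.
#'
#' @param record Aligned sequence: single string or character vector of
#'   bases.
#' @param reference Aligned reference sequence, same aligned length.
#' @param genemap A [gene_map()] covering every reference position.
#' @return `data.frame` with columns `pos`, `subpos`, `ref`, `alt`,
#'   `vclass` (`transition`/`transversion`/`indel`), `region`
#'   (`coding`/`control`/`RNA`), `effect` (`synonymous`/`nonsynonymous`/
#'   `noncoding`/`NA`) and `gene`.
#' @export
call_variants <- function(record, reference, genemap) {
  rec <- as_base_vector(record)
  ref <- as_base_vector(reference)
  if (length(rec) != length(ref))
    stop("record and reference have different aligned lengths")
  refpos <- cumsum(ref != "-")
  subpos <- integer(length(ref))
  ins <- which(ref == "-")
  if (length(ins)) {
    runs <- split(ins, cumsum(c(1L, diff(ins) != 1L)))
    for (r in runs) subpos[r] <- seq_along(r)
  }
  refbases <- ref[ref != "-"]

  diff_cols <- which(rec != ref)
  if (!length(diff_cols)) return(empty_variants())

  rows <- vector("list", length(diff_cols))
  n <- 0L
  for (col in diff_cols) {
    a <- ref[col]; b <- rec[col]
    if (a == "N" || b == "N") next
    p <- max(refpos[col], 1L)
    if (a == "-" || b == "-") {
      reg <- region_of(genemap, p)
      n <- n + 1L
      rows[[n]] <- data.frame(pos = p, subpos = subpos[col], ref = a,
                              alt = b, vclass = "indel",
                              region = reg$region, effect = NA_character_,
                              gene = reg$gene)
      next
    }
    vclass <- if (paste0(sort(c(a, b)), collapse = "") %in% c("AG", "CT"))
      "transition" else "transversion"
    reg <- region_of(genemap, p)
    effect <- NA_character_
    if (reg$region == "coding") {
      g <- genemap[genemap$name == reg$gene & genemap$kind == "protein", ][1, ]
      ctx <- codon_context(refbases, g, p)
      if (!is.na(ctx$codon)) {
        alt_b <- if (g$strand == "-") complement_base(b) else b
        mcod <- ctx$codon
        substr(mcod, ctx$cpos, ctx$cpos) <- alt_b
        aa0 <- translate_mt(ctx$codon); aa1 <- translate_mt(mcod)
        if (!is.na(aa0) && !is.na(aa1))
          effect <- if (aa0 == aa1) "synonymous" else "nonsynonymous"
      }
    } else effect <- "noncoding"
    n <- n + 1L
    rows[[n]] <- data.frame(pos = p, subpos = subpos[col], ref = a, alt = b,
                            vclass = vclass, region = reg$region,
                            effect = effect, gene = reg$gene)
  }
  if (!n) return(empty_variants())
  out <- do.call(rbind, rows[seq_len(n)])
  out <- out[order(out$pos, out$subpos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_variants <- function() {
  data.frame(pos = integer(), subpos = integer(), ref = character(),
             alt = character(), vclass = character(), region = character(),
             effect = character(), gene = character())
}

as_base_vector <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "")[[1]]
  toupper(x)
}

#' Export variants as a minimal VCF
#'
#' One line per substitution/indel, `CHROM` set to the reference id,
#' 1-based `POS`, and `INFO` tags `REGION` and `EFFECT`.
#'
#' @param variants A variant `data.frame` from [call_variants()].
#' @param reference_id Reference record id (CHROM field).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, reference_id, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##contig=<ID=", reference_id, ">"),
               "##INFO=<ID=REGION,Number=1,Type=String,Description=\"coding/control/RNA\">",
               "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"substitution effect\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  v <- variants[variants$subpos == 0L, , drop = FALSE]  # VCF: reference-anchored only
  for (i in seq_len(nrow(v))) {
    info <- paste0("REGION=", v$region[i],
                   ifelse(is.na(v$effect[i]), "",
                          paste0(";EFFECT=", v$effect[i])))
    writeLines(paste(reference_id, v$pos[i], ".",
                     sub("-", ".", v$ref[i]), sub("-", ".", v$alt[i]),
                     ".", ".", info, sep = "\t"), con)
  }
  invisible(path)
}
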