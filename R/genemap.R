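#' Construct / validate a gene map
#'
#' A gene map lists the features of the mitogenome in 1-based inclusive
#' reference coordinates: the 13 protein-coding genes, rRNA/tRNA genes
#' and the control region. Protein entries must not overlap one another
#' and the control region must be disjoint from all coding entries.
#'
#' @param entries `data.frame` with columns `name`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`), `kind` (`"protein"`, `"rRNA"`, `"tRNA"`,
#'   `"control"`); optional `trim3` (integer: bases to trim from the 3'
#'   end of a protein gene before translation — complete or incomplete
#'   stop codons; inferred automatically when absent).
#' @param reference_id Id of the reference record whose coordinates the
#'   map uses.
#' @return `data.frame` of class `gene_map` with attribute
#'   `reference_id`.
#' @export
gene_map <- function(entries, reference_id) {
  need <- c("name", "start", "end", "strand", "kind")
  if (!all(need %in% names(entries)))
    stop("gene map needs columns: ", paste(need, collapse = ", "))
  entries$start <- as.integer(entries$start)
  entries$end <- as.integer(entries$end)
  if (any(entries$start > entries$end)) stop("start > end in gene map")
  if (!all(entries$strand %in% c("+", "-"))) stop("strand must be + or -")
  if (!all(entries$kind %in% c("protein", "rRNA", "tRNA", "control")))
    stop("kind must be protein, rRNA, tRNA or control")
  prot <- entries[entries$kind == "protein", , drop = FALSE]
  if (nrow(prot) > 1) {
    o <- order(prot$start)
    if (any(prot$start[o][-1] <= prot$end[o][-nrow(prot)]))
      stop("overlapping protein entries in gene map")
  }
  ctl <- entries[entries$kind == "control", , drop = FALSE]
  for (i in seq_len(nrow(ctl))) {
    ov <- prot$start <= ctl$end[i] & prot$end >= ctl$start[i]
    if (any(ov)) stop("control region overlaps coding entries")
  }
  entries <- entries[order(entries$start), , drop = FALSE]
  rownames(entries) <- NULL
  structure(entries, class = c("gene_map", "data.frame"),
            reference_id = reference_id)
}

#' Read a gene map from a tab-separated file
#'
#' @param path TSV with header `name start end strand kind` (optional
#'   `trim3`).
#' @param reference_id Reference record id for the coordinate system.
#' @return A [gene_map()].
#' @export
read_genemap <- function(path, reference_id) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "")
  gene_map(tab, reference_id)
}

#' Write a gene map to TSV
#' @param gm A [gene_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genemap <- function(gm, path) {
  utils::write.table(as.data.frame(gm), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# classify a reference position: "coding", "control", "RNA";
# positions outside every entry are an error.
region_of <- function(gm, pos) {
  kind_prio <- c(protein = 1, control = 2, rRNA = 3, tRNA = 3)
  out <- character(length(pos))
  gene <- character(length(pos))
  for (i in seq_along(pos)) {
    hit <- which(gm$start <= pos[i] & gm$end >= pos[i])
    if (!length(hit))
      stop("position ", pos[i], " outside gene-map coverage")
    hit <- hit[order(kind_prio[gm$kind[hit]])][1]
    out[i] <- switch(gm$kind[hit], protein = "coding",
                     control = "control", "RNA")
    gene[i] <- gm$name[hit]
  }
  data.frame(region = out, gene = gene)
}

# codon context of reference position `pos` inside protein gene `g`
# (one row of the gene map), honouring strand.  `refbases` is the
# ungapped reference base vector indexed by reference coordinate.
# Returns list(codon, cpos, sites) with codon in reading direction;
# sites may fall outside the gene (incomplete terminal codon) -> NA codon.
codon_context <- function(refbases, g, pos) {
  if (g$strand == "+") {
    off <- pos - g$start
    cpos <- off %% 3L + 1L
    first <- pos - (cpos - 1L)
    sites <- first + 0:2
  } else {
    off <- g$end - pos
    cpos <- off %% 3L + 1L
    first <- pos + (cpos - 1L)   # reading starts at the higher coordinate
    sites <- first - (0:2)
  }
  if (any(sites < g$start | sites > g$end | sites < 1 |
          sites > length(refbases)))
    return(list(codon = NA_character_, cpos = cpos, sites = sites))
  b <- refbases[sites]
  if (g$strand == "-") b <- complement_base(b)
  list(codon = paste(b, collapse = ""), cpos = cpos, sites = sites)
}
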