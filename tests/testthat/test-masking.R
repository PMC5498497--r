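test_that("coding extraction concatenates, strand-flips and trims stops", {
  # two plus-strand genes of 9 nt each including a 3-nt stop -> 12 nt
  ref <- c("A","T","G","G","G","A","T","A","A",    # ATG GGA TAA
           "A","T","G","C","T","T","T","A","G",    # ATG CTT TAG
           "C","C")
  gm <- gene_map(data.frame(name = c("g1", "g2", "cr"),
                            start = c(1, 10, 19), end = c(9, 18, 20),
                            strand = "+", kind = c("protein", "protein",
                                                   "control")), "r1")
  x <- mitogenomes(rbind(r1 = ref, r2 = ref))
  cod <- extract_coding(x, gm, reference = "r1")
  expect_equal(cod$length_nt, 12L)
  expect_equal(cod$codon_count, 4L)
  expect_equal(paste(cod$seq["r1", ], collapse = ""), "ATGGGAATGCTT")
  expect_equal(cod$source_map$gene, rep(c("g1", "g2"), each = 6))
  expect_equal(cod$source_map$codon_pos, rep(1:3, 4))
})

test_that("minus-strand genes appear reverse-complemented and stop-free", {
  x <- mitogenomes(rbind(r1 = toy_reference()))
  cod <- extract_coding(x, toy_genemap(), reference = "r1")
  s <- cod$seq["r1", cod$source_map$gene == "g2"]
  expect_equal(paste(s, collapse = ""), "ATGCTA")   # TAG stop trimmed
  codons <- paste0(s[c(1, 4)], s[c(2, 5)], s[c(3, 6)])
  expect_false(any(translate_mt(codons) == "*"))
})

test_that("incomplete terminal stops (T / TA) are trimmed", {
  # 7-nt gene: ATG GGA + incomplete stop T
  ref <- c("A","T","G","G","G","A","T","C","C","C")
  gm <- gene_map(data.frame(name = c("g", "cr"), start = c(1, 8),
                            end = c(7, 10), strand = "+",
                            kind = c("protein", "control")), "r1")
  cod <- extract_coding(mitogenomes(rbind(r1 = ref)), gm, reference = "r1")
  expect_equal(cod$length_nt, 6L)
  # 8-nt gene: ATG GGA + TA
  ref2 <- c("A","T","G","G","G","A","T","A","C","C")
  gm2 <- gene_map(data.frame(name = c("g", "cr"), start = c(1, 9),
                             end = c(8, 10), strand = "+",
                             kind = c("protein", "control")), "r1")
  cod2 <- extract_coding(mitogenomes(rbind(r1 = ref2)), gm2,
                         reference = "r1")
  expect_equal(cod2$length_nt, 6L)
})

test_that("internal reference stops are a frame violation error", {
  ref <- c("A","T","G","T","A","A","G","G","A","T","A","A","C")
  gm <- gene_map(data.frame(name = c("bad", "cr"), start = c(1, 13),
                            end = c(12, 13), strand = "+",
                            kind = c("protein", "control")), "r1")
  expect_error(extract_coding(mitogenomes(rbind(r1 = ref)), gm,
                              reference = "r1"), "bad")
})

test_that("outgroup consensus ancestral inference", {
  ref <- toy_reference()
  m <- rbind(og = ref,
             a = replace(ref, 6, "G"),
             b = replace(ref, 6, "G"),
             c = ref)
  cod <- extract_coding(mitogenomes(m), toy_genemap(), reference = "og")
  anc <- infer_ancestral(cod, outgroup_ids = "og")
  expect_equal(anc$method, "outgroup")
  expect_equal(anc$bases[6], "A")       # outgroup state at polymorphic col
  expect_equal(anc$bases[1], "A")       # invariant column: shared base
})

test_that("Fitch-mode ancestral inference breaks ties toward the outgroup", {
  # 4 taxa: column split 2|2 (A,A,G,G) -> root set {A,G}; outgroup G
  m <- rbind(og = c("G", "C"), t1 = c("A", "C"), t2 = c("A", "C"),
             t3 = c("G", "C"))
  tr <- ape::read.tree(text = "((t1,t2),(t3,og));")
  cod <- structure(list(seq = m, codon_count = NA, length_nt = 2L,
                        source_map = NULL), class = "coding_alignment")
  anc <- infer_ancestral(cod, tree = tr, outgroup_ids = "og")
  expect_equal(anc$method, "fitch")
  expect_equal(anc$bases[1], "G")
})

test_that("masking keeps synonymous changes, reverts non-synonymous ones", {
  ref <- toy_reference()
  m <- rbind(og = ref,
             keep = replace(ref, 6, "G"),     # GGA->GGG Gly/Gly
             revert = replace(ref, 5, "C"))   # GGA->GCA Gly/Ala
  cod <- extract_coding(mitogenomes(m), toy_genemap(), reference = "og")
  anc <- infer_ancestral(cod, outgroup_ids = "og")
  masked <- mask_nonsynonymous(cod, anc)
  expect_equal(unname(masked$seq["keep", 6]), "G")
  expect_equal(unname(masked$seq["revert", 5]), "G")
  audit <- attr(masked, "audit")
  expect_setequal(audit$action[audit$record == "keep"], "kept")
  expect_setequal(audit$action[audit$record == "revert"], "masked")
})

test_that("ATA->ACA (Met->Thr under the mitochondrial code) is masked", {
  ref <- c("A","T","G","A","T","A","T","A","A","C","C")
  gm <- gene_map(data.frame(name = c("g", "cr"), start = c(1, 10),
                            end = c(9, 11), strand = "+",
                            kind = c("protein", "control")), "og")
  m <- rbind(og = ref, x = replace(ref, 5, "C"))
  cod <- extract_coding(mitogenomes(m), gm, reference = "og")
  masked <- mask_nonsynonymous(cod, infer_ancestral(cod,
                                                    outgroup_ids = "og"))
  expect_equal(unname(masked$seq["x", 5]), "T")
})

test_that("masked alignments translate identically to the ancestor", {
  set.seed(21)
  demo <- demographic_model(data.frame(start = 0, end = Inf, ne = 500))
  gm <- toy_study_genemap()
  sim <- simulate_sequences(simulate_genealogy(demo, 8, seed = 4)$tree,
                            evolution_model(rate = 5e-6,
                                            nonsyn_suppression = 0.3),
                            gm, seed = 5)
  cod <- extract_coding(sim$records, gm,
                        reference = rownames(sim$records$seq)[1])
  anc <- infer_ancestral(cod, outgroup_ids = rownames(sim$records$seq)[1])
  masked <- mask_nonsynonymous(cod, anc)
  anc_aa <- translate_mt(codon_strings(anc$bases))
  for (r in rownames(masked$seq)) {
    aa <- translate_mt(codon_strings(unname(masked$seq[r, ])))
    expect_equal(aa, anc_aa)
  }
  # idempotence and conservation
  again <- mask_nonsynonymous(masked, anc)
  expect_identical(again$seq, masked$seq)
  audit <- attr(masked, "audit")
  changed <- which(apply(masked$seq != cod$seq, 2, any))
  expect_true(all(changed %in% audit$column[audit$action == "masked"]))
})

test_that("codon-context masking decision matches exhaustive translation", {
  skip_if_not_installed("seqinr")
  set.seed(31)
  bases <- c("A", "C", "G", "T")
  codons <- names(mt_code())
  sense <- codons[translate_mt(codons) != "*"]
  tr2 <- function(cod) seqinr::translate(seqinr::s2c(tolower(cod)),
                                         numcode = 2)
  for (i in 1:100) {
    anc_cod <- strsplit(sample(sense, 1), "")[[1]]
    p <- sample(3, 1)
    obs_cod <- anc_cod
    obs_cod[p] <- sample(setdiff(bases, anc_cod[p]), 1)
    keep <- mitochronos:::joint_synonymous(anc_cod, obs_cod, p)
    expect_equal(keep, tr2(paste(obs_cod, collapse = "")) ==
                         tr2(paste(anc_cod, collapse = "")))
  }
})
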