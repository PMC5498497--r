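test_that("FASTA read/write round-trips content and order", {
  set.seed(1)
  seqs <- apply(random_base_matrix(3, 50), 1, paste, collapse = "")
  f <- withr::local_tempfile(fileext = ".fa")
  write_alignment(seqs, f)
  x <- read_alignment(f)
  expect_equal(rownames(x$seq), names(seqs))
  expect_equal(apply(x$seq, 1, paste, collapse = ""), seqs)
})

test_that("reading normalizes case and maps IUPAC ambiguity to N", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "acgR", ">b", "ACGT"), f)
  expect_warning(x <- read_alignment(f), "converted to N")
  expect_equal(paste(x$seq["a", ], collapse = ""), "ACGN")
})

test_that("ragged alignments and empty files are hard errors", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">b", "ACG"), f)
  expect_error(read_alignment(f), "b")
  f2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), f2)
  expect_error(read_alignment(f2), "empty")
})

test_that("variant calling classifies substitutions against the reference", {
  ref <- toy_reference()
  gm <- toy_genemap()
  expect_equal(nrow(call_variants(ref, ref, gm)), 0L)
  # control-region transition
  rec <- replace(ref, 20, "T")   # C -> T
  v <- call_variants(rec, ref, gm)
  expect_equal(v$vclass, "transition")
  expect_equal(v$region, "control")
  expect_equal(v$effect, "noncoding")
  # third-position GGA -> GGG is synonymous (both Gly)
  v2 <- call_variants(replace(ref, 6, "G"), ref, gm)
  expect_equal(v2$effect, "synonymous")
  # second-position plus-strand missense
  v3 <- call_variants(replace(ref, 5, "A"), ref, gm)
  expect_equal(v3$effect, "nonsynonymous")
  # minus-strand gene: position 15 is codon 2 pos 2 of g2 (CTA, Leu);
  # genome G->A makes the read codon CCA wait -- compute via the code
  v4 <- call_variants(replace(ref, 13, "A"), ref, gm)
  expect_equal(v4$region, "coding")
  expect_true(v4$effect %in% c("synonymous", "nonsynonymous"))
  # N columns emit nothing
  expect_equal(nrow(call_variants(replace(ref, 5, "N"), ref, gm)), 0L)
})

test_that("insertion columns get sub-indexed positions", {
  ref <- c("A", "C", "-", "G")
  rec <- c("A", "C", "T", "G")
  gm <- gene_map(data.frame(name = "cr", start = 1, end = 3,
                            strand = "+", kind = "control"), "ref")
  v <- call_variants(rec, ref, gm)
  expect_equal(v$pos, 2L)       # anchored to the preceding reference base
  expect_equal(v$subpos, 1L)
  expect_equal(v$vclass, "indel")
})

test_that("haplotype collapsing groups identical substitution patterns", {
  ref <- toy_reference()
  m <- rbind(r1 = ref, r2 = ref, r3 = ref, r4 = ref, r5 = ref)
  x <- mitogenomes(m)
  ht <- collapse_haplotypes(x)
  expect_equal(nrow(ht$haplotypes), 1L)
  expect_equal(ht$haplotypes$n_members, 5L)

  m2 <- rbind(a1 = ref, a2 = ref, b1 = replace(ref, 20, "T"))
  ht2 <- collapse_haplotypes(mitogenomes(m2), genemap = toy_genemap())
  expect_equal(ht2$haplotypes$n_members, c(2L, 1L))
  expect_equal(ht2$members$HT01, c("a1", "a2"))
})

test_that("member counts always partition the input (property)", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(2:12, 1)
    m <- random_base_matrix(n, 8)
    ht <- collapse_haplotypes(mitogenomes(m))
    expect_equal(sum(ht$haplotypes$n_members), n)
    expect_setequal(unlist(ht$members), rownames(m))
  }
})

test_that("collapsing is deterministic and byte-identical across runs", {
  set.seed(7)
  m <- random_base_matrix(8, 30)
  x <- mitogenomes(m)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_haplotype_table(collapse_haplotypes(x), f1)
  write_haplotype_table(collapse_haplotypes(x), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("strict mode keeps N-differing sequences distinct; lax merges", {
  ref <- toy_reference()
  m <- rbind(a = replace(ref, 20, "T"),
             b = replace(replace(ref, 20, "T"), 21, "N"),
             c = ref)
  x <- mitogenomes(m)
  expect_message(ht_strict <- collapse_haplotypes(x, strict = TRUE),
                 "strict")
  expect_equal(nrow(ht_strict$haplotypes), 3L)
  ht_lax <- collapse_haplotypes(x, strict = FALSE)
  expect_equal(nrow(ht_lax$haplotypes), 2L)
})

test_that("haplogroup assignment returns the deepest full-motif match", {
  rules <- haplogroup_rules(data.frame(
    label = c("SA", "SA1", "SA1a", "SB"),
    parent = c(NA, "SA", "SA1", NA),
    motif = c("100:T", "100:T;200:G", "100:T;200:G;16066:A", "300:C")))
  expect_equal(assign_haplogroup(c("100:T"), rules), "SA")
  expect_equal(assign_haplogroup(c("100:T", "200:G"), rules), "SA1")
  expect_equal(assign_haplogroup(c("100:T", "200:G", "16066:A"), rules),
               "SA1a")
  expect_equal(assign_haplogroup(character(), rules), "unassigned")
  expect_equal(assign_haplogroup(c("100:T", "300:C"), rules),
               "conflict:SA,SB")
})

test_that("assignment is monotone under added variants (property)", {
  rules <- haplogroup_rules(data.frame(
    label = c("SA", "SA1", "SA1a", "SB", "SB1"),
    parent = c(NA, "SA", "SA1", NA, "SB"),
    motif = c("1:T", "1:T;2:G", "1:T;2:G;3:A", "9:C", "9:C;8:T")))
  depth_of <- function(lab) {
    if (lab == "unassigned") return(0L)
    if (startsWith(lab, "conflict")) {
      tied <- strsplit(sub("^conflict:", "", lab), ",")[[1]]
      return(rules$depth[rules$label == tied[1]])
    }
    rules$depth[rules$label == lab]
  }
  pool <- c("1:T", "2:G", "3:A", "9:C", "8:T", "5:G")
  set.seed(3)
  for (i in 1:50) {
    v <- sample(pool, sample(0:4, 1))
    extra <- sample(setdiff(pool, v), 1)
    d1 <- depth_of(assign_haplogroup(v, rules))
    d2 <- depth_of(assign_haplogroup(c(v, extra), rules))
    expect_gte(d2, d1)
  }
})

test_that("rule validation rejects cycles and non-nested motifs", {
  expect_error(haplogroup_rules(data.frame(
    label = c("A", "B"), parent = c("B", "A"), motif = c("1:T", "1:T;2:G"))),
    "cycle")
  expect_error(haplogroup_rules(data.frame(
    label = c("A", "B"), parent = c(NA, "A"), motif = c("1:T", "2:G"))),
    "extend")
})

test_that("the shipped synthetic haplogroup rule fixture is well-formed", {
  path <- system.file("extdata", "haplogroup_rules_synthetic.tsv",
                      package = "mitochronos")
  rules <- read_haplogroup_rules(path)
  expect_gte(nrow(rules), 21L)
  expect_true("SA1a" %in% rules$label)
  m <- rules$motif[[which(rules$label == "SA1a")]]
  expect_true("16066" %in% names(m))
})

test_that("variants export as minimal VCF", {
  ref <- toy_reference()
  v <- call_variants(replace(ref, 20, "T"), ref, toy_genemap())
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(v, "ref", f)
  lines <- readLines(f)
  expect_true(any(grepl("^##fileformat", lines)))
  body <- lines[!startsWith(lines, "#")]
  expect_match(body, "ref\t20\t.\tC\tT", fixed = TRUE)
  expect_match(body, "REGION=control")
})
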