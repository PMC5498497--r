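test_that("demographic model validation enforces tiling", {
  expect_error(demographic_model(data.frame(start = 10, end = Inf,
                                            ne = 100)), "start at 0")
  expect_error(demographic_model(data.frame(start = c(0, 50),
                                            end = c(40, Inf),
                                            ne = c(1, 1))), "tile")
  expect_error(demographic_model(data.frame(start = 0, end = 100,
                                            ne = 10)), "Inf")
})

test_that("pairwise coalescent times match the constant-Ne expectation", {
  ne <- 200
  demo <- demographic_model(data.frame(start = 0, end = Inf, ne = ne))
  times <- vapply(1:800, function(i)
    simulate_genealogy(demo, 2, seed = i)$genealogy$coal_times / 6,
    numeric(1))
  # E[T2] = Ne generations, SD = Ne
  expect_lt(abs(mean(times) - ne), 3 * ne / sqrt(length(times)))
})

test_that("total tree length matches the coalescent expectation", {
  ne <- 150; n <- 10
  demo <- demographic_model(data.frame(start = 0, end = Inf, ne = ne))
  lens <- vapply(1:400, function(i) {
    tr <- simulate_genealogy(demo, n, seed = 5000 + i)$tree
    sum(tr$edge.length) / 6
  }, numeric(1))
  expected <- 2 * ne * sum(1 / (1:(n - 1)))
  expect_lt(abs(mean(lens) - expected), 3 * stats::sd(lens) / sqrt(400))
})

test_that("a bottleneck epoch concentrates coalescences inside it", {
  # severe 100x bottleneck 50-100 generations back
  g <- 6
  demo_b <- demographic_model(data.frame(
    start = c(0, 50 * g, 100 * g), end = c(50 * g, 100 * g, Inf),
    ne = c(1000, 10, 1000)))
  demo_c <- demographic_model(data.frame(start = 0, end = Inf, ne = 1000))
  frac_in <- function(model, seeds) {
    mean(vapply(seeds, function(i) {
      ct <- simulate_genealogy(model, 10, seed = i)$genealogy$coal_times / g
      mean(ct >= 50 & ct <= 100)
    }, numeric(1)))
  }
  expect_gt(frac_in(demo_b, 1:100), frac_in(demo_c, 101:200) + 0.2)
})

test_that("ancient tips enter the genealogy at their ages", {
  demo <- demographic_model(data.frame(start = 0, end = Inf, ne = 100))
  sim <- simulate_genealogy(demo, 4, tip_ages = c(0, 0, 0, 3000), seed = 2)
  expect_equal(sort(sim$genealogy$samp_times), c(0, 0, 0, 3000))
  expect_true(all(sim$genealogy$coal_times >= 0))
  expect_true(all(sim$tree$edge.length >= 0))
  # the dated tip's age is reflected in its node age
  expect_equal(unname(sim$tree$ages_yr[4]), 3000)
})

test_that("zero rate propagates the root sequence unchanged", {
  demo <- demographic_model(data.frame(start = 0, end = Inf, ne = 100))
  tr <- simulate_genealogy(demo, 5, seed = 3)$tree
  out <- simulate_sequences(tr, evolution_model(rate = 0),
                            toy_study_genemap(), seed = 4)
  expect_true(all(apply(out$records$seq, 1,
                        function(r) all(r == out$root_seq))))
  expect_equal(sum(out$truth$n_subs), 0L)
})

test_that("simulation is deterministic under a fixed seed", {
  demo <- demographic_model(data.frame(start = 0, end = Inf, ne = 100))
  tr <- simulate_genealogy(demo, 5, seed = 3)$tree
  a <- simulate_sequences(tr, evolution_model(rate = 1e-6),
                          toy_study_genemap(), seed = 7)
  b <- simulate_sequences(tr, evolution_model(rate = 1e-6),
                          toy_study_genemap(), seed = 7)
  expect_identical(a$records$seq, b$records$seq)
  expect_identical(a$truth, b$truth)
})

test_that("realized substitutions match the Poisson expectation", {
  # one long two-tip branch, no selection, no invariant sites
  demo <- demographic_model(data.frame(start = 0, end = Inf, ne = 10))
  gm <- toy_study_genemap()
  evo <- evolution_model(rate = 2e-6, p_invariant = 0, gamma_shape = 100,
                         nonsyn_suppression = 0,
                         partition_multipliers = c(coding = 1, control = 1))
  tot <- 0; exp_tot <- 0
  for (i in 1:15) {
    tr <- simulate_genealogy(demo, 2, seed = 600 + i)$tree
    out <- simulate_sequences(tr, evo, gm, seed = 700 + i)
    tot <- tot + sum(out$truth$n_subs)
    # stop-codon sites are frozen by design (4 genes x 3 nt... 3 stops)
    L_eff <- 600 - 9
    exp_tot <- exp_tot + evo$rate * L_eff * sum(tr$edge.length)
  }
  expect_lt(abs(tot - exp_tot), 3 * sqrt(exp_tot))
})

test_that("large kappa makes transversions vanish", {
  demo <- demographic_model(data.frame(start = 0, end = Inf, ne = 50))
  tr <- simulate_genealogy(demo, 6, seed = 9)$tree
  gm <- toy_study_genemap()
  out <- simulate_sequences(tr, evolution_model(rate = 5e-5, kappa = 1e6,
                                                nonsyn_suppression = 0),
                            gm, seed = 10)
  ref <- out$root_seq
  tv <- 0; ts <- 0
  for (r in rownames(out$records$seq)) {
    v <- call_variants(out$records$seq[r, ], ref, gm)
    tv <- tv + sum(v$vclass == "transversion")
    ts <- ts + sum(v$vclass == "transition")
  }
  expect_gt(ts, 0)
  expect_equal(tv, 0)
})

test_that("the purifying-selection knob moves the synonymous fraction", {
  demo <- demographic_model(data.frame(start = 0, end = Inf, ne = 300))
  tr <- simulate_genealogy(demo, 8, seed = 21)$tree
  gm <- toy_study_genemap()
  syn_frac <- vapply(c(0, 0.9), function(s) {
    out <- simulate_sequences(tr, evolution_model(rate = 2e-5,
                                                  nonsyn_suppression = s),
                              gm, seed = 22)
    ref <- out$root_seq
    eff <- unlist(lapply(rownames(out$records$seq), function(r)
      call_variants(out$records$seq[r, ], ref, gm)$effect))
    eff <- eff[!is.na(eff) & eff != "noncoding"]
    mean(eff == "synonymous")
  }, numeric(1))
  expect_gt(syn_frac[2], syn_frac[1] + 0.15)
})

test_that("study-like fixtures are reproducible and self-consistent", {
  d1 <- make_study_like_dataset(seed = 5, n_ingroup = 12)
  d2 <- make_study_like_dataset(seed = 5, n_ingroup = 12)
  expect_identical(d1$records$seq, d2$records$seq)
  expect_identical(d1$truth$branch_counts, d2$truth$branch_counts)
  # haplotype count equals the number of distinct sequences in truth
  ht <- collapse_haplotypes(d1$records)
  expect_equal(nrow(ht$haplotypes),
               length(unique(apply(d1$records$seq, 1, paste,
                                   collapse = ""))))
  # metadata markers
  expect_equal(sum(d1$records$meta$btype == "swamp"), 12L)
  expect_equal(d1$records$meta$tip_age[d1$records$meta$id == "AUR01"],
               6700)
  # written files round-trip
  dir <- withr::local_tempdir()
  make_study_like_dataset(seed = 5, n_ingroup = 12, write_dir = dir)
  expect_true(all(file.exists(file.path(dir,
    c("alignment.fa", "metadata.tsv", "genemap.tsv", "calibrations.tsv",
      "truth.json")))))
  x <- read_alignment(file.path(dir, "alignment.fa"),
                      file.path(dir, "metadata.tsv"))
  expect_identical(x$seq, d1$records$seq)
})
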