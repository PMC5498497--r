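#' Run the full mitogenome analysis pipeline
#'
#' Orchestrates the stages end-to-end from a single configuration:
#' haplotype collapsing, diversity statistics, synonymous masking,
#' maximum-parsimony tree, clock dating and skyline inference. Every
#' intermediate artifact is persisted under the output directory; the
#' machine-readable report (`report.json`) is deterministic for a fixed
#' config (wall times go to the human-readable `pipeline.log`).
#'
#' @param config Path to a YAML file or a named list with entries:
#'   `fasta`, `metadata`, `genemap`, `calibrations` (paths);
#'   optional `rules` (haplogroup rules path), `reference` (record id),
#'   `outgroup` (tip ids; default = records with btype river/outgroup),
#'   `stages` (subset of `collapse`, `diversity`, `mask`, `tree`,
#'   `date`, `skyline`), `tree_seed`, `skyline_seed`, `site_unit`
#'   (`"codon"` or `"nt"`), `skyline_groups`, `skyline_iters`,
#'   `skyline_thin`, `gen_time`, `output_dir`.
#' @param output_dir Output directory (overrides the config entry).
#' @return The report, invisibly (a named list, also written as JSON).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- validate_config(config, output_dir)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(cfg$output_dir, "pipeline.log")
  cat("", file = logf)
  report <- list(config = cfg[setdiff(names(cfg), "output_dir")],
                 inputs = lapply(cfg[c("fasta", "metadata", "genemap",
                                       "calibrations")],
                                 function(p) unname(tools::md5sum(p))))

  st <- new.env()
  stage <- function(name, fun) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    t0 <- Sys.time()
    ok <- tryCatch({ fun(); TRUE }, error = function(e) {
      cat(sprintf("[%s] FAILED: %s\n", name, conditionMessage(e)),
          file = logf, append = TRUE)
      stop("pipeline halted at stage '", name, "': ",
           conditionMessage(e), call. = FALSE)
    })
    cat(sprintf("[%s] done in %.1f s\n", name,
                as.numeric(difftime(Sys.time(), t0, units = "secs"))),
        file = logf, append = TRUE)
  }

  st$records <- read_alignment(cfg$fasta, cfg$metadata)
  st$genemap <- read_genemap(cfg$genemap,
                             cfg$reference %||% rownames(st$records$seq)[1])
  st$reference <- cfg$reference %||% rownames(st$records$seq)[1]
  st$outgroup <- cfg$outgroup %||%
    st$records$meta$id[st$records$meta$btype %in% c("river", "outgroup")]
  st$swamp_ids <- st$records$meta$id[st$records$meta$btype == "swamp"]

  stage("collapse", function() {
    st$ht <- collapse_haplotypes(st$records, reference = st$reference,
                                 genemap = st$genemap)
    if (!is.null(cfg$rules)) {
      st$ht <- assign_haplogroups(st$ht, read_haplogroup_rules(cfg$rules))
    }
    write_haplotype_table(st$ht, file.path(cfg$output_dir, "haplotypes.tsv"))
    report$haplotypes <<- list(n = nrow(st$ht$haplotypes))
  })

  stage("diversity", function() {
    swamp <- subset_records(st$records, st$swamp_ids)
    ht_sw <- collapse_haplotypes(swamp, reference = st$reference,
                                 genemap = st$genemap)
    ds <- diversity_summary(swamp, ht_sw, genemap = st$genemap,
                            reference = st$reference)
    utils::write.table(ds, file.path(cfg$output_dir, "diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$diversity <<- as.list(ds)
  })

  stage("mask", function() {
    st$coding <- extract_coding(st$records, st$genemap,
                                reference = st$reference)
    st$anc <- infer_ancestral(st$coding, outgroup_ids = st$outgroup)
    st$masked <- mask_nonsynonymous(st$coding, st$anc)
    write_masked(st$masked, file.path(cfg$output_dir, "masked.fa"),
                 file.path(cfg$output_dir, "mask_audit.tsv"))
    report$coding <<- list(length_nt = st$masked$length_nt,
                           codons = st$masked$codon_count)
  })

  stage("tree", function() {
    if (is.null(st$ht))
      st$ht <- collapse_haplotypes(st$records, reference = st$reference,
                                   genemap = st$genemap)
    reps <- vapply(st$ht$members, `[`, "", 1L)
    og_reps <- unique(vapply(st$outgroup, function(o)
      reps[vapply(st$ht$members, function(m) o %in% m, logical(1))][1],
      character(1)))
    og_reps <- og_reps[!is.na(og_reps)]
    st$reps <- reps
    src <- if (!is.null(st$masked)) st$masked else st$records
    mat <- sequence_matrix(src)[reps, , drop = FALSE]
    st$tree <- mp_search(mat, outgroup = og_reps, seed = cfg$tree_seed)
    anc <- if (!is.null(st$anc)) st$anc else NULL
    st$tree <- assign_branch_mutations(st$tree, mat, anc)
    ape::write.tree(st$tree, file.path(cfg$output_dir, "mp_tree.nwk"))
    report$tree <<- list(n_tips = length(st$tree$tip.label),
                         length = attr(st$tree, "pscore"))
  })

  stage("date", function() {
    calibs <- read_calibrations(cfg$calibrations)
    sites <- if (cfg$site_unit == "codon") st$masked$codon_count
      else st$masked$length_nt
    ta <- st$records$meta$tip_age
    names(ta) <- st$records$meta$id
    ta <- ta[names(ta) %in% st$tree$tip.label & ta > 0]
    st$fit <- fit_clock(st$tree, calibs, site_count = sites,
                        tip_ages = if (length(ta)) ta else NULL)
    write_dated_tree(st$fit, file.path(cfg$output_dir, "dated.nwk"))
    swamp_reps <- intersect(st$tree$tip.label,
                            unname(st$reps[vapply(st$ht$members, function(m)
                              any(m %in% st$swamp_ids), logical(1))]))
    rep_tab <- node_age_report(st$fit, list(swamp = swamp_reps))
    utils::write.table(rep_tab, file.path(cfg$output_dir, "node_ages.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$clock <<- list(rate = st$fit$rate, rate_se = st$fit$rate_se,
                          site_count = st$fit$site_count,
                          swamp_mrca_ky = rep_tab$age_ky[1],
                          swamp_mrca_se_ky = rep_tab$se_ky[1])
  })

  stage("skyline", function() {
    swamp_reps <- intersect(st$tree$tip.label,
                            unname(st$reps[vapply(st$ht$members, function(m)
                              any(m %in% st$swamp_ids), logical(1))]))
    gen <- genealogy_from_tree(st$fit$tree, 1000 * st$fit$node_ages_ky,
                               tips = swamp_reps)
    traj <- run_skyline_mcmc(gen, m_groups = cfg$skyline_groups,
                             iters = cfg$skyline_iters,
                             thin = cfg$skyline_thin,
                             seed = cfg$skyline_seed,
                             gen_time = cfg$gen_time)
    write_skyline(traj, file.path(cfg$output_dir, "skyline.tsv"))
    report$skyline <<- list(ess = attr(traj, "ess"),
                            converged = attr(traj, "converged"),
                            nef_recent = traj$median_nef[1],
                            nef_max = max(traj$median_nef))
  })

  jsonlite::write_json(report, file.path(cfg$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_config <- function(config, output_dir = NULL) {
  need <- c("fasta", "metadata", "genemap", "calibrations")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config missing entries: ",
                         paste(miss, collapse = ", "))
  for (p in c(need, if (!is.null(config$rules)) "rules")) {
    if (!file.exists(config[[p]]))
      stop("config path does not exist: ", p, " = ", config[[p]])
  }
  all_stages <- c("collapse", "diversity", "mask", "tree", "date", "skyline")
  config$stages <- config$stages %||% all_stages
  bad <- setdiff(config$stages, all_stages)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  config$tree_seed <- as.integer(config$tree_seed %||% 7L)
  config$skyline_seed <- as.integer(config$skyline_seed %||% 11L)
  config$site_unit <- config$site_unit %||% "codon"
  if (!config$site_unit %in% c("codon", "nt"))
    stop("site_unit must be 'codon' or 'nt'")
  config$skyline_groups <- as.integer(config$skyline_groups %||% 10L)
  config$skyline_iters <- as.integer(config$skyline_iters %||% 100000L)
  config$skyline_thin <- as.integer(config$skyline_thin %||% 100L)
  config$gen_time <- as.numeric(config$gen_time %||% 6)
  config$output_dir <- output_dir %||% config$output_dir %||% "mitochronos_out"
  config
}
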