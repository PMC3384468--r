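# Stage orchestration: runs the analysis stages over a (typically
# synthetic) study directory, writing diff-able TSV/JSON artifacts plus a
# manifest recording inputs, parameters and seed. Each stage reads the
# artifacts of its upstream stage and fails with the name of the stage
# that produces a missing input.

default_config <- function() {
  list(species = "synthetic_human",
       n_targets = 2L,            # diverged genomes derived from the reference
       scale = 0.1,               # class-size multiplier on the reference spec
       n_codons = 120L,
       substitution_rate = 0.02,
       delta_gc3_by_category = c(BLUE = -0.03, BLACK = -0.04, RED = -0.06),
       min_class_size = 2L,       # scaled-down synthetic classes are small
       evalue_max = 1e-5,
       alpha = 0.05,
       n_perm = 1000L,
       band_slope = 6,
       cds_policy = "strict")
}

artifact <- function(out_dir, name) file.path(out_dir, name)

require_artifact <- function(out_dir, name, producer) {
  p <- artifact(out_dir, name)
  if (!file.exists(p))
    stop_kog(sprintf("missing artifact '%s'; run stage '%s' first", name, producer),
             "kogGC3_missing_artifact")
  p
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages over a study directory. `"simulate"` generates
#' a reference genome plus diverged target genomes, a gene-to-class map
#' and a band map; the analysis stages (`"compose"`, `"classify"`,
#' `"orthologs"`, `"categories"`, `"definetti"`, `"butterfly"`,
#' `"bands"`) each read their upstream artifacts from `out_dir` and write
#' TSV/JSON results there. `"all"` chains every stage. A `manifest.json`
#' records configuration, seed and package version; identical
#' (config, seed) reruns reproduce identical artifacts.
#'
#' @param stages Character vector of stage names, or `"all"`.
#' @param out_dir Study directory (created if needed).
#' @param seed Integer master seed (mandatory; stage-specific seeds are
#'   derived from it).
#' @param config Named list overriding entries of the default
#'   configuration (species, n_targets, scale, n_codons,
#'   substitution_rate, delta_gc3_by_category, min_class_size, evalue_max,
#'   alpha, n_perm, band_slope, cds_policy).
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(stages = "all", out_dir, seed, config = list(),
                         quiet = FALSE) {
  if (missing(seed)) stop_kog("seed is mandatory", "kogGC3_bad_argument")
  cfg <- utils::modifyList(default_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  all_stages <- c("simulate", "compose", "classify", "orthologs",
                  "categories", "definetti", "butterfly", "bands")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad))
    stop_kog(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
             "kogGC3_bad_argument")
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  for (st in all_stages[all_stages %in% stages]) {
    t1 <- Sys.time()
    switch(st,
           simulate = stage_simulate(out_dir, seed, cfg),
           compose = stage_compose(out_dir, cfg),
           classify = stage_classify(out_dir, cfg),
           orthologs = stage_orthologs(out_dir, cfg),
           categories = stage_categories(out_dir, cfg),
           definetti = stage_definetti(out_dir, seed, cfg),
           butterfly = stage_butterfly(out_dir, cfg),
           bands = stage_bands(out_dir, cfg))
    say("stage %-10s %.1fs", st, as.numeric(Sys.time() - t1, units = "secs"))
  }
  manifest <- list(stages = stages, seed = seed, config = cfg,
                   package_version = as.character(utils::packageVersion("kogGC3")),
                   elapsed_s = as.numeric(Sys.time() - t0, units = "secs"))
  jsonlite::write_json(manifest, artifact(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

species_names <- function(cfg) {
  c(cfg$species,
    if (cfg$n_targets > 0) sprintf("target_%02d", seq_len(cfg$n_targets)))
}

stage_simulate <- function(out_dir, seed, cfg) {
  spec <- table1_spec(cfg$species, scale = cfg$scale, n_codons = cfg$n_codons,
                      seed = derive_seed(seed, 1))
  ref <- generate_genome(spec)
  write_cds_fasta(ref$cds, artifact(out_dir, paste0(cfg$species, ".fasta")))
  write_tsv(ref$map, artifact(out_dir, "kog_map.tsv"))
  write_tsv(ref$truth, artifact(out_dir, paste0(cfg$species, "_truth.tsv")))
  for (i in seq_len(cfg$n_targets)) {
    sp <- sprintf("target_%02d", i)
    tgt <- mutate_orthologs(ref, cfg$substitution_rate,
                            cfg$delta_gc3_by_category,
                            seed = derive_seed(seed, 1 + i), species = sp)
    write_cds_fasta(tgt$cds, artifact(out_dir, paste0(sp, ".fasta")))
    write_tsv(tgt$pairs, artifact(out_dir, paste0(sp, "_true_pairs.tsv")))
  }
  rec <- gene_records(validate_cds(ref$cds, cfg$cds_policy))
  bm <- generate_band_map(rec, slope = cfg$band_slope,
                          seed = derive_seed(seed, 99))
  write_tsv(bm, artifact(out_dir, "band_map.tsv"))
}

stage_compose <- function(out_dir, cfg) {
  for (sp in species_names(cfg)) {
    fa <- require_artifact(out_dir, paste0(sp, ".fasta"), "simulate")
    cds <- validate_cds(read_cds_fasta(fa, sp), cfg$cds_policy)
    write_gene_records(gene_records(cds),
                       artifact(out_dir, paste0(sp, "_genes.tsv")))
  }
}

read_labeled <- function(out_dir, sp) {
  rec <- read_tsv(require_artifact(out_dir, paste0(sp, "_genes.tsv"), "compose"))
  lab <- read_tsv(require_artifact(out_dir, paste0(sp, "_labels.tsv"), "classify"))
  label_records(rec, lab)
}

stage_classify <- function(out_dir, cfg) {
  map <- load_kog_map(require_artifact(out_dir, "kog_map.tsv", "simulate"))
  filt <- apply_kog_filters(map, cfg$min_class_size)
  jsonlite::write_json(filt$report, artifact(out_dir, "filter_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_tsv(filt$map[, c("gene_id", "kog_class")],
            artifact(out_dir, paste0(cfg$species, "_labels.tsv")))
}

stage_orthologs <- function(out_dir, cfg) {
  ref_sp <- cfg$species
  ref_fa <- require_artifact(out_dir, paste0(ref_sp, ".fasta"), "simulate")
  ref_cds <- validate_cds(read_cds_fasta(ref_fa, ref_sp), cfg$cds_policy)
  ref_prot <- setNames(translate_cds(ref_cds$seq), ref_cds$id)
  ref_labels <- read_tsv(require_artifact(out_dir, paste0(ref_sp, "_labels.tsv"),
                                          "classify"))
  for (i in seq_len(cfg$n_targets)) {
    sp <- sprintf("target_%02d", i)
    tgt_cds <- validate_cds(read_cds_fasta(
      require_artifact(out_dir, paste0(sp, ".fasta"), "simulate"), sp),
      cfg$cds_policy)
    tgt_prot <- setNames(translate_cds(tgt_cds$seq), tgt_cds$id)
    fwd <- all_vs_all_search(ref_prot, tgt_prot)
    rev <- all_vs_all_search(tgt_prot, ref_prot)
    pairs <- best_reciprocal_hits(fwd, rev, cfg$evalue_max)
    write_tsv(pairs[, c("ref_id", "target_id", "fwd_evalue", "rev_evalue")],
              artifact(out_dir, paste0(sp, "_pairs.tsv")))
    write_tsv(transfer_labels(pairs, ref_labels)[, c("gene_id", "kog_class")],
              artifact(out_dir, paste0(sp, "_labels.tsv")))
  }
}

stage_categories <- function(out_dir, cfg) {
  res <- list()
  for (sp in species_names(cfg)) {
    rec <- read_labeled(out_dir, sp)
    h <- category_hierarchy_test(rec, cfg$alpha)
    res[[sp]] <- list(verdict = h$verdict, means = as.list(h$means),
                      comparisons = h$comparisons)
  }
  jsonlite::write_json(res, artifact(out_dir, "hierarchy.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  # GC3 increments of the reference over each target, across ortholog pairs
  ref <- read_labeled(out_dir, cfg$species)
  deltas <- list()
  for (i in seq_len(cfg$n_targets)) {
    sp <- sprintf("target_%02d", i)
    pairs <- read_tsv(require_artifact(out_dir, paste0(sp, "_pairs.tsv"),
                                       "orthologs"))
    tgt <- read_tsv(require_artifact(out_dir, paste0(sp, "_genes.tsv"), "compose"))
    d <- delta_gc3(pairs, ref, tgt)
    write_tsv(d$deltas, artifact(out_dir, paste0(sp, "_delta_gc3.tsv")))
    deltas[[sp]] <- list(summary = d$summary,
                         tests = lapply(d$tests, function(t)
                           list(U = t$U, p = t$p)))
  }
  jsonlite::write_json(deltas, artifact(out_dir, "delta_gc3.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

class_table_all <- function(out_dir, cfg) {
  do.call(rbind, lapply(species_names(cfg), function(sp) {
    rec <- read_labeled(out_dir, sp)
    cs <- summarize_by_class(rec)$classes
    data.frame(genome = sp, kog_class = cs$kog_class, category = cs$category,
               mean_gc3 = cs$mean_gc3)
  }))
}

stage_definetti <- function(out_dir, seed, cfg) {
  tab <- class_table_all(out_dir, cfg)
  pts <- do.call(rbind, lapply(split(tab, tab$genome), function(g)
    ternary_points(g, genome = g$genome[1])))
  write_tsv(pts, artifact(out_dir, "ternary_points.tsv"))
  pt <- definetti_permutation_test(tab, n_perm = cfg$n_perm,
                                   seed = derive_seed(seed, 7))
  jsonlite::write_json(list(observed_stat = pt$observed_stat,
                            p_value = pt$p_value, n_perm = pt$n_perm,
                            seed = pt$seed, statistic = pt$statistic),
                       artifact(out_dir, "definetti.json"),
                       auto_unbox = TRUE, digits = NA)
}

stage_butterfly <- function(out_dir, cfg) {
  entries <- list()
  for (sp in species_names(cfg)) {
    rec <- read_labeled(out_dir, sp)
    gm <- mean(rec$gc3)  # synthetic study: full CDS set = KOG subset
    bf <- butterfly_analysis(rec, gm, cfg$alpha)
    write_tsv(as.data.frame(bf), artifact(out_dir, paste0(sp, "_butterfly.tsv")))
    entries[[sp]] <- bf
  }
  if (length(entries) >= 2L)
    write_tsv(butterfly_recurrence(entries),
              artifact(out_dir, "butterfly_recurrence.tsv"))
}

stage_bands <- function(out_dir, cfg) {
  rec <- read_labeled(out_dir, cfg$species)
  bm <- load_band_map(require_artifact(out_dir, "band_map.tsv", "simulate"))
  bf <- band_frequencies(rec, bm)
  write_tsv(cbind(kog_class = rownames(bf$counts), as.data.frame(bf$counts)),
            artifact(out_dir, "band_counts.tsv"))
  cat_counts <- rowsum(bf$counts, kog_classes()$category[
    match(rownames(bf$counts), kog_classes()$letter)])
  chi <- category_band_chisq(cat_counts[c("BLUE", "BLACK", "RED"),
                                        c("H3-", "H3+")])
  bfly <- read_tsv(require_artifact(
    out_dir, paste0(cfg$species, "_butterfly.tsv"), "butterfly"))
  grp <- group_band_comparison(bfly, rec, bm)
  jsonlite::write_json(list(
    chisq = list(chi2 = chi$chi2, df = chi$df, p = chi$p),
    positive_group_h3p_vs_l1p = list(z = grp$test$z, p = grp$test$p),
    group_shares = as.data.frame(grp$group_shares)),
    artifact(out_dir, "band_tests.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
}
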