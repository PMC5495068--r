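#' Read a pipeline configuration file
#'
#' YAML file whose keys override [sim_config()] defaults (generator section)
#' and the analysis thresholds: `W`, `G`, `fdr`, `p_elig` (island caller),
#' `enrich_threshold` (gene overlap rule, 0.8), `min_peri_dist`
#' (pericentromere distance filter, 1 Mb), `n_perm`, `shift_magnitudes`,
#' `body_bins`, `flank`. Unknown keys are an error, so typos cannot silently
#' fall back to defaults.
#'
#' @param path YAML file (or `NULL` for all defaults)
#' @return list with `sim` (a `sim_config`) and `analysis` (threshold list)
#' @export
read_pipeline_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  analysis_defaults <- list(W = 1000, G = 3000, fdr = 0.01, p_elig = 0.2,
                            enrich_threshold = 0.8, min_peri_dist = 1e6,
                            n_perm = 999, shift_magnitudes = c(5e4, 1e5),
                            body_bins = 40, flank = 20000,
                            stages = c("simulate", "tracks", "domains",
                                       "compartments", "enrichment",
                                       "metaprofiles"))
  sim_keys <- names(formals(sim_config))
  bad <- setdiff(names(raw), c(sim_keys, names(analysis_defaults)))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  analysis <- utils::modifyList(analysis_defaults,
                                raw[intersect(names(raw), names(analysis_defaults))])
  sim <- do.call(sim_config, raw[intersect(names(raw), sim_keys)])
  list(sim = sim, analysis = analysis)
}

#' End-to-end domain recovery on synthetic data
#'
#' The headline parameter-recovery run: simulates the standard dataset
#' (two GFP replicates plus matched IgG), bins fragments at W, calls islands
#' per replicate, intersects the replicates, subtracts pericentromeric bp
#' (true domains are defined on the arms; pericentromeric heterochromatin is
#' treated as its own, constitutively peripheral compartment), and compares
#' the result with the ground truth.
#'
#' @param config a `sim_config`
#' @param params an `island_params`
#' @return list with `layout`, `truth` (true domains), `called` (replicate-
#'   intersected, pericentromere-subtracted domains), `summary` (from
#'   [domain_summary()]), `coverage_pct` (percent of genome bp covered),
#'   `median_length_kb`, `jaccard` (bp-Jaccard vs truth), `dataset`
#' @export
domain_recovery <- function(config = sim_config(seed = 7),
                            params = island_params()) {
  layout <- simulate_layout(config)
  truth <- simulate_true_domains(layout, config)
  frag <- list()
  for (rep in 1:2)
    for (kind in c("GFP", "IgG"))
      frag[[paste0(kind, rep)]] <-
        simulate_fragments(layout, truth, config, kind, rep)
  calls <- call_domains(frag$GFP1, frag$IgG1, frag$GFP2, frag$IgG2,
                        layout, params)
  called <- interval_setdiff(calls$domains, layout$pericentromere)
  summ <- domain_summary(called, layout)
  list(layout = layout, truth = truth, called = called, summary = summ,
       coverage_pct = 100 * summ$genome_coverage,
       median_length_kb = summ$median_length / 1000,
       jaccard = bp_jaccard(called, truth),
       replicate_calls = calls)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Orchestrates simulate -> tracks -> domain calling -> compartments ->
#' enrichment -> metaprofiles from one configuration, writing every stage's
#' outputs under `outdir` and a JSON manifest listing them. All randomness
#' flows from `seed`; rerunning with the same config and seed reproduces the
#' BED/TSV outputs byte-identically.
#'
#' @param config path to a YAML config file, or a list as returned by
#'   [read_pipeline_config()]
#' @param seed root seed (overrides the config's seed)
#' @param outdir output directory
#' @return (invisibly) the manifest list
#' @export
run_pipeline <- function(config = NULL, seed = 7, outdir = "pipeline_out") {
  cfg <- if (is.character(config)) read_pipeline_config(config)
         else if (is.null(config)) read_pipeline_config()
         else config
  sim <- cfg$sim
  sim$seed <- seed
  an <- cfg$analysis
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed,
                   config_hash = unname(tools::md5sum(
                     {f <- file.path(outdir, "config.yaml")
                      yaml::write_yaml(c(unclass(sim), an[setdiff(names(an), "stages")]), f)
                      f})),
                   thresholds = an[c("W", "G", "fdr", "p_elig",
                                     "enrich_threshold", "min_peri_dist")],
                   stages = list())
  stage_env <- new.env(parent = emptyenv())
  outputs <- character(0)

  run_stage <- function(name, fun) {
    if (!name %in% an$stages) return(invisible(NULL))
    message("[", name, "] running")
    paths <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages[[name]] <<- list(status = "ok", outputs = paths)
    outputs <<- c(outputs, paths)
  }

  run_stage("simulate", function() {
    d <- file.path(outdir, "data")
    stage_env$ds <- simulate_dataset(sim, outdir = d)
    message("  simulated ", nrow(stage_env$ds$truth$domains),
            " true domains, ", nrow(stage_env$ds$genes), " genes")
    list.files(d, full.names = TRUE)
  })
  run_stage("tracks", function() {
    ds <- stage_env$ds
    paths <- character(0)
    for (w in c(50000, 20000)) {
      gfp <- normalize_per_million(bin_fragments(ds$fragments$GFP_rep1,
                                                 ds$layout, w))
      igg <- normalize_per_million(bin_fragments(ds$fragments$IgG_rep1,
                                                 ds$layout, w))
      lr <- log2_ratio(gfp, igg)
      p <- file.path(outdir, sprintf("signal_log2_%dkb.bedGraph", w / 1000))
      write_bedgraph(track_to_bedgraph(lr, ds$layout), p)
      stage_env[[paste0("signal_", w)]] <- lr
      paths <- c(paths, p)
    }
    paths
  })
  run_stage("domains", function() {
    ds <- stage_env$ds
    params <- island_params(an$W, an$G, an$fdr, an$p_elig)
    calls <- call_domains(ds$fragments$GFP_rep1, ds$fragments$IgG_rep1,
                          ds$fragments$GFP_rep2, ds$fragments$IgG_rep2,
                          ds$layout, params)
    stage_env$domains <- calls$domains
    summ <- domain_summary(calls$domains, ds$layout)
    message("  W=", an$W, " G=", an$G, " FDR<", an$fdr, ": ",
            summ$count, " domains, ",
            round(100 * summ$genome_coverage, 1), "% of the genome")
    p1 <- file.path(outdir, "domains.bed")
    dom_bed <- calls$domains
    dom_bed$name <- sprintf("domain_%d", seq_len(nrow(dom_bed)))
    write_bed(dom_bed, p1)
    p2 <- file.path(outdir, "domain_summary.tsv")
    utils::write.table(as.data.frame(summ), p2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    c(p1, p2)
  })
  run_stage("compartments", function() {
    ds <- stage_env$ds
    sig <- stage_env[["signal_20000"]]
    paths <- character(0)
    for (ch in names(ds$hic$matrices)) {
      res <- compartment_analysis(ds$hic$matrices[[ch]], ds$layout, ch, sig)
      rows <- do.call(rbind, lapply(names(res), function(arm) {
        r <- res[[arm]]
        data.frame(chrom = ch, start = (r$bins - 1) * sim$hic_binsize,
                   end = r$bins * sim$hic_binsize, value = r$scores,
                   label = r$labels, arm = arm)
      }))
      p <- file.path(outdir, sprintf("compartments_%s.tsv", ch))
      utils::write.table(rows, p, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, p)
    }
    paths
  })
  run_stage("enrichment", function() {
    ds <- stage_env$ds
    domains <- stage_env$domains
    far <- filter_pericentromere_distance(domains, ds$layout, an$min_peri_dist)
    res <- list()
    for (bt in c("TE_gene", "protein_coding", "pseudogene")) {
      pt <- permutation_test(
        function(d) count_genes_in_domains(ds$genes, d, bt),
        far, ds$layout, n_perm = an$n_perm,
        magnitudes = an$shift_magnitudes, seed = seed + 101)
      res[[bt]] <- list(observed = pt$observed, null_mean = mean(pt$null),
                        p_greater = pt$p_greater)
      message("  ", bt, ": observed ", pt$observed, ", null mean ",
              round(mean(pt$null), 1), ", p = ", signif(pt$p_greater, 3))
    }
    enr <- assign_enriched_genes(ds$genes, domains, an$enrich_threshold)
    pc <- ds$genes$biotype == "protein_coding"
    res$expression <- rank_sum_compare(ds$genes$expression[pc & enr],
                                       ds$genes$expression[pc & !enr])
    res$loops <- classify_loops(ds$loops, domains)
    p <- file.path(outdir, "enrichment.json")
    jsonlite::write_json(res, p, auto_unbox = TRUE, digits = NA)
    p
  })
  run_stage("metaprofiles", function() {
    ds <- stage_env$ds
    domains <- stage_env$domains
    tes <- ds$genes[ds$genes$biotype == "TE_gene", , drop = FALSE]
    groups <- group_tes_by_location(
      tes, interval_union(rbind(domains[, c("chrom", "start", "end")],
                                ds$layout$pericentromere)))
    rows <- list()
    for (gt in names(ds$methylation))
      for (grp in names(groups)) {
        if (nrow(groups[[grp]]) == 0) next
        for (ctx in c("CG", "CHG", "CHH")) {
          prof <- scaled_body_profile(ds$methylation[[gt]][[ctx]],
                                      groups[[grp]], bins = an$body_bins)
          rows[[length(rows) + 1]] <- cbind(genotype = gt, group = grp,
                                            context = ctx, prof)
        }
      }
    p <- file.path(outdir, "methylation_metaprofiles.tsv")
    utils::write.table(do.call(rbind, rows), p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p
  })

  missing <- outputs[!file.exists(outputs)]
  if (length(missing)) stop("manifest lists missing outputs: ",
                            paste(missing, collapse = ", "))
  manifest$version <- as.character(utils::packageVersion("plads"))
  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
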