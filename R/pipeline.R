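#' Pipeline configuration
#'
#' Thresholds, sampling design and output location for [run_pipeline()].
#' Round-trips losslessly through JSON.
#'
#' @param out_dir output directory (created if absent).
#' @param seed master seed; also seeds the embedded [sim_config()] unless a
#'   custom one is given.
#' @param sim a [sim_config()] for the synthetic-data stage, or `NULL` to
#'   reuse `seed` with generator defaults.
#' @param tau ASV assignment threshold (strict >, default 0.8).
#' @param alpha envfit / phylosig significance level.
#' @param abundance_threshold specialist mean-western-abundance floor.
#' @param min_fraction OG prevalence filter.
#' @param k ordination dimension.
#' @param n_permutations permutation count for envfit.
#' @param n_sim Brownian simulations for phylANOVA.
#' @return an object of class `popspec_pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed, sim = NULL, tau = 0.8,
                            alpha = 0.05, abundance_threshold = 0.01,
                            min_fraction = 0.5, k = 2L,
                            n_permutations = 999L, n_sim = 10000L) {
  stopifnot(tau > 0, tau < 1, alpha > 0, alpha < 1,
            abundance_threshold >= 0, abundance_threshold < 1,
            min_fraction >= 0, min_fraction <= 1, k >= 1)
  if (is.null(sim)) sim <- sim_config(seed = seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 tau = tau, alpha = alpha,
                 abundance_threshold = abundance_threshold,
                 min_fraction = min_fraction, k = as.integer(k),
                 n_permutations = as.integer(n_permutations),
                 n_sim = as.integer(n_sim)),
            class = "popspec_pipeline_config")
}

#' Run the full synthetic-data pipeline
#'
#' Chains simulate -> assign -> aggregate -> enrich -> classify-specialists
#' -> phylo-assoc -> convergence. Gene trees for the convergence stage are,
#' in the absence of externally supplied trees, the species tree pruned to
#' the genomes carrying each retained OG. All stage outputs plus a
#' machine-readable run manifest are written under `config$out_dir`; a stage
#' failure aborts with the stage name while retaining earlier outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisible list with all stage results (`tree`, `metadata`,
#'   `asv_tables`, `assignments`, `abundance`, `specialists`, `phylanova`,
#'   `gene_assoc`, `convergent_ogs`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "popspec_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "popspec",
    version = as.character(utils::packageVersion("popspec")),
    r_version = R.version.string,
    seed = config$seed,
    thresholds = list(tau = config$tau, alpha = config$alpha,
                      abundance_threshold = config$abundance_threshold,
                      min_fraction = config$min_fraction, k = config$k,
                      n_permutations = config$n_permutations,
                      n_sim = config$n_sim),
    stages = list()
  )
  res <- list()
  stage <- function(name, fn) {
    out <- tryCatch(fn(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, force = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(status = "ok")
    out
  }

  res$tree <- stage("simulate", function() {
    ptree <- simulate_population_tree(config$sim)
    res$metadata <<- simulate_sample_metadata(config$sim)
    res$alignments <<- simulate_marker_alignments(ptree, config$sim)
    res$asv_tables <<- simulate_asv_tables(ptree, res$alignments,
                                           res$metadata, config$sim)
    res$gene_pa <<- simulate_gene_pa(ptree, config$sim)
    res$rates <<- simulate_rates(ptree, config$sim)
    write_population_tree(ptree, file.path(config$out_dir, "tree.nwk"))
    write_tsv(res$metadata, file.path(config$out_dir, "metadata.tsv"))
    write_tsv(data.frame(mc = ptree$specialist_mcs),
              file.path(config$out_dir, "ground_truth_specialists.tsv"))
    for (m in names(res$asv_tables)) {
      write_tsv(res$asv_tables[[m]]$counts,
                file.path(config$out_dir, paste0("counts_", m, ".tsv")),
                row_names = TRUE)
      write_fasta(res$asv_tables[[m]]$sequences,
                  file.path(config$out_dir, paste0("asv_", m, ".fasta")))
    }
    write_tsv(res$gene_pa$pa, file.path(config$out_dir, "gene_pa.tsv"),
              row_names = TRUE)
    ptree
  })

  res$assignments <- stage("assign", function() {
    lapply(names(res$asv_tables), function(m) {
      aln <- res$alignments[[m]]
      tab <- res$asv_tables[[m]]
      ref <- labeled_alignment(aln$seqs[aln$group == "ingroup"],
                               rep("ingroup", sum(aln$group == "ingroup")),
                               mc = aln$mc, marker = m)
      ja <- align_queries_to_reference(ref, tab$sequences)
      jt <- build_joint_tree(ja$alignment, names(ref$seqs),
                             res$tree$mc_of_tip[names(ref$seqs)])
      asg <- assign_all_asvs(jt, tau = config$tau)
      write_tsv(asg, file.path(config$out_dir, paste0("assignments_", m, ".tsv")))
      asg
    }) |> stats::setNames(names(res$asv_tables))
  })

  res$abundance <- stage("aggregate", function() {
    lapply(names(res$asv_tables), function(m) {
      agg <- aggregate_population_abundance(res$asv_tables[[m]],
                                            res$assignments[[m]])
      write_tsv(agg$abundance,
                file.path(config$out_dir, paste0("mc_abundance_", m, ".tsv")),
                row_names = TRUE)
      agg$abundance
    }) |> stats::setNames(names(res$asv_tables))
  })

  res$specialists <- stage("classify_specialists", function() {
    scr <- specialist_screen(res$abundance, res$metadata$site_group,
                             alpha = config$alpha,
                             abundance_threshold = config$abundance_threshold,
                             n_permutations = config$n_permutations,
                             seed = child_seed(config$seed, 7L),
                             k = config$k)
    for (m in names(scr$screens)) {
      write_tsv(scr$screens[[m]],
                file.path(config$out_dir, paste0("envfit_", m, ".tsv")))
    }
    write_tsv(scr$calls, file.path(config$out_dir, "specialist_calls.tsv"))
    scr$calls
  })

  called <- res$specialists$mc[res$specialists$call == "specialist"]
  spec_of_genome <- stats::setNames(
    res$tree$mc_of_tip %in% called, names(res$tree$mc_of_tip))

  res$phylanova <- stage("phylanova", function() {
    if (length(unique(spec_of_genome)) < 2L) return(NULL)
    pa <- phylanova(res$tree$tree,
                    groups = ifelse(spec_of_genome, "specialist", "non-specialist"),
                    trait = res$rates, n_sim = config$n_sim,
                    seed = child_seed(config$seed, 8L))
    write_tsv(data.frame(F = pa$F, p = pa$p, n_sim = pa$n_simulations,
                         sigma2_hat = pa$sigma2_hat),
              file.path(config$out_dir, "phylanova.tsv"))
    pa
  })

  res$gene_assoc <- stage("phylo_assoc", function() {
    if (length(unique(spec_of_genome)) < 2L) return(NULL)
    ga <- gene_trait_association_workflow(res$tree$tree, res$gene_pa$pa,
                                          spec_of_genome,
                                          alpha = config$alpha)
    write_tsv(ga, file.path(config$out_dir, "gene_association.tsv"))
    ga
  })

  res$convergent_ogs <- stage("convergence", function() {
    kept <- filter_ogs(res$gene_pa$pa, min_fraction = config$min_fraction)
    calls <- lapply(kept, function(og) {
      carriers <- rownames(res$gene_pa$pa)[res$gene_pa$pa[, og] == 1]
      if (length(carriers) < 2L) {
        return(list(convergent = FALSE, witness_node = NA_integer_,
                    specialist_mcs_in_clade = character(0), clade_size = 0L))
      }
      gt <- ape::keep.tip(res$tree$tree, carriers)
      detect_specialist_convergent_clade(gt, res$tree$mc_of_tip, called)
    })
    names(calls) <- kept
    summ <- summarize_convergent_ogs(calls)
    write_tsv(summ, file.path(config$out_dir, "convergent_ogs.tsv"))
    summ
  })

  manifest$stages <- manifest$stages[c("simulate", "assign", "aggregate",
                                       "classify_specialists", "phylanova",
                                       "phylo_assoc", "convergence")]
  res$manifest <- manifest
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(res)
}
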