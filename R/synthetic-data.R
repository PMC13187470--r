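#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator. One master `seed`
#' fully determines all outputs; each generator stage draws from a child
#' stream derived with [child_seed()] so stages can be re-run independently.
#'
#' Defaults state the emulated world: a genus split into 20 sub-genus
#' populations ("main clusters", MCs) of 4 isolates each, of which 4 MCs are
#' planted specialists; 4 reef sites (2 western high-nutrient, 2 non-western)
#' with 6 coral samples each (12 per site group); a 10-fold specialist
#' enrichment at western sites on the Dirichlet-multinomial scale; marker
#' divergence calibrated so within-MC identity is ~99% and between-MC
#' identity 80-97%, matching sub-genus population structure.
#'
#' @param seed master seed (required integer).
#' @param n_populations number of MCs (>= 2).
#' @param isolates_per_population tips per MC (>= 3).
#' @param n_specialists number of planted specialist MCs.
#' @param depth_fraction within-MC subtree depth as a fraction of backbone
#'   depth (< 0.05 so within-MC similarity exceeds between-MC similarity).
#' @param n_sites,samples_per_site sampling design; the first
#'   `ceiling(n_sites/2)` sites form the western (high-nutrient) group.
#' @param enrichment_log_fold planted log-fold specialist effect on Dirichlet
#'   concentrations at western sites (0 = null world).
#' @param dm_overdispersion Dirichlet-multinomial concentration theta (> 0;
#'   smaller = more overdispersed).
#' @param sequencing_depth reads per sample (> 0).
#' @param read_noise per-base substitution probability applied once per
#'   ASV sequence (default 0: ASVs equal reference sequences).
#' @param baseline_log_sd SD of the lognormal baseline MC abundance profile.
#' @param mutation_rate substitutions/site per unit branch length for the
#'   Jukes-Cantor marker simulation.
#' @param marker_lengths named integer vector of alignment lengths for the
#'   two taxonomic markers and the functional marker.
#' @param functional_marker_carriage probability a non-specialist tip carries
#'   the functional marker (specialist tips always carry it).
#' @param n_outgroups,outgroup_extra_depth,n_diagnostic_cols outgroup rows
#'   per alignment, extra branch length from the root to each outgroup, and
#'   number of planted genus-diagnostic columns.
#' @param bm_sigma2 Brownian-motion rate for trait simulation (> 0).
#' @param specialist_rate_shift additive trait shift for specialist tips.
#' @param gene_gain_rate,gene_loss_rate two-state Markov rates for gene
#'   presence/absence evolution (> 0).
#' @param n_genes,n_associated_genes,assoc_rate_multiplier gene-content
#'   simulation size, number of planted specialist-associated genes, and the
#'   gain/loss rate bias applied on specialist branches for those genes.
#' @return an object of class `popspec_sim_config` (a validated list).
#' @export
sim_config <- function(seed,
                       n_populations = 20L,
                       isolates_per_population = 4L,
                       n_specialists = 4L,
                       depth_fraction = 0.04,
                       n_sites = 4L,
                       samples_per_site = 6L,
                       enrichment_log_fold = log(10),
                       dm_overdispersion = 200,
                       sequencing_depth = 20000L,
                       read_noise = 0,
                       baseline_log_sd = 1,
                       mutation_rate = 0.1,
                       marker_lengths = c(taxonomic_1 = 600L, taxonomic_2 = 560L,
                                          functional = 420L),
                       functional_marker_carriage = 0.8,
                       n_outgroups = 3L,
                       outgroup_extra_depth = 1,
                       n_diagnostic_cols = 40L,
                       bm_sigma2 = 1,
                       specialist_rate_shift = 0,
                       gene_gain_rate = 0.5,
                       gene_loss_rate = 0.5,
                       n_genes = 100L,
                       n_associated_genes = 10L,
                       assoc_rate_multiplier = 8) {
  if (missing(seed)) stop("sim_config(): a master seed is required")
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (n_populations < 2) stop("n_populations must be >= 2")
  if (isolates_per_population < 3) {
    stop("isolates_per_population must be >= 3 (each MC needs at least three isolates)")
  }
  if (n_specialists < 0 || n_specialists > n_populations) {
    stop("n_specialists must be in [0, n_populations]")
  }
  if (depth_fraction <= 0 || depth_fraction >= 0.05) {
    stop("depth_fraction must be in (0, 0.05)")
  }
  if (n_sites < 2) stop("n_sites must be >= 2 (need two site groups)")
  check_positive(dm_overdispersion, "dm_overdispersion")
  check_positive(bm_sigma2, "bm_sigma2")
  check_positive(gene_gain_rate, "gene_gain_rate")
  check_positive(gene_loss_rate, "gene_loss_rate")
  check_scalar_prob(functional_marker_carriage, "functional_marker_carriage")
  check_scalar_prob(read_noise, "read_noise")
  if (sequencing_depth <= 0) stop("sequencing_depth must be positive")
  stopifnot(all(c("taxonomic_1", "taxonomic_2", "functional") %in% names(marker_lengths)))
  cfg <- list(
    seed = as.integer(seed), n_populations = as.integer(n_populations),
    isolates_per_population = as.integer(isolates_per_population),
    n_specialists = as.integer(n_specialists), depth_fraction = depth_fraction,
    n_sites = as.integer(n_sites), samples_per_site = as.integer(samples_per_site),
    enrichment_log_fold = enrichment_log_fold,
    dm_overdispersion = dm_overdispersion,
    sequencing_depth = as.integer(sequencing_depth), read_noise = read_noise,
    baseline_log_sd = baseline_log_sd, mutation_rate = mutation_rate,
    marker_lengths = marker_lengths,
    functional_marker_carriage = functional_marker_carriage,
    n_outgroups = as.integer(n_outgroups),
    outgroup_extra_depth = outgroup_extra_depth,
    n_diagnostic_cols = as.integer(n_diagnostic_cols),
    bm_sigma2 = bm_sigma2, specialist_rate_shift = specialist_rate_shift,
    gene_gain_rate = gene_gain_rate, gene_loss_rate = gene_loss_rate,
    n_genes = as.integer(n_genes),
    n_associated_genes = as.integer(n_associated_genes),
    assoc_rate_multiplier = assoc_rate_multiplier
  )
  structure(cfg, class = "popspec_sim_config")
}

# --- tree helpers ------------------------------------------------------------

rescale_tree_depth <- function(tree, target) {
  d <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * (target / d)
  tree
}

# Compress internal node heights so that the shallowest split is at least
# `1 - max_height` below the tips (tips stay at depth 1). Guarantees that
# between-population distances exceed within-population distances when
# subtrees of bounded depth are grafted at the tips.
compress_internal_heights <- function(tree, max_height) {
  ntip <- length(tree$tip.label)
  h <- ape::node.depth.edgelength(tree) # root = 0
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  hmax <- max(h[internal])
  if (hmax > max_height && hmax > 0) {
    h[internal] <- h[internal] * (max_height / hmax)
    tree$edge.length <- h[tree$edge[, 2]] - h[tree$edge[, 1]]
  }
  tree
}

#' Simulate a population-labelled phylogeny
#'
#' Pure-birth backbone over populations (scaled to depth 1, with internal
#' splits compressed below `1 - 3 * depth_fraction` so populations are
#' well separated), with a pure-birth within-population subtree of depth
#' `depth_fraction` grafted at each backbone tip. A configured subset of MCs
#' is flagged specialist.
#'
#' @param config a [sim_config()].
#' @return an object of class `popspec_tree`: list with `tree` (rooted
#'   ultrametric `phylo`), `mc_of_tip` (named character), `specialist_mcs`.
#' @export
simulate_population_tree <- function(config) {
  stopifnot(inherits(config, "popspec_sim_config"))
  n <- config$n_populations
  m <- config$isolates_per_population
  f <- config$depth_fraction
  with_seed(child_seed(config$seed, 1L), {
    backbone <- ape::rphylo(n, birth = 1, death = 0)
    backbone <- rescale_tree_depth(backbone, 1)
    backbone <- compress_internal_heights(backbone, 1 - 3 * f)
    mcs <- sprintf("MC%d", seq_len(n))
    backbone$tip.label <- mcs
    tree <- backbone
    for (mc in mcs) {
      sub <- ape::rphylo(m, birth = 1, death = 0)
      sub <- rescale_tree_depth(sub, f)
      sub$tip.label <- sprintf("%s-g%02d", mc, seq_len(m))
      sub$root.edge <- 0
      tree <- ape::bind.tree(tree, sub, where = which(tree$tip.label == mc))
    }
    specialists <- sort(sample(mcs, config$n_specialists))
    mc_of_tip <- stats::setNames(sub("-g\\d+$", "", tree$tip.label), tree$tip.label)
    structure(list(tree = tree, mc_of_tip = mc_of_tip,
                   specialist_mcs = specialists),
              class = "popspec_tree")
  })
}

#' @export
print.popspec_tree <- function(x, ...) {
  cat("popspec_tree:", length(x$tree$tip.label), "tips,",
      length(unique(x$mc_of_tip)), "MCs,",
      length(x$specialist_mcs), "specialist MCs",
      if (length(x$specialist_mcs)) paste0("(", paste(x$specialist_mcs, collapse = ", "), ")"),
      "\n")
  invisible(x)
}

#' Simulate per-sample metadata along a nutrient gradient
#'
#' Sites split into a western (high-nutrient) and a non-western group;
#' nutrient covariates are lognormal with group-specific medians chosen to
#' emulate a chronically eutrophic western coastline (nitrate ~8 uM west vs
#' ~1.5 uM elsewhere). Hosts and compartments are cycled deterministically.
#'
#' @param config a [sim_config()].
#' @return a data.frame with columns sample_id, site, site_group, host,
#'   compartment, nitrate_uM, nitrite_uM, ammonia_uM, total_phosphorus_uM.
#' @export
simulate_sample_metadata <- function(config) {
  stopifnot(inherits(config, "popspec_sim_config"))
  n_west <- ceiling(config$n_sites / 2)
  sites <- c(sprintf("W%d", seq_len(n_west)),
             sprintf("E%d", seq_len(config$n_sites - n_west)))
  grp <- ifelse(startsWith(sites, "W"), "western", "non-western")
  site <- rep(sites, each = config$samples_per_site)
  n <- length(site)
  with_seed(child_seed(config$seed, 2L), {
    west <- rep(grp, each = config$samples_per_site) == "western"
    ln <- function(mu_w, mu_e, sd = 0.3) {
      stats::rlnorm(n, meanlog = ifelse(west, log(mu_w), log(mu_e)), sdlog = sd)
    }
    data.frame(
      sample_id = sprintf("S%03d", seq_len(n)),
      site = site,
      site_group = rep(grp, each = config$samples_per_site),
      host = sprintf("host_%d", (seq_len(n) - 1L) %% 5L + 1L),
      compartment = c("mucus", "tissue", "skeleton")[(seq_len(n) - 1L) %% 3L + 1L],
      nitrate_uM = ln(8, 1.5),
      nitrite_uM = ln(0.8, 0.15),
      ammonia_uM = ln(3, 1),
      total_phosphorus_uM = ln(1.5, 0.4),
      stringsAsFactors = FALSE
    )
  })
}

# --- sequence evolution ------------------------------------------------------

.bases <- c("A", "C", "G", "T")

# Jukes-Cantor substitution along one branch: each site flips with
# probability 3/4 (1 - exp(-4/3 rate t)) to one of the three other bases.
jc_mutate <- function(seq_chars, t, rate) {
  p <- 0.75 * (1 - exp(-4 / 3 * rate * t))
  hit <- stats::runif(length(seq_chars)) < p
  if (any(hit)) {
    cur <- seq_chars[hit]
    # uniform over the three non-current bases
    shift <- sample.int(3L, sum(hit), replace = TRUE)
    idx <- (match(cur, .bases) - 1L + shift) %% 4L + 1L
    seq_chars[hit] <- .bases[idx]
  }
  seq_chars
}

# simulate sequences at all tips of `tree` from a random root sequence
sim_jc_tips <- function(tree, len, rate) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root_seq <- sample(.bases, len, replace = TRUE)
  seqs <- vector("list", nnode)
  seqs[[ntip + 1L]] <- root_seq
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    seqs[[ch]] <- jc_mutate(seqs[[p]], tree$edge.length[k], rate)
  }
  tips <- do.call(rbind, seqs[seq_len(ntip)])
  rownames(tips) <- tree$tip.label
  list(tips = tips, root = root_seq)
}

#' Simulate marker alignments with outgroups
#'
#' Evolves each marker under a Jukes-Cantor model along the population tree.
#' The two taxonomic markers are present in every genome; the functional
#' marker is carried by each non-specialist tip with probability
#' `functional_marker_carriage` (specialist tips always carry it). Outgroup
#' sequences are evolved from the root over an extra branch and, at the
#' planted genus-diagnostic columns, ingroup rows are homogenized to the
#' ingroup consensus while outgroups receive a fixed different base — giving
#' genus-discriminating SNP columns for primer design.
#'
#' @param ptree a [simulate_population_tree()] result.
#' @param config a [sim_config()].
#' @return named list of `popspec_alignment` objects (markers `taxonomic_1`,
#'   `taxonomic_2`, `functional`), each a list with `seqs` (named aligned
#'   strings), `group` ("ingroup"/"outgroup"), `mc` (ingroup rows), `marker`,
#'   and attributes `diagnostic_cols`, `carriers`, `degenerate`.
#' @export
simulate_marker_alignments <- function(ptree, config) {
  stopifnot(inherits(ptree, "popspec_tree"), inherits(config, "popspec_sim_config"))
  if (length(ptree$tree$tip.label) == 0) stop("empty tree")
  markers <- c("taxonomic_1", "taxonomic_2", "functional")
  out <- vector("list", length(markers))
  names(out) <- markers
  for (i in seq_along(markers)) {
    marker <- markers[i]
    len <- as.integer(config$marker_lengths[[marker]])
    out[[i]] <- with_seed(child_seed(config$seed, 10L + i), {
      sim <- sim_jc_tips(ptree$tree, len, config$mutation_rate)
      tips <- sim$tips
      # outgroups: extra divergence from the ingroup root
      og <- matrix("", nrow = config$n_outgroups, ncol = len,
                   dimnames = list(sprintf("OUT%d", seq_len(config$n_outgroups)), NULL))
      for (j in seq_len(config$n_outgroups)) {
        og[j, ] <- jc_mutate(sim$root, config$outgroup_extra_depth, config$mutation_rate)
      }
      # planted diagnostic columns: ingroup fixed at consensus, outgroup
      # fixed at the next base in A->C->G->T order
      dcols <- unique(round(seq(10, len - 10, length.out = config$n_diagnostic_cols)))
      for (cc in dcols) {
        tab <- table(tips[, cc])
        cons <- names(tab)[which.max(tab)]
        tips[, cc] <- cons
        og[, cc] <- .bases[match(cons, .bases) %% 4L + 1L]
      }
      carriers <- rownames(tips)
      degenerate <- FALSE
      if (marker == "functional") {
        keep <- stats::runif(nrow(tips)) < config$functional_marker_carriage
        keep[ptree$mc_of_tip[rownames(tips)] %in% ptree$specialist_mcs] <- TRUE
        carriers <- rownames(tips)[keep]
        tips <- tips[keep, , drop = FALSE]
        degenerate <- nrow(tips) == 0L
      }
      seqs <- c(apply(tips, 1, paste, collapse = ""),
                apply(og, 1, paste, collapse = ""))
      aln <- labeled_alignment(
        seqs = seqs,
        group = c(rep("ingroup", nrow(tips)), rep("outgroup", nrow(og))),
        mc = ptree$mc_of_tip[rownames(tips)],
        marker = marker
      )
      attr(aln, "diagnostic_cols") <- dcols
      attr(aln, "carriers") <- carriers
      attr(aln, "degenerate") <- degenerate
      aln
    })
  }
  out
}

#' Simulate ASV count tables per marker
#'
#' Per sample, MC relative abundances are drawn from a Dirichlet with
#' concentration `theta * pi(site)`, where `log pi` is a fixed lognormal
#' baseline profile plus `enrichment_log_fold` for specialist MCs at western
#' sites; read counts are multinomial at the configured sequencing depth.
#' ASV sequences are the simulated marker sequences of the sampled tips,
#' optionally perturbed once per tip by per-base substitution noise.
#'
#' @param ptree a [simulate_population_tree()] result.
#' @param alignments result of [simulate_marker_alignments()].
#' @param metadata result of [simulate_sample_metadata()] (needs >= 2 site
#'   groups).
#' @param config a [sim_config()].
#' @return named list of `popspec_asv_table` objects: `counts` (ASV x sample
#'   integer matrix), `sequences` (named by ASV id), `marker`, `truth`
#'   (data.frame asv_id, mc, tip).
#' @export
simulate_asv_tables <- function(ptree, alignments, metadata, config) {
  stopifnot(inherits(ptree, "popspec_tree"), inherits(config, "popspec_sim_config"))
  if (length(unique(metadata$site_group)) < 2) {
    stop("metadata must define at least two site groups")
  }
  if (config$sequencing_depth <= 0) stop("sequencing depth must be positive")
  mcs <- sort(unique(ptree$mc_of_tip))
  base_log <- with_seed(child_seed(config$seed, 3L), {
    b <- stats::setNames(stats::rnorm(length(mcs), 0, config$baseline_log_sd), mcs)
    # specialists start rare (~0.1-2% of the community) so that the planted
    # enrichment reproduces the 1-10% western vs 0.1-2% non-western pattern
    spec <- intersect(mcs, ptree$specialist_mcs)
    b[spec] <- log(0.1) + stats::rnorm(length(spec), 0, 0.3)
    b
  })
  western <- metadata$site_group == "western"
  out <- vector("list", length(alignments))
  names(out) <- names(alignments)
  for (i in seq_along(alignments)) {
    aln <- alignments[[i]]
    out[[i]] <- with_seed(child_seed(config$seed, 20L + i), {
      carriers <- names(aln$seqs)[aln$group == "ingroup"]
      if (length(carriers) == 0L) {
        return(structure(list(counts = matrix(integer(0), 0, nrow(metadata),
                                              dimnames = list(NULL, metadata$sample_id)),
                              sequences = character(0), marker = aln$marker,
                              truth = data.frame(asv_id = character(0),
                                                 mc = character(0),
                                                 tip = character(0))),
                         class = "popspec_asv_table"))
      }
      tip_mc <- ptree$mc_of_tip[carriers]
      # ASV sequence per carrier tip (noise applied once per tip)
      tip_seq <- aln$seqs[carriers]
      if (config$read_noise > 0) {
        tip_seq <- vapply(tip_seq, function(s) {
          ch <- strsplit(s, "", fixed = TRUE)[[1]]
          paste(jc_mutate_fixed(ch, config$read_noise), collapse = "")
        }, "")
      }
      n_per_mc <- table(tip_mc)
      counts <- matrix(0L, nrow = length(carriers), ncol = nrow(metadata),
                       dimnames = list(carriers, metadata$sample_id))
      for (s in seq_len(nrow(metadata))) {
        lp <- base_log[mcs]
        if (western[s] && length(ptree$specialist_mcs)) {
          lp[ptree$specialist_mcs] <- lp[ptree$specialist_mcs] + config$enrichment_log_fold
        }
        pi_s <- exp(lp - max(lp)); pi_s <- pi_s / sum(pi_s)
        present <- mcs %in% names(n_per_mc)
        pi_s <- pi_s[present] / sum(pi_s[present])
        alpha <- config$dm_overdispersion * pi_s
        g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
        if (sum(g) == 0) g[which.max(alpha)] <- 1
        p_mc <- stats::setNames(g / sum(g), mcs[present])
        p_tip <- p_mc[tip_mc] / as.numeric(n_per_mc[tip_mc])
        counts[, s] <- stats::rmultinom(1, config$sequencing_depth, p_tip)[, 1]
      }
      # collapse identical sequences into ASVs
      uniq <- !duplicated(tip_seq)
      asv_seq <- tip_seq[uniq]
      asv_of_tip <- match(tip_seq, asv_seq)
      asv_id <- sprintf("%s_ASV%03d", aln$marker, seq_along(asv_seq))
      agg <- rowsum(counts, group = asv_id[asv_of_tip])
      mc_per_asv <- vapply(seq_along(asv_seq), function(k) {
        u <- unique(tip_mc[asv_of_tip == k])
        if (length(u) == 1L) u else NA_character_
      }, "")
      truth <- data.frame(asv_id = asv_id, mc = mc_per_asv,
                          tip = carriers[uniq], stringsAsFactors = FALSE)
      keep <- rownames(agg)[rowSums(agg) > 0]
      agg <- agg[keep, , drop = FALSE]
      storage.mode(agg) <- "integer"
      sequences <- stats::setNames(asv_seq, asv_id)[keep]
      structure(list(counts = agg, sequences = sequences, marker = aln$marker,
                     truth = truth[truth$asv_id %in% keep, ]),
                class = "popspec_asv_table")
    })
  }
  out
}

# substitute each base independently with probability p (used for ASV noise)
jc_mutate_fixed <- function(seq_chars, p) {
  hit <- stats::runif(length(seq_chars)) < p
  if (any(hit)) {
    shift <- sample.int(3L, sum(hit), replace = TRUE)
    idx <- (match(seq_chars[hit], .bases) - 1L + shift) %% 4L + 1L
    seq_chars[hit] <- .bases[idx]
  }
  seq_chars
}

#' Simulate a binary gene presence/absence matrix on the tree
#'
#' Each gene evolves as a two-state continuous-time Markov chain
#' (gain rate `gene_gain_rate`, loss rate `gene_loss_rate`) along the tree;
#' root states are stationary. A planted subset of genes is
#' specialist-associated: on branches whose descendant tips all belong to
#' specialist MCs, the gain rate is multiplied and the loss rate divided by
#' `assoc_rate_multiplier`.
#'
#' @param ptree a [simulate_population_tree()] result.
#' @param config a [sim_config()].
#' @return a `popspec_gene_pa` object: `pa` (genomes x genes 0/1 matrix),
#'   `truth` (data.frame gene, associated), `invariant` (genes constant
#'   across genomes, flagged).
#' @export
simulate_gene_pa <- function(ptree, config) {
  stopifnot(inherits(ptree, "popspec_tree"), inherits(config, "popspec_sim_config"))
  a <- config$gene_gain_rate; b <- config$gene_loss_rate
  tree <- ape::reorder.phylo(ptree$tree, "cladewise")
  ntip <- length(tree$tip.label)
  # branch is specialist-context if all descendant tips are specialist-MC tips
  spec_tip <- ptree$mc_of_tip[tree$tip.label] %in% ptree$specialist_mcs
  n_desc <- spec_desc <- numeric(ntip + tree$Nnode)
  po <- ape::reorder.phylo(tree, "postorder")
  n_desc[seq_len(ntip)] <- 1
  spec_desc[seq_len(ntip)] <- as.numeric(spec_tip)
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    n_desc[p] <- n_desc[p] + n_desc[ch]
    spec_desc[p] <- spec_desc[p] + spec_desc[ch]
  }
  spec_branch <- spec_desc[tree$edge[, 2]] == n_desc[tree$edge[, 2]] &
    n_desc[tree$edge[, 2]] > 0
  n_assoc <- min(config$n_associated_genes, config$n_genes)
  genes <- sprintf("gene%03d", seq_len(config$n_genes))
  associated <- c(rep(TRUE, n_assoc), rep(FALSE, config$n_genes - n_assoc))
  with_seed(child_seed(config$seed, 4L), {
    pa <- matrix(0L, nrow = ntip, ncol = config$n_genes,
                 dimnames = list(tree$tip.label, genes))
    for (g in seq_len(config$n_genes)) {
      mult <- if (associated[g]) config$assoc_rate_multiplier else 1
      state <- integer(ntip + tree$Nnode)
      state[ntip + 1L] <- stats::rbinom(1, 1, a / (a + b))
      for (k in seq_len(nrow(tree$edge))) {
        p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
        ga <- if (spec_branch[k]) a * mult else a
        lo <- if (spec_branch[k]) b / mult else b
        t <- tree$edge.length[k]
        tot <- ga + lo
        pstay1 <- ga / tot + lo / tot * exp(-tot * t)
        p01 <- ga / tot * (1 - exp(-tot * t))
        pr <- if (state[p] == 1L) pstay1 else p01
        state[ch] <- stats::rbinom(1, 1, pr)
      }
      pa[, g] <- state[seq_len(ntip)]
    }
    invariant <- genes[apply(pa, 2, function(x) length(unique(x)) == 1L)]
    structure(list(pa = pa,
                   truth = data.frame(gene = genes, associated = associated,
                                      stringsAsFactors = FALSE),
                   invariant = invariant),
              class = "popspec_gene_pa")
  })
}

#' Simulate a phenotype (e.g., denitrification rate) under Brownian motion
#'
#' Brownian-motion realization on the tree with rate `bm_sigma2`, plus
#' `specialist_rate_shift` added to specialist tips. With `log_scale = TRUE`
#' the simulated value is exponentiated, giving a positive rate-like trait.
#'
#' @param ptree a [simulate_population_tree()] result.
#' @param config a [sim_config()].
#' @param log_scale return `exp(trait)` instead of the raw trait.
#' @return named numeric vector, one value per tip.
#' @export
simulate_rates <- function(ptree, config, log_scale = FALSE) {
  stopifnot(inherits(ptree, "popspec_tree"), inherits(config, "popspec_sim_config"))
  tree <- ape::reorder.phylo(ptree$tree, "cladewise")
  ntip <- length(tree$tip.label)
  with_seed(child_seed(config$seed, 5L), {
    x <- numeric(ntip + tree$Nnode)
    incr <- stats::rnorm(nrow(tree$edge), 0,
                         sqrt(config$bm_sigma2 * tree$edge.length))
    for (k in seq_len(nrow(tree$edge))) {
      x[tree$edge[k, 2]] <- x[tree$edge[k, 1]] + incr[k]
    }
    trait <- x[seq_len(ntip)]
    names(trait) <- tree$tip.label
    spec <- ptree$mc_of_tip[names(trait)] %in% ptree$specialist_mcs
    trait[spec] <- trait[spec] + config$specialist_rate_shift
    if (log_scale) exp(trait) else trait
  })
}
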