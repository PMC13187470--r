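# Fixture builders and independent oracles. Oracles deliberately re-derive
# quantities from scratch (recursive descent, naive enumeration, stats::lm)
# rather than calling package internals.

# --- independent descendant enumeration (recursive) --------------------------

oracle_tips_below <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, function(k) oracle_tips_below(tree, k)))
}

# --- brute-force ASV assignment ----------------------------------------------

oracle_assign <- function(tree, tip_kind, mc_of_tip, asv_id, tau = 0.8) {
  tip <- match(asv_id, tree$tip.label)
  node <- tree$edge[tree$edge[, 2] == tip, 1]
  root <- length(tree$tip.label) + 1L
  repeat {
    tips <- tree$tip.label[oracle_tips_below(tree, node)]
    refs <- tips[tip_kind[tips] == "reference"]
    if (length(refs) > 0 || node == root) break
    node <- tree$edge[tree$edge[, 2] == node, 1]
  }
  if (length(refs) == 0) return(NA_character_)
  counts <- table(mc_of_tip[refs])
  top <- names(counts)[counts == max(counts)]
  if (length(top) > 1) return(NA_character_)
  if (max(counts) / length(refs) > tau) top else NA_character_
}

# random joint tree for oracle comparisons
random_joint_tree <- function(n, n_mcs = 3) {
  tr <- ape::rtree(n)
  kinds <- sample(c("reference", "query"), n, replace = TRUE, prob = c(0.75, 0.25))
  if (!any(kinds == "query")) kinds[sample(n, 1)] <- "query"
  if (sum(kinds == "reference") < 1) kinds[which(kinds == "query")[1]] <- "reference"
  mc <- paste0("MC", sample(seq_len(n_mcs), n, replace = TRUE))
  names(kinds) <- names(mc) <- tr$tip.label
  structure(list(tree = tr, tip_kind = kinds,
                 mc_of_tip = mc[names(kinds)[kinds == "reference"]]),
            class = "popspec_joint_tree")
}

# --- brute-force convergence detection ---------------------------------------

oracle_convergent <- function(tree, mc_of_leaf, specialist_mcs) {
  ntip <- length(tree$tip.label)
  for (node in (ntip + 1L):(ntip + tree$Nnode)) {
    mcs <- mc_of_leaf[tree$tip.label[oracle_tips_below(tree, node)]]
    if (all(mcs %in% specialist_mcs) && length(unique(mcs)) >= 2) return(TRUE)
  }
  FALSE
}

# --- brute-force permutation statistics --------------------------------------

# exact permanova p re-derived with fresh code (no shared helpers)
oracle_permanova_exact <- function(d, groups) {
  n <- length(groups)
  ssF <- function(g) {
    sst <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) sst <- sst + d[i, j]^2
    sst <- sst / n
    ssw <- 0
    for (lev in unique(g)) {
      idx <- which(g == lev)
      if (length(idx) > 1) {
        s <- 0
        for (i in idx) for (j in idx) if (i < j) s <- s + d[i, j]^2
        ssw <- ssw + s / length(idx)
      }
    }
    a <- length(unique(g))
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- ssF(groups)
  perms <- oracle_perms(n)
  fs <- apply(perms, 1, function(ix) ssF(groups[ix]))
  list(F = f_obs, p = mean(fs >= f_obs - 1e-12 * (1 + abs(f_obs))))
}

oracle_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- oracle_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(pos) {
    t(apply(sub, 1, function(p) append(p, n, after = pos - 1)))
  }))
}

# exact envfit p via stats::lm per permutation
oracle_envfit_exact <- function(scores, v) {
  r2 <- function(vv) summary(stats::lm(vv ~ scores))$r.squared
  obs <- r2(v)
  perms <- oracle_perms(length(v))
  r2s <- apply(perms, 1, function(ix) r2(v[ix]))
  list(r_squared = obs, p = mean(r2s >= obs - 1e-12 * (1 + abs(obs))))
}

# --- small fixtures ----------------------------------------------------------

# alignment with planted genus-discriminating columns
make_design_alignment <- function(len = 60, snp_cols = c(20, 40),
                                  n_in = 4, n_out = 2, seed = 1) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    base <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    rows <- c(
      stats::setNames(lapply(seq_len(n_in), function(i) base), sprintf("in%d", seq_len(n_in))),
      stats::setNames(lapply(seq_len(n_out), function(i) {
        b <- base
        b[snp_cols] <- vapply(base[snp_cols], function(x) {
          setdiff(c("A", "C", "G", "T"), x)[1]
        }, "")
        b
      }), sprintf("out%d", seq_len(n_out)))
    )
    labeled_alignment(vapply(rows, paste, "", collapse = ""),
                      group = c(rep("ingroup", n_in), rep("outgroup", n_out)))
  })
}
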