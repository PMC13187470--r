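make_ref_aln <- function(seqs) {
  labeled_alignment(seqs, rep("ingroup", length(seqs)))
}

test_that("query alignment preserves the reference frame", {
  set.seed(31)
  ref_seq <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                   collapse = "")
  ref <- make_ref_aln(c(r1 = ref_seq, r2 = ref_seq))

  # identical query: aligned row equals the reference row
  out <- align_queries_to_reference(ref, c(q1 = ref_seq))
  expect_identical(unname(out$alignment[["q1"]]), ref_seq)
  expect_length(out$excluded, 0)

  # one substitution: same placement, one mismatch column
  mut <- strsplit(ref_seq, "")[[1]]
  mut[50] <- setdiff(c("A", "C", "G", "T"), mut[50])[1]
  out2 <- align_queries_to_reference(ref, c(q2 = paste(mut, collapse = "")))
  diffs <- which(strsplit(out2$alignment[["q2"]], "")[[1]] !=
                   strsplit(ref_seq, "")[[1]])
  expect_identical(diffs, 50L)

  # junk query: excluded with a message
  expect_message(
    out3 <- align_queries_to_reference(ref, c(qbad = strrep("A", 120))),
    "excluded"
  )
  expect_identical(out3$excluded, "qbad")
})

test_that("simulated noisy ASVs align at their generating columns", {
  cfg <- sim_config(seed = 77, read_noise = 0.01)
  pt <- simulate_population_tree(cfg)
  md <- simulate_sample_metadata(cfg)
  alns <- simulate_marker_alignments(pt, cfg)
  tb <- simulate_asv_tables(pt, alns, md, cfg)$taxonomic_1
  aln <- alns$taxonomic_1
  ref <- labeled_alignment(aln$seqs[aln$group == "ingroup"],
                           rep("ingroup", sum(aln$group == "ingroup")),
                           mc = aln$mc)
  ja <- align_queries_to_reference(ref, tb$sequences)
  expect_length(ja$excluded, 0)
  # generator emits full-length ungapped ASVs: a correctly placed query is
  # returned verbatim in the reference frame
  placed <- vapply(names(tb$sequences), function(q) {
    identical(unname(ja$alignment[[q]]), unname(tb$sequences[[q]]))
  }, logical(1))
  expect_gte(mean(placed), 0.99)
})

test_that("joint NJ tree is order-invariant and resolves simulated MCs", {
  cfg <- sim_config(seed = 78, n_populations = 5)
  pt <- simulate_population_tree(cfg)
  aln <- simulate_marker_alignments(pt, cfg)$taxonomic_1
  seqs <- aln$seqs[aln$group == "ingroup"]
  jt <- build_joint_tree(seqs, names(seqs)[-(1:2)],
                         pt$mc_of_tip[names(seqs)[-(1:2)]])
  shuffled <- seqs[sample(length(seqs))]
  jt2 <- build_joint_tree(shuffled, names(seqs)[-(1:2)],
                          pt$mc_of_tip[names(seqs)[-(1:2)]])
  expect_identical(ape::write.tree(jt$tree), ape::write.tree(jt2$tree))

  # >= 90% of MCs monophyletic among reference tips
  ref_tree <- ape::keep.tip(jt$tree, names(seqs)[-(1:2)])
  res <- score_population_resolution(ref_tree, pt$mc_of_tip)
  expect_gte(res$fraction_monophyletic, 0.9)

  expect_error(build_joint_tree(seqs[c(1, 1, 2, 3)], names(seqs)[1:3],
                                pt$mc_of_tip),
               "duplicate")
  expect_error(build_joint_tree(seqs[1:3], names(seqs)[1:3], pt$mc_of_tip),
               "at least 4")
})

test_that("the parental-node rule is strict at 80% and handles ascent", {
  mk_jt <- function(text, ref_mcs) {
    tr <- ape::read.tree(text = text)
    kinds <- ifelse(tr$tip.label %in% names(ref_mcs), "reference", "query")
    names(kinds) <- tr$tip.label
    structure(list(tree = tr, tip_kind = kinds, mc_of_tip = ref_mcs),
              class = "popspec_joint_tree")
  }
  # parent subtends five MC6 references -> assigned, fraction 1
  jt1 <- mk_jt("((q,a,b,c,d,e),out);",
               stats::setNames(rep("MC6", 6), c("a", "b", "c", "d", "e", "out")))
  r1 <- assign_asv_to_population(jt1, "q")
  expect_identical(r1$assigned_mc, "MC6")
  expect_identical(r1$supporting_fraction, 1)
  expect_identical(r1$ancestor_depth_used, 0L)

  # 4:1 composition -> fraction exactly 0.8, NOT over 80% -> unassigned
  jt2 <- mk_jt("((q,a,b,c,d,e),out);",
               stats::setNames(c(rep("MC1", 4), "MC3", "MC9"),
                               c("a", "b", "c", "d", "e", "out")))
  r2 <- assign_asv_to_population(jt2, "q")
  expect_true(is.na(r2$assigned_mc))
  expect_identical(r2$supporting_fraction, 0.8)

  # 9:1 -> fraction 0.9 -> assigned MC1
  jt3 <- mk_jt(paste0("((q,", paste(letters[1:10], collapse = ","), "),out);"),
               stats::setNames(c(rep("MC1", 9), "MC3", "MC9"),
                               c(letters[1:10], "out")))
  r3 <- assign_asv_to_population(jt3, "q")
  expect_identical(r3$assigned_mc, "MC1")
  expect_identical(r3$supporting_fraction, 0.9)

  # parent subtends only co-placed queries: ascend minimally, apply once
  jt4 <- mk_jt("(((q,q2),a,b),out);",
               stats::setNames(c("MC5", "MC5", "MC9"), c("a", "b", "out")))
  r4 <- assign_asv_to_population(jt4, "q")
  expect_identical(r4$assigned_mc, "MC5")
  expect_identical(r4$ancestor_depth_used, 1L)

  expect_error(assign_asv_to_population(jt1, "nope"), "not in tree")
  expect_error(assign_asv_to_population(jt1, "a"), "reference tip")
})

test_that("assignment equals brute-force recomputation on random trees", {
  set.seed(41)
  for (r in 1:200) {
    jt <- random_joint_tree(sample(8:30, 1))
    queries <- names(jt$tip_kind)[jt$tip_kind == "query"]
    for (q in queries[seq_len(min(3, length(queries)))]) {
      got <- assign_asv_to_population(jt, q)$assigned_mc
      want <- oracle_assign(jt$tree, jt$tip_kind, jt$mc_of_tip, q)
      expect_identical(got, want)
    }
  }
})

test_that("assignment is invariant to re-rooting outside the local clade", {
  # q's parent clade is (q,a1,a2); rerooting within the distant (d1,d2)
  # clade must not change the verdict
  tr <- ape::read.tree(text = "(((q,a1,a2),(b1,b2)),((c1,c2),(d1,d2)));")
  mcs <- stats::setNames(c("MC1", "MC1", "MC2", "MC2", "MC3", "MC3", "MC4", "MC4"),
                         c("a1", "a2", "b1", "b2", "c1", "c2", "d1", "d2"))
  mk <- function(tree) {
    kinds <- ifelse(tree$tip.label == "q", "query", "reference")
    names(kinds) <- tree$tip.label
    structure(list(tree = tree, tip_kind = kinds, mc_of_tip = mcs),
              class = "popspec_joint_tree")
  }
  r0 <- assign_asv_to_population(mk(tr), "q")
  rr <- ape::root(tr, outgroup = c("d1", "d2"), resolve.root = TRUE)
  r1 <- assign_asv_to_population(mk(rr), "q")
  expect_identical(r0$assigned_mc, r1$assigned_mc)
  expect_identical(r0$supporting_fraction, r1$supporting_fraction)
})

test_that("population abundances aggregate and normalize correctly", {
  counts <- matrix(c(10L, 30L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  asg <- data.frame(asv_id = c("a", "b"), assigned_mc = c("MC1", "MC2"))
  agg <- aggregate_population_abundance(counts, asg)
  expect_identical(unname(agg$abundance[, "s1"]), c(0.25, 0.75))
  expect_length(agg$flagged_samples, 0)

  # all unassigned -> flagged sample
  asg_na <- data.frame(asv_id = c("a", "b"), assigned_mc = NA_character_)
  agg_na <- aggregate_population_abundance(counts, asg_na)
  expect_identical(agg_na$flagged_samples, "s1")

  expect_error(aggregate_population_abundance(counts, asg[1, ]), "missing")

  # noise-free synthetic data: truth-based aggregation reproduces the
  # generating proportions and sums to one
  cfg <- sim_config(seed = 79)
  pt <- simulate_population_tree(cfg)
  md <- simulate_sample_metadata(cfg)
  tb <- simulate_asv_tables(pt, simulate_marker_alignments(pt, cfg), md, cfg)$taxonomic_1
  agg2 <- aggregate_population_abundance(
    tb, data.frame(asv_id = tb$truth$asv_id, assigned_mc = tb$truth$mc))
  expect_true(all(abs(colSums(agg2$abundance) - 1) < 1e-12))
  mc <- tb$truth$mc[match(rownames(tb$counts), tb$truth$asv_id)]
  manual <- rowsum(sweep(tb$counts, 2, colSums(tb$counts), "/"), mc)
  expect_equal(agg2$abundance, manual[rownames(agg2$abundance), ],
               tolerance = 1e-12)
})

test_that("end-to-end placement recovers >= 95% of generating MCs", {
  cfg <- sim_config(seed = 83, read_noise = 0.01,
                    isolates_per_population = 5, n_populations = 10)
  pt <- simulate_population_tree(cfg)
  md <- simulate_sample_metadata(cfg)
  alns <- simulate_marker_alignments(pt, cfg)
  tb <- simulate_asv_tables(pt, alns, md, cfg)$taxonomic_1
  aln <- alns$taxonomic_1
  ref <- labeled_alignment(aln$seqs[aln$group == "ingroup"],
                           rep("ingroup", sum(aln$group == "ingroup")),
                           mc = aln$mc)
  ja <- align_queries_to_reference(ref, tb$sequences)
  jt <- build_joint_tree(ja$alignment, names(ref$seqs),
                         pt$mc_of_tip[names(ref$seqs)])
  asg <- assign_all_asvs(jt)
  truth <- tb$truth$mc[match(asg$asv_id, tb$truth$asv_id)]
  expect_gte(mean(!is.na(asg$assigned_mc) & asg$assigned_mc == truth), 0.95)
})
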