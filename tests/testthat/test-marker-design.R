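test_that("discriminating SNP columns are exactly the set-disjoint ones", {
  aln <- labeled_alignment(
    c(a = "AAC-A", b = "AGC-A", o1 = "GACTA", o2 = "GACTA"),
    group = c("ingroup", "ingroup", "outgroup", "outgroup")
  )
  # col1: {A} vs {G} disjoint; col2: {A,G} vs {A} overlap; col3 identical;
  # col4 gap-containing; col5 identical
  expect_identical(find_discriminating_snps(aln), 1L)

  # randomized columns against a per-column set-disjointness oracle
  set.seed(42)
  for (r in 1:20) {
    n_in <- sample(2:4, 1); n_out <- sample(1:3, 1)
    len <- 30
    mat <- matrix(sample(c("A", "C", "G", "T", "-"), (n_in + n_out) * len,
                         replace = TRUE, prob = c(rep(0.23, 4), 0.08)),
                  n_in + n_out, len)
    seqs <- apply(mat, 1, paste, collapse = "")
    names(seqs) <- c(sprintf("i%d", 1:n_in), sprintf("o%d", 1:n_out))
    aln <- labeled_alignment(seqs, c(rep("ingroup", n_in), rep("outgroup", n_out)))
    got <- find_discriminating_snps(aln)
    want <- which(vapply(seq_len(len), function(j) {
      ci <- mat[1:n_in, j]; co <- mat[-(1:n_in), j]
      !any(c(ci, co) == "-") && !any(ci %in% co) && !any(co %in% ci)
    }, logical(1)))
    expect_identical(got, as.integer(want))
  }

  only_in <- labeled_alignment(c(a = "ACGT"), group = "ingroup")
  expect_error(find_discriminating_snps(only_in), "outgroup")
})

test_that("degenerate consensus follows the IUPAC table", {
  expect_identical(degenerate_consensus("A"), "A")
  expect_identical(degenerate_consensus(c("C", "T")), "Y")
  expect_identical(degenerate_consensus(c("C", "G", "T")), "B")
  expect_identical(degenerate_consensus(c("A", "C", "G", "T")), "N")
  expect_identical(degenerate_consensus(c("A", "A", "G")), "R")
  # IUPAC inputs are expanded before the minimal cover is chosen
  expect_identical(degenerate_consensus(c("R", "C")), "V")
  expect_error(degenerate_consensus(character(0)), "empty")
})

test_that("cross-complementarity equals a brute-force scan", {
  expect_false(check_cross_complementarity(
    "AAAAAAAAAAAAAAAAA", "CCCCCCCCCCCCCCCCC"))
  # palindromic 4-mer: forward ends ACGT, revcomp(ACGT) = ACGT in reverse
  expect_true(check_cross_complementarity("AAAAAAAAAAAAAACGT",
                                          "CCCCCCCACGTCCCCCC"))
  expect_error(check_cross_complementarity("ACGT", "ACGTACGT", k = 5), "k")

  # randomized non-degenerate pairs vs an independent all-window scan
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  set.seed(7)
  n_checked <- 0
  for (r in 1:1000) {
    f <- paste(sample(c("A", "C", "G", "T"), sample(6:12, 1), replace = TRUE),
               collapse = "")
    g <- paste(sample(c("A", "C", "G", "T"), sample(6:12, 1), replace = TRUE),
               collapse = "")
    brute <- grepl(rc(substr(f, nchar(f) - 3, nchar(f))), g, fixed = TRUE) ||
      grepl(rc(substr(g, nchar(g) - 3, nchar(g))), f, fixed = TRUE)
    expect_identical(check_cross_complementarity(f, g, k = 4), brute)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 1000)
})

test_that("product size follows the inclusive primer-name arithmetic", {
  expect_identical(product_size(562, 1111), 550L)
  expect_identical(product_size(668, 1189), 522L)
  expect_identical(product_size(514, 895), 382L)
  expect_identical(product_size(1, 1), 1L)
  expect_error(product_size(10, 9), "reverse")
})

test_that("primer enumeration meets all three criteria and matches brute force", {
  # planted SNPs at columns 20 and 500 in a 520-column alignment
  set.seed(11)
  base <- sample(c("A", "C", "G", "T"), 520, replace = TRUE)
  outg <- base
  for (cc in c(20, 500)) outg[cc] <- setdiff(c("A", "C", "G", "T"), base[cc])[1]
  aln <- labeled_alignment(
    c(i1 = paste(base, collapse = ""), i2 = paste(base, collapse = ""),
      o1 = paste(outg, collapse = "")),
    group = c("ingroup", "ingroup", "outgroup")
  )
  snps <- find_discriminating_snps(aln)
  expect_setequal(snps, c(20L, 500L))
  pairs <- enumerate_primer_pairs(aln, snps)
  expect_gt(nrow(pairs), 0)
  # every pair: forward window covers col 20, reverse covers col 500,
  # product < 600, lengths 17-25, >= 1 SNP per primer, degeneracy <= 16
  expect_true(all(pairs$forward_start <= 20 &
                    pairs$forward_start + nchar(pairs$forward_seq) - 1 >= 20))
  expect_true(all(pairs$reverse_end >= 500 &
                    pairs$reverse_end - nchar(pairs$reverse_seq) + 1 <= 500))
  expect_true(all(pairs$product_size < 600))
  expect_true(all(pairs$product_size ==
                    pairs$reverse_end - pairs$forward_start + 1))
  expect_true(all(nchar(pairs$forward_seq) %in% 17:25))
  expect_true(all(nchar(pairs$reverse_seq) %in% 17:25))
  expect_true(all(pairs$n_snps_forward >= 1 & pairs$n_snps_reverse >= 1))
  expect_true(all(pairs$degeneracy <= 16))

  # SNP reachable by forward windows only -> no pair (criterion i)
  aln1 <- labeled_alignment(
    c(i1 = paste(base[1:100], collapse = ""),
      o1 = paste(c(outg[1:20], base[21:100]), collapse = "")),
    group = c("ingroup", "outgroup")
  )
  expect_identical(nrow(enumerate_primer_pairs(aln1, 20L)), 0L)

  # strict < 600: a pair whose product would be exactly 600 is excluded
  set.seed(12)
  b600 <- sample(c("A", "C", "G", "T"), 600, replace = TRUE)
  o600 <- b600
  for (cc in c(10, 591)) o600[cc] <- setdiff(c("A", "C", "G", "T"), b600[cc])[1]
  aln600 <- labeled_alignment(
    c(i = paste(b600, collapse = ""), o = paste(o600, collapse = "")),
    group = c("ingroup", "outgroup")
  )
  p600 <- enumerate_primer_pairs(aln600, c(10L, 591L), min_len = 17L,
                                 max_len = 17L)
  # the only windows covering both SNPs at length 17 span cols 1..600
  expect_true(all(p600$product_size < 600))

  # enumeration completeness vs naive brute force on a short alignment
  set.seed(13)
  b60 <- sample(c("A", "C", "G", "T"), 60, replace = TRUE)
  o60 <- b60
  for (cc in c(8, 52)) o60[cc] <- setdiff(c("A", "C", "G", "T"), b60[cc])[1]
  aln60 <- labeled_alignment(
    c(i1 = paste(b60, collapse = ""), o1 = paste(o60, collapse = "")),
    group = c("ingroup", "outgroup")
  )
  snps60 <- find_discriminating_snps(aln60)
  got <- enumerate_primer_pairs(aln60, snps60, min_len = 17L, max_len = 20L)
  # naive O(L^2 W^2) enumeration with fresh logic
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  brute <- list()
  for (fs in 1:60) for (fl in 17:20) {
    fe <- fs + fl - 1
    if (fe > 60 || !any(snps60 >= fs & snps60 <= fe)) next
    for (rs in 1:60) for (rl in 17:20) {
      re <- rs + rl - 1
      if (re > 60 || rs <= fe || !any(snps60 >= rs & snps60 <= re)) next
      if (re - fs + 1 >= 600) next
      fseq <- paste(b60[fs:fe], collapse = "")
      rseq <- rc(paste(b60[rs:re], collapse = ""))
      f3 <- substr(fseq, fl - 3, fl); r3 <- substr(rseq, rl - 3, rl)
      if (grepl(rc(f3), rseq, fixed = TRUE) || grepl(rc(r3), fseq, fixed = TRUE)) next
      brute[[length(brute) + 1]] <- paste(fs, re)
    }
  }
  expect_setequal(paste(got$forward_start, got$reverse_end), unlist(brute))
})

test_that("population resolution scoring agrees with brute-force monophyly", {
  # each MC a clade -> fraction 1
  t1 <- ape::read.tree(text = "(((a1,a2),(b1,b2)),(c1,c2));")
  mc1 <- stats::setNames(c("A", "A", "B", "B", "C", "C"),
                         c("a1", "a2", "b1", "b2", "c1", "c2"))
  s1 <- score_population_resolution(t1, mc1)
  expect_identical(s1$fraction_monophyletic, 1)

  # perfectly interleaved ladder: both MCs non-monophyletic
  t2 <- ape::read.tree(text = "(a1,(b1,(a2,(b2,(a3,b3)))));")
  mc2 <- stats::setNames(c("A", "B", "A", "B", "A", "B"),
                         c("a1", "b1", "a2", "b2", "a3", "b3"))
  s2 <- score_population_resolution(t2, mc2)
  expect_identical(unname(s2$monophyletic), c(FALSE, FALSE))
  expect_identical(s2$fraction_monophyletic, 0)

  expect_error(score_population_resolution(t2, mc2[-1]), "unlabelled")

  # random 20-tip trees vs brute-force clade enumeration
  set.seed(21)
  for (r in 1:20) {
    tr <- ape::rtree(20)
    mc <- stats::setNames(paste0("M", sample(1:4, 20, replace = TRUE)),
                          tr$tip.label)
    got <- score_population_resolution(tr, mc)$monophyletic
    for (m in names(got)) {
      tips <- tr$tip.label[mc[tr$tip.label] == m]
      is_clade <- length(tips) == 1 ||
        any(vapply(21:(20 + tr$Nnode), function(nd) {
          setequal(tr$tip.label[oracle_tips_below(tr, nd)], tips)
        }, logical(1)))
      expect_identical(unname(got[m]), is_clade)
    }
  }
})
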