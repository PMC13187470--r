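#' Labelled multiple alignment
#'
#' Container for an aligned set of marker sequences with ingroup/outgroup
#' labels and, for ingroup rows, population (MC) labels. Coordinates are
#' 1-based alignment columns, inclusive.
#'
#' @param seqs named character vector of equal-length aligned sequences
#'   (IUPAC codes and `-` gaps).
#' @param group character vector, one of `"ingroup"`/`"outgroup"` per row.
#' @param mc optional named character vector of MC labels for ingroup rows.
#' @param marker optional marker name.
#' @return an object of class `popspec_alignment`.
#' @export
labeled_alignment <- function(seqs, group, mc = NULL, marker = NULL) {
  stopifnot(is.character(seqs), length(seqs) >= 1L,
            length(group) == length(seqs))
  if (length(unique(nchar(seqs))) != 1L) stop("alignment rows have unequal lengths")
  if (!all(group %in% c("ingroup", "outgroup"))) {
    stop("group must be 'ingroup' or 'outgroup'")
  }
  if (is.null(names(seqs))) names(seqs) <- sprintf("row%d", seq_along(seqs))
  structure(list(seqs = stats::setNames(toupper(seqs), names(seqs)),
                 group = stats::setNames(group, names(seqs)),
                 mc = mc, marker = marker),
            class = "popspec_alignment")
}

#' Find genus-discriminating SNP columns
#'
#' A column discriminates the ingroup from the outgroup when, after IUPAC
#' expansion, the set of bases observed in ingroup rows is disjoint from the
#' set observed in outgroup rows. Columns containing a gap in any row are
#' excluded.
#'
#' @param aln a [labeled_alignment()] with at least one ingroup and one
#'   outgroup row.
#' @return integer vector of 1-based alignment columns.
#' @export
find_discriminating_snps <- function(aln) {
  stopifnot(inherits(aln, "popspec_alignment"))
  ing <- aln$seqs[aln$group == "ingroup"]
  outg <- aln$seqs[aln$group == "outgroup"]
  if (length(ing) == 0L || length(outg) == 0L) {
    stop("need at least one ingroup and one outgroup row")
  }
  mi <- seq_matrix(ing)
  mo <- seq_matrix(outg)
  which(vapply(seq_len(ncol(mi)), function(j) {
    ci <- mi[, j]; co <- mo[, j]
    if (any(ci == "-") || any(co == "-")) return(FALSE)
    si <- unique(unlist(lapply(unique(ci), iupac_expand)))
    so <- unique(unlist(lapply(unique(co), iupac_expand)))
    length(intersect(si, so)) == 0L
  }, logical(1)))
}

#' Minimal degenerate IUPAC code for a set of bases
#'
#' @param residues character vector of observed bases (subset of A, C, G, T;
#'   IUPAC codes are expanded first).
#' @return single IUPAC code covering exactly the observed base set.
#' @export
degenerate_consensus <- function(residues) {
  if (length(residues) == 0L) stop("empty residue set")
  bases <- sort(unique(unlist(lapply(toupper(residues), iupac_expand))))
  code <- .iupac_codes[[paste(bases, collapse = "")]]
  if (is.null(code)) stop("invalid residues: ", paste(residues, collapse = ","))
  code
}

# per-column degenerate ingroup consensus and degeneracy; gap columns get NA
ingroup_consensus_profile <- function(aln) {
  m <- seq_matrix(aln$seqs[aln$group == "ingroup"])
  cons <- character(ncol(m))
  degen <- integer(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (any(col == "-")) {
      cons[j] <- NA_character_
      degen[j] <- NA_integer_
    } else {
      cons[j] <- degenerate_consensus(col)
      degen[j] <- length(iupac_expand(cons[j]))
    }
  }
  list(consensus = cons, degeneracy = degen)
}

#' 3'-anchored cross-complementarity between two primers
#'
#' Returns `TRUE` (incompatible pair) when the 3'-terminal `k`-mer of either
#' primer has a reverse-complement match anywhere in the other primer, where
#' a match at a position means the IUPAC base sets intersect at every offset
#' (i.e., some concrete realization of each primer is complementary there).
#'
#' @param forward,reverse primer sequences (IUPAC).
#' @param k 3'-anchor length (default 4).
#' @return logical.
#' @export
check_cross_complementarity <- function(forward, reverse, k = 4L) {
  stopifnot(nchar(forward) >= 1L, nchar(reverse) >= 1L)
  if (k > nchar(forward) || k > nchar(reverse)) {
    stop("k exceeds a primer length")
  }
  hit <- function(anchor_src, target) {
    kmer <- substr(anchor_src, nchar(anchor_src) - k + 1L, nchar(anchor_src))
    probe <- revcomp_iupac(kmer)
    pc <- strsplit(probe, "", fixed = TRUE)[[1]]
    tc <- strsplit(toupper(target), "", fixed = TRUE)[[1]]
    if (length(tc) < k) return(FALSE)
    for (s in seq_len(length(tc) - k + 1L)) {
      ok <- TRUE
      for (j in seq_len(k)) {
        if (length(intersect(iupac_expand(pc[j]), iupac_expand(tc[s + j - 1L]))) == 0L) {
          ok <- FALSE
          break
        }
      }
      if (ok) return(TRUE)
    }
    FALSE
  }
  hit(forward, reverse) || hit(reverse, forward)
}

#' Amplicon product size from primer position names
#'
#' Primer naming convention: the forward primer name carries the amplicon
#' 5' start position, the reverse primer name the amplicon 3' end position;
#' the product spans both primers inclusively, so
#' `size = reverse - forward + 1`.
#'
#' @param forward_name_pos,reverse_name_pos 1-based positions.
#' @return integer product size in bp.
#' @export
product_size <- function(forward_name_pos, reverse_name_pos) {
  stopifnot(is.numeric(forward_name_pos), is.numeric(reverse_name_pos))
  if (any(reverse_name_pos < forward_name_pos)) {
    stop("reverse position must be >= forward position")
  }
  as.integer(reverse_name_pos - forward_name_pos + 1)
}

#' Enumerate degenerate population-resolving primer pairs
#'
#' Exhaustively enumerates forward/reverse window pairs over the ingroup
#' consensus satisfying the three design criteria: (i) each primer window
#' covers at least one discriminating SNP; (ii) primer lengths within
#' `[min_len, max_len]` and product size strictly below `max_product`;
#' (iii) no 3'-anchored cross-complementarity. Windows never include gap
#' columns; a degeneracy cap prunes hyper-degenerate windows. Product size
#' is measured on the ungapped ingroup consensus, primers inclusive.
#'
#' @param aln a [labeled_alignment()].
#' @param snp_positions discriminating columns, e.g. from
#'   [find_discriminating_snps()].
#' @param min_len,max_len primer length bounds (default 17, 25).
#' @param max_product exclusive product-size bound (default 600).
#' @param max_degeneracy cap on the product of per-base alternative counts
#'   (default 16).
#' @param k 3'-anchor length for the complementarity check.
#' @return data.frame of candidate pairs sorted by ascending total
#'   degeneracy then descending SNP coverage, with columns forward_seq,
#'   reverse_seq, forward_start, reverse_end (ungapped consensus
#'   coordinates), product_size, n_snps_forward, n_snps_reverse, degeneracy.
#'   Empty (zero rows) when no pair qualifies.
#' @export
enumerate_primer_pairs <- function(aln, snp_positions,
                                   min_len = 17L, max_len = 25L,
                                   max_product = 600L, max_degeneracy = 16L,
                                   k = 4L) {
  stopifnot(inherits(aln, "popspec_alignment"))
  if (length(snp_positions) == 0L) stop("snp_positions is empty")
  prof <- ingroup_consensus_profile(aln)
  L <- length(prof$consensus)
  nongap <- !is.na(prof$consensus)
  # ungapped consensus coordinate of each alignment column
  upos <- cumsum(nongap)
  is_snp <- logical(L)
  is_snp[snp_positions] <- TRUE

  windows <- list()
  wi <- 0L
  for (start in seq_len(L)) {
    if (!nongap[start]) next
    for (len in min_len:max_len) {
      end <- start + len - 1L
      if (end > L) break
      if (!all(nongap[start:end])) break # gap interrupts all longer windows
      degen <- prod(prof$degeneracy[start:end])
      if (degen > max_degeneracy) next
      nsnp <- sum(is_snp[start:end])
      if (nsnp < 1L) next
      wi <- wi + 1L
      windows[[wi]] <- list(start = start, end = end, degen = degen, nsnp = nsnp,
                            seq = paste(prof$consensus[start:end], collapse = ""))
    }
  }
  empty <- data.frame(forward_seq = character(0), reverse_seq = character(0),
                      forward_start = integer(0), reverse_end = integer(0),
                      product_size = integer(0), n_snps_forward = integer(0),
                      n_snps_reverse = integer(0), degeneracy = integer(0),
                      stringsAsFactors = FALSE)
  if (wi == 0L) return(empty)

  rows <- list()
  ri <- 0L
  for (f in windows) {
    for (r in windows) {
      if (r$start <= f$end) next # windows must not overlap, reverse downstream
      psize <- upos[r$end] - upos[f$start] + 1L
      if (psize >= max_product) next
      rseq <- revcomp_iupac(r$seq)
      if (check_cross_complementarity(f$seq, rseq, k = k)) next
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        forward_seq = f$seq, reverse_seq = rseq,
        forward_start = upos[f$start], reverse_end = upos[r$end],
        product_size = psize,
        n_snps_forward = f$nsnp, n_snps_reverse = r$nsnp,
        degeneracy = f$degen * r$degen, stringsAsFactors = FALSE
      )
    }
  }
  if (ri == 0L) return(empty)
  res <- do.call(rbind, rows)
  res <- res[order(res$degeneracy, -(res$n_snps_forward + res$n_snps_reverse)), ]
  rownames(res) <- NULL
  res
}

#' Advisory Wallace-rule melting temperature
#'
#' `2 * (A + T) + 4 * (G + C)` averaged over the degenerate realizations of
#' each position. Reported as metadata only; never used as a design filter.
#'
#' @param primer IUPAC primer sequence.
#' @return numeric Tm estimate in degrees C.
#' @export
wallace_tm <- function(primer) {
  ch <- strsplit(toupper(primer), "", fixed = TRUE)[[1]]
  sum(vapply(ch, function(code) {
    s <- iupac_expand(code)
    mean(ifelse(s %in% c("A", "T"), 2, 4))
  }, numeric(1)))
}

#' Score population resolution of a marker tree
#'
#' Fraction of MCs whose tips form a monophyletic clade on the rooted tree.
#'
#' @param tree a rooted `phylo`.
#' @param mc_of_tip named character vector mapping every tip to an MC.
#' @return list with `fraction_monophyletic` and named logical
#'   `monophyletic` per MC.
#' @export
score_population_resolution <- function(tree, mc_of_tip) {
  stopifnot(inherits(tree, "phylo"))
  if (!all(tree$tip.label %in% names(mc_of_tip))) {
    stop("unlabelled tip(s): ",
         paste(setdiff(tree$tip.label, names(mc_of_tip)), collapse = ", "))
  }
  labs <- mc_of_tip[tree$tip.label]
  mcs <- sort(unique(labs))
  mono <- vapply(mcs, function(mc) {
    tips <- tree$tip.label[labs == mc]
    if (length(tips) == 1L) return(TRUE)
    ape::is.monophyletic(tree, tips)
  }, logical(1))
  list(fraction_monophyletic = mean(mono),
       monophyletic = stats::setNames(mono, mcs))
}
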