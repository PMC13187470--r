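#' Align query ASVs to a reference alignment
#'
#' Reference-guided profile alignment: each query is globally aligned (affine
#' gaps) to the ungapped reference consensus, then mapped back into the
#' reference column frame. Reference columns are never changed and
#' query-induced insertions are discarded. Queries under 50% identity to the
#' consensus are excluded and reported.
#'
#' @param reference a [labeled_alignment()] (ingroup rows define the
#'   profile).
#' @param asv_sequences named character vector of ungapped query sequences.
#' @return list with `alignment` (named character vector: reference rows
#'   followed by aligned query rows, equal length), `excluded` (names of
#'   rejected queries), `identity` (named numeric, per query).
#' @export
align_queries_to_reference <- function(reference, asv_sequences) {
  stopifnot(inherits(reference, "popspec_alignment"), length(reference$seqs) >= 1L)
  ing <- reference$seqs[reference$group == "ingroup"]
  if (length(ing) == 0L) ing <- reference$seqs
  m <- seq_matrix(ing)
  # majority-base consensus per column; gap-majority columns stay gaps
  cons_chars <- apply(m, 2, function(col) {
    tab <- sort(table(col), decreasing = TRUE)
    names(tab)[1]
  })
  nongap_cols <- which(cons_chars != "-")
  profile <- paste(cons_chars[nongap_cols], collapse = "")
  L <- length(cons_chars)

  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                     baseOnly = TRUE)
  aligned <- character(0)
  identity <- numeric(0)
  excluded <- character(0)
  for (qname in names(asv_sequences)) {
    q <- toupper(asv_sequences[[qname]])
    pa <- Biostrings::pairwiseAlignment(
      pattern = q, subject = profile, type = "global",
      substitutionMatrix = submat, gapOpening = 8, gapExtension = 2
    )
    pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    # walk alignment; subject non-gap positions index the profile columns
    row <- rep("-", L)
    spos <- 0L
    nmatch <- 0L; ncomp <- 0L
    for (i in seq_along(sub)) {
      if (sub[i] != "-") {
        spos <- spos + 1L
        if (pat[i] != "-") {
          row[nongap_cols[spos]] <- pat[i]
          ncomp <- ncomp + 1L
          if (pat[i] == sub[i]) nmatch <- nmatch + 1L
        }
      }
      # pattern insertions (sub == "-") are discarded
    }
    idy <- if (ncomp > 0) nmatch / ncomp else 0
    identity[qname] <- idy
    if (idy < 0.5) {
      excluded <- c(excluded, qname)
      message("align_queries_to_reference: query '", qname,
              "' below 50% identity to profile; excluded")
    } else {
      aligned[qname] <- paste(row, collapse = "")
    }
  }
  list(alignment = c(reference$seqs, aligned),
       excluded = excluded, identity = identity)
}

#' Build a joint reference + query tree
#'
#' Neighbor-joining on Jukes-Cantor distances, midpoint-rooted. Rows are
#' sorted lexicographically by name before distance computation so the
#' result is independent of input order.
#'
#' @param joint_alignment named character vector of equal-length aligned
#'   sequences (references and queries together).
#' @param reference_names names of the reference rows.
#' @param mc_of_reference named character vector: MC label per reference row.
#' @return an object of class `popspec_joint_tree`: list with `tree`
#'   (rooted `phylo`), `tip_kind` (named, "reference"/"query"), `mc_of_tip`.
#' @export
build_joint_tree <- function(joint_alignment, reference_names, mc_of_reference) {
  if (length(joint_alignment) < 4L) stop("need at least 4 sequences")
  if (anyDuplicated(names(joint_alignment))) {
    stop("duplicate tip names in joint alignment")
  }
  joint_alignment <- joint_alignment[order(names(joint_alignment))]
  bin <- ape::as.DNAbin(strsplit(tolower(joint_alignment), ""))
  d <- ape::dist.dna(bin, model = "JC69", pairwise.deletion = TRUE)
  d[is.na(d) | !is.finite(d)] <- max(d[is.finite(d)], 1)
  tree <- ape::nj(d)
  tree <- phangorn::midpoint(tree)
  kind <- ifelse(tree$tip.label %in% reference_names, "reference", "query")
  names(kind) <- tree$tip.label
  if (!any(kind == "reference")) stop("joint tree has no reference tips")
  structure(list(tree = tree, tip_kind = kind,
                 mc_of_tip = mc_of_reference),
            class = "popspec_joint_tree")
}

# descendant tip indices of every node (tips included), as a list
.descendant_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  desc <- vector("list", nn)
  for (i in seq_len(ntip)) desc[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

#' Assign one ASV to a population by the parental-node majority rule
#'
#' Takes the parent node of the query tip and, among the reference tips it
#' subtends, assigns the plurality MC when its fraction strictly exceeds
#' `tau` ("over 80% of the descending tips"). If the parent subtends no
#' reference tips, ancestors are ascended minimally until at least one
#' reference tip is subtended, and the rule applied once there. Co-placed
#' query tips never enter the denominator.
#'
#' @param jt a [build_joint_tree()] result.
#' @param asv_id a query tip label.
#' @param tau assignment threshold (default 0.8, strict inequality).
#' @return list with `asv_id`, `assigned_mc` (NA when unassigned),
#'   `supporting_fraction`, `n_reference_tips_considered`,
#'   `ancestor_depth_used` (0 = immediate parent).
#' @export
assign_asv_to_population <- function(jt, asv_id, tau = 0.8) {
  stopifnot(inherits(jt, "popspec_joint_tree"))
  tree <- jt$tree
  tip_idx <- match(asv_id, tree$tip.label)
  if (is.na(tip_idx)) stop("asv_id not in tree: ", asv_id)
  if (jt$tip_kind[[asv_id]] == "reference") {
    stop("asv_id is a reference tip: ", asv_id)
  }
  ntip <- length(tree$tip.label)
  parent_of <- integer(ntip + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  desc <- .descendant_tips(tree)
  root <- ntip + 1L

  node <- parent_of[tip_idx]
  depth <- 0L
  repeat {
    tips <- tree$tip.label[desc[[node]]]
    refs <- tips[jt$tip_kind[tips] == "reference"]
    if (length(refs) > 0L) break
    if (node == root || parent_of[node] == 0L) break
    node <- parent_of[node]
    depth <- depth + 1L
  }
  if (length(refs) == 0L) {
    return(list(asv_id = asv_id, assigned_mc = NA_character_,
                supporting_fraction = 0, n_reference_tips_considered = 0L,
                ancestor_depth_used = depth))
  }
  tab <- sort(table(jt$mc_of_tip[refs]), decreasing = TRUE)
  frac <- as.numeric(tab[1]) / length(refs)
  tied <- sum(tab == tab[1]) > 1L
  assigned <- if (!tied && frac > tau) names(tab)[1] else NA_character_
  list(asv_id = asv_id, assigned_mc = assigned,
       supporting_fraction = frac,
       n_reference_tips_considered = length(refs),
       ancestor_depth_used = depth)
}

#' Assign every query tip of a joint tree
#'
#' @param jt a [build_joint_tree()] result.
#' @param tau assignment threshold.
#' @return data.frame with one row per query tip (columns asv_id,
#'   assigned_mc, supporting_fraction, n_reference_tips_considered,
#'   ancestor_depth_used).
#' @export
assign_all_asvs <- function(jt, tau = 0.8) {
  queries <- names(jt$tip_kind)[jt$tip_kind == "query"]
  rows <- lapply(queries, function(q) {
    as.data.frame(assign_asv_to_population(jt, q, tau = tau),
                  stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(asv_id = character(0), assigned_mc = character(0),
                      supporting_fraction = numeric(0),
                      n_reference_tips_considered = integer(0),
                      ancestor_depth_used = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate ASV counts into per-sample MC relative abundances
#'
#' Per sample, an MC's abundance is the summed counts of its assigned ASVs
#' divided by the total counts of all assigned ASVs; the unassigned mass is
#' reported separately. Samples with zero assigned counts are flagged and
#' carry NA abundances.
#'
#' @param asv_table a `popspec_asv_table` or a plain ASV x sample count
#'   matrix.
#' @param assignments data.frame with columns `asv_id`, `assigned_mc`
#'   (NA = unassigned); every ASV row must have a record.
#' @return list with `abundance` (MC x sample relative-abundance matrix),
#'   `unassigned_fraction` (per sample), `flagged_samples`.
#' @export
aggregate_population_abundance <- function(asv_table, assignments) {
  counts <- if (inherits(asv_table, "popspec_asv_table")) asv_table$counts else asv_table
  if (!all(rownames(counts) %in% assignments$asv_id)) {
    stop("assignment records missing for: ",
         paste(setdiff(rownames(counts), assignments$asv_id), collapse = ", "))
  }
  mc <- assignments$assigned_mc[match(rownames(counts), assignments$asv_id)]
  assigned <- !is.na(mc)
  totals <- colSums(counts)
  assigned_totals <- if (any(assigned)) colSums(counts[assigned, , drop = FALSE]) else
    stats::setNames(numeric(ncol(counts)), colnames(counts))
  flagged <- colnames(counts)[assigned_totals == 0]
  if (any(assigned)) {
    agg <- rowsum(counts[assigned, , drop = FALSE], group = mc[assigned])
    abundance <- sweep(agg, 2, assigned_totals, "/")
    abundance[, assigned_totals == 0] <- NA_real_
  } else {
    abundance <- matrix(NA_real_, 0, ncol(counts),
                        dimnames = list(NULL, colnames(counts)))
  }
  list(abundance = abundance,
       unassigned_fraction = ifelse(totals > 0, 1 - assigned_totals / totals, NA_real_),
       flagged_samples = flagged)
}
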