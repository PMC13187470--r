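#' Filter ortholog groups by prevalence
#'
#' Keeps an OG when the fraction of genomes carrying it is at least
#' `min_fraction` (inclusive, per the "at least 50%" rule).
#'
#' @param pa genomes x genes binary matrix.
#' @param min_fraction prevalence threshold (default 0.5).
#' @return character vector of retained OG (column) names.
#' @export
filter_ogs <- function(pa, min_fraction = 0.5) {
  pa <- as.matrix(pa)
  if (nrow(pa) == 0L || ncol(pa) == 0L) stop("empty presence/absence matrix")
  keep <- colMeans(pa > 0) >= min_fraction
  colnames(pa)[keep]
}

#' Detect a specialist-exclusive convergent clade in a gene tree
#'
#' Scans every internal node of the (rooted) gene tree; a node witnesses
#' convergence when its descendant leaves carry genes from at least two
#' distinct specialist MCs and from no non-specialist MC. Among qualifying
#' nodes the one subtending the most leaves is reported. Unrooted input is
#' midpoint-rooted with a warning.
#'
#' @param tree a `phylo` gene tree.
#' @param mc_of_leaf named character vector mapping every leaf to an MC.
#' @param specialist_mcs character vector of specialist MC labels.
#' @return list with `convergent` (logical), `witness_node` (internal node
#'   id or NA), `specialist_mcs_in_clade`, `clade_size`.
#' @export
detect_specialist_convergent_clade <- function(tree, mc_of_leaf, specialist_mcs) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) {
    warning("unrooted gene tree: midpoint-rooting")
    tree <- phangorn::midpoint(tree)
  }
  if (!all(tree$tip.label %in% names(mc_of_leaf))) {
    stop("leaf without MC label: ",
         paste(setdiff(tree$tip.label, names(mc_of_leaf)), collapse = ", "))
  }
  labs <- mc_of_leaf[tree$tip.label]
  ntip <- length(tree$tip.label)
  no_call <- list(convergent = FALSE, witness_node = NA_integer_,
                  specialist_mcs_in_clade = character(0), clade_size = 0L)
  if (sum(unique(labs) %in% specialist_mcs) < 2L) return(no_call)
  desc <- .descendant_tips(tree)
  best <- no_call
  for (node in (ntip + 1L):(ntip + tree$Nnode)) {
    mcs <- labs[desc[[node]]]
    if (any(!mcs %in% specialist_mcs)) next
    u <- unique(mcs)
    if (length(u) < 2L) next
    size <- length(desc[[node]])
    if (size > best$clade_size) {
      best <- list(convergent = TRUE, witness_node = node,
                   specialist_mcs_in_clade = sort(u), clade_size = size)
    }
  }
  best
}

#' Summarize convergent OGs across gene trees
#'
#' @param calls named list of [detect_specialist_convergent_clade()]
#'   results, names = OG ids.
#' @param annotations optional named character vector of OG annotations.
#' @return data.frame of convergent OGs (og, witness_node, clade_size,
#'   specialist_mcs_in_clade, annotation); zero rows when nothing is
#'   convergent.
#' @export
summarize_convergent_ogs <- function(calls, annotations = NULL) {
  rows <- lapply(names(calls), function(og) {
    cl <- calls[[og]]
    if (!isTRUE(cl$convergent)) return(NULL)
    data.frame(og = og, witness_node = cl$witness_node,
               clade_size = cl$clade_size,
               specialist_mcs_in_clade = paste(cl$specialist_mcs_in_clade,
                                               collapse = ","),
               annotation = if (!is.null(annotations) && og %in% names(annotations))
                 annotations[[og]] else NA_character_,
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) {
    return(data.frame(og = character(0), witness_node = integer(0),
                      clade_size = integer(0),
                      specialist_mcs_in_clade = character(0),
                      annotation = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
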