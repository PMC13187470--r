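# File I/O shared across modules. All user-facing coordinates are 1-based
# inclusive; tables are TSV with samples as columns; trees are newick with
# MC labels encoded in tip names as <genome>|<MC>.

#' Read/write FASTA
#'
#' Thin wrappers over Biostrings; `read_fasta` returns a plain named
#' character vector (gaps preserved), `write_fasta` takes one.
#'
#' @param path file path.
#' @param seqs named character vector.
#' @return `read_fasta`: named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read/write TSV tables
#'
#' @param x data.frame or matrix.
#' @param path file path.
#' @param row_names write/read row names in a leading `id` column.
#' @return `read_tsv`: data.frame.
#' @export
write_tsv <- function(x, path, row_names = FALSE) {
  if (row_names) {
    x <- data.frame(id = rownames(x), as.data.frame(x), check.names = FALSE,
                    stringsAsFactors = FALSE)
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path, row_names = FALSE) {
  x <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (row_names) {
    rownames(x) <- x[[1]]
    x <- x[, -1, drop = FALSE]
  }
  x
}

#' Write a population-labelled tree as newick
#'
#' Tip names are rewritten to `<genome>|<MC>` so the MC map survives the
#' round trip; [read_population_tree()] inverts this.
#'
#' @param ptree a `popspec_tree`.
#' @param path file path.
#' @export
write_population_tree <- function(ptree, path) {
  tree <- ptree$tree
  tree$tip.label <- paste0(tree$tip.label, "|", ptree$mc_of_tip[tree$tip.label])
  ape::write.tree(tree, path)
  invisible(path)
}

#' @rdname write_population_tree
#' @param specialist_mcs specialist set to attach on read.
#' @export
read_population_tree <- function(path, specialist_mcs = character(0)) {
  tree <- ape::read.tree(path)
  parts <- strsplit(tree$tip.label, "|", fixed = TRUE)
  genome <- vapply(parts, `[[`, "", 1L)
  mc <- vapply(parts, function(p) if (length(p) > 1L) p[[2]] else NA_character_, "")
  tree$tip.label <- genome
  structure(list(tree = tree, mc_of_tip = stats::setNames(mc, genome),
                 specialist_mcs = specialist_mcs),
            class = "popspec_tree")
}
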