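#' Classify denitrification-pathway completeness for one genome
#'
#' Complete pathway: a nitrate reductase (`napA` or `narG`), a nitrite
#' reductase (`nirS` or `nirK`), nitric oxide reductase `norB`, and nitrous
#' oxide reductase `nosZ`. No gene at all classifies as "none"; anything in
#' between is "partial".
#'
#' @param napA,narG,nirS,nirK,norB,nosZ logical gene-presence flags.
#' @return one of `"complete"`, `"partial"`, `"none"`.
#' @export
classify_pathway <- function(napA, narG, nirS, nirK, norB, nosZ) {
  flags <- list(napA = napA, narG = narG, nirS = nirS, nirK = nirK,
                norB = norB, nosZ = nosZ)
  for (nm in names(flags)) {
    f <- flags[[nm]]
    if (length(f) != 1L || is.na(f) || !is.logical(f)) {
      stop("flag '", nm, "' must be a single TRUE/FALSE")
    }
  }
  if ((napA || narG) && (nirS || nirK) && norB && nosZ) return("complete")
  if (!any(unlist(flags))) return("none")
  "partial"
}

#' Summarize pathway classes over a set of genomes
#'
#' @param profiles data.frame with logical columns napA, narG, nirS, nirK,
#'   norB, nosZ (one row per genome).
#' @return list with `class` (per-genome vector), `counts` and `fractions`
#'   over the classes complete/partial/none.
#' @export
summarize_pathway_counts <- function(profiles) {
  need <- c("napA", "narG", "nirS", "nirK", "norB", "nosZ")
  if (nrow(profiles) < 1L) stop("need at least one profile")
  if (!all(need %in% names(profiles))) {
    stop("missing flag column(s): ", paste(setdiff(need, names(profiles)), collapse = ", "))
  }
  cls <- vapply(seq_len(nrow(profiles)), function(i) {
    classify_pathway(profiles$napA[i], profiles$narG[i], profiles$nirS[i],
                     profiles$nirK[i], profiles$norB[i], profiles$nosZ[i])
  }, "")
  lev <- c("complete", "partial", "none")
  counts <- table(factor(cls, levels = lev))
  list(class = cls, counts = counts, fractions = counts / nrow(profiles))
}
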