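# Internal helpers shared across modules: seeded RNG streams, IUPAC tables,
# small argument checks.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a master seed
#'
#' Stage-specific RNG streams are derived deterministically from one master
#' seed so that a single integer reproduces every stochastic stage. The
#' derivation is a Lehmer step modulo 2^31 - 1; results stay in
#' `[1, 2^31 - 2]` and so are always valid `set.seed()` inputs.
#'
#' @param seed master seed (single integer).
#' @param stream stream index (nonnegative integer; 0 returns a distinct
#'   stream, not the master seed itself).
#' @return a single integer seed.
#' @export
child_seed <- function(seed, stream = 0L) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(stream) == 1L)
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m)
  # 48271 * m < 2^53: exact in double arithmetic
  s <- (s * 48271 + as.numeric(stream) * 7919 + 1) %% m
  as.integer(s %% (m - 2) + 1)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  old <- get0(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  expr
}

# IUPAC nucleotide code -> base set
.iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# base set (sorted, unique) -> IUPAC code
.iupac_codes <- local({
  codes <- names(.iupac_sets)
  keys <- vapply(.iupac_sets, function(s) paste(sort(s), collapse = ""), "")
  stats::setNames(codes, keys)
})

iupac_expand <- function(code) {
  s <- .iupac_sets[[toupper(code)]]
  if (is.null(s)) stop("not an IUPAC nucleotide code: ", code)
  s
}

# complement of an IUPAC code (set-wise)
.iupac_complement <- c(
  A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S", W = "W",
  K = "M", M = "K", B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Reverse-complement an IUPAC nucleotide string
#' @param x a character string over the IUPAC alphabet.
#' @return the reverse complement, degeneracy preserved.
#' @export
revcomp_iupac <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, nchar(x) >= 1L)
  ch <- rev(strsplit(toupper(x), "", fixed = TRUE)[[1]])
  comp <- .iupac_complement[ch]
  if (anyNA(comp)) stop("non-IUPAC character in sequence: ", x)
  paste(comp, collapse = "")
}

# split aligned sequences (equal length, may contain '-') into a character
# matrix, rows = sequences
seq_matrix <- function(seqs) {
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("sequences are not aligned (unequal lengths)")
  m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

# tie-tolerant >= for permutation counting: a permuted statistic equal to the
# observed one up to last-ulp BLAS jitter must count as an exceedance
ge_tie <- function(a, b) a >= b - 1e-12 * (1 + abs(b))

check_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(name, " must be a probability in [0, 1]")
  }
  invisible(x)
}

check_positive <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && (if (strict) x > 0 else x >= 0)
  if (!ok) stop(name, " must be a ", if (strict) "positive" else "nonnegative", " number")
  invisible(x)
}
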