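#' Bray-Curtis dissimilarity between samples
#'
#' `d(i, j) = sum |x_i - x_j| / sum (x_i + x_j)` over features, for samples
#' in columns.
#'
#' @param x nonnegative feature x sample matrix (>= 2 samples; no all-zero
#'   sample).
#' @return symmetric sample x sample matrix with zero diagonal, entries in
#'   `[0, 1]`.
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need at least two samples")
  if (any(x < 0, na.rm = TRUE)) stop("negative abundances")
  zero <- colSums(x, na.rm = TRUE) == 0
  if (any(zero)) {
    stop("all-zero sample(s): ", paste(colnames(x)[zero], collapse = ", "))
  }
  n <- ncol(x)
  d <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      num <- sum(abs(x[, i] - x[, j]))
      den <- sum(x[, i] + x[, j])
      d[i, j] <- d[j, i] <- num / den
    }
  }
  d
}

# all permutations of 1..n as an n! x n matrix (n <= 8 guarded by callers)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L), drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Iterative stress majorization: monotone (isotonic) regression of the
#' configuration distances on the dissimilarity order gives disparities,
#' followed by a Guttman transform update. A step that fails to decrease
#' stress-1 is reverted and the restart stops, so the stress sequence is
#' non-increasing by construction. Initialized from classical metric scaling
#' plus seeded random starts; the best (lowest-stress) solution is returned
#' with scores rotated to principal axes with deterministic sign.
#'
#' @param d symmetric dissimilarity matrix.
#' @param k embedding dimension (default 2; requires `nrow(d) >= k + 1`).
#' @param n_restarts total starts (1 metric + `n_restarts - 1` random).
#' @param seed RNG seed for the random starts.
#' @param max_iter,tol iteration cap and relative stress-decrease tolerance.
#' @return list with `scores` (n x k), `stress`, `stress_sequence` (of the
#'   winning restart), `n_restarts_used`, `converged`.
#' @export
nmds <- function(d, k = 2L, n_restarts = 4L, seed = 1L, max_iter = 200L,
                 tol = 1e-8) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < k + 1) stop("need at least k + 1 samples")
  lower <- lower.tri(d)
  dv <- d[lower]
  ord <- order(dv)
  run_start <- function(X) {
    dx <- as.matrix(stats::dist(X))[lower]
    seqs <- numeric(0)
    best <- list(X = X, stress = Inf)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      fit <- stats::isoreg(seq_along(ord), dx[ord])
      dhat <- numeric(length(dv))
      dhat[ord] <- fit$yf
      stress <- sqrt(sum((dx - dhat)^2) / sum(dx^2))
      if (stress > best$stress + 1e-15) break # revert: keep previous best
      seqs <- c(seqs, stress)
      improved <- best$stress - stress
      best <- list(X = X, stress = stress)
      if (is.finite(improved) && improved < tol) {
        converged <- TRUE
        break
      }
      if (stress < 1e-12) {
        converged <- TRUE
        break
      }
      # Guttman transform
      ratio <- matrix(0, n, n)
      dxm <- matrix(0, n, n)
      dxm[lower] <- dx; dxm <- dxm + t(dxm)
      dhm <- matrix(0, n, n)
      dhm[lower] <- dhat; dhm <- dhm + t(dhm)
      pos <- dxm > 0
      ratio[pos] <- dhm[pos] / dxm[pos]
      B <- -ratio
      diag(B) <- -rowSums(B)
      X <- B %*% X / n
      dx <- as.matrix(stats::dist(X))[lower]
    }
    list(scores = best$X, stress = best$stress, stress_sequence = seqs,
         converged = converged)
  }
  cmd <- suppressWarnings(stats::cmdscale(d, k = k))
  if (ncol(cmd) < k) cmd <- cbind(cmd, matrix(0, n, k - ncol(cmd)))
  starts <- list(cmd)
  if (n_restarts > 1) {
    starts <- c(starts, with_seed(seed, {
      lapply(seq_len(n_restarts - 1L), function(i) {
        matrix(stats::rnorm(n * k), n, k)
      })
    }))
  }
  fits <- lapply(starts, run_start)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "stress"))]]
  X <- scale(best$scores, center = TRUE, scale = FALSE)
  # principal-axis rotation, deterministic sign
  sv <- svd(X)
  X <- sv$u %*% diag(sv$d, k, k)
  for (j in seq_len(k)) {
    i0 <- which(abs(X[, j]) > 1e-12)[1]
    if (!is.na(i0) && X[i0, j] < 0) X[, j] <- -X[, j]
  }
  rownames(X) <- rownames(d)
  list(scores = X, stress = best$stress,
       stress_sequence = best$stress_sequence,
       n_restarts_used = length(starts), converged = best$converged)
}

# pseudo-F partition from squared distances (Anderson): SS_total = sum of all
# pairwise d^2 / n; SS_within = per-group analogue; F = between/within mean sq
.permanova_F <- function(d2, groups) {
  n <- length(groups)
  ss_t <- sum(d2[lower.tri(d2)]) / n
  ss_w <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ss_w <- ss_w + sum(d2[idx, idx][lower.tri(d2[idx, idx, drop = FALSE])]) / length(idx)
  }
  a <- length(unique(groups))
  ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a))
}

#' One-factor PERMANOVA
#'
#' Pseudo-F from the total and within-group sums of squared distances, with
#' whole-sample label permutation. With `exact = TRUE` all `n!` label
#' permutations are enumerated (identity included) and
#' `p = #\{F_perm >= F_obs\} / n!`; otherwise
#' `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_permutations)`.
#'
#' @param d symmetric distance matrix.
#' @param groups factor-like vector (>= 2 groups, each >= 2 samples).
#' @param n_permutations random permutation count (default 999).
#' @param seed RNG seed.
#' @param exact enumerate all permutations (requires `n <= 8`).
#' @return list with `F`, `p`, `df` (between, within), `n_permutations`.
#' @export
permanova <- function(d, groups, n_permutations = 999L, seed = 1L,
                      exact = FALSE) {
  d <- as.matrix(d)
  groups <- as.character(groups)
  n <- length(groups)
  stopifnot(nrow(d) == n)
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least two groups")
  if (any(tab < 2L)) {
    stop("singleton group(s): ", paste(names(tab)[tab < 2], collapse = ", "))
  }
  d2 <- d^2
  f_obs <- .permanova_F(d2, groups)
  a <- length(tab)
  if (exact) {
    if (n > 8L) stop("exact enumeration limited to n <= 8")
    perms <- all_permutations(n)
    f_perm <- apply(perms, 1, function(ix) .permanova_F(d2, groups[ix]))
    p <- mean(ge_tie(f_perm, f_obs))
    np <- nrow(perms)
  } else {
    f_perm <- with_seed(seed, {
      vapply(seq_len(n_permutations), function(b) {
        .permanova_F(d2, groups[sample.int(n)])
      }, numeric(1))
    })
    p <- (1 + sum(ge_tie(f_perm, f_obs))) / (1 + n_permutations)
    np <- n_permutations
  }
  list(F = f_obs, p = p, df = c(between = a - 1L, within = n - a),
       n_permutations = np)
}

#' Fit an environmental/abundance vector onto ordination scores
#'
#' Least-squares regression of the centered variable on the (centered)
#' ordination scores. `R^2 = 1 - SS_res / SS_tot`; significance by permuting
#' the variable across samples, `p = (1 + #\{R^2_perm >= R^2\}) /
#' (1 + n_permutations)` (with `exact = TRUE`, all `n!` permutations,
#' identity included, `p = #\{>=\} / n!`).
#'
#' @param ord an [nmds()] result or a plain score matrix.
#' @param v numeric variable, one value per sample (nonzero variance).
#' @param n_permutations,seed,exact as in [permanova()].
#' @return list with `r_squared`, `p`, `direction` (unit vector),
#'   `n_permutations`.
#' @export
envfit_vector <- function(ord, v, n_permutations = 999L, seed = 1L,
                          exact = FALSE) {
  scores <- if (is.list(ord)) ord$scores else ord
  scores <- as.matrix(scores)
  n <- nrow(scores)
  stopifnot(length(v) == n)
  if (stats::var(v) == 0) stop("variable has zero variance")
  S <- scale(scores, center = TRUE, scale = FALSE)
  qrS <- qr(S)
  Q <- qr.Q(qrS)[, seq_len(qrS$rank), drop = FALSE]
  vc <- v - mean(v)
  sst <- sum(vc^2)
  r2 <- sum(crossprod(Q, vc)^2) / sst
  coef <- qr.coef(qrS, vc)
  coef[is.na(coef)] <- 0
  nrm <- sqrt(sum(coef^2))
  direction <- if (nrm > 0) coef / nrm else coef
  if (exact) {
    if (n > 8L) stop("exact enumeration limited to n <= 8")
    perms <- all_permutations(n)
    Vp <- matrix(vc[t(perms)], nrow = n) # n x n! (columns are permutations)
    r2p <- colSums(crossprod(Q, Vp)^2) / sst
    p <- mean(ge_tie(r2p, r2))
    np <- nrow(perms)
  } else {
    r2p <- with_seed(seed, {
      Vp <- replicate(n_permutations, vc[sample.int(n)])
      colSums(crossprod(Q, Vp)^2) / sst
    })
    p <- (1 + sum(ge_tie(r2p, r2))) / (1 + n_permutations)
    np <- n_permutations
  }
  list(r_squared = r2, p = p, direction = direction, n_permutations = np)
}

#' Envfit screen of every MC against a marker ordination
#'
#' Computes the Bray-Curtis NMDS of one marker's MC abundance table and fits
#' each MC's relative abundance as a vector, recording permutation P and the
#' west/non-west mean abundances.
#'
#' @param abundance MC x sample relative-abundance matrix.
#' @param site_group character vector per sample ("western"/"non-western").
#' @param n_permutations,seed,k,alpha see [envfit_vector()] / [nmds()].
#' @return data.frame with columns mc, r_squared, p, mean_western,
#'   mean_nonwestern, enriched.
#' @export
envfit_mc_screen <- function(abundance, site_group, n_permutations = 999L,
                             seed = 1L, k = 2L, alpha = 0.05) {
  ok <- !apply(abundance, 2, function(x) any(is.na(x)))
  ab <- abundance[, ok, drop = FALSE]
  grp <- site_group[ok]
  d <- bray_curtis(ab)
  ord <- nmds(d, k = k, seed = child_seed(seed, 101L))
  west <- grp == "western"
  rows <- lapply(rownames(ab), function(mc) {
    v <- ab[mc, ]
    if (stats::var(v) == 0) {
      return(data.frame(mc = mc, r_squared = 0, p = 1,
                        mean_western = mean(v[west]),
                        mean_nonwestern = mean(v[!west]),
                        enriched = FALSE, stringsAsFactors = FALSE))
    }
    ef <- envfit_vector(ord, v, n_permutations = n_permutations,
                        seed = child_seed(seed, 200L + match(mc, rownames(ab))))
    mw <- mean(v[west]); mnw <- mean(v[!west])
    data.frame(mc = mc, r_squared = ef$r_squared, p = ef$p,
               mean_western = mw, mean_nonwestern = mnw,
               enriched = ef$p < alpha && mw > mnw,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify denitrifying specialist populations
#'
#' An MC is "enriched" for a marker when its envfit permutation P is below
#' `alpha` and its mean relative abundance is higher in western than in
#' non-western samples. The specialist call requires enrichment in at least
#' one taxonomic marker AND in the functional marker AND mean western
#' relative abundance above `abundance_threshold` in the taxonomic tables
#' (averaged over the taxonomic markers carrying the MC).
#'
#' @param screens named list of [envfit_mc_screen()] data.frames, one per
#'   marker; must include both taxonomic markers and the functional marker.
#' @param taxonomic_markers,functional_marker names into `screens`.
#' @param abundance_threshold minimum mean western relative abundance
#'   (default 0.01, i.e. >1%).
#' @return data.frame with one row per MC: per-marker P values,
#'   enriched_taxonomic, enriched_functional, mean_western_abundance, call.
#' @export
classify_specialists <- function(screens,
                                 taxonomic_markers = c("taxonomic_1", "taxonomic_2"),
                                 functional_marker = "functional",
                                 abundance_threshold = 0.01) {
  stopifnot(all(c(taxonomic_markers, functional_marker) %in% names(screens)))
  mcs <- sort(unique(unlist(lapply(screens, `[[`, "mc"))))
  get <- function(marker, mc, col) {
    s <- screens[[marker]]
    i <- match(mc, s$mc)
    if (is.na(i)) NA else s[[col]][i]
  }
  rows <- lapply(mcs, function(mc) {
    enr_tax <- vapply(taxonomic_markers, function(m) {
      isTRUE(get(m, mc, "enriched"))
    }, logical(1))
    enr_fun <- isTRUE(get(functional_marker, mc, "enriched"))
    mw <- vapply(taxonomic_markers, function(m) {
      x <- get(m, mc, "mean_western")
      if (is.null(x)) NA_real_ else as.numeric(x)
    }, numeric(1))
    mean_west <- if (all(is.na(mw))) 0 else mean(mw, na.rm = TRUE)
    call <- any(enr_tax) && enr_fun && mean_west > abundance_threshold
    data.frame(mc = mc,
               p_taxonomic_1 = as.numeric(get(taxonomic_markers[1], mc, "p")),
               p_taxonomic_2 = as.numeric(get(taxonomic_markers[2], mc, "p")),
               p_functional = as.numeric(get(functional_marker, mc, "p")),
               enriched_taxonomic = any(enr_tax),
               enriched_functional = enr_fun,
               mean_western_abundance = mean_west,
               call = if (call) "specialist" else "non-specialist",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-call specialist screen from marker abundance tables
#'
#' Convenience wrapper: runs [envfit_mc_screen()] on each marker table and
#' feeds the results to [classify_specialists()].
#'
#' @param abundance_tables named list of MC x sample relative-abundance
#'   matrices (names matching the marker arguments).
#' @param site_group per-sample group vector (order matching the table
#'   columns).
#' @param alpha envfit significance level.
#' @param abundance_threshold see [classify_specialists()].
#' @param n_permutations,seed,k passed to [envfit_mc_screen()].
#' @inheritParams classify_specialists
#' @return list with `calls` (the classification data.frame) and `screens`.
#' @export
specialist_screen <- function(abundance_tables, site_group,
                              taxonomic_markers = c("taxonomic_1", "taxonomic_2"),
                              functional_marker = "functional",
                              alpha = 0.05, abundance_threshold = 0.01,
                              n_permutations = 999L, seed = 1L, k = 2L) {
  screens <- lapply(seq_along(abundance_tables), function(i) {
    envfit_mc_screen(abundance_tables[[i]], site_group,
                     n_permutations = n_permutations,
                     seed = child_seed(seed, 1000L + i), k = k, alpha = alpha)
  })
  names(screens) <- names(abundance_tables)
  calls <- classify_specialists(screens,
                                taxonomic_markers = taxonomic_markers,
                                functional_marker = functional_marker,
                                abundance_threshold = abundance_threshold)
  list(calls = calls, screens = screens)
}
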