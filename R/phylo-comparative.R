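#' Brownian-motion covariance matrix of a rooted tree
#'
#' `C[i, j]` is the shared root-to-MRCA path length of tips i and j; the
#' diagonal holds root-to-tip distances.
#'
#' @param tree a rooted `phylo` with nonnegative branch lengths.
#' @return symmetric positive semi-definite matrix in tip-label order.
#' @export
brownian_cov <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip_ <- length(tree$tip.label)
  root_kids <- tree$edge[tree$edge[, 1] == ntip_ + 1L, 2]
  # star phylogenies (all root children are tips) are valid rooted trees even
  # though ape flags the basal polytomy as unrooted
  if (!ape::is.rooted(tree) && !all(root_kids <= ntip_)) {
    stop("tree must be rooted")
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  ntip <- length(tree$tip.label)
  h <- ape::node.depth.edgelength(tree) # root = 0
  C <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  mrcas <- ape::mrca(tree)
  C[] <- h[mrcas]
  diag(C) <- h[seq_len(ntip)]
  C
}

# one-way ANOVA F for trait(s) ~ groups; x may be a matrix (columns = traits)
.anova_F <- function(x, groups) {
  x <- as.matrix(x)
  n <- nrow(x)
  G <- stats::model.matrix(~ 0 + factor(groups))
  a <- ncol(G)
  ng <- colSums(G)
  gm <- sweep(crossprod(G, x), 1, ng, "/") # group means (a x traits)
  tm <- colMeans(x)
  ssb <- colSums(ng * sweep(gm, 2, tm)^2)
  sst <- colSums(sweep(x, 2, tm)^2)
  ssw <- sst - ssb
  (ssb / (a - 1)) / (ssw / (n - a))
}

# ML estimate of the Brownian rate (GLS mean profiled out)
.bm_sigma2_ml <- function(trait, C) {
  Ci <- solve(C)
  one <- rep(1, length(trait))
  mu <- as.numeric((t(one) %*% Ci %*% trait) / (t(one) %*% Ci %*% one))
  r <- trait - mu
  as.numeric(t(r) %*% Ci %*% r) / length(trait)
}

#' Phylogenetic ANOVA (simulation-based null F distribution)
#'
#' The observed statistic is the standard one-way ANOVA F of trait ~ groups.
#' The Brownian rate is estimated by maximum likelihood on the pooled trait;
#' `n_sim` traits are then simulated under Brownian motion on the tree with
#' that rate, F recomputed for each, and
#' `p = (1 + #\{F_sim >= F_obs\}) / (1 + n_sim)`.
#'
#' @param tree rooted `phylo`.
#' @param groups group labels per tip (>= 2 groups, each >= 2 tips).
#' @param trait named numeric vector per tip (nonzero variance).
#' @param n_sim number of Brownian null simulations (default 10000).
#' @param seed RNG seed.
#' @return list with `F`, `p`, `n_simulations`, `sigma2_hat`.
#' @export
phylanova <- function(tree, groups, trait, n_sim = 10000L, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(names(trait))) trait <- trait[tree$tip.label]
  if (!is.null(names(groups))) groups <- groups[tree$tip.label]
  if (stats::var(trait) == 0) stop("trait is constant")
  tab <- table(groups)
  if (length(tab) < 2L || any(tab < 2L)) {
    stop("need >= 2 groups with >= 2 tips each")
  }
  C <- brownian_cov(tree)
  s2 <- .bm_sigma2_ml(trait, C)
  f_obs <- as.numeric(.anova_F(trait, groups))
  L <- chol(C)
  f_sim <- with_seed(seed, {
    Z <- matrix(stats::rnorm(length(trait) * n_sim), length(trait), n_sim)
    X <- sqrt(s2) * crossprod(L, Z) # t(L) %*% Z: BM traits, mean irrelevant
    .anova_F(X, groups)
  })
  list(F = f_obs, p = (1 + sum(f_sim >= f_obs)) / (1 + n_sim),
       n_simulations = n_sim, sigma2_hat = s2)
}

# profile log-likelihood of a trait under the lambda model (mean and rate
# profiled out analytically)
.lambda_loglik <- function(lambda, trait, C) {
  V <- lambda * C
  diag(V) <- diag(C)
  Lc <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(Lc)) return(-Inf)
  n <- length(trait)
  logdet <- 2 * sum(log(diag(Lc)))
  Vi_one <- backsolve(Lc, forwardsolve(t(Lc), rep(1, n)))
  Vi_x <- backsolve(Lc, forwardsolve(t(Lc), trait))
  mu <- sum(Vi_x) / sum(Vi_one)
  r <- trait - mu
  Vi_r <- backsolve(Lc, forwardsolve(t(Lc), r))
  s2 <- sum(r * Vi_r) / n
  if (s2 <= 0) return(-Inf)
  -0.5 * (n * log(2 * pi * s2) + logdet + n)
}

#' Pagel's lambda phylogenetic signal test
#'
#' Maximizes the Gaussian likelihood of the trait with covariance
#' `C_lambda` (off-diagonal of the Brownian covariance scaled by
#' `lambda in [0, 1]`, diagonal unchanged), profiling the mean and rate.
#' Significance is a likelihood ratio against `lambda = 0` referred to a
#' chi-square with 1 degree of freedom. A constant trait is returned as an
#' excluded (NaN-pattern) result rather than an error, matching the gene
#' screen workflow.
#'
#' @param tree rooted `phylo`.
#' @param trait numeric per tip; binary 0/1 traits are accepted as numeric.
#' @return list with `lambda`, `logL`, `logL0`, `LR`, `p`, `excluded`.
#' @export
pagel_lambda_signal <- function(tree, trait) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(names(trait))) trait <- trait[tree$tip.label]
  if (stats::var(trait) == 0) {
    return(list(lambda = NA_real_, logL = NA_real_, logL0 = NA_real_,
                LR = NA_real_, p = NA_real_, excluded = TRUE))
  }
  C <- brownian_cov(tree)
  opt <- stats::optimize(function(l) .lambda_loglik(l, trait, C),
                         interval = c(0, 1), maximum = TRUE, tol = 1e-8)
  l0 <- .lambda_loglik(0, trait, C)
  l1 <- .lambda_loglik(1, trait, C)
  # optimizer sanity: never report worse than the boundary evaluations
  cand <- c(opt$maximum, 0, 1)
  vals <- c(opt$objective, l0, l1)
  best <- which.max(vals)
  lam <- cand[best]
  ll <- vals[best]
  LR <- max(0, 2 * (ll - l0))
  list(lambda = lam, logL = ll, logL0 = l0, LR = LR,
       p = stats::pchisq(LR, df = 1, lower.tail = FALSE), excluded = FALSE)
}

#' Binary phylogenetic generalized linear mixed model
#'
#' Logistic mixed model `logit P(y = 1) = X beta + b`,
#' `b ~ N(0, s2 * C)`, estimated by iterated working-response penalized
#' quasi-likelihood (the Ives-Garland scheme): for a candidate `s2`, the
#' working response is refit by alternating GLS updates of `beta` and the
#' random effect until relative change falls below `tol`; `s2 >= 0` is then
#' chosen by minimizing the working-model restricted likelihood. Wald tests
#' for the coefficients. `C` is standardized to unit mean diagonal so the
#' `s2` scale is comparable across trees.
#'
#' @param tree rooted `phylo` (or a covariance matrix via `C`).
#' @param y binary 0/1 response per tip (non-constant).
#' @param x predictor per tip (binary or continuous, non-constant).
#' @param C optional covariance matrix overriding `tree`.
#' @param s2_fixed optionally fix the phylogenetic variance (e.g. 0 for an
#'   ordinary logistic fit).
#' @param tol,max_iter inner-loop convergence controls.
#' @return list with `coefficients` (data.frame: estimate, se, z, p for
#'   intercept and slope), `s2`, `converged`, `separation`.
#' @export
binary_pglmm <- function(tree, y, x, C = NULL, s2_fixed = NULL,
                         tol = 1e-6, max_iter = 100L) {
  if (is.null(C)) C <- brownian_cov(tree)
  if (!is.null(names(y))) y <- y[rownames(C)]
  if (!is.null(names(x))) x <- x[rownames(C)]
  n <- length(y)
  stopifnot(nrow(C) == n, length(x) == n)
  if (stats::var(y) == 0) stop("y is constant")
  if (stats::var(x) == 0) stop("x is constant")
  C <- C / mean(diag(C))
  X <- cbind(`(Intercept)` = 1, x = as.numeric(x))
  y <- as.numeric(y)

  fit_inner <- function(s2) {
    B <- c(stats::qlogis(mean(y) * 0.98 + 0.01), 0)
    b <- rep(0, n)
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      eta <- as.numeric(X %*% B + b)
      mu <- stats::plogis(eta)
      mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
      w <- mu * (1 - mu)
      Z <- eta + (y - mu) / w
      V <- diag(1 / w) + s2 * C
      Vi <- solve(V)
      XtVi <- crossprod(X, Vi)
      covB <- solve(XtVi %*% X)
      Bnew <- as.numeric(covB %*% XtVi %*% Z)
      bnew <- as.numeric(s2 * C %*% Vi %*% (Z - X %*% Bnew))
      del <- max(abs(Bnew - B), abs(bnew - b))
      B <- Bnew; b <- bnew
      if (del < tol * (1 + max(abs(B)))) {
        ok <- TRUE
        break
      }
    }
    eta <- as.numeric(X %*% B + b)
    mu <- stats::plogis(eta)
    w <- pmin(pmax(mu * (1 - mu), 1e-10), 0.25)
    Z <- eta + (y - mu) / pmin(pmax(mu * (1 - mu), 1e-10), 1)
    V <- diag(1 / w) + s2 * C
    Vi <- solve(V)
    XtViX <- crossprod(X, Vi) %*% X
    r <- Z - as.numeric(X %*% B)
    crit <- 0.5 * (determinant(V, logarithm = TRUE)$modulus +
                     determinant(XtViX, logarithm = TRUE)$modulus +
                     t(r) %*% Vi %*% r)
    list(B = B, b = b, mu = mu, covB = solve(XtViX),
         crit = as.numeric(crit), converged = ok)
  }

  if (is.null(s2_fixed)) {
    opt <- stats::optimize(function(s2) fit_inner(s2)$crit,
                           interval = c(0, 10), tol = 1e-4)
    s2 <- opt$minimum
    if (fit_inner(0)$crit <= opt$objective) s2 <- 0
  } else {
    s2 <- s2_fixed
  }
  fin <- fit_inner(s2)
  se <- sqrt(diag(fin$covB))
  z <- fin$B / se
  coefs <- data.frame(estimate = fin$B, se = se, z = z,
                      p = 2 * stats::pnorm(-abs(z)),
                      row.names = colnames(X))
  separation <- any(fin$mu > 1 - 1e-6 | fin$mu < 1e-6)
  if (separation) warning("binary_pglmm: fitted probabilities pinned at 0/1 (separation)")
  if (!fin$converged) warning("binary_pglmm: inner loop did not converge")
  list(coefficients = coefs, s2 = s2, converged = fin$converged,
       separation = separation)
}

#' Gene-by-gene specialist association workflow
#'
#' Per gene: an invariant presence/absence pattern is excluded (the
#' NaN-pattern rule); otherwise the phylogenetic signal of the 0/1 pattern
#' is tested with [pagel_lambda_signal()]; significant signal
#' (`p <= alpha`) routes the gene to [binary_pglmm()] against specialist
#' status, otherwise to a Pearson chi-square on the 2x2 gene-by-specialist
#' table plus an ordinary linear-regression coefficient.
#'
#' @param tree rooted `phylo` over the genomes.
#' @param pa genomes x genes binary matrix (rownames = tip labels).
#' @param specialist named logical (or 0/1) vector per genome.
#' @param alpha phylogenetic-signal significance level (default 0.05).
#' @param chisq_correct apply Yates continuity correction in the chi-square
#'   branch (default FALSE).
#' @return data.frame with one row per gene: gene, branch
#'   ("pglmm"/"chisq"/"excluded"), lambda, phylosig_p, effect, assoc_p, s2.
#' @export
gene_trait_association_workflow <- function(tree, pa, specialist,
                                            alpha = 0.05,
                                            chisq_correct = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  pa <- as.matrix(pa)
  if (!all(tree$tip.label %in% rownames(pa))) stop("pa rows must cover all tips")
  pa <- pa[tree$tip.label, , drop = FALSE]
  if (!all(tree$tip.label %in% names(specialist))) {
    stop("specialist labels must cover all tips")
  }
  spec <- as.numeric(specialist[tree$tip.label])
  rows <- lapply(colnames(pa), function(g) {
    yg <- pa[, g]
    if (stats::var(yg) == 0) {
      return(data.frame(gene = g, branch = "excluded", lambda = NA_real_,
                        phylosig_p = NA_real_, effect = NA_real_,
                        assoc_p = NA_real_, s2 = NA_real_,
                        stringsAsFactors = FALSE))
    }
    sig <- pagel_lambda_signal(tree, yg)
    if (!is.na(sig$p) && sig$p <= alpha) {
      fit <- tryCatch(
        suppressWarnings(binary_pglmm(tree, y = yg, x = spec)),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        return(data.frame(gene = g, branch = "pglmm", lambda = sig$lambda,
                          phylosig_p = sig$p, effect = NA_real_,
                          assoc_p = NA_real_, s2 = NA_real_,
                          stringsAsFactors = FALSE))
      }
      data.frame(gene = g, branch = "pglmm", lambda = sig$lambda,
                 phylosig_p = sig$p,
                 effect = fit$coefficients["x", "estimate"],
                 assoc_p = fit$coefficients["x", "p"], s2 = fit$s2,
                 stringsAsFactors = FALSE)
    } else {
      tab <- table(factor(yg, levels = 0:1), factor(spec, levels = 0:1))
      ct <- suppressWarnings(stats::chisq.test(tab, correct = chisq_correct))
      slope <- stats::coef(stats::lm(yg ~ spec))[2]
      data.frame(gene = g, branch = "chisq", lambda = sig$lambda,
                 phylosig_p = sig$p, effect = as.numeric(slope),
                 assoc_p = ct$p.value, s2 = NA_real_,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Median-dichotomized chi-square test of activity vs site group
#'
#' Values strictly above the whole-dataset median form group A ("higher than
#' the median"); ties and lower values form group B. Pearson chi-square of
#' independence on the 2x2 activity-group x site-group table, no continuity
#' correction by default.
#'
#' @param values numeric activity measurements.
#' @param site_group group label per value (each group needs >= 2 values).
#' @param correct Yates correction flag (default FALSE).
#' @return list with `chisq`, `p`, `table`, `median`.
#' @export
median_dichotomize_chisq <- function(values, site_group, correct = FALSE) {
  site_group <- as.character(site_group)
  tab0 <- table(site_group)
  if (length(tab0) < 2L || any(tab0 < 2L)) {
    stop("each site group needs at least two values")
  }
  med <- stats::median(values)
  act <- factor(ifelse(values > med, "A", "B"), levels = c("A", "B"))
  tab <- table(activity = act, site_group = site_group)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(chisq = as.numeric(ct$statistic), p = ct$p.value, table = tab,
       median = med)
}
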