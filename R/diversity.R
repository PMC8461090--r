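# Alpha diversity, taxonomic and phylogenetic beta diversity, ordination
# and one-way PERMANOVA.

#' Observed richness of one sample
#' @param x count vector.
#' @return number of taxa with count > 0.
#' @export
observed_richness <- function(x) sum(x > 0)

#' Shannon diversity (natural log)
#' @param x count vector with positive total.
#' @return Shannon entropy in nats, \eqn{-\sum p_i \ln p_i}.
#' @export
shannon <- function(x) {
  if (sum(x) <= 0) stop("Shannon undefined for zero-total sample")
  as.numeric(vegan::diversity(x, index = "shannon"))
}

#' Gini-Simpson diversity
#' @param x count vector with positive total.
#' @return \eqn{1 - \sum p_i^2}.
#' @export
simpson <- function(x) {
  if (sum(x) <= 0) stop("Simpson undefined for zero-total sample")
  as.numeric(vegan::diversity(x, index = "simpson"))
}

#' Bias-corrected Chao1 richness estimate
#'
#' \eqn{S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))} with \eqn{F_1} singletons
#' and \eqn{F_2} doubletons; the bias-corrected denominator keeps the
#' estimator defined when no doubletons are observed.
#'
#' @param x integer count vector.
#' @return the Chao1 estimate.
#' @export
chao1 <- function(x) {
  if (any(x < 0) || any(x != round(x)))
    stop("Chao1 requires nonnegative integer counts")
  as.numeric(vegan::estimateR(round(x))["S.chao1"])
}

#' Per-sample alpha diversity table
#' @param table samples x taxa count matrix.
#' @return data.frame with columns sample_id, observed_richness, shannon,
#'   simpson, chao1.
#' @export
alpha_diversity <- function(table) {
  validate_community_table(table)
  data.frame(
    sample_id = rownames(table),
    observed_richness = apply(table, 1, observed_richness),
    shannon = apply(table, 1, shannon),
    simpson = apply(table, 1, simpson),
    chao1 = apply(table, 1, chao1),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d(x, y) = 1 - 2 \sum_i \min(x_i, y_i) / (\sum_i x_i + \sum_i y_i)}.
#' Intended for an even-depth (rarefied) table; a warning is emitted when
#' row sums differ.
#'
#' @param table samples x taxa count matrix.
#' @return a `dist` object of pairwise dissimilarities in `[0, 1]`.
#' @export
bray_curtis <- function(table) {
  totals <- rowSums(table)
  if (any(totals <= 0))
    stop("zero-sum sample(s): ",
         paste(rownames(table)[totals <= 0], collapse = ", "))
  if (diff(range(totals)) > 0)
    warning("sample totals are uneven; consider rarefying first")
  vegan::vegdist(table, method = "bray")
}

#' Unweighted UniFrac distance matrix
#'
#' Presence/absence phylogenetic dissimilarity: the fraction of the branch
#' length in the union of two samples' lineages that is unique to one of
#' them, with each branch attributed by the presence of its descendant tips.
#'
#' @param table samples x taxa count matrix; presence is count > 0.
#' @param tree rooted `phylo` tree whose tips include all table taxa.
#' @return a `dist` object with entries in `[0, 1]`.
#' @export
unweighted_unifrac <- function(table, tree) {
  check_tree_covers(tree, colnames(table))
  if (length(tree$tip.label) > ncol(table))
    tree <- ape::keep.tip(tree, colnames(table))
  if (!ape::is.rooted(tree))
    tree <- ape::multi2di(tree, random = FALSE)  # zero-length resolution
  pa <- (table > 0) * 1
  picante::unifrac(pa, tree)
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a dissimilarity matrix by double-centering
#' \eqn{-d^2/2}. Axes are ordered by decreasing eigenvalue; axes belonging
#' to negative or null eigenvalues are not returned (with a warning when
#' that truncates below the requested dimension), but the full eigenvalue
#' spectrum is reported.
#'
#' @param d `dist` or square symmetric matrix.
#' @param k number of requested axes.
#' @return object of class `ordination`: list with `points` (samples x
#'   axes), `eig` (all eigenvalues, nonincreasing) and `method = "PCoA"`.
#' @export
pcoa_ordination <- function(d, k = 2) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (k < 1) stop("k must be >= 1")
  fit <- suppressWarnings(
    cmdscale(d, k = min(k, n - 1), eig = TRUE, add = FALSE))
  eig <- sort(fit$eig, decreasing = TRUE)
  tol <- max(abs(eig), 1) * 1e-12
  npos <- sum(eig > tol)
  pts <- fit$points
  if (npos == 0) {
    pts <- matrix(0, n, k,
                  dimnames = list(attr(d, "Labels"), paste0("Axis", seq_len(k))))
  } else if (k > npos) {
    warning("only ", npos, " positive eigenvalue(s); returning ", npos,
            " axis/axes instead of ", k)
    pts <- pts[, seq_len(npos), drop = FALSE]
  }
  if (is.null(rownames(pts))) rownames(pts) <- attr(d, "Labels")
  colnames(pts) <- paste0("Axis", seq_len(ncol(pts)))
  structure(list(points = pts, eig = eig, method = "PCoA"),
            class = "ordination")
}

#' Non-metric multidimensional scaling
#'
#' Minimizes Kruskal stress-1 with monotone (isotonic) regression on ranked
#' dissimilarities, taking the best of `n_starts` configurations: the first
#' start is the PCoA solution, the rest are random. Tied dissimilarities
#' receive Kruskal's primary treatment.
#'
#' @param d `dist` or square symmetric matrix.
#' @param k target dimension.
#' @param seed integer seed for the random restarts.
#' @param n_starts number of starting configurations (default 20).
#' @param max_iter maximum iterations per start.
#' @param tol stress-improvement convergence tolerance.
#' @return object of class `ordination`: `points`, `stress` (stress-1),
#'   `converged` flag, `method = "NMDS"`.
#' @export
nmds_ordination <- function(d, k = 2, seed = 1L, n_starts = 20,
                            max_iter = 500, tol = 1e-9) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (k < 1) stop("k must be >= 1")
  if (all(d == 0)) {
    pts <- matrix(0, n, k, dimnames = list(attr(d, "Labels"), NULL))
    return(structure(list(points = pts, stress = 0, converged = TRUE,
                          method = "NMDS"), class = "ordination"))
  }
  run_one <- function(y0) {
    suppressWarnings(vegan::monoMDS(
      d, y = y0, k = k, model = "global",
      maxit = max_iter, smin = 1e-10, sfgrmin = 1e-10,
      sratmax = 1 - tol))
  }
  best <- NULL
  with_seed_(seed, {
    init <- suppressWarnings(cmdscale(d, k = k))
    if (ncol(init) < k)
      init <- cbind(init, matrix(rnorm(n * (k - ncol(init)), sd = 1e-4),
                                 n, k - ncol(init)))
    best <- run_one(init)
    for (i in seq_len(max(0, n_starts - 1))) {
      cand <- run_one(matrix(runif(n * k, -1, 1), n, k))
      if (cand$stress < best$stress) best <- cand
    }
  })
  pts <- best$points
  rownames(pts) <- attr(d, "Labels")
  structure(list(points = pts, stress = best$stress,
                 converged = best$maxits >= best$iters, method = "NMDS"),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(x$method, "ordination:", nrow(x$points), "samples,",
      ncol(x$points), "axes\n")
  if (x$method == "NMDS") cat("stress-1:", format(x$stress), "\n")
  if (x$method == "PCoA")
    cat("first eigenvalues:",
        paste(format(head(x$eig, 4), digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' One-way PERMANOVA (ADONIS)
#'
#' Permutational multivariate analysis of variance on a dissimilarity
#' matrix for a single grouping factor, using the Anderson partition of
#' squared inter-point distances. The permutation p-value counts the
#' observed statistic, so it can never reach zero.
#'
#' @param d `dist` or square symmetric matrix.
#' @param groups grouping factor, one level per sample.
#' @param n_perm number of permutations (paper-style default 999).
#' @param seed integer seed; p-values are seed-reproducible.
#' @return object of class `permanova`: list with `f`, `r2`, `p`,
#'   `n_perm`, `seed`, `df`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1L) {
  d <- stats::as.dist(d)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (length(groups) != attr(d, "Size"))
    stop("groups length must match the distance matrix")
  if (n_perm < 1) stop("n_perm must be >= 1")
  fit <- with_seed_(seed,
    vegan::adonis2(d ~ groups, permutations = n_perm))
  structure(list(
    f = fit$F[1], r2 = fit$R2[1], p = fit$`Pr(>F)`[1],
    n_perm = n_perm, seed = as.integer(seed),
    df = c(between = fit$Df[1], within = fit$Df[2])),
    class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: pseudo-F = %.4g, R2 = %.4g, p = %.4g (%d permutations)\n",
    x$f, x$r2, x$p, x$n_perm))
  invisible(x)
}
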