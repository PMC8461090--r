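# Core assembly partitioning: phylogenetic binning, per-bin null models of
# beta diversity (bNRI and modified Raup-Crick), classification of each
# sample pair x bin into one of five ecological processes, and
# abundance-weighted aggregation to pair- and group-level process fractions.

#' Null-model configuration
#'
#' Parameters of the phylogenetic-bin null-model framework.
#'
#' @param n_null number of null-model randomizations (default 1000; 200 is
#'   acceptable for exploratory or test-scale runs).
#' @param bnri_threshold absolute bNRI threshold for selection (default
#'   1.96, the two-sided 95% normal bound).
#' @param rc_threshold absolute modified Raup-Crick threshold for dispersal
#'   processes (default 0.95).
#' @param bin_size_min minimum taxa per phylogenetic bin after merging
#'   (default 24; 6 is a reasonable small-data choice).
#' @param ds_cut phylogenetic-distance (cophenetic diameter) cut used to
#'   slice the tree into bins (default 0.2, in the tree's branch-length
#'   units).
#' @param abundance_weighted use within-bin relative abundances as bMPD
#'   weights (default TRUE); FALSE gives the presence/absence variant.
#' @param seed master seed for all null randomizations.
#' @return object of class `null_model_config`.
#' @export
null_model_config <- function(n_null = 1000, bnri_threshold = 1.96,
                              rc_threshold = 0.95, bin_size_min = 24,
                              ds_cut = 0.2, abundance_weighted = TRUE,
                              seed = 1L) {
  stopifnot(n_null >= 1, bnri_threshold > 0, rc_threshold > 0,
            bin_size_min >= 1, ds_cut >= 0)
  structure(list(n_null = as.integer(n_null),
                 bnri_threshold = bnri_threshold,
                 rc_threshold = rc_threshold,
                 bin_size_min = as.integer(bin_size_min),
                 ds_cut = ds_cut,
                 abundance_weighted = isTRUE(abundance_weighted),
                 seed = as.integer(seed)),
            class = "null_model_config")
}

#' @export
print.null_model_config <- function(x, ...) {
  cat(sprintf(
    "null-model config: n_null=%d, |bNRI|>%.3g, |RC|>%.3g, bins>=%d taxa, ds_cut=%.3g, %s bMPD\n",
    x$n_null, x$bnri_threshold, x$rc_threshold, x$bin_size_min, x$ds_cut,
    if (x$abundance_weighted) "abundance-weighted" else "unweighted"))
  invisible(x)
}

# Per-node subtree height and cophenetic diameter (max tip-tip path within
# the clade), computed bottom-up over the postorder edge list.
node_diameters <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  h <- numeric(nn)      # max node-to-descendant-tip distance
  diam <- numeric(nn)   # max within-clade tip-tip distance
  po <- ape::reorder.phylo(tree, "postorder")
  edges <- po$edge; lens <- po$edge.length
  # children are processed before parents in postorder edge order
  best1 <- numeric(nn)  # largest child height+edge seen so far at a node
  for (e in seq_len(nrow(edges))) {
    p <- edges[e, 1]; c <- edges[e, 2]
    hc <- h[c] + lens[e]
    diam[p] <- max(diam[p], diam[c], best1[p] + hc)
    best1[p] <- max(best1[p], hc)
    h[p] <- max(h[p], hc)
  }
  list(height = h, diameter = diam)
}

#' Partition taxa into phylogenetic bins
#'
#' Cuts the phylogeny into maximal clades whose within-clade cophenetic
#' diameter does not exceed `ds_cut`, then merges clades smaller than
#' `bin_size_min` into their phylogenetically nearest neighbour (smallest
#' mean inter-clade cophenetic distance, ties to the smaller bin index)
#' until every bin meets the minimum. Deterministic for a fixed tree; bin
#' identities do not depend on the column order of the count table.
#'
#' @param tree rooted `phylo` covering all table taxa.
#' @param table samples x taxa count matrix (defines the taxon set).
#' @param config a [null_model_config()].
#' @return object of class `phylo_bins`: `assignment` (named integer
#'   vector taxon -> bin), `members` (list of taxon-id vectors),
#'   `diameter` (within-bin max cophenetic distance), `n_bins`.
#' @export
bin_taxa <- function(tree, table, config = null_model_config()) {
  taxa <- colnames(table)
  check_tree_covers(tree, taxa)
  if (config$bin_size_min > length(taxa))
    stop("bin_size_min (", config$bin_size_min,
         ") exceeds the number of taxa (", length(taxa), ")")
  tr <- if (length(tree$tip.label) > length(taxa))
    ape::keep.tip(tree, taxa) else tree
  nt <- length(tr$tip.label)
  nd <- node_diameters(tr)
  qual <- nd$diameter <= config$ds_cut
  # bin root of a tip = its highest qualifying ancestor (diameter is
  # nondecreasing toward the root, so qualifying nodes form a path prefix)
  parent <- integer(nt + tr$Nnode)
  parent[tr$edge[, 2]] <- tr$edge[, 1]
  root <- nt + 1L
  binroot <- integer(nt)
  for (tip in seq_len(nt)) {
    node <- tip
    while (node != root && qual[parent[node]]) node <- parent[node]
    binroot[tip] <- node
  }
  members <- split(tr$tip.label, binroot)
  coph <- cophenetic(tr)
  # merge undersized bins into their nearest neighbouring bin
  repeat {
    sizes <- lengths(members)
    if (length(members) == 1 || all(sizes >= config$bin_size_min)) break
    small <- which(sizes < config$bin_size_min)
    b <- small[which.min(sizes[small])]
    others <- setdiff(seq_along(members), b)
    dmean <- vapply(others, function(o)
      mean(coph[members[[b]], members[[o]], drop = FALSE]), numeric(1))
    tgt <- others[which.min(dmean)]
    keep <- min(b, tgt)
    members[[keep]] <- c(members[[min(b, tgt)]], members[[max(b, tgt)]])
    members[[max(b, tgt)]] <- NULL
  }
  # canonical ordering: bins sorted by their alphabetically smallest member
  members <- lapply(members, sort)
  members <- members[order(vapply(members, `[`, character(1), 1))]
  names(members) <- NULL
  assignment <- integer(length(taxa)); names(assignment) <- taxa
  diameter <- numeric(length(members))
  for (b in seq_along(members)) {
    assignment[members[[b]]] <- b
    diameter[b] <- if (length(members[[b]]) > 1)
      max(coph[members[[b]], members[[b]]]) else 0
  }
  structure(list(assignment = assignment, members = members,
                 diameter = diameter, n_bins = length(members),
                 ds_cut = config$ds_cut,
                 bin_size_min = config$bin_size_min),
            class = "phylo_bins")
}

#' @export
print.phylo_bins <- function(x, ...) {
  cat("phylogenetic bins:", x$n_bins, "bins over",
      length(x$assignment), "taxa (sizes",
      paste(range(lengths(x$members)), collapse = "-"), ")\n")
  invisible(x)
}

#' Between-sample mean pairwise phylogenetic distance (bMPD)
#'
#' Abundance-weighted mean of the phylogenetic distance between taxa of one
#' sample and taxa of the other, with weights equal to the product of
#' within-sample relative abundances over the supplied taxon set (typically
#' one bin). The unweighted variant averages uniformly over present taxa.
#'
#' @param xa,xb count or abundance vectors over the same taxa.
#' @param d square matrix of pairwise phylogenetic distances for those taxa.
#' @param abundance_weighted logical.
#' @return the bMPD value.
#' @export
beta_mpd <- function(xa, xb, d, abundance_weighted = TRUE) {
  if (sum(xa) <= 0 || sum(xb) <= 0)
    stop("bMPD undefined when a sample holds no individuals of these taxa")
  if (abundance_weighted) {
    a <- xa / sum(xa); b <- xb / sum(xb)
  } else {
    a <- (xa > 0) / sum(xa > 0); b <- (xb > 0) / sum(xb > 0)
  }
  as.numeric(a %*% d %*% b)
}

# --- internal null-model engine -------------------------------------------

# bNRI for all sample pairs within one bin.  W: samples x m weight matrix
# (rows summing to 1 where the bin is present, all-zero otherwise);
# Db: m x m member distance matrix.  The null shuffles member identities
# (rows/columns of Db) within the bin, holding abundances fixed.
bin_bnri <- function(W, Db, n_null, seed) {
  O <- W %*% Db %*% t(W)
  m <- ncol(Db)
  S <- nrow(W)
  nsum <- matrix(0, S, S); nsq <- matrix(0, S, S)
  with_seed_(seed, {
    for (k in seq_len(n_null)) {
      p <- sample.int(m)
      Nk <- W %*% Db[p, p] %*% t(W)
      nsum <- nsum + Nk
      nsq <- nsq + Nk * Nk
    }
  })
  nmean <- nsum / n_null
  nvar <- (nsq - n_null * nmean^2) / (n_null - 1)
  nvar[nvar < 0] <- 0
  nsd <- sqrt(nvar)
  # relative tolerance: catastrophic cancellation in the running sums puts
  # the numerical floor of nsd near 1e-8 x the mean for exactly-invariant
  # (e.g. star-shaped) nulls
  degenerate <- nsd <= 1e-6 * pmax(abs(nmean), 1)
  denom <- nsd
  denom[degenerate] <- 1
  bnri <- (O - nmean) / denom
  bnri[degenerate] <- 0
  list(obs = O, bnri = bnri, degenerate = degenerate)
}

# Null count communities for one sample within one bin: preserve the
# sample's bin richness (taxa drawn with probability proportional to
# occurrence frequency across samples) and bin abundance (one individual
# per drawn taxon, the remainder multinomial with probability proportional
# to the taxa's mean relative abundance).  Returns an n_null x m matrix.
bin_null_counts <- function(n_null, m, richness, total, occ_freq, mean_ab,
                            seed) {
  out <- matrix(0L, n_null, m)
  avail <- which(occ_freq > 0)
  with_seed_(seed, {
    for (k in seq_len(n_null)) {
      idx <- if (richness >= length(avail)) avail
             else avail[sample.int(length(avail), richness,
                                   prob = occ_freq[avail])]
      counts <- rep(1L, length(idx))
      extra <- total - length(idx)
      if (extra > 0) {
        pr <- mean_ab[idx]
        if (sum(pr) <= 0) pr <- rep(1, length(idx))
        counts <- counts + as.integer(rmultinom(1, extra, pr))
      }
      out[k, idx] <- counts
    }
  })
  out
}

bray_rows <- function(X, Y) {
  rowSums(abs(X - Y)) / rowSums(X + Y)
}

# Score all requested sample pairs against all bins.  `pairs` is a
# 2-column character matrix of sample ids.
assembly_pair_scores <- function(table, tree, bins, pairs, config) {
  taxa <- colnames(table)
  tr <- if (length(tree$tip.label) > length(taxa))
    ape::keep.tip(tree, taxa) else tree
  coph <- cophenetic(tr)[taxa, taxa]
  P <- relative_abundance(table)
  totals <- rowSums(table)
  sample_ids <- rownames(table)
  i1 <- match(pairs[, 1], sample_ids)
  i2 <- match(pairs[, 2], sample_ids)
  if (anyNA(i1) || anyNA(i2)) stop("pair sample ids not found in table")
  out <- vector("list", bins$n_bins)
  for (b in seq_len(bins$n_bins)) {
    mem <- bins$members[[b]]
    m <- length(mem)
    Db <- coph[mem, mem, drop = FALSE]
    cnt <- table[, mem, drop = FALSE]
    bin_tot <- rowSums(cnt)
    rich <- rowSums(cnt > 0)
    ok <- bin_tot[i1] > 0 & bin_tot[i2] > 0
    if (!any(ok)) next
    bin_seed <- derive_seed(config$seed, paste(mem, collapse = ","))
    if (config$abundance_weighted) {
      W <- cnt / pmax(bin_tot, 1)
    } else {
      W <- (cnt > 0) / pmax(rich, 1)
    }
    nb <- bin_bnri(W, Db, config$n_null, derive_seed(bin_seed, "bnri"))
    occ_freq <- colSums(cnt > 0)
    mean_ab <- colMeans(P[, mem, drop = FALSE])
    need <- sort(unique(c(i1[ok], i2[ok])))
    nulls <- vector("list", nrow(table))
    for (s in need)
      nulls[[s]] <- bin_null_counts(config$n_null, m, rich[s], bin_tot[s],
                                    occ_freq, mean_ab,
                                    derive_seed(bin_seed, sample_ids[s]))
    wok <- which(ok)
    rc <- obs_bc <- numeric(length(wok))
    for (j in seq_along(wok)) {
      a <- i1[wok[j]]; bb <- i2[wok[j]]
      x <- cnt[a, ]; y <- cnt[bb, ]
      obs <- sum(abs(x - y)) / sum(x + y)
      nullbc <- bray_rows(nulls[[a]], nulls[[bb]])
      lt <- sum(nullbc < obs - 1e-12)
      eq <- sum(abs(nullbc - obs) <= 1e-12)
      rc[j] <- 2 * ((lt + 0.5 * eq) / config$n_null - 0.5)
      obs_bc[j] <- obs
    }
    idx <- cbind(i1[wok], i2[wok])
    bnri <- nb$bnri[idx]
    proc <- classify_process(bnri, rc, config)
    out[[b]] <- data.frame(
      sample_1 = unname(pairs[wok, 1]), sample_2 = unname(pairs[wok, 2]),
      bin = b,
      bmpd_obs = nb$obs[idx],
      bnri = bnri,
      degenerate_null = nb$degenerate[idx],
      rc = rc,
      bray_obs = obs_bc,
      process = proc,
      weight = (bin_tot[i1[wok]] / totals[i1[wok]] +
                bin_tot[i2[wok]] / totals[i2[wok]]) / 2,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Beta net relatedness index for one sample pair and one bin
#'
#' Standardized effect size of the observed between-sample bMPD against a
#' null distribution obtained by shuffling taxon identities among the bin's
#' members while holding abundances fixed. A degenerate null (zero standard
#' deviation, e.g. a star-shaped bin where every shuffle preserves all
#' distances) returns 0 with attribute `degenerate = TRUE`, deferring
#' classification to the Raup-Crick index.
#'
#' @param table samples x taxa count matrix.
#' @param tree rooted `phylo` covering the taxa.
#' @param pair character vector of two sample ids.
#' @param taxa character vector: the bin's member taxa.
#' @param config a [null_model_config()].
#' @return the bNRI value with attribute `degenerate`.
#' @export
beta_nri <- function(table, tree, pair, taxa, config = null_model_config()) {
  sc <- one_bin_scores(table, tree, pair, taxa, config)
  structure(sc$bnri, degenerate = sc$degenerate_null)
}

#' Modified Raup-Crick index on Bray-Curtis for one sample pair and one bin
#'
#' Ranks the observed bin-restricted Bray-Curtis dissimilarity within a
#' null ensemble that preserves each sample's bin richness (taxa drawn with
#' probability proportional to occurrence frequency) and bin abundance
#' (individuals drawn proportionally to mean relative abundance), rescaled
#' to `[-1, 1]`.
#'
#' @inheritParams beta_nri
#' @return the RC value in `[-1, 1]`.
#' @export
rc_bray <- function(table, pair, taxa, config = null_model_config(),
                    tree = NULL) {
  # the tree plays no role in RC; accepted for interface symmetry
  sc <- one_bin_scores(table, NULL, pair, taxa, config)
  sc$rc
}

one_bin_scores <- function(table, tree, pair, taxa, config) {
  stopifnot(length(pair) == 2)
  if (is.null(tree)) {
    # star distances; only RC fields are meaningful downstream
    m <- length(taxa)
    tree <- ape::read.tree(text = paste0(
      "(", paste0(taxa, ":1", collapse = ","), ");"))
  }
  bins <- structure(list(assignment = stats::setNames(rep(1L, length(taxa)),
                                                      taxa),
                         members = list(sort(taxa)), diameter = 0,
                         n_bins = 1L), class = "phylo_bins")
  sc <- assembly_pair_scores(table[, taxa, drop = FALSE], tree, bins,
                             matrix(pair, 1, 2), config)
  if (is.null(sc) || nrow(sc) == 0)
    stop("bin absent from one or both samples; score undefined")
  sc
}

#' Classify a (bNRI, RC) pair into an ecological process
#'
#' Selection first: bNRI above the positive threshold is heterogeneous
#' selection (communities more phylogenetically dissimilar than the null),
#' below the negative threshold homogeneous selection. Otherwise dispersal
#' is judged from RC: above the positive threshold dispersal limitation,
#' below the negative threshold homogenizing dispersal; anything else is
#' drift. All comparisons are strict, so boundary equality falls to the
#' stochastic side.
#'
#' @param bnri,rc numeric vectors (recycled to a common length).
#' @param config a [null_model_config()] supplying the thresholds.
#' @return character vector of process labels among
#'   `c("HeS", "HoS", "HD", "DL", "DR")`.
#' @export
classify_process <- function(bnri, rc, config = null_model_config()) {
  tb <- config$bnri_threshold; tr <- config$rc_threshold
  ifelse(bnri > tb, "HeS",
    ifelse(bnri < -tb, "HoS",
      ifelse(rc > tr, "DL",
        ifelse(rc < -tr, "HD", "DR"))))
}

#' Aggregate pair-bin scores to per-pair process fractions
#'
#' Each scored bin contributes its weight (mean bin relative abundance in
#' the two samples, renormalized over the pair's scored bins) to its
#' assigned process; pairs with no scored bin are excluded with a warning.
#'
#' @param scores data.frame of pair-bin scores from the null-model engine.
#' @return data.frame with one row per pair: `sample_1`, `sample_2`,
#'   `n_bins`, and the five process-fraction columns summing to 1.
#' @export
aggregate_pair_scores <- function(scores) {
  if (is.null(scores) || nrow(scores) == 0)
    stop("no scored pair-bin combinations to aggregate")
  key <- paste(scores$sample_1, scores$sample_2, sep = "\r")
  rows <- lapply(split(seq_len(nrow(scores)), key), function(ii) {
    w <- scores$weight[ii]
    if (sum(w) <= 0) w <- rep(1, length(ii))
    w <- w / sum(w)
    fr <- vapply(PROCESSES,
                 function(p) sum(w[scores$process[ii] == p]), numeric(1))
    data.frame(sample_1 = scores$sample_1[ii[1]],
               sample_2 = scores$sample_2[ii[1]],
               n_bins = length(ii), t(fr), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Quantify community assembly processes
#'
#' The full phylogenetic-bin null-model analysis: taxa are binned once on
#' the whole table, every within-group sample pair is scored per bin with
#' bNRI and modified Raup-Crick null models, each pair-bin is classified
#' into one of five processes, and bin weights (relative abundance)
#' aggregate these into per-pair and per-group process fractions.
#'
#' @param table samples x taxa count matrix (rarefied recommended).
#' @param tree rooted `phylo` covering the taxa.
#' @param metadata optional data.frame with `sample_id` plus grouping
#'   columns; rows are matched to table samples.
#' @param group_by character vector of metadata column names defining the
#'   groups (e.g. `c("day", "nucleic")`); `NULL` treats all samples as one
#'   group.
#' @param config a [null_model_config()].
#' @return object of class `assembly_partition` with elements `groups`
#'   (per-group mean process fractions), `pairs` (per-pair fractions),
#'   `scores` (every pair-bin score), `bins`, `config`.
#' @export
quantify_assembly <- function(table, tree, metadata = NULL, group_by = NULL,
                              config = null_model_config()) {
  validate_community_table(table)
  sample_ids <- rownames(table)
  if (!is.null(metadata) && !is.null(group_by)) {
    ix <- match(sample_ids, metadata$sample_id)
    if (anyNA(ix)) stop("metadata missing sample(s): ",
                        paste(sample_ids[is.na(ix)], collapse = ", "))
    md <- metadata[ix, , drop = FALSE]
    groups <- interaction(md[group_by], drop = TRUE, sep = ".")
  } else {
    groups <- factor(rep("all", length(sample_ids)))
  }
  tab <- base::table(groups)
  skip <- names(tab)[tab < 2]
  if (length(skip) > 0)
    warning("skipping group(s) with fewer than 2 samples: ",
            paste(skip, collapse = ", "))
  pair_list <- lapply(setdiff(levels(groups), skip), function(g) {
    ids <- sample_ids[groups == g]
    cbind(t(utils::combn(ids, 2)), g)
  })
  pairs <- do.call(rbind, pair_list)
  if (is.null(pairs)) stop("no group with at least 2 samples")
  bins <- bin_taxa(tree, table, config)
  scores <- assembly_pair_scores(table, tree, bins, pairs[, 1:2, drop = FALSE],
                                 config)
  pair_fr <- aggregate_pair_scores(scores)
  pkey <- paste(pairs[, 1], pairs[, 2], sep = "\r")
  fkey <- paste(pair_fr$sample_1, pair_fr$sample_2, sep = "\r")
  dropped <- setdiff(pkey, fkey)
  if (length(dropped) > 0)
    warning(length(dropped), " pair(s) had no scored bin and were excluded")
  pair_fr$group <- pairs[match(fkey, pkey), 3]
  grp_rows <- lapply(split(pair_fr, pair_fr$group), function(df) {
    data.frame(group = df$group[1], n_pairs = nrow(df),
               t(colMeans(df[PROCESSES])), stringsAsFactors = FALSE)
  })
  groups_fr <- do.call(rbind, grp_rows)
  rownames(groups_fr) <- NULL
  structure(list(groups = groups_fr, pairs = pair_fr, scores = scores,
                 bins = bins, config = config),
            class = "assembly_partition")
}

#' @export
print.assembly_partition <- function(x, ...) {
  cat("community assembly partition (", x$bins$n_bins, " bins, ",
      nrow(x$pairs), " sample pairs)\n", sep = "")
  df <- x$groups
  df[PROCESSES] <- round(df[PROCESSES], 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.assembly_partition <- function(object, ...) {
  cat("Phylogenetic-bin null-model assembly partition\n")
  print(object$config)
  print(object$bins)
  cat("pairs scored:", nrow(object$pairs), "; pair-bin scores:",
      nrow(object$scores), "; degenerate nulls:",
      sum(object$scores$degenerate_null), "\n")
  print(object)
  invisible(object)
}

#' Stacked-bar plot of group-level process fractions
#' @param x an `assembly_partition`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.assembly_partition <- function(x, ...) {
  m <- t(as.matrix(x$groups[PROCESSES]))
  colnames(m) <- x$groups$group
  cols <- c(HeS = "#d95f02", HoS = "#1b9e77", HD = "#7570b3",
            DL = "#e7298a", DR = "#666666")
  graphics::barplot(m, col = cols[rownames(m)], border = NA,
                    ylab = "process fraction", las = 2, ...)
  graphics::legend("topright", legend = rownames(m), fill = cols[rownames(m)],
                   bty = "n", cex = 0.8)
  invisible(x)
}
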