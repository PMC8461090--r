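cfg_small <- function(...) null_model_config(n_null = 200, bin_size_min = 2,
                                             seed = 77, ...)

test_that("binning respects the distance cut and the size floor", {
  tr <- two_clade_tree()
  tab <- matrix(1, 2, 12, dimnames = list(c("s1", "s2"), tr$tip.label))
  # cut between the cluster scale (~0.06-0.1) and the stem scale (~2)
  b <- bin_taxa(tr, tab, null_model_config(bin_size_min = 2, ds_cut = 0.3))
  expect_equal(b$n_bins, 2)
  expect_setequal(b$members[[1]], paste0("a", 1:6))
  expect_setequal(b$members[[2]], paste0("b", 1:6))
  expect_true(all(b$diameter <= 0.3))
  # brute-force check: every bin's diameter really is below the cut
  coph <- cophenetic(tr)
  for (m in b$members) expect_lte(max(coph[m, m]), 0.3)
  # cut above the tree diameter -> a single bin
  b1 <- bin_taxa(tr, tab, null_model_config(bin_size_min = 2, ds_cut = 10))
  expect_equal(b1$n_bins, 1)
  expect_equal(lengths(b1$members), 12)
  # tiny cut with unit size floor -> one bin per tip
  b12 <- bin_taxa(tr, tab, null_model_config(bin_size_min = 1, ds_cut = 1e-9))
  expect_equal(b12$n_bins, 12)
  # undersized clades are merged up to the floor
  b4 <- bin_taxa(tr, tab, null_model_config(bin_size_min = 4, ds_cut = 0.05))
  expect_true(all(lengths(b4$members) >= 4))
  expect_error(bin_taxa(tr, tab, null_model_config(bin_size_min = 13)),
               "exceeds")
})

test_that("bins always partition the taxon set", {
  for (s in 1:5) {
    tr <- simulate_tree(40, seed = s)
    tab <- matrix(1, 2, 40, dimnames = list(c("s1", "s2"), tr$tip.label))
    b <- bin_taxa(tr, tab, null_model_config(bin_size_min = 5, ds_cut = 0.08))
    expect_setequal(unlist(b$members), tr$tip.label)
    expect_equal(sum(lengths(b$members)), 40)
    expect_false(anyDuplicated(unlist(b$members)) > 0)
  }
})

test_that("bMPD matches its definition", {
  d <- matrix(c(0, 2, 2, 0), 2, 2)
  expect_equal(beta_mpd(c(1, 0), c(1, 0), d), 0)
  expect_equal(beta_mpd(c(1, 0), c(0, 1), d), 2)
  d3 <- matrix(0, 3, 3)
  d3[1, 3] <- d3[3, 1] <- 2; d3[2, 3] <- d3[3, 2] <- 4; d3[1, 2] <- d3[2, 1] <- 1
  expect_equal(beta_mpd(c(0.5, 0.5, 0), c(0, 0, 1), d3), 3)  # 0.5*2 + 0.5*4
  expect_error(beta_mpd(c(0, 0), c(1, 1), d), "undefined")
  # unweighted variant averages over present taxa
  expect_equal(beta_mpd(c(5, 1, 0), c(0, 0, 9), d3, abundance_weighted = FALSE),
               mean(c(2, 4)))
})

test_that("bMPD agrees with picante::comdist on random communities", {
  tr <- simulate_tree(10, seed = 6)
  coph <- cophenetic(tr)[tr$tip.label, tr$tip.label]
  set.seed(8)
  tab <- matrix(rpois(30, 2), 3, 10,
                dimnames = list(paste0("s", 1:3), tr$tip.label))
  tab[tab == 0 | col(tab) == 1] <- 1  # keep all samples populated
  ref <- as.matrix(picante::comdist(tab, coph, abundance.weighted = TRUE))
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(beta_mpd(tab[i, ], tab[j, ], coph), ref[i, j],
                 tolerance = 1e-9)
})

test_that("bNRI matches exact permutation-null enumeration on a 4-taxon bin", {
  tr <- simulate_tree(4, seed = 12)
  taxa <- tr$tip.label
  tab <- rbind(s1 = c(8, 4, 2, 1), s2 = c(1, 2, 4, 8))
  colnames(tab) <- taxa
  coph <- cophenetic(tr)[taxa, taxa]
  a <- tab[1, ] / sum(tab[1, ]); b <- tab[2, ] / sum(tab[2, ])
  obs <- as.numeric(a %*% coph %*% b)
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  nulls <- apply(perms, 1, function(p)
    as.numeric(a %*% coph[p, p] %*% b))
  exact <- (obs - mean(nulls)) / sd(nulls)
  got <- beta_nri(tab, tr, c("s1", "s2"), taxa,
                  null_model_config(n_null = 4000, seed = 5, bin_size_min = 2))
  # a large sampled null should sit close to the exact enumeration
  expect_lt(abs(as.numeric(got) - exact), 0.25)
  expect_false(attr(got, "degenerate"))
})

test_that("a star-shaped bin yields a degenerate null deferring to RC", {
  star <- ape::read.tree(text = "(x1:1,x2:1,x3:1,x4:1);")
  tab <- rbind(s1 = c(5, 3, 2, 1), s2 = c(1, 1, 6, 4))
  colnames(tab) <- star$tip.label
  got <- beta_nri(tab, star, c("s1", "s2"), star$tip.label, cfg_small())
  expect_equal(as.numeric(got), 0)
  expect_true(attr(got, "degenerate"))
})

test_that("RC hits its floor, ceiling and exact midpoint", {
  cfg <- cfg_small()
  # floor: identical samples over many taxa, membership churn makes every
  # null draw strictly more dissimilar than the observed zero
  taxa <- paste0("t", 1:20)
  base <- c(rep(40, 5), rep(2, 10), rep(0, 5))
  tab1 <- rbind(s1 = base, s2 = base,
                s3 = c(rep(40, 5), rep(0, 10), rep(2, 5)))
  colnames(tab1) <- taxa
  expect_equal(rc_bray(tab1, c("s1", "s2"), taxa, cfg), -1)
  # ceiling: disjoint dominant taxa, nulls overlap through shared occupancy
  tab2 <- rbind(s1 = c(rep(30, 5), rep(1, 5), rep(0, 10)),
                s2 = c(rep(0, 10), rep(30, 5), rep(1, 5)))
  colnames(tab2) <- taxa
  expect_equal(rc_bray(tab2, c("s1", "s2"), taxa, cfg), 1)
  # midpoint: every taxon present once everywhere -> null == observed
  tab3 <- rbind(s1 = rep(1, 20), s2 = rep(1, 20))
  colnames(tab3) <- taxa
  expect_equal(rc_bray(tab3, c("s1", "s2"), taxa, cfg), 0)
})

test_that("classification covers the plane exhaustively with strict bounds", {
  cfg <- null_model_config()
  expect_equal(classify_process(2.5, 0, cfg), "HeS")
  expect_equal(classify_process(-2.5, 0, cfg), "HoS")
  expect_equal(classify_process(0.3, 0.97, cfg), "DL")
  expect_equal(classify_process(0.3, -0.97, cfg), "HD")
  expect_equal(classify_process(0.3, 0, cfg), "DR")
  # boundary equality falls to the stochastic side
  expect_equal(classify_process(1.96, 0.95, cfg), "DR")
  expect_equal(classify_process(-1.96, -0.95, cfg), "DR")
  set.seed(3)
  lab <- classify_process(runif(500, -4, 4), runif(500, -1, 1), cfg)
  expect_true(all(lab %in% c("HeS", "HoS", "HD", "DL", "DR")))
  expect_equal(length(lab), 500)
})

test_that("aggregation renormalizes bin weights into unit fractions", {
  sc <- data.frame(sample_1 = "s1", sample_2 = "s2", bin = 1:2,
                   process = c("HoS", "DR"), weight = c(0.7, 0.3))
  fr <- aggregate_pair_scores(sc)
  expect_equal(fr$HoS, 0.7); expect_equal(fr$DR, 0.3)
  expect_equal(fr$HeS + fr$HD + fr$DL, 0)
  one <- aggregate_pair_scores(data.frame(sample_1 = "a", sample_2 = "b",
                                          bin = 1, process = "DL",
                                          weight = 0.4))
  expect_equal(one$DL, 1)
  # 3-pair group mean matches hand computation
  sc3 <- data.frame(
    sample_1 = c("a", "a", "b"), sample_2 = c("b", "c", "c"),
    bin = 1, process = c("HoS", "DR", "DL"), weight = 1)
  fr3 <- aggregate_pair_scores(sc3)
  expect_equal(colMeans(fr3[c("HoS", "DR", "DL")]),
               c(HoS = 1 / 3, DR = 1 / 3, DL = 1 / 3))
})

test_that("scores are invariant to taxon column order and seed-reproducible", {
  st <- simulate_scenario(scenario_config("DR", n_taxa = 30, n_samples = 4,
                                          depth = 300, seed = 21))
  cfg <- null_model_config(n_null = 100, bin_size_min = 4, seed = 9)
  ap1 <- quantify_assembly(st$table, st$tree, config = cfg)
  perm <- withr::with_seed(1, sample(ncol(st$table)))
  ap2 <- quantify_assembly(st$table[, perm], st$tree, config = cfg)
  ord1 <- ap1$scores[order(ap1$scores$sample_1, ap1$scores$sample_2,
                           ap1$scores$bin), ]
  ord2 <- ap2$scores[order(ap2$scores$sample_1, ap2$scores$sample_2,
                           ap2$scores$bin), ]
  expect_equal(ord1$bnri, ord2$bnri, tolerance = 1e-12)
  expect_equal(ord1$rc, ord2$rc, tolerance = 1e-12)
  ap3 <- quantify_assembly(st$table, st$tree, config = cfg)
  expect_identical(ap1$pairs, ap3$pairs)
})

test_that("doubling n_null moves bNRI by less than its sampling error", {
  st <- simulate_scenario(scenario_config("HoS", n_taxa = 30, n_samples = 3,
                                          depth = 400, seed = 31))
  bins <- bin_taxa(st$tree, st$table,
                   null_model_config(bin_size_min = 30))
  taxa <- bins$members[[1]]
  ids <- rownames(st$table)[1:2]
  b1 <- as.numeric(beta_nri(st$table, st$tree, ids, taxa,
                            null_model_config(n_null = 500, seed = 1,
                                              bin_size_min = 2)))
  b2 <- as.numeric(beta_nri(st$table, st$tree, ids, taxa,
                            null_model_config(n_null = 1000, seed = 2,
                                              bin_size_min = 2)))
  # se of the standardized effect estimate is ~ sqrt(1/n + z^2/(2n))
  se <- sqrt(1 / 500 + b1^2 / 1000) + sqrt(1 / 1000 + b1^2 / 2000)
  expect_lt(abs(b1 - b2), 3 * max(se, 0.1))
})

test_that("identical communities never show heterogeneous selection", {
  tr <- simulate_tree(24, seed = 14)
  row <- withr::with_seed(15, as.integer(rmultinom(1, 600, rep(1, 24))))
  tab <- matrix(row, 6, 24, byrow = TRUE,
                dimnames = list(paste0("s", 1:6), tr$tip.label))
  cfg <- null_model_config(n_null = 200, bin_size_min = 4, seed = 3)
  ap <- quantify_assembly(tab, tr, config = cfg)
  expect_equal(ap$groups$HeS, 0, tolerance = 1e-12)
  expect_gt(ap$groups$HoS + ap$groups$DR + ap$groups$HD, 0.99)
  expect_equal(rowSums(ap$pairs[c("HeS", "HoS", "HD", "DL", "DR")]),
               rep(1, nrow(ap$pairs)), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("group-level fractions are a partition of unity", {
  st <- simulate_scenario(scenario_config("HD", n_taxa = 30, n_samples = 6,
                                          depth = 300, seed = 41))
  md <- st$metadata
  md$day <- rep(c(1L, 30L), each = 3)
  cfg <- null_model_config(n_null = 100, bin_size_min = 4, seed = 8)
  ap <- quantify_assembly(st$table, st$tree, md, "day", cfg)
  expect_equal(rowSums(ap$groups[c("HeS", "HoS", "HD", "DL", "DR")]),
               rep(1, nrow(ap$groups)), tolerance = 1e-9, ignore_attr = TRUE)
  expect_setequal(ap$groups$group, c("1", "30"))
  # pairs stay within their group
  expect_true(all(md$day[match(ap$pairs$sample_1, md$sample_id)] ==
                  md$day[match(ap$pairs$sample_2, md$sample_id)]))
})

test_that("groups with fewer than two samples are skipped with a warning", {
  st <- simulate_scenario(scenario_config("DR", n_taxa = 20, n_samples = 3,
                                          depth = 200, seed = 51))
  md <- st$metadata
  md$day <- c(1L, 1L, 30L)
  cfg <- null_model_config(n_null = 50, bin_size_min = 3, seed = 2)
  expect_warning(ap <- quantify_assembly(st$table, st$tree, md, "day", cfg),
                 "fewer than 2")
  expect_equal(ap$groups$group, "1")
})
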