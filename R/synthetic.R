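# Metacommunity simulator: Yule trees, Brownian niche traits, and five
# canonical assembly regimes (HeS, HoS, HD, DL, DR) with known ground
# truth, plus a study-shaped generator mirroring a membrane-biofilm
# time-series design (biofilm samples colonized from a suspended-biomass
# regional pool).

#' Simulate a pure-birth phylogeny
#'
#' Yule tree with `n_taxa` tips, rescaled to a fixed root-to-tip height.
#' The default height of 0.115 matches the typical root-to-tip depth of 16S
#' rRNA gene trees in substitutions per site, so that the binning
#' distance cut of the null-model framework (`ds_cut = 0.2`) carves the
#' tree at the same relative depth as it does on real amplicon data.
#'
#' @param n_taxa number of tips (>= 2).
#' @param seed integer seed.
#' @param height root-to-tip depth of the returned tree.
#' @return an ultrametric rooted binary `phylo` with tips `t0001, ...`.
#' @export
simulate_tree <- function(n_taxa, seed = 1L, height = 0.115) {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  stopifnot(height > 0)
  tree <- with_seed_(seed, ape::rphylo(n_taxa, birth = 1, death = 0))
  h0 <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * (height / h0)
  tree$tip.label <- sprintf("t%04d", seq_len(n_taxa))
  tree
}

#' Simulate Brownian-motion niche traits on a tree
#'
#' One continuous niche optimum per taxon, evolved by Brownian motion along
#' the branches from a root value of 0, so closely related taxa have
#' correlated niches -- the phylogenetic signal the bin-based null-model
#' framework assumes.
#'
#' @param tree a `phylo` with branch lengths.
#' @param trait_sigma Brownian rate (per unit branch length); variance of a
#'   tip trait equals `trait_sigma^2` times its root-to-tip path length.
#' @param seed integer seed.
#' @return named numeric vector of tip traits.
#' @export
simulate_traits <- function(tree, trait_sigma = 1, seed = 1L) {
  if (trait_sigma <= 0) stop("trait_sigma must be > 0")
  with_seed_(seed,
    ape::rTraitCont(tree, model = "BM", sigma = trait_sigma, root.value = 0))
}

SCENARIOS <- c("HoS", "HeS", "HD", "DL", "DR")

# Clade-conserved niche optima: the Brownian trait of each tip's lineage
# as it stood `niche_depth` x height before the present.  Niches are
# therefore identical within recently diverged clades and diverge between
# older ones -- the strong within-clade conservatism that phylogenetic-bin
# null models presuppose.  niche_depth = 0 returns the tip traits
# themselves (pure Brownian endpoints).
clade_niche <- function(tree, trait_sigma, niche_depth, seed) {
  vals <- with_seed_(seed,
    ape::rTraitCont(tree, model = "BM", sigma = trait_sigma,
                    root.value = 0, ancestor = TRUE))
  nt <- length(tree$tip.label)
  if (niche_depth <= 0) return(vals[seq_len(nt)])
  H <- max(ape::node.depth.edgelength(tree))
  age <- H - ape::node.depth.edgelength(tree)  # time before present
  cut <- niche_depth * H
  parent <- integer(nt + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- nt + 1L
  niche <- numeric(nt)
  for (tip in seq_len(nt)) {
    node <- tip
    while (node != root && age[node] < cut) node <- parent[node]
    niche[tip] <- vals[node]
  }
  names(niche) <- tree$tip.label
  niche
}

# Per-scenario defaults for the dials that define each regime.  Migration
# is the per-generation immigration fraction from the regional pool.
scenario_defaults <- function(scenario) {
  switch(scenario,
    HoS = list(selection_strength = 200, migration_rate = 0),
    HeS = list(selection_strength = 60, migration_rate = 0),
    HD  = list(selection_strength = 0, migration_rate = 1),
    DL  = list(selection_strength = 0, migration_rate = 0.02),
    DR  = list(selection_strength = 0, migration_rate = 0.25),
    stop("unknown scenario: ", scenario))
}

#' Configuration of a simulated assembly scenario
#'
#' @param scenario one of `"HoS"`, `"HeS"`, `"HD"`, `"DL"`, `"DR"`.
#' @param n_taxa,n_samples,depth community dimensions and reads per sample.
#' @param selection_strength inverse squared niche-breadth of the Gaussian
#'   fitness filter `exp(-s (trait - optimum)^2)`; 0 disables selection.
#'   Default depends on the scenario.
#' @param migration_rate per-generation immigration fraction from the
#'   regional pool, in `[0, 1]`. Default depends on the scenario.
#' @param trait_sigma Brownian rate of niche evolution (default 1).
#' @param n_env number of distinct environments for HeS (>= 2).
#' @param pool_sigma log-normal sigma of regional pool abundances.
#' @param community_size individuals in each drifting local community
#'   (default equal to `depth`).
#' @param n_generations drift generations (default 50).
#' @param niche_depth fraction of the tree height over which niches are
#'   conserved: selection acts on the Brownian trait of each lineage as it
#'   stood `niche_depth * height` before the present, so recently diverged
#'   clades share a niche (default 0.2; 0 uses the raw tip traits).
#' @param seed integer master seed.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(scenario, n_taxa = 200, n_samples = 10,
                            depth = 1000, selection_strength = NULL,
                            migration_rate = NULL, trait_sigma = 1,
                            n_env = 2, pool_sigma = 1,
                            community_size = depth, n_generations = 50,
                            niche_depth = 0.2, seed = 1L) {
  scenario <- match.arg(scenario, SCENARIOS)
  defs <- scenario_defaults(scenario)
  selection_strength <- selection_strength %||% defs$selection_strength
  migration_rate <- migration_rate %||% defs$migration_rate
  stopifnot(n_taxa >= 2, n_samples >= 2, depth >= 1,
            selection_strength >= 0,
            migration_rate >= 0, migration_rate <= 1,
            trait_sigma > 0, community_size >= 2, n_generations >= 1,
            niche_depth >= 0, niche_depth <= 1)
  if (scenario == "HeS" && n_env < 2)
    stop("HeS requires at least 2 environments")
  structure(list(scenario = scenario, n_taxa = as.integer(n_taxa),
                 n_samples = as.integer(n_samples), depth = as.integer(depth),
                 selection_strength = selection_strength,
                 migration_rate = migration_rate, trait_sigma = trait_sigma,
                 n_env = as.integer(n_env), pool_sigma = pool_sigma,
                 community_size = as.integer(community_size),
                 n_generations = as.integer(n_generations),
                 niche_depth = niche_depth,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# One local community: initial colonization from the pool, `gens`
# generations of Wright-Fisher style multinomial resampling of `J`
# individuals with immigration fraction `m` from the pool, then a final
# multinomial read draw of `depth` from the community's sampling
# distribution.  With m = 1 the sampling distribution is exactly the pool.
drift_community <- function(pool, J, gens, m, depth) {
  local <- as.integer(rmultinom(1, J, pool))
  for (g in seq_len(gens)) {
    pr <- (1 - m) * local / J + m * pool
    local <- as.integer(rmultinom(1, J, pr))
  }
  as.integer(rmultinom(1, depth, (1 - m) * local / J + m * pool))
}

gaussian_filter <- function(pool, traits, strength, optimum) {
  p <- pool * exp(-strength * (traits - optimum)^2)
  p / sum(p)
}

#' Simulate one assembly scenario
#'
#' Builds a regional pool (log-normal rank abundances), a Yule phylogeny
#' with Brownian niche traits, and `n_samples` communities assembled under
#' the configured regime:
#' * **HoS** -- one shared environmental optimum; per-sample reads are
#'   multinomial draws from the pool filtered by a Gaussian fitness kernel.
#' * **HeS** -- `n_env` divergent optima placed across +/- 2 SD of the tip
#'   traits, assigned round-robin to samples.
#' * **HD** -- drifting local communities re-homogenized by full migration
#'   each generation, so every sample draws from the pool distribution.
#' * **DL** -- independent local communities drifting without immigration.
#' * **DR** -- local communities drifting under weak immigration, diverging
#'   noticeably but less than under dispersal limitation.
#'
#' @param config a [scenario_config()].
#' @return object of class `synthetic_study`: list with `table` (samples x
#'   taxa counts, rows summing to `depth`), `tree`, `metadata`, `truth`
#'   (per-sample ground-truth process), `traits`, `pool`, `config`.
#' @export
simulate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  sc <- config$scenario
  truth_label <- sc
  if (sc %in% c("HoS", "HeS") && config$selection_strength == 0) {
    warning("selection_strength = 0 degenerates to the neutral pool; ",
            "ground truth recorded as DR")
    truth_label <- "DR"
  }
  tree <- simulate_tree(config$n_taxa, derive_seed(config$seed, "tree"))
  traits <- clade_niche(tree, config$trait_sigma, config$niche_depth,
                        derive_seed(config$seed, "traits"))
  pool <- with_seed_(derive_seed(config$seed, "pool"), {
    p <- rlnorm(config$n_taxa, 0, config$pool_sigma); p / sum(p)
  })
  names(pool) <- tree$tip.label
  n <- config$n_samples
  env <- rep_len(seq_len(config$n_env), n)
  counts <- with_seed_(derive_seed(config$seed, "communities"), {
    if (sc %in% c("HoS", "HeS") && config$selection_strength > 0) {
      optima <- if (sc == "HoS") mean(traits) else
        seq(mean(traits) - sd(traits), mean(traits) + sd(traits),
            length.out = config$n_env)
      probs <- lapply(optima, function(o)
        gaussian_filter(pool, traits, config$selection_strength, o))
      t(vapply(seq_len(n), function(s)
        as.integer(rmultinom(1, config$depth,
                             probs[[if (sc == "HoS") 1 else env[s]]])),
        integer(config$n_taxa)))
    } else {
      m <- if (sc %in% c("HoS", "HeS")) 1 else config$migration_rate
      t(vapply(seq_len(n), function(s)
        drift_community(pool, config$community_size, config$n_generations,
                        m, config$depth), integer(config$n_taxa)))
    }
  })
  sample_ids <- sprintf("S%02d", seq_len(n))
  dimnames(counts) <- list(sample_ids, tree$tip.label)
  metadata <- data.frame(
    sample_id = sample_ids, membrane_type = "COM",
    surface_character = "n/a", flux = "n/a", day = 1L,
    compartment = "biofilm", nucleic = "DNA",
    env = if (sc == "HeS") env else 1L,
    stringsAsFactors = FALSE)
  truth <- data.frame(sample_id = sample_ids, process = truth_label,
                      stringsAsFactors = FALSE)
  structure(list(table = counts, tree = tree, metadata = metadata,
                 truth = truth, traits = traits, pool = pool,
                 config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("synthetic study:", nrow(x$table), "samples x", ncol(x$table),
      "taxa; truth:", paste(unique(x$truth$process), collapse = ", "), "\n")
  invisible(x)
}

STUDY_MEMBRANES <- c(POX = "hydrophobic", PTA = "hydrophobic",
                     SPTA = "hydrophilic", SPSU = "hydrophilic",
                     COM = "hydrophobic")

#' Generate a study-shaped synthetic data set
#'
#' Emulates the sampling design of a membrane-biofilm bioreactor
#' time-series: for each nucleic-acid dataset (DNA and cDNA), biofilm
#' samples from 5 membrane types x flux/no-flux at days 1, 10, 20 and 30,
#' plus one suspended-biomass (MLSS) sample per day -- 44 samples per
#' dataset. The MLSS community acts as the regional pool. The assembly
#' regime shifts with biofilm age: days 1 and 10 are generated under strong
#' homogeneous selection from the pool; day 20 under weakened selection
#' with ecological drift; day 30 under drift with near-zero immigration
#' (dispersal limitation). Membrane type, surface chemistry and flux do not
#' enter the sampling probabilities (the design's null factors).
#'
#' @param seed integer master seed.
#' @param n_taxa number of taxa (default 480).
#' @param depth reads per sample (default 4386).
#' @param selection_strength Gaussian-filter strength for the early-biofilm
#'   selection regime.
#' @param community_size,n_generations drift parameters for the aged
#'   biofilm (days 20 and 30).
#' @param trait_sigma,pool_sigma,niche_depth as in [scenario_config()].
#' @return object of class `synthetic_study` whose `truth` maps each
#'   day group to its generating regime.
#' @export
generate_study_like <- function(seed = 1L, n_taxa = 480, depth = 4386,
                                selection_strength = 200,
                                community_size = depth, n_generations = 50,
                                trait_sigma = 1, pool_sigma = 1,
                                niche_depth = 0.2) {
  tree <- simulate_tree(n_taxa, derive_seed(seed, "tree"))
  traits <- clade_niche(tree, trait_sigma, niche_depth,
                        derive_seed(seed, "traits"))
  pool <- with_seed_(derive_seed(seed, "pool"), {
    p <- rlnorm(n_taxa, 0, pool_sigma); p / sum(p)
  })
  names(pool) <- tree$tip.label
  opt <- mean(traits)
  p_early <- gaussian_filter(pool, traits, selection_strength, opt)
  p_mid <- gaussian_filter(pool, traits, selection_strength / 2, opt)
  days <- c(1L, 10L, 20L, 30L)
  rows <- list(); meta <- list()
  for (nuc in c("DNA", "cDNA")) {
    cseed <- derive_seed(seed, paste0("communities-", nuc))
    with_seed_(cseed, {
      for (day in days) {
        # regional pool sample
        id <- sprintf("MLSS_D%d_%s", day, nuc)
        rows[[id]] <- as.integer(rmultinom(1, depth, pool))
        meta[[id]] <- data.frame(
          sample_id = id, membrane_type = "MLSS", surface_character = "n/a",
          flux = "n/a", day = day, compartment = "MLSS", nucleic = nuc,
          stringsAsFactors = FALSE)
        for (mb in names(STUDY_MEMBRANES)) for (fx in c("flux", "no-flux")) {
          id <- sprintf("%s_%s_D%d_%s", mb,
                        if (fx == "flux") "F" else "NF", day, nuc)
          rows[[id]] <- if (day %in% c(1L, 10L)) {
            as.integer(rmultinom(1, depth, p_early))
          } else if (day == 20L) {
            # weakened selection with drift setting in: local lottery
            # anchored to the mid-strength selected profile
            drift_community(p_mid, community_size, n_generations %/% 2,
                            0.25, depth)
          } else {
            # aged biofilm: colonization lottery and drift from the pool;
            # half the modules are dispersal-limited (canonical DL
            # migration), half drift under moderate immigration (canonical
            # DR migration)
            m30 <- if (fx == "flux") 0.02 else 0.25
            drift_community(pool, community_size %/% 2, n_generations,
                            m30, depth)
          }
          meta[[id]] <- data.frame(
            sample_id = id, membrane_type = mb,
            surface_character = unname(STUDY_MEMBRANES[mb]), flux = fx,
            day = day, compartment = "biofilm", nucleic = nuc,
            stringsAsFactors = FALSE)
        }
      }
    })
  }
  counts <- do.call(rbind, rows)
  dimnames(counts) <- list(names(rows), tree$tip.label)
  metadata <- do.call(rbind, c(meta, list(make.row.names = FALSE)))
  truth <- data.frame(
    day = days,
    process = c("HoS", "HoS", "HoS+DR", "DR+DL"),
    stringsAsFactors = FALSE)
  structure(list(table = counts, tree = tree,
                 metadata = validate_sample_metadata(metadata),
                 truth = truth, traits = traits, pool = pool,
                 config = list(seed = as.integer(seed), n_taxa = n_taxa,
                               depth = depth,
                               selection_strength = selection_strength,
                               community_size = community_size,
                               n_generations = n_generations)),
            class = "synthetic_study")
}

#' Write a synthetic study to disk
#'
#' Emits `<prefix>table.tsv` (taxa x samples), `<prefix>tree.nwk`,
#' `<prefix>metadata.tsv` and `<prefix>truth.tsv`.
#'
#' @param study a `synthetic_study`.
#' @param prefix path prefix for the four output files.
#' @return invisibly, the vector of file paths.
#' @export
write_study <- function(study, prefix) {
  paths <- paste0(prefix, c("table.tsv", "tree.nwk", "metadata.tsv",
                            "truth.tsv"))
  write_count_table(study$table, paths[1])
  write_tree(study$tree, paths[2])
  write.table(study$metadata, paths[3], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(study$truth, paths[4], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
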