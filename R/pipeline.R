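# Orchestration of the full study-shaped run: ingest or simulate, rarefy,
# alpha/beta diversity, ordination, PERMANOVA per design factor, assembly
# partitioning, and a plain-text manifest. All stage seeds derive from one
# master seed so stages are individually reproducible.

#' Pipeline run configuration
#'
#' Exactly one of `table`/`tree`/`metadata` paths or a `scenario` /
#' `study_seed` simulation source must be given.
#'
#' @param table_path,tree_path,metadata_path input files (TSV counts with
#'   taxa as rows, newick, TSV metadata), or `NULL` to simulate.
#' @param scenario optional [scenario_config()] to simulate from.
#' @param study_seed optional seed for [generate_study_like()].
#' @param depth rarefaction depth (default 4386).
#' @param seed master seed.
#' @param group_by metadata factors defining assembly groups.
#' @param permanova_factors metadata factors each tested by one-way
#'   PERMANOVA on Bray-Curtis.
#' @param n_perm PERMANOVA permutations (default 999).
#' @param assembly_config a [null_model_config()].
#' @param top_n taxa kept in the exported abundance summary (default 25).
#' @param out_dir output directory.
#' @return object of class `run_config`.
#' @export
run_config <- function(table_path = NULL, tree_path = NULL,
                       metadata_path = NULL, scenario = NULL,
                       study_seed = NULL, depth = 4386, seed = 1L,
                       group_by = c("day", "nucleic"),
                       permanova_factors = c("day", "membrane_type",
                                             "surface_character", "flux"),
                       n_perm = 999,
                       assembly_config = null_model_config(),
                       top_n = 25, out_dir = tempfile("campart_run_")) {
  have_paths <- !is.null(table_path)
  have_sim <- !is.null(scenario) || !is.null(study_seed)
  if (have_paths == have_sim)
    stop("give either input paths or a simulation source, not both")
  if (have_paths && (is.null(tree_path) || is.null(metadata_path)))
    stop("table_path, tree_path and metadata_path are all required")
  stopifnot(depth >= 1)
  structure(list(table_path = table_path, tree_path = tree_path,
                 metadata_path = metadata_path, scenario = scenario,
                 study_seed = study_seed, depth = as.integer(depth),
                 seed = as.integer(seed), group_by = group_by,
                 permanova_factors = permanova_factors,
                 n_perm = as.integer(n_perm),
                 assembly_config = assembly_config,
                 top_n = as.integer(top_n), out_dir = out_dir),
            class = "run_config")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_square <- function(d, path) {
  m <- as.matrix(d)
  write_tsv(data.frame(sample_id = rownames(m), m, check.names = FALSE),
            path)
}

#' Run the full pipeline
#'
#' Stage order: load/simulate -> rarefy -> alpha diversity -> Bray-Curtis
#' and unweighted UniFrac -> PCoA and NMDS -> one-way PERMANOVA per tested
#' factor -> assembly partitioning -> top-taxa export. DNA and cDNA samples
#' are processed as separate datasets for the distance, ordination and
#' assembly stages. Rerunning with an identical configuration reproduces
#' every numeric output bit-identically.
#'
#' @param config a [run_config()].
#' @return object of class `run_manifest`: list with the config echo, the
#'   per-stage output files, dropped samples, and wall times.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  times <- numeric(0)
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(code, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    times[[name]] <<- proc.time()[["elapsed"]] - t0
    res
  }
  out <- function(name) file.path(config$out_dir, name)

  study <- stage("input", {
    if (!is.null(config$table_path)) {
      tab <- read_count_table(config$table_path)
      md <- read_sample_metadata(config$metadata_path)
      list(table = tab, tree = read_tree(config$tree_path, colnames(tab)),
           metadata = md)
    } else if (!is.null(config$scenario)) {
      simulate_scenario(config$scenario)
    } else {
      generate_study_like(config$study_seed, depth = config$depth)
    }
  })

  rare <- stage("rarefy", rarefy_counts(study$table, config$depth,
                                        derive_seed(config$seed, "rarefy")))
  dropped <- attr(rare, "dropped")
  md <- study$metadata[study$metadata$sample_id %in% rownames(rare), ,
                       drop = FALSE]
  files["rarefied_table"] <- stage("write_rarefied",
    write_count_table(rare, out("rarefied_table.tsv")))

  files["alpha"] <- stage("alpha",
    write_tsv(alpha_diversity(rare), out("alpha.tsv")))

  nucs <- intersect(c("DNA", "cDNA"), unique(md$nucleic))
  perm_rows <- list()
  for (nuc in nucs) {
    ids <- md$sample_id[md$nucleic == nuc]
    sub <- rare[ids, , drop = FALSE]
    sub_md <- md[match(ids, md$sample_id), , drop = FALSE]
    tag <- if (length(nucs) > 1) paste0("_", nuc) else ""

    bc <- stage(paste0("bray_curtis", tag), bray_curtis(sub))
    files[paste0("bray_curtis", tag)] <-
      write_square(bc, out(paste0("bray_curtis", tag, ".tsv")))
    uf <- stage(paste0("unifrac", tag), unweighted_unifrac(sub, study$tree))
    files[paste0("unifrac", tag)] <-
      write_square(uf, out(paste0("unifrac", tag, ".tsv")))

    pc <- stage(paste0("pcoa", tag), pcoa_ordination(uf, k = 2))
    files[paste0("pcoa", tag)] <- write_tsv(
      data.frame(sample_id = rownames(pc$points), pc$points,
                 check.names = FALSE),
      out(paste0("pcoa", tag, ".tsv")))
    nm <- stage(paste0("nmds", tag),
      nmds_ordination(bc, k = 2, seed = derive_seed(config$seed, "nmds")))
    files[paste0("nmds", tag)] <- write_tsv(
      data.frame(sample_id = rownames(nm$points), nm$points,
                 stress = nm$stress, check.names = FALSE),
      out(paste0("nmds", tag, ".tsv")))

    for (fac in config$permanova_factors) {
      keep <- if (fac == "day") rep(TRUE, nrow(sub_md)) else
        sub_md$compartment == "biofilm"
      g <- sub_md[[fac]][keep]
      if (length(unique(g)) < 2) next
      pr <- stage(paste0("permanova_", fac, tag), {
        dsub <- stats::as.dist(as.matrix(bc)[keep, keep])
        permanova(dsub, g, n_perm = config$n_perm,
                  seed = derive_seed(config$seed, paste0("perm-", fac)))
      })
      perm_rows[[paste0(fac, tag)]] <- data.frame(
        nucleic = nuc, factor = fac, f = pr$f, r2 = pr$r2, p = pr$p,
        n_perm = pr$n_perm, stringsAsFactors = FALSE)
    }
  }
  perm_df <- if (length(perm_rows) > 0) do.call(rbind, perm_rows) else
    data.frame(nucleic = character(0), factor = character(0),
               f = numeric(0), r2 = numeric(0), p = numeric(0),
               n_perm = integer(0))
  files["permanova"] <- write_tsv(perm_df, out("permanova.tsv"))

  asm <- stage("assembly", {
    cfg <- config$assembly_config
    cfg$seed <- derive_seed(config$seed, "assembly")
    biofilm <- md$sample_id[md$compartment == "biofilm"]
    quantify_assembly(rare[biofilm, , drop = FALSE], study$tree,
                      md, config$group_by, cfg)
  })
  files["assembly_groups"] <- write_tsv(asm$groups,
                                        out("assembly_groups.tsv"))
  files["assembly_pairs"] <- write_tsv(asm$pairs, out("assembly_pairs.tsv"))
  files["pair_bin_scores"] <- write_tsv(asm$scores,
                                        out("pair_bin_scores.tsv"))
  files["bins"] <- write_tsv(
    data.frame(taxon_id = names(asm$bins$assignment),
               bin = unname(asm$bins$assignment)),
    out("bins.tsv"))

  files["top_taxa"] <- stage("top_taxa", write_tsv(
    export_top_taxa(rare, md, n = config$top_n,
                    group_by = config$group_by),
    out("top_taxa.tsv")))

  manifest <- structure(list(
    config = config, files = files, dropped_samples = dropped,
    assembly = asm, stage_seconds = times,
    version = as.character(utils::packageVersion("campart"))),
    class = "run_manifest")
  mf <- out("manifest.txt")
  writeLines(c(
    paste("campart", manifest$version),
    paste("seed:", config$seed),
    paste("depth:", config$depth),
    paste("dropped_samples:", paste(dropped, collapse = ",")),
    paste("outputs:"), paste(" ", files),
    paste("stage_seconds:"),
    sprintf("  %s: %.2f", names(times), times)), mf)
  manifest$files["manifest"] <- mf
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("campart run:", length(x$files), "output files in",
      x$config$out_dir, "\n")
  if (length(x$dropped_samples))
    cat("dropped at rarefaction:",
        paste(x$dropped_samples, collapse = ", "), "\n")
  invisible(x)
}

#' Mean relative abundance of the top taxa per group
#'
#' The tabular equivalent of a top-N abundance heatmap: the `n` taxa with
#' the highest overall mean relative abundance, with their mean relative
#' abundance in each metadata group.
#'
#' @param table samples x taxa count matrix.
#' @param metadata data.frame with `sample_id` and the grouping columns.
#' @param n number of taxa to keep (default 25; truncated with a warning if
#'   it exceeds the number of taxa).
#' @param group_by metadata columns defining the groups.
#' @return data.frame: `taxon_id`, `overall_mean`, one column per group.
#' @export
export_top_taxa <- function(table, metadata, n = 25,
                            group_by = c("day", "nucleic")) {
  stopifnot(n >= 1)
  P <- relative_abundance(table)
  if (n > ncol(P)) {
    warning("n exceeds the number of taxa; using ", ncol(P))
    n <- ncol(P)
  }
  overall <- colMeans(P)
  top <- names(sort(overall, decreasing = TRUE))[seq_len(n)]
  ix <- match(rownames(P), metadata$sample_id)
  if (anyNA(ix)) stop("metadata missing sample(s)")
  groups <- interaction(metadata[ix, group_by, drop = FALSE], drop = TRUE,
                        sep = ".")
  gm <- vapply(levels(groups), function(g)
    colMeans(P[groups == g, top, drop = FALSE]), numeric(length(top)))
  if (length(top) == 1)
    gm <- matrix(gm, nrow = 1, dimnames = list(NULL, levels(groups)))
  data.frame(taxon_id = top, overall_mean = overall[top], gm,
             check.names = FALSE, row.names = NULL)
}
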