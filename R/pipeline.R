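# Pipeline orchestration: curate -> fragment -> profile -> diversity ->
# overlap -> map over one or more datasets, with a run manifest whose
# counts reconcile exactly with the stage outputs.

#' Pipeline configuration
#'
#' @param datasets List of dataset entries, each a list with `name`,
#'   `path`, and optionally `format` (smi/csv/sdf) and `smiles_col`/`id_col`
#'   for CSV input.
#' @param curation A [curation_config()].
#' @param min_fragment_heavy_atoms Heavy-atom floor for terminal fragments.
#' @param diversity_kinds Fingerprint kinds to evaluate
#'   (subset of `"circular_r2_1024"`, `"keys_166"`).
#' @param n_samples,sample_size Diversity sampling parameters.
#' @param chemspace List with `d`, `n_trees`, `k`, `kc`.
#' @param seed Master seed (expanded deterministically per stage).
#' @param output_dir Where stage outputs are written.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(datasets, curation = curation_config(),
                            min_fragment_heavy_atoms = 0L,
                            diversity_kinds = c("circular_r2_1024", "keys_166"),
                            n_samples = 10L, sample_size = 10000L,
                            chemspace = list(d = 128L, n_trees = 8L,
                                             k = 50L, kc = 10L),
                            seed = 1L, output_dir = tempfile("fraglib_run")) {
  nm <- vapply(datasets, `[[`, character(1L), "name")
  if (anyDuplicated(nm)) stop("dataset names must be unique")
  structure(list(datasets = datasets, curation = curation,
                 min_fragment_heavy_atoms = as.integer(min_fragment_heavy_atoms),
                 diversity_kinds = diversity_kinds,
                 n_samples = as.integer(n_samples),
                 sample_size = as.integer(sample_size),
                 chemspace = chemspace,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

.PIPELINE_STAGES <- c("curate", "fragment", "profile", "diversity",
                      "overlap", "map")
.STAGE_DEPS <- list(curate = character(), fragment = "curate",
                    profile = "fragment", diversity = "fragment",
                    overlap = "fragment", map = "curate")

#' Run the pipeline
#'
#' Executes the requested stages in dependency order for every configured
#' dataset, writing stable filenames under `cfg$output_dir`
#' (`<name>_curated.csv`, `<name>_rejections.csv`, `<name>_fragments.csv`,
#' `diversity.json`, `overlap.json`, `chemspace_edges.csv`,
#' `chemspace_layout.csv`, `summary_*.csv`, `manifest.json`). Requesting a
#' stage whose upstream stage was neither requested nor previously written
#' raises a dependency error naming the stage.
#'
#' @param cfg A [pipeline_config()].
#' @param stages Subset of `curate`, `fragment`, `profile`, `diversity`,
#'   `overlap`, `map` (default: all).
#' @return A `run_manifest` (list) with per-dataset counts, config echo
#'   and per-stage durations.
#' @export
run_pipeline <- function(cfg, stages = .PIPELINE_STAGES) {
  stages <- match.arg(stages, .PIPELINE_STAGES, several.ok = TRUE)
  stages <- .PIPELINE_STAGES[.PIPELINE_STAGES %in% stages]
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  state <- new.env(parent = emptyenv())
  manifest <- list(package_version = as.character(utils::packageVersion("fraglib")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   seed = cfg$seed, datasets = list(), durations = list())

  for (st in stages) {
    dep <- .STAGE_DEPS[[st]]
    if (length(dep) && !(dep %in% stages) && !.stage_cached(cfg, dep)) {
      stop(sprintf("dependency error: stage '%s' requires output of stage '%s'",
                   st, dep))
    }
  }

  for (st in stages) {
    t0 <- Sys.time()
    manifest <- switch(st,
      curate = .stage_curate(cfg, state, manifest),
      fragment = .stage_fragment(cfg, state, manifest),
      profile = .stage_profile(cfg, state, manifest),
      diversity = .stage_diversity(cfg, state, manifest),
      overlap = .stage_overlap(cfg, state, manifest),
      map = .stage_map(cfg, state, manifest)
    )
    manifest$durations[[st]] <- round(as.numeric(Sys.time() - t0, units = "secs"), 3)
  }
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  class(manifest) <- "run_manifest"
  path <- file.path(cfg$output_dir, "manifest.json")
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  manifest
}

.stage_cached <- function(cfg, stage) {
  nm <- vapply(cfg$datasets, `[[`, character(1L), "name")
  suffix <- switch(stage, curate = "_curated.csv", fragment = "_fragments.csv",
                   return(FALSE))
  all(file.exists(file.path(cfg$output_dir, paste0(nm, suffix))))
}

.get_curated <- function(cfg, state, name) {
  key <- paste0("curated_", name)
  if (!exists(key, envir = state)) {
    # reload from the cached stage output
    path <- file.path(cfg$output_dir, paste0(name, "_curated.csv"))
    if (!file.exists(path)) {
      stop(sprintf("dependency error: no curated output for dataset '%s'", name))
    }
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    mols <- lapply(df$Smiles, parse_smiles)
    res <- structure(list(
      kept = new_molecule_table(df$ID, mols, rep(name, nrow(df))),
      smiles = df$Smiles,
      rejections = data.frame(id = character(), step = character(),
                              reason = character(), stringsAsFactors = FALSE),
      duplicate_map = character(), n_input = nrow(df)
    ), class = "curation_result")
    assign(key, res, envir = state)
  }
  get(key, envir = state)
}

.stage_curate <- function(cfg, state, manifest) {
  for (ds in cfg$datasets) {
    rd <- read_molecule_table(ds$path,
                              format = if (is.null(ds$format)) "auto" else ds$format,
                              dataset = ds$name,
                              smiles_col = if (is.null(ds$smiles_col)) "Smiles" else ds$smiles_col,
                              id_col = if (is.null(ds$id_col)) "ID" else ds$id_col)
    cu <- curate_dataset(rd$table, cfg$curation)
    assign(paste0("curated_", ds$name), cu, envir = state)
    write_curated_csv(cu, file.path(cfg$output_dir, paste0(ds$name, "_curated.csv")))
    utils::write.csv(cu$rejections,
                     file.path(cfg$output_dir, paste0(ds$name, "_rejections.csv")),
                     row.names = FALSE)
    manifest$datasets[[ds$name]] <- list(
      original = rd$report$n_input,
      parsed = rd$report$n_parsed,
      parse_failures = nrow(rd$report$failures),
      processed = length(cu$kept$ids),
      rejected = nrow(cu$rejections),
      duplicates = length(cu$duplicate_map)
    )
    message(sprintf("[curate] %s: %d original, %d parsed, %d processed, %d rejected, %d duplicates",
                    ds$name, rd$report$n_input, rd$report$n_parsed,
                    length(cu$kept$ids), nrow(cu$rejections),
                    length(cu$duplicate_map)))
  }
  manifest
}

.stage_fragment <- function(cfg, state, manifest) {
  for (ds in cfg$datasets) {
    cu <- .get_curated(cfg, state, ds$name)
    frags <- lapply(cu$kept$molecules, function(m) {
      terminal_fragments(m, min_fragment_heavy_atoms = cfg$min_fragment_heavy_atoms)$leaf_smiles
    })
    names(frags) <- cu$kept$ids
    lib <- build_library(cu, frags, dataset_name = ds$name)
    assign(paste0("library_", ds$name), lib, envir = state)
    assign(paste0("frags_", ds$name), frags, envir = state)
    write_library(lib, file.path(cfg$output_dir, paste0(ds$name, "_fragments.csv")))
    write_curated_csv(cu, file.path(cfg$output_dir, paste0(ds$name, "_curated.csv")),
                      fragments = frags)
    manifest$datasets[[ds$name]]$fragments <- nrow(lib$records)
    message(sprintf("[fragment] %s: %d unique terminal fragments from %d compounds",
                    ds$name, nrow(lib$records), lib$n_source_compounds))
  }
  manifest
}

.get_library <- function(cfg, state, name) {
  key <- paste0("library_", name)
  if (!exists(key, envir = state)) {
    path <- file.path(cfg$output_dir, paste0(name, "_fragments.csv"))
    if (!file.exists(path)) {
      stop(sprintf("dependency error: no fragment library for dataset '%s'", name))
    }
    assign(key, read_library(path), envir = state)
  }
  get(key, envir = state)
}

.stage_profile <- function(cfg, state, manifest) {
  sm <- summarize_tables(cfg, state)
  utils::write.csv(sm$counts, file.path(cfg$output_dir, "summary_counts.csv"),
                   row.names = FALSE)
  utils::write.csv(sm$compound_means,
                   file.path(cfg$output_dir, "summary_compound_descriptors.csv"),
                   row.names = FALSE)
  utils::write.csv(sm$fragment_means,
                   file.path(cfg$output_dir, "summary_fragment_descriptors.csv"),
                   row.names = FALSE)
  manifest$summaries <- c("summary_counts.csv", "summary_compound_descriptors.csv",
                          "summary_fragment_descriptors.csv")
  manifest
}

.dataset_fingerprints <- function(mols, kind) {
  if (kind == "keys_166") keys_fingerprint(mols)
  else lapply(mols, circular_fingerprint)
}

.stage_diversity <- function(cfg, state, manifest) {
  results <- list()
  rows <- list()
  for (ds in cfg$datasets) {
    cu <- .get_curated(cfg, state, ds$name)
    lib <- .get_library(cfg, state, ds$name)
    frag_mols <- lapply(lib$records$fragment_smiles, parse_smiles)
    for (kind in cfg$diversity_kinds) {
      for (what in c("compounds", "fragments")) {
        mols <- if (what == "compounds") cu$kept$molecules else frag_mols
        if (length(mols) < 2L) next
        fps <- .dataset_fingerprints(mols, kind)
        cfg_div <- diversity_config(n_samples = cfg$n_samples,
                                    sample_size = cfg$sample_size,
                                    seed = cfg$seed, kind = kind)
        dr <- sampled_median(fps, cfg_div)
        key <- paste(ds$name, what, kind, sep = ".")
        results[[key]] <- dr
        rows[[key]] <- data.frame(dataset = ds$name, set = what, kind = kind,
                                  median_similarity = dr$averaged_median,
                                  n = dr$n_used, sampled = dr$sampled)
      }
    }
  }
  write_diversity_json(results, file.path(cfg$output_dir, "diversity.json"))
  df <- do.call(rbind, rows); rownames(df) <- NULL
  utils::write.csv(df, file.path(cfg$output_dir, "summary_diversity.csv"),
                   row.names = FALSE)
  assign("diversity", results, envir = state)
  manifest$diversity <- df$median_similarity
  manifest
}

.stage_overlap <- function(cfg, state, manifest) {
  if (length(cfg$datasets) < 2L) {
    message("[overlap] skipped: needs >= 2 datasets")
    return(manifest)
  }
  nm <- vapply(cfg$datasets, `[[`, character(1L), "name")
  comp_sets <- lapply(nm, function(n) .get_curated(cfg, state, n)$smiles)
  names(comp_sets) <- nm
  frag_sets <- lapply(nm, function(n) .get_library(cfg, state, n)$records$fragment_smiles)
  names(frag_sets) <- nm
  rep_c <- overlap_report(comp_sets)
  rep_f <- overlap_report(frag_sets)
  jsonlite::write_json(
    list(compounds = .overlap_payload(rep_c), fragments = .overlap_payload(rep_f)),
    file.path(cfg$output_dir, "overlap.json"), auto_unbox = TRUE, digits = NA)
  assign("overlap", list(compounds = rep_c, fragments = rep_f), envir = state)
  manifest$overlap <- list(compounds_allway = rep_c$allway_count,
                           fragments_allway = rep_f$allway_count)
  manifest
}

.overlap_payload <- function(rep) {
  list(set_names = rep$set_names, sizes = as.list(rep$sizes),
       unique_counts = as.list(rep$unique_counts), pairwise = rep$pairwise,
       allway_count = rep$allway_count, allway_members = rep$allway_members)
}

.stage_map <- function(cfg, state, manifest) {
  smiles <- character(); labels <- character()
  for (ds in cfg$datasets) {
    cu <- .get_curated(cfg, state, ds$name)
    smiles <- c(smiles, cu$smiles)
    labels <- c(labels, rep(ds$name, length(cu$smiles)))
  }
  keep <- !duplicated(smiles)
  smiles <- smiles[keep]; labels <- labels[keep]
  if (length(smiles) < 2L) {
    message("[map] skipped: fewer than 2 unique compounds")
    return(manifest)
  }
  fps <- lapply(smiles, function(s) circular_fingerprint(parse_smiles(s)))
  M <- minhash_matrix(fps, d = cfg$chemspace$d, seed = cfg$seed)
  idx <- build_index(M, n_trees = cfg$chemspace$n_trees, ids = smiles)
  g <- suppressWarnings(knn_graph(idx, k = cfg$chemspace$k, kc = cfg$chemspace$kc))
  lay <- spanning_tree_layout(g, idx, seed = cfg$seed)
  write_chemspace_csv(g, lay,
                      file.path(cfg$output_dir, "chemspace_edges.csv"),
                      file.path(cfg$output_dir, "chemspace_layout.csv"),
                      labels = labels)
  manifest$map <- list(nodes = length(smiles), edges = nrow(g$edges),
                       component_links = lay$n_component_links)
  manifest
}

#' Summary tables (counts, descriptor means, diversity)
#'
#' Emits the count table (original / processed / fragments per dataset),
#' per-dataset arithmetic means of the descriptor distributions for
#' compounds and for fragments (fragments table gains an "Overlapping
#' Fragments" column - the fragments shared by all libraries - when at
#' least two datasets are present), printed to 3 decimals. Datasets with
#' an empty fragment library get explicit NA rows, not zeros.
#'
#' @param cfg A `pipeline_config`.
#' @param state Internal pipeline state environment (from [run_pipeline()]).
#' @return List with `counts`, `compound_means`, `fragment_means`.
#' @export
summarize_tables <- function(cfg, state) {
  nm <- vapply(cfg$datasets, `[[`, character(1L), "name")
  counts <- do.call(rbind, lapply(nm, function(n) {
    cu <- .get_curated(cfg, state, n)
    lib <- tryCatch(.get_library(cfg, state, n), error = function(e) NULL)
    data.frame(Dataset = n,
               OriginalCompounds = cu$n_input,
               ProcessedCompounds = length(cu$kept$ids),
               GeneratedFragments = if (is.null(lib)) NA_integer_ else nrow(lib$records))
  }))
  desc_names <- c("n_carbon", "n_oxygen", "n_nitrogen", "n_heavy",
                  "frac_sp3", "frac_chiral_c", "n_rings", "n_aliphatic_rings",
                  "n_aromatic_rings", "n_heterocycles",
                  "n_aliphatic_heterocycles", "n_aromatic_heterocycles",
                  "n_spiro", "n_bridgehead")
  mean_col <- function(mols) {
    if (length(mols) == 0L) return(rep(NA_real_, length(desc_names)))
    dt <- descriptor_table(mols)
    round(colMeans(dt[, desc_names]), 3)
  }
  comp <- lapply(nm, function(n) mean_col(.get_curated(cfg, state, n)$kept$molecules))
  compound_means <- data.frame(Feature = desc_names)
  for (i in seq_along(nm)) compound_means[[nm[i]]] <- comp[[i]]

  frag <- lapply(nm, function(n) {
    lib <- tryCatch(.get_library(cfg, state, n), error = function(e) NULL)
    if (is.null(lib) || nrow(lib$records) == 0L) return(rep(NA_real_, length(desc_names)))
    mean_col(lapply(lib$records$fragment_smiles, parse_smiles))
  })
  fragment_means <- data.frame(Feature = desc_names)
  for (i in seq_along(nm)) fragment_means[[nm[i]]] <- frag[[i]]
  if (length(nm) >= 2L) {
    sets <- lapply(nm, function(n) {
      lib <- tryCatch(.get_library(cfg, state, n), error = function(e) NULL)
      if (is.null(lib)) character() else lib$records$fragment_smiles
    })
    shared <- Reduce(intersect, sets)
    fragment_means[["OverlappingFragments"]] <-
      if (length(shared)) mean_col(lapply(shared, parse_smiles))
      else rep(NA_real_, length(desc_names))
  }
  list(counts = counts, compound_means = compound_means,
       fragment_means = fragment_means)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>\n")
  for (n in names(x$datasets)) {
    d <- x$datasets[[n]]
    cat(sprintf("  %s: original %d, parsed %d, processed %d, fragments %s\n",
                n, d$original, d$parsed, d$processed,
                if (is.null(d$fragments)) "-" else d$fragments))
  }
  invisible(x)
}
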