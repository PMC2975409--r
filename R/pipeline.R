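#' Build a pipeline configuration
#'
#' Collects every setting for an end-to-end run: the simulated study
#' designs, the statistic and permutation settings, the panel rule, and how
#' reference biomarker sets and the pathway annotation are obtained
#' (generated, or read from files). Defaults mirror the package's standard
#' analysis: pooled-variance t statistic, 100000 permutations, alpha =
#' 0.001, panel rule `"any"`.
#'
#' @param studies Named list of per-study design settings; each element is a
#'   list of arguments for [study_design()] (label -> settings). At most 3
#'   studies are compared in the Venn stage.
#' @param statistic,n_perm,alpha,panel_rule Testing and panel settings; see
#'   [permutation_test()] and [derive_panel()].
#' @param reference Either `list(paths = <character>)` naming biomarker-set
#'   files, or generation settings
#'   `list(n_sets, set_size, n_overlap)` — sets are drawn from the first
#'   study's protein universe with `n_overlap` members shared with its true
#'   differential set.
#' @param annotation Either `list(path = <gmt file>)` or generation settings
#'   `list(n_pathways, size_min, size_max)` over the first study's protein
#'   universe.
#' @param seed Base integer seed; stage seeds are derived from it.
#' @return A list of class `pipeline_config`.
#' @seealso [run_pipeline()], [read_pipeline_config()]
#' @export
pipeline_config <- function(studies = list(A = list()),
                            statistic = "pooled_t",
                            n_perm = 100000L,
                            alpha = 0.001,
                            panel_rule = "any",
                            reference = list(n_sets = 4, set_size = 150,
                                             n_overlap = 30),
                            annotation = list(n_pathways = 30,
                                              size_min = 10, size_max = 80),
                            seed = 1L) {
  if (length(studies) < 1 || is.null(names(studies)) ||
      anyDuplicated(names(studies))) {
    abort("`studies` must be a uniquely named list of design settings.")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie in (0, 1).")
  }
  if (n_perm < 1) abort("`n_perm` must be >= 1.")
  structure(
    list(studies = studies, statistic = statistic,
         n_perm = as.integer(n_perm), alpha = alpha,
         panel_rule = panel_rule, reference = reference,
         annotation = annotation, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; missing keys take the
#' defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw), names(formals(pipeline_config)))]
  do.call(pipeline_config, args)
}

# deterministic 31-bit stage seed derived from the base seed
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}

study_dir <- function(out_dir, label) file.path(out_dir, paste0("study_", label))

#' Run the full discovery pipeline
#'
#' Executes simulate -> quantify -> test -> panel -> pathways -> similarity,
#' writing every stage artifact as TSV/GMT text under `out_dir`, then a JSON
#' run manifest (`manifest.json`) recording the effective configuration,
#' package version, per-file MD5 checksums, stage seeds, and timestamps.
#' Identical configuration and seed reproduce byte-identical stage outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress per-stage log lines.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be a `pipeline_config` object.")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) inform(sprintf(...))
  started <- Sys.time()

  stage_simulate(config, out_dir)
  say("[simulate] %d study/studies written", length(config$studies))
  for (lab in names(config$studies)) {
    n <- stage_quantify(study_dir(out_dir, lab))
    say("[quantify] %s: %d peptides -> %d proteins", lab, n[1], n[2])
  }
  for (lab in names(config$studies)) {
    s <- stage_test(study_dir(out_dir, lab), config)
    say("[test] %s: %d / %d significant at alpha = %g",
        lab, s$n_significant, s$n_tested, s$alpha)
  }
  sizes <- stage_panel(config, out_dir)
  say("[panel] panel sizes: %s",
      paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "))
  np <- stage_pathways(config, out_dir)
  say("[pathways] %d pathways scored", np)
  ns <- stage_similarity(config, out_dir)
  say("[similarity] %d study pair(s) compared", ns)

  manifest <- list(
    package = "permpanel",
    version = as.character(packageVersion("permpanel")),
    created = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = unclass(config),
    checksums = pipeline_checksums(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("[manifest] %s", file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

pipeline_checksums <- function(out_dir) {
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  sums <- tools::md5sum(files)
  names(sums) <- sub(paste0("^", out_dir, "/?"), "", names(sums))
  as.list(sums)
}

#' Pipeline stages
#'
#' Each stage reads its inputs from, and writes its outputs to, the run
#' directory, so stages can be re-run individually and compose to the same
#' result as [run_pipeline()].
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory.
#' @param dir A single study's directory (`<out_dir>/study_<label>`).
#' @return `stage_simulate`: the study directories; `stage_quantify`:
#'   c(peptides, proteins); `stage_test`: the significance summary;
#'   `stage_panel`: named panel sizes; `stage_pathways`: pathway count;
#'   `stage_similarity`: number of pairs.
#' @name pipeline-stages
NULL

#' @rdname pipeline-stages
#' @export
stage_simulate <- function(config, out_dir) {
  labs <- names(config$studies)
  dirs <- character()
  for (i in seq_along(labs)) {
    lab <- labs[i]
    args <- config$studies[[lab]]
    args$seed <- args$seed %||% derive_seed(config$seed, i)
    design <- do.call(study_design, args)
    sim <- simulate_study(design, scale = "raw")
    d <- study_dir(out_dir, lab)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    write_intensity_tsv(sim$intensities, file.path(d, "intensities_raw.tsv"))
    write_group_map(sim$groups, file.path(d, "groups.tsv"))
    write_peptide_map(sim$peptide_map, file.path(d, "peptide_map.tsv"))
    readr::write_tsv(sim$truth, file.path(d, "truth.tsv"))
    dirs <- c(dirs, d)
  }
  invisible(dirs)
}

#' @rdname pipeline-stages
#' @export
stage_quantify <- function(dir) {
  peptides <- read_intensity_tsv(file.path(dir, "intensities_raw.tsv"))
  map <- read_peptide_map(file.path(dir, "peptide_map.tsv"))
  groups <- read_group_map(file.path(dir, "groups.tsv"))
  logged <- log2_transform(peptides)

  # normality diagnostics on pooled control-sample log2 intensities
  ctrl <- groups$sample_id[groups$group == "control"]
  pooled <- unlist(logged[, ctrl], use.names = FALSE)
  readr::write_tsv(ks_normality(pooled), file.path(dir, "normality.tsv"))
  readr::write_tsv(qq_table(pooled), file.path(dir, "qq.tsv"))

  proteins <- logged |> quantile_normalize() |> rollup_proteins(map)
  write_intensity_tsv(proteins, file.path(dir, "proteins.tsv"))
  invisible(c(nrow(peptides), nrow(proteins)))
}

#' @rdname pipeline-stages
#' @export
stage_test <- function(dir, config) {
  proteins <- read_intensity_tsv(file.path(dir, "proteins.tsv"))
  groups <- read_group_map(file.path(dir, "groups.tsv"))
  fit <- permutation_test(proteins, groups, statistic = config$statistic,
                          n_perm = config$n_perm,
                          seed = derive_seed(config$seed, 101))
  sig <- select_significant(fit, alpha = config$alpha)
  readr::write_tsv(tidy(sig), file.path(dir, "results.tsv"))
  summary <- glance(sig)
  readr::write_tsv(
    tibble::tibble(key = names(summary),
                   value = as.character(unlist(summary))),
    file.path(dir, "summary.tsv")
  )
  invisible(summary)
}

#' @rdname pipeline-stages
#' @export
stage_panel <- function(config, out_dir) {
  labs <- names(config$studies)
  refs <- pipeline_references(config, out_dir)
  for (i in seq_along(refs)) {
    write_biomarker_set(refs[[i]],
                        file.path(out_dir, sprintf("reference_%d.txt", i)))
  }
  sizes <- integer()
  panels <- list()
  for (lab in labs) {
    d <- study_dir(out_dir, lab)
    res <- readr::read_tsv(file.path(d, "results.tsv"),
                           show_col_types = FALSE)
    sig <- biomarker_set(lab, res$protein_id[res$significant])
    panel <- derive_panel(sig, refs, rule = config$panel_rule,
                          name = paste0("panel_", lab))
    write_biomarker_set(panel, file.path(d, "panel.txt"))
    panels[[lab]] <- panel
    sizes[lab] <- length(panel$members)
  }
  if (length(panels) >= 2) {
    readr::write_tsv(venn_counts(panels[seq_len(min(3, length(panels)))]),
                     file.path(out_dir, "venn.tsv"))
  }
  invisible(sizes)
}

pipeline_references <- function(config, out_dir) {
  ref_cfg <- config$reference
  if (!is.null(ref_cfg$paths)) {
    return(purrr::map(ref_cfg$paths, read_biomarker_set))
  }
  lab1 <- names(config$studies)[1]
  map <- read_peptide_map(file.path(study_dir(out_dir, lab1),
                                    "peptide_map.tsv"))
  truth <- readr::read_tsv(file.path(study_dir(out_dir, lab1), "truth.tsv"),
                           show_col_types = FALSE)
  universe <- unique(map$protein_id)
  n_overlap <- min(ref_cfg$n_overlap %||% 30,
                   ref_cfg$set_size %||% 150, nrow(truth))
  simulate_reference_sets(
    universe,
    n_sets = ref_cfg$n_sets %||% 4,
    set_size = min(ref_cfg$set_size %||% 150, length(universe)),
    overlap_with = truth$protein_id,
    n_overlap = n_overlap,
    seed = derive_seed(config$seed, 201)
  )
}

pipeline_annotation <- function(config, out_dir) {
  ann_cfg <- config$annotation
  if (!is.null(ann_cfg$path)) return(read_gmt(ann_cfg$path))
  lab1 <- names(config$studies)[1]
  map <- read_peptide_map(file.path(study_dir(out_dir, lab1),
                                    "peptide_map.tsv"))
  universe <- unique(map$protein_id)
  size_max <- min(ann_cfg$size_max %||% 80, length(universe))
  simulate_pathway_annotation(
    universe,
    n_pathways = ann_cfg$n_pathways %||% 30,
    size_range = c(min(ann_cfg$size_min %||% 10, size_max), size_max),
    seed = derive_seed(config$seed, 301)
  )
}

read_pipeline_panels <- function(config, out_dir) {
  labs <- names(config$studies)
  panels <- purrr::map(labs, function(lab) {
    read_biomarker_set(file.path(study_dir(out_dir, lab), "panel.txt"))
  })
  names(panels) <- labs
  panels
}

#' @rdname pipeline-stages
#' @export
stage_pathways <- function(config, out_dir) {
  ann <- pipeline_annotation(config, out_dir)
  write_gmt(ann, file.path(out_dir, "annotation.gmt"))
  panels <- read_pipeline_panels(config, out_dir)
  fcm <- build_ppfcm(panels, ann)
  readr::write_tsv(fcm, file.path(out_dir, "ppfcm.tsv"))
  readr::write_tsv(ppfcm_long(fcm), file.path(out_dir, "ppfcm_long.tsv"))
  for (lab in names(panels)) {
    d <- study_dir(out_dir, lab)
    readr::write_tsv(build_association_matrix(panels[[lab]], ann),
                     file.path(d, "association_matrix.tsv"))
    readr::write_tsv(fisher_enrichment(panels[[lab]], ann),
                     file.path(d, "enrichment.tsv"))
    readr::write_tsv(rank_pathways(fcm, lab),
                     file.path(d, "pathway_ranks.tsv"))
  }
  invisible(nrow(fcm))
}

#' @rdname pipeline-stages
#' @export
stage_similarity <- function(config, out_dir) {
  ann <- read_gmt(file.path(out_dir, "annotation.gmt"))
  panels <- read_pipeline_panels(config, out_dir)
  rep <- similarity_report(panels, annotation = if (length(ann$sets) >= 2) ann)
  readr::write_tsv(rep, file.path(out_dir, "similarity.tsv"))
  invisible(nrow(rep))
}
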