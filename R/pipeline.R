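#' Run the full analysis pipeline
#'
#' Wires every stage over one configuration: obtain the inputs (either a
#' synthetic spec or paths to an existing table/metadata/traits), then run
#' rarefaction, core-set analysis, taxon and pathway multiple-site
#' beta-partitioning, stochasticity-ratio estimation and the
#' signature-feature screen, writing TSV/JSON results plus a run manifest
#' (version, seed, config hash, per-stage parameters) to `out_dir`.
#' Identical configs and seeds produce identical result files.
#'
#' @param config either a list or a path to a JSON file. Recognized
#'   entries: `synthetic` (arguments for [synthetic_spec]) or `table` /
#'   `metadata` / `traits` (file paths); `rarefy_depth` (default: the
#'   smallest sample total); `core_threshold` (default 0.75);
#'   `n_randomizations` (default 1000); `alpha` (0.05); `lda_cutoff` (3).
#' @param out_dir output directory (created if needed).
#' @param seed integer master seed; overrides any seed in the config.
#' @param verbose log stage timings to standard error.
#' @return (invisibly) the manifest as a list.
#' @export
run_pipeline <- function(config, out_dir, seed = 1L, verbose = FALSE) {
  if (is.character(config)) {
    .assert(file.exists(config), "no such config file: '%s'", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  .assert(is.list(config), "config must be a list or a JSON file path")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(fmt, ...) {
    if (verbose) message(sprintf("[stochbeta] %s", sprintf(fmt, ...)))
  }
  t0 <- Sys.time()

  if (!is.null(config$synthetic)) {
    args <- config$synthetic
    args$seed <- seed
    if (!is.null(args$cohorts)) args$cohorts <- unlist(args$cohorts)
    spec <- do.call(synthetic_spec, args)
    ds <- make_dataset(spec)
    table <- ds$table; design <- ds$design; traits <- ds$traits
    write_feature_table(table, file.path(out_dir, "table.tsv"))
    writeLines(c("sample_id\tcohort",
                 paste(names(design$assignments), design$assignments,
                       sep = "\t")),
               file.path(out_dir, "metadata.tsv"))
    say("simulated %d samples x %d taxa", n_samples(table),
        length(feature_ids(table)))
  } else {
    .assert(!is.null(config$table) && !is.null(config$metadata),
            "config needs either 'synthetic' or 'table' + 'metadata'")
    table <- read_feature_table(config$table)
    design <- read_design(config$metadata)
    traits <- if (!is.null(config$traits)) read_trait_matrix(config$traits)
              else NULL
  }

  depth <- config$rarefy_depth
  if (is.null(depth)) depth <- min(rowSums(table$counts))
  rare <- rarefy(table, depth, seed = .mix_seed(seed, 2L))
  keep <- intersect(names(design$assignments), sample_ids(rare))
  design <- cohort_design(design$assignments[keep], design$cohort_order)
  say("rarefied to depth %d (%d samples retained)", as.integer(depth),
      n_samples(rare))

  threshold <- if (is.null(config$core_threshold)) 0.75 else config$core_threshold
  cores <- core_sets(rare, design, threshold = threshold)
  write_results(cores, file.path(out_dir, "core_sets.tsv"), "tsv")
  write_results(cores, file.path(out_dir, "core_sets.json"), "json")
  say("core sets done")

  beta_taxa <- cohort_partitions(rare, design)
  write_results(beta_taxa, file.path(out_dir, "beta_taxa.tsv"), "tsv")

  n_rand <- if (is.null(config$n_randomizations)) 1000L
            else as.integer(config$n_randomizations)
  cfg <- null_model_config(n_randomizations = n_rand,
                           seed = .mix_seed(seed, 3L))
  stoch_taxa <- stochasticity_ratio(rare, design, cfg)
  for (co in names(stoch_taxa)) {
    write_results(stoch_taxa[[co]],
                  file.path(out_dir, sprintf("stochasticity_taxa_%s.json", co)),
                  "json")
  }
  say("taxon stochasticity done")

  if (!is.null(traits)) {
    pathways <- project_traits(rare, traits)
    beta_path <- cohort_partitions(pathways, design)
    write_results(beta_path, file.path(out_dir, "beta_pathways.tsv"), "tsv")
    stoch_path <- stochasticity_ratio(pathways, design, cfg)
    for (co in names(stoch_path)) {
      write_results(stoch_path[[co]],
                    file.path(out_dir,
                              sprintf("stochasticity_pathways_%s.json", co)),
                    "json")
    }
    say("pathway analyses done")
  }

  alpha <- if (is.null(config$alpha)) 0.05 else config$alpha
  cutoff <- if (is.null(config$lda_cutoff)) 3 else config$lda_cutoff
  sig <- signature_features(rare, design, alpha = alpha, lda_cutoff = cutoff,
                            seed = .mix_seed(seed, 4L))
  write_results(as.data.frame(sig), file.path(out_dir, "signatures.tsv"), "tsv")
  say("signature screen done (%d passing)", sum(sig$passes))

  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  cfg_path <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfg_path)
  manifest <- list(
    package = "stochbeta",
    version = as.character(utils::packageVersion("stochbeta")),
    seed = as.integer(seed),
    config_hash = unname(tools::md5sum(cfg_path)),
    rarefy_depth = as.integer(depth),
    core_threshold = threshold,
    n_randomizations = n_rand,
    alpha = alpha,
    lda_cutoff = cutoff,
    n_samples = n_samples(rare),
    n_features = length(feature_ids(rare)),
    elapsed_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1))
  jsonlite::write_json(manifest[names(manifest) != "elapsed_s"],
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("pipeline finished in %.1fs", manifest$elapsed_s)
  invisible(manifest)
}
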