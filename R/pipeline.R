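## Reproducible pipeline wiring: a validated flat configuration, staged
## execution (simulate -> filter -> phase -> call -> detect -> map) and a
## manifest recording the configuration, seed and output checksums.

#' Pipeline configuration with validated defaults
#'
#' Defaults correspond to a large, low-coverage (~2x) population: 100-SNV
#' phasing windows with a 1-SNV shift; 50-SNV calling windows shifted by 5
#' with at least 5 non-missing calls; 0.95 crossover probability; 40%
#' missingness cap; hom-ref depth floor 2; BH FDR 0.05; LD threshold 0.2;
#' 10,000 permutations; Haldane map function.
#'
#' @param ... Overrides for any default field.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    population = "pop1",
    seed = 1L,
    ## simulation
    n_chrom = 3L, chrom_length = 5e6, snv_density = 1000,
    n_individuals = 90L, lambda_co = 1, coverage = 2, base_error = 0.01,
    missing_rate = 0,
    ## filtering
    fdr = 0.05, ld_n_sample = 25L, ld_min_r2 = 0.2,
    min_depth = 2L, max_missing = 0.4,
    ## phasing / calling
    phase_window = 100L, phase_shift = 1L,
    call_window = 50L, call_step = 5L, min_calls = 5L,
    ## crossovers / map
    co_threshold = 0.95, map_fun = "haldane", rate_binsize = 1e5,
    n_perm = 10000L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  chk <- function(cond, msg) if (!cond) stopf("invalid config: %s", msg)
  chk(cfg$max_missing >= 0 && cfg$max_missing <= 1,
      "max_missing must be in [0, 1]")
  chk(cfg$fdr > 0 && cfg$fdr < 1, "fdr must be in (0, 1)")
  chk(cfg$ld_min_r2 >= 0 && cfg$ld_min_r2 <= 1, "ld_min_r2 must be in [0, 1]")
  chk(cfg$co_threshold > 0 && cfg$co_threshold < 1,
      "co_threshold must be in (0, 1)")
  chk(cfg$min_depth >= 0, "min_depth must be >= 0")
  chk(cfg$phase_window >= 2, "phase_window must be >= 2")
  chk(cfg$call_window >= 1 && cfg$call_step >= 1,
      "call_window and call_step must be >= 1")
  chk(cfg$min_calls >= 1, "min_calls must be >= 1")
  chk(cfg$map_fun %in% c("haldane", "kosambi"),
      "map_fun must be 'haldane' or 'kosambi'")
  chk(cfg$n_perm >= 1, "n_perm must be >= 1")
  chk(cfg$base_error >= 0 && cfg$base_error < 0.5,
      "base_error must be in [0, 0.5)")
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#' @param path Flat key-value YAML file.
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) do.call(pipeline_config, yaml::read_yaml(path))

#' Run the crossover-mapping pipeline
#'
#' Chains the pipeline stages on simulated data (or on a user VCF given
#' via `vcf`) and writes every stage artifact plus a manifest (serialized
#' configuration, seed and MD5 checksums) to `outdir`.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @param vcf Optional input VCF; when `NULL`, a population is simulated
#'   from the config.
#' @param repeats Optional repeat BED/`GRanges` for masking.
#' @return Invisibly, a list with the main in-memory results
#'   (`matrix`, `error_rate`, `labels`, `windows`, `skeleton`,
#'   `crossovers`, `marey`, `track`, `truth` when simulated).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = ".",
                         vcf = NULL, repeats = NULL) {
  validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = config)
  set.seed(config$seed)
  if (is.null(vcf)) {
    xo_log("simulating population '", config$population, "'")
    layout <- genome_layout(paste0("chr", seq_len(config$n_chrom)),
                            rep(config$chrom_length, config$n_chrom))
    parents <- simulate_parents(layout, config$snv_density)
    sim <- simulate_population(parents, config$n_individuals,
                               lambda_co = config$lambda_co,
                               coverage = config$coverage,
                               base_error = config$base_error,
                               missing_rate = config$missing_rate,
                               seed = config$seed)
    m <- sim$matrix
    res$truth <- sim$truth
    write_snv_vcf(m, file.path(outdir, "simulated.vcf"), layout)
    write_truth_bed(sim$truth, file.path(outdir, "true_crossovers.bed"))
  } else {
    m <- load_genotypes(vcf)
  }
  xo_log("filtering ", ncol(m$geno), " sites")
  filt <- filter_variants(m, repeats = repeats, fdr = config$fdr,
                          ld_n_sample = config$ld_n_sample,
                          min_median_r2 = config$ld_min_r2,
                          min_depth = config$min_depth,
                          max_missing = config$max_missing,
                          seed = config$seed)
  res$matrix <- filt$matrix
  res$error_rate <- filt$error_rate
  write_filter_stats(filt, file.path(outdir, "filter_stats.tsv"))
  xo_log("phasing ", ncol(res$matrix$geno), " sites (E_T = ",
         signif(res$error_rate$E_T, 3), ")")
  phased <- phase_snvs(res$matrix, window = config$phase_window,
                       shift = config$phase_shift)
  res$labels <- genotype_to_haplotype(res$matrix, phased)
  write_phase_table(phased, res$matrix, file.path(outdir, "phase_table.tsv"))
  xo_log("calling haplotype windows")
  res$windows <- call_windows(res$labels, window = config$call_window,
                              step = config$call_step,
                              min_calls = config$min_calls,
                              E_T = res$error_rate)
  res$skeleton <- build_skeleton(res$windows)
  write_skeleton_bed(res$skeleton, file.path(outdir, "skeleton_bins.bed"))
  xo_log("detecting crossovers")
  res$crossovers <- call_crossovers(res$skeleton, res$labels,
                                    threshold = config$co_threshold,
                                    population = config$population)
  write_crossovers_tsv(res$crossovers, file.path(outdir, "crossovers.tsv"))
  write_crossovers_bed(res$crossovers, file.path(outdir, "crossovers.bed"))
  xo_log("building recombination map")
  res$marey <- genetic_positions(res$windows, map_fun = config$map_fun)
  res$track <- interpolate_rate(res$marey, binsize = config$rate_binsize)
  write_marey_tsv(res$marey, file.path(outdir, "marey_map.tsv"))
  write_track_bedgraph(res$track, file.path(outdir, "recomb_rate.bedgraph"))
  write_manifest(config, outdir)
  xo_log("done: ", nrow(res$crossovers), " crossovers, total map ",
         round(sum(map_length(res$marey)), 1), " cM")
  invisible(res)
}

write_manifest <- function(config, outdir) {
  files <- setdiff(list.files(outdir), "manifest.yaml")
  sums <- tools::md5sum(file.path(outdir, files))
  manifest <- list(config = unclass(config), seed = config$seed,
                   files = as.list(setNames(unname(sums), files)))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(manifest)
}
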