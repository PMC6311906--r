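## Stage orchestration behind the command-line wrapper (inst/cli/csrehmm.R).
## Every stage is a thin composition of exported functions, driven by one
## YAML config and a single root seed, and drops a JSON provenance record
## next to its outputs so any artifact can be reproduced.

PIPELINE_DEFAULTS <- list(
  bin_size = 200, alpha = 1e-4, signal_threshold = 2, s = 2, K = 30,
  p0 = 0.3, mode = "incremental", max_iter = 300, tol = 1e-6,
  n_sim = 1000, seed = 1, ext_len = 200, control_mark = "WCE",
  decode_method = "posterior", outdir = ".")

#' Read a pipeline configuration file
#'
#' YAML key-value file; unset keys fall back to the standard defaults
#' (200-bp bins, Poisson alpha 1e-4, signal threshold 2, s = 2, K = 30,
#' p0 = 0.3, incremental EM with 300 iterations and tol 1e-6, 1000 null
#' simulations, seed 1).
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return named list of parameters.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- PIPELINE_DEFAULTS
  if (!is.null(path)) {
    if (!file.exists(path)) stop2("config file not found: ", path)
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  cfg
}

check_inputs <- function(cfg, keys) {
  for (k in keys) {
    if (is.null(cfg[[k]])) stop2("config key '", k, "' is required")
    missing <- !vapply(unlist(cfg[[k]]), file.exists, logical(1))
    if (any(missing))
      stop2("input file(s) for '", k, "' not found: ",
            paste(unlist(cfg[[k]])[missing], collapse = ", "))
  }
}

write_provenance <- function(cfg, stage, inputs, outputs) {
  rec <- list(stage = stage,
              parameters = cfg[setdiff(names(cfg), c("outdir"))],
              inputs = lapply(inputs, function(p)
                list(path = p, md5 = unname(tools::md5sum(p)))),
              outputs = outputs)
  path <- file.path(cfg$outdir, paste0(stage, "_provenance.json"))
  jsonlite::write_json(rec, path, digits = NA, auto_unbox = TRUE)
  path
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (synthetic dataset + companions), `binarize` (reads ->
#' peak calls per track), `specify` (peak matrices -> observation files),
#' `fit` (EM training -> model JSON), `decode` (state path TSV),
#' `call-states` (state classification + CSRE BED), `annotate` (feature
#' classes and proximal genes), `enrich` (peak overlap + gene sets),
#' `select-model` (score table over fitted models). Identical config and
#' seed give byte-identical numeric outputs.
#'
#' @param subcommand stage name.
#' @param config path to a YAML config, or a named list (see
#'   [read_run_config]).
#' @return invisibly, a named list of output paths.
#' @export
run_pipeline <- function(subcommand, config = NULL) {
  cfg <- if (is.character(config)) read_run_config(config)
         else utils::modifyList(PIPELINE_DEFAULTS, config %||% list())
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- switch(
    subcommand,
    "simulate" = stage_simulate(cfg),
    "binarize" = stage_binarize(cfg),
    "specify" = stage_specify(cfg),
    "fit" = stage_fit(cfg),
    "decode" = stage_decode(cfg),
    "call-states" = stage_call_states(cfg),
    "annotate" = stage_annotate(cfg),
    "enrich" = stage_enrich(cfg),
    "select-model" = stage_select_model(cfg),
    stop2("unknown subcommand: ", subcommand))
  invisible(out)
}

stage_simulate <- function(cfg) {
  sc <- sim_config(N = cfg$sim_N %||% 4, M = cfg$sim_M %||% 3,
                   K = cfg$sim_K %||% 4, s = cfg$s,
                   chrom_lengths = unlist(cfg$chrom_lengths %||%
                                            c(chr1 = 5e6, chr2 = 5e6)),
                   bin_size = cfg$bin_size, seed = cfg$seed)
  ds <- simulate_dataset(sc)
  obs_dir <- file.path(cfg$outdir, "observations")
  obs_paths <- write_observations(ds$O, ds$bins, obs_dir)
  truth_tsv <- file.path(cfg$outdir, "truth_states.tsv")
  coords <- bin_coords(ds$bins)
  utils::write.table(cbind(coords, state = ds$truth$states), truth_tsv,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  model_json <- file.path(cfg$outdir, "model_true.json")
  write_hmm_model(sc$true_params, model_json)
  comp <- simulate_companions(sc, ds$truth,
                              dir = file.path(cfg$outdir, "companions"))
  sizes_path <- file.path(cfg$outdir, "chrom.sizes")
  utils::write.table(data.frame(names(sc$bins$chrom_sizes),
                                format(sc$bins$chrom_sizes,
                                       scientific = FALSE, trim = TRUE)),
                     sizes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  outputs <- list(observations = obs_paths, truth = truth_tsv,
                  model_true = model_json, chrom_sizes = sizes_path,
                  companions = as.list(comp$paths))
  write_provenance(cfg, "simulate", character(0), outputs)
  outputs
}

stage_binarize <- function(cfg) {
  check_inputs(cfg, c("reads_bed", "chrom_sizes"))
  bins <- genome_bins(read_chrom_sizes(cfg$chrom_sizes), cfg$bin_size)
  reads <- read_bed(cfg$reads_bed)
  reads$pos <- ifelse((reads$strand %||% "+") == "-", reads$end - 1,
                      reads$start)
  reads$strand <- reads$strand %||% "+"
  track <- bin_reads(reads, bins, ext_len = cfg$ext_len)
  peaks <- call_peaks_poisson(track, alpha = cfg$alpha)
  out_bed <- file.path(cfg$outdir, "peaks.bed")
  write_bed(bin_vector_to_intervals(peaks, bins), out_bed)
  write_provenance(cfg, "binarize",
                   c(cfg$reads_bed, cfg$chrom_sizes),
                   list(peaks = out_bed,
                        lambda = attr(peaks, "lambda"),
                        cutoff = attr(peaks, "cutoff")))
  list(peaks = out_bed)
}

stage_specify <- function(cfg) {
  check_inputs(cfg, c("peak_beds", "chrom_sizes"))
  bins <- genome_bins(read_chrom_sizes(cfg$chrom_sizes), cfg$bin_size)
  marks <- names(cfg$peak_beds)
  S <- lapply(marks, function(m) {
    files <- unlist(cfg$peak_beds[[m]])       # named by cell
    mat <- do.call(rbind, lapply(files, read_peaks_bed, bins = bins))
    specificity_transform(peak_matrix(mat, mark = m, cells = names(files)),
                          s = cfg$s)
  })
  O <- stack_observations(S)
  obs_dir <- file.path(cfg$outdir, "observations")
  paths <- write_observations(O, bins, obs_dir)
  write_provenance(cfg, "specify", unlist(cfg$peak_beds),
                   list(observations = paths))
  list(observations = paths)
}

load_obs_bins <- function(cfg) {
  check_inputs(cfg, c("observations", "chrom_sizes"))
  bins <- genome_bins(read_chrom_sizes(cfg$chrom_sizes), cfg$bin_size)
  O <- read_observations(unlist(cfg$observations))
  list(O = O, bins = bins)
}

stage_fit <- function(cfg) {
  d <- load_obs_bins(cfg)
  init <- if (identical(cfg$init, "random"))
    init_random(cfg$K, nrow(d$O$mat), cfg$seed)
  else init_entropy(d$O, d$bins, cfg$K)
  fit <- em_fit(d$O, d$bins, init = init, mode = cfg$mode,
                max_iter = cfg$max_iter, tol = cfg$tol)
  fit$params$row_labels <- d$O$row_labels
  model_json <- file.path(cfg$outdir, sprintf("model_K%d.json", cfg$K))
  write_hmm_model(fit$params, model_json)
  trace_tsv <- file.path(cfg$outdir, sprintf("trace_K%d.tsv", cfg$K))
  utils::write.table(data.frame(iteration = seq_along(fit$trace$loglik),
                                loglik = fit$trace$loglik),
                     trace_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  write_provenance(cfg, "fit", unlist(cfg$observations),
                   list(model = model_json, trace = trace_tsv,
                        converged = fit$trace$converged))
  list(model = model_json, trace = trace_tsv)
}

stage_decode <- function(cfg) {
  d <- load_obs_bins(cfg)
  check_inputs(cfg, "model")
  params <- read_hmm_model(cfg$model)
  path <- decode(d$O, d$bins, params, method = cfg$decode_method)
  states_tsv <- file.path(cfg$outdir, "states.tsv")
  utils::write.table(cbind(bin_coords(d$bins), state = path$states),
                     states_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_provenance(cfg, "decode",
                   c(unlist(cfg$observations), cfg$model),
                   list(states = states_tsv))
  list(states = states_tsv)
}

stage_call_states <- function(cfg) {
  check_inputs(cfg, c("model", "states", "chrom_sizes"))
  params <- read_hmm_model(cfg$model)
  bins <- genome_bins(read_chrom_sizes(cfg$chrom_sizes), cfg$bin_size)
  classes <- classify_states(params, p0 = cfg$p0,
                             control_mark = cfg$control_mark)
  st <- utils::read.table(cfg$states, header = TRUE, sep = "\t")
  path <- structure(list(states = st$state, bins = bins,
                         method = "loaded", posterior = NULL),
                    class = "state_path")
  csres <- extract_csres(path, classes, bins)
  csre_bed <- file.path(cfg$outdir, "csres.bed")
  write_csre_bed(csres, csre_bed)
  class_tsv <- file.path(cfg$outdir, "state_classes.tsv")
  utils::write.table(classes$table, class_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  emission_tsv <- file.path(cfg$outdir, "emissions.tsv")
  export_emission_table(params, classes, emission_tsv)
  summary_tsv <- file.path(cfg$outdir, "csre_summary.tsv")
  utils::write.table(csre_summary(csres), summary_tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_provenance(cfg, "call-states",
                   c(cfg$model, cfg$states),
                   list(csres = csre_bed, classes = class_tsv,
                        emissions = emission_tsv, summary = summary_tsv))
  list(csres = csre_bed, classes = class_tsv, emissions = emission_tsv,
       summary = summary_tsv)
}

stage_annotate <- function(cfg) {
  check_inputs(cfg, c("csres", "genes"))
  csres <- read_bed(cfg$csres)
  genes <- read_gene_models(cfg$genes, tx_prefix = cfg$tx_prefix %||% NULL)
  feats <- assign_feature(csres, genes)
  feat_tsv <- file.path(cfg$outdir, "csre_features.tsv")
  utils::write.table(cbind(csres, feature = as.character(feats)), feat_tsv,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  prox <- lapply(split(csres, csres$name), proximal_genes, genes = genes)
  prox_tsv <- file.path(cfg$outdir, "proximal_genes.tsv")
  utils::write.table(
    data.frame(state = rep(names(prox), lengths(prox)),
               gene = unlist(prox, use.names = FALSE)),
    prox_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  write_provenance(cfg, "annotate", c(cfg$csres, cfg$genes),
                   list(features = feat_tsv, proximal = prox_tsv))
  list(features = feat_tsv, proximal = prox_tsv)
}

stage_enrich <- function(cfg) {
  check_inputs(cfg, c("csres", "chrom_sizes"))
  csres <- read_bed(cfg$csres)
  sizes <- read_chrom_sizes(cfg$chrom_sizes)
  outputs <- list()
  if (!is.null(cfg$peaks)) {
    check_inputs(cfg, "peaks")
    peaks <- read_bed(cfg$peaks)
    rows <- lapply(split(csres, csres$name), function(cs) {
      er <- overlap_enrichment(cs, peaks, sizes, n_sim = cfg$n_sim,
                               seed = cfg$seed)
      data.frame(state = cs$name[1], observed = er$observed,
                 null_mean = mean(er$null), p_empirical = er$p_empirical,
                 p_wilcoxon = er$p_wilcoxon)
    })
    peak_tsv <- file.path(cfg$outdir, "peak_enrichment.tsv")
    utils::write.table(do.call(rbind, rows), peak_tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    outputs$peak_enrichment <- peak_tsv
  }
  if (!is.null(cfg$gmt) && !is.null(cfg$proximal)) {
    check_inputs(cfg, c("gmt", "proximal"))
    sets <- read_gmt(cfg$gmt)
    prox <- utils::read.table(cfg$proximal, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    universe <- unlist(cfg$universe %||% unique(unlist(sets)))
    rows <- lapply(split(prox$gene, prox$state), function(g) {
      gene_set_enrichment(g, sets, universe)
    })
    go_tsv <- file.path(cfg$outdir, "gene_set_enrichment.tsv")
    utils::write.table(
      cbind(state = rep(names(rows), vapply(rows, nrow, 0L)),
            do.call(rbind, rows)),
      go_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs$gene_set_enrichment <- go_tsv
  }
  write_provenance(cfg, "enrich", c(cfg$csres), outputs)
  outputs
}

stage_select_model <- function(cfg) {
  d <- load_obs_bins(cfg)
  check_inputs(cfg, "models")
  fits <- lapply(unlist(cfg$models), function(p)
    list(params = read_hmm_model(p)))
  N <- length(unique(d$O$row_labels$cell))
  M <- length(unique(d$O$row_labels$mark))
  tab <- score_table(fits, d$O, d$bins, N, M)
  score_tsv <- file.path(cfg$outdir, "model_scores.tsv")
  utils::write.table(tab, score_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_provenance(cfg, "select-model", unlist(cfg$models),
                   list(scores = score_tsv))
  list(scores = score_tsv)
}
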