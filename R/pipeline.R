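# Configuration, pipeline wrappers and provenance-stamped I/O.
#
# These tie the modules into reproducible runs: a validated config object,
# one wrapper per stage writing TSV with provenance headers, and a full
# synthetic-data pipeline (generate -> train -> attribute -> test -> enrich
# -> evaluate). A thin command-line script over these functions lives at
# inst/cli/eig.R.

PATH_KINDS <- c("O-L", "O-N", "H-L", "H-N")
BASELINE_STRATEGIES <- c("zero", "encoded_zero", "random", "kmeans",
                         "median", "close")

#' Build and validate a run configuration
#'
#' All enumerations are validated before any computation; unknown fields are
#' rejected. The configuration hash is recorded in every output header.
#'
#' @param ... configuration fields overriding the defaults: `path_kind`,
#'   `baseline` (strategy), `baseline_m`, `kmeans_k`, `knn_k`, `n_steps`,
#'   `tol`, `fwer`, `rank_transform`, `meta_threshold`, `target`, `seed`.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- utils::modifyList(
    list(path_kind = "O-L", baseline = "zero", baseline_m = 3, kmeans_k = 3,
         knn_k = 10, n_steps = 250, tol = 0.01, fwer = 0.05,
         rank_transform = FALSE, meta_threshold = 0.8, target = "default",
         seed = 1),
    list(...))
  known <- c("path_kind", "baseline", "baseline_m", "kmeans_k", "knn_k",
             "n_steps", "tol", "fwer", "rank_transform", "meta_threshold",
             "target", "seed")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0)
    stop("unknown config fields: ", paste(extra, collapse = ", "))
  if (!cfg$path_kind %in% PATH_KINDS)
    stop("path_kind must be one of: ", paste(PATH_KINDS, collapse = ", "))
  if (!cfg$baseline %in% BASELINE_STRATEGIES)
    stop("baseline must be one of: ",
         paste(BASELINE_STRATEGIES, collapse = ", "))
  if (cfg$n_steps < 2) stop("n_steps must be >= 2")
  if (cfg$tol <= 0) stop("tol must be > 0")
  if (!(cfg$fwer > 0 && cfg$fwer <= 1)) stop("fwer must be in (0, 1]")
  if (!(cfg$meta_threshold > 0 && cfg$meta_threshold <= 1))
    stop("meta_threshold must be in (0, 1]")
  cfg$hash <- config_hash(cfg[known])
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#' @param file YAML path; fields as in [run_config()].
#' @export
read_run_config <- function(file) {
  do.call(run_config, yaml::read_yaml(file))
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run config [hash ", x$hash, "]: path ", x$path_kind, ", baseline ",
      x$baseline, ", n_steps ", x$n_steps, ", FWER ", x$fwer, ", seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

# TSV with "# key=value" provenance headers
write_tsv_prov <- function(df, file, prov = list()) {
  con <- base::file(file, "w")
  on.exit(close(con))
  for (k in names(prov)) writeLines(paste0("# ", k, "=", prov[[k]]), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

read_tsv_prov <- function(file) {
  utils::read.table(file, sep = "\t", header = TRUE, comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

# baselines for a configured strategy
config_baselines <- function(cfg, baseline_class_points, codec = NULL) {
  switch(cfg$baseline,
    zero = zero_baseline(ncol(baseline_class_points)),
    encoded_zero = encoded_zero_baseline(codec),
    random = random_baseline(baseline_class_points, cfg$baseline_m, cfg$seed),
    kmeans = kmeans_baseline(baseline_class_points, cfg$kmeans_k, cfg$seed),
    median = median_baseline(baseline_class_points, cfg$baseline_m),
    close = function(s) close_baseline(baseline_class_points, s,
                                       cfg$baseline_m))
}

# path_config for class_attributions under a run_config
config_path <- function(cfg, models, train_features) {
  needs_graph <- cfg$path_kind %in% c("O-N", "H-N")
  graph <- NULL
  if (needs_graph) {
    pts <- if (cfg$path_kind == "H-N")
      encode(models$codec, train_features) else train_features
    graph <- knn_graph(pts, k = cfg$knn_k,
                       space = if (cfg$path_kind == "H-N") "latent"
                               else "original")
  }
  list(kind = cfg$path_kind, n_steps = cfg$n_steps,
       codec = models$codec, graph = graph)
}

#' Run the full attribution pipeline on synthetic tabular data
#'
#' Generates two-class data, trains the reference codec + predictor,
#' computes class-of-interest and random-set attributions under the
#' configured path/baseline, aggregates to meta-features, runs the
#' significance test, the enrichment curve against the planted truth, and a
#' feature-subset predictive-power curve. Each stage's table is written to
#' `out_dir` with provenance headers when `out_dir` is given.
#'
#' @param config a `run_config`.
#' @param data optional `synth_tabular`; generated from the config seed when
#'   missing.
#' @param out_dir optional output directory.
#' @param sizes subset sizes for the evaluation curve.
#' @param n_class_samples samples per set entering the significance test.
#' @return list with `data`, `models`, `attr_G`, `attr_R`, `map`,
#'   `significance`, `ranked`, `curve`.
#' @export
run_pipeline <- function(config = run_config(), data = NULL, out_dir = NULL,
                         sizes = c(2, 5, 10, 20), n_class_samples = 100) {
  cfg <- config
  if (is.null(data)) data <- synth_tabular(seed = cfg$seed)
  X <- data$features
  labels <- data$labels
  models <- train_reference_models(X, labels, seed = cfg$seed)
  class_b <- X[labels == "B", , drop = FALSE]
  class_a <- X[labels == "A", , drop = FALSE]
  set.seed(cfg$seed)
  gi <- sample.int(nrow(class_b), min(n_class_samples, nrow(class_b)))
  ri <- sample_random_set(nrow(X), min(n_class_samples, nrow(X)),
                          seed = cfg$seed + 1)
  baselines <- config_baselines(cfg, class_a, models$codec)
  path_cfg <- config_path(cfg, models, X)
  attr_G <- class_attributions(models$model, class_b[gi, , drop = FALSE],
                               baselines, path_cfg)
  attr_R <- class_attributions(models$model, X[ri, , drop = FALSE],
                               baselines, path_cfg)
  map <- build_meta_features(X, threshold = cfg$meta_threshold)
  mG <- meta_attributions(attr_G, map)
  mR <- meta_attributions(attr_R, map)
  sig <- significance_test(mG, mR, fwer = cfg$fwer,
                           rank_transform = cfg$rank_transform)
  ranked <- rank_by_attribution(mG)
  known_members <- unique(map$feature_to_group[data$truth$informative])
  enrich <- enrichment_curve(ranked$meta_feature, known_members,
                             universe = length(map$groups))
  curve <- feature_subset_curve(X, labels, "A", "B",
                                ranked$meta_feature, sizes = sizes,
                                metric = "auc", seed = cfg$seed, map = map)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    prov <- list(config_hash = cfg$hash, path = cfg$path_kind,
                 baseline = cfg$baseline, seed = cfg$seed)
    write_attributions(attr_G, file.path(out_dir, "attributions_class.tsv"),
                       extra = list(config_hash = cfg$hash))
    write_attributions(attr_R, file.path(out_dir, "attributions_random.tsv"),
                       extra = list(config_hash = cfg$hash))
    write_meta_features(map, file.path(out_dir, "meta_features.tsv"))
    write_significance(sig, file.path(out_dir, "significance.tsv"),
                       extra = prov)
    write_tsv_prov(enrich, file.path(out_dir, "enrichment_curve.tsv"), prov)
    write_tsv_prov(as.data.frame(curve),
                   file.path(out_dir, "subset_curve.tsv"), prov)
  }
  list(data = data, models = models, attr_G = attr_G, attr_R = attr_R,
       map = map, significance = sig, ranked = ranked, enrichment = enrich,
       curve = curve, config = cfg)
}

#' Run the motif-map pipeline on synthetic sequence data
#'
#' Generates regulated/control splice-region arms, computes per-position
#' motif frequencies, smoothed tracks, sliding-window Fisher tests and
#' CLIP-tag proximity enrichment.
#'
#' @param seed integer seed.
#' @param out_dir optional output directory for the track TSVs.
#' @param ... arguments forwarded to [synth_sequences()].
#' @return list with `data`, `freq_reg`, `freq_ctl`, `windows`, `clip`.
#' @export
run_motifmap <- function(seed = 1, out_dir = NULL, ...) {
  data <- synth_sequences(seed = seed, ...)
  motifs <- data$truth$motifs
  freq_reg <- motif_frequency(data$regulated, motifs)
  freq_ctl <- motif_frequency(data$control, motifs)
  windows <- window_fisher(data$regulated, data$control, motifs)
  clip <- clip_proximity(data$tags, data$events)
  if (!is.null(out_dir))
    write_motif_tracks(freq_reg, freq_ctl, windows, out_dir)
  list(data = data, freq_reg = freq_reg, freq_ctl = freq_ctl,
       windows = windows, clip = clip)
}

#' Run the latent-stability diagnostic
#'
#' Trains several codecs differing in seed (and optionally architecture) on
#' the same data and reports the Spearman stability matrix of their latent
#' pairwise-distance structure.
#'
#' @param features n x p matrix.
#' @param q latent dimensionality.
#' @param seeds integer vector, one codec per seed.
#' @param hidden hidden widths (recycled over seeds).
#' @param epochs training epochs per codec.
#' @return the stability correlation matrix.
#' @export
run_stability <- function(features, q = 8, seeds = 1:3, hidden = 32,
                          epochs = 200) {
  hidden <- rep(hidden, length.out = length(seeds))
  codecs <- lapply(seq_along(seeds), function(i)
    codec_autoencoder(features, q = q, hidden = hidden[i], epochs = epochs,
                      seed = seeds[i]))
  latent_stability(codecs, features)
}
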