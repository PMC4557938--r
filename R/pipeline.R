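#' Assemble the four feature sets from pipeline inputs
#'
#' Builds the genomes-by-features matrix for each feature type:
#' `enzyme_profile` (raw EC function counts), `metabolome` (PRMT scores from
#' the full reaction list), `secondary_metabolome` (PRMT scores from the
#' reaction list restricted to the secondary-metabolism enzyme set) and
#' `transportome` (PRTT scores from the binary transporter-ligand matrix).
#' All scores are taken against the across-genome average reference.
#'
#' @param enzyme_profiles,transporter_profiles Genomes-by-functions count
#'   matrices.
#' @param reactions Reaction data frame ([read_reactions()] layout).
#' @param transportome A binary [interaction_matrix()]
#'   (`mode = "transportome"`).
#' @param secondary_functions Character vector of EC ids forming the
#'   secondary-metabolism subset (`NULL` skips that feature type).
#' @param pseudocount Pseudocount for the log transform.
#' @param normalize,reversible Passed to [build_ein()].
#' @return Named list of feature matrices, one per available feature type.
#' @export
build_feature_sets <- function(enzyme_profiles, transporter_profiles,
                               reactions, transportome,
                               secondary_functions = NULL, pseudocount = 1,
                               normalize = "none", reversible = "forward") {
  ein <- build_ein(reactions, normalize = normalize, reversible = reversible)
  fs <- list(
    enzyme_profile = enzyme_profiles * 1.0,
    metabolome = unclass_scores(
      prmt_scores(ein, enzyme_profiles, pseudocount = pseudocount)),
    transportome = unclass_scores(
      prtt_scores(transportome, transporter_profiles,
                  pseudocount = pseudocount))
  )
  if (!is.null(secondary_functions)) {
    sub <- subset_network(reactions, secondary_functions)
    if (nrow(sub) > 0L) {
      ein2 <- build_ein(sub, normalize = normalize, reversible = reversible)
      fs$secondary_metabolome <- unclass_scores(
        prmt_scores(ein2, enzyme_profiles, pseudocount = pseudocount))
    }
  }
  fs[intersect(c("enzyme_profile", "metabolome", "secondary_metabolome",
                 "transportome"), names(fs))]
}

unclass_scores <- function(s) {
  m <- unclass(s)
  attr(m, "kind") <- NULL
  m
}

#' Run the full factorial niche-prediction pipeline
#'
#' Drives the end-to-end analysis: assembles the feature sets
#' ([build_feature_sets()]), fits a [niche_svm()] per feature type (one
#' binary classifier per niche inside each fit), and collects the F-score
#' summary across the feature-type-by-niche factorial together with the
#' high-weight-feature overlap across niches per feature type. With the four
#' default niches and all four feature types this is the 16-model run.
#' Deterministic given `seed`.
#'
#' @inheritParams build_feature_sets
#' @param labels Genomes-by-niches logical matrix.
#' @param out_dir Optional directory: per-model prediction and weight tables,
#'   the F-score summary, overlap tables and a JSON run manifest (config,
#'   seed, selected costs, config hash — also stamped into every table's
#'   header line) are written there.
#' @param feature_types Which feature types to run (default all four).
#' @param seed Integer seed for all fits.
#' @param ... Further arguments to [niche_svm()] (e.g. `filter_per_fold`,
#'   `cost_grid`, `confidence_mode`).
#' @return A `niche_pipeline` object: list of `fits` (per feature type),
#'   `f_scores` (feature type x niche matrix), `overlap` (per feature type),
#'   `seed` and `config`.
#' @export
run_pipeline <- function(enzyme_profiles, transporter_profiles, reactions,
                         transportome, labels, secondary_functions = NULL,
                         out_dir = NULL,
                         feature_types = c("enzyme_profile", "metabolome",
                                           "secondary_metabolome",
                                           "transportome"),
                         pseudocount = 1, seed = 1, ...) {
  missing_g <- setdiff(rownames(enzyme_profiles), rownames(labels))
  if (length(missing_g))
    stop("genome(s) absent from labels: ", paste(missing_g, collapse = ", "))
  fs <- build_feature_sets(enzyme_profiles, transporter_profiles, reactions,
                           transportome, secondary_functions,
                           pseudocount = pseudocount)
  feature_types <- intersect(feature_types, names(fs))
  config <- list(feature_types = feature_types, pseudocount = pseudocount,
                 seed = seed, extra = list(...))
  cfg_hash <- config_hash(config)

  fits <- list()
  for (ft in feature_types) {
    message(sprintf("[nichecast] fitting %-20s (%d features) ...",
                    ft, ncol(fs[[ft]])))
    fits[[ft]] <- niche_svm(fs[[ft]], labels, seed = seed,
                            feature_type = ft, ...)
  }

  niche_names <- colnames(labels)
  f_scores <- sapply(niche_names, function(nm) {
    vapply(fits, function(fit) {
      f <- fit$niches[[nm]]
      if (is.null(f)) NA_real_ else f$f_score
    }, numeric(1))
  })
  if (is.null(dim(f_scores)))
    f_scores <- matrix(f_scores, nrow = length(fits),
                       dimnames = list(names(fits), niche_names))

  overlap <- lapply(fits, function(fit) {
    sets <- lapply(Filter(Negate(is.null), fit$niches), function(f) {
      names(f$high_weight)[f$high_weight]
    })
    if (length(sets) >= 2L && length(unlist(sets)) > 0L)
      niche_overlap(sets) else NULL
  })

  res <- structure(list(fits = fits, f_scores = f_scores, overlap = overlap,
                        labels = labels, seed = seed, config = config,
                        config_hash = cfg_hash),
                   class = "niche_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

# Stable hash of the run configuration (md5 of its deparsed form).
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config), f)
  unname(tools::md5sum(f))
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- sprintf("# nichecast config_hash=%s seed=%d", res$config_hash,
                   res$seed)
  put <- function(df, name) {
    path <- file.path(out_dir, name)
    con <- file(path, "w")
    writeLines(stamp, con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  for (ft in names(res$fits)) {
    fit <- res$fits[[ft]]
    for (nm in names(fit$niches)) {
      f <- fit$niches[[nm]]
      if (is.null(f)) next
      put(f$predictions, sprintf("predictions_%s_%s.tsv", ft, nm))
      put(data.frame(feature = names(f$weights), weight = f$weights,
                     high_weight = as.integer(f$high_weight),
                     row.names = NULL),
          sprintf("weights_%s_%s.tsv", ft, nm))
    }
    if (!is.null(res$overlap[[ft]]))
      put(res$overlap[[ft]], sprintf("overlap_%s.tsv", ft))
  }
  put(data.frame(feature_type = rownames(res$f_scores), res$f_scores,
                 check.names = FALSE), "f_scores.tsv")
  manifest <- list(
    config = res$config, config_hash = res$config_hash, seed = res$seed,
    costs = lapply(res$fits, function(fit) {
      lapply(Filter(Negate(is.null), fit$niches), function(f) f$cost)
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Verify a pipeline output table against a manifest
#'
#' Refuses tables whose embedded config hash does not match the manifest in
#' the same directory, guarding against mixing intermediates from different
#' runs.
#'
#' @param path A pipeline output TSV.
#' @return The table (header comment stripped) if the hash matches.
#' @export
read_pipeline_table <- function(path) {
  first <- readLines(path, n = 1L)
  manifest_path <- file.path(dirname(path), "manifest.json")
  if (file.exists(manifest_path) && grepl("config_hash=", first)) {
    h <- sub(".*config_hash=(\\S+).*", "\\1", first)
    m <- jsonlite::read_json(manifest_path)
    if (!identical(h, m$config_hash))
      stop("stale intermediate: ", path, " was produced under another config")
  }
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' @export
print.niche_pipeline <- function(x, ...) {
  cat("nichecast pipeline run\n")
  cat(sprintf("seed %d, config hash %s\n", x$seed, x$config_hash))
  cat("\nLOOV F-scores (feature type x niche):\n")
  print(round(x$f_scores, 3))
  invisible(x)
}

#' @export
plot.niche_pipeline <- function(x, ...) {
  graphics::barplot(x$f_scores, beside = TRUE, ylim = c(0, 1),
                    legend.text = rownames(x$f_scores),
                    ylab = "LOOV F-score", ...)
  invisible(x)
}

#' Load a pipeline run configuration from YAML
#'
#' The YAML schema mirrors the arguments of [run_pipeline()] plus input file
#' paths (`enzyme_profiles`, `transporter_profiles`, `reactions`,
#' `transportome`, `labels`, optional `secondary_functions`). Referenced
#' files must exist at validation time.
#'
#' @param path YAML file.
#' @return Named list of validated configuration values.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  cfg <- yaml::read_yaml(path)
  paths <- c("enzyme_profiles", "transporter_profiles", "reactions",
             "transportome", "labels", "secondary_functions")
  for (p in intersect(paths, names(cfg))) {
    if (!file.exists(cfg[[p]]))
      stop("config references a missing file: ", p, " = ", cfg[[p]])
  }
  cfg
}
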