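#' Specification for the synthetic study conditions
#'
#' Bundles every parameter of the synthetic-data generator with defaults that
#' emulate the statistical shape of real genome-derived inputs: overdispersed
#' (negative-binomial) gene-family counts with a realistic zero fraction,
#' a sparse random reaction network, a sparse binary transporter-ligand
#' matrix, and non-exclusive niche labels drawn independently per niche.
#' Discriminative signal is planted as an additive count shift in chosen
#' features of the genomes positive for a niche.
#'
#' @param n_genomes Number of genomes (default 60).
#' @param n_enzyme_functions,n_transporters Function-namespace sizes
#'   (defaults 120 EC functions, 60 KO transporters).
#' @param n_metabolites,n_ligands Compound-namespace sizes (defaults 150
#'   metabolites, 40 ligands).
#' @param reactions_per_function Mean reactions per enzyme function (Poisson,
#'   floored at 1; default 2).
#' @param ligands_per_transporter Mean ligands per transporter (1 plus a
#'   Poisson; default 2).
#' @param count_mean,count_dispersion Negative-binomial baseline of the
#'   per-function gene counts (mean 1.5, size/dispersion 2: about a third of
#'   the cells are zero).
#' @param niches Niche names (default the four rhizosphere roles:
#'   biocontrol, biofilm, plant_pathogen, plant_growth).
#' @param planted Named list (by niche) of planted signals, each a list with
#'   `kind` (`"transporter"` or `"enzyme"`), `n_features` and `effect_size`
#'   (additive count shift in positive genomes). Default: 5 transporter
#'   features with effect size 4 planted for the first niche.
#' @param label_prevalence Per-niche positive fraction (scalar or named
#'   vector; default 0.4). Every niche is forced to keep at least 2 positive
#'   and 2 negative genomes.
#' @param secondary_fraction Fraction of enzyme functions labelled as the
#'   secondary-metabolism subset (default 0.3).
#' @param reversible_fraction Fraction of reactions marked reversible
#'   (default 0.2).
#' @param seed Integer seed; all randomness flows from it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genomes = 60, n_enzyme_functions = 120,
                           n_transporters = 60, n_metabolites = 150,
                           n_ligands = 40, reactions_per_function = 2,
                           ligands_per_transporter = 2, count_mean = 1.5,
                           count_dispersion = 2,
                           niches = c("biocontrol", "biofilm",
                                      "plant_pathogen", "plant_growth"),
                           planted = NULL, label_prevalence = 0.4,
                           secondary_fraction = 0.3,
                           reversible_fraction = 0.2, seed = 1) {
  if (is.null(planted))
    planted <- stats::setNames(
      list(list(kind = "transporter", n_features = 5, effect_size = 4)),
      niches[1])
  stopifnot(n_genomes >= 1, n_enzyme_functions >= 1, n_transporters >= 1,
            n_metabolites >= 1, n_ligands >= 1,
            all(label_prevalence > 0), all(label_prevalence < 1),
            all(names(planted) %in% niches))
  for (p in planted) stopifnot(p$effect_size >= 0,
                               p$kind %in% c("enzyme", "transporter"))
  if (length(label_prevalence) == 1L)
    label_prevalence <- stats::setNames(rep(label_prevalence, length(niches)),
                                        niches)
  structure(list(
    n_genomes = n_genomes, n_enzyme_functions = n_enzyme_functions,
    n_transporters = n_transporters, n_metabolites = n_metabolites,
    n_ligands = n_ligands, reactions_per_function = reactions_per_function,
    ligands_per_transporter = ligands_per_transporter,
    count_mean = count_mean, count_dispersion = count_dispersion,
    niches = niches, planted = planted, label_prevalence = label_prevalence,
    secondary_fraction = secondary_fraction,
    reversible_fraction = reversible_fraction, seed = seed),
    class = "synthetic_spec")
}

#' Generate a synthetic input bundle with planted niche signal
#'
#' Draws every input the pipeline consumes: a reaction list, a binary
#' transporter-ligand matrix, enzyme and transporter count profiles, and
#' non-exclusive niche labels — reproducible bit-for-bit from the spec's
#' seed. For each planted niche, the genomes positive for that niche have the
#' planted features' counts shifted up by `effect_size`. Planted transporters
#' are given one dedicated ligand each (transported by no other transporter)
#' so the signal has an unambiguous ground truth at the score level; the
#' manifest records both the planted functions and those ligands.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `reactions`, `transportome`, `enzyme_profiles`,
#'   `transporter_profiles`, `labels` (logical genomes x niches matrix),
#'   `secondary_functions`, `ground_truth` and the `spec`.
#' @export
synthetic_niche_data <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    genomes <- sprintf("genome_%02d", seq_len(spec$n_genomes))
    ec_ids <- sprintf("%d.%d.%d.%d", sample(1:6, spec$n_enzyme_functions, TRUE),
                      sample(1:9, spec$n_enzyme_functions, TRUE),
                      sample(1:9, spec$n_enzyme_functions, TRUE),
                      seq_len(spec$n_enzyme_functions))
    ko_ids <- sprintf("K%05d", sort(sample.int(99999, spec$n_transporters)))
    met_ids <- sprintf("C%05d", sort(sample.int(49999, spec$n_metabolites)))
    lig_ids <- sprintf("C%05d", 50000 + sort(sample.int(49999, spec$n_ligands)))

    # reaction list: Poisson number of reactions per enzyme function
    rx <- list(); k <- 0L
    for (f in ec_ids) {
      for (r in seq_len(max(1L, rpois(1L, spec$reactions_per_function)))) {
        k <- k + 1L
        rx[[k]] <- list(
          reaction_id = sprintf("R%05d", k), ec = f,
          substrates = sample(met_ids, 1L + rpois(1L, 0.5)),
          products = sample(met_ids, 1L + rpois(1L, 0.5)),
          reversible = runif(1L) < spec$reversible_fraction)
      }
    }
    reactions <- data.frame(
      reaction_id = vapply(rx, `[[`, character(1), "reaction_id"),
      ec = vapply(rx, `[[`, character(1), "ec"),
      substrates = I(lapply(rx, `[[`, "substrates")),
      products = I(lapply(rx, `[[`, "products")),
      reversible = vapply(rx, `[[`, logical(1), "reversible"),
      stringsAsFactors = FALSE)

    # planted features per niche
    planted <- list()
    planted_t <- character(0); planted_e <- character(0)
    for (niche in names(spec$planted)) {
      p <- spec$planted[[niche]]
      pool <- if (p$kind == "transporter") setdiff(ko_ids, planted_t)
      else setdiff(ec_ids, planted_e)
      feats <- p$features %||% sample(pool, p$n_features)
      planted[[niche]] <- list(kind = p$kind, features = feats,
                               effect_size = p$effect_size)
      if (p$kind == "transporter") planted_t <- c(planted_t, feats)
      else planted_e <- c(planted_e, feats)
    }
    if (!all(planted_t %in% ko_ids) || !all(planted_e %in% ec_ids))
      stop("planted feature id(s) outside the generated function namespace")

    # transporter-ligand matrix: planted transporters get one dedicated
    # ligand each; the rest share the remaining pool
    dedicated <- stats::setNames(
      lig_ids[seq_along(planted_t)], planted_t)
    if (length(planted_t) > spec$n_ligands)
      stop("more planted transporters than ligands")
    shared_pool <- setdiff(lig_ids, dedicated)
    T_mat <- matrix(0, spec$n_ligands, spec$n_transporters,
                    dimnames = list(lig_ids, ko_ids))
    for (t in ko_ids) {
      ligs <- if (t %in% planted_t) dedicated[[t]]
      else sample(shared_pool,
                  min(length(shared_pool),
                      1L + rpois(1L, spec$ligands_per_transporter - 1)))
      T_mat[ligs, t] <- 1
    }
    transportome <- interaction_matrix(T_mat, mode = "transportome")
    for (niche in names(planted)) {
      if (planted[[niche]]$kind == "transporter")
        planted[[niche]]$ligands <-
          unname(dedicated[planted[[niche]]$features])
    }

    # labels: independent Bernoulli per niche, forced to >= 2 of each class
    pick_one <- function(idx) idx[sample.int(length(idx), 1L)]
    labels <- sapply(spec$niches, function(nm) {
      y <- rbinom(spec$n_genomes, 1L, spec$label_prevalence[[nm]]) == 1L
      while (sum(y) < 2L) y[pick_one(which(!y))] <- TRUE
      while (sum(!y) < 2L) y[pick_one(which(y))] <- FALSE
      y
    })
    rownames(labels) <- genomes

    draw_counts <- function(p, ids) {
      matrix(rnbinom(spec$n_genomes * p, mu = spec$count_mean,
                     size = spec$count_dispersion),
             spec$n_genomes, p, dimnames = list(genomes, ids))
    }
    enzyme_profiles <- draw_counts(spec$n_enzyme_functions, ec_ids)
    transporter_profiles <- draw_counts(spec$n_transporters, ko_ids)
    for (niche in names(planted)) {
      p <- planted[[niche]]
      pos <- labels[, niche]
      if (p$kind == "transporter")
        transporter_profiles[pos, p$features] <-
          transporter_profiles[pos, p$features] + p$effect_size
      else
        enzyme_profiles[pos, p$features] <-
          enzyme_profiles[pos, p$features] + p$effect_size
    }

    secondary_functions <- sort(sample(ec_ids,
                                       round(spec$secondary_fraction *
                                               spec$n_enzyme_functions)))

    list(reactions = reactions, transportome = transportome,
         enzyme_profiles = enzyme_profiles,
         transporter_profiles = transporter_profiles, labels = labels,
         secondary_functions = secondary_functions,
         ground_truth = list(planted = planted, seed = spec$seed),
         spec = spec)
  })
}

#' Write a synthetic bundle to a directory in the flat-file dialects
#'
#' @param bundle Output of [synthetic_niche_data()] (or
#'   [generate_worked_example()]).
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_synthetic_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_reactions(bundle$reactions, file.path(dir, "reactions.tsv"))
  write_interaction_matrix(bundle$transportome,
                           file.path(dir, "transportome.txt"))
  write_profile_matrix(bundle$enzyme_profiles,
                       file.path(dir, "enzyme_profiles.tsv"))
  write_profile_matrix(bundle$transporter_profiles,
                       file.path(dir, "transporter_profiles.tsv"))
  write_niche_labels(bundle$labels, file.path(dir, "labels.tsv"))
  if (!is.null(bundle$secondary_functions))
    writeLines(bundle$secondary_functions,
               file.path(dir, "secondary_functions.txt"))
  invisible(dir)
}

#' The toy worked example
#'
#' A hand-sized membrane-and-metabolism cartoon used throughout the
#' documentation and round-trip tests: three transporters (`t1` moving
#' extracellular ligands A and B, `t2` moving C, `t3` moving B and C), four
#' enzyme steps chaining the imported compounds into intracellular products,
#' and two genomes — one with a single copy of every function and one with a
#' doubled `t1`. Scoring the doubled-`t1` genome against the average
#' reference yields a positive relative transport score for exactly the
#' ligands A and B.
#'
#' @param dir Optional directory; when given, all files are written there via
#'   [write_synthetic_bundle()].
#' @return The bundle list (reactions, transportome, profiles, labels).
#' @export
generate_worked_example <- function(dir = NULL) {
  transportome <- interaction_matrix(
    matrix(c(1, 1, 0,
             0, 0, 1,
             0, 1, 1),
           nrow = 3, byrow = FALSE,
           dimnames = list(c("A", "B", "C"), c("t1", "t2", "t3"))),
    mode = "transportome")
  reactions <- data.frame(
    reaction_id = c("r1", "r2", "r3", "r4"),
    ec = c("e1", "e2", "e3", "e4"),
    substrates = I(list("A", "B", c("C", "D"), c("E", "F"))),
    products = I(list("D", "E", "F", "G")),
    reversible = FALSE, stringsAsFactors = FALSE)
  enzyme_profiles <- matrix(
    1L, 2, 4, dimnames = list(c("g_reference", "g_doubled_t1"),
                              c("e1", "e2", "e3", "e4")))
  transporter_profiles <- matrix(
    c(1L, 2L, 1L, 1L, 1L, 1L), 2, 3,
    dimnames = list(c("g_reference", "g_doubled_t1"), c("t1", "t2", "t3")))
  labels <- matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2,
                   dimnames = list(c("g_reference", "g_doubled_t1"),
                                   c("biocontrol", "biofilm")))
  bundle <- list(reactions = reactions, transportome = transportome,
                 enzyme_profiles = enzyme_profiles,
                 transporter_profiles = transporter_profiles,
                 labels = labels)
  if (!is.null(dir)) write_synthetic_bundle(bundle, dir)
  bundle
}

#' Read and write niche label tables
#'
#' Wide dialect: tab-separated, first column `genome`, then one 0/1 column
#' per niche. Long dialect (auto-detected on read): three columns `genome`,
#' `niche`, `value`.
#'
#' @param path File path.
#' @return `read_niche_labels()`: logical genomes-by-niches matrix.
#' @export
read_niche_labels <- function(path) {
  stopifnot(file.exists(path))
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "", comment.char = "")
  if (ncol(df) == 3L && all(tolower(names(df)) %in%
                            c("genome", "niche", "value", "label"))) {
    gids <- unique(df[[1]]); niches <- unique(df[[2]])
    m <- matrix(FALSE, length(gids), length(niches),
                dimnames = list(gids, niches))
    m[cbind(match(df[[1]], gids), match(df[[2]], niches))] <- df[[3]] > 0
    m
  } else {
    m <- as.matrix(df[, -1, drop = FALSE]) > 0
    rownames(m) <- df[[1]]
    m
  }
}

#' @rdname read_niche_labels
#' @param labels Logical/0-1 genomes-by-niches matrix to write (wide
#'   dialect).
#' @export
write_niche_labels <- function(labels, path) {
  df <- data.frame(genome = rownames(labels),
                   apply(labels, 2L, as.integer),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
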