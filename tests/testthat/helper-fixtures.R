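# Shared in-code fixtures. Everything is generated; no files ship with the
# tests beyond what the writers themselves produce in tempdirs.

# Minimal hit-table rows in the layout of read_blast_hits() output.
make_hits <- function(query_id, function_id, evalue,
                      bitscore = rep(50, length(query_id)),
                      subject_id = paste0("s", seq_along(query_id),
                                          "|", function_id)) {
  data.frame(query_id = query_id, subject_id = subject_id,
             function_id = function_id, evalue = evalue,
             bitscore = bitscore, stringsAsFactors = FALSE)
}

# Random reaction list over given namespaces.
random_reactions <- function(n, functions, metabolites) {
  data.frame(
    reaction_id = sprintf("R%03d", seq_len(n)),
    ec = sample(functions, n, replace = TRUE),
    substrates = I(replicate(n, sample(metabolites, sample(1:2, 1)),
                             simplify = FALSE)),
    products = I(replicate(n, sample(metabolites, sample(1:2, 1)),
                           simplify = FALSE)),
    reversible = runif(n) < 0.3, stringsAsFactors = FALSE)
}

# Naive per-cell EIN oracle: loop over reactions and metabolites.
ein_oracle <- function(reactions) {
  mets <- sort(unique(unlist(c(reactions$substrates, reactions$products))))
  funs <- sort(unique(reactions$ec))
  M <- matrix(0, length(mets), length(funs), dimnames = list(mets, funs))
  for (i in seq_len(nrow(reactions))) {
    for (m in reactions$products[[i]]) M[m, reactions$ec[i]] <-
        M[m, reactions$ec[i]] + 1
    for (m in reactions$substrates[[i]]) M[m, reactions$ec[i]] <-
        M[m, reactions$ec[i]] - 1
  }
  M
}

# Naive per-compound, per-genome scoring oracle (double loop, no matrix
# algebra): score(g, c) = sum_f M[c, f] * (log2(x_gf + p) - log2(ref_f + p)).
score_oracle <- function(M, profiles, pseudocount = 1) {
  funs <- colnames(M)
  counts <- matrix(0, nrow(profiles), length(funs),
                   dimnames = list(rownames(profiles), funs))
  common <- intersect(funs, colnames(profiles))
  counts[, common] <- profiles[, common]
  ref <- colMeans(counts)
  out <- matrix(NA_real_, nrow(profiles), nrow(M),
                dimnames = list(rownames(profiles), rownames(M)))
  for (g in seq_len(nrow(profiles))) {
    for (cmp in seq_len(nrow(M))) {
      s <- 0
      for (f in seq_along(funs)) {
        s <- s + M[cmp, f] * (log2(counts[g, f] + pseudocount) -
                                log2(ref[f] + pseudocount))
      }
      out[g, cmp] <- s
    }
  }
  out
}

# A small, quickly-fit synthetic study for classifier tests.
small_spec <- function(seed = 11, ...) {
  synthetic_spec(
    n_genomes = 24, n_enzyme_functions = 30, n_transporters = 20,
    n_metabolites = 40, n_ligands = 15,
    niches = c("biocontrol", "biofilm"),
    planted = list(biocontrol = list(kind = "transporter", n_features = 3,
                                     effect_size = 5)),
    seed = seed, ...)
}

# Leaves merged at step k of an hclust tree.
merge_members <- function(hc, k) {
  grab <- function(i) {
    if (i < 0) return(-i)
    c(grab(hc$merge[i, 1]), grab(hc$merge[i, 2]))
  }
  sort(grab(k))
}
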