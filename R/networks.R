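#' Read a reaction list
#'
#' The reaction-list dialect is a five-column tab-separated table:
#' `reaction_id`, `ec` (enzyme function id), `substrates` and `products`
#' (each a `;`-joined metabolite list), `reversible` (0/1). A header row is
#' optional and detected by the literal column name `reaction_id`.
#'
#' @param path File path.
#' @return Data frame with columns `reaction_id`, `ec`, `substrates`,
#'   `products` (list columns of character vectors) and `reversible`
#'   (logical).
#' @export
read_reactions <- function(path) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1L)
  has_header <- grepl("^reaction_id\t", first)
  df <- read.table(path, sep = "\t", header = has_header,
                   col.names = c("reaction_id", "ec", "substrates",
                                 "products", "reversible"),
                   stringsAsFactors = FALSE, quote = "", comment.char = "")
  split_ids <- function(x) {
    lapply(strsplit(x, ";", fixed = TRUE),
           function(v) v[nzchar(v)])
  }
  data.frame(
    reaction_id = df$reaction_id, ec = df$ec,
    substrates = I(split_ids(df$substrates)),
    products = I(split_ids(df$products)),
    reversible = as.logical(as.integer(df$reversible)),
    stringsAsFactors = FALSE
  )
}

#' Write a reaction list in the five-column dialect
#'
#' @param reactions Reaction data frame as from [read_reactions()].
#' @param path Output path.
#' @export
write_reactions <- function(reactions, path) {
  df <- data.frame(
    reaction_id = reactions$reaction_id,
    ec = reactions$ec,
    substrates = vapply(reactions$substrates, paste, character(1),
                        collapse = ";"),
    products = vapply(reactions$products, paste, character(1),
                      collapse = ";"),
    reversible = as.integer(reactions$reversible),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build the enzyme interaction network (EIN) matrix
#'
#' Constructs the metabolite-by-enzyme-function matrix `M` underlying PRMT
#' scoring. The EIN deliberately ignores enzymatic flux, stoichiometric
#' coefficients and mass balance: for each reaction of a function, each
#' product contributes +1 and each substrate -1 to that function's column,
#' summed over the function's reactions. A metabolite appearing on both sides
#' of one reaction therefore contributes net 0 for that reaction.
#'
#' @param reactions Reaction data frame ([read_reactions()] layout: columns
#'   `reaction_id`, `ec`, `substrates`, `products`, `reversible`).
#' @param normalize `"none"` (default) or `"per_function"`, which divides each
#'   column by its number of nonzero entries (the count of metabolites that
#'   function touches), the convention of some upstream turnover-score
#'   generators.
#' @param reversible `"forward"` (default) counts a reversible reaction once
#'   in its annotated direction; `"both"` also adds the mirrored reaction
#'   (substrates and products swapped).
#' @return An `interaction_matrix`: numeric matrix, rows = sorted metabolite
#'   ids, columns = sorted enzyme function ids, with attribute
#'   `mode = "ein"`.
#' @examples
#' rx <- data.frame(reaction_id = c("r1", "r2"), ec = c("e1", "e2"),
#'                  substrates = I(list("A", "B")), products = I(list("B", "C")),
#'                  reversible = c(FALSE, FALSE))
#' build_ein(rx)
#' @export
build_ein <- function(reactions, normalize = c("none", "per_function"),
                      reversible = c("forward", "both")) {
  normalize <- match.arg(normalize)
  reversible <- match.arg(reversible)
  stopifnot(is.data.frame(reactions), nrow(reactions) >= 1L)
  empty <- vapply(seq_len(nrow(reactions)), function(i) {
    length(reactions$substrates[[i]]) + length(reactions$products[[i]]) == 0L
  }, logical(1))
  if (any(empty))
    stop("reaction(s) referencing no metabolites: ",
         paste(reactions$reaction_id[empty], collapse = ", "))
  mets <- sort(unique(unlist(c(reactions$substrates, reactions$products))))
  funs <- sort(unique(reactions$ec))
  M <- matrix(0, length(mets), length(funs), dimnames = list(mets, funs))
  add <- function(j, subs, prods) {
    for (m in unique(prods)) M[m, j] <<- M[m, j] + sum(prods == m)
    for (m in unique(subs)) M[m, j] <<- M[m, j] - sum(subs == m)
  }
  for (i in seq_len(nrow(reactions))) {
    j <- reactions$ec[i]
    add(j, reactions$substrates[[i]], reactions$products[[i]])
    if (reversible == "both" && isTRUE(reactions$reversible[i]))
      add(j, reactions$products[[i]], reactions$substrates[[i]])
  }
  if (normalize == "per_function") {
    nz <- colSums(M != 0)
    nz[nz == 0] <- 1
    M <- sweep(M, 2L, nz, "/")
  }
  interaction_matrix(M, mode = "ein")
}

#' Construct / validate an interaction matrix
#'
#' @param values Numeric matrix with row names (metabolites or ligands) and
#'   column names (enzyme or transporter function ids).
#' @param mode `"ein"` (signed, real-valued) or `"transportome"` (strictly
#'   binary 0/1).
#' @return The matrix with class `interaction_matrix` and a `mode` attribute.
#' @export
interaction_matrix <- function(values, mode = c("ein", "transportome")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate row id(s): ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate column id(s): ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (!all(is.finite(values))) stop("interaction matrix has non-finite cells")
  if (mode == "transportome" && !all(values %in% c(0, 1))) {
    bad <- which(matrix(!(values %in% c(0, 1)), nrow(values)),
                 arr.ind = TRUE)[1, ]
    stop(sprintf("non-binary cell at row '%s', column '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  if (any(colSums(values != 0) == 0))
    warning("all-zero column(s): ",
            paste(colnames(values)[colSums(values != 0) == 0], collapse = ", "))
  structure(values, class = c("interaction_matrix", "matrix", "array"),
            mode_tag = mode)
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("<interaction_matrix> mode=%s: %d compound(s) x %d function(s), %d nonzero cell(s)\n",
              attr(x, "mode_tag"), nrow(x), ncol(x), sum(x != 0)))
  invisible(x)
}

#' Restrict a reaction list to an allowed enzyme-function set
#'
#' Used to derive the secondary-metabolism model: the EIN rebuilt from the
#' subset of reactions whose function belongs to a secondary-metabolite
#' biosynthesis pathway set.
#'
#' @param reactions Reaction data frame.
#' @param allowed_functions Character vector of allowed enzyme function ids.
#' @return The filtered reaction data frame (a warning, not an error, if
#'   empty).
#' @export
subset_network <- function(reactions, allowed_functions) {
  keep <- reactions$ec %in% allowed_functions
  out <- reactions[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("no reactions remain after restriction to the allowed function set")
  out
}

#' Read and write interaction matrices in the flat-table dialect
#'
#' Tab-separated text: header row of function ids, first column of
#' metabolite/ligand ids — the layout commonly used for transporter-ligand
#' specificity tables, so matrices round-trip with the original turnover
#' scripts' inputs.
#'
#' @param path File path.
#' @param mode Validation mode passed to [interaction_matrix()].
#' @return `read_interaction_matrix()`: an `interaction_matrix`.
#' @export
read_interaction_matrix <- function(path, mode = c("ein", "transportome")) {
  mode <- match.arg(mode)
  stopifnot(file.exists(path))
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "", comment.char = "")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate row id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cell(s) in ", path)
  rownames(m) <- ids
  interaction_matrix(m, mode = mode)
}

#' @rdname read_interaction_matrix
#' @param mat Matrix to write.
#' @export
write_interaction_matrix <- function(mat, path) {
  df <- data.frame(compound = rownames(mat), unclass(mat),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a binary transporter-ligand specificity matrix
#'
#' A `1` at (ligand, transporter) means the ligand is transported by a
#' transporter of that annotation, a `0` that it is not; any other cell value
#' is a fatal validation error reported with its coordinates.
#'
#' @param path File path (tab-separated; header row of transporter KO ids,
#'   first column of ligand ids).
#' @return An `interaction_matrix` with `mode = "transportome"`.
#' @export
load_transportome <- function(path) {
  read_interaction_matrix(path, mode = "transportome")
}
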