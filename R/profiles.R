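#' Read a 12-column tabular protein alignment hit table
#'
#' Parses the standard 12-column tab-separated hit format (query, subject,
#' percent identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end, e-value, bit score), the default tabular output of the
#' common protein aligners. Malformed rows are skipped with a warning naming
#' their line numbers; they are never fatal.
#'
#' @param path Path to the tab-separated hit table (no header).
#' @param function_map Optional map from subject identifiers to function
#'   identifiers (EC numbers or KO ids): either a two-column data frame
#'   (subject, function) or a named character vector. When supplied, a
#'   `function_id` column is added; subjects absent from the map get `NA`.
#' @param function_field When no `function_map` is given, the function id is
#'   parsed from the subject id itself: the subject is split on
#'   `function_sep` and element `function_field` is taken. Default `2`, for
#'   headers of the form `proteinid|EC`. Set to `NULL` to leave function ids
#'   unassigned.
#' @param function_sep Separator used with `function_field` (default `"|"`,
#'   fixed, not a regex).
#' @return A data frame of hits with columns `query_id`, `subject_id`,
#'   `pident`, `length`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`,
#'   `send`, `evalue`, `bitscore`, and `function_id` when derivable.
#' @seealso [assign_annotations()]
#' @export
read_blast_hits <- function(path, function_map = NULL, function_field = 2,
                            function_sep = "|") {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, length, integer(1)) >= 12L
  hits <- NULL
  if (any(ok)) {
    mat <- do.call(rbind, lapply(fields[ok], `[`, 1:12))
    hits <- data.frame(
      query_id = mat[, 1], subject_id = mat[, 2],
      pident = as.numeric(mat[, 3]), length = as.integer(mat[, 4]),
      mismatch = as.integer(mat[, 5]), gapopen = as.integer(mat[, 6]),
      qstart = as.integer(mat[, 7]), qend = as.integer(mat[, 8]),
      sstart = as.integer(mat[, 9]), send = as.integer(mat[, 10]),
      evalue = as.numeric(mat[, 11]), bitscore = as.numeric(mat[, 12]),
      stringsAsFactors = FALSE
    )
    bad_num <- is.na(hits$evalue) | is.na(hits$bitscore) | hits$evalue < 0
    if (any(bad_num)) {
      warning(sprintf("skipping %d malformed hit row(s) at line(s): %s",
                      sum(bad_num),
                      paste(which(ok)[bad_num], collapse = ", ")))
      hits <- hits[!bad_num, , drop = FALSE]
    }
  }
  if (any(!ok)) {
    warning(sprintf("skipping %d row(s) with fewer than 12 fields at line(s): %s",
                    sum(!ok), paste(which(!ok), collapse = ", ")))
  }
  if (is.null(hits)) {
    hits <- data.frame(query_id = character(), subject_id = character(),
                       pident = numeric(), length = integer(),
                       mismatch = integer(), gapopen = integer(),
                       qstart = integer(), qend = integer(),
                       sstart = integer(), send = integer(),
                       evalue = numeric(), bitscore = numeric(),
                       stringsAsFactors = FALSE)
  }
  if (!is.null(function_map)) {
    map <- as_function_map(function_map)
    hits$function_id <- unname(map[hits$subject_id])
  } else if (!is.null(function_field)) {
    parts <- strsplit(hits$subject_id, function_sep, fixed = TRUE)
    hits$function_id <- vapply(parts, function(p) {
      if (length(p) >= function_field) p[[function_field]] else NA_character_
    }, character(1))
  }
  hits
}

as_function_map <- function(function_map) {
  if (is.data.frame(function_map)) {
    stopifnot(ncol(function_map) >= 2)
    stats::setNames(as.character(function_map[[2]]),
                    as.character(function_map[[1]]))
  } else if (is.character(function_map) && !is.null(names(function_map))) {
    function_map
  } else {
    stop("'function_map' must be a two-column data frame or a named character vector")
  }
}

#' Assign each query protein its single best annotation
#'
#' Implements the single-best-hit rule: among hits with e-value strictly below
#' the cutoff, a query is assigned the function of its minimum-e-value hit.
#' E-value ties are broken by the higher bit score, remaining ties by the
#' lexicographically smallest subject id, so the assignment is deterministic
#' and invariant to input row order. Queries with no passing hit are absent
#' from the result.
#'
#' @param hits Data frame with columns `query_id`, `subject_id`,
#'   `function_id`, `evalue` and (optionally) `bitscore`, as from
#'   [read_blast_hits()]. Rows with missing `function_id` are ignored.
#' @param evalue_cutoff Strict e-value cutoff (default `1e-10`); only hits
#'   with `evalue < evalue_cutoff` are eligible.
#' @return Named character vector: `query_id -> function_id`.
#' @examples
#' hits <- data.frame(
#'   query_id = c("q1", "q1"), subject_id = c("s1|1.1.1.1", "s2|2.2.2.2"),
#'   function_id = c("1.1.1.1", "2.2.2.2"),
#'   evalue = c(1e-20, 1e-5), bitscore = c(100, 80))
#' assign_annotations(hits)
#' @export
assign_annotations <- function(hits, evalue_cutoff = 1e-10) {
  stopifnot(is.data.frame(hits), evalue_cutoff > 0)
  need <- c("query_id", "subject_id", "function_id", "evalue")
  missing_cols <- setdiff(need, names(hits))
  if (length(missing_cols))
    stop("hits lack column(s): ", paste(missing_cols, collapse = ", "))
  if (is.null(hits$bitscore)) hits$bitscore <- 0
  hits <- hits[!is.na(hits$function_id) & nzchar(hits$function_id) &
                 !is.na(hits$evalue) & hits$evalue < evalue_cutoff, ,
               drop = FALSE]
  if (nrow(hits) == 0L) return(stats::setNames(character(0), character(0)))
  # total order: e-value asc, bitscore desc, subject_id asc
  ord <- order(hits$query_id, hits$evalue, -hits$bitscore, hits$subject_id,
               method = "radix")
  hits <- hits[ord, , drop = FALSE]
  best <- hits[!duplicated(hits$query_id), , drop = FALSE]
  stats::setNames(best$function_id, best$query_id)
}

#' Build a per-genome function-count profile
#'
#' Tallies query-to-function assignments into a count profile. A protein may
#' legitimately appear in both an enzyme and a transporter profile (the two
#' annotation namespaces are independent); the `kind` tag records which
#' namespace a profile lives in.
#'
#' @param assignments Named character vector `query -> function_id`, as from
#'   [assign_annotations()].
#' @param genome_id Genome identifier.
#' @param kind `"enzyme"` (EC namespace) or `"transporter"` (KO namespace).
#' @return A `function_profile`: list with `genome_id`, `kind` and `counts`
#'   (named integer vector, names sorted).
#' @export
build_profile <- function(assignments, genome_id,
                          kind = c("enzyme", "transporter")) {
  kind <- match.arg(kind)
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  counts <- if (length(assignments) == 0L) {
    stats::setNames(integer(0), character(0))
  } else {
    tab <- table(unname(assignments))
    stats::setNames(as.integer(tab), names(tab))
  }
  structure(list(genome_id = genome_id, kind = kind,
                 counts = counts[order(names(counts))]),
            class = "function_profile")
}

#' Merge per-genome profiles into a genomes-by-functions count matrix
#'
#' @param profiles List of `function_profile` objects of the same kind with
#'   unique genome ids.
#' @return Integer matrix, rows = genomes (input order), columns = sorted
#'   union of observed function ids; functions unobserved in a genome are 0.
#' @export
merge_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  kinds <- vapply(profiles, function(p) p$kind, character(1))
  if (length(unique(kinds)) != 1L)
    stop("all profiles must share one kind; got: ",
         paste(unique(kinds), collapse = ", "))
  gids <- vapply(profiles, function(p) p$genome_id, character(1))
  dup <- gids[duplicated(gids)]
  if (length(dup))
    stop("duplicate genome id(s): ", paste(unique(dup), collapse = ", "))
  fids <- sort(unique(unlist(lapply(profiles, function(p) names(p$counts)))))
  mat <- matrix(0L, nrow = length(gids), ncol = length(fids),
                dimnames = list(gids, fids))
  for (p in profiles) mat[p$genome_id, names(p$counts)] <- p$counts
  mat
}

#' Split a profile matrix back into per-genome profiles
#'
#' Inverse of [merge_profiles()] up to zero-count columns, which are dropped
#' from each genome's profile.
#'
#' @param mat Genomes-by-functions count matrix.
#' @param kind Profile kind tag.
#' @return List of `function_profile` objects, one per row.
#' @export
split_profiles <- function(mat, kind = c("enzyme", "transporter")) {
  kind <- match.arg(kind)
  lapply(rownames(mat), function(g) {
    v <- mat[g, ]
    v <- v[v != 0]
    structure(list(genome_id = g, kind = kind,
                   counts = stats::setNames(as.integer(v), names(v))),
              class = "function_profile")
  })
}

#' @export
print.function_profile <- function(x, ...) {
  cat(sprintf("<function_profile> genome %s (%s): %d function(s), %d gene(s)\n",
              x$genome_id, x$kind, length(x$counts), sum(x$counts)))
  invisible(x)
}

#' Read and write genomes-by-functions count matrices
#'
#' The wide dialect is a tab-separated table whose header row holds function
#' ids and whose first column holds genome ids. The long dialect has three
#' columns `genome`, `function`, `count` (with or without a header);
#' `read_profile_matrix()` auto-detects which of the two it is given.
#'
#' @param path File path.
#' @return `read_profile_matrix()`: integer matrix genomes x functions.
#' @export
read_profile_matrix <- function(path) {
  stopifnot(file.exists(path))
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  long <- length(first) == 3L &&
    (identical(tolower(first[3]), "count") ||
       !is.na(suppressWarnings(as.numeric(first[3]))))
  if (long) {
    has_header <- is.na(suppressWarnings(as.numeric(first[3])))
    df <- read.table(path, sep = "\t", header = has_header,
                     col.names = c("genome", "fun", "count"),
                     stringsAsFactors = FALSE, quote = "", comment.char = "")
    gids <- unique(df$genome)
    fids <- sort(unique(df$fun))
    mat <- matrix(0L, length(gids), length(fids),
                  dimnames = list(gids, fids))
    mat[cbind(match(df$genome, gids), match(df$fun, fids))] <-
      as.integer(df$count)
    mat
  } else {
    df <- read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                     check.names = FALSE, stringsAsFactors = FALSE,
                     quote = "", comment.char = "")
    as.matrix(df)
  }
}

#' @rdname read_profile_matrix
#' @param mat Genomes-by-functions matrix to write (wide dialect).
#' @export
write_profile_matrix <- function(mat, path) {
  df <- data.frame(genome = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
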