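## Delimited-text I/O and alignment for the four pipeline tables.
## Files are RFC-4180 CSV, UTF-8, '.' decimal; the first column is the id
## column, the header row names the remaining columns.

.kindConstructors <- list(
  community = CommunityMatrix,
  traits = TraitTable,
  functions = FunctionMatrix,
  environment = EnvironmentTable
)

#' Read a pipeline table from CSV
#'
#' Reads one of the four table kinds (community, traits, functions,
#' environment) from a CSV file whose first column holds the row
#' identifiers. Row and column order are preserved exactly as read, and the
#' result is validated against the kind's invariants (unique ids,
#' non-negative abundances, finite values, ...).
#'
#' @param path path to a CSV file.
#' @param kind one of `"community"`, `"traits"`, `"functions"`,
#'   `"environment"`.
#' @param fill missing-value policy: `"error"` (default) rejects any missing
#'   cell; `"drop"` removes rows containing missing values (never imputes)
#'   and reports them via a warning.
#' @return a validated object of the matching class.
#' @seealso [writeBemfTable()], [alignTables()]
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines("plot_id,spA,spB\np1,2,0\np2,1,1\np3,0,3", tf)
#' readBemfTable(tf, "community")
#' @export
readBemfTable <- function(path, kind = c("community", "traits", "functions",
                                         "environment"),
                          fill = c("error", "drop")) {
  kind <- match.arg(kind)
  fill <- match.arg(fill)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = NA)
  if (ncol(df) < 2)
    stop("expected an id column plus at least one data column in ", path,
         call. = FALSE)
  ids <- as.character(df[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate identifiers in ", basename(path), ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  vals <- df[, -1, drop = FALSE]
  # locate non-numeric cells before coercion so errors carry row/col
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (is.character(col)) {
      conv <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(conv) & !is.na(col) & trimws(col) != "" &
                     !toupper(trimws(col)) %in% c("NA", "NAN"))
      if (length(bad))
        stop(sprintf("non-numeric value %s at row '%s', column '%s' in %s",
                     dQuote(col[bad[1]]), ids[bad[1]], names(vals)[j],
                     basename(path)), call. = FALSE)
      vals[[j]] <- conv
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (anyNA(m)) {
    if (fill == "error") {
      idx <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop(sprintf("missing value at row '%s', column '%s' in %s (use fill = \"drop\" to remove incomplete rows)",
                   rownames(m)[idx[1]], colnames(m)[idx[2]], basename(path)),
           call. = FALSE)
    }
    bad <- rownames(m)[apply(m, 1, anyNA)]
    warning("dropping rows with missing values: ", paste(bad, collapse = ", "),
            call. = FALSE)
    m <- m[!rownames(m) %in% bad, , drop = FALSE]
  }
  .kindConstructors[[kind]](m)
}

#' Write a pipeline table to CSV
#'
#' Inverse of [readBemfTable()]: writes the matrix with its row identifiers
#' as the first column. A write/read round trip reproduces the values.
#'
#' @param x a [CommunityMatrix-class], [TraitTable-class],
#'   [FunctionMatrix-class], [EnvironmentTable-class] or
#'   [DiversityTable-class].
#' @param path output file path.
#' @param idName header for the identifier column.
#' @return `path`, invisibly.
#' @export
writeBemfTable <- function(x, path, idName = "plot_id") {
  if (is(x, "DiversityTable")) {
    df <- as.data.frame(x)
  } else {
    m <- x@.Data
    if (is(x, "TraitTable") && identical(idName, "plot_id"))
      idName <- "species_id"
    df <- data.frame(rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[1] <- idName
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align community, function and environment tables on shared plots
#'
#' Restricts all plot-indexed tables to the intersection of their plot ids
#' and puts them in a single canonical order: the order of the community
#' table. Dropped ids are recorded per table. Matching is exact and
#' case-sensitive. Alignment is idempotent.
#'
#' @param community a [CommunityMatrix-class].
#' @param functions a [FunctionMatrix-class].
#' @param environment an optional [EnvironmentTable-class].
#' @param traits an optional [TraitTable-class], carried through unchanged
#'   (traits are species-indexed, not plot-indexed).
#' @return a [BemfData-class] bundle.
#' @examples
#' com <- CommunityMatrix(matrix(1, 3, 2, dimnames = list(c("a","b","c"),
#'                                                        c("s1","s2"))))
#' fun <- FunctionMatrix(matrix(rnorm(6), 3, 2,
#'                              dimnames = list(c("b","c","d"), c("F1","F2"))))
#' droppedIds(alignTables(com, fun))
#' @export
alignTables <- function(community, functions, environment = NULL,
                        traits = NULL) {
  stopifnot(is(community, "CommunityMatrix"), is(functions, "FunctionMatrix"))
  idSets <- list(community = plotIds(community),
                 functions = plotIds(functions))
  if (!is.null(environment)) {
    stopifnot(is(environment, "EnvironmentTable"))
    idSets$environment <- plotIds(environment)
  }
  keep <- Reduce(intersect, idSets)
  if (!length(keep))
    stop("tables share no plot ids; nothing to align", call. = FALSE)
  # canonical order: as the community table lists them
  keep <- idSets$community[idSets$community %in% keep]
  dropped <- lapply(idSets, function(ids) setdiff(ids, keep))
  com <- CommunityMatrix(community@.Data[keep, , drop = FALSE])
  fun <- FunctionMatrix(functions@.Data[keep, , drop = FALSE])
  env <- if (is.null(environment)) NULL
         else EnvironmentTable(environment@.Data[keep, , drop = FALSE])
  new("BemfData", community = com, traits = traits, functions = fun,
      environment = env, dropped = dropped)
}

#' Validate a set of pipeline tables together
#'
#' Cross-table checks used by the command-line `validate` entry point:
#' every table valid on its own, every species present in the community
#' covered by the trait table, and a non-empty plot intersection.
#'
#' @param community a [CommunityMatrix-class].
#' @param traits an optional [TraitTable-class].
#' @param functions an optional [FunctionMatrix-class].
#' @param environment an optional [EnvironmentTable-class].
#' @return character vector of problems; empty when everything checks out.
#' @export
validateBundle <- function(community, traits = NULL, functions = NULL,
                           environment = NULL) {
  problems <- character(0)
  if (!is.null(traits)) {
    present <- speciesIds(community)[colSums(abundance(community) > 0) > 0]
    missing <- setdiff(present, speciesIds(traits))
    if (length(missing))
      problems <- c(problems, paste0("species present but absent from trait table: ",
                                     paste(missing, collapse = ", ")))
  }
  for (tab in list(functions, environment)) {
    if (is.null(tab)) next
    shared <- intersect(plotIds(community), plotIds(tab))
    if (!length(shared))
      problems <- c(problems, paste0("no shared plot ids between community and ",
                                     class(tab)))
    else if (length(shared) < length(plotIds(community)))
      problems <- c(problems,
                    paste0(class(tab), " misses plots: ",
                           paste(setdiff(plotIds(community), shared),
                                 collapse = ", ")))
  }
  problems
}
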