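# Reading and writing labelled adjacency matrices and edge lists.
# Conventions fixed here and relied on everywhere else:
#   * rows = consumers, columns = resources;
#   * blank body cells read as 0 (spreadsheet exports often omit zeros);
#   * labels are case-sensitive exact strings, never normalised.

#' Read a labelled adjacency matrix as a FoodWeb
#'
#' Expects a header row and a header column of species labels; body cells must
#' be 0, 1 or blank (blank is read as 0).  Row and column labels must agree in
#' order.  Because the direction convention of third-party matrix files is not
#' always documented, `transpose = TRUE` flips the matrix after reading for
#' files stored as resource-by-consumer.
#'
#' @param path file to read.
#' @param dialect `"csv"` or `"tsv"`.
#' @param transpose flip the matrix after reading (for files whose rows are
#'   resources rather than consumers).
#' @return a validated [FoodWeb-class].
#' @seealso [writeAdjacency()], [readEdgelist()]
#' @export
readAdjacency <- function(path, dialect = c("csv", "tsv"), transpose = FALSE) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", na.strings = NULL)
  if (ncol(raw) < 2L)
    stop("adjacency file must have a label column and at least one species column")
  labs <- raw[[1L]]
  body <- as.matrix(raw[, -1L, drop = FALSE])
  cols <- colnames(body)
  if (nrow(body) != ncol(body))
    stop(sprintf("adjacency matrix is not square: %d rows, %d columns",
                 nrow(body), ncol(body)))
  if (anyDuplicated(labs))
    stop(sprintf("duplicate row labels: %s",
                 paste(unique(labs[duplicated(labs)]), collapse = ", ")))
  if (!identical(labs, cols)) {
    bad <- which(labs != cols)[1L]
    stop(sprintf(
      "row/column label mismatch at position %d: row '%s' vs column '%s'",
      bad, labs[bad], cols[bad]))
  }
  body[body == "" | is.na(body)] <- "0"
  ok <- body %in% c("0", "1")
  if (!all(ok)) {
    idx <- arrayInd(which(!ok)[1L], dim(body))
    stop(sprintf("non-binary cell '%s' at row '%s', column '%s'",
                 body[idx], labs[idx[1L]], cols[idx[2L]]))
  }
  a <- matrix(as.integer(body), nrow(body), ncol(body),
              dimnames = list(labs, labs))
  if (transpose) a <- t(a)
  FoodWeb(a)
}

#' Read a two-column edge list as a FoodWeb
#'
#' Each line is `consumer<sep>resource`.  The node set is the union of all
#' labels in order of first appearance; duplicate edges collapse to one.
#' Self-loops (cannibalism) are allowed.
#'
#' @param path file to read.
#' @param sep field separator (default tab).
#' @return a validated [FoodWeb-class].
#' @export
readEdgelist <- function(path, sep = "\t") {
  el <- tryCatch(
    utils::read.table(path, sep = sep, header = FALSE, check.names = FALSE,
                      colClasses = "character", quote = "\"",
                      comment.char = ""),
    error = function(e) stop("empty or unreadable edge list: ",
                             conditionMessage(e)))
  if (nrow(el) == 0L) stop("empty edge list")
  if (ncol(el) < 2L) stop("edge list must have two columns: consumer, resource")
  consumer <- el[[1L]]; resource <- el[[2L]]
  labs <- unique(c(rbind(consumer, resource)))
  a <- matrix(0L, length(labs), length(labs), dimnames = list(labs, labs))
  a[cbind(match(consumer, labs), match(resource, labs))] <- 1L
  FoodWeb(a)
}

#' Write a FoodWeb as a labelled adjacency matrix
#'
#' The output has a header row and header column of labels and re-reads
#' bit-exactly with [readAdjacency()].
#'
#' @param web a [FoodWeb-class].
#' @param path destination file.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
setMethod("writeAdjacency", "FoodWeb", function(web, path,
                                                dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  utils::write.table(web@adj, file = path, sep = sep, col.names = NA,
                     row.names = TRUE, quote = TRUE)
  invisible(path)
})

#' Read a species table
#'
#' A CSV with columns `label`, `name`, `category` (one row per species).
#' When `web` is supplied, the table's labels are checked against the web.
#'
#' @param path file to read.
#' @param web optional [FoodWeb-class] to validate labels against.
#' @return data.frame with columns label, name, category.
#' @export
readSpeciesTable <- function(path, web = NULL) {
  tab <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character")
  need <- c("label", "name", "category")
  if (!all(need %in% names(tab)))
    stop("species table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$label))
    stop("species table has duplicate labels")
  if (!is.null(web)) {
    missing <- setdiff(speciesLabels(web), tab$label)
    if (length(missing))
      stop("species table is missing web labels: ",
           paste(missing, collapse = ", "))
  }
  tab[need]
}
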