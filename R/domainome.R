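#' Create a domainome
#'
#' A domainome is the set of distinct protein-domain types in one genome —
#' extant, ancestral, or a merged meta-organism.
#'
#' @param label genome or node name.
#' @param domains character vector of domain accessions; duplicates removed.
#' @return An object of class `domainome`.
#' @export
domainome <- function(label, domains = character()) {
  structure(list(label = as.character(label)[1L],
                 domains = sort(unique(as.character(domains)))),
            class = "domainome")
}

#' @export
print.domainome <- function(x, ...) {
  cat(sprintf("domainome '%s': %d distinct domains\n",
              x$label, length(x$domains)))
  invisible(x)
}

#' @export
length.domainome <- function(x) length(x$domains)

#' Merge domainomes into a meta-organism repertoire
#'
#' The union of the input domain sets under a new label, e.g. a host genome
#' merged with its gut commensals.
#'
#' @param domainomes list of [domainome()] objects (at least one).
#' @param label label of the merged repertoire.
#' @return A [domainome()].
#' @export
merge_domainomes <- function(domainomes, label = "merged") {
  stopifnot(length(domainomes) >= 1L)
  domainome(label, unlist(lapply(domainomes, function(d) d$domains),
                          use.names = FALSE))
}

#' Build a taxon-by-domain presence/absence matrix
#'
#' Rows are taxa in input order; columns are domain accessions in
#' lexicographic order. Domains absent from every taxon are dropped with a
#' warning: Dollo parsimony has no event to place for them.
#'
#' @param domainomes list of [domainome()] objects with unique labels.
#' @return A binary integer matrix of class `presence_matrix` with taxon
#'   row names and accession column names.
#' @export
build_matrix <- function(domainomes) {
  labels <- vapply(domainomes, function(d) d$label, "")
  if (anyDuplicated(labels))
    stop("duplicate domainome labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  all_dom <- sort(unique(unlist(lapply(domainomes, function(d) d$domains),
                                use.names = FALSE)))
  m <- matrix(0L, nrow = length(labels), ncol = length(all_dom),
              dimnames = list(labels, all_dom))
  for (i in seq_along(domainomes))
    m[i, domainomes[[i]]$domains] <- 1L
  empty <- colSums(m) == 0L
  if (any(empty)) {
    warning(sprintf("dropping %d all-absent domain column(s)", sum(empty)))
    m <- m[, !empty, drop = FALSE]
  }
  class(m) <- c("presence_matrix", class(m))
  m
}

#' Extract one taxon's domain set from a presence matrix
#' @param matrix a `presence_matrix`.
#' @param taxon row label.
#' @return Character vector of accessions present in that taxon.
#' @export
matrix_row_domains <- function(matrix, taxon) {
  if (!taxon %in% rownames(matrix)) stop("unknown taxon: ", taxon)
  colnames(matrix)[matrix[taxon, ] == 1L]
}

#' Write / read a presence matrix as TSV
#'
#' Header row of domain accessions (first cell `taxon`), one 0/1 row per
#' taxon.
#'
#' @param matrix a `presence_matrix`.
#' @param path file path.
#' @export
write_matrix_tsv <- function(matrix, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("taxon", colnames(matrix)), collapse = "\t"), con)
  for (i in seq_len(nrow(matrix)))
    writeLines(paste(c(rownames(matrix)[i], matrix[i, ]), collapse = "\t"),
               con)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1L]]
  if (!all(m %in% c(0L, 1L)))
    stop("presence matrix cells must be 0/1: ", path)
  class(m) <- c("presence_matrix", class(m))
  m
}

#' Write / read a domainome as a one-accession-per-line file
#' @param x a [domainome()].
#' @param path file path.
#' @export
write_domainome <- function(x, path) {
  writeLines(x$domains, path)
  invisible(path)
}

#' @rdname write_domainome
#' @param label label for the loaded domainome (default: file base name).
#' @export
read_domainome <- function(path, label = NULL) {
  if (is.null(label))
    label <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  domainome(label, lines[nzchar(trimws(lines)) & !grepl("^#", lines)])
}
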