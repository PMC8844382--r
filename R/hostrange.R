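#' Construct a host-range matrix
#'
#' A host-range matrix records, for a panel of bacterial strains (rows) and a
#' collection of phages (columns), which phage lyses which strain. Cells may be
#' quantitative (e.g. efficiency-of-plating scores); a binarized view is kept
#' alongside the raw values, with a cell counted as lytic when its value is
#' strictly greater than `threshold`.
#'
#' @param cells numeric matrix of non-negative values with unique, non-empty
#'   row names (bacterial strain labels) and column names (phage labels).
#' @param threshold non-negative number; cells strictly greater than this
#'   binarize to 1 (lytic), all others to 0. Default 0: any lysis counts.
#' @return an object of class `host_range_matrix`: a list with elements
#'   `cells` (the raw numeric matrix), `binary` (the 0/1 integer view),
#'   and `threshold`.
#' @examples
#' m <- matrix(c(1, 0, 0, 1), 2, 2,
#'             dimnames = list(c("b1", "b2"), c("p1", "p2")))
#' hrm <- host_range_matrix(m)
#' n_lytic(hrm)
#' @export
host_range_matrix <- function(cells, threshold = 0) {
  if (!is.matrix(cells) || !is.numeric(cells))
    stop("`cells` must be a numeric matrix", call. = FALSE)
  if (nrow(cells) < 1L || ncol(cells) < 1L)
    stop("host-range matrix must have at least one bacterium and one phage",
         call. = FALSE)
  bac <- rownames(cells)
  phg <- colnames(cells)
  if (is.null(bac) || is.null(phg))
    stop("`cells` must carry row names (bacteria) and column names (phages)",
         call. = FALSE)
  check_ids(bac, "bacterium")
  check_ids(phg, "phage")
  if (anyNA(cells) || any(!is.finite(cells)))
    stop("cells must be finite and non-missing", call. = FALSE)
  if (any(cells < 0))
    stop("cells must be non-negative", call. = FALSE)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    stop("`threshold` must be a single non-negative number", call. = FALSE)
  bin <- matrix(as.integer(cells > threshold), nrow(cells), ncol(cells),
                dimnames = dimnames(cells))
  structure(list(cells = cells, binary = bin, threshold = threshold),
            class = "host_range_matrix")
}

check_ids <- function(ids, what) {
  if (any(is.na(ids)) || any(!nzchar(trimws(ids))))
    stop(sprintf("empty %s label", what), call. = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop(sprintf("duplicate %s label(s): %s", what,
                 paste(dQuote(dup, FALSE), collapse = ", ")), call. = FALSE)
  invisible(ids)
}

#' @export
print.host_range_matrix <- function(x, ...) {
  cat(sprintf("host-range matrix: %d bacteria x %d phages, %d lytic cells (fill %.1f%%)\n",
              n_bacteria(x), n_phages(x), n_lytic(x),
              100 * n_lytic(x) / length(x$binary)))
  if (x$threshold != 0)
    cat(sprintf("  binarization threshold: > %g\n", x$threshold))
  invisible(x)
}

#' Host-range matrix accessors
#'
#' @param x a `host_range_matrix` (or an object carrying one, such as a
#'   [build_pbin()] result).
#' @return `bacteria_ids()` / `phage_ids()` return character vectors of axis
#'   labels; `n_bacteria()` / `n_phages()` their lengths; `n_lytic()` the
#'   number of lytic (binarized 1) cells.
#' @export
bacteria_ids <- function(x) rownames(as_hrm(x)$binary)

#' @rdname bacteria_ids
#' @export
phage_ids <- function(x) colnames(as_hrm(x)$binary)

#' @rdname bacteria_ids
#' @export
n_bacteria <- function(x) nrow(as_hrm(x)$binary)

#' @rdname bacteria_ids
#' @export
n_phages <- function(x) ncol(as_hrm(x)$binary)

#' @rdname bacteria_ids
#' @export
n_lytic <- function(x) sum(as_hrm(x)$binary)

as_hrm <- function(x) {
  if (inherits(x, "host_range_matrix")) return(x)
  if (inherits(x, "pbin")) return(x$matrix)
  stop("expected a host_range_matrix or pbin object", call. = FALSE)
}

#' Read a host-range matrix from delimited text
#'
#' Reads a delimited text file with one header row of column labels and one
#' leading column of row labels, auto-detecting the delimiter among tab,
#' comma and semicolon. The matrix is returned in canonical orientation
#' (rows = bacteria, columns = phages); use `orientation = "rows_are_phages"`
#' for transposed sources.
#'
#' @param path path to a delimited text file (UTF-8).
#' @param orientation `"rows_are_bacteria"` (default) or `"rows_are_phages"`.
#' @param threshold binarization threshold passed to [host_range_matrix()].
#' @param delim optional explicit delimiter; when `NULL` it is auto-detected.
#' @return a [host_range_matrix()].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("\tp1\tp2", "b1\t1\t0", "b2\t0\t1"), tf)
#' read_host_range(tf)
#' @export
read_host_range <- function(path,
                            orientation = c("rows_are_bacteria", "rows_are_phages"),
                            threshold = 0, delim = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path))
    stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop(sprintf("parse error in %s: need a header row and at least one data row",
                 path), call. = FALSE)
  if (is.null(delim)) delim <- detect_delim(lines[1:min(5L, length(lines))])
  fields <- strsplit(lines, delim, fixed = TRUE)
  nf <- lengths(fields)
  body_n <- nf[-1L]
  if (length(unique(body_n)) != 1L)
    stop(sprintf("parse error in %s: ragged rows (field counts %s)",
                 path, paste(sort(unique(nf)), collapse = "/")), call. = FALSE)
  # header may or may not carry a label for the row-name corner cell
  header <- fields[[1L]]
  if (nf[1L] == body_n[1L]) header <- header[-1L]
  else if (nf[1L] != body_n[1L] - 1L)
    stop(sprintf("parse error in %s: header has %d fields but rows have %d",
                 path, nf[1L], body_n[1L]), call. = FALSE)
  col_ids <- trimws(header)
  row_ids <- trimws(vapply(fields[-1L], `[[`, "", 1L))
  vals <- lapply(fields[-1L], function(f) suppressWarnings(as.numeric(f[-1L])))
  for (i in seq_along(vals)) {
    bad <- which(is.na(vals[[i]]))
    if (length(bad))
      stop(sprintf("parse error in %s: non-numeric cell at row %s, column %s",
                   path, dQuote(row_ids[i], FALSE),
                   dQuote(col_ids[bad[1L]], FALSE)), call. = FALSE)
  }
  cells <- do.call(rbind, vals)
  dimnames(cells) <- list(row_ids, col_ids)
  if (orientation == "rows_are_phages") cells <- t(cells)
  host_range_matrix(cells, threshold = threshold)
}

detect_delim <- function(lines) {
  cands <- c("\t", ",", ";")
  n_hits <- function(line, d) {
    m <- gregexpr(d, line, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) 0L else length(m)
  }
  # a delimiter must appear on every line; prefer the most frequent one
  counts <- vapply(cands, function(d)
    min(vapply(lines, n_hits, integer(1L), d = d)), integer(1L))
  if (all(counts == 0L))
    stop("could not detect delimiter (none of tab/comma/semicolon present)",
         call. = FALSE)
  cands[which.max(counts)]
}

#' Write and re-import lytic interactions as an edge list
#'
#' `write_edge_list()` writes one tab-separated row per lytic cell, phage
#' first, matching the phage-to-bacterium direction of the infection network.
#' `matrix_from_edges()` rebuilds the binary matrix from such edges given the
#' full axis label sets (edge lists alone cannot recover resistant bacteria
#' or non-infecting phages).
#'
#' @param x a [host_range_matrix()] or [build_pbin()] result.
#' @param path output file path.
#' @return `write_edge_list()` invisibly returns the number of edges written;
#'   `matrix_from_edges()` returns a [host_range_matrix()].
#' @export
write_edge_list <- function(x, path) {
  hrm <- as_hrm(x)
  idx <- which(hrm$binary == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
  df <- data.frame(phage = phage_ids(hrm)[idx[, 2L]],
                   bacterium = bacteria_ids(hrm)[idx[, 1L]])
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop(sprintf("cannot write edge list to %s: %s", path,
                 conditionMessage(ok)), call. = FALSE)
  invisible(nrow(df))
}

#' @rdname write_edge_list
#' @param edges data frame with columns `phage` and `bacterium`, as written by
#'   `write_edge_list()` (e.g. read back with `read.delim()`).
#' @param bacteria,phages character vectors giving the complete axis label sets.
#' @export
matrix_from_edges <- function(edges, bacteria, phages) {
  stopifnot(is.data.frame(edges), all(c("phage", "bacterium") %in% names(edges)))
  if (!all(edges$bacterium %in% bacteria) || !all(edges$phage %in% phages))
    stop("edge list refers to labels absent from the supplied axis sets",
         call. = FALSE)
  cells <- matrix(0, length(bacteria), length(phages),
                  dimnames = list(bacteria, phages))
  if (nrow(edges))
    cells[cbind(match(edges$bacterium, bacteria), match(edges$phage, phages))] <- 1
  host_range_matrix(cells)
}
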