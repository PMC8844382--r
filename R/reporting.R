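#' Run the full cocktail-design pipeline over a collection of matrices
#'
#' For each input: build the PBIN, run both cocktail searches, extract the
#' PCN of the exhaustive cocktail, and compute efficacy and redundancy
#' statistics. Inputs that fail to parse or analyse are reported with a
#' warning and skipped; the batch fails only if nothing succeeds. Character
#' inputs are treated as file paths (processed in sorted order for
#' determinism); a list of `host_range_matrix` objects is analysed directly.
#'
#' @param inputs character vector of matrix file paths, or a (optionally
#'   named) list of [host_range_matrix()] objects.
#' @param max_size exhaustive-search size cap (default 12); when coverage is
#'   incomplete at the cap a warning is issued and `mcs` is reported as `NA`.
#' @param threshold binarization threshold for file inputs.
#' @param out_dir optional directory; when given, a JSON detail report per
#'   dataset is written there.
#' @return a data frame with one row per analysed input: `dataset`,
#'   `n_bacteria`, `n_phages`, `fill_percent`, `mcs`, `heuristic_size`,
#'   `efficacy_percent`, `median_rv`. The per-dataset `pcn` and cocktail
#'   objects are attached as attribute `"details"`.
#' @export
batch_analyze <- function(inputs, max_size = 12L, threshold = 0,
                          out_dir = NULL) {
  if (is.character(inputs)) {
    inputs <- sort(inputs)
    nm <- basename(inputs)
    loader <- function(i) read_host_range(inputs[i], threshold = threshold)
  } else if (is.list(inputs) && length(inputs)) {
    nm <- if (!is.null(names(inputs))) names(inputs)
          else sprintf("dataset%02d", seq_along(inputs))
    loader <- function(i) inputs[[i]]
  } else stop("`inputs` must be file paths or a list of host-range matrices",
              call. = FALSE)
  if (!length(inputs)) stop("no inputs", call. = FALSE)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  rows <- list(); details <- list()
  for (i in seq_along(inputs)) {
    res <- tryCatch(
      analyze_one(loader(i), nm[i], max_size = max_size),
      error = function(e) {
        warning(sprintf("skipping %s: %s", nm[i], conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    if (is.null(res)) next
    rows[[length(rows) + 1L]] <- res$summary
    details[[nm[i]]] <- res
    if (!is.null(out_dir))
      write_dataset_report(res, file.path(out_dir, paste0(nm[i], ".json")))
  }
  if (!length(rows)) stop("no input could be analysed", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "details") <- details
  out
}

analyze_one <- function(hrm, name, max_size = 12L) {
  pbin <- build_pbin(hrm)
  cmp <- compare_methods(pbin, max_size = max_size)
  exh <- cmp$exhaustive
  if (!exh$complete)
    warning(sprintf("%s: exhaustive search incomplete at size cap %d", name,
                    max_size), call. = FALSE)
  pcn <- extract_pcn(pbin, exh)
  rec <- redundancy_records(pcn)
  summary <- data.frame(
    dataset = name,
    n_bacteria = n_bacteria(pbin),
    n_phages = n_phages(pbin),
    fill_percent = 100 * pbin$fill,
    mcs = if (exh$complete) exh$size else NA_integer_,
    heuristic_size = cmp$heuristic$size,
    efficacy_percent = efficacy(pbin, exh),
    median_rv = if (nrow(rec)) stats::median(rec$rv) else NA_real_)
  list(summary = summary, pbin = pbin, comparison = cmp, pcn = pcn,
       redundancy = rec)
}

write_dataset_report <- function(res, path) {
  report <- list(
    dataset = res$summary$dataset,
    network = network_descriptors(res$pbin),
    heuristic = cocktail_report(res$comparison$heuristic),
    exhaustive = cocktail_report(res$comparison$exhaustive),
    efficacy_percent = res$summary$efficacy_percent,
    redundancy = res$redundancy)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' JSON-ready description of a cocktail
#'
#' @param cocktail a `cocktail` object.
#' @return a list mirroring the cocktail fields (`method`, `phages`, `size`,
#'   `complete`, `n_covered`, `n_susceptible`, `per_size_trace`), suitable
#'   for `jsonlite::write_json()`.
#' @export
cocktail_report <- function(cocktail) {
  stopifnot(inherits(cocktail, "cocktail"))
  list(method = cocktail$method, phages = cocktail$phages,
       size = cocktail$size, complete = cocktail$complete,
       n_covered = cocktail$n_covered, n_susceptible = cocktail$n_susceptible,
       per_size_trace = cocktail$per_size_trace)
}

#' Spearman rank correlations between dataset descriptors
#'
#' Computes Spearman's rank correlation (average ranks for ties, two-sided
#' p-value) for each requested pair of numeric descriptor columns. Pairs
#' involving a constant column are omitted with a warning, since rank
#' correlation is undefined there.
#'
#' @param summaries a data frame of per-dataset descriptors (e.g. from
#'   [batch_analyze()]); at least 3 rows.
#' @param pairs either `NULL` (all unordered pairs of numeric columns) or a
#'   two-column character matrix / list of length-2 character vectors naming
#'   descriptor pairs.
#' @return a data frame with columns `var1`, `var2`, `rho`, `p_value`, `n`.
#' @export
correlate_summaries <- function(summaries, pairs = NULL) {
  stopifnot(is.data.frame(summaries))
  if (nrow(summaries) < 3L)
    stop("need at least 3 summaries to correlate", call. = FALSE)
  num <- names(summaries)[vapply(summaries, is.numeric, TRUE)]
  if (is.null(pairs)) {
    if (length(num) < 2L) stop("fewer than two numeric descriptors", call. = FALSE)
    pairs <- t(utils::combn(num, 2L))
  } else if (is.list(pairs)) {
    pairs <- do.call(rbind, pairs)
  }
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2L)
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    v1 <- pairs[i, 1L]; v2 <- pairs[i, 2L]
    if (!all(c(v1, v2) %in% names(summaries)))
      stop(sprintf("unknown descriptor in pair (%s, %s)", v1, v2), call. = FALSE)
    x <- summaries[[v1]]; y <- summaries[[v2]]
    ok <- stats::complete.cases(x, y)
    if (length(unique(x[ok])) < 2L || length(unique(y[ok])) < 2L) {
      warning(sprintf("descriptor pair (%s, %s) has a constant column; omitted",
                      v1, v2), call. = FALSE)
      next
    }
    ct <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
    out[[length(out) + 1L]] <- data.frame(
      var1 = v1, var2 = v2, rho = unname(ct$estimate),
      p_value = ct$p.value, n = sum(ok))
  }
  if (!length(out)) stop("no computable descriptor pairs", call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' JSON network summary of a PBIN
#'
#' @param pbin a [build_pbin()] result.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_network_summary <- function(pbin, path) {
  desc <- network_descriptors(pbin)
  desc$ei_phage <- as.list(pbin$ei_phage)
  desc$ei_bacterium <- as.list(pbin$ei_bacterium)
  jsonlite::write_json(desc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
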