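#' Metadata for the 50-dataset host-range corpus
#'
#' The package ships a transcription of the published corpus of 50
#' experimental host-range matrices (dataset name, number of bacterial hosts,
#' number of phages, matrix size). The raw matrices themselves are not
#' redistributed; the metadata feed corpus-level summary statistics and the
#' synthetic generator's notion of a realistic size distribution.
#'
#' @return a data frame with 50 rows and columns `dataset`, `n_hosts`,
#'   `n_phages`, `matrix_size`.
#' @examples
#' meta <- load_table1_metadata()
#' summarize_corpus_metadata(meta)
#' @export
load_table1_metadata <- function() {
  path <- system.file("extdata", "table1_metadata.tsv", package = "cocktailnet")
  if (!nzchar(path) || !file.exists(path))
    stop("corpus metadata fixture is missing from the installed package",
         call. = FALSE)
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("dataset", "n_hosts", "n_phages", "matrix_size")
  if (!identical(names(meta), need) || nrow(meta) != 50L)
    stop("corpus metadata fixture is corrupt", call. = FALSE)
  if (!all(meta$matrix_size == meta$n_hosts * meta$n_phages))
    stop("corpus metadata fixture is corrupt: matrix_size != n_hosts * n_phages",
         call. = FALSE)
  meta
}

#' Summarise the host-range corpus metadata
#'
#' Aggregates dataset metadata into the corpus-level descriptors used to
#' characterise collections of phage-bacteria infection networks: totals of
#' hosts, phages and matrix cells, the share of datasets with more bacteria
#' than phages, the range of node counts (hosts + phages), and per-dataset
#' means (reported both at full precision and rounded for display).
#'
#' @param meta a data frame as returned by [load_table1_metadata()], or any
#'   data frame with columns `n_hosts`, `n_phages` and (optionally)
#'   `matrix_size`.
#' @return a list with elements `n_datasets`, `total_hosts`, `total_phages`,
#'   `total_cells`, `pct_hosts_gt_phages`, `min_nodes`, `max_nodes`,
#'   `mean_hosts`, `mean_phages`, `mean_hosts_rounded`, `mean_phages_rounded`.
#' @export
summarize_corpus_metadata <- function(meta) {
  stopifnot(is.data.frame(meta), all(c("n_hosts", "n_phages") %in% names(meta)),
            nrow(meta) >= 1L)
  size <- if ("matrix_size" %in% names(meta)) meta$matrix_size
          else meta$n_hosts * meta$n_phages
  nodes <- meta$n_hosts + meta$n_phages
  list(n_datasets = nrow(meta),
       total_hosts = sum(meta$n_hosts),
       total_phages = sum(meta$n_phages),
       total_cells = sum(size),
       pct_hosts_gt_phages = 100 * mean(meta$n_hosts > meta$n_phages),
       min_nodes = min(nodes),
       max_nodes = max(nodes),
       mean_hosts = mean(meta$n_hosts),
       mean_phages = mean(meta$n_phages),
       mean_hosts_rounded = round(mean(meta$n_hosts)),
       mean_phages_rounded = round(mean(meta$n_phages)))
}
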