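#' Extract a Phage Cocktail Network (PCN)
#'
#' The PCN is the subnetwork of a PBIN restricted to the cocktail's phages
#' and all bacteria susceptible to at least one phage of the full network.
#' Resistant bacteria (indegree 0 in the parent) are excluded; they can never
#' be part of a cocktail's coverage. Each retained bacterium carries its
#' cocktail indegree `in_dc`: the number of cocktail phages lysing it, i.e.
#' the expected number of coinfecting phages under the cocktail.
#'
#' @param pbin a [build_pbin()] result.
#' @param cocktail a `cocktail` object, or a character vector of phage ids
#'   (useful for evaluating externally specified formulations).
#' @return an object of class `pcn`: list with `parent`, `cocktail`,
#'   `bacteria` (susceptible bacteria ids), `cocktail_indegree` (named
#'   integer `in_dc` per bacterium) and `mcs` (the cocktail size).
#' @export
extract_pcn <- function(pbin, cocktail) {
  stopifnot(inherits(pbin, "pbin"))
  sel <- if (is.character(cocktail)) cocktail else cocktail$phages
  unknown <- setdiff(sel, phage_ids(pbin))
  if (length(unknown))
    stop(sprintf("cocktail phage(s) not in the network: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  bin <- pbin$matrix$binary
  if (is.character(cocktail))
    cocktail <- new_cocktail("manual", cocktail, bin, n_susceptible(pbin))
  stopifnot(inherits(cocktail, "cocktail"))
  bacteria <- bacteria_ids(pbin)[pbin$in_degree >= 1L]
  in_dc <- if (length(cocktail$phages)) {
    v <- rowSums(bin[bacteria, cocktail$phages, drop = FALSE])
    storage.mode(v) <- "integer"
    v
  } else stats::setNames(integer(length(bacteria)), bacteria)
  structure(list(parent = pbin, cocktail = cocktail, bacteria = bacteria,
                 cocktail_indegree = in_dc, mcs = cocktail$size),
            class = "pcn")
}

#' @export
print.pcn <- function(x, ...) {
  cat(sprintf("PCN: %d-phage cocktail over %d susceptible bacteria; coinfection range %s\n",
              x$mcs, length(x$bacteria),
              if (length(x$bacteria)) paste(range(x$cocktail_indegree), collapse = "-")
              else "NA"))
  invisible(x)
}

#' Expected cocktail efficacy
#'
#' The percentage of all bacteria in the PBIN (including resistant strains)
#' lysed by at least one phage of the cocktail. A complete cocktail on a
#' network without resistant bacteria scores exactly 100.
#'
#' @param pbin a [build_pbin()] result.
#' @param cocktail a `cocktail` object or character vector of phage ids.
#' @return a percentage in `[0, 100]`.
#' @export
efficacy <- function(pbin, cocktail) {
  stopifnot(inherits(pbin, "pbin"))
  if (is.character(cocktail))
    cocktail <- new_cocktail("manual", cocktail, pbin$matrix$binary,
                             n_susceptible(pbin))
  100 * cocktail$n_covered / n_bacteria(pbin)
}

#' Coinfection distribution across PCNs grouped by cocktail size
#'
#' For each group of PCNs sharing the same MCS, the percentage of bacterial
#' strains lysed by exactly k cocktail phages, k = 1..max(MCS). Each row
#' (group) sums to 100 within floating tolerance. Groups contributing no
#' bacteria are dropped with a warning.
#'
#' @param pcns a list of `pcn` objects (all complete).
#' @param group_by grouping key; only `"mcs"` is supported.
#' @return a data frame: one row per MCS group with columns `mcs`,
#'   `n_bacteria` and `k1`, `k2`, ... percentages.
#' @export
coinfection_distribution <- function(pcns, group_by = "mcs") {
  group_by <- match.arg(group_by, "mcs")
  if (inherits(pcns, "pcn")) pcns <- list(pcns)
  stopifnot(length(pcns) >= 1L, all(vapply(pcns, inherits, TRUE, "pcn")))
  if (!all(vapply(pcns, function(x) isTRUE(x$cocktail$complete), TRUE)))
    stop("all PCNs must come from complete cocktails", call. = FALSE)
  mcs <- vapply(pcns, function(x) x$mcs, 0L)
  groups <- sort(unique(mcs[mcs >= 1L]))
  kmax <- max(groups)
  rows <- lapply(groups, function(g) {
    indc <- unlist(lapply(pcns[mcs == g], function(x) x$cocktail_indegree),
                   use.names = FALSE)
    if (!length(indc)) {
      warning(sprintf("MCS group %d has no bacteria; omitted", g))
      return(NULL)
    }
    pct <- 100 * tabulate(indc, nbins = kmax) / length(indc)
    c(mcs = g, n_bacteria = length(indc), stats::setNames(pct, paste0("k", seq_len(kmax))))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) stop("no non-empty MCS groups", call. = FALSE)
  as.data.frame(do.call(rbind, rows))
}

#' Redundancy variation of a bacterium between PBIN and PCN
#'
#' Redundancy `r` is the fraction of a network's phages that lyse a given
#' bacterium: `r_PBIN = in_d / |P|` in the full network and
#' `r_PCN = in_dc / MCS` in the cocktail network. Redundancy variation is
#' their log10 ratio `rv = log10(r_PCN / r_PBIN)`, bounded analytically by
#' `rv_min = log10(|P| / (MCS * in_d))` (one cocktail phage lyses the host)
#' and `rv_max = log10(|P| / MCS)` (every lysing phage is in the cocktail),
#' so `rv_max - rv_min = log10(in_d)` always. Positive rv means coinfection
#' pressure on that strain is relatively higher inside the cocktail than in
#' the original network.
#'
#' @param in_d bacterium indegree in the PBIN (>= 1; resistant strains have
#'   no redundancy).
#' @param in_dc bacterium indegree within the cocktail, in `[1, min(in_d, mcs)]`.
#' @param n_phages number of phages in the PBIN.
#' @param mcs cocktail size (>= 1).
#' @return a data frame (one row per input, vectorized) with columns `in_d`,
#'   `in_dc`, `r_pbin`, `r_pcn`, `rv`, `rv_min`, `rv_max`.
#' @examples
#' redundancy_variation(in_d = 4, in_dc = 1, n_phages = 10, mcs = 2)
#' # rv = rv_min = log10(1.25), rv_max = log10(5)
#' @export
redundancy_variation <- function(in_d, in_dc, n_phages, mcs) {
  n <- max(length(in_d), length(in_dc))
  in_d <- rep_len(in_d, n); in_dc <- rep_len(in_dc, n)
  if (!is.numeric(mcs) || length(mcs) != 1L || mcs < 1 ||
      !is.numeric(n_phages) || length(n_phages) != 1L || n_phages < mcs)
    stop("`mcs` must be >= 1 and `n_phages` >= `mcs`", call. = FALSE)
  if (any(in_d < 1))
    stop("resistant bacteria (in_d = 0) have no redundancy variation",
         call. = FALSE)
  if (any(in_d > n_phages))
    stop("`in_d` cannot exceed `n_phages`", call. = FALSE)
  if (any(in_dc < 1) || any(in_dc > pmin(in_d, mcs)))
    stop("`in_dc` must lie in [1, min(in_d, mcs)]", call. = FALSE)
  r_pbin <- in_d / n_phages
  r_pcn <- in_dc / mcs
  data.frame(in_d = in_d, in_dc = in_dc, r_pbin = r_pbin, r_pcn = r_pcn,
             rv = log10(r_pcn / r_pbin),
             rv_min = log10(n_phages / (mcs * in_d)),
             rv_max = log10(n_phages / mcs))
}

#' Per-bacterium redundancy records of a PCN
#'
#' Applies [redundancy_variation()] to every bacterium of the PCN that is
#' lysed by at least one cocktail phage (under a complete cocktail, all of
#' them).
#'
#' @param pcn a [extract_pcn()] result.
#' @return a data frame with columns `bacterium_id`, `mcs`, `in_d`, `in_dc`,
#'   `r_pbin`, `r_pcn`, `rv`, `rv_min`, `rv_max`.
#' @export
redundancy_records <- function(pcn) {
  stopifnot(inherits(pcn, "pcn"))
  if (pcn$mcs < 1L || !length(pcn$bacteria))
    return(data.frame(bacterium_id = character(), mcs = integer(),
                      in_d = integer(), in_dc = integer(), r_pbin = numeric(),
                      r_pcn = numeric(), rv = numeric(), rv_min = numeric(),
                      rv_max = numeric()))
  keep <- pcn$cocktail_indegree >= 1L
  ids <- pcn$bacteria[keep]
  rec <- redundancy_variation(in_d = unname(pcn$parent$in_degree[ids]),
                              in_dc = unname(pcn$cocktail_indegree[keep]),
                              n_phages = n_phages(pcn$parent),
                              mcs = pcn$mcs)
  cbind(data.frame(bacterium_id = ids, mcs = pcn$mcs), rec)
}

#' Convert a redundancy variation to a fold change
#'
#' rv is a log10 ratio; `rv_to_fold(rv) = 10^rv` expresses the same change as
#' a multiplicative factor (e.g. rv = 0.8 is a 6.3-fold redundancy increase).
#'
#' @param rv redundancy variation(s) in log10 units.
#' @return fold change(s).
#' @export
rv_to_fold <- function(rv) 10^rv

#' Group-wise summary of redundancy variation
#'
#' Summarises redundancy records either by cocktail size (`"mcs"`) or by the
#' number of cocktail phages lysing the bacterium (`"n_lysing_phages"`, i.e.
#' `in_dc`). Medians use the usual midpoint convention for even counts.
#'
#' @param records a data frame as returned by [redundancy_records()] (rows
#'   from several PCNs may be concatenated with `rbind`).
#' @param group_by `"mcs"` or `"n_lysing_phages"`.
#' @return a data frame with columns `group`, `n`, `median_rv`, `min_rv`,
#'   `max_rv`.
#' @export
rv_by_group <- function(records, group_by = c("mcs", "n_lysing_phages")) {
  group_by <- match.arg(group_by)
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  key <- if (group_by == "mcs") records$mcs else records$in_dc
  split_rv <- split(records$rv, key)
  out <- data.frame(group = as.integer(names(split_rv)),
                    n = vapply(split_rv, length, 0L),
                    median_rv = vapply(split_rv, stats::median, 0),
                    min_rv = vapply(split_rv, min, 0),
                    max_rv = vapply(split_rv, max, 0))
  rownames(out) <- NULL
  out
}
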