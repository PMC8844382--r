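#' Heuristic (network-metrics) cocktail search
#'
#' Two-stage greedy selection. Stage 1: every bacterium lysed by exactly one
#' phage (indegree 1) forces that phage into the cocktail, since no other
#' phage can cover it. Stage 2: the remaining phages are visited in
#' decreasing `EI_p` order (ties broken by input column order) and a phage is
#' added only if it lyses at least one bacterium not yet covered; the pass
#' stops once every susceptible bacterium is covered. The heuristic always
#' completes — the union of all phages' host ranges covers all susceptible
#' bacteria by definition — but may select more phages than the true minimum.
#'
#' @param pbin a [build_pbin()] result.
#' @return an object of class `cocktail`: list with `method`, `phages` (in
#'   selection order), `size`, `covered_bacteria`, `n_covered`,
#'   `n_susceptible`, `complete`, and `per_size_trace` (`NULL` for the
#'   heuristic).
#' @seealso [exhaustive_cocktail()], [compare_methods()]
#' @export
heuristic_cocktail <- function(pbin) {
  stopifnot(inherits(pbin, "pbin"))
  bin <- pbin$matrix$binary
  susceptible <- pbin$in_degree >= 1L
  n_susc <- sum(susceptible)
  if (n_susc == 0L)
    return(new_cocktail("heuristic", character(), bin, n_susc))

  covered <- rep(FALSE, nrow(bin))
  chosen <- character()
  # stage 1: unique lysers are mandatory
  unique_idx <- which(pbin$in_degree == 1L)
  if (length(unique_idx)) {
    forced <- unique(colnames(bin)[apply(bin[unique_idx, , drop = FALSE] == 1L,
                                         1L, which.max)])
    # keep input column order for determinism
    forced <- colnames(bin)[sort(match(forced, colnames(bin)))]
    chosen <- forced
    covered <- rowSums(bin[, chosen, drop = FALSE]) > 0L
  }
  # stage 2: descending EI_p, stable input-order tie-break
  if (sum(covered) < n_susc) {
    remaining <- setdiff(colnames(bin)[pbin$out_degree >= 1L], chosen)
    ord <- remaining[order(-pbin$ei_phage[remaining], match(remaining, colnames(bin)))]
    for (p in ord) {
      gains <- bin[, p] == 1L & !covered
      if (any(gains)) {
        chosen <- c(chosen, p)
        covered <- covered | gains
      }
      if (sum(covered) == n_susc) break
    }
  }
  new_cocktail("heuristic", chosen, bin, n_susc)
}

new_cocktail <- function(method, phages, bin, n_susc, trace = NULL,
                         complete = NULL) {
  covered <- if (length(phages))
    rownames(bin)[rowSums(bin[, phages, drop = FALSE]) > 0L] else character()
  if (is.null(complete)) complete <- length(covered) == n_susc
  structure(list(method = method, phages = phages, size = length(phages),
                 covered_bacteria = covered, n_covered = length(covered),
                 n_susceptible = n_susc, complete = complete,
                 per_size_trace = trace),
            class = "cocktail")
}

#' @export
print.cocktail <- function(x, ...) {
  cat(sprintf("%s cocktail: %d phage(s) covering %d/%d susceptible bacteria%s\n",
              x$method, x$size, x$n_covered, x$n_susceptible,
              if (x$complete) "" else " [incomplete at size cap]"))
  if (x$size) cat("  phages:", paste(x$phages, collapse = ", "), "\n")
  invisible(x)
}

#' Exhaustive minimum-cocktail search
#'
#' Enumerates phage combinations of size k = 1, 2, ... (phages that lyse no
#' bacterium are excluded: they can never improve coverage), recording the
#' best coverage achieved at each size, and stops at the first size whose
#' best subset covers every susceptible bacterium. That size is the Minimum
#' Cocktail Size (MCS). Among equal-coverage subsets of the same size the
#' first in lexicographic order of phage column indices is reported.
#'
#' The default search is exact but heavily pruned. Three admissible devices
#' are used, none of which can change the reported result: (i) a phage whose
#' host set is contained in another phage's host set is dropped while
#' computing the best attainable coverage, since any subset using it is
#' matched by one using its dominator; (ii) a partial selection is abandoned
#' when its coverage plus an optimistic completion bound — the smaller of the
#' sum of the largest remaining outdegrees and the number of still-coverable
#' uncovered bacteria — cannot beat the incumbent; (iii) the best coverage
#' value per size is established first on a degree-ordered search, after
#' which the reported subset is recovered by a lexicographic scan that stops
#' at the first subset attaining that value, preserving the documented
#' tie-break. Set `prune = FALSE` to force plain enumeration over all
#' subsets (used in tests to validate the pruned search).
#'
#' @param pbin a [build_pbin()] result.
#' @param max_size largest cocktail size to consider (default 12). If no
#'   subset of size `<= max_size` achieves full coverage the best subset at
#'   `max_size` is returned with `complete = FALSE`.
#' @param prune logical; use the admissible bound (default `TRUE`).
#' @return a `cocktail` object; `per_size_trace` is a data frame with columns
#'   `size` and `best_coverage` for each size explored, and `size` is the MCS
#'   when `complete` is `TRUE`.
#' @export
exhaustive_cocktail <- function(pbin, max_size = 12L, prune = TRUE) {
  stopifnot(inherits(pbin, "pbin"))
  if (!is.numeric(max_size) || length(max_size) != 1L || max_size < 1)
    stop("`max_size` must be a positive integer", call. = FALSE)
  max_size <- as.integer(max_size)
  bin <- pbin$matrix$binary
  n_susc <- n_susceptible(pbin)
  if (n_susc == 0L)
    return(new_cocktail("exhaustive", character(), bin, n_susc,
                        trace = data.frame(size = integer(),
                                           best_coverage = integer())))
  active <- which(pbin$out_degree >= 1L)
  hosts <- bin[, active, drop = FALSE] == 1L  # logical B x P'
  p <- length(active)
  k_top <- min(max_size, p)
  keep <- if (prune) non_dominated(hosts) else seq_len(p)

  trace_size <- integer(); trace_cov <- integer()
  best_set <- NULL
  prev_best <- 0L
  for (k in seq_len(k_top)) {
    if (prune) {
      val <- if (k >= length(keep)) n_susc
             else max_coverage_value(hosts[, keep, drop = FALSE], k, n_susc,
                                     lower = prev_best)
      set <- if (k == k_top || val == n_susc)
        lex_first_subset(hosts, k, val) else NULL
    } else {
      res <- enumerate_best_subset(hosts, k, n_susc)
      val <- res$coverage; set <- res$set
    }
    trace_size <- c(trace_size, k); trace_cov <- c(trace_cov, val)
    if (!is.null(set)) best_set <- set
    prev_best <- val
    if (val == n_susc) break
  }
  phages <- colnames(bin)[active[best_set]]
  cocktail <- new_cocktail("exhaustive", phages, bin, n_susc,
                           trace = data.frame(size = trace_size,
                                              best_coverage = trace_cov))
  cocktail
}

# indices of phages whose host set is not strictly contained in (or, for
# equal sets, not preceded by) another phage's host set; dropping the rest
# never changes the best attainable coverage at any size
non_dominated <- function(hosts) {
  p <- ncol(hosts)
  if (p <= 1L) return(seq_len(p))
  deg <- colSums(hosts)
  overlap <- crossprod(hosts * 1L)  # overlap[i, j] = |hosts_i & hosts_j|
  keep <- rep(TRUE, p)
  for (j in seq_len(p)) {
    subset_of <- overlap[j, ] == deg[j]
    dominated <- subset_of & (deg > deg[j] | (deg == deg[j] & seq_len(p) < j))
    if (any(dominated)) keep[j] <- FALSE
  }
  which(keep)
}

# exact best attainable coverage with (at most) k columns. Because at least
# k columns always exist, padding a smaller subset with arbitrary phages
# never lowers coverage, so the exactly-k optimum equals the at-most-k
# optimum. Compiled branch and bound (gain-ordered children, dynamic
# top-gain completion bound), seeded with the greedy value and a lower bound
# carried over from smaller sizes.
max_coverage_value <- function(hosts, k, n_target, lower = 0L) {
  p <- ncol(hosts)
  if (k >= p) return(sum(rowSums(hosts) > 0L))
  cover_value_cpp(hosts, as.integer(k), as.integer(n_target),
                  as.integer(lower))
}

# first size-k subset in lexicographic column order attaining the (known
# optimal) coverage value; the compiled scan only discards branches that
# provably cannot reach the value, so the first hit is the true
# lexicographic winner
lex_first_subset <- function(hosts, k, value) {
  p <- ncol(hosts)
  if (k >= p) return(seq_len(p))
  res <- lex_first_cover_cpp(hosts, as.integer(k), as.integer(value))
  if (!length(res)) stop("internal error: no subset attains the bound value")
  res
}

# plain enumeration in lexicographic order (no reductions, no bounds);
# retained as the reference the pruned search is validated against
enumerate_best_subset <- function(hosts, k, n_target) {
  p <- ncol(hosts)
  if (k >= p)
    return(list(set = seq_len(p), coverage = sum(rowSums(hosts) > 0L)))
  best_val <- -1L
  best_set <- NULL
  sel <- integer(k)
  done <- FALSE
  recurse <- function(depth, start, covered) {
    remaining <- k - depth
    for (j in start:(p - remaining + 1L)) {
      if (done) return()
      newcov <- covered | hosts[, j]
      sel[depth + 1L] <<- j
      if (remaining == 1L) {
        newn <- sum(newcov)
        if (newn > best_val) {
          best_val <<- newn
          best_set <<- sel
          if (best_val == n_target) { done <<- TRUE; return() }
        }
      } else recurse(depth + 1L, j + 1L, newcov)
    }
  }
  recurse(0L, 1L, rep(FALSE, nrow(hosts)))
  list(set = best_set, coverage = best_val)
}

#' Compare heuristic and exhaustive cocktail search on one network
#'
#' @param pbin a [build_pbin()] result.
#' @param max_size cap for the exhaustive search (default 12).
#' @return a list with both `cocktail` objects (`heuristic`, `exhaustive`),
#'   the two sizes, both coverages, and `gap = heuristic_size -
#'   exhaustive_size` (non-negative whenever both searches complete).
#' @export
compare_methods <- function(pbin, max_size = 12L) {
  h <- heuristic_cocktail(pbin)
  e <- exhaustive_cocktail(pbin, max_size = max_size)
  list(heuristic = h, exhaustive = e,
       heuristic_size = h$size, exhaustive_size = e$size,
       heuristic_covered = h$n_covered, exhaustive_covered = e$n_covered,
       gap = h$size - e$size,
       both_complete = h$complete && e$complete)
}
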