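#' Build a phage-bacteria infection network (PBIN)
#'
#' A PBIN is the directed bipartite network obtained from a binarized
#' host-range matrix, with one edge per lytic interaction pointing from the
#' phage (source) to the bacterium (target). Node importance is scored by
#' Expected Importance (EI): phages with broad host ranges score high
#' (`EI_p = 100 * out_d / |B|`, in 0..100) and bacteria susceptible to few
#' phages score low (`EI_b = -100 * (1 - in_d / |P|)`, in -100..0), so the
#' hardest-to-cover bacteria sit at -100 and generalist phages near 100.
#'
#' @param x a [host_range_matrix()], or a numeric matrix coercible to one.
#' @param threshold binarization threshold, used only when `x` is a bare
#'   matrix.
#' @return an object of class `pbin`: a list with the underlying `matrix`,
#'   per-phage `out_degree` and `ei_phage`, per-bacterium `in_degree` and
#'   `ei_bacterium`, the network `fill` (fraction of lytic cells), `n_nodes`,
#'   and the id vectors of `resistant` bacteria (indegree 0) and `inert`
#'   phages (outdegree 0), which are kept in the network but ignored by
#'   cocktail search.
#' @examples
#' m <- diag(2)
#' dimnames(m) <- list(c("b1", "b2"), c("p1", "p2"))
#' pbin <- build_pbin(m)
#' pbin$ei_phage      # both 50: each phage lyses half the panel
#' pbin$ei_bacterium  # both -50
#' @export
build_pbin <- function(x, threshold = 0) {
  hrm <- if (inherits(x, "host_range_matrix")) x else {
    if (!is.matrix(x)) stop("`x` must be a host_range_matrix or a matrix",
                            call. = FALSE)
    host_range_matrix(x, threshold = threshold)
  }
  bin <- hrm$binary
  out_d <- colSums(bin); storage.mode(out_d) <- "integer"
  in_d <- rowSums(bin); storage.mode(in_d) <- "integer"
  structure(list(
    matrix = hrm,
    out_degree = out_d,
    in_degree = in_d,
    ei_phage = ei_phage(out_d, nrow(bin)),
    ei_bacterium = ei_bacterium(in_d, ncol(bin)),
    fill = sum(bin) / length(bin),
    n_nodes = nrow(bin) + ncol(bin),
    resistant = rownames(bin)[in_d == 0L],
    inert = colnames(bin)[out_d == 0L]
  ), class = "pbin")
}

#' @export
print.pbin <- function(x, ...) {
  cat(sprintf("PBIN: %d bacteria, %d phages (%d nodes), %d interactions, fill %.1f%%\n",
              n_bacteria(x), n_phages(x), sum(x$out_degree), x$n_nodes,
              100 * x$fill))
  cat(sprintf("  susceptible bacteria: %d; resistant: %d; non-infecting phages: %d\n",
              n_susceptible(x), length(x$resistant), length(x$inert)))
  invisible(x)
}

#' Expected Importance of a phage
#'
#' `EI_p = 100 * out_d / |B|`: the percentage of the bacterial panel a phage
#' lyses. A phage lysing no bacterium scores 0; one lysing the whole panel
#' scores 100.
#'
#' @param out_d phage outdegree(s): number of bacteria lysed.
#' @param n_bacteria panel size `|B|` (at least 1).
#' @return numeric in `[0, 100]`, vectorized over `out_d`.
#' @export
ei_phage <- function(out_d, n_bacteria) {
  check_degree(out_d, n_bacteria, "out_d", "n_bacteria")
  100 * out_d / n_bacteria
}

#' Expected Importance of a bacterium
#'
#' `EI_b = -100 * (1 - in_d / |P|)`: non-positive by construction, so that
#' bacteria lysed by no phage score -100 (the most problematic targets) and
#' bacteria lysed by every phage score 0. The opposite signs of `EI_p` and
#' `EI_b` keep source and target nodes on separate colour scales in network
#' renderings.
#'
#' @param in_d bacterium indegree(s): number of phages lysing it.
#' @param n_phages collection size `|P|` (at least 1).
#' @return numeric in `[-100, 0]`, vectorized over `in_d`.
#' @export
ei_bacterium <- function(in_d, n_phages) {
  check_degree(in_d, n_phages, "in_d", "n_phages")
  -100 * (1 - in_d / n_phages)
}

check_degree <- function(d, n, dname, nname) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != as.integer(n))
    stop(sprintf("`%s` must be a single positive integer", nname), call. = FALSE)
  if (!is.numeric(d) || any(d < 0) || any(d != as.integer(d)))
    stop(sprintf("`%s` must be non-negative integer(s)", dname), call. = FALSE)
  if (any(d > n))
    stop(sprintf("`%s` cannot exceed `%s` (%d)", dname, nname, as.integer(n)),
         call. = FALSE)
  invisible(d)
}

#' Number of susceptible bacteria in a PBIN
#'
#' @param pbin a [build_pbin()] result.
#' @return count of bacteria with indegree >= 1.
#' @export
n_susceptible <- function(pbin) {
  stopifnot(inherits(pbin, "pbin"))
  sum(pbin$in_degree >= 1L)
}

#' Network-level descriptors of a PBIN
#'
#' Summarises the complexity and shape of a PBIN: axis sizes, node count,
#' fill (as a percentage), a three-way symmetry category (square bipartite
#' networks admit the most possible edges for their node count), and the
#' number of susceptible bacteria.
#'
#' @param pbin a [build_pbin()] result.
#' @return a list with `n_bacteria`, `n_phages`, `n_nodes`, `fill_percent`,
#'   `symmetry` (one of `"more_bacteria"`, `"square"`, `"more_phages"`) and
#'   `n_susceptible`.
#' @export
network_descriptors <- function(pbin) {
  stopifnot(inherits(pbin, "pbin"))
  nb <- n_bacteria(pbin); np <- n_phages(pbin)
  list(n_bacteria = nb, n_phages = np, n_nodes = pbin$n_nodes,
       fill_percent = 100 * pbin$fill,
       symmetry = if (nb > np) "more_bacteria"
                  else if (nb < np) "more_phages" else "square",
       n_susceptible = n_susceptible(pbin))
}

#' Convert a PBIN to an igraph object
#'
#' Builds the directed bipartite graph (phage -> bacterium edges) with node
#' attributes `type` (`"phage"`/`"bacterium"`) and `ei`. Requires the igraph
#' package.
#'
#' @param pbin a [build_pbin()] result.
#' @return an igraph graph.
#' @export
as_igraph <- function(pbin) {
  stopifnot(inherits(pbin, "pbin"))
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("the igraph package is required for as_igraph()", call. = FALSE)
  bin <- pbin$matrix$binary
  idx <- which(bin == 1L, arr.ind = TRUE)
  edges <- rbind(colnames(bin)[idx[, 2L]], rownames(bin)[idx[, 1L]])
  verts <- data.frame(
    name = c(colnames(bin), rownames(bin)),
    type = rep(c("phage", "bacterium"), c(ncol(bin), nrow(bin))),
    ei = c(pbin$ei_phage, pbin$ei_bacterium))
  igraph::graph_from_data_frame(
    data.frame(from = edges[1L, ], to = edges[2L, ]),
    directed = TRUE, vertices = verts)
}
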