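# run code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

label_axes <- function(cells) {
  dimnames(cells) <- list(sprintf("b%d", seq_len(nrow(cells))),
                          sprintf("p%d", seq_len(ncol(cells))))
  cells
}

#' Generate a random host-range matrix
#'
#' Each cell is lytic independently with probability `fill` (an
#' Erdos-Renyi-style bipartite network). Deterministic for a given seed; the
#' caller's RNG stream is left untouched.
#'
#' @param n_bacteria,n_phages matrix dimensions (>= 1).
#' @param fill lysis probability per cell, in `[0, 1]`.
#' @param seed RNG seed (mandatory in spirit: the default is a fixed
#'   constant so results are always reproducible).
#' @return a [host_range_matrix()] with labels `b1..`, `p1..`.
#' @export
random_matrix <- function(n_bacteria, n_phages, fill = 0.5, seed = 101L) {
  check_gen_config(n_bacteria, n_phages, fill)
  cells <- with_seed(seed, matrix(
    stats::rbinom(n_bacteria * n_phages, 1L, fill), n_bacteria, n_phages))
  host_range_matrix(label_axes(cells * 1))
}

#' Generate a (noisy) nested host-range matrix
#'
#' Builds a perfectly nested matrix — phage host ranges totally ordered by
#' inclusion: phage j lyses the first `k_j` bacteria with `k_1 >= k_2 >= ...`
#' chosen to approximate the target fill — then optionally degrades
#' nestedness by swapping a `noise` fraction of (lytic, non-lytic) cell pairs
#' at random. Swaps preserve the total number of lytic cells, so fill is held
#' constant while the inclusion hierarchy erodes. Empirical phage-bacteria
#' infection networks are typically nested, which is why a perfectly nested
#' matrix always admits a single-phage cocktail: the broadest host range
#' contains every other one.
#'
#' @inheritParams random_matrix
#' @param noise fraction of swappable cell pairs to swap, in `[0, 1]`.
#' @return a [host_range_matrix()].
#' @export
nested_matrix <- function(n_bacteria, n_phages, fill = 0.5, noise = 0,
                          seed = 101L) {
  check_gen_config(n_bacteria, n_phages, fill)
  if (!is.numeric(noise) || length(noise) != 1L || noise < 0 || noise > 1)
    stop("`noise` must be in [0, 1]", call. = FALSE)
  target <- round(fill * n_bacteria * n_phages)
  # non-increasing column sums k_j summing to the target lytic count
  k <- integer(n_phages)
  remaining <- target
  for (j in seq_len(n_phages)) {
    k[j] <- min(n_bacteria, ceiling(remaining / (n_phages - j + 1L)))
    remaining <- remaining - k[j]
  }
  cells <- matrix(0, n_bacteria, n_phages)
  for (j in seq_len(n_phages)) if (k[j] > 0L) cells[seq_len(k[j]), j] <- 1
  if (noise > 0) {
    cells <- with_seed(seed, {
      lytic <- which(cells == 1)
      zero <- which(cells == 0)
      n_swap <- round(noise * min(length(lytic), length(zero)))
      if (n_swap > 0) {
        off <- sample(lytic, n_swap)
        on <- sample(zero, n_swap)
        cells[off] <- 0
        cells[on] <- 1
      }
      cells
    })
  }
  host_range_matrix(label_axes(cells))
}

check_gen_config <- function(n_bacteria, n_phages, fill) {
  if (!is.numeric(n_bacteria) || n_bacteria < 1 ||
      !is.numeric(n_phages) || n_phages < 1)
    stop("matrix dimensions must be >= 1", call. = FALSE)
  if (!is.numeric(fill) || length(fill) != 1L || fill < 0 || fill > 1)
    stop("`fill` must be in [0, 1]", call. = FALSE)
  invisible(TRUE)
}

#' Sample a corpus-shaped collection of synthetic matrices
#'
#' Draws matrices whose size distribution mimics published host-range
#' surveys: about 80% of matrices have more bacteria than phages, with
#' log-uniform axis sizes (7-840 bacteria, 3-66 phages) so node counts span
#' roughly 10 to 900; the phage-heavy minority is drawn small (5-80
#' bacteria) with 1.1-2.5 times as many phages as bacteria, the shape such
#' datasets take in practice. Fills are moderate (0.1-0.6) and structure is
#' noisy-nested (noise 0.05-0.3), since empirical infection networks are
#' predominantly nested. Intended for end-to-end pipeline tests without
#' external data.
#'
#' @param n_datasets number of matrices to draw (>= 1).
#' @param seed RNG seed; the full draw is deterministic given the seed.
#' @return a named list of [host_range_matrix()] objects
#'   (`dataset01`, `dataset02`, ...).
#' @export
corpus_like_sample <- function(n_datasets, seed = 101L) {
  if (!is.numeric(n_datasets) || length(n_datasets) != 1L || n_datasets < 1)
    stop("`n_datasets` must be >= 1", call. = FALSE)
  n_datasets <- as.integer(n_datasets)
  params <- with_seed(seed, {
    more_bacteria <- stats::runif(n_datasets) < 0.8
    nb <- np <- integer(n_datasets)
    for (i in seq_len(n_datasets)) {
      if (more_bacteria[i]) {
        nb[i] <- round(10^stats::runif(1, log10(7), log10(840)))
        np[i] <- min(nb[i] - 1L,
                     round(10^stats::runif(1, log10(3),
                                           log10(min(66, nb[i] - 1L)))))
      } else {
        nb[i] <- round(10^stats::runif(1, log10(5), log10(80)))
        np[i] <- max(nb[i] + 1L, round(nb[i] * stats::runif(1, 1.1, 2.5)))
      }
    }
    data.frame(nb, np,
               fill = stats::runif(n_datasets, 0.1, 0.6),
               noise = stats::runif(n_datasets, 0.05, 0.3),
               sub_seed = sample.int(.Machine$integer.max, n_datasets))
  })
  out <- lapply(seq_len(n_datasets), function(i)
    nested_matrix(params$nb[i], params$np[i], fill = params$fill[i],
                  noise = params$noise[i], seed = params$sub_seed[i]))
  names(out) <- sprintf("dataset%02d", seq_len(n_datasets))
  out
}
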