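# 6 bacteria x 4 phages worked matrix:
# A lyses b1..b4, B lyses b1,b2,b5, C lyses b3,b4,b6, D lyses b5,b6
worked_matrix <- function() {
  cells <- cbind(A = c(1, 1, 1, 1, 0, 0),
                 B = c(1, 1, 0, 0, 1, 0),
                 C = c(0, 0, 1, 1, 0, 1),
                 D = c(0, 0, 0, 0, 1, 1))
  rownames(cells) <- paste0("b", 1:6)
  host_range_matrix(cells)
}

# independent brute-force minimum set cover: enumerate every phage subset by
# bitmask and return the smallest one whose union covers all susceptible
# bacteria (0 when no bacterium is susceptible)
oracle_mcs <- function(bin) {
  p <- ncol(bin)
  susc <- which(rowSums(bin) > 0)
  if (!length(susc)) return(0L)
  best <- p
  for (mask in seq_len(2^p - 1)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, 0:(p - 1))) != 0L)
    if (length(idx) >= best) next
    if (all(rowSums(bin[susc, idx, drop = FALSE]) > 0))
      best <- length(idx)
  }
  best
}

# write a host-range matrix to a delimited file for I/O tests
write_matrix_file <- function(cells, delim = "\t", path = tempfile()) {
  header <- paste(c("", colnames(cells)), collapse = delim)
  rows <- vapply(seq_len(nrow(cells)), function(i)
    paste(c(rownames(cells)[i], cells[i, ]), collapse = delim), "")
  writeLines(c(header, rows), path)
  path
}
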