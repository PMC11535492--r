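# shared fixtures and small independent oracles used across the suite

cass <- diagpair::cass_counts()

# draw a random but analysable fundamental-counts table
random_counts <- function() {
  repeat {
    cells <- stats::rmultinom(1, size = sample(60:400, 1),
                              prob = rep(1 / 8, 8))
    if (sum(cells[1:4]) >= 5 && sum(cells[5:8]) >= 5) {
      return(diagpair::fundamental_counts(cells[1], cells[2], cells[3],
                                          cells[4], cells[5], cells[6],
                                          cells[7], cells[8]))
    }
  }
}

# brute-force nested-loop tally of subject rows into the eight cells,
# independent of tabulate_pairs()
brute_force_cells <- function(df) {
  out <- c(s11 = 0, s10 = 0, s01 = 0, s00 = 0,
           r11 = 0, r10 = 0, r01 = 0, r00 = 0)
  for (i in seq_len(nrow(df))) {
    g <- df$gold[i]; a <- df$test1[i]; b <- df$test2[i]
    key <- paste0(if (g == 1) "s" else "r", a, b)
    out[key] <- out[key] + 1
  }
  out
}
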