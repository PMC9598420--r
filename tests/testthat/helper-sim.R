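# Shared fixtures, all generated in code.

# random stretch-stretch pair table (not tied to a genome)
mk_pairs <- function(K, seed = NULL, max_L = 1000, max_len = 500) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(L = runif(K, 0, max_L),
             a = sample.int(max_len, K, replace = TRUE),
             b = sample.int(max_len, K, replace = TRUE))
}

mk_point_pairs <- function(K, seed = NULL) {
  p <- mk_pairs(K, seed)
  p$b <- 0
  p
}

# labelled sequence in extract_pairs() input form
mk_seq <- function(labels, centers) {
  data.frame(label = labels, center = centers, start = centers,
             end = centers, length = 0, idx = seq_along(labels),
             stringsAsFactors = FALSE)
}

write_tmp_bed <- function(lines, gz = FALSE) {
  path <- tempfile(fileext = if (gz) ".bed.gz" else ".bed")
  con <- if (gz) gzfile(path, "w") else file(path, "w")
  writeLines(lines, con)
  close(con)
  path
}

# threshold table shared across tests; built once per run (Monte-Carlo,
# ~half a minute) and memoized
.test_env <- new.env()
test_thresholds <- function() {
  if (is.null(.test_env$tb))
    .test_env$tb <- calibrate_thresholds(
      k_grid = c(50, 100, 200, 400, 800), n_realizations = 2000,
      seed = 20260923)
  .test_env$tb
}
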