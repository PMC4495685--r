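# shared fixture builders; everything is generated in code at test time

write_matrix_file <- function(M, dialect = "pm1") {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  if (is.null(rownames(M))) rownames(M) <- paste0("d", seq_len(nrow(M)))
  if (is.null(colnames(M))) colnames(M) <- paste0("t", seq_len(ncol(M)))
  out <- if (dialect == "01") (M + 1) / 2 else M
  utils::write.table(as.data.frame(out), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  path
}

# a small scenario with its perfect kernels, cached per (u, r, seed)
quick_scenario <- local({
  cache <- new.env(parent = emptyenv())
  function(u = 0.5, r = 0.3, seed = 1, N = 50, M = 50) {
    key <- paste(u, r, seed, N, M)
    if (is.null(cache[[key]]))
      cache[[key]] <- simulate_scenario(u, r, 0, N = N, M = M, seed = seed)
    cache[[key]]
  }
})

# fast KBMF settings for loop-heavy tests
fast_trace <- function(Y, Kd, Kt, strategy, seed, init = "random", batch = NULL) {
  run_trace(Y, Kd, Kt, strategy = strategy, init = init,
            batch = batch %||% ceiling(0.1 * length(Y)),
            R = 10, iterations = 60, tol = 1e-3, seed = seed,
            stop_fraction = 0.95)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
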