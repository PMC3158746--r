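# Fixture builders shared across test files; everything is generated in
# code so no binary or bulky data ships with the package.

# control pool with exactly the requested mean and sd
scaled_controls <- function(m, s, n) {
  z <- seq_len(n)
  m + s * (z - mean(z)) / stats::sd(z)
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# random metagene profiles as plain lists: list(offset=, log_ratio=)
random_profiles <- function(n, max_points = 33L) {
  lapply(seq_len(n), function(i) {
    k <- sample.int(max_points, 1L)
    list(offset = sort(sample(seq(-4000L, 4000L, by = 250L), k)),
         log_ratio = stats::runif(k, -1, 3))
  })
}

# independent point-by-point rule scan (the caller oracle)
brute_force_bound <- function(offset, log_ratio, global = 1.5, win = 0.8,
                              lo = -1250, hi = 750) {
  hit <- FALSE
  for (i in seq_along(offset)) {
    if (log_ratio[i] > global) hit <- TRUE
    if (offset[i] >= lo && offset[i] <= hi && log_ratio[i] > win) hit <- TRUE
  }
  hit
}

# probe-signal records that build_metagene/call_chip decode back to the
# given log-ratios (pseudocount 1)
records_from_profiles <- function(profiles, gene_ids = NULL) {
  gene_ids <- gene_ids %||% sprintf("RG%05d", seq_along(profiles))
  do.call(rbind, lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    data.frame(probe_id = paste0(gene_ids[i], "_", seq_along(p$offset)),
               gene_id = gene_ids[i], offset = p$offset,
               h3k4me3 = 200 * 2^p$log_ratio - 1, panh3 = 199,
               stringsAsFactors = FALSE)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# named state vectors realising a 3x3 transition count matrix
states_from_counts <- function(counts) {
  states <- c("ACTIVE", "PAUSED", "SILENT")
  from <- rep(rep(states, each = 3L), times = as.vector(t(counts)))
  to <- rep(rep(states, times = 3L), times = as.vector(t(counts)))
  ids <- sprintf("L%06d", seq_along(from))
  list(before = stats::setNames(from, ids), after = stats::setNames(to, ids))
}

random_state_vectors <- function(n) {
  ids <- sprintf("R%05d", seq_len(n))
  list(before = stats::setNames(sample(c("ACTIVE", "PAUSED", "SILENT"), n,
                                       replace = TRUE), ids),
       after = stats::setNames(sample(c("ACTIVE", "PAUSED", "SILENT"), n,
                                      replace = TRUE), ids))
}
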