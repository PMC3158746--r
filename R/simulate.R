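#' Default two-condition transition matrix
#'
#' Builds a 3x3 row-stochastic matrix over (ACTIVE, PAUSED, SILENT) whose
#' stationary behaviour matches the configured overall changing fraction,
#' category shares among changing loci, and direct-transition share.
#'
#' @param state_dist Condition-1 state distribution (A, P, S).
#' @param changing Overall fraction of loci changing state (default 0.12).
#' @param shares Category shares among changing loci (activation,
#'   silencing, priming, archiving; default c(.22, .17, .30, .31)).
#' @param direct Share of changing loci moving directly A<->S
#'   (default 0.01, split evenly between S->A and A->S).
#' @return 3x3 matrix with rows/columns ACTIVE, PAUSED, SILENT.
#' @export
default_transition_matrix <- function(state_dist = c(0.47, 0.48, 0.05),
                                      changing = 0.12,
                                      shares = c(activation = 0.22,
                                                 silencing = 0.17,
                                                 priming = 0.30,
                                                 archiving = 0.31),
                                      direct = 0.01) {
  if (abs(sum(shares) - 1) > 1e-8)
    stop_validation("category shares must sum to 1")
  # absolute per-transition masses (fractions of all loci)
  sa <- changing * direct / 2                 # S->A
  as_ <- changing * direct / 2                # A->S
  pa <- changing * shares[["activation"]] - sa
  ap <- changing * shares[["silencing"]] - as_
  sp <- changing * shares[["priming"]]
  ps <- changing * shares[["archiving"]]
  if (min(pa, ap, sp, ps) < 0)
    stop_validation("direct share incompatible with category shares")
  m <- rbind(
    ACTIVE = c(0, ap, as_) / state_dist[1],
    PAUSED = c(pa, 0, ps) / state_dist[2],
    SILENT = c(sa, sp, 0) / state_dist[3])
  diag(m) <- 1 - rowSums(m)
  colnames(m) <- STATES
  if (any(m < 0))
    stop_validation("transition parameters imply a negative probability")
  m
}

#' Parameters of the synthetic two-platform study
#'
#' Defaults emulate the study conditions: ~2000 protein-coding loci with a
#' 47/48/5 active/paused/silent split in condition 1, ~12% of loci
#' changing state with category shares (activation .22, silencing .17,
#' priming .30, archiving .31) and ~1% direct transitions; a promoter
#' tiling array of 33 probes per locus at 250-bp spacing over +/-4 kb with
#' a Gaussian H3K4me3 enrichment bump (height 2 log2 units, sd 500 bp) at
#' initiating loci over log-ratio noise of sd 0.3; and a bead expression
#' array with a 750-probe negative-control pool (mean 100, sd 10), 30
#' beads per probe, 2 replicates per condition, and expressed loci shifted
#' +10 control SDs.
#'
#' @param n_genes Number of loci (default 2000).
#' @param state_dist Condition-1 state probabilities over (A, P, S).
#' @param transition_matrix Row-stochastic 3x3 matrix; default from
#'   [default_transition_matrix()].
#' @param conditions Labels of the two cell populations.
#' @param chip_peak_height,chip_peak_sd Gaussian bump height (log2 units)
#'   and width (bp) at initiating loci.
#' @param chip_noise_sd Log-ratio noise sd (0 = noise-free arrays).
#' @param chip_probe_step,chip_window Probe spacing and half-window (bp).
#' @param ctrl_mean,ctrl_sd Negative-control intensity mean and sd.
#' @param expr_shift_sds Expressed-locus mean shift in control SDs.
#' @param n_controls Negative-control probes per sample.
#' @param bead_count Beads per probe.
#' @param n_replicates Expression replicates per condition.
#' @param expr_noise Noise scale for the expression platform (1 = nominal
#'   sampling noise, 0 = noise-free).
#' @param go_genes_per_term,go_purity,go_n_background Gene-set size,
#'   lineage purity and number of background terms for the synthetic
#'   annotations.
#' @param seed Integer seed; every generator derives its own sub-stream
#'   from it, so outputs are byte-identical across runs.
#' @return A list of class \code{sim_params}.
#' @export
sim_params <- function(n_genes = 2000L,
                       state_dist = c(ACTIVE = 0.47, PAUSED = 0.48,
                                      SILENT = 0.05),
                       transition_matrix = NULL,
                       conditions = c("pluripotent", "mesoderm"),
                       chip_peak_height = 2.0, chip_peak_sd = 500,
                       chip_noise_sd = 0.3, chip_probe_step = 250L,
                       chip_window = 4000L,
                       ctrl_mean = 100, ctrl_sd = 10, expr_shift_sds = 10,
                       n_controls = 750L, bead_count = 30L,
                       n_replicates = 2L, expr_noise = 1,
                       go_genes_per_term = 60L, go_purity = 0.8,
                       go_n_background = 10L, seed = 1L) {
  if (length(state_dist) != 3L || any(state_dist < 0) ||
      abs(sum(state_dist) - 1) > 1e-8)
    stop_validation("state_dist must be 3 non-negative probabilities summing to 1")
  if (is.null(transition_matrix))
    transition_matrix <- default_transition_matrix(state_dist)
  if (!is.matrix(transition_matrix) || any(dim(transition_matrix) != 3L) ||
      any(transition_matrix < 0) ||
      any(abs(rowSums(transition_matrix) - 1) > 1e-8))
    stop_validation("transition_matrix must be 3x3 row-stochastic")
  check_scalar_number(chip_noise_sd, "chip_noise_sd", 0)
  check_scalar_number(expr_noise, "expr_noise", 0)
  check_scalar_number(ctrl_sd, "ctrl_sd", 0, strict_lower = TRUE)
  if (length(conditions) != 2L)
    stop_validation("exactly two condition labels are required")
  structure(list(n_genes = as.integer(n_genes), state_dist = state_dist,
                 transition_matrix = transition_matrix,
                 conditions = conditions,
                 chip_peak_height = chip_peak_height,
                 chip_peak_sd = chip_peak_sd,
                 chip_noise_sd = chip_noise_sd,
                 chip_probe_step = as.integer(chip_probe_step),
                 chip_window = as.integer(chip_window),
                 ctrl_mean = ctrl_mean, ctrl_sd = ctrl_sd,
                 expr_shift_sds = expr_shift_sds,
                 n_controls = as.integer(n_controls),
                 bead_count = as.integer(bead_count),
                 n_replicates = as.integer(n_replicates),
                 expr_noise = expr_noise,
                 go_genes_per_term = as.integer(go_genes_per_term),
                 go_purity = go_purity,
                 go_n_background = as.integer(go_n_background),
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Ground-truth states and lineage tags
#'
#' Draws each locus's condition-1 state from the configured distribution
#' and its condition-2 state from the corresponding transition-matrix row,
#' then tags loci by archetype: \code{mesoderm-like} (P->A),
#' \code{ectoderm-like} (P->S), \code{housekeeping} (stable ACTIVE),
#' otherwise \code{none}.
#'
#' @param params A [sim_params()].
#' @return Data frame of class \code{truth_table}: \code{gene_id},
#'   \code{state_1}, \code{state_2}, \code{lineage}.
#' @export
generate_truth <- function(params = sim_params()) {
  set.seed(substream_seed(params$seed, 0L))
  n <- params$n_genes
  gene_id <- sprintf("G%05d", seq_len(n))
  s1 <- sample(STATES, n, replace = TRUE, prob = params$state_dist)
  s2 <- character(n)
  for (st in STATES) {
    i <- which(s1 == st)
    if (length(i))
      s2[i] <- sample(STATES, length(i), replace = TRUE,
                      prob = params$transition_matrix[st, ])
  }
  lineage <- rep("none", n)
  lineage[s1 == "PAUSED" & s2 == "ACTIVE"] <- "mesoderm-like"
  lineage[s1 == "PAUSED" & s2 == "SILENT"] <- "ectoderm-like"
  lineage[s1 == "ACTIVE" & s2 == "ACTIVE"] <- "housekeeping"
  out <- data.frame(gene_id = gene_id, state_1 = s1, state_2 = s2,
                    lineage = lineage, stringsAsFactors = FALSE)
  class(out) <- c("truth_table", "data.frame")
  out
}

#' Synthetic TSS annotation for the truth set
#'
#' Random chromosome, strand and position per locus, written in BED6
#' semantics (TSS = start on +, = end on -).
#'
#' @param truth A [generate_truth()] table.
#' @param params A [sim_params()].
#' @return Data frame in BED6 column order (\code{chromosome},
#'   \code{start}, \code{end}, \code{gene_id}, \code{score},
#'   \code{strand}).
#' @export
generate_tss <- function(truth, params = sim_params()) {
  set.seed(substream_seed(params$seed, 7L))
  n <- nrow(truth)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  start <- sample.int(2e8L, n)
  data.frame(chromosome = paste0("chr", sample.int(22L, n, replace = TRUE)),
             start = start, end = start + 5000L,
             gene_id = truth$gene_id, score = 0L, strand = strand,
             stringsAsFactors = FALSE)
}

#' Simulate promoter-array probe signals for one condition
#'
#' Lays 33 probes per locus at 250-bp spacing across +/-4 kb of the TSS.
#' Initiating loci (ACTIVE or PAUSED in the condition) carry a Gaussian
#' log2-enrichment bump centred on the TSS; silent loci carry noise only.
#' Channel intensities are back-computed so that [build_metagene()] with
#' the default pseudocount recovers the intended log-ratios exactly.
#'
#' @param truth A [generate_truth()] table.
#' @param params A [sim_params()].
#' @param condition 1 or 2.
#' @return Probe-signal data frame (\code{probe_id}, \code{gene_id},
#'   \code{offset}, \code{h3k4me3}, \code{panh3}).
#' @export
simulate_chip <- function(truth, params = sim_params(), condition = 1L) {
  stopifnot(condition %in% c(1L, 2L))
  set.seed(substream_seed(params$seed, 10L + condition))
  offsets <- seq(-params$chip_window, params$chip_window,
                 by = params$chip_probe_step)
  state <- truth[[paste0("state_", condition)]]
  initiating <- state %in% c("ACTIVE", "PAUSED")
  n_probe <- length(offsets)
  gene_id <- rep(truth$gene_id, each = n_probe)
  off <- rep(offsets, times = nrow(truth))
  mu <- ifelse(rep(initiating, each = n_probe),
               params$chip_peak_height *
                 exp(-off^2 / (2 * params$chip_peak_sd^2)),
               0)
  lr <- mu + if (params$chip_noise_sd > 0)
    stats::rnorm(length(mu), 0, params$chip_noise_sd) else 0
  # panh3 + pseudocount = 200 exactly; h3k4me3 back-computed from the ratio
  panh3 <- rep(199, length(lr))
  h3k4me3 <- pmax(200 * 2^lr - 1, 0)
  data.frame(
    probe_id = paste0(gene_id, "_", sprintf("%02d", rep(seq_len(n_probe),
                                                        times = nrow(truth)))),
    gene_id = gene_id, offset = as.integer(off),
    h3k4me3 = h3k4me3, panh3 = panh3, stringsAsFactors = FALSE)
}

#' Simulate bead-array expression samples for one condition
#'
#' One expression probe per locus plus a negative-control probe pool.
#' Loci elongating in the condition (truth state ACTIVE) draw their probe
#' mean around control mean + \code{expr_shift_sds} control SDs; paused
#' and silent loci draw around the control mean.  Bead summaries (mean,
#' sd, count) are sampled consistently with the bead count; at
#' \code{expr_noise = 0} all summaries sit exactly at their expectations.
#'
#' @param truth A [generate_truth()] table.
#' @param params A [sim_params()].
#' @param condition 1 or 2.
#' @param replicate Replicate index (1-based).
#' @return Long expression data frame (one sample) with the columns
#'   documented in [read_expression_table()].
#' @export
simulate_expression <- function(truth, params = sim_params(),
                                condition = 1L, replicate = 1L) {
  stopifnot(condition %in% c(1L, 2L), replicate >= 1L)
  set.seed(substream_seed(params$seed,
                          100L + 10L * condition + replicate))
  state <- truth[[paste0("state_", condition)]]
  elong <- state == "ACTIVE"
  n <- nrow(truth)
  nb <- params$bead_count
  noise <- params$expr_noise
  mu <- params$ctrl_mean + ifelse(elong,
                                  params$expr_shift_sds * params$ctrl_sd, 0)
  mean_i <- mu + noise * stats::rnorm(n) * params$ctrl_sd / sqrt(nb)
  sd_i <- if (noise > 0)
    params$ctrl_sd * sqrt(stats::rchisq(n, nb - 1L) / (nb - 1L))
  else rep(params$ctrl_sd, n)
  ctrl_val <- params$ctrl_mean +
    noise * stats::rnorm(params$n_controls) * params$ctrl_sd
  ctrl_sd_i <- if (noise > 0)
    params$ctrl_sd * sqrt(stats::rchisq(params$n_controls, nb - 1L) / (nb - 1L))
  else rep(params$ctrl_sd, params$n_controls)
  cond_lab <- params$conditions[condition]
  sample_id <- paste(cond_lab, replicate, sep = "_")
  probes <- data.frame(
    probe_id = paste0(truth$gene_id, "_expr"), gene_id = truth$gene_id,
    control = 0L, sample_id = sample_id, condition = cond_lab,
    replicate = as.integer(replicate), mean_intensity = mean_i,
    bead_sd = sd_i, bead_count = nb, stringsAsFactors = FALSE)
  ctrls <- data.frame(
    probe_id = sprintf("NC%04d", seq_len(params$n_controls)),
    gene_id = "-", control = 1L, sample_id = sample_id,
    condition = cond_lab, replicate = as.integer(replicate),
    mean_intensity = ctrl_val, bead_sd = ctrl_sd_i, bead_count = nb,
    stringsAsFactors = FALSE)
  rbind(probes, ctrls)
}

#' Synthetic gene2go-format annotations keyed to the truth
#'
#' Emits lineage-informative terms — \code{mesoderm-like} terms drawing at
#' least \code{go_purity} of their members from P->A loci,
#' \code{ectoderm-like} terms from P->S loci, \code{housekeeping} terms
#' from stable-ACTIVE loci — plus background terms with random membership.
#'
#' @param truth A [generate_truth()] table.
#' @param params A [sim_params()].
#' @return Data frame in NCBI gene2go column order (tax_id, GeneID,
#'   GO_ID, Evidence, Qualifier, GO_term, PubMed, Category), with
#'   attribute \code{term_lineage} naming each synthetic term's archetype.
#' @export
generate_go_annotations <- function(truth, params = sim_params()) {
  set.seed(substream_seed(params$seed, 50L))
  size <- params$go_genes_per_term
  pools <- list(
    `mesoderm-like` = truth$gene_id[truth$lineage == "mesoderm-like"],
    `ectoderm-like` = truth$gene_id[truth$lineage == "ectoderm-like"],
    housekeeping = truth$gene_id[truth$lineage == "housekeeping"])
  term_spec <- data.frame(
    lineage = c(rep("mesoderm-like", 3), rep("ectoderm-like", 3),
                rep("housekeeping", 2),
                rep("background", params$go_n_background)),
    stringsAsFactors = FALSE)
  term_spec$go_id <- sprintf("GO:%07d", 1000000L + seq_len(nrow(term_spec)))
  term_spec$term <- paste0("synthetic ", term_spec$lineage, " term ",
                      stats::ave(seq_len(nrow(term_spec)), term_spec$lineage,
                                 FUN = seq_along))
  rows <- vector("list", nrow(term_spec))
  for (i in seq_len(nrow(term_spec))) {
    lin <- term_spec$lineage[i]
    if (lin == "background") {
      members <- sample(truth$gene_id, min(size, nrow(truth)))
    } else {
      pool <- pools[[lin]]
      k <- min(round(params$go_purity * size), length(pool))
      members <- unique(c(sample(pool, k),
                          sample(truth$gene_id, size - k)))
    }
    rows[[i]] <- data.frame(
      tax_id = 9606L, gene_id = members, go_id = term_spec$go_id[i],
      evidence = "IEA", qualifier = "-", term = term_spec$term[i],
      pubmed = "-", category = "Process", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "term_lineage") <- stats::setNames(term_spec$lineage, term_spec$go_id)
  out
}

#' Write a complete synthetic study to disk
#'
#' Generates truth, TSS annotation, per-condition ChIP probe tables,
#' per-sample expression tables and gene2go annotations, and writes them
#' as the plain-text files the pipeline readers consume.  Fully
#' deterministic under \code{params$seed} (byte-identical files across
#' runs).
#'
#' @param params A [sim_params()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the truth table and all file paths
#'   (\code{tss}, \code{chip} (named by condition), \code{expr} (named by
#'   sample), \code{gene2go}, \code{truth}).
#' @export
simulate_study <- function(params = sim_params(), outdir = tempfile("study")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  truth <- generate_truth(params)
  tss <- generate_tss(truth, params)
  tss_path <- file.path(outdir, "tss.bed")
  utils::write.table(tss, tss_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  chip_paths <- character(2)
  for (cond in 1:2) {
    chip <- simulate_chip(truth, params, cond)
    chip_paths[cond] <- file.path(outdir,
                                  paste0("chip_", params$conditions[cond],
                                         ".tsv"))
    write_hash_table(chip, chip_paths[cond],
                     comments = sprintf("synthetic promoter-array signal, condition %s",
                                        params$conditions[cond]))
  }
  names(chip_paths) <- params$conditions
  expr_paths <- character(0)
  for (cond in 1:2) for (rep_i in seq_len(params$n_replicates)) {
    e <- simulate_expression(truth, params, cond, rep_i)
    p <- file.path(outdir, paste0("expr_", params$conditions[cond], "_",
                                  rep_i, ".tsv"))
    write_hash_table(e, p,
                     comments = sprintf("synthetic bead-array expression, sample %s_%d",
                                        params$conditions[cond], rep_i))
    expr_paths[paste(params$conditions[cond], rep_i, sep = "_")] <- p
  }
  g2g <- generate_go_annotations(truth, params)
  g2g_path <- file.path(outdir, "gene2go.tsv")
  con <- file(g2g_path, "wt", encoding = "UTF-8")
  writeLines("#tax_id\tGeneID\tGO_ID\tEvidence\tQualifier\tGO_term\tPubMed\tCategory",
             con)
  utils::write.table(g2g, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  truth_path <- file.path(outdir, "truth.tsv")
  write_hash_table(truth, truth_path, comments = "synthetic ground truth")
  invisible(list(truth = truth, term_lineage = attr(g2g, "term_lineage"),
                 tss = tss_path, chip = chip_paths, expr = expr_paths,
                 gene2go = g2g_path, truth_path = truth_path))
}
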