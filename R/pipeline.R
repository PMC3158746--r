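#' End-to-end transition analysis of two cell populations
#'
#' Runs the full chain: H3K4me3 binding calls per condition from the
#' promoter-array probe signals, transcript detection / probe filtering /
#' gene-level full-length transcript calls from the bead expression
#' samples, three-way state assignment on the loci shared by both
#' platforms, transition classification and tallying, and (optionally)
#' per-ontology transition profiles.
#'
#' @param tss TSS annotation: a path to a BED6 file or a data frame from
#'   [read_tss_annotation()].
#' @param chip Length-2 list or character vector (named by condition, in
#'   before/after order) of probe-signal tables or file paths.
#' @param expr Character vector of expression sample file paths, or a
#'   single long data frame covering all samples.
#' @param gene2go Optional path to a gene2go file or an
#'   \code{ontology_map}; when given, term profiles are computed.
#' @param chip_conf A [chip_config()].
#' @param expr_conf An [expr_config()].
#' @param coerce_discordant Passed to [make_transitions()].
#' @return An object of class \code{transition_analysis}: a list with
#'   \code{states} (per-condition state-call data frames),
#'   \code{records} (transition records), \code{tally}
#'   (a \code{transition_tally}), \code{binding}, \code{transcripts},
#'   \code{retained_probes}, \code{profiles} (or \code{NULL}) and
#'   \code{conditions}.
#' @export
run_transition_analysis <- function(tss, chip, expr, gene2go = NULL,
                                    chip_conf = chip_config(),
                                    expr_conf = expr_config(),
                                    coerce_discordant = c("exclude",
                                                          "active")) {
  annotation <- if (is.character(tss)) read_tss_annotation(tss) else tss
  if (length(chip) != 2L)
    stop_validation("'chip' must give probe signals for exactly two conditions")
  conditions <- names(chip) %||% c("before", "after")
  chip_tabs <- lapply(chip, function(x)
    if (is.character(x)) read_probe_signals(x, annotation) else x)
  binding <- lapply(chip_tabs, call_chip, config = chip_conf)
  names(binding) <- conditions

  expr_tab <- if (is.character(expr)) read_expression_table(expr) else expr
  detections <- detect_expression(expr_tab)
  retained <- filter_probes(detections, expr_conf)
  transcripts <- call_transcripts(detections, retained, expr_conf)
  expr_conds <- unique(expr_tab$condition[expr_tab$control == 0L])
  if (!setequal(expr_conds, conditions) && length(expr_conds) == 2L)
    # map expression condition labels onto the chip order if they differ
    conditions <- intersect(c(conditions, expr_conds), expr_conds)

  states <- lapply(seq_along(conditions), function(i) {
    tc <- transcripts[transcripts$condition == conditions[i], , drop = FALSE]
    if (!nrow(tc))
      stop_validation("no transcript calls for condition '%s'", conditions[i])
    locus_state_calls(binding[[i]], tc, condition = conditions[i])
  })
  names(states) <- conditions
  shared <- intersect(states[[1]]$gene_id, states[[2]]$gene_id)
  s1 <- states[[1]][match(shared, states[[1]]$gene_id), , drop = FALSE]
  s2 <- states[[2]][match(shared, states[[2]]$gene_id), , drop = FALSE]
  records <- make_transitions(s1, s2,
                              coerce_discordant = match.arg(coerce_discordant))
  tally <- tally_transitions(records)
  profiles <- NULL
  if (!is.null(gene2go)) {
    ont <- if (is.character(gene2go)) read_gene2go(gene2go) else gene2go
    profiles <- profile_terms(ont, records)
  }
  structure(list(states = list(before = s1, after = s2), records = records,
                 tally = tally, binding = binding,
                 transcripts = transcripts, retained_probes = retained,
                 profiles = profiles, conditions = conditions),
            class = "transition_analysis")
}

#' @export
print.transition_analysis <- function(x, ...) {
  cat(sprintf("Transcriptional state transition analysis: %s -> %s\n",
              x$conditions[1], x$conditions[2]))
  print(x$tally)
  if (!is.null(x$profiles))
    cat(sprintf("  ontology profiles: %d terms\n", nrow(x$profiles)))
  invisible(x)
}
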