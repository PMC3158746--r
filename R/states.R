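#' Three-way transcriptional state from initiation and elongation calls
#'
#' Truth table: ACTIVE = initiating and elongating; PAUSED = initiating
#' only; SILENT = neither; DISCORDANT = elongating without initiation (a
#' cell of the table the three-state scheme leaves undefined; tracked so
#' the logic is total, and excluded from transition tallies by default).
#'
#' @param initiating,elongating Logical vectors (recycled to a common
#'   length): promoter H3K4me3 binding and full-length transcript calls.
#' @return Character vector over \{ACTIVE, PAUSED, SILENT, DISCORDANT\}.
#' @examples
#' assign_state(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, FALSE, TRUE))
#' @export
assign_state <- function(initiating, elongating) {
  if (anyNA(initiating) || anyNA(elongating))
    stop_validation("initiation/elongation calls must be non-missing")
  ifelse(initiating,
         ifelse(elongating, "ACTIVE", "PAUSED"),
         ifelse(elongating, "DISCORDANT", "SILENT"))
}

#' Combine binding and transcript calls into locus state calls
#'
#' The analyzed locus set is the intersection of genes represented on both
#' platforms (at least one ChIP probe and at least one expression probe);
#' genes missing from either call set are dropped.
#'
#' @param binding Binding calls from [call_chip()] (needs \code{gene_id},
#'   \code{bound}).
#' @param transcripts Transcript calls from [call_transcripts()] for one
#'   condition (needs \code{gene_id}, \code{expressed}).
#' @param condition Condition label stored in the result; defaults to the
#'   transcript calls' condition.
#' @return Data frame: \code{gene_id}, \code{condition},
#'   \code{initiating}, \code{elongating}, \code{state}.
#' @export
locus_state_calls <- function(binding, transcripts, condition = NULL) {
  shared <- intersect(binding$gene_id, transcripts$gene_id)
  if (!length(shared))
    stop_validation("no genes shared between the ChIP and expression platforms")
  b <- binding$bound[match(shared, binding$gene_id)]
  e <- transcripts$expressed[match(shared, transcripts$gene_id)]
  cond <- condition %||%
    (if ("condition" %in% names(transcripts))
       transcripts$condition[match(shared, transcripts$gene_id)]
     else NA_character_)
  out <- data.frame(gene_id = shared, condition = cond,
                    initiating = b, elongating = e,
                    state = assign_state(b, e), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

TRANSITION_CATEGORY <- c(
  "A->A" = "stable",    "A->P" = "silencing", "A->S" = "silencing",
  "P->A" = "activation", "P->P" = "stable",   "P->S" = "archiving",
  "S->A" = "activation", "S->P" = "priming",  "S->S" = "stable")
DIRECT_TRANSITIONS <- c("S->A", "A->S")

#' Classify a state transition
#'
#' Maps an ordered (from, to) pair of three-way states to one of the nine
#' transitions and its category: \code{stable} (A->A, P->P, S->S),
#' \code{activation} (P->A, S->A), \code{silencing} (A->P, A->S),
#' \code{priming} (S->P), \code{archiving} (P->S).  The \code{direct} flag
#' additionally marks S->A and A->S, which bypass the paused intermediate.
#' A DISCORDANT state yields \code{NA} fields as an exclusion signal
#' rather than an error.
#'
#' @param from_state,to_state Character vectors of states.
#' @return Data frame: \code{from_state}, \code{to_state},
#'   \code{transition} (e.g. \code{"P->A"}), \code{category},
#'   \code{direct}.
#' @examples
#' classify_transition("PAUSED", "SILENT")   # archiving
#' classify_transition("SILENT", "ACTIVE")   # activation, direct
#' @export
classify_transition <- function(from_state, to_state) {
  n <- max(length(from_state), length(to_state))
  from_state <- rep_len(from_state, n)
  to_state <- rep_len(to_state, n)
  bad <- !(from_state %in% c(STATES, "DISCORDANT")) |
    !(to_state %in% c(STATES, "DISCORDANT"))
  if (any(bad))
    stop_validation("unknown state label: %s",
                    paste(unique(c(from_state, to_state)[
                      c(bad, bad)]), collapse = ", "))
  ok <- from_state %in% STATES & to_state %in% STATES
  trans <- ifelse(ok, paste(STATE_CODES[from_state], STATE_CODES[to_state],
                            sep = "->"), NA_character_)
  data.frame(from_state = from_state, to_state = to_state,
             transition = trans,
             category = unname(TRANSITION_CATEGORY[trans]),
             direct = ifelse(ok, trans %in% DIRECT_TRANSITIONS, NA),
             stringsAsFactors = FALSE)
}

as_state_calls <- function(x, which) {
  if (is.data.frame(x)) {
    if (!all(c("gene_id", "state") %in% names(x)))
      stop_validation("'%s' needs gene_id and state columns", which)
    stats::setNames(x$state, x$gene_id)
  } else if (is.character(x) && !is.null(names(x))) {
    x
  } else stop_validation("'%s' must be a state-call data frame or a named character vector", which)
}

#' Per-locus transition records between two conditions
#'
#' Pairs each locus's state in two conditions (identical gene sets
#' required) and classifies the transition.  Loci DISCORDANT in either
#' condition are excluded (default) or coerced to ACTIVE before
#' classification.
#'
#' @param before,after Locus state calls for the two conditions: data
#'   frames from [locus_state_calls()] or named character state vectors.
#' @param coerce_discordant \code{"exclude"} (default) or \code{"active"}.
#' @return Data frame: \code{gene_id}, \code{from_state}, \code{to_state},
#'   \code{transition}, \code{category}, \code{direct}; attribute
#'   \code{n_discordant} counts excluded loci.
#' @export
make_transitions <- function(before, after,
                             coerce_discordant = c("exclude", "active")) {
  coerce_discordant <- match.arg(coerce_discordant)
  s1 <- as_state_calls(before, "before")
  s2 <- as_state_calls(after, "after")
  if (length(s1) != length(s2) || !setequal(names(s1), names(s2)))
    stop_validation("'before' and 'after' must cover the identical locus set")
  s2 <- s2[names(s1)]
  disc <- s1 == "DISCORDANT" | s2 == "DISCORDANT"
  n_disc <- sum(disc)
  if (coerce_discordant == "active") {
    s1[s1 == "DISCORDANT"] <- "ACTIVE"
    s2[s2 == "DISCORDANT"] <- "ACTIVE"
  } else {
    s1 <- s1[!disc]; s2 <- s2[!disc]
  }
  out <- cbind(data.frame(gene_id = names(s1), stringsAsFactors = FALSE),
               classify_transition(unname(s1), unname(s2)))
  rownames(out) <- NULL
  attr(out, "n_discordant") <- n_disc
  out
}

#' Tally the nine state transitions between two conditions
#'
#' Counts every ordered transition between the three states, the changing
#' loci and their split into activation / silencing / priming / archiving,
#' and the share passing through (vs bypassing) the paused intermediate.
#' Percentages of changing loci are reported to one decimal
#' (half-to-even).
#'
#' @param before,after Locus state calls (see [make_transitions()]), or a
#'   transition-record data frame as \code{before} with
#'   \code{after = NULL}.
#' @param coerce_discordant Passed to [make_transitions()].
#' @return An object of class \code{transition_tally}: a list with
#'   \code{n_loci}, \code{counts} (3x3 from-by-to matrix),
#'   \code{transition_counts} (named length-9 vector), \code{n_changing},
#'   \code{changing_percent}, \code{category_counts},
#'   \code{category_percent}, \code{n_direct}, \code{direct_percent},
#'   \code{paused_intermediate_percent}, \code{state_distribution}
#'   (fractions by condition) and \code{n_discordant}.
#' @examples
#' before <- setNames(rep(c("ACTIVE", "SILENT", "PAUSED"), c(4, 3, 3)),
#'                    paste0("G", 1:10))
#' after <- setNames(rep(c("ACTIVE", "PAUSED", "SILENT", "ACTIVE"),
#'                       c(4, 3, 2, 1)), paste0("G", 1:10))
#' tally_transitions(before, after)
#' @export
tally_transitions <- function(before, after = NULL,
                              coerce_discordant = c("exclude", "active")) {
  records <- if (is.null(after)) {
    if (!all(c("from_state", "to_state", "transition") %in% names(before)))
      stop_validation("single-argument form needs transition records")
    before
  } else make_transitions(before, after, match.arg(coerce_discordant))
  counts <- table(from = factor(records$from_state, levels = STATES),
                  to = factor(records$to_state, levels = STATES))
  n <- nrow(records)
  trans_counts <- stats::setNames(as.integer(t(counts)),
                                  as.vector(t(outer(STATE_CODES, STATE_CODES,
                                                    paste, sep = "->"))))
  stable <- sum(diag(counts))
  n_changing <- n - stable
  cats <- c("activation", "silencing", "priming", "archiving")
  cat_counts <- stats::setNames(integer(4), cats)
  tabc <- table(records$category)
  cat_counts[names(tabc)[names(tabc) %in% cats]] <-
    as.integer(tabc[names(tabc) %in% cats])
  n_direct <- sum(records$direct, na.rm = TRUE)
  pct <- function(x) if (n_changing > 0) round1(100 * x / n_changing)
         else rep(NA_real_, length(x))
  dist <- function(s) {
    tb <- table(factor(s, levels = STATES))
    as.numeric(tb) / max(n, 1L)
  }
  structure(list(
    n_loci = n,
    counts = counts,
    transition_counts = trans_counts,
    n_changing = n_changing,
    changing_percent = if (n > 0) round1(100 * n_changing / n) else NA_real_,
    category_counts = cat_counts,
    category_percent = stats::setNames(pct(cat_counts), cats),
    n_direct = n_direct,
    direct_percent = pct(n_direct),
    paused_intermediate_percent = pct(n_changing - n_direct),
    state_distribution = list(
      before = stats::setNames(dist(records$from_state), STATES),
      after = stats::setNames(dist(records$to_state), STATES)),
    n_discordant = attr(records, "n_discordant") %||% 0L),
    class = "transition_tally")
}

#' @export
print.transition_tally <- function(x, ...) {
  cat(sprintf("Transition tally over %d loci (%d DISCORDANT excluded)\n",
              x$n_loci, x$n_discordant))
  cat(sprintf("  state distribution (A/P/S, %%): before %s | after %s\n",
              paste(round1(100 * x$state_distribution$before), collapse = "/"),
              paste(round1(100 * x$state_distribution$after), collapse = "/")))
  cat(sprintf("  changing: %d loci (%.1f%%)\n", x$n_changing,
              x$changing_percent))
  if (x$n_changing > 0) {
    for (cc in names(x$category_counts))
      cat(sprintf("    %-10s %5d  (%.1f%% of changing)\n", cc,
                  x$category_counts[[cc]], x$category_percent[[cc]]))
    cat(sprintf("  via paused intermediate: %.1f%%; direct A<->S: %.1f%% (%d loci)\n",
                x$paused_intermediate_percent, x$direct_percent, x$n_direct))
  }
  invisible(x)
}

#' @export
summary.transition_tally <- function(object, ...) {
  print(object)
  cat("\nNine-transition counts:\n")
  print(object$transition_counts)
  invisible(object)
}

#' State distribution of one condition
#'
#' Fractions of ACTIVE, PAUSED and SILENT loci among non-discordant calls.
#'
#' @param calls Locus state calls (data frame with a \code{state} column,
#'   or a character vector of states).
#' @return Named numeric vector of three fractions summing to 1.
#' @export
state_distribution <- function(calls) {
  s <- if (is.data.frame(calls)) calls$state else calls
  s <- s[s %in% STATES]
  if (!length(s)) stop_validation("no non-discordant loci")
  tb <- table(factor(s, levels = STATES))
  stats::setNames(as.numeric(tb) / length(s), STATES)
}
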