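#' Transition profile of one Gene Ontology term
#'
#' Restricts the genome-wide transition records to a term's gene set and
#' tabulates the nine transitions, the fraction of member loci changing
#' state, and — among changing loci that start PAUSED — the shares that
#' archive (P->S) versus activate (P->A).  Both fate percentages share the
#' denominator of paused-start changing loci.
#'
#' @param genes Character vector of the term's gene ids.
#' @param records Transition records from [make_transitions()].
#' @param go_id,term Term id and name carried into the output.
#' @return A one-row data frame (\code{go_id}, \code{term},
#'   \code{n_genes}, the nine \code{t_*} counts, \code{n_changing},
#'   \code{percent_changing}, \code{n_paused_changing},
#'   \code{percent_archiving}, \code{percent_activating}), or \code{NULL}
#'   (with a message) when the term does not intersect the analyzed loci.
#' @export
profile_term <- function(genes, records, go_id = NA_character_,
                         term = NA_character_) {
  sub <- records[records$gene_id %in% genes, , drop = FALSE]
  if (!nrow(sub)) {
    message(sprintf("profile_term: term %s has no genes among the analyzed loci; skipped",
                    go_id))
    return(NULL)
  }
  trans_names <- as.vector(t(outer(STATE_CODES, STATE_CODES, paste,
                                   sep = "->")))
  tc <- table(factor(sub$transition, levels = trans_names))
  n_genes <- nrow(sub)
  changing <- sub$category != "stable"
  n_changing <- sum(changing)
  paused_start <- changing & sub$from_state == "PAUSED"
  n_ps <- sum(paused_start)
  out <- data.frame(go_id = go_id, term = term, n_genes = n_genes,
                    stringsAsFactors = FALSE)
  cnt <- as.data.frame(as.list(as.integer(tc)))
  names(cnt) <- paste0("t_", sub("->", "", trans_names, fixed = TRUE))
  out <- cbind(out, cnt)
  out$n_changing <- n_changing
  out$percent_changing <- round1(100 * n_changing / n_genes)
  out$n_paused_changing <- n_ps
  out$percent_archiving <- if (n_ps > 0)
    round1(100 * sum(sub$transition == "P->S") / n_ps) else NA_real_
  out$percent_activating <- if (n_ps > 0)
    round1(100 * sum(sub$transition == "P->A") / n_ps) else NA_real_
  out
}

#' Transition profiles for every term of an ontology map
#'
#' @param ontology An \code{ontology_map} from [read_gene2go()].
#' @param records Transition records from [make_transitions()].
#' @return Data frame with one row per term that intersects the analyzed
#'   loci (terms with empty intersection are skipped with a message).
#' @export
profile_terms <- function(ontology, records) {
  if (!inherits(ontology, "ontology_map"))
    stop_validation("'ontology' must be an ontology_map from read_gene2go()")
  rows <- lapply(seq_len(nrow(ontology$terms)), function(i) {
    id <- ontology$terms$go_id[i]
    profile_term(ontology$genes[[id]], records, go_id = id,
                 term = ontology$terms$term[i])
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    stop_validation("no ontology term intersects the analyzed loci")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paused-exit fate report across ontology terms
#'
#' Ranks ontology terms by how their paused-start changing loci exit the
#' paused state: archiving terms (losing initiation) anticipate lineages
#' being shut down, activating terms (gaining elongation) anticipate the
#' fate the population is committing to.
#'
#' @param profiles Term profiles from [profile_terms()].
#' @param sort_by \code{"archiving"} (default) or \code{"activating"}.
#' @param decreasing Sort direction (default \code{TRUE}); ties are broken
#'   by term id.
#' @return Data frame (\code{go_id}, \code{term}, \code{n_genes},
#'   \code{n_paused_changing}, \code{percent_archiving},
#'   \code{percent_activating}) sorted by the chosen column.
#' @export
fate_report <- function(profiles, sort_by = c("archiving", "activating"),
                        decreasing = TRUE) {
  if (is.null(profiles) || !nrow(profiles))
    stop_validation("fate_report needs >= 1 term profile")
  sort_by <- match.arg(sort_by)
  key <- profiles[[paste0("percent_", sort_by)]]
  o <- order(if (decreasing) -key else key, profiles$go_id, na.last = TRUE)
  out <- profiles[o, c("go_id", "term", "n_genes", "n_paused_changing",
                       "percent_archiving", "percent_activating")]
  rownames(out) <- NULL
  out
}
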