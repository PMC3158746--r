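#' Configuration for the H3K4me3 metagene binding call
#'
#' The caller declares a locus H3K4me3-bound if any metagene point exceeds
#' \code{global_threshold} log2 units over panH3 at any offset, or exceeds
#' \code{window_threshold} within the promoter-proximal window
#' \code{[window_start, window_end]} around the TSS.  Both comparisons are
#' strict ("over"); the window endpoints are inclusive.
#'
#' @param global_threshold Genome-wide log2 enrichment threshold
#'   (default 1.5).
#' @param window_threshold Promoter-window log2 enrichment threshold
#'   (default 0.8).
#' @param window_start,window_end Window bounds in bp relative to the TSS,
#'   transcription-oriented (defaults -1250 and +750).
#' @param pseudocount Intensity added to both channels before the ratio to
#'   guard against zero signal (default 1).
#' @param average_replicates Average replicate arrays probe-wise before the
#'   ratio is taken (default \code{TRUE}); \code{FALSE} treats duplicated
#'   offsets as distinct points.
#' @return A list of class \code{chip_config}.
#' @export
chip_config <- function(global_threshold = 1.5, window_threshold = 0.8,
                        window_start = -1250L, window_end = 750L,
                        pseudocount = 1, average_replicates = TRUE) {
  check_scalar_number(global_threshold, "global_threshold", 0, strict_lower = TRUE)
  check_scalar_number(window_threshold, "window_threshold", 0, strict_lower = TRUE)
  check_scalar_number(pseudocount, "pseudocount", 0, strict_lower = TRUE)
  if (!is.numeric(window_start) || !is.numeric(window_end) ||
      window_start >= window_end)
    stop_validation("window_start must be < window_end")
  structure(list(global_threshold = global_threshold,
                 window_threshold = window_threshold,
                 window_start = as.integer(window_start),
                 window_end = as.integer(window_end),
                 pseudocount = pseudocount,
                 average_replicates = isTRUE(average_replicates)),
            class = "chip_config")
}

#' Build a single-locus metagene profile
#'
#' Collapses probe-level two-channel signal for one gene into an ordered
#' metagene of log2(H3K4me3/panH3) values at signed TSS offsets.  A
#' pseudocount is added to both channels; replicate measurements at the
#' same offset are averaged channel-wise before the ratio is taken
#' (when \code{config$average_replicates} is \code{TRUE}).
#'
#' @param records Probe-signal data frame for one gene (columns
#'   \code{gene_id}, \code{offset}, \code{h3k4me3}, \code{panh3}).
#' @param config A [chip_config()].
#' @return A data frame of class \code{metagene} with columns
#'   \code{offset} (strictly increasing) and \code{log_ratio}, and
#'   attribute \code{gene_id}.
#' @examples
#' rec <- data.frame(gene_id = "G1", offset = c(500, -500),
#'                   h3k4me3 = c(63, 15), panh3 = c(15, 15))
#' build_metagene(rec, chip_config())
#' @export
build_metagene <- function(records, config = chip_config()) {
  if (is.null(records) || !nrow(records))
    stop_validation("no probe records for this gene (excluded from the analyzed set)")
  gid <- unique(records$gene_id)
  if (length(gid) != 1L)
    stop_validation("build_metagene expects records for exactly one gene, got %d",
                    length(gid))
  if (any(records$h3k4me3 < 0 | records$panh3 < 0))
    stop_validation("negative intensity for gene '%s'", gid)
  if (config$average_replicates && anyDuplicated(records$offset)) {
    k4 <- tapply(records$h3k4me3, records$offset, mean)
    h3 <- tapply(records$panh3, records$offset, mean)
    off <- as.integer(names(k4))
  } else {
    off <- records$offset
    k4 <- records$h3k4me3
    h3 <- records$panh3
  }
  o <- order(off)
  prof <- data.frame(
    offset = off[o],
    log_ratio = log2((k4[o] + config$pseudocount) /
                     (h3[o] + config$pseudocount)))
  rownames(prof) <- NULL
  attr(prof, "gene_id") <- gid
  class(prof) <- c("metagene", "data.frame")
  prof
}

#' Dual-threshold H3K4me3 binding call on a metagene
#'
#' A locus is called bound if any point's log-ratio strictly exceeds the
#' global threshold (trigger \code{"global"}), or failing that, if any
#' point within the promoter window strictly exceeds the window threshold
#' (trigger \code{"window"}); otherwise the locus is unbound (trigger
#' \code{"none"}).
#'
#' @param profile A metagene from [build_metagene()], or any data frame
#'   with \code{offset} and \code{log_ratio} columns.
#' @param config A [chip_config()].
#' @return A one-row data frame: \code{gene_id}, \code{bound},
#'   \code{trigger}, \code{max_log_ratio}, \code{max_window_log_ratio}
#'   (\code{NA} if the profile has no in-window point).
#' @export
call_h3k4me3 <- function(profile, config = chip_config()) {
  if (!nrow(profile)) stop_validation("empty metagene profile")
  lr <- profile$log_ratio
  in_win <- profile$offset >= config$window_start &
    profile$offset <= config$window_end
  max_lr <- max(lr)
  max_win <- if (any(in_win)) max(lr[in_win]) else NA_real_
  trigger <- if (max_lr > config$global_threshold) "global"
             else if (any(in_win) && max_win > config$window_threshold) "window"
             else "none"
  data.frame(gene_id = attr(profile, "gene_id") %||% NA_character_,
             bound = trigger != "none", trigger = trigger,
             max_log_ratio = max_lr, max_window_log_ratio = max_win,
             stringsAsFactors = FALSE)
}

#' Binding calls for every gene on a promoter array
#'
#' Vectorised application of [build_metagene()] + [call_h3k4me3()] over all
#' genes present in a probe-signal table.
#'
#' @param records Probe-signal data frame (as returned by
#'   [read_probe_signals()]) covering many genes.
#' @param config A [chip_config()].
#' @return A data frame with one row per gene: \code{gene_id},
#'   \code{bound}, \code{trigger}, \code{max_log_ratio},
#'   \code{max_window_log_ratio}, \code{n_probes}.
#' @export
call_chip <- function(records, config = chip_config()) {
  if (!nrow(records)) stop_validation("no probe records")
  if (any(records$h3k4me3 < 0 | records$panh3 < 0))
    stop_validation("negative intensity in probe records")
  if (config$average_replicates) {
    key <- paste(records$gene_id, records$offset, sep = "\r")
    if (anyDuplicated(key)) {
      k4 <- tapply(records$h3k4me3, key, mean)
      h3 <- tapply(records$panh3, key, mean)
      parts <- strsplit(names(k4), "\r", fixed = TRUE)
      records <- data.frame(
        gene_id = vapply(parts, `[`, "", 1L),
        offset = as.integer(vapply(parts, `[`, "", 2L)),
        h3k4me3 = as.numeric(k4), panh3 = as.numeric(h3),
        stringsAsFactors = FALSE)
    }
  }
  lr <- log2((records$h3k4me3 + config$pseudocount) /
             (records$panh3 + config$pseudocount))
  in_win <- records$offset >= config$window_start &
    records$offset <= config$window_end
  gene <- records$gene_id
  max_lr <- tapply(lr, gene, max)
  max_win <- tapply(ifelse(in_win, lr, -Inf), gene, max)
  n_probes <- as.integer(tapply(lr, gene, length))
  ids <- names(max_lr)
  max_win_out <- ifelse(is.finite(max_win), max_win, NA_real_)
  trigger <- ifelse(max_lr > config$global_threshold, "global",
             ifelse(is.finite(max_win) & max_win > config$window_threshold,
                    "window", "none"))
  out <- data.frame(gene_id = ids, bound = trigger != "none",
                    trigger = trigger,
                    max_log_ratio = as.numeric(max_lr),
                    max_window_log_ratio = as.numeric(max_win_out),
                    n_probes = n_probes, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
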