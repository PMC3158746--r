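#' Configuration for transcript detection calls
#'
#' @param detection_alpha Detection p-value below which a probe is taken as
#'   evidence of full-length transcript (default \code{1e-3}).
#' @param score_floor Detection-score floor for the probe filter: a probe
#'   with score \eqn{1 - p} below this floor in \emph{every} sample is
#'   discarded (default 0.99).
#' @param replicate_rule,probe_rule How detections aggregate to the gene
#'   level: \code{"any"} (default) requires the criterion in at least one
#'   replicate / probe, \code{"all"} in every one.
#' @return A list of class \code{expr_config}.
#' @export
expr_config <- function(detection_alpha = 1e-3, score_floor = 0.99,
                        replicate_rule = c("any", "all"),
                        probe_rule = c("any", "all")) {
  check_scalar_number(detection_alpha, "detection_alpha", 0, 1)
  if (detection_alpha <= 0 || detection_alpha >= 1)
    stop_validation("detection_alpha must be in (0, 1)")
  check_scalar_number(score_floor, "score_floor", 0, 1)
  if (score_floor <= 0 || score_floor >= 1)
    stop_validation("score_floor must be in (0, 1)")
  structure(list(detection_alpha = detection_alpha,
                 score_floor = score_floor,
                 replicate_rule = match.arg(replicate_rule),
                 probe_rule = match.arg(probe_rule)),
            class = "expr_config")
}

#' Detection p-value against the negative-control pool
#'
#' One-sided (signal above background) pooled-variance two-sample Student
#' t-test of a probe's bead summary against the sample's negative-control
#' intensity pool, computed from the two groups' means, SDs and counts.
#' With zero pooled variance the p-value degenerates to 0.5 for equal
#' means, and to 0 / 1 for a probe mean above / below the controls.
#'
#' @param mean,sd,n Probe bead summaries (vectorised over probes);
#'   \code{n} must be \eqn{\ge 2}.
#' @param controls Numeric vector of negative-control intensities for the
#'   sample (length \eqn{\ge 2}).
#' @return A data frame with columns \code{p_value} and
#'   \code{detection_score} (\eqn{1 - p}).
#' @examples
#' detection_pvalue(120, 10, 30, rnorm(50, 100, 10))
#' @export
detection_pvalue <- function(mean, sd, n, controls) {
  if (length(controls) < 2L)
    stop_validation("negative-control pool must have >= 2 members")
  k <- max(length(mean), length(sd), length(n))
  if (!all(lengths(list(mean, sd, n)) %in% c(1L, k)))
    stop_validation("probe mean/sd/n lengths must match or be scalar")
  mean <- rep_len(mean, k); sd <- rep_len(sd, k); n <- rep_len(n, k)
  if (any(n < 2L))
    stop_validation("probe bead_count must be >= 2")
  if (any(sd < 0))
    stop_validation("probe sd must be >= 0")
  m0 <- base::mean(controls)
  s0 <- stats::sd(controls)
  n0 <- length(controls)
  df <- n + n0 - 2L
  sp2 <- ((n - 1L) * sd^2 + (n0 - 1L) * s0^2) / df
  se <- sqrt(sp2 * (1 / n + 1 / n0))
  p <- ifelse(se > 0,
              stats::pt((mean - m0) / se, df, lower.tail = FALSE),
              ifelse(mean == m0, 0.5, ifelse(mean > m0, 0, 1)))
  data.frame(p_value = p, detection_score = 1 - p)
}

#' Score every probe in every expression sample
#'
#' Applies [detection_pvalue()] to each non-control probe of each sample,
#' using that sample's negative-control probes as the background pool.
#'
#' @param expr Long expression data frame from [read_expression_table()]
#'   or [simulate_expression()].
#' @return Data frame: \code{probe_id}, \code{gene_id}, \code{sample_id},
#'   \code{condition}, \code{replicate}, \code{p_value},
#'   \code{detection_score}.
#' @export
detect_expression <- function(expr) {
  if (!nrow(expr)) stop_validation("empty expression table")
  out <- lapply(split(expr, expr$sample_id), function(s) {
    ctrl <- s$mean_intensity[s$control == 1L]
    if (length(ctrl) < 2L)
      stop_validation("sample '%s': negative-control pool must have >= 2 members",
                      s$sample_id[1])
    probes <- s[s$control == 0L, , drop = FALSE]
    det <- detection_pvalue(probes$mean_intensity, probes$bead_sd,
                            probes$bead_count, ctrl)
    cbind(probes[c("probe_id", "gene_id", "sample_id", "condition",
                   "replicate")], det)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Filter probes undetected in every sample
#'
#' A probe is discarded if and only if its detection score falls below the
#' floor in \emph{all} samples; detection anywhere retains it everywhere.
#'
#' @param detections Detection results from [detect_expression()] covering
#'   every sample of the study.
#' @param config An [expr_config()].
#' @return Character vector of retained probe ids.
#' @export
filter_probes <- function(detections, config = expr_config()) {
  if (!nrow(detections) || !length(unique(detections$sample_id)))
    stop_validation("filter_probes needs scored probes for >= 1 sample")
  below_everywhere <- tapply(detections$detection_score < config$score_floor,
                             detections$probe_id, all)
  names(below_everywhere)[!below_everywhere]
}

#' Quantile normalization across samples
#'
#' Forces every column (sample) of an intensity matrix onto the common
#' reference distribution given by the row-wise mean of the per-column
#' sorted values, preserving within-column ranks; ties receive the average
#' of the tied reference quantiles.  Delegates to
#' \code{limma::normalizeQuantiles}.
#'
#' @param mat Numeric matrix, probes in rows, samples in columns; no
#'   missing values.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (!ncol(mat)) stop_validation("quantile_normalize needs >= 1 sample")
  if (anyNA(mat)) stop_validation("missing values among retained probes")
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Gene-level full-length transcript calls
#'
#' Aggregates retained-probe detection p-values to one call per gene and
#' condition: under the default \code{any}/\code{any} rules a gene is
#' called expressed if any retained probe reaches
#' \eqn{p < } \code{detection_alpha} in any replicate of the condition.
#' Genes whose probes were all discarded by [filter_probes()] are called
#' not expressed with flag \code{"no_probe"}.
#'
#' @param detections Detection results from [detect_expression()].
#' @param retained Character vector of retained probe ids from
#'   [filter_probes()].
#' @param config An [expr_config()].
#' @param genes Gene universe to report (default: all genes present in
#'   \code{detections}).
#' @return Data frame: \code{gene_id}, \code{condition}, \code{expressed},
#'   \code{min_p}, \code{flag} (\code{"ok"} or \code{"no_probe"}), one row
#'   per gene and condition.
#' @export
call_transcripts <- function(detections, retained = NULL,
                             config = expr_config(), genes = NULL) {
  if (is.null(retained)) retained <- unique(detections$probe_id)
  if (is.null(genes)) genes <- sort(unique(detections$gene_id))
  det <- detections[detections$probe_id %in% retained, , drop = FALSE]
  conds <- sort(unique(detections$condition))
  rows <- vector("list", length(conds))
  for (ci in seq_along(conds)) {
    d <- det[det$condition == conds[ci], , drop = FALSE]
    expressed <- stats::setNames(rep(FALSE, length(genes)), genes)
    min_p <- stats::setNames(rep(NA_real_, length(genes)), genes)
    flag <- stats::setNames(rep("no_probe", length(genes)), genes)
    if (nrow(d)) {
      hit <- d$p_value < config$detection_alpha
      # collapse replicates within probe, then probes within gene
      rep_agg <- if (config$replicate_rule == "any") any else all
      probe_agg <- if (config$probe_rule == "any") any else all
      by_probe <- tapply(hit, list(d$gene_id, d$probe_id),
                         function(h) rep_agg(h))
      gene_hit <- apply(by_probe, 1L, function(h) probe_agg(h[!is.na(h)]))
      gmin <- tapply(d$p_value, d$gene_id, min)
      g <- intersect(names(gene_hit), genes)
      expressed[g] <- gene_hit[g]
      min_p[g] <- gmin[g]
      flag[g] <- "ok"
    }
    rows[[ci]] <- data.frame(gene_id = genes, condition = conds[ci],
                             expressed = as.logical(expressed),
                             min_p = as.numeric(min_p), flag = flag,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
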