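#' Read a BED6 TSS annotation
#'
#' Reads a tab-delimited BED6 file (chrom, start, end, name, score, strand)
#' and derives the transcription start site of each gene under 0-based,
#' half-open BED semantics: the TSS of a plus-strand gene is the interval
#' start, and of a minus-strand gene the interval end.
#'
#' @param path Path to a BED6 file.  Lines starting with \code{#} or
#'   \code{track} are skipped.
#' @return A data frame with columns \code{gene_id}, \code{chromosome},
#'   \code{strand} (\code{"+"} or \code{"-"}) and \code{tss} (0-based
#'   genomic coordinate), one row per gene.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t1000\t2000\tGENE1\t0\t+",
#'              "chr1\t5000\t9000\tGENE2\t0\t-"), bed)
#' read_tss_annotation(bed)
#' @export
read_tss_annotation <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: '%s'", path)
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !startsWith(lines, "#") & !startsWith(lines, "track") &
    nzchar(lines)
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  recs <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    line_no <- idx[i]
    if (length(f) < 6L)
      stop_validation("line %d: expected 6 tab-delimited BED fields, got %d",
                      line_no, length(f))
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end))
      stop_validation("line %d: non-integer start/end coordinate", line_no)
    if (start < 0L || end < start)
      stop_validation("line %d: invalid interval [%d, %d)", line_no,
                      start, end)
    if (!f[6] %in% c("+", "-"))
      stop_validation("line %d: strand must be '+' or '-', got '%s'",
                      line_no, f[6])
    recs[[i]] <- data.frame(
      gene_id = f[4], chromosome = f[1], strand = f[6],
      tss = if (f[6] == "+") start else end,
      stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, recs)
  if (is.null(ann))
    ann <- data.frame(gene_id = character(), chromosome = character(),
                      strand = character(), tss = integer())
  dup <- unique(ann$gene_id[duplicated(ann$gene_id)])
  if (length(dup))
    stop_validation("duplicate gene_id(s) in TSS annotation: %s",
                    paste(utils::head(dup, 5L), collapse = ", "))
  ann
}

#' Read a probe-level ChIP signal table
#'
#' Reads a tab-delimited table of promoter-array probe signals with columns
#' \code{probe_id}, \code{gene_id}, \code{offset} (signed bp from the TSS,
#' oriented in the direction of transcription; negative = upstream),
#' \code{h3k4me3} and \code{panh3} (non-negative raw intensities).  Records
#' for genes absent from \code{annotation} are dropped with a message giving
#' the count; offsets outside the array's \eqn{\pm 4} kb design window are
#' rejected.
#'
#' @param path Path to a tab-delimited probe-signal table with a
#'   \code{#}-prefixed header line.
#' @param annotation TSS annotation from [read_tss_annotation()], used as
#'   the gene universe.  \code{NULL} skips the membership filter.
#' @param max_offset Half-width of the probe design window in bp
#'   (default 4000).
#' @return Data frame of retained probe records, with attribute
#'   \code{n_dropped} giving the number of records dropped for unknown
#'   gene ids.
#' @export
read_probe_signals <- function(path, annotation = NULL, max_offset = 4000L) {
  df <- read_hash_table(path, col_types = list(
    probe_id = "character", gene_id = "character", offset = "integer",
    h3k4me3 = "numeric", panh3 = "numeric"))
  need <- c("probe_id", "gene_id", "offset", "h3k4me3", "panh3")
  if (!all(need %in% names(df)))
    stop_validation("probe-signal table must have columns: %s",
                    paste(need, collapse = ", "))
  if (any(is.na(df$offset)))
    stop_validation("non-integer probe offset in '%s'", path)
  bad <- abs(df$offset) > max_offset
  if (any(bad))
    stop_validation(
      "%d probe offset(s) outside the [-%d, +%d] design window (first: %s at %+d)",
      sum(bad), max_offset, max_offset,
      df$probe_id[bad][1], df$offset[bad][1])
  if (any(df$h3k4me3 < 0 | df$panh3 < 0, na.rm = TRUE) ||
      any(is.na(df$h3k4me3)) || any(is.na(df$panh3)))
    stop_validation("negative or missing intensity in '%s'", path)
  n_dropped <- 0L
  if (!is.null(annotation)) {
    known <- df$gene_id %in% annotation$gene_id
    n_dropped <- sum(!known)
    if (n_dropped)
      message(sprintf("read_probe_signals: dropped %d record(s) for genes absent from the annotation",
                      n_dropped))
    df <- df[known, , drop = FALSE]
    rownames(df) <- NULL
  }
  attr(df, "n_dropped") <- n_dropped
  df
}

#' Read an expression sample table
#'
#' Reads one or more bead-array expression sample tables (tab-delimited,
#' \code{#}-prefixed header) with columns \code{probe_id}, \code{gene_id}
#' (empty or \code{"-"} for negative-control probes), \code{control}
#' (0/1 flag), \code{sample_id}, \code{condition}, \code{replicate},
#' \code{mean_intensity}, \code{bead_sd}, \code{bead_count}.
#'
#' @param paths Character vector of file paths; rows are concatenated.
#' @return A long data frame, one row per (probe, sample).
#' @export
read_expression_table <- function(paths) {
  out <- lapply(paths, function(p) {
    df <- read_hash_table(p, col_types = list(
      probe_id = "character", gene_id = "character", control = "integer",
      sample_id = "character", condition = "character",
      replicate = "integer", mean_intensity = "numeric",
      bead_sd = "numeric", bead_count = "integer"))
    need <- c("probe_id", "gene_id", "control", "sample_id", "condition",
              "replicate", "mean_intensity", "bead_sd", "bead_count")
    if (!all(need %in% names(df)))
      stop_validation("expression table '%s' must have columns: %s", p,
                      paste(need, collapse = ", "))
    df
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  if (nrow(df)) {
    if (any(df$bead_count < 1L))
      stop_validation("bead_count must be >= 1")
    per_sample_ctrl <- tapply(df$control == 1L, df$sample_id, sum)
    if (any(per_sample_ctrl < 1L))
      stop_validation("every sample needs at least one negative-control probe")
    multi <- tapply(df$gene_id[df$control == 0L], df$probe_id[df$control == 0L],
                    function(g) length(unique(g)))
    if (any(multi > 1L))
      stop_validation("a non-control probe maps to more than one gene_id")
  }
  df
}

#' Read an NCBI gene2go annotation file
#'
#' Parses the NCBI \code{gene2go} dialect: an optional \code{#} header
#' line followed by tab-delimited columns tax_id, GeneID, GO_ID, Evidence,
#' Qualifier, GO_term, PubMed, Category.  Rows whose Qualifier contains
#' \code{NOT} are excluded and (gene, term) memberships are deduplicated.
#'
#' @param path Path to an uncompressed gene2go-format file.
#' @return An object of class \code{ontology_map}: a list with
#'   \code{terms} (data frame: \code{go_id}, \code{term}, \code{category})
#'   and \code{genes} (named list mapping \code{go_id} to a character
#'   vector of gene ids).
#' @export
read_gene2go <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: '%s'", path)
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !startsWith(lines, "#") & nzchar(lines)
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  n_col <- lengths(fields)
  if (any(n_col != 8L)) {
    i <- which(n_col != 8L)[1]
    stop_validation("line %d: expected 8 tab-delimited gene2go columns, got %d",
                    idx[i], n_col[i])
  }
  m <- do.call(rbind, fields)
  colnames(m) <- c("tax_id", "gene_id", "go_id", "evidence", "qualifier",
                   "term", "pubmed", "category")
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  df <- df[!grepl("NOT", df$qualifier, fixed = TRUE), , drop = FALSE]
  bad_id <- !grepl("^GO:[0-9]{7}$", df$go_id)
  if (any(bad_id))
    stop_validation("malformed GO id(s): %s",
                    paste(utils::head(unique(df$go_id[bad_id]), 5L),
                          collapse = ", "))
  df <- df[!duplicated(df[c("gene_id", "go_id")]), , drop = FALSE]
  ids <- sort(unique(df$go_id))
  genes <- lapply(ids, function(g) unique(df$gene_id[df$go_id == g]))
  names(genes) <- ids
  terms <- df[!duplicated(df$go_id), c("go_id", "term", "category")]
  terms <- terms[match(ids, terms$go_id), , drop = FALSE]
  rownames(terms) <- NULL
  structure(list(terms = terms, genes = genes), class = "ontology_map")
}

#' @export
print.ontology_map <- function(x, ...) {
  cat(sprintf("Ontology map: %d terms, %d distinct genes\n",
              nrow(x$terms), length(unique(unlist(x$genes)))))
  invisible(x)
}

#' Write / read locus state-call tables
#'
#' State tables are tab-delimited with a \code{#}-prefixed header and one
#' row per locus (\code{gene_id}, \code{condition}, \code{initiating},
#' \code{elongating}, \code{state}); they round-trip losslessly through
#' [read_state_table()].
#'
#' @param calls Data frame of locus state calls (see [locus_state_calls()]).
#' @param path Output (input) file path.
#' @return \code{write_state_table} returns \code{path} invisibly;
#'   \code{read_state_table} returns the state-call data frame.
#' @export
write_state_table <- function(calls, path) {
  cols <- c("gene_id", "condition", "initiating", "elongating", "state")
  if (!all(cols %in% names(calls)))
    stop_validation("state table needs columns: %s", paste(cols, collapse = ", "))
  invisible(write_hash_table(calls[cols], path,
                             comments = "locus transcriptional state calls"))
}

#' @rdname write_state_table
#' @export
read_state_table <- function(path) {
  read_hash_table(path, col_types = list(
    gene_id = "character", condition = "character",
    initiating = "logical", elongating = "logical", state = "character"))
}

#' Write / read transition tables
#'
#' Transition tables are tab-delimited with a \code{#}-prefixed header and
#' one row per locus (\code{gene_id}, \code{from_state}, \code{to_state},
#' \code{transition}, \code{category}, \code{direct}); they round-trip
#' losslessly through [read_transition_table()].
#'
#' @param records Transition records from [make_transitions()].
#' @param path Output (input) file path.
#' @export
write_transition_table <- function(records, path) {
  cols <- c("gene_id", "from_state", "to_state", "transition", "category",
            "direct")
  if (!all(cols %in% names(records)))
    stop_validation("transition table needs columns: %s",
                    paste(cols, collapse = ", "))
  invisible(write_hash_table(records[cols], path,
                             comments = "locus state transitions"))
}

#' @rdname write_transition_table
#' @export
read_transition_table <- function(path) {
  read_hash_table(path, col_types = list(
    gene_id = "character", from_state = "character", to_state = "character",
    transition = "character", category = "character", direct = "logical"))
}
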