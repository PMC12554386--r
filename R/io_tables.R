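# Community-table container, readers/writers and the abundance transforms
# shared by every downstream stage.

#' Construct a validated community table
#'
#' The universal input of the package: a taxa-by-samples matrix of
#' non-negative counts plus a sample-to-group mapping. Validation enforces
#' the invariants every downstream stage relies on: at least 2 OTUs and 2
#' samples, duplicate-free ids, every sample mapped to a group, and positive
#' library sizes.
#'
#' @param counts Numeric matrix, rows = OTUs, columns = samples. Row and
#'   column names are the OTU and sample ids and must be present and unique.
#' @param groups Named character vector mapping every sample id to a group
#'   label.
#' @return An object of class `community_table` with elements `counts`
#'   (integer-valued numeric matrix) and `groups`.
#' @export
#' @examples
#' m <- matrix(rpois(12, 5), 3, 4,
#'             dimnames = list(paste0("OTU", 1:3), paste0("S", 1:4)))
#' ct <- community_table(m, setNames(rep(c("A", "B"), each = 2), colnames(m)))
community_table <- function(counts, groups) {
  if (!is.matrix(counts)) abort_arg("`counts` must be a matrix")
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    abort_arg("community table needs at least 2 OTUs and 2 samples, got %d x %d",
              nrow(counts), ncol(counts))
  }
  otu_ids <- rownames(counts)
  sample_ids <- colnames(counts)
  if (is.null(otu_ids) || anyNA(otu_ids) || any(otu_ids == "")) {
    abort_arg("`counts` must have non-empty row names (OTU ids)")
  }
  if (is.null(sample_ids) || anyNA(sample_ids) || any(sample_ids == "")) {
    abort_arg("`counts` must have non-empty column names (sample ids)")
  }
  if (anyDuplicated(otu_ids)) {
    abort_arg("duplicate OTU ids: %s",
              paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    abort_arg("duplicate sample ids: %s",
              paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (!is.numeric(counts) || anyNA(counts) || any(!is.finite(counts))) {
    abort_arg("counts must be finite and numeric")
  }
  bad <- which(counts < 0 | abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort_arg("invalid count %s for OTU '%s' in sample '%s' (must be a non-negative integer)",
              format(counts[bad[1L, , drop = FALSE]]),
              otu_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]])
  }
  counts <- round(counts)
  if (!is.character(groups) || is.null(names(groups))) {
    abort_arg("`groups` must be a named character vector (sample_id -> group)")
  }
  unmapped <- setdiff(sample_ids, names(groups))
  if (length(unmapped) > 0L) {
    abort_arg("samples missing from metadata: %s", paste(unmapped, collapse = ", "))
  }
  groups <- groups[sample_ids]
  if (anyNA(groups) || any(groups == "")) {
    abort_arg("empty group label for sample(s): %s",
              paste(sample_ids[is.na(groups) | groups == ""], collapse = ", "))
  }
  libsize <- colSums(counts)
  if (any(libsize == 0)) {
    abort_arg("zero library size (all-zero column) for sample(s): %s",
              paste(sample_ids[libsize == 0], collapse = ", "))
  }
  structure(list(counts = counts, groups = groups), class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("community_table: %d OTUs x %d samples, %d group(s) (%s)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$groups)),
              paste(unique(x$groups), collapse = ", ")))
  cat(sprintf("library sizes: %s\n",
              paste(range(colSums(x$counts)), collapse = " - ")))
  invisible(x)
}

#' @export
dim.community_table <- function(x) dim(x$counts)

#' Sample ids, OTU ids and group labels of a community table
#' @param table A `community_table`.
#' @return Character vector.
#' @export
otu_ids <- function(table) rownames(table$counts)

#' @rdname otu_ids
#' @export
sample_ids <- function(table) colnames(table$counts)

#' Restrict a community table to a subset of samples and/or OTUs
#'
#' Used by every group- or guild-stratified stage. OTUs that become all-zero
#' inside the restriction are dropped (the global table keeps them; restricted
#' computations do not see them). Errors if fewer than 2 samples or 2 OTUs
#' remain.
#'
#' @param table A `community_table`.
#' @param samples,otus Character vectors of ids to keep (default: all).
#' @param drop_empty_otus Drop OTUs with zero total in the restriction.
#' @return A `community_table`.
#' @export
subset_table <- function(table, samples = NULL, otus = NULL, drop_empty_otus = TRUE) {
  stopifnot(inherits(table, "community_table"))
  counts <- table$counts
  if (!is.null(otus)) {
    missing_otus <- setdiff(otus, rownames(counts))
    if (length(missing_otus)) abort_arg("unknown OTU id(s): %s", paste(missing_otus, collapse = ", "))
    counts <- counts[otus, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, colnames(counts))
    if (length(missing_s)) abort_arg("unknown sample id(s): %s", paste(missing_s, collapse = ", "))
    counts <- counts[, samples, drop = FALSE]
  }
  if (drop_empty_otus) counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  community_table(counts, table$groups[colnames(counts)])
}

#' Read an OTU table and its sample metadata
#'
#' The OTU table is tab-separated UTF-8 with a header row of sample ids and
#' the first column holding OTU ids ("." decimal, ids unquoted; the first
#' header cell is ignored). Metadata is a TSV with columns `sample_id` and
#' `group`. Samples absent from the metadata are rejected; metadata rows for
#' unknown samples are ignored.
#'
#' @param path Path to the OTU count TSV.
#' @param metadata_path Path to the metadata TSV.
#' @return A validated [community_table()].
#' @export
read_community_table <- function(path, metadata_path) {
  force(path)
  force(metadata_path)
  raw <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE, quote = ""),
    error = function(e) abort_arg("failed to parse OTU table '%s': %s", path, conditionMessage(e))
  )
  if (ncol(raw) < 3L) abort_arg("OTU table '%s' needs an id column plus >= 2 samples", path)
  ids <- as.character(raw[[1L]])
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(mat, 2, as.numeric))), arr.ind = TRUE)
    line_hint <- if (nrow(bad)) sprintf(" (first offending row %d, line %d of file)",
                                        bad[1L, 1L], bad[1L, 1L] + 1L) else ""
    abort_arg("non-numeric count value in OTU table '%s'%s", path, line_hint)
  }
  rownames(mat) <- ids
  meta <- tryCatch(
    utils::read.delim(metadata_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, quote = ""),
    error = function(e) abort_arg("failed to parse metadata '%s': %s", metadata_path, conditionMessage(e))
  )
  if (!all(c("sample_id", "group") %in% names(meta))) {
    abort_arg("metadata '%s' must have columns sample_id and group", metadata_path)
  }
  groups <- stats::setNames(as.character(meta$group), as.character(meta$sample_id))
  community_table(mat, groups)
}

#' Convert counts to relative abundances
#'
#' `per_sample` divides each column by its library size (columns sum to 1);
#' `per_otu` divides each row by its total (rows sum to 1), the normalization
#' under which Levins' niche breadth is conventionally computed. Rows with
#' zero total are dropped with a warning under `per_otu`.
#'
#' @param table A `community_table`.
#' @param axis `"per_sample"` or `"per_otu"`.
#' @return An object of class `relative_abundance_table` with elements
#'   `proportions`, `groups`, `axis`.
#' @export
to_relative_abundance <- function(table, axis = c("per_sample", "per_otu")) {
  stopifnot(inherits(table, "community_table"))
  axis <- match.arg(axis)
  counts <- table$counts
  if (axis == "per_sample") {
    libsize <- colSums(counts)
    if (any(libsize == 0)) {
      abort_arg("all-zero column(s): %s", paste(colnames(counts)[libsize == 0], collapse = ", "))
    }
    prop <- sweep(counts, 2L, libsize, "/")
  } else {
    totals <- rowSums(counts)
    if (any(totals == 0)) {
      warning(sprintf("dropping %d all-zero OTU row(s): %s", sum(totals == 0),
                      paste(utils::head(rownames(counts)[totals == 0], 5L), collapse = ", ")),
              call. = FALSE)
      counts <- counts[totals > 0, , drop = FALSE]
      totals <- totals[totals > 0]
    }
    prop <- sweep(counts, 1L, totals, "/")
  }
  structure(list(proportions = prop, groups = table$groups, axis = axis),
            class = "relative_abundance_table")
}

#' Keep the n most abundant OTUs
#'
#' Abundance is the total count across all samples. Ties are broken by
#' lexicographic OTU id so results are platform-independent. If the table has
#' fewer than `n` OTUs, all are retained with a warning. Idempotent.
#'
#' @param table A `community_table`.
#' @param n Number of OTUs to keep (>= 2).
#' @return A `community_table` with the retained OTUs, in decreasing-total
#'   (then lexicographic) order.
#' @export
filter_top_n <- function(table, n) {
  stopifnot(inherits(table, "community_table"))
  if (!is.numeric(n) || length(n) != 1L || n < 2) abort_arg("`n` must be a single integer >= 2")
  n <- as.integer(n)
  totals <- rowSums(table$counts)
  ord <- order(-totals, rownames(table$counts), method = "radix")
  if (n >= length(ord)) {
    if (n > length(ord)) {
      warning(sprintf("requested top %d of %d OTUs; returning all", n, length(ord)),
              call. = FALSE)
    }
    keep <- ord
  } else {
    keep <- ord[seq_len(n)]
  }
  community_table(table$counts[keep, , drop = FALSE], table$groups)
}

# ---- result record serialization --------------------------------------------

RESULT_SCHEMA_VERSION <- "1.0"

result_record_classes <- c(
  "community_table", "guild_classification", "ncm_fit", "nst_result",
  "co_network", "topology_metrics", "study_report"
)

#' Write a result record to TSV or JSON
#'
#' All package result records (guild classifications, NCM fits, NST results,
#' networks, topology metrics, study reports) and community tables share one
#' writer. JSON output is lossless for numeric fields (full double precision)
#' and carries a `schema_version` key; [read_results()] restores the record.
#' TSV output gives the record's natural tabular form at >= 15 significant
#' digits.
#'
#' @param record A package result record.
#' @param path Output file path.
#' @param format `"TSV"` or `"JSON"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(record, path, format = c("JSON", "TSV")) {
  format <- match.arg(toupper(format[1L]), c("JSON", "TSV"))
  cls <- intersect(class(record), result_record_classes)
  if (length(cls) == 0L) {
    abort_arg("write_results: unknown record type <%s>", paste(class(record), collapse = "/"))
  }
  if (format == "JSON") {
    payload <- list(schema_version = RESULT_SCHEMA_VERSION,
                    record_class = cls[1L],
                    record = strip_for_json(record))
    ok <- tryCatch({
      jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null")
      TRUE
    }, error = function(e) abort_arg("cannot write '%s': %s", path, conditionMessage(e)))
  } else {
    df <- as_result_df(record)
    num <- vapply(df, is.numeric, logical(1L))
    df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE, scientific = FALSE))
    tryCatch(
      utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE),
      error = function(e) abort_arg("cannot write '%s': %s", path, conditionMessage(e))
    )
  }
  invisible(path)
}

# Attributes (seeds, parameters) are folded into the JSON payload so the
# round-trip is complete.
strip_for_json <- function(record) {
  at <- attributes(record)
  at$class <- NULL; at$names <- NULL; at$row.names <- NULL
  if (is.data.frame(record)) {
    out <- list(data = record)
  } else {
    out <- list(data = unclass(record))
  }
  if (length(at)) out$attrs <- at
  out
}

#' Re-read a JSON result record written by write_results
#' @param path Path to a JSON file from [write_results()].
#' @return The restored record.
#' @export
read_results <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(payload$schema_version)) abort_arg("'%s' lacks a schema_version key", path)
  rec <- payload$record$data
  if (identical(payload$record_class, "community_table")) {
    counts <- rec$counts
    rec$counts <- matrix(unlist(counts), nrow = length(counts), byrow = TRUE,
                         dimnames = list(names(counts), names(counts[[1L]])))
    if (is.null(dimnames(rec$counts)[[2L]])) {
      # jsonlite keeps matrix shape when homogeneous; fall back to stored dimnames
      rec$counts <- payload$record$data$counts
    }
    return(community_table(rec$counts, unlist(rec$groups)))
  }
  if (!is.null(payload$record$attrs)) {
    for (nm in names(payload$record$attrs)) attr(rec, nm) <- payload$record$attrs[[nm]]
  }
  class(rec) <- c(payload$record_class, class(rec))
  rec
}

as_result_df <- function(record) {
  if (is.data.frame(record)) return(as.data.frame(record))
  if (inherits(record, "community_table")) {
    return(data.frame(otu_id = rownames(record$counts), record$counts,
                      check.names = FALSE))
  }
  if (inherits(record, "ncm_fit")) return(record$taxa)
  if (inherits(record, "nst_result")) return(record$pairs)
  if (inherits(record, "co_network")) return(record$edges)
  if (inherits(record, "topology_metrics")) {
    return(as.data.frame(unclass(record)))
  }
  abort_arg("no tabular (TSV) form for record type <%s>", class(record)[1L])
}

#' Write a community table and its metadata as TSV files
#' @param table A `community_table`.
#' @param path Output path for the count TSV.
#' @param metadata_path Output path for the `sample_id`/`group` metadata TSV.
#' @return `path`, invisibly.
#' @export
write_community_table <- function(table, path, metadata_path) {
  stopifnot(inherits(table, "community_table"))
  df <- data.frame(otu_id = rownames(table$counts), table$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = names(table$groups), group = unname(table$groups))
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
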