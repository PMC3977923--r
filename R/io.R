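#' Read a two-condition gene expression table
#'
#' Parses a tab-separated table with a `gene_id` column and one FPKM column
#' per condition. Condition columns may be named either by the bare condition
#' label (e.g. `LT`) or prefixed `FPKM_<label>`; the prefix is stripped.
#'
#' @param path Path to a TSV file with header.
#' @param conditions Optional character vector of condition labels to keep
#'   (in order). Defaults to all non-`gene_id` columns.
#' @return A data.frame of class `expression_table` with columns `gene_id`
#'   and one numeric FPKM column per condition; condition labels are stored
#'   in `attr(, "conditions")`.
#' @export
read_expression <- function(path, conditions = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(df))
    stop("expression table at '", path, "' lacks a 'gene_id' column")
  names(df) <- sub("^FPKM_", "", names(df))
  cond <- setdiff(names(df), "gene_id")
  if (!is.null(conditions)) {
    missing <- setdiff(conditions, cond)
    if (length(missing))
      stop("missing condition column(s): ", paste(missing, collapse = ", "))
    cond <- conditions
  }
  if (length(cond) < 1L) stop("no condition columns found")
  df <- df[, c("gene_id", cond), drop = FALSE]
  as_expression_table(df)
}

#' Construct/validate an expression table
#'
#' @param df data.frame with `gene_id` plus numeric condition columns.
#' @return Validated `expression_table`.
#' @export
as_expression_table <- function(df) {
  stopifnot(is.data.frame(df), "gene_id" %in% names(df))
  cond <- setdiff(names(df), "gene_id")
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup))
    stop("duplicate gene row(s): ", paste(utils::head(unique(dup), 5), collapse = ", "))
  for (cc in cond) {
    v <- df[[cc]]
    if (!is.numeric(v)) stop("condition column '", cc, "' is not numeric")
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad))
      stop("negative or non-finite FPKM in column '", cc, "' at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "),
           " (gene ", df$gene_id[bad[1]], ")")
  }
  df$gene_id <- as.character(df$gene_id)
  rownames(df) <- NULL
  structure(df, conditions = cond,
            class = c("expression_table", "data.frame"))
}

#' Read a motif-hit table
#'
#' Two dialects are accepted. The TSS-relative dialect has columns
#' `gene_id tfbs_id position strand score` with `position` a signed integer
#' in bp relative to the TSS (negative = upstream, 0 = the TSS base). The
#' genomic dialect has columns `gene_id tfbs_id position strand score` with
#' genomic point coordinates and requires `tss`, a table with columns
#' `gene_id tss strand`: for a plus-strand TSS the relative position is
#' `position - tss`, for a minus-strand TSS it is `tss - position`.
#' Conversion happens exactly once at ingest; the returned object is flagged
#' TSS-relative and cannot be converted again.
#'
#' Hits whose relative position falls outside `[-half_window, half_window]`
#' are dropped; the dropped count is kept in `attr(, "n_dropped")`.
#'
#' @param path TSV file with header.
#' @param half_window Promoter half-window in bp (default 5000).
#' @param tss Optional data.frame `gene_id, tss, strand` switching on the
#'   genomic-coordinate dialect.
#' @return data.frame of class `motif_hits` with columns
#'   `gene_id, tfbs_id, position, strand, score`.
#' @export
read_hits <- function(path, half_window = 5000, tss = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "tfbs_id", "position", "strand", "score")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("hit table lacks column(s): ", paste(missing, collapse = ", "))
  df <- df[, need]
  if (!is.null(tss)) df <- convert_to_tss_relative(df, tss)
  as_motif_hits(df, half_window = half_window)
}

# Genomic point coordinates -> TSS-relative signed positions.
convert_to_tss_relative <- function(df, tss) {
  if (isTRUE(attr(df, "tss_relative")))
    stop("positions are already TSS-relative; refusing to convert twice")
  stopifnot(all(c("gene_id", "tss", "strand") %in% names(tss)))
  i <- match(df$gene_id, tss$gene_id)
  if (anyNA(i))
    stop("no TSS entry for gene(s): ",
         paste(utils::head(unique(df$gene_id[is.na(i)]), 5), collapse = ", "))
  minus <- tss$strand[i] == "-"
  df$position <- ifelse(minus, tss$tss[i] - df$position,
                        df$position - tss$tss[i])
  df
}

#' Construct/validate a motif-hit set (TSS-relative positions)
#'
#' @param df data.frame with `gene_id, tfbs_id, position, strand, score`.
#' @param half_window Promoter half-window in bp; out-of-window hits dropped.
#' @return `motif_hits` data.frame; `attr(,"n_dropped")` counts removed rows,
#'   `attr(,"half_window")` records the window.
#' @export
as_motif_hits <- function(df, half_window = 5000) {
  need <- c("gene_id", "tfbs_id", "position", "strand", "score")
  stopifnot(is.data.frame(df), all(need %in% names(df)))
  df <- df[, need]
  if (any(!df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  bad <- which(!is.finite(df$score) | df$score < 0 | df$score > 1)
  if (length(bad))
    stop("match score outside [0,1] at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  keep <- abs(df$position) <= half_window
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " hit(s) outside the ±", half_window, " bp window dropped")
  df <- df[keep, , drop = FALSE]
  df$gene_id <- as.character(df$gene_id)
  df$tfbs_id <- as.character(df$tfbs_id)
  rownames(df) <- NULL
  structure(df, half_window = half_window, n_dropped = n_dropped,
            tss_relative = TRUE, class = c("motif_hits", "data.frame"))
}

#' Read a TFBS-to-TF binding map
#'
#' TSV with columns `tfbs_id tf_gene_id`, one row per (site, TF) pair.
#'
#' @param path TSV file with header.
#' @return Named list: `tfbs_id` -> character vector of TF gene ids.
#' @export
read_binding_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("tfbs_id", "tf_gene_id") %in% names(df)))
    stop("binding map needs columns tfbs_id, tf_gene_id")
  as_binding_map(df)
}

#' @rdname read_binding_map
#' @param df data.frame with columns `tfbs_id`, `tf_gene_id`.
#' @export
as_binding_map <- function(df) {
  m <- split(as.character(df$tf_gene_id), as.character(df$tfbs_id))
  m <- lapply(m, unique)
  if (any(lengths(m) == 0L)) stop("binding map has an empty TF set")
  m
}

# Check that every TFBS appearing in hits is covered by the binding map.
check_binding_coverage <- function(hits, binding) {
  missing <- setdiff(unique(hits$tfbs_id), names(binding))
  if (length(missing))
    stop("TFBS(s) in hit table absent from binding map: ",
         paste(utils::head(missing, 5), collapse = ", "))
  invisible(TRUE)
}

#' Write / read tabular results
#'
#' Plain TSV writers and readers for the package's table types, plus a JSON
#' run manifest. `write_tsv`/`read_tsv` are thin wrappers used by all of
#' them so round-trips are exact for character/numeric columns.
#'
#' @param x data.frame (or object coercible to one).
#' @param path Output file.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname write_tsv
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expression_table"))
  write_tsv(x, path)
}

#' @rdname write_tsv
#' @export
write_hits <- function(x, path) {
  stopifnot(inherits(x, "motif_hits"))
  write_tsv(x, path)
}

#' Write / read a TGAS matrix (genes in rows, TFBS columns)
#' @param x Numeric matrix with gene row names and TFBS column names.
#' @param path TSV file.
#' @export
write_tgas <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_tgas
#' @export
read_tgas <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  m
}

#' Write / read an interaction graph edge table
#' @param graph `interaction_graph` from [run_sampling()] or a data.frame
#'   with columns `tf_a, tf_b, t, f, Pr`.
#' @param path TSV file.
#' @export
write_interaction_graph <- function(graph, path) {
  df <- if (is.data.frame(graph)) graph else interaction_table(graph)
  write_tsv(df, path)
}

#' @rdname write_interaction_graph
#' @export
read_interaction_graph <- function(path) {
  df <- read_tsv(path)
  stopifnot(all(c("tf_a", "tf_b", "t", "f", "Pr") %in% names(df)))
  df
}

#' Write a JSON run manifest
#'
#' Records the resolved configuration, seeds and package version of a run so
#' results are reproducible from the manifest alone.
#'
#' @param config Named list of settings.
#' @param path Output JSON file.
#' @export
write_manifest <- function(config, path) {
  config$package_version <- as.character(utils::packageVersion("promod"))
  config$r_version <- R.version.string
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
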