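# Annotated CT tables -------------------------------------------------------
#
# A ct_table is a data.frame of one row per sample (or per technical
# replicate, before collapsing) carrying three annotation roles -- a sample
# identifier, a subject/donor identifier and a treatment label -- plus one
# numeric column of cycle thresholds per gene. The original column headers
# are preserved so that model formulas can refer to them verbatim
# (e.g. MMP10 ~ Donor + Treatment + GAPDH).

.role_synonyms <- list(
  sample    = c("sample", "sample_id", "group"),
  subject   = c("subject", "donor"),
  treatment = c("treatment"),
  replicate = c("replicate", "replicate_index", "rep"),
  gene      = c("gene"),
  ct        = c("ct", "value")
)

.find_role <- function(nms, role, required = TRUE) {
  hit <- nms[tolower(nms) %in% .role_synonyms[[role]]]
  if (length(hit) == 0) {
    if (required)
      stop_user("schema error: no column for role '", role,
                "' (accepted names: ",
                paste(.role_synonyms[[role]], collapse = ", "), ")")
    return(NA_character_)
  }
  hit[1]
}

#' Construct an annotated CT table
#'
#' Builds a `ct_table` from a data.frame with one row per sample (or per
#' technical replicate) holding sample annotations and per-gene cycle
#' thresholds (CT). Missing CT values are represented as `NA`, never as
#' sentinel values such as 0 or 40.
#'
#' @param data data.frame with the annotation and gene columns.
#' @param sample,subject,treatment names of the annotation columns holding
#'   the sample identifier, the subject (donor) identifier, and the
#'   treatment label.
#' @param genes character vector of gene column names, in display order.
#' @param replicate optional name of an integer technical-replicate index
#'   column; `NULL` when the table holds one measurement per sample.
#' @return An object of class `ct_table` (a data.frame with role and gene
#'   metadata attached).
#' @examples
#' tab <- read_ct_table(system.file("extdata", "table2.csv", package = "qpcrmlm"))
#' ct_genes(tab)
#' @export
ct_table <- function(data, sample, subject, treatment, genes, replicate = NULL) {
  stopifnot(is.data.frame(data))
  need <- c(sample, subject, treatment, replicate, genes)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop_user("schema error: missing column(s): ", paste(miss, collapse = ", "))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  for (g in genes) {
    if (!is.numeric(data[[g]]))
      stop_user("parse error: gene column '", g, "' is not numeric")
  }
  roles <- c(sample = sample, subject = subject, treatment = treatment,
             replicate = if (is.null(replicate)) NA_character_ else replicate)
  out <- structure(data,
                   roles = roles, genes = genes,
                   class = c("ct_table", "data.frame"))
  validate_ct_table(out)
  out
}

#' @export
`[.ct_table` <- function(x, ...) {
  roles <- attr(x, "roles"); genes <- attr(x, "genes")
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "roles") <- roles
    attr(out, "genes") <- intersect(genes, names(out))
    class(out) <- c("ct_table", "data.frame")
  }
  out
}

.role <- function(x, role) {
  r <- attr(x, "roles")[[role]]
  if (is.na(r)) NULL else r
}

.role_col <- function(x, role) {
  r <- .role(x, role)
  if (is.null(r)) NULL else x[[r]]
}

#' @rdname ct_table
#' @param x a `ct_table`.
#' @export
ct_genes <- function(x) attr(x, "genes")

#' @rdname ct_table
#' @export
ct_samples <- function(x) unique(as.character(.role_col(x, "sample")))

#' Validate a CT table
#'
#' Checks the `ct_table` invariants: gene columns numeric, all CT values
#' finite and non-negative (or `NA` for missing wells), no duplicated
#' (sample, replicate) rows, and consistent subject/treatment annotation
#' within each sample.
#'
#' @param x a `ct_table`.
#' @return `x`, invisibly; stops with a descriptive error on violation.
#' @export
validate_ct_table <- function(x) {
  stopifnot(inherits(x, "ct_table"))
  genes <- ct_genes(x)
  for (g in genes) {
    v <- x[[g]]
    bad <- which(!is.na(v) & (!is.finite(v) | v < 0))
    if (length(bad))
      stop_user("invalid CT in gene '", g, "' at row(s) ",
                paste(bad, collapse = ", "), ": CT must be finite and >= 0")
  }
  sid <- as.character(.role_col(x, "sample"))
  rep_col <- .role_col(x, "replicate")
  key <- if (is.null(rep_col)) sid else paste(sid, rep_col, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(sid[duplicated(key)])
    stop_user("duplication error: repeated (sample, replicate) rows for sample(s) ",
              paste(dup, collapse = ", "),
              if (is.null(rep_col)) " (add a replicate column for technical replicates)" else "")
  }
  # each sample must carry a single (subject, treatment) annotation
  ann <- paste(.role_col(x, "subject"), .role_col(x, "treatment"), sep = "\r")
  if (any(tapply(ann, sid, function(a) length(unique(a))) > 1L))
    stop_user("inconsistent subject/treatment annotation within a sample")
  invisible(x)
}

#' Read an annotated CT table from CSV
#'
#' Reads a comma-separated, UTF-8, header-first CT table in either layout:
#' \describe{
#'   \item{wide}{one row per sample (or replicate), columns for the sample
#'     id, subject (donor), treatment, optional replicate index, and one
#'     numeric CT column per gene;}
#'   \item{long}{columns sample, subject, treatment, gene, ct, and an
#'     optional replicate index.}
#' }
#' Role columns are recognised by common header names case-insensitively
#' (sample/sample_id/group, subject/donor, treatment, replicate). Empty CT
#' fields become `NA`. Gene names are matched case-sensitively everywhere
#' downstream.
#'
#' @param path path to the CSV file.
#' @param layout `"auto"` (default) detects the long layout by the presence
#'   of `gene` and `ct` columns; or force `"wide"`/`"long"`.
#' @return A validated [ct_table].
#' @examples
#' tab <- read_ct_table(system.file("extdata", "table2.csv", package = "qpcrmlm"))
#' head(tab)
#' @export
read_ct_table <- function(path, layout = c("auto", "wide", "long")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop_user("input file not found: ", path)
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character", fileEncoding = "UTF-8"),
    error = function(e) stop_user("schema error: cannot parse '", path, "': ",
                                  conditionMessage(e)))
  if (nrow(raw) == 0 || ncol(raw) == 0)
    stop_user("schema error: '", path, "' has no data rows")
  nms <- names(raw)
  if (layout == "auto") {
    has_long <- !is.na(.find_role(nms, "gene", required = FALSE)) &&
      !is.na(.find_role(nms, "ct", required = FALSE))
    layout <- if (has_long) "long" else "wide"
  }
  s_col <- .find_role(nms, "sample")
  u_col <- .find_role(nms, "subject")
  t_col <- .find_role(nms, "treatment")
  r_col <- .find_role(nms, "replicate", required = FALSE)

  to_num <- function(v, what) {
    v[v == ""] <- NA_character_
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad))
      stop_user("parse error: non-numeric ", what, " at data row(s) ",
                paste(bad, collapse = ", "))
    out
  }

  if (layout == "long") {
    g_col <- .find_role(nms, "gene")
    c_col <- .find_role(nms, "ct")
    raw[[c_col]] <- to_num(raw[[c_col]], "CT value")
    genes <- unique(raw[[g_col]])
    rep_idx <- if (is.na(r_col)) rep(1L, nrow(raw)) else as.integer(raw[[r_col]])
    key <- paste(raw[[s_col]], raw[[g_col]], rep_idx, sep = "\r")
    if (anyDuplicated(key))
      stop_user("duplication error: repeated (sample, gene, replicate) entries")
    sample_key <- paste(raw[[s_col]], rep_idx, sep = "\r")
    rows <- !duplicated(sample_key)
    wide <- raw[rows, c(s_col, u_col, t_col), drop = FALSE]
    if (!is.na(r_col)) wide[[r_col]] <- rep_idx[rows]
    for (g in genes) {
      v <- rep(NA_real_, nrow(wide))
      sel <- raw[[g_col]] == g
      v[match(sample_key[sel], sample_key[rows])] <- raw[[c_col]][sel]
      wide[[g]] <- v
    }
    rownames(wide) <- NULL
    return(ct_table(wide, sample = s_col, subject = u_col, treatment = t_col,
                    genes = genes,
                    replicate = if (is.na(r_col)) NULL else r_col))
  }

  genes <- setdiff(nms, c(s_col, u_col, t_col, if (!is.na(r_col)) r_col))
  if (length(genes) == 0)
    stop_user("schema error: wide layout requires at least one gene column")
  for (g in genes) raw[[g]] <- to_num(raw[[g]], paste0("CT in column '", g, "'"))
  if (!is.na(r_col)) raw[[r_col]] <- as.integer(raw[[r_col]])
  ct_table(raw, sample = s_col, subject = u_col, treatment = t_col,
           genes = genes, replicate = if (is.na(r_col)) NULL else r_col)
}

#' Write an annotated CT table to CSV
#'
#' Inverse of [read_ct_table()]: `read_ct_table(write_ct_table(x, p), )`
#' reproduces `x` cell for cell. Missing CT cells are written as empty
#' fields.
#'
#' @param x a [ct_table].
#' @param path output file path.
#' @param layout `"wide"` (default) or `"long"`.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(x, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  validate_ct_table(x)
  if (layout == "wide") {
    out <- as.data.frame(x)
  } else {
    roles <- attr(x, "roles")
    genes <- ct_genes(x)
    ann_cols <- stats::na.omit(unname(roles))
    blocks <- lapply(genes, function(g) {
      b <- as.data.frame(x)[, ann_cols, drop = FALSE]
      b$gene <- g
      b$ct <- x[[g]]
      b
    })
    out <- do.call(rbind, blocks)
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_user("cannot write to: ", path)
  invisible(path)
}

#' Collapse technical replicates
#'
#' Reduces a CT table with several technical replicates per (sample, gene)
#' cell to one CT per cell, using the mean (default, as for triplicate qPCR
#' wells) or the median. A cell whose replicates are all missing stays
#' missing and a warning reports the count. Idempotent on already-collapsed
#' tables.
#'
#' @param x a [ct_table].
#' @param statistic `"mean"` or `"median"`.
#' @return A [ct_table] with one row per sample and no replicate column.
#' @export
collapse_replicates <- function(x, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  validate_ct_table(x)
  fun <- switch(statistic, mean = mean, median = stats::median)
  sid <- as.character(.role_col(x, "sample"))
  keep <- !duplicated(sid)
  roles <- attr(x, "roles")
  ann_cols <- stats::na.omit(unname(roles[c("sample", "subject", "treatment")]))
  out <- as.data.frame(x)[keep, ann_cols, drop = FALSE]
  n_empty <- 0L
  for (g in ct_genes(x)) {
    agg <- tapply(x[[g]], sid, function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0) NA_real_ else fun(v)
    })
    v <- as.numeric(agg[sid[keep]])
    n_empty <- n_empty + sum(is.na(v))
    out[[g]] <- v
  }
  if (n_empty > 0)
    warning(n_empty, " (sample, gene) cell(s) had no non-missing replicate",
            call. = FALSE)
  rownames(out) <- NULL
  ct_table(out, sample = roles[["sample"]], subject = roles[["subject"]],
           treatment = roles[["treatment"]], genes = ct_genes(x))
}

# one row per sample, collapsing replicates by mean if needed
.collapsed <- function(x) {
  sid <- as.character(.role_col(x, "sample"))
  if (!is.null(.role(x, "replicate")) || anyDuplicated(sid)) {
    message("collapsing technical replicates by mean")
    collapse_replicates(x, "mean")
  } else x
}

#' @export
print.ct_table <- function(x, ...) {
  cat("CT table: ", length(ct_samples(x)), " samples, ",
      length(ct_genes(x)), " gene(s) [",
      paste(ct_genes(x), collapse = ", "), "]\n", sep = "")
  tr <- .role_col(x, "treatment")
  cat("treatment levels:", paste(sort(unique(as.character(tr))), collapse = ", "), "\n")
  print(as.data.frame(x), ...)
  invisible(x)
}
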