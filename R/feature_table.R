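#' Assemble an LC-MS feature table
#'
#' The feature table is the pipeline's universal currency: one row per m/z
#' feature -- a detected ion defined by its mass-to-charge ratio and
#' retention time -- and one column per run, where a run is one technical
#' replicate injection of one sample. Cells hold nonnegative integrated ion
#' intensities in arbitrary units. Missing cells (`NA`) mean "no peak
#' detected for this feature in this run" and are kept distinct from an
#' intensity of zero, which is a legitimate measurement; the detection
#' filter relies on that distinction.
#'
#' @param intensities numeric matrix, `n_features x n_runs`, nonnegative or
#'   `NA`.
#' @param mz numeric vector of mass-to-charge ratios (Da), one per feature.
#' @param rt numeric vector of retention times (seconds), one per feature.
#' @param sample_id character vector, one per run.
#' @param replicate integer replicate index within sample, one per run.
#' @param feature_id optional character ids; generated (`F00001`, ...) when
#'   absent. Must be unique, as must `(mz, rt)` pairs.
#' @param group optional per-run group label (`control`, `slow`, `rapid`);
#'   may also be attached later with [attach_groups()].
#' @return An object of class `feature_table`: a list with elements
#'   `features` (data.frame: feature_id, mz, rt), `intensities` (matrix),
#'   and `runs` (data.frame: sample_id, replicate, group).
#' @seealso [read_feature_table()], [average_replicates()], [sample_matrix()]
#' @export
feature_table <- function(intensities, mz, rt, sample_id, replicate,
                          feature_id = NULL, group = NULL) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  n <- nrow(intensities)
  r <- ncol(intensities)
  if (is.null(feature_id)) feature_id <- sprintf("F%05d", seq_len(n))
  if (length(mz) != n || length(rt) != n || length(feature_id) != n)
    stop("mz, rt and feature_id must have one entry per feature row")
  if (length(sample_id) != r || length(replicate) != r)
    stop("sample_id and replicate must have one entry per run column")
  features <- data.frame(feature_id = as.character(feature_id),
                         mz = as.numeric(mz), rt = as.numeric(rt),
                         stringsAsFactors = FALSE)
  runs <- data.frame(sample_id = as.character(sample_id),
                     replicate = as.integer(replicate),
                     group = if (is.null(group)) NA_character_
                             else as.character(group),
                     stringsAsFactors = FALSE)
  dimnames(intensities) <- list(features$feature_id,
                                paste(runs$sample_id, runs$replicate,
                                      sep = "."))
  x <- structure(list(features = features, intensities = intensities,
                      runs = runs),
                 class = "feature_table")
  validate_feature_table(x)
}

#' Validate a feature table's invariants
#'
#' Checks uniqueness of `feature_id` and `(mz, rt)` pairs, nonnegativity of
#' all observed intensities, and a well-formed replicate structure (each
#' sample's replicate indices distinct).
#'
#' @param x a `feature_table`.
#' @return `x`, invisibly unchanged, or an error naming the violation.
#' @export
validate_feature_table <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  ft <- x$features
  runs <- x$runs
  ints <- x$intensities
  dup <- ft$feature_id[duplicated(ft$feature_id)]
  if (length(dup))
    stop("duplicate feature_id: ", paste(unique(dup), collapse = ", "))
  if (anyDuplicated(ft[c("mz", "rt")]))
    stop("duplicate (mz, rt) pair among features")
  neg <- !is.na(ints) & ints < 0
  if (any(neg)) {
    i <- which(neg, arr.ind = TRUE)[1L, 1L]
    stop("negative intensity in feature ", ft$feature_id[i])
  }
  bad <- vapply(split(runs$replicate, runs$sample_id),
                function(z) anyDuplicated(z) > 0, logical(1))
  if (any(bad))
    stop("duplicated replicate index within sample: ",
         paste(names(bad)[bad], collapse = ", "))
  x
}

#' @export
print.feature_table <- function(x, ...) {
  ns <- length(unique(x$runs$sample_id))
  cat(sprintf(
    "feature_table: %d features x %d runs (%d samples, up to %d replicates)\n",
    nrow(x$intensities), ncol(x$intensities), ns,
    max(x$runs$replicate)))
  if (!all(is.na(x$runs$group))) {
    tab <- table(x$runs$group[!duplicated(x$runs$sample_id)])
    cat("groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  cat(sprintf("missing cells: %d (%.2f%%)\n", sum(is.na(x$intensities)),
              100 * mean(is.na(x$intensities))))
  invisible(x)
}

#' Subset a feature table
#'
#' `x[i, j]` keeps features `i` (index, logical or feature_id) and runs `j`.
#'
#' @param x a `feature_table`.
#' @param i feature selector.
#' @param j run selector.
#' @param ... ignored.
#' @return a `feature_table`.
#' @export
`[.feature_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$intensities))
  if (missing(j)) j <- seq_len(ncol(x$intensities))
  if (is.character(i)) i <- match(i, x$features$feature_id)
  x$features <- x$features[i, , drop = FALSE]
  x$runs <- x$runs[j, , drop = FALSE]
  x$intensities <- x$intensities[i, j, drop = FALSE]
  rownames(x$features) <- NULL
  rownames(x$runs) <- NULL
  validate_feature_table(x)
}

#' Attach group labels to a table's runs
#'
#' @param x a `feature_table`.
#' @param meta a sample-metadata data.frame with columns `sample_id`,
#'   `group`.
#' @return the table with `runs$group` filled in.
#' @export
attach_groups <- function(x, meta) {
  m <- match(x$runs$sample_id, meta$sample_id)
  if (anyNA(m))
    stop("samples missing from metadata: ",
         paste(unique(x$runs$sample_id[is.na(m)]), collapse = ", "))
  x$runs$group <- as.character(meta$group)[m]
  x
}

sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
}

resolve_delim <- function(path, delim = c("auto", "tab", "comma")) {
  delim <- match.arg(delim)
  switch(delim, auto = sniff_delim(path), tab = "\t", comma = ",")
}

#' Read a delimited feature table
#'
#' Expects the tabular convention of apLCMS/xMSanalyzer-style extractions:
#' feature columns (`feature_id` optional, `mz`, and `time` or `rt`)
#' followed by one run column per injection named `<sample_id>.<replicate>`.
#' Missing intensities may be empty fields or `NA`; zeros are read as
#' measured zeros.
#'
#' @param path file path.
#' @param delim `"auto"` (default; sniffs tab vs comma), `"tab"`, or
#'   `"comma"`.
#' @return a validated [feature_table()].
#' @export
read_feature_table <- function(path, delim = c("auto", "tab", "comma")) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- resolve_delim(path, delim)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), comment.char = "")
  nm <- names(df)
  rt_col <- intersect(c("time", "rt"), nm)[1]
  if (!("mz" %in% nm) || is.na(rt_col))
    stop("malformed header: need columns 'mz' and 'time' (or 'rt'), got: ",
         paste(utils::head(nm, 5), collapse = ", "))
  meta_cols <- c(intersect("feature_id", nm), "mz", rt_col)
  run_cols <- setdiff(nm, meta_cols)
  if (!length(run_cols)) stop("malformed header: no run columns")
  ok <- grepl("^.+\\.[0-9]+$", run_cols)
  if (any(!ok))
    stop("malformed run column (expected <sample_id>.<replicate>): ",
         run_cols[!ok][1])
  sample_id <- sub("\\.[0-9]+$", "", run_cols)
  replicate <- as.integer(sub("^.*\\.([0-9]+)$", "\\1", run_cols))
  ints <- as.matrix(df[run_cols])
  message(sprintf("read_feature_table: %d features x %d runs from %s",
                  nrow(df), length(run_cols), path))
  feature_table(ints, mz = df$mz, rt = df[[rt_col]],
                sample_id = sample_id, replicate = replicate,
                feature_id = if ("feature_id" %in% nm) df$feature_id)
}

fmt_num <- function(v) {
  out <- vapply(v, function(z) {
    if (is.na(z)) return(NA_character_)
    if (!is.na(z) && z == round(z) && abs(z) < 1e15)
      sprintf("%.0f", z)
    else
      sprintf("%.17g", z)
  }, character(1))
  out
}

#' Write a feature table as delimited text
#'
#' Numbers are written to full double precision so that
#' `read_feature_table(write_feature_table(x))` reproduces `x` exactly;
#' missing cells are written as `NA`.
#'
#' @param x a `feature_table`.
#' @param path output path.
#' @param delim `"tab"` (default) or `"comma"`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path, delim = c("tab", "comma")) {
  validate_feature_table(x)
  sep <- switch(match.arg(delim), tab = "\t", comma = ",")
  ints <- x$intensities
  header <- c("feature_id", "mz", "time", colnames(ints))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = sep), con)
  if (nrow(ints)) {
    body <- cbind(x$features$feature_id,
                  fmt_num(x$features$mz),
                  fmt_num(x$features$rt),
                  matrix(fmt_num(ints), nrow = nrow(ints)))
    utils::write.table(body, con, sep = sep, quote = FALSE, na = "NA",
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read or write sample metadata
#'
#' Delimited text with columns `sample_id` and `group`; group labels must
#' come from the closed set `control`, `slow`, `rapid`.
#'
#' @param path file path.
#' @param delim see [read_feature_table()].
#' @return data.frame with columns `sample_id`, `group`.
#' @export
read_sample_meta <- function(path, delim = c("auto", "tab", "comma")) {
  sep <- resolve_delim(path, delim)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("metadata needs columns sample_id, group")
  validate_sample_meta(df)
}

#' @rdname read_sample_meta
#' @param meta data.frame with `sample_id`, `group`.
#' @export
write_sample_meta <- function(meta, path, delim = c("tab", "comma")) {
  sep <- switch(match.arg(delim), tab = "\t", comma = ",")
  utils::write.table(validate_sample_meta(meta), path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_sample_meta <- function(meta) {
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata")
  bad <- setdiff(unique(meta$group), c("control", "slow", "rapid"))
  if (length(bad))
    stop("unknown group label: ", paste(bad, collapse = ", "))
  meta[c("sample_id", "group")]
}

#' Replicate-averaged sample-by-feature matrix
#'
#' Collapses technical replicates by their mean (missing-aware) and returns
#' the analysis-ready `samples x features` matrix, by default on the log10
#' scale used throughout the statistical stages. Nonpositive intensities
#' cannot be log-transformed and become `NA` with a warning.
#'
#' @param x a `feature_table`.
#' @param log10 logical; transform to log10 (default `TRUE`).
#' @return numeric matrix, samples in rows (named), features in columns.
#' @export
sample_matrix <- function(x, log10 = TRUE) {
  a <- average_replicates(x)
  m <- t(a$intensities)
  rownames(m) <- a$runs$sample_id
  if (log10) {
    bad <- !is.na(m) & m <= 0
    if (any(bad)) {
      warning(sum(bad), " nonpositive intensities set to NA on log scale")
      m[bad] <- NA
    }
    m <- log10(m)
  }
  m
}
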