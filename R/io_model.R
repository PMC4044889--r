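# Core data model: intensity matrices and study designs, plus the tabular
# readers/writers every other stage consumes.

#' Construct an intensity matrix
#'
#' An intensity matrix holds one row per protein and one column per injection
#' (replicate LC-MS/MS run). Values are intensities, typically on the log2
#' scale after [log2_transform()]; missing measurements are `NA`.
#'
#' @param values numeric matrix, proteins in rows, injections in columns.
#' @param protein_ids,injection_ids unique character ids; default to the
#'   dimnames of `values`.
#' @return a numeric matrix of class `intensity_matrix` with protein ids as
#'   rownames and injection ids as colnames.
#' @export
intensity_matrix <- function(values, protein_ids = rownames(values),
                             injection_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    pf_stop("pf_format_error", "values must be a numeric matrix")
  protein_ids <- as.character(protein_ids)
  injection_ids <- as.character(injection_ids)
  if (length(protein_ids) != nrow(values))
    pf_stop("pf_format_error", "protein_ids length %d != %d rows",
            length(protein_ids), nrow(values))
  if (length(injection_ids) != ncol(values))
    pf_stop("pf_format_error", "injection_ids length %d != %d columns",
            length(injection_ids), ncol(values))
  dup <- unique(protein_ids[duplicated(protein_ids)])
  if (length(dup))
    pf_stop("pf_format_error", "duplicate protein id: %s", dup[1])
  dup <- unique(injection_ids[duplicated(injection_ids)])
  if (length(dup))
    pf_stop("pf_format_error", "duplicate injection id: %s", dup[1])
  if (anyNA(protein_ids) || any(!nzchar(protein_ids)))
    pf_stop("pf_format_error", "empty or missing protein id")
  dimnames(values) <- list(protein_ids, injection_ids)
  class(values) <- c("intensity_matrix", class(values))
  values
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("<intensity_matrix> %d proteins x %d injections (%d missing cells)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

#' @rdname intensity_matrix
#' @param x an `intensity_matrix`.
#' @export
protein_ids <- function(x) rownames(x)

#' @rdname intensity_matrix
#' @export
injection_ids <- function(x) colnames(x)

#' Construct a study design
#'
#' Per-injection metadata tying each injection to a biological sample, a
#' group (cancer/control), a study label, and a replicate index. The design
#' defines both the nested ANOVA layout (replicates within samples within
#' groups) and, across studies, the three-way data split.
#'
#' @param df data.frame with columns `injection_id`, `sample_id`, `group`
#'   (cancer/control, case-insensitive), `study`, `replicate` (positive
#'   integer).
#' @return a validated data.frame of class `study_design`.
#' @export
study_design <- function(df) {
  required <- c("injection_id", "sample_id", "group", "study", "replicate")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    pf_stop("pf_validation_error", "metadata missing column(s): %s",
            paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[required]
  df$injection_id <- as.character(df$injection_id)
  df$sample_id <- as.character(df$sample_id)
  df$group <- tolower(trimws(as.character(df$group)))
  df$study <- toupper(trimws(as.character(df$study)))
  bad <- setdiff(unique(df$group), c("cancer", "control"))
  if (length(bad))
    pf_stop("pf_validation_error", "unknown group label: %s", bad[1])
  rep_num <- suppressWarnings(as.numeric(df$replicate))
  if (anyNA(rep_num) || any(rep_num < 1) || any(rep_num != floor(rep_num)))
    pf_stop("pf_validation_error", "replicate must be a positive integer")
  df$replicate <- as.integer(rep_num)
  dup <- unique(df$injection_id[duplicated(df$injection_id)])
  if (length(dup))
    pf_stop("pf_validation_error", "duplicate injection id: %s", dup[1])
  for (field in c("group", "study")) {
    tab <- unique(df[c("sample_id", field)])
    dup <- unique(tab$sample_id[duplicated(tab$sample_id)])
    if (length(dup))
      pf_stop("pf_validation_error",
              "sample %s is assigned to more than one %s", dup[1], field)
  }
  rownames(df) <- NULL
  class(df) <- c("study_design", "data.frame")
  df
}

#' Is a study design balanced?
#'
#' Balanced means every sample carries the same number of replicate
#' injections and, within each study, the cancer and control groups have
#' equal sample counts. The balanced case is where the nested ANOVA F-test
#' is exact.
#'
#' @param design a `study_design`.
#' @return logical scalar.
#' @export
design_is_balanced <- function(design) {
  design <- study_design(design)
  reps <- table(design$sample_id)
  if (length(unique(as.integer(reps))) > 1) return(FALSE)
  samples <- unique(design[c("sample_id", "group", "study")])
  for (st in unique(samples$study)) {
    counts <- table(factor(samples$group[samples$study == st],
                           levels = c("cancer", "control")))
    if (counts[["cancer"]] != counts[["control"]]) return(FALSE)
  }
  TRUE
}

#' Check that a design covers a matrix exactly
#' @noRd
check_design_matches <- function(matrix, design) {
  miss <- setdiff(injection_ids(matrix), design$injection_id)
  if (length(miss))
    pf_stop("pf_validation_error",
            "injection %s present in matrix but absent from metadata", miss[1])
  invisible(TRUE)
}

pf_sep <- function(dialect) {
  dialect <- match.arg(dialect, c("tsv", "csv"))
  if (dialect == "tsv") "\t" else ","
}

#' Read a protein-by-injection intensity table
#'
#' Expects a header row of injection ids and a first column of protein ids.
#' Cells must be numeric or an explicit missing token (`NA` or empty), which
#' becomes a flagged-missing (`NA`) entry. Orientation is fixed
#' proteins-in-rows; pass `transpose = TRUE` for tables written the other
#' way (never autodetected).
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param transpose logical; set when the file has injections in rows.
#' @param missing_tokens character vector of tokens parsed as missing.
#' @return an [intensity_matrix()].
#' @export
read_intensity_table <- function(path, dialect = "tsv", transpose = FALSE,
                                 missing_tokens = c("NA", "")) {
  if (!file.exists(path))
    pf_stop("pf_io_error", "no such file: %s", path)
  sep <- pf_sep(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1) pf_stop("pf_format_error", "empty table: %s", path)
  cells <- strsplit(lines, sep, fixed = TRUE)
  header <- cells[[1]]
  inj <- header[-1]
  body <- cells[-1]
  prot <- vapply(body, `[`, character(1), 1L)
  n <- length(inj)
  vals <- matrix(NA_real_, length(body), n)
  for (r in seq_along(body)) {
    row <- body[[r]][-1]
    length(row) <- n # pad short rows (trailing empties) with NA tokens
    row[is.na(row)] <- ""
    tok <- trimws(row)
    is_missing <- tok %in% missing_tokens
    num <- suppressWarnings(as.numeric(tok))
    bad <- which(!is_missing & is.na(num))
    if (length(bad))
      pf_stop("pf_parse_error",
              "non-numeric cell '%s' at protein %s (row %d), injection %s (column %d)",
              tok[bad[1]], prot[r], r, inj[bad[1]], bad[1])
    num[is_missing] <- NA_real_
    vals[r, ] <- num
  }
  m <- intensity_matrix(vals, protein_ids = prot, injection_ids = inj)
  if (transpose)
    m <- intensity_matrix(t(unclass(m)))
  m
}

#' Write an intensity table readable by [read_intensity_table()]
#'
#' @param matrix an [intensity_matrix()].
#' @inheritParams read_intensity_table
#' @param id_column header name of the protein-id column.
#' @export
write_intensity_table <- function(matrix, path, dialect = "tsv",
                                  id_column = "protein_id") {
  sep <- pf_sep(dialect)
  df <- data.frame(protein_ids(matrix), unclass(matrix), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  ok <- tryCatch({
    write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                na = "NA")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) pf_stop("pf_io_error", "cannot write %s", path)
  invisible(path)
}

#' Read per-injection sample metadata
#'
#' Expects columns `injection_id`, `sample_id`, `group`, `study`,
#' `replicate`. Group and study labels are normalized case-insensitively.
#'
#' @inheritParams read_intensity_table
#' @return a [study_design()].
#' @export
read_sample_metadata <- function(path, dialect = "tsv") {
  if (!file.exists(path))
    pf_stop("pf_io_error", "no such file: %s", path)
  df <- read.table(path, sep = pf_sep(dialect), header = TRUE,
                   colClasses = "character", check.names = FALSE,
                   quote = "", comment.char = "")
  study_design(df)
}

#' Write a metadata table readable by [read_sample_metadata()]
#' @inheritParams read_sample_metadata
#' @param design a [study_design()].
#' @export
write_sample_metadata <- function(design, path, dialect = "tsv") {
  write.table(as.data.frame(design), path, sep = pf_sep(dialect),
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

panel_string <- function(ids) paste(ids, collapse = ";")

#' Write a panel-search report
#'
#' Emits a single structured text file: `key=value` header lines, a flat TSV
#' ranking table (one row per evaluated panel, descending validation AUC),
#' and the confusion matrices plus performance metrics of the selected panel
#' C*. The format round-trips through [read_report()].
#'
#' @param result a `search_result` from [search_panels()] or
#'   [run_pipeline()].
#' @param path output file path.
#' @export
write_report <- function(result, path) {
  con <- tryCatch(suppressWarnings(file(path, "w")),
                  error = function(e) NULL)
  if (is.null(con)) pf_stop("pf_io_error", "cannot open %s for writing", path)
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("# panelforge report v1")
  cfg <- result$config %||% list()
  for (k in names(cfg)) wl("# %s=%s", k, paste(cfg[[k]], collapse = ","))
  wl("[ranking]")
  cols <- c("rank", "panel", "training_sse", "cv_mean_auc", "validation_auc",
            "training_accuracy", "validation_accuracy")
  wl(paste(cols, collapse = "\t"))
  for (pc in result$ranking) {
    wl("%d\t%s\t%.10g\t%.10g\t%.10g\t%.10g\t%.10g", pc$rank,
       panel_string(pc$panel), pc$training_sse, pc$cv_mean_auc,
       pc$validation_auc, pc$training_accuracy, pc$validation_accuracy)
  }
  if (!is.null(result$cstar)) {
    wl("[cstar]")
    wl("panel=%s", panel_string(result$cstar$panel))
    tm <- result$cstar$test_metrics
    if (!is.null(tm)) {
      wl("[cstar_confusion]")
      wl("set\ttp\tfp\tfn\ttn")
      for (nm in names(tm$confusion)) {
        cm <- tm$confusion[[nm]]
        wl("%s\t%d\t%d\t%d\t%d", nm, cm$tp, cm$fp, cm$fn, cm$tn)
      }
      wl("[cstar_metrics]")
      wl("set\tsensitivity\tspecificity\tprecision\taccuracy\tauc")
      for (nm in names(tm$metrics)) {
        mt <- tm$metrics[[nm]]
        wl("%s\t%.10g\t%.10g\t%.10g\t%.10g\t%.10g", nm, mt$sensitivity,
           mt$specificity, mt$precision, mt$accuracy, mt$auc)
      }
    }
  }
  invisible(path)
}

#' Read a report written by [write_report()]
#' @param path report file path.
#' @return list with elements `config`, `ranking` (data.frame), `cstar`
#'   (list with `panel`, and when present `confusion` and `metrics`
#'   data.frames).
#' @export
read_report <- function(path) {
  if (!file.exists(path)) pf_stop("pf_io_error", "no such file: %s", path)
  lines <- readLines(path)
  hdr <- grep("^# (\\S+)=", lines, value = TRUE)
  config <- list()
  for (h in hdr) {
    kv <- sub("^# ", "", h)
    k <- sub("=.*$", "", kv)
    config[[k]] <- sub("^[^=]*=", "", kv)
  }
  section <- function(name) {
    i <- match(paste0("[", name, "]"), lines)
    if (is.na(i)) return(character(0))
    j <- grep("^\\[", lines)
    j <- j[j > i]
    end <- if (length(j)) min(j) - 1 else length(lines)
    if (end < i + 1) return(character(0))
    lines[(i + 1):end]
  }
  parse_tsv <- function(txt) {
    if (!length(txt)) return(data.frame())
    read.table(text = txt, sep = "\t", header = TRUE, check.names = FALSE,
               stringsAsFactors = FALSE)
  }
  ranking <- parse_tsv(section("ranking"))
  cstar <- NULL
  cs <- section("cstar")
  if (length(cs)) {
    cstar <- list(panel = strsplit(sub("^panel=", "", cs[1]), ";")[[1]])
    conf <- parse_tsv(section("cstar_confusion"))
    if (nrow(conf)) cstar$confusion <- conf
    mets <- parse_tsv(section("cstar_metrics"))
    if (nrow(mets)) cstar$metrics <- mets
  }
  list(config = config, ranking = ranking, cstar = cstar)
}
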