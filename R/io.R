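## Shared table readers/writers and the run report. Tables are UTF-8,
## tab-delimited, '#'-comment lines ignored, missing values as "NA";
## residue numbering is the author-assigned 1-based numbering.

.table_schemas <- list(
  relaxation = list(
    cols = c("res_num", "res_name", "field_MHz", "R1", "R1_err",
             "R2", "R2_err", "NOE", "NOE_err"),
    numeric = c("res_num", "field_MHz", "R1", "R1_err", "R2", "R2_err",
                "NOE", "NOE_err"),
    positive = c("field_MHz", "R1", "R1_err", "R2", "R2_err", "NOE_err")
  ),
  hdx = list(
    cols = c("res_num", "time_s", "intensity"),
    optional = "intensity_err",
    numeric = c("res_num", "time_s", "intensity", "intensity_err"),
    positive = character(0)
  ),
  shifts = list(
    cols = c("res_num", "H_ppm", "N_ppm"),
    optional = "res_name",
    numeric = c("res_num", "H_ppm", "N_ppm"),
    positive = character(0)
  ),
  rdc = list(
    cols = c("res_num", "D_Hz"),
    optional = "D_err",
    numeric = c("res_num", "D_Hz", "D_err"),
    positive = character(0)
  )
)

#' Read and validate a tab-delimited data table
#'
#' Schema-checked reader for the pipeline's table formats. Header names
#' must include the schema's required columns; `#`-prefixed lines are
#' ignored; the literal "NA" marks missing values. Validation failures name
#' the offending column or row.
#'
#' @param path file path
#' @param schema one of "relaxation", "hdx", "shifts", "rdc"
#' @return validated data.frame
#' @export
read_table <- function(path, schema = c("relaxation", "hdx", "shifts", "rdc")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("no such file: ", path)
  sch <- .table_schemas[[schema]]
  df <- utils::read.delim(path, comment.char = "#", na.strings = "NA",
                          stringsAsFactors = FALSE)
  miss <- setdiff(sch$cols, names(df))
  if (length(miss)) {
    stop(sprintf("schema '%s': missing column(s): %s",
                 schema, paste(miss, collapse = ", ")))
  }
  for (cn in intersect(sch$numeric, names(df))) {
    v <- df[[cn]]
    if (is.character(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad)) {
        stop(sprintf("schema '%s': non-numeric value in column '%s' at row %d",
                     schema, cn, bad[1]))
      }
      df[[cn]] <- num
    }
  }
  for (cn in intersect(sch$positive, names(df))) {
    bad <- which(is.finite(df[[cn]]) & df[[cn]] <= 0)
    if (length(bad)) {
      stop(sprintf("schema '%s': column '%s' must be > 0 (row %d has %g)",
                   schema, cn, bad[1], df[[cn]][bad[1]]))
    }
  }
  if (schema == "hdx") {
    bad <- which(is.finite(df$intensity) & df$intensity < 0)
    if (length(bad)) {
      stop(sprintf("schema 'hdx': negative intensity at row %d", bad[1]))
    }
  }
  df
}

#' Read the relaxation table format
#'
#' Convenience wrapper: `read_table(path, "relaxation")`. Columns:
#' res_num, res_name, field_MHz, R1, R1_err, R2, R2_err, NOE, NOE_err.
#' @param path file path
#' @return data.frame
#' @export
read_relaxation_table <- function(path) read_table(path, "relaxation")

#' Write a pipeline table as tab-delimited text
#' @param df data.frame
#' @param path output file
#' @return `path`, invisibly
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein sequence from a FASTA file
#'
#' Minimal single-record FASTA reader for the sequence the intrinsic-rate
#' predictor needs.
#' @param path FASTA file (first record used)
#' @return one-letter sequence string
#' @export
read_fasta_sequence <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !startsWith(lines[1], ">")) {
    stop("not a FASTA file: ", path)
  }
  body <- lines[-1]
  nxt <- which(startsWith(body, ">"))
  if (length(nxt)) body <- body[seq_len(nxt[1] - 1)]
  toupper(gsub("\\s", "", paste(body, collapse = "")))
}

#' Bundle stage outputs into a reloadable run report
#'
#' Writes a JSON results bundle (reloadable with [load_report()]) plus a
#' human-readable text summary listing the constants, seeds, exclusions
#' and per-stage headline numbers.
#'
#' @param stages named list of stage outputs; any structure jsonlite can
#'   serialize (lists, data.frames, numbers)
#' @param path output path for the JSON bundle; the text summary goes to
#'   `paste0(path, ".txt")`
#' @return `path`, invisibly
#' @export
run_report <- function(stages, path) {
  stopifnot(is.list(stages), !is.null(names(stages)))
  jsonlite::write_json(stages, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  txt <- c("nmrdyn run report", strrep("=", 60))
  for (nm in names(stages)) {
    txt <- c(txt, "", paste0("[", nm, "]"))
    s <- stages[[nm]]
    if (is.list(s) && !is.data.frame(s)) {
      for (k in names(s)) {
        v <- s[[k]]
        if (is.numeric(v) && length(v) == 1) {
          txt <- c(txt, sprintf("  %s = %g", k, v))
        } else if (is.character(v) && length(v) == 1) {
          txt <- c(txt, sprintf("  %s = %s", k, v))
        } else if (is.data.frame(v)) {
          txt <- c(txt, sprintf("  %s: %d rows", k, nrow(v)))
        }
      }
    }
  }
  writeLines(txt, paste0(path, ".txt"))
  invisible(path)
}

#' Reload a run-report bundle
#' @param path JSON bundle written by [run_report()]
#' @return named list
#' @export
load_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
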