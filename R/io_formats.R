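#' Read capture histories from CSV or MARK-style .inp
#'
#' The CSV dialect has a header with columns `nest_id`, `colony`, `history`,
#' the history written as a contiguous 0/1 string (e.g. `"101"`). The .inp
#' dialect follows program MARK: one statement per history,
#' `"<history> <freq per group>;"`, with `/* ... */` comments allowed. The
#' number of flyover occasions `T` is inferred from the first history and
#' enforced on all rows.
#'
#' .inp files carry no group labels, so the writer records the colony labels
#' in a `/* colonies: ... */` header comment, which the reader recovers. If
#' the comment is absent, supply `groups`, otherwise labels `g1`, `g2`, ...
#' are synthesized. Nest ids are synthesized on .inp read.
#'
#' @param path path to an existing file.
#' @param dialect `"csv"` or `"inp"`.
#' @param groups optional character vector of colony labels for the .inp
#'   frequency columns (in column order); ignored for CSV.
#' @return A validated [capture_dataset()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("nest_id,colony,history", "n1,A,101", "n2,A,110", "n3,B,011"), f)
#' read_capture_table(f, "csv")
#' @export
read_capture_table <- function(path, dialect = c("csv", "inp"), groups = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_contract("file not found: ", path)
  if (dialect == "csv") read_capture_csv(path) else read_capture_inp(path, groups)
}

read_capture_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("nest_id", "colony", "history")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop_contract("CSV is missing required column(s): ",
                  paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) stop_contract("CSV contains no records")
  hist <- histories_from_strings(df$history, context = "row")
  capture_dataset(hist, colony = df$colony, nest_id = df$nest_id)
}

read_capture_inp <- function(path, groups = NULL) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  # recover colony labels from the writer's header comment, if present
  m <- regmatches(txt, regexpr("/\\*\\s*colonies:\\s*([^*]*)\\*/", txt))
  if (is.null(groups) && length(m) == 1L) {
    lab <- sub("^/\\*\\s*colonies:\\s*", "", sub("\\*/$", "", m))
    groups <- strsplit(trimws(lab), "\\s+")[[1L]]
  }
  txt <- gsub("/\\*.*?\\*/", " ", txt)  # strip comments (non-greedy, multiline ok)
  stmts <- trimws(strsplit(txt, ";", fixed = TRUE)[[1L]])
  stmts <- stmts[nzchar(stmts)]
  if (length(stmts) == 0L) stop_contract(".inp contains no capture histories")
  hist_str <- character()
  colony <- character()
  G <- NULL
  for (i in seq_along(stmts)) {
    tok <- strsplit(stmts[i], "\\s+")[[1L]]
    if (length(tok) < 2L) {
      stop_contract("malformed .inp statement ", i, ": '", stmts[i], "'")
    }
    h <- tok[1L]
    freq <- suppressWarnings(as.numeric(tok[-1L]))
    if (anyNA(freq) || any(freq < 0) || any(freq != floor(freq))) {
      stop_contract("non-integer or negative frequency in .inp statement ", i)
    }
    if (is.null(G)) {
      G <- length(freq)
    } else if (length(freq) != G) {
      stop_contract(".inp statement ", i, " has ", length(freq),
                    " frequency columns; expected ", G)
    }
    for (g in seq_len(G)) {
      k <- freq[g]
      if (k > 0) {
        hist_str <- c(hist_str, rep(h, k))
        colony <- c(colony, rep(g, k))
      }
    }
  }
  labels <- groups %||% paste0("g", seq_len(G))
  if (length(labels) != G) {
    stop_contract("'groups' has ", length(labels), " labels but the .inp has ",
                  G, " frequency columns")
  }
  hist <- histories_from_strings(hist_str, context = "expanded record")
  capture_dataset(hist, colony = labels[as.integer(colony)],
                  colony_levels = labels)
}

#' Write capture histories to CSV or MARK-style .inp
#'
#' `read_capture_table(write_capture_table(d))` reproduces `d` exactly for
#' CSV, and up to nest-id renaming for .inp. The .inp writer emits one
#' frequency column per colony in sorted (lexicographic) label order, one
#' semicolon-terminated statement per nest, preceded by a
#' `/* colonies: ... */` header comment documenting the column order.
#'
#' @param dataset a valid [capture_dataset()].
#' @param path output file path.
#' @param dialect `"csv"` or `"inp"`.
#' @return `path`, invisibly.
#' @export
write_capture_table <- function(dataset, path, dialect = c("csv", "inp")) {
  stopifnot(inherits(dataset, "capture_dataset"))
  dialect <- match.arg(dialect)
  hs <- history_strings(dataset)
  if (dialect == "csv") {
    ids <- rownames(dataset$histories)
    col <- as.character(dataset$colony)
    if (any(grepl(",", c(ids, col), fixed = TRUE))) {
      stop_contract("nest_id and colony labels must not contain commas")
    }
    lines <- c("nest_id,colony,history", paste(ids, col, hs, sep = ","))
  } else {
    labels <- levels(dataset$colony)
    freq <- vapply(seq_along(hs), function(i) {
      f <- integer(length(labels))
      f[match(as.character(dataset$colony)[i], labels)] <- 1L
      paste(f, collapse = " ")
    }, character(1))
    lines <- c(paste0("/* colonies: ", paste(labels, collapse = " "), " */"),
               paste0(hs, " ", freq, ";"))
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) stop_contract("cannot write '", path, "': ",
                                                   conditionMessage(e)))
  invisible(path)
}
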