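#' Capture-history dataset for a closed session
#'
#' Container for nest detection histories from one closed session of repeated
#' drone flyovers. Each record is one nest that was detected at least once:
#' a unique id, the colony it belongs to, and a binary history of length `T`
#' (the number of flyovers), 1 where the image interpreter detected the
#' occupied nest and 0 where it was not detected. All-zero histories are
#' unobservable in the field and are rejected.
#'
#' @param histories either a character vector of 0/1 strings (e.g. `"101"`)
#'   or a 0/1 matrix with one row per nest and one column per flyover.
#' @param colony colony label per nest (character or factor); at least one
#'   label must be present.
#' @param nest_id unique nest identifiers; synthesized as `"n1"`, `"n2"`, ...
#'   when `NULL`.
#' @param session_label optional free-text label for the closed session.
#' @param colony_levels optional full set of colony labels; allows a dataset
#'   with zero records for a colony that was surveyed but produced no
#'   detections (such a dataset cannot be fitted).
#'
#' @return An object of class `capture_dataset`: a list with elements
#'   `occasions` (integer `T`), `histories` (n x T integer matrix, rownames =
#'   nest ids), `colony` (factor of length n) and `session_label`.
#' @examples
#' d <- capture_dataset(c("101", "110", "011"), colony = c("A", "A", "B"))
#' d
#' @seealso [read_capture_table()], [fit_closed()]
#' @export
capture_dataset <- function(histories, colony, nest_id = NULL,
                            session_label = NULL, colony_levels = NULL) {
  if (is.character(histories)) {
    histories <- histories_from_strings(histories)
  }
  if (!is.matrix(histories)) {
    stop_contract("'histories' must be a 0/1 matrix or a vector of 0/1 strings")
  }
  storage.mode(histories) <- "integer"
  n <- nrow(histories)
  T <- ncol(histories)
  if (T < 1L) stop_contract("at least one occasion is required")
  if (n > 0L) {
    if (anyNA(histories) || !all(histories %in% c(0L, 1L))) {
      bad <- which(apply(histories, 1L, function(h) anyNA(h) || !all(h %in% c(0L, 1L))))[1L]
      stop_contract("non-binary history entries in record ", bad)
    }
    zero <- which(rowSums(histories) == 0L)
    if (length(zero) > 0L) {
      stop_contract("all-zero capture history in record ", zero[1L],
                    ": a nest never detected cannot appear in the data")
    }
  }
  if (length(colony) != n) {
    stop_contract("'colony' must have one label per history row")
  }
  colony <- as.character(colony)
  if (n > 0L && any(!nzchar(colony) | is.na(colony))) {
    stop_contract("colony labels must be non-empty")
  }
  levels <- sort(unique(c(colony, as.character(colony_levels %||% character()))))
  if (length(levels) == 0L) stop_contract("at least one colony label is required")
  if (is.null(nest_id)) {
    nest_id <- if (n == 0L) character() else paste0("n", seq_len(n))
  }
  nest_id <- as.character(nest_id)
  if (length(nest_id) != n) stop_contract("'nest_id' must have one entry per record")
  if (anyDuplicated(nest_id)) {
    dup <- nest_id[duplicated(nest_id)][1L]
    stop_contract("duplicate nest_id: '", dup, "'")
  }
  rownames(histories) <- nest_id
  structure(
    list(occasions = as.integer(T),
         histories = histories,
         colony = factor(colony, levels = levels),
         session_label = session_label),
    class = "capture_dataset"
  )
}

histories_from_strings <- function(x, context = NULL) {
  if (length(x) == 0L) return(matrix(integer(), 0L, 0L))
  T <- nchar(x[1L])
  for (i in seq_along(x)) {
    if (nchar(x[i]) != T) {
      stop_contract("history length ", nchar(x[i]), " in ",
                    context %||% "record", " ", i,
                    " differs from expected length ", T)
    }
    chars <- strsplit(x[i], "", fixed = TRUE)[[1L]]
    bad <- which(!chars %in% c("0", "1"))
    if (length(bad) > 0L) {
      stop_contract("non-binary character '", chars[bad[1L]], "' in ",
                    context %||% "record", " ", i)
    }
  }
  do.call(rbind, lapply(strsplit(x, "", fixed = TRUE), as.integer))
}

#' @export
print.capture_dataset <- function(x, ...) {
  ng <- table(x$colony)
  cat("Capture-history dataset: ", nrow(x$histories), " nests, ",
      x$occasions, " occasions, ", nlevels(x$colony), " colonies\n", sep = "")
  if (!is.null(x$session_label)) cat("Session:", x$session_label, "\n")
  cat("Nests per colony:\n")
  print(ng)
  invisible(x)
}

#' History strings of a capture dataset
#' @param dataset a [capture_dataset()].
#' @return character vector of 0/1 strings, one per record.
#' @export
history_strings <- function(dataset) {
  stopifnot(inherits(dataset, "capture_dataset"))
  apply(dataset$histories, 1L, paste, collapse = "")
}

# Sufficient statistics for the closed likelihood: per-colony sample sizes
# n_g and the T x G matrix x of per-occasion detection counts.
suff_stats <- function(dataset) {
  stopifnot(inherits(dataset, "capture_dataset"))
  labels <- levels(dataset$colony)
  G <- length(labels)
  T <- dataset$occasions
  n_g <- as.integer(table(dataset$colony))
  x <- matrix(0L, T, G, dimnames = list(NULL, labels))
  for (g in seq_len(G)) {
    rows <- dataset$colony == labels[g]
    if (any(rows)) x[, g] <- colSums(dataset$histories[rows, , drop = FALSE])
  }
  list(labels = labels, G = G, T = T, n = n_g, x = x,
       n_total = nrow(dataset$histories))
}
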