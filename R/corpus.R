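#' Thought-record corpora
#'
#' A corpus is a flat utterance table (one row per utterance) with class
#' `tr_corpus`. Required columns:
#' \describe{
#'   \item{participant_id, record_id}{opaque identifiers; record ids are
#'     globally unique and every utterance of a record shares one
#'     participant.}
#'   \item{record_type}{`"closed"` (scripted scenario) or `"open"`
#'     (real-life situation).}
#'   \item{scenario_type}{`"interpersonal"` or `"achievement"`.}
#'   \item{scenario_id}{scenario identifier, `NA` for open records.}
#'   \item{emotion}{`"sadness"`, `"fear"`, `"anger"` or `"happiness"`;
#'     happiness records have no downward-arrow chain, hence exactly one
#'     utterance.}
#'   \item{depth}{position in the downward-arrow chain; 1 is the automatic
#'     thought and depths are consecutive within a record.}
#'   \item{text}{the utterance, possibly multi-sentence.}
#'   \item{s1..s9}{manual ordinal schema scores in `{0,1,2,3}` in canonical
#'     schema order, or all-`NA` when unscored. An all-zero row is a legal
#'     no-schema utterance; zero is a meaningful score and is never used to
#'     encode missingness.}
#' }
#'
#' @param data A data.frame with the columns above.
#' @return `as_corpus()` returns the validated `tr_corpus` data.frame.
#' @seealso [read_corpus()], [write_corpus()], [validate_corpus()]
#' @export
as_corpus <- function(data) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  validate_corpus(data)
  class(data) <- unique(c("tr_corpus", class(data)))
  data
}

corpus_columns <- function() {
  c("participant_id", "record_id", "record_type", "scenario_type",
    "scenario_id", "emotion", "depth", "text", score_columns())
}

#' Validate a corpus table
#'
#' Checks the structural invariants of the utterance table: required columns
#' present, scores integer in `{0..3}` or `NA` (per row either all nine
#' scores present or all absent), depths consecutive `1..D` within a record,
#' unique record-to-participant assignment, and the happiness rule (records
#' with emotion `"happiness"` carry no downward-arrow steps, i.e. exactly
#' one utterance). Violations raise an error naming the offending rows.
#'
#' @param data A data.frame in the corpus layout.
#' @param check_design If `TRUE`, additionally require the full study design
#'   per participant: four closed records (two interpersonal, two
#'   achievement) plus one open record.
#' @return Invisibly `TRUE`; errors on any violation.
#' @export
validate_corpus <- function(data, check_design = FALSE) {
  missing_cols <- setdiff(corpus_columns(), names(data))
  if (length(missing_cols) > 0L) {
    stop("corpus table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  sc <- as.matrix(data[score_columns()])
  storage.mode(sc) <- "double"
  bad <- which(!is.na(sc) & (sc < 0 | sc > 3 | sc != round(sc)), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("invalid schema score in row %d, column %s (scores must be integers 0..3)",
                 bad[1, 1], score_columns()[bad[1, 2]]), call. = FALSE)
  }
  part_na <- which(apply(is.na(sc), 1L, function(z) any(z) && !all(z)))
  if (length(part_na) > 0L) {
    stop("rows with partially missing scores (all nine must be present or all absent): ",
         paste(utils::head(part_na, 5L), collapse = ", "), call. = FALSE)
  }
  if (any(is.na(data$depth)) || any(data$depth < 1) ||
      any(data$depth != round(data$depth))) {
    stop("depth must be an integer >= 1 for every utterance", call. = FALSE)
  }
  if (!all(data$record_type %in% RECORD_TYPES)) {
    stop("record_type must be one of: ", paste(RECORD_TYPES, collapse = ", "),
         call. = FALSE)
  }
  if (!all(data$scenario_type %in% SCENARIO_TYPES)) {
    stop("scenario_type must be one of: ",
         paste(SCENARIO_TYPES, collapse = ", "), call. = FALSE)
  }
  if (!all(data$emotion %in% EMOTIONS)) {
    stop("emotion must be one of: ", paste(EMOTIONS, collapse = ", "),
         call. = FALSE)
  }
  for (rid in unique(data$record_id)) {
    rows <- which(data$record_id == rid)
    d <- sort(data$depth[rows])
    if (!identical(as.integer(d), seq_len(length(rows)))) {
      stop(sprintf("record %s: depths are not consecutive 1..D (rows %s)",
                   rid, paste(rows, collapse = ",")), call. = FALSE)
    }
    if (length(unique(data$participant_id[rows])) != 1L) {
      stop(sprintf("record %s: utterances name more than one participant", rid),
           call. = FALSE)
    }
    if (data$emotion[rows[1]] == "happiness" && length(rows) != 1L) {
      stop(sprintf("record %s: happiness records must have exactly one utterance", rid),
           call. = FALSE)
    }
  }
  if (check_design) {
    for (pid in unique(data$participant_id)) {
      recs <- unique(data[data$participant_id == pid,
                          c("record_id", "record_type", "scenario_type")])
      n_open <- sum(recs$record_type == "open")
      n_int  <- sum(recs$record_type == "closed" &
                    recs$scenario_type == "interpersonal")
      n_ach  <- sum(recs$record_type == "closed" &
                    recs$scenario_type == "achievement")
      if (n_open != 1L || n_int != 2L || n_ach != 2L) {
        stop(sprintf(
          "participant %s: expected 2 interpersonal + 2 achievement closed records and 1 open record (found %d/%d/%d)",
          pid, n_int, n_ach, n_open), call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Read a thought-record corpus from a delimited table
#'
#' Reads a UTF-8 delimited utterance table (comma by default, tab accepted)
#' into a validated corpus. Rows are grouped into records by `record_id` and
#' ordered by depth within each record. Score columns may be renamed in the
#' source file via the `dialect` mapping; empty score cells denote unscored
#' utterances (never zero).
#'
#' @param path Path to the table.
#' @param dialect Optional list adapting foreign layouts:
#'   `sep` (field separator, default `","`), and `columns`, a named character
#'   vector mapping canonical column names to the names used in the file,
#'   e.g. `c(text = "utterance_text")`. Unmapped columns are looked up under
#'   their canonical names.
#' @return A `tr_corpus` data.frame.
#' @export
read_corpus <- function(path, dialect = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (is.null(dialect$sep)) "," else dialect$sep
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, comment.char = "",
                           colClasses = "character", check.names = FALSE,
                           fileEncoding = "UTF-8")
  colmap <- dialect$columns
  if (!is.null(colmap)) {
    for (canon in names(colmap)) {
      src <- colmap[[canon]]
      if (!src %in% names(raw)) {
        stop("dialect maps ", canon, " to absent column ", src, call. = FALSE)
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  missing_cols <- setdiff(corpus_columns(), names(raw))
  if (length(missing_cols) > 0L) {
    stop("corpus file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- raw[corpus_columns()]
  raw$depth <- as.integer(raw$depth)
  raw$scenario_id[raw$scenario_id == ""] <- NA_character_
  for (j in score_columns()) {
    cell <- raw[[j]]
    cell[cell == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & is.na(num))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric score in data row %d, column %s: '%s'",
                   bad[1], j, cell[bad[1]]), call. = FALSE)
    }
    raw[[j]] <- num
  }
  raw <- raw[order(match(raw$record_id, unique(raw$record_id)), raw$depth), ,
             drop = FALSE]
  rownames(raw) <- NULL
  as_corpus(raw)
}

#' Write a corpus to a delimited table
#'
#' One utterance per row with the stable canonical column order; the output
#' is re-readable by [read_corpus()] with identical text and scores. Absent
#' manual scores are written as empty cells.
#'
#' @param corpus A `tr_corpus` (or conforming data.frame).
#' @param path Output file path.
#' @param sep Field separator, default comma.
#' @return Invisibly `path`.
#' @export
write_corpus <- function(corpus, path, sep = ",") {
  validate_corpus(corpus)
  out <- as.data.frame(corpus)[corpus_columns()]
  for (j in score_columns()) {
    out[[j]] <- ifelse(is.na(out[[j]]), "", format(out[[j]], trim = TRUE))
  }
  out$scenario_id[is.na(out$scenario_id)] <- ""
  ok <- tryCatch({
    utils::write.table(out, path, sep = sep, row.names = FALSE,
                       col.names = TRUE, qmethod = "double",
                       fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("could not write corpus to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Extract the manual score matrix of a corpus
#'
#' @param corpus A corpus table.
#' @return Integer matrix, one row per utterance, nine columns in canonical
#'   schema order.
#' @export
score_matrix <- function(corpus) {
  m <- as.matrix(as.data.frame(corpus)[score_columns()])
  storage.mode(m) <- "double"
  colnames(m) <- schema_names()
  m
}
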