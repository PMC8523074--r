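#' Word-embedding tables
#'
#' An embedding table maps words to real vectors of one shared dimension.
#' Lookup of an absent word is reported distinctly (`NULL`) rather than as a
#' vector, so out-of-vocabulary handling stays explicit downstream.
#'
#' @param vectors Numeric matrix, one row per word, with rownames giving the
#'   words.
#' @return An `embedding_table` object.
#' @export
embedding_table <- function(vectors) {
  stopifnot(is.matrix(vectors), is.numeric(vectors),
            !is.null(rownames(vectors)))
  structure(list(dimension = ncol(vectors), vectors = vectors),
            class = "embedding_table")
}

#' @exportS3Method base::print
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table: %d words, dimension %d>\n",
              nrow(x$vectors), x$dimension))
  invisible(x)
}

#' Look up a word vector
#'
#' @param table An [embedding_table()].
#' @param word A single word.
#' @return The word's vector, or `NULL` when the word is out of vocabulary.
#' @export
lookup_word <- function(table, word) {
  i <- match(word, rownames(table$vectors))
  if (is.na(i)) NULL else table$vectors[i, ]
}

#' Read word vectors in GLoVE plain-text format
#'
#' Each line holds a token followed by `d` whitespace-separated decimal
#' floats (the standard format of the pretrained GLoVE distributions, e.g.
#' the 100-dimensional Wikipedia-trained vectors). Duplicate tokens keep the
#' first occurrence, matching the usual embedding-file convention.
#'
#' @param path Path to the vector file.
#' @param expected_dim Required vector dimension; a line with any other
#'   number of floats is a format error reported with its line number.
#' @return An [embedding_table()] of dimension `expected_dim`.
#' @export
read_glove_text <- function(path, expected_dim) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  stopifnot(is.numeric(expected_dim), expected_dim >= 1)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty embedding file: ", path, call. = FALSE)
  parts <- strsplit(lines, "[ \t]+")
  nfloat <- lengths(parts) - 1L
  bad <- which(nfloat != expected_dim)
  if (length(bad) > 0L) {
    stop(sprintf("line %d: expected %d floats after the token, found %d",
                 bad[1], as.integer(expected_dim), nfloat[bad[1]]),
         call. = FALSE)
  }
  words <- vapply(parts, `[[`, character(1), 1L)
  vals <- lapply(parts, function(p) as.numeric(p[-1L]))
  bad_num <- which(vapply(vals, anyNA, logical(1)))
  if (length(bad_num) > 0L) {
    stop(sprintf("line %d: non-numeric vector component", bad_num[1]),
         call. = FALSE)
  }
  keep <- !duplicated(words)
  m <- do.call(rbind, vals[keep])
  rownames(m) <- words[keep]
  embedding_table(m)
}
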