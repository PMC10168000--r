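#' Read / write identifier tables
#'
#' The exchange format of the pipeline is a two-column UTF-8 TSV with header
#' `id<TAB>class`; prediction-only tables may omit the `class` column.
#'
#' @param path TSV file path.
#' @param table a data frame with an `id` column and optionally `class`.
#' @return `read_id_table()` returns a tibble; `write_id_table()` returns
#'   `path` invisibly.
#' @export
read_id_table <- function(path) {
  tab <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (!"id" %in% names(tab)) stopf("'%s' has no 'id' column", path)
  tab
}

#' @rdname read_id_table
#' @export
write_id_table <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}

#' Remove invalid rows from a raw identifier table
#'
#' Drops rows whose `id` is missing or empty (after trimming surrounding
#' whitespace) and collapses exact duplicate `(id, class)` rows to one.
#' Idempotent; row order of surviving rows is preserved.
#'
#' @param raw a data frame with an `id` column and optionally a `class`
#'   column.
#' @return A tibble with the same columns, cleaned.
#' @export
clean_table <- function(raw) {
  if (!"id" %in% names(raw)) stopf("input has no 'id' column")
  tab <- tibble::as_tibble(raw)
  tab$id <- trimws(as.character(tab$id))
  keep <- !is.na(tab$id) & nzchar(tab$id)
  if ("class" %in% names(tab)) {
    keep <- keep & !is.na(tab$class) & nzchar(as.character(tab$class))
  }
  tab <- tab[keep, , drop = FALSE]
  tab[!duplicated(tab), , drop = FALSE]
}

#' Length of the longest identifier
#'
#' Determines the width of the positional feature matrix: every identifier is
#' padded out to this length.
#'
#' @param table a non-empty identifier table (or character vector of ids).
#' @return Integer pad length, at least 1.
#' @export
pad_length <- function(table) {
  ids <- if (is.character(table)) table else table$id
  if (length(ids) == 0L) stopf("cannot take pad length of an empty table")
  max(nchar(ids))
}

#' Split identifiers into a fixed-width character matrix
#'
#' Each identifier occupies one row, left-aligned; positions beyond its last
#' character hold the pad symbol `""`. Row order follows the input.
#'
#' @param table an identifier table (or character vector of ids).
#' @param len pad length; must be at least the longest identifier.
#' @return An `n x len` character matrix with columns `pos1 ... pos<len>`.
#' @export
split_and_pad <- function(table, len) {
  ids <- if (is.character(table)) table else table$id
  if (length(ids) && len < max(nchar(ids))) {
    stopf("pad length %d is smaller than the longest identifier (%d)",
      len, max(nchar(ids)))
  }
  mat <- matrix("", nrow = length(ids), ncol = len,
    dimnames = list(NULL, paste0("pos", seq_len(len))))
  if (length(ids)) {
    chars <- strsplit(ids, "", fixed = TRUE)
    for (i in seq_along(chars)) {
      v <- chars[[i]]
      if (length(v)) mat[i, seq_along(v)] <- v
    }
  }
  mat
}

#' Encode a character matrix as integer positional features
#'
#' Applies the character-to-code map position-wise; the pad symbol maps to
#' the reserved code 0. By default an unknown character is an error that
#' names the offending character and row; with `unknown = "pad"` it is mapped
#' to the pad code with a warning (the lenient behaviour used at prediction
#' time, where the training inventory must not be extended).
#'
#' @param char_mat character matrix from [split_and_pad()].
#' @param encoding a [default_encoding()]-style `char_encoding`.
#' @param unknown `"error"` (default) or `"pad"`.
#' @return Integer matrix of the same shape, entries in
#'   `{0} + range(code_map)`.
#' @export
encode_chars <- function(char_mat, encoding, unknown = c("error", "pad")) {
  unknown <- match.arg(unknown)
  stopifnot(inherits(encoding, "char_encoding"))
  flat <- as.vector(char_mat)
  codes <- unname(encoding$code_map[flat])
  codes[flat == ""] <- encoding$pad_code
  bad <- is.na(codes)
  if (any(bad)) {
    idx <- which(bad)[1]
    row <- ((idx - 1L) %% nrow(char_mat)) + 1L
    if (unknown == "error") {
      stopf("unknown character '%s' in row %d", flat[idx], row)
    }
    warnf(
      "%d character(s) outside the encoding inventory (first: '%s' in row %d) mapped to the pad code",
      sum(bad), flat[idx], row
    )
    codes[bad] <- encoding$pad_code
  }
  matrix(as.integer(codes),
    nrow = nrow(char_mat),
    dimnames = dimnames(char_mat)
  )
}

#' Encode an identifier table as a fixed-width integer feature matrix
#'
#' Convenience wrapper chaining [pad_length()], [split_and_pad()] and
#' [encode_chars()]. When `len` comes from a trained model, identifiers
#' longer than `len` are truncated with a warning rather than rejected.
#'
#' @param table an identifier table (cleaned; see [clean_table()]).
#' @param encoding a `char_encoding`; defaults to [default_encoding()].
#' @param len pad length; defaults to the longest identifier in `table`.
#' @param classes optional fixed class-level ordering for the label factor.
#' @param unknown passed to [encode_chars()].
#' @return An object of class `encoded_ids`: list with `X` (n x len integer
#'   matrix), `y` (factor of length n, or `NULL` for unlabelled tables),
#'   `encoding`, and `ids` (the original strings, in row order).
#' @examples
#' tab <- tibble::tibble(id = c("CHEMBL25", "RF00001"), class = c("a", "b"))
#' enc <- encode_ids(tab)
#' enc$X
#' @export
encode_ids <- function(table, encoding = default_encoding(), len = NULL,
                       classes = NULL, unknown = "error") {
  ids <- as.character(table$id)
  if (is.null(len)) len <- pad_length(ids)
  too_long <- nchar(ids) > len
  if (any(too_long)) {
    warnf(
      "%d identifier(s) longer than the pad length %d were truncated",
      sum(too_long), len
    )
    ids[too_long] <- substr(ids[too_long], 1L, len)
  }
  X <- encode_chars(split_and_pad(ids, len), encoding, unknown = unknown)
  y <- NULL
  if ("class" %in% names(table)) {
    y <- if (is.null(classes)) {
      factor(table$class)
    } else {
      factor(table$class, levels = classes)
    }
  }
  new_encoded_ids(X, y, encoding, ids)
}

new_encoded_ids <- function(X, y, encoding, ids = NULL) {
  structure(
    list(X = X, y = y, encoding = encoding, ids = ids),
    class = "encoded_ids"
  )
}

#' @export
print.encoded_ids <- function(x, ...) {
  cat("<encoded_ids> ", nrow(x$X), " x ", ncol(x$X),
    if (is.null(x$y)) " (unlabelled)" else
      paste0(" (", nlevels(x$y), " classes)"), "\n", sep = "")
  invisible(x)
}

#' Decode an integer feature matrix back to identifier strings
#'
#' Inverse of [encode_chars()]: codes map back to their characters and
#' trailing pad codes are stripped, so `decode_ids(encode_ids(tab)$X, enc)`
#' returns the original identifiers.
#'
#' @param X integer matrix of positional codes.
#' @param encoding the `char_encoding` used to produce `X`.
#' @return Character vector of identifiers.
#' @export
decode_ids <- function(X, encoding) {
  stopifnot(inherits(encoding, "char_encoding"))
  lookup <- character(max(encoding$code_map))
  lookup[encoding$code_map] <- names(encoding$code_map)
  apply(X, 1L, function(r) {
    r <- r[r != encoding$pad_code]
    paste(lookup[r], collapse = "")
  })
}
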