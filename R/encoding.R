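#' Character encodings for identifier strings
#'
#' An identifier is represented as a fixed-width vector of integer character
#' codes: feature `j` is the code of character `j`, and positions past the end
#' of the identifier carry the reserved pad code `0`. A `char_encoding` holds
#' the character-to-code map; it is injective, case-sensitive (identifier case
#' is meaningful: `ENSG...` and `uc...` differ by case alone) and is stored
#' with a trained model so prediction reuses the training map.
#'
#' The default inventory covers the characters that occur in accession-style
#' identifiers: digits `0`-`9` (codes 1-10), `A`-`Z` (11-36), `a`-`z` (37-62),
#' then `.`, `_`, `-`, `:`, `/`, `(`, `)` (63-69).
#'
#' @param extra optional character vector of additional single characters to
#'   append to the default inventory (assigned the next free codes).
#' @return An object of class `char_encoding`: a list with `code_map` (named
#'   integer vector, names are single characters) and `pad_code` (always 0).
#' @examples
#' enc <- default_encoding()
#' enc$code_map[c("0", "9", "A", "Z", "a")]
#' @export
default_encoding <- function(extra = character()) {
  chars <- c(as.character(0:9), LETTERS, letters, ".", "_", "-", ":", "/", "(", ")")
  chars <- c(chars, setdiff(extra, chars))
  code_map <- seq_along(chars)
  names(code_map) <- chars
  new_encoding(code_map)
}

new_encoding <- function(code_map) {
  code_map <- stats::setNames(as.integer(code_map), names(code_map))
  if (is.null(names(code_map)) || any(!nzchar(names(code_map)))) {
    stopf("encoding map must be named by single characters")
  }
  if (anyDuplicated(code_map) || any(code_map == 0L)) {
    stopf("encoding must be injective and must not use the reserved pad code 0")
  }
  structure(list(code_map = code_map, pad_code = 0L), class = "char_encoding")
}

#' @export
print.char_encoding <- function(x, ...) {
  cat("<char_encoding> ", length(x$code_map), " characters, pad code ",
    x$pad_code, "\n",
    sep = ""
  )
  invisible(x)
}

#' Serialize / restore a character encoding
#'
#' The encoding is written as a flat JSON object mapping each character to its
#' integer code, so a model directory is self-describing and the training map
#' can be reloaded for prediction.
#'
#' @param encoding a [default_encoding()]-style `char_encoding`.
#' @param path file path for the JSON map.
#' @return `write_encoding()` returns `path` invisibly; `read_encoding()`
#'   returns a `char_encoding`.
#' @export
write_encoding <- function(encoding, path) {
  stopifnot(inherits(encoding, "char_encoding"))
  jsonlite::write_json(as.list(encoding$code_map), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_encoding
#' @export
read_encoding <- function(path) {
  raw <- jsonlite::read_json(path)
  code_map <- vapply(raw, as.integer, integer(1))
  new_encoding(code_map)
}
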