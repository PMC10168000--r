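#' Identifier pattern registry
#'
#' A registry holds, per database class, an anchored regular-expression
#' template describing all valid identifiers of that class, plus an optional
#' structured generator hint used to sample synthetic identifiers that match
#' the template. Registry order is insertion order and is preserved by all
#' operations, so matching and generation are deterministic.
#'
#' @name id_registry
NULL

#' Create a pattern specification
#'
#' @param name class label, unique within a registry (e.g. `"ChEMBL"`).
#' @param template regular-expression string anchored at both ends
#'   (`^...$`); must compile.
#' @param generator_hint optional list of segments created by [hint_seg()];
#'   identifiers are sampled segment by segment. Every string producible from
#'   the hint must match `template`.
#' @param description free-text description of the database / ID type.
#' @return An object of class `id_pattern_spec`.
#' @examples
#' id_pattern_spec("ChEMBL", "^CHEMBL\\d+$",
#'   generator_hint = list(hint_seg("CHEMBL", 1), hint_seg(DIGITS, 4, 7))
#' )
#' @export
id_pattern_spec <- function(name, template, generator_hint = NULL,
                            description = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  ok <- tryCatch(
    {
      suppressWarnings(grepl(template, "x", perl = TRUE))
      TRUE
    },
    error = function(e) FALSE
  )
  if (!ok) stopf("template for '%s' does not compile: %s", name, template)
  if (!is.null(generator_hint)) {
    lapply(generator_hint, function(s) {
      stopifnot(inherits(s, "hint_seg"))
    })
  }
  structure(
    list(
      name = name, template = template,
      generator_hint = generator_hint, description = description
    ),
    class = "id_pattern_spec"
  )
}

#' Generator hint segment
#'
#' One segment of a structured generation template: `min` to `max` characters
#' drawn uniformly from `chars`. A literal prefix is a segment whose `chars`
#' is the whole prefix string with `min = max = 1` repetition of the literal;
#' for convenience, a multi-character `chars` string with `literal = TRUE`
#' (the default when `min == 1` and `nchar(chars) > 1` and `max == 1`) is
#' emitted verbatim.
#'
#' @param chars either a single string treated as the set of allowed
#'   characters (split into single characters), or — when `literal = TRUE` —
#'   a verbatim literal.
#' @param min,max repeat counts (inclusive); for a literal these are ignored.
#' @param literal emit `chars` verbatim instead of sampling from it.
#' @return An object of class `hint_seg`.
#' @export
hint_seg <- function(chars, min = 1L, max = min, literal = FALSE) {
  stopifnot(is.character(chars), length(chars) == 1L)
  if (literal) {
    structure(list(literal = chars), class = "hint_seg")
  } else {
    stopifnot(min >= 0L, max >= min)
    structure(
      list(
        chars = strsplit(chars, "", fixed = TRUE)[[1]],
        min = as.integer(min), max = as.integer(max)
      ),
      class = "hint_seg"
    )
  }
}

#' @rdname hint_seg
#' @format NULL
#' @export
DIGITS <- "0123456789"

#' @rdname hint_seg
#' @format NULL
#' @export
UPPER <- paste(LETTERS, collapse = "")

#' @rdname hint_seg
#' @format NULL
#' @export
LOWER <- paste(letters, collapse = "")

#' @rdname hint_seg
#' @format NULL
#' @export
ALNUM_UPPER <- paste0("0123456789", paste(LETTERS, collapse = ""))

#' Create an empty registry
#'
#' @return An object of class `id_registry`.
#' @seealso [builtin_registry()] for the shipped 39-class registry.
#' @export
id_registry <- function() {
  structure(list(specs = list()), class = "id_registry")
}

#' @export
print.id_registry <- function(x, ...) {
  cat("<id_registry> ", length(x$specs), " pattern(s)\n", sep = "")
  for (s in x$specs) cat("  ", format(s$name, width = 24), s$template, "\n")
  invisible(x)
}

#' @export
length.id_registry <- function(x) length(x$specs)

#' Register a pattern specification
#'
#' Appends `spec` to the registry. Re-registering an existing name is an
#' error: a registry maps each class name to exactly one template.
#'
#' @param registry an [id_registry()].
#' @param spec an [id_pattern_spec()].
#' @return The updated registry.
#' @export
register_pattern <- function(registry, spec) {
  stopifnot(inherits(registry, "id_registry"), inherits(spec, "id_pattern_spec"))
  if (spec$name %in% names(registry$specs)) {
    stopf("class '%s' is already registered", spec$name)
  }
  registry$specs[[spec$name]] <- spec
  registry
}

#' Match a query string against all registered patterns
#'
#' Because identifier surface forms are not unique across databases (e.g. a
#' broad `^[A-Z0-9]+$` class also matches every ChEMBL accession), a query can
#' match several classes; all full matches are returned in registry order.
#'
#' @param registry a non-empty [id_registry()].
#' @param query a single identifier string. An empty string matches nothing.
#' @return Character vector of matching class names (possibly empty), in
#'   registry order.
#' @examples
#' reg <- builtin_registry()
#' match_patterns(reg, "ENSG00000164197")
#' @export
match_patterns <- function(registry, query) {
  stopifnot(inherits(registry, "id_registry"))
  if (length(registry$specs) == 0L) stopf("registry is empty")
  stopifnot(is.character(query), length(query) == 1L)
  if (is.na(query) || !nzchar(query)) {
    return(character(0))
  }
  hits <- vapply(
    registry$specs,
    function(s) grepl(s$template, query, perl = TRUE),
    logical(1)
  )
  names(registry$specs)[hits]
}

hint_capacity <- function(hint) {
  caps <- vapply(hint, function(seg) {
    if (!is.null(seg$literal)) {
      return(1)
    }
    k <- length(seg$chars)
    sum(k^(seg$min:seg$max))
  }, numeric(1))
  prod(caps)
}

sample_hint_batch <- function(hint, n) {
  parts <- lapply(hint, function(seg) {
    if (!is.null(seg$literal)) {
      return(rep.int(seg$literal, n))
    }
    lens <- if (seg$min == seg$max) {
      rep.int(seg$min, n)
    } else {
      sample(seg$min:seg$max, n, replace = TRUE)
    }
    total <- sum(lens)
    draws <- sample(seg$chars, total, replace = TRUE)
    out <- character(n)
    idx <- c(0L, cumsum(lens))
    for (i in seq_len(n)) {
      out[i] <- paste(draws[(idx[i] + 1L):idx[i + 1L]], collapse = "")
    }
    out[lens == 0L] <- ""
    out
  })
  do.call(paste0, parts)
}

#' Generate synthetic identifiers for one class
#'
#' Samples `n` distinct identifier strings from the class's generator hint.
#' Every output matches the class template, and identical seeds give
#' identical output.
#'
#' @param registry an [id_registry()].
#' @param class a registered class name that has a generator hint.
#' @param n number of distinct identifiers; must not exceed the hint's
#'   enumerable capacity.
#' @param seed integer seed.
#' @return Character vector of `n` distinct identifiers.
#' @examples
#' generate_ids(builtin_registry(), "Ensembl gene", 3, seed = 7)
#' @export
generate_ids <- function(registry, class, n, seed) {
  stopifnot(inherits(registry, "id_registry"))
  spec <- registry$specs[[class]]
  if (is.null(spec)) stopf("unknown class '%s'", class)
  if (is.null(spec$generator_hint)) {
    stopf("class '%s' has no generator hint", class)
  }
  n <- as.numeric(n)
  stopifnot(n >= 0)
  cap <- hint_capacity(spec$generator_hint)
  if (n > cap) {
    stopf(
      "cannot generate %s distinct '%s' identifiers: capacity is %s",
      format(n, big.mark = ","), class, format(cap, big.mark = ",")
    )
  }
  if (n == 0) {
    return(character(0))
  }
  with_seed(seed, {
    out <- character(0)
    tries <- 0L
    while (length(out) < n) {
      need <- n - length(out)
      batch <- sample_hint_batch(spec$generator_hint, ceiling(need * 1.2) + 8L)
      out <- unique(c(out, batch))
      tries <- tries + 1L
      if (tries > 1000L) {
        stopf("could not draw %s distinct '%s' identifiers", n, class)
      }
    }
    out[seq_len(n)]
  })
}

#' Generate a labelled synthetic corpus
#'
#' Draws, for each class in `profile`, the requested number of distinct
#' identifiers, and stacks them into a long table of `(id, class)` pairs —
#' the universal exchange record of the pipeline. Identifiers are unique
#' within a class but may collide across classes, as real database
#' identifiers do.
#'
#' @param registry an [id_registry()].
#' @param profile named numeric vector: requested count per class (all
#'   positive; every name must be registered).
#' @param seed integer seed; each class draws from a seed derived from it, so
#'   a class's identifiers do not depend on the other classes requested.
#' @return A tibble with columns `id` (character) and `class` (character),
#'   classes in profile order.
#' @examples
#' generate_dataset(builtin_registry(), c(ChEMBL = 3, Rfam = 2), seed = 1)
#' @export
generate_dataset <- function(registry, profile, seed) {
  stopifnot(inherits(registry, "id_registry"))
  stopifnot(is.numeric(profile), !is.null(names(profile)), all(profile >= 1))
  unknown <- setdiff(names(profile), names(registry$specs))
  if (length(unknown)) {
    stopf("unknown class(es): %s", paste(unknown, collapse = ", "))
  }
  pieces <- lapply(names(profile), function(cl) {
    ids <- generate_ids(registry, cl, profile[[cl]],
      seed = stage_seed(seed, paste0("gen:", cl))
    )
    tibble::tibble(id = ids, class = cl)
  })
  dplyr::bind_rows(pieces)
}

#' Read / write a pattern registry as delimited text
#'
#' One row per pattern: `name`, `template`, `generator_hint` (JSON-encoded
#' segment list, empty when absent) and `description`, tab-separated.
#'
#' @param registry an [id_registry()].
#' @param path TSV file path.
#' @return `write_registry()` returns `path` invisibly; `read_registry()`
#'   returns an `id_registry`.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "id_registry"))
  rows <- lapply(registry$specs, function(s) {
    hint <- if (is.null(s$generator_hint)) {
      ""
    } else {
      as.character(jsonlite::toJSON(lapply(s$generator_hint, unclass)))
    }
    tibble::tibble(
      name = s$name, template = s$template,
      generator_hint = hint, description = s$description
    )
  })
  # written unquoted: the JSON hint column contains quote characters but
  # never tabs or newlines
  utils::write.table(dplyr::bind_rows(rows), path,
    sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  tab <- utils::read.delim(path,
    sep = "\t", quote = "", colClasses = "character",
    fileEncoding = "UTF-8", check.names = FALSE
  )
  tab$description[is.na(tab$description)] <- ""
  reg <- id_registry()
  for (i in seq_len(nrow(tab))) {
    hint <- NULL
    hj <- tab$generator_hint[i]
    if (!is.na(hj) && nzchar(hj)) {
      hint <- lapply(jsonlite::fromJSON(hj, simplifyVector = FALSE), function(seg) {
        if (!is.null(seg$literal)) {
          hint_seg(unlist(seg$literal), literal = TRUE)
        } else {
          structure(
            list(
              chars = unlist(seg$chars), min = as.integer(unlist(seg$min)),
              max = as.integer(unlist(seg$max))
            ),
            class = "hint_seg"
          )
        }
      })
    }
    reg <- register_pattern(reg, id_pattern_spec(
      tab$name[i], tab$template[i],
      generator_hint = hint, description = tab$description[i]
    ))
  }
  reg
}
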