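#' Citation corpora
#'
#' A corpus is a tibble with one row per MEDLINE-like citation and columns:
#'
#' * `doc_id` — opaque unique identifier (character).
#' * `title`, `abstract` — free text.
#' * `mesh_headings` — list column; each element a tibble with columns
#'   `descriptor` (character), `major` (logical) and `qualifiers` (list of
#'   character vectors).
#' * `publication_types` — list column of character vectors.
#' * `language` — character (e.g. `"eng"`).
#' * `entry_date` — integer `YYYYMMDD`, `NA` when absent.
#' * `extra` — list column of named character vectors holding any unrecognized
#'   nbib tags, preserved verbatim so round trips never drop data.
#'
#' `citation_corpus()` builds and validates such a tibble from vectors;
#' `validate_corpus()` checks the invariants (unique ids, non-empty
#' descriptors) on an existing tibble.
#'
#' @param doc_id Character vector of unique identifiers.
#' @param title,abstract Character vectors (recycled empty strings allowed).
#' @param mesh_headings List of tibbles (or `NULL` for none).
#' @param publication_types List of character vectors.
#' @param language Character vector.
#' @param entry_date Integer `YYYYMMDD` vector.
#' @param extra List of named character vectors.
#' @return A validated corpus tibble.
#' @export
citation_corpus <- function(doc_id,
                            title = "",
                            abstract = "",
                            mesh_headings = NULL,
                            publication_types = NULL,
                            language = "eng",
                            entry_date = NA_integer_,
                            extra = NULL) {
  n <- length(doc_id)
  empty_mh <- list(mesh_tibble(character(), logical(), list()))
  corpus <- tibble(
    doc_id = as.character(doc_id),
    title = rep_len(as.character(title), n),
    abstract = rep_len(as.character(abstract), n),
    mesh_headings = mesh_headings %||% rep(empty_mh, n),
    publication_types = publication_types %||% rep(list(character()), n),
    language = rep_len(as.character(language), n),
    entry_date = rep_len(as.integer(entry_date), n),
    extra = extra %||% rep(list(character()), n)
  )
  validate_corpus(corpus)
}

mesh_tibble <- function(descriptor, major, qualifiers) {
  tibble(
    descriptor = as.character(descriptor),
    major = as.logical(major),
    qualifiers = qualifiers
  )
}

#' @rdname citation_corpus
#' @param corpus A corpus tibble.
#' @export
validate_corpus <- function(corpus) {
  stopifnot(is.data.frame(corpus))
  required <- c(
    "doc_id", "title", "abstract", "mesh_headings",
    "publication_types", "language", "entry_date", "extra"
  )
  missing <- setdiff(required, names(corpus))
  if (length(missing) > 0) {
    abort_boolrank(
      paste0("corpus is missing columns: ", paste(missing, collapse = ", ")),
      "boolrank_format_error"
    )
  }
  dups <- unique(corpus$doc_id[duplicated(corpus$doc_id)])
  if (length(dups) > 0) {
    abort_boolrank(
      paste0("duplicate doc_id in corpus: ", paste(head(dups, 5), collapse = ", ")),
      "boolrank_duplicate_id"
    )
  }
  for (mh in corpus$mesh_headings) {
    if (nrow(mh) > 0 && any(!nzchar(mh$descriptor))) {
      abort_boolrank("empty MeSH descriptor string", "boolrank_format_error")
    }
  }
  as_tibble(corpus)
}

# ---- nbib (MEDLINE tagged flat format) ------------------------------------

#' Read and write MEDLINE nbib tagged flat files
#'
#' `read_nbib()` parses the tag-prefixed flat format exported by
#' PubMed/MEDLINE (`PMID- `, `TI  - `, `AB  - `, `MH  - `, `PT  - `,
#' `LA  - `, `EDAT- `); records are separated by blank lines and continuation
#' lines are indented. Both the padded PubMed spacing (`MH  - term`) and the
#' compact form (`MH- term`) are accepted. `MH` values of the form
#' `Descriptor/Qualifier` are split; a leading `*` marks a major heading.
#' Unknown tags are kept in the `extra` column rather than dropped.
#'
#' @param x For `read_nbib()`, a file path or a character vector of lines (a
#'   vector with more than one element, or containing newlines, is treated as
#'   content). For `write_nbib()`, a corpus tibble.
#' @return `read_nbib()` returns a corpus tibble (see [citation_corpus()]);
#'   `write_nbib()` returns the text invisibly after writing.
#' @export
read_nbib <- function(x) {
  lines <- read_input_lines(x)
  # Split into records on blank lines.
  blank <- !nzchar(trimws(lines))
  grp <- cumsum(blank)
  recs <- split(lines[!blank], grp[!blank])
  recs <- recs[vapply(recs, length, integer(1)) > 0]
  parsed <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    parsed[[i]] <- parse_nbib_record(recs[[i]], ordinal = i)
  }
  corpus <- dplyr::bind_rows(parsed)
  if (nrow(corpus) == 0) {
    return(citation_corpus(character()))
  }
  validate_corpus(corpus)
}

parse_nbib_record <- function(lines, ordinal) {
  # Fold continuation lines (leading whitespace) into the previous field.
  tags <- character()
  values <- character()
  for (ln in lines) {
    if (grepl("^\\s", ln) && length(values) > 0) {
      values[length(values)] <- paste(values[length(values)], trimws(ln))
    } else {
      m <- regexec("^([A-Z]{1,6})\\s*-\\s?(.*)$", ln)
      parts <- regmatches(ln, m)[[1]]
      if (length(parts) == 0) {
        abort_boolrank(
          sprintf("record %d: unparseable nbib line: %s", ordinal, ln),
          "boolrank_format_error"
        )
      }
      tags <- c(tags, parts[2])
      values <- c(values, parts[3])
    }
  }
  pmid <- values[tags == "PMID"]
  if (length(pmid) == 0) {
    abort_boolrank(
      sprintf("record %d has no PMID", ordinal),
      "boolrank_format_error"
    )
  }
  mh_raw <- values[tags == "MH"]
  mh <- parse_mh_values(mh_raw)
  edat <- values[tags == "EDAT"]
  known <- c("PMID", "TI", "AB", "MH", "PT", "LA", "EDAT")
  extra_idx <- !(tags %in% known)
  tibble(
    doc_id = trimws(pmid[1]),
    title = paste(values[tags == "TI"], collapse = " "),
    abstract = paste(values[tags == "AB"], collapse = " "),
    mesh_headings = list(mh),
    publication_types = list(trimws(values[tags == "PT"])),
    language = if (any(tags == "LA")) trimws(values[tags == "LA"][1]) else NA_character_,
    entry_date = if (length(edat) > 0) parse_entry_date(edat[1]) else NA_integer_,
    extra = list(if (any(extra_idx)) {
      setNames(values[extra_idx], tags[extra_idx])
    } else {
      character()
    })
  )
}

parse_mh_values <- function(values) {
  if (length(values) == 0) {
    return(mesh_tibble(character(), logical(), list()))
  }
  values <- trimws(values)
  major <- startsWith(values, "*")
  values <- sub("^\\*", "", values)
  parts <- strsplit(values, "/", fixed = TRUE)
  descriptor <- vapply(parts, function(p) trimws(p[1]), character(1))
  qualifiers <- lapply(parts, function(p) {
    q <- trimws(p[-1])
    # a qualifier may itself carry the major marker ("Child/*therapy")
    sub("^\\*", "", q)
  })
  major <- major | vapply(parts, function(p) any(startsWith(trimws(p[-1]), "*")), logical(1))
  mesh_tibble(descriptor, major, qualifiers)
}

parse_entry_date <- function(x) {
  digits <- gsub("[^0-9]", "", x)
  if (nchar(digits) < 8) return(NA_integer_)
  as.integer(substr(digits, 1, 8))
}

#' @rdname read_nbib
#' @param path Optional file path; when `NULL` the text is only returned.
#' @export
write_nbib <- function(x, path = NULL) {
  corpus <- validate_corpus(x)
  recs <- vapply(seq_len(nrow(corpus)), function(i) {
    row <- corpus[i, ]
    mh <- row$mesh_headings[[1]]
    mh_lines <- character()
    if (nrow(mh) > 0) {
      mh_lines <- vapply(seq_len(nrow(mh)), function(j) {
        val <- paste(c(mh$descriptor[j], mh$qualifiers[[j]]), collapse = "/")
        if (mh$major[j]) val <- paste0("*", val)
        paste0("MH  - ", val)
      }, character(1))
    }
    lines <- c(
      paste0("PMID- ", row$doc_id),
      if (nzchar(row$title)) paste0("TI  - ", row$title),
      if (nzchar(row$abstract)) paste0("AB  - ", row$abstract),
      mh_lines,
      if (length(row$publication_types[[1]]) > 0)
        paste0("PT  - ", row$publication_types[[1]]),
      if (!is.na(row$language)) paste0("LA  - ", row$language),
      if (!is.na(row$entry_date)) paste0("EDAT- ", row$entry_date),
      if (length(row$extra[[1]]) > 0)
        paste0(format(names(row$extra[[1]]), width = 4), "- ", row$extra[[1]])
    )
    paste(lines, collapse = "\n")
  }, character(1))
  text <- paste(recs, collapse = "\n\n")
  if (!is.null(path)) writeLines(text, path)
  invisible(text)
}

# ---- JSON-lines ------------------------------------------------------------

#' Read and write citation corpora as JSON-lines
#'
#' One JSON object per line; round trip is the identity on all fields.
#'
#' @param x For `write_jsonl()`, a corpus tibble; for `read_jsonl()`, a file
#'   path or character vector of lines.
#' @param path Optional output file path.
#' @return `write_jsonl()` returns the lines invisibly (after writing when
#'   `path` is given); `read_jsonl()` returns a corpus tibble.
#' @export
write_jsonl <- function(x, path = NULL) {
  corpus <- validate_corpus(x)
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    row <- corpus[i, ]
    mh <- row$mesh_headings[[1]]
    obj <- list(
      doc_id = row$doc_id,
      title = row$title,
      abstract = row$abstract,
      mesh_headings = lapply(seq_len(nrow(mh)), function(j) {
        list(
          descriptor = mh$descriptor[j],
          major = mh$major[j],
          qualifiers = as.list(mh$qualifiers[[j]])
        )
      }),
      publication_types = as.list(row$publication_types[[1]]),
      language = row$language,
      entry_date = row$entry_date,
      extra = as.list(row$extra[[1]])
    )
    jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", na = "null")
  }, character(1))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' @rdname write_jsonl
#' @export
read_jsonl <- function(x) {
  lines <- read_input_lines(x)
  lines_keep <- which(nzchar(trimws(lines)))
  if (length(lines_keep) == 0) {
    return(citation_corpus(character()))
  }
  rows <- vector("list", length(lines_keep))
  for (k in seq_along(lines_keep)) {
    i <- lines_keep[k]
    obj <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
      error = function(e) {
        abort_boolrank(
          sprintf("malformed JSON on line %d: %s", i, conditionMessage(e)),
          "boolrank_format_error"
        )
      }
    )
    mh <- obj$mesh_headings %||% list()
    extra <- obj$extra %||% list()
    rows[[k]] <- tibble(
      doc_id = as.character(obj$doc_id),
      title = as.character(obj$title %||% ""),
      abstract = as.character(obj$abstract %||% ""),
      mesh_headings = list(mesh_tibble(
        vapply(mh, function(h) h$descriptor, character(1)),
        vapply(mh, function(h) isTRUE(h$major), logical(1)),
        lapply(mh, function(h) as.character(unlist(h$qualifiers)))
      )),
      publication_types = list(as.character(unlist(obj$publication_types))),
      language = as.character(obj$language %||% NA_character_),
      entry_date = if (is.null(obj$entry_date)) NA_integer_ else as.integer(obj$entry_date),
      extra = list(if (length(extra) > 0) {
        setNames(as.character(unlist(extra)), names(extra))
      } else {
        character()
      })
    )
  }
  validate_corpus(dplyr::bind_rows(rows))
}

# Accept either a path or in-memory content for readers.
read_input_lines <- function(x) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    parts <- strsplit(as.character(x), "\n", fixed = TRUE)
    # strsplit("") yields character(0); keep blank lines, they separate records
    parts[lengths(parts) == 0] <- list("")
    unlist(parts, use.names = FALSE)
  }
}
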