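#' Parse an Ovid-dialect Boolean search strategy
#'
#' A strategy is plain text with one numbered clause per line (blank lines
#' ignored), exactly as printed in published systematic reviews:
#'
#' ```
#' 1 Attention Deficit Disorder with Hyperactivity/
#' 2 adhd
#' 5 hyperactiv$
#' 9 or/1-8
#' 23 (vitamin adj1 ("B6" or "B 6")).mp.
#' 26 limit 25 to English language
#' ```
#'
#' Supported syntax: bare terms and multiword phrases (default scope `.mp.`),
#' quoted phrases, `$`/`:` truncation, `#`/`?` single-character wildcards,
#' field suffixes `.mp. .ti. .ab. .tw. .sh. .fs. .pt. .ed.` (compound
#' suffixes such as `.sh,pt.` denote the union of scopes), MeSH heading lines
#' ending in `/` with optional `exp` (explosion) and `*` (major topic)
#' prefixes, infix `or` / `and` / `not` / `adjN`, line references, range
#' folds (`or/1-8`), and `limit N to <constraint>` lines.
#'
#' Line numbers must be strictly increasing and references may only point to
#' earlier lines; violations are parse errors reporting line and column.
#' Truncation with a stem shorter than 2 characters raises a warning and is
#' matched literally.
#'
#' @param x File path, or strategy text (character scalar with newlines, or a
#'   vector of lines).
#' @return An object of class `search_strategy`: a list with `lines`, each a
#'   list of `line_no` and a query AST `node`. The final line defines the
#'   strategy result.
#' @export
parse_strategy <- function(x) {
  lines <- read_input_lines(x)
  lines <- lines[nzchar(trimws(lines))]
  parsed <- list()
  seen <- integer()
  for (raw in lines) {
    m <- regexec("^\\s*(\\d+)[.)]?\\s+(.*\\S)\\s*$", raw)
    parts <- regmatches(raw, m)[[1]]
    if (length(parts) == 0) {
      abort_boolrank(
        paste0("cannot read numbered clause from line: ", raw),
        "boolrank_parse_error"
      )
    }
    line_no <- as.integer(parts[2])
    if (length(seen) > 0 && line_no <= max(seen)) {
      abort_boolrank(
        sprintf("line numbers must be strictly increasing (line %d after %d)",
                line_no, max(seen)),
        "boolrank_parse_error"
      )
    }
    node <- parse_clause(parts[3], line_no)
    check_refs(node, line_no, seen)
    seen <- c(seen, line_no)
    parsed[[length(parsed) + 1]] <- list(line_no = line_no, node = node)
  }
  structure(list(lines = parsed), class = "search_strategy")
}

# Validate line references at parse time. Plain references and limit targets
# must name an already-defined line; a range fold must ascend, end before the
# current line, and cover at least one defined line (interior gaps are
# tolerated so that simplified strategies with removed lines stay parseable).
check_refs <- function(node, line_no, seen) {
  walk <- function(n) {
    switch(
      n$type,
      lineref = ,
      limit = {
        ref <- if (n$type == "lineref") n$n else n$target
        if (!(ref %in% seen)) {
          abort_boolrank(
            sprintf("line %d references undefined or later line %d", line_no, ref),
            "boolrank_parse_error"
          )
        }
      },
      rangeop = {
        if (n$to >= line_no) {
          abort_boolrank(
            sprintf("line %d contains forward range reference %s/%d-%d",
                    line_no, n$op, n$from, n$to),
            "boolrank_parse_error"
          )
        }
        if (!any(seq(n$from, n$to) %in% seen)) {
          abort_boolrank(
            sprintf("line %d range %s/%d-%d covers no defined lines",
                    line_no, n$op, n$from, n$to),
            "boolrank_parse_error"
          )
        }
      },
      adj = ,
      not = {
        walk(n$lhs); walk(n$rhs)
      },
      and = ,
      or = lapply(n$args, walk),
      invisible(NULL)
    )
    invisible(NULL)
  }
  walk(node)
}

# ---- lexer -----------------------------------------------------------------

FIELD_CODES <- c("mp", "ti", "ab", "tw", "sh", "fs", "pt", "ed")

lex_clause <- function(text, line_no) {
  tokens <- list()
  pos <- 1
  n <- nchar(text)
  push <- function(type, value, col) {
    tokens[[length(tokens) + 1]] <<- list(type = type, value = value, col = col)
  }
  fail <- function(col, what) {
    abort_boolrank(
      sprintf("parse error at line %d column %d: %s", line_no, col, what),
      "boolrank_parse_error"
    )
  }
  while (pos <= n) {
    rest <- substr(text, pos, n)
    ws <- regmatches(rest, regexpr("^\\s+", rest))
    if (length(ws) == 1) {
      pos <- pos + nchar(ws)
      next
    }
    ch <- substr(text, pos, pos)
    if (ch == "(") {
      push("LPAREN", "(", pos); pos <- pos + 1; next
    }
    if (ch == ")") {
      push("RPAREN", ")", pos); pos <- pos + 1; next
    }
    if (ch == "/") {
      push("SLASH", "/", pos); pos <- pos + 1; next
    }
    if (ch == ",") {
      push("COMMA", ",", pos); pos <- pos + 1; next
    }
    if (ch == "*") {
      push("STAR", "*", pos); pos <- pos + 1; next
    }
    if (ch == "\"") {
      m <- regmatches(rest, regexpr('^"[^"]*"', rest))
      if (length(m) == 0) fail(pos, "unterminated quote")
      push("QUOTED", substr(m, 2, nchar(m) - 1), pos)
      pos <- pos + nchar(m)
      next
    }
    if (ch == ".") {
      m <- regmatches(rest, regexpr("^\\.([A-Za-z]{2})(,[A-Za-z]{2})*\\.", rest))
      if (length(m) == 1) {
        codes <- tolower(strsplit(gsub("\\.", "", m), ",")[[1]])
        unknown <- setdiff(codes, FIELD_CODES)
        if (length(unknown) > 0) fail(pos, paste0("unknown field code .", unknown[1], "."))
        push("FIELD", codes, pos)
        pos <- pos + nchar(m)
        next
      }
      # a stray period (e.g. sentence punctuation) is skipped
      pos <- pos + 1
      next
    }
    m <- regmatches(rest, regexpr("^[A-Za-z0-9][A-Za-z0-9$#?'=-]*:?", rest))
    if (length(m) == 1) {
      push("WORD", m, pos)
      pos <- pos + nchar(m)
      next
    }
    if (ch == "-") {
      m <- regmatches(rest, regexpr("^-+", rest))
      push("DASH", m, pos)
      pos <- pos + nchar(m)
      next
    }
    fail(pos, paste0("unexpected character '", ch, "'"))
  }
  tokens
}

# ---- recursive-descent parser ---------------------------------------------

parse_clause <- function(text, line_no) {
  tokens <- lex_clause(text, line_no)
  if (length(tokens) == 0) {
    abort_boolrank(
      sprintf("parse error at line %d: empty clause", line_no),
      "boolrank_parse_error"
    )
  }
  st <- new.env(parent = emptyenv())
  st$tokens <- tokens
  st$i <- 1L
  st$line_no <- line_no
  st$text <- text

  first <- peek(st)
  if (first$type == "WORD" && tolower(first$value) %in% c("or", "and") &&
      !is.null(peek(st, 2)) && peek(st, 2)$type == "SLASH") {
    return(parse_rangeop(st))
  }
  if (first$type == "WORD" && tolower(first$value) == "limit") {
    return(parse_limit(st, text))
  }
  node <- parse_or(st)
  leftover <- peek(st)
  if (!is.null(leftover)) {
    parse_fail(st, paste0("unexpected input '", paste(leftover$value, collapse = ","), "'"))
  }
  node
}

peek <- function(st, ahead = 1) {
  idx <- st$i + ahead - 1L
  if (idx > length(st$tokens)) NULL else st$tokens[[idx]]
}

advance <- function(st) {
  tok <- peek(st)
  st$i <- st$i + 1L
  tok
}

parse_fail <- function(st, what) {
  col <- if (!is.null(peek(st))) peek(st)$col else nchar(st$text) + 1L
  abort_boolrank(
    sprintf("parse error at line %d column %d: %s", st$line_no, col, what),
    "boolrank_parse_error"
  )
}

is_keyword <- function(tok, kw) {
  !is.null(tok) && tok$type == "WORD" && tolower(tok$value) %in% kw
}

is_adj_token <- function(tok) {
  !is.null(tok) && tok$type == "WORD" && grepl("^adj[0-9]*$", tolower(tok$value))
}

parse_rangeop <- function(st) {
  op <- tolower(advance(st)$value)
  advance(st) # SLASH
  parts <- character()
  while (!is.null(peek(st))) {
    tok <- advance(st)
    parts <- c(parts, tok$value)
  }
  joined <- paste(parts, collapse = "")
  m <- regexec("^([0-9]+)-+([0-9]+)$", joined)
  g <- regmatches(joined, m)[[1]]
  if (length(g) == 0) parse_fail(st, paste0("malformed range '", joined, "'"))
  from <- as.integer(g[2]); to <- as.integer(g[3])
  if (from >= to) {
    abort_boolrank(
      sprintf("parse error at line %d: range %d-%d must ascend", st$line_no, from, to),
      "boolrank_parse_error"
    )
  }
  qn_rangeop(op, from, to)
}

parse_limit <- function(st, text) {
  advance(st) # 'limit'
  tok <- advance(st)
  if (is.null(tok) || tok$type != "WORD" || !grepl("^[0-9]+$", tok$value)) {
    parse_fail(st, "limit requires a target line number")
  }
  target <- as.integer(tok$value)
  to_tok <- advance(st)
  if (!is_keyword(to_tok, "to")) parse_fail(st, "expected 'to' in limit clause")
  raw <- trimws(substr(text, to_tok$col + 2, nchar(text)))
  raw <- sub("[.,;]+$", "", raw)
  if (!nzchar(raw)) parse_fail(st, "empty limit constraint")
  st$i <- length(st$tokens) + 1L
  qn_limit(target, parse_limit_constraint(raw))
}

LANGUAGE_CODES <- c(
  english = "eng", german = "ger", french = "fre", spanish = "spa",
  italian = "ita", dutch = "dut", russian = "rus", chinese = "chi",
  japanese = "jpn", portuguese = "por"
)

parse_limit_constraint <- function(raw) {
  low <- tolower(raw)
  if (grepl("language$", low)) {
    name <- trimws(sub("language$", "", low))
    code <- unname(LANGUAGE_CODES[name])
    if (is.na(code)) code <- name
    return(list(kind = "language", value = code, raw = raw))
  }
  m <- regexec("^(?:ed|yr)\\s*=\\s*([0-9]{4,8})\\s*-\\s*([0-9]{4,8})$", low)
  g <- regmatches(low, m)[[1]]
  if (length(g) > 0) {
    pad <- function(x, fill) as.integer(paste0(x, strrep(fill, 8 - nchar(x))))
    return(list(
      kind = "entry_date",
      value = c(pad(g[2], "0"), pad(g[3], "9")),
      raw = raw
    ))
  }
  list(kind = "pubtype", value = low, raw = raw)
}

parse_or <- function(st) {
  args <- list(parse_and(st))
  while (is_keyword(peek(st), "or")) {
    advance(st)
    args <- c(args, list(parse_and(st)))
  }
  if (length(args) == 1) args[[1]] else qn_or(args)
}

parse_and <- function(st) {
  args <- list(parse_not(st))
  while (is_keyword(peek(st), "and")) {
    advance(st)
    args <- c(args, list(parse_not(st)))
  }
  if (length(args) == 1) args[[1]] else qn_and(args)
}

parse_not <- function(st) {
  node <- parse_adj(st)
  while (is_keyword(peek(st), "not")) {
    advance(st)
    node <- qn_not(node, parse_adj(st))
  }
  node
}

parse_adj <- function(st) {
  node <- parse_primary(st)
  while (is_adj_token(peek(st))) {
    tok <- advance(st)
    digits <- sub("^adj", "", tolower(tok$value))
    n <- if (nzchar(digits)) as.integer(digits) else 1L
    if (n < 1) parse_fail(st, "adjacency window must be at least 1")
    node <- qn_adj(n, node, parse_primary(st))
  }
  node
}

OPERATOR_WORDS <- c("and", "or", "not")

parse_primary <- function(st) {
  tok <- peek(st)
  if (is.null(tok)) parse_fail(st, "expected an operand")
  if (tok$type == "LPAREN") {
    advance(st)
    node <- parse_or(st)
    if (is.null(peek(st)) || peek(st)$type != "RPAREN") {
      parse_fail(st, "expected ')'")
    }
    advance(st)
    nxt <- peek(st)
    if (!is.null(nxt) && nxt$type == "FIELD") {
      advance(st)
      node$group_fields <- nxt$value
      node <- set_fields(node, nxt$value)
    }
    return(node)
  }
  if (tok$type == "QUOTED") {
    advance(st)
    fields <- "default"
    nxt <- peek(st)
    if (!is.null(nxt) && nxt$type == "FIELD") {
      advance(st)
      fields <- nxt$value
    }
    return(make_text_node(tok$value, fields, quoted = TRUE, st = st))
  }
  if (tok$type == "STAR" || tok$type == "WORD") {
    return(parse_words(st))
  }
  parse_fail(st, paste0("unexpected token '", paste(tok$value, collapse = ","), "'"))
}

# Parse a run of words, deciding between a MeSH heading (terminated by "/"),
# a line reference (bare integer), and a term/phrase with optional fields.
parse_words <- function(st) {
  exploded <- FALSE
  major <- FALSE
  if (is_keyword(peek(st), "exp")) {
    nxt <- peek(st, 2)
    if (!is.null(nxt) && (nxt$type %in% c("WORD", "STAR"))) {
      advance(st)
      exploded <- TRUE
    }
  }
  if (!is.null(peek(st)) && peek(st)$type == "STAR") {
    advance(st)
    major <- TRUE
  }
  words <- character()
  commas <- logical()
  repeat {
    tok <- peek(st)
    if (is.null(tok)) break
    if (tok$type == "WORD") {
      low <- tolower(tok$value)
      if (length(words) > 0 && (low %in% OPERATOR_WORDS || is_adj_token(tok))) break
      if (low %in% OPERATOR_WORDS || is_adj_token(tok)) {
        if (length(words) == 0) parse_fail(st, paste0("operator '", low, "' lacks a left operand"))
      }
      advance(st)
      words <- c(words, tok$value)
      commas <- c(commas, FALSE)
      next
    }
    if (tok$type == "COMMA") {
      advance(st)
      if (length(commas) > 0) commas[length(commas)] <- TRUE
      next
    }
    break
  }
  if (length(words) == 0) parse_fail(st, "expected a term")

  nxt <- peek(st)
  if (!is.null(nxt) && nxt$type == "SLASH") {
    advance(st)
    name <- paste0(words, ifelse(commas, ",", ""), collapse = " ")
    name <- sub(",$", "", name)
    return(qn_mesh(name, exploded = exploded, major = major))
  }
  if (exploded || major) {
    parse_fail(st, "exp/* prefixes require a MeSH heading ending in '/'")
  }
  fields <- "default"
  if (!is.null(nxt) && nxt$type == "FIELD") {
    advance(st)
    fields <- nxt$value
  }
  if (length(words) == 1 && grepl("^[0-9]+$", words) && identical(fields, "default")) {
    return(qn_lineref(as.integer(words)))
  }
  make_text_node(paste(words, collapse = " "), fields, quoted = FALSE, st = st)
}

# Build a term or phrase node from raw surface text, handling truncation and
# wildcards per word. Truncation stems shorter than 2 characters trigger a
# warning and fall back to a literal match.
make_text_node <- function(raw, fields, quoted, st = NULL) {
  words <- strsplit(trimws(raw), "\\s+")[[1]]
  slots <- lapply(words, function(w) {
    trunc <- grepl("[$:]$", w)
    trunc_char <- if (trunc) substr(w, nchar(w), nchar(w)) else "$"
    stem <- if (trunc) substr(w, 1, nchar(w) - 1) else w
    short <- trunc && nchar(stem) < 2
    if (short) {
      warn(paste0(
        "truncation stem '", stem, "' shorter than 2 characters; matching literally"
      ), class = "boolrank_short_stem")
      trunc <- FALSE
    }
    node <- qn_term(stem, truncated = trunc, trunc_char = trunc_char, raw = stem)
    if (short) node$short_stem <- TRUE
    node
  })
  if (length(slots) == 1) {
    node <- slots[[1]]
    node$fields <- fields
    node$quoted <- quoted
    node$raw <- sub("[$:]$", "", raw)
    node
  } else {
    qn_phrase(slots, fields = fields, raw = raw, quoted = quoted)
  }
}
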