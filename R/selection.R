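#' Select atoms by a small query grammar
#'
#' Queries combine keyword predicates with `and`, `or`, `not` and
#' parentheses. Keywords: `name`, `element`, `resname`, `resid` (alias
#' `residue_index`), `mol` (alias `molecule_id`). Each keyword takes one or
#' more values; `resid` also accepts ranges written `1:42` or `1-42`.
#' `and` binds tighter than `or`. Examples:
#'
#' ```
#' select_atoms(ens, "name CA")
#' select_atoms(ens, "resname GLU and name CD")
#' select_atoms(ens, "resid 1:42 and not element H")
#' ```
#'
#' @param ens a [traj_ensemble()] or [topology()].
#' @param query selection string.
#' @return Sorted (possibly empty) integer vector of 1-based atom indices.
#' @export
select_atoms <- function(ens, query) {
  top <- if (inherits(ens, "traj_ensemble")) ens$top else ens
  stopifnot(is.data.frame(top))
  toks <- sel_tokenize(query)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L; st$query <- query
  mask <- sel_parse_or(st, top)
  if (st$pos <= length(st$toks$text))
    sel_err(st, "unexpected token '", st$toks$text[st$pos], "'")
  sort(which(mask))
}

sel_tokenize <- function(query) {
  if (!is.character(query) || length(query) != 1 || !nzchar(trimws(query)))
    stop("selection error: empty query")
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, query)[[1]]
  list(text = regmatches(query, gregexpr(pat, query))[[1]],
       at = as.integer(m))
}

sel_err <- function(st, ...) {
  at <- if (st$pos <= length(st$toks$at)) st$toks$at[st$pos]
        else nchar(st$query) + 1L
  stop("selection error at position ", at, " in '", st$query, "': ", ...,
       call. = FALSE)
}

sel_peek <- function(st) {
  if (st$pos <= length(st$toks$text)) st$toks$text[st$pos] else NA_character_
}

sel_parse_or <- function(st, top) {
  x <- sel_parse_and(st, top)
  while (identical(tolower(sel_peek(st)), "or")) {
    st$pos <- st$pos + 1L
    x <- x | sel_parse_and(st, top)
  }
  x
}

sel_parse_and <- function(st, top) {
  x <- sel_parse_factor(st, top)
  while (identical(tolower(sel_peek(st)), "and")) {
    st$pos <- st$pos + 1L
    x <- x & sel_parse_factor(st, top)
  }
  x
}

sel_keywords <- c("name", "element", "resname", "resid", "residue_index",
                  "mol", "molecule_id")
sel_reserved <- c(sel_keywords, "and", "or", "not", "(", ")")

sel_parse_factor <- function(st, top) {
  tok <- sel_peek(st)
  if (is.na(tok)) sel_err(st, "unexpected end of query")
  if (tolower(tok) == "not") {
    st$pos <- st$pos + 1L
    return(!sel_parse_factor(st, top))
  }
  if (tok == "(") {
    st$pos <- st$pos + 1L
    x <- sel_parse_or(st, top)
    if (!identical(sel_peek(st), ")")) sel_err(st, "expected ')'")
    st$pos <- st$pos + 1L
    return(x)
  }
  key <- tolower(tok)
  if (!key %in% sel_keywords)
    sel_err(st, "expected a keyword (", paste(sel_keywords, collapse = ", "),
            "), got '", tok, "'")
  st$pos <- st$pos + 1L
  vals <- character(0)
  while (!is.na(sel_peek(st)) && !tolower(sel_peek(st)) %in% sel_reserved) {
    vals <- c(vals, sel_peek(st))
    st$pos <- st$pos + 1L
  }
  if (!length(vals)) sel_err(st, "keyword '", key, "' needs at least one value")
  col <- switch(key, residue_index = "resid", molecule_id = "mol", key)
  if (col == "resid") {
    ids <- integer(0)
    for (v in vals) {
      r <- regmatches(v, regexec("^(-?[0-9]+)[:–-](-?[0-9]+)$", v))[[1]]
      if (length(r) == 3) {
        ids <- c(ids, seq(as.integer(r[2]), as.integer(r[3])))
      } else {
        iv <- suppressWarnings(as.integer(v))
        if (is.na(iv)) sel_err(st, "'", v, "' is not a residue index or range")
        ids <- c(ids, iv)
      }
    }
    top[[col]] %in% ids
  } else {
    top[[col]] %in% vals
  }
}
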