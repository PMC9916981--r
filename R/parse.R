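# Parser for the AU-configuration notation used in the published model tables:
#   "6 + 12"                 AUs occur together
#   "1 + 15, 4, 17"          terms after a comma are optional
#   "(9 ∨ 10), (25 ∨ 26)"    "∨" separates mutually exclusive alternatives
#   separate strings (bullets) are alternative configurations of one category
# parse_au_spec() expands a spec into the full deduplicated list of AU sets:
# cartesian product over alternations x power set over optionals x union over
# bullets.

#' Parse AU-configuration notation into explicit AU sets
#'
#' @param text Character vector; each element is one configuration expression
#'   (a "bullet"). A single string may also contain several bullets separated
#'   by `"•"`, `";"` or newlines. Within an expression, `+` joins required
#'   AUs, terms after a comma are optional, and `(a ∨ b)` is an alternation
#'   (ASCII `v` and `|` are accepted as the alternation symbol).
#' @return List of sorted integer vectors, deduplicated: every AU set the
#'   expression licenses.
#' @export
#' @examples
#' parse_au_spec("(9 ∨ 10), (25 ∨ 26)")  # 6 sets
#' parse_au_spec("1 + 15, 4, 17")          # 4 sets
parse_au_spec <- function(text) {
  stopifnot(is.character(text), length(text) >= 1)
  bullets <- unlist(lapply(text, function(s)
    strsplit(s, "[•;\n]")[[1]]), use.names = FALSE)
  bullets <- trimws(bullets)
  bullets <- bullets[nzchar(bullets)]
  if (!length(bullets)) stop("empty configuration expression")
  sets <- list()
  for (b in bullets) sets <- c(sets, expand_bullet(b))
  dedup_sets(sets)
}

# Expand one bullet expression into its list of AU sets.
expand_bullet <- function(expr) {
  chunks <- split_top_level(expr, ",")
  if (!nzchar(trimws(chunks[1])))
    stop("malformed expression (no required term): '", expr, "'")
  required <- parse_terms(chunks[1], expr)
  optionals <- lapply(chunks[-1], parse_terms, context = expr)
  if (!length(required))
    stop("malformed expression (no required term): '", expr, "'")
  base_sets <- cross_terms(required)
  sets <- base_sets
  # power set over optional groups; an included group contributes all its
  # terms (each term an alternation resolved by cartesian product)
  for (opt in optionals) {
    opt_sets <- cross_terms(opt)
    sets <- c(sets,
              unlist(lapply(sets, function(s)
                lapply(opt_sets, function(o) sort(unique(c(s, o))))),
                recursive = FALSE))
  }
  sets
}

# Split on a separator at paren depth 0.
split_top_level <- function(s, sep) {
  chars <- strsplit(s, "")[[1]]
  depth <- 0L
  cut <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") depth <- depth - 1L
    else if (chars[i] == sep && depth == 0L) cut <- c(cut, i)
    if (depth < 0L) stop("unbalanced parentheses at position ", i, ": '", s, "'")
  }
  if (depth != 0L) stop("unbalanced parentheses: '", s, "'")
  starts <- c(1L, cut + 1L)
  ends <- c(cut - 1L, length(chars))
  vapply(seq_along(starts), function(k)
    paste(chars[seq.int(starts[k], length.out = max(0L, ends[k] - starts[k] + 1L))],
          collapse = ""), character(1))
}

# Parse a chunk like "4 + (5 v 7) + 22" into a list of alternation vectors.
parse_terms <- function(chunk, context) {
  toks <- split_top_level(chunk, "+")
  toks <- trimws(toks)
  if (any(!nzchar(toks)))
    stop("malformed expression (empty term) in '", context, "'")
  lapply(toks, parse_alternation, context = context)
}

# One term: a number, "AU12", or an alternation "(9 v 10 v 27)".
parse_alternation <- function(tok, context) {
  t <- trimws(tok)
  t <- sub("^\\(", "", t)
  t <- sub("\\)$", "", t)
  alts <- strsplit(t, "∨|\\|| v ", perl = FALSE)[[1]]
  alts <- trimws(alts)
  alts <- alts[nzchar(alts)]
  if (!length(alts))
    stop("malformed expression (empty alternation) at '", tok, "' in '", context, "'")
  nums <- suppressWarnings(as.integer(gsub("^AU", "", alts, ignore.case = TRUE)))
  if (any(is.na(nums)))
    stop("unknown token '", alts[which(is.na(nums))[1]], "' in '", context, "'")
  nums
}

# Cartesian product of a list of alternation vectors -> list of sorted sets.
cross_terms <- function(terms) {
  sets <- list(integer(0))
  for (alts in terms) {
    sets <- unlist(lapply(sets, function(s)
      lapply(alts, function(a) sort(unique(c(s, a))))), recursive = FALSE)
  }
  sets
}

dedup_sets <- function(sets) {
  sets <- lapply(sets, function(s) sort(unique(as.integer(s))))
  keys <- vapply(sets, paste, character(1), collapse = ",")
  sets[!duplicated(keys)]
}

#' Turn an AU-number set into a configuration vector over the canonical space
#'
#' Bridges the bilateral notation of published model tables to the recoded
#' canonical space: a lateralized AU number sets both its `L` and `R`
#' coordinates, other numbers set their single coordinate. Canonical labels
#' (e.g. `"12L"`) are also accepted.
#'
#' @param aus Integer vector of AU numbers (or character canonical labels).
#' @param weights Optional numeric weights in `[0, 1]`, recycled to
#'   `length(aus)`; default 1 (binary configuration).
#' @param drop_unknown If `TRUE`, AU numbers with no canonical counterpart are
#'   dropped (recorded in the `"dropped"` attribute) instead of causing an
#'   error.
#' @return Numeric vector of length 33 named by [au_labels()].
#' @export
#' @examples
#' au_config_vector(c(6, 12))  # 1 at 6L, 6R, 12L, 12R
au_config_vector <- function(aus, weights = NULL, drop_unknown = FALSE) {
  v <- stats::setNames(numeric(33), au_labels())
  if (!length(aus)) return(v)
  if (is.null(weights)) weights <- 1
  weights <- rep_len(weights, length(aus))
  if (any(weights < 0 | weights > 1)) stop("configuration weights must lie in [0, 1]")
  dropped <- character(0)
  for (i in seq_along(aus)) {
    labs <- if (is.character(aus) && normalize_au_label(aus[i]) %in% au_labels()) {
      normalize_au_label(aus[i])
    } else {
      resolve_au_number(as.integer(normalize_au_label(as.character(aus[i]))))
    }
    if (is.null(labs)) {
      if (drop_unknown) { dropped <- c(dropped, as.character(aus[i])); next }
      stop("AU", aus[i], " has no canonical counterpart in the 33-AU space")
    }
    v[labs] <- pmax(v[labs], weights[i])
  }
  if (length(dropped)) attr(v, "dropped") <- dropped
  v
}
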