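# Canonical 33-variable AU space: the unilateral/bilateral recoding scheme and
# embedding of amplitude maps as numeric vectors. The canonical order is total
# and fixed; it is shipped as a versioned JSON document in inst/extdata.

.hka_env <- new.env(parent = emptyenv())

au_space <- function() {
  if (is.null(.hka_env$space)) {
    path <- system.file("extdata", "au_space.json", package = "hka")
    sp <- jsonlite::read_json(path, simplifyVector = TRUE)
    sp$canonical <- as.character(sp$canonical)
    sp$lateralized <- as.integer(sp$lateralized)
    sp$compounds <- lapply(sp$compounds, as.integer)
    .hka_env$space <- sp
  }
  .hka_env$space
}

#' Canonical Action Unit labels
#'
#' The 33 independent AU variables spanning the analysis space, in canonical
#' order: compound generative AUs are expanded into their constituents and
#' bilateral AUs into left/right variables (e.g. `12L`, `12R`).
#'
#' @return Character vector of length 33.
#' @export
#' @examples
#' au_labels()
au_labels <- function() au_space()$canonical

#' Trial-table column names for the canonical AU space
#'
#' Zero-padded column names (`AU01`, `AU02L`, ..., `AU43`) corresponding
#' one-to-one to [au_labels()].
#'
#' @return Character vector of length 33.
#' @export
au_columns <- function() {
  vapply(au_labels(), au_label_to_column, character(1), USE.NAMES = FALSE)
}

au_label_to_column <- function(label) {
  num <- sub("[LR]$", "", label)
  side <- sub("^[0-9]+", "", label)
  paste0("AU", sprintf("%02d", as.integer(num)), side)
}

#' AU numbers encoded as separate left/right variables
#'
#' @return Integer vector of the AU numbers that are lateralized in the
#'   canonical space (both `L` and `R` variables exist).
#' @export
au_lateralized <- function() au_space()$lateralized

#' Default generative AU vocabulary of the simulator
#'
#' The 42 labels the stimulus generator draws from: 3 compound labels
#' (`"1+2"`, `"6+12"`, `"12+25"`), 14 unilateral labels and 25 bilateral
#' (plain-number) labels. A stand-in for the original generator's 42-label
#' set, which is not published in full.
#'
#' @return Character vector of 42 generative labels.
#' @export
hk_vocabulary <- function() {
  v <- au_space()$vocabulary
  c(as.character(v$compound), as.character(v$unilateral), as.character(v$bilateral))
}

# Normalize a user-facing label: strip an "AU" prefix and whitespace;
# "AU1+2" / "AU1 + AU2" -> "1+2".
normalize_au_label <- function(x) {
  x <- gsub("\\s+", "", x)
  x <- gsub("AU", "", x, fixed = TRUE)
  x
}

# Resolve one generative label to its canonical labels. Returns character
# vector of canonical labels, or NULL if unknown.
resolve_au_label <- function(label) {
  sp <- au_space()
  lab <- normalize_au_label(label)
  if (lab %in% names(sp$compounds)) {
    nums <- sp$compounds[[lab]]
    return(unlist(lapply(nums, resolve_au_number), use.names = FALSE))
  }
  if (lab %in% sp$canonical) return(lab)
  if (grepl("^[0-9]+$", lab)) {
    num <- as.integer(lab)
    res <- resolve_au_number(num)
    if (!is.null(res)) return(res)
  }
  NULL
}

# Resolve a bare AU number to canonical labels (both laterals if lateralized).
resolve_au_number <- function(num) {
  sp <- au_space()
  if (num %in% sp$lateralized) {
    labs <- paste0(num, c("L", "R"))
  } else {
    labs <- as.character(num)
  }
  if (!all(labs %in% sp$canonical)) return(NULL)
  labs
}

#' Recode generative AU amplitudes into the canonical space
#'
#' Expands compound labels (e.g. `"1+2"` activates AU1 and AU2) and bilateral
#' labels (e.g. `"12"` activates both `12L` and `12R`) at the same amplitude;
#' canonical labels pass through. When two raw labels reach the same canonical
#' variable the conflict is resolved by `conflict`: the maximum amplitude
#' (default, preserves "active" semantics) or the sum clipped at 1.
#'
#' @param raw Named numeric vector of amplitudes in `[0, 1]`; names are
#'   generative or canonical AU labels (an `"AU"` prefix is accepted).
#' @param conflict `"max"` or `"sum"` (sum is clipped at 1).
#' @return Named numeric vector over canonical labels (only nonzero entries).
#' @export
#' @examples
#' au_recode(c("1+2" = 0.8))        # AU1, AU2L, AU2R at 0.8
#' au_recode(c("12" = 0.5))         # AU12L, AU12R at 0.5
au_recode <- function(raw, conflict = c("max", "sum")) {
  conflict <- match.arg(conflict)
  if (length(raw) == 0) return(stats::setNames(numeric(0), character(0)))
  if (is.null(names(raw)) || any(!nzchar(names(raw))))
    stop("amplitudes must be a named vector of AU labels")
  if (any(!is.finite(raw)) || any(raw < 0) || any(raw > 1))
    stop("AU amplitudes must lie in [0, 1]")
  out <- numeric(0)
  for (i in seq_along(raw)) {
    labs <- resolve_au_label(names(raw)[i])
    if (is.null(labs))
      stop("unknown AU label: '", names(raw)[i], "'")
    for (lab in labs) {
      if (lab %in% names(out)) {
        out[lab] <- if (conflict == "max") max(out[lab], raw[[i]])
                    else min(1, out[lab] + raw[[i]])
      } else {
        out[lab] <- raw[[i]]
      }
    }
  }
  # canonical order
  out[order(match(names(out), au_labels()))]
}

#' Embed a canonical AU amplitude map as a stimulus vector
#'
#' @param map Named numeric vector over canonical AU labels (absent = 0), as
#'   returned by [au_recode()].
#' @return Numeric vector of length 33 in canonical order, named by
#'   [au_labels()].
#' @export
#' @examples
#' au_embed(c("1" = 1.0))
au_embed <- function(map) {
  labs <- au_labels()
  v <- stats::setNames(numeric(length(labs)), labs)
  if (length(map)) {
    if (is.null(names(map)) || !all(names(map) %in% labs))
      stop("map keys must be canonical AU labels; recode first with au_recode()")
    if (any(map < 0) || any(map > 1)) stop("amplitudes must lie in [0, 1]")
    v[names(map)] <- map
  }
  v
}

#' Canonical stimulus key
#'
#' A stimulus is identified by its exact AU pattern: the multiset of
#' (canonical label, rounded amplitude) pairs. Two presentations with the same
#' AUs and amplitudes receive equal keys, which is how repeated trials are
#' found for noise-ceiling estimation.
#'
#' @param x A named amplitude map, a numeric length-33 vector, or a matrix /
#'   data frame whose columns include [au_columns()].
#' @param digits Amplitude rounding precision used in the key (default 6).
#' @return Character vector of keys (length 1 for a single stimulus).
#' @export
stimulus_key <- function(x, digits = 6) {
  if (is.data.frame(x)) x <- as.matrix(x[, au_columns(), drop = FALSE])
  if (is.matrix(x)) {
    if (ncol(x) != 33) stop("expected 33 AU columns")
    labs <- au_labels()
    return(apply(x, 1, function(row) key_one(labs, row, digits)))
  }
  if (!is.null(names(x)) && !all(names(x) %in% au_labels()) ) {
    x <- au_recode(x)
  }
  v <- if (length(x) == 33 && is.null(names(x))) stats::setNames(x, au_labels()) else au_embed(x)
  key_one(au_labels(), v, digits)
}

key_one <- function(labs, amps, digits) {
  amps <- round(amps, digits)
  on <- amps > 0
  if (!any(on)) return("<neutral>")
  paste(paste0(labs[on], "=", format(amps[on], trim = TRUE, scientific = FALSE)),
        collapse = ";")
}
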