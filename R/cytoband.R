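# ---------------------------------------------------------------------------
# Polytene cytogenetic coordinates (autosomes only)
#
# A position on the Drosophila salivary-gland polytene map is written as
# numbered division (21-100), optional subdivision letter (A-F), optional
# numbered band within the letter, e.g. "46C7". Divisions 21-60 tile
# chromosome 2 (arms 2L/2R), 61-100 chromosome 3 (3L/3R). An arm-terminal
# sentinel such as "3Rt" marks the telomere.
#
# Interval arithmetic runs on a continuous key line. Every entity maps to a
# half-open key interval:
#   numbered band (d, L, b) -> [K + 10*b, K + 10*(b+1)) with K = 1e4*d + 1e3*L
#   letter-only   (d, L)    -> [K, K + 1e3)      (the whole subdivision)
#   division-only (d)       -> [1e4*d + 1e3, 1e4*d + 7e3)
#   telomere of an arm      -> a width-10 cell beyond the arm's last division
# A letter-only endpoint therefore spans its subdivision without ever
# inventing a terminal band number (the bands-per-subdivision count is
# map-dependent and not modeled).
# ---------------------------------------------------------------------------

.ARM_TABLE <- data.frame(
  arm     = c("2L", "2R", "3L", "3R"),
  div_lo  = c(21, 41, 61, 81),
  div_hi  = c(40, 60, 80, 100),
  stringsAsFactors = FALSE
)

.letter_idx <- function(letter) match(letter, LETTERS[1:6])

.arm_of_division <- function(division) {
  .ARM_TABLE$arm[division >= .ARM_TABLE$div_lo & division <= .ARM_TABLE$div_hi]
}

.chromosome_of_arm <- function(arm) as.integer(substr(arm, 1, 1))

#' Parse a polytene cytogenetic band token
#'
#' Accepts `division[letter[band]]` tokens such as `"46C7"`, `"61A"`, `"46"`
#' and arm-telomere sentinels such as `"3Rt"`. Only autosomal divisions
#' (21-100) are valid.
#'
#' @param text A single band token.
#' @return An object of class `cytoband` with fields `division`, `letter`,
#'   `band`, `telomere`, `arm` and `chromosome`.
#' @examples
#' parse_band("46C7")
#' parse_band("3Rt")
#' @export
parse_band <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tok <- trimws(text)
  m <- regmatches(tok, regexec("^([23])([LR])t$", tok))[[1]]
  if (length(m)) {
    arm <- paste0(m[2], m[3])
    row <- .ARM_TABLE[.ARM_TABLE$arm == arm, ]
    return(new_cytoband(row$div_hi, NA_character_, NA_integer_, telomere = arm))
  }
  m <- regmatches(tok, regexec("^([0-9]{1,3})([A-Fa-f])?([0-9]{1,3})?$", tok))[[1]]
  if (!length(m)) {
    stop("malformed cytogenetic band token: '", text, "'", call. = FALSE)
  }
  division <- as.integer(m[2])
  letter <- if (nzchar(m[3])) toupper(m[3]) else NA_character_
  band <- if (nzchar(m[4])) as.integer(m[4]) else NA_integer_
  if (division < 21 || division > 100) {
    stop("division outside the autosomal map (21-100) in token '", text, "'",
         call. = FALSE)
  }
  if (!is.na(band) && is.na(letter)) {
    stop("band number without a subdivision letter in token '", text, "'",
         call. = FALSE)
  }
  if (!is.na(band) && band < 1) {
    stop("band number must be >= 1 in token '", text, "'", call. = FALSE)
  }
  new_cytoband(division, letter, band)
}

new_cytoband <- function(division, letter, band, telomere = NA_character_) {
  arm <- if (!is.na(telomere)) telomere else .arm_of_division(division)
  structure(
    list(
      division = as.integer(division),
      letter = letter,
      band = if (is.na(band)) NA_integer_ else as.integer(band),
      telomere = telomere,
      arm = arm,
      chromosome = .chromosome_of_arm(arm)
    ),
    class = "cytoband"
  )
}

#' @export
format.cytoband <- function(x, ...) {
  if (!is.na(x$telomere)) {
    return(paste0(x$telomere, "t"))
  }
  paste0(
    x$division,
    if (!is.na(x$letter)) x$letter else "",
    if (!is.na(x$band)) x$band else ""
  )
}

#' @export
print.cytoband <- function(x, ...) {
  cat("<cytoband> ", format(x), " (arm ", x$arm, ")\n", sep = "")
  invisible(x)
}

# continuous key interval of a single band entity
.band_start <- function(b) {
  if (!is.na(b$telomere)) {
    row <- .ARM_TABLE[.ARM_TABLE$arm == b$telomere, ]
    return((row$div_hi + 1) * 1e4)
  }
  if (is.na(b$letter)) {
    return(b$division * 1e4 + 1e3)
  }
  k <- b$division * 1e4 + .letter_idx(b$letter) * 1e3
  if (is.na(b$band)) k else k + 10 * b$band
}

.band_end <- function(b) {
  if (!is.na(b$telomere)) return(.band_start(b) + 10)
  if (is.na(b$letter)) return(b$division * 1e4 + 7e3)
  if (is.na(b$band)) return(b$division * 1e4 + (.letter_idx(b$letter) + 1) * 1e3)
  .band_start(b) + 10
}

.check_same_chromosome <- function(a, b) {
  if (a$chromosome != b$chromosome) {
    stop("cannot order bands on different chromosomes (",
         format(a), " vs ", format(b), ")", call. = FALSE)
  }
}

#' Total order on same-chromosome cytogenetic bands
#'
#' `band_le(a, b)` is `TRUE` when `a` does not lie distal to `b`. Letter-only
#' and division-only tokens are ordered by the proximal edge of the span they
#' denote, then by the distal edge, which yields a deterministic total order.
#' Telomere sentinels compare greater than every concrete band on their arm.
#'
#' @param a,b `cytoband` objects on the same chromosome.
#' @return Logical scalar.
#' @examples
#' band_le(parse_band("46C1"), parse_band("46C7"))
#' @export
band_le <- function(a, b) {
  stopifnot(inherits(a, "cytoband"), inherits(b, "cytoband"))
  .check_same_chromosome(a, b)
  sa <- .band_start(a); sb <- .band_start(b)
  if (sa != sb) return(sa < sb)
  .band_end(a) <= .band_end(b)
}

# ---------------------------------------------------------------------------
# Band ranges ("49C1-4", "50C23-D2") and deficiency intervals
# ---------------------------------------------------------------------------

new_band_range <- function(lo, hi) {
  structure(list(lo = lo, hi = hi), class = "band_range")
}

.range_start <- function(r) .band_start(r$lo)
.range_end <- function(r) .band_end(r$hi)

#' @export
format.band_range <- function(x, ...) {
  lo <- format(x$lo); hi <- format(x$hi)
  if (identical(lo, hi)) lo else paste0(lo, "-", hi)
}

#' @export
print.band_range <- function(x, ...) {
  cat("<band_range> ", format(x), "\n", sep = "")
  invisible(x)
}

# resolve the right-hand token of "A-B" against the fully parsed left band
.resolve_suffix <- function(lo, tok, text) {
  if (grepl("^[0-9]+$", tok)) {
    # bare band number: inherit division and letter from the left endpoint
    if (is.na(lo$letter)) {
      stop("range suffix '", tok, "' in '", text,
           "' has no subdivision letter to inherit", call. = FALSE)
    }
    return(new_cytoband(lo$division, lo$letter, as.integer(tok)))
  }
  if (grepl("^[0-9]+[A-Fa-f][0-9]*$", tok) || grepl("^[23][LR]t$", tok)) {
    # token carries its own division (or is a telomere): parse outright
    return(parse_band(tok))
  }
  m <- regmatches(tok, regexec("^([A-Fa-f])([0-9]{1,3})?$", tok))[[1]]
  if (length(m)) {
    band <- if (nzchar(m[3])) as.integer(m[3]) else NA_integer_
    return(new_cytoband(lo$division, toupper(m[2]), band))
  }
  stop("malformed range suffix '", tok, "' in '", text, "'", call. = FALSE)
}

#' Parse a breakpoint-range string
#'
#' A breakpoint may be printed as a single band (`"46C7"`), or as an
#' uncertainty span `"A-B"` where the right endpoint may omit the division
#' and/or subdivision letter it shares with the left endpoint (`"49C1-4"`,
#' `"50C23-D2"`). A compact double-letter token such as `"45DE3"` is read as
#' the span from the first subdivision to the second (`45D-45E3`).
#'
#' @param text A breakpoint-range string.
#' @return A `band_range` with fields `lo` and `hi` (both `cytoband`).
#' @examples
#' parse_band_range("49C1-4")
#' parse_band_range("50C23-D2")
#' @export
parse_band_range <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tok <- trimws(text)
  # compact double-letter form, e.g. "45DE3" = 45D-45E3
  m <- regmatches(tok, regexec("^([0-9]{1,3})([A-Fa-f])([A-Fa-f])([0-9]{0,3})$",
                               tok))[[1]]
  if (length(m)) {
    lo <- parse_band(paste0(m[2], m[3]))
    band <- if (nzchar(m[5])) as.integer(m[5]) else NA_integer_
    hi <- new_cytoband(lo$division, toupper(m[4]), band)
    r <- new_band_range(lo, hi)
  } else if (grepl("-", tok, fixed = TRUE)) {
    parts <- strsplit(tok, "-", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop("expected a single '-' in breakpoint range '", text, "'",
           call. = FALSE)
    }
    lo <- parse_band(parts[1])
    hi <- .resolve_suffix(lo, parts[2], text)
    r <- new_band_range(lo, hi)
  } else {
    b <- parse_band(tok)
    r <- new_band_range(b, b)
  }
  .check_same_chromosome(r$lo, r$hi)
  if (.band_start(r$hi) < .band_start(r$lo)) {
    stop("descending breakpoint range '", text, "'", call. = FALSE)
  }
  r
}

new_deficiency <- function(name, proximal, distal) {
  structure(
    list(
      name = name,
      proximal = proximal,
      distal = distal,
      chromosome = proximal$lo$chromosome
    ),
    class = "deficiency"
  )
}

#' Parse a deficiency (deletion) breakpoint descriptor
#'
#' The breakpoint text is two breakpoint-range strings separated by `";"`
#' (a stray `","` separator and a bare `"PROX-DIST"` form, both of which occur
#' in printed tables, are also accepted). The proximal and distal breakpoints
#' each carry their own positional uncertainty; the maximal extent of the
#' deletion runs from the proximal range's start to the distal range's end,
#' the minimal (certainly deleted) extent from the proximal range's end to the
#' distal range's start.
#'
#' @param name Line identifier, e.g. `"Df(2R)X1"`.
#' @param breakpoints Breakpoint text, e.g. `"46C;47A1"`.
#' @return An object of class `deficiency`.
#' @examples
#' parse_deficiency("Df(2R)X1", "46C;47A1")
#' @export
parse_deficiency <- function(name, breakpoints) {
  stopifnot(is.character(breakpoints), length(breakpoints) == 1L)
  txt <- trimws(breakpoints)
  txt <- gsub(",", ";", txt, fixed = TRUE)
  if (!grepl(";", txt, fixed = TRUE)) {
    # pointwise form "27B2-27F2": both sides are complete band tokens
    parts <- strsplit(txt, "-", fixed = TRUE)[[1]]
    if (length(parts) == 2L && all(grepl("^[0-9]", parts))) {
      txt <- paste(parts, collapse = ";")
    } else {
      stop("deficiency '", name, "': breakpoints '", breakpoints,
           "' lack a ';' separator", call. = FALSE)
    }
  }
  parts <- strsplit(txt, ";", fixed = TRUE)[[1]]
  if (length(parts) != 2L) {
    stop("deficiency '", name, "': expected exactly two breakpoints in '",
         breakpoints, "'", call. = FALSE)
  }
  proximal <- parse_band_range(parts[1])
  distal <- parse_band_range(parts[2])
  if (proximal$lo$chromosome != distal$lo$chromosome) {
    stop("deficiency '", name, "': breakpoints span two chromosomes",
         call. = FALSE)
  }
  if (.range_end(distal) <= .range_start(proximal) &&
      !identical(format(proximal), format(distal))) {
    stop("deficiency '", name, "': descending interval '", breakpoints, "'",
         call. = FALSE)
  }
  new_deficiency(name, proximal, distal)
}

#' @export
format.deficiency <- function(x, ...) {
  paste0(x$name, " [", format(x$proximal), ";", format(x$distal), "]")
}

#' @export
print.deficiency <- function(x, ...) {
  cat("<deficiency> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Maximal and minimal extents of a deficiency
#'
#' The maximal extent includes every band the deletion could reach under
#' breakpoint uncertainty; the minimal extent only the bands certainly
#' deleted. `minimal_extent()` returns `NULL` when breakpoint uncertainty
#' leaves no certainly deleted band (the two uncertainty ranges overlap).
#'
#' @param x A `deficiency`.
#' @return A `band_range`, or `NULL` (minimal extent only).
#' @export
maximal_extent <- function(x) {
  stopifnot(inherits(x, "deficiency"))
  new_band_range(x$proximal$lo, x$distal$hi)
}

#' @rdname maximal_extent
#' @export
minimal_extent <- function(x) {
  stopifnot(inherits(x, "deficiency"))
  if (.band_end(x$proximal$hi) >= .band_start(x$distal$lo)) return(NULL)
  new_band_range(x$proximal$hi, x$distal$lo)
}

.as_range <- function(x) {
  if (inherits(x, "deficiency")) maximal_extent(x) else x
}

#' Do two deficiencies overlap?
#'
#' Overlap is judged on maximal extents (inclusive under breakpoint
#' uncertainty). Intervals on different chromosomes do not overlap (this is
#' `FALSE`, not an error).
#'
#' @param d1,d2 `deficiency` or `band_range` objects.
#' @return Logical scalar.
#' @export
df_overlaps <- function(d1, d2) {
  r1 <- .as_range(d1); r2 <- .as_range(d2)
  if (r1$lo$chromosome != r2$lo$chromosome) return(FALSE)
  max(.range_start(r1), .range_start(r2)) < min(.range_end(r1), .range_end(r2))
}

#' Intersection of two intervals
#'
#' Computed on maximal extents; endpoints of the result are the original
#' breakpoint bands (never fabricated terminal band numbers). Returns `NULL`
#' when the intervals are disjoint or lie on different chromosomes.
#'
#' @param d1,d2 `deficiency` or `band_range` objects.
#' @return A `band_range` or `NULL`.
#' @export
df_intersect <- function(d1, d2) {
  r1 <- .as_range(d1); r2 <- .as_range(d2)
  if (r1$lo$chromosome != r2$lo$chromosome) return(NULL)
  lo <- if (.band_start(r2$lo) > .band_start(r1$lo)) r2$lo else r1$lo
  hi <- if (.band_end(r2$hi) < .band_end(r1$hi)) r2$hi else r1$hi
  if (.band_start(lo) >= .band_end(hi)) return(NULL)
  new_band_range(lo, hi)
}

#' Subtract one band interval from another
#'
#' Set difference at breakpoint resolution. Because a breakpoint band may be
#' only partially removed by the subtracted interval, the flanking pieces keep
#' the subtracted interval's own boundary bands as (uncertain) endpoints:
#' `"23C1-23E2"` minus `"23C5-23E3"` is the single piece `23C1-23C5`.
#'
#' @param r1 Interval to subtract from (`band_range` or `deficiency`).
#' @param r2 Interval to remove.
#' @return A list of 0-2 `band_range` pieces, ordered proximal to distal.
#' @export
range_subtract <- function(r1, r2) {
  r1 <- .as_range(r1); r2 <- .as_range(r2)
  if (r1$lo$chromosome != r2$lo$chromosome ||
      .range_start(r2) >= .range_end(r1) || .range_end(r2) <= .range_start(r1)) {
    return(list(r1))
  }
  pieces <- list()
  if (.band_start(r2$lo) > .band_start(r1$lo)) {
    pieces <- c(pieces, list(new_band_range(r1$lo, r2$lo)))
  }
  if (.band_end(r2$hi) < .band_end(r1$hi)) {
    pieces <- c(pieces, list(new_band_range(r2$hi, r1$hi)))
  }
  pieces
}

# Remove a deficiency's *certainly deleted* interior from a range, keeping the
# breakpoint bands themselves as possibly-retained endpoints. Used by hotspot
# refinement, where only bands certainly deleted by a nonmodifying deletion
# can be exonerated.
.subtract_certain <- function(range, sub) {
  stopifnot(inherits(sub, "deficiency"))
  rm_start <- .band_end(sub$proximal$hi)
  rm_end <- .band_start(sub$distal$lo)
  if (sub$chromosome != range$lo$chromosome || rm_start >= rm_end ||
      rm_start >= .range_end(range) || rm_end <= .range_start(range)) {
    return(list(range))
  }
  pieces <- list()
  if (rm_start > .range_start(range)) {
    pieces <- c(pieces, list(new_band_range(range$lo, sub$proximal$hi)))
  }
  if (rm_end < .range_end(range)) {
    pieces <- c(pieces, list(new_band_range(sub$distal$lo, range$hi)))
  }
  pieces
}
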