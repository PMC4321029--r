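# ---------------------------------------------------------------------------
# Submapping: delimit a modifier hotspot with smaller overlapping deletions
# ---------------------------------------------------------------------------

.opposite_class <- function(class) {
  switch(class, suppressor = "enhancer", enhancer = "suppressor",
         stop("unknown class '", class, "'", call. = FALSE))
}

#' Refine a modifier hotspot with overlapping smaller deletions
#'
#' Combines the classification of smaller deletions that overlap a parent
#' modifier deficiency to delimit the critical interval:
#'
#' * comment code 1 — at least one smaller deletion shares the parent's
#'   class: the critical region is the intersection of the parent with every
#'   same-class deletion (their common tested region), minus the certainly
#'   deleted interiors of nonmodifying deletions;
#' * comment code 2 — all smaller deletions are nonmodifiers: the critical
#'   region is the parent minus their certainly deleted interiors (it lies
#'   outside the tested subregions);
#' * comment code 3 — some smaller deletion shows the opposite behavior: its
#'   region is reported separately under its own class (clipped to the
#'   parent and excluding same-class evidence), and the parent-class region
#'   excludes it.
#'
#' Only bands *certainly* deleted by a deletion (its minimal extent interior)
#' can be exonerated or reassigned; same-class evidence combines maximal
#' extents. A case may satisfy several code definitions at once (e.g. an
#' opposite-class deletion alongside a same-class one); `comment_codes` holds
#' every applicable code and `comment_code` the primary one.
#'
#' @param parent A `deficiency` (see [parse_deficiency()]).
#' @param parent_class `"suppressor"` or `"enhancer"`.
#' @param subs List of `deficiency` objects overlapping the parent.
#' @param sub_classes Character vector of classifications for `subs`
#'   (`"suppressor"`, `"enhancer"` or `"nonmodifier"`).
#' @return An object of class `submap_result`: fields `parent`,
#'   `parent_class`, `subs`, `sub_classes`, `comment_code`, `comment_codes`,
#'   and `refined`, a list of `list(class =, range =)` entries whose ranges
#'   all lie within the parent's maximal extent.
#' @examples
#' x1 <- parse_deficiency("Df(2R)X1", "46C;47A1")
#' subs <- list(parse_deficiency("Df(2R)BSC152", "46C1;46D7"),
#'              parse_deficiency("Df(2R)BSC298", "46B2;46C7"),
#'              parse_deficiency("Df(2R)eve", "46C7;46C9-46C11"))
#' r <- refine_hotspot(x1, "suppressor", subs,
#'                     c("suppressor", "suppressor", "nonmodifier"))
#' format(r$refined[[1]]$range) # "46C1-46C7"
#' @export
refine_hotspot <- function(parent, parent_class, subs, sub_classes) {
  stopifnot(inherits(parent, "deficiency"), length(subs) == length(sub_classes))
  if (parent_class == "nonmodifier") {
    stop("nothing to refine: parent is classified nonmodifier", call. = FALSE)
  }
  for (i in seq_along(subs)) {
    if (!df_overlaps(parent, subs[[i]])) {
      warning("deletion '", subs[[i]]$name, "' does not overlap parent '",
              parent$name, "'", call. = FALSE)
    }
  }
  same <- subs[sub_classes == parent_class]
  opp <- subs[sub_classes == .opposite_class(parent_class)]
  non <- subs[sub_classes == "nonmodifier"]

  codes <- integer()
  if (length(same)) codes <- c(codes, 1L)
  if (length(opp)) codes <- c(codes, 3L)
  if (length(non) && !length(same)) codes <- c(codes, 2L)
  primary <- if (length(same)) 1L else if (length(opp)) 3L else 2L

  parent_max <- maximal_extent(parent)

  # parent-class region
  pieces <- list(parent_max)
  for (s in same) {
    pieces <- Filter(Negate(is.null),
                     lapply(pieces, function(r) df_intersect(r, s)))
  }
  for (s in non) {
    pieces <- unlist(lapply(pieces, .subtract_certain, sub = s),
                     recursive = FALSE)
  }
  if (!length(same)) {
    # without direct same-class evidence, opposite-class interiors are
    # excluded from the parent-class region too
    for (s in opp) {
      pieces <- unlist(lapply(pieces, .subtract_certain, sub = s),
                       recursive = FALSE)
    }
  }
  refined <- lapply(pieces, function(r) list(class = parent_class, range = r))

  # opposite-class regions, clipped to the parent and excluding bands that
  # same-class or nonmodifying deletions certainly delete
  opp_class <- .opposite_class(parent_class)
  for (s in opp) {
    op <- df_intersect(s, parent_max)
    if (is.null(op)) next
    op_pieces <- list(op)
    for (w in c(same, non)) {
      op_pieces <- unlist(lapply(op_pieces, .subtract_certain, sub = w),
                          recursive = FALSE)
    }
    refined <- c(refined,
                 lapply(op_pieces, function(r) list(class = opp_class, range = r)))
  }

  structure(
    list(parent = parent, parent_class = parent_class, subs = subs,
         sub_classes = sub_classes, comment_code = primary,
         comment_codes = codes, refined = refined),
    class = "submap_result"
  )
}

#' @export
format.submap_result <- function(x, ...) {
  rr <- vapply(x$refined,
               function(e) paste0(format(e$range), " (", e$class, ")"),
               character(1))
  paste0(x$parent$name, " [", x$parent_class, ", comment ",
         paste(x$comment_codes, collapse = "+"), "]: ",
         if (length(rr)) paste(rr, collapse = ", ") else "no refined region")
}

#' @export
print.submap_result <- function(x, ...) {
  cat("<submap_result> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Refined ranges of a given class
#'
#' @param result A `submap_result`.
#' @param class Modifier class to extract; default: the parent's class.
#' @return List of `band_range` pieces.
#' @export
refined_ranges <- function(result, class = result$parent_class) {
  lapply(Filter(function(e) e$class == class, result$refined), `[[`, "range")
}

#' Candidate genes intersecting refined ranges
#'
#' @param ranges List of `band_range` objects (e.g. [refined_ranges()]).
#' @param annotation A data frame with columns `symbol` and `location`
#'   (breakpoint-range strings), e.g. from [read_annotation_tsv()].
#' @return Gene symbols whose annotated interval intersects any of the
#'   ranges, in annotation order, deduplicated.
#' @export
candidate_genes <- function(ranges, annotation) {
  stopifnot(is.data.frame(annotation), nrow(annotation) > 0)
  if (!length(ranges)) return(character())
  locs <- lapply(annotation$location, parse_band_range)
  hit <- vapply(locs, function(loc) {
    any(vapply(ranges, function(r) !is.null(df_intersect(loc, r)), logical(1)))
  }, logical(1))
  unique(annotation$symbol[hit])
}

#' Filter gene symbols by annotation biotype
#'
#' @param symbols Character vector of gene symbols.
#' @param annotation Annotation data frame; an optional `biotype` column
#'   defaults to `"miRNA"` for symbols beginning `"mir-"` and `"gene"`
#'   otherwise.
#' @param exclude_biotypes Biotypes to drop (e.g. `"miRNA"`).
#' @return The filtered symbol vector.
#' @export
gene_class_filter <- function(symbols, annotation, exclude_biotypes = character()) {
  if (!length(exclude_biotypes)) return(symbols)
  bio <- .annotation_biotype(annotation)
  lookup <- bio[match(symbols, annotation$symbol)]
  lookup[is.na(lookup)] <- "gene"
  symbols[!lookup %in% exclude_biotypes]
}

.annotation_biotype <- function(annotation) {
  if ("biotype" %in% names(annotation)) {
    annotation$biotype
  } else {
    ifelse(startsWith(annotation$symbol, "mir-"), "miRNA", "gene")
  }
}

#' Run the refinement over a packaged-style submapping table
#'
#' Each case couples one parent modifier deficiency with the smaller
#' overlapping deletions tested against it. Classifications come from the
#' counts via [classify()] except where a `starred` flag records that a line
#' with fold change slightly below threshold was considered a suppressor on
#' the strength of a significant increase in F1 males.
#'
#' @param submap A data frame like the `table2_submap.tsv` fixture: columns
#'   `case_id`, `role` (`"parent"`/`"sub"`), `line_id`, `breakpoints`,
#'   `males`, `females`, optional `starred`.
#' @param config A [screen_config()].
#' @return Named list of `submap_result`, one per case.
#' @export
refine_submap <- function(submap, config = screen_config()) {
  stopifnot(all(c("case_id", "role", "line_id", "breakpoints",
                  "males", "females") %in% names(submap)))
  cls <- classify(pct_males(submap$males, submap$females), config)
  if ("starred" %in% names(submap)) {
    cls[!is.na(submap$starred) & submap$starred == "*"] <- "suppressor"
  }
  out <- list()
  for (id in unique(submap$case_id)) {
    rows <- which(submap$case_id == id)
    prow <- rows[submap$role[rows] == "parent"]
    srow <- rows[submap$role[rows] == "sub"]
    stopifnot(length(prow) == 1)
    parent <- parse_deficiency(submap$line_id[prow], submap$breakpoints[prow])
    subs <- lapply(srow, function(i) {
      parse_deficiency(submap$line_id[i], submap$breakpoints[i])
    })
    out[[id]] <- refine_hotspot(parent, cls[prow], subs, cls[srow])
  }
  out
}
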