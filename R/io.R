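# ---------------------------------------------------------------------------
# Tabular I/O: screen TSV dialect, submapping table, gene annotation
# ---------------------------------------------------------------------------

#' Read a screen TSV
#'
#' The screen dialect is tab-separated with a header; required columns
#' `line_id`, `males`, `females`; optional `breakpoints`, `p_printed`
#' (printed significance values, `"< x"` and `"-"` accepted), `replicates`
#' (semicolon-separated `"males,females"` pairs per independent cross), and
#' any further columns, which are carried through. Control rows are those
#' with missing breakpoints.
#'
#' @param path File path.
#' @return A tibble of validated tallies; printed p-values are parsed into a
#'   numeric `p_value` column, replicate strings into a list column of
#'   two-column matrices.
#' @export
read_screen_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  if (nrow(x) == 0) stop("no records in ", path, call. = FALSE)
  missing_cols <- setdiff(c("line_id", "males", "females"), names(x))
  if (length(missing_cols)) {
    stop("missing columns in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in intersect(c("males", "females", "total"), names(x))) {
    v <- x[[col]]
    bad <- which(is.na(v) | !grepl("^[0-9]+$", v))
    if (length(bad)) {
      stop("column '", col, "' must hold non-negative integers; offending ",
           "rows (after header): ", paste(head(bad, 5), collapse = ", "),
           call. = FALSE)
    }
    x[[col]] <- as.integer(v)
  }
  if ("p_printed" %in% names(x)) {
    x$p_value <- parse_p_printed(x$p_printed)
  }
  if ("pct_printed" %in% names(x)) x$pct_printed <- as.integer(x$pct_printed)
  if ("replicates" %in% names(x)) {
    x$replicates <- lapply(x$replicates, .parse_replicates)
  }
  if ("true_m" %in% names(x)) x$true_m <- as.numeric(x$true_m)
  x
}

#' Parse printed significance values
#'
#' `"-"` (not calculated) becomes `NA`; censored values such as `"< 0.0001"`
#' are read at their bound.
#'
#' @param p Character vector of printed p-values.
#' @return Numeric vector.
#' @export
parse_p_printed <- function(p) {
  p <- trimws(p)
  out <- rep(NA_real_, length(p))
  keep <- !is.na(p) & p != "-" & p != ""
  out[keep] <- as.numeric(sub("^<\\s*", "", p[keep]))
  out
}

.parse_replicates <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  pairs <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ",", fixed = TRUE)
  mat <- do.call(rbind, lapply(pairs, function(p) as.integer(trimws(p))))
  if (ncol(mat) != 2 || anyNA(mat)) {
    stop("malformed replicates field '", s, "'", call. = FALSE)
  }
  colnames(mat) <- c("males", "females")
  mat
}

#' Write a table in the screen TSV dialect
#'
#' @param x A data frame; a `replicates` list column is serialized back to
#'   `"males,females;..."` strings.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen_tsv <- function(x, path) {
  if ("replicates" %in% names(x)) {
    x$replicates <- vapply(x$replicates, function(m) {
      if (is.null(m)) return("")
      paste(apply(m, 1, paste, collapse = ","), collapse = ";")
    }, character(1))
  }
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read a candidate-gene annotation TSV
#'
#' Columns `symbol` and `location` (breakpoint-range strings) are required;
#' a missing `biotype` column is filled with `"miRNA"` for `mir-*` symbols
#' and `"gene"` otherwise. Locations are validated by parsing.
#'
#' @param path File path.
#' @return A tibble with `symbol`, `location`, `biotype` (plus any extra
#'   columns present).
#' @export
read_annotation_tsv <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  missing_cols <- setdiff(c("symbol", "location"), names(x))
  if (length(missing_cols)) {
    stop("missing columns in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  invisible(lapply(x$location, parse_band_range))
  x$biotype <- .annotation_biotype(x)
  x
}

#' Read a submapping table
#'
#' @param path File path to a table in the `table2_submap.tsv` layout.
#' @return A validated tibble.
#' @export
read_submap_tsv <- function(path) {
  x <- read_screen_tsv(path)
  missing_cols <- setdiff(c("case_id", "role"), names(x))
  if (length(missing_cols)) {
    stop("missing columns in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x
}

#' Write a screen report in the printed-table layout
#'
#' One row per line with counts, display-rounded percent and fold change,
#' classification and p-value. When the input carries printed `pct_printed` /
#' `fold_printed` columns they are emitted side by side with a `mismatch`
#' flag, so known printing artifacts are visible rather than fatal.
#'
#' @param records Output of [score_screen()] (printed columns are looked up
#'   in `tallies` when given).
#' @param path Output path.
#' @param tallies Optional original input table holding printed columns.
#' @return `path`, invisibly.
#' @export
write_screen_report <- function(records, path, tallies = NULL) {
  out <- tibble::tibble(
    line_id = records$line_id,
    breakpoints = records$breakpoints,
    males = records$males,
    females = records$females,
    total = records$total,
    pct_males = records$pct_display,
    fold_change = format_fold(records$fold_change),
    classification = records$classification,
    p_value = records$p_value
  )
  if (!is.null(tallies) &&
      all(c("pct_printed", "fold_printed") %in% names(tallies))) {
    idx <- match(out$line_id, tallies$line_id)
    out$pct_printed <- tallies$pct_printed[idx]
    out$fold_printed <- tallies$fold_printed[idx]
    out$mismatch <- out$pct_males != out$pct_printed |
      out$fold_change != out$fold_printed
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Run the scoring pipeline end to end
#'
#' Reads a screen TSV, scores and classifies every line, writes a
#' printed-table-style report and a JSON summary, and optionally runs the
#' submapping refinement. All outputs are deterministic for fixed inputs.
#'
#' @param input Path to a screen TSV (e.g.
#'   `f1screen_fixture("table1_screen.tsv")`).
#' @param out_dir Output directory, created if absent.
#' @param config A [screen_config()].
#' @param submap Optional path to a submapping TSV; triggers refinement.
#' @param annotation Optional path to a gene annotation TSV; adds candidate
#'   genes to the refinement report.
#' @param verbose Log progress to stderr.
#' @return Invisibly, a list with `records`, `summary`, `refinements` (or
#'   `NULL`) and the written `paths`.
#' @export
run_pipeline <- function(input, out_dir, config = screen_config(),
                         submap = NULL, annotation = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message("[f1screen] ", ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say("reading ", input, " (md5 ", unname(tools::md5sum(input)), ")")
  tallies <- read_screen_tsv(input)
  records <- score_screen(tallies, config)
  summary <- summarize_screen(records, config)
  report_path <- file.path(out_dir, "screen_report.tsv")
  write_screen_report(records, report_path, tallies)
  summary_path <- file.path(out_dir, "screen_summary.json")
  jsonlite::write_json(
    list(
      baseline_pct = config$baseline_pct,
      threshold_mode = config$threshold_mode,
      n_lines = summary$n_lines,
      mean_pct = summary$mean_pct,
      sd_pct = summary$sd_pct,
      n_suppressors = summary$n_suppressors,
      n_enhancers = summary$n_enhancers,
      input_md5 = unname(tools::md5sum(input))
    ),
    summary_path, auto_unbox = TRUE, digits = NA
  )
  say("scored ", nrow(records), " lines: ", summary$n_suppressors,
      " suppressors, ", summary$n_enhancers, " enhancers")
  paths <- c(report = report_path, summary = summary_path)

  refinements <- NULL
  if (!is.null(submap)) {
    sm <- read_submap_tsv(submap)
    refinements <- refine_submap(sm, config)
    ann <- if (!is.null(annotation)) read_annotation_tsv(annotation)
    lines <- vapply(names(refinements), function(id) {
      r <- refinements[[id]]
      genes <- if (!is.null(ann)) {
        paste(candidate_genes(refined_ranges(r), ann), collapse = ",")
      } else ""
      paste(id, r$parent_class, paste(r$comment_codes, collapse = "+"),
            paste(vapply(r$refined, function(e)
              paste0(format(e$range), ":", e$class), character(1)),
              collapse = ";"),
            genes, sep = "\t")
    }, character(1))
    refine_path <- file.path(out_dir, "refinement_report.tsv")
    writeLines(c("case_id\tparent_class\tcomment_codes\trefined\tcandidates",
                 lines), refine_path)
    paths <- c(paths, refine = refine_path)
    say("refined ", length(refinements), " cases")
  }
  invisible(list(records = records, summary = summary,
                 refinements = refinements, paths = paths))
}
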