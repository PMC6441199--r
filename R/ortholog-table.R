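#' Read a two-species orthologous count-and-length table
#'
#' Reads a delimited text file with one row per orthologous gene pair and named
#' columns for the identifier, the read count and gene (or transcript) length
#' in each species. Lines starting with `#` are treated as comments. The
#' delimiter is taken from the file extension (`.csv` for comma, anything else
#' for tab) unless given explicitly.
#'
#' Multiple samples per species are accepted as extra count columns and pooled
#' by summation, since the conditional test consumes one count per species:
#' pass a character vector of column names for `x1` and/or `x2` in `col_map`.
#'
#' @param path Path to a TSV/CSV file with a header row.
#' @param col_map Named list or character vector mapping the standard names
#'   `gene_id`, `x1`, `L1`, `x2`, `L2` to the column names in the file.
#'   Defaults to the standard names themselves. `x1`/`x2` may map to several
#'   columns, which are summed.
#' @param delim Field delimiter; `NULL` (default) guesses from the extension.
#'
#' @return A tibble with columns `gene_id` (character), `x1`, `L1`, `x2`, `L2`
#'   (integers). The sequencing depths `N1 = sum(x1)`, `N2 = sum(x2)` are
#'   derived quantities; see [ortholog_depths()].
#' @seealso [filter_transcripts()], [write_ortholog_table()]
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\tx1\tL1\tx2\tL2",
#'              "a\t5\t100\t0\t120",
#'              "b\t2\t250\t2\t240",
#'              "c\t0\t300\t7\t310"), tf)
#' tab <- read_ortholog_table(tf)
#' ortholog_depths(tab)
read_ortholog_table <- function(path, col_map = NULL, delim = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "crossnorm_format_error")
  }
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, comment = "#",
                           show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0L) {
    abort("empty ortholog table", class = "crossnorm_validation_error")
  }
  std <- c("gene_id", "x1", "L1", "x2", "L2")
  map <- stats::setNames(as.list(std), std)
  if (!is.null(col_map)) {
    col_map <- as.list(col_map)
    bad <- setdiff(names(col_map), std)
    if (length(bad)) {
      abort(paste0("unknown col_map entries: ", paste(bad, collapse = ", ")),
            class = "crossnorm_format_error")
    }
    map[names(col_map)] <- col_map
  }
  missing_cols <- setdiff(unlist(map), names(raw))
  if (length(missing_cols)) {
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")),
          class = "crossnorm_format_error")
  }
  pool <- function(cols) {
    m <- as.matrix(raw[, cols, drop = FALSE])
    if (!is.numeric(m)) {
      abort("count columns must be numeric", class = "crossnorm_validation_error")
    }
    rowSums(m)
  }
  tab <- tibble(
    gene_id = as.character(raw[[map$gene_id[[1]]]]),
    x1 = pool(unlist(map$x1)),
    L1 = raw[[map$L1[[1]]]],
    x2 = pool(unlist(map$x2)),
    L2 = raw[[map$L2[[1]]]]
  )
  validate_ortholog_table(tab)
}

#' Validate an orthologous table and coerce count/length columns to integer
#'
#' Checks that counts are non-negative whole numbers and lengths are whole
#' numbers of at least one base. Rows failing validation are named in the
#' error. Missing values are allowed here (they mark "unmatched" rows and are
#' removed by [filter_transcripts()]).
#'
#' @param tab A data frame with columns `gene_id`, `x1`, `L1`, `x2`, `L2`.
#' @return The validated tibble with integer count/length columns.
#' @export
validate_ortholog_table <- function(tab) {
  need <- c("gene_id", "x1", "L1", "x2", "L2")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")),
          class = "crossnorm_format_error")
  }
  tab <- as_tibble(tab)
  bad_row <- function(v, test) which(!is.na(v) & !test(v))
  chk <- function(col, test, what) {
    v <- tab[[col]]
    if (!is.numeric(v)) {
      abort(paste0("column ", col, " must be numeric"),
            class = "crossnorm_validation_error")
    }
    rows <- bad_row(v, test)
    if (length(rows)) {
      abort(paste0("column ", col, " has ", what, " in row(s) ",
                   paste(utils::head(rows, 5L), collapse = ", ")),
            class = "crossnorm_validation_error")
    }
  }
  whole <- function(v) abs(v - round(v)) < 1e-8
  chk("x1", function(v) v >= 0 & whole(v), "negative or non-integer counts")
  chk("x2", function(v) v >= 0 & whole(v), "negative or non-integer counts")
  chk("L1", function(v) v >= 1 & whole(v), "lengths below 1 or non-integer")
  chk("L2", function(v) v >= 1 & whole(v), "lengths below 1 or non-integer")
  tab$gene_id <- as.character(tab$gene_id)
  for (col in c("x1", "L1", "x2", "L2")) {
    tab[[col]] <- as.integer(round(tab[[col]]))
  }
  tab
}

#' Sequencing depths of an orthologous table
#'
#' The depth of species `t` is the total number of reads mapped to the
#' orthologous set, `N_t = sum(x_t)` over the retained rows. Recompute after
#' any filtering.
#'
#' @param tab An orthologous table (see [read_ortholog_table()]).
#' @return Named numeric vector `c(N1 = ..., N2 = ...)`.
#' @export
ortholog_depths <- function(tab) {
  c(N1 = sum(as.numeric(tab$x1), na.rm = TRUE),
    N2 = sum(as.numeric(tab$x2), na.rm = TRUE))
}

#' Apply the transcript-filtering rules
#'
#' Removes, in one pass: "unmatched" rows (a missing identifier, count or
#' length field -- structurally incomplete ortholog assignments), duplicated
#' identifiers (all copies are dropped, since a duplicated ortholog mapping is
#' ambiguous in both species), and "unexpressed" rows with zero counts in both
#' species. A gene expressed in exactly one species is a unique gene and is
#' retained: it is testable. The operation is idempotent.
#'
#' @param tab An orthologous table.
#' @param quiet Suppress the per-rule removal message.
#' @return The filtered tibble; depths must be recomputed by the caller via
#'   [ortholog_depths()].
#' @export
filter_transcripts <- function(tab, quiet = FALSE) {
  tab <- validate_ortholog_table(tab)
  unmatched <- is.na(tab$gene_id) | is.na(tab$x1) | is.na(tab$L1) |
    is.na(tab$x2) | is.na(tab$L2)
  dup_ids <- unique(tab$gene_id[duplicated(tab$gene_id) & !is.na(tab$gene_id)])
  duplicated_row <- !is.na(tab$gene_id) & tab$gene_id %in% dup_ids
  unexpressed <- !is.na(tab$x1) & !is.na(tab$x2) & tab$x1 == 0L & tab$x2 == 0L
  keep <- !(unmatched | duplicated_row | unexpressed)
  if (!quiet) {
    inform(sprintf(
      "filter_transcripts: removed %d unmatched, %d duplicated, %d unexpressed; %d of %d rows retained",
      sum(unmatched), sum(duplicated_row & !unmatched),
      sum(unexpressed & !unmatched & !duplicated_row), sum(keep), nrow(tab)))
  }
  out <- tab[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    warn("filter_transcripts: no rows retained")
  }
  out
}

#' Read a conserved orthologous gene list
#'
#' Reads identifiers of orthologous genes assumed non-differentially expressed
#' (the anchor set for normalization, analogous to housekeeping genes within
#' one species), one per line or as the first field of a CSV, and intersects
#' them with the table. Identifiers absent from the table are reported with a
#' warning, not silently dropped.
#'
#' @param path Path to a plain-text or single-column CSV file; `#` comment
#'   lines and blank lines are ignored. A header line is detected and skipped
#'   when its first field does not occur in the table while later ones do.
#' @param tab The orthologous table the identifiers must refer to.
#' @return Character vector of conserved identifiers present in the table.
#' @export
read_conserved_list <- function(path, tab) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "crossnorm_format_error")
  }
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  ids <- vapply(strsplit(lines, "[,\t]"), function(f) trimws(f[[1]]), character(1))
  ids <- ids[nzchar(ids)]
  if (length(ids) > 1L && !(ids[[1]] %in% tab$gene_id) &&
      any(ids[-1] %in% tab$gene_id)) {
    ids <- ids[-1]  # header line
  }
  conserved_set(ids, tab)
}

#' Validate a conserved set against a table
#'
#' @param ids Character vector of gene identifiers.
#' @param tab The orthologous table.
#' @return The de-duplicated subset of `ids` present in `tab$gene_id`; errors
#'   if the intersection is empty (the type-I-error objective is undefined for
#'   an empty anchor set).
#' @export
conserved_set <- function(ids, tab) {
  ids <- unique(as.character(ids))
  present <- ids %in% tab$gene_id
  if (!any(present)) {
    abort("no conserved identifiers found in the table",
          class = "crossnorm_validation_error")
  }
  if (any(!present)) {
    warn(paste0(sum(!present), " conserved identifier(s) absent from the table: ",
                paste(utils::head(ids[!present], 10L), collapse = ", ")))
  }
  ids[present]
}

#' Write an orthologous table (or any result tibble) as delimited text
#'
#' Writes `#`-prefixed provenance comment lines followed by a header row and
#' the data. The delimiter follows the extension (`.csv` for comma, otherwise
#' tab), so `read_ortholog_table()` round-trips the integer fields exactly.
#'
#' @param tab Tibble to write.
#' @param path Output path.
#' @param comments Character vector of provenance lines (written as `# ...`).
#' @param delim Field delimiter; `NULL` guesses from the extension.
#' @return `path`, invisibly.
#' @export
write_ortholog_table <- function(tab, path, comments = character(), delim = NULL) {
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  hdr <- c(sprintf("# written by crossnorm %s",
                   as.character(utils::packageVersion("crossnorm"))),
           paste0("# ", comments))
  writeLines(hdr, path)
  readr::write_delim(tab, path, delim = delim, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  invisible(path)
}
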