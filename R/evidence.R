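#' Load the shrub-versus-tree growth study table
#'
#' Reads a tab-separated table of published comparisons of above-ground
#' growth between shrubs and small trees, one study per row, with an evidence
#' grade for the faster-shrub-growth prediction: `++` (good support), `+`
#' (support), `+/-` (inconclusive) or `-` (against). The packaged fixture
#' transcribes the 14-study literature review shipped with the model.
#'
#' @param path Path to a TSV file. Defaults to the packaged study table.
#' @return A data.frame of class `study_records` with columns `category`,
#'   `region`, `habitat`, `comparison`, `main_result`, `grade`, `reference`,
#'   `footnotes`. An empty file yields a zero-row table.
#' @examples
#' studies <- load_studies()
#' nrow(studies)  # 14
#' @export
load_studies <- function(path = system.file("extdata",
                                            "shrub_tree_growth_studies.tsv",
                                            package = "multistem")) {
  if (!nzchar(path) || !file.exists(path)) stop("study table not found: ", path)
  cols <- c("category", "region", "habitat", "comparison", "main_result",
            "grade", "reference", "footnotes")
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           blank.lines.skip = TRUE)
  if (nrow(raw) == 0) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    class(out) <- c("study_records", "data.frame")
    return(out)
  }
  missing_cols <- setdiff(cols, names(raw))
  if (length(missing_cols) > 0)
    stop("study table is missing columns: ", paste(missing_cols, collapse = ", "))
  out <- raw[, cols]
  valid <- c("++", "+", "+/-", "-")
  bad <- which(!(out$grade %in% valid))
  if (length(bad) > 0)
    stop(sprintf("invalid evidence grade '%s' in row %d (expected ++, +, +/- or -)",
                 out$grade[bad[1]], bad[1]))
  known <- c("disturbed_resprouting", "disturbed_seeders", "lab_experiment",
             "field_experiment", "natural_colonization", "other")
  badcat <- which(!(out$category %in% known))
  if (length(badcat) > 0)
    stop(sprintf("unknown study category '%s' in row %d",
                 out$category[badcat[1]], badcat[1]))
  class(out) <- c("study_records", "data.frame")
  out
}

#' Vote-count tally of the study evidence
#'
#' Counts studies per evidence grade. `supportive_total` is the number with
#' grade `++` or `+`; the four grade counts always sum to `n_studies`.
#'
#' @param records A data.frame from [load_studies()] (or any data.frame with
#'   a validated `grade` column).
#' @return An object of class `support_tally`: a list with `good_support`
#'   (`++`), `support` (`+`), `inconclusive` (`+/-`), `negative` (`-`),
#'   `supportive_total` and `n_studies`.
#' @examples
#' tally_support(load_studies())
#' @export
tally_support <- function(records) {
  stopifnot(is.data.frame(records), "grade" %in% names(records))
  g <- records$grade
  out <- list(
    good_support = sum(g == "++"),
    support = sum(g == "+"),
    inconclusive = sum(g == "+/-"),
    negative = sum(g == "-"),
    supportive_total = sum(g %in% c("++", "+")),
    n_studies = length(g)
  )
  class(out) <- "support_tally"
  out
}

#' @export
print.support_tally <- function(x, ...) {
  cat(sprintf("%d studies: %d supportive (%d with good support), %d inconclusive, %d against\n",
              x$n_studies, x$supportive_total, x$good_support,
              x$inconclusive, x$negative))
  invisible(x)
}
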