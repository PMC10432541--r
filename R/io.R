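GROUP_LEVELS <- c("control", "massed", "distributed")

#' Construct a cohort of per-ROI c-Fos counts
#'
#' A cohort couples a long-format count table with the grid and subregion
#' scheme it was sampled on. One row is one sampled ROI of one animal;
#' ROIs that were not sampled (missing ROIs) are encoded by row absence,
#' never by zero counts -- zero is a legitimate count.
#'
#' @param counts data frame with columns `animal_id`, `group` (one of
#'   "control", "massed", "distributed"), `hemisphere` ("H1"/"H2"),
#'   `section`, `roi`, `count` (non-negative integers).
#' @param grid a `fos_grid` (default canonical grid).
#' @param scheme a `fos_scheme` (default scheme).
#' @return An object of class `fos_cohort`: list with `counts` (canonically
#'   ordered), `grid`, `scheme`.
#' @export
fos_cohort <- function(counts, grid = build_canonical_grid(),
                       scheme = default_subregion_scheme()) {
  required <- c("animal_id", "group", "hemisphere", "section", "roi", "count")
  missing_cols <- setdiff(required, names(counts))
  if (length(missing_cols)) {
    stop("count table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  counts <- as.data.frame(counts)[required]
  counts$animal_id <- as.character(counts$animal_id)
  counts$group <- as.character(counts$group)
  counts$hemisphere <- as.character(counts$hemisphere)
  counts$section <- as.integer(counts$section)
  counts$roi <- as.integer(counts$roi)
  counts$count <- as.integer(counts$count)

  bad <- which(!(counts$group %in% GROUP_LEVELS))
  if (length(bad)) {
    stop("unknown group label(s) at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), ": ",
         paste(unique(counts$group[bad]), collapse = ", "))
  }
  bad <- which(is.na(counts$count) | counts$count < 0L)
  if (length(bad)) {
    stop("negative or missing count at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  validate_coords(counts, grid, what = "count table")
  key <- paste(counts$animal_id, counts$hemisphere, counts$section,
               counts$roi, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicate (animal, hemisphere, section, roi) at row(s) ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  grp <- tapply(counts$group, counts$animal_id,
                function(g) length(unique(g)))
  if (any(grp > 1)) {
    stop("animal(s) with more than one group label: ",
         paste(names(grp)[grp > 1], collapse = ", "))
  }
  counts <- counts[order(counts$animal_id, counts$hemisphere,
                         counts$section, counts$roi), , drop = FALSE]
  rownames(counts) <- NULL
  structure(list(counts = counts, grid = grid, scheme = scheme),
            class = "fos_cohort")
}

#' @export
print.fos_cohort <- function(x, ...) {
  tab <- table(animal_groups(x))
  cat("c-Fos count cohort:", length(unique(x$counts$animal_id)),
      "animals (", paste(names(tab), tab, sep = "=", collapse = ", "),
      "),", nrow(x$counts), "sampled ROI records\n")
  invisible(x)
}

# internal: named vector animal_id -> group, in canonical animal order
animal_groups <- function(cohort) {
  d <- cohort$counts[!duplicated(cohort$counts$animal_id), ]
  stats::setNames(d$group, d$animal_id)
}

# internal: list of per-animal data frames
split_animals <- function(cohort) {
  split(cohort$counts, cohort$counts$animal_id)
}

#' Read / write a cohort count table
#'
#' Plain-text long format with header `animal_id,group,hemisphere,section,
#' roi,count`; comma-separated for `.csv`, tab-separated for `.tsv`/`.txt`.
#' Missing ROIs are rows that are absent. Writing uses canonical row order
#' (animal, hemisphere, section, roi), so write-then-read is the identity
#' and re-writing a freshly read file is byte-identical.
#'
#' @param path file path.
#' @param grid,scheme grid and scheme the table is validated against.
#' @return `read_count_table` returns a `fos_cohort`; `write_count_table`
#'   returns `path` invisibly.
#' @export
read_count_table <- function(path, grid = build_canonical_grid(),
                             scheme = default_subregion_scheme()) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", strip.white = TRUE,
                           stringsAsFactors = FALSE)
  required <- c("animal_id", "group", "hemisphere", "section", "roi", "count")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop(path, ": missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("section", "roi", "count")) {
    v <- suppressWarnings(as.integer(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad)) {
      stop(path, ": non-integer `", col, "` at data row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    raw[[col]] <- v
  }
  fos_cohort(raw, grid = grid, scheme = scheme)
}

#' @param cohort a `fos_cohort`.
#' @rdname read_count_table
#' @export
write_count_table <- function(cohort, path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(cohort$counts, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
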