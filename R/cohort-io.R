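# Delimited-text round trip for cohort datasets.
#
# The cohort file is UTF-8 delimited text (comma by default, tab accepted),
# one header row, one row per patient, empty cells for missing values.
# A companion YAML file maps columns to views and declares categorical
# levels, so a file written by another tool can be read as long as the
# mapping is supplied.

.default_views_yaml <- function() {
  list(views = cohort_views(),
       categorical = list(diagnosis = c("AD", "MCI", "HC"),
                          gender = c("F", "M"),
                          apoe = c("e2e3", "e3e3", "e3e4", "e4e4", "e2e4")))
}

#' Write a cohort to delimited text
#'
#' Numeric cells are serialised with 17 significant digits so that a
#' write/read round trip reproduces every double bit-exactly.
#'
#' @param dataset A `cohort_dataset`.
#' @param path Output file path.
#' @param views_path Path for the companion view-mapping YAML; default
#'   `paste0(path, ".views.yaml")`.
#' @param sep Field delimiter, `","` (default) or `"\t"`.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(dataset, path, views_path = paste0(path, ".views.yaml"),
                         sep = ",") {
  stopifnot(inherits(dataset, "cohort_dataset"))
  d <- dataset$data
  out <- d
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- ""
      out[[j]] <- v
    } else {
      v <- as.character(out[[j]])
      v[is.na(v)] <- ""
      out[[j]] <- v
    }
  }
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  vy <- list(views = dataset$views,
             categorical = .default_views_yaml()$categorical)
  yaml::write_yaml(vy, views_path)
  invisible(path)
}

#' Read a cohort from delimited text
#'
#' @param path Cohort file path.
#' @param views_path View-mapping YAML; when the file does not exist the
#'   package's standard view layout is assumed.
#' @param sep Field delimiter; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @return A `cohort_dataset`.
#' @export
read_cohort <- function(path, views_path = paste0(path, ".views.yaml"),
                        sep = NULL) {
  vy <- if (file.exists(views_path)) yaml::read_yaml(views_path)
        else .default_views_yaml()
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  d <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                  na.strings = "", colClasses = "character",
                  fileEncoding = "UTF-8", check.names = FALSE)
  views <- lapply(vy$views, unlist)
  known <- c("patient_id", unlist(views, use.names = FALSE))
  unknown <- setdiff(unlist(views, use.names = FALSE), names(d))
  if (length(unknown))
    stop("view mapping names columns absent from the file: ",
         paste(unknown, collapse = ", "))
  cat_levels <- lapply(vy$categorical, unlist)
  for (col in names(d)) {
    if (col %in% c("patient_id")) next
    if (col %in% names(cat_levels)) {
      bad <- which(!is.na(d[[col]]) & !(d[[col]] %in% cat_levels[[col]]))
      if (length(bad))
        stop("invalid level '", d[[col]][bad[1]], "' for '", col,
             "' at row ", bad[1])
    } else {
      d[[col]] <- as.numeric(d[[col]])
    }
  }
  structure(list(data = d, views = views, config = NULL, planted = list(),
                 plasma_subset = d$patient_id[
                   if (length(views$plasma_elements) && nrow(d))
                     apply(!is.na(d[, views$plasma_elements, drop = FALSE]),
                           1, any) else logical(0)]),
            class = "cohort_dataset")
}
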