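#' Read a behavioral endpoint table
#'
#' Endpoint tables carry per-subject behavioral read-outs (distance
#' traveled, swim velocity, coiling counts, ...) as tidy rows
#' `subject_id  group  endpoint  value` in a tab-separated file. Each
#' (subject, endpoint) pair may appear at most once and every value must be
#' a finite number; group labels may optionally be checked against a
#' declared set.
#'
#' @param path TSV path with header `subject_id`, `group`, `endpoint`,
#'   `value`.
#' @param groups Optional character vector of allowed group labels.
#' @return A `data.frame` of class `endpoint_table` with the four columns,
#'   `group` as a factor.
#' @export
read_endpoint_table <- function(path, groups = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  req <- c("subject_id", "group", "endpoint", "value")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("schema error: missing column(s) ", paste(miss, collapse = ", "),
         " in ", path)
  as_endpoint_table(df[req], groups = groups, origin = path)
}

#' Validate a data frame as an endpoint table
#'
#' @param df Data frame with columns `subject_id`, `group`, `endpoint`,
#'   `value`.
#' @param groups Optional allowed group labels.
#' @param origin Label used in error messages.
#' @return The validated `endpoint_table`.
#' @export
as_endpoint_table <- function(df, groups = NULL, origin = "input") {
  req <- c("subject_id", "group", "endpoint", "value")
  if (!all(req %in% names(df)))
    stop("schema error: endpoint table needs columns ",
         paste(req, collapse = ", "))
  df <- as.data.frame(df)[req]
  val <- suppressWarnings(as.numeric(df$value))
  bad <- which(!is.finite(val))
  if (length(bad))
    stop("schema error: non-finite or empty value at row ", bad[1],
         " of ", origin)
  df$value <- val
  key <- paste(df$subject_id, df$endpoint, sep = "\r")
  if (anyDuplicated(key))
    stop("duplication error: (subject_id, endpoint) pair '",
         sub("\r", ", ", key[duplicated(key)][1]), "' appears more than once")
  if (!is.null(groups)) {
    extra <- setdiff(unique(df$group), groups)
    if (length(extra))
      stop("unknown group label(s): ", paste(extra, collapse = ", "))
    df$group <- factor(df$group, levels = groups)
  } else {
    df$group <- factor(df$group)
  }
  class(df) <- c("endpoint_table", "data.frame")
  df
}

#' Write an endpoint table as TSV
#'
#' @param tbl An `endpoint_table` (or compatible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_endpoint_table <- function(tbl, path) {
  out <- as.data.frame(tbl)[c("subject_id", "group", "endpoint", "value")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
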