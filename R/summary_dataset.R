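## Summary datasets: the unit of comparison between simulated and observed
## experiments.  Values are indexed by quantity names and split into
## ordinary quantities (means, SEMs, counts; index set I) and p-values
## (index set P), which enter the fitting distance through a five-level
## quantization.

#' Create a summary dataset
#'
#' @param experiment experiment name.
#' @param values named numeric vector of measured quantities.
#' @param is_pvalue named logical vector (same names) marking p-value
#'   entries.
#' @param raw optional list of per-group, per-bird measurement matrices.
#' @return A `summary_dataset` object.
#' @export
summary_dataset <- function(experiment, values, is_pvalue, raw = NULL) {
  stopifnot(length(values) == length(is_pvalue),
            setequal(names(values), names(is_pvalue)))
  is_pvalue <- is_pvalue[names(values)]
  pv <- values[is_pvalue]
  if (any(pv < 0 | pv > 1, na.rm = TRUE)) {
    stop("p-value entries must lie in [0, 1]", call. = FALSE)
  }
  structure(list(experiment = experiment, values = values,
                 is_pvalue = is_pvalue, raw = raw),
            class = "summary_dataset")
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat("<summary_dataset ", x$experiment, "> ",
      sum(!x$is_pvalue), " quantities + ", sum(x$is_pvalue),
      " p-values\n", sep = "")
  invisible(x)
}

#' Tidy a summary dataset into a tibble
#'
#' @param x a [summary_dataset()].
#' @param ... unused.
#' @return A tibble with columns `experiment`, `group`, `quantity_name`,
#'   `value`, `is_pvalue` (group is `NA` for test entries).
#' @method tidy summary_dataset
#' @export
tidy.summary_dataset <- function(x, ...) {
  nm <- names(x$values)
  parts <- strsplit(nm, ":", fixed = TRUE)
  grp <- vapply(parts, function(p) if (length(p) >= 3L) p[1L] else
    NA_character_, "")
  tibble::tibble(experiment = x$experiment, group = grp,
                 quantity_name = nm, value = unname(x$values),
                 is_pvalue = unname(x$is_pvalue))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Write / read summary datasets as CSV
#'
#' The delimited interchange format for observed data: columns
#' `experiment`, `group`, `quantity_name`, `value`, `is_pvalue`.
#'
#' @param x a [summary_dataset()] or list of them.
#' @param path CSV file path.
#' @return `write_summary_csv()`: the path, invisibly;
#'   `read_summary_csv()`: a list of `summary_dataset` objects (a single
#'   object if only one experiment is present).
#' @export
write_summary_csv <- function(x, path) {
  if (inherits(x, "summary_dataset")) x <- list(x)
  df <- dplyr::bind_rows(lapply(x, tidy.summary_dataset))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_csv
#' @export
read_summary_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("experiment", "quantity_name", "value", "is_pvalue")
  if (!all(need %in% names(df))) {
    stop("summary CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(split(df, df$experiment), function(d) {
    summary_dataset(d$experiment[1L],
                    setNames(d$value, d$quantity_name),
                    setNames(as.logical(d$is_pvalue), d$quantity_name))
  })
  if (length(out) == 1L) out[[1L]] else out
}

#' Bar chart of a summary dataset
#'
#' Group means with SEM error bars, faceted p-values excluded.
#'
#' @param object a [summary_dataset()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot summary_dataset
#' @export
autoplot.summary_dataset <- function(object, ...) {
  df <- tidy.summary_dataset(object)
  df <- df[!df$is_pvalue, , drop = FALSE]
  parts <- strsplit(df$quantity_name, ":", fixed = TRUE)
  df$measure <- vapply(parts, `[`, "", 2L)
  df$stat <- vapply(parts, `[`, "", 3L)
  wide <- merge(df[df$stat == "mean", c("group", "measure", "value")],
                df[df$stat == "sem", c("group", "measure", "value")],
                by = c("group", "measure"), suffixes = c("_mean", "_sem"))
  ggplot2::ggplot(wide, ggplot2::aes(x = .data$measure, y = .data$value_mean,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$value_mean - .data$value_sem,
                   ymax = .data$value_mean + .data$value_sem),
      position = ggplot2::position_dodge(width = 0.9), width = 0.25) +
    ggplot2::labs(x = NULL, y = "group mean ± SEM",
                  title = object$experiment) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
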