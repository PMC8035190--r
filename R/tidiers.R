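# broom-style accessors for the two summary classes: tidy() gives one row per
# outcome category, glance() the one-row run-level view.

#' Tidy an amplicon-mode summary
#'
#' @param x An `amplicon_summary`.
#' @param ... Unused.
#' @return Tibble with one row per outcome category: `sample`, `category`,
#'   `rate`.
#' @export
tidy.amplicon_summary <- function(x, ...) {
  tibble(sample = x$sample,
         category = c("precise_edit", "indel", "wild_type",
                      "substitution_other", "ambiguous"),
         rate = c(x$precise_rate, x$indel_rate, x$wild_type_rate,
                  x$substitution_other_rate, x$ambiguous_rate))
}

#' @rdname tidy.amplicon_summary
#' @export
glance.amplicon_summary <- function(x, ...) {
  as_tibble(unclass(x))
}

#' Tidy a UDiTaS summary
#'
#' @param x A `uditas_summary`.
#' @param ... Unused.
#' @return Tibble with one row per category: `sample`, `category`, `umis`,
#'   `ratio`.
#' @export
tidy.uditas_summary <- function(x, ...) {
  tibble(sample = x$sample, category = UDITAS_CATEGORIES,
         umis = vapply(paste0("n_", UDITAS_CATEGORIES), function(cc) x[[cc]], numeric(1)),
         ratio = vapply(paste0("ratio_", UDITAS_CATEGORIES), function(cc) x[[cc]], numeric(1)))
}

#' @rdname tidy.uditas_summary
#' @export
glance.uditas_summary <- function(x, ...) {
  as_tibble(unclass(x))
}
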