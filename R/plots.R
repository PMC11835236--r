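#' Plot intron counts by organism category
#'
#' Bar plot of the number of database introns per organism category,
#' ordered by decreasing count.
#'
#' @param introns Intron database tibble (needs `organism_category`).
#' @return A ggplot object.
#' @export
plot_category_counts <- function(introns) {
  counts <- dplyr::count(introns, .data$organism_category)
  ggplot2::ggplot(counts, ggplot2::aes(
    x = stats::reorder(.data$organism_category, -.data$n), y = .data$n
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "organism category", y = "introns") +
    ggplot2::theme_minimal()
}

#' Plot subtype composition per organism category
#'
#' @param introns Intron database tibble (needs `organism_category` and
#'   `subtype`).
#' @return A ggplot object (stacked bars, one per category).
#' @export
plot_subtypes_by_category <- function(introns) {
  ggplot2::ggplot(introns, ggplot2::aes(
    x = .data$organism_category, fill = .data$subtype
  )) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "organism category", y = "introns", fill = "subtype") +
    ggplot2::theme_minimal()
}

#' Plot intron length distributions, split by HEG presence
#'
#' Density comparison of intron lengths with and without putative homing
#' endonucleases; introns carrying a HEG-sized ORF are expected to be
#' longer.
#'
#' @param introns Intron database tibble (needs `intron_seq`, `n_hegs`).
#' @return A ggplot object.
#' @export
plot_length_by_heg <- function(introns) {
  df <- introns |>
    dplyr::mutate(
      length = nchar(.data$intron_seq),
      heg = ifelse(.data$n_hegs > 0, "with HEG", "without HEG")
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length, fill = .data$heg)) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 30) +
    ggplot2::labs(x = "intron length (nt)", y = "introns", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot structural-element presence frequencies by subtype
#'
#' @param introns Intron database tibble with `subtype` and
#'   `structural_elements` (semicolon list) columns.
#' @return A ggplot object (one facet per subtype).
#' @export
plot_element_frequencies <- function(introns) {
  df <- introns |>
    dplyr::filter(!is.na(.data$subtype)) |>
    dplyr::mutate(element = strsplit(
      ifelse(is.na(.data$structural_elements), "", .data$structural_elements), ";"
    )) |>
    tidyr::unnest_longer("element") |>
    dplyr::mutate(element = sub(":.*$", "", .data$element)) |>
    dplyr::count(.data$subtype, .data$element)
  n_sub <- dplyr::count(
    dplyr::filter(introns, !is.na(.data$subtype)), .data$subtype,
    name = "n_introns"
  )
  df <- dplyr::left_join(df, n_sub, by = "subtype") |>
    dplyr::mutate(frequency = .data$n / .data$n_introns)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$element, y = .data$frequency)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::facet_wrap(~subtype) +
    ggplot2::labs(x = "structural element", y = "frequency of occurrence") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a built database
#'
#' Default visualisation of an `intron_db`: intron counts by organism
#' category.
#'
#' @param object An `intron_db` from [build_db()].
#' @param type One of `"categories"`, `"lengths"`, `"subtypes"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.intron_db <- function(object, type = c("categories", "lengths", "subtypes"), ...) {
  type <- match.arg(type)
  switch(type,
    categories = plot_category_counts(object$introns),
    lengths = plot_length_by_heg(object$introns),
    subtypes = plot_subtypes_by_category(object$introns)
  )
}
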