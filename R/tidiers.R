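# broom-style tidiers and autoplot methods for the package's result objects.

#' Tidy an ancestry report
#'
#' One row per candidate pair, ranked by cumulative coverage.
#'
#' @param x An `ancestry_report`.
#' @param ... Unused.
#' @return A tibble (`species_i`, `species_j`, `percent`), or the singles
#'   table when only one candidate was analysed.
#' @export
tidy.ancestry_report <- function(x, ...) {
  if (is.null(x$pairs)) return(x$singles)
  x$pairs
}

#' @describeIn tidy.ancestry_report One-row summary: target size, candidate
#'   count, best single candidate and the nominated pair.
#' @export
glance.ancestry_report <- function(x, ...) {
  best_single <- x$singles |> arrange(desc(.data$percent)) |> slice(1)
  tibble(target_bp = x$params$target_bp,
         n_candidates = x$params$n_candidates,
         top_species = best_single$species,
         top_percent = best_single$percent,
         winner_i = if (is.null(x$winner)) NA_character_ else x$winner$species_i,
         winner_j = if (is.null(x$winner)) NA_character_ else x$winner$species_j,
         winner_percent = if (is.null(x$winner)) NA_real_ else x$winner$percent)
}

#' Tidy a pair-coverage matrix into long form
#'
#' @param x A `pair_coverage` object.
#' @param ... Unused.
#' @return A tibble `species_i`, `species_j`, `percent` covering the full
#'   (symmetric) matrix including the diagonal.
#' @export
tidy.pair_coverage <- function(x, ...) {
  as_tibble(as.data.frame(as.table(x$values),
                          responseName = "percent")) |>
    rename(species_i = "Var1", species_j = "Var2") |>
    mutate(species_i = as.character(.data$species_i),
           species_j = as.character(.data$species_j))
}

#' Heatmap of the pairwise cumulative coverage matrix
#'
#' @param object A `pair_coverage` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pair_coverage <- function(object, ...) {
  d <- tidy.pair_coverage(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$species_i, .data$species_j,
                                  fill = .data$percent)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$percent)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac",
                                 name = "% target\ncovered") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Cumulative pairwise coverage of the target genome") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.pair_coverage
#' @export
autoplot.ancestry_report <- function(object, ...) {
  if (is.null(object$matrix)) abort("no pair matrix in this report")
  autoplot.pair_coverage(object$matrix, ...)
}

#' Tidy a genome-size estimate
#'
#' @param x A `genome_size_estimate`.
#' @param ... Unused.
#' @return A two-column tibble of the formula's terms (`N`, `L`, `K`, `B`,
#'   `D`, `G`).
#' @export
tidy.genome_size_estimate <- function(x, ...) {
  tibble(term = c("N", "L", "K", "B", "D", "G"),
         value = c(x$N, x$L, x$K, x$B, x$D, x$G))
}

#' @describeIn tidy.genome_size_estimate One-row summary.
#' @export
glance.genome_size_estimate <- function(x, ...) {
  tibble(G = x$G, G_bases = x$G_bases, D = x$D, B = x$B, N = x$N, L = x$L,
         K = x$K, cutoff = x$cutoff)
}

#' k-mer spectrum plot with the detected depth peak
#'
#' @param object A `genome_size_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.genome_size_estimate <- function(object, ...) {
  h <- object$histogram
  ggplot2::ggplot(h, ggplot2::aes(.data$multiplicity, .data$count)) +
    ggplot2::geom_col(width = 1, fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$D, colour = "#b2182b",
                        linetype = 2) +
    ggplot2::annotate("text", x = object$D, y = max(h$count),
                      label = paste0("D = ", object$D), hjust = -0.1,
                      vjust = 1, colour = "#b2182b") +
    ggplot2::labs(x = "k-mer multiplicity", y = "distinct k-mers",
                  title = sprintf("%d-mer spectrum; G = %.0f bases",
                                  object$K, object$G)) +
    ggplot2::theme_minimal()
}
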