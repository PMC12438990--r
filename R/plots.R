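#' Fixed state color palette
#'
#' Reads the shipped palette file mapping each of the 21 alphabet states to
#' a fixed color, so plots are comparable across runs.
#'
#' @return Named character vector of colors.
#' @export
default_state_palette <- function() {
  path <- system.file("extdata", "state_palette.csv",
                      package = "diagtraj", mustWork = TRUE)
  pal <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  setNames(pal$color, pal$state)
}

#' Sequence frequency plot
#'
#' Renders a stratum's distinct displayed sequences as stacked horizontal
#' bands: one band per sequence, band height proportional to its count, the
#' x axis running over the follow-up periods, each cell colored by state.
#' Suppressed sequences are never drawn — if everything in the stratum is
#' suppressed, a placeholder notice is rendered instead. Rendering is
#' metadata-first: alongside the ggplot, the returned object carries a
#' machine-readable description of every band drawn, so the suppression and
#' proportionality contracts are testable without image diffing.
#'
#' @param freq Output of [sequence_frequency_table()].
#' @param palette Named color vector (default [default_state_palette()]).
#' @param title Optional plot title.
#' @return Object of class `seq_plot`: list with `plot` (ggplot) and `meta`
#'   (list: `kind`, `placeholder`, `n_displayed`, `n_total`,
#'   `suppressed_count`, and a `bands` tibble with `sequence`, `count`,
#'   `height_fraction`).
#' @export
plot_sequence_frequency <- function(freq, palette = default_state_palette(),
                                    title = NULL) {
  shown <- freq[!freq$suppressed, ]
  suppressed_count <- sum(freq$count[freq$suppressed])
  total <- sum(freq$count)
  if (nrow(shown) == 0) {
    p <- ggplot2::ggplot() +
      ggplot2::annotate("text", x = 0, y = 0,
                        label = "All sequences suppressed (< 5 persons each)") +
      ggplot2::theme_void()
    meta <- list(kind = "sequence_frequency", placeholder = TRUE,
                 n_displayed = 0L, n_total = total,
                 suppressed_count = suppressed_count,
                 bands = tibble::tibble(sequence = character(0),
                                        count = integer(0),
                                        height_fraction = numeric(0)))
    return(structure(list(plot = p, meta = meta), class = "seq_plot"))
  }
  shown_total <- sum(shown$count)
  bands <- tibble::tibble(
    sequence = shown$sequence,
    count = shown$count,
    height_fraction = shown$count / shown_total
  )
  # cell rectangles: band i, period j
  states <- strsplit(shown$sequence, "-", fixed = TRUE)
  np <- length(states[[1]])
  y1 <- cumsum(bands$height_fraction)
  y0 <- y1 - bands$height_fraction
  cells <- dplyr::bind_rows(lapply(seq_along(states), function(i) {
    tibble::tibble(period = seq_len(np), state = states[[i]],
                   ymin = y0[i], ymax = y1[i])
  }))
  p <- ggplot2::ggplot(cells) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$period - 1, xmax = .data$period,
                                    ymin = .data$ymin, ymax = .data$ymax,
                                    fill = .data$state),
                       color = "white", linewidth = 0.1) +
    ggplot2::scale_fill_manual(values = palette, name = "State") +
    ggplot2::scale_x_continuous(breaks = seq_len(np) - 0.5,
                                labels = seq_len(np)) +
    ggplot2::labs(x = "12-month period", y = "Share of displayed sequences",
                  title = title) +
    ggplot2::theme_minimal()
  meta <- list(kind = "sequence_frequency", placeholder = FALSE,
               n_displayed = nrow(shown), n_total = total,
               suppressed_count = suppressed_count, bands = bands)
  structure(list(plot = p, meta = meta), class = "seq_plot")
}

#' Entropy bar chart
#'
#' Mean normalized entropy per stratum, suppressed strata omitted from the
#' drawing (their existence is recorded in the metadata).
#'
#' @param summary Output of [summarize_entropy()].
#' @param title Optional title.
#' @return A `seq_plot` object (see [plot_sequence_frequency()]).
#' @export
plot_entropy_bars <- function(summary, title = NULL) {
  by_cols <- setdiff(names(summary), c("n", "mean_h", "sd_h", "suppressed"))
  shown <- summary[!summary$suppressed, ]
  shown$stratum <- do.call(paste, c(lapply(by_cols, function(b) shown[[b]]),
                                    sep = "/"))
  fill_col <- if ("sex" %in% by_cols) "sex" else NULL
  p <- ggplot2::ggplot(shown,
                       ggplot2::aes(x = .data$stratum, y = .data$mean_h)) +
    (if (!is.null(fill_col)) {
      ggplot2::geom_col(ggplot2::aes(fill = .data$sex), position = "dodge")
    } else ggplot2::geom_col()) +
    ggplot2::labs(x = NULL, y = "Mean normalized entropy", title = title) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  meta <- list(kind = "entropy_bars", placeholder = nrow(shown) == 0,
               n_displayed = nrow(shown),
               n_suppressed_strata = sum(summary$suppressed),
               bars = shown[c(by_cols, "n", "mean_h")])
  structure(list(plot = p, meta = meta), class = "seq_plot")
}

#' @export
print.seq_plot <- function(x, ...) {
  print(x$plot)
  invisible(x)
}

#' Save a plot with its metadata sidecar
#'
#' Writes the image (format from the file extension, png or svg via
#' [ggplot2::ggsave()]) and a `<path>.meta.json` sidecar describing exactly
#' what was drawn.
#'
#' @param x A `seq_plot`.
#' @param path Image output path.
#' @param width,height Size in inches.
#' @return `path`, invisibly.
#' @export
save_seq_plot <- function(x, path, width = 8, height = 5) {
  stopifnot(inherits(x, "seq_plot"))
  ggplot2::ggsave(path, x$plot, width = width, height = height)
  jsonlite::write_json(x$meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
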