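#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the fork events of an assembly
#'
#' @param x an `assembly_report`.
#' @param ... unused.
#' @return tibble: one row per fork with position, branch count,
#'   resolution, committed bases, and the reason when AMBIGUOUS.
#' @export
tidy.assembly_report <- function(x, ...) {
  if (length(x$forks) == 0) {
    return(tibble(position = integer(), n_branches = integer(),
                  resolution = character(), committed = integer(),
                  reason = character()))
  }
  dplyr::bind_rows(lapply(x$forks, function(f) {
    tibble(position = f$position, n_branches = length(f$successors),
           resolution = f$resolution,
           committed = if (is.null(f$commit)) 0L else nchar(f$commit),
           reason = f$reason)
  }))
}

#' One-row summary of an assembly
#'
#' @param x an `assembly_report`.
#' @param ... unused.
#' @return one-row tibble: status, circularized, length, fork counts, and
#'   the three validation outcomes.
#' @export
glance.assembly_report <- function(x, ...) {
  val <- x$validation
  getv <- function(check) {
    if (is.null(val)) NA else val$pass[val$check == check]
  }
  tibble(
    status = x$status,
    circularized = x$circularized,
    length = if (x$circularized) x$assembled$length else NA_integer_,
    n_forks = x$n_forks,
    n_ambiguous = sum(vapply(x$forks, function(f)
      identical(f$resolution, "AMBIGUOUS"), TRUE)),
    mito_kmer_threshold = x$threshold,
    long_read_check = getv("long_read_consistency"),
    amplicon_check = getv("amplicon_length_consistency"),
    coverage_check = getv("coverage_continuity")
  )
}

#' @export
tidy.numt_hits <- function(x, ...) as_tibble(x)

#' @export
glance.numt_report <- function(x, ...) as_tibble(x)

#' @export
tidy.parsimony_stats <- function(x, ...) as_tibble(x)

#' Plot a variant-density track
#'
#' @param object a [block_density()] track.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.density_track <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                       y = .data$count)) +
    ggplot2::geom_col(width = attr(object, "window"), fill = "grey25") +
    ggplot2::labs(x = "position (bp)",
                  y = sprintf("variants per %d bp", attr(object, "window"))) +
    ggplot2::theme_minimal()
}

#' Plot a k-mer coverage profile
#'
#' @param object a [map_kmer_coverage()] profile.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.coverage_profile <- function(object, ...) {
  df <- tibble(pos = seq_along(object$coverage) - 1L,
               coverage = object$coverage)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$coverage)) +
    ggplot2::geom_step(color = "grey25") +
    ggplot2::labs(x = "position (bp)",
                  y = sprintf("%d-mer count at start", object$k),
                  title = object$reference_id) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
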