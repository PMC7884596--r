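# tidy()/glance() methods and plotting helpers.

#' Tidy read placements of an assembly
#' @param x An `assembly_state`.
#' @param ... Unused.
#' @return The placements tibble (`read_id`, `contig`, `offset`, `strand`,
#'   `ambiguous`).
#' @export
tidy.assembly_state <- function(x, ...) {
  as_tibble(x$placements)
}

#' One-row assembly summary
#' @param x An `assembly_state`.
#' @param ... Unused.
#' @return Tibble with `n_contigs`, `n_recruited`, `total_length`,
#'   `iterations`, `converged`.
#' @export
glance.assembly_state <- function(x, ...) {
  tibble(n_contigs = length(x$contigs),
         n_recruited = length(x$recruited),
         total_length = sum(vapply(x$contigs, function(cc)
           nchar(cc$consensus), 0)),
         iterations = x$iteration,
         converged = x$converged)
}

#' Tidy a mass report
#' @param x A `mass_report`.
#' @param ... Unused.
#' @return The per-decamer breakdown tibble.
#' @export
tidy.mass_report <- function(x, ...) x$breakdown

#' One-row mass report summary
#' @param x A `mass_report`.
#' @param ... Unused.
#' @export
glance.mass_report <- function(x, ...) {
  tibble(total_mass_kda = x$total_mass_kda,
         binding_sites = x$binding_sites,
         extra_mass_kda = x$extra_mass_kda)
}

#' Plot a hydropathy profile
#'
#' Windowed Kyte-Doolittle hydropathy along the protein; hydrophilic
#' stretches (e.g. the His/Asp-rich FU-g insertion) dip far below zero.
#'
#' @param object A [hydropathy_profile()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hydropathy_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position,
                                       y = .data$hydropathy)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line(colour = "#2166AC") +
    ggplot2::labs(x = "residue position",
                  y = sprintf("mean KD hydropathy (window %d)",
                              attr(object, "window"))) +
    ggplot2::theme_minimal()
}

#' Plot an identity-window scan
#'
#' @param object A [scan_identity_windows()] report.
#' @param ... Unused.
#' @return A ggplot with the flag threshold marked.
#' @export
autoplot.identity_window_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$start_a,
                                       y = .data$identity)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_point(data = object[object$flagged, , drop = FALSE],
                        colour = "#B2182B", size = 1) +
    ggplot2::labs(x = "window start (sequence A)",
                  y = "gapless window identity") +
    ggplot2::theme_minimal()
}

#' Plot per-contig coverage of an assembly
#'
#' @param object An `assembly_state`.
#' @param ... Unused.
#' @return A ggplot, one facet per contig.
#' @export
autoplot.assembly_state <- function(object, ...) {
  df <- dplyr::bind_rows(lapply(object$contigs, function(cc)
    tibble(contig = cc$id, position = seq_along(cc$coverage),
           coverage = cc$coverage)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$coverage)) +
    ggplot2::geom_area(fill = "#4393C3", alpha = 0.7) +
    ggplot2::facet_wrap(~contig, scales = "free_x", ncol = 1) +
    ggplot2::labs(x = "contig position (nt)", y = "read depth") +
    ggplot2::theme_minimal()
}
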