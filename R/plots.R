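# ggplot2 visualisations of reliability reports and torsion measurements.

#' Plot a reliability report
#'
#' `type = "modality"` scatters MRI against CT per reader (modality
#' agreement), `type = "reader"` scatters reader 2 against reader 1 per
#' modality, and `type = "bland_altman"` shows pooled MRI - CT differences
#' against pair means with the bias and 95% limits of agreement.
#'
#' @param object A `fem_reliability` object... but the plot needs the raw
#'   table, so pass it via `table` (e.g. the same table given to
#'   [build_report()]).
#' @param table The measurement table the report was built from.
#' @param type One of `"modality"`, `"reader"`, `"bland_altman"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fem_reliability <- function(object, table, type = c("modality", "reader", "bland_altman"),
                                     ...) {
  type <- match.arg(type)
  tb <- as_measurement_table(table)
  if (type == "modality") {
    w <- tidyr::pivot_wider(tb, id_cols = c("subject", "side", "reader"),
                            names_from = "modality", values_from = "angle_deg")
    p <- ggplot2::ggplot(w, ggplot2::aes(x = .data$CT, y = .data$MRI)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
      ggplot2::geom_point(alpha = 0.8) +
      ggplot2::facet_wrap(~ paste("reader", .data$reader)) +
      ggplot2::labs(x = "CT torsion (deg)", y = "MRI torsion (deg)",
                    title = "Inter-modality agreement")
  } else if (type == "reader") {
    w <- tidyr::pivot_wider(tb, id_cols = c("subject", "side", "modality"),
                            names_from = "reader", values_from = "angle_deg",
                            names_prefix = "reader_")
    p <- ggplot2::ggplot(w, ggplot2::aes(x = .data$reader_1, y = .data$reader_2)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
      ggplot2::geom_point(alpha = 0.8) +
      ggplot2::facet_wrap(~ .data$modality) +
      ggplot2::labs(x = "reader 1 torsion (deg)", y = "reader 2 torsion (deg)",
                    title = "Inter-reader agreement")
  } else {
    w <- tidyr::pivot_wider(tb, id_cols = c("subject", "side", "reader"),
                            names_from = "modality", values_from = "angle_deg")
    w <- w[complete.cases(w[c("CT", "MRI")]), ]
    w$mean_pair <- (w$CT + w$MRI) / 2
    w$diff_pair <- w$MRI - w$CT
    d <- object$difference
    p <- ggplot2::ggplot(w, ggplot2::aes(x = .data$mean_pair, y = .data$diff_pair)) +
      ggplot2::geom_hline(yintercept = d$mean_diff, colour = "steelblue") +
      ggplot2::geom_hline(yintercept = c(d$loa_low, d$loa_high),
                          linetype = 2, colour = "steelblue") +
      ggplot2::geom_point(ggplot2::aes(shape = .data$reader), alpha = 0.8) +
      ggplot2::labs(x = "mean of CT and MRI (deg)", y = "MRI - CT (deg)",
                    title = "Bland-Altman: modality agreement")
  }
  p + ggplot2::theme_minimal()
}

#' Axial-projection diagram of a torsion measurement
#'
#' Projects the neck axis, the condylar tangent and the neck cross-section
#' boundary onto the plane perpendicular to the anatomical axis, the plane in
#' which the torsion angle is defined.
#'
#' @param object A `fem_torsion` object from [measure_torsion()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fem_torsion <- function(object, ...) {
  a <- object$anatomical_axis$direction
  e1 <- unitize(if (abs(a[1]) < 0.9) cross3(a, c(1, 0, 0)) else cross3(a, c(0, 1, 0)))
  e2 <- cross3(a, e1)
  proj2 <- function(P) {
    P <- sweep(matrix(P, ncol = 3), 2, object$anatomical_axis$point)
    cbind(u = P %*% e1, v = P %*% e2)
  }
  seg <- function(p, d, len, label) {
    ends <- rbind(p - len * d, p + len * d)
    uv <- proj2(ends)
    tibble::tibble(u = uv[1, 1], v = uv[1, 2], uend = uv[2, 1], vend = uv[2, 2],
                   axis = label)
  }
  segs <- dplyr::bind_rows(
    seg(object$neck_axis$point, object$neck_axis$direction, 60, "neck axis"),
    seg(object$condylar_tangent$point, object$condylar_tangent$direction, 40,
        "condylar tangent"))
  li <- object$neck_section$selected_loop %||% object$neck_section$largest_loop
  loop_uv <- proj2(object$neck_section$loops[[li]])
  loop_df <- tibble::tibble(u = loop_uv[, 1], v = loop_uv[, 2])
  ggplot2::ggplot() +
    ggplot2::geom_polygon(data = loop_df, ggplot2::aes(x = .data$u, y = .data$v),
                          fill = "grey85", colour = "grey60") +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$u, y = .data$v,
                                       xend = .data$uend, yend = .data$vend,
                                       colour = .data$axis),
                          linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s femur: torsion %.1f deg", object$side,
                                  object$angle_deg),
                  x = "in-plane u (mm)", y = "in-plane v (mm)") +
    ggplot2::theme_minimal()
}
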