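# Figure rendering (ggplot2). Figures are regenerable artifacts; tests
# inspect structural metadata of the returned plot objects, not pixels.

phi_plot_range <- function(analysis, margin = 0.6) {
  r <- range(analysis$points$phi)
  span <- max(diff(r), 1)
  c(r[1] - margin * span, r[2] + margin * span)
}

#' Render a sense-making landscape figure
#'
#' Draws `F(phi)` with the stationary points marked, state labels, the
#' automatic-attention marker, bias arrows between the alert-protection and
#' trust-explore states, and a zero-curiosity annotation for the
#' catastrophizing landscape. In overlay mode a list of analyses is drawn
#' as one curve each (e.g. `T > T0`, `T = T0`, `T < T0`).
#'
#' @param analysis A `"landscape_analysis"`, or a list of them for overlay
#'   mode.
#' @param path Optional output file (png/svg/pdf via [ggplot2::ggsave()]).
#' @param show_attention Draw the automatic-attention point. Default TRUE.
#' @param width,height Device size in inches for `path` output.
#' @return The ggplot object, invisibly.
#' @export
render_landscape_figure <- function(analysis, path = NULL,
                                    show_attention = TRUE,
                                    width = 6, height = 4.5) {
  overlay <- !inherits(analysis, "landscape_analysis")
  analyses <- if (overlay) analysis else list(analysis)
  stopifnot(all(vapply(analyses, inherits, logical(1),
                       "landscape_analysis")))
  rng <- range(unlist(lapply(analyses, phi_plot_range)))
  grid <- seq(rng[1], rng[2], length.out = 501)
  curves <- do.call(rbind, lapply(seq_along(analyses), function(i) {
    a <- analyses[[i]]
    data.frame(curve = sprintf("%d: %s", i, a$regime), phi = grid,
               F = sense_making_energy(grid, a$params))
  }))
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = phi, y = F,
                                            colour = curve)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = expression(phi ~ "(perception)"),
                  y = expression(F(phi) == -S),
                  colour = NULL,
                  title = if (!overlay) analyses[[1]]$regime else
                    "Sense-making landscapes") +
    ggplot2::theme_minimal()
  if (!overlay) p <- p + ggplot2::guides(colour = "none")

  if (!overlay) {
    a <- analyses[[1]]
    w <- a$wells
    role_lab <- vapply(w$phi, function(x) {
      if (abs(x) <= a$tol) "neutral" else
        if (x < 0) "alert-protection" else "trust-explore"
    }, character(1))
    p <- p +
      ggplot2::geom_point(data = data.frame(phi = w$phi, F = w$F_value),
                          ggplot2::aes(x = phi, y = F),
                          inherit.aes = FALSE, size = 2) +
      ggplot2::geom_text(data = data.frame(phi = w$phi, F = w$F_value,
                                           lab = role_lab),
                         ggplot2::aes(x = phi, y = F,
                                      label = lab),
                         inherit.aes = FALSE, vjust = 1.8, size = 3)
    if (show_attention) {
      att <- automatic_attention(a)
      p <- p + ggplot2::geom_point(
        data = data.frame(phi = att$phi, F = att$F_value),
        ggplot2::aes(x = phi, y = F),
        inherit.aes = FALSE, shape = 21, fill = "black", size = 4)
    }
    if (!is.null(a$alert_protection) && !is.null(a$trust_explore)) {
      arr <- data.frame(x = a$alert_protection$phi,
                        xend = a$trust_explore$phi,
                        y = a$alert_protection$F_value,
                        yend = a$trust_explore$F_value)
      p <- p + ggplot2::geom_segment(
        data = arr, ggplot2::aes(x = x, xend = xend,
                                 y = y, yend = yend),
        inherit.aes = FALSE, linetype = "dotted",
        arrow = grid::arrow(length = grid::unit(0.15, "cm"),
                            ends = "both"))
    }
    if (a$regime == "CATASTROPHIZING" && !is.null(a$neutral)) {
      p <- p + ggplot2::annotate("text", x = a$neutral$phi,
                                 y = a$neutral$F_value,
                                 label = "no curiosity: F = 0",
                                 vjust = -1, size = 3)
    }
  }
  if (!is.null(path))
    ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
  invisible(p)
}

#' Render a hysteresis-loop figure
#'
#' Draws the up- and down-swept branches, the unstable middle branch dashed
#' (it does not belong to the loop), jumps as vertical arrows, vertical
#' guides at the spinodal fields and horizontal guides at the default-mode
#' perceptions.
#'
#' @param loop A `"hysteresis_loop"`.
#' @param path Optional output file.
#' @param width,height Device size in inches for `path` output.
#' @return The ggplot object, invisibly.
#' @export
render_hysteresis_figure <- function(loop, path = NULL, width = 6,
                                     height = 4.5) {
  stopifnot(inherits(loop, "hysteresis_loop"))
  br <- rbind(
    data.frame(branch = "up sweep", h = loop$up_branch$h_values,
               phi = loop$up_branch$phi_values),
    data.frame(branch = "down sweep", h = loop$down_branch$h_values,
               phi = loop$down_branch$phi_values))
  p <- ggplot2::ggplot(br, ggplot2::aes(x = h, y = phi,
                                        colour = branch)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = expression(h[ext] ~ "(expert information)"),
                  y = expression(phi ~ "(perception)"), colour = NULL,
                  title = "Perception vs expert information") +
    ggplot2::theme_minimal()

  if (!is.null(loop$spinodals)) {
    sp <- loop$spinodals
    un <- unstable_branch(loop$params,
                          seq(sp$h_down, sp$h_up, length.out = 101))
    if (nrow(un))
      p <- p + ggplot2::geom_line(
        data = data.frame(h = un$h, phi = un$phi),
        ggplot2::aes(x = h, y = phi), inherit.aes = FALSE,
        linetype = "dashed", colour = "grey40")
    p <- p + ggplot2::geom_vline(xintercept = c(sp$h_down, sp$h_up),
                                 linetype = "dotted", colour = "grey55")
    jumps <- do.call(rbind, lapply(
      list(loop$up_branch, loop$down_branch), function(b) {
        j <- b$jump_index
        if (is.null(j)) return(NULL)
        data.frame(h = b$h_values[j], y = b$phi_values[j - 1],
                   yend = b$phi_values[j])
      }))
    if (!is.null(jumps))
      p <- p + ggplot2::geom_segment(
        data = jumps,
        ggplot2::aes(x = h, xend = h, y = y,
                     yend = yend),
        inherit.aes = FALSE,
        arrow = grid::arrow(length = grid::unit(0.18, "cm")))
  }
  dm <- loop$dm_plateaus[!is.na(loop$dm_plateaus)]
  if (length(dm))
    p <- p + ggplot2::geom_hline(yintercept = as.numeric(dm),
                                 linetype = "dotdash", colour = "grey70")
  if (!is.null(path))
    ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
  invisible(p)
}
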