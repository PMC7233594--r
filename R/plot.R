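# Convenience polar visualization of trunk angular deviation by initial
# hemisphere of visual field defect. The SVG writer renders by hand so the
# report bytes are identical across runs; eyes with severe shift (index 1)
# carry no measurable angle and are omitted.

polar_xy <- function(alpha_deg, radius) {
  # nasal 0 deg at the right, superior positive upward
  a <- alpha_deg * pi / 180
  list(x = radius * cos(a), y = radius * sin(a))
}

hemi_colour <- function(h) {
  c(superior = "#c62828", inferior = "#1565c0", bi = "#2e7d32",
    none = "#9e9e9e", undetermined = "#9e9e9e")[h]
}

#' Write a polar scatter of trunk deviation by onset hemisphere (SVG)
#'
#' Each eye with a measurable trunk is drawn as a ray at its angular
#' deviation, with length equal to its shift index; colour encodes the
#' initial hemisphere of visual field defect.
#'
#' @param cohort Cohort table with `alpha_deg`, `shift_index`,
#'   `initial_hemisphere`.
#' @param path Output SVG path.
#' @return Invisibly, `path`.
#' @export
write_polar_svg <- function(cohort, path) {
  d <- cohort[!is.na(cohort$alpha_deg), , drop = FALSE]
  size <- 420; cx <- size / 2; cy <- size / 2; r0 <- 170
  fmt <- function(x) sprintf("%.2f", x)
  lines <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
            size, size),
    sprintf('<rect width="%d" height="%d" fill="white"/>', size, size),
    sprintf('<circle cx="%d" cy="%d" r="%d" fill="none" stroke="#bbbbbb"/>',
            cx, cy, r0),
    sprintf('<circle cx="%d" cy="%d" r="%d" fill="none" stroke="#dddddd"/>',
            cx, cy, r0 %/% 2),
    sprintf('<line x1="%d" y1="%d" x2="%d" y2="%d" stroke="#bbbbbb"/>',
            cx - r0, cy, cx + r0, cy),
    sprintf('<line x1="%d" y1="%d" x2="%d" y2="%d" stroke="#bbbbbb"/>',
            cx, cy - r0, cx, cy + r0),
    sprintf('<text x="%d" y="%d" font-size="12">nasal 0°</text>',
            cx + r0 + 4, cy + 4),
    sprintf('<text x="%d" y="%d" font-size="12">superior +90°</text>',
            cx - 35, cy - r0 - 6))
  if (nrow(d)) {
    xy <- polar_xy(d$alpha_deg, d$shift_index * r0)
    lines <- c(lines, sprintf(
      '<line x1="%d" y1="%d" x2="%s" y2="%s" stroke="%s" stroke-width="1.5"/>',
      cx, cy, fmt(cx + xy$x), fmt(cy - xy$y),
      hemi_colour(d$initial_hemisphere)))
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, path)
  invisible(path)
}

#' Polar plot of trunk deviation by onset hemisphere
#'
#' Base-graphics version of [write_polar_svg()] for interactive use.
#'
#' @param x An `lcshift_report`.
#' @param ... Ignored.
#' @return Invisibly, `x`.
#' @export
plot.lcshift_report <- function(x, ...) {
  d <- x$cohort[!is.na(x$cohort$alpha_deg), , drop = FALSE]
  graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
                 xlab = "", ylab = "", axes = FALSE,
                 main = "Vascular trunk deviation by initial hemisphere")
  th <- seq(0, 2 * pi, length.out = 181)
  graphics::lines(cos(th), sin(th), col = "grey70")
  graphics::segments(-1, 0, 1, 0, col = "grey80")
  graphics::segments(0, -1, 0, 1, col = "grey80")
  if (nrow(d)) {
    xy <- polar_xy(d$alpha_deg, d$shift_index)
    graphics::segments(0, 0, xy$x, xy$y,
                       col = hemi_colour(d$initial_hemisphere))
  }
  graphics::legend("topleft", bty = "n", lty = 1,
                   col = hemi_colour(c("superior", "inferior", "bi")),
                   legend = c("superior onset", "inferior onset",
                              "bi-hemispheric"))
  graphics::text(1.05, 0, "nasal 0°", adj = 0, cex = 0.8)
  invisible(x)
}
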