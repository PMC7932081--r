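# Compositional displays: barycentric (ternary) coordinates, the
# ternary-balance colour blend used for choropleth maps, and trajectory
# fan plots. The three-component map composition is (any-method use,
# unmet need, no need): modern and traditional methods are merged into
# "use" for display.

# reference triangle: component 1 at the top vertex, components 2 and 3
# at the bottom-left and bottom-right vertices of an equilateral triangle
TERNARY_VERTICES <- matrix(c(0.5, sqrt(3) / 2,
                             0, 0,
                             1, 0),
                           ncol = 2, byrow = TRUE,
                           dimnames = list(c("v1", "v2", "v3"),
                                           c("x", "y")))

check_composition3 <- function(comp, tol = 0.01) {
  if (length(comp) != 3) stop("need exactly 3 components", call. = FALSE)
  if (any(comp < 0)) stop("negative component", call. = FALSE)
  if (abs(sum(comp) - 100) > tol) {
    stop("components must sum to 100 (±", tol, ")", call. = FALSE)
  }
  comp / 100
}

#' Barycentric coordinates of a three-part composition
#'
#' Maps a composition (components in percent, summing to 100) into the
#' reference triangle: each pure component maps to its vertex, the
#' balanced composition (33 1/3 each) to the centroid.
#'
#' @param composition3 numeric length-3 vector in percent.
#' @param vertices optional 3 x 2 matrix of vertex coordinates.
#' @return named numeric `c(x, y)`.
#' @export
ternary_coordinates <- function(composition3,
                                vertices = TERNARY_VERTICES) {
  w <- check_composition3(composition3)
  xy <- as.vector(t(vertices) %*% w)
  c(x = xy[1], y = xy[2])
}

#' Ternary-balance colour blend
#'
#' Blends three primary colours in the proportions of the composition:
#' a country with 65% use, 25% unmet need and 10% no need is coloured by
#' mixing the use, unmet and no-need primaries with weights 0.65, 0.25
#' and 0.10. Mixing happens in linear RGB and the result is
#' gamma-encoded, so a pure component returns its primary exactly.
#' Default primaries: green for contraceptive use, pink for unmet need,
#' blue for no need.
#'
#' @param composition3 numeric length-3 vector in percent (use, unmet,
#'   no need).
#' @param primaries character length-3 of colours.
#' @return hex colour string.
#' @export
ternary_color <- function(composition3,
                          primaries = c(use = "#25A244",
                                        unmet = "#E05780",
                                        no_need = "#3A86FF")) {
  w <- check_composition3(composition3)
  srgb <- grDevices::col2rgb(primaries) / 255
  lin <- ifelse(srgb <= 0.04045, srgb / 12.92,
                ((srgb + 0.055) / 1.055)^2.4)
  mix <- as.vector(lin %*% w)
  enc <- ifelse(mix <= 0.0031308, mix * 12.92,
                1.055 * mix^(1 / 2.4) - 0.055)
  enc <- pmin(pmax(enc, 0), 1)
  grDevices::rgb(enc[1], enc[2], enc[3])
}

#' Trajectory fan plot
#'
#' Writes a figure for one location, indicator and marital group: the
#' posterior median as a solid line, the 80% interval as dashed lines
#' (omitted with a notice when the records carry no 80% bounds), the 95%
#' interval as a grey ribbon, and source observations as points coloured
#' by source type when provided.
#'
#' @param records estimate records for a single location, indicator and
#'   marital group, with columns `year`, `median`, `ui_low`, `ui_high`
#'   and optionally `pi80_low`, `pi80_high`.
#' @param file output file path (PNG).
#' @param observations optional `fp_observations` subset to overlay; the
#'   column matching the indicator is plotted.
#' @param obs_column which observation column to overlay (default
#'   `"p_any"`).
#' @param main plot title.
#' @return invisibly, the file path.
#' @export
trajectory_plot <- function(records, file, observations = NULL,
                            obs_column = "p_any", main = "") {
  if (!nrow(records)) stop("empty records", call. = FALSE)
  records <- records[order(records$year), ]
  grDevices::png(file, width = 900, height = 600)
  on.exit(grDevices::dev.off(), add = TRUE)
  ylim <- range(records$ui_low, records$ui_high, na.rm = TRUE)
  graphics::plot(records$year, records$median, type = "n", ylim = ylim,
                 xlab = "year", ylab = unique(records$indicator)[1],
                 main = main)
  graphics::polygon(c(records$year, rev(records$year)),
                    c(records$ui_low, rev(records$ui_high)),
                    col = "grey85", border = NA)
  has80 <- all(c("pi80_low", "pi80_high") %in% names(records)) &&
    !all(is.na(records$pi80_low))
  if (has80) {
    graphics::lines(records$year, records$pi80_low, lty = 2)
    graphics::lines(records$year, records$pi80_high, lty = 2)
  } else {
    message("records carry no 80% bounds; dashed lines omitted")
  }
  graphics::lines(records$year, records$median, lwd = 2)
  if (!is.null(observations) && nrow(observations)) {
    src_col <- c(DHS = "red", MICS = "seagreen", RHS = "seagreen",
                 WFS = "seagreen", PMA = "seagreen", national = "orange",
                 other = "orange")
    graphics::points(observations$ref_year, observations[[obs_column]],
                     pch = 19,
                     col = src_col[observations$source_type])
  }
  invisible(file)
}
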