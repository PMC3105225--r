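#' MEA electrode layout
#'
#' Describes the geometry of a multielectrode array: electrode labels, their
#' (row, column) positions on the grid, the inter-electrode pitch and the
#' electrode diameter.
#'
#' @param electrode_ids character vector of unique electrode labels.
#' @param grid_positions integer matrix with one row per electrode and columns
#'   `row`, `col`; positions must be unique.
#' @param pitch centre-to-centre spacing between adjacent electrodes, in
#'   micrometers. Must be positive.
#' @param electrode_diameter electrode diameter in micrometers.
#'
#' @return An object of class `mea_layout`.
#' @seealso [default_mea_layout()] for the standard 60-electrode grid.
#' @export
mea_layout <- function(electrode_ids, grid_positions, pitch = 200,
                       electrode_diameter = 30) {
  electrode_ids <- as.character(electrode_ids)
  if (anyDuplicated(electrode_ids))
    stop_bad_arg("electrode ids must be unique")
  grid_positions <- as.matrix(grid_positions)
  if (nrow(grid_positions) != length(electrode_ids) ||
      ncol(grid_positions) != 2L)
    stop_bad_arg("`grid_positions` must be a matrix with one (row, col) pair ",
                 "per electrode")
  if (anyDuplicated(grid_positions))
    stop_bad_arg("grid positions must be unique")
  if (!is_number(pitch) || pitch <= 0)
    stop_bad_arg("`pitch` must be a positive number (micrometers)")
  if (!is_number(electrode_diameter) || electrode_diameter <= 0)
    stop_bad_arg("`electrode_diameter` must be positive (micrometers)")
  dimnames(grid_positions) <- list(electrode_ids, c("row", "col"))
  structure(
    list(electrode_ids = electrode_ids,
         grid_positions = grid_positions,
         pitch = pitch,
         electrode_diameter = electrode_diameter),
    class = "mea_layout")
}

#' Standard 60-electrode MEA layout
#'
#' The commercial 8 x 8 grid with the four corner positions absent (60
#' recording electrodes), 200 um pitch and 30 um electrode diameter.
#' Electrodes are labelled by grid row letter and column number (`"A2"` ...
#' `"H7"`).
#'
#' @param pitch,electrode_diameter geometry in micrometers.
#' @return An `mea_layout` with 60 electrodes.
#' @export
default_mea_layout <- function(pitch = 200, electrode_diameter = 30) {
  pos <- expand.grid(row = 1:8, col = 1:8)
  corner <- (pos$row %in% c(1L, 8L)) & (pos$col %in% c(1L, 8L))
  pos <- pos[!corner, , drop = FALSE]
  pos <- pos[order(pos$row, pos$col), ]
  ids <- paste0(LETTERS[pos$row], pos$col)
  mea_layout(ids, as.matrix(pos), pitch = pitch,
             electrode_diameter = electrode_diameter)
}

#' @export
print.mea_layout <- function(x, ...) {
  cat("MEA layout:", length(x$electrode_ids), "electrodes,",
      x$pitch, "um pitch,", x$electrode_diameter, "um diameter\n")
  invisible(x)
}
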