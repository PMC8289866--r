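#' Electrode maps
#'
#' An electrode map records the label and planar position of every electrode
#' on the array. The default map models a 120-electrode MEA: a 12 x 12 grid
#' with 100 µm pitch, row letters A--M (skipping I) and column numbers 1--12,
#' with 6-electrode triangular cut-outs at the four corners.
#'
#' @param labels Character vector of unique electrode labels.
#' @param x,y Numeric electrode coordinates in µm.
#' @param pitch Inter-electrode distance in µm (metadata only).
#'
#' @return A tibble of class `axo_electrode_map` with columns `electrode`,
#'   `x`, `y` and attribute `pitch`.
#' @export
#' @examples
#' m <- default_electrode_map()
#' nrow(m) # 120
electrode_map <- function(labels, x, y, pitch = NA_real_) {
  if (anyDuplicated(labels)) {
    abort("electrode labels must be unique")
  }
  if (anyDuplicated(cbind(x, y))) {
    abort("electrode coordinates must be unique")
  }
  out <- tibble::tibble(electrode = as.character(labels), x = x, y = y)
  attr(out, "pitch") <- pitch
  class(out) <- c("axo_electrode_map", class(out))
  out
}

#' @rdname electrode_map
#' @export
default_electrode_map <- function() {
  row_letters <- setdiff(LETTERS[1:13], "I")
  grid <- expand.grid(row = 1:12, col = 1:12)
  # triangular 6-electrode cut-out at each corner: 144 - 24 = 120
  r <- grid$row
  c_ <- grid$col
  corner <- (r + c_ <= 4) | (r + (13 - c_) <= 4) |
    ((13 - r) + c_ <= 4) | ((13 - r) + (13 - c_) <= 4)
  grid <- grid[!corner, , drop = FALSE]
  electrode_map(
    labels = paste0(row_letters[grid$row], grid$col),
    x = (grid$col - 1) * 100,
    y = (grid$row - 1) * 100,
    pitch = 100
  )
}
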