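#' Standard 32-channel 10-20 montage template
#'
#' Schematic 2-D layout coordinates for a 32-channel actiCap-style montage on
#' the international 10-20 system, as used with infant EEG caps. Coordinates
#' are unitless layout-space positions: the head circumference is
#' approximately the unit circle centred on `Cz`, the nose points towards
#' positive y. `TP9`/`TP10` sit below the circle (mastoid positions).
#'
#' @return An object of class `erp_layout`: a data.frame with columns
#'   `name`, `x`, `y`.
#' @examples
#' lay <- layout_1020_32()
#' nrow(lay)  # 32
#' @export
layout_1020_32 <- function() {
  pos <- matrix(c(
    -0.22,  0.69,   # Fp1
     0.22,  0.69,   # Fp2
    -0.59,  0.44,   # F7
    -0.30,  0.35,   # F3
     0.00,  0.36,   # Fz
     0.30,  0.35,   # F4
     0.59,  0.44,   # F8
    -0.55,  0.20,   # FC5
    -0.19,  0.18,   # FC1
     0.00,  0.18,   # FCz
     0.19,  0.18,   # FC2
     0.55,  0.20,   # FC6
    -0.72,  0.00,   # T7
    -0.36,  0.00,   # C3
     0.00,  0.00,   # Cz
     0.36,  0.00,   # C4
     0.72,  0.00,   # T8
    -0.82, -0.14,   # TP9
    -0.55, -0.20,   # CP5
    -0.19, -0.18,   # CP1
     0.19, -0.18,   # CP2
     0.55, -0.20,   # CP6
     0.82, -0.14,   # TP10
    -0.59, -0.44,   # P7
    -0.30, -0.35,   # P3
     0.00, -0.36,   # Pz
     0.30, -0.35,   # P4
     0.59, -0.44,   # P8
    -0.22, -0.69,   # O1
     0.00, -0.72,   # Oz
     0.22, -0.69,   # O2
     0.62, -0.60    # PO10
  ), ncol = 2, byrow = TRUE)
  nm <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
          "FC5", "FC1", "FCz", "FC2", "FC6",
          "T7", "C3", "Cz", "C4", "T8",
          "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
          "P7", "P3", "Pz", "P4", "P8",
          "O1", "Oz", "O2", "PO10")
  erp_layout(nm, pos[, 1], pos[, 2])
}

#' Construct a channel layout
#'
#' @param name character vector of unique channel names.
#' @param x,y numeric planar coordinates (unitless layout space), finite.
#' @return An `erp_layout` data.frame with columns `name`, `x`, `y`.
#' @export
erp_layout <- function(name, x, y) {
  name <- as.character(name)
  if (anyDuplicated(name)) stop("channel names must be unique")
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(name) || length(y) != length(name))
    stop("name, x, y must have equal length")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("layout coordinates must be finite")
  out <- data.frame(name = name, x = x, y = y, stringsAsFactors = FALSE)
  class(out) <- c("erp_layout", "data.frame")
  out
}

#' Read a channel layout from a tab-separated file
#'
#' Expects columns `name`, `x`, `y` (extra columns ignored).
#'
#' @param path path to a tsv file.
#' @return An `erp_layout`.
#' @export
read_layout <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y")
  if (!all(need %in% names(df)))
    stop("layout file must have columns: ", paste(need, collapse = ", "))
  erp_layout(df$name, df$x, df$y)
}
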