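# Synthetic 64-channel montage on an idealized spherical head.
#
# Labels follow the extended 10-20 (10-10 subset) nomenclature; positions are
# generated procedurally by mapping a rectangular label grid onto the upper
# hemisphere (Chebyshev radius -> polar angle). These are idealized, synthetic
# coordinates, not digitized electrode positions: downstream code only needs a
# geometrically plausible layout in which C3/Cz/C4 sit over central cortex and
# the O/PO rows sit occipitally.

montage_grid <- function() {
  rows <- list(
    `4`  = c("Fp1", "Fpz", "Fp2"),
    `3`  = c("AF7", "AF3", "AFz", "AF4", "AF8"),
    `2`  = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"),
    `1`  = c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8"),
    `0`  = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"),
    `-1` = c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8"),
    `-2` = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8"),
    `-3` = c("PO7", "PO3", "POz", "PO4", "PO8"),
    `-4` = c("O1", "Oz", "O2")
  )
  out <- do.call(rbind, lapply(names(rows), function(y) {
    labs <- rows[[y]]
    k <- length(labs)
    # lateral indices symmetric about the midline; full rows span -4..4
    x <- seq(-(k - 1) / 2, (k - 1) / 2) * (8 / max(k - 1, 1)) / 2
    if (k == 9) x <- -4:4
    if (k == 5) x <- c(-3, -1.5, 0, 1.5, 3)
    if (k == 3) x <- c(-1.5, 0, 1.5)
    data.frame(label = labs, gx = x, gy = as.numeric(y),
               stringsAsFactors = FALSE)
  }))
  # three extra inferior sites to reach 64 channels
  extra <- data.frame(label = c("P9", "P10", "Iz"),
                      gx = c(-5, 5, 0), gy = c(-2, -2, -5),
                      stringsAsFactors = FALSE)
  rbind(out, extra)
}

grid_to_sphere <- function(gx, gy, radius = 1) {
  r <- pmax(abs(gx), abs(gy)) / 4          # Chebyshev radius, Cz at 0
  theta <- r * (pi / 2)                    # polar angle from vertex
  phi <- atan2(gx, gy)                     # 0 = anterior midline
  phi[gx == 0 & gy == 0] <- 0
  cbind(x = radius * sin(theta) * sin(phi),
        y = radius * sin(theta) * cos(phi),
        z = radius * cos(theta))
}

#' Standard 64-channel synthetic montage
#'
#' Returns an idealized spherical 64-channel montage with extended 10-20
#' labels (10-10 subset plus P9/P10/Iz). Positions lie on a sphere of the
#' given radius, vertex at `(0, 0, radius)`, +y anterior, +x right.
#'
#' @param radius sphere radius of the electrode shell.
#' @return data.frame with columns `label`, `x`, `y`, `z`.
#' @export
#' @examples
#' m <- standard_montage_64()
#' m[m$label %in% c("C3", "Cz", "C4"), ]
standard_montage_64 <- function(radius = 1) {
  g <- montage_grid()
  pos <- grid_to_sphere(g$gx, g$gy, radius)
  data.frame(label = g$label, x = pos[, "x"], y = pos[, "y"], z = pos[, "z"],
             stringsAsFactors = FALSE)
}

#' Read / write a montage file
#'
#' Montages are exchanged as whitespace-delimited text with four columns:
#' `label x y z` (one electrode per line, `#` comments allowed).
#'
#' @param path file path.
#' @return `read_montage` returns a data.frame with columns
#'   `label`, `x`, `y`, `z`.
#' @export
read_montage <- function(path) {
  assert_that(file.exists(path), "parse_error",
              sprintf("montage file not found: %s", path))
  d <- utils::read.table(path, header = FALSE, comment.char = "#",
                         col.names = c("label", "x", "y", "z"),
                         stringsAsFactors = FALSE)
  assert_that(!anyDuplicated(d$label), "parse_error",
              "duplicate electrode labels in montage")
  d
}

#' @rdname read_montage
#' @param montage data.frame with columns `label`, `x`, `y`, `z`.
#' @export
write_montage <- function(montage, path) {
  writeLines(sprintf("%s % .8f % .8f % .8f",
                     montage$label, montage$x, montage$y, montage$z), path)
  invisible(path)
}

# labels regarded as non-EEG when present in a recording
NON_EEG_PATTERN <- "^(EOG|HEOG|VEOG|ECG|EMG|STI|TRIG|Status)"

is_eeg_label <- function(labels) !grepl(NON_EEG_PATTERN, labels, ignore.case = TRUE)
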