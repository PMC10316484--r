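#' Serialize a velocity field as a plain-text CSV stack
#'
#' Writes a gridded hourly current field to a directory of CSV files:
#' `grid.csv` (x and y cell-centre coordinates and spacing), `mask.csv`
#' (0/1 land mask, one row per x cell), and `u_###.csv` / `v_###.csv`
#' (one matrix per hourly snapshot, rows = x cells, columns = y cells).
#' `read_velocity_field()` is the exact inverse.
#'
#' @param field A `velocity_field` (see [simulate_velocity_field()]).
#' @param dir Output directory (created if needed).
#' @return `dir` invisibly for the writer; a `velocity_field` for the
#'   reader.
#' @export
write_velocity_field <- function(field, dir) {
  stopifnot(inherits(field, "velocity_field"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- data.frame(
    axis = c(rep("x", length(field$x)), rep("y", length(field$y)), "spacing", "hour0"),
    value = c(field$x, field$y, field$spacing, field$hours[1])
  )
  utils::write.csv(grid, file.path(dir, "grid.csv"), row.names = FALSE)
  utils::write.table(field$mask + 0, file.path(dir, "mask.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  for (t in seq_along(field$hours)) {
    utils::write.table(field$u[, , t], file.path(dir, sprintf("u_%04d.csv", t)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
    utils::write.table(field$v[, , t], file.path(dir, sprintf("v_%04d.csv", t)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_velocity_field
#' @export
read_velocity_field <- function(dir) {
  grid <- utils::read.csv(file.path(dir, "grid.csv"))
  x <- grid$value[grid$axis == "x"]
  y <- grid$value[grid$axis == "y"]
  spacing <- grid$value[grid$axis == "spacing"]
  hour0 <- grid$value[grid$axis == "hour0"]
  mask <- as.matrix(utils::read.table(file.path(dir, "mask.csv"), sep = ",")) > 0
  dimnames(mask) <- NULL
  uf <- sort(list.files(dir, "^u_\\d+\\.csv$", full.names = TRUE))
  vf <- sort(list.files(dir, "^v_\\d+\\.csv$", full.names = TRUE))
  stopifnot(length(uf) == length(vf), length(uf) >= 1)
  nt <- length(uf)
  u <- array(0, c(length(x), length(y), nt))
  v <- array(0, c(length(x), length(y), nt))
  for (t in seq_len(nt)) {
    u[, , t] <- as.matrix(utils::read.table(uf[t], sep = ","))
    v[, , t] <- as.matrix(utils::read.table(vf[t], sep = ","))
  }
  structure(
    list(x = x, y = y, spacing = spacing, hours = hour0 + seq_len(nt) - 1,
         u = u, v = v, mask = mask),
    class = "velocity_field"
  )
}
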