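# CSV readers/writers for cusp change-score datasets and power curves.

# Atomic write: write to a temporary file in the target directory, then
# rename, so an interrupted run never leaves a truncated file behind.
atomic_write_lines <- function(lines, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) {
    stop("could not move temporary file into place at ", path,
         call. = FALSE)
  }
  invisible(path)
}

#' Write a cusp dataset to CSV
#'
#' Writes the five columns `x,y,z1,z2,dz`, one observation per line, at full
#' double precision (17 significant digits, so a read-back reproduces the
#' values bit for bit), with no row-name column. The write is atomic
#' (write-then-rename).
#'
#' @param data a [cusp_data()] frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_cusp_data()]
#' @export
write_cusp_data <- function(data, path) {
  data <- as_cusp_data(data)
  cols <- c("x", "y", "z1", "z2", "dz")
  body <- do.call(paste, c(lapply(cols, function(cn) {
    sprintf("%.17g", data[[cn]])
  }), sep = ","))
  atomic_write_lines(c(paste(cols, collapse = ","), body), path)
}

#' Read a cusp dataset from CSV
#'
#' Expects a header with columns `x`, `y`, `z1` and at least one of `z2`,
#' `dz` (extra columns are ignored). The change-score definition is enforced
#' on load: when both `z2` and `dz` are present, `dz` is recomputed as
#' `z2 - z1` (with a warning if the supplied column disagrees by more than
#' `1e-8`); when only `dz` is present, `z2` is reconstructed as `z1 + dz`.
#' Rows containing missing values are dropped with a message.
#'
#' @param path CSV file path.
#' @return A [cusp_data()] frame.
#' @export
read_cusp_data <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path)
  need <- c("x", "y", "z1")
  have <- names(raw)
  if (!all(need %in% have) || !any(c("z2", "dz") %in% have)) {
    stop("malformed header in ", path, ": found [",
         paste(have, collapse = ", "), "], need x, y, z1 and at least ",
         "one of z2, dz", call. = FALSE)
  }
  keep <- intersect(c("x", "y", "z1", "z2", "dz"), have)
  raw <- raw[keep]
  complete <- stats::complete.cases(raw)
  if (!all(complete)) {
    message("dropped ", sum(!complete), " row(s) with missing values")
    raw <- raw[complete, , drop = FALSE]
  }
  if (nrow(raw) == 0L) {
    stop("no usable rows in ", path, call. = FALSE)
  }
  as_cusp_data(raw)
}

#' Write a power curve grid to CSV
#'
#' Columns `n,replicates,detections,power,mc_se,power_smoothed`; atomic
#' write.
#'
#' @param curve a `"cusp_power_curve"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_power_curve <- function(curve, path) {
  if (!inherits(curve, "cusp_power_curve")) {
    stop("`curve` must be a cusp_power_curve", call. = FALSE)
  }
  g <- curve$grid
  body <- sprintf("%d,%d,%d,%.17g,%.17g,%.17g", g$n, g$replicates,
                  g$detections, g$power, g$mc_se, g$power_smoothed)
  atomic_write_lines(
    c("n,replicates,detections,power,mc_se,power_smoothed", body), path)
}
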