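# Plain-text serialisation of images and z-stacks. The toolchain is
# text-only: matrices are CSV (no header, rows = image rows) and stacks use a
# small sectioned format with one header line.

#' Read/write a numeric matrix as CSV
#'
#' @param m Numeric matrix (rows = image rows / y).
#' @param path File path.
#' @return `read_matrix_txt` returns a matrix; writers return `path`
#'   invisibly.
#' @export
write_matrix_txt <- function(m, path) {
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_txt
#' @export
read_matrix_txt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  as.matrix(utils::read.table(path, sep = ",", header = FALSE))
}

#' Read/write a z-stack as plain text
#'
#' Format: a header line `STACK ny nx nz dz`, then the `nz` planes
#' concatenated as CSV rows.
#'
#' @param stack `ny x nx x nz` array.
#' @param path File path.
#' @param dz Plane spacing recorded in the header.
#' @return `read_stack_txt` returns a list with `stack` and `dz`.
#' @export
write_stack_txt <- function(stack, path, dz = 1) {
  d <- dim(stack)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("STACK %d %d %d %.17g", d[1], d[2], d[3], dz), con)
  for (k in seq_len(d[3]))
    utils::write.table(stack[, , k], con, sep = ",",
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_stack_txt
#' @export
read_stack_txt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- strsplit(lines[1], "\\s+")[[1]]
  if (hdr[1] != "STACK" || length(hdr) != 5)
    stop("line 1: expected 'STACK ny nx nz dz'", call. = FALSE)
  d <- as.integer(hdr[2:4]); dz <- as.numeric(hdr[5])
  body <- do.call(rbind, lapply(strsplit(lines[-1], ","), as.numeric))
  if (nrow(body) != d[1] * d[3] || ncol(body) != d[2])
    stop("stack body does not match header dimensions", call. = FALSE)
  stack <- array(0, d)
  for (k in seq_len(d[3]))
    stack[, , k] <- body[((k - 1) * d[1] + 1):(k * d[1]), , drop = FALSE]
  list(stack = stack, dz = dz)
}
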