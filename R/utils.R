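#' @importFrom stats median quantile rnorm sd setNames
#' @importFrom utils read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(sprintf(...), call. = FALSE)

#' Cross product of two 3-vectors (or row-wise for matrices)
#' @noRd
cross3 <- function(a, b) {
  if (is.matrix(a)) {
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  } else {
    c(a[2] * b[3] - a[3] * b[2],
      a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1])
  }
}

row_norms <- function(m) sqrt(rowSums(m * m))

#' Stable content hash of an R object (canonical JSON, key-sorted)
#'
#' Used to stamp provenance into study outputs; invariant under list key
#' reordering.
#' @param x A list/vector of plain data.
#' @return Character md5 hash.
#' @export
config_hash <- function(x) {
  canon <- function(v) {
    if (is.list(v)) {
      nm <- names(v)
      if (!is.null(nm) && any(nzchar(nm))) v <- v[order(nm)]
      lapply(v, canon)
    } else v
  }
  js <- jsonlite::toJSON(canon(x), auto_unbox = TRUE, digits = NA, null = "null")
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}
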