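# Small shared helpers: timestamp handling, error constructors, misc.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom stats runif rbinom rpois setNames aggregate
#' @importFrom utils read.csv write.csv modifyList
NULL

ppi_stop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "ppisentinel_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

#' Parse timestamps used throughout the package
#'
#' Timestamps are ISO-8601 in a single implicit timezone per dataset and are
#' represented internally as UTC `POSIXct`. Date-only strings are taken as
#' midnight. Empty strings and `NA` become `NA` (used for open intervals).
#'
#' @param x character vector (or POSIXct, returned as-is after UTC coercion)
#' @return POSIXct vector in UTC
#' @keywords internal
parse_ts <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  x <- as.character(x)
  x[!is.na(x) & !nzchar(x)] <- NA_character_
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  has <- !is.na(x)
  if (any(has)) {
    xs <- gsub("T", " ", x[has], fixed = TRUE)
    parsed <- as.POSIXct(xs, tz = "UTC",
                         tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M",
                                        "%Y-%m-%d"))
    out[has] <- parsed
  }
  out
}

format_ts <- function(x) {
  out <- format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  out[is.na(x)] <- ""
  out
}

parse_date <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & !nzchar(x)] <- NA_character_
  as.Date(x)
}

hours <- function(n) n * 3600

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

# md5 of an in-memory object via its canonical JSON rendering (for manifests)
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(f))
}

# run `expr` with a private RNG stream so callers' .Random.seed is untouched
with_private_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
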