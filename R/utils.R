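# Internal helpers shared across modules.

#' @importFrom rlang abort warn .data %||%
#' @importFrom stats coef lm pchisq pf rpois runif rlnorm shapiro.test setNames
#' @importFrom utils head
NULL

# Deterministic sub-stream seeds: all randomness in the simulator flows from a
# single user seed through named streams so each protocol can be regenerated
# independently. Kept below 2^31 - 1 to stay a valid R integer.
stream_seed <- function(seed, stream, index = 0L) {
  offsets <- c(pool = 11L, communities = 23L, uav = 37L, quadrat = 53L,
               sites = 71L, misc = 97L)
  if (!stream %in% names(offsets)) {
    abort(paste0("unknown random stream '", stream, "'"))
  }
  base <- (as.double(seed) * 7919 + offsets[[stream]] * 104729 + index * 131) %%
    2147483647
  as.integer(base)
}

trim_ws <- function(x) gsub("^\\s+|\\s+$", "", x)

# stop() with a consistent prefix naming the offending rows of a table read.
row_error <- function(path, rows, msg) {
  abort(sprintf("%s: %s (row%s %s)",
                basename(path), msg,
                if (length(rows) > 1) "s" else "",
                paste(rows, collapse = ", ")))
}

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing required column%s: %s",
                  basename(path),
                  if (length(missing) > 1) "s" else "",
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}
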