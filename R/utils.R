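# shared helpers

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic 31-bit per-item seed derived from a master seed.
derive_seed <- function(master, index) {
  m <- 2147483647
  s <- (as.numeric(master) %% m) * 48271 + as.numeric(index) * 10007
  as.integer(s %% m)
}

# atomic file write: run writer(tmp) then rename into place
write_atomic <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

# timestamped, level-tagged log line to stderr and (if set via
# options(gmic3d.log_file = path)) appended to a log file
log_msg <- function(level, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", level, "] ", ...)
  message(msg)
  lf <- getOption("gmic3d.log_file", NULL)
  if (!is.null(lf)) cat(msg, "\n", sep = "", file = lf, append = TRUE)
  invisible(msg)
}
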