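# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  seed <- as.integer(seed)
  if (is.na(seed)) stop("`seed` must be a single integer", call. = FALSE)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  withr::defer(assign(".Random.seed", old, envir = globalenv()), envir = envir)
  set.seed(seed)
  invisible(seed)
}

# deterministic named substreams off one run seed; offsets keep results
# reproducible when a single stage is re-run in isolation
substream_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  offsets <- c(covariates = 1, blood_pressure = 2, design = 3,
               medication = 4, subsample = 5, pipeline = 6)
  k <- offsets[[stream]]
  as.integer((as.double(seed) + 104729 * k) %% 2147483629)
}

# significance markers: *** p<0.01, ** p<0.05, * p<0.1
p_stars <- function(p) {
  ifelse(p < 0.01, "***", ifelse(p < 0.05, "**", ifelse(p < 0.1, "*", "")))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == trunc(x)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
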