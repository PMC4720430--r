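#' Timestamped log line to standard error
#'
#' Emits a message only when verbosity is enabled, either via the
#' `verbose` argument or the global option `condiag.verbose`.
#'
#' @param ... parts of the message, pasted together.
#' @param verbose logical; overrides `getOption("condiag.verbose", FALSE)`.
#' @return invisibly, the formatted line.
#' @export
condiag_log <- function(..., verbose = getOption("condiag.verbose", FALSE)) {
  line <- paste0("[", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "] ", paste0(...))
  if (isTRUE(verbose)) message(line)
  invisible(line)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a 31-bit substream seed from a base seed and an index.  Used so that
# per-gene noise streams are independent of how many genes fall in each class.
substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 100003L) * 20011 + as.numeric(index)) %% 2147483647L
}

# Round half away from zero (display convention for percentage tables).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Per-row standard deviation with denominator n - 1 (two-pass).
row_sds <- function(x) {
  n <- ncol(x)
  if (n < 2L) stop("row_sds(): need at least 2 columns")
  mu <- rowMeans(x)
  sqrt(rowSums((x - mu)^2) / (n - 1L))
}

# Scale rows to mean 0, SD 1.  Rows with zero SD are returned as all-zero and
# flagged in the "zero_sd" attribute.
scale_rows <- function(x) {
  mu <- rowMeans(x)
  sd <- row_sds(x)
  zero <- sd == 0 | !is.finite(sd)
  sd[zero] <- 1
  out <- (x - mu) / sd
  out[zero, ] <- 0
  attr(out, "zero_sd") <- rownames(x)[zero]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
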