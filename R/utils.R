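# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
.assert <- function(cond, msg, call. = FALSE) {
  if (!isTRUE(cond)) stop(msg, call. = call.)
}

# Deterministic 31-bit string hash used to derive independent per-sample RNG
# streams from one parent seed.  Pure double arithmetic, always < 2^31 - 1,
# so the result is a valid `set.seed()` input on 32-bit R integers.
#' @noRd
.hash32 <- function(id, parent = 0L) {
  chars <- utf8ToInt(paste0(id, "#", format(parent, scientific = FALSE)))
  h <- 0
  for (ch in chars) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so simulation helpers do not perturb user code.
#' @noRd
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Rate of a gene model for a given cell line, 0 when absent.
#' @noRd
.rate_of <- function(gene, cellline) {
  if (cellline %in% names(gene$cellline_rates))
    gene$cellline_rates[[cellline]] else 0
}

#' @noRd
.is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 1 && x == floor(x)

#' @noRd
.is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
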