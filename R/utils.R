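# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. `seed = NULL` leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  code
}

# A single cohort seed is expanded into per-stage substreams by fixed offsets
# so that stages are reproducible independently of one another.
.stage_offsets <- c(field = 101L, variants = 202L, growth = 303L,
                    domains = 404L, counts = 505L)

stage_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  off <- .stage_offsets[[stage]]
  as.integer((as.numeric(seed) + off) %% (.Machine$integer.max - 1))
}

# Symmetric-capable Dirichlet sampler via normalised gammas.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha, rate = 1),
              nrow = n, ncol = k, byrow = TRUE)
  x / rowSums(x)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0 & x <= 1)

abort_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

need_cols <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  abort_if(length(missing) > 0,
           sprintf("%s is missing mandatory column(s): %s",
                   what, paste(missing, collapse = ", ")))
  invisible(df)
}
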