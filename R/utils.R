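#' Round half-up to an integer
#'
#' Base `round()` rounds half-to-even; WISN tables are conventionally
#' produced with half-up rounding (14.5 -> 15), so this is the package
#' default wherever a requirement is converted to whole staff.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_up <- function(x) floor(x + 0.5)

# Apply the configured integer-rounding rule to a raw requirement.
apply_rounding <- function(x, rule = c("half_up", "ceiling")) {
  rule <- match.arg(rule)
  switch(rule, half_up = round_half_up(x), ceiling = ceiling(x))
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stop_config <- function(field, msg) {
  stop(errorCondition(sprintf("invalid configuration field `%s`: %s", field, msg),
                      class = c("wisn_config_error", "error", "condition")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
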