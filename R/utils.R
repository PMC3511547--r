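# Internal helpers shared across modules.

# Round half away from zero (base round() is banker's rounding).
round_half_away <- function(x) trunc(x + 0.5 * sign(x))

clip01 <- function(x) pmin(1, pmax(0, x))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed, restoring global RNG state
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic child seeds for pipeline stages: one root seed fans out into
# independent per-stage seeds (all < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Connected components via union-find. `ids` is the universe; `pairs` a
# 2-column character matrix of linked ids. Returns a list of components
# (only components of size >= 1 containing every id).
components_from_pairs <- function(ids, pairs) {
  parent <- stats::setNames(seq_along(ids), ids)
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  if (length(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      ri <- find(match(pairs[k, 1], ids))
      rj <- find(match(pairs[k, 2], ids))
      if (ri != rj) parent[[rj]] <- ri
    }
  }
  roots <- vapply(seq_along(ids), find, integer(1))
  unname(split(ids, roots))
}

stop_stage <- function(stage, code, msg) {
  cond <- structure(
    class = c("imputeval_error", "error", "condition"),
    list(message = sprintf("[%s:%s] %s", stage, code, msg), call = sys.call(-1),
         stage = stage, code = code)
  )
  stop(cond)
}
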